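# Loopless FBA: excludes thermodynamically infeasible internal cycles
# (futile loops) from the optimal flux.
#
# Formulation: the ll-FBA null-space/energy-potential method. Each
# internal reaction i gets a binary direction indicator a_i and a
# potential G_i with sign opposite to its flux; G must be orthogonal to
# every circulation (null-space vector of the internal stoichiometric
# matrix). Exchange and biomass reactions are exempt. Only reactions
# appearing in the circulation space are constrained, so the indicator
# search is restricted to that support and solved exactly by
# enumeration with an LP pair per assignment - equivalent to the MILP
# on the small networks this package targets.

#' Solve a loopless flux balance analysis problem
#'
#' Same contract as [solve_fba()], but the returned flux admits no
#' nonzero internal circulation. When the plain-FBA optimum is
#' attainable without internal cycles the objective value is unchanged;
#' otherwise it is the best loop-free value (e.g. zero for ATP
#' production "from nothing" through an erroneous reversible pair).
#'
#' @inheritParams solve_fba
#' @param max_indicators Safety cap on the number of enumerated
#'   direction indicators (default 16).
#' @return A `flux_solution`.
#' @export
solve_loopless <- function(model, objective = model$biomass_id,
                           sense = c("max", "min"), fixed = NULL,
                           blocked = NULL, max_indicators = 16L) {
  sense <- match.arg(sense)
  ids <- names(model$reactions)
  exempt <- union(model$exchange_ids, model$biomass_id)
  internal <- setdiff(ids, exempt)
  S <- stoich_matrix(model)
  K <- null_space(S[, internal, drop = FALSE])
  if (!ncol(K)) return(solve_fba(model, objective, sense, fixed, blocked))
  support <- internal[apply(abs(K), 1, max) > 1e-7]
  k <- length(support)
  if (k > max_indicators)
    abort(sprintf(paste0("loopless enumeration over %d cycle reactions exceeds the cap of %d; ",
                         "this solver targets small networks"), k, max_indicators))
  K_sup <- K[match(support, internal), , drop = FALSE]

  obj <- objective_vector(objective, ids)
  bd0 <- apply_restrictions(model, fixed, blocked)
  best <- NULL
  for (code in 0:(2^k - 1)) {
    a <- as.logical(bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L))  # TRUE = forward
    if (!potentials_feasible(K_sup, a)) next
    bd <- bd0
    lo <- pmax(bd$lb[support], 0); hi <- bd$ub[support]
    lo[!a] <- bd$lb[support][!a]; hi[!a] <- pmin(bd$ub[support][!a], 0)
    if (any(lo > hi + 1e-12)) next
    bd$lb[support] <- lo; bd$ub[support] <- hi
    sol <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, sense)
    if (sol$status != "optimal") next
    if (is.null(best) ||
        (sense == "max" && sol$value > best$value + 1e-12) ||
        (sense == "min" && sol$value < best$value - 1e-12)) best <- sol
  }
  if (is.null(best))
    return(flux_solution(list(status = "infeasible", value = NA_real_,
                              v = setNames(rep(NA_real_, length(ids)), ids)),
                         obj, sense))
  flux_solution(best, obj, sense)
}

# Is there a potential vector G with K' G = 0 and G_i <= -1 for forward
# (a_i TRUE), G_i >= +1 for backward reactions?
potentials_feasible <- function(K_sup, a) {
  k <- nrow(K_sup)
  lb <- ifelse(a, -1000, 1)
  ub <- ifelse(a, -1, 1000)
  sol <- lp_solve(rep(0, k), t(K_sup), rep(0, ncol(K_sup)), lb, ub, "max")
  sol$status == "optimal"
}

#' Maximum internal circulation compatible with a flux pattern
#'
#' Measures the largest circulation (null-space flux of the internal
#' network) whose direction pattern matches the signs of the given flux
#' on its support and which is zero off the support. A loopless
#' solution yields 0 (within tolerance).
#'
#' @param model A `metabolic_model`.
#' @param fluxes Named flux vector (e.g. from a `flux_solution`).
#' @param tol Support threshold on fluxes.
#' @return Maximum circulation magnitude (sum over cycle reactions).
#' @export
max_circulation <- function(model, fluxes, tol = 1e-6) {
  ids <- names(model$reactions)
  exempt <- union(model$exchange_ids, model$biomass_id)
  internal <- setdiff(ids, exempt)
  if (!length(internal)) return(0)
  S_int <- stoich_matrix(model)[, internal, drop = FALSE]
  v <- fluxes[internal]
  lb <- setNames(numeric(length(internal)), internal)
  ub <- lb
  on <- abs(v) > tol
  ub[on & v > 0] <- 1
  lb[on & v < 0] <- -1
  obj <- sign(v) * on
  if (!any(on)) return(0)
  sol <- lp_solve(obj, S_int, rep(0, nrow(S_int)), lb, ub, "max")
  if (sol$status != "optimal") return(0)
  sol$value
}
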