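# Flux balance analysis: LP over steady-state fluxes S v = 0 with bounds,
# reaction fixing/blocking, and lexicographic source-flux minimization.

#' Solve a flux balance analysis problem
#'
#' Optimises a flux objective over the steady-state polytope
#' `{v : S v = 0, lb <= v <= ub}`, optionally with reactions fixed to
#' given flux values or blocked (bounds set to zero).
#'
#' @param model A `metabolic_model`.
#' @param objective A reaction id, or a named numeric vector of
#'   objective coefficients over reactions.
#' @param sense `"max"` or `"min"`.
#' @param fixed Named numeric vector of reaction fluxes to fix.
#' @param blocked Character vector of reaction ids to block.
#' @param balanced Species ids to hold at steady state; defaults to all
#'   species in the model.
#' @return A `flux_solution`: list with `objective_value`, `fluxes`
#'   (named vector) and `status` (`"optimal"`, `"infeasible"`).
#'   Infeasibility is reported through `status`, not as an error.
#' @export
solve_fba <- function(model, objective = model$biomass_id,
                      sense = c("max", "min"), fixed = NULL, blocked = NULL,
                      balanced = NULL) {
  sense <- match.arg(sense)
  ids <- names(model$reactions)
  obj <- objective_vector(objective, ids)
  bd <- apply_restrictions(model, fixed, blocked)
  S <- stoich_matrix(model)
  if (!is.null(balanced)) S <- S[intersect(rownames(S), balanced), , drop = FALSE]
  sol <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, sense)
  flux_solution(sol, obj, sense)
}

objective_vector <- function(objective, ids) {
  if (is.character(objective) && length(objective) == 1L) {
    if (!objective %in% ids)
      abort(sprintf("objective reaction '%s' not in model", objective))
    objective <- setNames(1, objective)
  }
  if (is.null(objective)) abort("no objective given and model has no biomass reaction")
  unknown <- setdiff(names(objective), ids)
  if (length(unknown))
    abort(sprintf("objective names unknown reaction(s): %s", paste(unknown, collapse = ", ")))
  obj <- setNames(numeric(length(ids)), ids)
  obj[names(objective)] <- objective
  obj
}

apply_restrictions <- function(model, fixed, blocked) {
  bd <- reaction_bounds(model)
  ids <- names(model$reactions)
  if (!is.null(blocked)) {
    unknown <- setdiff(blocked, ids)
    if (length(unknown))
      abort(sprintf("blocked ids not in model: %s", paste(unknown, collapse = ", ")))
    bd$lb[blocked] <- 0
    bd$ub[blocked] <- 0
  }
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), ids)
    if (length(unknown))
      abort(sprintf("fixed ids not in model: %s", paste(unknown, collapse = ", ")))
    for (id in names(fixed)) {
      v <- fixed[[id]]
      if (v < bd$lb[[id]] - 1e-9 || v > bd$ub[[id]] + 1e-9)
        abort(sprintf("fixed value %g for '%s' violates bounds [%g, %g]",
                      v, id, bd$lb[[id]], bd$ub[[id]]))
      bd$lb[id] <- v
      bd$ub[id] <- v
    }
  }
  bd
}

flux_solution <- function(sol, obj, sense) {
  structure(
    list(objective_value = sol$value, fluxes = sol$v, status = sol$status,
         objective = obj[obj != 0], sense = sense),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s", x$status))
  if (x$status == "optimal")
    cat(sprintf(", objective (%s): %g", x$sense, x$objective_value))
  cat("\n")
  invisible(x)
}

#' @export
tidy.flux_solution <- function(x, ...) {
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.flux_solution <- function(x, ...) {
  tibble(objective_value = x$objective_value, status = x$status, sense = x$sense)
}

#' Lexicographic minimization of source fluxes
#'
#' Minimises the flux through each source reaction in turn: the first
#' source is minimised, fixed at its optimum, then the next, and so on.
#' Used with artificial ATP/NADH input reactions to measure the energy
#' cost of a fixed demand; the order (ATP first) is the documented
#' canonical choice when interconversions make the pair non-unique.
#'
#' @param model A `metabolic_model`.
#' @param sources Ordered character vector of irreversible input
#'   reaction ids.
#' @param fixed,blocked As in [solve_fba()].
#' @return A `flux_solution` for the final stage, with the attained
#'   minima in `attr(, "minima")`.
#' @export
minimize_sources <- function(model, sources, fixed = NULL, blocked = NULL) {
  stopifnot(length(sources) >= 1L)
  fixed <- fixed %||% setNames(numeric(0), character(0))
  minima <- setNames(numeric(0), character(0))
  sol <- NULL
  for (src in sources) {
    sol <- solve_fba(model, objective = src, sense = "min",
                     fixed = fixed, blocked = blocked)
    if (sol$status != "optimal") {
      attr(sol, "minima") <- minima
      return(sol)
    }
    minima[src] <- sol$objective_value
    fixed[src] <- sol$objective_value
  }
  attr(sol, "minima") <- minima
  sol
}
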