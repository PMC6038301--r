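# Stoichiometric algebra: reactions, net-reaction combination, and the
# biomass mass-balance contract (1 gDW per unit biomass flux).

#' Create a reaction
#'
#' A reaction is a signed stoichiometric map over species: negative
#' coefficients are consumed, positive are produced. Flux bounds are in
#' mmol gDW^-1 h^-1; the conventional "unbounded" sentinel is 1000.
#'
#' @param id Short unique token identifying the reaction.
#' @param stoich Named numeric vector, species id -> signed coefficient.
#'   Zero coefficients are dropped.
#' @param lb,ub Lower and upper flux bounds. Defaults: `c(0, 1000)`, or
#'   `c(-1000, 1000)` when `reversible = TRUE`.
#' @param reversible Convenience flag used only to pick default bounds.
#' @param name,subsystem,genes Optional annotation strings.
#' @return An object of class `rxn`.
#' @examples
#' reaction("ATP_Synt", c(h_p = -4, adp = -1, pi = -1, h_c = 3, atp = 1, h2o = 1))
#' @export
reaction <- function(id, stoich, lb = NULL, ub = NULL, reversible = FALSE,
                     name = "", subsystem = "", genes = "") {
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  if (lb > ub) abort(sprintf("reaction '%s': lower bound %g exceeds upper bound %g", id, lb, ub))
  stoich <- stoich[abs(stoich) > 0]
  if (length(stoich) && (is.null(names(stoich)) || any(!nzchar(names(stoich)))))
    abort(sprintf("reaction '%s': stoichiometry must be a fully named vector", id))
  structure(
    list(id = id, stoich = stoich, lb = lb, ub = ub,
         name = name, subsystem = subsystem, genes = genes),
    class = "rxn"
  )
}

#' @export
print.rxn <- function(x, ...) {
  cat(sprintf("<rxn> %s: %s  [%g, %g]\n", x$id, render_equation(x), x$lb, x$ub))
  invisible(x)
}

is_reversible <- function(r) r$lb < 0

#' Combine reactions into a net reaction
#'
#' Forms the flux-weighted sum of reactions: the net coefficient of each
#' species s is `sum(flux[r] * stoich_r[s])`. This is how a pathway's
#' reactions are lumped into one overall reaction. Coefficients below
#' 1e-9 in magnitude are pruned (LP round-off).
#'
#' @param model A `metabolic_model`, `pathway_def`, or a list of `rxn`
#'   objects.
#' @param flux Named numeric vector, reaction id -> flux value. Reactions
#'   absent from `flux` contribute nothing.
#' @param id Id given to the returned reaction.
#' @return A `rxn` holding the net stoichiometry.
#' @export
net_reaction <- function(model, flux, id = "net") {
  rxns <- as_reaction_list(model)
  unknown <- setdiff(names(flux), names(rxns))
  if (length(unknown))
    abort(sprintf("unknown reaction id(s): %s", paste(unknown, collapse = ", ")))
  acc <- numeric(0)
  for (rid in names(flux)) {
    st <- rxns[[rid]]$stoich * flux[[rid]]
    new <- setdiff(names(st), names(acc))
    if (length(new)) acc[new] <- 0
    acc[names(st)] <- acc[names(st)] + st
  }
  acc <- acc[abs(acc) >= .tol_coef]
  reaction(id, acc, lb = 0, ub = 1000)
}

as_reaction_list <- function(x) {
  if (inherits(x, "metabolic_model") || inherits(x, "pathway_def")) x <- x$reactions
  if (inherits(x, "rxn")) x <- list(x)
  if (!length(x)) return(list())
  nm <- vapply(x, function(r) r$id, character(1))
  setNames(x, nm)
}

# --- biomass equation ------------------------------------------------------

# Growth-associated maintenance (GAM) is carried inside the biomass
# reaction as ATP + H2O -> ADP + Pi + H+ at `gam` mmol gDW^-1. It is
# held apart from the component coefficients so mass-balance scaling can
# leave it untouched.
.gam_pattern <- c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)

#' Create a biomass equation
#'
#' Biomass coefficients are in mmol per gDW: negative entries are growth
#' requirements, positive entries by-products. The GAM hydrolysis
#' (`atp_c + h2o_c -> adp_c + pi_c + h_c`, `gam` mmol gDW^-1) is stored
#' separately and excluded from mass-balance scaling.
#'
#' @param stoich Named numeric vector of component coefficients
#'   (mmol gDW^-1), excluding the GAM contribution.
#' @param gam Growth-associated maintenance, mmol ATP gDW^-1.
#' @param id Reaction id to use when the equation is realised as a reaction.
#' @return An object of class `biomass_eq`.
#' @export
biomass_equation <- function(stoich, gam = 25, id = "BIOMASS") {
  if (gam < 0) abort("gam must be >= 0")
  structure(list(id = id, stoich = stoich[abs(stoich) > 0], gam = gam),
            class = "biomass_eq")
}

#' Realise a biomass equation as a reaction
#'
#' Adds the GAM hydrolysis into the component stoichiometry and returns
#' an irreversible `rxn`.
#'
#' @param biomass A `biomass_eq`.
#' @return A `rxn`.
#' @export
biomass_reaction <- function(biomass) {
  st <- biomass$stoich
  gp <- .gam_pattern * biomass$gam
  new <- setdiff(names(gp), names(st))
  if (length(new)) st[new] <- 0
  st[names(gp)] <- st[names(gp)] + gp
  reaction(biomass$id, st, lb = 0, ub = 1000, subsystem = "biomass")
}

#' Mass-balance residual of a biomass equation
#'
#' For requirements R_i (consumed) and by-products B_j (produced) with
#' molecular masses M, the biomass reaction must satisfy
#' `(sum S_i M_i - sum S_j M_j) / 1000 = 1 gDW`. The residual is the
#' signed deviation from 1 g; a correctly normalized equation returns 0.
#'
#' @param biomass A `biomass_eq`.
#' @param masses Named numeric vector, species id -> molar mass (g mol^-1).
#' @return Residual in grams.
#' @export
mass_balance_residual <- function(biomass, masses) {
  st <- biomass_reaction(biomass)$stoich
  missing <- setdiff(names(st), names(masses))
  if (length(missing))
    abort(sprintf("missing molar mass for species: %s", paste(missing, collapse = ", ")))
  # requirements enter positively (-coef), by-products negatively
  sum(-st * masses[names(st)]) / 1000 - 1
}

#' Normalize a biomass equation to the 1 gDW mass balance
#'
#' Applies one uniform scale factor to all non-GAM coefficients so that
#' the mass-balance residual becomes zero; the GAM hydrolysis is re-added
#' unchanged (it is mass-neutral under consistent masses). Idempotent.
#'
#' @inheritParams mass_balance_residual
#' @return A normalized `biomass_eq`.
#' @export
normalize_biomass <- function(biomass, masses) {
  st <- biomass$stoich
  missing <- setdiff(names(st), names(masses))
  if (length(missing))
    abort(sprintf("missing molar mass for species: %s", paste(missing, collapse = ", ")))
  non_gam_mass <- sum(-st * masses[names(st)])      # mg per gDW, before scaling
  gp <- .gam_pattern * biomass$gam
  gp_mass <- sum(-gp * masses_or_zero(masses, names(gp)))
  if (abs(non_gam_mass) < .tol_coef)
    abort("degenerate biomass equation: net non-GAM mass is zero, scaling undefined")
  s <- (1000 - gp_mass) / non_gam_mass
  biomass_equation(st * s, gam = biomass$gam, id = biomass$id)
}

masses_or_zero <- function(masses, ids) {
  out <- setNames(numeric(length(ids)), ids)
  hit <- intersect(ids, names(masses))
  out[hit] <- masses[hit]
  out
}
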