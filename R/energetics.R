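# The ATP and reducing-equivalent cost of making 1 g biomass from CO2:
# block the ammonia-oxidation energy module, feed the network from
# artificial ATP/NADH inputs, fix biomass flux at 1 h^-1 and minimize
# the inputs lexicographically (ATP first, then NADH).

.src_atp_id <- "SRC_ATP"
.src_nadh_id <- "SRC_NADH"

#' ATP and NADH cost of synthesizing 1 g biomass from CO2
#'
#' Implements the blocked-oxidation, artificial-input procedure: the
#' ammonia-oxidation reaction set (the model's `oxidation_ids`) is
#' blocked, artificial input reactions
#' `adp_c + pi_c + h_c -> atp_c + h2o_c` and `nad_c + h_c -> nadh_c`
#' are added, the biomass flux is fixed at 1 gDW gDW^-1 h^-1, and the
#' ATP input flux is minimized, then the NADH input at the ATP optimum
#' (lexicographic; makes the reported pair well-defined). Fluxes in
#' mmol gDW^-1 h^-1 divide by 1000 to mol per gDW. The model must carry
#' its NADH interconversions (NADH to NADPH 1:1, NADH to 2 reduced
#' ferredoxin) for the NADH input to stand in for all reducing
#' equivalents.
#'
#' @param model A `metabolic_model` whose biomass route runs on CO2
#'   given free ATP/NADH.
#' @param nadh_atp_factor ATP-equivalents per NADH (default 1: both
#'   cost 4 translocated protons).
#' @param block Reaction ids to block; defaults to the model's
#'   `oxidation_ids`.
#' @return An `energy_cost`: one-row tibble with `atp`, `nadh`
#'   (mol gDW^-1), `atp_equivalent`, `atp_excl_gam`, `gam` (mmol),
#'   `gam_included` (the reported `atp` contains the GAM hydrolysis)
#'   and `nadh_atp_factor`.
#' @export
biomass_energy_cost <- function(model, nadh_atp_factor = 1,
                                block = model$oxidation_ids) {
  if (is.null(model$biomass_id)) abort("model has no biomass reaction")
  if (nadh_atp_factor <= 0) abort("nadh_atp_factor must be > 0")
  m <- add_energy_sources(model)
  sol <- minimize_sources(m, c(.src_atp_id, .src_nadh_id),
                          fixed = setNames(1, model$biomass_id),
                          blocked = intersect(block, names(m$reactions)))
  if (sol$status != "optimal") diagnose_blocked(m, block)
  minima <- attr(sol, "minima")
  atp <- minima[[.src_atp_id]] / 1000
  nadh <- minima[[.src_nadh_id]] / 1000
  structure(
    tibble(
      atp = atp, nadh = nadh,
      atp_equivalent = atp + nadh_atp_factor * nadh,
      atp_excl_gam = atp - model$gam / 1000,
      gam = model$gam, gam_included = TRUE,
      nadh_atp_factor = nadh_atp_factor
    ),
    class = c("energy_cost", class(tibble())),
    solution = sol
  )
}

add_energy_sources <- function(model) {
  need <- c("atp_c", "adp_c", "pi_c", "h_c", "h2o_c")
  missing <- setdiff(c(need, "nad_c", "nadh_c"), model$species$id)
  if (length(missing))
    abort(sprintf("model lacks the currency species needed for artificial inputs: %s",
                  paste(missing, collapse = ", ")))
  src_atp <- reaction(.src_atp_id, c(adp_c = -1, pi_c = -1, h_c = -1, atp_c = 1, h2o_c = 1),
                      lb = 0, ub = 1000, name = "artificial ATP input")
  src_nadh <- reaction(.src_nadh_id, c(nad_c = -1, h_c = -1, nadh_c = 1),
                       lb = 0, ub = 1000, name = "artificial NADH input")
  model$reactions <- c(model$reactions, setNames(list(src_atp, src_nadh),
                                                 c(.src_atp_id, .src_nadh_id)))
  model
}

diagnose_blocked <- function(m, block) {
  # which biomass requirements cannot be produced with the oxidation set blocked?
  bm <- m$reactions[[m$biomass_id]]
  req <- names(bm$stoich)[bm$stoich < 0]
  bad <- character(0)
  for (sp in req) {
    probe <- m
    sink_id <- paste0("SINK_", sp)
    probe$reactions[[sink_id]] <- reaction(sink_id, setNames(-1, sp), lb = 0, ub = 1000)
    s <- solve_fba(probe, objective = sink_id, sense = "max",
                   blocked = intersect(block, names(probe$reactions)))
    if (s$status != "optimal" || s$objective_value < 1e-9) bad <- c(bad, sp)
  }
  abort(sprintf(
    "biomass is infeasible with the oxidation set blocked%s",
    if (length(bad)) sprintf("; precursors that cannot be produced: %s",
                             paste(bad, collapse = ", ")) else ""))
}

#' Overall ATP-equivalent cost
#'
#' Converts an (ATP, NADH) requirement pair into a single
#' ATP-equivalent figure: `atp + factor * nadh`. With the default
#' factor of 1 (4 translocated protons for either), the pair
#' (0.120, 0.093) mol gDW^-1 gives 0.213 mol ATP-equivalent gDW^-1.
#'
#' @param cost An `energy_cost`, or a numeric ATP value (mol gDW^-1).
#' @param nadh NADH requirement (mol gDW^-1); ignored when `cost` is an
#'   `energy_cost`.
#' @param factor ATP-equivalents per NADH.
#' @return ATP-equivalent cost, mol gDW^-1.
#' @export
atp_equivalent <- function(cost, nadh = NULL, factor = 1) {
  if (factor <= 0) abort("factor must be > 0")
  if (inherits(cost, "energy_cost")) return(cost$atp + factor * cost$nadh)
  cost + factor * nadh
}
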