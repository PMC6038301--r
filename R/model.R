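# The metabolic model container: species + reactions + designated
# biomass/exchange reactions, and the stoichiometric matrix S.

#' Create a metabolic model
#'
#' @param reactions List of `rxn` objects (see [reaction()],
#'   [parse_equation()]).
#' @param species Optional tibble with columns `id`, `name`,
#'   `compartment`, `molar_mass`. When omitted it is derived from the
#'   reactions; compartments follow the id-suffix convention `_c`
#'   cytoplasm, `_p` outside/pseudo-periplasm, `_e` boundary.
#' @param biomass_id Id of the biomass reaction, or `NULL` for models
#'   without one (e.g. pure electron-transport fixtures).
#' @param exchange_ids Ids of exchange reactions. Defaults to reactions
#'   with a single-species stoichiometry or an `EX_` prefix.
#' @param gam Growth-associated maintenance carried inside the biomass
#'   reaction, mmol ATP gDW^-1 (default 25).
#' @param oxidation_ids Explicit id list of the ammonia-oxidation
#'   reaction set (used by [biomass_energy_cost()] to block it).
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, species = NULL, biomass_id = NULL,
                            exchange_ids = NULL, gam = 25,
                            oxidation_ids = character()) {
  reactions <- as_reaction_list(reactions)
  ids <- names(reactions)
  if (anyDuplicated(ids))
    abort(sprintf("duplicate reaction id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich)))) %||% character(0)
  if (is.null(species)) {
    species <- tibble(
      id = used, name = used,
      compartment = compartment_from_id(used),
      molar_mass = NA_real_
    )
  } else {
    species <- as_tibble(species)
    if (!"name" %in% names(species)) species$name <- species$id
    if (!"compartment" %in% names(species)) species$compartment <- compartment_from_id(species$id)
    if (!"molar_mass" %in% names(species)) species$molar_mass <- NA_real_
    orphan <- setdiff(used, species$id)
    if (length(orphan))
      abort(sprintf("reactions reference unknown species: %s", paste(orphan, collapse = ", ")))
  }
  if (anyDuplicated(species$id))
    abort("duplicate species id(s) in species table")
  bad_mass <- !is.na(species$molar_mass) & species$molar_mass <= 0
  if (any(bad_mass))
    abort(sprintf("non-positive molar mass for species: %s",
                  paste(species$id[bad_mass], collapse = ", ")))
  if (!is.null(biomass_id) && !biomass_id %in% ids)
    abort(sprintf("biomass reaction '%s' not present in model", biomass_id))
  if (is.null(exchange_ids))
    exchange_ids <- ids[vapply(reactions, function(r)
      length(r$stoich) == 1L || startsWith(r$id, "EX_"), logical(1))]
  structure(
    list(species = species, reactions = reactions, biomass_id = biomass_id,
         exchange_ids = exchange_ids, gam = gam, oxidation_ids = oxidation_ids),
    class = "metabolic_model"
  )
}

compartment_from_id <- function(id) {
  case_when(
    endsWith(id, "_e") ~ "boundary",
    endsWith(id, "_p") ~ "outside",
    .default = "cytoplasm"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d species", length(x$reactions), nrow(x$species)))
  if (!is.null(x$biomass_id)) cat(sprintf(", biomass '%s' (GAM %g mmol/gDW)", x$biomass_id, x$gam))
  cat("\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, species x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  sp <- model$species$id
  S <- matrix(0, nrow = length(sp), ncol = length(model$reactions),
              dimnames = list(sp, names(model$reactions)))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

species_masses <- function(model) {
  setNames(model$species$molar_mass, model$species$id)
}

reaction_bounds <- function(model) {
  list(
    lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
    ub = vapply(model$reactions, function(r) r$ub, numeric(1))
  )
}

#' Adjust the growth-associated maintenance of a model
#'
#' Rewrites the biomass reaction so its GAM hydrolysis
#' (`atp_c + h2o_c -> adp_c + pi_c + h_c`) carries `gam` mmol gDW^-1
#' instead of the current `model$gam`.
#'
#' @param model A `metabolic_model` with a biomass reaction using the
#'   `atp_c`/`adp_c`/`pi_c`/`h2o_c`/`h_c` currency ids.
#' @param gam New GAM value, mmol ATP gDW^-1.
#' @return The modified model.
#' @export
set_gam <- function(model, gam) {
  if (is.null(model$biomass_id)) abort("model has no biomass reaction")
  bm <- model$reactions[[model$biomass_id]]
  delta <- .gam_pattern * (gam - model$gam)
  st <- bm$stoich
  new <- setdiff(names(delta), names(st))
  if (length(new)) st[new] <- 0
  st[names(delta)] <- st[names(delta)] + delta
  model$reactions[[model$biomass_id]] <-
    reaction(bm$id, st, lb = bm$lb, ub = bm$ub, name = bm$name,
             subsystem = bm$subsystem, genes = bm$genes)
  miss <- setdiff(names(st)[abs(st) > 0], model$species$id)
  if (length(miss))
    model$species <- bind_rows(model$species, tibble(
      id = miss, name = miss, compartment = compartment_from_id(miss),
      molar_mass = NA_real_))
  model$gam <- gam
  model
}

#' Tidy a model's reactions into a table
#'
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: `id`, `name`, `equation`,
#'   `lb`, `ub`, `subsystem`, `genes`.
#' @export
tidy.metabolic_model <- function(x, ...) {
  tibble(
    id = names(x$reactions),
    name = map_chr(x$reactions, "name"),
    equation = map_chr(x$reactions, render_equation),
    lb = map_dbl(x$reactions, "lb"),
    ub = map_dbl(x$reactions, "ub"),
    subsystem = map_chr(x$reactions, "subsystem"),
    genes = map_chr(x$reactions, "genes")
  )
}

#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(
    n_reactions = length(x$reactions),
    n_species = nrow(x$species),
    n_exchanges = length(x$exchange_ids),
    biomass_id = x$biomass_id %||% NA_character_,
    gam = x$gam
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
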