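# Synthetic fixture models with planted, analytically known ground
# truth: toy autotrophs with a known ATP/NADH biomass cost, futile-loop
# fixtures, mass-imbalanced biomass equations, random models for I/O
# round-trips, and a genome-scale-sized synthetic emulator.

# Toy molar masses chosen so the GAM hydrolysis is exactly mass-neutral
# (atp + h2o = adp + pi + h = 525).
.toy_masses <- c(pre_c = 100, atp_c = 507, adp_c = 427, pi_c = 97,
                 h2o_c = 18, h_c = 1, co2_e = 44, co2_c = 44,
                 nad_c = 663, nadh_c = 664, nadp_c = 743, nadph_c = 744,
                 fdox_c = 6, fdred_c = 7)

#' Generate a toy autotroph with planted biomass energy costs
#'
#' Builds a small CO2-fixing model whose unique biomass route consumes
#' exactly `1000 * atp_cost` mmol ATP (beyond GAM) and
#' `1000 * nadh_cost` mmol NADH per unit biomass flux. Carbon fixation
#' is a lumped reaction (CO2 + ATP + NADPH -> precursor); the reducing
#' equivalents are demanded as NADPH so the NADH-to-NADPH
#' interconversion must run, and an NADH-to-ferredoxin conversion is
#' present as in the full-organism network. With the oxidation module
#' the pathway-1 ammonia-oxidation reactions are wired in, making the
#' model chemolithoautotrophic. Construction is deterministic; the seed
#' is recorded in the model for provenance.
#'
#' Defaults emulate the study organism: non-GAM ATP cost 0.095 and NADH
#' cost 0.093 mol gDW^-1 with GAM 25 mmol gDW^-1, so the recovered
#' GAM-inclusive requirement pair is (0.120, 0.093) mol gDW^-1.
#'
#' @param atp_cost Planted non-GAM ATP cost, mol gDW^-1.
#' @param nadh_cost Planted NADH cost, mol gDW^-1.
#' @param gam Growth-associated maintenance, mmol ATP gDW^-1.
#' @param include_oxidation_module Wire in the pathway-1 energy module.
#' @param include_futile_loop Add the futile-loop fixtures of
#'   [make_loop_fixture()].
#' @param imbalance_factor Scale applied to the non-GAM biomass
#'   coefficients (1 = mass-balanced).
#' @param seed Integer recorded in the model; output is byte-identical
#'   for identical arguments.
#' @return A `metabolic_model`.
#' @export
make_toy_autotroph <- function(atp_cost = 0.095, nadh_cost = 0.093, gam = 25,
                               include_oxidation_module = FALSE,
                               include_futile_loop = FALSE,
                               imbalance_factor = 1, seed = 1L) {
  if (atp_cost < 0 || nadh_cost < 0) abort("planted costs must be >= 0")
  if (atp_cost == 0 && nadh_cost == 0 && gam == 0)
    abort("degenerate toy: zero ATP cost, zero NADH cost and zero GAM leave no energy demand to plant")
  ra <- 100 * atp_cost   # mmol ATP per mmol precursor (10 mmol precursor/gDW)
  rb <- 100 * nadh_cost  # mmol NADPH per mmol precursor
  fix_st <- c(co2_c = -1, pre_c = 1)
  if (ra > 0) fix_st <- c(fix_st, atp_c = -ra, h2o_c = -ra, adp_c = ra, pi_c = ra, h_c = ra)
  if (rb > 0) fix_st <- c(fix_st, nadph_c = -rb, nadp_c = rb)
  bm <- biomass_equation(c(pre_c = -10 * imbalance_factor), gam = gam)
  rxns <- list(
    reaction("EX_co2", c(co2_e = -1), lb = -1000, ub = 1000),
    reaction("EX_h2o", c(h2o_c = -1), lb = -1000, ub = 1000),
    reaction("EX_h", c(h_c = -1), lb = -1000, ub = 1000),
    reaction("T_co2", c(co2_e = -1, co2_c = 1), lb = 0, ub = 1000),
    reaction("CFIX", fix_st, lb = 0, ub = 1000, name = "lumped carbon fixation"),
    reaction("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
             lb = 0, ub = 1000, name = "NADH:NADP+ transhydrogenase"),
    reaction("FDR", c(nadh_c = -1, fdox_c = -2, nad_c = 1, fdred_c = 2),
             lb = 0, ub = 1000, name = "NADH:ferredoxin oxidoreductase"),
    reaction("FDX_USE", c(fdred_c = -2, fdox_c = 2, nadp_c = -1, nadph_c = 1),
             lb = 0, ub = 1000, name = "ferredoxin-driven NADP+ reduction"),
    biomass_reaction(bm)
  )
  oxidation_ids <- character()
  exchange_extra <- character()
  if (include_oxidation_module) {
    ox <- oxidation_module_reactions()
    rxns <- c(rxns, ox$reactions)
    oxidation_ids <- ox$ids
    exchange_extra <- ox$exchange_ids
  }
  if (include_futile_loop) rxns <- c(rxns, loop_reactions())
  species_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  species <- tibble(
    id = species_ids, name = species_ids,
    compartment = compartment_from_id(species_ids),
    molar_mass = unname(.toy_masses[species_ids])
  )
  m <- metabolic_model(
    rxns, species = species, biomass_id = "BIOMASS",
    exchange_ids = c("EX_co2", "EX_h2o", "EX_h", exchange_extra),
    gam = gam, oxidation_ids = oxidation_ids
  )
  m$seed <- as.integer(seed)
  m
}

# Pathway-1 reactions mapped onto model species ids: boundary pathway
# species become exchanged *_e metabolites, protons map to h_c (inside)
# and h_p (outside), currency metabolites to their *_c ids.
oxidation_module_reactions <- function() {
  p1 <- get_pathway(1)
  map <- c(nh4 = "nh4_e", o2 = "o2_e", hno2 = "hno2_e", n2o = "n2o_e",
           h2o = "h2o_c", adp = "adp_c", pi = "pi_c", atp = "atp_c",
           h_c = "h_c", h_p = "h_p", nad = "nad_c", nadh = "nadh_c",
           nh3 = "nh3_c", nh2oh = "nh2oh_c", no = "no_c", q = "q_c",
           qh2 = "qh2_c", pcym = "pcym_c", pcyme = "pcyme_c",
           pcy = "pcy_c", pcye = "pcye_c")
  rxns <- lapply(p1$reactions, function(r) {
    st <- r$stoich
    names(st) <- map[names(st)]
    reaction(r$id, st, lb = r$lb, ub = r$ub, name = r$name, subsystem = r$subsystem)
  })
  ex <- list(
    reaction("EX_nh4", c(nh4_e = -1), lb = -1000, ub = 1000),
    reaction("EX_o2", c(o2_e = -1), lb = -1000, ub = 1000),
    reaction("EX_hno2", c(hno2_e = -1), lb = -1000, ub = 1000),
    reaction("EX_n2o", c(n2o_e = -1), lb = -1000, ub = 1000)
  )
  list(reactions = c(rxns, ex),
       ids = names(p1$reactions),
       exchange_ids = c("EX_nh4", "EX_o2", "EX_hno2", "EX_n2o"))
}

loop_reactions <- function() {
  list(
    # objective-neutral 3-cycle
    reaction("CYC1", c(loopa_c = -1, loopb_c = 1), lb = 0, ub = 1000),
    reaction("CYC2", c(loopb_c = -1, loopc_c = 1), lb = 0, ub = 1000),
    reaction("CYC3", c(loopc_c = -1, loopa_c = 1), lb = 0, ub = 1000),
    # 2-reaction reversible futile pair
    reaction("PAIR_F", c(fp_c = -1, fq_c = 1), lb = -1000, ub = 1000),
    reaction("PAIR_R", c(fq_c = -1, fp_c = 1), lb = -1000, ub = 1000),
    # erroneous reversible isomerase closing an ATP-generating cycle
    reaction("ERR_XY", c(lx_c = -1, ly_c = 1), lb = -1000, ub = 1000),
    reaction("SYN_ERR", c(ly_c = -1, adp_c = -1, pi_c = -1,
                          lx_c = 1, atp_c = 1, h2o_c = 1), lb = 0, ub = 1000),
    reaction("ATPASE", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
             lb = 0, ub = 1000)
  )
}

#' Futile-loop fixture model
#'
#' A small model containing (i) an objective-neutral irreversible
#' 3-cycle, (ii) a reversible 2-reaction futile pair, and (iii) an
#' erroneous reversible isomerase that closes a cycle generating ATP
#' from nothing (`ERR_XY` + `SYN_ERR` + `ATPASE`), alongside a
#' legitimate substrate-limited ATP route (`EX_glc` at 10, two ATP per
#' substrate via `CAT`). Plain FBA can exploit the cycles; loopless FBA
#' must not.
#'
#' @return A `metabolic_model` (no biomass reaction).
#' @export
make_loop_fixture <- function() {
  rxns <- c(
    list(
      reaction("EX_glc", c(glc_e = -1), lb = -10, ub = 1000),
      reaction("T_glc", c(glc_e = -1, glc_c = 1), lb = 0, ub = 1000),
      reaction("CAT", c(glc_c = -1, adp_c = -2, pi_c = -2,
                        atp_c = 2, h2o_c = 2, waste_c = 1), lb = 0, ub = 1000),
      reaction("EX_waste", c(waste_c = -1), lb = -1000, ub = 1000)
    ),
    loop_reactions()
  )
  metabolic_model(rxns, biomass_id = NULL,
                  exchange_ids = c("EX_glc", "EX_waste"), gam = 0)
}

#' Mass-imbalanced biomass fixture
#'
#' A one-component biomass equation (10 mmol of a 100 g mol^-1
#' precursor per gDW, exactly 1 g) scaled by `factor`:
#' `mass_balance_residual` is `factor - 1` grams, and
#' [normalize_biomass()] restores it.
#'
#' @param factor Scale applied to the biomass coefficients.
#' @param gam GAM carried in the equation (mass-neutral under the toy
#'   masses).
#' @return A `biomass_eq`.
#' @export
make_imbalanced_biomass <- function(factor = 2, gam = 0) {
  biomass_equation(c(pre_c = -10 * factor), gam = gam)
}

#' Molar masses of the toy species set
#'
#' @return Named vector of g mol^-1 values consistent with the toy
#'   generators (GAM exactly mass-neutral).
#' @export
toy_masses <- function() .toy_masses

#' Random model generator for round-trip testing
#'
#' Random sparse stoichiometries, random bounds, no FBA semantics -
#' used to exercise serialization round-trips.
#'
#' @param n_species,n_reactions Model size.
#' @param seed RNG seed (fixed seed gives identical output).
#' @return A `metabolic_model`.
#' @export
make_random_model <- function(n_species = 8, n_reactions = 6, seed = 1L) {
  set.seed(seed)
  sp <- sprintf("m%02d_c", seq_len(n_species))
  rxns <- lapply(seq_len(n_reactions), function(i) {
    k <- sample(2:min(4, n_species), 1)
    ids <- sample(sp, k)
    coef <- round(stats::runif(k, -3, 3), 3)
    coef[coef == 0] <- 1
    rev <- stats::runif(1) < 0.5
    reaction(sprintf("R%02d", i), setNames(coef, ids),
             lb = if (rev) -1000 else 0, ub = 1000)
  })
  species <- tibble(id = sp, name = sp, compartment = "cytoplasm",
                    molar_mass = round(stats::runif(n_species, 10, 500), 1))
  metabolic_model(rxns, species = species, biomass_id = NULL,
                  exchange_ids = character(), gam = 25)
}

#' Synthetic genome-scale emulator
#'
#' A model of the size of a curated archaeal genome-scale
#' reconstruction (by default 765 reactions over 825 metabolites),
#' built as the planted-cost toy autotroph with the ammonia-oxidation
#' module plus inert linear biosynthesis branches that carry no flux at
#' the optimum. It is SYNTHETIC: its only ground truth is the planted
#' energy cost; it stands in for a real reconstruction in size only.
#'
#' @inheritParams make_toy_autotroph
#' @param n_reactions,n_species Target model dimensions.
#' @return A `metabolic_model`.
#' @export
make_synthetic_genome_model <- function(n_reactions = 765, n_species = 825,
                                        atp_cost = 0.095, nadh_cost = 0.093,
                                        gam = 25, seed = 1L) {
  base <- make_toy_autotroph(atp_cost, nadh_cost, gam,
                             include_oxidation_module = TRUE, seed = seed)
  n0_r <- length(base$reactions)
  n0_s <- nrow(base$species)
  extra_r <- n_reactions - n0_r
  extra_s <- n_species - n0_s
  if (extra_r < 0 || extra_s < 0)
    abort("target dimensions smaller than the core model")
  k2 <- extra_s - extra_r   # filler reactions that mint two species
  if (k2 < 0 || k2 > extra_r)
    abort("target dimensions unreachable: need 1-2 new species per filler reaction")
  # Dead-end biosynthesis stubs off the precursor: every filler product
  # is produced but never consumed, so species balance forces zero flux
  # and the planted costs are untouched. Each filler reaction mints one
  # or two fresh species to hit the requested dimensions exactly.
  rxns <- base$reactions
  filler_sp <- sprintf("fil%03d_c", seq_len(max(extra_s, 0)))
  s_idx <- 0L
  for (i in seq_len(extra_r)) {
    n_new <- if (i <= k2) 2L else 1L
    prods <- filler_sp[s_idx + seq_len(n_new)]
    s_idx <- s_idx + n_new
    st <- setNames(c(-1, rep(1, n_new)), c("pre_c", prods))
    rxns[[sprintf("FIL%03d", i)]] <-
      reaction(sprintf("FIL%03d", i), st, lb = 0, ub = 1000, subsystem = "filler")
  }
  species <- bind_rows(
    base$species,
    tibble(id = filler_sp, name = filler_sp, compartment = "cytoplasm",
           molar_mass = NA_real_)
  )
  m <- metabolic_model(rxns, species = species, biomass_id = base$biomass_id,
                       exchange_ids = base$exchange_ids, gam = gam,
                       oxidation_ids = base$oxidation_ids)
  m$seed <- as.integer(seed)
  m
}
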