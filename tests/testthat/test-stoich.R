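# Stoichiometric algebra: net-reaction combination and the biomass
# mass-balance contract.

test_that("pathway-1 fluxes combine into the printed overall reaction", {
  p1 <- get_pathway(1)
  flux <- c(Trans_NH4 = 1, AMO = 1, HAO = 1, QH2_Synt = 2,
            Cytbc1 = 1, Cytaa3 = 1, ATP_Synt = 1.5)
  net <- net_reaction(p1, flux)
  expected <- c(nh4 = -1, o2 = -1.5, h_c = -0.5, adp = -1.5, pi = -1.5,
                atp = 1.5, h2o = 2.5, hno2 = 1)
  expect_setequal(names(net$stoich), names(expected))
  expect_equal(net$stoich[names(expected)], expected, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("an all-zero flux map combines to the empty reaction", {
  p1 <- get_pathway(1)
  flux <- setNames(rep(0, length(p1$reactions)), names(p1$reactions))
  expect_length(net_reaction(p1, flux)$stoich, 0)
})

test_that("combination of an unknown reaction id is an identifier error", {
  p1 <- get_pathway(1)
  expect_error(net_reaction(p1, c(NOPE = 1)), "unknown reaction")
})

test_that("random sparse combinations match the dictionary-accumulation oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    n_r <- sample(3:8, 1)
    rxns <- setNames(lapply(seq_len(n_r), function(i) {
      k <- sample(2:5, 1)
      sp <- sample(sprintf("x%02d", 1:10), k)
      reaction(sprintf("r%d", i),
               setNames(sample(c(-3, -2, -1, -0.5, 0.5, 1, 2), k, replace = TRUE), sp))
    }), sprintf("r%d", seq_len(n_r)))
    flux <- setNames(sample(c(-2, -0.5, 0, 0.25, 1, 3), n_r, replace = TRUE),
                     names(rxns))
    got <- net_reaction(rxns, flux)$stoich
    want <- oracle_net(rxns, flux)
    expect_setequal(names(got), names(want))
    expect_equal(got[sort(names(got))], want[sort(names(got))], tolerance = 1e-9)
  }
})

test_that("net_reaction is linear in the flux vector", {
  p1 <- get_pathway(1)
  ids <- names(p1$reactions)
  set.seed(42)
  for (i in 1:10) {
    f1 <- setNames(stats::runif(length(ids), 0, 3), ids)
    f2 <- setNames(stats::runif(length(ids), 0, 3), ids)
    n12 <- net_reaction(p1, f1 + f2)$stoich
    n1 <- net_reaction(p1, f1)$stoich
    n2 <- net_reaction(p1, f2)$stoich
    sp <- union(names(n1), names(n2))
    sum12 <- setNames(numeric(length(sp)), sp)
    sum12[names(n1)] <- sum12[names(n1)] + n1
    sum12[names(n2)] <- sum12[names(n2)] + n2
    sum12 <- sum12[abs(sum12) >= 1e-9]
    expect_equal(n12[sort(names(n12))], sum12[sort(names(sum12))], tolerance = 1e-9)
  }
})

test_that("single-component biomass residuals follow the 1 gDW contract", {
  masses <- c(glc_c = 180)
  # 1000/180 mmol of a 180 g/mol species is exactly 1 g
  bm <- biomass_equation(c(glc_c = -1000 / 180), gam = 0)
  expect_equal(mass_balance_residual(bm, masses), 0, tolerance = 1e-12)
  # doubling the coefficient adds one gram
  bm2 <- biomass_equation(c(glc_c = -2000 / 180), gam = 0)
  expect_equal(mass_balance_residual(bm2, masses), 1, tolerance = 1e-12)
})

test_that("random biomass compositions match the hand-summed residual oracle", {
  set.seed(7)
  for (i in 1:20) {
    sp <- sprintf("c%02d", 1:10)
    coef <- stats::runif(10, -20, 5)
    masses <- setNames(stats::runif(10, 20, 400), sp)
    bm <- biomass_equation(setNames(coef, sp), gam = 0)
    expect_equal(mass_balance_residual(bm, masses),
                 oracle_mass_residual(bm$stoich, masses), tolerance = 1e-9)
  }
})

test_that("a missing molar mass is a data error naming the species", {
  bm <- biomass_equation(c(aa_c = -5, bb_c = -2), gam = 0)
  expect_error(mass_balance_residual(bm, c(aa_c = 100)), "bb_c")
})

test_that("normalization rescales to zero residual and is idempotent", {
  masses <- toy_masses()
  # factor-2 overweight: scale back by one half
  bm <- make_imbalanced_biomass(2)
  norm <- normalize_biomass(bm, masses)
  expect_equal(unname(norm$stoich["pre_c"]), -10, tolerance = 1e-12)
  expect_equal(mass_balance_residual(norm, masses), 0, tolerance = 1e-9)
  # an already balanced equation is returned unchanged
  again <- normalize_biomass(norm, masses)
  expect_equal(again$stoich, norm$stoich, tolerance = 1e-9)
  # GAM is excluded from scaling and re-added unchanged
  bm_gam <- make_imbalanced_biomass(3, gam = 25)
  norm_gam <- normalize_biomass(bm_gam, masses)
  expect_equal(norm_gam$gam, 25)
  expect_equal(mass_balance_residual(norm_gam, masses), 0, tolerance = 1e-9)
})

test_that("normalization of random imbalanced fixtures always restores balance", {
  masses <- toy_masses()
  set.seed(11)
  for (factor in stats::runif(15, 0.1, 5)) {
    bm <- make_imbalanced_biomass(factor)
    expect_equal(mass_balance_residual(bm, masses), factor - 1, tolerance = 1e-9)
    norm <- normalize_biomass(bm, masses)
    expect_lt(abs(mass_balance_residual(norm, masses)), 1e-9)
    expect_equal(normalize_biomass(norm, masses)$stoich, norm$stoich,
                 tolerance = 1e-9)
  }
})

test_that("a zero-mass biomass equation is a normalization error", {
  bm <- biomass_equation(c(aa_c = -1, bb_c = 1), gam = 0)
  expect_error(normalize_biomass(bm, c(aa_c = 100, bb_c = 100)), "degenerate")
})
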