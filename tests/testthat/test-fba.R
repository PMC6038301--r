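# The LP flux-balance engine against closed forms, brute-force vertex
# enumeration, and LP duality.

chain_model <- function(cap = 10) {
  metabolic_model(list(
    reaction("EX_a", c(a_c = -1), lb = -cap, ub = 1000),
    reaction("CONV", c(a_c = -1, b_c = 1), lb = 0, ub = 1000),
    reaction("GROW", c(b_c = -1), lb = 0, ub = 1000)
  ), biomass_id = "GROW", gam = 0)
}

branched_model <- function() {
  # uptake splits into a 1:1 branch and a 2:1 branch with different
  # objective payoffs; optimum sits at a nontrivial vertex
  metabolic_model(list(
    reaction("EX_a", c(a_c = -1), lb = -10, ub = 1000),
    reaction("B1", c(a_c = -1, p_c = 1), lb = 0, ub = 6),
    reaction("B2", c(a_c = -2, q_c = 1), lb = 0, ub = 1000),
    reaction("EX_p", c(p_c = -1), lb = 0, ub = 1000),
    reaction("EX_q", c(q_c = -1), lb = 0, ub = 1000)
  ), biomass_id = NULL, gam = 0)
}

test_that("a single linear path carries its uptake cap to the objective", {
  m <- chain_model(10)
  sol <- solve_fba(m, "GROW", "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_a"]), -10, tolerance = 1e-9)
})

test_that("blocking the only feed drives the optimum to zero", {
  m <- chain_model(10)
  sol <- solve_fba(m, "GROW", "max", blocked = "EX_a")
  expect_equal(sol$objective_value, 0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (m in list(chain_model(7), branched_model(),
                 make_toy_autotroph(0.1, 0.05, include_oxidation_module = TRUE))) {
    obj <- if (is.null(m$biomass_id)) "EX_p" else m$biomass_id
    if (!is.null(m$reactions$EX_nh4)) m$reactions$EX_nh4$lb <- -1
    sol <- solve_fba(m, obj, "max")
    expect_equal(sol$status, "optimal")
    S <- aoaflux:::stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    bd <- aoaflux:::reaction_bounds(m)
    expect_true(all(sol$fluxes >= bd$lb - 1e-8 & sol$fluxes <= bd$ub + 1e-8))
  }
})

test_that("the branched optimum equals brute-force vertex enumeration", {
  m <- branched_model()
  S <- aoaflux:::stoich_matrix(m)
  bd <- aoaflux:::reaction_bounds(m)
  for (objective in list(c(EX_p = 1), c(EX_q = 1), c(EX_p = 1, EX_q = 3))) {
    obj <- aoaflux:::objective_vector(objective, names(m$reactions))
    got <- solve_fba(m, objective, "max")
    want <- oracle_lp_vertex(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, "max")
    expect_equal(got$objective_value, want$value, tolerance = 1e-8)
  }
})

test_that("random small networks agree with vertex enumeration", {
  for (seed in 1:15) {
    m <- random_acyclic_model(seed)
    S <- aoaflux:::stoich_matrix(m)
    bd <- aoaflux:::reaction_bounds(m)
    obj_id <- "EX_out"
    obj <- aoaflux:::objective_vector(obj_id, names(m$reactions))
    got <- solve_fba(m, obj_id, "max")
    want <- oracle_lp_vertex(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, "max")
    expect_equal(got$objective_value, want$value, tolerance = 1e-8)
  }
})

test_that("the primal optimum matches the LP dual objective", {
  # dual of max c'v s.t. S v = 0, lb <= v <= ub:
  #   min  w_u'ub - w_l'lb  s.t.  S'y + w_u - w_l = c,  w_u, w_l >= 0.
  m <- branched_model()
  S <- aoaflux:::stoich_matrix(m)
  bd <- aoaflux:::reaction_bounds(m)
  n <- length(m$reactions); ms <- nrow(S)
  obj <- aoaflux:::objective_vector(c(EX_p = 1, EX_q = 3), names(m$reactions))
  primal <- solve_fba(m, c(EX_p = 1, EX_q = 3), "max")
  # dual variables: y (free, split +-), w_u, w_l
  Ad <- cbind(t(S), -t(S), diag(n), -diag(n))
  cd <- c(rep(0, 2 * ms), bd$ub, -bd$lb)
  dual <- aoaflux:::lp_solve(cd, Ad, obj,
                             lb = rep(0, 2 * ms + 2 * n),
                             ub = rep(2000, 2 * ms + 2 * n), sense = "min")
  expect_equal(dual$status, "optimal")
  expect_equal(primal$objective_value, dual$value, tolerance = 1e-6)
})

test_that("infeasible problems report status instead of raising", {
  m <- chain_model(10)
  sol <- solve_fba(m, "GROW", "max", fixed = c(GROW = 5), blocked = "EX_a")
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("fixed fluxes outside bounds are rejected up front", {
  m <- chain_model(10)
  expect_error(solve_fba(m, "GROW", "max", fixed = c(GROW = -5)), "violates bounds")
})
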