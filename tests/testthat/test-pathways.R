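# The three ammonia-oxidation pathways: fixture content, LP-derived
# combined reactions and yields, proton bookkeeping, and equivalence
# with an independent vertex-enumeration oracle.

test_that("pathway fixtures contain the printed key reactions", {
  p1 <- get_pathway(1)
  expect_stoich_equal(p1$reactions$AMO,
    parse_equation("nh3 + o2 + qh2 -> nh2oh + h2o + q"))
  p2 <- get_pathway(2)
  expect_stoich_equal(p2$reactions$AMO_NO,
    parse_equation("nh3 + o2 + 2 no + h2o -> nh2oh + 2 hno2"))
  expect_false("AMO" %in% names(p2$reactions))
  p3 <- get_pathway(3)
  expect_stoich_equal(p3$reactions$CuP460,
    parse_equation("nh2oh + 2 h2o + 5 pcym + no -> 2 hno2 + 5 pcyme + 5 h_p"))
  expect_false("HAO" %in% names(p3$reactions))
  # shared backbone
  for (p in list(p1, p2, p3)) {
    expect_stoich_equal(p$reactions$ATP_Synt,
      parse_equation("4 h_p + adp + pi -> 3 h_c + atp + h2o"))
    expect_true(all(vapply(p$reactions, function(r) r$lb == 0, logical(1))))
  }
})

test_that("unknown pathway ids are rejected", {
  expect_error(get_pathway(4), "unknown pathway")
})

table2 <- list(
  list(id = 1, mode = "atp", atp = 1.5, nadh = 0,
       net = c(nh4 = -1, o2 = -1.5, h_c = -0.5, adp = -1.5, pi = -1.5,
               atp = 1.5, h2o = 2.5, hno2 = 1)),
  list(id = 1, mode = "nadh", atp = 0.5, nadh = 1,
       net = c(nh4 = -1, o2 = -1, nad = -1, adp = -0.5, pi = -0.5,
               atp = 0.5, h2o = 0.5, hno2 = 1, h_c = 1.5, nadh = 1)),
  list(id = 2, mode = "atp", atp = 1.75, nadh = 0,
       net = c(nh4 = -1, o2 = -1.5, h_c = -0.75, adp = -1.75, pi = -1.75,
               atp = 1.75, h2o = 2.75, hno2 = 1)),
  list(id = 2, mode = "nadh", atp = 0.75, nadh = 1,
       net = c(nh4 = -1, o2 = -1, nad = -1, adp = -0.75, pi = -0.75,
               atp = 0.75, h2o = 0.75, hno2 = 1, h_c = 1.25, nadh = 1)),
  list(id = 3, mode = "atp", atp = 1.625, nadh = 0,
       net = c(nh4 = -1, o2 = -1.5, h_c = -0.625, adp = -1.625, pi = -1.625,
               atp = 1.625, h2o = 2.625, hno2 = 1)),
  list(id = 3, mode = "nadh", atp = 0.625, nadh = 1,
       net = c(nh4 = -1, o2 = -1, nad = -1, adp = -0.625, pi = -0.625,
               atp = 0.625, h2o = 0.625, hno2 = 1, h_c = 1.375, nadh = 1))
)

test_that("all six combined reactions and yields match the published table", {
  for (case in table2) {
    y <- theoretical_yield(get_pathway(case$id), case$mode)
    expect_equal(y$atp_per_nh4, case$atp, tolerance = 1e-9,
                 label = sprintf("ATP yield, pathway %d %s", case$id, case$mode))
    expect_equal(y$nadh_per_nh4, case$nadh, tolerance = 1e-9,
                 label = sprintf("NADH yield, pathway %d %s", case$id, case$mode))
    expect_setequal(names(y$net$stoich), names(case$net))
    expect_equal(y$net$stoich[names(case$net)], case$net, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("net reactions eliminate every internal species", {
  for (id in 1:3) for (mode in c("atp", "nadh")) {
    y <- theoretical_yield(get_pathway(id), mode)
    leftovers <- intersect(names(y$net$stoich), y$pathway$internal_species)
    expect_length(leftovers, 0)
    expect_equal(unname(y$net$stoich["nh4"]), -1, tolerance = 1e-9)
  }
})

test_that("the abiotic N2O route carries no flux at any optimum", {
  for (id in 1:3) for (mode in c("atp", "nadh")) {
    y <- theoretical_yield(get_pathway(id), mode)
    expect_lt(abs(y$fluxes[["N2O_spon"]]), 1e-9)
  }
})

test_that("ATP yields equal the proton ledger divided by four", {
  protons_expected <- c(`1` = 6, `2` = 7, `3` = 6.5)
  for (id in 1:3) {
    y <- theoretical_yield(get_pathway(id), "atp")
    led <- proton_ledger(y)
    expect_equal(led$protons_translocated, unname(protons_expected[as.character(id)]),
                 tolerance = 1e-9)
    expect_equal(y$atp_per_nh4, led$protons_translocated / 4, tolerance = 1e-9)
    # NADH mode: the same proton-equivalent total, split 4-per-NADH
    yn <- theoretical_yield(get_pathway(id), "nadh")
    ledn <- proton_ledger(yn)
    expect_equal(ledn$proton_equivalents, led$proton_equivalents, tolerance = 1e-9)
    expect_equal(yn$atp_per_nh4, ledn$protons_translocated / 4, tolerance = 1e-9)
  }
})

test_that("hand bookkeeping of pathway-1 fluxes reproduces the ledger", {
  y <- theoretical_yield(get_pathway(1), "atp")
  # Trans +1, HAO +4, QRED -4, bc1 +3, aa3 +2 = 6 protons
  expect_equal(unname(y$fluxes[c("Trans_NH4", "HAO", "QH2_Synt", "Cytbc1", "Cytaa3")]),
               c(1, 1, 2, 1, 1), tolerance = 1e-9)
  expect_equal(proton_ledger(y)$protons_translocated,
               1 * 1 + 1 * 4 + 2 * (-2) + 1 * 3 + 1 * 2, tolerance = 1e-9)
})

test_that("a zero-flux result has an empty proton ledger", {
  y <- theoretical_yield(get_pathway(1), "atp")
  y$fluxes[] <- 0
  y$nadh_per_nh4 <- 0
  expect_equal(proton_ledger(y)$protons_translocated, 0)
})

test_that("LP yields equal the independent vertex-enumeration optimum", {
  for (id in 1:3) {
    p <- get_pathway(id)
    rxns <- p$reactions
    ids <- names(rxns)
    all_sp <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
    S <- matrix(0, length(all_sp), length(ids), dimnames = list(all_sp, ids))
    for (r in rxns) S[names(r$stoich), r$id] <- r$stoich
    internal <- intersect(c(p$internal_species, "nad", "nadh"), all_sp)
    A <- rbind(S[internal, , drop = FALSE], S["nh4", ])
    b <- c(rep(0, length(internal)), -1)
    obj <- S["atp", ]
    want <- oracle_lp_vertex(obj, A, b, rep(0, length(ids)),
                             rep(1000, length(ids)), "max")
    got <- theoretical_yield(p, "atp")
    expect_equal(got$atp_per_nh4, want$value, tolerance = 1e-8)
  }
})

test_that("an empty pathway is infeasible with a diagnostic", {
  empty <- structure(list(id = 1L, reactions = list(),
                          internal_species = character(),
                          boundary_species = character()),
                     class = "pathway_def")
  expect_error(theoretical_yield(empty, "atp"), "infeasible")
})
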