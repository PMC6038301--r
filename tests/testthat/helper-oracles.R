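# Independent oracles used to cross-check the package implementations.
# Deliberately written with plain loops / direct linear algebra,
# sharing no code with the implementation paths they verify.

# Dictionary-accumulation oracle for net-reaction combination.
oracle_net <- function(rxns, flux) {
  acc <- list()
  for (rid in names(flux)) {
    st <- rxns[[rid]]$stoich
    for (sp in names(st)) {
      acc[[sp]] <- (if (is.null(acc[[sp]])) 0 else acc[[sp]]) + flux[[rid]] * st[[sp]]
    }
  }
  out <- unlist(acc)
  if (is.null(out)) return(setNames(numeric(0), character(0)))
  out[abs(out) >= 1e-9]
}

# Brute-force vertex enumeration for small LPs
#   optimise obj'v  s.t.  A v = b, lb <= v <= ub.
# Enumerates all basic solutions: choose a candidate basic set of
# size rank(A), fix the remaining variables at either bound, solve the
# square system, keep feasible points. Exact for nondegenerate and
# degenerate problems alike (the optimum is attained at some vertex).
oracle_lp_vertex <- function(obj, A, b, lb, ub, sense = "max") {
  n <- ncol(A)
  qa <- qr(t(A), tol = 1e-10)
  r <- qa$rank
  keep <- sort(qa$pivot[seq_len(r)])
  A <- A[keep, , drop = FALSE]
  b <- b[keep]
  best <- NULL
  basic_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basic_sets) {
    AB <- A[, B, drop = FALSE]
    if (r > 0 && qr(AB, tol = 1e-10)$rank < r) next
    Fset <- setdiff(seq_len(n), B)
    n_f <- length(Fset)
    for (mask in 0:(2^n_f - 1)) {
      v <- numeric(n)
      if (n_f > 0) {
        at_up <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(n_f) - 1L), 1L))
        v[Fset] <- ifelse(at_up, ub[Fset], lb[Fset])
      }
      rhs <- b - (if (n_f) A[, Fset, drop = FALSE] %*% v[Fset] else 0)
      vB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      v[B] <- vB
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      val <- sum(obj * v)
      if (is.null(best) ||
          (sense == "max" && val > best$value + 1e-12) ||
          (sense == "min" && val < best$value - 1e-12))
        best <- list(value = val, v = v)
    }
  }
  best
}

# Hand-summed mass balance for a biomass stoichiometry (full, GAM included).
oracle_mass_residual <- function(stoich, masses) {
  req <- 0; byp <- 0
  for (sp in names(stoich)) {
    cf <- stoich[[sp]]
    if (cf < 0) req <- req + (-cf) * masses[[sp]]
    else byp <- byp + cf * masses[[sp]]
  }
  (req - byp) / 1000 - 1
}

# Small acyclic (tree-shaped) random models: a chain plus random
# irreversible branches, no cycles possible, so plain and loopless FBA
# must agree.
random_acyclic_model <- function(seed) {
  set.seed(seed)
  n_chain <- sample(3:5, 1)
  sp <- sprintf("s%d_c", seq_len(n_chain))
  rxns <- list(reaction("EX_in", setNames(-1, sp[1]), lb = -sample(5:20, 1), ub = 1000))
  for (i in seq_len(n_chain - 1)) {
    coef <- sample(1:3, 1)
    rxns[[length(rxns) + 1]] <-
      reaction(sprintf("C%d", i), setNames(c(-1, coef), sp[i + 0:1]), lb = 0, ub = 1000)
  }
  # random side branches to exported by-products
  for (j in seq_len(sample(1:3, 1))) {
    from <- sample(sp[-n_chain], 1)
    out_sp <- sprintf("b%d_c", j)
    rxns[[length(rxns) + 1]] <-
      reaction(sprintf("BR%d", j), setNames(c(-1, 1), c(from, out_sp)), lb = 0, ub = sample(2:8, 1))
    rxns[[length(rxns) + 1]] <-
      reaction(sprintf("EX_b%d", j), setNames(-1, out_sp), lb = -1000, ub = 1000)
  }
  rxns[[length(rxns) + 1]] <- reaction("EX_out", setNames(-1, sp[n_chain]), lb = -1000, ub = 1000)
  metabolic_model(rxns, biomass_id = NULL, gam = 0)
}

# Random reaction with default bounds for parser round-trips.
random_reaction <- function(seed) {
  set.seed(seed)
  k <- sample(2:6, 1)
  sp <- sample(sprintf("met%02d", 1:12), k)
  coef <- sample(c(1, 2, 3, 0.5, 1.625, 0.25), k, replace = TRUE) *
    sample(c(-1, 1), k, replace = TRUE)
  if (all(coef < 0)) coef[1] <- -coef[1]
  if (all(coef > 0)) coef[1] <- -coef[1]
  reaction(sprintf("rx%d", seed), setNames(coef, sp),
           reversible = stats::runif(1) < 0.5)
}

expect_stoich_equal <- function(a, b, tol = 1e-9) {
  expect_setequal(names(a$stoich), names(b$stoich))
  ord <- sort(names(a$stoich))
  expect_equal(unname(a$stoich[ord]), unname(b$stoich[ord]), tolerance = tol)
}
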