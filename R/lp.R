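# Internal linear-programming wrapper.
#
# Problems are box-bounded:  optimise c'v  s.t.  Aeq v = beq, lb <= v <= ub,
# with all bounds finite (the FBA "unbounded" sentinel is +-1000). They are
# shifted to standard form (x = v - lb) and handed to the package's
# bounded-variable simplex (simplex.R), which is deterministic (fixed
# Bland pivoting, no randomisation), so repeated solves agree bit-wise.

lp_solve <- function(obj, Aeq, beq, lb, ub, sense = c("max", "min"),
                     eps = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    abort("lp_solve requires finite bounds (use the +-1000 sentinel)")
  if (any(lb > ub + 1e-12)) return(lp_result(NULL, n, "infeasible", obj, lb))

  fixed_all <- all(ub - lb < 1e-15)
  if (fixed_all) {  # fully determined point: just check feasibility
    v <- lb
    res <- if (is.null(Aeq)) 0 else max(abs(Aeq %*% v - beq))
    status <- if (res < 1e-6) "optimal" else "infeasible"
    return(lp_result(v, n, status, obj, lb))
  }

  if (is.null(Aeq)) {
    Aeq <- matrix(0, 0, n)
    beq <- numeric(0)
  }
  Aeq <- as.matrix(Aeq)
  b3 <- as.numeric(beq - Aeq %*% lb)
  # Drop redundant equality rows (simplex cannot handle rank-deficient
  # systems); declare infeasibility if a dropped row is inconsistent.
  if (nrow(Aeq) > 1L) {
    qa <- qr(t(Aeq), tol = 1e-10)
    if (qa$rank < nrow(Aeq)) {
      qaug <- qr(t(cbind(Aeq, b3)), tol = 1e-10)
      if (qaug$rank > qa$rank) return(lp_result(NULL, n, "infeasible", obj, lb))
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      Aeq <- Aeq[keep, , drop = FALSE]
      b3 <- b3[keep]
    }
  }
  span <- ub - lb
  cc <- if (sense == "max") -obj else obj
  out <- simplex_core(Aeq, b3, cc, span, tol = eps)
  if (out$status != "optimal") return(lp_result(NULL, n, out$status, obj, lb))
  v <- out$x + lb
  lp_result(v, n, "optimal", obj, lb)
}

lp_result <- function(v, n, status, obj, lb) {
  if (is.null(v)) {
    list(status = status, v = setNames(rep(NA_real_, n), names(lb)),
         value = NA_real_)
  } else {
    names(v) <- names(lb)
    list(status = status, v = v, value = sum(obj * v))
  }
}

# Orthonormal basis of the null space of A (A x = 0), via pivoted QR of t(A).
null_space <- function(A, tol = 1e-9) {
  n <- ncol(A)
  if (!n) return(matrix(0, 0, 0))
  qr_t <- qr(t(A), tol = tol)
  r <- qr_t$rank
  if (r >= n) return(matrix(0, n, 0))
  Q <- qr.Q(qr_t, complete = TRUE)
  Q[, (r + 1L):n, drop = FALSE]
}
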