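# Dense two-phase primal simplex with variable upper bounds and
# Bland's anti-cycling rule. Written for the moderate, rational-
# coefficient LPs of this package (tens to a few hundred variables):
# robustness and determinism over speed. Solves
#
#     min c'x   s.t.  A x = b,  0 <= x <= u      (u finite)
#
# Phase 1 introduces artificial variables with an identity basis and
# minimizes their sum; phase 2 then minimizes c over the feasible
# basis. Nonbasic variables sit at either bound (bounded-variable
# simplex); entering/leaving choices follow Bland's rule throughout,
# which guarantees termination.

simplex_core <- function(A, b, c, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # no constraints: each variable at whichever bound minimizes c
    x <- ifelse(c >= 0, 0, u)
    return(list(status = "optimal", x = x, value = sum(c * x)))
  }
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  Tab <- cbind(A, diag(m))          # structural + artificial columns
  uu <- c(u, rep(Inf, m))
  at_upper <- rep(FALSE, n + m)
  basis <- n + seq_len(m)
  xB <- b
  scale_ref <- max(abs(b), 1)

  run_phase <- function(cost, Tab, basis, xB, at_upper, uu) {
    is_basic <- rep(FALSE, n + m)
    is_basic[basis] <- TRUE
    repeat {
      cB <- cost[basis]
      z <- cost - as.numeric(crossprod(cB, Tab))   # reduced costs
      movable <- !is_basic & uu > tol              # fixed (u = 0) columns cannot move
      cand <- which(movable & ((!at_upper & z < -tol) | (at_upper & z > tol)))
      if (!length(cand))
        return(list(status = "optimal", Tab = Tab, basis = basis, xB = xB,
                    at_upper = at_upper))
      e <- cand[1]                                  # Bland: smallest index
      dir <- if (at_upper[e]) -1 else 1             # increase from lower / decrease from upper
      col <- Tab[, e] * dir
      # ratio test: basic value xB_i changes at rate -col_i
      ti <- rep(Inf, m)
      to_upper <- rep(FALSE, m)
      dec <- col > tol
      inc <- col < -tol & is.finite(uu[basis])
      ti[dec] <- xB[dec] / col[dec]
      ti[inc] <- (uu[basis[inc]] - xB[inc]) / (-col[inc])
      to_upper[inc] <- TRUE
      t_rows <- suppressWarnings(min(ti))
      t_star <- min(t_rows, uu[e])
      if (!is.finite(t_star)) return(list(status = "unbounded"))
      if (uu[e] < t_rows - tol) {                   # bound flip, basis unchanged
        xB <- xB - col * uu[e]
        at_upper[e] <- !at_upper[e]
        next
      }
      tie <- which(ti <= t_rows + tol)
      leave <- tie[which.min(basis[tie])]           # Bland: smallest leaving index
      t_star <- max(t_rows, 0)
      xB <- xB - col * t_star
      lv <- basis[leave]
      piv <- Tab[leave, e]
      Tab[leave, ] <- Tab[leave, ] / piv
      other <- setdiff(seq_len(m), leave)
      if (length(other)) {
        fac <- Tab[other, e]
        Tab[other, ] <- Tab[other, ] - outer(fac, Tab[leave, ])
      }
      xB[leave] <- if (at_upper[e]) uu[e] - t_star else t_star
      at_upper[e] <- FALSE
      at_upper[lv] <- to_upper[leave]
      is_basic[lv] <- FALSE
      is_basic[e] <- TRUE
      basis[leave] <- e
      # clamp tiny negatives from round-off
      xB[xB < 0 & xB > -1e-7 * scale_ref] <- 0
    }
  }

  # phase 1
  ph1 <- run_phase(c(rep(0, n), rep(1, m)), Tab, basis, xB, at_upper, uu)
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  art_val <- sum(ph1$xB[ph1$basis > n])
  if (art_val > 1e-6 * scale_ref) return(list(status = "infeasible"))
  # freeze artificials at zero and run phase 2 on the real costs
  uu[(n + 1):(n + m)] <- 0
  ph1$at_upper[(n + 1):(n + m)] <- FALSE
  ph2 <- run_phase(c(c, rep(0, m)), ph1$Tab, ph1$basis, ph1$xB, ph1$at_upper, uu)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- ifelse(ph2$at_upper[seq_len(n)], u, 0)
  x[ph2$basis[ph2$basis <= n]] <- ph2$xB[ph2$basis <= n]
  list(status = "optimal", x = x, value = sum(c * x))
}
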