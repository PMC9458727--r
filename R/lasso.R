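# Exact lasso homotopy (LARS with drops) for
#   min_w ||X w - b||^2 + lam * ||w||_1
# on a column matrix X whose columns the caller has already standardized.
#
# The discovery designs built from sigmoid trajectories are numerically
# near-degenerate (high-degree monomials of a sigmoid are almost linearly
# dependent), and coordinate-descent solvers do not converge there at the
# tiny penalties this pipeline uses.  The homotopy is exact for the small
# term counts involved (p <= 15) and is stopped early once the active set
# already explains b to numerical precision ("saturation"): beyond that
# point the path only chases rounding noise.
#
# KKT conditions used: with g = 2 X'(Xw - b), an optimal w satisfies
# g_j = -lam * sign(w_j) on the active set and |g_j| <= lam elsewhere;
# the solution is piecewise linear in lam between add/drop events.
.lasso_homotopy <- function(X, b, lam, sat_tol = 1e-10, max_steps = 1000L) {
  p <- ncol(X)
  bb <- sum(b^2)
  w <- numeric(p)
  if (bb == 0) return(list(w = w, steps = 0L, saturated = FALSE))
  cor0 <- 2 * as.numeric(crossprod(X, b))
  lam_cur <- max(abs(cor0))
  if (lam_cur <= lam) return(list(w = w, steps = 0L, saturated = FALSE))
  active <- which.max(abs(cor0))
  sgn <- sign(cor0[active])
  step <- 0L
  saturated <- FALSE
  while (step < max_steps) {
    step <- step + 1L
    XA <- X[, active, drop = FALSE]
    G <- crossprod(XA)
    sv <- tryCatch(
      list(a = solve(G, as.numeric(crossprod(XA, b))), d = solve(G, sgn / 2)),
      error = function(e) NULL)
    if (is.null(sv)) break  # exactly singular active set: keep last iterate
    r0 <- as.numeric(b - XA %*% sv$a)
    if (sum(r0^2) < sat_tol * bb) {
      # active set is numerically exact; finish at the target penalty
      w[active] <- sv$a - lam * sv$d
      saturated <- TRUE
      break
    }
    c0 <- 2 * as.numeric(crossprod(X, r0))
    c1 <- 2 * as.numeric(crossprod(X, XA %*% sv$d))
    cand <- numeric(0); lab <- integer(0)
    for (jj in setdiff(seq_len(p), active)) {
      for (ss in c(1, -1)) {
        den <- ss - c1[jj]
        if (abs(den) > 1e-14) {
          l <- c0[jj] / den
          if (l > lam + 1e-15 && l < lam_cur - 1e-12) {
            cand <- c(cand, l); lab <- c(lab, jj)
          }
        }
      }
    }
    for (ii in seq_along(active)) {
      if (abs(sv$d[ii]) > 1e-14) {
        l <- sv$a[ii] / sv$d[ii]
        if (l > lam + 1e-15 && l < lam_cur - 1e-12) {
          cand <- c(cand, l); lab <- c(lab, -active[ii])
        }
      }
    }
    if (!length(cand)) {  # no event before the target: final segment
      w[active] <- sv$a - lam * sv$d
      break
    }
    i <- which.max(cand)
    lam_cur <- cand[i]
    ev <- lab[i]
    if (ev > 0) {
      active <- c(active, ev)
      sgn <- c(sgn, sign(c0[ev] + lam_cur * c1[ev]))
    } else {
      k <- which(active == -ev)
      active <- active[-k]
      sgn <- sgn[-k]
      if (!length(active)) break
    }
  }
  if (step >= max_steps)
    stop("lasso homotopy did not terminate in ", max_steps,
         " steps (last penalty ", format(lam_cur), ")")
  list(w = w, steps = step, saturated = saturated)
}
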