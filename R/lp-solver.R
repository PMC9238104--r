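## Dense bounded-variable two-phase primal simplex.
##
## Solves  min/max c'x  s.t.  A x = b,  l <= x <= u  (all bounds finite).
## Written for the small dense LPs of flux balance analysis, where general
## tableau implementations proved numerically fragile. Bland's smallest-
## index rule guarantees termination; redundant equality rows are handled
## by leaving their artificial variables basic at zero with frozen bounds.

lp_solve_bounded <- function(cc, A, b, lb, ub, maximize = FALSE,
                             tol = 1e-9, max_iter = NULL) {
  n <- length(cc)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  if (maximize) cc <- -cc
  max_iter <- max_iter %||% (2000L + 200L * (n + m))

  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    abort("lp_solve_bounded requires finite bounds")
  ## start: every structural var nonbasic AT the bound nearest zero
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.numeric(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)

  ## augmented problem: [x, a]; artificials absorb the residual
  N <- n + m
  Aa <- cbind(A, diag(sg, m))
  lo <- c(lb, rep(0, m))
  hi <- c(ub, abs(r))             # artificials never need to exceed |r|
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)
  at_upper <- c(x0 == ub & ub > lb, rep(FALSE, m))
  is_basic <- logical(N); is_basic[basis] <- TRUE

  run_phase <- function(cost, x, basis, is_basic, at_upper, hi) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "iteration_limit", x = x, basis = basis,
                    is_basic = is_basic, at_upper = at_upper))
      B <- Aa[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y))
        return(list(status = "singular", x = x, basis = basis,
                    is_basic = is_basic, at_upper = at_upper))
      nonbasic <- which(!is_basic & (hi - lo > tol))
      d <- cost[nonbasic] - as.numeric(crossprod(Aa[, nonbasic, drop = FALSE], y))
      improving <- (d < -tol & !at_upper[nonbasic]) |
                   (d > tol & at_upper[nonbasic])
      if (!any(improving))
        return(list(status = "optimal", x = x, basis = basis,
                    is_basic = is_basic, at_upper = at_upper))
      e <- nonbasic[improving][1]          # Bland: smallest index
      dir <- if (at_upper[e]) -1 else 1    # entering moves off its bound
      w <- as.numeric(solve(B, Aa[, e])) * dir
      ## max step before a basic variable or the entering bound blocks
      t_max <- hi[e] - lo[e]
      block <- 0L                          # 0 = entering hits other bound
      for (k in seq_along(basis)) {
        i <- basis[k]
        if (w[k] > tol) {
          tk <- (x[i] - lo[i]) / w[k]
        } else if (w[k] < -tol) {
          tk <- (x[i] - hi[i]) / w[k]
        } else next
        if (tk < t_max - tol ||
            (tk < t_max + tol && block > 0L && i < basis[block])) {
          t_max <- max(tk, 0); block <- k
        }
      }
      x[basis] <- x[basis] - t_max * w
      x[e] <- x[e] + dir * t_max
      if (block == 0L) {
        at_upper[e] <- !at_upper[e]        # bound flip, basis unchanged
      } else {
        leave <- basis[block]
        wl <- w[block]
        at_upper[leave] <- wl < 0          # w > 0: fell to lower bound
        x[leave] <- if (wl > 0) lo[leave] else hi[leave]
        is_basic[leave] <- FALSE
        is_basic[e] <- TRUE
        at_upper[e] <- FALSE
        basis[block] <- e
      }
    }
  }

  ## phase 1: drive artificials to zero
  p1 <- run_phase(c(rep(0, n), rep(1, m)), x, basis, is_basic, at_upper, hi)
  if (p1$status != "optimal")
    return(list(status = "failed", objective = NA_real_, x = NULL))
  if (sum(p1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ## freeze artificials (redundant rows may keep them basic at zero)
  hi[n + seq_len(m)] <- 0
  x <- p1$x; x[n + seq_len(m)] <- 0

  p2 <- run_phase(c(cc, rep(0, m)), x, p1$basis, p1$is_basic, p1$at_upper, hi)
  if (p2$status != "optimal")
    return(list(status = "failed", objective = NA_real_, x = NULL))
  xs <- p2$x[seq_len(n)]
  xs <- pmin(pmax(xs, lb), ub)   # clip tolerance-level bound violations
  obj <- sum(cc * xs) * (if (maximize) -1 else 1)
  list(status = "optimal", objective = obj, x = xs)
}
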