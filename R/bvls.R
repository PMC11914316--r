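#' Bounded-variable linear least squares
#'
#' Solves `min ||A x - b||^2` subject to `lower <= x <= upper` with an
#' active-set method on the normal equations (the bounded-variable analogue
#' of Lawson-Hanson nonnegative least squares). Used for the linearized
#' subproblem inside the Levenberg-Marquardt iteration, where the problem
#' is small (<= 14 unknowns) and, with a positive damping term stacked into
#' `A`, strictly convex.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param lower,upper Bound vectors (length n); `lower <= upper`, and the
#'   zero vector need not be feasible.
#' @param max_pass Safety cap on active-set changes.
#' @return List with `x` (the solution), `active` (signed active-bound
#'   indicator: -1 lower, 0 free, +1 upper).
#' @export
bvls <- function(A, b, lower, upper, max_pass = 200L) {
  n <- ncol(A)
  stopifnot(length(lower) == n, length(upper) == n, all(lower <= upper))
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  x <- pmin(pmax(0, lower), upper)
  free <- !(upper == lower) # degenerate intervals stay fixed
  x[!free] <- lower[!free]
  tol <- 1e-12 * max(1, max(abs(Atb)))
  solve_free <- function(free, x) {
    f <- which(free)
    rhs <- Atb[f] - if (length(f) < n) AtA[f, -f, drop = FALSE] %*% x[-f] else 0
    M <- AtA[f, f, drop = FALSE]
    z <- tryCatch(drop(solve(M, rhs)),
                  error = function(e) drop(qr.solve(M + diag(1e-10 * max(diag(M)), length(f)), rhs)))
    z
  }
  for (pass in seq_len(max_pass)) {
    if (any(free)) {
      repeat {
        f <- which(free)
        z <- solve_free(free, x)
        lo <- lower[f]; hi <- upper[f]
        if (all(z >= lo - 1e-14) && all(z <= hi + 1e-14)) {
          x[f] <- pmin(pmax(z, lo), hi)
          break
        }
        # step from x towards z, stopping at the first bound hit
        d <- z - x[f]
        alpha <- 1
        hit <- 0L
        for (q in seq_along(f)) {
          if (d[q] > 0 && z[q] > hi[q]) a <- (hi[q] - x[f[q]]) / d[q]
          else if (d[q] < 0 && z[q] < lo[q]) a <- (lo[q] - x[f[q]]) / d[q]
          else next
          if (a < alpha) { alpha <- a; hit <- q }
        }
        x[f] <- x[f] + alpha * d
        if (hit == 0L) { # numerical corner: clamp and stop
          x[f] <- pmin(pmax(x[f], lo), hi)
          break
        }
        q <- f[hit]
        x[q] <- if (d[hit] > 0) upper[q] else lower[q]
        free[q] <- FALSE
        if (!any(free)) break
      }
    }
    # KKT check at bound variables: free the most negative multiplier
    gradient <- drop(AtA %*% x) - Atb # 1/2 gradient of the objective
    cand_lo <- which(!free & x <= lower + 1e-14 & upper > lower & gradient < -tol)
    cand_hi <- which(!free & x >= upper - 1e-14 & upper > lower & gradient > tol)
    if (length(cand_lo) == 0 && length(cand_hi) == 0) break
    viol <- c(-gradient[cand_lo], gradient[cand_hi])
    pick <- c(cand_lo, cand_hi)[which.max(viol)]
    free[pick] <- TRUE
  }
  list(x = x, active = ifelse(free, 0L, ifelse(x <= lower + 1e-14, -1L, 1L)))
}
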