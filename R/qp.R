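## Exact minimum-norm flux solver.
##
## pFBA's quadratic program  min ||v||^2  s.t.  S v = 0, lb <= v <= ub
## has special structure: with any working set of active bounds, the
## equality-constrained subproblem "minimise the norm subject to S v = 0
## and v_i fixed at its bound" is solved exactly by a pseudoinverse. A
## textbook primal active-set loop around that subproblem is therefore
## both simple and numerically sturdy, which matters because the measured
## conditions routinely pin many variables (l = u) and leave the active
## set highly degenerate.

#' Minimise the squared flux norm over a box-constrained null space
#'
#' Solves \eqn{\min \sum_j v_j^2} subject to \eqn{S v = 0} and
#' \eqn{l \le v \le u} with a primal active-set method whose subproblems
#' are pseudoinverse solves. The strictly convex objective makes the
#' solution unique; the algorithm is deterministic.
#'
#' @param S constraint matrix (need not have full row rank).
#' @param lb,ub finite bounds.
#' @param tol numerical tolerance.
#' @param maxit iteration cap.
#' @return list(status, x) with status \code{"optimal"} or
#'   \code{"infeasible"}.
#' @keywords internal
qpMinNorm <- function(S, lb, ub, tol = 1e-9, maxit = 1000L) {
  n <- ncol(S)
  ## independent rows only
  qrS <- qr(t(S))
  Sred <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  m <- nrow(Sred)

  ## feasible start from the LP phase-1 machinery
  start <- lpSolve2(rep(0, n), Sred, rep(0, m), lb, ub)
  if (start$status != "optimal")
    return(list(status = "infeasible", x = rep(NA_real_, n)))
  x <- pmin(pmax(start$x, lb), ub)

  pinnedVar <- ub - lb < 1e-12
  ## working set: named integer of active bounds, value +1 upper, -1 lower
  side <- integer(n)
  side[pinnedVar] <- -1L
  side[!pinnedVar & abs(x - lb) < tol] <- -1L
  side[!pinnedVar & abs(x - ub) < tol & side == 0L] <- 1L

  solveSub <- function(side) {
    act <- which(side != 0L)
    Ew <- matrix(0, length(act), n)
    if (length(act)) Ew[cbind(seq_along(act), act)] <- 1
    Eq <- rbind(Sred, Ew)
    beq <- c(rep(0, m),
             ifelse(side[act] < 0, lb[act], ub[act]))
    as.vector(MASS::ginv(Eq) %*% beq)
  }

  for (it in seq_len(maxit)) {
    q <- solveSub(side)
    p <- q - x
    if (max(abs(p)) < 1e-10) {
      ## multipliers from the stationarity rows of the inactive variables
      act <- which(side != 0L & !pinnedVar)
      inact <- which(side == 0L)
      y <- if (length(inact)) {
        M <- t(Sred)[inact, , drop = FALSE]
        co <- qr.coef(qr(M), 2 * x[inact])
        co[is.na(co)] <- 0
        co
      } else rep(0, m)
      g <- 2 * x - as.vector(t(Sred) %*% y)
      ## lower-active needs g >= 0, upper-active needs g <= 0
      viol <- numeric(0); who <- integer(0)
      if (length(act)) {
        lowBad <- act[side[act] < 0 & g[act] < -1e-7]
        upBad <- act[side[act] > 0 & g[act] > 1e-7]
        who <- c(lowBad, upBad)
        viol <- c(-g[lowBad], g[upBad])
      }
      if (!length(who)) {
        return(list(status = "optimal", x = x))
      }
      side[who[which.max(viol)]] <- 0L       # drop the worst violator
    } else {
      ## longest feasible step along p
      alpha <- 1; block <- 0L; blockSide <- 0L
      for (j in which(side == 0L)) {
        if (p[j] > tol) {
          aj <- (ub[j] - x[j]) / p[j]
          if (aj < alpha - 1e-12) { alpha <- aj; block <- j; blockSide <- 1L }
        } else if (p[j] < -tol) {
          aj <- (lb[j] - x[j]) / p[j]
          if (aj < alpha - 1e-12) { alpha <- aj; block <- j; blockSide <- -1L }
        }
      }
      x <- pmin(pmax(x + max(alpha, 0) * p, lb), ub)
      if (block > 0L) side[block] <- blockSide
    }
  }
  stop("qpMinNorm: iteration limit reached")
}
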