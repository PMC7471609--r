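## Dense bounded-variable two-phase primal simplex.
##
## Solves   min/max  obj'x   s.t.  A x = rhs,  lb <= x <= ub
## with finite lower bounds and possibly infinite upper bounds.
## Bland's smallest-index rule throughout, so the method terminates on
## degenerate bases; problem sizes here (tens of reactions) make the
## O(m^3)-per-iteration basis solves irrelevant.

#' Solve a bounded-variable linear program
#'
#' Minimises or maximises the linear objective subject to the equality system
#' \code{A x = rhs} and box constraints \code{lb <= x <= ub}. This is the
#' computational core behind [fba()], [fva()] and the loopless
#' flux-variability branch-and-bound; it is exported because the screening
#' and fitting modules reuse it for small bespoke programs.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param rhs right-hand side (length m).
#' @param lb,ub variable bounds; \code{lb} must be finite, \code{ub} may be
#'   \code{Inf}.
#' @param maximize logical; maximise instead of minimise.
#' @param tol reduced-cost / pivot tolerance.
#' @param maxit iteration cap per phase.
#' @return list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{x} (primal solution,
#'   length n), \code{objective} (on the requested sense) and
#'   \code{unbounded_var} (index of an unbounded direction when relevant).
#' @keywords internal
#' @export
lpSolve2 <- function(obj, A, rhs, lb, ub, maximize = FALSE,
                     tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("lpSolve2: lower bounds must be finite")
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, unbounded_var = NA_integer_))
  }
  cvec <- if (maximize) -obj else obj

  ## augment with one artificial per row
  xN0 <- lb
  resid <- rhs - as.vector(A %*% xN0)
  sgn <- ifelse(resid >= 0, 1, -1)
  Abig <- cbind(A, diag(sgn, m, m))
  nt <- n + m
  lbb <- c(lb, rep(0, m))
  ubb <- c(ub, rep(Inf, m))

  ## state: basis = indices of basic vars (initially the artificials);
  ## atUpper[j] for nonbasic structural vars (all start at lower bound)
  basis <- (n + 1L):nt
  atUpper <- rep(FALSE, nt)

  runPhase <- function(cost, basis, atUpper, lbb, ubb) {
    for (it in seq_len(maxit)) {
      nonb <- setdiff(seq_len(nt), basis)
      xN <- ifelse(atUpper[nonb], ubb[nonb], lbb[nonb])
      B <- Abig[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) stop("lpSolve2: singular basis")
      xB <- as.vector(Binv %*% (rhs - Abig[, nonb, drop = FALSE] %*% xN))
      y <- as.vector(crossprod(Binv, cost[basis]))
      dvec <- cost[nonb] - as.vector(crossprod(Abig[, nonb, drop = FALSE], y))
      elig <- (!atUpper[nonb] & dvec < -tol) | (atUpper[nonb] & dvec > tol)
      if (!any(elig)) {
        return(list(status = "optimal", basis = basis, atUpper = atUpper,
                    xB = xB, nonb = nonb, xN = xN))
      }
      q <- nonb[elig][which.min(nonb[elig])]        # Bland
      fromUpper <- atUpper[q]
      w <- as.vector(Binv %*% Abig[, q])
      if (fromUpper) w <- -w                        # entering var decreases
      ## ratio test over basic variables
      cand_i <- integer(0); cand_t <- numeric(0); cand_to <- character(0)
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (w[i] > tol) {                           # xB[i] decreases
          cand_i <- c(cand_i, i)
          cand_t <- c(cand_t, max(0, (xB[i] - lbb[bi]) / w[i]))
          cand_to <- c(cand_to, "L")
        } else if (w[i] < -tol && is.finite(ubb[bi])) {  # xB[i] increases
          cand_i <- c(cand_i, i)
          cand_t <- c(cand_t, max(0, (ubb[bi] - xB[i]) / (-w[i])))
          cand_to <- c(cand_to, "U")
        }
      }
      tmax <- if (length(cand_t)) min(cand_t) else Inf
      leave <- NA_integer_; leaveTo <- NA_character_
      if (is.finite(tmax)) {
        tie <- which(cand_t <= tmax + 1e-12)
        pick <- tie[which.min(basis[cand_i[tie]])]  # Bland on leaving index
        leave <- cand_i[pick]; leaveTo <- cand_to[pick]
      }
      span <- ubb[q] - lbb[q]                       # bound-flip limit
      flip <- is.finite(span) && span < tmax - 1e-12
      if (flip) tmax <- span
      if (!is.finite(tmax)) {
        return(list(status = "unbounded", var = q))
      }
      if (flip) {
        atUpper[q] <- !atUpper[q]
      } else {
        atUpper[q] <- FALSE
        bi <- basis[leave]
        atUpper[bi] <- (leaveTo == "U")
        basis[leave] <- q
      }
    }
    stop("lpSolve2: iteration limit reached")
  }

  ## phase 1: minimise sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- runPhase(c1, basis, atUpper, lbb, ubb)
  if (p1$status != "optimal")
    stop("lpSolve2: phase 1 unbounded (internal error)")
  art <- p1$basis > n
  artVal <- sum(pmax(p1$xB[art], 0))
  xfull <- numeric(nt)
  xfull[p1$nonb] <- p1$xN; xfull[p1$basis] <- p1$xB
  if (artVal > 1e-7 || sum(xfull[(n + 1L):nt]) > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, unbounded_var = NA_integer_))
  }

  ## phase 2: pin artificials to zero, optimise true objective
  ubb[(n + 1L):nt] <- 0
  c2 <- c(cvec, rep(0, m))
  p2 <- runPhase(c2, p1$basis, p1$atUpper, lbb, ubb)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = if (maximize) Inf else -Inf,
                unbounded_var = if (p2$var <= n) p2$var else NA_integer_))
  }
  xfull <- numeric(nt)
  xfull[p2$nonb] <- p2$xN; xfull[p2$basis] <- p2$xB
  x <- xfull[seq_len(n)]
  objv <- sum(obj * x)
  list(status = "optimal", x = x, objective = objv,
       unbounded_var = NA_integer_)
}
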