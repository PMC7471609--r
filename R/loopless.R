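## Loopless FVA: mixed-integer exclusion of thermodynamically infeasible
## internal cycles, solved by depth-first branch-and-bound over the binary
## flux-direction variables with the bounded-variable simplex as
## relaxation solver.
##
## For each internal reaction j (not an exchange, biomass variant or the
## ATP-hydrolysis pseudo-reaction) a binary a_j and a potential G_j are
## introduced with big-M = 1000:
##   v_j <= 1000 a_j,        v_j >= -1000 (1 - a_j)
##   a_j = 1  =>  G_j in [-1000, -1];   a_j = 0  =>  G_j in [1, 1000]
##   N' G = 0 for N a basis of the null space of the internal
##   stoichiometric matrix (so no internal cycle can carry flux in a
##   direction with all potentials decreasing).

buildLooplessProgram <- function(model) {
  S <- model@stoich
  rid <- colnames(S)
  n <- length(rid)
  exempt <- union(exchangeReactions(model),
                  c(model@biomassVariants,
                    if (!is.na(model@atpmReaction)) model@atpmReaction))
  internal <- setdiff(rid, exempt)
  ni <- length(internal)
  ii <- match(internal, rid)
  Nmat <- NULL
  if (ni) {
    Sint <- S[, ii, drop = FALSE]
    Nmat <- MASS::Null(t(Sint))      # basis of { z : Sint z = 0 }
    if (!is.null(Nmat) && ncol(Nmat) == 0) Nmat <- NULL
  }
  nz <- if (is.null(Nmat)) 0L else ncol(Nmat)

  ## variable layout: v (n) | a (ni) | G (ni) | slacks (4 ni)
  nv <- n + 2L * ni + 4L * ni
  iA <- function(k) n + k          # a_k
  iG <- function(k) n + ni + k     # G_k
  iS <- function(block, k) n + 2L * ni + (block - 1L) * ni + k

  m <- nrow(S)
  nrows <- m + 4L * ni + nz
  A <- matrix(0, nrows, nv)
  rhs <- numeric(nrows)
  A[seq_len(m), seq_len(n)] <- S
  for (k in seq_len(ni)) {
    j <- ii[k]
    r1 <- m + k                    # v_j - 1000 a_k + s1 = 0
    A[r1, j] <- 1; A[r1, iA(k)] <- -1000; A[r1, iS(1, k)] <- 1
    r2 <- m + ni + k               # v_j - 1000 a_k - s2 = -1000  => v_j >= -1000 (1 - a_k)
    A[r2, j] <- 1; A[r2, iA(k)] <- -1000; A[r2, iS(2, k)] <- -1
    rhs[r2] <- -1000
    r3 <- m + 2L * ni + k          # G_k + 1001 a_k + s3 = 1000
    A[r3, iG(k)] <- 1; A[r3, iA(k)] <- 1001; A[r3, iS(3, k)] <- 1
    rhs[r3] <- 1000
    r4 <- m + 3L * ni + k          # G_k + 1001 a_k - s4 = 1
    A[r4, iG(k)] <- 1; A[r4, iA(k)] <- 1001; A[r4, iS(4, k)] <- -1
    rhs[r4] <- 1
  }
  if (nz)
    A[m + 4L * ni + seq_len(nz), n + ni + seq_len(ni)] <- t(Nmat)

  lb <- c(unname(model@lb), rep(0, ni), rep(-1000, ni), rep(0, 4L * ni))
  ub <- c(unname(model@ub), rep(1, ni), rep(1000, ni), rep(Inf, 4L * ni))
  list(A = A, rhs = rhs, lb = lb, ub = ub, n = n, ni = ni,
       aIdx = if (ni) (n + 1L):(n + ni) else integer(0), rid = rid)
}

## branch-and-bound for max/min of one flux over the loopless space
solveLooplessLP <- function(prog, cvec, maximize) {
  best <- list(obj = if (maximize) -Inf else Inf, x = NULL)
  intTol <- 1e-6
  recurse <- function(lb, ub) {
    r <- lpSolve2(cvec, prog$A, prog$rhs, lb, ub, maximize = maximize)
    if (r$status != "optimal") return(invisible(NULL))
    if (maximize && r$objective <= best$obj + 1e-9) return(invisible(NULL))
    if (!maximize && r$objective >= best$obj - 1e-9) return(invisible(NULL))
    av <- r$x[prog$aIdx]
    frac <- abs(av - round(av))
    if (!length(frac) || max(frac) < intTol) {
      best <<- list(obj = r$objective, x = r$x)
      return(invisible(NULL))
    }
    k <- which.max(frac)
    vi <- prog$aIdx[k]
    ## branch a_k = round toward the relaxation value first
    first <- if (av[k] >= 0.5) 1 else 0
    for (val in c(first, 1 - first)) {
      lb2 <- lb; ub2 <- ub
      lb2[vi] <- val; ub2[vi] <- val
      recurse(lb2, ub2)
    }
  }
  recurse(prog$lb, prog$ub)
  best
}

fvaLoopless <- function(model, reactions) {
  prog <- buildLooplessProgram(model)
  nv <- ncol(prog$A)
  res <- lapply(reactions, function(j) {
    cvec <- numeric(nv)
    cvec[match(j, prog$rid)] <- 1
    lo <- solveLooplessLP(prog, cvec, maximize = FALSE)
    hi <- solveLooplessLP(prog, cvec, maximize = TRUE)
    if (is.null(lo$x) || is.null(hi$x))
      stop("loopless FVA infeasible")
    c(lo$obj, hi$obj)
  })
  new("FluxRange",
      ranges = data.frame(reaction = reactions,
                          min = vapply(res, `[`, numeric(1), 1),
                          max = vapply(res, `[`, numeric(1), 2),
                          status = "ok", stringsAsFactors = FALSE),
      loopless = TRUE)
}
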