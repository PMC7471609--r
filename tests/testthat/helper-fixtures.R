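## Shared test fixtures, all built in code.

## tiny hand-solvable chain model: EX_A (uptake <= 10), A -> B, EX_B
chainModel3 <- function() {
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "B_e"),
                     name = "", formula = "",
                     charge = NA_integer_,
                     compartment = c("e", "c", "c", "e"),
                     stringsAsFactors = FALSE)
  makeModel("chain3", mets, list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -10, ub = 0),
    list(id = "T_A", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
    list(id = "R1", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000),
    list(id = "T_B", stoich = c(B_c = -1, B_e = 1), lb = 0, ub = 1000),
    list(id = "EX_B", stoich = c(B_e = -1), lb = 0, ub = 1000)))
}

## chain toy plus a dead-end metabolite fed by one reaction
deadEndModel <- function() {
  m <- toyModel()
  mets <- rbind(m@mets,
                data.frame(id = "dead_c", name = "", formula = "",
                           charge = NA_integer_, compartment = "c",
                           stringsAsFactors = FALSE))
  rxns <- lapply(reactionIds(m), function(j) {
    st <- m@stoich[, j]; st <- st[st != 0]
    list(id = j, name = j, stoich = st, lb = m@lb[[j]], ub = m@ub[[j]],
         gpr = deparseGPR(m@gpr[[j]]))
  })
  rxns <- c(rxns, list(list(id = "DEADR", stoich = c(sub_c = -1, dead_c = 1),
                            lb = 0, ub = 1000, gpr = "gDead")))
  makeModel("dead_end", mets, rxns,
            biomassVariants = biomassVariants(m), atpmReaction = "ATPM")
}

## metabolite table with real chemistry for balance tests
chemModel <- function() {
  mets <- data.frame(
    id = c("glc_c", "etoh_c", "co2_c", "atp_c", "adp_c", "pi_c",
           "h_c", "h2o_c", "fe2_c"),
    name = "",
    formula = c("C6H12O6", "C2H6O", "CO2", "C10H12N5O13P3",
                "C10H12N5O10P2", "HO4P", "H", "H2O", "Fe"),
    charge = c(0L, 0L, 0L, -4L, -3L, -2L, 1L, 0L, 2L),
    compartment = "c", stringsAsFactors = FALSE)
  makeModel("chem", mets, list(
    list(id = "FERM", stoich = c(glc_c = -1, etoh_c = 2, co2_c = 2)),
    list(id = "ATPH", stoich = c(atp_c = -1, h2o_c = -1, adp_c = 1,
                                 pi_c = 1)),
    list(id = "ATPH_OK", stoich = c(atp_c = -1, h2o_c = -1, adp_c = 1,
                                    pi_c = 1, h_c = 1)),
    list(id = "BADC", stoich = c(glc_c = -1, co2_c = 5)),
    list(id = "FEH", stoich = c(fe2_c = -1, h_c = 2))),
    compartments = c(c = "cytosol"))
}

## random GPR tree over a gene pool, for property tests
randomGPR <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(sample(genes, 1))
  nargs <- sample(2:3, 1)
  list(op = sample(c("and", "or"), 1),
       args = lapply(seq_len(nargs), function(i) randomGPR(genes, depth - 1)))
}

## brute-force LP oracle: enumerate basic solutions of
## max c'x s.t. A x = b, lb <= x <= ub  (small n only)
bruteForceLP <- function(cvec, A, b, lb, ub) {
  keep <- qr(t(A))$pivot[seq_len(qr(t(A))$rank)]   # independent rows only
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  n <- ncol(A); m <- nrow(A)
  best <- -Inf
  combs <- utils::combn(n, min(m, n), simplify = FALSE)
  for (Bset in combs) {
    Nset <- setdiff(seq_len(n), Bset)
    Bm <- A[, Bset, drop = FALSE]
    if (abs(det(Bm)) < 1e-10) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(Nset)))
    if (!nrow(grid)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xN <- ifelse(unlist(grid[g, ]), ub[Nset], lb[Nset])
      if (length(Nset) == 0) xN <- numeric(0)
      rhs <- b - if (length(Nset)) A[, Nset, drop = FALSE] %*% xN else 0
      xB <- solve(Bm, rhs)
      x <- numeric(n); x[Bset] <- xB; x[Nset] <- xN
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8))
        best <- max(best, sum(cvec * x))
    }
  }
  best
}
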