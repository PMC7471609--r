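test_that("growth percentages and the lethality call behave", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  ## empty deletion set: exactly 100%
  r0 <- mutantGrowthPercent(m, cond, character(0))
  expect_equal(r0$percent, 100)
  expect_false(r0$lethal)
  ## maturase deletion reroutes but survives
  r1 <- mutantGrowthPercent(m, cond, "gMat")
  expect_equal(r1$percent, 80, tolerance = 1e-6)
  expect_false(r1$lethal)
  ## removing the remaining ferredoxin sink as well is lethal
  r2 <- mutantGrowthPercent(m, cond, c("gMat", "gEch"))
  expect_equal(r2$percent, 0, tolerance = 1e-6)
  expect_true(r2$lethal)
})

test_that("an external electron sink rescues the lethal mutant", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  rs <- rescueScreen(m, cond, c("gMat", "gEch"), c(EX_so4_e = 1000))
  expect_true(rs$rescued)
  expect_gt(rs$percent, 20)
  ## percent is relative to the unsupplemented wild type
  expect_equal(rs$wt_growth, mutantGrowthPercent(m, cond,
                                                 character(0))$wt_growth)
  expect_error(rescueScreen(m, cond, "gMat", c(EX_unknown_e = 10)),
               "absent from model")
})

test_that("opening an extra uptake never decreases growth", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  set.seed(17)
  sinks <- c("EX_so4_e", "EX_etoh_e", "EX_ac_e", "EX_h2_e")
  for (i in 1:10) {
    genes <- sample(geneIds(m), sample(0:2, 1))
    base <- tryCatch(
      mutantGrowthPercent(m, cond, genes)$mut_growth, error = function(e) 0)
    extra <- sample(sinks, 1)
    cond2 <- cond
    cond2@uptake[extra] <- 1000
    withSupp <- tryCatch(
      mutantGrowthPercent(m, cond2, genes)$mut_growth, error = function(e) 0)
    expect_gte(withSupp, base - 1e-9)
  }
})

test_that("percent of wild type is non-increasing under deletion supersets", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  set.seed(29)
  genes <- geneIds(m)
  for (trial in 1:50) {
    chain <- sample(genes, 3)
    pcts <- vapply(1:3, function(k)
      mutantGrowthPercent(m, cond, chain[1:k])$percent, numeric(1))
    expect_true(all(diff(pcts) <= 1e-9))
  }
})

test_that("the deletion scan equals exhaustive re-solving", {
  m <- toyModel(chainLength = 2, nRoutes = 2)   # 12 reactions
  cond <- toyCondition(m)
  got <- reactionDeletionScan(m, cond, character(0), threshold = 0.20)
  ## oracle: brute-force re-solve for every closable reaction
  mm <- applyCondition(m, cond)
  wt <- fba(mm, "BIOMASS_CELLOBIOSE")@objective
  closed <- reactionIds(mm)[mm@lb == 0 & mm@ub == 0]
  targets <- setdiff(reactionIds(mm), c(closed, "BIOMASS_CELLOBIOSE"))
  oracle <- vapply(targets, function(j) {
    m2 <- setBounds(mm, j, lb = 0, ub = 0)
    s <- tryCatch(fba(m2, "BIOMASS_CELLOBIOSE")@objective,
                  error = function(e) 0)
    s
  }, numeric(1))
  expected <- sort(names(oracle)[oracle < 0.2 * wt])
  expect_setequal(got$reaction, expected)
  expect_equal(got$growth[order(got$reaction)],
               unname(oracle[sort(got$reaction)]), tolerance = 1e-6)
})

test_that("a vanishing threshold selects exactly the biomass-disconnecting cuts", {
  m <- toyModel(chainLength = 2, nRoutes = 2)
  cond <- toyCondition(m)
  got <- reactionDeletionScan(m, cond, character(0), threshold = 1e-9)
  ## graph argument: the chain and uptake are single points of failure,
  ## the parallel routes and the secretion valve are not; the ATP
  ## hydrolysis sink is also essential because the chain yields more ATP
  ## than biomass consumes, and the surplus must go somewhere
  expect_setequal(got$reaction, c("EX_sub_e", "SUBt", "CH1", "CH2", "ATPM"))
})

test_that("already-closed reactions never become candidates", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  got <- reactionDeletionScan(m, cond, "gMat")
  expect_false(any(c("BIF", "H2ASE") %in% got$reaction))
  expect_false("EX_so4_e" %in% got$reaction)     # closed by the medium
})

test_that("screening without viable wild type is rejected", {
  m <- toyModel()
  cond <- toyCondition(m)
  cond@uptake <- numeric(0)        # nothing to eat
  expect_error(mutantGrowthPercent(m, cond, "gT"), "zero or infeasible")
})
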