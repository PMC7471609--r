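test_that("FBA reproduces hand-computed chain yields", {
  m3 <- chainModel3()
  expect_equal(fba(m3, "EX_B")@objective, 10)       # uptake-limited
  m <- toyModel()
  mm <- applyCondition(m, toyCondition(m))
  expect_equal(fba(mm, "BIOMASS_CELLOBIOSE")@objective, 10)
  expect_error(fba(mm, "NOPE"), "not in model")
  expect_error(fba(mm, stats::setNames(0, "CH1")), "nonzero")
})

test_that("FBA with pinned growth matches the enumeration oracle", {
  ## growth fixed, maximise ATP hydrolysis; oracle enumerates vertices
  m <- toyModel(chainLength = 1, nRoutes = 1)
  mm <- applyCondition(m, toyCondition(m))
  mm <- setBounds(mm, c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                  lb = c(-10, 0.3), ub = c(-10, 0.3))
  got <- fba(mm, "ATPM")@objective
  cvec <- as.numeric(reactionIds(mm) == "ATPM")
  ref <- bruteForceLP(cvec, stoichiometry(mm),
                      rep(0, length(metaboliteIds(mm))),
                      unname(lowerBounds(mm)), unname(upperBounds(mm)))
  expect_equal(got, ref, tolerance = 1e-8)
  expect_equal(got, 4 * 10 - 2 * 0.3)               # hand value
})

test_that("inconsistent bounds raise an infeasibility error", {
  m <- toyModel()
  mm <- applyCondition(m, toyCondition(m))
  mm@lb[["EX_sub_e"]] <- 5        # demand uptake secretion simultaneously
  mm@ub[["EX_sub_e"]] <- 5
  mm@lb[["BIOMASS_CELLOBIOSE"]] <- 3
  expect_error(fba(mm, "BIOMASS_CELLOBIOSE"), "infeasible")
})

test_that("every distribution satisfies mass balance", {
  m <- toyModel(includeRedox = TRUE)
  mm <- applyCondition(m, toyCondition(m))
  S <- stoichiometry(mm)
  for (sol in list(fba(mm, "BIOMASS_CELLOBIOSE"),
                   pfba(setBounds(mm, "BIOMASS_CELLOBIOSE", lb = 3, ub = 3)))) {
    expect_lt(max(abs(S %*% fluxes(sol))), 1e-6)
    v <- fluxes(sol)
    expect_true(all(v >= lowerBounds(mm)[names(v)] - 1e-6))
    expect_true(all(v <= upperBounds(mm)[names(v)] + 1e-6))
  }
})

test_that("quadratic pFBA is unique, symmetric and norm-optimal", {
  m <- toyModel()                  # two parallel routes
  mm <- applyCondition(m, toyCondition(m))
  mm <- setBounds(mm, c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                  lb = c(-10, 10), ub = c(-10, 10))
  p1 <- pfba(mm); p2 <- pfba(mm)
  ## identical demand splits evenly over identical routes
  expect_equal(fluxes(p1)[["RT1"]], fluxes(p1)[["RT2"]], tolerance = 1e-8)
  expect_equal(fluxes(p1)[["RT1"]], 5, tolerance = 1e-6)
  ## chain carries the full uptake (no alternative)
  expect_equal(fluxes(p1)[["CH1"]], 10, tolerance = 1e-6)
  ## repeat solves agree
  expect_lt(max(abs(fluxes(p1) - fluxes(p2))), 1e-6)
  ## norm optimality vs an FBA vertex under identical constraints
  f <- fba(mm, "ATPM")
  expect_lte(sum(fluxes(p1)^2), sum(fluxes(f)^2) + 1e-6)
})

test_that("the min-norm solver agrees with an independent QP implementation", {
  ## dual route: our active-set solver vs quadprog on random feasible
  ## boxes where the dense QP formulation is well conditioned
  set.seed(61)
  for (i in 1:20) {
    n <- 8; mrow <- 4
    A <- matrix(sample(-2:2, mrow * n, TRUE), mrow, n)
    lb <- runif(n, -3, -1); ub <- runif(n, 1, 3)
    ref <- tryCatch(
      quadprog::solve.QP(diag(2, n), rep(0, n),
                         t(rbind(A, -A, diag(n), -diag(n))),
                         c(rep(0, 2 * mrow), lb, -ub), meq = 0)$solution,
      error = function(e) NULL)
    if (is.null(ref)) next
    mine <- fluxkit:::qpMinNorm(A, lb, ub)
    expect_equal(mine$status, "optimal")
    expect_lt(max(abs(mine$x - ref)), 1e-6)
  }
})

test_that("pFBA nests inside FVA ranges", {
  m <- toyModel(includeRedox = TRUE)
  cond <- toyCondition(m)
  mm <- applyCondition(m, cond)
  mm <- setBounds(mm, c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                  lb = c(-10, 4), ub = c(-10, 4))
  p <- pfba(mm)
  fr <- ranges(fva(mm))
  expect_true(all(fr$min - 1e-6 <= fluxes(p)[fr$reaction]))
  expect_true(all(fluxes(p)[fr$reaction] <= fr$max + 1e-6))
})

test_that("FVA brackets fixed chains and free parallel routes", {
  m <- toyModel()
  mm <- applyCondition(m, toyCondition(m))
  mm <- setBounds(mm, c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                  lb = c(-10, 10), ub = c(-10, 10))
  fr <- ranges(fva(mm, c("CH1", "CH2", "RT1", "RT2")))
  expect_equal(fr$min[1:2], c(10, 10), tolerance = 1e-6)
  expect_equal(fr$max[1:2], c(10, 10), tolerance = 1e-6)
  expect_equal(fr$min[3:4], c(0, 0), tolerance = 1e-6)
  expect_equal(fr$max[3:4], c(10, 10), tolerance = 1e-6)
})

test_that("loopless FVA zeroes a two-reaction cycle and nests in plain FVA", {
  m <- toyModel(includeCycle = TRUE)
  mm <- applyCondition(m, toyCondition(m))
  plain <- ranges(fva(mm, c("CYCA", "CYCB", "CH1")))
  ## the disconnected cycle can spin arbitrarily without loop exclusion
  expect_equal(plain$max[1:2], c(1000, 1000))
  ll <- ranges(fva(mm, c("CYCA", "CYCB", "CH1"), loopless = TRUE))
  expect_equal(ll$min, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(ll$max[1:2], c(0, 0), tolerance = 1e-6)
  ## chain fluxes are untouched by the loop constraints
  expect_equal(ll$max[3], plain$max[3], tolerance = 1e-6)
  ## loopless ranges nest inside plain ranges elementwise
  expect_true(all(ll$min >= plain$min - 1e-6))
  expect_true(all(ll$max <= plain$max + 1e-6))
})

test_that("blocked reactions are detected with open exchanges", {
  dm <- deadEndModel()
  b <- findBlockedReactions(dm)
  expect_true("DEADR" %in% b$blocked)   # dead-end metabolite forces zero
  expect_equal(b$percent, 100 * length(b$blocked) / length(reactionIds(dm)))
  ## a clean chain toy has no blocked reactions
  expect_length(findBlockedReactions(toyModel())$blocked, 0)
  ## doubling the exchange bound magnitude does not change the set
  b2 <- findBlockedReactions(dm, mag = 2000)
  expect_setequal(b$blocked, b2$blocked)
})
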