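test_that("maximum ATP yield matches stoichiometric hand values", {
  m <- toyModel()                        # 4 ATP per substrate
  cond <- toyCondition(m)
  cond@measured <- data.frame(reaction = c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                              mean = c(-10, 0), sd = c(0, 0))
  pt <- maxATPYield(m, cond)
  expect_equal(pt$atp, 40)               # uptake 10 x yield 4, growth 0
  ## with biomass ATP zeroed, growth only consumes precursor, not ATP
  cond@measured$mean <- c(-10, 5)
  expect_equal(maxATPYield(m, cond)$atp, 40)
  expect_equal(pt$growth, 0)
  ## zero uptake: zero ATP
  cond@measured$mean <- c(0, 0)
  expect_equal(maxATPYield(m, cond)$atp, 0)
  ## leaving the shipped GAM (2 ATP/gCDW) in place: growth mu = 10
  ## consumes 20 ATP-equivalents, leaving 40 - 20 = 20
  cond@measured$mean <- c(-10, 10)
  expect_equal(maxATPYield(m, cond, zeroGAM = FALSE)$atp, 20)
})

test_that("maximum ATP yield is monotone under tightening bounds", {
  m <- toyModel()
  cond <- toyCondition(m)
  cond@measured <- data.frame(reaction = c("EX_sub_e", "BIOMASS_CELLOBIOSE"),
                              mean = c(-8, 1), sd = c(2, 1))
  loose <- maxATPYield(m, cond)$atp
  cond@measured$sd <- c(1, 0.5)
  tight <- maxATPYield(m, cond)$atp
  expect_lte(tight, loose + 1e-9)
})

test_that("noiseless synthetic conditions recover GAM/NGAM exactly", {
  m <- toyModel()
  conds <- maintenanceDataset(m, gam = 60, ngam = 3,
                              growthRates = seq(0.05, 0.4, length.out = 8))
  pts <- do.call(rbind, lapply(conds, function(k) maxATPYield(m, k)))
  fit <- fitMaintenance(pts)
  expect_lt(abs(fit@gam - 60), 1e-8)
  expect_lt(abs(fit@ngam - 3), 1e-8)
  expect_equal(fit@n, 8L)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
})

test_that("noisy recovery lands within two standard errors", {
  m <- toyModel()
  conds <- maintenanceDataset(m, gam = 60, ngam = 3,
                              growthRates = seq(0.05, 0.5, length.out = 10),
                              noiseSd = 0.5, seed = 42)
  pts <- do.call(rbind, lapply(conds, function(k) maxATPYield(m, k)))
  fit <- fitMaintenance(pts)
  se <- summary(stats::lm(atp ~ growth, data = pts))$coefficients[, 2]
  expect_lt(abs(fit@gam - 60), 2 * se[["growth"]])
  expect_lt(abs(fit@ngam - 3), 2 * se[["(Intercept)"]])
})

test_that("flagged outliers are excluded and unflagged ones distort", {
  m <- toyModel()
  conds <- maintenanceDataset(m, gam = 60, ngam = 3,
                              growthRates = seq(0.05, 0.4, length.out = 8))
  pts <- do.call(rbind, lapply(conds, function(k) maxATPYield(m, k)))
  pts$atp[3] <- pts$atp[3] + 15          # plant a gross outlier
  unflagged <- fitMaintenance(pts)
  flagged <- fitMaintenance(pts, outliers = pts$label[3])
  expect_gt(abs(unflagged@gam - 60), 1e-6)
  expect_lt(abs(flagged@gam - 60), 1e-8)
  expect_equal(flagged@excluded, pts$label[3])
  expect_false(identical(unflagged@gam, flagged@gam))
})

test_that("the fit is order-invariant but duplication-sensitive (plain OLS)", {
  pts <- data.frame(label = paste0("p", 1:5),
                    growth = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    atp = c(9.1, 15.2, 20.8, 27.1, 32.9))
  f1 <- fitMaintenance(pts)
  f2 <- fitMaintenance(pts[sample(5), ])
  expect_equal(f1@gam, f2@gam)
  expect_equal(f1@ngam, f2@ngam)
  ## duplicating a point re-weights it: the fit legitimately moves
  f3 <- fitMaintenance(rbind(pts, pts[5, ]))
  expect_false(isTRUE(all.equal(f1@gam, f3@gam)))
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(fitMaintenance(data.frame(label = "a", growth = 1, atp = 5)),
               "at least 2")
  pts <- data.frame(label = c("a", "b", "c"), growth = c(0.1, 0.2, 0.3),
                    atp = c(0, 1, 2))           # intercept -1
  expect_warning(fitMaintenance(pts), "negative")
})

test_that("growth validation is self-consistent and class-sensitive", {
  m <- toyModel()
  conds <- maintenanceDataset(m, gam = 60, ngam = 3,
                              growthRates = seq(0.05, 0.4, length.out = 6))
  good <- list(`chemostat-cellobiose` = list(gam = 60, ngam = 3))
  vg <- validateGrowth(m, conds, good)
  expect_true(all(vg$table$status == "ok"))
  expect_gt(vg$r2, 0.99)
  expect_lt(max(abs(vg$table$predicted - vg$table$measured)), 1e-6)
  ## single condition: correlation undefined
  vg1 <- validateGrowth(m, conds[1], good)
  expect_true(is.na(vg1$r2))
  ## deliberately wrong-class parameters predict worse (a smaller GAM
  ## lets the same measured fluxes support faster predicted growth)
  wrong <- list(`chemostat-cellobiose` = list(gam = 30, ngam = 3))
  vgw <- validateGrowth(m, conds, wrong)
  errGood <- mean(abs(vg$table$predicted - vg$table$measured))
  errWrong <- mean(abs(vgw$table$predicted - vgw$table$measured))
  expect_gt(errWrong, errGood)
})
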