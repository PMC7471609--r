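test_that("model validity catches structural problems", {
  m <- toyModel()
  expect_error(makeModel("bad", m@mets, list(
    list(id = "R", stoich = c(nothere_c = 1)))), "undeclared species")
  bad <- m
  bad@lb[["CH1"]] <- 5; bad@ub[["CH1"]] <- 1
  expect_error(validObject(bad), "lower bound exceeds upper")
  expect_error(setBounds(m, "NOPE", lb = 0), "unknown reaction")
})

test_that("accessors expose the model components", {
  m <- toyModel(includeRedox = TRUE)
  expect_true("BIOMASS_CELLOBIOSE" %in% reactionIds(m))
  expect_true("atp_c" %in% metaboliteIds(m))
  expect_true(all(c("gMat", "gEch") %in% geneIds(m)))
  expect_setequal(exchangeReactions(m),
                  c("EX_sub_e", "EX_etoh_e", "EX_ac_e", "EX_h2_e",
                    "EX_so4_e", "EX_h2s_e"))
  expect_equal(unname(biomassVariants(m)[["cellulose"]]),
               "BIOMASS_CELLULOSE")
  expect_equal(atpmReaction(m), "ATPM")
  expect_output(show(m), "metabolites")
})

test_that("applying a condition configures biomass, NGAM, GAM and medium", {
  m <- toyModel()
  cond <- toyCondition(m)
  cond@ngam <- 1.5
  cond@gam <- 7
  mm <- applyCondition(m, cond)
  ## only the cellobiose biomass stays open
  expect_equal(unname(mm@ub[["BIOMASS_CELLOBIOSE"]]), 1000)
  expect_equal(unname(mm@ub[["BIOMASS_CELLULOSE"]]), 0)
  expect_equal(unname(mm@ub[["BIOMASS_NO_CELLULOSOME"]]), 0)
  ## NGAM as ATPM lower bound
  expect_equal(unname(mm@lb[["ATPM"]]), 1.5)
  ## GAM replaces the shipped biomass ATP coefficient (was 2)
  expect_equal(mm@stoich[["atp_c", "BIOMASS_CELLOBIOSE"]], -7)
  expect_equal(mm@stoich[["adp_c", "BIOMASS_CELLOBIOSE"]], 7)
  ## uptake: only the listed exchange opens
  expect_equal(unname(mm@lb[["EX_sub_e"]]), -10)
  expect_equal(unname(mm@ub[["EX_sub_e"]]), 0)
  expect_equal(unname(mm@lb[["EX_p_e"]]), 0)
  expect_equal(unname(mm@ub[["EX_p_e"]]), 1000)   # allowed secretion

  bad <- cond; bad@biomassVariant <- "martian"
  expect_error(applyCondition(m, bad), "biomass variant")
  bad2 <- cond; bad2@uptake <- c(EX_unknown_e = 5)
  expect_error(applyCondition(m, bad2), "unknown exchange")
})

test_that("cellulose conditions open the cellodextrin pseudo-reactions", {
  m <- toyModel(includeCellulose = TRUE)
  cond <- toyCondition(m)
  cond@carbonSource <- "cellulose"
  cond@biomassVariant <- "cellulose"
  cond@uptake <- c(EX_glceq_e = 40)
  mm <- applyCondition(m, cond)
  expect_equal(unname(mm@ub[["CLDX4"]]), 1000)
  expect_equal(unname(mm@ub[["BIOMASS_CELLULOSE"]]), 1000)
  expect_equal(unname(mm@ub[["BIOMASS_CELLOBIOSE"]]), 0)
  ## growth through the cellodextrin route is feasible
  sol <- fba(mm, "BIOMASS_CELLULOSE")
  expect_gt(sol@objective, 1)
  ## on cellobiose the pseudo-reactions stay closed
  mm2 <- applyCondition(m, toyCondition(m))
  expect_equal(unname(mm2@ub[["CLDX4"]]), 0)
})

test_that("measured bounds are mean plus/minus one sd", {
  m <- toyModel()
  cond <- toyCondition(m)
  cond@measured <- data.frame(reaction = c("EX_sub_e", "EX_p_e"),
                              mean = c(5, 5), sd = c(1, 0))
  b <- buildMeasuredBounds(m, cond)
  expect_equal(b$lb, c(4, 5))
  expect_equal(b$ub, c(6, 5))
  cond@measured$reaction[1] <- "EX_bogus"
  expect_error(buildMeasuredBounds(m, cond), "EX_bogus")
  cond@measured <- cond@measured[0, ]
  expect_error(buildMeasuredBounds(m, cond), "no measured table")
})

test_that("conditions round-trip through YAML", {
  m <- toyModel(includeRedox = TRUE)
  ds <- omicsDataset(m)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeCondition(ds$conditionWt, f)
  back <- readCondition(f, name = ds$conditionWt@name)
  expect_equal(back@reactorMode, ds$conditionWt@reactorMode)
  expect_equal(back@uptake, ds$conditionWt@uptake)
  expect_equal(back@secretion, ds$conditionWt@secretion)
  expect_equal(back@measured$mean, ds$conditionWt@measured$mean)
  expect_equal(back@ngam, ds$conditionWt@ngam)
})
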