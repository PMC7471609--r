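test_that("flooring pushes small magnitudes away from zero", {
  eps <- 1e-4
  expect_equal(floorValue(0.00005, eps), 0.00015)
  expect_equal(floorValue(-0.00005, eps), -0.00015)
  expect_equal(floorValue(0.5, eps), 0.5)
  expect_equal(floorValue(-0.5, eps), -0.5)
  expect_equal(floorValue(0, eps), eps)          # zero convention
  expect_equal(floorValue(eps, eps), eps)        # boundary passes through
  expect_error(floorValue(1, 0), "epsilon > 0")
})

test_that("simulated fold changes follow the log2-ratio arithmetic", {
  fc <- simulatedFoldChange(2, 1, 2, 2)$fc
  expect_equal(fc, 1)                            # log2(1) - log2(0.5)
  expect_equal(simulatedFoldChange(0, 0, 2, 2)$fc, 0)   # both floor to +eps
  expect_equal(simulatedFoldChange(1, 1, 2, 2)$fc, 0)   # identical ratios
  expect_match(simulatedFoldChange(0, 1, 2, 2)$flag, "floored_zero")
  expect_match(simulatedFoldChange(-1, 1, 2, 2)$flag, "sign_reversal")
  expect_error(simulatedFoldChange(1, 1, 0, 2), "zero substrate uptake")
})

test_that("simulated fold changes are antisymmetric away from the floor", {
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 0.01, 5) * sample(c(-1, 1), 1)
    b <- runif(1, 0.01, 5) * sample(c(-1, 1), 1)
    u <- runif(1, 1, 10)
    expect_equal(simulatedFoldChange(a, b, u, u)$fc,
                 -simulatedFoldChange(b, a, u, u)$fc, tolerance = 1e-12)
  }
})

test_that("FVA centers are midpoints bracketed by their interval", {
  expect_equal(fvaCenter(-1, 3), 1)
  expect_equal(fvaCenter(2, 2), 2)
  expect_equal(fvaCenter(-3, 3), 0)
  set.seed(4)
  lo <- runif(20, -5, 5); hi <- lo + runif(20, 0, 5)
  ctr <- fvaCenter(lo, hi)
  expect_true(all(lo <= ctr & ctr <= hi))
  expect_error(fvaCenter(3, -1))
})

test_that("gene fold changes map to reactions by the nonzero-gene mean", {
  m <- toyModel(includeRedox = TRUE)    # BIF GPR: gBif and gMat
  fcs <- c(gBif = 2, gMat = 0, gE = -1)
  tab <- mapGeneFoldChanges(m, fcs)
  bif <- tab[tab$reaction == "BIF", ]
  expect_equal(bif$fc_meas, 2)          # gMat measured-at-zero drops out
  expect_equal(bif$n_zero, 1)
  alcd <- tab[tab$reaction == "ALCD", ]
  expect_equal(alcd$fc_meas, -1)
  ## all genes unmeasured -> unmapped
  por <- tab[tab$reaction == "POR", ]
  expect_false(por$mapped)
  expect_equal(por$n_unmeasured, 1)
  ## a three-gene mean: {2, 0, -1} -> 0.5 over the nonzero pair
  m2 <- makeModel("t", data.frame(id = c("a_c", "b_c"), name = "",
                                  formula = "", charge = NA_integer_,
                                  compartment = "c"),
                  list(list(id = "R", stoich = c(a_c = -1, b_c = 1),
                            gpr = "g1 or g2 or g3")),
                  compartments = c(c = "cytosol"))
  tab2 <- mapGeneFoldChanges(m2, c(g1 = 2, g2 = 0, g3 = -1))
  expect_equal(tab2$fc_meas, 0.5)
  ## adding a zero-FC gene never changes the mean; a nonzero one updates it
  tab3 <- mapGeneFoldChanges(m2, c(g1 = 2, g3 = -1))
  expect_equal(tab3$fc_meas, tab2$fc_meas)
  tab4 <- mapGeneFoldChanges(m2, c(g1 = 2, g2 = 4, g3 = -1))
  expect_equal(tab4$fc_meas, (2 + 4 - 1) / 3)
})

test_that("consistency membership equals the brute-force sign table", {
  rec <- data.frame(fc_meas = 1, fc_pfba = -0.5, fc_fva = 0.2)
  expect_true(consistentReactions(rec))          # positive FVA witness
  expect_false(consistentReactions(
    data.frame(fc_meas = 1, fc_pfba = -1, fc_fva = 0)))
  expect_false(consistentReactions(
    data.frame(fc_meas = 0, fc_pfba = 5, fc_fva = 5)))  # strict sign
  set.seed(99)
  vals <- c(-1, -0.3, 0, 0.3, 1)
  rec <- data.frame(fc_meas = sample(vals, 1000, TRUE),
                    fc_pfba = sample(vals, 1000, TRUE),
                    fc_fva = sample(vals, 1000, TRUE))
  got <- consistentReactions(rec)
  oracle <- mapply(function(fm, fp, fv) {
    (fm < 0 && (fp < 0 || fv < 0)) || (fm > 0 && (fp > 0 || fv > 0))
  }, rec$fc_meas, rec$fc_pfba, rec$fc_fva)
  expect_identical(got, unname(oracle))
})

test_that("identical conditions with null omics give an empty consistent set", {
  m <- toyModel(includeRedox = TRUE)
  ds <- omicsDataset(m)
  geneFC0 <- data.frame(gene = geneIds(m), log2fc = 0)
  rep <- runFoldChangeProtocol(m, ds$conditionWt, ds$conditionWt,
                               character(0), geneFC0, ds$config)
  rec <- records(rep)
  expect_true(all(abs(rec$fc_pfba) < 1e-9))
  expect_true(all(abs(rec$fc_fva) < 1e-9))
  expect_equal(sum(rec$consistent), 0)
  expect_equal(unname(rep@counts["mapped"]), 0)
})

test_that("the protocol recovers a planted consistent set exactly", {
  m <- toyModel(includeRedox = TRUE)
  ds <- omicsDataset(m)
  rep <- runFoldChangeProtocol(m, ds$conditionWt, ds$conditionMut,
                               ds$deletions, ds$geneFC, ds$config)
  rec <- records(rep)
  expect_setequal(rec$reaction[rec$consistent], ds$expectedConsistent)
  expect_equal(unname(rep@correlations["pearson_pfba"]), 1,
               tolerance = 1e-9)
  ## report count invariants
  ct <- rep@counts
  expect_lte(ct[["consistent"]], ct[["mapped"]])
  expect_lte(ct[["mapped"]], ct[["total"]])
  ## the map-viewer table is the consistent subset
  esc <- escherTable(rep)
  expect_setequal(esc$reaction, ds$expectedConsistent)
})

test_that("sign-flipped gene fold changes drop a branch from the set", {
  m <- toyModel(includeRedox = TRUE)
  ds <- omicsDataset(m)
  flip <- ds$geneFC
  gEthanol <- "gE"                     # ethanol branch gene
  flip$log2fc[flip$gene == gEthanol] <- -flip$log2fc[flip$gene == gEthanol]
  rep <- runFoldChangeProtocol(m, ds$conditionWt, ds$conditionMut,
                               ds$deletions, flip, ds$config)
  rec <- records(rep)
  expect_false("ALCD" %in% rec$reaction[rec$consistent])
  expect_setequal(rec$reaction[rec$consistent],
                  setdiff(ds$expectedConsistent, "ALCD"))
})

test_that("missing uptake reactions are rejected", {
  m <- toyModel(includeRedox = TRUE)
  ds <- omicsDataset(m)
  cfg <- fcProtocolConfig(uptakeWt = "EX_missing_e", loopless = FALSE)
  expect_error(runFoldChangeProtocol(m, ds$conditionWt, ds$conditionMut,
                                     ds$deletions, ds$geneFC, cfg),
               "uptake reaction absent")
  expect_error(fcProtocolConfig(epsilon = 0, uptakeWt = "EX_sub_e"),
               "epsilon")
})
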