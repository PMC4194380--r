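test_that("simulateYuleTree grows valid, deterministic ultrametric trees", {
  cherry <- simulateYuleTree(simConfig(seed = 1, nTips = 2))
  expect_equal(ape::Ntip(cherry), 2)
  expect_equal(cherry$Nnode, 1)

  cfg <- simConfig(seed = 5, nTips = 30)
  tr <- simulateYuleTree(cfg)
  expect_equal(ape::Ntip(tr), 30)
  expect_equal(tr$Nnode, 29)                      # strictly binary
  expect_true(all(table(tr$edge[, 1]) == 2))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(writeNewick(simulateYuleTree(cfg)), writeNewick(tr))
  expect_false(identical(writeNewick(simulateYuleTree(simConfig(seed = 6,
                                                                nTips = 30))),
                         writeNewick(tr)))
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(simulateYuleTree(cfg))
  expect_identical(.Random.seed, before)
})

test_that("the vertical model obeys its limits and records true events", {
  tr <- simulateYuleTree(simConfig(seed = 2, nTips = 40))
  frozen <- simulateCharacterVertical(tr, simConfig(
    seed = 3, nTips = 40, gainRate = 0, lossRate = 0, rootState = 1))
  expect_true(all(frozen$states == 1))
  expect_equal(nrow(frozen$events), 0)

  lost <- simulateCharacterVertical(tr, simConfig(
    seed = 3, nTips = 40, gainRate = 0, lossRate = 50, rootState = 1))
  expect_true(all(lost$states == 0))  # absorbing loss limit

  # parsimony is a lower bound on the true number of events
  cfg <- simConfig(seed = 0, nTips = 40, gainRate = 0.05, lossRate = 0.1)
  set.seed(77)
  for (i in 1:100) {
    ci <- cfg; ci$seed <- sample.int(1e6, 1)
    sim <- simulateCharacterVertical(tr, ci)
    expect_lte(fitchScore(tr, sim$states), nrow(sim$events))
  }
})

test_that("the scattered model places exactly k presences", {
  tr <- simulateYuleTree(simConfig(seed = 2, nTips = 40))
  allOn <- simulateCharacterScattered(tr, simConfig(seed = 1, nTips = 40,
                                                    scatterCount = 40))
  expect_true(all(allOn == 1))
  one <- simulateCharacterScattered(tr, simConfig(seed = 1, nTips = 40,
                                                  scatterCount = 1))
  expect_equal(sum(one), 1)
  expect_equal(fitchScore(tr, one), 1)
  expect_equal(riValue(retentionIndex(1, 40, 1)), 1)
  k30 <- simulateCharacterScattered(tr, simConfig(seed = 9, nTips = 40,
                                                  scatterCount = 17))
  expect_equal(sum(k30), 17)
})

test_that("genus assignment forms contiguous groups of the requested size", {
  tr <- simulateYuleTree(simConfig(seed = 4, nTips = 22))
  g <- assignGenera(tr, genusSize = 5)
  expect_equal(length(unique(g)), 5)  # 4 full genera + remainder
  expect_equal(unname(table(g)[unique(g)]), c(5L, 5L, 5L, 5L, 2L),
               ignore_attr = TRUE)
  expect_equal(names(g), tr$tip.label)
})

test_that("generateFixtureCorpus plants recoverable violations", {
  d <- withr::local_tempdir()
  man <- generateFixtureCorpus(d, simConfig(seed = 11, nTips = 30,
                                            genusSize = 3))
  expect_true(all(file.exists(unlist(man$paths))))

  qc <- qcFilterGenomes(readGenomeMetadata(man$paths$metadata))
  expect_setequal(qc$rejected$genome_id, man$planted$qcRejected)

  flt <- filterHits(parseDomtbl(man$paths$domtbl))
  expect_setequal(names(flt$best), names(man$planted$passingQueries))
  got <- vapply(flt$best, slot, "", "family")
  expect_equal(got[names(man$planted$passingQueries)],
               man$planted$passingQueries)
  expect_setequal(flt$unannotated, man$planted$failingQueries)

  pp <- loadPathwayReports(man$paths$reports)
  m <- presence(pp)
  # presence matches the simulated truth exactly: sub-threshold rows stay 0
  truth <- man$planted$presence
  expect_equal(m[rownames(truth), colnames(truth)], truth,
               ignore_attr = TRUE)
  low <- man$planted$subThreshold
  for (i in seq_len(nrow(low)))
    expect_equal(m[low$pathway_id[i], low$genome_id[i]], 0L)
})
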