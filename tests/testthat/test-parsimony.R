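test_that("fitchScore matches forced cases", {
  tr <- parseQuiet("((A,B),(C,D));")
  expect_equal(fitchScore(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  expect_equal(fitchScore(tr, c(A = 1, B = 0, C = 0, D = 0)), 1)
  expect_equal(fitchScore(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(fitchScore(tr, c(A = 1, B = 0, C = 1)), "D")
})

test_that("fitchScore equals the exhaustive minimum, also on multifurcations", {
  for (seed in 1:40) {
    tr <- randomTree(sample(4:10, 1), seed + 130)
    if (seed %% 3 == 0)  # collapse short edges into multifurcations
      tr <- ape::di2multi(tr, tol = quantile(tr$edge.length, 0.4))
    st <- randomStates(tr, seed + 7000)
    expect_equal(fitchScore(tr, st), bruteFitch(tr, st),
                 info = paste("seed", seed))
  }
})

test_that("fitchScore agrees with phangorn's sankoff parsimony", {
  for (seed in 1:10) {
    tr <- randomTree(20, seed + 550)
    st <- randomStates(tr, seed + 8000)
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c(0, 1))
    expect_equal(fitchScore(tr, st),
                 as.integer(phangorn::parsimony(tr, dat, method = "sankoff")))
  }
})

test_that("fitchAncestral returns a valid minimum-change labeling", {
  tr <- parseQuiet("((A,B),(C,D));")
  allp <- fitchAncestral(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(all(allp@states == 1))

  anc <- fitchAncestral(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(anc@states[5]), 0)  # ambiguous root -> absent
  expect_equal(unname(anc@states[6]), 1)  # the (A,B) clade
  expect_equal(unname(anc@states[7]), 0)
  anc1 <- fitchAncestral(tr, c(A = 1, B = 1, C = 0, D = 0),
                         rootTie = "present")
  expect_equal(unname(anc1@states[5]), 1)

  for (seed in 1:60) {
    tr <- randomTree(sample(5:30, 1), seed + 300)
    st <- randomStates(tr, seed + 9000)
    anc <- fitchAncestral(tr, st)
    induced <- sum(anc@states[tr$edge[, 1]] != anc@states[tr$edge[, 2]])
    expect_equal(induced, anc@score, info = paste("seed", seed))
    expect_equal(anc@score, fitchScore(tr, st))
    # tip assignments equal observations; assignment within preliminary set
    expect_equal(unname(anc@states[seq_len(ape::Ntip(tr))]),
                 unname(st[tr$tip.label]))
    expect_true(all(anc@prelim[cbind(seq_along(anc@states),
                                     anc@states + 1L)]))
  }
})

test_that("retentionIndex reproduces printed corpus statistics", {
  # occurrence counts and parsimony scores of six reference pathways
  cases <- data.frame(
    n = c(9383, 1353, 6005, 1121, 2236),
    s = c(290, 592, 528, 409, 387),
    ri2 = c(0.95, 0.56, 0.91, 0.64, 0.83))
  for (i in seq_len(nrow(cases))) {
    r <- retentionIndex(cases$n[i], 14727, cases$s[i])
    expect_equal(roundHalfUp(riValue(r)), cases$ri2[i])
  }
  # lysine biosynthesis I: printed 0.97, formula gives 0.9767 (lower bound)
  expect_gte(riValue(retentionIndex(8372, 14727, 149)), 0.97)
  # mercury detoxification counts: direct formula check
  expect_equal(riValue(retentionIndex(2319, 14727, 944)), 1375 / 2318)
})

test_that("retentionIndex conventions and guards hold", {
  expect_equal(riValue(retentionIndex(1, 10, 1)), 1)       # g = m forces 1
  expect_equal(riValue(retentionIndex(3, 10, 1)), 1)       # s = m
  const <- retentionIndex(10, 10, 0)
  expect_true(isConstant(const))
  expect_equal(riValue(const), 1)
  expect_error(retentionIndex(3, 10, 4), "exceeds")
  expect_error(retentionIndex(3, 10, 0), "below")
  expect_error(retentionIndex(11, 10, 0), "nPresent")
  # monotone decreasing in s at fixed g
  ri <- vapply(1:5, function(s) riValue(retentionIndex(5, 100, s)), 0)
  expect_true(all(diff(ri) < 0))
  expect_true(all(ri >= 0 & ri <= 1))
})

test_that("classifyConsistency applies the strict thresholds", {
  expect_equal(classifyConsistency(c(0.95, 0.80, 0.56, 0.9, 0.7)),
               c("consistent", "intermediate", "inconsistent",
                 "intermediate", "intermediate"))
  expect_error(classifyConsistency(1.2), "0, 1")
})

test_that("changeEvents clocks state flips at branch midpoints", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  ages <- assignNodeAges(tr)
  anc <- fitchAncestral(tr, c(A = 1, B = 1, C = 0))
  ev <- changeEvents(anc, ages)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "gain")
  expect_equal(ev$child, "N5")
  expect_equal(ev$age_lo, 50); expect_equal(ev$age_hi, 100)
  expect_equal(ev$age_mid, 75)

  none <- changeEvents(fitchAncestral(tr, c(A = 1, B = 1, C = 1)), ages)
  expect_equal(nrow(none), 0)

  for (seed in 1:25) {
    tr <- randomTree(sample(5:30, 1), seed + 20)
    st <- randomStates(tr, seed + 60)
    anc <- fitchAncestral(tr, st)
    ev <- changeEvents(anc, assignNodeAges(tr))
    expect_equal(nrow(ev), anc@score)
    expect_true(all(ev$age_hi >= ev$age_lo))
    expect_true(all(diff(ev$age_mid) <= 0))  # sorted oldest first
  }
})

test_that("scorePathways summarizes a profile matrix row-wise", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(p1 = c(A = 1, B = 1, C = 0, D = 0),
             p2 = c(A = 1, B = 0, C = 1, D = 0),
             p3 = c(A = 1, B = 1, C = 1, D = 1))
  sc <- scorePathways(tr, PathwayProfiles(m))
  expect_equal(sc$s, c(1L, 2L, 0L))
  expect_equal(sc$ri, c(1, 0, 1))
  expect_equal(sc$constant, c(FALSE, FALSE, TRUE))
  expect_equal(sc$class, c("consistent", "inconsistent", "consistent"))
  frac <- summarizeConsistency(sc)
  expect_equal(as.numeric(frac), c(2 / 3, 0, 1 / 3))
})
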