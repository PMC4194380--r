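domLine <- function(fam, tlen, query, qlen, ev, hf, ht, af, at)
  sprintf("%s - %d %s - %d %g 50.0 0.1 1 1 %g %g 45.0 0.1 %d %d %d %d %d %d 0.9 desc",
          fam, tlen, query, qlen, ev, ev, ev, hf, ht, af, at, af, at)

test_that("parseDomtbl aggregates domain rows per query/family pair", {
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.domtblout")
  writeLines(c("# comment",
               domLine("famA", 200, "q1", 150, 1e-6, 1, 100, 1, 80),
               domLine("famA", 200, "q1", 150, 1e-6, 120, 180, 90, 140),
               domLine("famB", 300, "q2", 100, 1e-4, 1, 150, 1, 60)), f)
  hits <- parseDomtbl(f)
  expect_length(hits, 2)
  h1 <- hits[[which(vapply(hits, slot, "", "query") == "q1")]]
  expect_equal(nrow(h1@qIntervals), 2)
  expect_equal(h1@evalue, 1e-6)
  expect_equal(h1@hmmlen, 200L)

  writeLines("# only comments", f)
  expect_length(parseDomtbl(f), 0)

  writeLines(c(domLine("famA", 200, "q1", 150, 1e-6, 1, 100, 1, 80),
               "famX - 200 q9 - 150 notanumber"), f)
  expect_error(parseDomtbl(f), "line 2")
  writeLines(gsub("1e-06", "abc", domLine("famA", 200, "q1", 150, 1e-6,
                                          1, 100, 1, 80)), f)
  expect_error(parseDomtbl(f), "non-numeric")
})

test_that("hitCoverage merges intervals before summing", {
  h <- makeHit(qlen = 100, qiv = cbind(from = c(1, 41), to = c(30, 65)))
  expect_equal(hitCoverage(h)[["query"]], 0.55)
  h2 <- makeHit(qlen = 100, qiv = cbind(from = c(1, 26), to = c(50, 75)))
  expect_equal(hitCoverage(h2)[["query"]], 0.75)  # overlap counted once
  expect_equal(hitCoverage(makeHit())[["hmm"]], 1.0)
  # invariant to interval order and to splitting into adjacent pieces
  h3 <- makeHit(qlen = 100, qiv = cbind(from = c(41, 1), to = c(65, 30)))
  expect_equal(hitCoverage(h3)[["query"]], 0.55)
  h4 <- makeHit(qlen = 100,
                qiv = cbind(from = c(1, 16, 41), to = c(15, 30, 65)))
  expect_equal(hitCoverage(h4)[["query"]], 0.55)
})

test_that("filterHits enforces all three thresholds and picks the best", {
  good <- makeHit("q1", "famZ", 1e-4,
                  qlen = 100, qiv = cbind(from = 1, to = 60),
                  hmmlen = 100, hiv = cbind(from = 1, to = 55))
  better <- makeHit("q1", "famA", 1e-6)
  badEv <- makeHit("q2", "famA", 5e-3)
  badQcov <- makeHit("q3", "famA", 1e-8, qlen = 100,
                     qiv = cbind(from = 1, to = 49))
  out <- filterHits(list(good, better, badEv, badQcov))
  expect_equal(names(out$best), "q1")
  expect_equal(out$best$q1@family, "famA")  # smaller e-value wins
  expect_setequal(out$unannotated, c("q2", "q3"))

  # exact threshold behavior: e-value strict, coverage inclusive
  edgeEv <- makeHit("q4", "famA", 1e-3)
  edgeCov <- makeHit("q5", "famA", 1e-4, qlen = 100,
                     qiv = cbind(from = 1, to = 50),
                     hmmlen = 100, hiv = cbind(from = 1, to = 50))
  out2 <- filterHits(list(edgeEv, edgeCov))
  expect_equal(names(out2$best), "q5")
  expect_equal(out2$unannotated, "q4")

  # equal e-values: lexicographically smallest family id
  tie <- filterHits(list(makeHit("q6", "famB", 1e-5),
                         makeHit("q6", "famA", 1e-5)))
  expect_equal(tie$best$q6@family, "famA")

  # relaxing thresholds never drops a previously annotated query
  strict <- filterHits(list(good, badEv, badQcov),
                       annotationFilterConfig(1e-3, 0.5))
  relaxed <- filterHits(list(good, badEv, badQcov),
                        annotationFilterConfig(1e-2, 0.4))
  expect_true(all(names(strict$best) %in% names(relaxed$best)))
})

test_that("mergeFamilyAnnotations takes field-wise unions", {
  a <- familyAnnotation("fam1", productNames = "kinase", ec = "1.1.1.1",
                        go = "GO:0008150")
  b <- familyAnnotation("fam1", productNames = "kinase", ec = "1.1.1.1",
                        go = "GO:0003674")
  m <- mergeFamilyAnnotations(list(a, b))
  expect_equal(m@ec, "1.1.1.1")
  expect_setequal(m@go, c("GO:0008150", "GO:0003674"))
  expect_equal(mergeFamilyAnnotations(list(a)), a)
  # associative + commutative
  c_ <- familyAnnotation("fam1", geneNames = c("abcZ", "abcA"))
  expect_equal(mergeFamilyAnnotations(list(mergeFamilyAnnotations(list(a, b)), c_)),
               mergeFamilyAnnotations(list(a, mergeFamilyAnnotations(list(b, c_)))))
  expect_equal(mergeFamilyAnnotations(list(c_, b, a)),
               mergeFamilyAnnotations(list(a, b, c_)))
  expect_error(mergeFamilyAnnotations(list()), "no member")
  expect_error(familyAnnotation("f", go = "GO:123"), "malformed GO")
})

test_that("validateCluster applies strict identity and length-ratio rules", {
  ok <- validateCluster(c(1.0, 0.85), c(100, 90))
  expect_true(ok$valid)
  expect_length(ok$violations, 0)
  badId <- validateCluster(c(1.0, 0.79), c(100, 95))
  expect_false(badId$valid)
  expect_match(badId$violations, "identity")
  badLen <- validateCluster(c(1.0, 0.9), c(100, 79))
  expect_false(badLen$valid)
  expect_match(badLen$violations, "length ratio")
  # boundary: exactly 0.80 fails the strict rule
  expect_false(validateCluster(c(1.0, 0.80), c(100, 100))$valid)
  expect_false(validateCluster(c(1.0, 0.9), c(100, 80))$valid)
})

test_that("writeAnnotationTable joins transferred annotation fields", {
  d <- withr::local_tempdir()
  flt <- filterHits(list(makeHit("q1", "famA", 1e-6),
                         makeHit("q2", "famB", 5e-3)))
  ann <- list(famA = familyAnnotation("famA", productNames = "kinase",
                                      ec = c("1.1.1.1", "2.7.1.1"),
                                      go = "GO:0008150"))
  f <- file.path(d, "annot.tsv")
  writeAnnotationTable(flt, ann, f)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(tab$query_id, "q1")
  expect_equal(tab$EC, "1.1.1.1;2.7.1.1")
  expect_equal(tab$GO, "GO:0008150")
  expect_equal(tab$qcov, 1)
})
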