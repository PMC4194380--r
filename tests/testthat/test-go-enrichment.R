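test_that("loadObo builds the DAG, skipping obsolete terms", {
  d <- withr::local_tempdir()
  f <- miniObo(file.path(d, "mini.obo"),
               extra = c("", "[Term]", "id: GO:0000009",
                         "name: gone", "is_obsolete: true"))
  dag <- loadObo(f)
  expect_setequal(dag@ids, c("GO:0008150", "GO:0000001", "GO:0000003"))
  expect_equal(dag@parents[["GO:0000003"]], "GO:0000001")
  expect_equal(unname(dag@termNames["GO:0000001"]), "branch A")

  cyc <- file.path(d, "cyclic.obo")
  writeLines(c("[Term]", "id: GO:0000001", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "is_a: GO:0000001"), cyc)
  expect_error(loadObo(cyc), "cyclic")
})

test_that("annotateUp propagates to all ancestors and is idempotent", {
  d <- withr::local_tempdir()
  dag <- loadObo(miniObo(file.path(d, "mini.obo")))
  ann <- annotateUp(dag, list(gene1 = "GO:0000003", gene2 = "GO:0008150"))
  expect_setequal(ann$gene1, c("GO:0000003", "GO:0000001", "GO:0008150"))
  expect_equal(ann$gene2, "GO:0008150")
  expect_equal(annotateUp(dag, ann), ann)
  expect_warning(annotateUp(dag, list(g = "GO:9999999")), "not in the ontology")
})

test_that("fisherClassic equals the exhaustive hypergeometric tail", {
  expect_equal(fisherClassic(0, 5, 10, 100), 1)
  expect_error(fisherClassic(6, 5, 10, 100), "inconsistent")
  for (N in c(8, 15, 25)) {
    for (K in 0:N) for (n in 0:N) for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(fisherClassic(k, n, K, N), bruteHyperTail(k, n, K, N),
                   tolerance = 1e-12,
                   info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
    }
  }
})

test_that("elim removes significant children's genes from ancestors", {
  d <- withr::local_tempdir()
  dag <- loadObo(miniObo(file.path(d, "mini.obo")))
  # 40 genes; the leaf term annotates g01..g10, all in the study set;
  # the mid term annotates those plus g11..g14; everything is_a the root.
  genes <- sprintf("g%02d", 1:40)
  direct <- setNames(rep(list("GO:0008150"), 40), genes)
  for (g in genes[1:10]) direct[[g]] <- "GO:0000003"
  for (g in genes[11:14]) direct[[g]] <- "GO:0000001"
  ann <- annotateUp(dag, direct)
  study <- genes[1:12]
  res <- elimEnrichment(dag, study, genes, ann)
  res <- res[order(res$term), ]

  leaf <- res[res$term == "GO:0000003", ]
  expect_equal(leaf$k, 10); expect_equal(leaf$K, 10)
  expect_equal(leaf$p_classic, bruteHyperTail(10, 12, 10, 40))
  expect_equal(leaf$p_elim, leaf$p_classic)  # no significant descendants
  expect_lt(leaf$p_elim, 0.01)

  # mid term classic counts include the leaf genes (K = 14, k = 12), but
  # the significant leaf strips its 10 genes before the elim test
  mid <- res[res$term == "GO:0000001", ]
  expect_equal(mid$K, 14); expect_equal(mid$k, 12)
  expect_equal(mid$p_classic, bruteHyperTail(12, 12, 14, 40))
  expect_equal(mid$p_elim, bruteHyperTail(2, 12, 4, 40))
  expect_gt(mid$p_elim, mid$p_classic)

  # with an unattainable cutoff nothing is eliminated anywhere
  res0 <- elimEnrichment(dag, study, genes, ann,
                         enrichmentConfig(elimCutoff = 1e-30))
  expect_equal(res0$p_elim, res0$p_classic)

  # input order never matters
  res2 <- elimEnrichment(dag, rev(study), rev(genes), ann)
  expect_equal(res2[order(res2$term), ], res)
})

test_that("filterAndRank applies the >10-gene and elim-p filters", {
  res <- data.frame(
    term = c("GO:0000010", "GO:0000011", "GO:0000012", "GO:0000013"),
    name = letters[1:4], k = c(5, 6, 7, 8), n = 10,
    K = c(10, 11, 30, 12), N = 100,
    p_classic = c(1e-4, 1e-3, 5e-3, 2e-2),
    p_elim = c(1e-4, 5e-3, 2e-2, 5e-3))
  out <- filterAndRank(res, enrichmentConfig())
  # term 1: K = 10 is not "more than 10"; term 3: p_elim 0.02 > 0.01
  expect_equal(out$term, c("GO:0000011", "GO:0000013"))
  expect_equal(out$p_elim, c(5e-3, 5e-3))  # tie broken by term id
  expect_equal(nrow(filterAndRank(res, enrichmentConfig(topK = 1))), 1)
})
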