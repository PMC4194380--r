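test_that("qcFilterGenomes applies the contig and gene thresholds", {
  rec <- data.frame(
    genome_id = c("g1", "g2", "g3", "g4", "g5"),
    n_contigs = c(1001, 10, 1000, 500, 1200),
    n_genes = c(5000, 399, 400, 4000, 100),
    stringsAsFactors = FALSE)
  out <- qcFilterGenomes(rec, qcConfig())
  expect_equal(out$kept$genome_id, c("g3", "g4"))  # boundaries kept
  expect_equal(out$rejected$genome_id, c("g1", "g2", "g5"))
  expect_match(out$rejected$reason[1], "contigs")
  expect_match(out$rejected$reason[2], "genes")
  expect_match(out$rejected$reason[3], "contigs.*genes")
})

test_that("loadPathwayReports thresholds confidence and collapses duplicates", {
  d <- withr::local_tempdir()
  f1 <- writeTsv(data.frame(
    genome_id = c("g1", "g1", "g1", "g1", "g2"),
    pathway_id = c("pwyA", "pwyB", "pwyC", "pwyC", "pwyA"),
    confidence = c(70, 69.9, 40, 80, 95)), file.path(d, "r1.tsv"))
  pp <- loadPathwayReports(f1)
  m <- presence(pp)
  expect_equal(m["pwyA", "g1"], 1L)   # inclusive >= 70
  expect_equal(m["pwyB", "g1"], 0L)   # 69.9 below threshold
  expect_equal(m["pwyC", "g1"], 1L)   # max(40, 80) wins
  expect_equal(m["pwyC", "g2"], 0L)   # never reported for g2
  expect_error(loadPathwayReports(writeTsv(
    data.frame(pathway = "x", conf = 1), file.path(d, "bad.tsv"))),
    "bad.tsv")
  # genome id falls back to the file name
  f2 <- writeTsv(data.frame(pathway_id = "pwyA", confidence = 75),
                 file.path(d, "gX.tsv"))
  expect_equal(colnames(loadPathwayReports(f2)), "gX")
})

test_that("aggregateByGenus takes the member-wise OR", {
  m <- rbind(pwy1 = c(a1 = 1L, a2 = 0L, b1 = 0L),
             pwy2 = c(a1 = 0L, a2 = 0L, b1 = 0L))
  meta <- data.frame(genome_id = c("a1", "a2", "b1"),
                     genus = c("Alpha", "Alpha", "Beta"),
                     phylum = c("P1", "P1", "P2"),
                     stringsAsFactors = FALSE)
  g <- aggregateByGenus(PathwayProfiles(m, meta))
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(presence(g)["pwy1", "Alpha"], 1L)  # any member suffices
  expect_equal(presence(g)["pwy1", "Beta"], 0L)
  expect_equal(presence(g)["pwy2", "Alpha"], 0L)
  expect_true(all(rowSums(presence(g)) <= rowSums(m)))
  # idempotent when every genus has one genome
  meta1 <- data.frame(genome_id = colnames(m), genus = colnames(m),
                      stringsAsFactors = FALSE)
  g1 <- aggregateByGenus(PathwayProfiles(m, meta1))
  expect_equal(unname(presence(g1)), unname(m))
})

test_that("manhattanDistance is the differing-entry count and a metric", {
  expect_equal(manhattanDistance(c(1, 0, 1), c(1, 1, 1)), 1)
  expect_equal(manhattanDistance(c(1, 0), c(1, 0)), 0)
  v <- c(1, 0, 1, 1, 0)
  expect_equal(manhattanDistance(v, 1 - v), 5)
  expect_error(manhattanDistance(c(1, 0), c(1, 0, 1)), "mismatch")
  set.seed(11)
  for (i in 1:30) {
    a <- sample(0:1, 12, TRUE); b <- sample(0:1, 12, TRUE)
    c_ <- sample(0:1, 12, TRUE)
    expect_equal(manhattanDistance(a, b), manhattanDistance(b, a))
    expect_lte(manhattanDistance(a, c_),
               manhattanDistance(a, b) + manhattanDistance(b, c_))
    expect_equal(manhattanDistance(a, a), 0)
  }
})

test_that("clusterProfiles reproduces hand agglomerations deterministically", {
  # pairwise Manhattan distances 1 (a,b), 4 (a,c), 5 (b,c)
  m <- t(rbind(a = c(0, 0, 0, 0, 0),
               b = c(1, 0, 0, 0, 0),
               c = c(0, 1, 1, 1, 1)))
  rownames(m) <- paste0("p", 1:5)
  hc <- clusterProfiles(m, axis = "columns", linkage = "complete")
  expect_equal(hc$height, c(1, 5))  # complete linkage: max(4, 5)
  hcs <- clusterProfiles(m, axis = "columns", linkage = "single")
  expect_equal(hcs$height, c(1, 4))

  # identical pair merges first at height zero
  m2 <- t(rbind(x = c(1, 1, 0), y = c(1, 1, 0), z = c(0, 0, 1)))
  hc2 <- clusterProfiles(m2, axis = "columns")
  expect_equal(hc2$height[1], 0)

  # permutation invariance through the lexicographic pre-sort
  perm <- m[, c(2, 3, 1)]
  expect_equal(clusterProfiles(perm, axis = "columns")$height, hc$height)
  expect_equal(clusterProfiles(perm, axis = "columns")$labels, hc$labels)

  one <- clusterProfiles(m[, 1, drop = FALSE], axis = "columns")
  expect_s3_class(one, "hclust")
  expect_equal(dendrogramNewick(one), "(a:0);")
  nwk <- dendrogramNewick(hc)
  expect_setequal(parseNewick(nwk)$tip.label, c("a", "b", "c"))
})

test_that("PathwayProfiles validates its matrix and metadata", {
  m <- rbind(p = c(g1 = 1L, g2 = 0L))
  expect_s4_class(PathwayProfiles(m), "PathwayProfiles")
  expect_error(PathwayProfiles(rbind(p = c(g1 = 2L, g2 = 0L))), "0 or 1")
  expect_error(PathwayProfiles(m, data.frame(genome_id = "g1")), "g2")
})
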