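#' Generate a complete fixture corpus on disk
#'
#' Emits every input format the pipeline consumes — Newick tree, genome
#' metadata TSV, pathway-report TSV, HMMER domtblout, gene-to-GO TSV and
#' an OBO ontology stub — for a simulated corpus with known ground
#' truth. Some genomes deliberately violate each QC threshold, some
#' homology hits deliberately fail each annotation-filter clause, and
#' some pathway rows sit below the confidence threshold, so filter
#' contracts can be checked exactly against the planted truth.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [simConfig()]; drives the tree, characters and all
#'   random choices.
#' @param nVertical,nScattered number of vertically evolved and
#'   scattered pathways (plus one constant pathway, always present).
#' @return a manifest list: \code{paths} (named file paths),
#'   \code{tree}, and \code{planted} ground truth (QC rejections with
#'   reasons, presence matrix, pathway regimes, sub-threshold report
#'   rows, domtblout queries expected to pass/fail and the expected best
#'   family per annotated query).
#' @export
generateFixtureCorpus <- function(dir, cfg, nVertical = 5, nScattered = 5) {
  stopifnot(inherits(cfg, "simConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- list(tree = p("tree.nwk"), metadata = p("metadata.tsv"),
                reports = p("pathway_reports.tsv"),
                domtbl = p("hits.domtblout"), gene2go = p("gene2go.tsv"),
                obo = p("ontology.obo"))

  tree <- simulateYuleTree(cfg)
  writeNewick(tree, file = paths$tree)
  tips <- tree$tip.label
  n <- length(tips)
  genera <- assignGenera(tree, cfg$genusSize)

  # -- genome metadata with planted QC violations --------------------
  meta <- .withSeed(cfg$seed + 1L, {
    viol <- sample(tips, 3L)
    df <- data.frame(
      genome_id = tips, genus = unname(genera[tips]),
      stringsAsFactors = FALSE)
    genusIdx <- as.integer(sub("genus", "", df$genus))
    phylumIdx <- ceiling(genusIdx / 2)
    df$phylum <- sprintf("Phylum%02d", phylumIdx)
    df$domain <- ifelse(phylumIdx == max(phylumIdx), "Archaea", "Bacteria")
    df$status <- sample(c("finished", "draft"), n, replace = TRUE)
    df$n_contigs <- sample(10:900, n, replace = TRUE)
    df$n_genes <- sample(1500:4500, n, replace = TRUE)
    df$n_contigs[df$genome_id == viol[1L]] <- 1500L    # > 1000 contigs
    df$n_genes[df$genome_id == viol[2L]] <- 300L       # < 400 genes
    df$n_contigs[df$genome_id == viol[3L]] <- 2000L    # fails both
    df$n_genes[df$genome_id == viol[3L]] <- 100L
    attr(df, "viol") <- viol
    df
  })
  viol <- attr(meta, "viol")
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- binary characters ---------------------------------------------
  charSeeds <- .withSeed(cfg$seed + 2L,
                         sample.int(.Machine$integer.max - 1L,
                                    nVertical + nScattered))
  pwys <- list()
  regime <- character(0)
  for (i in seq_len(nVertical)) {
    ci <- cfg; ci$seed <- charSeeds[i]
    id <- sprintf("PWY-V%02d", i)
    pwys[[id]] <- simulateCharacterVertical(tree, ci)$states
    regime[id] <- "vertical"
  }
  for (i in seq_len(nScattered)) {
    ci <- cfg; ci$seed <- charSeeds[nVertical + i]
    id <- sprintf("PWY-S%02d", i)
    pwys[[id]] <- simulateCharacterScattered(tree, ci)
    regime[id] <- "scattered"
  }
  pwys[["PWY-CONST"]] <- stats::setNames(rep(1L, n), tips)
  regime["PWY-CONST"] <- "constant"
  truth <- do.call(rbind, pwys)

  # -- pathway reports with planted sub-threshold rows ---------------
  reports <- .withSeed(cfg$seed + 3L, {
    rows <- list()
    low <- list()
    for (id in rownames(truth)) {
      present <- tips[truth[id, ] == 1L]
      if (length(present))
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = present, pathway_id = id,
          confidence = sample(70:100, length(present), replace = TRUE),
          stringsAsFactors = FALSE)
      absent <- tips[truth[id, ] == 0L]
      if (length(absent)) {  # planted: below-threshold calls must stay 0
        pick <- absent[sample.int(length(absent), min(2L, length(absent)))]
        low[[length(low) + 1L]] <- data.frame(
          genome_id = pick, pathway_id = id,
          confidence = sample(10:69, length(pick), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    # planted duplicate: one present pair also gets a low-confidence row
    dupTip <- tips[truth[1L, ] == 1L][1L]
    dup <- if (!is.na(dupTip)) data.frame(
      genome_id = dupTip, pathway_id = rownames(truth)[1L],
      confidence = 40, stringsAsFactors = FALSE) else NULL
    out <- do.call(rbind, c(rows, low, list(dup)))
    attr(out, "low") <- do.call(rbind, low)
    out
  })
  utils::write.table(reports, paths$reports, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- domtblout with one planted case per filter clause -------------
  dl <- function(fam, tlen, query, qlen, ev, hf, ht, af, at)
    sprintf(paste0("%s - %d %s - %d %.2g 100.0 0.1 1 1 %.2g %.2g 90.0 0.1 ",
                   "%d %d %d %d %d %d 0.95 planted_fixture"),
            fam, tlen, query, qlen, ev, ev, ev, hf, ht, af, at, af, at)
  domLines <- c(
    "# planted synthetic domtblout fixture",
    dl("FAM00001", 200, "q_pass_simple", 210, 1e-6, 1, 190, 10, 205),
    # two domains whose union reaches 50% on both axes
    dl("FAM00002", 300, "q_pass_split", 280, 1e-5, 1, 80, 1, 75),
    dl("FAM00002", 300, "q_pass_split", 280, 1e-5, 100, 180, 90, 170),
    dl("FAM00003", 200, "q_fail_evalue", 200, 5e-3, 1, 200, 1, 200),
    dl("FAM00004", 200, "q_fail_qcov", 500, 1e-8, 1, 180, 1, 120),
    dl("FAM00005", 400, "q_fail_hcov", 150, 1e-8, 1, 120, 1, 140),
    dl("FAM00006", 200, "q_two_hits", 210, 1e-9, 1, 190, 1, 200),
    dl("FAM00007", 200, "q_two_hits", 210, 1e-4, 1, 190, 1, 200))
  writeLines(domLines, paths$domtbl)
  plantedPass <- c(q_pass_simple = "FAM00001", q_pass_split = "FAM00002",
                   q_two_hits = "FAM00006")
  plantedFail <- c("q_fail_evalue", "q_fail_qcov", "q_fail_hcov")

  # -- ontology stub + gene annotations ------------------------------
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0008150", "name: biological_process",
           "namespace: biological_process", "",
           "[Term]", "id: GO:0000001", "name: branch A process",
           "namespace: biological_process", "is_a: GO:0008150 ! bp", "",
           "[Term]", "id: GO:0000002", "name: branch B process",
           "namespace: biological_process", "is_a: GO:0008150 ! bp", "",
           "[Term]", "id: GO:0000003", "name: specific A1 process",
           "namespace: biological_process", "is_a: GO:0000001 ! A", "",
           "[Term]", "id: GO:0000004", "name: specific A2 process",
           "namespace: biological_process", "is_a: GO:0000001 ! A", "",
           "[Term]", "id: GO:0000005", "name: specific B1 process",
           "namespace: biological_process", "is_a: GO:0000002 ! B", "",
           "[Term]", "id: GO:0000006", "name: defunct process",
           "namespace: biological_process", "is_a: GO:0008150 ! bp",
           "is_obsolete: true")
  writeLines(obo, paths$obo)

  gene2go <- .withSeed(cfg$seed + 4L, {
    rows <- lapply(tips, function(g) {
      arch <- meta$domain[meta$genome_id == g] == "Archaea"
      terms <- if (arch) c("GO:0000003", "GO:0000003", "GO:0000003",
                           "GO:0000003", "GO:0000004", "GO:0000005")
               else c("GO:0000005", "GO:0000005", "GO:0000005",
                      "GO:0000004", "GO:0000005", "GO:0000005")
      data.frame(genome_id = g,
                 gene_id = sprintf("%s_gene%02d", g, seq_along(terms)),
                 go = terms, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(gene2go, paths$gene2go, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = paths, tree = tree,
       planted = list(
         qcRejected = sort(viol[c(1L, 2L, 3L)]),
         qcReasons = stats::setNames(c("contigs", "genes", "both"), viol),
         presence = truth, regime = regime,
         subThreshold = attr(reports, "low"),
         passingQueries = plantedPass, failingQueries = plantedFail))
}
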