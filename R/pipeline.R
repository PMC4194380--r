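# End-to-end orchestration: QC -> profiles -> parsimony/RI -> events ->
# subtrees -> genus clustering -> enrichment, with a thin CLI wrapper.

.logmsg <- function(...) {
  if (isTRUE(getOption("pathphylo.quiet"))) return(invisible())
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Pipeline configuration
#'
#' Collects the input paths and the analysis constants: QC thresholds,
#' annotation/enrichment settings, RI classification bounds (0.7, 0.9),
#' the scaled root age (100) and the clustering linkage.
#'
#' @param treeFile Newick tree whose tips are genome ids.
#' @param metadataFile genome metadata TSV (see [readGenomeMetadata()]).
#' @param reportFiles character vector of pathway-report TSVs.
#' @param outDir output directory.
#' @param oboFile,gene2goFile optional ontology and gene-annotation
#'   inputs enabling GO enrichment (gene2go TSV: genome_id, gene_id, go).
#' @param enrichTaxa phylum names to test against the pooled background.
#' @param subtreePathways pathway ids for which reduced subtrees are
#'   written.
#' @param qc a [qcConfig()].
#' @param enrichment an [enrichmentConfig()].
#' @param riLower,riUpper consistency classification bounds.
#' @param rootAge scaled age of the root (default 100).
#' @param rootTie root tie rule for [fitchAncestral()].
#' @param linkage clustering linkage for [clusterProfiles()].
#' @return a validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(treeFile, metadataFile, reportFiles, outDir,
                           oboFile = NULL, gene2goFile = NULL,
                           enrichTaxa = NULL, subtreePathways = NULL,
                           qc = qcConfig(), enrichment = enrichmentConfig(),
                           riLower = 0.7, riUpper = 0.9, rootAge = 100,
                           rootTie = "absent", linkage = "complete") {
  stopifnot(riLower < riUpper, rootAge > 0)
  structure(list(treeFile = treeFile, metadataFile = metadataFile,
                 reportFiles = reportFiles, outDir = outDir,
                 oboFile = oboFile, gene2goFile = gene2goFile,
                 enrichTaxa = enrichTaxa, subtreePathways = subtreePathways,
                 qc = qc, enrichment = enrichment, riLower = riLower,
                 riUpper = riUpper, rootAge = rootAge, rootTie = rootTie,
                 linkage = linkage),
            class = "pipelineConfig")
}

#' Run the functional phylogenomics pipeline
#'
#' Reads and QC-filters the corpus, builds the pathway presence/absence
#' matrix, prunes the tree to the surviving genomes, dates its nodes,
#' scores every pathway (parsimony score, retention index, consistency
#' class), clocks all gain/loss events, writes reduced subtrees for
#' requested pathways, clusters genus-level profiles on both axes, and
#' (when ontology inputs are configured) runs GO enrichment per
#' requested taxon. All tables are written under \code{outDir} together
#' with a MANIFEST; the result bundle is also returned invisibly.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list: tree, ages, profiles, genusProfiles,
#'   scores, events, summary, subtrees, dendrograms, enrichment, qc.
#' @export
runFunctionPhylogenomics <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  for (f in c(cfg$treeFile, cfg$metadataFile, cfg$reportFiles,
              cfg$oboFile, cfg$gene2goFile))
    if (!file.exists(f)) .stopf("input file not found: %s", f)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)
  manifest <- character(0)
  emit <- function(df, f) {
    utils::write.table(df, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <<- c(manifest, f)
  }

  tree <- readNewick(cfg$treeFile)
  meta <- readGenomeMetadata(cfg$metadataFile)
  qc <- qcFilterGenomes(meta, cfg$qc)
  .logmsg("QC: kept %d of %d genomes", nrow(qc$kept), nrow(meta))
  emit(qc$rejected, "qc_rejected.tsv")

  notInTree <- setdiff(qc$kept$genome_id, tree$tip.label)
  if (length(notInTree))
    .stopf("genome id(s) missing from the tree: %s",
           paste(notInTree, collapse = ", "))

  profiles <- loadPathwayReports(cfg$reportFiles, cfg$qc)
  if (nrow(profiles) == 0L) .stopf("empty pathway matrix")
  m <- presence(profiles)
  # zero-profile genomes that passed QC still occupy a column
  missing <- setdiff(qc$kept$genome_id, colnames(m))
  if (length(missing)) {
    m <- cbind(m, matrix(0L, nrow(m), length(missing),
                         dimnames = list(rownames(m), missing)))
  }
  m <- m[, qc$kept$genome_id, drop = FALSE]
  profiles <- PathwayProfiles(m, genomeData = qc$kept)

  drop <- setdiff(tree$tip.label, qc$kept$genome_id)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  .logmsg("analysis tree: %d tips, %d pathways", ape::Ntip(tree),
          nrow(profiles))

  ages <- assignNodeAges(tree, cfg$rootAge)
  ntip <- ape::Ntip(tree)

  scoreRows <- list(); eventRows <- list(); subtrees <- list()
  wanted <- intersect(cfg$subtreePathways, rownames(m))
  unknownSub <- setdiff(cfg$subtreePathways, rownames(m))
  if (length(unknownSub))
    .warnf("no such pathway for subtree reduction: %s",
           paste(unknownSub, collapse = ", "))
  for (pwy in rownames(m)) {
    st <- m[pwy, tree$tip.label]
    anc <- fitchAncestral(tree, st, rootTie = cfg$rootTie)
    r <- retentionIndex(sum(st == 1L), ntip, anc@score, pathway = pwy)
    scoreRows[[pwy]] <- data.frame(
      pathway_id = pwy, n_present = r@nPresent, n_total = r@nTotal,
      g = r@g, s = r@s, m = r@m, ri = r@ri, constant = r@constant,
      stringsAsFactors = FALSE)
    ev <- changeEvents(anc, ages)
    if (nrow(ev)) eventRows[[pwy]] <- cbind(pathway_id = pwy, ev)
    if (pwy %in% wanted) {
      red <- if (all(st == 0L)) {
        .warnf("pathway %s absent from all genomes; degenerate subtree", pwy)
        suppressWarnings(reduceSubtree(anc))
      } else reduceSubtree(anc)
      subtrees[[pwy]] <- red
      safe <- gsub("[^A-Za-z0-9._-]", "_", pwy)
      writeReducedSubtree(red, out(paste0("subtree_", safe)))
      manifest <- c(manifest, paste0("subtree_", safe, ".nwk"),
                    paste0("subtree_", safe, "_nodes.tsv"))
    }
  }
  scores <- do.call(rbind, scoreRows)
  scores$class <- classifyConsistency(scores$ri, cfg$riLower, cfg$riUpper)
  rownames(scores) <- NULL
  emit(scores, "pathway_results.tsv")
  events <- if (length(eventRows)) do.call(rbind, eventRows)
            else data.frame(pathway_id = character(0))
  rownames(events) <- NULL
  emit(events, "events.tsv")

  summary <- summarizeConsistency(scores)
  emit(data.frame(class = names(summary), fraction = as.numeric(summary)),
       "summary.tsv")

  genus <- aggregateByGenus(profiles)
  emitMatrix <- function(x, f) {
    writeProfileMatrix(x, out(f)); manifest <<- c(manifest, f)
  }
  emitMatrix(genus, "genus_matrix.tsv")
  dendros <- list()
  if (ncol(genus) >= 2L) {
    dendros$genera <- clusterProfiles(genus, "columns", cfg$linkage)
    writeLines(dendrogramNewick(dendros$genera), out("genus_dendrogram.nwk"))
    manifest <- c(manifest, "genus_dendrogram.nwk")
  }
  if (nrow(genus) >= 2L) {
    dendros$pathways <- clusterProfiles(genus, "rows", cfg$linkage)
    writeLines(dendrogramNewick(dendros$pathways),
               out("pathway_dendrogram.nwk"))
    manifest <- c(manifest, "pathway_dendrogram.nwk")
  }

  enrichment <- list()
  if (!is.null(cfg$oboFile) && !is.null(cfg$gene2goFile) &&
      length(cfg$enrichTaxa)) {
    dag <- loadObo(cfg$oboFile)
    g2g <- utils::read.delim(cfg$gene2goFile, stringsAsFactors = FALSE)
    need <- c("genome_id", "gene_id", "go")
    if (length(setdiff(need, names(g2g))))
      .stopf("gene2go file lacks column(s): %s",
             paste(setdiff(need, names(g2g)), collapse = ", "))
    g2g <- g2g[g2g$genome_id %in% qc$kept$genome_id, , drop = FALSE]
    direct <- lapply(split(g2g$go, g2g$gene_id),
                     function(x) unique(unlist(strsplit(x, ";", fixed = TRUE))))
    ann <- annotateUp(dag, direct)
    geneGenome <- g2g$genome_id[match(names(ann), g2g$gene_id)]
    background <- names(ann)
    for (taxon in cfg$enrichTaxa) {
      gset <- qc$kept$genome_id[qc$kept$phylum == taxon]
      study <- background[geneGenome %in% gset]
      if (!length(study)) {
        .warnf("no genes for taxon %s; skipping enrichment", taxon)
        next
      }
      res <- elimEnrichment(dag, study, background, ann, cfg$enrichment)
      enrichment[[taxon]] <- filterAndRank(res, cfg$enrichment)
      safe <- gsub("[^A-Za-z0-9._-]", "_", taxon)
      emit(enrichment[[taxon]], paste0("enrichment_", safe, ".tsv"))
    }
  }

  writeLines(c("# pathphylo run outputs", sort(unique(manifest))),
             out("MANIFEST.txt"))
  .logmsg("wrote %d output file(s) to %s", length(unique(manifest)),
          cfg$outDir)
  invisible(list(tree = tree, ages = ages, profiles = profiles,
                 genusProfiles = genus, scores = scores, events = events,
                 summary = summary, subtrees = subtrees,
                 dendrograms = dendros, enrichment = enrichment, qc = qc))
}

# --- command-line front end ------------------------------------------

.cliUsage <- function() {
  paste(
    "usage: pathphylo <subcommand> [options]",
    "  compare-trees <a.nwk> <b.nwk>          print RF and branch score",
    "  score-pathways --tree F --metadata F --reports F[,F...] --out DIR",
    "                 [--subtree PWY[,PWY...]]",
    "  reduce-subtree --tree F --metadata F --reports F[,F...] --out DIR",
    "                 --pathway PWY",
    "  cluster-genera --tree F --metadata F --reports F[,F...] --out DIR",
    "  enrich         --tree F --metadata F --reports F[,F...] --out DIR",
    "                 --obo F --gene2go F --taxa T[,T...]",
    "  simulate       --seed N --out DIR [--ntips N]",
    "common: --log-level quiet|info", sep = "\n")
}

.cliOpts <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args)) .stopf("flag %s needs a value", a)
      opts[[substring(a, 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{compare-trees},
#' \code{score-pathways}, \code{reduce-subtree}, \code{cluster-genera},
#' \code{enrich} and \code{simulate} over the package functions. Results
#' go to files (except \code{compare-trees}, which prints its two
#' numbers); log messages go to stderr.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments, so an Rscript wrapper can call
#'   \code{quit(status = pathphyloCli())}).
#' @return integer exit status: 0 on success, 2 on usage or validation
#'   errors.
#' @export
pathphyloCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) .stopf("no subcommand given")
    sub <- args[1L]
    pa <- .cliOpts(args[-1L])
    o <- pa$opts
    known <- c("tree", "metadata", "reports", "out", "subtree", "pathway",
               "obo", "gene2go", "taxa", "seed", "ntips", "log-level")
    bad <- setdiff(names(o), known)
    if (length(bad)) .stopf("unknown flag(s): --%s", paste(bad, collapse = ", --"))
    if (identical(o[["log-level"]], "quiet")) {
      old <- options(pathphylo.quiet = TRUE); on.exit(options(old))
    }
    need <- function(flags) {
      miss <- flags[!flags %in% names(o)]
      if (length(miss)) .stopf("%s requires --%s", sub,
                               paste(miss, collapse = ", --"))
    }
    splitArg <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
    if (sub == "compare-trees") {
      if (length(pa$pos) != 2L) .stopf("compare-trees needs two tree files")
      t1 <- readNewick(pa$pos[1L]); t2 <- readNewick(pa$pos[2L])
      cat(sprintf("robinson_foulds\t%d\nbranch_score\t%s\n",
                  robinsonFoulds(t1, t2), .fmtLen(branchScore(t1, t2))))
    } else if (sub == "simulate") {
      need(c("seed", "out"))
      cfg <- simConfig(seed = as.integer(o$seed),
                       nTips = if (is.null(o$ntips)) 40L
                               else as.integer(o$ntips))
      generateFixtureCorpus(o$out, cfg)
    } else if (sub %in% c("score-pathways", "reduce-subtree",
                          "cluster-genera", "enrich")) {
      need(c("tree", "metadata", "reports", "out"))
      if (sub == "reduce-subtree") need("pathway")
      if (sub == "enrich") need(c("obo", "gene2go", "taxa"))
      cfg <- pipelineConfig(
        treeFile = o$tree, metadataFile = o$metadata,
        reportFiles = splitArg(o$reports), outDir = o$out,
        oboFile = o$obo, gene2goFile = o$gene2go,
        enrichTaxa = if (is.null(o$taxa)) NULL else splitArg(o$taxa),
        subtreePathways = if (!is.null(o$pathway)) splitArg(o$pathway)
                          else if (!is.null(o$subtree)) splitArg(o$subtree)
                          else NULL)
      runFunctionPhylogenomics(cfg)
    } else {
      .stopf("unknown subcommand: %s", sub)
    }
    0L
  }
  tryCatch(run(), error = function(e) {
    message(conditionMessage(e))
    message(.cliUsage())
    2L
  })
}
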