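#' Construct a PathwayProfiles object
#'
#' @param presence a pathways x genomes matrix with values in \{0, 1\};
#'   dimnames are required (pathway ids, genome ids).
#' @param genomeData optional data.frame of genome metadata with a
#'   \code{genome_id} column (or rownames) covering every matrix column.
#' @return a \linkS4class{PathwayProfiles}.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("pwy1", "pwy2"), c("g1", "g2")))
#' PathwayProfiles(m)
#' @export
PathwayProfiles <- function(presence, genomeData = NULL) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (is.null(genomeData)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(presence))
  } else {
    gd <- as.data.frame(genomeData)
    if ("genome_id" %in% names(gd)) rownames(gd) <- gd$genome_id
    miss <- setdiff(colnames(presence), rownames(gd))
    if (length(miss))
      .stopf("metadata missing for genome(s): %s", paste(miss, collapse = ", "))
    cd <- S4Vectors::DataFrame(gd[colnames(presence), , drop = FALSE])
  }
  new("PathwayProfiles", SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = presence), colData = cd))
}

#' Genome quality-control configuration
#'
#' Thresholds used when assembling the analysis corpus: genomes with more
#' contigs than \code{maxContigs} (highly fragmented assemblies) or fewer
#' predicted genes than \code{minGenes} (likely incomplete) are
#' discarded, and pathway calls below \code{minConfidence} are ignored.
#'
#' @param maxContigs keep genomes with at most this many contigs (1000).
#' @param minGenes keep genomes with at least this many predicted
#'   protein-coding genes (400).
#' @param minConfidence inclusive lower bound on the pathway-inference
#'   confidence factor (70).
#' @return a validated list of class \code{qcConfig}.
#' @export
qcConfig <- function(maxContigs = 1000, minGenes = 400, minConfidence = 70) {
  stopifnot(maxContigs > 0, minGenes > 0, minConfidence > 0)
  structure(list(maxContigs = maxContigs, minGenes = minGenes,
                 minConfidence = minConfidence), class = "qcConfig")
}

#' Read a genome metadata table
#'
#' Tab-delimited with header columns \code{genome_id}, \code{genus},
#' \code{phylum}, \code{domain}, \code{status}, \code{n_contigs},
#' \code{n_genes}.
#'
#' @param file path to the TSV.
#' @return a data.frame, one row per genome.
#' @export
readGenomeMetadata <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("genome_id", "genus", "phylum", "domain", "status",
            "n_contigs", "n_genes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("metadata file %s lacks column(s): %s", file,
           paste(miss, collapse = ", "))
  if (anyDuplicated(df$genome_id))
    .stopf("duplicate genome_id in %s", file)
  if (any(df$n_contigs < 1) || any(df$n_genes < 0))
    .stopf("invalid contig/gene counts in %s", file)
  df
}

#' Quality-filter genomes
#'
#' Keeps genomes with \code{n_contigs <= maxContigs} and
#' \code{n_genes >= minGenes}; every rejection is logged with its reason.
#'
#' @param records genome metadata data.frame (see [readGenomeMetadata()]).
#' @param cfg a [qcConfig()].
#' @return list with elements \code{kept} (data.frame) and
#'   \code{rejected} (data.frame: genome_id, reason).
#' @export
qcFilterGenomes <- function(records, cfg = qcConfig()) {
  stopifnot(nrow(records) > 0)
  badContigs <- records$n_contigs > cfg$maxContigs
  badGenes <- records$n_genes < cfg$minGenes
  reason <- character(nrow(records))
  reason[badContigs] <- sprintf("contigs>%d", cfg$maxContigs)
  reason[badGenes] <- sprintf("genes<%d", cfg$minGenes)
  reason[badContigs & badGenes] <- sprintf("contigs>%d;genes<%d",
                                           cfg$maxContigs, cfg$minGenes)
  drop <- badContigs | badGenes
  list(kept = records[!drop, , drop = FALSE],
       rejected = data.frame(genome_id = records$genome_id[drop],
                             reason = reason[drop], stringsAsFactors = FALSE))
}

#' Load per-genome pathway reports into a presence/absence matrix
#'
#' Each report row states a pathway call with a confidence factor; a
#' pathway is present in a genome iff some row for that pair reaches
#' \code{minConfidence} (duplicate rows collapse by maximum confidence —
#' presence is an existential claim). The pathway universe is the union
#' of pathway ids observed across all files.
#'
#' @param files character vector of TSV paths with columns
#'   \code{pathway_id} and \code{confidence}; an optional
#'   \code{genome_id} column overrides the default genome id (the file's
#'   base name without extension).
#' @param cfg a [qcConfig()]; only \code{minConfidence} is used.
#' @param metadata optional genome metadata attached as \code{colData}.
#' @return a \linkS4class{PathwayProfiles} (pathways x genomes).
#' @export
loadPathwayReports <- function(files, cfg = qcConfig(), metadata = NULL) {
  parts <- lapply(files, function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    miss <- setdiff(c("pathway_id", "confidence"), names(df))
    if (length(miss))
      .stopf("pathway report %s lacks column(s): %s", f,
             paste(miss, collapse = ", "))
    if (!("genome_id" %in% names(df)))
      df$genome_id <- sub("\\.[^.]*$", "", basename(f))
    df[, c("genome_id", "pathway_id", "confidence")]
  })
  all <- do.call(rbind, parts)
  genomes <- sort(unique(all$genome_id))
  pathways <- sort(unique(all$pathway_id))
  best <- tapply(all$confidence,
                 list(factor(all$pathway_id, pathways),
                      factor(all$genome_id, genomes)),
                 max)
  m <- matrix(0L, length(pathways), length(genomes),
              dimnames = list(pathways, genomes))
  m[!is.na(best) & best >= cfg$minConfidence] <- 1L
  PathwayProfiles(m, genomeData = metadata)
}

#' Aggregate genome profiles to genus pan-genome profiles
#'
#' A pathway is present in a genus if it is present in any member genome
#' (logical OR over columns), reducing the effect of uneven genus
#' representation.
#'
#' @param x a \linkS4class{PathwayProfiles} whose \code{colData} has a
#'   \code{genus} column.
#' @return a \linkS4class{PathwayProfiles} with one column per genus;
#'   \code{colData} records the member count and the domain/phylum when
#'   unique within the genus.
#' @export
aggregateByGenus <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!("genus" %in% names(cd)) || anyNA(cd$genus))
    .stopf("every genome needs a genus in colData")
  gen <- as.character(cd$genus)
  m <- presence(x)
  genera <- sort(unique(gen))
  agg <- vapply(genera,
                function(g) as.integer(rowSums(m[, gen == g, drop = FALSE]) > 0),
                integer(nrow(m)))
  dimnames(agg) <- list(rownames(m), genera)
  uniq <- function(col) vapply(genera, function(g) {
    u <- unique(as.character(cd[[col]][gen == g]))
    if (length(u) == 1L) u else NA_character_
  }, "")
  gd <- data.frame(genome_id = genera, genus = genera,
                   n_genomes = as.integer(table(factor(gen, genera))),
                   stringsAsFactors = FALSE)
  for (col in intersect(c("domain", "phylum"), names(cd))) gd[[col]] <- uniq(col)
  PathwayProfiles(agg, genomeData = gd)
}

#' Manhattan distance between two binary profiles
#'
#' The number of differing entries (Hamming count for 0/1 vectors).
#'
#' @param v1,v2 equal-length numeric vectors.
#' @return non-negative number; an integer count for binary input.
#' @export
manhattanDistance <- function(v1, v2) {
  if (length(v1) != length(v2))
    .stopf("length mismatch: %d vs %d", length(v1), length(v2))
  sum(abs(v1 - v2))
}

#' Hierarchically cluster pathway profiles
#'
#' Agglomerative clustering with Manhattan distance. Items are sorted by
#' id before clustering so the result is invariant to input order and
#' leaf order is deterministic.
#'
#' @param x a \linkS4class{PathwayProfiles} or a numeric matrix.
#' @param axis \code{"columns"} to cluster genomes/genera by their
#'   pathway profiles, \code{"rows"} to cluster pathways by their
#'   distribution.
#' @param linkage agglomeration rule (default complete).
#' @return an \code{hclust} object; a degenerate merge-free \code{hclust}
#'   when only one item is present.
#' @export
clusterProfiles <- function(x, axis = c("columns", "rows"),
                            linkage = c("complete", "single", "average")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- if (is(x, "PathwayProfiles")) presence(x) else as.matrix(x)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 1L) .stopf("nothing to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) == 1L)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = rownames(m), method = linkage,
                          dist.method = "manhattan"),
                     class = "hclust"))
  stats::hclust(stats::dist(m, method = "manhattan"), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} from [clusterProfiles()].
#' @return a Newick string with branch lengths derived from merge heights.
#' @export
dendrogramNewick <- function(hc) {
  if (length(hc$order) == 1L)
    return(sprintf("(%s:0);", hc$labels))
  writeNewick(ape::as.phylo(hc))
}

#' Write a presence/absence matrix as TSV
#'
#' @param x a \linkS4class{PathwayProfiles} or matrix.
#' @param file output path; row ids go in the first column.
#' @export
writeProfileMatrix <- function(x, file) {
  m <- if (is(x, "PathwayProfiles")) presence(x) else as.matrix(x)
  df <- data.frame(pathway_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
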