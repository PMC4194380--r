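#' @import methods
#' @importFrom ape Ntip
NULL

setOldClass("phylo")
setOldClass("hclust")

#' PathwayProfiles: pathway presence/absence profiles with genome metadata
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{presence} assay
#' is a pathways x genomes 0/1 matrix; \code{colData} carries the genome
#' metadata (genus, phylum, domain, completion status, contig and gene
#' counts). Rows are pathway identifiers, columns genome (or, after
#' [aggregateByGenus()], genus) identifiers.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [PathwayProfiles()], [aggregateByGenus()], [scorePathways()]
#' @export
setClass("PathwayProfiles", contains = "SummarizedExperiment")

setValidity("PathwayProfiles", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("presence" %in% a)) return("assay 'presence' is required")
  m <- SummarizedExperiment::assay(object, "presence")
  if (!all(m %in% c(0, 1))) return("presence values must be 0 or 1")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn)) return("pathway ids must be unique")
  if (is.null(cn) || anyDuplicated(cn)) return("genome ids must be unique")
  TRUE
})

#' RIResult: retention index of a binary character
#'
#' Holds the quantities entering the retention index
#' \eqn{RI = (g - s) / (g - m)}: \code{g}, the maximum possible number of
#' changes (the minority-state tip count for a binary character); \code{s},
#' the parsimony score; and \code{m}, the minimum possible number of
#' changes (1 when both states are observed, otherwise 0). Constant
#' characters, for which the ratio is 0/0, are assigned RI 1 and flagged.
#'
#' @slot pathway character id of the character (may be \code{NA}).
#' @slot nPresent,nTotal integer occurrence counts at the tips.
#' @slot g,s,m integer ingredients of the index.
#' @slot ri numeric retention index in [0, 1].
#' @slot constant logical; \code{TRUE} when only one state is observed.
#' @seealso [retentionIndex()], [classifyConsistency()]
#' @export
setClass("RIResult", representation(
  pathway = "character", nPresent = "integer", nTotal = "integer",
  g = "integer", s = "integer", m = "integer",
  ri = "numeric", constant = "logical"))

setValidity("RIResult", function(object) {
  if (object@constant) return(TRUE)
  if (object@m > object@s || object@s > object@g)
    return("requires m <= s <= g for a non-constant character")
  TRUE
})

#' AncestralStates: one most-parsimonious labeling of internal nodes
#'
#' Result of the two-pass Fitch/Hartigan reconstruction: per-node
#' preliminary state sets from the bottom-up pass and a single assigned
#' 0/1 state per node from the top-down pass. The number of edges whose
#' endpoint states differ equals the parsimony score.
#'
#' @slot tree the \code{phylo} object the states refer to.
#' @slot states integer 0/1 vector indexed by node number.
#' @slot prelim logical matrix (nodes x 2): can the node be 0 / be 1.
#' @slot score integer parsimony score.
#' @slot rootRule character, the tie rule applied at the root.
#' @seealso [fitchAncestral()], [changeEvents()], [reduceSubtree()]
#' @export
setClass("AncestralStates", representation(
  tree = "phylo", states = "integer", prelim = "matrix",
  score = "integer", rootRule = "character"))

#' ReducedSubtree: collapsed, colored subtree of a pathway
#'
#' The full tree with every maximal all-absent clade collapsed to a single
#' tip. Node colors record state changes relative to the immediate
#' ancestor (red = gain, blue = loss, none = no change); the root's color
#' encodes its state only (red = present, blue = absent) and does not
#' count as a change. Edges descending from presence-state nodes are
#' flagged green.
#'
#' @slot tree the reduced \code{phylo}; internal nodes are labeled
#'   \code{N<original node number>} for traceability.
#' @slot states named integer 0/1 per reduced-tree node label.
#' @slot colors named character in \code{red}/\code{blue}/\code{none}.
#' @slot rootState integer state at the root.
#' @slot greenEdges character labels of nodes whose parent edge is green.
#' @slot collapsed data.frame describing each collapsed clade
#'   (label, size, firstTip).
#' @slot changeCount integer; non-root colored nodes, equals the
#'   parsimony score of the reconstruction.
#' @seealso [reduceSubtree()]
#' @export
setClass("ReducedSubtree", representation(
  tree = "phylo", states = "integer", colors = "character",
  rootState = "integer", greenEdges = "character",
  collapsed = "data.frame", changeCount = "integer"))

#' GoDag: Gene Ontology graph over is_a edges
#'
#' @slot ids character vector of non-obsolete term ids.
#' @slot parents named list: term id -> character vector of is_a parents.
#' @slot termNames named character: term id -> name.
#' @slot namespace named character: term id -> namespace tag.
#' @seealso [loadObo()], [annotateUp()], [elimEnrichment()]
#' @export
setClass("GoDag", representation(
  ids = "character", parents = "list",
  termNames = "character", namespace = "character"))

#' HmmerHit: aggregated homology hit of a query protein against an HMM
#'
#' One object per (query, family) pair, pooling that pair's per-domain
#' alignment rows.
#'
#' @slot query,family character identifiers.
#' @slot evalue numeric whole-sequence e-value (> 0).
#' @slot qlen,hmmlen integer lengths of the query protein and the HMM.
#' @slot qIntervals,hIntervals integer matrices (from, to), 1-based
#'   inclusive, of the aligned regions on the query and on the HMM.
#' @seealso [parseDomtbl()], [hitCoverage()], [filterHits()]
#' @export
setClass("HmmerHit", representation(
  query = "character", family = "character", evalue = "numeric",
  qlen = "integer", hmmlen = "integer",
  qIntervals = "matrix", hIntervals = "matrix"))

setValidity("HmmerHit", function(object) {
  if (object@evalue <= 0) return("e-value must be > 0")
  ok <- function(iv, len) nrow(iv) == 0L ||
    (all(iv[, 1L] >= 1L) && all(iv[, 2L] <= len) && all(iv[, 1L] <= iv[, 2L]))
  if (!ok(object@qIntervals, object@qlen)) return("query intervals out of range")
  if (!ok(object@hIntervals, object@hmmlen)) return("HMM intervals out of range")
  TRUE
})

#' FamilyAnnotation: annotation payload of a protein family
#'
#' Deduplicated sets of recommended product names, EC numbers, gene names
#' and GO ids attached to a family and transferred to its matched queries.
#'
#' @slot family character family id.
#' @slot productNames,ec,geneNames,go character vectors (sets).
#' @seealso [mergeFamilyAnnotations()]
#' @export
setClass("FamilyAnnotation", representation(
  family = "character", productNames = "character", ec = "character",
  geneNames = "character", go = "character"))

setValidity("FamilyAnnotation", function(object) {
  bad <- object@go[!grepl("^GO:[0-9]{7}$", object@go)]
  if (length(bad))
    return(paste("malformed GO id(s):", paste(bad, collapse = ", ")))
  TRUE
})
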