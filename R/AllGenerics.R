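#' @name pathphylo-accessors
#' @title Accessors for pathphylo classes
#' @description Slot accessors: \code{riValue} and \code{parsimonyScore}
#'   extract the retention index and parsimony score, \code{isConstant}
#'   flags constant characters, \code{nodeStates}/\code{nodeColors}/
#'   \code{greenEdges}/\code{reducedTree} read reconstruction and subtree
#'   results, and \code{presence} returns the 0/1 pathway matrix of a
#'   \linkS4class{PathwayProfiles}.
#' @param x an object of the documented class.
#' @return the slot value (see each method's class documentation).
NULL

#' @rdname pathphylo-accessors
#' @export
setGeneric("riValue", function(x) standardGeneric("riValue"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("parsimonyScore", function(x) standardGeneric("parsimonyScore"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("isConstant", function(x) standardGeneric("isConstant"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("nodeColors", function(x) standardGeneric("nodeColors"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("greenEdges", function(x) standardGeneric("greenEdges"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("reducedTree", function(x) standardGeneric("reducedTree"))
#' @rdname pathphylo-accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname pathphylo-accessors
#' @export
setMethod("riValue", "RIResult", function(x) x@ri)
#' @rdname pathphylo-accessors
#' @export
setMethod("parsimonyScore", "RIResult", function(x) x@s)
#' @rdname pathphylo-accessors
#' @export
setMethod("isConstant", "RIResult", function(x) x@constant)
#' @rdname pathphylo-accessors
#' @export
setMethod("parsimonyScore", "AncestralStates", function(x) x@score)
#' @rdname pathphylo-accessors
#' @export
setMethod("nodeStates", "AncestralStates", function(x) x@states)
#' @rdname pathphylo-accessors
#' @export
setMethod("nodeStates", "ReducedSubtree", function(x) x@states)
#' @rdname pathphylo-accessors
#' @export
setMethod("nodeColors", "ReducedSubtree", function(x) x@colors)
#' @rdname pathphylo-accessors
#' @export
setMethod("greenEdges", "ReducedSubtree", function(x) x@greenEdges)
#' @rdname pathphylo-accessors
#' @export
setMethod("reducedTree", "ReducedSubtree", function(x) x@tree)
#' @rdname pathphylo-accessors
#' @export
setMethod("presence", "PathwayProfiles",
          function(x) SummarizedExperiment::assay(x, "presence"))

setMethod("show", "RIResult", function(object) {
  cat(sprintf(
    "RIResult%s: %d/%d present; g=%d s=%d m=%d; RI=%.4f (%.2f)%s\n",
    if (is.na(object@pathway)) "" else paste0(" [", object@pathway, "]"),
    object@nPresent, object@nTotal, object@g, object@s, object@m,
    object@ri, roundHalfUp(object@ri, 2),
    if (object@constant) " [constant]" else ""))
})

setMethod("show", "AncestralStates", function(object) {
  cat(sprintf(
    "AncestralStates: %d tips, %d internal nodes, parsimony score %d (root rule: %s)\n",
    ape::Ntip(object@tree), object@tree$Nnode, object@score, object@rootRule))
})

setMethod("show", "ReducedSubtree", function(object) {
  cat(sprintf(
    "ReducedSubtree: %d tips (%d collapsed clades), root state %d, %d change nodes\n",
    ape::Ntip(object@tree), nrow(object@collapsed), object@rootState,
    object@changeCount))
})

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag: %d terms, %d is_a edges, namespaces: %s\n",
              length(object@ids), sum(lengths(object@parents)),
              paste(unique(object@namespace), collapse = ", ")))
})

setMethod("show", "HmmerHit", function(object) {
  cv <- hitCoverage(object)
  cat(sprintf("HmmerHit: %s -> %s, e-value %.3g, qcov %.2f, hcov %.2f\n",
              object@query, object@family, object@evalue, cv[["query"]],
              cv[["hmm"]]))
})

setMethod("show", "FamilyAnnotation", function(object) {
  cat(sprintf("FamilyAnnotation [%s]: %d name(s), %d EC, %d gene name(s), %d GO\n",
              object@family, length(object@productNames), length(object@ec),
              length(object@geneNames), length(object@go)))
})
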