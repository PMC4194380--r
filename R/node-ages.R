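#' Assign scaled node ages by mean path length
#'
#' Each internal node's raw age is the mean path length (sum of branch
#' lengths) from the node to its descendant tips. Raw ages are then clamped
#' bottom-up so a parent is never younger than a child, and finally
#' rescaled linearly so the root sits at \code{rootAge} and extant tips at
#' 0. Only relative node ordering is meaningful downstream (gain/loss
#' clocking), for which this smoothing is sufficient.
#'
#' @param tree a \code{phylo} object with non-negative branch lengths and
#'   at least 2 tips.
#' @param rootAge age given to the root on the scaled clock (default 100).
#' @return a numeric vector of ages indexed by node number (tips first,
#'   then internal nodes, \pkg{ape} convention), named by tip label or
#'   \code{N<number>}; carries a \code{rootAge} attribute.
#' @examples
#' ages <- assignNodeAges(parseNewick("((A:1,B:1):1,C:2);"))
#' ages[["N5"]]  # 50: the cherry sits halfway up a tree of mean depth 2
#' @export
assignNodeAges <- function(tree, rootAge = 100) {
  .validateTree(tree)
  stopifnot(is.numeric(rootAge), length(rootAge) == 1L, rootAge > 0)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) .stopf("need at least 2 tips to date a tree")
  if (is.null(tree$edge.length)) .stopf("tree has no branch lengths")

  n <- ntip + tree$Nnode
  len <- .edgeLenAbove(tree)
  kids <- .childList(tree)
  nBelow <- lengths(.tipsBelow(tree))
  pathSum <- numeric(n)
  age <- numeric(n)
  for (v in .postorderNodes(tree)) {
    cs <- kids[[v]]
    pathSum[v] <- sum(pathSum[cs] + len[cs] * nBelow[cs])
    raw <- pathSum[v] / nBelow[v]
    age[v] <- max(raw, age[cs])  # clamp: parent at least as old as children
  }
  root <- ntip + 1L
  if (age[root] <= 0)
    .stopf("degenerate tree: total depth is zero, cannot scale ages")
  age <- age * (rootAge / age[root])
  names(age) <- c(tree$tip.label, paste0("N", seq_len(tree$Nnode) + ntip))
  attr(age, "rootAge") <- rootAge
  age
}
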