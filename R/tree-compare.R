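# Tree-comparison metrics. Trees are compared as unrooted: the split
# induced by each internal edge, canonicalized to its smaller tip set.

.SEPCHR <- "\x1f"

# key -> (labels, length) for every non-trivial split; a binary root's two
# child edges describe the same unrooted edge and their lengths are summed.
.splitTable <- function(tree) {
  .validateTree(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  below <- .tipsBelow(tree)
  len <- if (is.null(tree$edge.length)) NULL else .edgeLenAbove(tree)
  labs <- tree$tip.label
  keys <- character(0); sides <- list(); lens <- numeric(0)
  internal <- setdiff(seq_len(tree$Nnode) + ntip, root)
  for (v in internal) {
    clade <- labs[below[[v]]]
    if (length(clade) < 2L || ntip - length(clade) < 2L) next
    other <- setdiff(labs, clade)
    side <- if (length(clade) < length(other)) clade
            else if (length(other) < length(clade)) other
            else {  # equal halves: lexicographically smaller key wins
      a <- paste(sort(clade), collapse = .SEPCHR)
      b <- paste(sort(other), collapse = .SEPCHR)
      if (a <= b) clade else other
    }
    key <- paste(sort(side), collapse = .SEPCHR)
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      sides <- c(sides, list(sort(side)))
      lens <- c(lens, if (is.null(len)) NA_real_ else len[v])
    } else if (!is.null(len)) {
      lens[j] <- lens[j] + len[v]
    }
  }
  list(keys = keys, sides = sides, lens = lens)
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted version of the tree splits the tips in
#' two; the split is reported as its smaller side (sorted labels). Trivial
#' splits (a side with fewer than 2 tips) are excluded and the edge at a
#' binary root is counted once.
#'
#' @param tree a \code{phylo} object.
#' @return a list of sorted character vectors, one per internal edge; empty
#'   for trees with fewer than 4 tips or no internal edges.
#' @examples
#' treeBipartitions(parseNewick("((A,B),(C,D));"))
#' @export
treeBipartitions <- function(tree) {
  if (ape::Ntip(tree) < 4L) return(list())
  st <- .splitTable(tree)
  names(st$sides) <- st$keys
  st$sides
}

.checkSameTips <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b); only2 <- setdiff(b, a)
    .stopf("tip sets differ; only in first: {%s}; only in second: {%s}",
           paste(only1, collapse = ", "), paste(only2, collapse = ", "))
  }
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions implied by one tree but not the
#' other (symmetric difference of the two split sets).
#'
#' @param t1,t2 \code{phylo} objects on the same tip set.
#' @return a non-negative integer.
#' @examples
#' robinsonFoulds(parseNewick("((A,B),(C,D));"), parseNewick("((A,C),(B,D));"))
#' @export
robinsonFoulds <- function(t1, t2) {
  .checkSameTips(t1, t2)
  k1 <- .splitTable(t1)$keys
  k2 <- .splitTable(t2)$keys
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Branch-score distance between two trees
#'
#' Internal branches are matched by the bipartition they induce; a branch
#' present in only one tree is compared against length 0. The score is the
#' Euclidean norm of the length differences over the union of bipartitions.
#'
#' @param t1,t2 \code{phylo} objects with branch lengths on the same tips.
#' @return a non-negative real number; 0 for identical trees.
#' @export
branchScore <- function(t1, t2) {
  .checkSameTips(t1, t2)
  s1 <- .splitTable(t1); s2 <- .splitTable(t2)
  if (anyNA(s1$lens) || anyNA(s2$lens))
    .stopf("branchScore requires branch lengths on both trees")
  keys <- union(s1$keys, s2$keys)
  l1 <- s1$lens[match(keys, s1$keys)]; l1[is.na(l1)] <- 0
  l2 <- s2$lens[match(keys, s2$keys)]; l2[is.na(l2)] <- 0
  sqrt(sum((l1 - l2)^2))
}
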