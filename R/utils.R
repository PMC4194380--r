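# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reporting convention for retention indices: ties at the last kept digit
#' round up (0.975 -> 0.98), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon absorbs binary representation error of exact decimal ties
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# Shortest decimal string that round-trips through as.numeric().
.fmtLen <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

# Total length of the union of 1-based inclusive integer intervals.
.intervalUnionLength <- function(ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(0L)
  o <- order(ivs[, 1L], ivs[, 2L])
  from <- ivs[o, 1L]; to <- ivs[o, 2L]
  total <- 0L
  curF <- from[1L]; curT <- to[1L]
  if (length(from) > 1L) for (i in 2L:length(from)) {
    if (from[i] <= curT + 1L) {
      curT <- max(curT, to[i])
    } else {
      total <- total + (curT - curF + 1L)
      curF <- from[i]; curT <- to[i]
    }
  }
  unname(total + (curT - curF + 1L))
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Children of every node as a list indexed by node number (edge order kept).
.childList <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1L]]] <- c(kids[[e[i, 1L]]], e[i, 2L])
  kids
}

# Internal nodes ordered so every child precedes its parent.
.postorderNodes <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  unique(e[, 1L])
}

# Parent of each node (NA for the root).
.parentVec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# Tip indices below each node (tips below a tip = itself).
.tipsBelow <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  below <- vector("list", n)
  for (i in seq_len(ntip)) below[[i]] <- i
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e)))
    below[[e[i, 1L]]] <- c(below[[e[i, 1L]]], below[[e[i, 2L]]])
  below
}

# Edge length above each node, indexed by child node number (NA for root).
.edgeLenAbove <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  len <- rep(NA_real_, n)
  if (is.null(tree$edge.length))
    .stopf("tree has no branch lengths")
  len[tree$edge[, 2L]] <- tree$edge.length
  len
}
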