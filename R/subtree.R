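#' Reduced, colored subtree of a pathway
#'
#' Collapses every maximal clade in which the pathway is absent at all
#' tips into a single tip (labeled \code{<size>_absent_<first tip>},
#' branch length the distance from the attachment point to the clade's
#' farthest original tip), then colors the remaining nodes from the
#' ancestral reconstruction: the root red/blue by its own state, every
#' other node red (gain) or blue (loss) when its state differs from its
#' parent's, and \code{none} otherwise. Edges descending from
#' presence-state nodes are flagged green. The non-root colored nodes are
#' exactly the change edges, so their count equals the parsimony score;
#' the root's color conveys state only and is excluded.
#'
#' @param anc an \linkS4class{AncestralStates} reconstruction of the
#'   pathway (holds the tree and all node states).
#' @return a \linkS4class{ReducedSubtree}. If the pathway is absent from
#'   every tip the result degenerates to a single collapsed tip, with a
#'   warning.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' anc <- fitchAncestral(tr, c(A = 1, B = 1, C = 0, D = 0))
#' reduceSubtree(anc)
#' @export
reduceSubtree <- function(anc) {
  tree <- anc@tree
  st <- anc@states
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- .childList(tree)
  len <- .edgeLenAbove(tree)
  below <- .tipsBelow(tree)

  # all-absent flag and depth to farthest tip, per node
  absentAll <- vapply(below, function(tp) all(st[tp] == 0L), TRUE)
  depth <- numeric(ntip + tree$Nnode)
  for (v in .postorderNodes(tree)) {
    cs <- kids[[v]]
    depth[v] <- max(len[cs] + depth[cs])
  }

  labmap <- integer(0)  # reduced-tree label -> original node number
  collapsed <- list()
  collapseLab <- function(v) {
    tp <- below[[v]]
    lab <- sprintf("%d_absent_%s", length(tp), tree$tip.label[min(tp)])
    collapsed[[length(collapsed) + 1L]] <<- data.frame(
      label = lab, size = length(tp), firstTip = tree$tip.label[min(tp)],
      stringsAsFactors = FALSE)
    lab
  }
  quoteLab <- function(lab) {
    if (grepl("[][(){}:;,' \t]", lab)) paste0("'", gsub("'", "''", lab), "'")
    else lab
  }
  rec <- function(v) {
    lab <- if (absentAll[v]) collapseLab(v)
           else if (v <= ntip) tree$tip.label[v]
           else paste0("N", v)
    labmap[lab] <<- v
    brlen <- if (v == root) NULL
             else if (absentAll[v]) len[v] + depth[v]
             else len[v]
    body <- if (absentAll[v] || v <= ntip) quoteLab(lab)
            else paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","),
                        ")", lab)
    if (is.null(brlen)) body else paste0(body, ":", .fmtLen(brlen))
  }

  if (absentAll[root]) {
    .warnf("pathway absent from all tips; returning a degenerate single-tip subtree")
    lab <- collapseLab(root)
    labmap[lab] <- root
    txt <- paste0("(", quoteLab(lab), ":", .fmtLen(depth[root]), ")N", root, ";")
    labmap[paste0("N", root)] <- root
  } else {
    txt <- paste0(rec(root), ";")
  }
  rtree <- parseNewick(txt)

  rlabs <- c(rtree$tip.label, rtree$node.label)
  orig <- labmap[rlabs]
  rst <- st[orig]
  names(rst) <- rlabs
  rparent <- .parentVec(rtree)
  rroot <- ape::Ntip(rtree) + 1L
  colors <- rep("none", length(rlabs))
  names(colors) <- rlabs
  for (i in seq_along(rlabs)) {
    v <- if (i <= ape::Ntip(rtree)) i else i  # node number == position
    p <- rparent[i]
    colors[i] <- if (i == rroot) {
      if (rst[i] == 1L) "red" else "blue"
    } else if (rst[i] != rst[p]) {
      if (rst[i] == 1L) "red" else "blue"
    } else "none"
  }
  green <- rlabs[!is.na(rparent) & rst[rparent] == 1L]
  changeCount <- sum(colors[-rroot] != "none")

  new("ReducedSubtree", tree = rtree, states = rst, colors = colors,
      rootState = unname(rst[rroot]),
      greenEdges = green,
      collapsed = if (length(collapsed)) do.call(rbind, collapsed)
                  else data.frame(label = character(0), size = integer(0),
                                  firstTip = character(0)),
      changeCount = as.integer(changeCount))
}

#' Write a reduced subtree to disk
#'
#' Emits the reduced tree as plain Newick plus a sidecar TSV of node
#' colors and states (color-in-comment Newick dialects are not portable).
#'
#' @param x a \linkS4class{ReducedSubtree}.
#' @param prefix output path prefix; writes \code{<prefix>.nwk} and
#'   \code{<prefix>_nodes.tsv}.
#' @return invisibly, the two file paths.
#' @export
writeReducedSubtree <- function(x, prefix) {
  nwk <- paste0(prefix, ".nwk")
  tsv <- paste0(prefix, "_nodes.tsv")
  writeNewick(x@tree, file = nwk)
  df <- data.frame(node_id = names(x@states), color = unname(x@colors),
                   state = unname(x@states),
                   green_edge_below = names(x@states) %in% x@greenEdges,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nwk, tsv))
}
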