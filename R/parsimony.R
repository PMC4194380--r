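# Fitch/Hartigan parsimony for binary characters on rooted (possibly
# multifurcating) trees, the retention index, and gain/loss clocking.

# Bottom-up pass. Returns the parsimony score and the per-node
# preliminary state sets as a logical (nodes x 2) matrix [can be 0, can
# be 1]. At a node, each state is scored by how many children allow it;
# the node's set is the argmax, and (children - max) changes are charged
# (Hartigan's generalization, exact on multifurcations).
.fitchUp <- function(tree, states) {
  .validateTree(tree)
  ntip <- ape::Ntip(tree)
  x <- states[tree$tip.label]
  miss <- tree$tip.label[is.na(x)]
  if (length(miss))
    .stopf("character lacks a state for tip(s): %s", paste(miss, collapse = ", "))
  if (!all(x %in% c(0, 1))) .stopf("states must be 0 or 1")

  n <- ntip + tree$Nnode
  can <- matrix(FALSE, n, 2L)
  can[seq_len(ntip), 1L] <- x == 0
  can[seq_len(ntip), 2L] <- x == 1
  kids <- .childList(tree)
  score <- 0L
  for (v in .postorderNodes(tree)) {
    cs <- kids[[v]]
    c0 <- sum(can[cs, 1L]); c1 <- sum(can[cs, 2L])
    m <- max(c0, c1)
    can[v, 1L] <- c0 == m
    can[v, 2L] <- c1 == m
    score <- score + (length(cs) - m)
  }
  list(score = as.integer(score), can = can)
}

#' Parsimony score of a binary character on a tree
#'
#' The minimum number of 0<->1 state changes along branches needed to
#' produce the observed tip states, computed with the Fitch algorithm
#' (Hartigan's majority recurrence at multifurcating nodes, so the score
#' remains minimal on non-binary trees).
#'
#' @param tree a \code{phylo} object.
#' @param states named 0/1 vector covering every tip label.
#' @return non-negative integer parsimony score.
#' @examples
#' tr <- parseNewick("((A,B),(C,D));")
#' fitchScore(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2 independent origins
#' @export
fitchScore <- function(tree, states) .fitchUp(tree, states)$score

#' One most-parsimonious ancestral reconstruction
#'
#' Top-down pass over the preliminary sets of [fitchScore()]'s bottom-up
#' pass: the root takes its unique allowed state (ties resolved by
#' \code{rootTie}); every other node takes its parent's state when its
#' preliminary set allows it, otherwise its unique allowed state. The
#' induced number of change edges equals the parsimony score.
#'
#' @inheritParams fitchScore
#' @param rootTie tie rule when both states are allowed at the root:
#'   \code{"absent"} (default, conservative about inferring ancient
#'   presence), \code{"present"}, or \code{"majority"} (majority tip
#'   state, ties resolved to absent).
#' @return an \linkS4class{AncestralStates} object.
#' @export
fitchAncestral <- function(tree, states,
                           rootTie = c("absent", "present", "majority")) {
  rootTie <- match.arg(rootTie)
  up <- .fitchUp(tree, states)
  can <- up$can
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  assign <- rep(NA_integer_, nrow(can))

  pick <- function(v, want) {
    if (can[v, want + 1L]) want
    else if (can[v, 1L]) 0L
    else 1L
  }
  rootWant <- switch(rootTie,
    absent = 0L, present = 1L,
    majority = {
      x <- states[tree$tip.label]
      if (sum(x == 1) > sum(x == 0)) 1L else 0L
    })
  assign[root] <- pick(root, rootWant)
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(e))))  # preorder: parents before children
    assign[e[i, 2L]] <- pick(e[i, 2L], assign[e[i, 1L]])

  new("AncestralStates", tree = tree, states = assign, prelim = can,
      score = up$score, rootRule = rootTie)
}

#' Retention index of a binary character
#'
#' \eqn{RI = (g - s)/(g - m)} where \code{g} is the maximum possible
#' number of changes (the smaller of the presence and absence tip
#' counts), \code{s} the parsimony score, and \code{m} the minimum
#' possible number of changes (1 when both states are observed, else 0).
#' RI 1 means the character fits the tree perfectly; low values indicate
#' homoplasy (e.g. horizontally transferred pathways). For constant
#' characters the ratio is 0/0; they are assigned RI 1 and flagged, so
#' downstream classification stays total. When \code{g == m} the score is
#' forced to its minimum and RI is likewise 1.
#'
#' @param nPresent number of tips carrying the character.
#' @param nTotal total number of tips.
#' @param s parsimony score of the character on the tree.
#' @param pathway optional character id recorded in the result.
#' @return an \linkS4class{RIResult}.
#' @examples
#' # aerobic respiration-like profile: 9383 of 14727 genomes, score 290
#' riValue(retentionIndex(9383, 14727, 290))  # 0.9459 -> prints as 0.95
#' @export
retentionIndex <- function(nPresent, nTotal, s, pathway = NA_character_) {
  nPresent <- as.integer(nPresent); nTotal <- as.integer(nTotal)
  s <- as.integer(s)
  stopifnot(length(nPresent) == 1L, length(nTotal) == 1L, length(s) == 1L)
  if (nPresent < 0L || nPresent > nTotal)
    .stopf("need 0 <= nPresent <= nTotal")
  g <- min(nPresent, nTotal - nPresent)
  m <- if (nPresent > 0L && nPresent < nTotal) 1L else 0L
  constant <- g == 0L
  if (s > g)
    .stopf("impossible parsimony score: s = %d exceeds g = %d", s, g)
  if (s < m)
    .stopf("impossible parsimony score: s = %d below minimum m = %d", s, m)
  ri <- if (constant || g == m) 1 else (g - s) / (g - m)
  new("RIResult", pathway = pathway, nPresent = nPresent, nTotal = nTotal,
      g = g, s = s, m = m, ri = ri, constant = constant)
}

#' Classify characters by retention index
#'
#' Characters with RI above the upper threshold are consistent with the
#' phylogeny; below the lower threshold they are inconsistent (a
#' signature of horizontal transfer); in between, intermediate.
#'
#' @param ri numeric vector of retention indices in [0, 1].
#' @param lower,upper class boundaries (defaults 0.7 and 0.9; the class
#'   tests are strict \code{<} and \code{>}).
#' @return character vector in
#'   \code{c("consistent", "intermediate", "inconsistent")}.
#' @examples
#' classifyConsistency(c(0.95, 0.80, 0.56))
#' @export
classifyConsistency <- function(ri, lower = 0.7, upper = 0.9) {
  stopifnot(lower < upper)
  if (any(ri < 0 | ri > 1, na.rm = TRUE)) .stopf("ri must lie in [0, 1]")
  out <- rep("intermediate", length(ri))
  out[ri > upper] <- "consistent"
  out[ri < lower] <- "inconsistent"
  out
}

#' Clocked gain/loss events of a reconstruction
#'
#' One event per edge whose endpoint states differ: a gain for 0 -> 1, a
#' loss for 1 -> 0. The event's age interval is [child age, parent age]
#' on the scaled clock and its point age is the branch midpoint (the
#' placement of a change within a branch is unidentifiable).
#'
#' @param anc an \linkS4class{AncestralStates}.
#' @param ages node ages from [assignNodeAges()] on the same tree.
#' @return a data.frame (parent, child, direction, age_lo, age_hi,
#'   age_mid) sorted by descending point age; zero rows for constant
#'   reconstructions.
#' @export
changeEvents <- function(anc, ages) {
  tree <- anc@tree
  n <- ape::Ntip(tree) + tree$Nnode
  if (length(ages) != n)
    .stopf("ages cover %d nodes but the tree has %d", length(ages), n)
  st <- anc@states
  e <- tree$edge
  diffp <- st[e[, 1L]] != st[e[, 2L]]
  e <- e[diffp, , drop = FALSE]
  out <- data.frame(
    parent = names(ages)[e[, 1L]],
    child = names(ages)[e[, 2L]],
    direction = ifelse(st[e[, 2L]] == 1L, "gain", "loss"),
    age_lo = unname(ages[e[, 2L]]),
    age_hi = unname(ages[e[, 1L]]),
    stringsAsFactors = FALSE)
  out$age_mid <- (out$age_lo + out$age_hi) / 2
  out[order(-out$age_mid, out$parent, out$child), , drop = FALSE]
}

#' Score every pathway of a profile matrix on a tree
#'
#' Runs [fitchScore()] and [retentionIndex()] for each pathway of a
#' \linkS4class{PathwayProfiles} whose genomes are the tree's tips, and
#' classifies each by RI.
#'
#' @param tree a \code{phylo} whose tip labels are the profile's genome ids.
#' @param profiles a \linkS4class{PathwayProfiles}.
#' @param lower,upper classification thresholds, see [classifyConsistency()].
#' @return a data.frame with one row per pathway: pathway_id, n_present,
#'   n_total, g, s, m, ri, constant, class.
#' @export
scorePathways <- function(tree, profiles, lower = 0.7, upper = 0.9) {
  m <- presence(profiles)
  miss <- setdiff(tree$tip.label, colnames(m))
  if (length(miss))
    .stopf("profiles lack tree tip(s): %s", paste(miss, collapse = ", "))
  m <- m[, tree$tip.label, drop = FALSE]
  ntip <- ncol(m)
  rows <- lapply(rownames(m), function(p) {
    st <- m[p, ]
    s <- fitchScore(tree, st)
    r <- retentionIndex(sum(st == 1), ntip, s, pathway = p)
    data.frame(pathway_id = p, n_present = r@nPresent, n_total = r@nTotal,
               g = r@g, s = r@s, m = r@m, ri = r@ri, constant = r@constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- classifyConsistency(out$ri, lower, upper)
  out
}

#' Fractions of consistent and inconsistent pathways
#'
#' @param scores the per-pathway table from [scorePathways()].
#' @return named numeric: fraction consistent, intermediate, inconsistent.
#' @export
summarizeConsistency <- function(scores) {
  cls <- factor(scores$class,
                levels = c("consistent", "intermediate", "inconsistent"))
  prop.table(table(class = cls))
}
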