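# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and share no code with the package internals.

# Minimum change count over all 2^Nnode internal labelings.
bruteFitch <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  x <- states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    lab <- c(x, as.integer(intToBits(mask))[seq_len(nnode)])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Non-trivial splits as a sorted character vector of canonical keys,
# computed by naive edge-by-edge tip harvesting.
bruteSplits <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  harvest <- function(v) {
    if (v <= ntip) return(labs[v])
    unlist(lapply(tree$edge[tree$edge[, 1] == v, 2], harvest))
  }
  keys <- character(0)
  for (v in setdiff(unique(tree$edge[, 1]), ntip + 1)) {
    side <- sort(harvest(v))
    other <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = "|") <= paste(other, collapse = "|")))
      paste(side, collapse = "|") else paste(other, collapse = "|")
    keys <- c(keys, key)
  }
  # a binary root contributes the same unrooted split through both children
  kids <- tree$edge[tree$edge[, 1] == ntip + 1, 2]
  if (length(kids) == 2) for (v in kids[kids > ntip]) {
    side <- sort(harvest(v))
    other <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = "|") <= paste(other, collapse = "|")))
      paste(side, collapse = "|") else paste(other, collapse = "|")
    keys <- c(keys, key)
  }
  sort(unique(keys))
}

bruteRF <- function(t1, t2) {
  s1 <- bruteSplits(t1); s2 <- bruteSplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Exhaustive upper hypergeometric tail from binomial coefficients.
bruteHyperTail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random rooted tree from ape (a generator independent of the package's).
randomTree <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips, tip.label = sprintf("t%02d", seq_len(ntips)))
  tr
}

randomStates <- function(tree, seed) {
  set.seed(seed)
  setNames(sample(0:1, ape::Ntip(tree), replace = TRUE), tree$tip.label)
}

# Canonical-key helper matching the package's bipartition representation.
keyOf <- function(labels) paste(sort(labels), collapse = "|")
packageSplitKeys <- function(tree)
  sort(unname(vapply(treeBipartitions(tree), keyOf, "")))

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

makeHit <- function(query = "q", family = "f", evalue = 1e-6, qlen = 100L,
                    hmmlen = 100L, qiv = cbind(from = 1, to = 100),
                    hiv = cbind(from = 1, to = 100)) {
  new("HmmerHit", query = query, family = family, evalue = evalue,
      qlen = as.integer(qlen), hmmlen = as.integer(hmmlen),
      qIntervals = qiv, hIntervals = hiv)
}

# Tiny three-term ontology used across GO tests: root <- A <- A1.
miniObo <- function(path, extra = character(0)) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: branch A",
    "namespace: biological_process", "is_a: GO:0008150 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf A1",
    "namespace: biological_process", "is_a: GO:0000001 ! A",
    extra), path)
  path
}

# topology-only trees in tests: silence the lengths-default-to-0 warning
parseQuiet <- function(txt) suppressWarnings(parseNewick(txt))
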