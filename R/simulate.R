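# Synthetic corpus generator: Yule trees, binary characters evolved
# under a vertical 2-state Markov model or a horizontal "scattered
# gains" model, genus assignments and fixture files for every pipeline
# stage. All generators are pure functions of (config, seed): the
# caller's RNG state is saved and restored.

#' Simulation configuration
#'
#' @param seed integer seed; mandatory — no generator draws implicit
#'   randomness.
#' @param nTips number of extant genomes (>= 2).
#' @param birthRate Yule speciation rate per unit branch length.
#' @param gainRate,lossRate vertical-model 0->1 and 1->0 switch rates per
#'   unit branch length. The defaults (0.001, 0.0075) put on the order
#'   of one loss and far fewer than one gain on a 200-tip Yule tree of
#'   total length about 200, emulating stably maintained clade-borne
#'   pathways with few losses.
#' @param rootState state at the root of the vertical model (default 1,
#'   present).
#' @param scatterCount number of tips given the character under the
#'   scattered (horizontal-transfer-like) model; default 15% of tips.
#' @param genusSize genomes per genus when assigning genera (default 4).
#' @return a validated list of class \code{simConfig}.
#' @export
simConfig <- function(seed, nTips = 200, birthRate = 1, gainRate = 0.001,
                      lossRate = 0.0075, rootState = 1,
                      scatterCount = max(1L, round(0.15 * nTips)),
                      genusSize = 4) {
  if (missing(seed)) .stopf("simConfig requires an explicit seed")
  stopifnot(nTips >= 2, birthRate > 0, gainRate >= 0, lossRate >= 0,
            rootState %in% c(0, 1), scatterCount >= 0,
            scatterCount <= nTips, genusSize >= 1)
  structure(list(seed = as.integer(seed), nTips = as.integer(nTips),
                 birthRate = birthRate, gainRate = gainRate,
                 lossRate = lossRate, rootState = as.integer(rootState),
                 scatterCount = as.integer(scatterCount),
                 genusSize = as.integer(genusSize)),
            class = "simConfig")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from two lineages at the root, waiting times between
#' speciations are exponential with rate (lineages x birthRate); a
#' uniformly chosen extant lineage splits at each event. After the last
#' split a final exponential epoch gives the tips non-zero pendant
#' edges, so the tree is ultrametric. Tips are labeled \code{g001},
#' \code{g002}, ... in cladewise order.
#'
#' @param cfg a [simConfig()].
#' @return a rooted binary \code{phylo} with branch lengths.
#' @export
simulateYuleTree <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$nTips
    parent <- c(NA_integer_, 1L, 1L)
    brlen <- c(NA_real_, 0, 0)
    extant <- c(2L, 3L)
    while (length(extant) < n) {
      k <- length(extant)
      brlen[extant] <- brlen[extant] + stats::rexp(1L, k * cfg$birthRate)
      j <- extant[sample.int(k, 1L)]
      id <- length(parent)
      parent <- c(parent, j, j)
      brlen <- c(brlen, 0, 0)
      extant <- c(setdiff(extant, j), id + 1L, id + 2L)
    }
    brlen[extant] <- brlen[extant] + stats::rexp(1L, n * cfg$birthRate)

    kids <- split(seq_along(parent)[-1L], parent[-1L])
    tipCounter <- 0L
    rec <- function(v) {
      cs <- kids[[as.character(v)]]
      body <- if (is.null(cs)) {
        tipCounter <<- tipCounter + 1L
        sprintf("g%03d", tipCounter)  # label tips in cladewise order
      } else {
        paste0("(", paste(vapply(cs, rec, ""), collapse = ","), ")")
      }
      if (v == 1L) body else paste0(body, ":", .fmtLen(brlen[v]))
    }
    parseNewick(paste0(rec(1L), ";"))
  })
}

#' Simulate a binary character under the vertical Markov model
#'
#' A 2-state continuous-time Markov chain (rates \code{gainRate},
#' \code{lossRate}) is run down every branch from the root state using
#' exact exponential waiting times, so the full list of true switch
#' events is known. The parsimony score of the resulting tip pattern is
#' a lower bound on the number of true events.
#'
#' @param tree a \code{phylo}.
#' @param cfg a [simConfig()]; \code{seed}, \code{gainRate},
#'   \code{lossRate} and \code{rootState} are used.
#' @return list with \code{states} (named 0/1 tip vector), \code{events}
#'   (data.frame: parent, child, direction, position along the branch)
#'   and \code{nodeStates} (0/1 per node).
#' @export
simulateCharacterVertical <- function(tree, cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  .validateTree(tree)
  .withSeed(cfg$seed, {
    ntip <- ape::Ntip(tree)
    n <- ntip + tree$Nnode
    len <- .edgeLenAbove(tree)
    st <- rep(NA_integer_, n)
    st[ntip + 1L] <- cfg$rootState
    e <- ape::reorder.phylo(tree, "postorder")$edge
    ev <- list()
    for (i in rev(seq_len(nrow(e)))) {  # preorder
      p <- e[i, 1L]; v <- e[i, 2L]
      s <- st[p]; remaining <- len[v]; pos <- 0
      repeat {
        rate <- if (s == 0L) cfg$gainRate else cfg$lossRate
        if (rate <= 0) break
        t <- stats::rexp(1L, rate)
        if (t > remaining) break
        pos <- pos + t; remaining <- remaining - t
        s <- 1L - s
        ev[[length(ev) + 1L]] <- data.frame(
          parent = p, child = v,
          direction = if (s == 1L) "gain" else "loss",
          position = pos, stringsAsFactors = FALSE)
      }
      st[v] <- s
    }
    states <- st[seq_len(ntip)]
    names(states) <- tree$tip.label
    list(states = states,
         events = if (length(ev)) do.call(rbind, ev)
                  else data.frame(parent = integer(0), child = integer(0),
                                  direction = character(0),
                                  position = numeric(0)),
         nodeStates = st)
  })
}

#' Simulate a scattered (horizontally dispersed) binary character
#'
#' Presence is assigned to \code{scatterCount} tips drawn uniformly
#' without replacement, emulating a pathway dispersed by horizontal
#' transfer with no phylogenetic signal.
#'
#' @param tree a \code{phylo}.
#' @param cfg a [simConfig()]; \code{seed} and \code{scatterCount} used.
#' @return named 0/1 tip state vector.
#' @export
simulateCharacterScattered <- function(tree, cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  .validateTree(tree)
  ntip <- ape::Ntip(tree)
  if (cfg$scatterCount > ntip) .stopf("scatterCount exceeds tip count")
  .withSeed(cfg$seed, {
    states <- rep(0L, ntip)
    names(states) <- tree$tip.label
    states[sample.int(ntip, cfg$scatterCount)] <- 1L
    states
  })
}

#' Assign genomes to genera by contiguous clades
#'
#' Tips are taken in cladewise order and grouped into runs of
#' \code{genusSize}, so genera are (near-)monophyletic and genus
#' aggregation has phylogenetic signal.
#'
#' @param tree a \code{phylo}.
#' @param genusSize genomes per genus.
#' @return named character vector: genome id -> genus.
#' @export
assignGenera <- function(tree, genusSize = 4) {
  labs <- tree$tip.label
  idx <- ceiling(seq_along(labs) / genusSize)
  stats::setNames(sprintf("genus%03d", idx), labs)
}
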