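#' Load a Gene Ontology graph from an OBO file
#'
#' Parses OBO 1.2 \code{[Term]} stanzas, keeping non-obsolete terms and
#' \code{is_a} edges only. Edges to terms absent from the file are
#' dropped with a warning; a cyclic \code{is_a} graph is an error.
#'
#' @param file path to the OBO file.
#' @return a \linkS4class{GoDag}.
#' @export
loadObo <- function(file) {
  lines <- readLines(file, warn = FALSE)
  ids <- character(0); nm <- character(0); ns <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return()
    ids <<- c(ids, cur$id)
    nm[cur$id] <<- if (is.null(cur$name)) NA_character_ else cur$name
    ns[cur$id] <<- if (is.null(cur$namespace)) NA_character_ else cur$namespace
    parents[[cur$id]] <<- cur$isa %||% character(0)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  inTerm <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(); inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(ln)) next
    if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
    else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
    else if (startsWith(ln, "namespace: "))
      cur$namespace <- sub("^namespace: ", "", ln)
    else if (startsWith(ln, "is_a: ")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a: ", "", ln)))
      cur$isa <- c(cur$isa, tgt)
    } else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  flush()

  drop <- lapply(parents, setdiff, y = ids)
  ndrop <- sum(lengths(parents) - lengths(lapply(parents, intersect, y = ids)))
  if (ndrop > 0)
    .warnf("dropped %d is_a edge(s) to term(s) not defined in %s", ndrop, file)
  parents <- lapply(parents, intersect, y = ids)

  # cycle check by repeated leaf-of-parent-graph elimination
  remaining <- ids
  repeat {
    free <- remaining[vapply(parents[remaining],
                             function(p) !any(p %in% remaining), TRUE)]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining))
    .stopf("cyclic is_a relationship involving term %s", remaining[1L])

  new("GoDag", ids = ids, parents = parents, termNames = nm, namespace = ns)
}

# Ancestor closure (strict: excludes the term itself), memoized per call.
.goAncestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- dag@parents[[id]]
    out <- unique(c(ps, unlist(lapply(ps, anc))))
    memo[[id]] <- out
    out
  }
  anc
}

#' Propagate gene annotations up the ontology
#'
#' Applies the true-path rule: a gene directly annotated to a term is
#' annotated to all the term's ancestors as well. Annotations to terms
#' not in the DAG are skipped with a warning.
#'
#' @param dag a \linkS4class{GoDag}.
#' @param annotations named list: gene id -> character vector of
#'   directly annotated term ids.
#' @return named list: gene id -> full (propagated) term set.
#' @export
annotateUp <- function(dag, annotations) {
  anc <- .goAncestors(dag)
  unknown <- setdiff(unique(unlist(annotations)), dag@ids)
  if (length(unknown))
    .warnf("skipping %d annotation term(s) not in the ontology: %s",
           length(unknown), paste(utils::head(unknown, 5), collapse = ", "))
  lapply(annotations, function(terms) {
    terms <- intersect(terms, dag@ids)
    sort(unique(c(terms, unlist(lapply(terms, anc)))))
  })
}

#' One-sided Fisher over-representation p-value
#'
#' Upper hypergeometric tail \eqn{P(X \ge k)} for drawing \code{k}
#' annotated genes in a study set of size \code{n} from a background of
#' \code{N} genes of which \code{K} are annotated.
#'
#' @param k annotated genes in the study set.
#' @param n study-set size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
fisherClassic <- function(k, n, K, N) {
  if (k < 0 || k > n || k > K || n > N || K > N)
    .stopf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment configuration
#'
#' @param minAnnotated report only terms annotated to strictly more than
#'   this many background genes (default 10).
#' @param elimCutoff significance threshold of the elim procedure and of
#'   reporting (default 0.01).
#' @param topK number of terms reported per study set (default 10).
#' @return a validated list of class \code{enrichmentConfig}.
#' @export
enrichmentConfig <- function(minAnnotated = 10, elimCutoff = 0.01, topK = 10) {
  stopifnot(minAnnotated >= 0, elimCutoff > 0, topK > 0)
  structure(list(minAnnotated = minAnnotated, elimCutoff = elimCutoff,
                 topK = topK), class = "enrichmentConfig")
}

#' GO enrichment with the elim decorrelation procedure
#'
#' Terms are tested leaf-ward first (decreasing depth, ties by id). Each
#' term gets a classic Fisher p-value on the full counts and an elim
#' p-value on counts excluding genes already claimed by significant
#' descendants; when a term's elim p-value reaches the cutoff, its
#' annotated genes are removed from all its ancestors' tests. This
#' suppresses very general terms that are significant only through their
#' specific children.
#'
#' @param dag a \linkS4class{GoDag}.
#' @param study character vector of study genes (subset of background).
#' @param background character vector of universe genes.
#' @param annotations propagated gene -> term sets from [annotateUp()],
#'   covering at least the background genes.
#' @param cfg an [enrichmentConfig()]; only \code{elimCutoff} is used here.
#' @return data.frame (term, name, k, n, K, N, p_classic, p_elim), one
#'   row per term with at least one annotated background gene, ordered
#'   by term id.
#' @export
elimEnrichment <- function(dag, study, background, annotations,
                           cfg = enrichmentConfig()) {
  study <- unique(study); background <- unique(background)
  if (length(setdiff(study, background)))
    .stopf("study set must be a subset of the background")
  miss <- setdiff(background, names(annotations))
  if (length(miss))
    .stopf("no annotations for %d background gene(s)", length(miss))

  # term -> annotated background genes
  ann <- annotations[background]
  genes <- rep(names(ann), lengths(ann))
  terms <- unlist(ann, use.names = FALSE)
  term2genes <- split(genes, terms)
  tested <- sort(intersect(names(term2genes), dag@ids))
  if (!length(tested)) return(data.frame(
    term = character(0), name = character(0), k = integer(0), n = integer(0),
    K = integer(0), N = integer(0), p_classic = numeric(0),
    p_elim = numeric(0)))

  # depth = longest path from a root; children always deeper than parents
  depth <- new.env(parent = emptyenv())
  d <- function(id) {
    if (!is.null(depth[[id]])) return(depth[[id]])
    ps <- dag@parents[[id]]
    out <- if (!length(ps)) 0L else 1L + max(vapply(ps, d, 0L))
    depth[[id]] <- out
    out
  }
  ord <- tested[order(-vapply(tested, d, 0L), tested)]

  anc <- .goAncestors(dag)
  n <- length(study); N <- length(background)
  removed <- new.env(parent = emptyenv())
  res <- vector("list", length(ord)); names(res) <- ord
  for (t in ord) {
    g <- term2genes[[t]]
    gs <- intersect(g, study)
    rem <- removed[[t]]
    gElim <- if (is.null(rem)) g else setdiff(g, rem)
    gsElim <- if (is.null(rem)) gs else setdiff(gs, rem)
    pC <- fisherClassic(length(gs), n, length(g), N)
    pE <- fisherClassic(length(gsElim), n, length(gElim), N)
    if (pE <= cfg$elimCutoff)
      for (a in anc(t)) removed[[a]] <- union(removed[[a]], g)
    res[[t]] <- data.frame(term = t, name = unname(dag@termNames[t]),
                           k = length(gs), n = n, K = length(g), N = N,
                           p_classic = pC, p_elim = pE,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

#' Filter and rank enrichment results for reporting
#'
#' Keeps terms annotated to strictly more than \code{minAnnotated}
#' background genes and with elim p-value at or below
#' \code{elimCutoff} (discarding very general or weakly supported
#' terms), ranks ascending by elim p-value (ties by term id) and
#' truncates to \code{topK}.
#'
#' @param results data.frame from [elimEnrichment()].
#' @param cfg an [enrichmentConfig()].
#' @return the filtered, ranked data.frame.
#' @export
filterAndRank <- function(results, cfg = enrichmentConfig()) {
  keep <- results$K > cfg$minAnnotated & results$p_elim <= cfg$elimCutoff
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_elim, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, cfg$topK)
}
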