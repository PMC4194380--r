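#' Annotation-transfer filter configuration
#'
#' @param maxEvalue whole-sequence e-value ceiling; comparison is strict
#'   \code{<} (default 1e-3).
#' @param minCoverage minimum fraction of both the HMM and the query
#'   covered by the (merged) aligned regions; comparison is inclusive
#'   \code{>=} (default 0.50).
#' @return a validated list of class \code{annotationFilterConfig}.
#' @export
annotationFilterConfig <- function(maxEvalue = 1e-3, minCoverage = 0.50) {
  stopifnot(maxEvalue > 0, minCoverage > 0, minCoverage <= 1)
  structure(list(maxEvalue = maxEvalue, minCoverage = minCoverage),
            class = "annotationFilterConfig")
}

#' Protein-family cluster validity configuration
#'
#' @param minIdentity every member must exceed this global-alignment
#'   identity to the cluster centroid (strict \code{>}, default 0.80).
#' @param minLengthRatio the shortest member must be more than this
#'   fraction as long as the longest (strict \code{>}, default 0.80).
#' @return a validated list of class \code{clusterRuleConfig}.
#' @export
clusterRuleConfig <- function(minIdentity = 0.80, minLengthRatio = 0.80) {
  stopifnot(minIdentity > 0, minIdentity <= 1,
            minLengthRatio > 0, minLengthRatio <= 1)
  structure(list(minIdentity = minIdentity, minLengthRatio = minLengthRatio),
            class = "clusterRuleConfig")
}

#' Parse HMMER3 per-domain tabular output
#'
#' Reads a \code{domtblout} stream (hmmscan orientation: the target is
#' the HMM family, the query the protein) and aggregates the per-domain
#' rows of each (query, family) pair into one \linkS4class{HmmerHit}
#' carrying the whole-sequence e-value and the alignment intervals on
#' both axes.
#'
#' @param file path to the domtblout file (\code{#} comment lines are
#'   skipped).
#' @return a list of \linkS4class{HmmerHit} objects.
#' @export
parseDomtbl <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) < 22L)
      .stopf("domtblout %s line %d: expected >= 22 columns, found %d",
             file, i, length(tok))
    num <- suppressWarnings(as.numeric(tok[c(3, 6, 7, 16, 17, 18, 19)]))
    if (anyNA(num))
      .stopf("domtblout %s line %d: non-numeric value in a numeric column",
             file, i)
    list(family = tok[1L], query = tok[4L], tlen = num[1L], qlen = num[2L],
         evalue = num[3L], hfrom = num[4L], hto = num[5L],
         qfrom = num[6L], qto = num[7L])
  })
  if (!length(rows)) return(list())
  key <- vapply(rows, function(r) paste(r$query, r$family, sep = "\x1f"), "")
  out <- lapply(split(rows, factor(key, unique(key))), function(grp) {
    r1 <- grp[[1L]]
    new("HmmerHit", query = r1$query, family = r1$family, evalue = r1$evalue,
        qlen = as.integer(r1$qlen), hmmlen = as.integer(r1$tlen),
        qIntervals = cbind(from = vapply(grp, `[[`, 0, "qfrom"),
                           to = vapply(grp, `[[`, 0, "qto")),
        hIntervals = cbind(from = vapply(grp, `[[`, 0, "hfrom"),
                           to = vapply(grp, `[[`, 0, "hto")))
  })
  unname(out)
}

#' Alignment coverage of a hit
#'
#' Overlapping or adjacent domain intervals are merged before summation
#' (the aligned regions need not be contiguous), then divided by the
#' axis length.
#'
#' @param hit a \linkS4class{HmmerHit}.
#' @return named numeric: \code{query} and \code{hmm} coverage fractions.
#' @examples
#' h <- new("HmmerHit", query = "q", family = "f", evalue = 1e-5,
#'          qlen = 100L, hmmlen = 50L,
#'          qIntervals = cbind(from = c(1, 41), to = c(30, 65)),
#'          hIntervals = cbind(from = 1, to = 50))
#' hitCoverage(h)  # query 0.55, hmm 1.0
#' @export
hitCoverage <- function(hit) {
  c(query = .intervalUnionLength(hit@qIntervals) / hit@qlen,
    hmm = .intervalUnionLength(hit@hIntervals) / hit@hmmlen)
}

#' Select the best annotated family per query
#'
#' Discards hits failing the e-value ceiling or either coverage
#' requirement, then keeps, per query, the surviving hit with the
#' smallest whole-sequence e-value (ties broken by lexicographically
#' smallest family id). Queries with no survivor are reported
#' unannotated.
#'
#' @param hits a list of \linkS4class{HmmerHit} (possibly many queries).
#' @param cfg an [annotationFilterConfig()].
#' @return list with \code{best} (named list of winning hits, one per
#'   annotated query) and \code{unannotated} (character query ids).
#' @export
filterHits <- function(hits, cfg = annotationFilterConfig()) {
  queries <- unique(vapply(hits, slot, "", "query"))
  pass <- Filter(function(h) {
    if (h@evalue >= cfg$maxEvalue) return(FALSE)
    cv <- hitCoverage(h)
    cv[["query"]] >= cfg$minCoverage && cv[["hmm"]] >= cfg$minCoverage
  }, hits)
  best <- list()
  for (h in pass) {
    cur <- best[[h@query]]
    if (is.null(cur) || h@evalue < cur@evalue ||
        (h@evalue == cur@evalue && h@family < cur@family))
      best[[h@query]] <- h
  }
  list(best = best, unannotated = sort(setdiff(queries, names(best))))
}

#' Construct a FamilyAnnotation
#'
#' @param family family id.
#' @param productNames,ec,geneNames,go character vectors; deduplicated
#'   and sorted on construction.
#' @return a \linkS4class{FamilyAnnotation}.
#' @export
familyAnnotation <- function(family, productNames = character(0),
                             ec = character(0), geneNames = character(0),
                             go = character(0)) {
  new("FamilyAnnotation", family = family,
      productNames = sort(unique(productNames)), ec = sort(unique(ec)),
      geneNames = sort(unique(geneNames)), go = sort(unique(go)))
}

#' Union the annotations of a family's curated members
#'
#' When curated member proteins of a cluster disagree on an annotation
#' field, the union of the field's values is taken as the cluster
#' annotation. The operation is associative, commutative and idempotent.
#'
#' @param members non-empty list of \linkS4class{FamilyAnnotation}.
#' @return a single \linkS4class{FamilyAnnotation}.
#' @export
mergeFamilyAnnotations <- function(members) {
  if (!length(members)) .stopf("no member annotations to merge")
  u <- function(f) sort(unique(unlist(lapply(members, slot, f))))
  new("FamilyAnnotation", family = members[[1L]]@family,
      productNames = u("productNames"), ec = u("ec"),
      geneNames = u("geneNames"), go = u("go"))
}

#' Validate a protein-family cluster
#'
#' A cluster is valid iff every member's identity to the centroid
#' exceeds \code{minIdentity} and the shortest member is more than
#' \code{minLengthRatio} as long as the longest; together these prevent
#' clustering of merely locally similar proteins.
#'
#' @param identity numeric vector of member identities to the centroid
#'   (the centroid's own entry is 1).
#' @param length integer vector of member sequence lengths.
#' @param cfg a [clusterRuleConfig()].
#' @return list with \code{valid} (logical) and \code{violations}
#'   (character descriptions, empty when valid).
#' @export
validateCluster <- function(identity, length, cfg = clusterRuleConfig()) {
  stopifnot(base::length(identity) == base::length(length),
            base::length(identity) >= 1L)
  viol <- character(0)
  bad <- which(identity <= cfg$minIdentity)
  if (base::length(bad))
    viol <- c(viol, sprintf("member %d identity %.3f <= %.2f",
                            bad, identity[bad], cfg$minIdentity))
  ratio <- min(length) / max(length)
  if (ratio <= cfg$minLengthRatio)
    viol <- c(viol, sprintf("length ratio %.3f <= %.2f",
                            ratio, cfg$minLengthRatio))
  list(valid = base::length(viol) == 0L, violations = viol)
}

#' Write the per-query annotation table
#'
#' @param filtered result of [filterHits()].
#' @param annotations named list of \linkS4class{FamilyAnnotation} keyed
#'   by family id (missing families get empty fields).
#' @param file output TSV path; multi-valued fields are ';'-joined.
#' @export
writeAnnotationTable <- function(filtered, annotations, file) {
  best <- filtered$best
  join <- function(x) paste(x, collapse = ";")
  rows <- lapply(best, function(h) {
    cv <- hitCoverage(h)
    a <- annotations[[h@family]]
    data.frame(query_id = h@query, family_id = h@family, evalue = h@evalue,
               qcov = cv[["query"]], hcov = cv[["hmm"]],
               product_names = if (is.null(a)) "" else join(a@productNames),
               EC = if (is.null(a)) "" else join(a@ec),
               gene_names = if (is.null(a)) "" else join(a@geneNames),
               GO = if (is.null(a)) "" else join(a@go),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(query_id = character(0))
  df <- df[order(df$query_id), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
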