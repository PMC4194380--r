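#' Parse a Newick string into a phylogenetic tree
#'
#' Wraps [ape::read.tree()] with a stricter front end: the string must be a
#' single tree terminated by \code{";"}, parentheses must balance (the first
#' offending character offset is reported), quoted labels (single quotes,
#' with \code{''} escaping an embedded quote) survive verbatim, duplicate or
#' empty tip labels are rejected, and branch lengths absent from the input
#' default to 0 with a warning.
#'
#' @param text a Newick string (may contain quoted labels, missing branch
#'   lengths and multifurcations).
#' @return an object of class \code{phylo} (see \pkg{ape}); child order is
#'   preserved from the input, so traversals are deterministic.
#' @examples
#' tr <- parseNewick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' ape::Ntip(tr)
#' @seealso [writeNewick()], [readNewick()]
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (nchar(s) == 0L) .stopf("empty Newick string")

  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  inq <- FALSE
  i <- 1L
  n <- length(chars)
  semi <- NA_integer_
  while (i <= n) {
    ch <- chars[i]
    if (inq) {
      if (ch == "'") {
        if (i < n && chars[i + 1L] == "'") i <- i + 1L else inq <- FALSE
      }
    } else if (ch == "'") {
      inq <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        .stopf("Newick parse error: unbalanced ')' at character offset %d", i)
    } else if (ch == ";") {
      semi <- i
      break
    }
    i <- i + 1L
  }
  if (inq) .stopf("Newick parse error: unterminated quoted label")
  if (is.na(semi))
    .stopf("Newick parse error: missing ';' terminator (scanned %d characters)", n)
  if (depth != 0L)
    .stopf("Newick parse error: %d unclosed '(' at character offset %d", depth, semi)
  s <- substr(s, 1L, semi)

  # shelter quoted labels from ape's tokenizer
  m <- gregexpr("'(?:[^']|'')*'", s, perl = TRUE)[[1L]]
  quoted <- character(0)
  if (m[1L] != -1L) {
    quoted <- regmatches(s, gregexpr("'(?:[^']|'')*'", s, perl = TRUE))[[1L]]
    quoted <- gsub("''", "'", substr(quoted, 2L, nchar(quoted) - 1L))
    ph <- sprintf("pqlbl%06d", seq_along(quoted))
    regmatches(s, gregexpr("'(?:[^']|'')*'", s, perl = TRUE)) <- list(ph)
  }

  tree <- tryCatch(ape::read.tree(text = s),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    .stopf("Newick parse error: ape could not interpret the string")

  restore <- function(lab) {
    hit <- grepl("^pqlbl[0-9]{6}$", lab)
    lab[hit] <- quoted[as.integer(sub("^pqlbl", "", lab[hit]))]
    lab
  }
  tree$tip.label <- restore(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- restore(tree$node.label)

  if (is.null(tree$edge.length)) {
    .warnf("no branch lengths in input; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    .warnf("%d missing branch length(s) defaulted to 0", sum(is.na(tree$edge.length)))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  .validateTree(tree)
  tree
}

# Invariant checks shared by every tree-consuming operation.
.validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) .stopf("not a 'phylo' object")
  if (any(tree$tip.label == "")) .stopf("empty tip label(s) in tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    .stopf("duplicate tip label(s): %s", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    .stopf("negative branch length(s)")
  invisible(tree)
}

#' Read a Newick tree from a file
#'
#' @param file path to a file whose contents are a single Newick tree.
#' @return a \code{phylo} object.
#' @export
readNewick <- function(file) {
  parseNewick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Serialize a phylogenetic tree to Newick
#'
#' Children are emitted in the stored edge order, labels needing protection
#' are single-quoted, and branch lengths are printed with the shortest
#' decimal representation that round-trips, so
#' \code{parseNewick(writeNewick(x))} reproduces topology, labels and
#' lengths exactly.
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
writeNewick <- function(tree, file = NULL) {
  .validateTree(tree)
  ntip <- ape::Ntip(tree)
  kids <- .childList(tree)
  len <- if (is.null(tree$edge.length)) rep(NA_real_, ntip + tree$Nnode)
         else .edgeLenAbove(tree)
  root <- ntip + 1L

  quoteLab <- function(lab) {
    need <- grepl("[][(){}:;,' \t]", lab)
    lab[need] <- paste0("'", gsub("'", "''", lab[need]), "'")
    lab
  }
  nodeLab <- function(v) {
    if (v <= ntip) return(quoteLab(tree$tip.label[v]))
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[v - ntip]
    if (is.na(lab) || lab == "") "" else quoteLab(lab)
  }
  rec <- function(v) {
    body <- if (v <= ntip) nodeLab(v)
            else paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","),
                        ")", nodeLab(v))
    if (v == root || is.na(len[v])) body else paste0(body, ":", .fmtLen(len[v]))
  }
  out <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
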