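#' Read and write set systems
#'
#' Two on-disk dialects, auto-detected by extension. Text (any extension
#' but `.json`): UTF-8, one block per line with comma-separated taxa,
#' `#` comments and blank lines ignored. JSON (`.json`):
#' `{"taxa": [...], "blocks": [[...], ...]}`. The canonical writer sorts
#' taxa within each block and blocks lexicographically, so
#' write-then-read is the identity on canonical form.
#'
#' @param path file path.
#' @return `read_set_system` returns a `set_system`; `write_set_system`
#'   returns `path` invisibly.
#' @export
read_set_system <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    blocks <- if (is.matrix(obj$blocks))
      lapply(seq_len(nrow(obj$blocks)), function(i) obj$blocks[i, ])
    else as.list(obj$blocks)
    return(set_system(lapply(blocks, as.character),
                      taxa = if (!is.null(obj$taxa)) obj$taxa))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  blocks <- lapply(keep, function(i) {
    b <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
    tryCatch(check_labels(b),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
    sort(b)
  })
  keys <- vapply(blocks, paste, "", collapse = ",")
  if (anyDuplicated(keys))
    stop("line ", keep[which(duplicated(keys))[1L]], ": duplicate block")
  set_system(blocks)
}

#' @rdname read_set_system
#' @param x a `set_system`.
#' @export
write_set_system <- function(x, path) {
  stopifnot(inherits(x, "set_system"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(list(taxa = x$taxa, blocks = x$blocks), path)
  else
    writeLines(format(x), path)
  invisible(path)
}

#' Read and write triple lists
#'
#' One triple per line in canonical `a,b|c` form; `#` comments and blank
#' lines ignored.
#'
#' @param path file path.
#' @return `read_triples` returns a character vector of canonical tokens.
#' @export
read_triples <- function(path) {
  lines <- sub("#.*$", "", readLines(path, encoding = "UTF-8"))
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) return(character())
  colnames(parse_triples(lines))
}

#' @rdname read_triples
#' @param triples character vector of triple tokens.
#' @export
write_triples <- function(triples, path) {
  writeLines(colnames(parse_triples(triples)), path)
  invisible(path)
}

phylo_to_node <- function(ph) {
  ntip <- length(ph$tip.label)
  if (anyDuplicated(ph$tip.label)) stop("duplicate leaf labels in Newick")
  kids <- split(ph$edge[, 2L], ph$edge[, 1L])
  build <- function(v) {
    if (v <= ntip) return(ph$tip.label[v])
    lapply(kids[[as.character(v)]], build)
  }
  build(ntip + 1L)
}

#' Read and write rooted trees in Newick format
#'
#' Reading uses the `ape` parser; branch lengths are tolerated and
#' dropped, internal labels ignored. The writer emits leaf labels only,
#' with children in canonical order (by smallest descendant leaf), so
#' read-then-write is idempotent.
#'
#' @param path file path, or for `read_newick` alternatively `text` as a
#'   literal Newick string.
#' @param text optional literal Newick string instead of a file.
#' @return `read_newick` returns a `rooted_tree`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  ph <- if (is.null(text)) ape::read.tree(path) else
    ape::read.tree(text = text)
  if (is.null(ph)) stop("could not parse Newick input")
  rooted_tree(phylo_to_node(ph))
}

#' @rdname read_newick
#' @param tree a `rooted_tree`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "rooted_tree"))
  writeLines(format(tree), path)
  invisible(path)
}

# Serialise an unrooted tree as Newick rooted at the neighbour of its
# first leaf; topology-only, for interchange.
unrooted_to_newick <- function(x) {
  stopifnot(inherits(x, "unrooted_tree"))
  g <- x$graph
  nm <- igraph::V(g)$name
  nb <- function(v) nm[as.integer(igraph::neighbors(g, v))]
  rec <- function(v, parent) {
    ch <- setdiff(nb(v), parent)
    if (!length(ch)) return(v)
    paste0("(", paste(vapply(ch, rec, "", parent = v), collapse = ","), ")")
  }
  root <- nb(x$leaves[1L])[1L]
  paste0(rec(root, character(0)), ";")
}
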