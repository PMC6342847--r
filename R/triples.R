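#' Rooted triples
#'
#' A rooted triple `ab|c` is the rooted binary tree on three leaves in which
#' `a`, `b` form the cherry and `c` is adjacent to the root. Triples are
#' represented as canonical text tokens `"a,b|c"` with the cherry pair
#' sorted; a set of triples is a character vector of such tokens.
#'
#' @param a,b cherry leaves (distinct).
#' @param c outgroup leaf.
#' @return canonical token `"a,b|c"`.
#' @examples
#' rooted_triple("b", "a", "c")  # "a,b|c"
#' @export
rooted_triple <- function(a, b, c) {
  labs <- c(a, b, c)
  check_labels(labs)
  if (anyDuplicated(labs)) stop("triple labels must be pairwise distinct")
  ch <- sort(c(a, b))
  paste0(ch[1L], ",", ch[2L], "|", c)
}

#' Parse rooted-triple tokens
#'
#' Accepts the canonical form `"a,b|c"`; for single-character labels the
#' compact form `"ab|c"` is also accepted.
#'
#' @param tokens character vector of triple tokens.
#' @return a 3-row character matrix with rows `a`, `b` (sorted cherry) and
#'   `c` (outgroup), one column per triple; columns named by the canonical
#'   token.
#' @export
parse_triples <- function(tokens) {
  tokens <- trimws(as.character(tokens))
  parts <- strsplit(tokens, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed triple token")
  out <- vapply(seq_along(parts), function(i) {
    ch <- parts[[i]][1L]; og <- parts[[i]][2L]
    cherry <- if (grepl(",", ch, fixed = TRUE))
      strsplit(ch, ",", fixed = TRUE)[[1L]]
    else strsplit(ch, "", fixed = TRUE)[[1L]]
    if (length(cherry) != 2L) stop("malformed triple token: ", tokens[i])
    labs <- c(sort(cherry), og)
    check_labels(labs)
    if (anyDuplicated(labs)) stop("triple labels must be distinct: ", tokens[i])
    labs
  }, character(3L))
  out <- matrix(out, nrow = 3L)
  rownames(out) <- c("a", "b", "c")
  colnames(out) <- paste0(out[1L, ], ",", out[2L, ], "|", out[3L, ])
  out
}

#' Leaf union of a triple set
#'
#' @param triples character vector of triple tokens.
#' @return sorted character vector of all labels used.
#' @export
triple_leaves <- function(triples) {
  if (length(triples) == 0L) return(character())
  sort(unique(as.vector(parse_triples(triples))))
}

#' The three rooted triples on a 3-taxon block
#'
#' @param block character vector of three distinct labels.
#' @return character vector of the three tokens `ab|c`, `ac|b`, `bc|a`.
#' @export
block_triples <- function(block) {
  block <- sort(as.character(block))
  if (length(block) != 3L) stop("'block' must have exactly 3 taxa")
  c(rooted_triple(block[1L], block[2L], block[3L]),
    rooted_triple(block[1L], block[3L], block[2L]),
    rooted_triple(block[2L], block[3L], block[1L]))
}

#' Cluster graph of a triple set restricted to a taxon subset
#'
#' The graph `[R, S]` has vertex set `S` and an edge `{a, b}` whenever some
#' triple `ab|c` of `R` has all three leaves inside `S`. By the
#' Bryant-Steel criterion, `R` is compatible iff `[R, S]` is disconnected
#' for every `S` of size at least 2.
#'
#' @param triples character vector of triple tokens.
#' @param S non-empty character vector of taxa.
#' @return an `igraph` undirected graph on vertex set `S`.
#' @export
cluster_graph <- function(triples, S) {
  S <- sort(unique(as.character(S)))
  if (length(S) == 0L) stop("'S' must be non-empty")
  g <- igraph::make_empty_graph(n = length(S), directed = FALSE)
  igraph::V(g)$name <- S
  if (length(triples)) {
    tp <- parse_triples(triples)
    keep <- tp["a", ] %in% S & tp["b", ] %in% S & tp["c", ] %in% S
    if (any(keep)) {
      el <- unique(t(tp[c("a", "b"), keep, drop = FALSE]))
      g <- igraph::add_edges(g, t(matrix(match(el, S), ncol = 2L)))
    }
  }
  g
}

# Connected-component labels for the taxa in `labels` under the cherry
# edges of the parsed triples fully contained in `labels` (plain
# union-find; this is the hot loop of BUILD).
component_labels <- function(labels, tp) {
  parent <- seq_along(labels)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (ncol(tp)) {
    ia <- match(tp["a", ], labels)
    ib <- match(tp["b", ], labels)
    ic <- match(tp["c", ], labels)
    keep <- !is.na(ia) & !is.na(ib) & !is.na(ic)
    for (j in which(keep)) {
      ra <- find(ia[j]); rb <- find(ib[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_along(labels), find, 0L)
}

build_node <- function(labels, tp) {
  if (length(labels) == 1L) return(labels)
  comp <- component_labels(labels, tp)
  groups <- split(labels, comp)
  if (length(groups) == 1L) return(NULL)          # connected => incompatible
  children <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sub <- groups[[i]]
    keep <- if (ncol(tp)) tp["a", ] %in% sub & tp["b", ] %in% sub &
      tp["c", ] %in% sub else logical(0)
    ch <- build_node(sub, tp[, keep, drop = FALSE])
    if (is.null(ch)) return(NULL)
    children[[i]] <- ch
  }
  canonical_node(children)
}

#' Test compatibility of a triple set (Aho BUILD)
#'
#' Runs the BUILD algorithm: recursively partition the current taxon set by
#' the connected components of its cluster graph; a connected level of size
#' at least 2 certifies incompatibility, otherwise the recursion assembles
#' the canonical (possibly non-binary) supertree displaying every triple.
#'
#' @param triples character vector of triple tokens (empty is compatible).
#' @param taxa optional taxon set (defaults to the triples' leaf union);
#'   extra taxa are attached at the root.
#' @return logical; when `TRUE` and at least two taxa are involved,
#'   attribute `"tree"` holds the canonical BUILD `rooted_tree`.
#' @examples
#' is_compatible(c("a,b|c", "a,b|d"))
#' @export
is_compatible <- function(triples, taxa = NULL) {
  triples <- unique(as.character(triples))
  tp <- if (length(triples)) parse_triples(triples) else
    matrix(character(), 3L, 0L, dimnames = list(c("a", "b", "c"), NULL))
  labels <- sort(unique(c(as.vector(tp), as.character(taxa))))
  if (length(labels) < 2L) return(structure(TRUE, tree = NULL))
  node <- build_node(labels, tp)
  if (is.null(node)) structure(FALSE, tree = NULL)
  else structure(TRUE, tree = rooted_tree(node))
}

#' Build the Aho supertree for a compatible triple set
#'
#' @inheritParams is_compatible
#' @param binary if `TRUE`, deterministically refine every multifurcation
#'   into a left-leaning caterpillar over children ordered by smallest leaf.
#' @return a `rooted_tree`, or an error if the triples are incompatible.
#' @export
build_supertree <- function(triples, taxa = NULL, binary = FALSE) {
  ok <- is_compatible(triples, taxa)
  if (!ok) stop("triples are incompatible: no supertree displays them")
  tree <- attr(ok, "tree")
  if (is.null(tree)) stop("need at least two taxa to build a tree")
  if (binary) binary_refinement(tree) else tree
}
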