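#' Rooted phylogenetic trees
#'
#' Trees are stored as recursive node structures: a leaf is a character
#' scalar, an internal node a list of two or more child nodes. Children are
#' kept in canonical order (by smallest descendant leaf label) so printing
#' and Newick output are deterministic. Every non-leaf vertex has out-degree
#' at least 2; a tree is binary when all out-degrees equal 2.
#'
#' @param node a recursive node structure (or an existing `rooted_tree`).
#' @return an object of class `rooted_tree`.
#' @export
rooted_tree <- function(node) {
  if (inherits(node, "rooted_tree")) return(node)
  node <- canonicalise(node)
  lv <- node_leaves(node)
  if (anyDuplicated(lv)) stop("duplicate leaf labels in tree")
  check_labels(lv)
  if (length(lv) < 2L) stop("a rooted tree needs at least 2 leaves")
  structure(list(root = node), class = "rooted_tree")
}

canonicalise <- function(node) {
  if (!is.list(node)) return(as.character(node))
  if (length(node) < 2L) stop("internal nodes must have out-degree >= 2")
  node <- lapply(node, canonicalise)
  mins <- vapply(node, function(ch) min(node_leaves(ch)), "")
  node[order(mins, method = "radix")]
}

canonical_node <- function(children) {
  mins <- vapply(children, function(ch) min(node_leaves(ch)), "")
  children[order(mins, method = "radix")]
}

node_leaves <- function(node) {
  if (!is.list(node)) return(node)
  unlist(lapply(node, node_leaves), use.names = FALSE)
}

#' Leaves of a rooted tree
#' @param tree a `rooted_tree`.
#' @return sorted character vector of leaf labels.
#' @export
tree_leaves <- function(tree) sort(node_leaves(tree$root))

#' Is a rooted tree binary?
#' @param tree a `rooted_tree`.
#' @return logical.
#' @export
is_binary_tree <- function(tree) {
  chk <- function(node) {
    if (!is.list(node)) return(TRUE)
    length(node) == 2L && all(vapply(node, chk, TRUE))
  }
  chk(tree$root)
}

#' Clusters (internal-vertex leaf sets) of a rooted tree
#'
#' @param tree a `rooted_tree`.
#' @return list of sorted character vectors, one per internal vertex
#'   (including the root), in depth-first order.
#' @export
tree_clusters <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (!is.list(node)) return(node)
    lv <- unlist(lapply(node, walk), use.names = FALSE)
    out[[length(out) + 1L]] <<- sort(lv)
    lv
  }
  walk(tree$root)
  out
}

node_to_newick <- function(node) {
  if (!is.list(node)) return(node)
  paste0("(", paste(vapply(node, node_to_newick, ""), collapse = ","), ")")
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(node_to_newick(x$root), ";\n", sep = "")
  invisible(x)
}

#' @export
format.rooted_tree <- function(x, ...) paste0(node_to_newick(x$root), ";")

#' Does a tree display a rooted triple?
#'
#' `T` displays `ab|c` when the most recent common ancestor of `a`, `b` is
#' a strict descendant of that of `a`, `b`, `c` — equivalently, some
#' cluster of `T` contains `a` and `b` but not `c`.
#'
#' @param tree a `rooted_tree` containing all three labels as leaves.
#' @param triple a triple token such as `"a,b|c"`.
#' @return logical.
#' @export
displays_triple <- function(tree, triple) {
  tp <- parse_triples(triple)
  if (ncol(tp) != 1L) stop("exactly one triple expected")
  lv <- tree_leaves(tree)
  if (!all(tp[, 1L] %in% lv))
    stop("triple labels must all be leaves of the tree")
  cl <- tree_clusters(tree)
  a <- tp["a", 1L]; b <- tp["b", 1L]; cc <- tp["c", 1L]
  any(vapply(cl, function(C)
    a %in% C && b %in% C && !(cc %in% C), TRUE))
}

#' All rooted triples displayed by a tree
#'
#' A binary tree on `n >= 3` leaves displays exactly one triple per
#' 3-subset of its leaves; multifurcations leave some 3-subsets unresolved.
#'
#' @param tree a `rooted_tree` with at least 3 leaves.
#' @return character vector of canonical triple tokens.
#' @export
induced_triples <- function(tree) {
  lv <- tree_leaves(tree)
  if (length(lv) < 3L) stop("tree must have at least 3 leaves")
  cl <- tree_clusters(tree)
  out <- character()
  for (s in utils::combn(lv, 3L, simplify = FALSE)) {
    for (C in cl) {
      inC <- s %in% C
      if (sum(inC) == 2L) {
        pair <- s[inC]
        out <- c(out, rooted_triple(pair[1L], pair[2L], s[!inC]))
        break
      }
    }
  }
  sort(unique(out))
}

#' Does one rooted tree display another?
#'
#' `T` displays a binary tree `T'` with leaves inside `L(T)` iff every
#' rooted triple displayed by `T'` is displayed by `T`.
#'
#' @param parent a `rooted_tree`.
#' @param child a binary `rooted_tree` with `L(child)` a subset of
#'   `L(parent)`.
#' @return logical.
#' @export
displays_tree <- function(parent, child) {
  if (!all(tree_leaves(child) %in% tree_leaves(parent)))
    stop("child leaves must be a subset of parent leaves")
  if (!is_binary_tree(child)) stop("'child' must be binary")
  if (length(tree_leaves(child)) == 2L) return(TRUE)
  all(vapply(induced_triples(child), function(t)
    displays_triple(parent, t), TRUE))
}

#' Deterministic binary refinement of a rooted tree
#'
#' Every multifurcation is resolved as a left-leaning caterpillar over its
#' children taken in canonical order, so the result is a binary tree
#' displaying the input.
#'
#' @param tree a `rooted_tree`.
#' @return a binary `rooted_tree`.
#' @export
binary_refinement <- function(tree) {
  refine <- function(node) {
    if (!is.list(node)) return(node)
    ch <- lapply(canonical_node(node), refine)
    while (length(ch) > 2L)
      ch <- c(list(ch[1:2]), ch[-(1:2)])
    ch
  }
  rooted_tree(refine(tree$root))
}

insert_leaf_everywhere <- function(node, leaf) {
  out <- list(list(node, leaf))
  if (is.list(node)) {
    for (i in seq_along(node)) {
      for (sub in insert_leaf_everywhere(node[[i]], leaf)) {
        nn <- node
        nn[[i]] <- sub
        out <- c(out, list(nn))
      }
    }
  }
  out
}

#' Enumerate all rooted binary trees on a taxon set
#'
#' Deterministic leaf-insertion enumeration: taxa are added in sorted
#' order, each into every node position (every edge plus a new root), so
#' each of the `(2n-3)!!` shapes appears exactly once and the stream is
#' reproducible.
#'
#' @param taxa character vector of at least 2 labels.
#' @param max_n capacity ceiling on `|taxa|` (default 9).
#' @return list of `rooted_tree` objects.
#' @export
enumerate_rooted_binary_trees <- function(taxa, max_n = 9L) {
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  if (length(taxa) > max_n)
    stop("enumeration refused above ", max_n, " taxa; raise 'max_n'")
  shapes <- list(taxa[1L])
  for (leaf in taxa[-1L])
    shapes <- unlist(lapply(shapes, insert_leaf_everywhere, leaf = leaf),
                     recursive = FALSE)
  lapply(shapes, rooted_tree)
}

#' Closed-form count of trees displaying leaf-disjoint triples
#'
#' For a set of `n/3` pairwise leaf-disjoint triples on `n` leaves, the
#' number of rooted binary trees on the `n` leaves displaying any one
#' assignment is `(2n-3)!! / 3^(n/3)`.
#'
#' @param n number of leaves; a positive multiple of 3.
#' @return the exact integer count (as a double for large `n`).
#' @export
disjoint_display_count <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L || n %% 3L != 0L)
    stop("'n' must be a multiple of 3, at least 3")
  dd <- prod(seq(2 * n - 3, 1, by = -2))
  dd / 3^(n / 3)
}

#' Count rooted binary trees displaying a triple set
#'
#' Exhaustive oracle: enumerates every rooted binary tree on `X` and counts
#' those displaying all triples.
#'
#' @param triples character vector of triple tokens.
#' @param taxa taxon set containing the triples' leaves.
#' @param max_n enumeration capacity ceiling.
#' @return non-negative integer count.
#' @export
count_displaying_trees <- function(triples, taxa, max_n = 9L) {
  taxa <- sort(unique(as.character(taxa)))
  if (!all(triple_leaves(triples) %in% taxa))
    stop("'taxa' must contain all triple leaves")
  trees <- enumerate_rooted_binary_trees(taxa, max_n = max_n)
  if (length(triples) == 0L) return(length(trees))
  D <- displayed_token_matrix(trees)
  tokens <- colnames(parse_triples(triples))
  sum(rowSums(D[, tokens, drop = FALSE]) == length(tokens))
}

# trees x triple-token logical matrix: D[i, t] iff tree i displays t.
displayed_token_matrix <- function(trees) {
  all_tokens <- sort(unique(unlist(lapply(trees, induced_triples))))
  D <- matrix(FALSE, length(trees), length(all_tokens),
              dimnames = list(NULL, all_tokens))
  for (i in seq_along(trees))
    D[i, induced_triples(trees[[i]])] <- TRUE
  D
}

delete_leaf <- function(node, leaf) {
  if (!is.list(node)) return(if (identical(node, leaf)) NULL else node)
  ch <- Filter(Negate(is.null), lapply(node, delete_leaf, leaf = leaf))
  if (length(ch) == 1L) ch[[1L]] else ch
}

# All cherries of a binary node, each with the leaves of the components of
# T - u (u = cherry grandparent) containing neither the root nor the
# cherry: i.e. the cherry's "uncle" subtrees' leaves.
cherry_contexts <- function(node) {
  out <- list()
  walk <- function(u) {
    if (!is.list(u)) return(invisible())
    is_cherry <- function(v) is.list(v) && length(v) == 2L &&
      !is.list(v[[1L]]) && !is.list(v[[2L]])
    for (i in seq_along(u)) {
      v <- u[[i]]
      if (is_cherry(v)) {
        others <- unlist(lapply(u[-i], node_leaves), use.names = FALSE)
        out[[length(out) + 1L]] <<-
          list(cherry = sort(c(v[[1L]], v[[2L]])), context = sort(others))
      }
      walk(v)
    }
  }
  walk(node)
  out
}

#' A defining triple set for a binary tree
#'
#' Returns `n - 2` rooted triples whose support system is thin and for
#' which the input tree is the unique rooted phylogenetic tree displaying
#' them. The recursion repeatedly picks the cherry `{a, b}` with the
#' smallest leaf label, records `ab|c` for `c` the smallest leaf outside
#' the cherry's parent subtree (but below its grandparent), and deletes
#' `a`.
#'
#' @param tree a binary `rooted_tree` with `n >= 3` leaves.
#' @return character vector of `n - 2` triple tokens.
#' @export
unique_defining_triples <- function(tree) {
  if (!is_binary_tree(tree)) stop("'tree' must be binary")
  node <- tree$root
  n <- length(node_leaves(node))
  if (n < 3L) stop("tree must have at least 3 leaves")
  out <- character()
  while (length(node_leaves(node)) > 3L) {
    ctx <- cherry_contexts(node)
    mins <- vapply(ctx, function(x) x$cherry[1L], "")
    pick <- ctx[[order(mins, method = "radix")[1L]]]
    a <- pick$cherry[1L]; b <- pick$cherry[2L]; cc <- pick$context[1L]
    out <- c(out, rooted_triple(a, b, cc))
    node <- delete_leaf(node, a)
  }
  # base: 3-leaf binary tree is itself a rooted triple
  ctx <- cherry_contexts(list(node))[[1L]]
  out <- c(out, rooted_triple(ctx$cherry[1L], ctx$cherry[2L],
                              setdiff(node_leaves(node), ctx$cherry)))
  rev(out)
}
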