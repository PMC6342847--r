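#' Unrooted phylogenetic trees
#'
#' An unrooted tree with labelled leaves (degree 1) and unlabelled interior
#' vertices of degree at least 3, stored as an `igraph` graph plus the leaf
#' set. Interior vertices get synthetic names `v1, v2, ...`.
#'
#' @param edges a two-column character matrix of vertex names.
#' @param leaves character vector of the leaf labels among the vertices.
#' @return an object of class `unrooted_tree` with elements `graph` and
#'   `leaves`.
#' @export
unrooted_tree <- function(edges, leaves) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  leaves <- sort(as.character(leaves))
  check_labels(leaves)
  if (!all(leaves %in% igraph::V(g)$name)) stop("leaves must be vertices")
  if (igraph::ecount(g) != igraph::vcount(g) - 1L ||
      igraph::components(g)$no != 1L) stop("edges must form a tree")
  degs <- igraph::degree(g)
  if (any(degs[leaves] != 1L)) stop("leaves must have degree 1")
  interior <- setdiff(igraph::V(g)$name, leaves)
  if (any(degs[interior] < 3L))
    stop("interior vertices must have degree >= 3")
  structure(list(graph = g, leaves = leaves), class = "unrooted_tree")
}

#' @export
print.unrooted_tree <- function(x, ...) {
  cat(sprintf("unrooted tree: %d leaves, %d interior vertices\n",
              length(x$leaves),
              igraph::vcount(x$graph) - length(x$leaves)))
  cat(" leaves:", paste(x$leaves, collapse = " "), "\n")
  invisible(x)
}

#' Is an unrooted tree a caterpillar?
#'
#' Binary (all interior degrees 3) with the interior vertices forming a
#' path, equivalently at most two cherries.
#'
#' @param x an `unrooted_tree`.
#' @return logical.
#' @export
is_caterpillar <- function(x) {
  stopifnot(inherits(x, "unrooted_tree"))
  interior <- setdiff(igraph::V(x$graph)$name, x$leaves)
  degs <- igraph::degree(x$graph)
  if (any(degs[interior] != 3L)) return(FALSE)
  if (length(interior) <= 1L) return(TRUE)
  sub <- igraph::induced_subgraph(x$graph, interior)
  d <- igraph::degree(sub)
  igraph::components(sub)$no == 1L && all(d <= 2L) && sum(d == 1L) == 2L
}

#' Median vertex of three leaves in an unrooted tree
#'
#' The unique vertex common to the three pairwise paths between the
#' leaves.
#'
#' @param tree an `unrooted_tree`.
#' @param s character vector of three distinct leaves.
#' @return the median vertex name.
#' @export
median_vertex <- function(tree, s) {
  stopifnot(inherits(tree, "unrooted_tree"))
  s <- as.character(s)
  if (length(unique(s)) != 3L) stop("'s' must contain three distinct leaves")
  if (!all(s %in% tree$leaves)) stop("all of 's' must be leaves of the tree")
  path <- function(u, v) igraph::V(tree$graph)$name[
    igraph::shortest_paths(tree$graph, u, v)$vpath[[1L]]]
  med <- Reduce(intersect, list(path(s[1L], s[2L]), path(s[1L], s[3L]),
                                path(s[2L], s[3L])))
  if (length(med) != 1L) stop("internal error: median not unique")
  med
}

#' Is the block-to-median map injective?
#'
#' @param tree an `unrooted_tree` whose leaves include all block members.
#' @param x a `set_system` of 3-taxon blocks.
#' @return logical: `TRUE` when distinct blocks map to distinct median
#'   vertices.
#' @export
is_median_injective <- function(tree, x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 3L) stop("requires uniform block size 3")
  meds <- vapply(x$blocks, function(b) median_vertex(tree, b), "")
  !anyDuplicated(meds)
}

# Unrooted caterpillar from a left-to-right leaf order (n >= 4):
# interior spine v1..v(n-2); leaf i attaches to v(min(max(i-1,1), n-2)).
caterpillar_from_order <- function(ord) {
  n <- length(ord)
  if (n < 4L) stop("caterpillar construction needs at least 4 leaves")
  vs <- paste0("v", seq_len(n - 2L))
  el <- rbind(
    if (n > 4L) cbind(vs[-(n - 2L)], vs[-1L]) else cbind(vs[1L], vs[2L]),
    cbind(vs[pmin(pmax(seq_len(n) - 1L, 1L), n - 2L)], ord))
  tr <- unrooted_tree(el, ord)
  attr(tr, "order") <- ord
  tr
}

# Middle (median-position) members of the blocks fully contained in `ord`;
# FALSE when two such blocks share a middle.
middles_ok <- function(ord, blocks) {
  meds <- character()
  for (b in blocks) {
    pos <- match(b, ord)
    if (anyNA(pos)) next
    m <- b[order(pos)][2L]
    if (m %in% meds) return(FALSE)
    meds <- c(meds, m)
  }
  TRUE
}

# Complete backtracking search for a median-injective leaf order: place
# taxa left to right; a block's middle is fixed the moment its last member
# is placed, so collisions prune early.
ct_order_dfs <- function(blocks, X) {
  X <- sort(X)
  sol <- NULL
  rec <- function(ord, remaining, meds) {
    if (!length(remaining)) { sol <<- ord; return(TRUE) }
    for (x in remaining) {
      ord2 <- c(ord, x)
      meds2 <- meds
      ok <- TRUE
      for (b in blocks) {
        if (!(x %in% b) || !all(b %in% ord2)) next
        m <- b[order(match(b, ord2))][2L]
        if (m %in% meds2) { ok <- FALSE; break }
        meds2 <- c(meds2, m)
      }
      if (ok && rec(ord2, setdiff(remaining, x), meds2)) return(TRUE)
    }
    FALSE
  }
  if (rec(character(), X, character())) sol else NULL
}

thin_quick <- function(blocks) {
  if (length(blocks) == 0L) return(TRUE)
  min_surplus_brute(blocks, rep.int(1L, length(blocks)))$value >= 2L
}

# Re-insert missing taxa into a partial order, trying every position and
# keeping middle-injectivity of the completed blocks (depth-first).
insert_missing <- function(ord, missing, blocks) {
  if (!length(missing))
    return(if (middles_ok(ord, blocks)) ord else NULL)
  x <- missing[1L]
  for (p in 0:length(ord)) {
    o2 <- append(ord, x, after = p)
    if (!middles_ok(o2, blocks)) next
    r <- insert_missing(o2, missing[-1L], blocks)
    if (!is.null(r)) return(r)
  }
  NULL
}

# Inductive leaf-order construction for a thin size-3 system over X =
# L(blocks): peel a taxon of occurrence <= 2, reduce the system (drop the
# block, or replace the two blocks by one), solve recursively, then
# re-insert the peeled taxa at a verified position. Falls back to the
# complete backtracking search.
ct_order <- function(blocks, X) {
  if (length(blocks) == 0L) return(sort(X))
  if (length(X) <= 6L) return(ct_order_dfs(blocks, X))
  occ <- table(factor(unlist(blocks), levels = sort(X)))
  x <- names(occ)[which.min(occ)]
  cands <- list()
  if (occ[[x]] <= 1L) {
    ti <- which(vapply(blocks, function(b) x %in% b, TRUE))[1L]
    cands <- list(blocks[-ti])
  } else if (occ[[x]] == 2L) {
    ti <- which(vapply(blocks, function(b) x %in% b, TRUE))
    t1 <- blocks[[ti[1L]]]; t2 <- blocks[[ti[2L]]]
    others <- setdiff(union(t1, t2), x)
    newbs <- if (length(others) == 3L) list(others) else
      utils::combn(others, 3L, simplify = FALSE)
    for (nb in newbs) {
      red <- blocks[-ti]
      keys <- vapply(red, paste, "", collapse = ",")
      if (!(paste(sort(nb), collapse = ",") %in% keys))
        red <- c(red, list(sort(nb)))
      cands <- c(cands, list(red))
    }
  } else return(ct_order_dfs(blocks, X))
  for (tau2 in cands) {
    if (!thin_quick(tau2)) next
    L2 <- leaf_union(tau2)
    ord2 <- if (length(L2) >= 4L) ct_order(tau2, L2) else sort(L2)
    if (is.null(ord2)) next
    ord <- insert_missing(ord2, sort(setdiff(X, L2)), blocks)
    if (!is.null(ord)) return(ord)
  }
  ct_order_dfs(blocks, X)
}

#' Caterpillar median representation of a thin system
#'
#' Constructs an unrooted caterpillar tree on the universe whose
#' block-to-median-vertex map is injective. Exists exactly for thin
#' size-3 systems (on at least 4 taxa); in a caterpillar, a block's median
#' is the spine vertex carrying its middle leaf, so the construction
#' searches for a leaf order under which block middles are pairwise
#' distinct, by the inductive peel with a complete backtracking fallback.
#' Universe taxa outside the leaf union are appended at the right end of
#' the spine, where they cannot collide with any median.
#'
#' @param x a thin `set_system` of 3-taxon blocks, `|L(tau)| >= 4`.
#' @return an `unrooted_tree` caterpillar (leaf order in attribute
#'   `"order"`) passing [is_median_injective()].
#' @examples
#' build_caterpillar_median(fig3_tau())
#' @export
build_caterpillar_median <- function(x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 3L) stop("requires uniform block size 3")
  th <- is_thin(x)
  if (!th) stop("system is not thin; witness excess ",
                attr(th, "report")$excess)
  L <- leaf_union(x)
  if (length(L) < 4L) stop("need at least 4 covered taxa")
  ord <- ct_order(x$blocks, L)
  if (is.null(ord)) stop("internal error: no caterpillar order found")
  caterpillar_from_order(c(ord, sort(setdiff(x$taxa, L))))
}

#' Least common ancestor of two leaves in a rooted tree
#'
#' @param tree a `rooted_tree`.
#' @param pair character vector of two distinct leaves.
#' @return the lca vertex, identified by its cluster (comma-joined leaf
#'   set below it); leaves identify themselves.
#' @export
lca_vertex <- function(tree, pair) {
  pair <- as.character(pair)
  if (length(unique(pair)) != 2L) stop("'pair' must be two distinct leaves")
  lv <- tree_leaves(tree)
  if (!all(pair %in% lv)) stop("both elements must be leaves of the tree")
  cl <- tree_clusters(tree)
  containing <- Filter(function(C) all(pair %in% C), cl)
  sizes <- vapply(containing, length, 0L)
  paste(containing[[which.min(sizes)]], collapse = ",")
}

lca_order <- function(blocks, X) {
  if (length(blocks) == 0L) return(sort(X))
  occ <- table(factor(unlist(blocks), levels = X))
  ones <- names(occ)[occ == 1L]
  if (!length(ones)) stop("no taxon of occurrence 1: system is not thin")
  x <- sort(ones)[1L]
  ti <- which(vapply(blocks, function(b) x %in% b, TRUE))
  a <- setdiff(blocks[[ti]], x)
  tau2 <- blocks[-ti]
  L2 <- leaf_union(tau2)
  ord2 <- lca_order(tau2, L2)
  tail <- c(if (!(a %in% L2)) a, x)
  c(ord2, tail)
}

#' Rooted caterpillar lca representation of a thin pair system
#'
#' For a thin system of 2-taxon blocks covering its universe, constructs a
#' rooted binary caterpillar on the universe under which the
#' block-to-least-common-ancestor map is injective. The construction peels
#' a taxon of occurrence 1 and re-attaches it (with its partner, when the
#' partner also leaves the reduced system) at the top of the caterpillar.
#'
#' @param x a thin `set_system` of 2-taxon blocks with `L(tau)` equal to
#'   the universe.
#' @return a `rooted_tree` caterpillar (leaf order, cherry first, in
#'   attribute `"order"`) whose lca map is injective on the blocks.
#' @export
build_rooted_caterpillar_lca <- function(x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 2L) stop("requires uniform block size 2")
  if (!setequal(leaf_union(x), x$taxa))
    stop("requires L(tau) equal to the universe")
  th <- is_thin(x)
  if (!th) stop("system is not thin; witness excess ",
                attr(th, "report")$excess)
  ord <- lca_order(x$blocks, x$taxa)
  node <- list(ord[1L], ord[2L])
  for (lf in ord[-(1:2)]) node <- list(node, lf)
  tr <- rooted_tree(node)
  attr(tr, "order") <- ord
  tr
}

#' Is the block-to-lca map injective?
#'
#' @param tree a `rooted_tree` whose leaves include all block members.
#' @param x a `set_system` of 2-taxon blocks.
#' @return logical.
#' @export
is_lca_injective <- function(tree, x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 2L) stop("requires uniform block size 2")
  lcas <- vapply(x$blocks, function(b) lca_vertex(tree, b), "")
  !anyDuplicated(lcas)
}

#' Forest criterion for thin pair systems
#'
#' A system of 2-taxon blocks covering its universe is thin iff its
#' bipartite incidence graph is acyclic.
#'
#' @param x a `set_system` of 2-taxon blocks.
#' @return logical: `TRUE` iff the incidence graph is a forest.
#' @export
incidence_forest_check <- function(x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 2L) stop("requires uniform block size 2")
  g <- incidence_graph(x)
  igraph::ecount(g) == igraph::vcount(g) - igraph::components(g)$no
}

# Kahn's algorithm on the orientation digraph.
orientation_acyclic <- function(from, to, verts) {
  n <- length(verts)
  fi <- match(from, verts); ti <- match(to, verts)
  indeg <- tabulate(ti, n)
  done <- 0L
  active <- rep(TRUE, length(fi))
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; done <- done + 1L
    out <- which(active & fi == v)
    active[out] <- FALSE
    for (w in ti[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  done == n
}

#' Total-order flexibility of a pair system
#'
#' A system of 2-taxon blocks is total-order flexible when every
#' orientation of the pairs extends to a total order of the taxa,
#' equivalently when every orientation's digraph is acyclic. Equivalent to
#' thinness (and to the incidence graph being a forest).
#'
#' @param x a `set_system` of 2-taxon blocks.
#' @param method `"auto"`, `"exhaustive"` (all `2^m` orientations),
#'   `"thin"`, or `"both"` (cross-validates).
#' @param max_exhaustive refuse exhaustive sweeps above this many blocks.
#' @return logical verdict; when `FALSE` under an exhaustive method,
#'   attribute `"counterexample"` holds a cyclic orientation as a
#'   character vector of `"x<y"` declarations, one per block.
#' @examples
#' is_total_order_flexible(set_system(list(c("a","b"), c("b","c"))))
#' @export
is_total_order_flexible <- function(x, method = c("auto", "exhaustive",
                                                  "thin", "both"),
                                    max_exhaustive = 20L) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 2L) stop("requires uniform block size 2")
  method <- match.arg(method)
  k <- length(x$blocks)
  if (method == "auto")
    method <- if (k <= max_exhaustive) "exhaustive" else "thin"
  if (method == "thin") return(structure(as.logical(is_thin(x))))
  if (k > max_exhaustive)
    stop("exhaustive orientation sweep refused above ", max_exhaustive,
         " blocks")
  verts <- x$taxa
  u <- vapply(x$blocks, `[`, "", 1L)
  v <- vapply(x$blocks, `[`, "", 2L)
  res <- structure(TRUE, counterexample = NULL)
  for (m in 0:(2^k - 1)) {
    flip <- bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L
    from <- ifelse(flip, v, u); to <- ifelse(flip, u, v)
    if (!orientation_acyclic(from, to, verts)) {
      res <- structure(FALSE,
                       counterexample = paste0(from, "<", to))
      break
    }
  }
  if (method == "both" && as.logical(res) != as.logical(is_thin(x)))
    stop("exhaustive and thin verdicts disagree")
  res
}
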