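#' Surplus functions of a set system
#'
#' For a sub-collection `S` of blocks, `sigma(S) = |L(S)| - |S|` and
#' `gamma(S) = |L(S)| - sum(|s| - 2)`; both are submodular set functions
#' over the blocks, with `sigma(NULL) = gamma(NULL) = 0`. On non-empty
#' sub-collections `gamma = exc' + 2`, and for size-3 blocks
#' `sigma = exc + 2`.
#'
#' @param x a `set_system`.
#' @param subset integer indices of blocks (canonical order); may be empty.
#' @return integer value.
#' @export
sigma_value <- function(x, subset = seq_along(x$blocks)) {
  stopifnot(inherits(x, "set_system"))
  if (length(subset) == 0L) return(0L)
  length(leaf_union(x$blocks[subset])) - length(subset)
}

#' @rdname sigma_value
#' @export
gamma_value <- function(x, subset = seq_along(x$blocks)) {
  stopifnot(inherits(x, "set_system"))
  if (length(subset) == 0L) return(0L)
  length(leaf_union(x$blocks[subset])) -
    sum(lengths(x$blocks[subset]) - 2L)
}

#' Bipartite incidence graph of a set system
#'
#' The containment graph between blocks and taxa of the leaf union:
#' block vertices (named by their comma-joined members, `type = FALSE`)
#' are adjacent to exactly the taxa they contain (`type = TRUE`).
#'
#' @param x a `set_system`.
#' @return a bipartite `igraph` graph.
#' @export
incidence_graph <- function(x) {
  stopifnot(inherits(x, "set_system"))
  bn <- vapply(x$blocks, paste, "", collapse = ",")
  taxa <- leaf_union(x$blocks)
  el <- do.call(rbind, lapply(seq_along(bn), function(i)
    cbind(bn[i], x$blocks[[i]])))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% taxa
  g
}

# Exact minimisation of cov(Y) - w(Y) over non-empty Y via one min-cut per
# forced block on the incidence network: source -> block_i (capacity w_i,
# or "infinite" for the forced block), block -> taxon and taxon -> sink
# edges (infinite resp. unit). Infinite = sum(w) + sum(degrees) + 1, which
# strictly exceeds any finite cut.
min_surplus_mincut <- function(blocks, w) {
  k <- length(blocks)
  if (k == 0L) stop("empty system")
  taxa <- leaf_union(blocks)
  n <- length(taxa)
  INF <- sum(w) + sum(lengths(blocks)) + 1
  src <- 1L; snk <- 2L
  bid <- 2L + seq_len(k)
  tid <- 2L + k + seq_len(n)
  el <- rbind(cbind(src, bid),
              do.call(rbind, lapply(seq_len(k), function(i)
                cbind(bid[i], tid[match(blocks[[i]], taxa)]))),
              cbind(tid, snk))
  base_caps <- c(w, rep(INF, sum(lengths(blocks))), rep(1, n))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  W <- sum(w)
  best <- NULL
  for (s in seq_len(k)) {
    caps <- base_caps
    caps[s] <- INF
    f <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
    Y <- intersect(as.integer(f$partition1), bid) - 2L
    val <- length(leaf_union(blocks[Y])) - sum(w[Y])
    if (val != f$value - W)
      stop("min-cut inconsistency: recomputed ", val, " vs ", f$value - W)
    if (is.null(best) || val < best$value)
      best <- list(value = as.integer(val), indices = sort(Y))
  }
  best
}

star_minimiser <- function(x, w, method, max_brute, what) {
  k <- length(x$blocks)
  if (method == "auto") method <- if (k > 15L) "mincut" else "brute"
  res <- switch(method,
    brute  = min_surplus_brute(x$blocks, w, max_brute),
    mincut = min_surplus_mincut(x$blocks, w),
    both   = {
      b <- min_surplus_brute(x$blocks, w, max_brute)
      m <- min_surplus_mincut(x$blocks, w)
      if (b$value != m$value)
        stop(what, ": brute (", b$value, ") and mincut (", m$value,
             ") disagree")
      b
    })
  structure(list(value = res$value, indices = res$indices,
                 subset = x$blocks[res$indices], what = what),
            class = "minimizer_result")
}

#' @export
print.minimizer_result <- function(x, ...) {
  cat(sprintf("%s* = %d, attained by %d block(s):\n", x$what, x$value,
              length(x$indices)))
  for (b in x$subset) cat(" {", paste(b, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Minimum surplus over non-empty sub-collections
#'
#' `sigma_star` minimises `sigma`, `gamma_star` minimises `gamma`, over all
#' non-empty sub-collections of blocks. The `brute` method enumerates
#' subsets; the `mincut` method solves one maximum-flow problem per forced
#' block on the bipartite incidence network, which is exact for these
#' coverage-type submodular functions; `both` cross-validates. A uniform
#' size-`r` system is thin iff `sigma* >= r - 1`, and a system of blocks
#' of size >= 3 is slim iff `gamma* >= 2`.
#'
#' @param x a non-empty `set_system`.
#' @param method `"auto"`, `"brute"`, `"mincut"` or `"both"`.
#' @param max_brute brute-force subset ceiling.
#' @return a `minimizer_result`: list with integer `value`, the attaining
#'   block `indices` (canonical order) and the `subset` itself. When
#'   several subsets attain the minimum, brute force returns the
#'   lexicographically least by (size, sorted block order); the mincut
#'   route returns the cut-derived subset for the first forced block
#'   attaining the minimum.
#' @export
sigma_star <- function(x, method = c("auto", "brute", "mincut", "both"),
                       max_brute = 20L) {
  stopifnot(inherits(x, "set_system"))
  star_minimiser(x, rep.int(1L, length(x$blocks)), match.arg(method),
                 max_brute, "sigma")
}

#' @rdname sigma_star
#' @export
gamma_star <- function(x, method = c("auto", "brute", "mincut", "both"),
                       max_brute = 20L) {
  stopifnot(inherits(x, "set_system"))
  if (any(block_sizes(x) < 3L)) stop("gamma_star requires blocks of size >= 3")
  star_minimiser(x, block_sizes(x) - 2L, match.arg(method), max_brute,
                 "gamma")
}

#' Polynomial-time thin/slim tests
#'
#' Threshold tests on the min-cut surplus minima: a uniform size-`r`
#' system is thin iff `sigma* >= r - 1`; a system of blocks of size >= 3
#' is slim iff `gamma* >= 2`.
#'
#' @param x a `set_system`.
#' @return logical, with the `minimizer_result` in attribute `"minimizer"`.
#' @export
is_thin_poly <- function(x) {
  r <- uniform_size(x)
  if (is.na(r)) stop("is_thin_poly requires uniform block sizes")
  res <- sigma_star(x, method = "mincut")
  structure(res$value >= r - 1L, minimizer = res)
}

#' @rdname is_thin_poly
#' @export
is_slim_poly <- function(x) {
  res <- gamma_star(x, method = "mincut")
  structure(res$value >= 2L, minimizer = res)
}

# sigma and gamma over every subset mask (index mask + 1; mask 0 = empty).
all_subset_values <- function(x) {
  k <- length(x$blocks)
  taxa <- leaf_union(x$blocks)
  M <- t(vapply(x$blocks, function(b) taxa %in% b, logical(length(taxa))))
  storage.mode(M) <- "integer"
  pow <- 2^(seq_len(k) - 1L)
  masks <- 0:(2^k - 1)
  S <- outer(masks, pow, function(m, p) bitwAnd(m, p) > 0L)
  storage.mode(S) <- "integer"
  cov <- rowSums((S %*% M) > 0L)
  list(sigma = cov - rowSums(S),
       gamma = cov - as.vector(S %*% (lengths(x$blocks) - 2L)))
}

#' Verify submodularity of the surplus functions
#'
#' Checks `f(A) + f(B) >= f(A | B) + f(A & B)` for `f` in `{sigma, gamma}`
#' over pairs of sub-collections: exhaustively for systems with at most 8
#' blocks, otherwise on seeded random pairs. Always `TRUE` by theory; this
#' is a verification utility.
#'
#' @param x a `set_system`.
#' @param trials number of sampled pairs when not exhaustive.
#' @param seed optional RNG seed for the sampled mode.
#' @return logical.
#' @export
check_submodularity <- function(x, trials = 200L, seed = NULL) {
  stopifnot(inherits(x, "set_system"))
  k <- length(x$blocks)
  vals <- all_subset_values(x)
  pairs <- if (k <= 8L) {
    m <- 0:(2^k - 1)
    cbind(rep(m, each = length(m)), rep(m, times = length(m)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    matrix(sample(0:(2^k - 1), 2L * trials, replace = TRUE), ncol = 2L)
  }
  A <- pairs[, 1L]; B <- pairs[, 2L]
  or_ <- bitwOr(A, B); and_ <- bitwAnd(A, B)
  ok <- function(v) all(v[A + 1L] + v[B + 1L] >= v[or_ + 1L] + v[and_ + 1L])
  ok(vals$sigma) && ok(vals$gamma)
}

#' Surplus of a bipartite incidence graph
#'
#' The minimum of `|N(Y)| - |Y|` over non-empty subsets `Y` of the block
#' side; equals `sigma_star` of the generating system.
#'
#' @param g a bipartite `igraph` graph with logical vertex attribute
#'   `type` (`FALSE` = block side), e.g. from [incidence_graph()], or a
#'   `set_system`.
#' @return integer surplus.
#' @export
graph_surplus <- function(g) {
  if (inherits(g, "set_system")) return(sigma_star(g, "mincut")$value)
  stopifnot(igraph::is_igraph(g))
  a_side <- which(!igraph::V(g)$type)
  blocks <- lapply(a_side, function(v)
    igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])
  min_surplus_mincut(blocks, rep.int(1L, length(blocks)))$value
}

#' Search for a spanning degree-2 forest from the block side
#'
#' A bipartite graph has positive surplus (viewed from the block side) iff
#' it contains a forest in which every block-side vertex has degree
#' exactly 2. This brute-force utility enumerates, per block vertex, all
#' pairs of incident edges and tests acyclicity of each combination.
#'
#' @param g a bipartite `igraph` graph (vertex attribute `type`, `FALSE` =
#'   block side) or a `set_system`.
#' @param max_combos refuse searches with more than this many edge-pair
#'   combinations.
#' @return logical; `TRUE` when such a forest exists.
#' @export
degree2_forest_exists <- function(g, max_combos = 2e5) {
  if (inherits(g, "set_system")) g <- incidence_graph(g)
  stopifnot(igraph::is_igraph(g))
  a_side <- which(!igraph::V(g)$type)
  nbrs <- lapply(a_side, function(v) as.integer(igraph::neighbors(g, v)))
  if (any(lengths(nbrs) < 2L)) return(FALSE)
  pair_sets <- lapply(nbrs, function(nb)
    utils::combn(nb, 2L, simplify = FALSE))
  if (prod(lengths(pair_sets)) > max_combos)
    stop("degree-2 forest search too large (", prod(lengths(pair_sets)),
         " combinations)")
  nv <- igraph::vcount(g)
  acyclic <- function(choice) {
    parent <- seq_len(nv)
    find <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (j in seq_along(choice)) {
      u <- a_side[j]
      for (t in choice[[j]]) {
        ru <- find(u); rt <- find(t)
        if (ru == rt) return(FALSE)
        parent[ru] <- rt
      }
    }
    TRUE
  }
  idx <- rep(1L, length(pair_sets))
  repeat {
    choice <- Map(function(ps, i) ps[[i]], pair_sets, idx)
    if (acyclic(choice)) return(TRUE)
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(pair_sets[[j]])) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > length(idx)) return(FALSE)
  }
}
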