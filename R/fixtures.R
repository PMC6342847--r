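#' Worked-example set systems and triple sets
#'
#' Small named instances used throughout the package's examples and tests:
#' `fig1_tau()` is a four-block system on six taxa that is thin and
#' phylogenetically flexible; `fig1_tau_prime()` adds the block `{b,d,e}`
#' and is neither; `fig1_counterexample_triples()` is an incompatible
#' assignment of one rooted triple per block of `fig1_tau_prime()`;
#' `sec1_tau()` is a thin four-block system that cannot be produced by the
#' sequential fresh-taxon construction; `fig3_tau()` is a thin five-block
#' system on seven taxa with a caterpillar median representation;
#' `order_flex_pair()` and `order_rigid_triangle()` are the standard
#' total-order examples; `prop1_family(n)` is the two-anchor family
#' `{{1,2,j}: 2 < j <= n}` of maximal thin size `n - 2`.
#'
#' @return a `set_system`, except `fig1_counterexample_triples()` which
#'   returns a character vector of triple tokens.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fig1_tau <- function()
  set_system(list(c("a", "b", "c"), c("a", "b", "d"), c("b", "c", "e"),
                  c("d", "e", "f")))

#' @rdname fixtures
#' @export
fig1_tau_prime <- function()
  set_system(c(fig1_tau()$blocks, list(c("b", "d", "e"))))

#' @rdname fixtures
#' @export
fig1_counterexample_triples <- function()
  c("a,b|c", "b,d|a", "b,c|e", "d,f|e", "b,e|d")

#' @rdname fixtures
#' @export
sec1_tau <- function()
  set_system(list(c("a", "b", "c"), c("c", "d", "e"), c("b", "e", "f"),
                  c("a", "d", "f")))

#' @rdname fixtures
#' @export
fig3_tau <- function()
  set_system(list(c("a", "b", "c"), c("c", "d", "e"), c("a", "e", "f"),
                  c("b", "e", "g"), c("a", "d", "g")))

#' @rdname fixtures
#' @export
order_flex_pair <- function()
  set_system(list(c("a", "b"), c("b", "c")))

#' @rdname fixtures
#' @export
order_rigid_triangle <- function()
  set_system(list(c("a", "b"), c("b", "c"), c("a", "c")))

#' @rdname fixtures
#' @param n number of taxa (labels `"1"` to `"n"`), `n >= 3`.
#' @export
prop1_family <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("'n' must be at least 3")
  set_system(lapply(3:n, function(j) as.character(c(1L, 2L, j))))
}

taxon_labels <- function(n) {
  if (n <= 26L) letters[seq_len(n)]
  else c(letters, sprintf("z%02d", seq_len(n - 26L)))
}

#' Random set system
#'
#' Samples `n_blocks` distinct blocks uniformly without replacement.
#'
#' @param n_taxa number of taxa (labelled `a`, `b`, ...).
#' @param n_blocks number of blocks.
#' @param block_size block size, a scalar or a vector of length
#'   `n_blocks` (mixed sizes allowed).
#' @param seed optional RNG seed for reproducibility.
#' @return a `set_system`.
#' @export
random_set_system <- function(n_taxa, n_blocks, block_size = 3L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- taxon_labels(n_taxa)
  sizes <- rep_len(as.integer(block_size), n_blocks)
  if (any(sizes > n_taxa)) stop("block size exceeds the number of taxa")
  for (s in unique(sizes))
    if (sum(sizes == s) > choose(n_taxa, s))
      stop("too many blocks of size ", s, " for ", n_taxa, " taxa")
  blocks <- list()
  keys <- character()
  for (s in sizes) {
    repeat {
      b <- sort(sample(labs, s))
      key <- paste(b, collapse = ",")
      if (!(key %in% keys)) break
    }
    blocks <- c(blocks, list(b))
    keys <- c(keys, key)
  }
  set_system(blocks, taxa = labs)
}

#' Random thin set system
#'
#' Sequential construction: every block after the first contains at least
#' one taxon not present in any earlier block, which guarantees thinness.
#' Not every thin system is reachable this way (e.g. [sec1_tau()] is not).
#'
#' @param n_blocks number of blocks.
#' @param block_size uniform block size (>= 2).
#' @param seed optional RNG seed.
#' @param max_taxa cap on the total number of taxa used; must allow at
#'   least one fresh taxon per block.
#' @return a thin `set_system` (verified internally).
#' @export
random_thin_system <- function(n_blocks, block_size = 3L, seed = NULL,
                               max_taxa = Inf) {
  if (!is.null(seed)) set.seed(seed)
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("'block_size' must be at least 2")
  if (max_taxa < block_size + n_blocks - 1L)
    stop("'max_taxa' too small to allow a fresh taxon per block")
  used <- character()
  fresh_pool <- function(k) taxon_labels(length(used) + k)[
    length(used) + seq_len(k)]
  blocks <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    if (i == 1L) {
      blocks[[i]] <- fresh_pool(block_size)
    } else {
      budget <- min(block_size - 1L, max_taxa - length(used))
      nf <- if (budget <= 1L) 1L else sample(budget, 1L)
      repeat {
        b <- sort(c(fresh_pool(nf), sample(used, block_size - nf)))
        if (!any(vapply(blocks[seq_len(i - 1L)], identical, TRUE, y = b)))
          break
      }
      blocks[[i]] <- b
    }
    used <- union(used, blocks[[i]])
  }
  out <- set_system(blocks)
  stopifnot(isTRUE(as.logical(is_thin(out))))
  out
}

#' Random rooted binary tree
#'
#' Uniform over the `(2n-3)!!` shapes: taxa are added in sorted order,
#' each at a uniformly chosen node position (every edge plus a new root).
#'
#' @param taxa character vector of at least 2 labels.
#' @param seed optional RNG seed.
#' @return a binary `rooted_tree`.
#' @export
random_rooted_binary_tree <- function(taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  node <- taxa[1L]
  for (leaf in taxa[-1L]) {
    opts <- insert_leaf_everywhere(node, leaf)
    node <- opts[[sample.int(length(opts), 1L)]]
  }
  rooted_tree(node)
}
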