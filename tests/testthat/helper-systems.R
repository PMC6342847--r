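# Shared helpers for building small random instances in tests.

# Random size-3 system at oracle scale (|X| <= 7, |tau| <= 5).
small_triple_system <- function(seed) {
  set.seed(seed)
  n <- sample(4:7, 1L)
  k <- sample(seq_len(min(5L, choose(n, 3L))), 1L)
  random_set_system(n, k, 3L, seed = seed)
}

# Random mixed-size system (sizes 3-4) at general-flexibility oracle scale.
small_mixed_system <- function(seed) {
  set.seed(seed)
  n <- sample(6:8, 1L)
  k <- sample(1:3, 1L)
  random_set_system(n, k, sample(3:4, k, replace = TRUE), seed = seed)
}

# Random mixed-size system with up to `max_blocks` blocks for minimiser
# cross-validation.
medium_mixed_system <- function(seed, max_blocks = 12L) {
  set.seed(seed)
  n <- sample(6:12, 1L)
  k <- sample(2:max_blocks, 1L)
  random_set_system(n, k, sample(3:4, k, replace = TRUE), seed = seed)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (i in 0:(n - 1L))
      out <- c(out, list(append(p, n, after = i)))
  out
}

# Unrooted tree built from a rooted one by attaching an extra leaf at the
# root (which then has degree 3). Used for the lca/median round trip.
unrooted_from_rooted <- function(tree, extra_leaf) {
  counter <- 0L
  edges <- NULL
  walk <- function(node) {
    if (!is.list(node)) return(node)
    counter <<- counter + 1L
    me <- paste0("v", counter)
    for (ch in node) {
      child_name <- walk(ch)
      edges <<- rbind(edges, c(me, child_name))
    }
    me
  }
  root <- walk(tree$root)
  edges <- rbind(edges, c(root, extra_leaf))
  unrooted_tree(edges, c(tree_leaves(tree), extra_leaf))
}
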