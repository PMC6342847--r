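test_that("triple construction and parsing canonicalise", {
  expect_identical(rooted_triple("b", "a", "c"), "a,b|c")
  expect_error(rooted_triple("a", "a", "c"), "distinct")
  m <- parse_triples(c("ab|c", "d,c|a"))
  expect_identical(colnames(m), c("a,b|c", "c,d|a"))
  expect_identical(unname(m[, 2L]), c("c", "d", "a"))
  expect_error(parse_triples("ab"), "malformed")
  expect_error(parse_triples("aa|b"), "distinct")
  expect_identical(block_triples(c("c", "a", "b")),
                   c("a,b|c", "a,c|b", "b,c|a"))
})

test_that("displays_triple matches the lca characterisation", {
  t3 <- read_newick(text = "((a,b),c);")
  expect_true(displays_triple(t3, "a,b|c"))
  expect_false(displays_triple(t3, "a,c|b"))
  t4 <- read_newick(text = "(((a,b),c),d);")
  expect_true(displays_triple(t4, "b,c|d"))
  expect_error(displays_triple(t3, "a,b|z"), "leaves")
})

test_that("induced_triples enumerates displayed triples", {
  expect_identical(induced_triples(read_newick(text = "((a,b),c);")),
                   "a,b|c")
  star <- rooted_tree(list("a", "b", "c"))
  expect_length(induced_triples(star), 0L)
  expect_identical(induced_triples(read_newick(text = "(((a,b),c),d);")),
                   c("a,b|c", "a,b|d", "a,c|d", "b,c|d"))
})

test_that("displays_tree reduces to triple containment", {
  p <- read_newick(text = "(((a,b),c),d);")
  expect_true(displays_tree(p, p))
  expect_true(displays_tree(p, read_newick(text = "((a,b),c);")))
  q <- read_newick(text = "((a,c),(b,d));")
  expect_false(displays_tree(q, read_newick(text = "((a,b),c);")))
})

test_that("cluster_graph builds [R, S] restricted to S", {
  g <- cluster_graph(fig1_counterexample_triples(), letters[1:6])
  expect_equal(igraph::components(g)$no, 1)
  g2 <- cluster_graph("a,b|c", c("a", "b"))
  expect_equal(igraph::ecount(g2), 0)
  g3 <- cluster_graph("a,b|c", c("a", "b", "c"))
  expect_equal(igraph::ecount(g3), 1)
  expect_true(igraph::are_adjacent(g3, "a", "b"))
})

test_that("BUILD decides compatibility with a displaying tree", {
  expect_false(as.logical(is_compatible(fig1_counterexample_triples())))
  ok <- is_compatible("a,b|c")
  expect_true(as.logical(ok))
  expect_identical(format(attr(ok, "tree")), "((a,b),c);")
  ok2 <- is_compatible(c("a,b|c", "a,b|d"))
  expect_true(as.logical(ok2))
  expect_true(any(vapply(tree_clusters(attr(ok2, "tree")), identical,
                         TRUE, y = c("a", "b"))))
  expect_true(as.logical(is_compatible(character())))
  expect_error(build_supertree(fig1_counterexample_triples()),
               "incompatible")
})

test_that("BUILD agrees with the all-subsets disconnection criterion", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(4:6, 1L)
    taxa <- letters[seq_len(n)]
    k <- sample(1:4, 1L)
    R <- unique(vapply(seq_len(k), function(i) {
      s <- sample(taxa, 3L)
      rooted_triple(s[1L], s[2L], s[3L])
    }, ""))
    aho <- as.logical(is_compatible(R, taxa))
    bs <- TRUE
    for (sz in 2:n) for (S in utils::combn(taxa, sz, simplify = FALSE)) {
      if (igraph::components(cluster_graph(R, S))$no == 1L && sz >= 2L) {
        bs <- FALSE
        break
      }
      if (!bs) break
    }
    expect_identical(aho, bs)
    if (aho) {
      tree <- attr(is_compatible(R, taxa), "tree")
      for (t in R) expect_true(displays_triple(tree, t))
    }
  }
})

test_that("a supporting triple set splits the cluster graph in two", {
  # caterpillar trees with one triple supporting each interior non-root
  # vertex: [R, X] must have exactly two connected components
  for (n in 4:6) {
    ord <- letters[seq_len(n)]
    R <- c(rooted_triple(ord[1L], ord[2L], ord[3L]),
           vapply(3:(n - 1L), function(i)
             rooted_triple(ord[1L], ord[i], ord[i + 1L]), ""))
    expect_equal(igraph::components(cluster_graph(R, ord))$no, 2)
  }
})

test_that("binary refinement displays the unrefined BUILD tree", {
  ok <- is_compatible(c("a,b|c", "a,b|d", "a,b|e"))
  tree <- attr(ok, "tree")
  expect_false(is_binary_tree(tree))
  bin <- binary_refinement(tree)
  expect_true(is_binary_tree(bin))
  for (t in induced_triples(tree)) expect_true(displays_triple(bin, t))
})

test_that("rooted binary tree enumeration hits the double factorial", {
  expect_length(enumerate_rooted_binary_trees(letters[1:3]), 3L)
  tr4 <- enumerate_rooted_binary_trees(letters[1:4])
  expect_length(tr4, 15L)
  expect_length(unique(vapply(tr4, format, "")), 15L)
  for (n in 5:6)
    expect_length(enumerate_rooted_binary_trees(letters[seq_len(n)]),
                  prod(seq(2 * n - 3, 1, by = -2)))
  expect_error(enumerate_rooted_binary_trees(letters[1:10]), "refused")
})

test_that("the closed-form disjoint display count matches arithmetic", {
  expect_identical(disjoint_display_count(3L), 1)
  expect_identical(disjoint_display_count(6L), 105)
  expect_identical(disjoint_display_count(9L), 75075)
  expect_error(disjoint_display_count(5L), "multiple of 3")
})

test_that("count_displaying_trees is an exact oracle", {
  expect_identical(count_displaying_trees("a,b|c", letters[1:3]), 1L)
  expect_identical(
    count_displaying_trees(fig1_counterexample_triples(), letters[1:6]), 0L)
  # two leaf-disjoint triples: closed form, for random cherry choices
  for (seed in 1:3) {
    set.seed(seed)
    s1 <- sample(letters[1:3]); s2 <- sample(letters[4:6])
    R <- c(rooted_triple(s1[1L], s1[2L], s1[3L]),
           rooted_triple(s2[1L], s2[2L], s2[3L]))
    expect_identical(count_displaying_trees(R, letters[1:6]), 105L)
  }
})

test_that("unique defining triples pin down their tree", {
  expect_identical(unique_defining_triples(read_newick(text = "((a,b),c);")),
                   "a,b|c")
  cat4 <- read_newick(text = "(((a,b),c),d);")
  R4 <- unique_defining_triples(cat4)
  expect_length(R4, 2L)
  expect_true("a,b|c" %in% R4)
  trees <- enumerate_rooted_binary_trees(letters[1:4])
  disp <- Filter(function(t2)
    all(vapply(R4, function(t) displays_triple(t2, t), TRUE)), trees)
  expect_length(disp, 1L)
  expect_identical(format(disp[[1L]]), format(cat4))
  expect_error(unique_defining_triples(rooted_tree(list("a", "b", "c"))),
               "binary")
})
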