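test_that("median_vertex finds the shared path vertex", {
  # quartet ab|cd: spine v1 - v2, a,b on v1, c,d on v2
  q <- unrooted_tree(rbind(c("v1", "v2"), c("v1", "a"), c("v1", "b"),
                           c("v2", "c"), c("v2", "d")),
                     c("a", "b", "c", "d"))
  expect_identical(median_vertex(q, c("a", "b", "c")), "v1")
  expect_identical(median_vertex(q, c("a", "c", "d")), "v2")
  expect_error(median_vertex(q, c("a", "b", "z")), "leaves")
})

test_that("is_median_injective detects median collisions", {
  cat5 <- phyloflex:::caterpillar_from_order(letters[1:5])
  expect_true(is_caterpillar(cat5))
  # {a,c,e} and {b,c,d} share middle leaf c, hence the same median vertex
  clash <- set_system(list(c("a", "c", "e"), c("b", "c", "d")))
  expect_false(is_median_injective(cat5, clash))
  expect_true(is_median_injective(cat5,
                                  set_system(list(c("a", "b", "c")))))
})

test_that("caterpillar median representations exist for thin systems", {
  for (x in list(fig3_tau(), sec1_tau(), fig1_tau())) {
    tr <- build_caterpillar_median(x)
    expect_true(is_caterpillar(tr))
    expect_setequal(tr$leaves, x$taxa)
    expect_true(is_median_injective(tr, x))
  }
  # |X| = 4 base case
  x4 <- set_system(list(c("a", "b", "c"), c("b", "c", "d")))
  tr4 <- build_caterpillar_median(x4)
  expect_true(is_caterpillar(tr4))
  expect_true(is_median_injective(tr4, x4))
  # universe taxa outside the leaf union are appended, not medians
  x5 <- set_system(list(c("a", "b", "c"), c("b", "c", "d")),
                   taxa = c("a", "b", "c", "d", "z"))
  tr5 <- build_caterpillar_median(x5)
  expect_true("z" %in% tr5$leaves)
  expect_true(is_median_injective(tr5, x5))
  expect_error(build_caterpillar_median(fig1_tau_prime()), "not thin")
})

test_that("constructed medians certify thinness on random systems", {
  for (seed in 1:30) {
    x <- random_thin_system(sample(3:7, 1L), 3L, seed = seed + 30L,
                            max_taxa = 10L)
    tr <- build_caterpillar_median(x)
    expect_true(is_caterpillar(tr))
    expect_true(is_median_injective(tr, x))
  }
})

test_that("rooted caterpillar lca representations exist for thin pairs", {
  x <- set_system(list(c("a", "b"), c("b", "c")))
  tr <- build_rooted_caterpillar_lca(x)
  expect_true(is_binary_tree(tr))
  expect_true(is_lca_injective(tr, x))
  expect_error(build_rooted_caterpillar_lca(order_rigid_triangle()),
               "not thin")
  for (seed in 1:20) {
    x <- random_thin_system(sample(1:5, 1L), 2L, seed = seed, max_taxa = 6L)
    tr <- build_rooted_caterpillar_lca(x)
    expect_true(is_binary_tree(tr))
    expect_true(is_lca_injective(tr, x))
    # rooted caterpillar: exactly one cherry (two leaves sharing a parent)
    cherries <- Filter(function(C) length(C) == 2L, tree_clusters(tr))
    expect_length(cherries, 1L)
  }
})

test_that("lca representations lift to median representations", {
  # attach a fresh root leaf and take medians of the augmented blocks
  for (seed in 1:10) {
    x <- random_thin_system(sample(2:4, 1L), 2L, seed = seed + 50L,
                            max_taxa = 6L)
    tr <- build_rooted_caterpillar_lca(x)
    un <- unrooted_from_rooted(tr, "zroot")
    aug <- set_system(lapply(x$blocks, c, "zroot"))
    expect_true(is_median_injective(un, aug))
  }
})

test_that("pair systems: thin, forest and total-order criteria coincide", {
  expect_true(incidence_forest_check(order_flex_pair()))
  expect_false(incidence_forest_check(order_rigid_triangle()))
  expect_true(incidence_forest_check(set_system(list(c("a", "b")))))

  expect_true(as.logical(is_total_order_flexible(order_flex_pair())))
  v <- is_total_order_flexible(order_rigid_triangle(),
                               method = "exhaustive")
  expect_false(as.logical(v))
  ce <- attr(v, "counterexample")
  expect_length(ce, 3L)
  # the counterexample orientation really is cyclic
  ends <- do.call(rbind, strsplit(ce, "<", fixed = TRUE))
  expect_false(phyloflex:::orientation_acyclic(ends[, 1L], ends[, 2L],
                                               c("a", "b", "c")))
  expect_true(as.logical(is_total_order_flexible(
    set_system(list(c("a", "b"))))))

  for (seed in 1:25) {
    set.seed(seed)
    x <- random_set_system(5L, sample(2:7, 1L), 2L, seed = seed + 70L)
    a <- as.logical(is_thin(x))
    b <- incidence_forest_check(x)
    cc <- as.logical(is_total_order_flexible(x, method = "both"))
    expect_identical(a, b)
    expect_identical(b, cc)
  }
})
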