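test_that("set_system validates and canonicalises its input", {
  x <- set_system(list(c("b", "a", "c"), c("d", "a", "b")))
  expect_equal(x$blocks, list(c("a", "b", "c"), c("a", "b", "d")))
  expect_equal(x$taxa, c("a", "b", "c", "d"))
  expect_error(set_system(list(c("a", "b", "c"), c("c", "b", "a"))),
               "duplicate block")
  expect_warning(y <- set_system(list(c("a", "b", "c"), c("c", "b", "a")),
                                 dedupe = TRUE), "duplicate")
  expect_length(y$blocks, 1L)
  expect_error(set_system(list(c("a"))), "at least 2")
  expect_error(set_system(list(c("a,x", "b"))), "invalid taxon label")
  expect_error(set_system(list(c("a", "b")), taxa = c("a", "c")),
               "universe")
})

test_that("leaf_union matches the worked examples", {
  expect_equal(leaf_union(fig1_tau()), letters[1:6])
  expect_equal(leaf_union(list()), character())
  expect_equal(leaf_union(list(c("a", "b", "c"))), c("a", "b", "c"))
})

test_that("excess functions reproduce the printed values", {
  expect_identical(excess_uniform(fig1_tau_prime(), 3L), -1L)
  expect_identical(excess_uniform(list(c("a", "b", "c")), 3L), 0L)
  expect_identical(excess_uniform(fig1_tau(), 3L), 0L)
  expect_error(excess_uniform(list(c("a", "b", "c", "d")), 3L), "size")
  expect_error(excess_uniform(list(), 3L), "empty")

  expect_identical(excess_general(list(c("a", "b", "c", "d"))), 0L)
  expect_identical(
    excess_general(list(c("a", "b", "c", "d"), c("b", "c", "d", "e"))), -1L)
  expect_identical(excess_general(fig1_tau_prime()), -1L)
  expect_error(excess_general(list(c("a", "b"))), "size at least 3")
})

test_that("excess_general agrees with excess_uniform on size-3 subsets", {
  for (seed in 1:25) {
    x <- small_triple_system(seed)
    k <- length(x$blocks)
    for (m in seq_len(2^k - 1)) {
      idx <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
      expect_identical(excess_general(x$blocks[idx]),
                       excess_uniform(x$blocks[idx], 3L))
    }
  }
})

test_that("is_thin decides the worked examples with witnesses", {
  th <- is_thin(fig1_tau())
  expect_true(as.logical(th))
  expect_identical(attr(th, "report")$excess, 0L)

  th2 <- is_thin(fig1_tau_prime())
  expect_false(as.logical(th2))
  rep2 <- attr(th2, "report")
  expect_identical(rep2$excess, -1L)
  expect_identical(excess_uniform(rep2$subset, 3L), -1L)
  # the full five-block collection also attains the minimum
  expect_identical(excess_uniform(fig1_tau_prime(), 3L), -1L)

  expect_true(as.logical(is_thin(sec1_tau())))
  expect_error(is_thin(set_system(list(c("a", "b"), c("a", "b", "c")))),
               "uniform")
})

test_that("brute and poly thin/slim deciders agree on random systems", {
  for (seed in 1:40) {
    x <- medium_mixed_system(seed + 500L, max_blocks = 10L)
    expect_identical(as.logical(is_slim(x, method = "brute")),
                     as.logical(is_slim(x, method = "poly")))
  }
  for (seed in 1:40) {
    set.seed(seed)
    r <- sample(2:4, 1L)
    n <- sample((r + 2):10, 1L)
    k <- sample(2:min(8L, choose(n, r)), 1L)
    x <- random_set_system(n, k, r, seed = seed)
    expect_identical(as.logical(is_thin(x, method = "brute")),
                     as.logical(is_thin(x, method = "poly")))
  }
})

test_that("slim implies thin for uniform systems, equivalently at r = 3", {
  for (seed in 1:30) {
    set.seed(seed)
    r <- sample(3:4, 1L)
    n <- sample((r + 2):9, 1L)
    k <- sample(2:min(6L, choose(n, r)), 1L)
    x <- random_set_system(n, k, r, seed = seed)
    sl <- as.logical(is_slim(x))
    th <- as.logical(is_thin(x))
    if (sl) expect_true(th)
    if (r == 3L) expect_identical(sl, th)
  }
})

test_that("thinness and slimness are hereditary", {
  for (seed in 1:15) {
    x <- random_thin_system(sample(2:5, 1L), 3L, seed = seed)
    k <- length(x$blocks)
    for (m in seq_len(2^k - 1)) {
      idx <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
      expect_true(as.logical(is_thin(set_system(x$blocks[idx]))))
    }
  }
})

test_that("occurrence counts and the low-occurrence guarantee hold", {
  n <- occurrence_counts(fig1_tau())
  expect_identical(n[["b"]], 3L)
  expect_identical(n[["f"]], 1L)
  expect_identical(unname(n[c("a", "c", "d", "e")]), rep(2L, 4L))
  expect_identical(sum(n), sum(lengths(fig1_tau()$blocks)))
  expect_identical(unname(occurrence_counts(
    set_system(list(c("a", "b", "c"))))), rep(1L, 3L))
  expect_identical(occurrence_counts(fig1_tau_prime())[["f"]], 1L)

  # Lemma-type bounds on generated thin systems covering their universe
  for (seed in 1:20) {
    x <- random_thin_system(sample(2:6, 1L), 3L, seed = seed)
    expect_lte(min(occurrence_counts(x)), 2L)
    expect_lte(length(x$blocks), length(x$taxa) - 3L + 1L)
  }
})

test_that("SDR after deletion follows Hall's condition", {
  ok <- has_sdr_after_deletion(fig1_tau(), c("a", "b"))
  expect_true(as.logical(ok))
  reps <- attr(ok, "representatives")
  expect_length(reps, 4L)
  expect_false(anyDuplicated(reps) > 0L)
  for (i in seq_along(reps))
    expect_true(reps[i] %in% setdiff(fig1_tau()$blocks[[i]], c("a", "b")))

  expect_false(as.logical(has_sdr_after_deletion(fig1_tau_prime(),
                                                 c("a", "c"))))
  expect_true(as.logical(has_sdr_after_deletion(
    set_system(list(c("a", "b", "c"))), c("a", "b"))))
  expect_error(has_sdr_after_deletion(fig1_tau(), c("a")), "r - 1")

  # thin systems admit an SDR for every deletion set B
  for (seed in 1:10) {
    x <- random_thin_system(sample(2:5, 1L), 3L, seed = seed)
    for (B in utils::combn(x$taxa, 2L, simplify = FALSE))
      expect_true(as.logical(has_sdr_after_deletion(x, B)))
  }
})

test_that("the zero-excess family of a slim system is a patchwork", {
  expect_true(zero_excess_family_is_patchwork(fig3_tau()))
  expect_true(zero_excess_family_is_patchwork(
    set_system(list(c("a", "b", "c", "d")))))
  expect_error(zero_excess_family_is_patchwork(fig1_tau_prime()),
               "not slim")
})
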