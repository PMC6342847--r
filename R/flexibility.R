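#' @rdname is_flexible_triples
#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("flexible: %s", x$flexible))
  if (!is.na(x$total) && !is.na(x$compatible))
    cat(sprintf(" (%d of %d assignments compatible)", x$compatible, x$total))
  else if (!is.na(x$total))
    cat(sprintf(" (%d assignments)", x$total))
  cat("\n")
  if (!is.null(x$counterexample)) {
    cat("incompatible assignment:\n")
    if (is.character(x$counterexample))
      cat(" ", paste(x$counterexample, collapse = "  "), "\n")
    else for (t in x$counterexample) cat(" ", format(t), "\n")
  }
  invisible(x)
}

assignment_report <- function(flexible, total = NA_real_,
                              compatible = NA_real_, counterexample = NULL) {
  structure(list(flexible = flexible, total = total, compatible = compatible,
                 counterexample = counterexample),
            class = "assignment_report")
}

# Iterate the cross product of parsed-triple-matrix choices; returns
# list(total, compatible, counterexample_idx or NULL). Short-circuits on
# the first incompatible assignment unless count = TRUE.
sweep_assignments <- function(option_mats, labels, count) {
  k <- length(option_mats)
  sizes <- lengths(option_mats)
  total <- prod(sizes)
  idx <- rep(1L, k)
  compatible <- 0
  ce <- NULL
  repeat {
    tp <- do.call(cbind, Map(function(opts, i) opts[[i]], option_mats, idx))
    if (!is.null(build_node(labels, tp))) compatible <- compatible + 1
    else if (is.null(ce)) {
      ce <- idx
      if (!count) break
    }
    j <- 1L
    while (j <= k) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > k) break
  }
  list(total = total, compatible = compatible, counterexample = ce)
}

#' Decide phylogenetic flexibility of a size-3 system
#'
#' A system of 3-taxon blocks is phylogenetically flexible when every
#' assignment of one rooted triple per block yields a compatible triple
#' set. The `exhaustive` method enumerates all `3^m` assignments and tests
#' each with the Aho BUILD algorithm; the `thin` method uses the
#' equivalence of flexibility with thinness; `both` cross-validates.
#'
#' @param x a `set_system` with uniform block size 3.
#' @param method `"auto"`, `"exhaustive"`, `"thin"` or `"both"`. `auto`
#'   enumerates up to `max_exhaustive` blocks, then defers to the thin
#'   criterion.
#' @param count if `TRUE`, the exhaustive sweep counts every compatible
#'   assignment instead of stopping at the first incompatible one.
#' @param max_exhaustive refuse exhaustive enumeration above this many
#'   blocks.
#' @return an `assignment_report`: `flexible`, `total` and `compatible`
#'   assignment counts (`NA` under the criterion-only method unless
#'   flexible is decided exhaustively), and an incompatible assignment as
#'   `counterexample` (one triple token per block) when not flexible.
#' @examples
#' is_flexible_triples(fig1_tau(), count = TRUE)
#' @export
is_flexible_triples <- function(x, method = c("auto", "exhaustive", "thin",
                                              "both"),
                                count = FALSE, max_exhaustive = 12L) {
  stopifnot(inherits(x, "set_system"))
  r <- uniform_size(x)
  if (is.na(r) || r != 3L) stop("requires uniform block size 3")
  method <- match.arg(method)
  k <- length(x$blocks)
  if (method == "auto")
    method <- if (k <= max_exhaustive) "exhaustive" else "thin"
  if (method == "exhaustive" && k > max_exhaustive)
    stop("exhaustive enumeration refused above ", max_exhaustive,
         " blocks; use method = 'thin' or raise the ceiling")
  thin_report <- function() {
    th <- is_thin(x)
    ce <- if (!th) counterexample_from_witness(x, attr(th, "report"),
                                               max_exhaustive)
    assignment_report(as.logical(th), counterexample = ce)
  }
  if (method == "thin") return(thin_report())
  opts <- lapply(x$blocks, function(b) {
    m <- parse_triples(block_triples(b))
    lapply(seq_len(3L), function(j) m[, j, drop = FALSE])
  })
  sw <- sweep_assignments(opts, x$taxa, count)
  tokens <- function(idx) vapply(seq_along(idx), function(i)
    colnames(opts[[i]][[idx[i]]]), "")
  rep_ex <- assignment_report(is.null(sw$counterexample),
                              total = sw$total,
                              compatible = if (count) sw$compatible else
                                if (is.null(sw$counterexample)) sw$total else
                                  NA_real_,
                              counterexample =
                                if (!is.null(sw$counterexample))
                                  tokens(sw$counterexample))
  if (method == "both") {
    th <- is_thin(x)
    if (as.logical(th) != rep_ex$flexible)
      stop("exhaustive (", rep_ex$flexible, ") and thin (", as.logical(th),
           ") verdicts disagree")
  }
  rep_ex
}

# For a non-thin/non-slim witness subset, search an incompatible triple
# assignment over the witness blocks (if small enough) and pad the other
# blocks with their first triple: a superset of an incompatible set stays
# incompatible.
counterexample_from_witness <- function(x, report, max_exhaustive) {
  if (length(report$subset) > max_exhaustive) return(NULL)
  sub <- subset_system(x, report$indices)
  sw <- is_flexible_triples(sub, method = "exhaustive",
                            max_exhaustive = max_exhaustive)
  if (is.null(sw$counterexample)) return(NULL)
  ce <- character(length(x$blocks))
  ce[report$indices] <- sw$counterexample
  rest <- setdiff(seq_along(x$blocks), report$indices)
  ce[rest] <- vapply(x$blocks[rest], function(b) block_triples(b)[1L], "")
  ce
}

#' Decide phylogenetic flexibility of a general system
#'
#' For blocks of size at least 3: the system is phylogenetically flexible
#' when every assignment of one rooted binary tree shape per block yields a
#' compatible tree collection. The `exhaustive` method enumerates all
#' `(2|s|-3)!!` shapes per block, reduces each collection to the union of
#' its induced triples and tests Aho compatibility; the `slim` method uses
#' the equivalence of flexibility with slimness; `both` cross-validates.
#'
#' @param x a `set_system` with all block sizes >= 3.
#' @param method `"auto"`, `"exhaustive"`, `"slim"` or `"both"`.
#' @param count count all compatible assignments (no short-circuit).
#' @param max_product refuse exhaustive sweeps whose shape-count product
#'   exceeds this bound.
#' @return an `assignment_report`; a counterexample is a list of
#'   `rooted_tree` objects, one per block in canonical order.
#' @export
is_flexible_general <- function(x, method = c("auto", "exhaustive", "slim",
                                              "both"),
                                count = FALSE, max_product = 1e6) {
  stopifnot(inherits(x, "set_system"))
  if (any(block_sizes(x) < 3L)) stop("requires block sizes >= 3")
  method <- match.arg(method)
  shape_counts <- vapply(block_sizes(x), function(s)
    prod(seq(2 * s - 3, 1, by = -2)), 0)
  if (method == "auto")
    method <- if (prod(shape_counts) <= max_product) "exhaustive" else "slim"
  if (method == "slim") {
    sl <- is_slim(x)
    return(assignment_report(as.logical(sl)))
  }
  if (prod(shape_counts) > max_product)
    stop("exhaustive sweep too large: ", prod(shape_counts),
         " assignments exceed the bound of ", max_product)
  shapes <- lapply(x$blocks, enumerate_rooted_binary_trees)
  opts <- lapply(shapes, function(trees)
    lapply(trees, function(t) parse_triples(induced_triples(t))))
  sw <- sweep_assignments(opts, x$taxa, count)
  rep_ex <- assignment_report(is.null(sw$counterexample),
                              total = sw$total,
                              compatible = if (count) sw$compatible else
                                if (is.null(sw$counterexample)) sw$total else
                                  NA_real_,
                              counterexample =
                                if (!is.null(sw$counterexample))
                                  Map(function(tr, i) tr[[i]], shapes,
                                      sw$counterexample))
  if (method == "both") {
    sl <- is_slim(x)
    if (as.logical(sl) != rep_ex$flexible)
      stop("exhaustive (", rep_ex$flexible, ") and slim (", as.logical(sl),
           ") verdicts disagree")
  }
  rep_ex
}

#' Verify that flexibility is hereditary
#'
#' Exhaustively confirms that every non-empty sub-collection of a flexible
#' size-3 system is itself flexible. Always `TRUE` for flexible input;
#' this is a verification utility at enumeration scale.
#'
#' @param x a flexible `set_system` of 3-taxon blocks.
#' @param max_exhaustive per-subset enumeration ceiling.
#' @return logical.
#' @export
flexibility_is_hereditary_check <- function(x, max_exhaustive = 12L) {
  stopifnot(inherits(x, "set_system"))
  k <- length(x$blocks)
  if (k > max_exhaustive) stop("sub-collection sweep refused above ",
                               max_exhaustive, " blocks")
  if (!is_flexible_triples(x, method = "exhaustive")$flexible)
    stop("input system is not flexible")
  for (m in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
    if (!is_flexible_triples(subset_system(x, idx),
                             method = "exhaustive")$flexible)
      return(FALSE)
  }
  TRUE
}

#' Check the size bound for flexible systems
#'
#' A flexible size-3 system covering its universe has at most `|X| - 2`
#' blocks. Returns the truth of the bound; vacuously `TRUE` when the
#' system is not flexible (not thin).
#'
#' @param x a `set_system` of 3-taxon blocks with `L(tau)` equal to the
#'   universe.
#' @return logical.
#' @export
flexible_size_bound_check <- function(x) {
  stopifnot(inherits(x, "set_system"))
  if (uniform_size(x) != 3L) stop("requires uniform block size 3")
  if (!setequal(leaf_union(x), x$taxa))
    stop("requires L(tau) equal to the universe")
  if (!is_thin(x)) return(TRUE)
  length(x$blocks) <= length(x$taxa) - 2L
}

#' Check the display-multiplicity floor for the two-anchor family
#'
#' For the family `{{1,2,j}: 2 < j <= n}` (a thin system of maximal size
#' `n - 2`), verifies by exhaustive enumeration that every assignment of
#' one rooted triple per block is displayed by at least two rooted binary
#' trees on the `n` taxa. Holds for `n >= 6`; fails for the singleton
#' family at `n = 3`, whose single triple has a unique 3-leaf display.
#'
#' @param x a `set_system` equal to the two-anchor family on its universe
#'   (e.g. from [prop1_family()]), with `3 <= n <= 7`.
#' @return logical: `TRUE` when every assignment has at least two
#'   displaying trees.
#' @export
multiplicity_floor_check <- function(x) {
  stopifnot(inherits(x, "set_system"))
  n <- length(x$taxa)
  if (n < 3L || n > 7L) stop("supported for 3 <= n <= 7 (oracle capacity)")
  if (uniform_size(x) != 3L) stop("requires uniform block size 3")
  trees <- enumerate_rooted_binary_trees(x$taxa)
  D <- displayed_token_matrix(trees)
  opts <- lapply(x$blocks, block_triples)
  sizes <- lengths(opts)
  idx <- rep(1L, length(opts))
  repeat {
    tokens <- vapply(seq_along(idx), function(i) opts[[i]][idx[i]], "")
    cnt <- sum(rowSums(D[, tokens, drop = FALSE]) == length(tokens))
    if (cnt < 2L) return(FALSE)
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > length(idx)) break
  }
  TRUE
}
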