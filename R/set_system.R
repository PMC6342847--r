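#' Construct a taxon set system
#'
#' A set system is a collection of distinct subsets ("blocks") of a taxon
#' universe. It is the object whose thin/slim/flexible status the package
#' decides. Blocks are stored sorted, in a canonical order (lexicographic by
#' their comma-joined sorted members), so that witnesses and constructions
#' are deterministic.
#'
#' @param blocks a list of character vectors, each a block of at least two
#'   distinct taxon labels. Labels may not contain commas, pipes,
#'   parentheses, semicolons or whitespace.
#' @param taxa optional universe; defaults to the union of the blocks. Must
#'   contain that union.
#' @param dedupe if `TRUE`, duplicate blocks are dropped with a warning
#'   instead of raising an error.
#' @return an object of class `set_system` with elements `blocks` (list of
#'   sorted character vectors, canonical order) and `taxa` (sorted universe).
#' @examples
#' set_system(list(c("a", "b", "c"), c("a", "b", "d")))
#' @export
set_system <- function(blocks, taxa = NULL, dedupe = FALSE) {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("'blocks' must be a non-empty list of character vectors")
  blocks <- lapply(blocks, function(b) {
    b <- as.character(b)
    check_labels(b)
    if (anyDuplicated(b)) stop("block has repeated taxon: ",
                               paste(b, collapse = ","))
    if (length(b) < 2L) stop("blocks must have at least 2 taxa")
    sort(b)
  })
  keys <- vapply(blocks, paste, "", collapse = ",")
  if (anyDuplicated(keys)) {
    if (dedupe) {
      warning("duplicate blocks dropped")
      blocks <- blocks[!duplicated(keys)]
      keys <- keys[!duplicated(keys)]
    } else stop("duplicate block: ", keys[duplicated(keys)][1L])
  }
  blocks <- blocks[order(keys, method = "radix")]
  lu <- leaf_union(blocks)
  if (is.null(taxa)) taxa <- lu else {
    taxa <- sort(as.character(taxa))
    check_labels(taxa)
    if (!all(lu %in% taxa)) stop("universe must contain every block member")
  }
  structure(list(blocks = blocks, taxa = taxa), class = "set_system")
}

check_labels <- function(x) {
  bad <- !nzchar(x) | grepl("[,|();[:space:]]", x)
  if (any(bad)) stop("invalid taxon label: '", x[bad][1L], "'")
  invisible(x)
}

#' @export
print.set_system <- function(x, ...) {
  r <- uniform_size(x)
  cat(sprintf("set system: %d blocks on %d taxa%s\n", length(x$blocks),
              length(x$taxa),
              if (!is.na(r)) sprintf(" (uniform size %d)", r) else ""))
  for (b in x$blocks) cat(" {", paste(b, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
format.set_system <- function(x, ...)
  vapply(x$blocks, paste, "", collapse = ",")

block_sizes <- function(x) vapply(x$blocks, length, 0L)

#' Uniform block size of a set system
#'
#' @param x a `set_system`.
#' @return the common block size `r`, or `NA` if blocks have mixed sizes.
#' @export
uniform_size <- function(x) {
  s <- unique(block_sizes(x))
  if (length(s) == 1L) s else NA_integer_
}

#' Union of the taxa appearing in a collection of blocks
#'
#' @param blocks a list of character vectors (possibly empty), or a
#'   `set_system` (whose blocks are then used).
#' @return sorted character vector of all labels occurring in some block.
#' @export
leaf_union <- function(blocks) {
  if (inherits(blocks, "set_system")) blocks <- blocks$blocks
  sort(unique(as.character(unlist(blocks))))
}

#' Excess of an r-uniform block collection
#'
#' For blocks all of size `r`, the excess is
#' `|L| - m - (r - 1)` where `L` is the leaf union and `m` the number of
#' blocks. A system is *thin* when every non-empty sub-collection has
#' non-negative excess.
#'
#' @param blocks non-empty list of blocks (or a `set_system`), all of size
#'   `r`.
#' @param r the uniform block size (>= 2).
#' @return integer excess.
#' @export
excess_uniform <- function(blocks, r) {
  if (inherits(blocks, "set_system")) blocks <- blocks$blocks
  if (length(blocks) == 0L) stop("excess is undefined for the empty subset")
  r <- as.integer(r)
  if (r < 2L) stop("'r' must be at least 2")
  if (!all(lengths(blocks) == r)) stop("all blocks must have size exactly ", r)
  length(leaf_union(blocks)) - length(blocks) - (r - 1L)
}

#' Excess of a mixed-size block collection
#'
#' For blocks all of size at least 3 the general excess is
#' `|L| - 2 - sum(|s| - 2)`. On uniform size-3 input it agrees with
#' [excess_uniform()] at `r = 3`. A system is *slim* when every non-empty
#' sub-collection has non-negative general excess.
#'
#' @param blocks non-empty list of blocks (or a `set_system`), sizes >= 3.
#' @return integer excess.
#' @export
excess_general <- function(blocks) {
  if (inherits(blocks, "set_system")) blocks <- blocks$blocks
  if (length(blocks) == 0L) stop("excess is undefined for the empty subset")
  if (any(lengths(blocks) < 3L)) stop("all blocks must have size at least 3")
  length(leaf_union(blocks)) - 2L - sum(lengths(blocks) - 2L)
}

excess_report <- function(system, indices, mode) {
  sub <- system$blocks[indices]
  exc <- if (mode == "uniform")
    excess_uniform(sub, uniform_size(system)) else excess_general(sub)
  structure(list(subset = sub, indices = as.integer(indices),
                 excess = exc, mode = mode),
            class = "excess_report")
}

#' @export
print.excess_report <- function(x, ...) {
  cat(sprintf("excess report (%s mode): excess %d on %d block(s)\n",
              x$mode, x$excess, length(x$subset)))
  for (b in x$subset) cat(" {", paste(b, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# Minimise cov(S) - sum(w[S]) over non-empty subsets S of the blocks by
# chunked bitmask enumeration. Ties broken by smallest subset size, then
# lexicographically smallest sorted index vector. Returns list(value, indices).
min_surplus_brute <- function(blocks, w, max_blocks = 20L) {
  k <- length(blocks)
  if (k == 0L) stop("empty system")
  if (k > max_blocks)
    stop("brute-force enumeration refused above ", max_blocks,
         " blocks; use the poly/mincut method or raise the ceiling")
  taxa <- leaf_union(blocks)
  M <- t(vapply(blocks, function(b) taxa %in% b, logical(length(taxa))))
  storage.mode(M) <- "integer"            # k x n incidence
  pow <- 2^(seq_len(k) - 1L)
  total <- 2^k - 1
  best_val <- Inf
  best_masks <- integer()
  chunk <- 65536L
  for (lo in seq(1, total, by = chunk)) {
    masks <- lo:min(total, lo + chunk - 1L)
    S <- outer(masks, pow, function(m, p) bitwAnd(m, p) > 0L)
    storage.mode(S) <- "integer"
    cov <- rowSums((S %*% M) > 0L)
    val <- cov - as.vector(S %*% w)
    mn <- min(val)
    if (mn < best_val) { best_val <- mn; best_masks <- masks[val == mn] }
    else if (mn == best_val) best_masks <- c(best_masks, masks[val == mn])
  }
  idx_of <- function(m) which(bitwAnd(m, pow) > 0L)
  sizes <- vapply(best_masks, function(m) sum(bitwAnd(m, pow) > 0L), 0)
  cand <- best_masks[sizes == min(sizes)]
  if (length(cand) > 1L) {
    key <- vapply(cand, function(m)
      paste(sprintf("%04d", idx_of(m)), collapse = ""), "")
    cand <- cand[order(key, method = "radix")][1L]
  }
  list(value = as.integer(best_val), indices = idx_of(cand[1L]))
}

#' Decide whether a uniform set system is thin
#'
#' A system of blocks all of size `r` is thin when every non-empty
#' sub-collection has non-negative excess ([excess_uniform()]). The `brute`
#' method enumerates all sub-collections; the `poly` method minimises the
#' submodular surplus function via [sigma_star()] min-cuts (thin iff
#' `sigma* >= r - 1`). `auto` uses brute force up to 15 blocks.
#'
#' @param x a `set_system` with uniform block size.
#' @param method `"auto"`, `"brute"` or `"poly"`.
#' @param max_brute refuse brute-force enumeration above this many blocks.
#' @return logical verdict, with an `excess_report` witness for a
#'   minimum-excess sub-collection in attribute `"report"`.
#' @examples
#' tau <- fig1_tau()
#' is_thin(tau)
#' @export
is_thin <- function(x, method = c("auto", "brute", "poly"), max_brute = 20L) {
  stopifnot(inherits(x, "set_system"))
  method <- match.arg(method)
  r <- uniform_size(x)
  if (is.na(r)) stop("is_thin requires uniform block sizes")
  k <- length(x$blocks)
  if (method == "auto") method <- if (k > 15L) "poly" else "brute"
  res <- if (method == "brute")
    min_surplus_brute(x$blocks, rep.int(1L, k), max_brute)
  else sigma_star(x, method = "mincut")
  rep <- excess_report(x, res$indices, "uniform")
  structure(rep$excess >= 0L, report = rep)
}

#' Decide whether a set system is slim
#'
#' A system of blocks all of size at least 3 is slim when every non-empty
#' sub-collection has non-negative general excess ([excess_general()]).
#' Slim implies thin for uniform systems, with equivalence at `r = 3`.
#' The `poly` method tests `gamma* >= 2` via [gamma_star()] min-cuts.
#'
#' @inheritParams is_thin
#' @return logical verdict with an `excess_report` witness in attribute
#'   `"report"`.
#' @export
is_slim <- function(x, method = c("auto", "brute", "poly"), max_brute = 20L) {
  stopifnot(inherits(x, "set_system"))
  method <- match.arg(method)
  if (any(block_sizes(x) < 3L)) stop("is_slim requires blocks of size >= 3")
  k <- length(x$blocks)
  if (method == "auto") method <- if (k > 15L) "poly" else "brute"
  res <- if (method == "brute")
    min_surplus_brute(x$blocks, block_sizes(x) - 2L, max_brute)
  else gamma_star(x, method = "mincut")
  rep <- excess_report(x, res$indices, "general")
  structure(rep$excess >= 0L, report = rep)
}

#' Per-taxon occurrence counts
#'
#' Counts, for each taxon of the universe, the number of blocks containing
#' it. For a thin uniform system covering its universe, some taxon occurs
#' at most `r - 1` times.
#'
#' @param x a `set_system`.
#' @return named integer vector over the universe.
#' @export
occurrence_counts <- function(x) {
  stopifnot(inherits(x, "set_system"))
  n <- setNames(integer(length(x$taxa)), x$taxa)
  tab <- table(unlist(x$blocks))
  n[names(tab)] <- as.integer(tab)
  n
}

#' System of distinct representatives after deleting a taxon set
#'
#' Given a uniform system of size-`r` blocks and a set `B` of `r - 1` taxa,
#' decides whether the residual sets `S - B` admit a system of distinct
#' representatives (an injective choice of one member per block), via
#' maximum bipartite matching. Hall's condition guarantees existence
#' whenever the system is thin.
#'
#' @param x a `set_system` with uniform block size `r`.
#' @param B character vector of `r - 1` taxa to delete.
#' @return logical; when `TRUE`, attribute `"representatives"` holds a
#'   character vector of chosen taxa, one per block (in canonical block
#'   order).
#' @export
has_sdr_after_deletion <- function(x, B) {
  stopifnot(inherits(x, "set_system"))
  r <- uniform_size(x)
  if (is.na(r)) stop("has_sdr_after_deletion requires uniform block sizes")
  B <- as.character(B)
  if (length(unique(B)) != r - 1L)
    stop("'B' must contain exactly r - 1 = ", r - 1L, " distinct taxa")
  resid <- lapply(x$blocks, setdiff, B)
  if (any(lengths(resid) == 0L)) return(structure(FALSE, representatives = NULL))
  m <- length(resid)
  taxa <- sort(unique(unlist(resid)))
  bnames <- paste0("block#", seq_len(m))
  edges <- do.call(rbind, lapply(seq_len(m), function(i)
    cbind(bnames[i], resid[[i]])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% taxa
  mm <- igraph::max_bipartite_match(g)
  if (mm$matching_size < m) return(structure(FALSE, representatives = NULL))
  reps <- unname(mm$matching[bnames])
  structure(TRUE, representatives = reps)
}

# All non-empty subset masks of a slim system with zero general excess,
# as integer bitmasks over canonical block order.
zero_excess_masks <- function(x) {
  k <- length(x$blocks)
  if (k > 20L) stop("zero-excess enumeration refused above 20 blocks")
  taxa <- leaf_union(x$blocks)
  M <- t(vapply(x$blocks, function(b) taxa %in% b, logical(length(taxa))))
  storage.mode(M) <- "integer"
  w <- lengths(x$blocks) - 2L
  pow <- 2^(seq_len(k) - 1L)
  masks <- seq_len(2^k - 1)
  S <- outer(masks, pow, function(m, p) bitwAnd(m, p) > 0L)
  storage.mode(S) <- "integer"
  exc <- rowSums((S %*% M) > 0L) - 2L - as.vector(S %*% w)
  masks[exc == 0L]
}

#' Check the patchwork property of the zero-excess family
#'
#' For a slim system, the family of non-empty sub-collections with zero
#' general excess is closed under union and intersection of every
#' intersecting pair (a *patchwork*); this follows from the submodularity
#' of the surplus functions. This check enumerates the family and verifies
#' the closure directly.
#'
#' @param x a slim `set_system` (blocks of size >= 3).
#' @return `TRUE` if the closure holds (it must, for slim input).
#' @export
zero_excess_family_is_patchwork <- function(x) {
  stopifnot(inherits(x, "set_system"))
  sl <- is_slim(x)
  if (!sl) stop("system is not slim; witness excess ",
                attr(sl, "report")$excess)
  fam <- zero_excess_masks(x)
  if (length(fam) <= 1L) return(TRUE)
  for (i in seq_along(fam)) for (j in seq_len(i - 1L)) {
    a <- fam[i]; b <- fam[j]
    if (bitwAnd(a, b) == 0L) next
    if (!(bitwAnd(a, b) %in% fam) || !(bitwOr(a, b) %in% fam)) return(FALSE)
  }
  TRUE
}

# Subset of a set system by block indices (non-empty), as a set_system.
subset_system <- function(x, indices, taxa = NULL)
  set_system(x$blocks[indices], taxa = taxa)
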