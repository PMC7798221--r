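#' Histogram profile of a PMI / ZPMI relation matrix
#'
#' Bins the defined off-diagonal PMI (or ZPMI) values — each unordered
#' feature pair counted once — into contiguous half-open bins
#' `[lo, lo + bin_width)`.  This is the "interrelation profile" view of a
#' compound set; export it with [write_profile_csv()] to plot with any tool.
#'
#' @param m a `relmat` of variant `"pmirm"` or `"zpmirm"`.
#' @param bin_width bin width in PMI units (default 0.1).
#' @return an object of class `"pmi_profile"`: a list with `histogram`
#'   (data.frame of `lower`, `count`), `bin_width`, `n_defined`, `bits_set`,
#'   `variant` and `matrix_ref`.
#' @examples
#' x <- fpset(rbind(c(1,1,0), c(1,1,0), c(1,0,1), c(0,0,1)),
#'            fingerprint_spec("custom", length = 3))
#' pmi_profile(as_pmirm(corm(x)), bin_width = 0.5)$histogram
#' @export
pmi_profile <- function(m, bin_width = 0.1) {
  stopifnot(inherits(m, "relmat"))
  if (!m$variant %in% c("pmirm", "zpmirm"))
    stop("profiles are built from pmirm or zpmirm matrices")
  stopifnot(bin_width > 0)
  v <- defined_offdiag(m)
  if (length(v) == 0L) stop("no defined feature pairs to profile")
  idx <- floor(v / bin_width)
  tab <- table(idx)
  lowers <- as.numeric(names(tab)) * bin_width
  hist <- data.frame(lower = lowers, count = as.integer(tab))
  hist <- hist[order(hist$lower), , drop = FALSE]
  rownames(hist) <- NULL
  structure(list(histogram = hist, bin_width = bin_width,
                 n_defined = length(v),
                 bits_set = sum(!is.na(diag(m$values))),
                 variant = m$variant,
                 matrix_ref = m$provenance$label),
            class = "pmi_profile")
}

#' @export
print.pmi_profile <- function(x, ...) {
  cat(sprintf("<%s profile '%s': %d defined pairs, %d occupied bins (width %g)>\n",
              toupper(sub("rm$", "", x$variant)), x$matrix_ref, x$n_defined,
              nrow(x$histogram), x$bin_width))
  invisible(x)
}

#' @export
plot.pmi_profile <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$lower + x$bin_width / 2, h$count, type = "h",
                 xlab = if (x$variant == "zpmirm") "ZPMI" else "PMI",
                 ylab = "feature pairs",
                 main = sprintf("Interrelation profile (%s)", x$matrix_ref),
                 ...)
  invisible(x)
}

#' Export a profile histogram as CSV
#'
#' @param x a [pmi_profile()].
#' @param path output CSV path (columns `lower`, `count`).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "pmi_profile"))
  utils::write.csv(x$histogram, path, row.names = FALSE)
  invisible(path)
}

#' Nested random subsets of a compound set
#'
#' Draws a family of overlapping random subsets of increasing size, each
#' larger subset containing the smaller ones — the construction used to study
#' how an interrelation profile depends on compound-set size (the default
#' ladder in database work being a x4 geometric series 8000 ... 2,048,000).
#'
#' @param x an [fpset()].
#' @param sizes ascending subset sizes; the largest must not exceed the
#'   population.
#' @param seed integer seed; the same seed reproduces the same family.
#' @return a named list of [fpset()] objects, one per size.
#' @export
subsample_sets <- function(x, sizes, seed) {
  stopifnot(inherits(x, "fpset"))
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly ascending")
  n <- nrow(x$bits)
  if (max(sizes) > n)
    stop(sprintf("largest size %d exceeds population %d", max(sizes), n))
  perm <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    sample.int(n)
  })
  out <- lapply(sizes, function(s) x[perm[seq_len(s)]])
  names(out) <- paste0("n", sizes)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mine feature pairs exclusive to one interrelation profile
#'
#' Finds the feature pairs whose PMI falls inside a closed range
#' `[lo, hi]` in the target matrix while being absent from that range in
#' every other matrix — the construction behind range-restricted exclusive
#' interrelation mining between chemical databases.
#'
#' Two readings of "not present elsewhere" are offered: `"range"` (default)
#' treats a pair as non-exclusive if any other matrix has a *defined in-range*
#' PMI for it; `"absent"` requires the pair to be entirely undefined (never
#' co-occurring) in every other matrix.
#'
#' @param target a `relmat` of variant `"pmirm"` or `"zpmirm"`.
#' @param others list of matrices of the same variant and spec (may be empty,
#'   in which case every in-range pair is exclusive).
#' @param lo,hi closed PMI interval bounds.
#' @param mode `"range"` or `"absent"` (see above).
#' @return a list with `pairs` (two-column matrix of 0-based feature indices
#'   `i < j` of the exclusive pairs), `n_in_range` (all in-range target
#'   pairs) and `n_exclusive`.
#' @export
exclusive_pairs <- function(target, others = list(), lo, hi,
                            mode = c("range", "absent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "relmat"), lo <= hi)
  if (!target$variant %in% c("pmirm", "zpmirm"))
    stop("exclusive_pairs operates on pmirm or zpmirm matrices")
  for (o in others) {
    stopifnot(inherits(o, "relmat"))
    stopifnot_spec_match(target$spec, o$spec, "target and other matrices")
  }
  ut <- upper.tri(target$values)
  in_range <- ut & target$defined &
    !is.na(target$values) & target$values >= lo & target$values <= hi
  excl <- in_range
  for (o in others) {
    blocked <- if (mode == "range")
      o$defined & !is.na(o$values) & o$values >= lo & o$values <= hi
    else
      o$defined
    excl <- excl & !blocked
  }
  idx <- which(excl, arr.ind = TRUE)
  pairs <- cbind(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  list(pairs = pairs, n_in_range = sum(in_range), n_exclusive = sum(excl))
}
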