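#' Relative feature tightness (RFT) and its Z-standardized form (ZRFT)
#'
#' RFT measures how tightly a query compound set \eqn{S} matches the feature
#' interrelation profile of a reference set \eqn{S'}:
#' \deqn{RFT = \mu(COPRM(S) \times PMIRM(S'))}
#' where \eqn{\times} is the element-wise (Hadamard) product — the query's
#' pair co-occurrence probabilities weight the reference's pairwise PMI — and
#' \eqn{\mu} averages over all \eqn{D^2} cells.  ZRFT substitutes the
#' standardized reference (ZPMIRM); positive ZRFT means the query contains
#' predominantly feature pairs rated above average in the reference profile.
#' Neither measure is symmetric: `rft(A, B)` generally differs from
#' `rft(B, A)`.
#'
#' Three cases are supported by the same formula: a single-compound query, a
#' set-vs-set comparison, and the "inner tightness" of a set against itself.
#'
#' Cells undefined in the reference contribute `missing_value` (default 0) to
#' the sum.  With `mean_over = "all"` (default) the denominator is the fixed
#' \eqn{D^2}, making scores comparable across queries; `"defined"` divides by
#' the number of reference-defined cells instead.
#'
#' @param query an [fpset()] (or 0/1 matrix) of query compounds.
#' @param reference a `relmat` of variant `"pmirm"` (for `rft`) or
#'   `"zpmirm"` (for `zrft`) sharing the query's fingerprint spec.
#' @param mean_over `"all"` (divide by \eqn{D^2}) or `"defined"`.
#' @param missing_value value contributed by query pairs whose reference cell
#'   is undefined; default 0 (the least-assumption choice).
#' @return an object of class `"tightness_score"`: the numeric score with
#'   attributes recording the conventions used.
#' @examples
#' ref <- fpset(rbind(c(1,1,0), c(1,1,0), c(1,0,1), c(0,0,1)),
#'              fingerprint_spec("custom", length = 3))
#' z <- as_zpmirm(corm(ref))
#' zrft(fpset(c(1, 1, 0), ref$spec), z)
#' @export
rft <- function(query, reference, mean_over = c("all", "defined"),
                missing_value = 0) {
  tightness(query, reference, "pmirm", match.arg(mean_over), missing_value)
}

#' @rdname rft
#' @export
zrft <- function(query, reference, mean_over = c("all", "defined"),
                 missing_value = 0) {
  tightness(query, reference, "zpmirm", match.arg(mean_over), missing_value)
}

tightness <- function(query, reference, want_variant, mean_over, missing_value) {
  if (is.matrix(query))
    query <- fpset(query, fingerprint_spec("custom", length = ncol(query)))
  stopifnot(inherits(query, "fpset"), inherits(reference, "relmat"))
  if (reference$variant != want_variant)
    stop(sprintf("reference must be a %s (got %s); use as_%s()",
                 want_variant, reference$variant, want_variant))
  stopifnot_spec_match(query$spec, reference$spec, "query and reference")
  if (nrow(query$bits) == 0L) stop("empty query")
  d <- reference$spec$length
  q <- as_coprm(corm(query))$values
  r <- reference$values
  r[is.na(r)] <- missing_value
  total <- sum(q * r)
  denom <- if (mean_over == "all") d * d else sum(reference$defined)
  score <- total / denom
  structure(score, class = "tightness_score",
            standardized = want_variant == "zpmirm",
            query_size = nrow(query$bits),
            reference_label = reference$provenance$label,
            conventions = list(mean_over = mean_over,
                               missing_value = missing_value))
}

#' @export
print.tightness_score <- function(x, ...) {
  cat(sprintf("%s = %.6g  (query |S| = %d, reference '%s', mean over %s cells)\n",
              if (attr(x, "standardized")) "ZRFT" else "RFT",
              as.numeric(x), attr(x, "query_size"),
              attr(x, "reference_label"),
              attr(x, "conventions")$mean_over))
  invisible(x)
}

#' Per-compound ZRFT scores
#'
#' Scores every query compound as a singleton set against the reference
#' ZPMIRM — the formulation behind per-compound tightness distributions and
#' easy/hard-to-synthesize calls.  For a single 0/1 vector \eqn{k} the
#' singleton COPRM is its own outer product, so the score reduces to the
#' quadratic form \eqn{k^T Z k / D^2} (with undefined reference cells
#' replaced by `missing_value`), which is evaluated for all compounds in one
#' matrix product.  Because a set's COPRM is exactly the average of its
#' singleton outer products, the set-level ZRFT equals the mean of these
#' per-compound scores.
#'
#' @inheritParams rft
#' @param queries an [fpset()] of query compounds.
#' @return a data.frame with columns `compound_id` and `zrft` (or `rft` when
#'   the reference is a plain PMIRM), one row per query compound, in input
#'   order.
#' @export
zrft_per_compound <- function(queries, reference,
                              mean_over = c("all", "defined"),
                              missing_value = 0) {
  mean_over <- match.arg(mean_over)
  if (is.matrix(queries))
    queries <- fpset(queries, fingerprint_spec("custom", length = ncol(queries)))
  stopifnot(inherits(queries, "fpset"), inherits(reference, "relmat"))
  if (!reference$variant %in% c("pmirm", "zpmirm"))
    stop("reference must be a pmirm or zpmirm")
  stopifnot_spec_match(queries$spec, reference$spec, "query and reference")
  if (nrow(queries$bits) == 0L) stop("empty query")
  d <- reference$spec$length
  r <- reference$values
  r[is.na(r)] <- missing_value
  x <- queries$bits
  storage.mode(x) <- "double"
  denom <- if (mean_over == "all") d * d else sum(reference$defined)
  scores <- rowSums((x %*% r) * x) / denom
  col <- if (reference$variant == "zpmirm") "zrft" else "rft"
  out <- data.frame(compound_id = rownames(queries$bits), scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2L] <- col
  out
}
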