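#' Design of a synthetic binary feature-vector set
#'
#' Describes a population of compounds-as-bit-vectors with known pairwise
#' structure: every feature \eqn{i} is on with marginal probability
#' \eqn{p_i}; selected disjoint feature pairs \eqn{(i,j)} are *planted* with
#' a co-occurrence enrichment \eqn{e_{ij}}, i.e. joint on-probability
#' \eqn{e_{ij} p_i p_j} instead of the independent \eqn{p_i p_j}.  By
#' construction the population PMI of a planted pair is exactly
#' \eqn{\log_2 e_{ij}}, so the generator provides ground truth for every
#' estimator in the package.  Unplanted features are independent Bernoulli.
#'
#' Feasibility requires \eqn{e_{ij} p_i p_j \le \min(p_i, p_j)} and a
#' nonnegative both-off probability; planted pairs must not share features
#' (this keeps the joint distribution exactly specifiable).
#'
#' @param n_features number of feature bits D.
#' @param marginals per-feature on-probability in (0,1); recycled to D.
#' @param planted_pairs data.frame with columns `i`, `j` (0-based feature
#'   indices, `i != j`) and `e` (enrichment > 0); may be empty.
#' @param n_compounds number of vectors to draw.
#' @param seed integer seed.
#' @return an object of class `"synthetic_design"`.
#' @examples
#' d <- synthetic_design(8, 0.2, data.frame(i = 0, j = 1, e = 2),
#'                       n_compounds = 1000, seed = 1)
#' generate_vectors(d)
#' @export
synthetic_design <- function(n_features, marginals, planted_pairs = NULL,
                             n_compounds, seed) {
  n_features <- as.integer(n_features)
  p <- rep_len(as.numeric(marginals), n_features)
  if (any(p <= 0 | p >= 1)) stop("marginals must lie strictly in (0,1)")
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(i = integer(), j = integer(), e = numeric())
  stopifnot(all(c("i", "j", "e") %in% names(planted_pairs)))
  pp <- planted_pairs
  if (nrow(pp)) {
    if (any(pp$i == pp$j) || any(pp$i < 0) || any(pp$j >= n_features) ||
        any(pp$i >= n_features) || any(pp$j < 0))
      stop("planted pair indices must be distinct 0-based features")
    feats <- c(pp$i, pp$j)
    if (anyDuplicated(feats))
      stop("planted pairs must be disjoint in features")
    if (any(pp$e <= 0)) stop("enrichment must be positive")
    p11 <- pp$e * p[pp$i + 1L] * p[pp$j + 1L]
    if (any(p11 > pmin(p[pp$i + 1L], p[pp$j + 1L]) + 1e-12))
      stop("infeasible design: joint probability exceeds a marginal")
    if (any(1 - p[pp$i + 1L] - p[pp$j + 1L] + p11 < -1e-12))
      stop("infeasible design: negative both-off probability")
  }
  structure(list(n_features = n_features, marginals = p, planted_pairs = pp,
                 n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate synthetic feature vectors from a design
#'
#' @param design a [synthetic_design()].
#' @return an [fpset()] with a `custom` spec of the design's length;
#'   reproducible from the design's seed.
#' @rdname synthetic_design
#' @export
generate_vectors <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design$n_features; n <- design$n_compounds; p <- design$marginals
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  bits <- matrix(0L, n, d)
  planted_feats <- integer()
  pp <- design$planted_pairs
  if (nrow(pp)) {
    for (k in seq_len(nrow(pp))) {
      i <- pp$i[k] + 1L; j <- pp$j[k] + 1L
      p11 <- pp$e[k] * p[i] * p[j]
      probs <- c(p11, p[i] - p11, p[j] - p11, 1 - p[i] - p[j] + p11)
      probs <- pmax(probs, 0)
      cell <- sample.int(4L, n, replace = TRUE, prob = probs)
      bits[, i] <- as.integer(cell <= 2L)          # 11 or 10
      bits[, j] <- as.integer(cell == 1L | cell == 3L)  # 11 or 01
    }
    planted_feats <- c(pp$i, pp$j) + 1L
  }
  free <- setdiff(seq_len(d), planted_feats)
  if (length(free))
    bits[, free] <- matrix(
      as.integer(stats::runif(n * length(free)) < rep(p[free], each = n)),
      n, length(free))
  fpset(bits, fingerprint_spec("custom", length = d))
}

#' Destroy co-occurrence structure by column scrambling
#'
#' Independently permutes every feature column across compounds: marginal
#' feature counts are preserved exactly while all pairwise co-occurrence
#' structure is destroyed.  Used to build "incoherent" surrogate sets (e.g.
#' the hard-to-synthesize surrogate in the end-to-end classification
#' property).
#'
#' @param x an [fpset()].
#' @param seed integer seed.
#' @return an [fpset()] of the same dimensions and spec.
#' @export
scramble_columns <- function(x, seed) {
  stopifnot(inherits(x, "fpset"))
  if (nrow(x$bits) == 0L) stop("empty set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bits <- apply(x$bits, 2L, function(col) col[sample.int(length(col))])
  fpset(matrix(as.integer(bits), nrow(x$bits), ncol(x$bits)), x$spec,
        ids = rownames(x$bits))
}
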