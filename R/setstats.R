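#' Jaccard overlap between two compound sets
#'
#' Exact set arithmetic on deduplicated identifier sets (typically
#' InChIKeys): \eqn{J(A,B) = |A \cap B| / |A \cup B|}.
#'
#' @param keys_a,keys_b character vectors of unique identifiers.
#' @return a list with `size_a`, `size_b`, `intersection` and `jaccard`.
#' @examples
#' jaccard_overlap(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard_overlap <- function(keys_a, keys_b) {
  keys_a <- unique(keys_a); keys_b <- unique(keys_b)
  if (length(keys_a) == 0L && length(keys_b) == 0L)
    stop("both sets are empty; Jaccard undefined")
  n_ab <- length(intersect(keys_a, keys_b))
  list(size_a = length(keys_a), size_b = length(keys_b),
       intersection = n_ab,
       jaccard = jaccard_index(length(keys_a), length(keys_b), n_ab))
}

#' @rdname jaccard_overlap
#' @param size_a,size_b,intersection unique-compound counts, for computing
#'   the index from published set sizes without the key sets themselves.
#' @export
jaccard_index <- function(size_a, size_b, intersection) {
  stopifnot(intersection <= min(size_a, size_b))
  intersection / (size_a + size_b - intersection)
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' \eqn{T_C(a,b) = |a \wedge b| / |a \vee b|}; defined as 0 when both
#' vectors are all-zero.
#'
#' @param a,b 0/1 vectors of equal length, or two single-compound
#'   [fpset()]s with matching specs.
#' @return the Tanimoto coefficient in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "fpset")) { spec_a <- a$spec; a <- drop(a$bits) }
  else spec_a <- NULL
  if (inherits(b, "fpset")) {
    if (!is.null(spec_a)) stopifnot_spec_match(spec_a, b$spec, "fingerprints")
    b <- drop(b$bits)
  }
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Average pairwise Tanimoto similarity of a random sample
#'
#' Draws `sample_n` compounds uniformly without replacement, enumerates all
#' \eqn{n(n-1)/2} unordered pairs exhaustively, and averages their Tanimoto
#' coefficients — the standard protocol for a database-scale mean similarity
#' (5000 compounds give 12,497,500 pairs).  Implemented with one
#' `tcrossprod` over the sampled bit matrix, which is arithmetic-identical
#' to the pairwise loop.
#'
#' @param x an [fpset()].
#' @param sample_n number of compounds to sample (must not exceed the
#'   population; the whole population may be used by passing its size).
#' @param seed integer seed for the sample, recorded in the summary.
#' @return a list with `n_sampled`, `n_pairs`, `mean_tc`, `seed`, `spec`
#'   and `rng` (the sampler name, for repeatability).
#' @export
avg_pairwise_tanimoto <- function(x, sample_n, seed) {
  stopifnot(inherits(x, "fpset"))
  n <- nrow(x$bits)
  sample_n <- as.integer(sample_n)
  if (sample_n > n)
    stop(sprintf("sample_n %d exceeds population %d", sample_n, n))
  if (sample_n < 2L) stop("need at least 2 compounds for a pair")
  idx <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    sample.int(n, sample_n)
  })
  a <- x$bits[idx, , drop = FALSE]
  storage.mode(a) <- "double"
  inter <- tcrossprod(a)
  pop <- rowSums(a)
  uni <- outer(pop, pop, `+`) - inter
  tc <- ifelse(uni > 0, inter / uni, 0)
  ut <- upper.tri(tc)
  list(n_sampled = sample_n,
       n_pairs = sample_n * (sample_n - 1) / 2,
       mean_tc = mean(tc[ut]),
       seed = as.integer(seed),
       spec = x$spec,
       rng = RNGkind()[1L])
}
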