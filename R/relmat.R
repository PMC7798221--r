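#' Relation matrices: CORM, COPRM, PMIRM, ZPMIRM
#'
#' A relation matrix is a symmetric feature-by-feature table describing the
#' pairwise co-occurrence structure of a compound set \eqn{S} in one of four
#' variants:
#'
#' \describe{
#'   \item{corm}{co-occurrence counts: the sum of outer products
#'     \eqn{\sum_o k_o k_o^T} over all feature vectors \eqn{k_o}.  The
#'     diagonal holds single-feature occurrence counts.}
#'   \item{coprm}{co-occurrence probabilities: CORM divided by \eqn{|S|}.}
#'   \item{pmirm}{pointwise mutual information
#'     \eqn{PMI_{ij} = \log_2 p_{ij} / (p_{ii} p_{jj})} for every defined
#'     feature pair; the diagonal of observed features is 0 by convention.}
#'   \item{zpmirm}{PMIRM standardized to Z-scores using the mean and
#'     (population) standard deviation of its defined off-diagonal values.}
#' }
#'
#' Cells whose value does not exist — pairs that never co-occur, or involve a
#' never-observed feature — are *undefined*: `values` holds `NA` there and
#' `defined` is `FALSE`.  No smoothing is applied.
#'
#' @name relation_matrix
#' @aliases relmat
#' @seealso [corm()], [as_coprm()], [as_pmirm()], [as_zpmirm()],
#'   [save_relmat()], [rft()], [zrft()]
NULL

new_relmat <- function(values, variant, set_size, spec,
                       defined = NULL, stats = NULL,
                       provenance = list(label = "", toolkit = relmat_toolkit())) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(list(values = values, defined = defined, variant = variant,
                 set_size = as.numeric(set_size), spec = spec,
                 stats = stats, provenance = provenance),
            class = "relmat")
}

relmat_toolkit <- function() {
  sprintf("fip/%s R/%s", as.character(utils::packageVersion("fip")),
          paste(R.version$major, R.version$minor, sep = "."))
}

#' Accumulate a co-occurrence relation matrix (CORM)
#'
#' Sums the outer products of all feature vectors of a compound set.  For a
#' 0/1 matrix this is exactly `crossprod(bits)`: cell \eqn{(i,j)} counts the
#' compounds in which features \eqn{i} and \eqn{j} are both on, and the
#' diagonal counts single-feature occurrences.  Counts are stored as doubles,
#' which is exact up to \eqn{2^{53}} — far beyond database scale.
#'
#' @param x an [fpset()] or a plain 0/1 matrix (compounds in rows); a matrix
#'   is wrapped in a `custom` spec.
#' @param label free-text provenance label stored with the matrix.
#' @return a `relmat` of variant `"corm"`.
#' @examples
#' x <- fpset(rbind(c(1,1,0), c(1,1,0), c(1,0,1), c(0,0,1)),
#'            fingerprint_spec("custom", length = 3))
#' corm(x)$values
#' @export
corm <- function(x, label = "") {
  if (is.matrix(x)) x <- fpset(x, fingerprint_spec("custom", length = ncol(x)))
  stopifnot(inherits(x, "fpset"))
  if (nrow(x$bits) == 0L) stop("cannot accumulate a CORM from an empty set")
  values <- crossprod(x$bits)
  dimnames(values) <- NULL
  new_relmat(values, "corm", nrow(x$bits), x$spec,
             provenance = list(label = label, toolkit = relmat_toolkit()))
}

#' Merge two CORMs accumulated over disjoint compound streams
#'
#' Element-wise sum of counts; set sizes add.  Merging the CORMs of two
#' disjoint sets equals accumulating one CORM over their concatenation.
#'
#' @param a,b `relmat` objects of variant `"corm"` with identical specs and
#'   toolkit versions.
#' @return the merged `relmat` of variant `"corm"`.
#' @export
corm_merge <- function(a, b) {
  stopifnot(inherits(a, "relmat"), inherits(b, "relmat"))
  if (a$variant != "corm" || b$variant != "corm")
    stop("corm_merge operates on corm-variant matrices only")
  stopifnot_spec_match(a$spec, b$spec, "relation matrices")
  if (!identical(a$provenance$toolkit, b$provenance$toolkit))
    stop("refusing to merge matrices from different toolkit versions: ",
         a$provenance$toolkit, " vs ", b$provenance$toolkit)
  new_relmat(a$values + b$values, "corm", a$set_size + b$set_size, a$spec,
             provenance = list(
               label = paste0("merge(", a$provenance$label, ",",
                              b$provenance$label, ")"),
               toolkit = a$provenance$toolkit))
}

#' @export
`+.relmat` <- function(e1, e2) corm_merge(e1, e2)

#' Convert counts to co-occurrence probabilities (COPRM)
#'
#' Divides every CORM cell by the compound-set size.  The diagonal then holds
#' the probabilities with which individual features are observed; off-diagonal
#' cells hold feature-pair co-occurrence probabilities.
#'
#' @param x a `relmat` of variant `"corm"`.
#' @return a `relmat` of variant `"coprm"`.
#' @export
as_coprm <- function(x) {
  stopifnot(inherits(x, "relmat"))
  if (x$variant != "corm") stop("as_coprm expects a corm")
  if (x$set_size < 1) stop("set_size must be >= 1")
  new_relmat(x$values / x$set_size, "coprm", x$set_size, x$spec,
             provenance = x$provenance)
}

#' Convert probabilities to pointwise mutual information (PMIRM)
#'
#' For every feature pair with nonzero co-occurrence probability,
#' \eqn{PMI_{ij} = \log_2 p_{ij} / (p_{ii} p_{jj})}.  A cell is undefined
#' (`NA`, `defined = FALSE`) iff \eqn{p_{ij} = 0}; this covers both pairs of
#' features that never co-occur and pairs involving a never-observed feature.
#' The diagonal of observed features is 0 by convention (not
#' \eqn{-\log_2 p_{ii}}); the diagonal of never-observed features is
#' undefined.
#'
#' @param x a `relmat` of variant `"coprm"` (a `"corm"` is converted first).
#' @return a `relmat` of variant `"pmirm"` with a `defined` mask.
#' @export
as_pmirm <- function(x) {
  stopifnot(inherits(x, "relmat"))
  if (x$variant == "corm") x <- as_coprm(x)
  if (x$variant != "coprm") stop("as_pmirm expects a coprm (or corm)")
  p <- x$values
  d <- diag(p)
  defined <- p > 0
  values <- matrix(NA_real_, nrow(p), ncol(p))
  values[defined] <- log2(p[defined] / (tcrossprod(d)[defined]))
  diag(values) <- ifelse(d > 0, 0, NA_real_)
  new_relmat(values, "pmirm", x$set_size, x$spec, defined = defined,
             provenance = x$provenance)
}

# defined off-diagonal values, each unordered pair counted once
defined_offdiag <- function(x) {
  ut <- upper.tri(x$values)
  x$values[ut & x$defined]
}

#' Standardize a PMIRM to Z-scores (ZPMIRM)
#'
#' Computes the mean \eqn{\mu} and population standard deviation \eqn{\sigma}
#' of the defined off-diagonal PMI values (each unordered pair counted once;
#' the convention-zeroed diagonal is an artifact, not data) and maps every
#' defined cell — including that diagonal — to \eqn{(v - \mu)/\sigma}.
#' Undefined cells stay undefined.
#'
#' @param x a `relmat` of variant `"pmirm"` (upstream variants are converted).
#' @return a `relmat` of variant `"zpmirm"`; `stats` holds `c(mu, sigma)`.
#' @export
as_zpmirm <- function(x) {
  stopifnot(inherits(x, "relmat"))
  if (x$variant %in% c("corm", "coprm")) x <- as_pmirm(x)
  if (x$variant != "pmirm") stop("as_zpmirm expects a pmirm")
  v <- defined_offdiag(x)
  if (length(v) < 2L)
    stop("degenerate profile: need at least 2 defined off-diagonal PMI values")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0)
    stop(sprintf(
      "degenerate profile '%s': all %d defined off-diagonal PMI values equal %.6g (sigma = 0)",
      x$provenance$label, length(v), mu))
  values <- (x$values - mu) / sigma
  new_relmat(values, "zpmirm", x$set_size, x$spec, defined = x$defined,
             stats = c(mu = mu, sigma = sigma), provenance = x$provenance)
}

#' @export
print.relmat <- function(x, ...) {
  d <- nrow(x$values)
  cat(sprintf("<relation matrix: %s, %dx%d features [%s], |S| = %s>\n",
              x$variant, d, d, format(x$spec),
              format(x$set_size, big.mark = ",")))
  if (!is.null(x$defined))
    cat(sprintf("  defined cells: %d of %d\n", sum(x$defined), d * d))
  if (!is.null(x$stats))
    cat(sprintf("  standardization: mu = %.6g, sigma = %.6g\n",
                x$stats[["mu"]], x$stats[["sigma"]]))
  if (nzchar(x$provenance$label))
    cat("  provenance:", x$provenance$label, "\n")
  invisible(x)
}

# ---- container I/O --------------------------------------------------------

pack_upper <- function(m) m[upper.tri(m, diag = TRUE)]

unpack_upper <- function(v, d) {
  m <- matrix(0, d, d)
  m[upper.tri(m, diag = TRUE)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Save and load relation-matrix containers
#'
#' The `.rm` container is a single JSON file: a metadata block (variant, spec,
#' set size, standardization stats, provenance, creation command) plus the
#' row-major packed upper triangle of the values (and of the defined mask for
#' PMI variants).  Counts and masks round-trip exactly; floating-point values
#' round-trip to better than 1e-12 (full double precision is serialized).
#' Loading refuses containers whose declared format version is unknown.
#'
#' @param x a `relmat`.
#' @param path file path (conventionally `*.rm`).
#' @param command free-text creation command recorded in the metadata.
#' @return `save_relmat` returns `path` invisibly; `load_relmat` a `relmat`.
#' @export
save_relmat <- function(x, path, command = "") {
  stopifnot(inherits(x, "relmat"))
  obj <- list(
    format = "fip-rm", format_version = 1L,
    variant = x$variant,
    spec = format(x$spec),
    n_features = nrow(x$values),
    set_size = x$set_size,
    stats = if (!is.null(x$stats)) as.list(x$stats),
    provenance = x$provenance,
    command = command,
    values = pack_upper(x$values),
    defined = if (!is.null(x$defined)) as.integer(pack_upper(x$defined))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname save_relmat
#' @export
load_relmat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupted relation-matrix container: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "fip-rm"))
    stop("not a relation-matrix container (missing fip-rm header)")
  if (!identical(as.integer(obj$format_version), 1L))
    stop("unsupported container format version: ", obj$format_version)
  d <- as.integer(obj$n_features)
  spec <- parse_spec_string(obj$spec)
  values <- unpack_upper(as.numeric(obj$values), d)
  defined <- NULL
  if (!is.null(obj$defined)) {
    defined <- unpack_upper(as.numeric(obj$defined), d) > 0
    values[!defined] <- NA_real_
  }
  stats <- if (!is.null(obj$stats)) unlist(obj$stats)
  new_relmat(values, obj$variant, obj$set_size, spec, defined = defined,
             stats = stats,
             provenance = list(label = obj$provenance$label %||% "",
                               toolkit = obj$provenance$toolkit %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
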