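#' Fingerprint specification
#'
#' Describes the binary feature space in which compounds are encoded: a
#' dictionary-based structure key (MACCS, 166 bits; PubChem key, 881 bits),
#' a hashed circular fingerprint (ECFP, folded to a fixed length), or a
#' custom/synthetic feature space of arbitrary length.
#'
#' Bit indexing is 0-based everywhere in this package; the hex interchange
#' dialect is the FPS format (see [write_fps()]).
#'
#' @param kind one of `"maccs"`, `"pubchemkey"`, `"ecfp"`, `"custom"`.
#' @param length number of bits.  Fixed at 166 for `maccs` and 881 for
#'   `pubchemkey`; defaults to 1024 for `ecfp`; required for `custom`.
#' @param radius bond radius for `ecfp` only (2 for ECFP4, 3 for ECFP6).
#' @return an object of class `"fp_spec"`: a list with elements `kind`,
#'   `length` and (for ecfp) `radius`.
#' @examples
#' fingerprint_spec("maccs")
#' fingerprint_spec("ecfp", radius = 2)
#' fingerprint_spec("custom", length = 64)
#' @export
fingerprint_spec <- function(kind = c("maccs", "pubchemkey", "ecfp", "custom"),
                             length = NULL, radius = NULL) {
  kind <- match.arg(kind)
  if (kind == "maccs") {
    if (!is.null(length) && length != 166L)
      stop("MACCS structure key has 166 bits")
    length <- 166L
  } else if (kind == "pubchemkey") {
    if (!is.null(length) && length != 881L)
      stop("PubChem structure key has 881 bits")
    length <- 881L
  } else if (kind == "ecfp") {
    if (is.null(length)) length <- 1024L
    if (is.null(radius))
      stop("ecfp requires a radius (2 for ECFP4, 3 for ECFP6)")
  } else {
    if (is.null(length)) stop("custom spec requires an explicit length")
  }
  if (kind != "ecfp" && !is.null(radius))
    stop("radius is only meaningful for kind = 'ecfp'")
  length <- as.integer(length)
  if (length <= 0L) stop("fingerprint length must be positive")
  spec <- list(kind = kind, length = length)
  if (kind == "ecfp") spec$radius <- as.integer(radius)
  structure(spec, class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  r <- if (!is.null(x$radius)) sprintf(", radius %d", x$radius) else ""
  cat(sprintf("<fingerprint spec: %s, %d bits%s>\n", x$kind, x$length, r))
  invisible(x)
}

#' @export
format.fp_spec <- function(x, ...) {
  if (x$kind == "ecfp")
    sprintf("ecfp/%d-%d", 2L * x$radius, x$length)
  else
    sprintf("%s-%d", x$kind, x$length)
}

spec_equal <- function(a, b) {
  identical(a$kind, b$kind) && identical(a$length, b$length) &&
    identical(a$radius, b$radius)
}

stopifnot_spec_match <- function(a, b, what = "inputs") {
  if (!spec_equal(a, b))
    stop(sprintf("fingerprint spec mismatch between %s: %s vs %s",
                 what, format(a), format(b)), call. = FALSE)
  invisible(TRUE)
}

parse_spec_string <- function(s) {
  # inverse of format.fp_spec, used by file headers
  if (grepl("^ecfp/", s)) {
    m <- regmatches(s, regexec("^ecfp/([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 3L) stop("unparsable fingerprint type string: ", s)
    fingerprint_spec("ecfp", length = as.integer(m[3]),
                     radius = as.integer(m[2]) %/% 2L)
  } else {
    m <- regmatches(s, regexec("^([a-z]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 3L) stop("unparsable fingerprint type string: ", s)
    fingerprint_spec(m[2], length = as.integer(m[3]))
  }
}
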