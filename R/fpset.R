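#' Sets of binary feature vectors
#'
#' An `fpset` stores the feature vectors of a compound set as a dense 0/1
#' integer matrix with one row per compound and one column per feature bit,
#' together with the [fingerprint_spec()] describing the feature space.
#' Compound identifiers live in the rownames.
#'
#' @param bits 0/1 matrix (compounds in rows, feature bits in columns) or a
#'   single vector (one compound).
#' @param spec a [fingerprint_spec()]; its `length` must equal `ncol(bits)`.
#' @param ids optional character vector of compound identifiers; defaults to
#'   existing rownames or `cpd1..cpdn`.
#' @return an object of class `"fpset"`.
#' @examples
#' x <- fpset(rbind(c(1, 1, 0), c(1, 0, 1)),
#'            fingerprint_spec("custom", length = 3))
#' x
#' @export
fpset <- function(bits, spec, ids = NULL) {
  if (is.vector(bits)) bits <- matrix(bits, nrow = 1L)
  if (!is.matrix(bits)) stop("bits must be a matrix or vector")
  storage.mode(bits) <- "integer"
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("feature vectors must contain only 0 and 1")
  if (!inherits(spec, "fp_spec")) stop("spec must be a fingerprint_spec()")
  if (ncol(bits) != spec$length)
    stop(sprintf("vector length %d does not match spec length %d",
                 ncol(bits), spec$length))
  if (is.null(ids)) ids <- rownames(bits)
  if (is.null(ids)) ids <- paste0("cpd", seq_len(nrow(bits)))
  if (length(ids) != nrow(bits)) stop("one id per compound required")
  rownames(bits) <- ids
  colnames(bits) <- NULL
  structure(list(bits = bits, spec = spec), class = "fpset")
}

#' @export
print.fpset <- function(x, ...) {
  cat(sprintf("<fpset: %d compounds x %d bits [%s], density %.3f>\n",
              nrow(x$bits), ncol(x$bits), format(x$spec),
              mean(x$bits)))
  invisible(x)
}

#' @export
length.fpset <- function(x) nrow(x$bits)

#' @export
`[.fpset` <- function(x, i, ...) fpset(x$bits[i, , drop = FALSE], x$spec)

#' @rdname fpset
#' @param x an `fpset`.
#' @export
fp_ids <- function(x) rownames(x$bits)

#' Concatenate fpsets sharing one spec
#' @param ... `fpset` objects with identical specs.
#' @return the row-bound `fpset`.
#' @export
fp_rbind <- function(...) {
  xs <- list(...)
  for (x in xs[-1L]) stopifnot_spec_match(xs[[1L]]$spec, x$spec, "fpsets")
  fpset(do.call(rbind, lapply(xs, `[[`, "bits")), xs[[1L]]$spec)
}

# ---- FPS text format ------------------------------------------------------
# Interchange dialect: one hex-encoded fingerprint + TAB + id per line, with
# a small header.  Bit b lives in byte b %/% 8, at position 2^(b %% 8)
# (least-significant-bit-first within the byte), bytes in ascending order.

fp_to_hex <- function(bits) {
  n <- length(bits)
  nbytes <- (n + 7L) %/% 8L
  padded <- c(bits, integer(nbytes * 8L - n))
  bytes <- colSums(matrix(padded, nrow = 8L) *
                     c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L))
  paste(sprintf("%02x", bytes), collapse = "")
}

hex_to_fp <- function(hex, nbits) {
  bytes <- strtoi(substring(hex, seq(1L, nchar(hex) - 1L, 2L),
                            seq(2L, nchar(hex), 2L)), 16L)
  if (anyNA(bytes)) stop("invalid hex fingerprint: ", hex)
  bits <- as.integer(bitwAnd(rep(bytes, each = 8L),
                             rep(c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
                                 times = length(bytes))) > 0L)
  if (length(bits) < nbits) stop("hex fingerprint shorter than declared length")
  bits[seq_len(nbits)]
}

#' Read and write fingerprints in FPS format
#'
#' FPS is a line-oriented text interchange format for binary fingerprints:
#' a header (`#FPS1`, `#num_bits=`, `#type=`, `#software=`) followed by one
#' `hex<TAB>id` record per compound.  Hex encoding is byte-ordered with the
#' least significant bit of each byte first, so round-trips are bit-exact.
#'
#' @param x an [fpset()].
#' @param path file path.
#' @return `write_fps` returns `path` invisibly; `read_fps` returns an
#'   [fpset()].
#' @examples
#' f <- tempfile(fileext = ".fps")
#' x <- fpset(rbind(a = c(1, 0, 1), b = c(0, 1, 1)),
#'            fingerprint_spec("custom", length = 3))
#' write_fps(x, f)
#' identical(read_fps(f)$bits, x$bits)
#' @export
write_fps <- function(x, path) {
  stopifnot(inherits(x, "fpset"))
  header <- c("#FPS1",
              sprintf("#num_bits=%d", x$spec$length),
              sprintf("#type=%s", format(x$spec)),
              sprintf("#software=fip/%s", as.character(utils::packageVersion("fip"))))
  recs <- if (nrow(x$bits) > 0L)
    paste0(apply(x$bits, 1L, fp_to_hex), "\t", rownames(x$bits))
  else character()
  writeLines(c(header, recs), path)
  invisible(path)
}

#' @rdname write_fps
#' @export
read_fps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(h) == 0L) return(NULL)
    sub(paste0("^#", key, "="), "", h[1L])
  }
  nbits <- get("num_bits")
  if (is.null(nbits)) stop("FPS header lacks #num_bits")
  nbits <- as.integer(nbits)
  type <- get("type")
  spec <- if (!is.null(type)) parse_spec_string(type)
          else fingerprint_spec("custom", length = nbits)
  if (spec$length != nbits)
    stop(sprintf("FPS header inconsistent: num_bits=%d but type declares %d",
                 nbits, spec$length))
  nhex <- 2L * ((nbits + 7L) %/% 8L)
  if (length(body) == 0L)
    return(fpset(matrix(integer(), 0L, nbits), spec, ids = character()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L || nchar(p[[1L]]) != nhex,
                logical(1L))
  if (any(bad))
    stop(sprintf("FPS record length mismatch at line(s) %s: expected %d hex chars",
                 paste(which(bad)[seq_len(min(3L, sum(bad)))], collapse = ","),
                 nhex))
  bits <- t(vapply(parts, function(p) hex_to_fp(p[[1L]], nbits),
                   integer(nbits)))
  fpset(bits, spec, ids = vapply(parts, `[[`, character(1L), 2L))
}
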