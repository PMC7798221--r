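# Compound reading, standardization, deduplication and fingerprint encoding.
# The chemistry backend is Open Babel: the `obabel` CLI for parsing,
# standardization and InChIKeys, ChemmineOB for fingerprints.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("the Open Babel CLI (obabel) is required for the chemistry path ",
         "but was not found on PATH", call. = FALSE)
  p
}

run_obabel <- function(input_lines, args) {
  inf <- tempfile(fileext = ".smi"); outf <- tempfile()
  on.exit(unlink(c(inf, outf)))
  writeLines(input_lines, inf)
  status <- suppressWarnings(
    system2(obabel_path(), c(inf, args, "-e"), stdout = outf,
            stderr = FALSE))
  if (!file.exists(outf)) return(character())
  readLines(outf, warn = FALSE)
}

compound_records <- function(id, smiles, inchikey = NA_character_,
                             rejects = empty_rejects()) {
  structure(data.frame(id = as.character(id), smiles = as.character(smiles),
                       inchikey = inchikey, stringsAsFactors = FALSE),
            rejects = rejects, class = c("compound_records", "data.frame"))
}

empty_rejects <- function()
  data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)

#' Rejected records of a compound pipeline step
#'
#' Every reading/standardization/encoding step carries the records it could
#' not process as a `rejects` attribute (data.frame of `id`, `reason`);
#' nothing is silently dropped.
#'
#' @param x a `compound_records` object.
#' @return data.frame with columns `id` and `reason`.
#' @export
rejects <- function(x) attr(x, "rejects") %||% empty_rejects()

#' Write a rejects report as TSV
#' @param x a `compound_records` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejects_tsv <- function(x, path) {
  utils::write.table(rejects(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.compound_records <- function(x, ...) {
  cat(sprintf("<%d compound record(s), %d reject(s)>\n", nrow(x),
              nrow(rejects(x))))
  NextMethod()
}

#' Read compounds from a SMILES or SDF file
#'
#' SMILES files carry one record per line: the SMILES string, whitespace,
#' then an identifier (records without an identifier get a positional one).
#' SDF input is converted through Open Babel.  Records whose structure does
#' not parse are counted in the [rejects()] report, never silently dropped.
#'
#' @param path input file.
#' @param format `"smi"` or `"sdf"` (default guessed from the extension).
#' @return a `compound_records` data.frame (`id`, `smiles`, `inchikey`) in
#'   file order, with a `rejects` attribute.
#' @export
read_compounds <- function(path, format = c("smi", "sdf")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(format))
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  format <- match.arg(format)
  if (format == "sdf") {
    out <- suppressWarnings(
      system2(obabel_path(), c(path, "-osmi", "-e"), stdout = TRUE,
              stderr = FALSE))
    parts <- strsplit(out, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[[`, character(1L), 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "",
                  character(1L))
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
    if (length(smiles) == 0L) stop("no parsable records in ", path)
    return(compound_records(ids, smiles))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty compound file: ", path)
  toks <- regmatches(lines, regexpr("^\\S+", lines))
  ids <- trimws(sub("^\\S+", "", lines))
  ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  # parse check: round-trip each record through obabel, matching by title
  parsed <- run_obabel(paste(toks, ids), "-osmi")
  ok_ids <- vapply(strsplit(parsed, "\t", fixed = TRUE),
                   function(p) if (length(p) > 1L) trimws(p[[2L]]) else "",
                   character(1L))
  keep <- ids %in% ok_ids
  if (!any(keep)) stop("no parsable records in ", path)
  rej <- data.frame(id = ids[!keep], reason = rep("unparsable SMILES", sum(!keep)),
                    stringsAsFactors = FALSE)
  compound_records(ids[keep], toks[keep], rejects = rej)
}

obabel_inchikeys <- function(smiles, ids) {
  keys <- run_obabel(paste(smiles, ids), "-oinchikey")
  if (length(keys) == length(smiles)) return(keys)
  # a record failed key generation: fall back to per-record conversion
  vapply(seq_along(smiles), function(k) {
    out <- run_obabel(paste(smiles[k], ids[k]), "-oinchikey")
    if (length(out) == 1L) out else NA_character_
  }, character(1L))
}

#' Standardize compound records
#'
#' Applies the package's standardization contract through Open Babel: keep
#' the largest fragment (salt stripping), neutralize charges where valence
#' permits, strip stereochemistry and isotope labels; no tautomer
#' canonicalization.  The InChIKey is recomputed on the standardized
#' structure, so stereoisomers and salt forms of one parent collapse to one
#' key.  Standardization is idempotent.  Records that fail are routed to
#' [rejects()].
#'
#' @param records a `compound_records` data.frame (see [read_compounds()]).
#' @return standardized `compound_records` with `inchikey` filled in.
#' @export
standardize_compounds <- function(records) {
  stopifnot(inherits(records, "compound_records"))
  prior_rejects <- rejects(records)
  out <- run_obabel(paste(records$smiles, records$id),
                    c("-osmi", "-r", "--neutralize", "-xi"))
  parts <- strsplit(out, "\t", fixed = TRUE)
  std_smiles <- vapply(parts, `[[`, character(1L), 1L)
  std_ids <- vapply(parts, function(p) if (length(p) > 1L) trimws(p[[2L]]) else "",
                    character(1L))
  m <- match(records$id, std_ids)
  failed <- is.na(m)
  smiles <- std_smiles[m[!failed]]
  ids <- records$id[!failed]
  keys <- if (length(ids)) obabel_inchikeys(smiles, ids) else character()
  bad_key <- is.na(keys) | !nzchar(keys)
  rej <- rbind(prior_rejects,
               data.frame(id = records$id[failed],
                          reason = rep("standardization failure", sum(failed)),
                          stringsAsFactors = FALSE),
               data.frame(id = ids[bad_key],
                          reason = rep("inchikey generation failure", sum(bad_key)),
                          stringsAsFactors = FALSE))
  compound_records(ids[!bad_key], smiles[!bad_key], keys[!bad_key],
                   rejects = rej)
}

#' Deduplicate standardized records by InChIKey
#'
#' Keeps the first occurrence of every InChIKey; the number of removed
#' duplicates is available as the `duplicates` attribute.
#'
#' @param records standardized `compound_records` (non-`NA` `inchikey`).
#' @return deduplicated `compound_records`.
#' @export
deduplicate_compounds <- function(records) {
  stopifnot(inherits(records, "compound_records"))
  if (anyNA(records$inchikey))
    stop("records must be standardized (inchikey present) before deduplication")
  keep <- !duplicated(records$inchikey)
  out <- compound_records(records$id[keep], records$smiles[keep],
                          records$inchikey[keep], rejects = rejects(records))
  attr(out, "duplicates") <- sum(!keep)
  out
}

# Open Babel's MACCS implementation sets key k (1..166) at 0-based bit k-1
# of a 256-bit array; the 166 semantic keys are therefore columns 1..166.
OB_MACCS_COLUMNS <- 1:166

fold_columns <- function(fp, length_out) {
  d <- ncol(fp)
  if (d <= length_out) return(fp[, seq_len(length_out), drop = FALSE])
  folded <- matrix(0L, nrow(fp), length_out)
  for (block in seq_len(ceiling(d / length_out))) {
    cols <- ((block - 1L) * length_out + 1L):min(block * length_out, d)
    folded[, seq_along(cols)] <-
      folded[, seq_along(cols), drop = FALSE] | fp[, cols, drop = FALSE]
  }
  matrix(as.integer(folded), nrow(fp), length_out)
}

#' Encode standardized compounds into binary feature vectors
#'
#' Generates fingerprints with Open Babel (via ChemmineOB): MACCS structure
#' keys (166 bits) or ECFP circular fingerprints (radius 2 = ECFP4,
#' radius 3 = ECFP6), folded by OR-ing hash positions modulo the requested
#' length (default 1024).  Encoding is deterministic for a fixed toolkit
#' version; unencodable structures go to [rejects()].  The PubChem 881-bit
#' key is accepted as a spec for pre-encoded input ([read_fps()]) but is not
#' generated here (the installed toolkit does not define it).
#'
#' @param records standardized `compound_records`.
#' @param spec a [fingerprint_spec()] of kind `"maccs"` or `"ecfp"`.
#' @return an [fpset()] (ids = record ids) with a `rejects` attribute.
#' @export
encode_compounds <- function(records, spec) {
  stopifnot(inherits(records, "compound_records"), inherits(spec, "fp_spec"))
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for fingerprint encoding")
  if (!spec$kind %in% c("maccs", "ecfp"))
    stop(sprintf("encoding of kind '%s' is not supported by the installed toolkit; ",
                 spec$kind),
         "supply pre-encoded vectors via read_fps()")
  if (nrow(records) == 0L) stop("no records to encode")
  fpname <- if (spec$kind == "maccs") "MACCS"
            else paste0("ECFP", 2L * spec$radius)
  acc <- new.env(parent = emptyenv()); acc$mols <- list()
  ChemmineOB::forEachMol("SMILES",
                         paste(records$smiles, records$id, collapse = "\n"),
                         function(m) acc$mols[[length(acc$mols) + 1L]] <- m)
  rej <- rejects(records)
  if (length(acc$mols) != nrow(records)) {
    # some structure failed in the batch: encode per record, reject failures
    acc$mols <- list(); ok <- logical(nrow(records))
    for (k in seq_len(nrow(records))) {
      good <- tryCatch({
        ChemmineOB::forEachMol("SMILES",
                               paste(records$smiles[k], records$id[k]),
                               function(m) acc$mols[[length(acc$mols) + 1L]] <- m)
        TRUE
      }, error = function(e) FALSE)
      ok[k] <- good && length(acc$mols) == sum(ok) + 1L
    }
    rej <- rbind(rej, data.frame(id = records$id[!ok],
                                 reason = rep("unencodable structure", sum(!ok)),
                                 stringsAsFactors = FALSE))
    records <- records[ok, , drop = FALSE]
    if (nrow(records) == 0L) stop("no encodable records")
  }
  raw <- ChemmineOB::fingerprint_OB(acc$mols, fpname)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)  # single molecule
  bits <- if (spec$kind == "maccs") {
    if (ncol(raw) < 166L) stop("unexpected MACCS fingerprint width")
    matrix(as.integer(raw[, OB_MACCS_COLUMNS, drop = FALSE] > 0),
           nrow(raw), 166L)
  } else {
    fold_columns(matrix(as.integer(raw > 0), nrow(raw), ncol(raw)),
                 spec$length)
  }
  out <- fpset(bits, spec, ids = records$id)
  attr(out, "rejects") <- rej
  out
}

#' One-call pipeline: read, standardize, deduplicate, encode
#'
#' @param path SMILES or SDF file.
#' @param spec a [fingerprint_spec()].
#' @param format passed to [read_compounds()].
#' @return an [fpset()]; rejects of all stages in the `rejects` attribute,
#'   duplicate count in the `duplicates` attribute.
#' @export
featurize_file <- function(path, spec, format) {
  recs <- if (missing(format)) read_compounds(path)
          else read_compounds(path, format)
  recs <- deduplicate_compounds(standardize_compounds(recs))
  out <- encode_compounds(recs, spec)
  attr(out, "duplicates") <- attr(recs, "duplicates")
  out
}
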