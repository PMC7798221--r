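#' Fit the interrelation profile of a compound set
#'
#' The central fitting function of the package.  Given the binary feature
#' vectors of a reference compound set it accumulates the co-occurrence
#' relation matrix and derives the probability, PMI and Z-standardized PMI
#' variants, returning a fitted profile object that can score new compounds.
#'
#' @param x an [fpset()] or 0/1 matrix (compounds in rows).
#' @param label free-text provenance label for the reference set.
#' @return an object of class `"interrelation"` with components `corm`,
#'   `coprm`, `pmirm`, `zpmirm` (each a `relmat`), `spec` and `set_size`.
#' @seealso [predict.interrelation()], [pmi_profile()], [zrft()]
#' @examples
#' x <- fpset(rbind(c(1,1,0), c(1,1,0), c(1,0,1), c(0,0,1)),
#'            fingerprint_spec("custom", length = 3))
#' fit <- interrelation(x, label = "toy")
#' fit
#' predict(fit, fpset(c(1, 1, 0), x$spec))
#' @export
interrelation <- function(x, label = "") {
  cm <- corm(x, label = label)
  pm <- as_pmirm(cm)
  zm <- tryCatch(as_zpmirm(pm), error = function(e) {
    warning("ZPMIRM unavailable: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  structure(list(corm = cm, coprm = as_coprm(cm), pmirm = pm, zpmirm = zm,
                 spec = cm$spec, set_size = cm$set_size, label = label),
            class = "interrelation")
}

#' @export
print.interrelation <- function(x, ...) {
  cat(sprintf("Interrelation profile '%s': %s compounds, %d features [%s]\n",
              x$label, format(x$set_size, big.mark = ","),
              x$spec$length, format(x$spec)))
  v <- defined_offdiag(x$pmirm)
  cat(sprintf("  defined feature pairs: %d of %d\n",
              length(v), choose(x$spec$length, 2)))
  if (!is.null(x$zpmirm))
    cat(sprintf("  PMI: mean %.4f, sd %.4f (population, defined pairs)\n",
                x$zpmirm$stats[["mu"]], x$zpmirm$stats[["sigma"]]))
  invisible(x)
}

#' @export
summary.interrelation <- function(object, ...) {
  v <- defined_offdiag(object$pmirm)
  out <- list(label = object$label, spec = object$spec,
              set_size = object$set_size,
              n_defined = length(v),
              n_pairs = choose(object$spec$length, 2),
              bits_set = sum(diag(object$corm$values) > 0),
              pmi_quantiles = stats::quantile(v, c(0, .25, .5, .75, 1)),
              stats = if (!is.null(object$zpmirm)) object$zpmirm$stats)
  class(out) <- "summary.interrelation"
  out
}

#' @export
print.summary.interrelation <- function(x, ...) {
  cat(sprintf("Interrelation profile '%s' [%s]\n", x$label, format(x$spec)))
  cat(sprintf("  compounds: %s; features with nonzero occurrence: %d of %d\n",
              format(x$set_size, big.mark = ","), x$bits_set, x$spec$length))
  cat(sprintf("  defined pairs: %d of %d (%.1f%%)\n", x$n_defined, x$n_pairs,
              100 * x$n_defined / x$n_pairs))
  cat("  PMI quantiles:\n")
  print(round(x$pmi_quantiles, 4))
  if (!is.null(x$stats))
    cat(sprintf("  standardization: mu = %.4f, sigma = %.4f\n",
                x$stats[["mu"]], x$stats[["sigma"]]))
  invisible(x)
}

#' Extract the fitted relation matrix
#'
#' @param object a fitted [interrelation()] profile.
#' @param variant which relation-matrix variant to return.
#' @param ... unused.
#' @return the requested symmetric matrix (with `NA` in undefined cells).
#' @export
coef.interrelation <- function(object,
                               variant = c("zpmirm", "pmirm", "coprm", "corm"),
                               ...) {
  variant <- match.arg(variant)
  m <- object[[variant]]
  if (is.null(m)) stop("this fit has no ", variant)
  m$values
}

#' Score new compounds against a fitted interrelation profile
#'
#' @param object a fitted [interrelation()] profile.
#' @param newdata an [fpset()] (or 0/1 matrix) of query compounds.
#' @param type `"zrft"` (default) or `"rft"`.
#' @param per_compound if `TRUE` (default) each compound is scored as a
#'   singleton set ([zrft_per_compound()]); otherwise one set-level score is
#'   returned.
#' @param ... passed on to the scoring functions (`mean_over`,
#'   `missing_value`).
#' @return a data.frame of per-compound scores, or a single
#'   `tightness_score`.
#' @export
predict.interrelation <- function(object, newdata, type = c("zrft", "rft"),
                                  per_compound = TRUE, ...) {
  type <- match.arg(type)
  ref <- if (type == "zrft") object$zpmirm else object$pmirm
  if (is.null(ref)) stop("fit has no ZPMIRM (degenerate profile)")
  if (per_compound) zrft_per_compound(newdata, ref, ...)
  else if (type == "zrft") zrft(newdata, ref, ...)
  else rft(newdata, ref, ...)
}

#' Plot the PMI interrelation profile of a fit
#'
#' Histogram of the defined off-diagonal PMI (or ZPMI) values, the package's
#' standard view of an interrelation profile.
#'
#' @param x a fitted [interrelation()] profile.
#' @param variant `"pmirm"` or `"zpmirm"`.
#' @param bin_width histogram bin width (PMI units).
#' @param ... passed to [graphics::plot()].
#' @return the [pmi_profile()] object, invisibly.
#' @export
plot.interrelation <- function(x, variant = c("pmirm", "zpmirm"),
                               bin_width = 0.1, ...) {
  variant <- match.arg(variant)
  m <- x[[variant]]
  if (is.null(m)) stop("fit has no ", variant)
  prof <- pmi_profile(m, bin_width = bin_width)
  plot(prof, ...)
  invisible(prof)
}
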