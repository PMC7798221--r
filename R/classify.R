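#' Scored compound sets for ES/HS classification
#'
#' A scored set is a data.frame with columns `compound_id`, `score`
#' (finite numeric — ZRFT or any external score column) and `label`
#' (`"ES"`/`"HS"`).  ES (easy to synthesize) is the positive class and
#' higher scores indicate ES throughout.
#'
#' @param compound_id character identifiers.
#' @param score finite numeric scores.
#' @param label `"ES"`/`"HS"` labels (character or factor).
#' @return a validated data.frame of class `"scored_set"`.
#' @export
scored_set <- function(compound_id, score, label) {
  label <- as.character(label)
  if (!all(label %in% c("ES", "HS"))) stop("labels must be 'ES' or 'HS'")
  if (!all(is.finite(score))) stop("scores must be finite")
  if (length(unique(label)) < 2L)
    stop("both classes (ES and HS) must be present")
  structure(data.frame(compound_id = as.character(compound_id),
                       score = as.numeric(score), label = label,
                       stringsAsFactors = FALSE),
            class = c("scored_set", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over all distinct-score cut-points with ES as the
#' positive class (higher score = ES).  Computed via the rank (Mann-Whitney)
#' identity, which is exactly the trapezoidal area with ties counting 0.5.
#'
#' @param s a [scored_set()] (or data.frame with `score` and `label`).
#' @return AUC in \[0, 1\].
#' @examples
#' s <- scored_set(letters[1:4], c(.3, .4, .1, .2), c("ES", "ES", "HS", "HS"))
#' roc_auc(s)  # 1
#' @export
roc_auc <- function(s) {
  es <- s$score[s$label == "ES"]
  hs <- s$score[s$label == "HS"]
  if (length(es) == 0L || length(hs) == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(c(es, hs))
  (sum(r[seq_along(es)]) - length(es) * (length(es) + 1) / 2) /
    (length(es) * length(hs))
}

confusion_metrics <- function(s, threshold) {
  pred_es <- s$score >= threshold
  is_es <- s$label == "ES"
  sn <- sum(pred_es & is_es) / sum(is_es)
  sp <- sum(!pred_es & !is_es) / sum(!is_es)
  acc <- mean(pred_es == is_es)
  c(acc = acc, sn = sn, sp = sp)
}

#' Youden-index optimal classification threshold
#'
#' Scans all candidate cut-points — midpoints of consecutive distinct sorted
#' scores, plus minus/plus infinity — and returns the threshold maximizing
#' the Youden index \eqn{J = SN + SP - 1} under the rule
#' `score >= threshold  =>  ES`.  Ties are broken toward the lowest
#' threshold.
#'
#' @param s a [scored_set()].
#' @return a list with `threshold`, `youden`, `acc`, `sn`, `sp` and `auc`.
#' @examples
#' s <- scored_set(letters[1:4], c(.3, .4, .1, .2), c("ES", "ES", "HS", "HS"))
#' youden_threshold(s)$threshold  # 0.25
#' @export
youden_threshold <- function(s) {
  if (length(unique(s$label)) < 2L) stop("both classes must be present")
  sc <- sort(unique(s$score))
  candidates <- c(-Inf, if (length(sc) > 1L) (sc[-1L] + sc[-length(sc)]) / 2, Inf)
  mets <- vapply(candidates, function(t) confusion_metrics(s, t), numeric(3L))
  j <- mets["sn", ] + mets["sp", ] - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # ties toward the lowest threshold
  list(threshold = candidates[best],
       youden = j[best],
       acc = mets["acc", best], sn = mets["sn", best], sp = mets["sp", best],
       auc = roc_auc(s))
}

#' Evaluate classification over multiple test-set instances
#'
#' Computes AUC, accuracy, sensitivity and specificity per instance — with
#' either a per-instance Youden threshold or a fixed one — and averages the
#' metrics arithmetically across instances (the protocol for small test sets
#' replicated many times with refreshed ES draws).
#'
#' @param instances a list of [scored_set()]s.
#' @param threshold_policy `"youden_per_instance"` (default) or a single
#'   number used as a fixed threshold for every instance.
#' @return an object of class `"classification_report"`: list with `auc`,
#'   `acc`, `sn`, `sp` (means), `threshold` (mean of per-instance thresholds,
#'   or the fixed value), `n_instances` and `per_instance` (data.frame).
#' @export
evaluate_instances <- function(instances, threshold_policy = "youden_per_instance") {
  stopifnot(length(instances) >= 1L)
  fixed <- suppressWarnings(as.numeric(threshold_policy))
  per <- lapply(instances, function(s) {
    if (length(unique(s$label)) < 2L)
      stop("every instance must contain both classes")
    if (is.na(fixed)) {
      y <- youden_threshold(s)
      c(auc = y$auc, acc = unname(y$acc), sn = unname(y$sn),
        sp = unname(y$sp), threshold = y$threshold)
    } else {
      m <- confusion_metrics(s, fixed)
      c(auc = roc_auc(s), acc = unname(m["acc"]), sn = unname(m["sn"]),
        sp = unname(m["sp"]), threshold = fixed)
    }
  })
  per <- as.data.frame(do.call(rbind, per))
  out <- list(auc = mean(per$auc), acc = mean(per$acc), sn = mean(per$sn),
              sp = mean(per$sp), threshold = mean(per$threshold),
              n_instances = length(instances), per_instance = per)
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification over %d instance(s):\n", x$n_instances))
  cat(sprintf("  AUC %.3f | Acc %.3f | SN %.3f | SP %.3f | threshold %.4g\n",
              x$auc, x$acc, x$sn, x$sp, x$threshold))
  invisible(x)
}
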