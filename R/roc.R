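#' Labelled biomarker scores
#'
#' Couples per-subject biomarker values (Ki or SUVR) with the binary
#' response label.  The positive class is the non-responder group (the
#' target of detection); the orientation flag records whether LOW values
#' indicate the positive class, as expected for dopamine-synthesis measures
#' where non-responders sit lower.
#'
#' @param value Numeric biomarker values.
#' @param is_positive Logical; `TRUE` for the positive (non-responder) class.
#' @param positive_low `TRUE` if low values indicate the positive class,
#'   `FALSE` if high values do, or `NA` (default) to auto-orient so that
#'   AUC >= 0.5; the resolved orientation is recorded.
#' @return A `labelled_scores` object.
#' @export
labelled_scores <- function(value, is_positive, positive_low = NA) {
  value <- as.numeric(value); is_positive <- as.logical(is_positive)
  if (length(value) != length(is_positive)) stop("length mismatch")
  if (anyNA(value) || anyNA(is_positive)) stop("missing values not allowed")
  if (!any(is_positive) || all(is_positive))
    stop("both classes must be non-empty")
  structure(list(value = value, is_positive = is_positive,
                 positive_low = positive_low),
            class = "labelled_scores")
}

#' Cohen's d effect size
#'
#' \eqn{d = (\bar a - \bar b) / s_p} with the pooled SD using the
#' \eqn{n_a + n_b - 2} denominator.  By package convention group `a` holds
#' the responders and `b` the non-responders, so positive d means responders
#' elevated; the sign convention travels with the result.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return An `effect_size_result`: `cohens_d`, `mean_a`, `mean_b`,
#'   `pooled_sd`, `n_a`, `n_b`.
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled SD; d undefined")
  structure(list(cohens_d = (mean(a) - mean(b)) / sqrt(sp2),
                 mean_a = mean(a), mean_b = mean(b), pooled_sd = sqrt(sp2),
                 n_a = length(a), n_b = length(b)),
            class = "effect_size_result")
}

#' Empirical ROC curve, AUC and the 100%-specificity operating point
#'
#' Builds the empirical ROC over all distinct score thresholds, integrates
#' the AUC by the trapezoid rule (equivalent to the Mann-Whitney rank
#' statistic with half-credit for ties), attaches a two-sided p-value
#' against AUC = 0.5 via the Wilcoxon rank-sum equivalence, and extracts the
#' sensitivity at the 100%-specificity cut-off: the largest fraction of
#' positives detected by a threshold that misclassifies no negative
#' (strict inequality, so ties with the extreme negative do not count).
#'
#' @param scores A [labelled_scores()].
#' @return A `roc_result`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `p_value`, `sens_at_full_spec`, `positive_low`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores) {
  stopifnot(inherits(scores, "labelled_scores"))
  v <- scores$value; pos <- scores$is_positive
  if (length(unique(v)) == 1L) {
    warning("single distinct score value; AUC set to 0.5")
    return(structure(list(thresholds = unique(v), sensitivity = 1,
                          specificity = 0, auc = 0.5, p_value = 1,
                          sens_at_full_spec = 0,
                          positive_low = isTRUE(scores$positive_low),
                          n_pos = sum(pos), n_neg = sum(!pos)),
                     class = "roc_result"))
  }
  orient <- scores$positive_low
  if (is.na(orient)) {
    # auto-orient so that AUC >= 0.5: positives lower => low-positive
    orient <- mean(rank(v)[pos]) <= mean(rank(v)[!pos])
  }
  s <- if (orient) -v else v   # after this, HIGH s indicates positive
  th <- sort(unique(s))
  # classify positive when s >= threshold; add +Inf for the all-negative end
  th <- c(th, Inf)
  sens <- vapply(th, function(t) mean(s[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(s[!pos] < t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1L] + sens[o][-length(o)]) / 2)
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(s[pos], s[!pos])$p.value),
    error = function(e) NA_real_)
  structure(list(thresholds = if (orient) -th else th,
                 sensitivity = sens, specificity = spec, auc = auc,
                 p_value = p,
                 sens_at_full_spec = mean(s[pos] > max(s[!pos])),
                 positive_low = orient,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (p = %.3g), sens@100%%spec = %.1f%% [%s-positive, %d pos / %d neg]\n",
    x$auc, x$p_value, 100 * x$sens_at_full_spec,
    if (x$positive_low) "low" else "high", x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_curve
#' @export
sensitivity_at_full_specificity <- function(scores) {
  roc_curve(scores)$sens_at_full_spec
}
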