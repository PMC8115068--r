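#' Paired test-retest measurements
#'
#' @param subject_id Character or integer ids.
#' @param test,retest Numeric vectors of the same metric in the two sessions.
#' @return A `paired_measurements` object.
#' @export
paired_measurements <- function(test, retest,
                                subject_id = seq_along(test)) {
  test <- as.numeric(test); retest <- as.numeric(retest)
  if (length(test) != length(retest) || length(test) < 2L)
    stop("test and retest must have equal length >= 2")
  if (anyNA(test) || anyNA(retest)) stop("missing values not allowed")
  structure(list(subject_id = subject_id, test = test, retest = retest),
            class = "paired_measurements")
}

#' Percentage test-retest difference (%VAR)
#'
#' Per-subject absolute percentage difference
#' \deqn{VAR = 2\,|retest - test| / (test + retest) \times 100,}
#' plus its mean across subjects.  Scale-invariant and symmetric in the two
#' sessions; 0 iff test = retest.
#'
#' @param pairs A [paired_measurements()].
#' @return A `var_result`: `var_percent` (per subject), `mean_var`.
#' @export
percent_var <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  denom <- pairs$test + pairs$retest
  if (any(denom <= 0))
    stop("test + retest must be > 0 for every subject")
  v <- 2 * abs(pairs$retest - pairs$test) / denom * 100
  structure(list(var_percent = v, mean_var = mean(v)), class = "var_result")
}

#' Two-way ANOVA intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way subjects x sessions layout, computed
#' from the ANOVA mean squares.  Both the consistency form ICC(3,1)
#' (sessions fixed, the primary variant here) and the absolute-agreement
#' form ICC(2,1) (sessions random) are returned, together with the variance
#' components, since the two conventions differ only in whether a systematic
#' session shift is counted as error.
#'
#' @param pairs A [paired_measurements()] with at least 3 subjects.
#' @return An `icc_result`: `icc` (consistency, ICC(3,1)),
#'   `icc_consistency`, `icc_agreement` (ICC(2,1)), `ms` (mean squares:
#'   subjects, sessions, error), `variance_components` (subject, session,
#'   residual), `model`.
#' @export
icc_two_way <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  n <- length(pairs$test)
  if (n < 3L) stop("need at least 3 subjects for the two-way ICC")
  k <- 2L
  m <- cbind(pairs$test, pairs$retest)
  grand <- mean(m)
  if (stats::var(as.numeric(m)) == 0)
    stop("zero total variance; ICC undefined")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  structure(list(icc = icc_c, icc_consistency = icc_c, icc_agreement = icc_a,
                 ms = c(subjects = msr, sessions = msc, error = mse),
                 variance_components = c(
                   subject = (msr - mse) / k,
                   session = max(0, (msc - mse) / n),
                   residual = mse),
                 model = "two-way, single measure; ICC(3,1) consistency / ICC(2,1) agreement"),
            class = "icc_result")
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk tests (alpha = 0.05, per variable) decide the estimator:
#' Pearson's product-moment correlation when both variables look Gaussian,
#' Spearman's rank correlation otherwise.  The chosen method is recorded.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alpha Normality-test level (default 0.05).
#' @return List: `coefficient`, `method` ("pearson"/"spearman"), `p_value`,
#'   `shapiro_p` (both variables).
#' @export
gated_correlation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("x and y must have equal length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  sw <- c(x = stats::shapiro.test(x)$p.value,
          y = stats::shapiro.test(y)$p.value)
  method <- if (all(sw > alpha)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(coefficient = unname(ct$estimate), method = method,
       p_value = ct$p.value, shapiro_p = sw)
}
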