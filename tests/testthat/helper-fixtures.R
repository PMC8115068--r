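# Shared fixtures and independent oracles.  Everything is generated in code;
# expensive shared objects are built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, envir = .fixture_env)
}

# small mask keeps voxel counts low for unit tests that do not need 2847
small_mask <- function() memo("small_mask", function()
  make_striatal_mask(n_striatal = 120L))

small_design <- function(...) {
  args <- utils::modifyList(
    list(n_control = 2L, n_responder = 4L, n_nonresponder = 4L), list(...))
  do.call(cohort_design, args)
}

noiseless_design <- function(...)
  small_design(noise_cv = 0, voxel_noise_cv = 0, voxel_jitter_cv = 0, ...)

# the default "stated world" cohort, shared by several acceptance criteria
default_cohort <- function() memo("default_cohort", function()
  simulate_cohort(cohort_design(), seed = 20260909L))

# ---- independent oracles ---------------------------------------------------

# two-way ANOVA mean squares via stats::anova(lm(...)) - an independent code
# path from the package's direct sums-of-squares computation
icc_oracle <- function(test, retest) {
  n <- length(test)
  d <- data.frame(v = c(test, retest),
                  subj = factor(rep(seq_len(n), 2L)),
                  sess = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::lm(v ~ subj + sess, data = d))
  msr <- a["subj", "Mean Sq"]; msc <- a["sess", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(consistency = (msr - mse) / (msr + mse),
       agreement = (msr - mse) / (msr + mse + 2 / n * (msc - mse)))
}

# AUC by exhaustive pair counting (low values indicate the positive class
# when positive_low is TRUE)
auc_pair_oracle <- function(values, is_pos, positive_low) {
  s <- if (positive_low) -values else values
  pos <- s[is_pos]; neg <- s[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# sensitivity at 100% specificity by brute-force threshold scan
sens_full_spec_oracle <- function(values, is_pos, positive_low) {
  s <- if (positive_low) -values else values
  best <- 0
  for (t in unique(s)) {
    fp <- mean(s[!is_pos] > t)       # classify positive when s > t
    if (fp == 0) best <- max(best, mean(s[is_pos] > t))
  }
  best
}
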