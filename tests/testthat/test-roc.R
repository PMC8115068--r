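test_that("cohens_d matches hand-computed cases", {
  # means 1 and 0, unit pooled SD
  a <- c(0, 1, 2); b <- c(-1, 0, 1)
  expect_equal(cohens_d(a, b)$cohens_d, 1)
  expect_equal(cohens_d(a, a)$cohens_d, 0)
  # a = {0,2}, b = {1,3}: mean diff -1, pooled var = (2+2)/2 = 2
  expect_equal(cohens_d(c(0, 2), c(1, 3))$cohens_d, -1 / sqrt(2))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("roc_curve handles the textbook cases", {
  # full separation, low = positive
  rc <- roc_curve(labelled_scores(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                                  positive_low = TRUE))
  expect_equal(rc$auc, 1)
  expect_equal(rc$sens_at_full_spec, 1)
  # interleaved: 3 of 4 pairs concordant
  rc2 <- roc_curve(labelled_scores(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE),
                                   positive_low = TRUE))
  expect_equal(rc2$auc, 0.75)
  # single distinct value: warning and AUC 0.5
  expect_warning(
    rc3 <- roc_curve(labelled_scores(rep(2, 4), c(TRUE, TRUE, FALSE, FALSE))),
    "single distinct")
  expect_equal(rc3$auc, 0.5)
})

test_that("AUC equals exhaustive pair counting, with ties and both orientations", {
  set.seed(12)
  for (i in 1:200) {
    n_pos <- sample(2:6, 1); n_neg <- sample(2:6, 1)
    v <- sample(1:8, n_pos + n_neg, replace = TRUE)  # integer scores force ties
    is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    for (low in c(TRUE, FALSE)) {
      rc <- roc_curve(labelled_scores(v, is_pos, positive_low = low))
      expect_equal(rc$auc, auc_pair_oracle(v, is_pos, low))
    }
  }
})

test_that("auto-orientation yields AUC >= 0.5 and is recorded", {
  set.seed(3)
  v <- c(rnorm(10, 0), rnorm(10, 2))
  is_pos <- rep(c(TRUE, FALSE), each = 10)     # positives LOWER here
  rc <- roc_curve(labelled_scores(v, is_pos))
  expect_true(rc$positive_low)
  expect_gte(rc$auc, 0.5)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  v <- rnorm(30, 1)
  is_pos <- rep(c(TRUE, FALSE), 15)
  base <- roc_curve(labelled_scores(v, is_pos, TRUE))$auc
  for (f in list(function(x) exp(x), function(x) x^3, function(x) 5 * x - 2))
    expect_equal(roc_curve(labelled_scores(f(v), is_pos, TRUE))$auc, base)
})

test_that("sensitivity at 100% specificity uses strict thresholds", {
  # {1,2} below the responder minimum 2.5; the tie case excluded
  expect_equal(sensitivity_at_full_specificity(
    labelled_scores(c(1, 2, 3, 2.5, 4, 5),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    positive_low = TRUE)), 2 / 3)
  # a non-responder tied with the responder minimum is NOT a detection
  expect_equal(sensitivity_at_full_specificity(
    labelled_scores(c(2.5, 1, 2.5, 4), c(TRUE, TRUE, FALSE, FALSE),
                    positive_low = TRUE)), 1 / 2)
  # full separation and full overlap
  expect_equal(sensitivity_at_full_specificity(
    labelled_scores(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), TRUE)), 1)
  expect_equal(sensitivity_at_full_specificity(
    labelled_scores(c(2, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE), TRUE)), 0)
})

test_that("sens@100%spec equals the brute-force threshold scan", {
  set.seed(23)
  for (i in 1:300) {
    n_pos <- sample(2:8, 1); n_neg <- sample(2:8, 1)
    v <- round(rnorm(n_pos + n_neg), 1)
    is_pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    for (low in c(TRUE, FALSE)) {
      got <- roc_curve(labelled_scores(v, is_pos, low))$sens_at_full_spec
      expect_equal(got, sens_full_spec_oracle(v, is_pos, low))
    }
  }
})

test_that("permuted labels give chance-level AUC", {
  set.seed(99)
  v <- rnorm(2000)
  is_pos <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(roc_curve(labelled_scores(v, is_pos, TRUE))$auc - 0.5), 0.05)
})

test_that("degenerate label vectors are rejected", {
  expect_error(labelled_scores(1:4, rep(TRUE, 4)), "both classes")
  expect_error(labelled_scores(1:3, c(TRUE, FALSE)), "length mismatch")
})
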