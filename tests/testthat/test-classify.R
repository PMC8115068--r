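# small synthetic feature sets keep the zoo tests fast; the full-scale
# 2847-voxel checks live in test-acceptance.R
make_features <- function(n_per = 8L, V = 60L, sep = 0, seed = 1L) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n_per)
  x <- matrix(rnorm(2 * n_per * V, 0.013, 0.003), 2 * n_per, V) +
    outer(ifelse(y > 0, -sep, sep), rep(1, V))
  feature_matrix(x, y)
}

test_that("extract_feature_matrix flattens striatal maps with +/-1 labels", {
  scans <- memo("clf_scans", function()
    simulate_cohort(small_design(), mask = small_mask(), seed = 61L))
  fm <- extract_feature_matrix(scans)
  expect_equal(dim(fm$x), c(8L, 120L))     # controls dropped
  expect_setequal(unique(fm$y), c(-1, 1))
  expect_equal(sum(fm$y == 1), 4L)         # non-responders are +1
  expect_equal(fm$voxel_idx, mask_region_idx(small_mask(), "striatum"))
  # identical scans give identical rows
  fm2 <- extract_feature_matrix(list(scans[[3L]], scans[[3L]]))
  expect_equal(fm2$x[1L, ], fm2$x[2L, ])
})

test_that("full-size masks give the canonical 2847-voxel feature dimension", {
  m <- make_striatal_mask()
  expect_length(mask_region_idx(m, "striatum"), 2847L)
})

test_that("combine_cohorts concatenates compatible cohorts", {
  a <- make_features(13L, 40L); b <- make_features(12L, 40L, seed = 2L)
  ab <- combine_cohorts(a, b)
  expect_equal(nrow(ab$x), 50L)
  expect_equal(ab$y, c(a$y, b$y))
  empty <- feature_matrix(a$x[0, , drop = FALSE], numeric(0))
  expect_identical(combine_cohorts(a, empty), a)
  wrong <- make_features(4L, 39L)
  expect_error(combine_cohorts(a, wrong), "different masks")
})

test_that("every family separates an easy problem and is labelled correctly", {
  fm <- make_features(sep = 0.004)
  fams <- c("bernoulli_logistic", "linear_svm", "rbf_svm", "knn", "gp_probit")
  for (fam in fams) {
    cv <- loocv_evaluate(model_spec(fam), fm, seeds = 1L)
    expect_gte(cv$mean_auc, 0.95)
    expect_equal(cv$sd_auc, 0)
    expect_false(model_spec(fam)$stochastic)
  }
  cv_rf <- loocv_evaluate(model_spec("random_forest", n_trees = 30L), fm,
                          seeds = 1:2)
  expect_gte(cv_rf$mean_auc, 0.9)
  expect_true(model_spec("random_forest")$stochastic)
})

test_that("deterministic families are seed-invariant", {
  fm <- make_features(6L, 30L, sep = 0.002)
  cv <- loocv_evaluate(model_spec("linear_svm"), fm, seeds = c(1L, 999L))
  expect_equal(cv$auc[1L], cv$auc[2L])
  expect_equal(cv$sd_auc, 0)
})

test_that("the held-out subject's label cannot influence its own score", {
  fm <- make_features(5L, 30L, sep = 0.002, seed = 7L)
  fm_poison <- fm
  fm_poison$y[1L] <- -fm_poison$y[1L]
  for (fam in c("linear_svm", "knn")) {
    spec <- model_spec(fam)
    # pooled LOO: subject 1 is scored by a fit that never sees subject 1
    sc <- loocv_evaluate(spec, fm, seeds = 1L, auc_method = "pooled")$scores
    scp <- loocv_evaluate(spec, fm_poison, seeds = 1L,
                          auc_method = "pooled")$scores
    expect_equal(sc[1L], scp[1L], tolerance = 1e-8)
  }
})

test_that("pooled-score AUC goes through the roc_curve code path", {
  fm <- make_features(5L, 30L, sep = 0.001, seed = 3L)
  cv <- loocv_evaluate(model_spec("knn"), fm, seeds = 1L,
                       auc_method = "pooled")
  expect_equal(cv$auc,
               roc_curve(labelled_scores(cv$scores, fm$y == 1,
                                         positive_low = FALSE))$auc)
})

test_that("degenerate inputs are rejected", {
  fm <- make_features(5L, 10L)
  expect_error(feature_matrix(fm$x, fm$y[-1L]), "one label per subject")
  expect_error(feature_matrix(fm$x, rep(2, 10)), "\\+1/-1")
  x_na <- fm$x; x_na[1L, 1L] <- NA
  expect_error(feature_matrix(x_na, fm$y), "missing")
  expect_error(loocv_evaluate(model_spec("knn"),
                              feature_matrix(fm$x[1:3, ], fm$y[1:3])),
               "N >= 4")
  expect_error(model_spec("linear_svm", alpha = 0), "alpha")
})
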