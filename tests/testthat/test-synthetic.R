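sched <- frame_schedule_dataset1()
ref <- make_reference_tac(sched)

test_that("tissue construction is Patlak-consistent and exactly invertible", {
  # ki = 0, v' = 1 reproduces the reference curve
  expect_equal(make_tissue_tac(ref, 0, 1)$activity, ref$activity)
  # noiseless recovery across parameter grid and both schedules
  for (s in list(sched, frame_schedule_dataset2())) {
    r <- make_reference_tac(s)
    for (ki in c(0.005, 0.01, 0.02)) for (vp in c(0.2, 0.5, 1)) {
      f <- fit_patlak(patlak_transform(make_tissue_tac(r, ki, vp), r), 30)
      expect_equal(f$ki_cer, ki, tolerance = 1e-6)
      expect_equal(f$intercept, vp, tolerance = 1e-6)
    }
  }
})

test_that("mismatched schedules and bad noise are rejected", {
  r2 <- make_reference_tac(frame_schedule_dataset2())
  tt <- make_tissue_tac(ref, 0.01, 0.5)
  expect_error(patlak_transform(tt, r2), "mismatch")
  expect_error(make_tissue_tac(ref, 0.01, 0.5, noise_cv = -1), ">= 0")
  expect_error(make_tissue_tac(ref, -0.01, 0.5), ">= 0")
})

test_that("frame-noise calibration hits the target CV on late frames", {
  n_rep <- 100
  acts <- sapply(seq_len(n_rep), function(i)
    make_tissue_tac(ref, 0.012, 0.5, noise_cv = 0.05, rng_seed = i)$activity)
  late <- which(sched$duration_s == max(sched$duration_s))
  cv <- apply(acts[late, ], 1L, stats::sd) / rowMeans(acts[late, ])
  # Monte-Carlo: every late-frame empirical CV within 30% of the 5% target
  expect_true(all(abs(cv - 0.05) / 0.05 < 0.30))
  # early (short) frames are noisier by the 1/duration variance scaling
  early_cv <- stats::sd(acts[2L, ]) / mean(acts[2L, ])
  expect_gt(early_cv, 2 * 0.05)
})

test_that("noise seeding is reproducible and leaves the global RNG intact", {
  a <- make_tissue_tac(ref, 0.01, 0.5, 0.05, rng_seed = 42L)
  set.seed(7); before <- rnorm(1)
  b <- make_tissue_tac(ref, 0.01, 0.5, 0.05, rng_seed = 42L)
  set.seed(7)
  expect_identical(before, rnorm(1))
  expect_identical(a$activity, b$activity)
})

test_that("cohort generator recovers configured effect sizes", {
  d08 <- cohort_design(n_control = 2L, n_responder = 200L,
                       n_nonresponder = 200L)
  set.seed(1)
  tr <- draw_cohort_truth(d08)
  d_hat <- cohens_d(tr$ki_associative[tr$group == "responder"],
                    tr$ki_associative[tr$group == "nonresponder"])$cohens_d
  expect_lt(abs(d_hat - 1.1), 0.15)     # configured associative d = 1.1

  d0 <- cohort_design(n_control = 2L, n_responder = 200L,
                      n_nonresponder = 200L,
                      cohens_d = c(limbic = 0, associative = 0,
                                   sensorimotor = 0))
  set.seed(2)
  tr0 <- draw_cohort_truth(d0)
  d_null <- cohens_d(tr0$ki_associative[tr0$group == "responder"],
                     tr0$ki_associative[tr0$group == "nonresponder"])$cohens_d
  expect_lt(abs(d_null), 0.2)
})

test_that("identical seeds give bit-identical cohorts", {
  d <- small_design()
  a <- simulate_cohort(d, mask = small_mask(), seed = 5L)
  b <- simulate_cohort(d, mask = small_mask(), seed = 5L)
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
  expect_identical(cohort_truth_table(a), cohort_truth_table(b))
  c3 <- simulate_cohort(d, mask = small_mask(), seed = 6L)
  expect_false(identical(a[[1]]$data, c3[[1]]$data))
})

test_that("empty groups are rejected", {
  d <- small_design()
  d$n[["responder"]] <- 0L
  expect_error(draw_cohort_truth(d), "non-empty")
})

test_that("responders sit above non-responders in expectation", {
  set.seed(3)
  tr <- draw_cohort_truth(cohort_design(n_control = 2L, n_responder = 150L,
                                        n_nonresponder = 150L))
  for (cc in c("ki_limbic", "ki_associative", "ki_sensorimotor"))
    expect_gt(mean(tr[[cc]][tr$group == "responder"]),
              mean(tr[[cc]][tr$group == "nonresponder"]))
})

test_that("test-retest generator honours the within-subject CV", {
  # within-subject CV = 0, no noise: %VAR = 0 and ICC = 1 downstream
  d0 <- noiseless_design(within_subject_cv = 0, n_control = 6L)
  tr <- simulate_test_retest(d0, mask = small_mask(), seed = 9L)
  ki_t <- sapply(tr$test, function(s) roi_ki(s, "striatum")$ki_cer)
  ki_r <- sapply(tr$retest, function(s) roi_ki(s, "striatum")$ki_cer)
  pm <- paired_measurements(ki_t, ki_r)
  expect_equal(percent_var(pm)$mean_var, 0, tolerance = 1e-9)
  expect_equal(icc_two_way(pm)$icc, 1, tolerance = 1e-9)
  expect_identical(vapply(tr$retest, `[[`, "", "session"),
                   rep("retest", length(tr$retest)))

  # within-subject CV = 2%: mean whole-striatum %VAR stays below 10
  d2 <- noiseless_design(within_subject_cv = 0.02, n_control = 8L,
                         n_responder = 1L, n_nonresponder = 1L)
  tr2 <- simulate_test_retest(d2, mask = small_mask(), seed = 10L)
  ki_t2 <- sapply(tr2$test, function(s) roi_ki(s, "striatum")$ki_cer)
  ki_r2 <- sapply(tr2$retest, function(s) roi_ki(s, "striatum")$ki_cer)
  expect_lt(percent_var(paired_measurements(ki_t2, ki_r2))$mean_var, 10)
})

test_that("mask geometry is labelled and sized as configured", {
  m <- make_striatal_mask()
  expect_equal(sum(m$data %in% 1:3), 2847L)
  expect_setequal(unique(as.integer(m$data)), 0:5)
  expect_equal(length(mask_region_idx(m, "striatum")),
               length(mask_region_idx(m, "limbic")) +
                 length(mask_region_idx(m, "associative")) +
                 length(mask_region_idx(m, "sensorimotor")))
  m2 <- make_striatal_mask(n_striatal = 300L)
  expect_equal(sum(m2$data %in% 1:3), 300L)
})
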