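sched <- frame_schedule_dataset1()
ref <- make_reference_tac(sched)

test_that("patlak_transform produces the reference-normalised coordinates", {
  as_tissue <- function(act) tissue_tac(sched, act)
  # identical curves: y = 1 everywhere the reference is positive
  p <- patlak_transform(as_tissue(ref$activity), ref)
  expect_equal(p$y, rep(1, 32))
  # doubled curve: y = 2, and the fitted slope is 0
  p2 <- patlak_transform(as_tissue(2 * ref$activity), ref)
  expect_equal(p2$y, rep(2, 32))
  f2 <- fit_patlak(p2, 30)
  expect_equal(f2$ki_cer, 0, tolerance = 1e-12)
  expect_equal(f2$intercept, 2, tolerance = 1e-12)
  # Patlak-consistent construction is collinear: y = 0.01 x + 0.5
  p3 <- patlak_transform(make_tissue_tac(ref, 0.01, 0.5), ref)
  expect_lt(max(abs(p3$y - (0.01 * p3$x + 0.5))), 1e-6)
  # x is non-decreasing after the reference peak
  pk <- which.max(ref$activity)
  expect_true(all(diff(p$x[pk:32]) >= 0))
})

test_that("zero reference activity after the first frame is reported by frame", {
  act <- ref$activity
  act[20] <- 0
  badref <- reference_tac(sched, act)
  expect_error(patlak_transform(tissue_tac(sched, act), badref), "frame\\(s\\) 20")
})

test_that("fit_patlak solves exact and weighted lines", {
  pts <- structure(list(x = c(1, 2, 3), y = c(1, 3, 5),
                        t_mid_min = c(40, 50, 60), dur_min = c(5, 5, 5)),
                   class = "patlak_points")
  f <- fit_patlak(pts, t_star = 30)
  expect_equal(f$ki_cer, 2)
  expect_equal(f$intercept, -1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points_used, 3L)
  # too few usable points
  expect_error(fit_patlak(pts, t_star = 45), "need >= 3")
  # duration weighting reproduces an exact line too
  f2 <- fit_patlak(pts, t_star = 30, weights = "duration")
  expect_equal(f2$ki_cer, 2)
})

test_that("slope and intercept are invariant to common rescaling of both curves", {
  tt <- make_tissue_tac(ref, 0.012, 0.6, noise_cv = 0.05, rng_seed = 3L)
  f1 <- fit_patlak(patlak_transform(tt, ref), 30)
  ref_s <- reference_tac(sched, 3.7 * ref$activity)
  tt_s <- tissue_tac(sched, 3.7 * tt$activity)
  f2 <- fit_patlak(patlak_transform(tt_s, ref_s), 30)
  expect_equal(f2$ki_cer, f1$ki_cer, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-12)
})

test_that("noisy ROI recovery is unbiased to within 5%", {
  kis <- vapply(1:100, function(i) {
    tt <- make_tissue_tac(ref, 0.013, 0.5, noise_cv = 0.05, rng_seed = 100 + i)
    fit_patlak(patlak_transform(tt, ref), 30)$ki_cer
  }, numeric(1))
  expect_lt(abs(mean(kis) - 0.013) / 0.013, 0.05)
})

noiseless_scan <- function() {
  memo("noiseless_scan", function()
    simulate_cohort(noiseless_design(), mask = small_mask(), seed = 31L)[[3L]])
}

test_that("roi_ki equals the single-voxel fit on homogeneous noiseless regions", {
  s <- noiseless_scan()
  f_roi <- roi_ki(s, "associative")
  idx <- mask_region_idx(s$mask, "associative")
  flat <- matrix(s$data, ncol = nframes(s$schedule))
  ref_s <- reference_tac(s$schedule, colMeans(
    matrix(s$data, ncol = nframes(s$schedule))[
      mask_region_idx(s$mask, "cerebellum"), , drop = FALSE]))
  f_vox <- fit_patlak(patlak_transform(
    tissue_tac(s$schedule, flat[idx[1L], ]), ref_s), 30)
  expect_equal(f_roi$ki_cer, f_vox$ki_cer, tolerance = 1e-9)
  expect_equal(f_roi$ki_cer, s$truth_roi$ki_associative, tolerance = 1e-6)
})

test_that("two equal voxel populations average to the midpoint Ki", {
  # analytic oracle: Patlak-linear curves are affine in ki, so the mean TAC
  # of ki = 0.008 and ki = 0.012 voxels fits to exactly 0.010
  t1 <- make_tissue_tac(ref, 0.008, 0.5)
  t2 <- make_tissue_tac(ref, 0.012, 0.5)
  mix <- tissue_tac(sched, (t1$activity + t2$activity) / 2)
  f <- fit_patlak(patlak_transform(mix, ref), 30)
  expect_equal(f$ki_cer, 0.010, tolerance = 1e-9)
})

test_that("whole-striatum fit equals the voxel-weighted mix of subdivisions", {
  s <- noiseless_scan()
  f_all <- roi_ki(s, "striatum")
  # oracle: fit the voxel-count-weighted mean of the subdivision mean TACs
  nf <- nframes(s$schedule)
  flat <- matrix(s$data, ncol = nf)
  regs <- striatal_region_names()
  counts <- vapply(regs, function(r) length(mask_region_idx(s$mask, r)), 0L)
  tacs <- vapply(regs, function(r)
    colMeans(flat[mask_region_idx(s$mask, r), , drop = FALSE]),
    numeric(nf))
  mean_tac <- as.numeric(tacs %*% (counts / sum(counts)))
  ref_s <- reference_tac(s$schedule,
    colMeans(flat[mask_region_idx(s$mask, "cerebellum"), , drop = FALSE]))
  f_oracle <- fit_patlak(patlak_transform(tissue_tac(s$schedule, mean_tac),
                                          ref_s), 30)
  expect_equal(f_all$ki_cer, f_oracle$ki_cer, tolerance = 1e-12)
})

test_that("parametric map reproduces voxel ground truth on noiseless data", {
  s <- simulate_cohort(small_design(noise_cv = 0, voxel_noise_cv = 0),
                       mask = small_mask(), seed = 77L)[[4L]]
  m <- parametric_map(s)
  idx <- mask_region_idx(s$mask, "striatum")
  expect_equal(m$n_failed, 0L)
  expect_lt(max(abs(m$ki[idx] - s$truth_ki) / pmax(s$truth_ki, 1e-9)), 1e-6)
  # extra-striatal brain was generated with ki 0
  eidx <- mask_region_idx(s$mask, "extrastriatal")
  expect_lt(max(abs(m$ki[eidx])), 1e-9)
  # background untouched
  expect_true(all(m$ki[s$mask$data == 0] == 0))
})

test_that("empty or unknown regions raise errors", {
  s <- noiseless_scan()
  expect_error(roi_ki(s, "thalamus"), "unknown region")
  expect_error(roi_ki(s, 17L), "empty region")
})
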