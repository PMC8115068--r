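#' Cohort design for the synthetic-data generator
#'
#' Describes the "stated world" every simulation draws from: group sizes,
#' per-subdivision dopamine-synthesis capacity (Patlak slope Ki, 1/min) with
#' between-subject spread, responder vs. non-responder separation expressed
#' as Cohen's d per subdivision, test-retest within-subject variability, and
#' the noise structure of the dynamic data.
#'
#' Responders share the control-group Ki distribution; non-responders are
#' shifted down by `cohens_d * between_subject_sd` in each subdivision, so the
#' population effect size equals the configured d with responders elevated.
#'
#' @param n_control,n_responder,n_nonresponder Subjects per group
#'   (defaults 13/13/13).
#' @param ki_mean Named per-subdivision mean Ki for controls/responders,
#'   1/min.
#' @param between_subject_sd Named per-subdivision between-subject SD of Ki,
#'   1/min.
#' @param cohens_d Named per-subdivision responder minus non-responder
#'   effect size (>= 0 means responders elevated).
#' @param subject_corr Correlation of a subject's Ki deviations across
#'   subdivisions (shared subject factor), in `[0, 1]`.
#' @param within_subject_cv Test-retest within-subject coefficient of
#'   variation of true Ki (default 0.02).
#' @param noise_cv ROI-level multiplicative noise CV on the longest frames:
#'   applied as a per-region shared frame-noise component (default 0.05).
#' @param voxel_noise_cv Additional independent per-voxel frame-noise CV on
#'   the longest frames (default 0.15).
#' @param voxel_jitter_cv CV of the static voxel-to-voxel Ki heterogeneity
#'   within a subdivision (default 0.05).
#' @param v_prime Patlak intercept shared by all tissue voxels (default 0.5).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_control = 13L, n_responder = 13L,
                          n_nonresponder = 13L,
                          ki_mean = c(limbic = 0.0125, associative = 0.013,
                                      sensorimotor = 0.014),
                          between_subject_sd = c(limbic = 0.00125,
                                                 associative = 0.0013,
                                                 sensorimotor = 0.0014),
                          cohens_d = c(limbic = 0.8, associative = 1.1,
                                       sensorimotor = 0.6),
                          subject_corr = 0.7,
                          within_subject_cv = 0.02,
                          noise_cv = 0.05,
                          voxel_noise_cv = 0.15,
                          voxel_jitter_cv = 0.05,
                          v_prime = 0.5) {
  subdiv <- striatal_region_names()
  stopifnot(all(subdiv %in% names(ki_mean)),
            all(subdiv %in% names(between_subject_sd)),
            all(subdiv %in% names(cohens_d)),
            all(ki_mean > 0), all(between_subject_sd >= 0),
            subject_corr >= 0, subject_corr <= 1,
            within_subject_cv >= 0, within_subject_cv < 1,
            noise_cv >= 0, noise_cv < 1,
            voxel_noise_cv >= 0, voxel_jitter_cv >= 0, v_prime >= 0)
  structure(list(n = c(control = as.integer(n_control),
                       responder = as.integer(n_responder),
                       nonresponder = as.integer(n_nonresponder)),
                 ki_mean = ki_mean[subdiv],
                 between_subject_sd = between_subject_sd[subdiv],
                 cohens_d = cohens_d[subdiv],
                 subject_corr = subject_corr,
                 within_subject_cv = within_subject_cv,
                 noise_cv = noise_cv,
                 voxel_noise_cv = voxel_noise_cv,
                 voxel_jitter_cv = voxel_jitter_cv,
                 v_prime = v_prime),
            class = "cohort_design")
}

#' Draw subject-level ground-truth Ki for a cohort
#'
#' Samples each subject's true per-subdivision Ki from its group
#' distribution, with a shared subject factor inducing correlation
#' `subject_corr` between subdivisions.  Used internally by
#' [simulate_cohort()]; exposed so that large effect-size recovery studies
#' can run without building voxel data.
#'
#' @param design A [cohort_design()].
#' @return Data frame: `subject_id`, `group`, one `ki_<subdivision>` column
#'   per subdivision (1/min).
#' @export
draw_cohort_truth <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(design$n <= 0L)) stop("all groups must be non-empty")
  subdiv <- striatal_region_names()
  rows <- list()
  sid <- 0L
  for (g in names(design$n)) {
    mu <- design$ki_mean
    if (g == "nonresponder")
      mu <- mu - design$cohens_d * design$between_subject_sd
    for (i in seq_len(design$n[[g]])) {
      sid <- sid + 1L
      z_shared <- stats::rnorm(1)
      z_own <- stats::rnorm(length(subdiv))
      dev <- sqrt(design$subject_corr) * z_shared +
        sqrt(1 - design$subject_corr) * z_own
      ki <- pmax(mu + design$between_subject_sd * dev, 1e-4)
      rows[[sid]] <- data.frame(subject_id = sprintf("sub-%03d", sid),
                                group = g, t(stats::setNames(ki, paste0("ki_", subdiv))))
    }
  }
  do.call(rbind, rows)
}

#' Container for one dynamic PET scan
#'
#' @param subject_id Character id.
#' @param group `"control"`, `"responder"` or `"nonresponder"`.
#' @param session `"test"` or `"retest"`.
#' @param data 4D numeric array, `dim(mask) x nframes`.
#' @param sched A [frame_schedule()].
#' @param mask A [make_striatal_mask()] mask volume.
#' @param truth_ki Per-voxel true Ki for all striatal voxels (1/min), aligned
#'   with `mask_region_idx(mask, "striatum")`, or `NULL` for scans read from
#'   disk without ground truth.
#' @param truth_roi Optional named list of subdivision-level true Ki and
#'   `v_prime`.
#' @return A `subject_scan` object.
#' @export
subject_scan <- function(subject_id, group, session, data, sched, mask,
                         truth_ki = NULL, truth_roi = NULL) {
  stopifnot(inherits(sched, "frame_schedule"),
            inherits(mask, "mask_volume"))
  d <- dim(data)
  if (length(d) != 4L || !all(d[1:3] == dim(mask$data)) ||
      d[4L] != nframes(sched))
    stop(sprintf(
      "scan dims [%s] inconsistent with mask [%s] and %d-frame schedule",
      paste(d, collapse = "x"), paste(dim(mask$data), collapse = "x"),
      nframes(sched)))
  if (any(data < 0)) stop("scan activity must be non-negative")
  if (!is.null(truth_ki) &&
      length(truth_ki) != length(mask_region_idx(mask, "striatum")))
    stop("truth_ki must cover every striatal voxel")
  structure(list(subject_id = subject_id, group = group, session = session,
                 data = data, schedule = sched, mask = mask,
                 truth_ki = truth_ki, truth_roi = truth_roi),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s [%s, %s], %s voxels x %d frames\n",
              x$subject_id, x$group, x$session,
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4L]))
  invisible(x)
}

# per-frame multiplicative noise SD scaled so the longest frames sit at `cv`
frame_noise_sd <- function(sched, cv) {
  cv * sqrt(max(sched$duration_s) / sched$duration_s)
}

# Build the 4D array for one subject.  Tissue curves are affine in
# (ki, v_prime) on the frame grid, so voxel TACs are assembled from the two
# basis vectors (cumulative-integral and reference) by outer products.
build_scan_array <- function(truth_row, design, sched, mask, ref) {
  labs <- region_labels()
  dims <- dim(mask$data)
  nf <- nframes(sched)
  basis_int <- cumtrapz_frames(sched, ref$activity)  # nf
  basis_ref <- ref$activity
  arr <- array(0, c(prod(dims), nf))

  stri_idx <- mask_region_idx(mask, "striatum")
  stri_lab <- mask$data[stri_idx]
  ki_sub <- unlist(truth_row[paste0("ki_", striatal_region_names())])
  ki_vox <- ki_sub[stri_lab] *
    (1 + stats::rnorm(length(stri_idx), 0, design$voxel_jitter_cv))
  ki_vox <- pmax(ki_vox, 0)
  arr[stri_idx, ] <- outer(ki_vox, basis_int) +
    design$v_prime * rep(basis_ref, each = length(stri_idx))

  cer_idx <- mask_region_idx(mask, "cerebellum")
  arr[cer_idx, ] <- rep(basis_ref, each = length(cer_idx))
  exs_idx <- mask_region_idx(mask, "extrastriatal")
  arr[exs_idx, ] <- design$v_prime * rep(basis_ref, each = length(exs_idx))

  sd_roi <- frame_noise_sd(sched, design$noise_cv)
  sd_vox <- frame_noise_sd(sched, design$voxel_noise_cv)
  for (lab in setdiff(unname(labs), 0L)) {
    idx <- which(mask$data == lab)
    if (!length(idx)) next
    fac <- rep(1 + stats::rnorm(nf, 0, sd_roi), each = length(idx))
    if (design$voxel_noise_cv > 0)
      fac <- fac * (1 + stats::rnorm(length(idx) * nf,
                                     rep(0, length(idx) * nf),
                                     rep(sd_vox, each = length(idx))))
    arr[idx, ] <- arr[idx, ] * fac
  }
  arr <- pmax(arr, 0)
  list(data = array(arr, c(dims, nf)),
       ki_vox = stats::setNames(ki_vox, NULL))
}

#' Simulate a cross-sectional dynamic PET cohort
#'
#' Draws subject-level true Ki per group and subdivision via
#' [draw_cohort_truth()], then builds each subject's 4D dynamic volume:
#' voxel Ki = subdivision Ki times small log-normal-like spatial jitter,
#' voxel TACs from the Patlak-consistent construction of
#' [make_tissue_tac()], cerebellar voxels carrying the reference curve, and
#' two multiplicative Gaussian frame-noise components (shared per region at
#' the design's ROI-level CV; independent per voxel).  All randomness flows
#' from `seed`; identical seeds give bit-identical cohorts.
#'
#' @param design A [cohort_design()].
#' @param sched A [frame_schedule()] (default the 32-frame 95-min schedule).
#' @param mask A mask volume (default [make_striatal_mask()]).
#' @param seed Integer seed.
#' @param session Session tag stamped on every scan.
#' @return List of [subject_scan()] objects with ground truth attached.
#' @export
simulate_cohort <- function(design, sched = frame_schedule_dataset1(),
                            mask = make_striatal_mask(), seed = 1L,
                            session = "test") {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  truth <- draw_cohort_truth(design)
  simulate_scans_from_truth(truth, design, sched, mask, session)
}

simulate_scans_from_truth <- function(truth, design, sched, mask, session) {
  ref <- make_reference_tac(sched)
  scans <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    built <- build_scan_array(truth[i, ], design, sched, mask, ref)
    roi <- as.list(unlist(truth[i, paste0("ki_", striatal_region_names())]))
    roi$v_prime <- design$v_prime
    scans[[i]] <- subject_scan(truth$subject_id[i], truth$group[i], session,
                               built$data, sched, mask,
                               truth_ki = built$ki_vox, truth_roi = roi)
  }
  scans
}

#' Simulate a paired test-retest cohort
#'
#' Draws one set of subject-level true Ki, then perturbs each subject's Ki by
#' a multiplicative within-subject factor `1 + N(0, within_subject_cv)` for
#' the retest session and rebuilds the dynamic data independently for both
#' sessions.
#'
#' @inheritParams simulate_cohort
#' @return List with elements `test` and `retest`, each a list of
#'   [subject_scan()] objects in the same subject order.
#' @export
simulate_test_retest <- function(design, sched = frame_schedule_dataset1(),
                                 mask = make_striatal_mask(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  truth <- draw_cohort_truth(design)
  ki_cols <- paste0("ki_", striatal_region_names())
  truth_re <- truth
  for (cc in ki_cols)
    truth_re[[cc]] <- pmax(truth[[cc]] *
      (1 + stats::rnorm(nrow(truth), 0, design$within_subject_cv)), 1e-4)
  list(test = simulate_scans_from_truth(truth, design, sched, mask, "test"),
       retest = simulate_scans_from_truth(truth_re, design, sched, mask,
                                          "retest"))
}

#' Ground-truth table of a simulated cohort
#'
#' @param scans List of [subject_scan()]s from [simulate_cohort()].
#' @return Data frame with subject metadata and per-subdivision true Ki.
#' @export
cohort_truth_table <- function(scans) {
  do.call(rbind, lapply(scans, function(s) {
    roi <- s$truth_roi
    data.frame(subject_id = s$subject_id, group = s$group,
               session = s$session,
               ki_limbic = roi$ki_limbic, ki_associative = roi$ki_associative,
               ki_sensorimotor = roi$ki_sensorimotor)
  }))
}
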