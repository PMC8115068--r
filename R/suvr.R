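#' Static late-window image from a dynamic scan
#'
#' Duration-weighted mean of all frames overlapping the requested window;
#' frames only partly inside the window contribute in proportion to their
#' overlap.  Emulates the single static acquisition of the simplified
#' protocol by averaging the corresponding stretch of the dynamic scan.
#'
#' @param scan A [subject_scan()].
#' @param window_start_min Window start, minutes post-injection.
#' @param window_length_min Window length, minutes.
#' @return 3D numeric array of mean activity (kBq/mL).
#' @export
static_frame <- function(scan, window_start_min, window_length_min) {
  stopifnot(inherits(scan, "subject_scan"), window_length_min > 0)
  sched <- scan$schedule
  w0 <- window_start_min * 60
  w1 <- w0 + window_length_min * 60
  total <- sum(sched$duration_s)
  if (w0 < 0 || w1 > total + 1e-9)
    stop(sprintf("window [%g, %g] min outside acquisition (0-%g min)",
                 window_start_min, window_start_min + window_length_min,
                 total / 60))
  f0 <- sched$start_s
  f1 <- sched$start_s + sched$duration_s
  overlap <- pmax(0, pmin(f1, w1) - pmax(f0, w0))
  if (sum(overlap) <= 0) stop("window overlaps no frame")
  wts <- overlap / sum(overlap)
  flat <- matrix(scan$data, ncol = nframes(sched))
  array(as.numeric(flat %*% wts), dim(scan$mask$data))
}

#' Simplified windowed uptake ratio (SUVR)
#'
#' Ratio of the mean activity of a (striatal) region to the mean cerebellar
#' activity in a late static window - the simplified, scan-shortening proxy
#' for dynamic Ki.  Window start (conventionally 60, 75 or 90 min) and length
#' are always explicit parameters.
#'
#' @inheritParams static_frame
#' @param region Region name or label(s) (see [roi_ki()]).
#' @return A `suvr_result`: `region`, `window_start_min`,
#'   `window_length_min`, `suvrc`.
#' @export
compute_suvrc <- function(scan, region, window_start_min,
                          window_length_min = 10) {
  vol <- static_frame(scan, window_start_min, window_length_min)
  ridx <- mask_region_idx(scan$mask, region)
  cidx <- mask_region_idx(scan$mask, "cerebellum")
  if (!length(ridx)) stop("empty region: ", region)
  if (!length(cidx)) stop("mask has no cerebellum label")
  denom <- mean(vol[cidx])
  if (denom <= 0) stop("zero or negative cerebellar mean in window")
  structure(list(region = if (is.character(region)) region else
                   paste(region, collapse = "+"),
                 window_start_min = window_start_min,
                 window_length_min = window_length_min,
                 suvrc = mean(vol[ridx]) / denom),
            class = "suvr_result")
}

#' Static-image signal-to-noise ratio
#'
#' Mean signal over the striatal labels divided by the standard deviation of
#' the signal over extra-striatal brain voxels.
#'
#' @param static_vol 3D array from [static_frame()].
#' @param mask A mask volume.
#' @return An `snr_result` with element `snr`.
#' @export
compute_snr <- function(static_vol, mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sidx <- mask_region_idx(mask, "striatum")
  eidx <- mask_region_idx(mask, "extrastriatal")
  if (!length(sidx) || !length(eidx))
    stop("mask must contain striatal and extra-striatal labels")
  s <- stats::sd(static_vol[eidx])
  if (s <= 0)
    stop("zero extra-striatal SD (degenerate noiseless image)")
  structure(list(snr = mean(static_vol[sidx]) / s), class = "snr_result")
}
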