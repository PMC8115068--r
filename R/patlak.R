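#' Patlak-Gjedde plot coordinates
#'
#' Transforms a target-tissue TAC and a reference-region TAC into the
#' reference-input Patlak coordinates: abscissa "normalised time"
#' \eqn{x(t) = \int_0^t C_R d\tau / C_R(t)} (minutes) and ordinate
#' \eqn{y(t) = C_T(t)/C_R(t)}, one point per frame at the frame midpoint.
#' The cumulative integral uses the trapezoid rule over frame midpoints with
#' the boundary \eqn{C_R(0) = 0}.  For an irreversibly trapped tracer the
#' points become linear after equilibration, with slope equal to the influx
#' constant Ki.
#'
#' @param tissue A [tissue_tac()].
#' @param ref A [reference_tac()] on the same schedule.
#' @return A `patlak_points` object: `x`, `y`, `t_mid_min`, `dur_min`.
#' @export
patlak_transform <- function(tissue, ref) {
  stopifnot(inherits(tissue, "tac"), inherits(ref, "reference_tac"))
  sched <- ref$schedule
  if (nframes(tissue$schedule) != nframes(sched))
    stop(sprintf("frame-count mismatch: tissue %d vs reference %d",
                 nframes(tissue$schedule), nframes(sched)))
  bad <- which(ref$activity[-1L] <= 0) + 1L
  if (length(bad))
    stop("non-positive reference activity in frame(s) ",
         paste(bad, collapse = ", "))
  ok <- ref$activity > 0
  x <- y <- rep(NA_real_, nframes(sched))
  x[ok] <- cumtrapz_frames(sched, ref$activity)[ok] / ref$activity[ok]
  y[ok] <- tissue$activity[ok] / ref$activity[ok]
  structure(list(x = x, y = y, t_mid_min = frame_mid_min(sched),
                 dur_min = frame_dur_min(sched)),
            class = "patlak_points")
}

#' Fit the linear portion of a Patlak plot
#'
#' Ordinary or frame-duration-weighted least squares through the Patlak
#' points with midpoint time at or after `t_star`.  The slope is reported as
#' the influx constant `ki_cer` (1/min); the intercept estimates the
#' effective distribution volume.
#'
#' @param points A [patlak_transform()] result.
#' @param t_star First fitted time, minutes post-injection (default 30).
#' @param weights `"uniform"` (default) or `"duration"` (weight = frame
#'   duration, down-weighting short noisy frames).
#' @return A `patlak_fit`: `ki_cer`, `intercept`, `t_star`, `n_points_used`,
#'   `r_squared`, `residual_sd`, `weights`.
#' @export
fit_patlak <- function(points, t_star = 30, weights = c("uniform", "duration")) {
  stopifnot(inherits(points, "patlak_points"))
  weights <- match.arg(weights)
  use <- which(points$t_mid_min >= t_star & is.finite(points$x) &
                 is.finite(points$y))
  if (length(use) < 3L)
    stop(sprintf("only %d usable points at t >= %.1f min (need >= 3)",
                 length(use), t_star))
  x <- points$x[use]; y <- points$y[use]
  w <- if (weights == "duration") points$dur_min[use] else rep(1, length(use))
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  res <- y - (fit$coefficients[1L] + fit$coefficients[2L] * x)
  ybar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ybar)^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(w * res^2) / sst)) else 1
  structure(list(ki_cer = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 t_star = t_star, n_points_used = length(use),
                 r_squared = r2,
                 residual_sd = stats::sd(res),
                 weights = weights),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "<patlak_fit> ki_cer = %.5f /min, intercept = %.3f (t* = %g min, n = %d, R2 = %.3f)\n",
    x$ki_cer, x$intercept, x$t_star, x$n_points_used, x$r_squared))
  invisible(x)
}

# mean TAC over a set of linear voxel indices
scan_region_tac <- function(scan, region) {
  idx <- mask_region_idx(scan$mask, region)
  if (!length(idx)) stop("empty region: ", region)
  nf <- nframes(scan$schedule)
  flat <- matrix(scan$data, ncol = nf)
  colMeans(flat[idx, , drop = FALSE])
}

#' Region-level Ki from a dynamic scan
#'
#' Averages the TAC over all voxels of `region` ("average-then-fit"), takes
#' the mean cerebellar-label TAC as reference, and fits the Patlak line.
#'
#' @param scan A [subject_scan()].
#' @param region Region name (`"limbic"`, `"associative"`, `"sensorimotor"`,
#'   `"striatum"`, `"extrastriatal"`) or integer label(s).
#' @inheritParams fit_patlak
#' @return A `patlak_fit`.
#' @export
roi_ki <- function(scan, region, t_star = 30, weights = "uniform") {
  stopifnot(inherits(scan, "subject_scan"))
  ref <- reference_tac(scan$schedule, scan_region_tac(scan, "cerebellum"))
  tis <- tissue_tac(scan$schedule, scan_region_tac(scan, region))
  fit_patlak(patlak_transform(tis, ref), t_star = t_star, weights = weights)
}

#' Voxel-wise Patlak parametric map
#'
#' Fits an independent Patlak line in every non-background, non-cerebellar
#' voxel (ordinary least squares; the common reference abscissa lets all
#' voxels share one design matrix).  Voxels with non-finite data are set to
#' `NA` and counted.  An optional isotropic Gaussian smooth of each frame
#' (in voxel units) may be applied first; it is off by default.
#'
#' @param scan A [subject_scan()].
#' @inheritParams fit_patlak
#' @param smooth_sd_vox SD of an optional per-frame Gaussian pre-smooth, in
#'   voxels (0 = off).
#' @return A `parametric_map`: `ki` and `intercept` 3D arrays (background 0),
#'   `n_failed`, `t_star`.
#' @export
parametric_map <- function(scan, t_star = 30, weights = "uniform",
                           smooth_sd_vox = 0) {
  stopifnot(inherits(scan, "subject_scan"))
  sched <- scan$schedule
  nf <- nframes(sched)
  flat <- matrix(scan$data, ncol = nf)
  if (smooth_sd_vox > 0)
    for (j in seq_len(nf))
      flat[, j] <- gaussian_smooth_3d(array(flat[, j], dim(scan$mask$data)),
                                      smooth_sd_vox)
  ref_act <- scan_region_tac(scan, "cerebellum")
  if (any(ref_act[-1L] <= 0))
    stop("non-positive reference activity; cannot build parametric map")
  labs <- region_labels()
  fit_idx <- which(!scan$mask$data %in%
                     c(labs[["background"]], labs[["cerebellum"]]))
  xall <- cumtrapz_frames(sched, ref_act) / ref_act
  usef <- which(frame_mid_min(sched) >= t_star & is.finite(xall))
  if (length(usef) < 3L) stop("fewer than 3 frames at t >= t_star")
  x <- xall[usef]
  w <- if (identical(weights, "duration")) frame_dur_min(sched)[usef]
       else rep(1, length(usef))
  Y <- sweep(flat[fit_idx, usef, drop = FALSE], 2L, ref_act[usef], `/`)
  bad <- !is.finite(rowSums(Y))
  # weighted simple regression, vectorised over voxels
  sw <- sum(w); xbar <- sum(w * x) / sw
  sxx <- sum(w * (x - xbar)^2)
  ybar <- as.numeric(Y %*% w) / sw
  slope <- as.numeric(Y %*% (w * (x - xbar))) / sxx
  inter <- ybar - slope * xbar
  slope[bad] <- NA_real_; inter[bad] <- NA_real_
  ki <- array(0, dim(scan$mask$data)); vb <- ki
  ki[fit_idx] <- slope; vb[fit_idx] <- inter
  structure(list(ki = ki, intercept = vb, n_failed = sum(bad),
                 t_star = t_star, weights = weights),
            class = "parametric_map")
}

# separable 3D Gaussian smoothing with a truncated (+/- 3 sd) kernel
gaussian_smooth_3d <- function(vol, sd_vox) {
  r <- max(1L, ceiling(3 * sd_vox))
  k <- stats::dnorm(-r:r, sd = sd_vox); k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    a <- aperm(a, order(replace(1:3, c(1, axis), c(axis, 1))))
    d <- dim(a)
    m <- matrix(a, nrow = d[1L])
    out <- matrix(0, d[1L], ncol(m))
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(d[1L]) + o, 1L), d[1L])
      out <- out + k[o + r + 1L] * m[src, , drop = FALSE]
    }
    aperm(array(out, d), order(replace(1:3, c(1, axis), c(axis, 1))))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}
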