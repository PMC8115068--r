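#' Time-activity curves
#'
#' A time-activity curve (TAC) holds the decay-corrected activity
#' concentration (kBq/mL) of a region or voxel in every acquisition frame.
#' `reference_tac` marks the cerebellar reference curve \eqn{C_R(t)};
#' `tissue_tac` a target-tissue curve \eqn{C_T(t)}.
#'
#' @param sched A [frame_schedule()].
#' @param activity Numeric per-frame activity, kBq/mL; must be non-negative
#'   and match the schedule length.
#' @return A `reference_tac` / `tissue_tac` object (also class `tac`).
#' @export
reference_tac <- function(sched, activity) {
  new_tac(sched, activity, "reference_tac")
}

#' @rdname reference_tac
#' @export
tissue_tac <- function(sched, activity) {
  new_tac(sched, activity, "tissue_tac")
}

new_tac <- function(sched, activity, subclass) {
  stopifnot(inherits(sched, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != nframes(sched))
    stop(sprintf("activity has %d values but schedule has %d frames",
                 length(activity), nframes(sched)))
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity must be finite and non-negative")
  structure(list(schedule = sched, activity = activity),
            class = c(subclass, "tac"))
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<%s> %d frames, peak %.2f kBq/mL at %.1f min\n",
              class(x)[1L], nframes(x$schedule), max(x$activity),
              frame_mid_min(x$schedule)[which.max(x$activity)]))
  invisible(x)
}

#' Synthesize a cerebellar reference curve
#'
#' Generates a gamma-variate input-like curve
#' \eqn{C(t) = A (t/t_p)^{\alpha} e^{\alpha(1 - t/t_p)}} (peak value `amplitude`
#' at `peak_time`), optionally mixed with a slowly-decaying washout tail, on a
#' fine time grid (step <= 1 s), then averaged within each acquisition frame.
#' The curve emulates the qualitative kinetics of the cerebellum after bolus
#' FDOPA injection: a single early peak followed by monotone washout.  It is a
#' modelling convenience only - the Patlak estimator never assumes this family.
#'
#' @param sched A [frame_schedule()].
#' @param peak_time_min Time of peak, minutes (default 5).
#' @param amplitude Peak activity, kBq/mL (default 20).
#' @param shape Gamma-variate shape \eqn{\alpha > 0} (default 2); larger values
#'   sharpen the peak.
#' @param washout_frac Fraction in `[0,1)` of the peak carried by a slow
#'   mono-exponential tail (default 0.3).
#' @param washout_halflife_min Half-life of that tail, minutes (default 90).
#' @return A [reference_tac()].  Deterministic given its inputs.
#' @export
make_reference_tac <- function(sched, peak_time_min = 5, amplitude = 20,
                               shape = 2, washout_frac = 0.3,
                               washout_halflife_min = 90) {
  stopifnot(inherits(sched, "frame_schedule"))
  if (peak_time_min <= 0 || amplitude <= 0 || shape <= 0 ||
      washout_frac < 0 || washout_frac >= 1 || washout_halflife_min <= 0)
    stop("non-physical reference-curve shape parameters")
  total_min <- sum(sched$duration_s) / 60
  if (peak_time_min >= total_min)
    stop("peak_time_min must fall within the scan duration")
  # fine grid, 1 s step, cell midpoints
  dt <- 1 / 60
  t_fine <- seq(dt / 2, total_min - dt / 2, by = dt)
  u <- t_fine / peak_time_min
  # fast gamma-variate component + slow washout tail; both peak at t_p with
  # joint peak value = amplitude, and both decay monotonically afterwards
  tail <- amplitude * washout_frac * pmin(u, 1)^shape *
    2^(-pmax(t_fine - peak_time_min, 0) / washout_halflife_min)
  curve <- amplitude * (1 - washout_frac) * u^shape * exp(shape * (1 - u)) +
    tail
  frame_of <- findInterval(t_fine * 60, sched$start_s)
  act <- as.numeric(tapply(curve, frame_of, mean))
  reference_tac(sched, act)
}

# Patlak basis on the frame grid: cumulative trapezoid of C_R over frame
# midpoints with the (t, C) = (0, 0) boundary point.  This exact rule is
# shared by the tissue-curve generator and the Patlak estimator so that
# noiseless generation is exactly invertible.
cumtrapz_frames <- function(sched, activity) {
  t <- c(0, frame_mid_min(sched))
  v <- c(0, activity)
  n <- length(t)
  cumsum(diff(t) * (v[-1L] + v[-n]) / 2)
}

#' Synthesize a Patlak-consistent tissue curve
#'
#' Builds a target-tissue TAC from a reference TAC and ground-truth kinetic
#' parameters via the irreversible-uptake construction
#' \deqn{C_T(t) = K_i \int_0^t C_R\, d\tau + v' C_R(t),}
#' with the cumulative integral taken by the trapezoid rule over frame
#' midpoints (boundary \eqn{C_R(0)=0}) - the same discretisation used by
#' [patlak_transform()], so with `noise_cv = 0` the downstream fit recovers
#' `ki_true` and `v_prime` exactly.  Noise is multiplicative Gaussian with
#' per-frame standard deviation `noise_cv * sqrt(max(duration)/duration)`,
#' i.e. variance inversely proportional to frame duration and calibrated so
#' the longest (late) frames have coefficient of variation `noise_cv`.
#'
#' @param ref A [reference_tac()].
#' @param ki_true Patlak influx slope, 1/min (>= 0).
#' @param v_prime Patlak intercept (effective distribution volume), unitless
#'   (>= 0).
#' @param noise_cv Target coefficient of variation on the longest frames
#'   (>= 0; 0 = noiseless).
#' @param rng_seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A [tissue_tac()].  Activities are clipped at zero.
#' @export
make_tissue_tac <- function(ref, ki_true, v_prime, noise_cv = 0,
                            rng_seed = NULL) {
  stopifnot(inherits(ref, "reference_tac"))
  if (ki_true < 0 || v_prime < 0) stop("ki_true and v_prime must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  sched <- ref$schedule
  ct <- ki_true * cumtrapz_frames(sched, ref$activity) +
    v_prime * ref$activity
  if (noise_cv > 0) {
    if (!is.null(rng_seed)) {
      old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(rng_seed)
    }
    sd_f <- noise_cv * sqrt(max(sched$duration_s) / sched$duration_s)
    ct <- ct * (1 + stats::rnorm(nframes(sched), 0, sd_f))
    ct <- pmax(ct, 0)
  }
  tissue_tac(sched, ct)
}
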