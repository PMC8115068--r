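#' Acquisition frame schedule
#'
#' A frame schedule defines the temporal binning of a dynamic PET
#' acquisition: per-frame start times and durations in seconds from tracer
#' injection.  Frames must be contiguous (each frame starts where the
#' previous one ends) with strictly positive durations.
#'
#' @param starts Numeric vector of frame start times (seconds post-injection).
#' @param durations Numeric vector of frame durations (seconds), same length.
#' @return An object of class `frame_schedule` with elements `start_s` and
#'   `duration_s`.
#' @examples
#' sched <- frame_schedule_dataset1()
#' nframes(sched)
#' @export
frame_schedule <- function(starts, durations) {
  starts <- as.numeric(starts)
  durations <- as.numeric(durations)
  if (length(starts) != length(durations) || length(starts) == 0L)
    stop("starts and durations must be non-empty vectors of equal length")
  if (any(durations <= 0))
    stop("all frame durations must be > 0")
  if (length(starts) > 1L && any(diff(starts) <= 0))
    stop("frame starts must be strictly increasing")
  gaps <- starts[-1L] - (starts[-length(starts)] + durations[-length(durations)])
  if (any(abs(gaps) > 1e-9))
    stop("frames must be contiguous: start[i+1] = start[i] + duration[i]")
  structure(list(start_s = starts, duration_s = durations),
            class = "frame_schedule")
}

#' @param durations_s Run-length encoded frame durations, seconds.
#' @rdname frame_schedule
#' @export
frame_schedule_from_durations <- function(durations_s) {
  starts <- cumsum(c(0, durations_s[-length(durations_s)]))
  frame_schedule(starts, durations_s)
}

#' 32-frame 95-min schedule (8 x 15 s, 3 x 60 s, 5 x 120 s, 16 x 300 s)
#' @rdname frame_schedule
#' @export
frame_schedule_dataset1 <- function() {
  frame_schedule_from_durations(rep(c(15, 60, 120, 300), c(8L, 3L, 5L, 16L)))
}

#' 26-frame 94.5-min schedule (1 x 30 s, 4 x 60 s, 3 x 120 s, 3 x 180 s,
#' 15 x 300 s)
#' @rdname frame_schedule
#' @export
frame_schedule_dataset2 <- function() {
  frame_schedule_from_durations(
    rep(c(30, 60, 120, 180, 300), c(1L, 4L, 3L, 3L, 15L)))
}

#' @rdname frame_schedule
#' @param x A `frame_schedule`.
#' @export
nframes <- function(x) length(x$start_s)

# frame midpoints / ends in minutes (internal unit for all kinetics)
frame_mid_min <- function(sched) (sched$start_s + sched$duration_s / 2) / 60
frame_end_min <- function(sched) (sched$start_s + sched$duration_s) / 60
frame_dur_min <- function(sched) sched$duration_s / 60

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f min total\n",
              nframes(x), sum(x$duration_s) / 60))
  invisible(x)
}

#' Read / write frame schedules as CSV
#'
#' CSV interchange format with header `start_s,duration_s`.
#'
#' @param path File path.
#' @param sched A `frame_schedule`.
#' @return `read_frame_schedule` returns a `frame_schedule`;
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("start_s", "duration_s") %in% names(df)))
    stop("schedule CSV must have columns start_s,duration_s")
  frame_schedule(df$start_s, df$duration_s)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(sched, path) {
  utils::write.csv(
    data.frame(start_s = sched$start_s, duration_s = sched$duration_s),
    path, row.names = FALSE)
  invisible(path)
}
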