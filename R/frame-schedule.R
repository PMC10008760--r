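#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records when each reconstruction frame of a dynamic PET
#' scan starts and how long it lasts. Frame mid-times (start + duration / 2)
#' are the time points at which kinetic model curves are evaluated.
#'
#' @param start_times Numeric vector of frame start times (minutes), strictly
#'   increasing, first frame starting at time >= 0.
#' @param durations Numeric vector of frame durations (minutes), all positive.
#'   Frames must not overlap.
#' @return An object of class `frame_schedule` with elements `start`, `dur`
#'   and `mid`.
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 1, 2))
#' fs$mid
#' @export
frame_schedule <- function(start_times, durations) {
  if (length(start_times) != length(durations))
    validation_error("start_times and durations must have equal length")
  if (any(!is.finite(start_times)) || any(!is.finite(durations)))
    validation_error("frame times must be finite")
  if (any(durations <= 0))
    validation_error("all frame durations must be positive (frame %d)",
                     which(durations <= 0)[1])
  if (length(start_times) > 1 && any(diff(start_times) <= 0))
    validation_error("frame start times must be strictly increasing")
  ends <- start_times + durations
  if (length(start_times) > 1 &&
      any(start_times[-1] < ends[-length(ends)] - 1e-9))
    validation_error("frames must not overlap")
  if (start_times[1] < 0)
    validation_error("first frame must start at time >= 0")
  structure(list(start = as.numeric(start_times),
                 dur = as.numeric(durations),
                 mid = as.numeric(start_times + durations / 2)),
            class = "frame_schedule")
}

#' Generic 20-frame, 91-minute schedule
#'
#' A typical schedule for a carbon-11 tracer: short early frames through the
#' vascular peak, lengthening to 10-minute frames at late times.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 4), rep(1, 3), rep(2, 3), rep(5, 4), rep(10, 6))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f-%.1f min\n",
              length(x$start), x$start[1], x$start[length(x$start)] +
                x$dur[length(x$dur)]))
  invisible(x)
}

n_frames <- function(schedule) length(schedule$start)
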