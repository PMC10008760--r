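#' Time activity curve
#'
#' A time activity curve (TAC) is the radioactivity concentration of one brain
#' region sampled over the frames of a dynamic PET scan, together with
#' relative fitting weights.
#'
#' @param schedule A [frame_schedule()].
#' @param values Radioactivity concentration per frame (arbitrary units).
#' @param weights Optional nonnegative relative weights, one per frame, with
#'   at least one positive; defaults to uniform weights.
#' @param region,subject Optional labels.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, weights = NULL, region = NA_character_,
                subject = NA_character_) {
  if (!inherits(schedule, "frame_schedule"))
    validation_error("schedule must be a frame_schedule")
  nf <- n_frames(schedule)
  if (length(values) != nf)
    validation_error("values length (%d) must equal number of frames (%d)",
                     length(values), nf)
  if (any(!is.finite(values)))
    validation_error("TAC values must be finite")
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf)
    validation_error("weights length must equal number of frames")
  if (any(weights < 0) || all(weights == 0))
    validation_error("weights must be nonnegative with at least one positive")
  structure(list(schedule = schedule, values = as.numeric(values),
                 weights = as.numeric(weights),
                 region = region, subject = subject),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s / %s: %d frames, peak %.3g\n",
              x$subject, x$region, n_frames(x$schedule), max(x$values)))
  invisible(x)
}

#' Frame weights from an approximate-counts noise model
#'
#' Computes relative nonlinear-least-squares weights for a TAC in the style of
#' the default weighting used by kinetic-modelling toolkits: the variance of a
#' frame's decay-corrected concentration estimate is taken proportional to the
#' (decay-corrected) count rate divided by the frame duration,
#' \deqn{\mathrm{var}_f \propto C_f \, e^{\lambda t_f} / \Delta_f,}
#' with \eqn{\lambda = \ln 2 / t_{1/2}}, \eqn{t_f} the frame mid-time and
#' \eqn{\Delta_f} the frame duration. Weights are the reciprocal variances,
#' floored at a small fraction of the peak value to avoid infinite weight at
#' near-zero frames, and normalised to mean 1. Longer frames at equal
#' decay-corrected activity therefore receive proportionally larger weights,
#' and weights are invariant to rescaling the whole TAC.
#'
#' Alternative schemes can be registered by passing a function
#' `method = function(values, mid, dur, halflife) ...` returning unnormalised
#' weights.
#'
#' @param x A [tac()] (or a numeric vector of frame values, in which case
#'   `schedule` must be supplied).
#' @param halflife Isotope half-life in minutes (default 20.4, carbon-11).
#' @param floor_frac Values below `floor_frac * max(values)` are floored
#'   before computing variances.
#' @param method `"counts"` (default) or a custom function as described above.
#' @param schedule Frame schedule when `x` is a plain numeric vector.
#' @return Numeric weight vector with mean 1.
#' @export
tac_weights <- function(x, halflife = 20.4, floor_frac = 0.01,
                        method = "counts", schedule = NULL) {
  if (inherits(x, "tac")) {
    schedule <- x$schedule
    values <- x$values
  } else {
    values <- as.numeric(x)
    if (is.null(schedule))
      validation_error("schedule is required when x is not a tac")
  }
  if (halflife <= 0) validation_error("halflife must be positive")
  if (max(values) <= 0) validation_error("TAC has no positive frames")
  if (is.function(method)) {
    w <- method(values, schedule$mid, schedule$dur, halflife)
  } else if (identical(method, "counts")) {
    lambda <- log(2) / halflife
    cfloor <- pmax(values, floor_frac * max(values))
    v <- cfloor * exp(lambda * schedule$mid) / schedule$dur
    w <- 1 / v
  } else {
    validation_error("unknown weighting method '%s'", method)
  }
  if (any(!is.finite(w)) || any(w < 0))
    validation_error("weighting scheme produced invalid weights")
  w / mean(w)
}
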