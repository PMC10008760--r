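#' Arterial input function
#'
#' The arterial input function (AIF) is the radiotracer concentration in
#' arterial plasma over time; it drives the tissue compartment models. The AIF
#' is represented as a piecewise-linear function on a sampled time grid and is
#' forced through (0, 0): tracer has not yet arrived at injection time.
#'
#' @param times Numeric vector of sample times (minutes); must start at 0 and
#'   be strictly increasing.
#' @param concentrations Nonnegative radioactivity concentrations (arbitrary
#'   units), one per time point; the value at time 0 must be 0.
#' @return An object of class `aif` with elements `time`, `conc`,
#'   `interpolation` (always `"linear"`).
#' @export
aif <- function(times, concentrations) {
  if (length(times) != length(concentrations))
    validation_error("times and concentrations must have equal length")
  if (length(times) < 2)
    validation_error("an AIF needs at least two samples")
  if (times[1] != 0)
    validation_error("AIF times must start at 0")
  if (any(diff(times) <= 0))
    validation_error("AIF times must be strictly increasing")
  if (any(concentrations < 0))
    validation_error("AIF concentrations must be nonnegative")
  if (concentrations[1] != 0)
    validation_error("AIF concentration at time 0 must be 0")
  structure(list(time = as.numeric(times),
                 conc = as.numeric(concentrations),
                 interpolation = "linear"),
            class = "aif")
}

#' Simulate a plausible arterial input function
#'
#' Generates a noiseless AIF from a Feng-type model: a sharp linear-rise /
#' multi-exponential-decay bolus shape,
#' \deqn{C_p(t) = (A_1 u - A_2 - A_3) e^{\lambda_1 u} + A_2 e^{\lambda_2 u} +
#'   A_3 e^{\lambda_3 u}, \quad u = t - t_0,}
#' zero before the appearance time \eqn{t_0}. The default coefficients give a
#' bolus peaking shortly after appearance with a slowly clearing tail, in
#' arbitrary concentration units.
#'
#' @param t_end End of the sampling grid (minutes).
#' @param t0 Tracer appearance time (minutes).
#' @param A Amplitudes `c(A1, A2, A3)`.
#' @param lambda Decay rates `c(l1, l2, l3)` (1/min, negative).
#' @param times Optional explicit sampling grid; defaults to a grid that is
#'   dense around the peak and coarser later.
#' @return An [aif()].
#' @export
simulate_aif <- function(t_end = 100, t0 = 0.5,
                         A = c(60, 3, 2),
                         lambda = c(-4, -0.45, -0.008),
                         times = NULL) {
  if (is.null(times)) {
    times <- unique(sort(c(seq(0, min(5, t_end), by = 0.05),
                           seq(0, t_end, by = 0.25))))
  }
  u <- pmax(times - t0, 0)
  conc <- ifelse(times <= t0, 0,
                 (A[1] * u - A[2] - A[3]) * exp(lambda[1] * u) +
                   A[2] * exp(lambda[2] * u) + A[3] * exp(lambda[3] * u))
  conc <- pmax(conc, 0)
  aif(times, conc)
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif> %d samples over %.1f min, peak %.3g at %.2f min\n",
              length(x$time), max(x$time), max(x$conc),
              x$time[which.max(x$conc)]))
  invisible(x)
}

# linear interpolation of the input curve (0 outside [0, max(time)] on the
# left; error on the right is handled by the callers' support checks)
aif_interp <- function(input, t) {
  approx(input$time, input$conc, xout = t, rule = 2)$y
}

aif_support_check <- function(input, schedule) {
  t_max <- max(schedule$start + schedule$dur)
  if (t_max > max(input$time) + 1e-9)
    validation_error(
      "frame schedule (to %.1f min) exceeds input-function support (%.1f min)",
      t_max, max(input$time))
  invisible(TRUE)
}
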