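#' Kinetic model parameter sets
#'
#' Constructors for the parameter sets of the three supported pharmacokinetic
#' models, in the parameterisations used throughout the package. Each model is
#' parameterised through a blood-delivery parameter, a binding parameter, and
#' remaining parameters chosen so that pooling towards a common mean across
#' regions is biologically defensible:
#'
#' * **Two-tissue compartment (2TC)**: `K1` (mL/cm3/min), `VND`, `BPP`, `k4`
#'   (1/min). Derived micro-constants `k2 = K1/VND`, `k3 = k4 * BPP / VND`,
#'   and derived totals `VT = VND + BPP`, `BPND = BPP/VND`.
#' * **One-tissue compartment (1TC)**: `K1`, `VT`; derived `k2 = K1/VT`.
#' * **Simplified reference tissue model (SRTM)**: `R1`, `k2prime` (1/min),
#'   `BPND`; derived `k2 = R1 * k2prime`, `k2a = k2 / (1 + BPND)`.
#'
#' All primary parameters must be strictly positive.
#'
#' @param K1,VND,BPP,k4,VT,R1,k2prime,BPND Model parameters as above.
#' @return A named list of class `pk_2tc`, `pk_1tc` or `pk_srtm` including the
#'   derived quantities.
#' @name pk_params
NULL

#' @rdname pk_params
#' @export
pk_2tc <- function(K1, VND, BPP, k4) {
  for (v in c(K1 = K1, VND = VND, BPP = BPP, k4 = k4))
    if (!is.finite(v) || v <= 0)
      validation_error("all 2TC parameters must be positive and finite")
  structure(list(K1 = K1, VND = VND, BPP = BPP, k4 = k4,
                 k2 = K1 / VND, k3 = k4 * BPP / VND,
                 VT = VND + BPP, BPND = BPP / VND),
            class = "pk_2tc")
}

#' @rdname pk_params
#' @export
pk_1tc <- function(K1, VT) {
  if (!is.finite(K1) || K1 <= 0 || !is.finite(VT) || VT <= 0)
    validation_error("1TC parameters must be positive and finite")
  structure(list(K1 = K1, VT = VT, k2 = K1 / VT), class = "pk_1tc")
}

#' @rdname pk_params
#' @export
pk_srtm <- function(R1, k2prime, BPND) {
  for (v in c(R1 = R1, k2prime = k2prime, BPND = BPND))
    if (!is.finite(v) || v <= 0)
      validation_error("all SRTM parameters must be positive and finite")
  k2 <- R1 * k2prime
  structure(list(R1 = R1, k2prime = k2prime, BPND = BPND,
                 k2 = k2, k2a = k2 / (1 + BPND)),
            class = "pk_srtm")
}

# Impulse response of the 2TC model: two exponentials whose rates are the
# roots of the standard quadratic in (k2, k3, k4) and whose amplitudes are
# scaled by K1. Returns list(phi = c(phi1, phi2), theta = c(theta1, theta2)).
irf_2tc <- function(params) {
  k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  disc <- max(disc, 0)
  theta1 <- (s + sqrt(disc)) / 2
  theta2 <- (s - sqrt(disc)) / 2
  if (theta1 - theta2 < 1e-10) {
    # repeated-root degeneracy: split the roots by a relative nudge of k4;
    # the curve changes by O(1e-8), far below fitting noise
    return(irf_2tc(pk_2tc(params$K1, params$VND, params$BPP,
                          params$k4 * (1 + 1e-8))))
  }
  phi1 <- params$K1 * (theta1 - k3 - k4) / (theta1 - theta2)
  phi2 <- params$K1 * (k3 + k4 - theta2) / (theta1 - theta2)
  list(phi = c(phi1, phi2), theta = c(theta1, theta2))
}

#' Simulate a noiseless tissue TAC from a kinetic model
#'
#' Forward models computing the tissue concentration as the convolution of
#' the model impulse response with the arterial input (2TC, 1TC) or with the
#' reference-region curve (SRTM), using exact piecewise-linear convolution.
#' Frame values are the model curve evaluated at frame mid-times.
#'
#' * 2TC: \eqn{C_T(t) = (\phi_1 e^{-\theta_1 t} + \phi_2 e^{-\theta_2 t})
#'   \otimes C_p(t)} with \eqn{\theta_{1,2}} the roots of
#'   \eqn{\theta^2 - (k_2+k_3+k_4)\theta + k_2 k_4}.
#' * 1TC: \eqn{C_T(t) = K_1 e^{-(K_1/V_T) t} \otimes C_p(t)}.
#' * SRTM: \eqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})
#'   (C_R \otimes e^{-k_{2a} t})(t)}.
#'
#' @param params A [pk_2tc()], [pk_1tc()] or [pk_srtm()] parameter set.
#' @param input An [aif()] (2TC/1TC) .
#' @param schedule A [frame_schedule()]; must lie within the input support.
#' @param reference_tac A [tac()] for the reference region (SRTM); its frame
#'   mid-times must cover the target schedule and be fine enough for
#'   quadrature of the convolution.
#' @param ... Passed through between methods.
#' @return A noiseless [tac()].
#' @export
simulate_tac <- function(params, ...) UseMethod("simulate_tac")

#' @rdname simulate_tac
#' @export
simulate_tac.pk_2tc <- function(params, input, schedule, ...) {
  aif_support_check(input, schedule)
  ir <- irf_2tc(params)
  v <- ir$phi[1] * exp_conv_lin(ir$theta[1], input$time, input$conc,
                                schedule$mid) +
    ir$phi[2] * exp_conv_lin(ir$theta[2], input$time, input$conc,
                             schedule$mid)
  tac(schedule, v)
}

#' @rdname simulate_tac
#' @export
simulate_tac.pk_1tc <- function(params, input, schedule, ...) {
  aif_support_check(input, schedule)
  v <- params$K1 * exp_conv_lin(params$k2, input$time, input$conc,
                                schedule$mid)
  tac(schedule, v)
}

#' @rdname simulate_tac
#' @export
simulate_tac.pk_srtm <- function(params, reference_tac, schedule, ...) {
  if (!inherits(reference_tac, "tac"))
    validation_error("reference_tac must be a tac")
  rt <- reference_tac$schedule$mid
  rv <- reference_tac$values
  if (max(schedule$mid) > max(rt) + 1e-9)
    validation_error("schedule exceeds reference TAC support")
  cr <- approx(c(0, rt), c(0, rv), xout = schedule$mid, rule = 2)$y
  conv <- exp_conv_lin(params$k2a, rt, rv, schedule$mid)
  v <- params$R1 * cr + (params$k2 - params$R1 * params$k2a) * conv
  tac(schedule, v)
}

#' @rdname simulate_tac
#' @export
simulate_tac_2tc <- function(params, input, schedule)
  simulate_tac.pk_2tc(params, input, schedule)

#' @rdname simulate_tac
#' @export
simulate_tac_1tc <- function(params, input, schedule)
  simulate_tac.pk_1tc(params, input, schedule)

#' @rdname simulate_tac
#' @export
simulate_tac_srtm <- function(params, reference_tac, schedule)
  simulate_tac.pk_srtm(params, reference_tac, schedule)
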