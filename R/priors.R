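#' Default prior settings for a PuMBA model
#'
#' Builds the prior block of a [pumba_spec()] from a tracer profile of
#' plausible central parameter values. Priors are moderately informative for
#' the global intercepts and regularising for everything else:
#'
#' * intercepts: `alpha_i ~ Normal(log(central value), intercept_sd)`
#'   (default SD 0.25);
#' * covariate coefficients: `beta ~ Normal(0, beta_sd)` (default SD 0.1);
#' * pooled standard deviations: half-normal with scale `sd_scale`
#'   (default 0.3);
#' * correlation matrices: LKJ with shape `lkj_eta` (default 2);
#' * per-region fixed effects: `Normal(0, region_fe_sd)` (default SD 2.5,
#'   weakly informative since regional binding differences can be large).
#'
#' @param central_values Named numeric vector of plausible natural-scale
#'   central values, one per model parameter (e.g. from a tracer profile).
#' @param intercept_sd,beta_sd,sd_scale,lkj_eta,region_fe_sd Scalars as
#'   described above.
#' @return A list of class `pumba_priors`.
#' @export
default_priors <- function(central_values, intercept_sd = 0.25,
                           beta_sd = 0.1, sd_scale = 0.3, lkj_eta = 2,
                           region_fe_sd = 2.5) {
  if (is.null(names(central_values)) || any(!nzchar(names(central_values))))
    validation_error("central_values must be a fully named vector")
  if (any(central_values <= 0))
    validation_error("central values must be positive (they are logged)")
  structure(list(intercept_mean = log(central_values),
                 intercept_sd = intercept_sd,
                 beta_sd = beta_sd,
                 sd_scale = sd_scale,
                 lkj_eta = lkj_eta,
                 region_fe_sd = region_fe_sd),
            class = "pumba_priors")
}

#' Randomly halve or double intercept prior means
#'
#' Prior-sensitivity utility: shifts each intercept prior mean by +0.69 or
#' -0.69 (i.e. doubling or halving the central value on the natural scale),
#' choosing the direction independently and at random per parameter. Used to
#' assess robustness of inferences to misspecified intercept priors.
#'
#' @param priors A `pumba_priors` object.
#' @param shift Absolute log-scale shift (default 0.69, i.e. a factor of 2).
#' @return A `pumba_priors` object with perturbed intercept means.
#' @export
perturb_intercept_priors <- function(priors, shift = 0.69) {
  if (!inherits(priors, "pumba_priors"))
    validation_error("priors must be a pumba_priors object")
  signs <- sample(c(-1, 1), length(priors$intercept_mean), replace = TRUE)
  priors$intercept_mean <- priors$intercept_mean + signs * shift
  priors
}

#' @export
print.pumba_priors <- function(x, ...) {
  cat("<pumba_priors>\n")
  cat("  intercepts: Normal(",
      paste(sprintf("%s=%.3f", names(x$intercept_mean), x$intercept_mean),
            collapse = ", "), "), sd", x$intercept_sd, "\n")
  cat(sprintf("  beta sd %.3g; pooled-sd scale %.3g; LKJ eta %.3g; region-FE sd %.3g\n",
              x$beta_sd, x$sd_scale, x$lkj_eta, x$region_fe_sd))
  invisible(x)
}
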