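#' Synthetic tracer profiles
#'
#' Generative profiles describing the population distribution of PK
#' parameters for a tracer-model combination: log-scale population intercepts,
#' fixed per-region offsets for nine named cortical/subcortical regions,
#' subject-level SD vector and correlation matrix, and residual
#' (region-within-subject, including estimation error) SD vector and
#' correlation matrix. These are *synthetic* profiles: values are plausible
#' for the tracer class named, chosen from the published kinetics literature,
#' and every value can be overridden via [generative_config()]. A notable
#' structural feature they reproduce is the strong positive subject-level
#' correlation between blood delivery and binding.
#'
#' @param model_id `"2tc"`, `"1tc"` or `"srtm"`.
#' @return A list with elements `parameters`, `alpha` (log scale),
#'   `region_offsets` (9 x m matrix, log scale), `subject_sds`, `subject_R`,
#'   `resid_sds`, `resid_R`, `binding`, `delivery`, `central_values`.
#' @export
synthetic_profile <- function(model_id = c("2tc", "1tc", "srtm")) {
  model_id <- match.arg(model_id)
  regions <- c("acc", "amygdala", "dlpfc", "drn", "hippocampus", "insula",
               "mpfc", "parahippocampus", "pcc")
  mk <- function(parameters, central, roff, ssd, sR, rsd, rR,
                 binding, delivery) {
    rownames(roff) <- regions; colnames(roff) <- parameters
    names(ssd) <- parameters; names(rsd) <- parameters
    dimnames(sR) <- list(parameters, parameters)
    dimnames(rR) <- list(parameters, parameters)
    check_correlation_matrix(sR, "subject_R")
    check_correlation_matrix(rR, "resid_R")
    list(model_id = model_id, parameters = parameters, regions = regions,
         alpha = log(central), central_values = central,
         region_offsets = roff, subject_sds = ssd, subject_R = sR,
         resid_sds = rsd, resid_R = rR, binding = binding,
         delivery = delivery)
  }
  corr <- function(v) {
    d <- (1 + sqrt(1 + 8 * length(v))) / 2
    R <- diag(d)
    R[lower.tri(R)] <- v
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
    R
  }
  switch(model_id,
    "2tc" = mk(
      parameters = c("K1", "VND", "BPP", "k4"),
      central = c(K1 = 0.35, VND = 1.4, BPP = 1.5, k4 = 0.06),
      roff = cbind(
        K1 = c(0.05, -0.10, 0.10, -0.20, -0.05, 0.08, 0.12, -0.08, 0.06),
        VND = c(0.02, -0.05, 0.04, -0.08, -0.02, 0.03, 0.05, -0.04, 0.02),
        BPP = c(0.25, 0.45, -0.15, -0.60, 0.35, 0.30, 0.05, 0.15, -0.10),
        k4 = c(0.02, 0.05, -0.03, -0.06, 0.04, 0.02, 0.00, 0.03, -0.02)),
      # strong delivery-binding coupling at the subject level
      ssd = c(0.12, 0.15, 0.22, 0.08),
      sR = corr(c(0.50, 0.85, 0.15, 0.40, 0.10, 0.15)),
      rsd = c(0.04, 0.12, 0.08, 0.15),
      rR = corr(c(0.05, 0.05, 0.05, -0.20, 0.05, 0.05)),
      binding = "BPP", delivery = "K1"),
    "1tc" = mk(
      parameters = c("K1", "VT"),
      central = c(K1 = 0.45, VT = 15),
      roff = cbind(
        K1 = c(0.05, -0.12, 0.10, -0.25, -0.06, 0.08, 0.12, -0.10, 0.06),
        VT = c(0.20, 0.40, -0.10, -0.50, 0.30, 0.25, 0.05, 0.10, -0.08)),
      ssd = c(0.12, 0.18),
      sR = corr(0.45),
      rsd = c(0.03, 0.05),
      rR = corr(0.05),
      binding = "VT", delivery = "K1"),
    "srtm" = mk(
      parameters = c("R1", "k2prime", "BPND"),
      central = c(R1 = 0.85, k2prime = 0.10, BPND = 2.0),
      roff = cbind(
        R1 = c(0.03, -0.08, 0.06, -0.12, -0.04, 0.05, 0.08, -0.06, 0.04),
        k2prime = c(0.01, -0.02, 0.02, -0.03, -0.01, 0.01, 0.02, -0.02, 0.01),
        BPND = c(0.30, 0.55, -0.20, -0.90, 0.45, 0.35, 0.05, 0.20, -0.15)),
      ssd = c(0.08, 0.10, 0.25),
      sR = corr(c(0.25, 0.55, 0.20)),
      rsd = c(0.03, 0.08, 0.10),
      rR = corr(c(0.05, 0.05, 0.05)),
      binding = "BPND", delivery = "R1"))
}

#' Configuration of a synthetic study condition
#'
#' Bundles everything that defines one simulation condition: the tracer
#' profile (overridable field by field), the true log-scale group difference
#' `delta` applied to the binding parameter in the patient group, the number
#' of subjects per group, the measurement-error multiplier (TAC mode), and
#' the mode (`"parameter"` draws PK parameter tables directly; `"tac"`
#' simulates 2TC time activity curves and returns them with the underlying
#' truth table).
#'
#' @param model_id `"2tc"`, `"1tc"` or `"srtm"`.
#' @param mode `"parameter"` or `"tac"` (TAC mode requires the 2TC).
#' @param delta True log-scale group difference on the binding parameter
#'   (0.1 corresponds to a 10.5% difference; 0.182 to 20%).
#' @param n_per_group Subjects per group (patients and controls alike),
#'   between 10 and 100 for study presets.
#' @param error_multiplier TAC measurement-error scaling, one of
#'   0.5, 1, 2 or 4 in study presets (0 gives noiseless TACs for checks).
#' @param uncorrelated If `TRUE`, all correlation matrices are replaced by
#'   identity (diagonal-covariance variant used for correlation-recovery
#'   checks).
#' @param profile A [synthetic_profile()]; defaults to the profile for
#'   `model_id`. Any element can be overridden via `overrides`.
#' @param overrides Named list of profile elements to replace.
#' @param noise_sigma0 Base TAC noise scale (see [generate_tac_dataset()]).
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(model_id = c("2tc", "1tc", "srtm"),
                              mode = c("parameter", "tac"),
                              delta = 0.1, n_per_group = 20,
                              error_multiplier = 1,
                              uncorrelated = FALSE,
                              profile = NULL, overrides = list(),
                              noise_sigma0 = 0.05) {
  model_id <- match.arg(model_id)
  mode <- match.arg(mode)
  if (mode == "tac" && model_id != "2tc")
    validation_error("TAC mode is implemented for the 2TC model")
  if (n_per_group < 2) validation_error("n_per_group must be at least 2")
  if (error_multiplier < 0)
    validation_error("error_multiplier must be nonnegative")
  profile <- profile %||% synthetic_profile(model_id)
  for (nm in names(overrides)) profile[[nm]] <- overrides[[nm]]
  if (uncorrelated) {
    m <- length(profile$parameters)
    profile$subject_R <- diag(m)
    profile$resid_R <- diag(m)
    dimnames(profile$subject_R) <- dimnames(profile$resid_R) <-
      list(profile$parameters, profile$parameters)
  }
  check_correlation_matrix(profile$subject_R, "subject_R")
  check_correlation_matrix(profile$resid_R, "resid_R")
  structure(list(model_id = model_id, mode = mode, delta = delta,
                 n_per_group = as.integer(n_per_group),
                 error_multiplier = error_multiplier,
                 uncorrelated = uncorrelated,
                 noise_sigma0 = noise_sigma0,
                 profile = profile),
            class = "generative_config")
}

#' Generate a parameter-level synthetic dataset
#'
#' Draws one study's worth of log-scale PK parameter estimates from the
#' generative model
#' \deqn{\theta_{i,j,k} = \alpha_i + \delta \, 1[\mathrm{binding},
#'   \mathrm{patient}] + \tau_{i,j} + \upsilon_{i,k} + \epsilon_{i,j,k},}
#' with subject deviations \eqn{\tau_j \sim \mathrm{MVN}(0,
#' \Sigma_\mathrm{Subject})}, fixed per-region offsets \eqn{\upsilon_k} from
#' the profile, and residuals \eqn{\epsilon_{j,k} \sim \mathrm{MVN}(0,
#' \Sigma_\mathrm{residual})}. In parameter mode the residual term absorbs
#' NLS estimation error in addition to region-within-subject biological
#' variation, so tables drawn here emulate NLS output without simulating
#' curves.
#'
#' @param cfg A [generative_config()].
#' @return A tibble with columns `subject`, `region`, `group` (factor,
#'   `control` then `patient`) and one `log<param>` column per parameter.
#' @export
generate_parameter_dataset <- function(cfg) {
  if (!inherits(cfg, "generative_config"))
    validation_error("cfg must be a generative_config")
  pf <- cfg$profile
  pars <- pf$parameters
  m <- length(pars)
  n <- 2L * cfg$n_per_group
  regions <- rownames(pf$region_offsets)
  K <- length(regions)
  group <- factor(rep(c("control", "patient"), each = cfg$n_per_group),
                  levels = c("control", "patient"))
  subj_id <- sprintf("s%03d", seq_len(n))

  tau <- rmvn(n, pf$subject_sds, pf$subject_R)
  eps <- rmvn(n * K, pf$resid_sds, pf$resid_R)
  bi <- match(pf$binding, pars)

  rows <- matrix(0, n * K, m)
  for (j in seq_len(n)) {
    base <- pf$alpha + tau[j, ]
    if (group[j] == "patient") base[bi] <- base[bi] + cfg$delta
    idx <- (j - 1L) * K + seq_len(K)
    rows[idx, ] <- matrix(base, K, m, byrow = TRUE) +
      pf$region_offsets + eps[idx, ]
  }
  out <- tibble::tibble(subject = rep(subj_id, each = K),
                        region = rep(regions, n),
                        group = rep(group, each = K))
  for (i in seq_len(m)) out[[paste0("log", pars[i])]] <- rows[, i]
  out
}

#' Generate a TAC-level synthetic dataset
#'
#' Draws true PK parameters per subject and region exactly as
#' [generate_parameter_dataset()], simulates the corresponding noiseless 2TC
#' tissue curves by analytic convolution with a common arterial input
#' function, and adds independent Gaussian measurement noise per frame with
#' standard deviation
#' \deqn{\sigma_f = \mathrm{mult} \times \sigma_0 \sqrt{C(t_f)\,
#'   e^{\lambda t_f} / \Delta_f},}
#' the same approximate-counts model that underlies [tac_weights()], so the
#' default weights are correctly specified under the generator. The error
#' multiplier scales the noise SD (0.5, 1, 2, 4 in the study presets).
#'
#' @param cfg A [generative_config()] in TAC mode.
#' @param input An [aif()]; defaults to [simulate_aif()].
#' @param schedule A [frame_schedule()]; defaults to
#'   [default_frame_schedule()].
#' @param halflife Isotope half-life (min) for the noise/weights model.
#' @return A list with `tacs` (a tibble in long TAC format: `subject`,
#'   `region`, `frame_start_min`, `frame_dur_min`, `value`, `weight`),
#'   `truth` (the true parameter table, same layout as
#'   [generate_parameter_dataset()]), `input` and `schedule`.
#' @export
generate_tac_dataset <- function(cfg, input = NULL, schedule = NULL,
                                 halflife = 20.4) {
  if (!inherits(cfg, "generative_config"))
    validation_error("cfg must be a generative_config")
  if (cfg$mode != "tac")
    validation_error("cfg must be in TAC mode")
  input <- input %||% simulate_aif()
  schedule <- schedule %||% default_frame_schedule()
  aif_support_check(input, schedule)

  truth <- generate_parameter_dataset(cfg)
  pars <- cfg$profile$parameters
  lambda <- log(2) / halflife
  nf <- n_frames(schedule)

  tac_rows <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    p <- exp(as.numeric(truth[r, paste0("log", pars)]))
    names(p) <- pars
    curve <- simulate_tac_2tc(pk_2tc(p["K1"], p["VND"], p["BPP"], p["k4"]),
                              input, schedule)
    sd_f <- cfg$error_multiplier * cfg$noise_sigma0 *
      sqrt(pmax(curve$values, 0.01 * max(curve$values)) *
             exp(lambda * schedule$mid) / schedule$dur)
    noisy <- curve$values + rnorm(nf, 0, sd_f)
    w <- tac_weights(tac(schedule, pmax(noisy, 0) + 1e-12), halflife)
    tac_rows[[r]] <- tibble::tibble(
      subject = truth$subject[r], region = truth$region[r],
      frame_start_min = schedule$start, frame_dur_min = schedule$dur,
      value = noisy, weight = w)
  }
  list(tacs = do.call(rbind, tac_rows), truth = truth,
       input = input, schedule = schedule)
}

#' Replicated study generator with a reproducible seed ledger
#'
#' Derives one child seed per replicate from the master seed with a
#' counter-based splitter (`seed_r = (master + r * 48271) mod (2^31 - 1)`),
#' records them in a seed ledger, and exposes a `generate(r)` closure that
#' re-seeds the RNG and generates replicate `r`'s dataset; any replicate is
#' therefore individually reproducible without regenerating the others.
#'
#' @param cfg A [generative_config()].
#' @param replicates Number of replicate datasets (the study presets use 250
#'   for parameter-mode and 500 for TAC-mode conditions).
#' @param master_seed Integer master seed.
#' @return An object of class `pumba_study` with elements `config`,
#'   `replicates`, `seeds` (the ledger: tibble of replicate and seed) and
#'   `generate(r)`.
#' @export
make_study <- function(cfg, replicates, master_seed = 1) {
  if (!inherits(cfg, "generative_config"))
    validation_error("cfg must be a generative_config")
  if (replicates < 1) validation_error("replicates must be >= 1")
  seeds <- (as.numeric(master_seed) + seq_len(replicates) * 48271) %%
    2147483647
  seeds <- as.integer(ifelse(seeds == 0, 1, seeds))
  gen <- function(r) {
    if (r < 1 || r > replicates) validation_error("replicate out of range")
    set.seed(seeds[r])
    if (cfg$mode == "tac") generate_tac_dataset(cfg)
    else generate_parameter_dataset(cfg)
  }
  structure(list(config = cfg, replicates = as.integer(replicates),
                 seeds = tibble::tibble(replicate = seq_len(replicates),
                                        seed = seeds),
                 generate = gen),
            class = "pumba_study")
}

#' @export
print.pumba_study <- function(x, ...) {
  cat(sprintf("<pumba_study> %s/%s mode, delta %.3g, n %d/group, %d replicates\n",
              x$config$model_id, x$config$mode, x$config$delta,
              x$config$n_per_group, x$replicates))
  invisible(x)
}
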