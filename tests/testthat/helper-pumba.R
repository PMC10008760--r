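# shared fixtures: everything is generated in code at test time

# canonical 2TC spec for a generative config's profile
spec_for <- function(cfg, ...) {
  pf <- cfg$profile
  pumba_spec(pf$parameters,
             formulas = setNames(list(~ group), pf$binding),
             binding = pf$binding, delivery = pf$delivery,
             priors = default_priors(pf$central_values, ...))
}

# short-chain fit used by non-acceptance tests
quick_fit <- function(tab, spec, seed = 1, chains = 2, warmup = 400,
                      sampling = 400) {
  fit_pumba(build_pumba(spec, tab), chains = chains, warmup = warmup,
            sampling = sampling, seed = seed)
}

# run PuMBA + LME over a study's replicates, returning long-format results
run_study_comparison <- function(study, spec, warmup = 500, sampling = 500) {
  rows <- lapply(seq_len(study$replicates), function(r) {
    tab <- study$generate(r)
    fit <- fit_pumba(build_pumba(spec, tab), chains = 4, warmup = warmup,
                     sampling = sampling, seed = study$seeds$seed[r])
    gd <- extract_group_difference(fit)
    lme <- fit_lme(tab, study$config$profile$binding)
    rbind(
      data.frame(method = "pumba", replicate = r, estimate = gd$estimate,
                 se = gd$se, ci_low = gd$ci_low, ci_high = gd$ci_high),
      data.frame(method = "lme", replicate = r, estimate = lme$estimate,
                 se = lme$se, ci_low = lme$ci_low, ci_high = lme$ci_high))
  })
  do.call(rbind, rows)
}

# trapezoidal running integral of an AIF at given times (independent oracle)
aif_integral <- function(input, t_eval) {
  vapply(t_eval, function(t) {
    grid <- sort(unique(c(input$time[input$time <= t], t)))
    cp <- approx(input$time, input$conc, xout = grid, rule = 2)$y
    if (length(grid) < 2) return(0)
    sum((cp[-1] + cp[-length(cp)]) / 2 * diff(grid))
  }, numeric(1))
}

# numerical-convolution oracle for any impulse response function
oracle_tac <- function(irf_fun, input, schedule, dt = 0.005) {
  pumba:::numeric_conv(irf_fun, input, schedule$mid, dt = dt)
}
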