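test_that("model designs place covariates exactly where the model specification asks", {
  set.seed(1)
  cfg <- generative_config("2tc", "parameter", delta = 0.1, n_per_group = 10)
  tab <- generate_parameter_dataset(cfg)
  spec <- spec_for(cfg)
  model <- build_pumba(spec, tab)
  # group enters only the binding parameter's design
  expect_equal(model$xnames,
               list(character(0), character(0), "grouppatient",
                    character(0)))
  expect_true(all(c("rfe_1", "rfe_3", "Omega_s", "Omega_e", "Omega_r") %in%
                    model$monitors))
  # age + sex on both parameters, group only on binding: 5 coefficients
  set.seed(2)
  cfg1 <- generative_config("1tc", "parameter", delta = 0, n_per_group = 10)
  tab1 <- generate_parameter_dataset(cfg1)
  tab1$age <- rnorm(nrow(tab1))
  tab1$sex <- factor(rep(c("f", "m"), length.out = nrow(tab1)))
  pf <- cfg1$profile
  spec1 <- pumba_spec(pf$parameters,
                      formulas = list(K1 = ~ age + sex,
                                      VT = ~ age + sex + group),
                      binding = "VT", delivery = "K1",
                      priors = default_priors(pf$central_values))
  model1 <- build_pumba(spec1, tab1)
  expect_equal(sum(lengths(model1$xnames)), 5)
  # both parameters region-fixed: no pooled region block in the code
  expect_false(grepl("Omega_r", model1$code))
})

test_that("input validation catches structural problems", {
  set.seed(3)
  cfg <- generative_config("2tc", "parameter", n_per_group = 10)
  tab <- generate_parameter_dataset(cfg)
  spec <- spec_for(cfg)
  expect_error(build_pumba(spec, tab[tab$subject == "s001", ]),
               "at least 2 subjects")
  expect_error(build_pumba(spec, tab[, -4]), "lacks column")
  tab2 <- tab
  tab2$logBPP[5] <- NA
  expect_warning(build_pumba(spec, tab2), "incomplete")
  # rank-deficient design
  tab3 <- tab
  tab3$dup <- as.integer(tab3$group == "patient")
  pf <- cfg$profile
  spec3 <- pumba_spec(pf$parameters, formulas = list(BPP = ~ group + dup),
                      binding = "BPP", delivery = "K1",
                      priors = default_priors(pf$central_values))
  expect_error(build_pumba(spec3, tab3), "rank-deficient")
})

test_that("fitting is deterministic given the seed", {
  set.seed(4)
  cfg <- generative_config("1tc", "parameter", delta = 0.1, n_per_group = 8)
  tab <- generate_parameter_dataset(cfg)
  spec <- spec_for(cfg)
  f1 <- quick_fit(tab, spec, seed = 42, chains = 2, warmup = 200,
                  sampling = 200)
  f2 <- quick_fit(tab, spec, seed = 42, chains = 2, warmup = 200,
                  sampling = 200)
  expect_equal(f1$summary, f2$summary)
  f3 <- quick_fit(tab, spec, seed = 43, chains = 2, warmup = 200,
                  sampling = 200)
  expect_false(identical(f1$summary$mean, f3$summary$mean))
})

test_that("posterior summaries expose interval, convergence and backend metadata", {
  set.seed(5)
  cfg <- generative_config("1tc", "parameter", delta = 0.1, n_per_group = 10)
  tab <- generate_parameter_dataset(cfg)
  fit <- quick_fit(tab, spec_for(cfg), seed = 7)
  s <- fit$summary
  expect_true(all(c("quantity", "mean", "sd", "q2.5", "q97.5", "rhat",
                    "ess") %in% names(s)))
  expect_true(all(s$q2.5 <= s$mean + 1e-9 & s$mean <= s$q97.5 + 1e-9))
  expect_true(all(is.finite(s$rhat)))
  expect_true(is.na(fit$meta$divergences))
  gd <- extract_group_difference(fit, "VT")
  expect_lt(gd$ci_low, gd$estimate)
  expect_gt(gd$ci_high, gd$estimate)
  expect_error(extract_group_difference(fit, "K1"), "group")
})

test_that("adding a constant to one parameter column shifts only its intercept", {
  set.seed(6)
  cfg <- generative_config("1tc", "parameter", delta = 0.1, n_per_group = 10)
  tab <- generate_parameter_dataset(cfg)
  spec <- spec_for(cfg)
  f0 <- quick_fit(tab, spec, seed = 8)
  tab_shift <- tab
  tab_shift$logK1 <- tab_shift$logK1 + 0.5
  # keep the intercept prior aligned with the shifted column
  pf <- cfg$profile
  cv <- pf$central_values
  cv["K1"] <- cv["K1"] * exp(0.5)
  spec_shift <- pumba_spec(pf$parameters, formulas = list(VT = ~ group),
                           binding = "VT", delivery = "K1",
                           priors = default_priors(cv))
  f1 <- quick_fit(tab_shift, spec_shift, seed = 8)
  a0 <- f0$summary[f0$summary$quantity == "alpha[K1]", ]
  a1 <- f1$summary[f1$summary$quantity == "alpha[K1]", ]
  mc <- 3 * sqrt(a0$sd^2 + a1$sd^2)
  expect_lt(abs((a1$mean - a0$mean) - 0.5), mc)
  r0 <- f0$summary[f0$summary$quantity == "cor_subject[K1,VT]", ]
  r1 <- f1$summary[f1$summary$quantity == "cor_subject[K1,VT]", ]
  expect_lt(abs(r1$mean - r0$mean), 3 * sqrt(r0$sd^2 + r1$sd^2))
})

test_that("a single unpooled parameter reduces to ordinary linear regression", {
  set.seed(7)
  n <- 40
  grp <- factor(rep(c("control", "patient"), each = n / 2),
                levels = c("control", "patient"))
  tab <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), each = 2),
    region = rep(c("a", "b"), n),
    group = rep(grp, each = 2),
    logVT = rnorm(2 * n, 2, 0.3))
  tab$logVT <- tab$logVT + 0.3 * (tab$group == "patient")
  pr <- default_priors(c(VT = exp(2)), intercept_sd = 10, beta_sd = 10,
                       region_fe_sd = 10)
  spec <- pumba_spec("VT", formulas = list(VT = ~ group),
                     region_fixed = c(VT = TRUE), priors = pr,
                     pool_subjects = FALSE)
  fit <- quick_fit(tab, spec, seed = 9, chains = 2, warmup = 400,
                   sampling = 600)
  ols <- lm(logVT ~ group + region, data = tab)
  b <- fit$summary[fit$summary$quantity == "beta[VT:grouppatient]", ]
  expect_lt(abs(b$mean - coef(ols)["grouppatient"]), 3 * b$sd)
  expect_equal(b$sd, summary(ols)$coefficients["grouppatient", 2],
               tolerance = 0.15)
})

test_that("prior utilities do log arithmetic and round-trip correctly", {
  pr <- default_priors(c(K1 = 0.35, VND = 1.4, BPP = 1.5, k4 = 0.06))
  # halving a central value shifts its intercept prior mean by -log(2)
  pr2 <- default_priors(c(K1 = 0.175, VND = 1.4, BPP = 1.5, k4 = 0.06))
  expect_equal(pr2$intercept_mean[["K1"]] - pr$intercept_mean[["K1"]],
               -log(2))
  set.seed(10)
  pp <- perturb_intercept_priors(pr)
  shifts <- pp$intercept_mean - pr$intercept_mean
  expect_true(all(abs(abs(shifts) - 0.69) < 1e-12))
  # serialisation round trip through YAML
  cfgp <- tempfile(fileext = ".yaml")
  spec <- pumba_spec(c("K1", "VND", "BPP", "k4"),
                     formulas = list(BPP = ~ group),
                     binding = "BPP", delivery = "K1", priors = pr)
  write_spec_yaml(spec, cfgp)
  spec2 <- read_spec_yaml(cfgp)
  expect_equal(spec2$priors$intercept_mean, pr$intercept_mean,
               tolerance = 1e-12)
  expect_equal(spec2$region_fixed, spec$region_fixed)
  expect_equal(deparse(spec2$formulas$BPP), deparse(spec$formulas$BPP))
})
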