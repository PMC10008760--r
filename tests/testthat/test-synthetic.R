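test_that("degenerate noise reproduces intercepts plus region offsets exactly", {
  pf <- synthetic_profile("2tc")
  cfg <- generative_config("2tc", "parameter", delta = 0, n_per_group = 3,
                           overrides = list(
                             subject_sds = setNames(rep(0, 4), pf$parameters),
                             resid_sds = setNames(rep(0, 4), pf$parameters)))
  tab <- generate_parameter_dataset(cfg)
  for (p in pf$parameters) {
    expected <- pf$alpha[p] + pf$region_offsets[tab$region, p]
    expect_equal(tab[[paste0("log", p)]], unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("the generated group difference averages to delta across replicates", {
  cfg <- generative_config("2tc", "parameter", delta = 0.1, n_per_group = 50)
  study <- make_study(cfg, 40, master_seed = 11)
  diffs <- vapply(seq_len(study$replicates), function(r) {
    tab <- study$generate(r)
    gm <- tapply(tab$logBPP, tab$group, mean)
    unname(gm["patient"] - gm["control"])
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.1), 3 * mc_se)
})

test_that("the diagonal-covariance variant decorrelates subject deviations", {
  cfg <- generative_config("2tc", "parameter", delta = 0, n_per_group = 100,
                           uncorrelated = TRUE)
  set.seed(12)
  tab <- generate_parameter_dataset(cfg)
  # subject-level deviations: average parameters within subject, centre per
  # region first to remove the fixed offsets
  pars <- cfg$profile$parameters
  dev <- sapply(paste0("log", pars), function(cl)
    tapply(tab[[cl]] - stats::ave(tab[[cl]], tab$region), tab$subject, mean))
  r <- cor(dev)[lower.tri(diag(4))]
  expect_lt(max(abs(r)), 4 / sqrt(200))
  # and the correlated default really is correlated
  cfg2 <- generative_config("2tc", "parameter", delta = 0,
                            n_per_group = 100)
  set.seed(12)
  tab2 <- generate_parameter_dataset(cfg2)
  dev2 <- sapply(paste0("log", pars), function(cl)
    tapply(tab2[[cl]] - stats::ave(tab2[[cl]], tab2$region), tab2$subject,
           mean))
  expect_gt(cor(dev2)["logK1", "logBPP"], 0.5)
})

test_that("truth-table marginals match the configured distribution", {
  cfg <- generative_config("2tc", "parameter", delta = 0, n_per_group = 100)
  study <- make_study(cfg, 6, master_seed = 13)
  pf <- cfg$profile
  z <- unlist(lapply(seq_len(study$replicates), function(r) {
    tab <- study$generate(r)
    sdtot <- sqrt(pf$subject_sds["BPP"]^2 + pf$resid_sds["BPP"]^2)
    (tab$logBPP - pf$alpha["BPP"] - pf$region_offsets[tab$region, "BPP"]) /
      sdtot
  }))
  expect_gt(length(z), 1e4)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(z), 0, tolerance = 4 / sqrt(length(z) / 9))
})

test_that("TAC generation is noiseless at multiplier 0 and scales with it", {
  pf <- synthetic_profile("2tc")
  base <- list(mode = "tac", model_id = "2tc", delta = 0.1, n_per_group = 2)
  cfg0 <- generative_config("2tc", "tac", delta = 0.1, n_per_group = 2,
                            error_multiplier = 0)
  set.seed(14)
  ds0 <- generate_tac_dataset(cfg0)
  # recompute the noiseless curve from the truth table for one cell
  row <- ds0$truth[1, ]
  p <- pk_2tc(exp(row$logK1), exp(row$logVND), exp(row$logBPP),
              exp(row$logk4))
  clean <- simulate_tac_2tc(p, ds0$input, ds0$schedule)
  got <- ds0$tacs[ds0$tacs$subject == row$subject &
                    ds0$tacs$region == row$region, ]
  expect_equal(got$value, clean$values, tolerance = 1e-10)

  # same replicate seed, multiplier 4 vs 1: residual SDs in exact ratio 4
  mk <- function(mult) {
    cfg <- generative_config("2tc", "tac", delta = 0.1, n_per_group = 2,
                             error_multiplier = mult)
    make_study(cfg, 1, master_seed = 15)$generate(1)
  }
  ds1 <- mk(1); ds4 <- mk(4)
  expect_equal(ds1$truth, ds4$truth)
  resid1 <- ds1$tacs$value - mk(0)$tacs$value
  resid4 <- ds4$tacs$value - mk(0)$tacs$value
  expect_equal(sd(resid4) / sd(resid1), 4, tolerance = 1e-9)
})

test_that("NLS on generated TACs recovers the true binding parameter", {
  cfg <- generative_config("2tc", "tac", delta = 0.1, n_per_group = 2,
                           error_multiplier = 1)
  set.seed(16)
  ds <- generate_tac_dataset(cfg)
  tacs <- ds$tacs
  keys <- unique(tacs[, c("subject", "region")])
  est <- truth <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    d <- tacs[tacs$subject == keys$subject[i] &
                tacs$region == keys$region[i], ]
    tc <- tac(frame_schedule(d$frame_start_min, d$frame_dur_min), d$value,
              d$weight)
    fit <- fit_nls(tc, "2tc", ds$input, starts = 3)
    est[i] <- fit$estimates["logBPP"]
    truth[i] <- ds$truth$logBPP[ds$truth$subject == keys$subject[i] &
                                  ds$truth$region == keys$region[i]]
  }
  expect_gt(cor(est, truth), 0.5)
  bias <- mean(est - truth)
  expect_lt(abs(bias), 0.5)
})

test_that("studies are reproducible from their seed ledger", {
  cfg <- generative_config("1tc", "parameter", delta = 0.1, n_per_group = 5)
  s1 <- make_study(cfg, 3, master_seed = 99)
  s2 <- make_study(cfg, 3, master_seed = 99)
  expect_equal(s1$seeds, s2$seeds)
  expect_equal(s1$generate(2), s2$generate(2))
  s3 <- make_study(cfg, 3, master_seed = 100)
  expect_false(any(s1$seeds$seed %in% s3$seeds$seed))
  # full-scale study conditions are constructible and lazily generated
  big <- make_study(generative_config("2tc", "tac", delta = 0.182,
                                      n_per_group = 100), 500,
                    master_seed = 1)
  expect_equal(nrow(big$seeds), 500)
  expect_equal(anyDuplicated(big$seeds$seed), 0)
})
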