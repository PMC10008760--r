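test_that("frame schedules and AIFs validate their invariants", {
  expect_s3_class(frame_schedule(c(0, 1), c(1, 2)), "frame_schedule")
  expect_error(frame_schedule(c(0, 1), c(1, -1)), "positive")
  expect_error(frame_schedule(c(1, 0), c(1, 1)), "increasing")
  expect_error(frame_schedule(c(0, 0.5), c(1, 1)), "overlap")
  expect_error(aif(c(0.5, 1), c(0, 1)), "start at 0")
  expect_error(aif(c(0, 1), c(1, 2)), "time 0 must be 0")
  expect_error(aif(c(0, 1), c(0, -1)), "nonnegative")
  sch <- default_frame_schedule()
  expect_equal(length(sch$mid), 20)
  expect_equal(sch$mid, sch$start + sch$dur / 2)
  # schedule beyond AIF support is rejected
  short <- aif(c(0, 10), c(0, 1))
  expect_error(simulate_tac_1tc(pk_1tc(0.1, 2), short, sch), "support")
})

test_that("derived micro-constants follow the standard mappings", {
  p <- pk_2tc(K1 = 0.2, VND = 0.5, BPP = 1.0, k4 = 0.05)
  expect_equal(p$k2, 0.2 / 0.5)
  expect_equal(p$k3, 0.05 * 1.0 / 0.5)
  expect_equal(p$VT, p$VND + p$BPP)
  expect_equal(p$BPND, p$BPP / p$VND)
  p1 <- pk_1tc(0.1, 2)
  expect_equal(p1$k2, 0.05)
  ps <- pk_srtm(0.8, 0.1, 1.5)
  expect_equal(ps$k2, 0.08)
  expect_equal(ps$k2a, 0.08 / 2.5)
  expect_error(pk_2tc(-0.1, 0.5, 1, 0.05), "positive")
})

test_that("analytic convolution matches the numerical oracle", {
  input <- simulate_aif()
  sch <- default_frame_schedule()
  rel_err <- function(model, oracle) {
    keep <- oracle > 1e-6 * max(oracle)
    max(abs(model[keep] - oracle[keep]) / oracle[keep])
  }
  p <- pk_2tc(0.2, 0.5, 1.0, 0.05)
  ir <- pumba:::irf_2tc(p)
  o2 <- oracle_tac(function(t) ir$phi[1] * exp(-ir$theta[1] * t) +
                     ir$phi[2] * exp(-ir$theta[2] * t), input, sch)
  expect_lt(rel_err(simulate_tac_2tc(p, input, sch)$values, o2), 1e-3)

  p1 <- pk_1tc(0.1, 2)
  o1 <- oracle_tac(function(t) p1$K1 * exp(-p1$k2 * t), input, sch)
  expect_lt(rel_err(simulate_tac_1tc(p1, input, sch)$values, o1), 1e-3)

  ref <- simulate_tac_1tc(pk_1tc(0.4, 3), input, sch)
  ps <- pk_srtm(0.8, 0.1, 1.5)
  ref_input <- aif(c(0, ref$schedule$mid), c(0, ref$values))
  conv_o <- oracle_tac(function(t) exp(-ps$k2a * t), ref_input, sch)
  cr <- approx(c(0, ref$schedule$mid), c(0, ref$values),
               xout = sch$mid, rule = 2)$y
  os <- ps$R1 * cr + (ps$k2 - ps$R1 * ps$k2a) * conv_o
  expect_lt(rel_err(simulate_tac_srtm(ps, ref, sch)$values, os), 1e-3)
})

test_that("limiting cases of the forward models hold", {
  input <- simulate_aif()
  sch <- default_frame_schedule()
  # 2TC with BPP -> 0 collapses to a 1TC with k2 = K1/VND
  t2 <- simulate_tac_2tc(pk_2tc(0.2, 0.5, 1e-9, 0.05), input, sch)
  t1 <- simulate_tac_1tc(pk_1tc(0.2, 0.5), input, sch)
  expect_equal(t2$values, t1$values, tolerance = 1e-6)
  # zero-input initial condition
  expect_equal(t2$values[1], 0)
  # 1TC amplitude linearity: doubling K1 at fixed efflux rate k2 = K1/VT
  # (i.e. doubling K1 and VT together) doubles the curve
  a <- simulate_tac_1tc(pk_1tc(0.1, 2), input, sch)$values
  b <- simulate_tac_1tc(pk_1tc(0.2, 4), input, sch)$values
  expect_equal(b, 2 * a, tolerance = 1e-12)
  # irreversible limit: k2 -> 0 gives K1 x running integral of the input
  irr <- simulate_tac_1tc(pk_1tc(0.1, 1e9), input, sch)$values
  expect_equal(irr, 0.1 * aif_integral(input, sch$mid), tolerance = 1e-4)
  # SRTM with R1 = 1, BPND -> 0: target equals reference
  ref <- simulate_tac_1tc(pk_1tc(0.4, 3), input, sch)
  same <- simulate_tac_srtm(pk_srtm(1, 0.1, 1e-12), ref, sch)
  expect_equal(same$values, approx(c(0, ref$schedule$mid),
                                   c(0, ref$values), xout = sch$mid)$y,
               tolerance = 1e-8)
})

test_that("doubling BPND raises the SRTM curve at every frame past the peak", {
  input <- simulate_aif()
  sch <- default_frame_schedule()
  ref <- simulate_tac_1tc(pk_1tc(0.4, 3), input, sch)
  lo <- simulate_tac_srtm(pk_srtm(0.8, 0.1, 1.5), ref, sch)$values
  hi <- simulate_tac_srtm(pk_srtm(0.8, 0.1, 3.0), ref, sch)$values
  past_peak <- seq(which.max(lo) + 1, length(lo))
  expect_true(all(hi[past_peak] > lo[past_peak]))
})

test_that("frame weights behave as a relative counts-model scheme", {
  # identical frames, constant activity, negligible decay -> uniform weights
  sch <- frame_schedule(0:4, rep(1, 5))
  w <- tac_weights(tac(sch, rep(2, 5)), halflife = 1e12)
  expect_equal(w, rep(1, 5))
  # 4x duration at equal decay-corrected activity -> 4x weight
  sch2 <- frame_schedule(c(0, 1), c(1, 4))
  halflife <- 20.4
  lam <- log(2) / halflife
  # equalise decay-corrected count rate C * exp(lambda * t_mid)
  v1 <- 1
  v2 <- v1 * exp(lam * (sch2$mid[1] - sch2$mid[2]))
  w2 <- tac_weights(tac(sch2, c(v1, v2)), halflife = halflife)
  expect_equal(w2[2] / w2[1], 4, tolerance = 1e-12)
  # invariance to rescaling the TAC
  sch3 <- default_frame_schedule()
  vals <- simulate_tac_1tc(pk_1tc(0.1, 2), simulate_aif(), sch3)$values
  vals[1] <- 1e-6
  expect_equal(tac_weights(tac(sch3, vals)),
               tac_weights(tac(sch3, 7.3 * vals)), tolerance = 1e-12)
  expect_equal(mean(tac_weights(tac(sch3, vals))), 1)
  expect_error(tac_weights(tac(sch3, rep(0, 20))), "no positive frames")
  expect_error(tac_weights(tac(sch3, rep(1, 20)), halflife = -1), "positive")
})
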