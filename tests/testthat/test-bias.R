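test_that("transmit bias scales angles and squares into apparent T1", {
  expect_identical(apply_transmit_bias(c(5, 20), 1), c(5, 20))
  expect_equal(apply_transmit_bias(10, 1.1), 11)
  expect_error(apply_transmit_bias(120, 1.6), "180")
  expect_error(apply_transmit_bias(10, -1), "f")

  expect_equal(correct_apparent_t1(1.21, 1.1), 1)
  expect_identical(correct_apparent_t1(2.41, 1), 2.41)
  m <- array(c(1.21, NA, 0.9025), c(3, 1, 1))
  out <- correct_apparent_t1(m, c(1.1, 1, 0.95))
  expect_equal(out[1], 1); expect_true(is.na(out[2])); expect_equal(out[3], 1)
  expect_error(correct_apparent_t1(-1, 1), "positive")
})

test_that("small-angle transmit bias inflates T1 by f^2 and A by f", {
  f <- 1.1; t1 <- 1; tr <- 0.011; amp <- 50
  d <- generate_vfa_signals(alpha_deg = seq(2, 15, 1), tr_s = tr, t1 = t1,
                            amplitude = amp, b1 = f)
  # fit against NOMINAL angles
  fit <- vfa_fit(d)
  ratio <- coef(fit)[["t1"]] / t1
  expect_equal(ratio, f^2, tolerance = 5e-3)             # 1.21 within 0.5%
  expect_equal(correct_apparent_t1(coef(fit)[["t1"]], f), t1,
               tolerance = 5e-3)
  expect_equal(coef(fit)[["amplitude"]], f * amp, tolerance = 5e-3)
  # correction commutes with signal rescaling
  d2 <- d; d2$signal <- d2$signal * 4
  expect_equal(correct_apparent_t1(coef(vfa_fit(d2))[["t1"]], f),
               correct_apparent_t1(coef(fit)[["t1"]], f), tolerance = 1e-10)
})

test_that("T1 recovery after f^2 correction across the bias range", {
  for (f in c(0.8, 0.9, 1.2)) {
    d <- generate_vfa_signals(alpha_deg = seq(2, 15, 1), tr_s = 0.011,
                              t1 = 0.85, amplitude = 10, b1 = f)
    t1app <- coef(vfa_fit(d))[["t1"]]
    expect_equal(correct_apparent_t1(t1app, f), 0.85, tolerance = 7e-3)
  }
})

test_that("clean data yield no exclusions in one pass", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100)
  rep0 <- detect_signal_bias(d)
  expect_true(all(rep0$included))
  expect_identical(rep0$iterations, 1L)
  expect_length(rep0$flagged_low, 0)
  expect_length(rep0$flagged_high, 0)
  expect_output(print(rep0), "no samples flagged")
  expect_error(detect_signal_bias(d[1:3, ]), "at least 4")
})

test_that("high-angle spoiling deviations are flagged exactly", {
  # MnCl2-like fixture: -5% multiplicative deviation for angles above 15 deg
  dev <- vfa_deviation("high_angle_multiplicative", magnitude = 0.05,
                       onset_alpha_deg = 15, sign = -1, ramp = FALSE)
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                            sigma = 0.02, seed = 21, deviation = dev)
  rep1 <- detect_signal_bias(d, sigma = 0.02)
  expect_setequal(rep1$flagged_high, which(d$alpha_deg > 15))
  expect_length(rep1$flagged_low, 0)
  # final fit on the unbiased subset recovers the truth
  expect_equal(coef(rep1$final_fit)[["t1"]], 0.54, tolerance = 0.01)
})

test_that("low-angle offsets are flagged on the low side", {
  dev <- vfa_deviation("low_angle_offset", magnitude = 0.02,
                       onset_alpha_deg = 2, sign = +1)
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                            sigma = 0.02, seed = 22, deviation = dev)
  rep2 <- detect_signal_bias(d, sigma = 0.02)
  expect_setequal(rep2$flagged_low, which(d$alpha_deg <= 2))
  expect_length(rep2$flagged_high, 0)
})

test_that("false-positive rate on clean noisy data is controlled", {
  # per iteration the chance of any |z| > 3 under Gaussian noise is at
  # most 2*pnorm(-3)*N ~ 3.5% for N = 13; allow binomial slack
  n_sets <- 150
  flagged <- vapply(seq_len(n_sets), function(i) {
    d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                              sigma = 0.2, seed = 1000 + i)
    r <- detect_signal_bias(d, sigma = 0.2)
    sum(!r$included)
  }, 0)
  p_bound <- 2 * pnorm(-3) * nrow(mncl2_design())
  expect_lt(mean(flagged > 0), p_bound + 3 * sqrt(p_bound / n_sets))
})

test_that("sigma is estimated from central residuals when not supplied", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                            sigma = 0.3, seed = 30)
  r <- detect_signal_bias(d)
  expect_equal(r$sigma[1], 0.3, tolerance = 0.8)  # order of magnitude
  # per-sample sd column is honoured
  d$sd <- rep(0.3, nrow(d))
  r2 <- detect_signal_bias(d)
  expect_identical(r2$sigma, d$sd)
})
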