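test_that("noiseless generation reduces to the exact Ernst model", {
  d <- generate_vfa_signals(vfa_protocol("brain_invivo"), t1 = 1.29,
                            amplitude = 3)
  e1 <- exp(-d$tr_s / 1.29)
  expect_equal(d$signal, ernst_signal(3, d$alpha_deg, e1), tolerance = 1e-14)
  expect_error(generate_vfa_signals(alpha_deg = 10, tr_s = 0.01, t1 = 1,
                                    sigma = 0.1), "seed")
  expect_error(generate_vfa_signals(t1 = 1), "supply either")
})

test_that("generation is bit-reproducible and preserves the RNG state", {
  set.seed(99); marker <- runif(1); set.seed(99)
  d1 <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10,
                             sigma = 0.1, seed = 5)
  d2 <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10,
                             sigma = 0.1, seed = 5)
  expect_identical(d1, d2)
  expect_identical(runif(1), marker)
})

test_that("gaussian noise has the requested variance", {
  sigma <- 0.37
  d <- generate_vfa_signals(alpha_deg = rep(20, 1e5), tr_s = 0.01, t1 = 1,
                            amplitude = 5, sigma = sigma, seed = 12)
  mu <- ernst_signal(5, 20, exp(-0.01))
  expect_equal(var(d$signal), sigma^2, tolerance = 0.02)
  expect_equal(mean(d$signal), mu, tolerance = 0.01)
})

test_that("rician noise carries the analytic low-noise positive bias", {
  # E[R] - S ~ sigma^2/(2S): at SNR 50 the offset is ~1% of sigma
  amp <- 5; alpha <- 30; tr <- 0.02; t1 <- 1
  S <- ernst_signal(amp, alpha, exp(-tr / t1))
  sigma <- S / 50
  d <- generate_vfa_signals(alpha_deg = rep(alpha, 2e5), tr_s = tr, t1 = t1,
                            amplitude = amp, sigma = sigma, noise = "rician",
                            seed = 77)
  offset <- mean(d$signal) - S
  expect_equal(offset, sigma^2 / (2 * S), tolerance = 0.15)
  expect_lt(abs(offset), 0.02 * sigma)
})

test_that("deviation kinds modify the ideal curve as designed", {
  base <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100)
  none <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                               deviation = vfa_deviation("none"))
  expect_identical(base$signal, none$signal)

  dev <- vfa_deviation("high_angle_multiplicative", 0.05, 15, sign = -1,
                       ramp = FALSE)
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
                            deviation = dev)
  hi <- base$alpha_deg > 15
  expect_equal(d$signal[hi], 0.95 * base$signal[hi], tolerance = 1e-14)
  expect_identical(d$signal[!hi], base$signal[!hi])

  ramped <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
    deviation = vfa_deviation("high_angle_multiplicative", 0.05, 15,
                              sign = -1, ramp = TRUE))
  frac <- 1 - ramped$signal[hi] / base$signal[hi]
  expect_true(all(diff(frac) > 0))            # grows with angle
  expect_equal(max(frac), 0.05, tolerance = 1e-12)

  off <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 100,
    deviation = vfa_deviation("low_angle_offset", 0.01, 2, sign = 1))
  lo <- base$alpha_deg <= 2
  expect_equal(off$signal[lo], base$signal[lo] + 1, tolerance = 1e-12)
  expect_identical(off$signal[!lo], base$signal[!lo])
})

test_that("slice-profile integration reproduces the known distortions", {
  t1 <- 2.41; tr <- 0.007; amp <- 1
  e1 <- exp(-tr / t1)
  alphas <- seq(1, 40, 0.5)
  ideal <- ernst_signal(amp, alphas, e1)

  # boxcar profile is the nonselective signal
  box <- slice_profile_signal(alphas, rep(1, 11), t1, tr, amp)
  expect_equal(box, ideal, tolerance = 1e-12)

  gauss <- exp(-seq(-2, 2, length.out = 41)^2)
  prof <- slice_profile_signal(alphas, gauss, t1, tr, amp)
  # maximum shifts to higher nominal angle than the nonselective Ernst angle
  expect_gt(alphas[which.max(prof)], alphas[which.max(ideal)])
  # positive bias of the high-angle tail relative to the (scaled) ideal:
  # compare shapes normalized at a low angle where both are linear
  k <- which(alphas == 2)
  expect_gt(prof[length(alphas)] / prof[k], ideal[length(alphas)] / ideal[k])

  expect_error(slice_profile_signal(10, numeric(0), t1, tr), "profile")
  expect_error(slice_profile_signal(10, c(-1, 1), t1, tr), "profile")
  expect_error(slice_profile_signal(10, c(0, 0), t1, tr), "zero")
})

test_that("phantom volumes embed the exact model per compartment", {
  p <- vfa_phantom("brain3c", dim = c(12, 12, 12))
  st <- generate_phantom_volumes(p, alpha_deg = c(2, 5, 9, 14, 18),
                                 tr_s = 0.011)
  expect_s3_class(st, "vfa_stack")
  lab <- p$labels
  for (k in 1:3) {
    vox <- which(lab == k)[1]
    s_expect <- algebraic_signal(p$amplitude[k],
                                 tau_from_alpha(5),
                                 rho1_from_relaxation(0.011, p$t1[k]))
    expect_equal(st$volumes[[2]][vox], s_expect, tolerance = 1e-14)
  }
  expect_true(all(st$volumes[[1]][lab == 0] == 0))
  # determinism with noise
  s1 <- generate_phantom_volumes(p, c(2, 9), 0.011, sigma = 0.01, seed = 4)
  s2 <- generate_phantom_volumes(p, c(2, 9), 0.011, sigma = 0.01, seed = 4)
  expect_identical(s1$volumes, s2$volumes)
  expect_error(generate_phantom_volumes(p, c(2, 9), 0.011, sigma = 0.01),
               "seed")
  expect_error(vfa_phantom("agar", dim = c(100, 10, 10)), "\\[4, 64\\]")
})
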