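test_that("all estimators recover the truth exactly on noiseless data", {
  amp <- 100; t1 <- 0.54; tr <- 0.007
  d <- generate_vfa_signals(mncl2_design(), t1 = t1, amplitude = amp)
  rho1 <- rho1_from_relaxation(tr, t1)

  for (m in c("linear", "conventional")) {
    f <- vfa_fit(d, method = m)
    expect_lt(rel_err(coef(f)[["amplitude"]], amp), 1e-10)
    expect_lt(rel_err(coef(f)[["rho1"]], rho1), 1e-10)
    expect_lt(rel_err(coef(f)[["t1"]], t1), 1e-8)
  }
  fn <- vfa_fit(d, method = "nonlinear")
  expect_true(fn$converged)
  expect_lt(rel_err(coef(fn)[["amplitude"]], amp), 1e-6)
  expect_lt(rel_err(coef(fn)[["t1"]], t1), 1e-6)
  # linear and conventional agree with each other on exact data
  expect_equal(coef(vfa_fit(d))[["t1"]],
               coef(vfa_fit(d, method = "conventional"))[["t1"]],
               tolerance = 1e-9)
})

test_that("conventional comparator has slope E1 and intercept A(1-E1)", {
  # E1 = 0.6, A = 1: regression of S/sin on S/tan
  tr <- -log(0.6) * 1       # T1 = 1 s
  alpha <- c(5, 10, 20, 35, 50, 70)
  d <- generate_vfa_signals(alpha_deg = alpha, tr_s = tr, t1 = 1)
  a <- alpha * pi / 180
  cf <- lm(I(d$signal / sin(a)) ~ I(d$signal / tan(a)))
  expect_equal(unname(coef(cf)[2]), 0.6, tolerance = 1e-10)
  expect_equal(unname(coef(cf)[1]), 0.4, tolerance = 1e-10)
  f <- vfa_fit(d, method = "conventional")
  expect_equal(coef(f)[["e1"]], 0.6, tolerance = 1e-10)
  expect_equal(coef(f)[["amplitude"]], 1, tolerance = 1e-9)
})

test_that("estimators are scale-equivariant and permutation-invariant", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 1,
                            sigma = 0.002, seed = 11)
  for (m in c("linear", "conventional", "nonlinear")) {
    f1 <- vfa_fit(d, method = m)
    d2 <- d; d2$signal <- d2$signal * 37
    f2 <- vfa_fit(d2, method = m)
    expect_equal(coef(f2)[["amplitude"]], 37 * coef(f1)[["amplitude"]],
                 tolerance = 1e-8)
    expect_equal(coef(f2)[["t1"]], coef(f1)[["t1"]], tolerance = 1e-8)
    d3 <- d[sample(nrow(d)), ]
    expect_equal(coef(vfa_fit(d3, method = m)), coef(f1), tolerance = 1e-9)
  }
  # replicated flip angles are legal repeated abscissae
  d4 <- rbind(d, d[3:5, ])
  expect_silent(vfa_fit(d4))
})

test_that("dual-angle closed form equals the two-point regression", {
  rho1 <- 0.5; amp <- 2
  u <- c(sqrt(2) - 1, sqrt(2) + 1)   # optimal pair; equal signals
  tau <- u * sqrt(2 * rho1)
  s <- algebraic_signal(amp, tau, rho1)
  expect_equal(s / amp, rep(0.35355, 2), tolerance = 1e-4)
  a <- alpha_from_tau(tau)
  s1 <- list(alpha_deg = a[1], tr_s = 0.01, signal = s[1])
  s2 <- list(alpha_deg = a[2], tr_s = 0.01, signal = s[2])
  f <- dual_angle_fit(s1, s2)
  expect_equal(coef(f)[["rho1"]], rho1, tolerance = 1e-12)
  expect_equal(coef(f)[["amplitude"]], amp, tolerance = 1e-12)
  # closed form rho1 = (x1-x2)/(2 (y2-y1))
  x <- s * tau; y <- s / tau
  expect_equal(coef(f)[["rho1"]], (x[1] - x[2]) / (2 * (y[2] - y[1])),
               tolerance = 1e-13)
  # identical to the general path and symmetric under swap
  g <- vfa_fit(data.frame(alpha_deg = a, tr_s = 0.01, signal = s))
  expect_identical(coef(f), coef(g))
  expect_equal(coef(dual_angle_fit(s2, s1)), coef(f), tolerance = 1e-14)
  expect_error(dual_angle_fit(s1, s1), "distinct")
})

test_that("multi-TR regression pools different repetition times", {
  d <- generate_vfa_signals(vfa_protocol("agar_multi_tr"),
                            t1 = 2.41, amplitude = 50)
  f <- vfa_fit(d, method = "multi_tr")
  expect_lt(rel_err(coef(f)[["t1"]], 2.41), 5e-4)   # within 0.05%
  expect_lt(rel_err(coef(f)[["amplitude"]], 50), 1e-3)
  # single-TR input: matches the exact path within the short-TR error
  one <- d[d$tr_s == 0.048, ]
  ft <- vfa_fit(one, method = "multi_tr")
  fl <- vfa_fit(one, method = "linear")
  approx_err <- (0.048 / 2.41)^2 / 12
  expect_lt(rel_err(coef(ft)[["t1"]], coef(fl)[["t1"]]), 2 * approx_err)
  # the short-TR bias shrinks quadratically in TR/T1
  bias_at <- function(tr) {
    di <- generate_vfa_signals(alpha_deg = seq(2, 30, 2), tr_s = tr, t1 = 1)
    abs(coef(vfa_fit(di, method = "multi_tr"))[["t1"]] - 1)
  }
  b <- vapply(c(0.02, 0.04, 0.08), bias_at, 0)
  expect_equal(b[2] / b[1], 4, tolerance = 0.1)
  expect_equal(b[3] / b[2], 4, tolerance = 0.1)
  # validity warning once TR/T1 is no longer small
  dl <- generate_vfa_signals(alpha_deg = seq(5, 120, 10), tr_s = 0.5, t1 = 1)
  expect_warning(vfa_fit(dl, method = "multi_tr"), "short-TR")
})

test_that("fit errors are informative for degenerate inputs", {
  d <- generate_vfa_signals(alpha_deg = c(5, 10, 20), tr_s = 0.01, t1 = 1)
  expect_error(vfa_fit(d[1, ]), "insufficient")
  same <- d[c(1, 1), ]
  expect_error(vfa_fit(same), "distinct")
  mixed <- d; mixed$tr_s <- c(0.01, 0.02, 0.01)
  expect_error(vfa_fit(mixed), "multi_tr")
  # rising line (signals increasing in x) has no physical relaxation term
  bad <- data.frame(alpha_deg = c(5, 10, 20), tr_s = 0.01,
                    signal = c(0.01, 0.1, 1.5))
  expect_error(vfa_fit(bad), "non-physical|degenerate")
  expect_error(vfa_fit(d, weights = c(1, 1)), "one entry per sample")
  expect_error(vfa_fit(d, weights = c(0, 0, 0)), "zero")
  neg <- d; neg$signal[2] <- -0.1
  expect_warning(f <- vfa_fit(neg), "excluded")
  expect_equal(f$n_used, 2L)
})

test_that("weights cannot move an exact line; optimal weighting iterates", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10)
  f0 <- vfa_fit(d)
  fw <- vfa_fit(d, weights = "optimal")
  expect_equal(coef(fw), coef(f0), tolerance = 1e-12)
  expect_gte(fw$passes, 2L)
  frand <- vfa_fit(d, weights = runif(nrow(d), 0.5, 2))
  expect_equal(coef(frand), coef(f0), tolerance = 1e-10)
})

test_that("linear estimates are near-unbiased in the first-order regime", {
  # ratio-type estimators carry an O((sigma/S)^2) bias; at sigma/A = 0.5%
  # on a mid-range tissue the relative bias stays below 0.2%
  amp <- 1; rho1 <- 0.5; sigma <- 0.005
  tau <- c(sqrt(2) - 1, 0.8, 1.25, sqrt(2) + 1)
  mc <- mc_linear(tau, amp, rho1, sigma, reps = 10000, seed = 42)
  expect_lt(abs(mean(mc$rho1) - rho1) / rho1, 2e-3)
  expect_lt(abs(mean(mc$amplitude) - amp) / amp, 2e-3)
  # package fit on one replicate agrees with the oracle's estimator
  t1 <- 0.54; tr <- 0.007
  d <- generate_vfa_signals(mncl2_design(), t1 = t1, amplitude = amp,
                            sigma = sigma, seed = 1)
  f <- vfa_fit(d)
  tau13 <- tau_from_alpha(d$alpha_deg)
  S <- d$signal
  x <- S * tau13; y <- S / tau13
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(coef(f)[["rho1"]], -1 / (2 * b), tolerance = 1e-12)
})

test_that("nonlinear oracle converges fast from the truth and matches", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10,
                            sigma = 0.01, seed = 3)
  fl <- vfa_fit(d)
  fn <- vfa_fit(d, method = "nonlinear")
  expect_true(fn$converged)
  expect_lt(rel_err(coef(fn)[["rho1"]], coef(fl)[["rho1"]]), 5e-3)
  rho1 <- rho1_from_relaxation(0.007, 0.54)
  d0 <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10)
  f0 <- vfa_fit(d0, method = "nonlinear",
                init = c(amplitude = 10, rho1 = rho1))
  expect_lte(f0$niter, 5L)
  expect_lt(rel_err(coef(f0)[["t1"]], coef(vfa_fit(d0))[["t1"]]), 1e-6)
})

test_that("fit methods: print, summary, predict, residuals, simulate", {
  d <- generate_vfa_signals(mncl2_design(), t1 = 0.54, amplitude = 10,
                            sigma = 0.02, seed = 5)
  f <- vfa_fit(d)
  expect_output(print(f), "VFA fit")
  expect_output(print(summary(f)), "Std. Error")
  expect_equal(predict(f), f$fitted)
  p <- predict(f, newdata = data.frame(alpha_deg = c(5, 40)))
  expect_true(all(p > 0))
  expect_equal(length(residuals(f)), nrow(d))
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_equal(names(sims[[1]]), c("alpha_deg", "tr_s", "signal", "sd"))
  # simulate is reproducible and leaves the global RNG state intact
  set.seed(123); before <- runif(1)
  set.seed(123)
  s1 <- simulate(f, seed = 7); invisible(runif(0)); s2 <- simulate(f, seed = 7)
  expect_identical(s1, s2)
  expect_equal(runif(1), before)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
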