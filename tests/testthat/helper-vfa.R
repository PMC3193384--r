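# Shared oracles and fixtures, all generated in code.

# Independent Monte-Carlo oracle for the linear-plot regression: draws
# Gaussian replicates of the model signals and solves the simple
# regression in closed form, vectorized over replicates.  Written from
# the estimator's definition, independent of the package's fitting path.
mc_linear <- function(tau, amplitude, rho1, sigma, reps, seed,
                      weights = NULL) {
  S0 <- 2 * amplitude * rho1 * tau / (tau^2 + 2 * rho1)
  set.seed(seed)
  n <- length(tau)
  S <- matrix(rnorm(reps * n, 0, sigma), nrow = reps) +
    matrix(S0, nrow = reps, ncol = n, byrow = TRUE)
  X <- sweep(S, 2L, tau, `*`)
  Y <- sweep(S, 2L, tau, `/`)
  w <- if (is.null(weights)) rep(1, n) else weights
  W <- sum(w)
  xb <- (X %*% w) / W
  yb <- (Y %*% w) / W
  dx <- X - as.vector(xb)
  dy <- Y - as.vector(yb)
  slope <- rowSums(sweep(dx * dy, 2L, w, `*`)) /
    rowSums(sweep(dx * dx, 2L, w, `*`))
  list(rho1 = -1 / (2 * slope),
       amplitude = as.vector(yb) - slope * as.vector(xb))
}

# MnCl2-like spoiling-experiment protocol (13 angles, TR 7 ms)
mncl2_design <- function() vfa_protocol("mncl2_spoiling")

# relative difference helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)
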