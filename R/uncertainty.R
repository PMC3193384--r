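#' Residual noise scaling of the linear plot
#'
#' Both coordinates of the linear plot, \eqn{x = S\tau} and
#' \eqn{y = S/\tau}, carry the same measured signal, so their errors are
#' correlated with covariance equal to the image noise variance
#' \eqn{\sigma_S^2}.  Propagating through the line residual
#' \eqn{F = y - (A - x/(2\rho_1))} gives
#' \deqn{\mathrm{var}\,F = \sigma_S^2
#'   \left[\frac{1}{\tau^2} + \frac{\tau^2}{4\rho_1^2} +
#'   \frac{1}{\rho_1}\right].}
#' This function returns the bracketed scaling factor.  It is minimal at
#' the Ernst point \eqn{\tau_E = \sqrt{2\rho_1}}, where it equals
#' \eqn{2/\rho_1}, and diverges toward both intercepts.
#'
#' @param tau half-angle tangent value(s) (> 0).
#' @param rho1 relaxation term in (0, 2).
#' @return the dimensionless variance scaling factor(s).
#' @seealso [weight_function()] for its reciprocal.
#' @export
residual_noise_scale <- function(tau, rho1) {
  .check_num(tau, "tau", lower = 0, open_lower = TRUE)
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE)
  1 / tau^2 + tau^2 / (4 * rho1^2) + 1 / rho1
}

#' Variance-cancelling regression weights
#'
#' Reciprocal of [residual_noise_scale()]: weights that cancel the
#' \eqn{\tau}-dependent scaling of the residual noise in the linear-plot
#' regression.  They are maximal at the Ernst point (value \eqn{\rho_1/2})
#' and decrease monotonically toward both intercepts.  Using them requires
#' an a-priori \eqn{\rho_1}; `vfa_fit(..., weights = "optimal")` obtains it
#' from an unweighted first pass.
#'
#' @inheritParams residual_noise_scale
#' @return weight(s) in (0, \eqn{\rho_1/2}].
#' @export
weight_function <- function(tau, rho1) {
  1 / residual_noise_scale(tau, rho1)
}

# partial derivatives of (rho1_hat, A_hat) of the linear-plot regression
# with respect to each signal, evaluated at the noiseless model point.
# Both x_i and y_i depend on S_i, so the quotient rule runs through both
# coordinates.
.vfa_partials <- function(tau, amplitude, rho1) {
  S <- .alg_signal(amplitude, tau, rho1)
  x <- S * tau
  y <- S / tau
  n <- length(tau)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx <= 0)
    stop("degenerate design: all tau values equal", call. = FALSE)
  b <- sum((x - xb) * (y - yb)) / sxx
  dSxy <- tau * (y - yb) + (x - xb) / tau
  dSxx <- 2 * tau * (x - xb)
  db <- (dSxy - b * dSxx) / sxx
  dA <- (1 / tau) / n - b * tau / n - xb * db
  drho <- db / (2 * b^2)            # rho1 = -1/(2b)
  list(drho = drho, dA = dA)
}

# normalization constants tying predictions to the dual-angle optima:
# the minimized two-point relaxation variance maps to 4.000 and the
# minimized two-point amplitude variance to 5.6133 (see optimize_schedule)
.calibration <- function(rho1) {
  key <- sprintf("cal_%.12g", rho1)
  if (!is.null(.vfatau_cache[[key]])) return(.vfatau_cache[[key]])
  min2 <- function(target) {
    obj <- function(lu) {
      p <- .vfa_partials(exp(lu) * sqrt(2 * rho1), 1, rho1)
      if (target == "rho1") sum(p$drho^2) else sum(p$dA^2)
    }
    starts <- list(c(-1, 1), c(-2, 0.5), c(-0.5, 2))
    vals <- vapply(starts, function(s)
      optim(s, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 5000))$value, 0)
    min(vals)
  }
  cal <- c(rho1 = 4 / min2("rho1"), amplitude = 5.6133 / min2("amplitude"))
  .vfatau_cache[[key]] <- cal
  cal
}

#' First-order noise propagation into the VFA estimates
#'
#' Propagates independent per-measurement Gaussian signal noise through the
#' linear-plot regression estimators of \eqn{\rho_1} and \eqn{A}.  The
#' partial derivatives \eqn{\partial\hat\rho_1/\partial S_i} and
#' \eqn{\partial\hat A/\partial S_i} are evaluated analytically at the
#' noiseless model point (both coordinates share \eqn{S_i}, so the chain
#' rule runs through abscissa and ordinate), and the variance is the sum of
#' squared partials times \eqn{\sigma_S^2}.
#'
#' The normalized variances place designs on a common unit-free scale,
#' independent of amplitude and noise level, calibrated so that the
#' optimal dual-angle (two-point) relaxation and amplitude designs score
#' 4.000 and 5.6133; m-fold replication of a design divides the variance
#' by m.
#'
#' @param taus flip-angle positions as \eqn{\tau} values (>= 2 distinct), or
#'   use `u` together with the tissue's \eqn{\tau_E}.
#' @param amplitude,rho1 tissue parameters at which to evaluate.
#' @param sigma_s per-measurement signal SD (Gaussian), same units as the
#'   amplitude.
#' @param method `"analytic"` (default) or `"numeric"` (central finite
#'   differences with step `1e-6 * S_i`, used as an internal cross-check).
#' @return a list of class `"vfa_variance"`: `var_rho1`, `var_amplitude`
#'   (absolute first-order variances), `normalized_rho1`,
#'   `normalized_amplitude` (calibrated unit-free variances), plus the
#'   evaluation settings.
#' @examples
#' u <- c(sqrt(2) - 1, sqrt(2) + 1)       # optimal dual-angle T1 design
#' v <- propagate_variance(u * 1, amplitude = 1, rho1 = 0.5, sigma_s = 1)
#' v$var_rho1          # 8.0
#' v$normalized_rho1   # 4.000 by calibration
#' @export
propagate_variance <- function(taus, amplitude = 1, rho1 = 0.5, sigma_s = 1,
                               method = c("analytic", "numeric")) {
  method <- match.arg(method)
  .check_num(taus, "taus", lower = 0, open_lower = TRUE)
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE,
             allow_vector = FALSE)
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE, allow_vector = FALSE)
  .check_num(sigma_s, "sigma_s", lower = 0, allow_vector = FALSE)
  if (length(taus) < 2L)
    stop("need at least 2 flip-angle positions", call. = FALSE)
  if (length(unique(taus)) < 2L)
    stop("degenerate design: all tau values equal", call. = FALSE)

  if (method == "analytic") {
    p <- .vfa_partials(taus, amplitude, rho1)
  } else {
    p <- .numeric_partials(taus, amplitude, rho1)
  }
  var_rho1 <- sigma_s^2 * sum(p$drho^2)
  var_amplitude <- sigma_s^2 * sum(p$dA^2)
  cal <- .calibration(rho1)
  # unit-free: variances at amplitude = 1, sigma_s = 1 for the same design.
  # first-order scaling: var_rho1 ~ (sigma_s/A)^2, var_A ~ sigma_s^2
  out <- list(var_rho1 = var_rho1,
              var_amplitude = var_amplitude,
              normalized_rho1 =
                var_rho1 * (amplitude / sigma_s)^2 * cal[["rho1"]],
              normalized_amplitude =
                var_amplitude / sigma_s^2 * cal[["amplitude"]],
              taus = taus, amplitude = amplitude, rho1 = rho1,
              sigma_s = sigma_s, method = method)
  class(out) <- "vfa_variance"
  out
}

# finite-difference partials: refit the regression after perturbing each
# signal by +/- 1e-6 * S_i
.numeric_partials <- function(tau, amplitude, rho1) {
  S0 <- .alg_signal(amplitude, tau, rho1)
  est <- function(S) {
    x <- S * tau; y <- S / tau
    xb <- mean(x); yb <- mean(y)
    b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    c(rho1 = -1 / (2 * b), A = yb - b * xb)
  }
  n <- length(tau)
  drho <- dA <- numeric(n)
  for (i in seq_len(n)) {
    h <- 1e-6 * S0[i]
    Sp <- S0; Sp[i] <- S0[i] + h
    Sm <- S0; Sm[i] <- S0[i] - h
    g <- (est(Sp) - est(Sm)) / (2 * h)
    drho[i] <- g[["rho1"]]; dA[i] <- g[["A"]]
  }
  list(drho = drho, dA = dA)
}

#' @export
print.vfa_variance <- function(x, ...) {
  cat("First-order VFA noise propagation\n")
  cat(sprintf("  design: %d points, tau = %s\n", length(x$taus),
              paste(signif(x$taus, 5), collapse = ", ")))
  cat(sprintf("  tissue: amplitude = %g, rho1 = %g; sigma_S = %g\n",
              x$amplitude, x$rho1, x$sigma_s))
  cat(sprintf("  var(rho1) = %.6g   normalized = %.4f\n",
              x$var_rho1, x$normalized_rho1))
  cat(sprintf("  var(A)    = %.6g   normalized = %.4f\n",
              x$var_amplitude, x$normalized_amplitude))
  invisible(x)
}
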