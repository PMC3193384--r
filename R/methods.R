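#' @export
print.vfa_fit <- function(x, digits = 4, ...) {
  cat(sprintf("VFA fit (%s), %d of %d samples used\n",
              x$method, x$n_used, nrow(x$data)))
  co <- x$coefficients
  cat(sprintf("  amplitude = %s   rho1 = %s   T1 = %s s\n",
              signif(co[["amplitude"]], digits),
              signif(co[["rho1"]], digits),
              signif(co[["t1"]], digits)))
  if (identical(x$converged, FALSE))
    cat("  WARNING: nonlinear fit did not converge\n")
  invisible(x)
}

#' @export
summary.vfa_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(fit = object, coefficients = tab,
                 residual_sd = sd(object$residuals[object$included])),
            class = "summary.vfa_fit")
}

#' @export
print.summary.vfa_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat(sprintf("VFA signal model fit, method \"%s\"\n", f$method))
  cat(sprintf("  %d samples used", f$n_used))
  if (any(!f$included)) cat(sprintf(" (%d excluded)", sum(!f$included)))
  cat("\n\nCoefficients:\n")
  print(signif(x$coefficients, digits))
  if (!is.na(x$residual_sd))
    cat(sprintf("\nResidual SD of the linear plot: %s\n",
                signif(x$residual_sd, digits)))
  if (!is.null(f$niter))
    cat(sprintf("Levenberg-Marquardt iterations: %d (converged: %s)\n",
                f$niter, f$converged))
  invisible(x)
}

#' Predicted VFA signals from a fitted model
#'
#' @param object a `"vfa_fit"`.
#' @param newdata optional data.frame with `alpha_deg` (and `tr_s`, needed
#'   for multi-TR fits); default: the training samples.
#' @param ... unused.
#' @return predicted signal values.
#' @export
predict.vfa_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  if (is.null(newdata)) return(object$fitted)
  if (!"alpha_deg" %in% names(newdata))
    stop("'newdata' needs an alpha_deg column", call. = FALSE)
  tau <- tau_from_alpha(newdata$alpha_deg)
  if (object$method == "multi_tr" || !is.null(newdata$tr_s)) {
    trs <- if (!is.null(newdata$tr_s)) newdata$tr_s
           else rep(object$tr_s, length(tau))
    rho <- rho1_from_relaxation(trs, co[["t1"]])
  } else {
    rho <- co[["rho1"]]
  }
  .alg_signal(co[["amplitude"]], tau, rho)
}

#' @export
residuals.vfa_fit <- function(object, type = c("linear", "signal"), ...) {
  type <- match.arg(type)
  if (type == "linear") return(object$residuals)
  object$data$signal - object$fitted
}

#' Linear display of a VFA fit
#'
#' Plots the data in the coordinates \eqn{x = S\tau}, \eqn{y = S/\tau}
#' with the fitted line, whose y-intercept is the amplitude and slope
#' \eqn{-1/(2\rho_1)}; the Ernst point sits halfway between the
#' intercepts at \eqn{y = A/2}.  Points excluded from the fit are drawn
#' open.  Systematic deviation from the line is the signature of signal
#' bias (imperfect spoiling, slice-profile effects, Rician floor).
#'
#' @param x a `"vfa_fit"`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.vfa_fit <- function(x, ...) {
  d <- x$data
  co <- x$coefficients
  plot(d$x, d$y, xlab = expression(S * tau), ylab = expression(S / tau),
       pch = ifelse(x$included, 19, 1),
       xlim = c(0, max(d$x) * 1.05), ylim = c(0, max(d$y, co[["amplitude"]]) * 1.05),
       ...)
  if (is.finite(co[["rho1"]]))
    abline(co[["amplitude"]], -1 / (2 * co[["rho1"]]), col = "grey40")
  abline(h = co[["amplitude"]] / 2, lty = 3, col = "grey70")
  invisible(x)
}

#' Simulate replicate measurements from a fitted VFA model
#'
#' Draws `nsim` noisy replicates of the training design from the fitted
#' signal model.  The noise SD defaults to an estimate from the fit's
#' y-residuals, each rescaled by its correlated-error noise factor
#' ([residual_noise_scale()]) before pooling.
#'
#' @param object a single-TR `"vfa_fit"`.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed (the global RNG state is preserved).
#' @param sigma noise SD; default estimated from the residuals.
#' @param ... unused.
#' @return a list of `nsim` data.frames of VFA samples.
#' @export
simulate.vfa_fit <- function(object, nsim = 1, seed = NULL, sigma = NULL,
                             ...) {
  co <- object$coefficients
  d <- object$data
  mu <- object$fitted
  if (is.null(sigma)) {
    r <- object$residuals[object$included]
    scl <- if (is.finite(co[["rho1"]]))
      residual_noise_scale(d$tau[object$included], co[["rho1"]])
    else 1
    sigma <- sqrt(mean(r^2 / scl))
    if (!is.finite(sigma)) sigma <- 0
  }
  with_seed(seed, lapply(seq_len(nsim), function(i)
    data.frame(alpha_deg = d$alpha_deg, tr_s = d$tr_s,
               signal = mu + rnorm(length(mu), 0, sigma),
               sd = sigma)))
}
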