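#' Fit the VFA signal model
#'
#' Estimates the signal amplitude \eqn{A} and the relaxation term
#' \eqn{\rho_1} (hence \eqn{E_1} and \eqn{T_1}) from variable flip angle
#' measurements of a spoiled gradient echo.  The default method regresses
#' \eqn{y = S/\tau} on \eqn{x = S\tau} with \eqn{\tau = 2\tan(\alpha/2)}:
#' ideal data satisfy \eqn{y = A - x/(2\rho_1)}, so the y-intercept is the
#' amplitude and the slope is \eqn{-1/(2\rho_1)}.
#'
#' Methods:
#' \describe{
#'   \item{`"linear"`}{ordinary or weighted least squares in the
#'     \eqn{(x, y)} coordinates; requires a single TR.}
#'   \item{`"multi_tr"`}{short-TR generalization using
#'     \eqn{x = S\tau/(2 TR)} as abscissa so that measurements at different
#'     TR combine into one regression whose negative slope is \eqn{T_1}
#'     directly.  Valid for \eqn{TR \ll T_1}; a warning is issued when the
#'     fitted \eqn{\max(TR/T_1)} exceeds 0.2.}
#'   \item{`"conventional"`}{the classic comparator: regression of
#'     \eqn{S/\sin\alpha} on \eqn{S/\tan\alpha}, slope \eqn{E_1},
#'     intercept \eqn{A(1-E_1)}.}
#'   \item{`"nonlinear"`}{Levenberg-Marquardt least squares of the algebraic
#'     signal model against the raw signals (via [minpack.lm::nls.lm()]);
#'     used mainly to corroborate the linear estimators.}
#' }
#'
#' With `weights = "optimal"` the linear fit is iterated: an unweighted
#' pass supplies \eqn{\rho_1}, then [weight_function()] weights (which
#' cancel the \eqn{\tau}-dependent scaling of the residual noise) are
#' applied and the fit repeated until \eqn{\rho_1} changes by less than
#' `pass_tol` (at most `max_passes` passes).  On noiseless data weighting
#' cannot move the exact line.
#'
#' Zero or negative signals (possible after background subtraction) are
#' excluded with a warning rather than failing the whole fit.
#'
#' @param data a data.frame with columns `alpha_deg` (degrees), `tr_s`
#'   (seconds), `signal` (a.u.) and optionally `sd` (signal SD, a.u.),
#'   as returned by [generate_vfa_signals()] or [read_vfa_table()].
#' @param method estimation method, see Details.
#' @param weights `NULL` (unweighted), a non-negative numeric vector, or
#'   `"optimal"` for iterated variance-cancelling weights (linear method
#'   only).
#' @param init optional named vector `c(amplitude=, rho1=)` starting the
#'   nonlinear method; defaults to the linear estimates.
#' @param max_passes,pass_tol iteration control for `weights = "optimal"`.
#' @return an object of class `"vfa_fit"`: a list with components
#'   `coefficients` (amplitude, rho1, e1, t1), `se` (delta-method standard
#'   errors, `NA` when not estimable), `slope`, `se_slope`, `residuals`
#'   (y-residuals of the linear plot, `NA` for excluded points), `fitted`
#'   (fitted signals), `included`, `n_used`, `method`, `tr_s`, `data`
#'   (input augmented with `tau`, `x`, `y`), `weights`, and for the
#'   nonlinear method `converged` and `niter`.
#' @seealso [dual_angle_fit()], [detect_signal_bias()], [fit_volume()].
#' @examples
#' d <- generate_vfa_signals(alpha_deg = c(3, 6, 10, 15, 20),
#'                           tr_s = 0.011, t1 = 1, amplitude = 100)
#' f <- vfa_fit(d)
#' coef(f)["t1"]   # 1 s, exactly, on noiseless data
#' @export
vfa_fit <- function(data,
                    method = c("linear", "conventional", "multi_tr",
                               "nonlinear"),
                    weights = NULL, init = NULL,
                    max_passes = 10L, pass_tol = 1e-6) {
  method <- match.arg(method)
  data <- .as_signal_set(data)
  n <- nrow(data)
  included <- data$signal > 0
  if (!all(included))
    warning(sprintf("%d sample(s) with non-positive signal excluded from fit",
                    sum(!included)), call. = FALSE)
  if (sum(included) < 2L)
    stop("insufficient data: need at least 2 samples with positive signal",
         call. = FALSE)

  tau <- tau_from_alpha(data$alpha_deg)
  data$tau <- tau
  data$x <- data$signal * tau
  data$y <- data$signal / tau

  if (method != "multi_tr" && length(unique(data$tr_s[included])) > 1L)
    stop("mixed TR values: use method = \"multi_tr\" for data acquired at ",
         "several repetition times", call. = FALSE)
  if (length(unique(tau[included])) < 2L)
    stop("insufficient data: need at least 2 distinct flip angles",
         call. = FALSE)

  fixed_w <- NULL
  iterate_w <- FALSE
  if (!is.null(weights)) {
    if (identical(weights, "optimal")) {
      if (method != "linear")
        stop("weights = \"optimal\" is only available for method = \"linear\"",
             call. = FALSE)
      iterate_w <- TRUE
    } else {
      .check_num(weights, "weights", lower = 0)
      if (length(weights) != n)
        stop("'weights' must have one entry per sample", call. = FALSE)
      if (all(weights[included] == 0))
        stop("'weights' must not all be zero", call. = FALSE)
      fixed_w <- weights
    }
  }

  fit <- switch(method,
    linear = .fit_linear(data, included, fixed_w, iterate_w,
                         max_passes, pass_tol),
    multi_tr = .fit_multi_tr(data, included, fixed_w),
    conventional = .fit_conventional(data, included, fixed_w),
    nonlinear = .fit_nonlinear(data, included, init))
  fit$data <- data
  fit$included <- included & fit$included_fit
  fit$included_fit <- NULL
  fit$n_used <- sum(fit$included)
  fit$method <- method
  fit$call <- match.call()
  class(fit) <- "vfa_fit"
  fit
}

# coerce/validate a signal table
.as_signal_set <- function(data) {
  if (!is.data.frame(data))
    stop("'data' must be a data.frame of VFA samples", call. = FALSE)
  need <- c("alpha_deg", "tr_s", "signal")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s) in VFA data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_num(data$alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  .check_num(data$tr_s, "tr_s", lower = 0, open_lower = TRUE)
  if (!is.numeric(data$signal) || anyNA(data$signal))
    stop("'signal' must be numeric without missing values", call. = FALSE)
  data
}

# weighted simple regression of y on x; returns slope/intercept, their
# covariance (delta-method inputs) and residuals
.wls <- function(x, y, w = NULL) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0)
    stop("degenerate design: no spread in the abscissa", call. = FALSE)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  r <- y - (intercept + slope * x)
  s2 <- if (n > 2) sum(w * r^2) / (n - 2) else NA_real_
  list(slope = slope, intercept = intercept, residuals = r,
       var_slope = s2 / sxx,
       var_intercept = s2 * (1 / W + xb^2 / sxx),
       cov_si = -s2 * xb / sxx)
}

# fill e1/t1 (+SEs) from rho1 at a single TR
.derive_relaxation <- function(amplitude, rho1, se_amplitude, se_rho1, tr) {
  e1 <- e1_from_rho1(rho1)
  t1 <- relaxation_from_rho1(rho1, tr)
  g <- atanh(rho1 / 2)
  dt1 <- tr * 0.5 / ((1 - (rho1 / 2)^2) * 2 * g^2)   # |dT1/drho1|
  de1 <- 4 / (2 + rho1)^2                            # |dE1/drho1|
  list(coefficients = c(amplitude = amplitude, rho1 = rho1, e1 = e1, t1 = t1),
       se = c(amplitude = se_amplitude, rho1 = se_rho1,
              e1 = de1 * se_rho1, t1 = dt1 * se_rho1))
}

.fit_linear <- function(data, included, fixed_w, iterate_w,
                        max_passes, pass_tol) {
  d <- data[included, ]
  w <- if (is.null(fixed_w)) NULL else fixed_w[included]
  fit <- .wls(d$x, d$y, w)
  if (fit$slope >= 0)
    stop("degenerate fit: non-negative slope in the linear plot implies a ",
         "non-physical relaxation term; check the data for signal bias",
         call. = FALSE)
  rho1 <- -1 / (2 * fit$slope)
  passes <- 1L
  if (iterate_w) {
    repeat {
      w <- weight_function(d$tau, rho1)
      fit <- .wls(d$x, d$y, w)
      if (fit$slope >= 0)
        stop("degenerate weighted fit: non-negative slope", call. = FALSE)
      rho1_new <- -1 / (2 * fit$slope)
      passes <- passes + 1L
      done <- abs(rho1_new - rho1) <= pass_tol * abs(rho1)
      rho1 <- rho1_new
      if (done || passes >= max_passes) break
    }
  }
  if (rho1 >= 2)
    stop("degenerate fit: estimated relaxation term outside (0, 2)",
         call. = FALSE)
  se_slope <- sqrt(fit$var_slope)
  se_rho1 <- se_slope / (2 * fit$slope^2)
  tr <- unique(d$tr_s)
  out <- .derive_relaxation(fit$intercept, rho1,
                            sqrt(fit$var_intercept), se_rho1, tr)
  res <- rep(NA_real_, nrow(data))
  res[included] <- fit$residuals
  c(out, list(slope = fit$slope, se_slope = se_slope,
              residuals = res,
              fitted = .alg_signal(fit$intercept, data$tau, rho1),
              tr_s = tr, weights = w, passes = passes,
              included_fit = rep(TRUE, nrow(data))))
}

.fit_multi_tr <- function(data, included, fixed_w) {
  d <- data[included, ]
  xs <- d$x / (2 * d$tr_s)                 # S*tau/(2 TR)
  w <- if (is.null(fixed_w)) NULL else fixed_w[included]
  fit <- .wls(xs, d$y, w)
  if (fit$slope >= 0)
    stop("degenerate fit: non-negative slope implies non-physical T1",
         call. = FALSE)
  t1 <- -fit$slope
  amplitude <- fit$intercept
  if (max(d$tr_s) / t1 > 0.2)
    warning(sprintf(paste0("short-TR approximation questionable: ",
                           "max(TR)/T1 = %.2f exceeds 0.2"),
                    max(d$tr_s) / t1), call. = FALSE)
  trs <- unique(d$tr_s)
  if (length(trs) == 1L) {
    rho1 <- rho1_from_relaxation(trs, t1)
    e1 <- exp(-trs / t1)
  } else {
    rho1 <- NA_real_; e1 <- NA_real_; trs <- NA_real_
  }
  res <- rep(NA_real_, nrow(data))
  res[included] <- fit$residuals
  fitted <- with(data, {
    rho_i <- rho1_from_relaxation(tr_s, t1)
    .alg_signal(amplitude, tau, rho_i)
  })
  list(coefficients = c(amplitude = amplitude, rho1 = rho1, e1 = e1, t1 = t1),
       se = c(amplitude = sqrt(fit$var_intercept), rho1 = NA_real_,
              e1 = NA_real_, t1 = sqrt(fit$var_slope)),
       slope = fit$slope, se_slope = sqrt(fit$var_slope),
       residuals = res, fitted = fitted, tr_s = trs, weights = w,
       included_fit = rep(TRUE, nrow(data)))
}

.fit_conventional <- function(data, included, fixed_w) {
  d <- data[included, ]
  a <- d$alpha_deg * pi / 180
  X <- d$signal / tan(a)
  Y <- d$signal / sin(a)
  w <- if (is.null(fixed_w)) NULL else fixed_w[included]
  fit <- .wls(X, Y, w)
  e1 <- fit$slope
  if (e1 <= 0 || e1 >= 1)
    stop("degenerate fit: conventional slope (E1) outside (0, 1)",
         call. = FALSE)
  amplitude <- fit$intercept / (1 - e1)
  rho1 <- rho1_from_e1(e1)
  tr <- unique(d$tr_s)
  t1 <- -tr / log(e1)
  se_e1 <- sqrt(fit$var_slope)
  # delta method: A = c/(1-m) with c = intercept, m = slope
  dA_dc <- 1 / (1 - e1)
  dA_dm <- fit$intercept / (1 - e1)^2
  var_A <- dA_dc^2 * fit$var_intercept + dA_dm^2 * fit$var_slope +
    2 * dA_dc * dA_dm * fit$cov_si
  se_rho1 <- 4 / (1 + e1)^2 * se_e1
  se_t1 <- tr / (e1 * log(e1)^2) * se_e1
  res <- rep(NA_real_, nrow(data))
  res[included] <- fit$residuals
  list(coefficients = c(amplitude = amplitude, rho1 = rho1, e1 = e1, t1 = t1),
       se = c(amplitude = sqrt(pmax(var_A, 0)), rho1 = se_rho1,
              e1 = se_e1, t1 = se_t1),
       slope = fit$slope, se_slope = se_e1,
       residuals = res,
       fitted = .alg_signal(amplitude, data$tau, rho1),
       tr_s = tr, weights = w,
       included_fit = rep(TRUE, nrow(data)))
}

.fit_nonlinear <- function(data, included, init) {
  d <- data[included, ]
  if (is.null(init)) {
    lin <- tryCatch(.fit_linear(data, included, NULL, FALSE, 1L, 0),
                    error = function(e) NULL)
    init <- if (is.null(lin)) c(amplitude = max(d$y), rho1 = 0.1)
            else lin$coefficients[c("amplitude", "rho1")]
  }
  init <- c(amplitude = unname(init[["amplitude"]]),
            rho1 = unname(init[["rho1"]]))
  resid_fn <- function(p) d$signal - .alg_signal(p[1], d$tau, p[2])
  nl <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                           lower = c(1e-12, 1e-12),
                           upper = c(Inf, 2 - 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  converged <- nl$info %in% 1:4
  if (!converged)
    warning("nonlinear fit did not converge: ", nl$message, call. = FALSE)
  amplitude <- nl$par[[1]]; rho1 <- nl$par[[2]]
  n <- nrow(d)
  se <- c(NA_real_, NA_real_)
  if (n > 2) {
    s2 <- nl$deviance / (n - 2)
    cv <- tryCatch(solve(nl$hessian) * s2, error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
  }
  tr <- unique(d$tr_s)
  out <- .derive_relaxation(amplitude, rho1, se[1], se[2], tr)
  yres <- rep(NA_real_, nrow(data))
  yres[included] <- d$y - (amplitude - d$x / (2 * rho1))
  c(out, list(slope = -1 / (2 * rho1), se_slope = NA_real_,
              residuals = yres,
              fitted = .alg_signal(amplitude, data$tau, rho1),
              tr_s = tr, weights = NULL,
              converged = converged, niter = nl$niter,
              included_fit = rep(TRUE, nrow(data))))
}

#' Closed-form dual flip angle fit
#'
#' The two-point special case of [vfa_fit()]: the line through two
#' measurements gives \eqn{\rho_1 = (x_1-x_2) / (2(y_2-y_1))} and the
#' amplitude as the y-intercept.  Identical to the linear regression on the
#' pair, and symmetric under swapping the samples.
#'
#' @param s1,s2 single VFA samples: named lists or one-row data.frames with
#'   fields `alpha_deg`, `tr_s`, `signal`.
#' @return a `"vfa_fit"` object (see [vfa_fit()]).
#' @examples
#' a <- list(alpha_deg = 15, tr_s = 0.02, signal = 80)
#' b <- list(alpha_deg = 60, tr_s = 0.02, signal = 55)
#' dual_angle_fit(a, b)
#' @export
dual_angle_fit <- function(s1, s2) {
  row <- function(s) {
    s <- as.list(s)
    need <- c("alpha_deg", "tr_s", "signal")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("sample missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    data.frame(alpha_deg = s$alpha_deg, tr_s = s$tr_s, signal = s$signal)
  }
  d <- rbind(row(s1), row(s2))
  if (tau_from_alpha(d$alpha_deg[1]) == tau_from_alpha(d$alpha_deg[2]))
    stop("insufficient data: the two samples must have distinct flip angles",
         call. = FALSE)
  vfa_fit(d, method = "linear")
}
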