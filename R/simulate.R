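#' Packaged VFA acquisition protocols
#'
#' Flip-angle / TR combinations emulating the package's reference
#' experiments on a clinical 3 T system:
#' \describe{
#'   \item{`"agar_multi_tr"`}{nonselective 3D FLASH on an agar phantom at
#'     four repetition times (6/12/24/48 ms), each with a flip-angle range
#'     matched to its Ernst angle (1-13, 1-18, 1-24 and 2-34 degrees).}
#'   \item{`"mncl2_spoiling"`}{13 flip angles from 2 to 36 degrees at
#'     TR = 7 ms, the design used to probe RF-spoiling residuals in a
#'     MnCl2 solution.}
#'   \item{`"brain_invivo"`}{16 flip angles from 2 to 60 degrees
#'     (steps of 2, 3, 4 and 10 degrees over successive ranges) at
#'     TR = 11 ms, an in-vivo whole-brain protocol.}
#' }
#'
#' @param name protocol preset name.
#' @return a data.frame with columns `alpha_deg` and `tr_s`.
#' @export
vfa_protocol <- function(name = c("agar_multi_tr", "mncl2_spoiling",
                                  "brain_invivo")) {
  name <- match.arg(name)
  switch(name,
    agar_multi_tr = {
      rows <- list(c(0.006, 1, 13, 1), c(0.012, 1, 18, 1),
                   c(0.024, 1, 24, 1), c(0.048, 2, 34, 2))
      do.call(rbind, lapply(rows, function(r)
        data.frame(alpha_deg = seq(r[2], r[3], by = r[4]), tr_s = r[1])))
    },
    mncl2_spoiling = data.frame(
      alpha_deg = c(2, 3, 4, 6, 8, 10, 12, 15, 18, 21, 24, 30, 36),
      tr_s = 0.007),
    brain_invivo = data.frame(
      alpha_deg = c(seq(2, 12, 2), seq(15, 24, 3), seq(28, 40, 4), 50, 60),
      tr_s = 0.011))
}

#' Describe a systematic signal deviation
#'
#' Phenomenological deviations from the ideal spoiled signal used by the
#' simulator:
#' \describe{
#'   \item{`"high_angle_multiplicative"`}{imperfect RF spoiling: a
#'     multiplicative deviation for angles above `onset_alpha_deg`.  With
#'     `ramp = TRUE` the magnitude grows linearly from 0 at onset to
#'     `magnitude` at the largest sampled angle (residual coherences grow
#'     with flip angle); with `ramp = FALSE` the full magnitude applies to
#'     every angle beyond onset.  `sign = -1` (partial-saturation-like
#'     signal loss) matches most spoiling phase increments; `sign = +1`
#'     regimes also occur.}
#'   \item{`"low_angle_offset"`}{an additive offset of
#'     `magnitude * amplitude` applied to angles at or below
#'     `onset_alpha_deg`, emulating Rician floor or amplifier-noise
#'     saturation at very low flip angles.}
#'   \item{`"none"`}{no deviation.}
#' }
#'
#' @param kind deviation type.
#' @param magnitude non-negative fractional magnitude.
#' @param onset_alpha_deg angle threshold, degrees.
#' @param sign +1 or -1, direction of the deviation.
#' @param ramp logical; ramp the multiplicative deviation linearly in
#'   angle above onset.
#' @return a `"vfa_deviation"` list.
#' @export
vfa_deviation <- function(kind = c("none", "high_angle_multiplicative",
                                   "low_angle_offset"),
                          magnitude = 0, onset_alpha_deg = 15,
                          sign = -1, ramp = TRUE) {
  kind <- match.arg(kind)
  .check_num(magnitude, "magnitude", lower = 0, allow_vector = FALSE)
  .check_num(onset_alpha_deg, "onset_alpha_deg", lower = 0, upper = 180,
             allow_vector = FALSE)
  if (!sign %in% c(-1, 1)) stop("'sign' must be -1 or +1", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude,
                 onset_alpha_deg = onset_alpha_deg, sign = sign,
                 ramp = isTRUE(ramp)),
            class = "vfa_deviation")
}

# deterministic deviation factor/offset applied to ideal signals
.apply_deviation <- function(signal, alpha_deg, amplitude, deviation) {
  if (is.null(deviation) || deviation$kind == "none") return(signal)
  m <- deviation$magnitude
  on <- deviation$onset_alpha_deg
  if (deviation$kind == "high_angle_multiplicative") {
    hi <- alpha_deg > on
    if (any(hi)) {
      frac <- if (deviation$ramp) {
        top <- max(alpha_deg)
        if (top > on) (alpha_deg[hi] - on) / (top - on) else 1
      } else 1
      signal[hi] <- signal[hi] * (1 + deviation$sign * m * frac)
    }
  } else if (deviation$kind == "low_angle_offset") {
    lo <- alpha_deg <= on
    signal[lo] <- signal[lo] + deviation$sign * m * amplitude
  }
  signal
}

#' Simulate VFA signal measurements
#'
#' Generates a table of spoiled gradient-echo signals from the exact
#' algebraic Ernst model, optionally with a transmit bias factor acting on
#' the flip angles, a systematic deviation ([vfa_deviation()]), and
#' additive Gaussian or magnitude (Rician) noise.  With `sigma = 0` and no
#' deviation the output equals [ernst_signal()] exactly.  Generation is
#' reproducible: the same `seed` yields bit-identical signals, and the
#' caller's RNG state is untouched.
#'
#' Rician noise replaces each signal by
#' \eqn{\sqrt{(S+n_1)^2 + n_2^2}} with independent
#' \eqn{n_{1,2} \sim N(0, \sigma^2)}: the magnitude of a complex
#' measurement, positively biased at low signal-to-noise ratio.
#'
#' @param data optional protocol data.frame with columns `alpha_deg`,
#'   `tr_s` (e.g. from [vfa_protocol()]); alternatively give `alpha_deg`
#'   and `tr_s` directly.
#' @param alpha_deg,tr_s flip angles (degrees) and repetition time(s),
#'   seconds; `tr_s` is recycled.
#' @param t1 longitudinal relaxation time, seconds.
#' @param amplitude signal amplitude, arbitrary units.
#' @param sigma signal noise SD, same units (0 for noiseless).
#' @param noise `"gaussian"` or `"rician"`.
#' @param deviation a [vfa_deviation()] or `NULL`.
#' @param b1 transmit bias factor applied to the nominal flip angles
#'   (default 1, i.e. none).
#' @param seed RNG seed; required whenever `sigma > 0`.
#' @return a data.frame with columns `alpha_deg`, `tr_s`, `signal`, `sd`.
#' @examples
#' d <- generate_vfa_signals(vfa_protocol("mncl2_spoiling"),
#'                           t1 = 0.54, amplitude = 100,
#'                           sigma = 0.5, seed = 1)
#' head(d)
#' @export
generate_vfa_signals <- function(data = NULL, alpha_deg = NULL, tr_s = NULL,
                                 t1, amplitude = 1, sigma = 0,
                                 noise = c("gaussian", "rician"),
                                 deviation = NULL, b1 = 1, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(data)) {
    if (!all(c("alpha_deg", "tr_s") %in% names(data)))
      stop("'data' must have columns alpha_deg and tr_s", call. = FALSE)
    alpha_deg <- data$alpha_deg
    tr_s <- data$tr_s
  }
  if (is.null(alpha_deg) || is.null(tr_s))
    stop("supply either 'data' or both 'alpha_deg' and 'tr_s'",
         call. = FALSE)
  .check_num(alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  .check_num(tr_s, "tr_s", lower = 0, open_lower = TRUE)
  .check_num(t1, "t1", lower = 0, open_lower = TRUE, allow_vector = FALSE)
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE,
             allow_vector = FALSE)
  .check_num(sigma, "sigma", lower = 0, allow_vector = FALSE)
  .check_num(b1, "b1", lower = 0, open_lower = TRUE)
  tr_s <- rep_len(tr_s, length(alpha_deg))
  if (sigma > 0 && is.null(seed))
    stop("a 'seed' is required when simulating with noise", call. = FALSE)
  if (!is.null(deviation) && !inherits(deviation, "vfa_deviation"))
    stop("'deviation' must be created by vfa_deviation()", call. = FALSE)

  alpha_act <- if (all(b1 == 1)) alpha_deg
               else apply_transmit_bias(alpha_deg, b1)
  rho1 <- rho1_from_relaxation(tr_s, t1)
  S <- .alg_signal(amplitude, tau_from_alpha(alpha_act), rho1)
  S <- .apply_deviation(S, alpha_deg, amplitude, deviation)
  if (sigma > 0) {
    S <- with_seed(seed, {
      if (noise == "gaussian") S + rnorm(length(S), 0, sigma)
      else sqrt((S + rnorm(length(S), 0, sigma))^2 +
                rnorm(length(S), 0, sigma)^2)
    })
  }
  data.frame(alpha_deg = alpha_deg, tr_s = tr_s, signal = S,
             sd = rep(sigma, length(S)))
}

#' Slice-profile-integrated spoiled signal
#'
#' In 2D slice-selective excitation the realized flip angle varies across
#' the slice, so the measured signal is the profile-weighted mean of the
#' Ernst signal at the local angle \eqn{f(z)\,\alpha_{nom}}.  This
#' distorts the flip-angle dependence: relative to the nonselective curve,
#' the signal maximum shifts to a higher nominal angle and the high-angle
#' tail is positively biased (the slice margins, flipped less, saturate
#' less).
#'
#' @param alpha_nominal_deg nominal flip angle(s), degrees.
#' @param profile non-negative relative flip-angle factors sampled evenly
#'   across the slice (length >= 2); linearly resampled to at least
#'   `n_points` positions and integrated by the trapezoidal rule.
#'   A constant (boxcar) profile of 1 reproduces the nonselective signal.
#' @param t1,tr tissue relaxation time and repetition time, seconds.
#' @param amplitude signal amplitude.
#' @param n_points minimum number of integration points (>= 101).
#' @return profile-integrated signal(s).
#' @examples
#' prof <- exp(-seq(-2, 2, length.out = 31)^2)   # Gaussian-tapered slice
#' slice_profile_signal(30, prof, t1 = 2.41, tr = 0.007)
#' @export
slice_profile_signal <- function(alpha_nominal_deg, profile, t1, tr,
                                 amplitude = 1, n_points = 201L) {
  .check_num(alpha_nominal_deg, "alpha_nominal_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  if (length(profile) < 2L)
    stop("'profile' must sample the slice at >= 2 positions", call. = FALSE)
  .check_num(profile, "profile", lower = 0)
  if (all(profile == 0))
    stop("'profile' must not be identically zero", call. = FALSE)
  n_points <- max(as.integer(n_points), 101L)
  .check_num(t1, "t1", lower = 0, open_lower = TRUE, allow_vector = FALSE)
  .check_num(tr, "tr", lower = 0, open_lower = TRUE, allow_vector = FALSE)

  z0 <- seq(0, 1, length.out = length(profile))
  z <- seq(0, 1, length.out = n_points)
  f <- stats::approx(z0, profile, xout = z)$y
  rho1 <- rho1_from_relaxation(tr, t1)
  # trapezoid weights on the uniform grid
  wt <- c(0.5, rep(1, n_points - 2L), 0.5)
  vapply(alpha_nominal_deg, function(a) {
    aa <- f * a
    if (any(aa >= 180))
      stop("profile-scaled flip angle reaches 180 degrees", call. = FALSE)
    s <- ifelse(aa > 0, .alg_signal(amplitude, 2 * tan(aa * pi / 360), rho1),
                0)
    sum(wt * s) / sum(wt)
  }, 0)
}
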