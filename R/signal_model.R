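#' Ernst signal of a perfectly spoiled gradient echo
#'
#' Classic steady-state signal of a spoiled gradient-echo sequence,
#' \deqn{S = A \sin\alpha (1 - E_1) / (1 - E_1\cos\alpha),}
#' where \eqn{A} is the fully relaxed 90-degree amplitude at the echo time
#' (absorbing proton density and transverse decay) and
#' \eqn{E_1 = \exp(-TR/T_1)}.
#'
#' The denominator is evaluated as \eqn{(1-E_1) + 2 E_1 \sin^2(\alpha/2)},
#' a sum of positive terms, so no cancellation occurs for small angles at
#' long E1 and the result agrees with [algebraic_signal()] to a few ulp
#' over the whole parameter range.
#'
#' @param amplitude signal amplitude A (> 0), arbitrary units.
#' @param alpha_deg flip angle(s) in degrees, in (0, 180).
#' @param e1 saturation factor(s) \eqn{\exp(-TR/T_1)} in (0, 1).
#' @return signal(s), same units as `amplitude`.
#' @seealso [algebraic_signal()] for the exact rational reformulation.
#' @examples
#' ernst_signal(1, 90, 0.6)   # 0.4
#' @export
ernst_signal <- function(amplitude, alpha_deg, e1) {
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  .check_num(alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  .check_num(e1, "e1", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  a <- alpha_deg * pi / 180
  # 1 - E1*cos(a) == (1 - E1) + 2*E1*sin(a/2)^2, cancellation-free
  amplitude * sin(a) * (1 - e1) / ((1 - e1) + 2 * e1 * sin(a / 2)^2)
}

#' Algebraic Ernst signal in the transformed variables
#'
#' The exact rational form of the Ernst equation under the half-angle
#' tangent and relaxation-term substitutions:
#' \deqn{S(\tau) = 2 A \rho_1 \tau / (\tau^2 + 2\rho_1).}
#' Identical (not approximately) to [ernst_signal()] with
#' \eqn{\tau = 2\tan(\alpha/2)} and \eqn{\rho_1 = 2(1-E_1)/(1+E_1)}.
#' The signal is symmetric in \eqn{\log\tau} about the Ernst point:
#' \eqn{S(u\tau_E) = S(\tau_E/u)}.
#'
#' @param amplitude signal amplitude A (> 0).
#' @param tau half-angle tangent value(s) (> 0).
#' @param rho1 relaxation term(s) in (0, 2).
#' @return signal(s).
#' @examples
#' algebraic_signal(1, 2, 0.5)  # 0.4, same point as ernst_signal(1, 90, 0.6)
#' @export
algebraic_signal <- function(amplitude, tau, rho1) {
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  .check_num(tau, "tau", lower = 0, open_lower = TRUE)
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE)
  2 * amplitude * rho1 * tau / (tau^2 + 2 * rho1)
}

#' Ernst point of a tissue
#'
#' The signal maximum over \eqn{\tau} is attained at
#' \eqn{\tau_E = \sqrt{2\rho_1}} (the Ernst angle,
#' \eqn{\cos\alpha_E = E_1}, in transformed variables), where the ordinate
#' of the linear plot equals half the amplitude:
#' \eqn{S_E/\tau_E = A/2}.
#'
#' @param amplitude signal amplitude A (> 0).
#' @param rho1 relaxation term in (0, 2).
#' @return a list with elements `tau_e`, `s_e` (maximum signal),
#'   `alpha_e_deg` (Ernst angle in degrees).
#' @examples
#' ernst_point(1, 0.5)  # tau_e = 1, alpha_e = 53.13 deg, s_e = 0.5
#' @export
ernst_point <- function(amplitude, rho1) {
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE,
             allow_vector = FALSE)
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE, allow_vector = FALSE)
  tau_e <- sqrt(2 * rho1)
  list(tau_e = tau_e,
       s_e = algebraic_signal(amplitude, tau_e, rho1),
       alpha_e_deg = alpha_from_tau(tau_e))
}

#' Linear-plot coordinates of VFA measurements
#'
#' Transforms measurements \eqn{(\alpha, S)} to the coordinates of the
#' linear display, \eqn{x = S\tau} and \eqn{y = S/\tau} with
#' \eqn{\tau = 2\tan(\alpha/2)}.  Noiseless model data satisfy
#' \eqn{y = A - x/(2\rho_1)}: the y-intercept is the amplitude, the slope
#' carries the relaxation term, and the x-intercept corresponds to
#' \eqn{\alpha \to 180} degrees.
#'
#' @param alpha_deg flip angle(s) in degrees, in (0, 180).
#' @param signal signal value(s), non-negative.
#' @param weight optional non-negative regression weight(s); defaults to 1.
#' @return a data.frame with columns `tau`, `x`, `y`, `weight`.
#' @export
linear_coords <- function(alpha_deg, signal, weight = NULL) {
  .check_num(signal, "signal", lower = 0)
  tau <- tau_from_alpha(alpha_deg)
  if (length(signal) != length(tau))
    stop("'alpha_deg' and 'signal' must have equal length", call. = FALSE)
  if (is.null(weight)) weight <- rep(1, length(tau))
  .check_num(weight, "weight", lower = 0)
  data.frame(tau = tau, x = signal * tau, y = signal / tau, weight = weight)
}

#' Tau value at a fractional amplitude level
#'
#' On the linear plot the ordinate falls from \eqn{A} at \eqn{\tau = 0} to 0
#' at the x-intercept.  The fractional level \eqn{p = (S/\tau)/A} is reached
#' at \deqn{\tau = \tau_E \sqrt{(1-p)/p}.}
#' Equidistant levels \eqn{p_i = i/(N+1)} give the equidistant sampling
#' schedule of [equidistant_schedule()].
#'
#' @param p fractional level(s) in (0, 1).
#' @param tau_e Ernst value \eqn{\tau_E} (> 0); default 1 returns the
#'   normalized ratio \eqn{u = \tau/\tau_E}.
#' @return tau value(s).
#' @examples
#' tau_for_level(0.5, 1)     # the Ernst point itself
#' tau_for_level(0.8536)     # ~0.4142, the low point of the optimal dual scheme
#' @export
tau_for_level <- function(p, tau_e = 1) {
  .check_num(p, "p", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  .check_num(tau_e, "tau_e", lower = 0, open_lower = TRUE)
  tau_e * sqrt((1 - p) / p)
}
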