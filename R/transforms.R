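#' Half-angle tangent transform of the flip angle
#'
#' Maps a flip angle \eqn{\alpha \in (0, 180)} degrees to the dimensionless
#' variable \eqn{\tau = 2\tan(\alpha/2)}, which ranges over \eqn{(0, \infty)}.
#' Under this substitution (together with [rho1_from_relaxation()]) the Ernst
#' equation becomes a low-order rational function, and VFA data plotted at
#' \eqn{x = S\tau}, \eqn{y = S/\tau} fall on a straight line.  For small
#' angles \eqn{\tau \approx \alpha} (in radians) with a third-order error;
#' at 40 degrees the radian angle underestimates \eqn{\tau} by about 4\%.
#'
#' @param alpha_deg flip angle(s) in degrees, strictly between 0 and 180.
#' @return \eqn{\tau = 2\tan(\alpha/2)}, same length as `alpha_deg`.
#' @seealso [alpha_from_tau()] for the inverse.
#' @examples
#' tau_from_alpha(90)            # 2
#' tau_from_alpha(2 * atan(0.5) * 180 / pi)  # 1, at alpha ~ 53.13 deg
#' @export
tau_from_alpha <- function(alpha_deg) {
  .check_num(alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  2 * tan(alpha_deg * pi / 360)
}

#' Flip angle corresponding to a half-angle tangent value
#'
#' Exact inverse of [tau_from_alpha()]: \eqn{\alpha = 2\arctan(\tau/2)},
#' returned in degrees.
#'
#' @param tau positive half-angle tangent value(s).
#' @return flip angle(s) in degrees, in (0, 180).
#' @examples
#' alpha_from_tau(2)    # 90
#' alpha_from_tau(1)    # 53.13 deg
#' @export
alpha_from_tau <- function(tau) {
  .check_num(tau, "tau", lower = 0, open_lower = TRUE)
  2 * atan(tau / 2) * 180 / pi
}

#' Algebraic relaxation term of a spoiled steady state
#'
#' Maps the repetition time and longitudinal relaxation time to the
#' dimensionless relaxation term
#' \eqn{\rho_1 = 2\tanh(TR/(2 T_1)) = 2(1-E_1)/(1+E_1)} with
#' \eqn{E_1 = \exp(-TR/T_1)}.  \eqn{\rho_1} ranges over (0, 2) and conforms
#' to \eqn{TR/T_1} for short TR with a third-order error.
#'
#' @param tr repetition time(s), seconds (> 0).
#' @param t1 longitudinal relaxation time(s), seconds (> 0).
#' @return \eqn{\rho_1 \in (0, 2)}.
#' @seealso [relaxation_from_rho1()], [rho1_from_e1()], [e1_from_rho1()].
#' @examples
#' rho1_from_relaxation(0.511, 1)  # 0.5 (E1 = 0.6)
#' @export
rho1_from_relaxation <- function(tr, t1) {
  .check_num(tr, "tr", lower = 0, open_lower = TRUE)
  .check_num(t1, "t1", lower = 0, open_lower = TRUE)
  2 * tanh(tr / (2 * t1))
}

#' T1 from the algebraic relaxation term
#'
#' Inverse of [rho1_from_relaxation()] at a known repetition time:
#' \eqn{T_1 = TR / (2\,\mathrm{artanh}(\rho_1/2))}.
#'
#' @param rho1 relaxation term(s) in (0, 2).
#' @param tr repetition time(s), seconds (> 0).
#' @return \eqn{T_1} in seconds.
#' @examples
#' relaxation_from_rho1(0.5, 0.511)  # 1 s
#' @export
relaxation_from_rho1 <- function(rho1, tr) {
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE)
  .check_num(tr, "tr", lower = 0, open_lower = TRUE)
  tr / (2 * atanh(rho1 / 2))
}

#' Convert between E1 and the relaxation term rho1
#'
#' The saturation factor \eqn{E_1 = \exp(-TR/T_1)} and the algebraic
#' relaxation term are related by the bijection
#' \eqn{\rho_1 = 2(1-E_1)/(1+E_1)}, \eqn{E_1 = (2-\rho_1)/(2+\rho_1)}.
#' The difference `1 - e1` is formed before any division, so the conversion
#' is accurate to a few ulp even as \eqn{E_1 \to 1}.
#'
#' @param e1 saturation factor(s) in (0, 1).
#' @param rho1 relaxation term(s) in (0, 2).
#' @return the converted quantity.
#' @examples
#' rho1_from_e1(0.6)  # 0.5
#' rho1_from_e1(0.2)  # 1.333...
#' e1_from_rho1(0.5)  # 0.6
#' @export
rho1_from_e1 <- function(e1) {
  .check_num(e1, "e1", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  2 * (1 - e1) / (1 + e1)
}

#' @rdname rho1_from_e1
#' @export
e1_from_rho1 <- function(rho1) {
  .check_num(rho1, "rho1", lower = 0, upper = 2,
             open_lower = TRUE, open_upper = TRUE)
  (2 - rho1) / (2 + rho1)
}
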