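#' Equidistant fractional-level flip-angle schedule
#'
#' Places N measurements at equidistant fractional amplitude levels
#' \eqn{p_i = i/(N+1)} (excluding 0 and 1) on the linear plot, giving
#' normalized positions \eqn{u_i = \tau_i/\tau_E = \sqrt{(N+1-i)/i}}.
#' The positions come in reciprocal pairs, \eqn{u_i = 1/u_{N+1-i}}, so the
#' corresponding signals are pairwise equal; such evenly spread designs
#' define the straight line well and make bias at either flip-angle
#' extreme conspicuous.
#'
#' @param n number of measurements (>= 2).
#' @param tau_e Ernst value \eqn{\tau_E} used to realize absolute
#'   \eqn{\tau} values; default 1 keeps the schedule normalized.
#' @return a `"vfa_schedule"` object; see [optimize_schedule()].
#' @examples
#' equidistant_schedule(3)$u_ratios   # 1/sqrt(3), 1, sqrt(3)
#' @export
equidistant_schedule <- function(n, tau_e = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  .check_num(tau_e, "tau_e", lower = 0, open_lower = TRUE,
             allow_vector = FALSE)
  i <- seq_len(n)
  p <- i / (n + 1)
  u <- sort(sqrt((1 - p) / p))
  structure(list(n = as.integer(n), target = NA_character_,
                 u_ratios = u, p_levels = 1 / (1 + u^2),
                 tau_e = tau_e, taus = u * tau_e,
                 flip_angles_deg = NULL, predicted = NULL,
                 scheme = "equidistant", branches = NULL),
            class = "vfa_schedule")
}

#' Minimal-variance flip-angle schedule by multi-start optimization
#'
#' Numerically minimizes the first-order noise propagation
#' ([propagate_variance()]) into the relaxation-term or amplitude estimate
#' over the N normalized positions \eqn{u_i = \tau_i/\tau_E}.  A
#' derivative-free Nelder-Mead search is run in \eqn{\log u} from a grid
#' of sorted starting combinations spanning \eqn{u \in [0.05, 20]}, each
#' polished by a restart; the best local minimum is returned.  Ties are
#' broken by the lexicographically smallest sorted \eqn{u}.
#'
#' Structure of the optima: for the relaxation term, even N reproduces the
#' dual-angle design \eqn{u = (\sqrt2 - 1, \sqrt2 + 1)} replicated N/2
#' times with variance proportional to 1/N; odd N clusters replicated
#' points at two positions.  For the amplitude, the absolute minimum
#' clusters N-1 points at a single low position; the replicated dual-angle
#' alternative is also reported (component `replicated`).  Alternative
#' local minima within 5\% of the best objective are kept in `branches`.
#'
#' The optimal positions are invariant to amplitude and noise level, and
#' (being expressed as ratios to \eqn{\tau_E}) to the tissue's
#' \eqn{\rho_1}.
#'
#' @param n number of measurements, 2 to 8.
#' @param target `"rho1"` (minimize relaxation-term variance; the T1
#'   design) or `"amplitude"`.
#' @param amplitude,rho1 tissue parameters at which the propagation is
#'   evaluated (positions are invariant; variances scale).
#' @param levels log-spaced grid levels of u from which sorted starting
#'   combinations are built (>= 25 multi-starts for n >= 2).
#' @param tol relative objective tolerance of each simplex run.
#' @return a `"vfa_schedule"` with the optimized `u_ratios`, predicted
#'   variances (`predicted`, a [propagate_variance()] result), alternative
#'   `branches`, and for even n the `replicated` dual-angle scheme.
#' @examples
#' \donttest{
#' s <- optimize_schedule(2, "rho1")
#' s$u_ratios          # 0.4142, 2.4142
#' }
#' @export
optimize_schedule <- function(n, target = c("rho1", "amplitude"),
                              amplitude = 1, rho1 = 0.5,
                              levels = exp(seq(log(0.1), log(10),
                                               length.out = 6)),
                              tol = 1e-12) {
  target <- match.arg(target)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n > 8 || n != round(n))
    stop("'n' must be an integer in [2, 8]", call. = FALSE)
  n <- as.integer(n)
  tau_e <- sqrt(2 * rho1)

  objective <- function(logu) {
    u <- exp(logu)
    if (any(u < 0.01) || any(u > 50)) return(Inf)
    if (max(u) - min(u) < 1e-12) return(Inf)
    p <- .vfa_partials(u * tau_e, amplitude, rho1)
    if (target == "rho1") sum(p$drho^2) else sum(p$dA^2)
  }

  # sorted combinations (with repetition, excluding all-equal) of grid levels
  grid <- as.matrix(expand.grid(rep(list(log(levels)), n)))
  keep <- apply(grid, 1L, function(r) all(diff(r) >= 0) && max(r) > min(r))
  starts <- grid[keep, , drop = FALSE]

  run <- function(par) {
    o <- optim(par, objective, method = "Nelder-Mead",
               control = list(reltol = tol, maxit = 50000))
    # polish: restart the simplex at the located minimum
    optim(o$par, objective, method = "Nelder-Mead",
          control = list(reltol = tol, maxit = 50000))
  }
  minima <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    o <- run(starts[i, ])
    minima[[i]] <- list(u = unname(sort(exp(o$par))), value = o$value,
                        convergence = o$convergence)
  }
  vals <- vapply(minima, `[[`, 0, "value")
  if (!any(is.finite(vals)))
    stop("schedule optimization failed to converge from any start",
         call. = FALSE)
  best_val <- min(vals)
  # tie-break among near-equal minima: lexicographically smallest sorted u
  near <- which(vals <= best_val * (1 + 1e-6))
  ord <- near[order(vapply(minima[near], function(m) m$u[1], 0),
                    vapply(minima[near], function(m) m$u[2], 0))]
  best <- minima[[ord[1]]]

  # distinct alternative local minima within 5% of the best objective
  all_u <- t(vapply(minima, function(m) round(m$u, 4), numeric(n)))
  cand <- which(vals <= best_val * 1.05)
  keys <- apply(all_u[cand, , drop = FALSE], 1L, paste, collapse = "/")
  branches <- lapply(cand[!duplicated(keys)], function(i)
    list(u_ratios = minima[[i]]$u, objective = vals[i]))

  replicated <- NULL
  if (n %% 2L == 0L && n > 2L) {
    base <- optimize_schedule(2L, target, amplitude, rho1, levels, tol)
    u_rep <- sort(rep(base$u_ratios, n / 2L))
    replicated <- list(
      u_ratios = u_rep,
      predicted = propagate_variance(u_rep * tau_e, amplitude, rho1))
  }

  structure(list(n = n, target = target,
                 u_ratios = best$u,
                 p_levels = 1 / (1 + best$u^2),
                 tau_e = tau_e, taus = best$u * tau_e,
                 flip_angles_deg = NULL,
                 predicted = propagate_variance(best$u * tau_e,
                                                amplitude, rho1),
                 objective = best$value,
                 branches = branches, replicated = replicated,
                 amplitude = amplitude, rho1 = rho1,
                 scheme = "optimized"),
            class = "vfa_schedule")
}

#' Realize a normalized schedule as flip angles
#'
#' Converts the normalized positions \eqn{u = \tau/\tau_E} of a schedule
#' into flip angles for a target tissue: \eqn{\tau_E} is computed from
#' (TR, T1), each \eqn{u\tau_E} is mapped through the inverse half-angle
#' tangent transform, and optionally rounded to whole degrees (scanners
#' often accept only integer flip angles).  Rounding shifts the realized
#' fractional levels; the shift is reported via `message()` and the
#' realized levels are recomputed.
#'
#' @param schedule a `"vfa_schedule"`.
#' @param tr repetition time, seconds.
#' @param t1 target T1, seconds.
#' @param integer_round round angles to the nearest whole degree.
#' @return the schedule with `flip_angles_deg`, realized `taus`,
#'   `u_ratios` and `p_levels` filled in, plus `tr`, `t1`.
#' @examples
#' s <- equidistant_schedule(3)
#' realize_flip_angles(s, tr = 0.011, t1 = 1)
#' @export
realize_flip_angles <- function(schedule, tr, t1, integer_round = FALSE) {
  if (!inherits(schedule, "vfa_schedule"))
    stop("'schedule' must be a vfa_schedule", call. = FALSE)
  .check_num(tr, "tr", lower = 0, open_lower = TRUE, allow_vector = FALSE)
  .check_num(t1, "t1", lower = 0, open_lower = TRUE, allow_vector = FALSE)
  rho1 <- rho1_from_relaxation(tr, t1)
  tau_e <- sqrt(2 * rho1)
  taus <- schedule$u_ratios * tau_e
  alphas <- alpha_from_tau(taus)
  if (any(alphas >= 180 - 1e-9))
    stop("schedule requires flip angles at or beyond 180 degrees for this ",
         "(TR, T1)", call. = FALSE)
  if (integer_round) {
    rounded <- round(alphas)
    if (any(rounded < 1))
      stop("integer rounding would give a flip angle below 1 degree; ",
           "choose a longer TR or drop integer_round", call. = FALSE)
    shift <- rounded - alphas
    message(sprintf("rounded flip angles by %s degrees",
                    paste(sprintf("%+.2f", shift), collapse = ", ")))
    alphas <- rounded
    taus <- tau_from_alpha(alphas)
  }
  schedule$flip_angles_deg <- alphas
  schedule$taus <- taus
  schedule$u_ratios <- taus / tau_e
  schedule$p_levels <- 1 / (1 + schedule$u_ratios^2)
  schedule$tau_e <- tau_e
  schedule$tr <- tr
  schedule$t1 <- t1
  if (!is.null(schedule$predicted))
    schedule$predicted <- propagate_variance(schedule$taus,
                                             amplitude = 1, rho1 = rho1)
  schedule
}

#' @export
print.vfa_schedule <- function(x, ...) {
  cat(sprintf("VFA schedule (%s), n = %d%s\n", x$scheme, x$n,
              if (!is.na(x$target)) paste0(", target: ", x$target) else ""))
  cat("  u = tau/tauE: ", paste(sprintf("%.4f", x$u_ratios), collapse = ", "),
      "\n")
  cat("  levels p:     ", paste(sprintf("%.3f", x$p_levels), collapse = ", "),
      "\n")
  if (!is.null(x$flip_angles_deg))
    cat("  flip angles:  ",
        paste(sprintf("%.2f", x$flip_angles_deg), collapse = ", "),
        " deg (TR = ", x$tr, " s, T1 = ", x$t1, " s)\n", sep = "")
  if (!is.null(x$predicted))
    cat(sprintf("  normalized variance: rho1 %.4f, amplitude %.4f\n",
                x$predicted$normalized_rho1,
                x$predicted$normalized_amplitude))
  invisible(x)
}
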