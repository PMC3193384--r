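#' Define a synthetic phantom
#'
#' Digital phantoms used to exercise the estimators end-to-end:
#' \describe{
#'   \item{`"agar"`}{uniform sphere, T1 = 2.41 s (a 6\% agar gel).}
#'   \item{`"mncl2"`}{uniform sphere, T1 = 0.54 s (a 0.1 mM MnCl2
#'     solution).}
#'   \item{`"brain3c"`}{three nested compartments with white-matter,
#'     gray-matter and CSF relaxation times of 0.85, 1.29 and 4.58 s and
#'     proton-density-like relative amplitudes 0.70, 0.82, 1.00: WM fills
#'     an outer ellipsoid, GM a shell inside it, CSF a central
#'     ventricle-like core.}
#'   \item{`"custom"`}{caller-supplied `labels`, `t1` and `amplitude`.}
#' }
#' Label 0 is background (zero signal).
#'
#' @param name phantom preset.
#' @param dim integer grid dimensions, each <= 64 (default 16^3).
#' @param t1 per-compartment T1 values (seconds), named by label, for
#'   `"custom"` (or to override a preset).
#' @param amplitude per-compartment amplitudes, recycled against `t1`.
#' @param labels integer label array for `"custom"`.
#' @return a `"vfa_phantom"`: list with `labels` (3D integer array), `t1`
#'   and `amplitude` (per-label vectors), `name`.
#' @examples
#' p <- vfa_phantom("brain3c", dim = c(12, 12, 12))
#' table(p$labels)
#' @export
vfa_phantom <- function(name = c("agar", "mncl2", "brain3c", "custom"),
                        dim = c(16L, 16L, 16L),
                        t1 = NULL, amplitude = NULL, labels = NULL) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 4L) || any(dim > 64L))
    stop("'dim' must be three integers in [4, 64]", call. = FALSE)

  if (name == "custom") {
    if (is.null(labels) || is.null(t1))
      stop("custom phantoms need 'labels' and 't1'", call. = FALSE)
    labels <- array(as.integer(labels), dim = dim(labels))
  } else {
    # normalized coordinates in [-1, 1]
    g <- lapply(dim, function(d) (seq_len(d) - (d + 1) / 2) / (d / 2))
    r2 <- outer(outer(g[[1]]^2, g[[2]]^2, `+`), g[[3]]^2, `+`)
    labels <- array(0L, dim)
    if (name == "brain3c") {
      labels[r2 <= 0.9^2] <- 1L      # WM bulk
      labels[r2 <= 0.55^2] <- 2L     # GM shell
      labels[r2 <= 0.3^2] <- 3L      # CSF core
      if (is.null(t1)) t1 <- c(wm = 0.85, gm = 1.29, csf = 4.58)
      if (is.null(amplitude)) amplitude <- c(wm = 0.70, gm = 0.82, csf = 1.00)
    } else {
      labels[r2 <= 0.9^2] <- 1L
      if (is.null(t1)) t1 <- c(bulk = if (name == "agar") 2.41 else 0.54)
      if (is.null(amplitude)) amplitude <- c(bulk = 1)
    }
  }
  nlab <- max(labels)
  t1 <- rep_len(t1, nlab)
  amplitude <- rep_len(if (is.null(amplitude)) 1 else amplitude, nlab)
  .check_num(t1, "t1", lower = 0, open_lower = TRUE)
  .check_num(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  structure(list(labels = labels, t1 = t1, amplitude = amplitude,
                 name = name),
            class = "vfa_phantom")
}

#' Simulate a VFA image volume stack from a phantom
#'
#' Generates one 3D volume per flip angle: each voxel's signal follows the
#' algebraic Ernst model for its compartment's (T1, amplitude), with an
#' optional per-voxel transmit bias field scaling the flip angle, plus
#' Gaussian or Rician noise.  Background voxels carry pure noise (or zero).
#' Reproducible: a fixed seed yields identical volumes.
#'
#' @param phantom a [vfa_phantom()].
#' @param alpha_deg flip angles, degrees (one volume each).
#' @param tr_s repetition time(s), seconds, recycled.
#' @param sigma noise SD in signal units (0 = noiseless).
#' @param noise `"gaussian"` or `"rician"`.
#' @param bias_field multiplicative flip-angle bias: a scalar or an array
#'   matching the phantom grid (default 1).
#' @param seed RNG seed, required when `sigma > 0`.
#' @return a `"vfa_stack"` (see [vfa_stack()]).
#' @examples
#' p <- vfa_phantom("agar", dim = c(8, 8, 8))
#' st <- generate_phantom_volumes(p, alpha_deg = c(2, 5, 9, 14),
#'                                tr_s = 0.012)
#' @export
generate_phantom_volumes <- function(phantom, alpha_deg, tr_s,
                                     sigma = 0,
                                     noise = c("gaussian", "rician"),
                                     bias_field = 1, seed = NULL) {
  noise <- match.arg(noise)
  if (!inherits(phantom, "vfa_phantom"))
    stop("'phantom' must be a vfa_phantom", call. = FALSE)
  .check_num(alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  .check_num(tr_s, "tr_s", lower = 0, open_lower = TRUE)
  .check_num(sigma, "sigma", lower = 0, allow_vector = FALSE)
  tr_s <- rep_len(tr_s, length(alpha_deg))
  if (sigma > 0 && is.null(seed))
    stop("a 'seed' is required when simulating with noise", call. = FALSE)
  dm <- dim(phantom$labels)
  if (length(bias_field) == 1L) {
    bias_field <- array(bias_field, dm)
  } else if (!identical(dim(bias_field), dm)) {
    stop("'bias_field' dimensions must match the phantom grid",
         call. = FALSE)
  }
  .check_num(as.vector(bias_field), "bias_field", lower = 0,
             open_lower = TRUE)

  lab <- as.vector(phantom$labels)
  inside <- lab > 0L
  t1v <- ifelse(inside, phantom$t1[pmax(lab, 1L)], NA_real_)
  av <- ifelse(inside, phantom$amplitude[pmax(lab, 1L)], 0)
  fv <- as.vector(bias_field)

  make_vol <- function(k) {
    s <- numeric(length(lab))
    aa <- fv[inside] * alpha_deg[k]
    if (any(aa >= 180))
      stop("bias field pushes a flip angle to 180 degrees", call. = FALSE)
    rho <- 2 * tanh(tr_s[k] / (2 * t1v[inside]))
    s[inside] <- .alg_signal(av[inside], 2 * tan(aa * pi / 360), rho)
    s
  }
  vols <- lapply(seq_along(alpha_deg), make_vol)
  if (sigma > 0) {
    vols <- with_seed(seed, lapply(vols, function(s) {
      if (noise == "gaussian") s + rnorm(length(s), 0, sigma)
      else sqrt((s + rnorm(length(s), 0, sigma))^2 +
                rnorm(length(s), 0, sigma)^2)
    }))
  }
  vfa_stack(lapply(vols, array, dim = dm), alpha_deg = alpha_deg,
            tr_s = tr_s)
}
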