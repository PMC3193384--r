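#' Construct a VFA volume stack
#'
#' A volume stack bundles one 3D signal volume per acquisition with its
#' per-volume metadata (flip angle, TR).  All volumes must share grid
#' dimensions; grid metadata (e.g. the NIfTI header of the first volume
#' read from disk) is carried through untouched.
#'
#' @param volumes a list of 3D numeric arrays with identical dimensions.
#' @param alpha_deg per-volume flip angles, degrees.
#' @param tr_s per-volume repetition times, seconds (recycled).
#' @param template optional reference object (e.g. an `RNifti` image)
#'   whose grid metadata is reused when writing.
#' @return an object of class `"vfa_stack"`.
#' @seealso [read_stack()], [write_stack()], [fit_volume()].
#' @export
vfa_stack <- function(volumes, alpha_deg, tr_s, template = NULL) {
  if (!is.list(volumes) || length(volumes) < 1L)
    stop("'volumes' must be a non-empty list of 3D arrays", call. = FALSE)
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 0L) != 3L))
    stop("each volume must be a 3D array", call. = FALSE)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent grids: all volumes must share dimensions",
         call. = FALSE)
  nv <- length(volumes)
  .check_num(alpha_deg, "alpha_deg", lower = 0, upper = 180,
             open_lower = TRUE, open_upper = TRUE)
  if (length(alpha_deg) != nv)
    stop("'alpha_deg' must have one entry per volume", call. = FALSE)
  .check_num(tr_s, "tr_s", lower = 0, open_lower = TRUE)
  tr_s <- rep_len(tr_s, nv)
  structure(list(volumes = volumes,
                 meta = data.frame(alpha_deg = alpha_deg, tr_s = tr_s),
                 dim = dims[[1]], template = template),
            class = "vfa_stack")
}

#' @export
print.vfa_stack <- function(x, ...) {
  cat(sprintf("VFA volume stack: %d volumes of %s voxels\n",
              length(x$volumes), paste(x$dim, collapse = " x ")))
  cat("  flip angles (deg):", paste(x$meta$alpha_deg, collapse = ", "), "\n")
  cat("  TR (s):", paste(unique(x$meta$tr_s), collapse = ", "), "\n")
  invisible(x)
}

#' Voxelwise VFA parameter maps
#'
#' Fits the linear-plot regression (or its short-TR multi-TR variant) in
#' every voxel of a volume stack in one vectorized pass, returning T1,
#' amplitude, standard-error and fit-count maps plus the analysis mask.
#'
#' An optional transmit bias field is handled either post hoc
#' (`b1_mode = "posthoc"`: fit with nominal angles, then divide the T1 map
#' by \eqn{f^2}; adequate in the small-angle regime) or exactly
#' (`b1_mode = "exact"`: each voxel's \eqn{\tau} values are computed from
#' its actual flip angles \eqn{f\alpha} before the regression).
#'
#' The mask keeps voxels whose mean signal exceeds `mask_k` times a
#' background level estimated from the lowest quintile of voxel means;
#' voxels with degenerate fits (non-negative slope, fewer than 2 positive
#' signals) are masked out and counted.
#'
#' @param stack a [vfa_stack()].
#' @param b1 optional bias field: scalar or array matching the grid.
#' @param angle_max optional flip-angle cutoff in degrees: volumes at
#'   larger nominal angles are excluded (e.g. after a bias analysis).
#' @param multi_tr use the multi-TR short-TR regression
#'   (\eqn{x = S\tau/(2TR)}, slope \eqn{-T_1}).
#' @param b1_mode `"posthoc"` or `"exact"`, see Details.
#' @param mask optional logical array overriding the automatic mask.
#' @param mask_k background multiplier of the automatic mask.
#' @return an object of class `"vfa_maps"`: list of arrays `t1`,
#'   `amplitude`, `se_t1`, `se_amplitude`, `nfit`, `mask`, and the count
#'   `n_degenerate`.  Values outside the mask are `NA`.
#' @examples
#' p <- vfa_phantom("agar", dim = c(8, 8, 8))
#' st <- generate_phantom_volumes(p, alpha_deg = c(2, 5, 9, 14, 18),
#'                                tr_s = 0.012)
#' m <- fit_volume(st)
#' range(m$t1, na.rm = TRUE)   # 2.41 s throughout the phantom
#' @export
fit_volume <- function(stack, b1 = NULL, angle_max = NULL,
                       multi_tr = FALSE,
                       b1_mode = c("posthoc", "exact"),
                       mask = NULL, mask_k = 5) {
  b1_mode <- match.arg(b1_mode)
  if (!inherits(stack, "vfa_stack"))
    stop("'stack' must be a vfa_stack", call. = FALSE)
  meta <- stack$meta
  sel <- if (is.null(angle_max)) rep(TRUE, nrow(meta))
         else meta$alpha_deg <= angle_max
  if (sum(sel) < 2L)
    stop("fewer than 2 volumes left after the flip-angle cutoff",
         call. = FALSE)
  if (!multi_tr && length(unique(meta$tr_s[sel])) > 1L)
    stop("mixed TR values: set multi_tr = TRUE", call. = FALSE)

  dm <- stack$dim
  nvox <- prod(dm)
  alpha <- meta$alpha_deg[sel]
  trs <- meta$tr_s[sel]
  S <- vapply(stack$volumes[sel], as.vector, numeric(nvox))  # nvox x nvol

  fvec <- NULL
  if (!is.null(b1)) {
    if (length(b1) == 1L) b1 <- array(b1, dm)
    if (!identical(dim(b1), dm))
      stop("'b1' dimensions must match the stack grid", call. = FALSE)
    fvec <- as.vector(b1)
    .check_num(fvec, "b1", lower = 0, open_lower = TRUE)
  }

  if (is.null(mask)) {
    mS <- rowMeans(S)
    bg <- median(mS[mS <= quantile(mS, 0.2)])
    if (!is.finite(bg) || bg < 0) bg <- 0
    mask_v <- mS > pmax(mask_k * bg, .Machine$double.eps)
  } else {
    if (!identical(dim(mask), dm))
      stop("'mask' dimensions must match the stack grid", call. = FALSE)
    mask_v <- as.vector(mask)
  }

  idx <- which(mask_v)
  Sm <- S[idx, , drop = FALSE]
  nv <- length(alpha)

  # tau: per-volume vector, or per-voxel matrix in exact-B1 mode
  tau0 <- tau_from_alpha(alpha)
  if (!is.null(fvec) && b1_mode == "exact") {
    aa <- outer(fvec[idx], alpha)            # actual angles per voxel
    if (any(aa >= 180))
      stop("bias field pushes a flip angle to 180 degrees", call. = FALSE)
    TAU <- 2 * tan(aa * pi / 360)
  } else {
    TAU <- matrix(tau0, nrow = length(idx), ncol = nv, byrow = TRUE)
  }

  pos <- Sm > 0
  X <- Sm * TAU
  if (multi_tr) X <- sweep(X, 2L, 2 * trs, `/`)
  Y <- Sm / TAU
  X[!pos] <- NA; Y[!pos] <- NA
  npos <- rowSums(pos)

  n <- pmax(npos, 1L)
  xb <- rowSums(X, na.rm = TRUE) / n
  yb <- rowSums(Y, na.rm = TRUE) / n
  dx <- X - xb
  dy <- Y - yb
  dx[!pos] <- 0; dy[!pos] <- 0
  sxx <- rowSums(dx * dx)
  sxy <- rowSums(dx * dy)
  slope <- sxy / sxx
  ok <- npos >= 2L & sxx > 0 & is.finite(slope) & slope < 0
  intercept <- yb - slope * xb

  rss <- rowSums((dy - slope * dx)^2)
  s2 <- ifelse(npos > 2L, rss / (npos - 2L), NA_real_)
  var_slope <- s2 / sxx
  var_int <- s2 * (1 / n + xb^2 / sxx)

  if (multi_tr) {
    t1v <- -slope
    se_t1v <- sqrt(var_slope)
  } else {
    rho1 <- -1 / (2 * slope)
    ok <- ok & rho1 > 0 & rho1 < 2
    tr1 <- trs[1]
    rr <- pmin(pmax(rho1, 1e-12), 2 - 1e-12)   # clamp degenerate voxels
    t1v <- ifelse(ok, tr1 / (2 * atanh(rr / 2)), NA_real_)
    g <- atanh(rr / 2)
    se_rho1 <- sqrt(var_slope) / (2 * slope^2)
    se_t1v <- tr1 * 0.5 / ((1 - (rho1 / 2)^2) * 2 * g^2) * se_rho1
  }
  t1v[!ok] <- NA_real_

  # post-hoc transmit-bias correction of apparent T1
  if (!is.null(fvec) && b1_mode == "posthoc")
    t1v <- t1v / fvec[idx]^2

  blank <- function() array(NA_real_, dm)
  fill <- function(vals) {
    a <- blank(); a[idx] <- ifelse(ok, vals, NA_real_); a
  }
  out <- list(t1 = fill(t1v),
              amplitude = fill(intercept),
              se_t1 = fill(se_t1v),
              se_amplitude = fill(sqrt(var_int)),
              nfit = { a <- array(0L, dm)
                       a[idx] <- as.integer(round(ifelse(ok, npos, 0)))
                       a },
              mask = { a <- array(FALSE, dm); a[idx] <- ok; a },
              n_degenerate = sum(!ok),
              multi_tr = multi_tr, angle_max = angle_max,
              b1_mode = if (is.null(fvec)) NA_character_ else b1_mode)
  class(out) <- "vfa_maps"
  out
}

#' @export
print.vfa_maps <- function(x, ...) {
  cat("VFA parameter maps:", paste(dim(x$t1), collapse = " x "), "voxels\n")
  cat(sprintf("  %d voxels in mask (%d degenerate fits dropped)\n",
              sum(x$mask), x$n_degenerate))
  if (sum(x$mask)) {
    cat(sprintf("  T1 [s]: median %.3f, IQR %.3f-%.3f\n",
                median(x$t1[x$mask]),
                quantile(x$t1[x$mask], 0.25),
                quantile(x$t1[x$mask], 0.75)))
  }
  invisible(x)
}
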