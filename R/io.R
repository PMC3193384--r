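#' Read a VFA measurement table
#'
#' Reads delimited text (tab, comma or semicolon autodetected from the
#' header line; decimal point, UTF-8) with header columns `alpha_deg`,
#' `tr_s`, `signal` and optionally `sd`, as produced by ROI analyses of
#' VFA series.
#'
#' @param path file path.
#' @return a validated data.frame of VFA samples.
#' @seealso [write_vfa_table()], [vfa_fit()].
#' @export
read_vfa_table <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";"
         else if (grepl(",", hdr)) "," else ""
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  .as_signal_set(d)
}

#' Write a VFA measurement table
#'
#' @param data a data.frame of VFA samples.
#' @param path output file path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_vfa_table <- function(data, path) {
  data <- .as_signal_set(data)
  utils::write.table(data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.sidecar_path <- function(dir) file.path(dir, "stack.json")

#' Read a VFA volume stack from NIfTI files
#'
#' Loads the volumes listed in a JSON sidecar together with their
#' per-volume acquisition metadata.  The sidecar must contain fields
#' `files`, `alpha_deg` and `tr_s` (one entry per volume); missing fields
#' are reported by name.  Grid metadata of the first volume is kept as the
#' template for later writes.
#'
#' @param dir directory containing the volumes and a `stack.json` sidecar,
#'   or the path of the sidecar itself.
#' @return a [vfa_stack()].
#' @export
read_stack <- function(dir) {
  sidecar <- if (dir.exists(dir)) .sidecar_path(dir) else dir
  if (!file.exists(sidecar))
    stop("sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  need <- c("files", "alpha_deg", "tr_s")
  miss <- need[!need %in% names(meta)]
  if (length(miss))
    stop("sidecar is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(sidecar)
  paths <- file.path(base, meta$files)
  if (!all(file.exists(paths)))
    stop("missing volume file(s): ",
         paste(meta$files[!file.exists(paths)], collapse = ", "),
         call. = FALSE)
  imgs <- lapply(paths, RNifti::readNifti)
  vols <- lapply(imgs, function(v) array(as.numeric(v), dim = dim(v)))
  vfa_stack(vols, alpha_deg = as.numeric(meta$alpha_deg),
            tr_s = as.numeric(meta$tr_s), template = imgs[[1]])
}

#' Write a VFA volume stack as NIfTI files plus sidecar
#'
#' Writes one NIfTI volume per flip angle (`vol_001.nii.gz`, ...) at
#' double precision, and a `stack.json` sidecar recording file names,
#' per-volume flip angles (degrees) and repetition times (seconds), so
#' that a write-read round trip reproduces data and metadata exactly.
#'
#' @param stack a [vfa_stack()].
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  if (!inherits(stack, "vfa_stack"))
    stop("'stack' must be a vfa_stack", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("vol_%03d.nii.gz", seq_along(stack$volumes))
  for (i in seq_along(stack$volumes)) {
    img <- if (!is.null(stack$template))
      RNifti::asNifti(stack$volumes[[i]], reference = stack$template)
    else stack$volumes[[i]]
    RNifti::writeNifti(img, file.path(dir, files[i]), datatype = "double")
  }
  meta <- list(files = files,
               alpha_deg = stack$meta$alpha_deg,
               tr_s = stack$meta$tr_s,
               units = list(alpha_deg = "degree", tr_s = "second"))
  jsonlite::write_json(meta, .sidecar_path(dir), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(.sidecar_path(dir))
}

#' Write parameter maps as NIfTI files
#'
#' Writes the T1, amplitude, standard-error, fit-count and mask maps of a
#' [fit_volume()] result as NIfTI volumes (`<prefix>_t1.nii.gz`, ...) with
#' a JSON sidecar recording the units (T1 in seconds) and the missing
#' value convention (NA outside the mask).
#'
#' @param maps a `"vfa_maps"` object.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"maps"`).
#' @return the sidecar path, invisibly.
#' @export
write_maps <- function(maps, dir, prefix = "maps") {
  if (!inherits(maps, "vfa_maps"))
    stop("'maps' must come from fit_volume()", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- c("t1", "amplitude", "se_t1", "se_amplitude", "nfit", "mask")
  files <- setNames(sprintf("%s_%s.nii.gz", prefix, layers), layers)
  for (nm in layers)
    RNifti::writeNifti(maps[[nm]] + 0, file.path(dir, files[[nm]]),
                       datatype = "double")
  side <- file.path(dir, paste0(prefix, "_maps.json"))
  jsonlite::write_json(
    list(files = as.list(files),
         units = list(t1 = "second", amplitude = "arbitrary"),
         missing_value = "NaN outside mask"),
    side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

#' Read parameter maps written by [write_maps()]
#'
#' @param sidecar path to the `<prefix>_maps.json` sidecar.
#' @return a `"vfa_maps"`-like list of arrays (mask restored to logical).
#' @export
read_maps <- function(sidecar) {
  if (!file.exists(sidecar))
    stop("sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  base <- dirname(sidecar)
  out <- lapply(meta$files, function(f) {
    v <- RNifti::readNifti(file.path(base, f))
    array(as.numeric(v), dim = dim(v))
  })
  out$mask <- array(out$mask > 0, dim = dim(out$mask))
  out$nfit <- array(as.integer(out$nfit), dim = dim(out$nfit))
  out$n_degenerate <- NA_integer_
  class(out) <- "vfa_maps"
  out
}
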