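## DCE series I/O: 4D NIfTI volumes with a JSON sidecar carrying acquisition
## metadata (frame interval, seed, ground-truth parameters for phantoms) and
## the signal -> concentration conversion under the linear-enhancement
## assumption.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Save a 4D DCE series as NIfTI-1 plus JSON sidecar
#'
#' @param values 4D array (signal or concentration).
#' @param grid the [volume_grid()] describing the series.
#' @param path output `.nii` / `.nii.gz` path; the sidecar is written next
#'   to it with extension `.json`.
#' @param sidecar named list of extra metadata stored in the sidecar
#'   (e.g. seed, ground-truth parameters). Spacing and frame interval are
#'   always included.
#' @return `path`, invisibly.
#' @export
save_series <- function(values, grid, path, sidecar = list()) {
  stopifnot_grid(grid)
  values <- as.array(values)
  if (length(dim(values)) != 4L ||
      !all(dim(values) == c(grid$dims, grid$n_frames)))
    stop("'values' must be a 4D array matching the grid")
  write_nifti(values, path,
              pixdim = c(grid$spacing, grid$frame_interval), datatype = 16L)
  meta <- c(list(spacing_mm = grid$spacing,
                 frame_interval_s = grid$frame_interval,
                 n_frames = grid$n_frames), sidecar)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a 4D DCE series
#'
#' Reads a 4D NIfTI-1 file; voxel spacing comes from the header (mm) and
#' the frame interval from the header time step (`pixdim[5]`) or the JSON
#' sidecar. When both are present and disagree the sidecar wins and the
#' mismatch is reported as a message.
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return list with `values` (4D array), `grid` ([volume_grid()]) and
#'   `sidecar` (named list, possibly empty).
#' @export
load_series <- function(path) {
  nii <- read_nifti(path)
  if (length(nii$dim) != 4L)
    stop(sprintf("'%s' is %dD; a 4D dynamic series is required",
                 path, length(nii$dim)))
  spacing <- nii$pixdim[2:4]
  dt_header <- nii$pixdim[5]
  sc_file <- sidecar_path(path)
  sidecar <- if (file.exists(sc_file))
    jsonlite::read_json(sc_file, simplifyVector = TRUE) else list()
  dt_sidecar <- sidecar$frame_interval_s
  dt <- if (!is.null(dt_sidecar) && is.finite(dt_sidecar) && dt_sidecar > 0) {
    if (is.finite(dt_header) && dt_header > 0 &&
        abs(dt_header - dt_sidecar) > 1e-6 * dt_sidecar)
      message(sprintf(
        "frame interval mismatch for %s: header %.6g s, sidecar %.6g s; using sidecar",
        path, dt_header, dt_sidecar))
    dt_sidecar
  } else if (is.finite(dt_header) && dt_header > 0) {
    dt_header
  } else {
    stop(sprintf("no temporal spacing in header or sidecar for '%s'", path))
  }
  grid <- volume_grid(dims = nii$dim[1:3], spacing = spacing,
                      n_frames = nii$dim[4], frame_interval = dt)
  list(values = nii$data, grid = grid, sidecar = sidecar)
}

#' Save / load a 3D ROI mask as NIfTI-1 (uint8)
#'
#' @param mask an [roi_mask()].
#' @param grid the [volume_grid()] (spatial part used for spacing).
#' @param path output path.
#' @return `path` invisibly (`save_mask`); an [roi_mask()] (`load_mask`).
#' @export
save_mask <- function(mask, grid, path) {
  stopifnot_grid(grid)
  check_mask_matches(mask, grid$dims)
  write_nifti(array(as.integer(mask$values), dim = dim(mask$values)),
              path, pixdim = grid$spacing, datatype = 2L)
  invisible(path)
}

#' @rdname save_mask
#' @param label label for the loaded mask.
#' @export
load_mask <- function(path, label = "tumor") {
  nii <- read_nifti(path)
  if (length(nii$dim) != 3L)
    stop(sprintf("'%s' is %dD; a 3D mask is required", path, length(nii$dim)))
  roi_mask(nii$data != 0, label = label)
}

#' Convert DCE signal to tracer concentration
#'
#' Applies the linear-enhancement assumption: concentration is proportional
#' to relative enhancement, `c(r,t) = (S(r,t) - S0(r)) / S0(r)`, with the
#' per-voxel baseline `S0` taken as the mean of the first
#' `baseline_frames` frames. Voxels whose baseline is not strictly positive
#' cannot be normalized; they are zeroed, flagged in the `valid` attribute
#' and counted. Negative concentrations (noise undershoot) are clipped to
#' zero by default, as the downstream transport inversion assumes
#' nonnegative tracer density.
#'
#' @param signal 4D array (or result of [synthesize_signal()]).
#' @param grid a [volume_grid()]; defaults to the array's `grid` attribute.
#' @param baseline_frames number of initial frames averaged into S0
#'   (default 1, matching a 5-frame acquisition).
#' @param clip_negative clip negative concentrations to 0 (default TRUE).
#' @param max_invalid_frac reject the series if more than this fraction of
#'   voxels has a nonpositive baseline (default 0.5).
#' @param s0 optional known baseline map (3D array or scalar), e.g. from a
#'   separate pre-contrast acquisition or a phantom's ground truth; when
#'   given it replaces the first-frames estimate and `baseline_frames` is
#'   ignored.
#' @return A [conc_series()] with attributes `valid` (logical 3D array) and
#'   `n_invalid`.
#' @export
signal_to_concentration <- function(signal, grid = attr(signal, "grid"),
                                    baseline_frames = 1L,
                                    clip_negative = TRUE,
                                    max_invalid_frac = 0.5,
                                    s0 = NULL) {
  if (is.null(grid)) stop("no 'grid' supplied and none attached to 'signal'")
  stopifnot_grid(grid)
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L ||
      !all(dim(signal) == c(grid$dims, grid$n_frames)))
    stop("'signal' must be a 4D array matching the grid")
  if (is.null(s0)) {
    k <- as.integer(baseline_frames)
    if (k < 1L || k >= grid$n_frames)
      stop("'baseline_frames' must be in [1, n_frames)")
    s0 <- apply(signal[, , , seq_len(k), drop = FALSE], 1:3, mean)
  } else {
    if (length(s0) == 1L) s0 <- array(s0, dim = grid$dims)
    s0 <- as.array(s0)
    if (!all(dim(s0) == grid$dims)) stop("'s0' must match the spatial grid")
  }
  valid <- is.finite(s0) & s0 > 0
  n_invalid <- sum(!valid)
  if (n_invalid > max_invalid_frac * length(valid))
    stop(sprintf(
      "%d of %d voxels (%.0f%%) have nonpositive baseline signal; series rejected",
      n_invalid, length(valid), 100 * n_invalid / length(valid)))
  s0_safe <- ifelse(valid, s0, 1)
  conc <- array(0, dim = dim(signal))
  for (f in seq_len(grid$n_frames)) {
    cf <- (frame3d(signal, f) - s0_safe) / s0_safe
    cf[!valid] <- 0
    conc[, , , f] <- cf
  }
  if (clip_negative) conc[conc < 0] <- 0
  out <- conc_series(conc, grid)
  attr(out, "valid") <- valid
  attr(out, "n_invalid") <- n_invalid
  out
}
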