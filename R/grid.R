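#' Spatiotemporal acquisition grid
#'
#' Describes the physical geometry of a 4D DCE-MRI acquisition: matrix size,
#' voxel spacing, number of dynamic frames and the interval between them.
#' Defaults mirror a typical hepatic DCE protocol: 0.84 mm in-plane
#' resolution, 3 mm slices and a 5 s frame interval with 5 frames.
#'
#' @param dims integer length-3, matrix size (Nx, Ny, Nz); all >= 1.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param n_frames integer, number of dynamic frames Nt >= 2.
#' @param frame_interval numeric, seconds between consecutive frames; > 0.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(32, 32, 8))
#' voxel_volume_mm3(g)
#' @export
volume_grid <- function(dims = c(32L, 32L, 8L),
                        spacing = c(0.84, 0.84, 3),
                        n_frames = 5L,
                        frame_interval = 5) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive values (mm)")
  n_frames <- as.integer(n_frames)
  if (length(n_frames) != 1L || is.na(n_frames) || n_frames < 2L)
    stop("'n_frames' must be an integer >= 2")
  frame_interval <- as.numeric(frame_interval)
  if (length(frame_interval) != 1L || !is.finite(frame_interval) ||
      frame_interval <= 0)
    stop("'frame_interval' must be a positive number of seconds")
  structure(list(dims = dims, spacing = spacing, n_frames = n_frames,
                 frame_interval = frame_interval),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d frames @ %.3g s\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$n_frames, x$frame_interval))
  invisible(x)
}

#' @rdname volume_grid
#' @param grid a `volume_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' @rdname volume_grid
#' @export
frame_times <- function(grid) (seq_len(grid$n_frames) - 1) * grid$frame_interval

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "volume_grid")) stop("expected a 'volume_grid' object")
  invisible(grid)
}

## Extract frame f of a 4D array as a 3D array, robust to singleton dims.
frame3d <- function(arr, f) {
  d <- dim(arr)
  array(arr[, , , f, drop = FALSE], dim = d[1:3])
}

#' 4D tracer concentration series
#'
#' Container pairing a 4D concentration array `c(x, y, z, t)` (relative
#' enhancement units, assumed proportional to tracer concentration) with its
#' acquisition grid.
#'
#' @param values 4D numeric array with dimensions `c(grid$dims, grid$n_frames)`.
#' @param grid a [volume_grid()].
#' @return An object of class `conc_series` with fields `values` and `grid`.
#' @export
conc_series <- function(values, grid) {
  stopifnot_grid(grid)
  values <- as.array(values)
  expect_dim <- c(grid$dims, grid$n_frames)
  if (length(dim(values)) != 4L || !all(dim(values) == expect_dim))
    stop(sprintf("concentration array is %s but grid implies %s",
                 paste(dim(values), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  if (!all(is.finite(values))) stop("concentration values must be finite")
  structure(list(values = values, grid = grid), class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat("conc_series over ")
  print(x$grid)
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Voxelwise velocity field
#'
#' A static 3-vector field u(r) = (ux, uy, uz) in mm/s on a spatial grid,
#' stored as a 4D array whose last dimension indexes the component.
#'
#' @param components 4D numeric array with dimensions `c(grid$dims, 3)`.
#' @param grid a [volume_grid()].
#' @return An object of class `velocity_field` with fields `components`
#'   and `grid`.
#' @export
velocity_field <- function(components, grid) {
  stopifnot_grid(grid)
  components <- as.array(components)
  expect_dim <- c(grid$dims, 3L)
  if (length(dim(components)) != 4L || !all(dim(components) == expect_dim))
    stop(sprintf("velocity array is %s but grid implies %s",
                 paste(dim(components), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  if (!all(is.finite(components))) stop("velocity components must be finite")
  structure(list(components = components, grid = grid),
            class = "velocity_field")
}

#' Uniform (constant) velocity field
#'
#' @param u numeric length-3 velocity vector in mm/s.
#' @param grid a [volume_grid()].
#' @return A [velocity_field()] constant over the volume.
#' @export
constant_velocity <- function(u, grid) {
  stopifnot_grid(grid)
  u <- as.numeric(u)
  if (length(u) != 3L || any(!is.finite(u)))
    stop("'u' must be a finite length-3 vector (mm/s)")
  comp <- array(rep(u, each = prod(grid$dims)), dim = c(grid$dims, 3L))
  velocity_field(comp, grid)
}

#' Speed map |u| of a velocity field
#'
#' @param u a [velocity_field()].
#' @return 3D array of voxelwise speeds sqrt(ux^2 + uy^2 + uz^2), mm/s.
#' @export
speed_map <- function(u) {
  if (!inherits(u, "velocity_field")) stop("expected a 'velocity_field'")
  sqrt(u$components[, , , 1, drop = FALSE]^2 +
       u$components[, , , 2, drop = FALSE]^2 +
       u$components[, , , 3, drop = FALSE]^2)[, , , 1]
}

#' Binary region-of-interest mask
#'
#' @param values logical 3D array (or coercible) marking member voxels.
#' @param label one of "tumor" or "artery" (free-form labels accepted).
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(values, label = "tumor") {
  values <- array(as.logical(values), dim = dim(as.array(values)))
  if (length(dim(values)) != 3L) stop("mask must be a 3D array")
  if (any(is.na(values))) stop("mask must not contain NA")
  if (!any(values)) stop("mask must contain at least one voxel")
  structure(list(values = values, label = label), class = "roi_mask")
}

check_mask_matches <- function(mask, dims) {
  if (!inherits(mask, "roi_mask")) stop("expected an 'roi_mask'")
  if (!all(dim(mask$values) == dims))
    stop(sprintf("mask is %s but volume is %s",
                 paste(dim(mask$values), collapse = "x"),
                 paste(dims, collapse = "x")))
  invisible(mask)
}
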