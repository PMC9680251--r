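#' Arterial input function container
#'
#' @param times numeric, strictly increasing sample times in seconds.
#' @param values numeric, nonnegative concentration samples (relative
#'   enhancement units), same length as `times`.
#' @return Object of class `aif`.
#' @export
aif <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (length(times) < 2L) stop("an AIF needs at least two samples")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("AIF values must be finite and nonnegative")
  structure(list(times = times, values = values), class = "aif")
}

#' Gamma-variate arterial input function
#'
#' Standard parametric bolus shape used throughout the DCE literature:
#' zero before `onset`, then
#' `amplitude * (x/(shape*scale))^shape * exp(shape - x/scale)` with
#' `x = t - onset`, so the peak value `amplitude` is reached at
#' `onset + shape * scale` seconds.
#'
#' @param times sample times in seconds, strictly increasing.
#' @param amplitude peak concentration (>= 0).
#' @param onset bolus arrival time in seconds; must lie within `times`.
#' @param shape gamma-variate shape parameter (> 0).
#' @param scale gamma-variate time scale in seconds (> 0).
#' @return An [aif()].
#' @examples
#' a <- make_aif(seq(0, 60, by = 0.5), amplitude = 1, onset = 5,
#'               shape = 3, scale = 2)
#' a$times[which.max(a$values)]  # == 5 + 3*2
#' @export
make_aif <- function(times, amplitude = 1, onset = 5, shape = 3, scale = 3) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("'amplitude' must be >= 0")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  if (!is.finite(shape) || shape <= 0) stop("'shape' must be positive")
  if (onset < min(times) || onset > max(times))
    stop("'onset' must lie within the sampled time range")
  x <- pmax(times - onset, 0)
  v <- amplitude * (x / (shape * scale))^shape * exp(shape - x / scale)
  v[times <= onset] <- 0
  aif(times, v)
}

## Linear interpolation of an AIF, zero outside its sampled support
## (pre-bolus and post-window are both treated as tracer-free).
aif_interp <- function(a, t) {
  y <- stats::approx(a$times, a$values, xout = t, yleft = 0, yright = 0,
                     ties = "ordered")$y
  y[is.na(y)] <- 0
  y
}

## ---------------------------------------------------------------------------
## Transport (advection) forward model
## ---------------------------------------------------------------------------

## Donor-cell (first-order upwind) flux divergence along one axis.
## Face velocity is the mean of the two adjacent voxel velocities; the face
## flux takes the upwind voxel's concentration. Boundary faces carry zero
## flux (closed box), so the scheme conserves total mass exactly.
upwind_divergence_axis <- function(cc, ua, h, axis) {
  ord <- c(axis, setdiff(1:3, axis))
  ccp <- aperm(cc, ord)
  uap <- aperm(ua, ord)
  n <- dim(ccp)[1]
  div <- array(0, dim = dim(ccp))
  if (n > 1L) {
    lo <- 1:(n - 1L); hi <- 2:n
    uface <- 0.5 * (uap[lo, , , drop = FALSE] + uap[hi, , , drop = FALSE])
    cup <- ccp[lo, , , drop = FALSE]
    cdn <- ccp[hi, , , drop = FALSE]
    fface <- uface * (cup * (uface > 0) + cdn * (uface <= 0))
    div[lo, , ] <- div[lo, , , drop = FALSE] + fface / h
    div[hi, , ] <- div[hi, , , drop = FALSE] - fface / h
  }
  aperm(div, order(ord))
}

cfl_numbers <- function(u, grid, dt_sub) {
  vapply(1:3, function(a)
    max(abs(u$components[, , , a])) * dt_sub / grid$spacing[a], numeric(1))
}

#' Simulate passive tracer transport (advection)
#'
#' Integrates the conservative transport equation dc/dt = -div(c u) for a
#' static velocity field with a donor-cell (first-order upwind) flux-form
#' finite-difference scheme and zero-flux (closed box) boundaries. The
#' scheme is positivity-preserving and conserves total mass exactly (up to
#' floating point); its price is numerical diffusion of order
#' u*h*(1 - CFL)/2 per axis, which smears sharp fronts over long
#' integrations.
#'
#' @param c0 3D nonnegative array, initial concentration at frame 1.
#' @param u a [velocity_field()] (mm/s).
#' @param grid a [volume_grid()]; frames are sampled every
#'   `grid$frame_interval` seconds.
#' @param substeps integration substeps per frame interval. `NULL` (default)
#'   picks the smallest count keeping every axis CFL number
#'   `max|u_a| * dt_sub / h_a` at or below 0.5; an explicit value violating
#'   that bound is rejected, naming the limiting axis.
#' @param scheme `"upwind"` (default): conservative donor-cell fluxes;
#'   `"central"`: the central-difference flux divergence used by the QTM
#'   inversion stencil, useful for inverse-consistency validation where the
#'   discrete forward and inverse operators must match exactly (not
#'   conservative; use `substeps = 1` for exact stencil matching).
#' @return A [conc_series()] with `grid$n_frames` frames, the first equal
#'   to `c0`.
#' @export
simulate_transport <- function(c0, u, grid, substeps = NULL,
                               scheme = c("upwind", "central")) {
  scheme <- match.arg(scheme)
  stopifnot_grid(grid)
  if (!inherits(u, "velocity_field")) stop("'u' must be a velocity_field")
  c0 <- as.array(c0)
  if (length(dim(c0)) != 3L || !all(dim(c0) == grid$dims))
    stop(sprintf("'c0' is %s but grid is %s",
                 paste(dim(c0), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  if (!all(dim(u$components)[1:3] == grid$dims))
    stop("velocity field does not match the grid")
  if (any(!is.finite(c0)) || any(c0 < 0))
    stop("'c0' must be finite and nonnegative")

  umax_h <- vapply(1:3, function(a)
    max(abs(u$components[, , , a])) / grid$spacing[a], numeric(1))
  if (is.null(substeps)) {
    substeps <- max(1L, ceiling(grid$frame_interval * max(umax_h) / 0.5))
  } else {
    substeps <- as.integer(substeps)
    if (substeps < 1L) stop("'substeps' must be >= 1")
    cfl <- umax_h * grid$frame_interval / substeps
    if (max(cfl) > 0.5 + 1e-12) {
      worst <- which.max(cfl)
      stop(sprintf(
        "CFL number %.3g on axis %s exceeds 0.5; increase 'substeps' (need >= %d)",
        cfl[worst], c("x", "y", "z")[worst],
        ceiling(grid$frame_interval * max(umax_h) / 0.5)))
    }
  }
  dt_sub <- grid$frame_interval / substeps

  ux <- u$components[, , , 1]; uy <- u$components[, , , 2]
  uz <- u$components[, , , 3]
  dim(ux) <- dim(uy) <- dim(uz) <- grid$dims
  ops <- if (scheme == "central") spatial_ops(grid) else NULL
  step_div <- function(cc) {
    if (scheme == "upwind") {
      upwind_divergence_axis(cc, ux, grid$spacing[1], 1L) +
        upwind_divergence_axis(cc, uy, grid$spacing[2], 2L) +
        upwind_divergence_axis(cc, uz, grid$spacing[3], 3L)
    } else {
      array(as.vector(ops$div[[1]] %*% as.vector(cc * ux)) +
              as.vector(ops$div[[2]] %*% as.vector(cc * uy)) +
              as.vector(ops$div[[3]] %*% as.vector(cc * uz)),
            dim = grid$dims)
    }
  }
  vals <- array(0, dim = c(grid$dims, grid$n_frames))
  cc <- c0
  vals[, , , 1] <- cc
  for (f in 2:grid$n_frames) {
    for (s in seq_len(substeps)) {
      cc <- cc - dt_sub * step_div(cc)
    }
    vals[, , , f] <- cc
  }
  out <- conc_series(vals, grid)
  attr(out, "substeps") <- substeps
  out
}

## ---------------------------------------------------------------------------
## Kety / extended Tofts forward model
## ---------------------------------------------------------------------------

broadcast_param <- function(p, dims, name) {
  if (length(p) == 1L) p <- array(p, dim = dims)
  p <- as.array(p)
  if (!all(dim(p) == dims))
    stop(sprintf("'%s' must be scalar or match the grid dims", name))
  if (any(!is.finite(p)) || any(p < 0))
    stop(sprintf("'%s' must be finite and nonnegative", name))
  p
}

## Shared Kety kernel: tissue response by exponential-convolution quadrature
## on an upsampled time axis,
##   c(t) = Ktrans * int_0^t ca(s - tau) exp(-kep (t - s)) ds,
## evaluated at arbitrary output times. Vectorized over voxels.
## ktrans, kep, tau: vectors of equal length (one entry per voxel).
kety_kernel <- function(ktrans, kep, tau, a, times_out, upsample = 20L) {
  nt <- length(times_out)
  nv <- length(ktrans)
  t_max <- max(times_out)
  dtf <- if (nt > 1L) min(diff(times_out)) / upsample else t_max / upsample
  dtf <- max(dtf, 1e-6)
  tf <- seq(0, t_max, by = dtf)
  if (tf[length(tf)] < t_max) tf <- c(tf, t_max)
  nf <- length(tf)

  ## shifted AIF per voxel: ca(tf - tau_v), zero before bolus support
  ca_mat <- matrix(aif_interp(a, as.vector(outer(tf, tau, "-"))),
                   nrow = nf, ncol = nv)
  ef <- exp(-kep * dtf)
  conc <- matrix(0, nrow = nf, ncol = nv)
  for (k in 2:nf) {
    dt_k <- tf[k] - tf[k - 1]
    e_k <- if (dt_k == dtf) ef else exp(-kep * dt_k)
    conc[k, ] <- conc[k - 1, ] * e_k +
      ktrans * dt_k / 2 * (ca_mat[k - 1, ] * e_k + ca_mat[k, ])
  }
  ## sample at requested output times
  idx <- vapply(times_out, function(t) which.min(abs(tf - t)), integer(1))
  out <- conc[idx, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Simulate Kety (extended Tofts) tissue concentration
#'
#' Generates voxelwise tissue concentration curves from the delay-shifted
#' Kety model dc/dt = Ktrans * ca(t - tau) - kep * c, i.e.
#' `c(t) = Ktrans * int_0^t ca(s - tau) exp(-kep (t - s)) ds`,
#' using trapezoidal exponential-convolution quadrature on an internally
#' upsampled time axis. kep = Ktrans / Ve is the efflux rate.
#'
#' @param ktrans transfer constant in 1/s; scalar or 3D array over the grid.
#' @param kep efflux rate in 1/s; scalar or 3D array.
#' @param tau bolus arrival delay in seconds; scalar or 3D array; must not
#'   exceed the acquisition window.
#' @param a an [aif()] sampled at least as densely as the frame interval.
#' @param grid a [volume_grid()]; output frames at [frame_times()].
#' @param upsample internal quadrature refinement factor (default 20).
#' @return A [conc_series()].
#' @export
simulate_kety <- function(ktrans, kep, tau, a, grid, upsample = 20L) {
  stopifnot_grid(grid)
  if (!inherits(a, "aif")) stop("'a' must be an aif")
  kt <- broadcast_param(ktrans, grid$dims, "ktrans")
  ke <- broadcast_param(kep, grid$dims, "kep")
  ta <- broadcast_param(tau, grid$dims, "tau")
  tt <- frame_times(grid)
  if (max(ta) > max(tt))
    stop(sprintf("delay tau = %.3g s exceeds the %.3g s acquisition window",
                 max(ta), max(tt)))
  conc <- kety_kernel(as.vector(kt), as.vector(ke), as.vector(ta),
                      a, tt, upsample = upsample)
  vals <- array(t(conc), dim = c(grid$dims, grid$n_frames))
  conc_series(vals, grid)
}

## ---------------------------------------------------------------------------
## Signal synthesis and virtual cohort
## ---------------------------------------------------------------------------

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthesize a DCE signal from a concentration series
#'
#' Applies the linear signal model S(r,t) = S0(r) * (1 + c(r,t)) relating
#' relative enhancement to tracer concentration, then adds zero-mean
#' Gaussian noise with voxelwise standard deviation `noise_sd * S0(r)`.
#'
#' @param conc a [conc_series()].
#' @param s0 baseline signal; positive scalar or 3D array over the grid.
#' @param noise_sd noise level as a fraction of baseline signal (>= 0).
#' @param seed integer seed for reproducible noise, or `NULL`.
#' @return 4D signal array with a `grid` attribute.
#' @export
synthesize_signal <- function(conc, s0, noise_sd = 0, seed = NULL) {
  if (!inherits(conc, "conc_series")) stop("'conc' must be a conc_series")
  grid <- conc$grid
  if (length(s0) == 1L) s0 <- array(s0, dim = grid$dims)
  s0 <- as.array(s0)
  if (!all(dim(s0) == grid$dims)) stop("'s0' must match the spatial grid")
  if (any(!is.finite(s0)) || any(s0 <= 0))
    stop("baseline signal 's0' must be positive everywhere")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  sig <- array(0, dim = c(grid$dims, grid$n_frames))
  for (f in seq_len(grid$n_frames))
    sig[, , , f] <- s0 * (1 + frame3d(conc$values, f))
  if (noise_sd > 0) {
    sig <- with_seed(seed, {
      sig + array(stats::rnorm(length(sig), sd = as.vector(s0) * noise_sd),
                  dim = dim(sig))
    })
  }
  attr(sig, "grid") <- grid
  sig
}

#' Generate a virtual patient cohort
#'
#' Draws a cohort whose lung shunt fraction (LSF, %) is a noisy linear
#' function of tumor ROI velocity, emulating the clinical observation that
#' arterio-venous shunting raises both tumor blood speed and lung shunting.
#' The remaining columns (Kety parameters, tumor volume, age, sex) are
#' drawn independently of LSF from distributions matching published hepatic
#' tumor cohorts, so that only `roi_speed` carries signal about LSF.
#'
#' @param n number of virtual patients (>= 4).
#' @param link list with `intercept` and `slope` mapping roi_speed (mm/s)
#'   to LSF (%); default `list(intercept = 1, slope = 60)`.
#' @param noise_sd Gaussian noise on LSF in percentage points (default 3).
#' @param speed_range range (mm/s) from which ROI speeds are drawn
#'   uniformly; default `c(0.02, 0.30)`.
#' @param seed integer seed, or `NULL`.
#' @param distributions optional list overriding the nuisance-column
#'   samplers; each element is `function(n)` returning `n` draws, named
#'   among `roi_ktrans`, `roi_ve`, `roi_tau`, `tumor_volume_cm3`, `age`.
#' @return data.frame of class `cohort_table` with columns `id`,
#'   `lsf_percent`, `roi_speed`, `roi_ktrans`, `roi_ve`, `roi_tau`,
#'   `tumor_volume_cm3`, `age`, `sex`.
#' @export
generate_cohort <- function(n = 25L,
                            link = list(intercept = 1, slope = 60),
                            noise_sd = 3,
                            speed_range = c(0.02, 0.30),
                            seed = NULL,
                            distributions = list()) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("'n' must be >= 4 (cohort statistics undefined below that)")
  if (any(!is.finite(speed_range)) || length(speed_range) != 2L ||
      speed_range[1] <= 0 || diff(speed_range) <= 0)
    stop("'speed_range' must be a positive increasing interval (mm/s)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")

  dists <- list(
    roi_ktrans = function(n) abs(stats::rnorm(n, 0.07, 0.05)) + 1e-4,
    roi_ve = function(n) pmin(pmax(stats::rnorm(n, 0.12, 0.04), 0.01), 0.6),
    roi_tau = function(n) pmax(stats::rnorm(n, 14, 4), 0),
    tumor_volume_cm3 = function(n) abs(stats::rnorm(n, 18.6, 15.7)) + 0.1,
    age = function(n) round(pmin(pmax(stats::rnorm(n, 66, 12), 42), 87))
  )
  for (nm in names(distributions)) dists[[nm]] <- distributions[[nm]]

  with_seed(seed, {
    speed <- stats::runif(n, speed_range[1], speed_range[2])
    lsf <- link$intercept + link$slope * speed +
      stats::rnorm(n, 0, noise_sd)
    lsf <- pmin(pmax(lsf, 0), 100)
    out <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      lsf_percent = lsf,
      roi_speed = speed,
      roi_ktrans = dists$roi_ktrans(n),
      roi_ve = dists$roi_ve(n),
      roi_tau = dists$roi_tau(n),
      tumor_volume_cm3 = dists$tumor_volume_cm3(n),
      age = dists$age(n),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(17, 8) / 25),
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Gaussian blob initial condition
#'
#' Convenience 3D Gaussian used as tumor-like tracer bolus in phantoms.
#'
#' @param grid a [volume_grid()].
#' @param center voxel-coordinate center (defaults to the volume center).
#' @param sigma_mm Gaussian standard deviation in mm, length 1 or 3.
#' @param amplitude peak value.
#' @return 3D array over the grid.
#' @export
gaussian_blob <- function(grid, center = NULL, sigma_mm = c(4, 4, 4),
                          amplitude = 1) {
  stopifnot_grid(grid)
  if (is.null(center)) center <- (grid$dims + 1) / 2
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3)
  x <- (seq_len(grid$dims[1]) - center[1]) * grid$spacing[1]
  y <- (seq_len(grid$dims[2]) - center[2]) * grid$spacing[2]
  z <- (seq_len(grid$dims[3]) - center[3]) * grid$spacing[3]
  gx <- exp(-x^2 / (2 * sigma_mm[1]^2))
  gy <- exp(-y^2 / (2 * sigma_mm[2]^2))
  gz <- exp(-z^2 / (2 * sigma_mm[3]^2))
  amplitude * outer(outer(gx, gy), gz)
}
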