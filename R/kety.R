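## Delay-fitted Kety / extended Tofts fitting.
##
## Tissue model: dc/dt = Ktrans * ca(t - tau) - kep * c, with kep =
## Ktrans / Ve. Integrating once,
##
##   c(t) = Ktrans * int_0^t ca(s - tau) ds - kep * int_0^t c(s) ds,
##
## which is linear in (Ktrans, kep) at fixed delay tau but nonlinear in
## tau. The fit alternates an exhaustive per-voxel tau grid search with
## TV-regularized nonnegative linear solves for the Ktrans and kep maps.

#' Kety fit configuration
#'
#' @param lambda TV weight on the Ktrans map (default 1e-3, the L-curve
#'   choice for hepatic DCE at this geometry).
#' @param mu TV weight on the kep map (default 1e-3).
#' @param tau_grid delay candidates in seconds (default 0..25 s step 1 s);
#'   must lie within the acquisition window.
#' @param outer_iters alternating (tau search / map solve) iterations.
#' @param inner_iters iterations of the projected descent map solve.
#' @param tol relative objective-decrease stopping tolerance.
#' @param tv_eps TV smoothing half-width.
#' @param kep_floor kep below this (1/s) leaves Ve undefined (NA).
#' @param upsample quadrature refinement factor for the time integrals.
#' @return list of class `kety_config`.
#' @export
kety_config <- function(lambda = 1e-3, mu = 1e-3,
                        tau_grid = seq(0, 25, by = 1),
                        outer_iters = 5L, inner_iters = 300L, tol = 1e-8,
                        tv_eps = 1e-8, kep_floor = 1e-6, upsample = 20L) {
  if (!is.finite(lambda) || lambda < 0 || !is.finite(mu) || mu < 0)
    stop("'lambda' and 'mu' must be >= 0")
  if (length(tau_grid) < 1L || any(tau_grid < 0))
    stop("'tau_grid' must be nonempty and nonnegative")
  structure(list(lambda = lambda, mu = mu, tau_grid = sort(unique(tau_grid)),
                 outer_iters = as.integer(outer_iters),
                 inner_iters = as.integer(inner_iters), tol = tol,
                 tv_eps = tv_eps, kep_floor = kep_floor,
                 upsample = as.integer(upsample)),
            class = "kety_config")
}

#' Extract an arterial input function from an artery mask
#'
#' The AIF is the voxelwise mean concentration curve over the feeding
#' artery mask, sampled at the frame times — the digital analogue of a
#' radiologist drawing the AIF in the tumor-feeding artery.
#'
#' @param conc a [conc_series()].
#' @param artery an [roi_mask()] over the artery (nonempty).
#' @return An [aif()].
#' @export
extract_aif <- function(conc, artery) {
  if (!inherits(conc, "conc_series")) stop("'conc' must be a conc_series")
  check_mask_matches(artery, conc$grid$dims)
  nt <- conc$grid$n_frames
  cmat <- matrix(conc$values, ncol = nt)
  curves <- cmat[as.vector(artery$values), , drop = FALSE]
  aif(frame_times(conc$grid), colMeans(curves))
}

#' Single-voxel Kety model curve
#'
#' Evaluates the delay-shifted Kety tissue response for one parameter set;
#' shares its quadrature kernel with [simulate_kety()] (bit-identical on a
#' 1-voxel grid).
#'
#' @param ktrans transfer constant, 1/s.
#' @param kep efflux rate, 1/s.
#' @param tau delay, s.
#' @param a an [aif()].
#' @param times output sample times (s).
#' @param upsample quadrature refinement factor.
#' @return numeric concentration curve at `times`.
#' @export
kety_curve <- function(ktrans, kep, tau, a, times, upsample = 20L) {
  if (!inherits(a, "aif")) stop("'a' must be an aif")
  if (any(!is.finite(c(ktrans, kep, tau))) || ktrans < 0 || kep < 0 ||
      tau < 0)
    stop("parameters must be finite and nonnegative")
  if (tau > max(times))
    stop(sprintf("delay tau = %.3g s exceeds the %.3g s window",
                 tau, max(times)))
  as.vector(kety_kernel(ktrans, kep, tau, a, times, upsample = upsample))
}

## Cumulative trapezoidal integral.
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

## Quadrature pieces for the integrated linear system: cumulative integral
## of the tau-shifted AIF at the frame times (one column per tau), and the
## cumulative integral of each voxel curve via natural-spline upsampling.
kety_designs <- function(a, times, tau_grid, upsample) {
  dtf <- min(diff(times)) / upsample
  tf <- seq(0, max(times), by = dtf)
  if (tf[length(tf)] < max(times)) tf <- c(tf, max(times))
  idx <- vapply(times, function(t) which.min(abs(tf - t)), integer(1))
  x1 <- vapply(tau_grid, function(tau) {
    cumtrapz(tf, aif_interp(a, tf - tau))[idx]
  }, numeric(length(times)))
  list(x1 = x1, tf = tf, idx = idx)
}

## Integral of measured voxel curves: spline-upsampled cumulative
## trapezoid, returning a frames x voxels matrix.
curve_integrals <- function(ymat, times, tf, idx) {
  nv <- ncol(ymat)
  out <- matrix(0, nrow = length(times), ncol = nv)
  for (v in seq_len(nv)) {
    yf <- stats::spline(times, ymat[, v], xout = tf, method = "natural")$y
    out[, v] <- cumtrapz(tf, yf)[idx]
  }
  out
}

## Vectorized nonnegative 2-parameter least squares across voxels:
## minimize ||y - kt*x1 - kep*(-intc)||^2 with kt, kep >= 0.
## Inputs are the per-voxel normal-equation moments.
nnls2 <- function(a11, a12, a22, b1, b2, yy) {
  det <- a11 * a22 - a12^2
  det_ok <- det > .Machine$double.eps * pmax(a11 * a22, 1)
  kt <- ifelse(det_ok, (b1 * a22 - b2 * a12) / det, 0)
  ke <- ifelse(det_ok, (b2 * a11 - b1 * a12) / det, 0)
  ## interior solution invalid if either is negative: test the two edges
  bad <- !det_ok | kt < 0 | ke < 0
  if (any(bad)) {
    kt_e <- pmax(ifelse(a11 > 0, b1 / pmax(a11, 1e-300), 0), 0)
    rss_e1 <- yy - 2 * kt_e * b1 + kt_e^2 * a11
    ke_e <- pmax(ifelse(a22 > 0, b2 / pmax(a22, 1e-300), 0), 0)
    rss_e2 <- yy - 2 * ke_e * b2 + ke_e^2 * a22
    use1 <- rss_e1 <= rss_e2
    kt[bad] <- ifelse(use1, kt_e, 0)[bad]
    ke[bad] <- ifelse(use1, 0, ke_e)[bad]
  }
  rss <- yy - 2 * kt * b1 - 2 * ke * b2 +
    kt^2 * a11 + 2 * kt * ke * a12 + ke^2 * a22
  list(kt = kt, kep = ke, rss = pmax(rss, 0))
}

#' Fit the delay-shifted Kety model voxelwise
#'
#' Solves, over the masked voxels,
#' `argmin sum_t ||c - Ktrans*Int[ca_tau] + kep*Int[c]||^2
#'  + lambda*||grad Ktrans||_1 + mu*||grad kep||_1, Ktrans, kep >= 0`,
#' alternating (a) an exhaustive per-voxel delay grid search with (b)
#' TV-regularized projected linear solves for the Ktrans and kep maps at
#' fixed delays. With `lambda = mu = 0` step (b) reduces to independent
#' per-voxel nonnegative least squares. Ve is derived as Ktrans/kep where
#' kep exceeds `config$kep_floor` and reported as NA elsewhere.
#'
#' @param conc a [conc_series()] with at least 3 frames.
#' @param a the arterial input function ([aif()]); must not be identically
#'   zero.
#' @param config a [kety_config()].
#' @param mask optional [roi_mask()]; voxels outside are left at zero.
#' @return list of class `kety_fit`: `maps` (list with 3D arrays `ktrans`,
#'   `kep`, `ve`, `tau`), `objective` (outer trace, non-increasing),
#'   `converged`, `n_ve_undefined`, `config`, `grid`.
#' @export
fit_kety <- function(conc, a, config = kety_config(), mask = NULL) {
  if (!inherits(conc, "conc_series")) stop("'conc' must be a conc_series")
  if (!inherits(a, "aif")) stop("'a' must be an aif")
  if (all(a$values == 0))
    stop("AIF is identically zero: the Kety model is unidentifiable")
  grid <- conc$grid
  times <- frame_times(grid)
  if (grid$n_frames < 3L) stop("need at least 3 frames to fit the model")
  tau_grid <- config$tau_grid
  if (max(tau_grid) > max(times))
    stop(sprintf("tau grid extends to %.3g s, beyond the %.3g s window",
                 max(tau_grid), max(times)))
  n <- prod(grid$dims)
  sel <- if (is.null(mask)) rep(TRUE, n) else {
    check_mask_matches(mask, grid$dims)
    as.vector(mask$values)
  }
  ymat <- t(matrix(conc$values, nrow = n, ncol = grid$n_frames))[, sel,
                                                                 drop = FALSE]
  nv <- ncol(ymat)
  des <- kety_designs(a, times, tau_grid, config$upsample)
  intc <- curve_integrals(ymat, times, des$tf, des$idx)   # frames x voxels
  x2 <- -intc
  yy <- colSums(ymat^2)
  ## tau-independent moments
  a22 <- colSums(x2^2)
  b2 <- colSums(x2 * ymat)
  ## tau-dependent moments, one column set per tau
  ntau <- length(tau_grid)
  a11m <- matrix(0, ntau, nv); a12m <- matrix(0, ntau, nv)
  b1m <- matrix(0, ntau, nv)
  for (k in seq_len(ntau)) {
    x1 <- des$x1[, k]
    a11m[k, ] <- sum(x1^2)
    a12m[k, ] <- colSums(x1 * x2)
    b1m[k, ] <- colSums(x1 * ymat)
  }

  ## (a) initial per-voxel grid search over tau with unregularized NNLS
  best <- list(rss = rep(Inf, nv), kt = numeric(nv), kep = numeric(nv),
               tau_i = rep(1L, nv))
  for (k in seq_len(ntau)) {
    s <- nnls2(a11m[k, ], a12m[k, ], a22, b1m[k, ], b2, yy)
    better <- s$rss < best$rss - 1e-15 * pmax(yy, 1)
    best$rss[better] <- s$rss[better]
    best$kt[better] <- s$kt[better]
    best$kep[better] <- s$kep[better]
    best$tau_i[better] <- k
  }
  kt <- best$kt; kep <- best$kep; tau_i <- best$tau_i

  regularized <- config$lambda > 0 || config$mu > 0
  data_rss <- function(kt, kep, tau_i) {
    ii <- cbind(tau_i, seq_len(nv))
    yy - 2 * kt * b1m[ii] - 2 * kep * b2 +
      kt^2 * a11m[ii] + 2 * kt * kep * a12m[ii] + kep^2 * a22
  }
  objective <- sum(data_rss(kt, kep, tau_i))
  trace <- objective
  converged <- TRUE

  if (regularized) {
    ops <- spatial_ops(grid)
    tvg <- ops$grad
    scatter <- function(v) { f <- numeric(n); f[sel] <- v; f }
    tv_pair <- function(kt, kep) {
      gk <- as.vector(tvg %*% scatter(kt))
      ge <- as.vector(tvg %*% scatter(kep))
      config$lambda * sum(sqrt(gk^2 + config$tv_eps^2) - config$tv_eps) +
        config$mu * sum(sqrt(ge^2 + config$tv_eps^2) - config$tv_eps)
    }
    full_obj <- function(kt, kep, tau_i)
      sum(data_rss(kt, kep, tau_i)) + tv_pair(kt, kep)
    objective <- full_obj(kt, kep, tau_i)
    trace <- objective
    converged <- FALSE
    for (outer in seq_len(config$outer_iters)) {
      ## (b) projected descent on the two maps at fixed tau
      ii <- cbind(tau_i, seq_len(nv))
      a11 <- a11m[ii]; a12 <- a12m[ii]; b1 <- b1m[ii]
      gradf <- function(kt, kep) {
        gk_d <- 2 * (a11 * kt + a12 * kep - b1)
        ge_d <- 2 * (a12 * kt + a22 * kep - b2)
        fk <- scatter(kt); fe <- scatter(kep)
        gk_tv <- as.vector(Matrix::crossprod(tvg, {
          g <- as.vector(tvg %*% fk); g / sqrt(g^2 + config$tv_eps^2)
        }))[sel]
        ge_tv <- as.vector(Matrix::crossprod(tvg, {
          g <- as.vector(tvg %*% fe); g / sqrt(g^2 + config$tv_eps^2)
        }))[sel]
        list(kt = gk_d + config$lambda * gk_tv,
             kep = ge_d + config$mu * ge_tv)
      }
      fcur <- full_obj(kt, kep, tau_i)
      g <- gradf(kt, kep)
      step <- 1 / max(2 * max(a11, a22, abs(a12)) +
                        max(config$lambda, config$mu) / config$tv_eps * 12,
                      1e-300)
      kt_o <- kt; kep_o <- kep; g_o <- g
      for (inner in seq_len(config$inner_iters)) {
        st <- step
        repeat {
          kt_n <- pmax(kt - st * g$kt, 0)
          kep_n <- pmax(kep - st * g$kep, 0)
          f_n <- full_obj(kt_n, kep_n, tau_i)
          if (is.finite(f_n) && f_n <= fcur) break
          st <- st / 2
          if (st < 1e-30) break
        }
        if (st < 1e-30) break
        rel <- (fcur - f_n) / max(fcur, 1e-300)
        kt_o <- kt; kep_o <- kep; g_o <- g
        kt <- kt_n; kep <- kep_n; fcur <- f_n
        g <- gradf(kt, kep)
        if (rel < config$tol) break
        sv <- c(kt - kt_o, kep - kep_o)
        yv <- c(g$kt - g_o$kt, g$kep - g_o$kep)
        sy <- sum(sv * yv)
        step <- if (sy > 0) sum(sv^2) / sy else st * 2
        if (!is.finite(step) || step <= 0) step <- st
      }
      ## (a) re-pick tau at the current maps (cannot increase the objective)
      rss_tau <- matrix(0, ntau, nv)
      for (k in seq_len(ntau)) {
        rss_tau[k, ] <- yy - 2 * kt * b1m[k, ] - 2 * kep * b2 +
          kt^2 * a11m[k, ] + 2 * kt * kep * a12m[k, ] + kep^2 * a22
      }
      tau_i <- max.col(-t(rss_tau), ties.method = "first")
      f_new <- full_obj(kt, kep, tau_i)
      trace <- c(trace, f_new)
      if ((objective - f_new) / max(objective, 1e-300) < config$tol) {
        objective <- f_new
        converged <- TRUE
        break
      }
      objective <- f_new
    }
    if (!converged)
      warning("Kety fit reached outer_iters without meeting tol; returning best iterate")
  }

  to_map <- function(v, fill = 0) {
    f <- rep(fill, n); f[sel] <- v; array(f, dim = grid$dims)
  }
  kt_map <- to_map(kt)
  kep_map <- to_map(kep)
  tau_map <- to_map(tau_grid[tau_i])
  ve <- ifelse(kep > config$kep_floor, kt / kep, NA_real_)
  ve_map <- to_map(ve, fill = NA_real_)
  n_undef <- sum(sel) - sum(!is.na(ve))
  structure(list(
    maps = list(ktrans = kt_map, kep = kep_map, ve = ve_map, tau = tau_map),
    objective = trace, converged = converged,
    n_ve_undefined = n_undef, config = config, grid = grid),
    class = "kety_fit")
}

#' @export
print.kety_fit <- function(x, ...) {
  cat(sprintf(
    "Kety fit: lambda = %.3g, mu = %.3g; objective %.6g -> %.6g%s\n",
    x$config$lambda, x$config$mu, x$objective[1],
    x$objective[length(x$objective)],
    if (x$converged) "" else " (not converged)"))
  cat(sprintf("  Ktrans range [%.4g, %.4g] 1/s; %d voxels with undefined Ve\n",
              min(x$maps$ktrans), max(x$maps$ktrans), x$n_ve_undefined))
  invisible(x)
}
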