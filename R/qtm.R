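## Quantitative transport mapping (QTM): voxelwise inversion of the
## advection equation dc/dt = -div(c u) for a static velocity field u,
## posed as TV-regularized least squares over all frames,
##
##   u = argmin_u  sum_t || d_t c + div(c_t u) ||_2^2 + lambda ||grad u||_1 .
##
## No arterial input function is involved: the data term couples each voxel
## only to its spatial neighbors through the flux divergence.

## 1D central-difference matrix (one-sided at the ends), spacing h.
diff1d_central <- function(n, h) {
  if (n == 1L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(1, 1)))
  if (n == 2L)
    return(Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                                x = c(-1, 1, -1, 1) / h, dims = c(2, 2)))
  i <- c(1, 1, rep(2:(n - 1), 2), n, n)
  j <- c(1, 2, 2:(n - 1) - 1, 2:(n - 1) + 1, n - 1, n)
  x <- c(-1 / h, 1 / h, rep(-0.5 / h, n - 2), rep(0.5 / h, n - 2),
         -1 / h, 1 / h)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

## 1D forward-difference matrix, (n-1) x n, spacing h.
diff1d_forward <- function(n, h) {
  if (n == 1L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(0, 1)))
  Matrix::sparseMatrix(i = c(1:(n - 1), 1:(n - 1)), j = c(1:(n - 1), 2:n),
                       x = c(rep(-1 / h, n - 1), rep(1 / h, n - 1)),
                       dims = c(n - 1, n))
}

## Lift a 1D operator to the 3D voxel space (x fastest index).
lift_op <- function(m1d, dims, axis) {
  ix <- Matrix::Diagonal(dims[1]); iy <- Matrix::Diagonal(dims[2])
  iz <- Matrix::Diagonal(dims[3])
  switch(axis,
         Matrix::kronecker(iz, Matrix::kronecker(iy, m1d)),
         Matrix::kronecker(iz, Matrix::kronecker(m1d, ix)),
         Matrix::kronecker(m1d, Matrix::kronecker(iy, ix)))
}

## Spatial operators for a grid: central divergence parts and stacked
## forward-difference gradient (for TV).
spatial_ops <- function(grid) {
  d <- lapply(1:3, function(a)
    lift_op(diff1d_central(grid$dims[a], grid$spacing[a]), grid$dims, a))
  g <- do.call(rbind, lapply(1:3, function(a)
    lift_op(diff1d_forward(grid$dims[a], grid$spacing[a]), grid$dims, a)))
  list(div = d, grad = methods::as(g, "CsparseMatrix"), n = prod(grid$dims))
}

#' QTM solver configuration
#'
#' @param lambda total-variation weight (default 1e-4, the L-curve choice
#'   for in vivo hepatic DCE at this acquisition geometry).
#' @param max_iters iteration cap for the first-order solver.
#' @param tol relative objective-decrease stopping tolerance.
#' @param tv_eps smoothing half-width for the L1 TV term, in gradient units
#'   ((mm/s)/mm); several orders below typical velocity gradients.
#' @param var_floor voxels whose temporal concentration variance falls at
#'   or below this floor carry no transport information and are frozen at
#'   u = 0 (flagged in the solver report).
#' @param warm_iters conjugate-gradient iterations on the unregularized
#'   data term used to initialize the TV phase. Unregularized CG
#'   semiconverges (late iterations fit discretization error and noise),
#'   so this also acts as mild iteration regularization; keep moderate for
#'   noisy data.
#' @return list of class `qtm_config`.
#' @export
qtm_config <- function(lambda = 1e-4, max_iters = 1000L, tol = 1e-9,
                       tv_eps = 1e-6, var_floor = 1e-12,
                       warm_iters = 2000L) {
  if (!is.finite(lambda) || lambda < 0) stop("'lambda' must be >= 0")
  if (!is.finite(tol) || tol < 0) stop("'tol' must be >= 0")
  structure(list(lambda = lambda, max_iters = as.integer(max_iters),
                 tol = tol, tv_eps = tv_eps, var_floor = var_floor,
                 warm_iters = as.integer(warm_iters)),
            class = "qtm_config")
}

#' Transport-equation residual
#'
#' Evaluates the discrete residual of the advection model,
#' `d_t c + div(c u)`, with forward temporal differences between
#' consecutive frames and central spatial differences of the flux `c u`
#' (one-sided at the volume faces, consistent with closed-box boundaries).
#' Units 1/s; all differences are divided by the physical spacing.
#'
#' @param conc a [conc_series()].
#' @param u a [velocity_field()] on the same grid.
#' @return 4D array with `n_frames - 1` temporal slices.
#' @export
transport_residual <- function(conc, u) {
  if (!inherits(conc, "conc_series")) stop("'conc' must be a conc_series")
  if (!inherits(u, "velocity_field")) stop("'u' must be a velocity_field")
  grid <- conc$grid
  if (!all(dim(u$components)[1:3] == grid$dims))
    stop("velocity field shape does not match the concentration grid")
  ops <- spatial_ops(grid)
  nt <- grid$n_frames
  dt <- grid$frame_interval
  res <- array(0, dim = c(grid$dims, nt - 1L))
  uxv <- as.vector(u$components[, , , 1])
  uyv <- as.vector(u$components[, , , 2])
  uzv <- as.vector(u$components[, , , 3])
  for (t in seq_len(nt - 1L)) {
    ct <- as.vector(conc$values[, , , t])
    dtc <- (as.vector(conc$values[, , , t + 1]) - ct) / dt
    divflux <- as.vector(ops$div[[1]] %*% (ct * uxv)) +
               as.vector(ops$div[[2]] %*% (ct * uyv)) +
               as.vector(ops$div[[3]] %*% (ct * uzv))
    res[, , , t] <- array(dtc + divflux, dim = grid$dims)
  }
  res
}

## Assemble the stacked sparse system A v = -b of the data term, restricted
## to "active" voxels (temporal variance above the floor). Frozen voxels
## keep u = 0.
qtm_system <- function(conc, var_floor) {
  grid <- conc$grid
  ops <- spatial_ops(grid)
  n <- ops$n
  nt <- grid$n_frames
  dt <- grid$frame_interval
  cmat <- matrix(conc$values, nrow = n, ncol = nt)
  tvar <- apply(cmat, 1, stats::var)
  active <- tvar > var_floor
  blocks <- vector("list", nt - 1L)
  bs <- vector("list", nt - 1L)
  for (t in seq_len(nt - 1L)) {
    dg <- Matrix::Diagonal(x = cmat[, t])
    blocks[[t]] <- cbind(ops$div[[1]] %*% dg, ops$div[[2]] %*% dg,
                         ops$div[[3]] %*% dg)
    bs[[t]] <- (cmat[, t + 1] - cmat[, t]) / dt
  }
  a_full <- do.call(rbind, blocks)
  col_idx <- c(which(active), n + which(active), 2L * n + which(active))
  list(a = methods::as(a_full[, col_idx, drop = FALSE], "CsparseMatrix"),
       b = unlist(bs), active = active, col_idx = col_idx,
       n = n, grad = ops$grad)
}

## Largest singular value squared of a sparse matrix by power iteration.
power_sigma2 <- function(a, iters = 30L) {
  if (ncol(a) == 0L) return(0)
  v <- rep(1 / sqrt(ncol(a)), ncol(a))
  s <- 0
  for (k in seq_len(iters)) {
    w <- as.vector(Matrix::crossprod(a, a %*% v))
    s <- sqrt(sum(w^2))
    if (s == 0) return(0)
    v <- w / s
  }
  s
}

## Linear CG on the normal equations (lambda = 0 path). Starting from 0 the
## iterates stay in range(A'), so the limit is the minimum-norm least-squares
## solution; the recorded objective ||Av + b||^2 is non-increasing.
cg_least_squares <- function(a, b, max_iters, tol) {
  nv <- ncol(a)
  v <- numeric(nv)
  r <- -as.vector(Matrix::crossprod(a, b))   # -grad/2 at v = 0
  p <- r
  rs <- sum(r^2)
  f <- sum(b^2)
  trace <- f
  gscale <- max(rs, 1e-300)
  for (k in seq_len(max_iters)) {
    ap <- as.vector(a %*% p)
    denom <- sum(ap^2)
    if (denom <= 0) break
    alpha <- rs / denom
    v <- v + alpha * p
    r <- r - alpha * as.vector(Matrix::crossprod(a, ap))
    f_new <- f - alpha * rs          # exact CG objective update
    trace <- c(trace, f_new)
    rel <- (f - f_new) / max(f, 1e-300)
    f <- f_new
    rs_new <- sum(r^2)
    if (rs_new / gscale < 1e-28 || (tol > 0 && rel < tol && k > 1)) {
      rs <- rs_new
      break
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(v = v, trace = trace, iterations = length(trace) - 1L,
       converged = TRUE, reason = "gradient/objective tolerance reached")
}

## Monotone Barzilai-Borwein descent with backtracking on
## f(v) = ||A v + b||^2 + lambda * sum smooth_tv(G u_c).
bb_tv_descent <- function(a, b, grad_op, col_idx, n_vox, lambda, tv_eps,
                          max_iters, tol, lower = NULL, v0 = NULL) {
  nv <- ncol(a)
  tv_val <- function(u_full) {
    s <- 0
    for (c_ in 0:2) {
      g <- as.vector(grad_op %*% u_full[(c_ * n_vox + 1):((c_ + 1) * n_vox)])
      s <- s + sum(sqrt(g^2 + tv_eps^2) - tv_eps)
    }
    s
  }
  tv_grad <- function(u_full) {
    out <- numeric(3L * n_vox)
    for (c_ in 0:2) {
      sel <- (c_ * n_vox + 1):((c_ + 1) * n_vox)
      g <- as.vector(grad_op %*% u_full[sel])
      out[sel] <- as.vector(Matrix::crossprod(grad_op,
                                              g / sqrt(g^2 + tv_eps^2)))
    }
    out
  }
  scatter <- function(v) {
    u_full <- numeric(3L * n_vox)
    u_full[col_idx] <- v
    u_full
  }
  fval <- function(v, r) sum(r^2) + lambda * tv_val(scatter(v))

  v <- if (is.null(v0)) numeric(nv) else v0
  r <- if (is.null(v0)) b else as.vector(a %*% v) + b
  f <- fval(v, r)
  trace <- f
  grad <- function(v, r) {
    2 * as.vector(Matrix::crossprod(a, r)) +
      lambda * tv_grad(scatter(v))[col_idx]
  }
  g <- grad(v, r)
  sig2 <- power_sigma2(a)
  lips <- 2 * sig2 + lambda / max(tv_eps, 1e-300) * 12  # crude ||G||^2 bound
  step <- 1 / max(lips, 1e-300)
  reason <- "max_iters reached"
  converged <- FALSE
  v_old <- v; g_old <- g
  for (k in seq_len(max_iters)) {
    st <- step
    accepted <- FALSE
    for (bt in 1:60) {
      v_new <- v - st * g
      if (!is.null(lower)) v_new <- pmax(v_new, lower)
      r_new <- as.vector(a %*% v_new) + b
      f_new <- fval(v_new, r_new)
      if (is.finite(f_new) && f_new <= f) { accepted <- TRUE; break }
      st <- st / 2
    }
    if (!accepted || !is.finite(f_new)) { reason <- "line search stalled"; break }
    rel <- (f - f_new) / max(f, 1e-300)
    v_old <- v; g_old <- g
    v <- v_new; r <- r_new
    f <- f_new
    trace <- c(trace, f)
    g <- grad(v, r)
    if (rel < tol && k > 1) { converged <- TRUE
      reason <- "relative objective decrease below tol"; break }
    ## BB1 step from the last accepted pair
    sv <- v - v_old; yv <- g - g_old
    sy <- sum(sv * yv)
    step <- if (sy > 0) sum(sv * sv) / sy else st * 2
    if (!is.finite(step) || step <= 0) step <- st
  }
  if (!converged && reason == "max_iters reached") converged <- FALSE
  list(v = v, trace = trace, iterations = length(trace) - 1L,
       converged = converged || reason != "max_iters reached",
       reason = reason)
}

#' Solve QTM: invert the transport equation for the velocity field
#'
#' Estimates the voxelwise static velocity field minimizing
#' `sum_t ||d_t c + div(c_t u)||^2 + lambda * ||grad u||_1`
#' (anisotropic TV, forward differences per axis and component), with the
#' L1 term handled through a tightly smoothed surrogate. The solver is a
#' deterministic first-order method (linear conjugate gradients when
#' `lambda = 0`, monotone Barzilai-Borwein descent with backtracking
#' otherwise) started from u = 0; the recorded objective is non-increasing.
#' Voxels without temporal signal (variance at or below
#' `config$var_floor`) are frozen at u = 0 and flagged.
#'
#' @param conc a [conc_series()] (use [signal_to_concentration()] first for
#'   raw signal).
#' @param config a [qtm_config()].
#' @param mask optional [roi_mask()] restricting estimation; voxels outside
#'   are frozen at u = 0.
#' @param init optional [velocity_field()] used as the starting iterate of
#'   the TV phase (e.g. the previous solution when tracing a
#'   regularization path); ignored when `lambda = 0`.
#' @return list of class `qtm_fit` with elements `u` ([velocity_field()]),
#'   `speed` (3D array, mm/s), `objective` (trace), `iterations`,
#'   `converged`, `reason`, `frozen` (logical 3D array), `lambda`.
#' @export
solve_qtm <- function(conc, config = qtm_config(), mask = NULL,
                      init = NULL) {
  if (!inherits(conc, "conc_series")) stop("'conc' must be a conc_series")
  if (!all(is.finite(conc$values))) stop("concentration must be finite")
  grid <- conc$grid
  if (grid$n_frames < 2L) stop("need at least two frames")
  sys <- qtm_system(conc, config$var_floor)
  if (!is.null(mask)) {
    check_mask_matches(mask, grid$dims)
    sys$active <- sys$active & as.vector(mask$values)
    sys <- within_active(sys)
  }
  if (!any(sys$active)) {
    u <- constant_velocity(c(0, 0, 0), grid)
    return(structure(list(u = u, speed = speed_map(u),
                          objective = sum(sys$b^2), iterations = 0L,
                          converged = TRUE, reason = "no informative voxels",
                          frozen = array(TRUE, grid$dims),
                          lambda = config$lambda),
                     class = "qtm_fit"))
  }
  fit <- if (config$lambda == 0) {
    cg_least_squares(sys$a, sys$b, config$max_iters, config$tol)
  } else {
    ## warm start from the data-term CG solution (or a supplied iterate);
    ## the reported objective trace covers the TV phase and is monotone by
    ## construction
    v0 <- if (!is.null(init)) {
      if (!inherits(init, "velocity_field")) stop("'init' must be a velocity_field")
      as.vector(init$components)[sys$col_idx]
    } else {
      cg_least_squares(sys$a, sys$b,
                       min(config$max_iters, config$warm_iters),
                       config$tol)$v
    }
    bb_tv_descent(sys$a, sys$b, sys$grad, sys$col_idx, sys$n,
                  config$lambda, config$tv_eps, config$max_iters,
                  config$tol, v0 = v0)
  }
  if (!fit$converged)
    warning(sprintf("QTM solver stopped without convergence: %s", fit$reason))
  u_full <- numeric(3L * sys$n)
  u_full[sys$col_idx] <- fit$v
  comp <- array(u_full, dim = c(grid$dims, 3L))
  u <- velocity_field(comp, grid)
  structure(list(u = u, speed = speed_map(u), objective = fit$trace,
                 iterations = fit$iterations, converged = fit$converged,
                 reason = fit$reason,
                 frozen = array(!sys$active, grid$dims),
                 lambda = config$lambda),
            class = "qtm_fit")
}

## Re-subset system columns after the active set shrinks (e.g. by a mask).
within_active <- function(sys) {
  keep_vox <- which(sys$active)
  new_idx <- c(keep_vox, sys$n + keep_vox, 2L * sys$n + keep_vox)
  keep_cols <- which(sys$col_idx %in% new_idx)
  sys$a <- sys$a[, keep_cols, drop = FALSE]
  sys$col_idx <- sys$col_idx[keep_cols]
  sys
}

#' @export
print.qtm_fit <- function(x, ...) {
  cat(sprintf(
    "QTM fit: lambda = %.3g, %d iterations (%s), objective %.6g -> %.6g\n",
    x$lambda, x$iterations, x$reason,
    x$objective[1], x$objective[length(x$objective)]))
  cat(sprintf("  speed range [%.4g, %.4g] mm/s, %d frozen voxels\n",
              min(x$speed), max(x$speed), sum(x$frozen)))
  invisible(x)
}

#' L-curve selection of the TV weight
#'
#' Solves the QTM problem over a grid of regularization weights, records
#' the (log residual norm, log TV norm) curve and returns the weight at its
#' point of maximum curvature (the "corner").
#'
#' @param conc a [conc_series()].
#' @param lambda_grid positive weights, sorted increasing, length >= 3
#'   (a single weight is returned as-is with a warning).
#' @param config base [qtm_config()]; its `lambda` is overridden.
#' @param mask optional [roi_mask()].
#' @return list with `lambda` (the corner), `curve` (data.frame with
#'   columns lambda, log_residual, log_tv, curvature) and `fits`.
#' @export
l_curve_select <- function(conc, lambda_grid, config = qtm_config(),
                           mask = NULL) {
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive")
  if (length(lambda_grid) < 3L) {
    warning("fewer than 3 lambda values: degenerate L-curve, returning the first")
    return(list(lambda = lambda_grid[1], curve = NULL, fits = NULL))
  }
  ## ascending-lambda continuation: each solve warm-starts from the
  ## previous solution, the standard way to trace a regularization path
  fits <- vector("list", length(lambda_grid))
  prev <- NULL
  for (i in seq_along(lambda_grid)) {
    cf <- config; cf$lambda <- lambda_grid[i]
    fits[[i]] <- solve_qtm(conc, cf, mask = mask, init = prev)
    prev <- fits[[i]]$u
  }
  ops <- spatial_ops(conc$grid)
  resid_norm <- vapply(fits, function(f)
    sqrt(sum(transport_residual(conc, f$u)^2)), numeric(1))
  tv_norm <- vapply(fits, function(f) {
    s <- 0
    for (c_ in 1:3)
      s <- s + sum(abs(ops$grad %*% as.vector(f$u$components[, , , c_])))
    s
  }, numeric(1))
  x <- log(pmax(resid_norm, 1e-300))
  y <- log(pmax(tv_norm, 1e-300))
  s <- log(lambda_grid)
  k <- curve_curvature(s, x, y)
  interior <- 2:(length(lambda_grid) - 1L)
  best <- interior[which.max(abs(k[interior]))]
  list(lambda = lambda_grid[best],
       curve = data.frame(lambda = lambda_grid, log_residual = x,
                          log_tv = y, curvature = k),
       fits = fits)
}

## Signed curvature of a curve (x(s), y(s)) sampled nonuniformly.
curve_curvature <- function(s, x, y) {
  n <- length(s)
  d1 <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    out[1] <- (v[2] - v[1]) / (s[2] - s[1])
    out[n] <- (v[n] - v[n - 1]) / (s[n] - s[n - 1])
    out
  }
  xp <- d1(x); yp <- d1(y)
  xpp <- d1(xp); ypp <- d1(yp)
  (xp * ypp - yp * xpp) / pmax((xp^2 + yp^2)^1.5, 1e-300)
}
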