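# Transport-equation inversion: residual operator, solver, L-curve.

test_that("residual vanishes for a static field and scales linearly in c", {
  g <- small_grid(n_frames = 4L)
  vals <- array(rep(gaussian_blob(g), 4L), dim = c(g$dims, 4L))
  cs <- conc_series(vals, g)
  res <- transport_residual(cs, constant_velocity(c(0, 0, 0), g))
  expect_true(all(res == 0))

  ph <- blob_phantom(small_grid(n_frames = 4L))
  u <- constant_velocity(c(0.03, -0.02, 0.01), ph$grid)
  r1 <- transport_residual(ph$conc, u)
  r2 <- transport_residual(conc_series(2 * ph$conc$values, ph$grid), u)
  expect_identical(r2, 2 * r1)
})

test_that("residual at the true velocity beats a wrong velocity on a matched phantom", {
  g <- small_grid(n_frames = 4L)
  ph <- blob_phantom(g, u = c(0.05, 0.03, 0), scheme = "central",
                     substeps = 1L)
  u_true <- constant_velocity(ph$u, g)
  u_wrong <- constant_velocity(2 * ph$u, g)
  expect_lt(sum(transport_residual(ph$conc, u_true)^2),
            sum(transport_residual(ph$conc, u_wrong)^2))
})

test_that("a spatiotemporally constant concentration yields u = 0", {
  g <- small_grid(n_frames = 4L)
  cs <- conc_series(array(0.7, c(g$dims, 4L)), g)
  fit <- solve_qtm(cs, qtm_config(lambda = 1e-4, max_iters = 50L))
  expect_true(all(fit$u$components == 0))
  expect_true(all(fit$speed == 0))
  expect_true(all(fit$frozen))
})

test_that("lambda = 0 solution matches the dense min-norm least-squares oracle", {
  g <- volume_grid(c(6L, 6L, 1L), c(1, 1, 1), 3L, 2)
  ph <- blob_phantom(g, u = c(0.1, -0.05, 0), sigma_mm = c(1.5, 1.5, 1),
                     substeps = 4L)
  fit <- solve_qtm(ph$conc, qtm_config(lambda = 0, max_iters = 50000L,
                                       tol = 0))
  sys <- qtmdce:::qtm_system(ph$conc, 1e-12)
  v_oracle <- -MASS::ginv(as.matrix(sys$a)) %*% sys$b
  v_hat <- as.vector(fit$u$components)[sys$col_idx]
  expect_lt(sqrt(sum((v_hat - v_oracle)^2)) / sqrt(sum(v_oracle^2)), 1e-6)
})

test_that("objective scaling identity: solve(alpha*c, alpha^2*lambda) = solve(c, lambda)", {
  g <- volume_grid(c(6L, 6L, 1L), c(1, 1, 1), 3L, 2)
  ph <- blob_phantom(g, u = c(0.1, -0.05, 0), sigma_mm = c(1.5, 1.5, 1),
                     substeps = 4L)
  alpha <- 2  # exactly representable scaling keeps the solver path identical
  cs2 <- conc_series(alpha * ph$conc$values, g)
  f1 <- suppressWarnings(solve_qtm(ph$conc,
                                   qtm_config(lambda = 1e-5,
                                              max_iters = 1500L,
                                              tol = 1e-13)))
  f2 <- suppressWarnings(solve_qtm(cs2,
                                   qtm_config(lambda = alpha^2 * 1e-5,
                                              max_iters = 1500L,
                                              tol = 1e-13)))
  expect_equal(f1$u$components, f2$u$components, tolerance = 1e-10)
})

test_that("objective trace is non-increasing and the speed map is consistent", {
  g <- small_grid(n_frames = 5L)
  # compactly supported blob: the far field carries no temporal signal
  c0 <- gaussian_blob(g, sigma_mm = c(2, 2, 2.5))
  c0[c0 < 0.05 * max(c0)] <- 0
  cs <- simulate_transport(c0, constant_velocity(c(0.08, 0.06, 0), g), g)
  fit <- suppressWarnings(solve_qtm(cs,
                                    qtm_config(lambda = 1e-4,
                                               max_iters = 200L)))
  obj <- fit$objective
  expect_true(all(diff(obj) <= 1e-10 * pmax(abs(obj[-length(obj)]), 1)))
  expect_equal(fit$speed, sqrt(fit$u$components[, , , 1]^2 +
                                 fit$u$components[, , , 2]^2 +
                                 fit$u$components[, , , 3]^2))
  expect_true(all(fit$speed >= 0))
  # frozen voxels (no temporal variance in the blob's far field) stay at 0
  expect_true(any(fit$frozen))
  expect_true(all(fit$speed[fit$frozen] == 0))
})

test_that("matched-discretization phantom is recovered voxelwise", {
  g <- volume_grid(c(16L, 16L, 4L), c(0.84, 0.84, 3), 5L, 5)
  ph <- blob_phantom(g, u = c(0.08, 0.06, 0), sigma_mm = c(3, 3, 4),
                     scheme = "central", substeps = 1L)
  fit <- suppressWarnings(
    solve_qtm(ph$conc, qtm_config(lambda = 1e-6, max_iters = 4000L,
                                  tol = 1e-12, warm_iters = 4000L)))
  err <- abs(fit$speed[ph$roi] - 0.1) / 0.1
  expect_lt(median(err), 0.10)
})

test_that("L-curve: degenerate grid warns, path is monotone, corner is interior", {
  expect_warning(out <- l_curve_select(blob_phantom()$conc, 1e-4),
                 "degenerate")
  expect_equal(out$lambda, 1e-4)

  g <- volume_grid(c(10L, 10L, 2L), c(0.84, 0.84, 3), 4L, 5)
  ph <- blob_phantom(g, sigma_mm = c(2.5, 2.5, 3))
  sig <- synthesize_signal(ph$conc, s0 = 100, noise_sd = 0.02, seed = 3L)
  conc <- signal_to_concentration(sig, g, s0 = array(100, g$dims))
  lc <- suppressWarnings(
    l_curve_select(conc, 10^seq(-7, -2, by = 1),
                   qtm_config(max_iters = 3000L, warm_iters = 2000L,
                              tol = 1e-14)))
  # regularization path: residual up, TV down with increasing lambda
  expect_true(all(diff(lc$curve$log_residual) >= -1e-4))
  expect_true(all(diff(lc$curve$log_tv) <= 1e-4))
  expect_true(lc$lambda > min(lc$curve$lambda) &
                lc$lambda < max(lc$curve$lambda))
})
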