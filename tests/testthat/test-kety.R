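# AIF extraction and delay-fitted Kety model fitting.

test_that("AIF extraction averages the artery-mask curves", {
  g <- small_grid(n_frames = 4L)
  vals <- array(0, c(g$dims, 4L))
  curve_a <- c(0, 1, 2, 1)
  curve_b <- c(0, 3, 4, 3)
  vals[2, 2, 1, ] <- curve_a
  vals[5, 5, 2, ] <- curve_b
  cs <- conc_series(vals, g)

  m1 <- array(FALSE, g$dims); m1[2, 2, 1] <- TRUE
  expect_equal(extract_aif(cs, roi_mask(m1, "artery"))$values, curve_a)

  m2 <- array(FALSE, g$dims); m2[2, 2, 1] <- TRUE; m2[5, 5, 2] <- TRUE
  expect_equal(extract_aif(cs, roi_mask(m2, "artery"))$values,
               (curve_a + curve_b) / 2)

  expect_error(roi_mask(array(FALSE, g$dims), "artery"), "at least one")
})

test_that("kety_curve shares its kernel with simulate_kety bit-exactly", {
  g1 <- volume_grid(c(1L, 1L, 1L), c(1, 1, 1), 20L, 5)
  a <- test_aif(95)
  sim <- simulate_kety(0.03, 0.2, 10, a, g1)
  cur <- kety_curve(0.03, 0.2, 10, a, frame_times(g1))
  expect_identical(as.vector(sim$values), cur)
  expect_true(all(kety_curve(0, 0.2, 0, a, frame_times(g1)) == 0))
})

test_that("zero tissue enhancement fits to a zero Ktrans map", {
  g <- volume_grid(c(4L, 4L, 1L), c(1, 1, 1), 12L, 5)
  cs <- conc_series(array(0, c(g$dims, 12L)), g)
  a <- test_aif(55)
  fit <- fit_kety(cs, a, kety_config(lambda = 0, mu = 0,
                                     tau_grid = seq(0, 20, 5)))
  expect_true(all(fit$maps$ktrans == 0))
  expect_true(all(is.na(fit$maps$ve)))
  expect_equal(fit$n_ve_undefined, 16L)
})

test_that("noiseless Kety phantom parameters are recovered", {
  g <- volume_grid(c(4L, 4L, 2L), c(0.84, 0.84, 3), 30L, 5)
  a <- test_aif(145)
  cs <- simulate_kety(0.03, 0.2, 10, a, g)   # Ve = 0.15
  fit <- fit_kety(cs, a, kety_config(lambda = 0, mu = 0))
  expect_equal(mean(fit$maps$ktrans), 0.03, tolerance = 0.05 * 0.03)
  expect_equal(mean(fit$maps$ve, na.rm = TRUE), 0.15,
               tolerance = 0.05 * 0.15)
  expect_equal(mean(fit$maps$tau), 10, tolerance = 1)   # one grid step
})

test_that("shifting the AIF one frame later raises tau by one frame interval", {
  g <- volume_grid(c(3L, 3L, 1L), c(1, 1, 1), 30L, 5)
  a <- test_aif(145)
  cs <- simulate_kety(0.03, 0.2, 10, a, g)
  fit0 <- fit_kety(cs, a, kety_config(lambda = 0, mu = 0))
  a_late <- aif(a$times + g$frame_interval, a$values)
  fit1 <- fit_kety(cs, a_late, kety_config(lambda = 0, mu = 0))
  expect_equal(mean(fit0$maps$tau) - mean(fit1$maps$tau), g$frame_interval,
               tolerance = 1)
})

test_that("joint rescaling of tissue and arterial curves leaves the fit unchanged", {
  g <- volume_grid(c(3L, 3L, 1L), c(1, 1, 1), 25L, 5)
  a <- test_aif(120)
  cs <- simulate_kety(0.04, 0.25, 5, a, g)
  alpha <- 2
  cs2 <- conc_series(alpha * cs$values, g)
  a2 <- aif(a$times, alpha * a$values)
  f1 <- fit_kety(cs, a, kety_config(lambda = 0, mu = 0))
  f2 <- fit_kety(cs2, a2, kety_config(lambda = 0, mu = 0))
  expect_equal(f1$maps$ktrans, f2$maps$ktrans, tolerance = 1e-10)
  expect_equal(f1$maps$kep, f2$maps$kep, tolerance = 1e-10)
  expect_identical(f1$maps$tau, f2$maps$tau)
})

test_that("fixed-tau unregularized fit matches a dense two-parameter LS oracle", {
  g <- volume_grid(c(2L, 2L, 1L), c(1, 1, 1), 25L, 5)
  a <- test_aif(120)
  set.seed(8)
  kt_true <- array(runif(4, 0.01, 0.06), g$dims)
  kep_true <- array(runif(4, 0.1, 0.3), g$dims)
  cs <- simulate_kety(kt_true, kep_true, 0, a, g)
  fit <- fit_kety(cs, a, kety_config(lambda = 0, mu = 0, tau_grid = 0))

  # independent oracle: rebuild the integrated design by plain quadrature
  tt <- frame_times(g)
  tf <- seq(0, max(tt), by = 0.25)
  caf <- approx(a$times, a$values, xout = tf, yleft = 0, yright = 0)$y
  x1 <- approx(tf, cumsum(c(0, diff(tf) * (head(caf, -1) + tail(caf, -1)) / 2)),
               xout = tt)$y
  for (v in 1:4) {
    ij <- arrayInd(v, g$dims[1:2])
    y <- cs$values[ij[1], ij[2], 1, ]
    yf <- spline(tt, y, xout = tf, method = "natural")$y
    x2 <- -approx(tf, cumsum(c(0, diff(tf) * (head(yf, -1) + tail(yf, -1)) / 2)),
                  xout = tt)$y
    th <- coef(lm(y ~ 0 + x1 + x2))
    expect_equal(fit$maps$ktrans[ij[1], ij[2], 1], unname(th[1]),
                 tolerance = 1e-8)
    expect_equal(fit$maps$kep[ij[1], ij[2], 1], unname(th[2]),
                 tolerance = 1e-8)
  }
})

test_that("Ve consistency, TV objective monotonicity and error contracts", {
  g <- volume_grid(c(6L, 6L, 1L), c(0.84, 0.84, 3), 20L, 5)
  a <- test_aif(95)
  set.seed(21)
  kt_true <- array(0.03, g$dims); kt_true[1:3, , ] <- 0.06
  cs <- simulate_kety(kt_true, 0.2, 5, a, g)
  sig <- synthesize_signal(cs, 100, noise_sd = 0.01, seed = 4L)
  conc <- signal_to_concentration(sig, g, s0 = array(100, g$dims))
  fit <- suppressWarnings(
    fit_kety(conc, a, kety_config(lambda = 1e-3, mu = 1e-3,
                                  tau_grid = seq(0, 15, 1),
                                  outer_iters = 4L)))
  obj <- fit$objective
  expect_true(all(diff(obj) <= 1e-10 * pmax(abs(obj[-length(obj)]), 1)))
  ok <- !is.na(fit$maps$ve)
  expect_equal(fit$maps$ve[ok] * fit$maps$kep[ok], fit$maps$ktrans[ok],
               tolerance = 1e-12)

  azero <- aif(a$times, a$values * 0)
  expect_error(fit_kety(cs, azero), "unidentifiable")
  expect_error(fit_kety(cs, a, kety_config(tau_grid = seq(0, 300, 50))),
               "window")
})
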