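# Forward simulators: advection, AIF, Kety kinetics, signal synthesis,
# virtual cohort.

test_that("stationary velocity leaves every frame equal to c0", {
  g <- small_grid()
  c0 <- gaussian_blob(g)
  cs <- simulate_transport(c0, constant_velocity(c(0, 0, 0), g), g)
  for (f in seq_len(g$n_frames))
    expect_identical(cs$values[, , , f], c0)
})

test_that("advected Gaussian translates its center of mass at u * dt", {
  g <- volume_grid(c(40L, 11L, 1L), c(0.84, 0.84, 3), 5L, 5)
  c0 <- gaussian_blob(g, center = c(12, 6, 1), sigma_mm = c(2.5, 2.5, 3))
  cs <- simulate_transport(c0, constant_velocity(c(0.1, 0, 0), g), g,
                           substeps = 8L)
  x_mm <- seq_len(40) * 0.84
  com <- vapply(seq_len(5), function(f) {
    w <- apply(cs$values[, , , f, drop = FALSE], 1, sum)
    sum(w * x_mm) / sum(w)
  }, numeric(1))
  # the advection solution is a pure translation: 0.1 mm/s * 5 s per frame
  expect_equal(diff(com), rep(0.5, 4), tolerance = 0.05)
})

test_that("donor-cell transport conserves mass and is linear in c0", {
  g <- small_grid(n_frames = 6L)
  set.seed(31)
  for (k in 1:3) {
    c0 <- gaussian_blob(g, center = c(4 + k, 7 - k, 2),
                        sigma_mm = c(2 + k / 2, 3, 3.5))
    u <- constant_velocity(c(0.05 * k, -0.04, 0.02), g)
    cs <- simulate_transport(c0, u, g)
    mass <- apply(cs$values, 4, sum) * voxel_volume_mm3(g)
    expect_lt(diff(range(mass)) / mass[1], 1e-6)
    # the flux-form update is exactly linear in the concentration
    # (a power-of-two scale keeps floating-point rounding identical)
    cs4 <- simulate_transport(4 * c0, u, g)
    expect_identical(cs4$values, 4 * cs$values)
  }
})

test_that("an explicit substep count violating the CFL bound is rejected", {
  g <- small_grid()
  u <- constant_velocity(c(0, 0.5, 0), g)   # CFL on y = 0.5*5/0.84 ~ 3
  expect_error(simulate_transport(gaussian_blob(g), u, g, substeps = 1L),
               "axis y")
  expect_silent(simulate_transport(gaussian_blob(g), u, g, substeps = 6L))
})

test_that("gamma-variate AIF peaks at onset + shape*scale", {
  tt <- seq(0, 60, by = 0.25)
  a <- make_aif(tt, amplitude = 2, onset = 5, shape = 3, scale = 2)
  expect_equal(a$times[which.max(a$values)], 5 + 3 * 2, tolerance = 0.25)
  expect_equal(max(a$values), 2, tolerance = 1e-12)
  expect_true(all(a$values[tt <= 5] == 0))

  a0 <- make_aif(tt, amplitude = 0)
  expect_true(all(a0$values == 0))

  expect_error(make_aif(c(0, 1, 1, 2)), "increasing")
  expect_error(make_aif(tt, scale = -1), "scale")
  expect_error(make_aif(tt, onset = 100), "onset")
})

test_that("Kety simulator: zero transfer, steady state, impulse response", {
  g <- volume_grid(c(2L, 2L, 1L), c(1, 1, 1), 41L, 5)
  a <- test_aif(200)
  expect_true(all(simulate_kety(0, 0.2, 0, a, g)$values == 0))

  # step AIF of height A: dc/dt = 0 at c = Ve * A
  astep <- aif(seq(0, 200, by = 1), c(0, rep(2, 200)))
  cs <- simulate_kety(0.03, 0.2, 0, astep, g)
  expect_equal(cs$values[1, 1, 1, 41], 0.15 * 2, tolerance = 0.01)

  # unit-area impulse at t0: c(t) = Ktrans * exp(-kep (t - t0))
  dtf <- 0.25
  at <- seq(0, 100, by = dtf)
  aimp <- aif(at, ifelse(abs(at - 10) < dtf / 1.9, 1 / dtf, 0))
  tt <- seq(0, 100, by = 5)
  cv <- kety_curve(0.05, 0.2, 0, aimp, tt)
  truth <- ifelse(tt >= 10, 0.05 * exp(-0.2 * (tt - 10)), 0)
  expect_equal(cv[tt > 10], truth[tt > 10], tolerance = 1e-3)

  expect_error(simulate_kety(0.03, 0.2, tau = 1e4, a, g), "window")
})

test_that("signal synthesis is the linear enhancement model and is seeded", {
  g <- small_grid(n_frames = 3L)
  czero <- conc_series(array(0, c(g$dims, 3L)), g)
  s <- synthesize_signal(czero, s0 = 50, noise_sd = 0)
  expect_true(all(s == 50))
  cone <- conc_series(array(1, c(g$dims, 3L)), g)
  expect_true(all(synthesize_signal(cone, s0 = 50, noise_sd = 0) == 100))

  s1 <- synthesize_signal(cone, s0 = 50, noise_sd = 0.05, seed = 9L)
  s2 <- synthesize_signal(cone, s0 = 50, noise_sd = 0.05, seed = 9L)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, synthesize_signal(cone, s0 = 50, noise_sd = 0.05, seed = 10L)))

  expect_error(synthesize_signal(cone, s0 = 0), "positive")
})

test_that("virtual cohort: monotone link, determinism, minimum size", {
  co <- generate_cohort(20, noise_sd = 0, seed = 5)
  expect_equal(cor(co$roi_speed, co$lsf_percent, method = "spearman"), 1)
  expect_identical(co, generate_cohort(20, noise_sd = 0, seed = 5))
  expect_error(generate_cohort(3), ">= 4")
  expect_true(all(co$lsf_percent >= 0 & co$lsf_percent <= 100))
  expect_equal(anyDuplicated(co$id), 0L)
})

test_that("a 25-patient cohort at defaults feeds the statistics end-to-end", {
  co <- generate_cohort(25, seed = 2024)
  rep <- build_report(co, boot_n = 100, seed = 1)
  expect_equal(nrow(rep$correlations), 6L)
  r_speed <- rep$correlations$r[rep$correlations$column == "roi_speed"]
  expect_gt(r_speed, 0)
  expect_true(rep$split["low"] >= 1 && rep$split["high"] >= 1)
})
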