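# Shared fixture builders: all synthetic, generated in code at test time.

# Small desk-scale grid with the clinical voxel geometry.
small_grid <- function(dims = c(12L, 12L, 4L), n_frames = 5L,
                       frame_interval = 5) {
  volume_grid(dims, c(0.84, 0.84, 3), n_frames, frame_interval)
}

# Gaussian-blob transport phantom with a constant velocity.
blob_phantom <- function(grid = small_grid(), u = c(0.08, 0.06, 0),
                         sigma_mm = c(3, 3, 4), amplitude = 1,
                         scheme = "upwind", substeps = NULL) {
  c0 <- gaussian_blob(grid, sigma_mm = sigma_mm, amplitude = amplitude)
  cs <- simulate_transport(c0, constant_velocity(u, grid), grid,
                           substeps = substeps, scheme = scheme)
  list(c0 = c0, conc = cs, u = u, grid = grid,
       roi = c0 > 0.1 * max(c0))
}

# Densely sampled gamma-variate AIF covering [0, t_max].
test_aif <- function(t_max, amplitude = 1, onset = 2, shape = 3,
                     scale = 4, by = 0.5) {
  make_aif(seq(0, t_max, by = by), amplitude = amplitude, onset = onset,
           shape = shape, scale = scale)
}

# Rank-formula AUC, reimplemented independently for identity checks.
oracle_auc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
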