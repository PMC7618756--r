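test_that("stimulus duration follows the segment/pad/lead layout and silences are exact zeros", {
  # arithmetic of the layout: lead + n * (segment + 2 * pad)
  spec <- usv_stimulus_spec(n_segments = 15, segment_duration = 8,
                            pad_silence = 1, lead_silence = 20,
                            sample_rate = 20000, band = c(4500, 9000))
  stim <- generate_usv_stimulus(spec, seed = 1)
  expect_equal(length(stim$waveform) / stim$sample_rate, 20 + 15 * 10)

  spec1 <- usv_stimulus_spec(n_segments = 1, lead_silence = 0,
                             sample_rate = 20000, band = c(4500, 9000))
  stim1 <- generate_usv_stimulus(spec1, seed = 1)
  fs <- stim1$sample_rate
  expect_equal(length(stim1$waveform) / fs, 10)
  expect_true(all(stim1$waveform[1:fs] == 0))                  # leading pad
  expect_true(all(rev(stim1$waveform)[1:fs] == 0))             # trailing pad
  expect_gt(sum(stim1$waveform != 0), 0)
})

test_that("stimulus generation is deterministic under a fixed seed", {
  spec <- scaled_stimulus_spec(n_segments = 1)
  a <- generate_usv_stimulus(spec, seed = 7)
  b <- generate_usv_stimulus(spec, seed = 7)
  c <- generate_usv_stimulus(spec, seed = 8)
  expect_identical(a$waveform, b$waveform)
  expect_false(identical(a$waveform, c$waveform))
})

test_that("synthesized energy is confined to the requested band", {
  stim <- generate_usv_stimulus(scaled_stimulus_spec(n_segments = 2), seed = 2)
  sg <- compute_spectrogram(stim, nfft = 512)
  in_band <- sg$freq_centers >= scaled_band[1] & sg$freq_centers <= scaled_band[2]
  frac <- sum(sg$power[, in_band]) / sum(sg$power)
  expect_gt(frac, 0.99)
})

test_that("band edges beyond Nyquist are rejected", {
  expect_error(usv_stimulus_spec(1, sample_rate = 100000,
                                 band = c(45000, 110000)),
               "Nyquist")
})

test_that("ground-truth construction reproduces the requested eigenstructure", {
  su <- scaled_setup()
  m1 <- gabor_map(center_t = 8, center_f = 8, freq_t = 0.1, freq_f = 0)
  m2 <- gabor_map(center_t = 20, center_f = 20, freq_t = 0, freq_f = 0.15)
  gt <- make_ground_truth(su$pca, list(m1, m2), eigenvalues = c(2, -1),
                          a = log(9))
  # dense symmetric eigensolver oracle on the constructed J
  eg <- eigen(gt$J, symmetric = TRUE)
  nz <- abs(eg$values) > 1e-10
  expect_equal(sort(eg$values[nz]), c(-1, 2), tolerance = 1e-10)
  # recovered eigenvectors match the projected, re-orthonormalized maps
  for (i in 1:2) {
    v_true <- crossprod(su$pca$basis, gt$feature_maps[, i])[, 1]
    j <- which(abs(eg$values - c(2, -1)[i]) < 1e-8)
    expect_gt(abs(sum(eg$vectors[, j] * v_true)), 1 - 1e-8)
  }
  expect_equal(gt$J, t(gt$J))
  expect_error(make_ground_truth(su$pca, list(m1), eigenvalues = NaN),
               "non-finite")
})

test_that("a zero-feature ground truth is a constant-rate model", {
  su <- scaled_setup()
  p0 <- 0.2
  gt <- make_ground_truth(su$pca, a = log(1 / p0 - 1))
  expect_equal(gt$base_rate, p0)
  p <- mne_probability(gt$a, gt$h, gt$J, su$X)
  expect_equal(p, rep(p0, nrow(su$X)))
})

test_that("trial averages of simulated rasters match model probabilities within binomial error", {
  su <- scaled_setup()
  X <- su$X[1:120, , drop = FALSE]
  gt <- make_ground_truth(su$pca, a = 0)      # p = 0.5 everywhere
  ra <- simulate_event_raster(gt, X, n_trials = 10000, seed = 21)
  means <- colMeans(ra$binary)
  expect_gte(length(means), 100)
  expect_true(all(abs(means - 0.5) < 0.02))   # 4 sigma at n = 10000

  # structured model: per-bin agreement at matched binomial scale
  # (rows spread across the stimulus so the quadratic term actually varies)
  X <- su$X[round(seq(1, nrow(su$X), length.out = 120)), , drop = FALSE]
  gt2 <- make_ground_truth(su$pca, list(gabor_map(center_t = 18)),
                           eigenvalues = 1, a = log(1 / 0.3 - 1),
                           patches = X, target_sd = 2)
  p2 <- mne_probability(gt2$a, gt2$h, gt2$J, X)
  ra2 <- simulate_event_raster(gt2, X, n_trials = 10000, seed = 22)
  tol <- 4.5 * sqrt(pmax(p2 * (1 - p2), 1e-6) / 10000) + 1e-3
  expect_true(all(abs(colMeans(ra2$binary) - p2) < tol))
})

test_that("extreme offsets and fixed seeds behave as expected in simulation", {
  su <- scaled_setup()
  X <- su$X[1:50, , drop = FALSE]
  silent <- make_ground_truth(su$pca, a = 50)   # p -> 0
  ra <- simulate_event_raster(silent, X, n_trials = 10, seed = 1)
  expect_true(all(ra$binary == 0))
  gt <- make_ground_truth(su$pca, a = 0)
  r1 <- simulate_event_raster(gt, X, n_trials = 5, seed = 9)
  r2 <- simulate_event_raster(gt, X, n_trials = 5, seed = 9)
  expect_identical(r1$binary, r2$binary)
  expect_error(simulate_event_raster(gt, X[, 1:3], n_trials = 2, seed = 1),
               "columns")
})

test_that("population generation yields the configured shared/private subspace structure", {
  su <- scaled_setup()
  X <- su$X
  # identical subspaces: all true principal angles 0
  ds_same <- generate_population(X, su$pca, shared_dim = 2, n_private_a = 0,
                                 n_private_b = 0, n_trials = 2, seed = 5)
  pa <- principal_angles(ds_same$true_features$A, ds_same$true_features$B)
  expect_true(all(pa$angles_deg < 1e-6))
  # fully private: all 90
  ds_orth <- generate_population(X, su$pca, shared_dim = 0, n_private_a = 2,
                                 n_private_b = 2, n_trials = 2, seed = 5)
  pa <- principal_angles(ds_orth$true_features$A, ds_orth$true_features$B)
  expect_true(all(abs(pa$angles_deg - 90) < 1e-6))
  # mixed: smallest 0, rest 90 (SVD oracle on the constructed bases)
  ds_mix <- generate_population(X, su$pca, shared_dim = 1, n_private_a = 2,
                                n_private_b = 2, n_trials = 2, seed = 5)
  pa <- principal_angles(ds_mix$true_features$A, ds_mix$true_features$B)
  expect_equal(length(pa$angles_deg), 3)
  expect_lt(pa$angles_deg[1], 1e-6)
  expect_true(all(abs(pa$angles_deg[2:3] - 90) < 1e-6))
  # raster shapes and labels
  expect_length(ds_mix$rasters, 6)
  expect_equal(dim(ds_mix$rasters[[1]]$binary), c(2L, nrow(X)))
  expect_equal(as.integer(table(ds_mix$population_labels)[c("popA", "popB")]),
               c(3L, 3L))
  expect_error(generate_population(X, su$pca, shared_dim = 10,
                                   n_private_a = 10, n_private_b = 10,
                                   n_trials = 2, seed = 1),
               "reduced dimensions")
})
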