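test_that("STFT geometry gives the standard bin duration and frequency resolution", {
  x <- sin(2 * pi * 1000 * seq_len(50000) / 250000)
  sg <- compute_spectrogram(x, sample_rate = 250000, nfft = 4096,
                            overlap_fraction = 0.5)
  expect_equal(sg$bin_duration, 0.008192)                    # 8.1920 ms
  expect_equal(diff(sg$freq_centers)[1], 61.03515625)        # 61.035 Hz
  expect_true(all(sg$power >= 0))
})

test_that("a pure tone concentrates power at the nearest FFT bin in every frame", {
  fs <- 250000
  x <- sin(2 * pi * 80000 * seq_len(fs %/% 5) / fs)
  sg <- compute_spectrogram(x, sample_rate = fs)
  target <- which.min(abs(sg$freq_centers - 80000))
  expect_true(all(apply(sg$power, 1, which.max) == target))
})

test_that("silence yields zero power and short input errors", {
  sg <- compute_spectrogram(numeric(20000), sample_rate = 25000, nfft = 512)
  expect_true(all(sg$power == 0))
  expect_error(compute_spectrogram(numeric(100), sample_rate = 25000,
                                   nfft = 512), "shorter")
})

test_that("frequency binning averages FFT bins into linear sub-intervals", {
  freqs <- seq(0, 12500, by = 48.828125)
  # constant (white) power: all 28 output bins equal
  sgw <- toy_spectrogram(matrix(1, 10, length(freqs)), freqs)
  out <- restrict_and_bin(sgw, 4500, 11000, 28)
  expect_equal(dim(out$power), c(10L, 28L))
  expect_true(all(out$power == 1))

  # aligned one-to-one binning is the identity up to ordering
  edges <- seq(4500, 11000, length.out = 29)
  centers <- (edges[-1] + edges[-29]) / 2
  vals <- matrix(seq_len(28), nrow = 1)
  sg1 <- toy_spectrogram(cbind(0, vals, 0), c(4400, centers, 11100))
  out1 <- restrict_and_bin(sg1, 4500, 11000, 28)
  expect_equal(out1$power, vals)

  expect_error(restrict_and_bin(sgw, 1000, 20000, 28), "outside")
})

test_that("tones land in the frequency bin dictated by the linear edge arithmetic", {
  # explicit edge arithmetic: the band midpoint (7750 Hz of [4500, 11000],
  # mirroring 77.5 kHz of the full-scale band) is the left edge of the
  # 15th (1-based) bin, and half-open intervals assign it there
  centers <- seq(4400, 11100, by = 25)        # includes 7750 exactly
  delta <- matrix(as.numeric(centers == 7750), nrow = 1)
  out <- restrict_and_bin(toy_spectrogram(delta, centers), 4500, 11000, 28)
  expect_equal(which(out$power[1, ] > 0), 15L)

  # a physical tone inside bin 15 keeps its (Hann-leaked) power there
  fs <- 25000
  x <- sin(2 * pi * 7861.328125 * seq_len(fs) / fs)   # FFT bin 161 exactly
  sg <- restrict_and_bin(compute_spectrogram(x, sample_rate = fs, nfft = 512),
                         4500, 11000, 28)
  prof <- colSums(sg$power)
  expect_equal(which.max(prof), 15L)
  expect_gt(prof[15] / sum(prof), 0.8)
})

test_that("patch extraction counts windows and indexes lags correctly", {
  # hand-unrolled toy case: 3 time bins x 2 freq bins, window 2
  sg <- toy_spectrogram(matrix(c(1, 3, 5, 2, 4, 6), nrow = 3), c(100, 200))
  ps <- extract_patches(sg, window = 2)
  expect_equal(nrow(ps$patches), 2L)
  expect_equal(ps$patches[1, ], c(1, 2, 3, 4))   # (t1,f1) (t1,f2) (t2,f1) (t2,f2)
  expect_equal(ps$patches[2, ], c(3, 4, 5, 6))
  expect_equal(ps$time_index, 2:3)

  # patch at time t, lag l, frequency f equals spectrogram entry (t-w+l, f)
  set.seed(4)
  P <- matrix(runif(40 * 5), 40, 5)
  ps2 <- extract_patches(toy_spectrogram(P, seq_len(5) * 100), window = 4)
  for (row in c(1, 17, 37)) {
    t_cur <- ps2$time_index[row]
    patch <- unflatten_map(ps2$patches[row, ], 4, 5)
    for (l in 1:4) expect_equal(patch[l, ], P[t_cur - 4 + l, ])
  }

  su <- scaled_setup()
  expect_equal(ncol(su$patches$patches), 784L)
  expect_equal(nrow(su$patches$patches), su$patches$n_bins_total - 27L)
  expect_error(extract_patches(toy_spectrogram(matrix(1, 5, 3), 1:3),
                               window = 28), "time bins")
})

test_that("100 time bins yield 73 patches of length 784 with a 28-bin window", {
  sg <- toy_spectrogram(matrix(runif(100 * 28), 100, 28), seq_len(28) * 100)
  ps <- extract_patches(sg, window = 28)
  expect_equal(nrow(ps$patches), 73L)
  expect_equal(ncol(ps$patches), 784L)
})

test_that("flatten and unflatten are mutually inverse", {
  set.seed(1)
  m <- matrix(rnorm(28 * 28), 28, 28)
  expect_identical(unflatten_map(flatten_map(m)), m)
  v <- rnorm(12)
  expect_identical(flatten_map(unflatten_map(v, 3, 4)), v)
})

test_that("PCA captures exact low-rank structure and keeps its basis orthonormal", {
  set.seed(11)
  basis5 <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
  X <- matrix(rnorm(200 * 5), 200, 5) %*% t(basis5) +
    matrix(rnorm(20), 200, 20, byrow = TRUE)
  pca <- fit_pca(X, n_components = 5)
  expect_equal(pca$explained_variance_fraction, 1, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(pca$basis) - diag(5))), 1e-8)
  # projector idempotence on the retained subspace
  s <- pca$mean + as.vector(basis5 %*% rnorm(5))
  rec <- pca_backproject(pca, pca_project(pca, s))
  expect_equal(as.vector(rec), s, tolerance = 1e-8)
  expect_error(fit_pca(matrix(1, 50, 4), 2), "zero variance")
  expect_error(fit_pca(matrix(rnorm(20), 4, 5), 10), "more patches")
})

test_that("explained variance on white noise approximates the flat-spectrum share", {
  set.seed(2)
  X <- matrix(rnorm(3000 * 50), 3000, 50)
  pca <- fit_pca(X, n_components = 10)
  lo <- 10 / 50
  hi <- 10 / 50 * (1 + 3 * sqrt(50 / 3000))   # Marchenko-Pastur slack
  expect_gt(pca$explained_variance_fraction, lo)
  expect_lt(pca$explained_variance_fraction, hi)
})
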