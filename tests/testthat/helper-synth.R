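# Shared fixtures, built in code. The "scaled" stimulus regime keeps the
# full analysis geometry (28 frequency bins, 28-bin windows, 784-dim
# patches) but runs at 25 kHz sampling in a 4.5-11 kHz band so fixtures
# stay fast to synthesize.

scaled_band <- c(4500, 11000)

scaled_stimulus_spec <- function(n_segments = 4, lead_silence = 0) {
  usv_stimulus_spec(n_segments = n_segments, segment_duration = 8,
                    pad_silence = 1, lead_silence = lead_silence,
                    sample_rate = 25000, band = scaled_band)
}

# Memoized stimulus -> spectrogram -> patches -> PCA chain.
scaled_setup <- local({
  cache <- list()
  function(n_segments = 4, K = 16, seed = 3) {
    key <- paste(n_segments, K, seed, sep = "_")
    if (is.null(cache[[key]])) {
      stim <- generate_usv_stimulus(scaled_stimulus_spec(n_segments),
                                    seed = seed)
      sg <- restrict_and_bin(compute_spectrogram(stim, nfft = 512),
                             scaled_band[1], scaled_band[2], 28)
      patches <- extract_patches(sg)
      pca <- fit_pca(patches, n_components = K)
      cache[[key]] <<- list(stim = stim, sgram = sg, patches = patches,
                            pca = pca, X = pca_project(pca, patches))
    }
    cache[[key]]
  }
})

# Aligned dataset over the full spectrogram for one simulated raster.
align_simulated <- function(raster, setup, ...) {
  n_trials <- nrow(raster$binary)
  full <- matrix(0L, n_trials, setup$patches$n_bins_total)
  full[, setup$patches$time_index] <- raster$binary
  align_responses(event_raster(full, raster$unit_id, raster$population),
                  setup$patches, setup$pca, ...)
}

# A hand-made spectrogram object for binning/patch bookkeeping tests.
toy_spectrogram <- function(power, freq_centers, bin_duration = 0.01) {
  structure(list(power = power, freq_centers = freq_centers,
                 bin_duration = bin_duration,
                 times = seq_len(nrow(power)) * bin_duration,
                 sample_rate = NA_real_, log_power = FALSE),
            class = "spectrogram")
}
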