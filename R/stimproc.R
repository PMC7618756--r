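# Stimulus processing: waveform -> binned spectrogram -> sliding
# spectrotemporal patches -> PCA-reduced stimulus coordinates.

#' Power spectral density spectrogram of a stimulus waveform
#'
#' Short-time Fourier transform on Hann-windowed segments, converted to a
#' one-sided power spectral density. With the defaults (4096-sample windows,
#' 50% overlap) at 250 kHz sampling this yields a temporal resolution of
#' 8.1920 ms and a frequency resolution of 61.035 Hz, the regime in which
#' ultrasonic vocalization stimuli are analyzed.
#'
#' @param waveform numeric vector, or the list returned by
#'   [generate_usv_stimulus()] (in which case `sample_rate` is taken from it).
#' @param sample_rate sampling rate in Hz.
#' @param nfft segment length in samples (default 4096).
#' @param overlap_fraction fractional overlap between segments (default 0.5).
#' @param log_power if `TRUE`, return `log(power + eps)` with
#'   `eps = 1e-12 * max(power)`; default is raw PSD.
#' @return object of class `spectrogram`: list with `power` (time bins x
#'   frequency bins, non-negative), `freq_centers` (Hz), `bin_duration` (s),
#'   `times` (segment centre times, s), `sample_rate`, `log_power`.
#' @export
compute_spectrogram <- function(waveform, sample_rate = NULL, nfft = 4096L,
                                overlap_fraction = 0.5, log_power = FALSE) {
  if (is.list(waveform)) {
    sample_rate <- sample_rate %||% waveform$sample_rate
    waveform <- waveform$waveform
  }
  stopifnot(is.numeric(waveform), !is.null(sample_rate))
  if (length(waveform) < nfft) {
    stop("waveform shorter than one analysis window (", nfft, " samples)",
         call. = FALSE)
  }
  assert_finite(waveform, "waveform")
  hop <- as.integer(round(nfft * (1 - overlap_fraction)))
  stopifnot(hop >= 1)
  w <- signal::hanning(nfft)
  sg <- signal::specgram(waveform, n = nfft, Fs = sample_rate,
                         window = w, overlap = nfft - hop)
  # specgram returns the windowed FFT (freq x time, one-sided, DC included,
  # Nyquist excluded); scale to a PSD and double the non-DC bins.
  psd <- Mod(sg$S)^2 / (sample_rate * sum(w^2))
  if (nrow(psd) > 1) psd[-1, ] <- 2 * psd[-1, ]
  power <- t(psd)                                  # time x freq
  if (log_power) {
    eps <- 1e-12 * max(power)
    power <- log(power + eps)
  }
  structure(
    list(power = power,
         freq_centers = as.numeric(sg$f),
         bin_duration = hop / sample_rate,
         times = as.numeric(sg$t),
         sample_rate = sample_rate,
         log_power = log_power),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d time bins x %d frequency bins; bin %.4f ms; %.1f-%.1f Hz\n",
    nrow(x$power), ncol(x$power), 1000 * x$bin_duration,
    min(x$freq_centers), max(x$freq_centers)))
  invisible(x)
}

#' Restrict a spectrogram to a frequency band and re-bin it linearly
#'
#' Keeps only the band of interest (default the 45-110 kHz ultrasonic
#' vocalization range) and aggregates the raw FFT bins into `n_bins`
#' linearly spaced frequency bins. Each output bin is the mean power of the
#' FFT bins whose centre falls inside its sub-interval; the mean (rather
#' than the sum) keeps units comparable when edge bins receive unequal
#' numbers of FFT bins.
#'
#' @param sgram a `spectrogram`.
#' @param f_lo,f_hi band edges in Hz (defaults 45000, 110000).
#' @param n_bins number of linear output bins (default 28).
#' @return a `spectrogram` with `n_bins` frequency columns; `freq_centers`
#'   are the sub-interval midpoints.
#' @export
restrict_and_bin <- function(sgram, f_lo = 45000, f_hi = 110000,
                             n_bins = 28L) {
  stopifnot(inherits(sgram, "spectrogram"), f_hi > f_lo, n_bins >= 1)
  fr <- sgram$freq_centers
  if (f_lo < min(fr) || f_hi > max(fr)) {
    stop(sprintf("band [%g, %g] Hz outside spectrogram range [%g, %g] Hz",
                 f_lo, f_hi, min(fr), max(fr)), call. = FALSE)
  }
  edges <- seq(f_lo, f_hi, length.out = n_bins + 1)
  # half-open [edge_k, edge_{k+1}); top edge closed
  idx <- findInterval(fr, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= n_bins & fr >= f_lo & fr <= f_hi
  binned <- matrix(NA_real_, nrow = nrow(sgram$power), ncol = n_bins)
  for (k in seq_len(n_bins)) {
    members <- which(keep & idx == k)
    if (length(members) == 0) {
      stop("empty frequency sub-interval ", k,
           ": band too narrow for the spectrogram resolution", call. = FALSE)
    }
    binned[, k] <- rowMeans(sgram$power[, members, drop = FALSE])
  }
  out <- sgram
  out$power <- binned
  out$freq_centers <- (edges[-1] + edges[-length(edges)]) / 2
  out$freq_bin_width <- diff(edges)[1]
  out
}

#' Sliding spectrotemporal patches from a spectrogram
#'
#' For every time bin `t >= window`, the patch covers that bin plus the
#' `window - 1` preceding bins (i.e. bins `t-27 .. t` for the default
#' 28-bin window) across all frequency bins, flattened row-major into a
#' vector of length `window * n_freq` (784 for the 28 x 28 defaults). The
#' first `window - 1` bins yield no patch: there is no fabricated stimulus
#' history at the leading edge.
#'
#' @param sgram a (band-restricted) `spectrogram`.
#' @param window number of time bins per patch (default 28).
#' @return object of class `patch_set`: `patches` (N x window*n_freq),
#'   `time_index` (1-based spectrogram bin of each patch's final/current
#'   bin), `window`, `n_freq`, `n_bins_total`, `bin_duration`,
#'   `freq_centers`, `freq_bin_width`.
#' @export
extract_patches <- function(sgram, window = 28L) {
  stopifnot(inherits(sgram, "spectrogram"))
  P <- sgram$power
  T_bins <- nrow(P)
  n_freq <- ncol(P)
  if (T_bins < window) {
    stop("spectrogram has ", T_bins, " time bins; need at least ", window,
         call. = FALSE)
  }
  N <- T_bins - window + 1L
  patches <- matrix(NA_real_, nrow = N, ncol = window * n_freq)
  # lag l (1 = oldest) occupies columns (l-1)*n_freq + 1 .. l*n_freq
  for (l in seq_len(window)) {
    patches[, ((l - 1L) * n_freq + 1L):(l * n_freq)] <-
      P[l:(l + N - 1L), , drop = FALSE]
  }
  structure(
    list(patches = patches,
         time_index = seq.int(window, T_bins),
         window = as.integer(window),
         n_freq = as.integer(n_freq),
         n_bins_total = as.integer(T_bins),
         bin_duration = sgram$bin_duration,
         freq_centers = sgram$freq_centers,
         freq_bin_width = sgram$freq_bin_width %||%
           (if (length(sgram$freq_centers) > 1) diff(sgram$freq_centers)[1] else NA_real_)),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d (=%d) from %d time bins\n",
              nrow(x$patches), x$window, x$n_freq, ncol(x$patches),
              x$n_bins_total))
  invisible(x)
}

#' PCA reduction of stimulus patches
#'
#' Fits a principal component basis to the patch matrix and records the
#' fraction of variance the retained components explain. Projection is
#' `(s - mean) %*% basis`; back-projection is `mean + basis %*% x`.
#'
#' @param patches a `patch_set` or a numeric matrix (rows = patches).
#' @param n_components number of retained components K (default 128).
#' @return object of class `pca_reduction`: `mean` (length-p vector),
#'   `basis` (p x K, orthonormal columns), `sdev` (all singular values /
#'   sqrt(N-1)), `n_components`, `explained_variance_fraction`.
#' @export
fit_pca <- function(patches, n_components = 128L) {
  X <- if (inherits(patches, "patch_set")) patches$patches else patches
  stopifnot(is.matrix(X))
  N <- nrow(X)
  if (N <= n_components) {
    stop("need more patches (", N, ") than components (", n_components, ")",
         call. = FALSE)
  }
  total_var <- sum(apply(X, 2, stats::var))
  if (total_var <= 0 || !is.finite(total_var)) {
    stop("degenerate input: patch matrix has zero variance", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  K <- min(n_components, ncol(pc$rotation))
  structure(
    list(mean = pc$center,
         basis = pc$rotation[, seq_len(K), drop = FALSE],
         sdev = pc$sdev,
         n_components = as.integer(K),
         explained_variance_fraction = sum(pc$sdev[seq_len(K)]^2) /
           sum(pc$sdev^2)),
    class = "pca_reduction"
  )
}

#' Project patches into the reduced PCA coordinates
#'
#' @param pca a `pca_reduction`.
#' @param x matrix of flattened patches (rows) or a `patch_set`.
#' @return N x K matrix of reduced coordinates.
#' @export
pca_project <- function(pca, x) {
  if (inherits(x, "patch_set")) x <- x$patches
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(x, 2, pca$mean) %*% pca$basis
}

#' Back-project reduced coordinates to the patch space
#'
#' @param pca a `pca_reduction`.
#' @param scores N x K matrix (or length-K vector) of reduced coordinates.
#' @param center add the patch mean back (default `TRUE`; use `FALSE` for
#'   directions such as receptive-field features).
#' @return N x p matrix in the flattened patch space.
#' @export
pca_backproject <- function(pca, scores, center = TRUE) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  out <- scores %*% t(pca$basis)
  if (center) out <- sweep(out, 2, pca$mean, `+`)
  out
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("<pca_reduction> %d -> %d components, %.1f%% variance retained\n",
              nrow(x$basis), x$n_components,
              100 * x$explained_variance_fraction))
  invisible(x)
}
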