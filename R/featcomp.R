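# Feature comparison: modulation power spectra, low-dimensional embedding,
# event-property clustering and pairwise unit correlations.

#' Modulation power spectrum of a spectrotemporal feature
#'
#' Squared magnitude of the 2-D discrete Fourier transform of a feature
#' map, zero-frequency centred, giving a joint representation of temporal
#' modulations (cycles/s) and spectral modulations (cycles/kHz). No
#' windowing or padding is applied by default since receptive-field
#' features are already compact; `pad` zero-pads each axis by an integer
#' factor for a finer modulation grid. The DFT is unnormalized, so
#' `sum(power) == prod(dim(map)) * sum(map^2)` (Parseval) at `pad = 1`.
#'
#' @param map numeric matrix (time x frequency).
#' @param bin_duration time-bin duration in seconds (default 8.192 ms).
#' @param freq_bin_width frequency-bin width in Hz (default the 45-110 kHz
#'   band split into 28 bins).
#' @param pad integer zero-padding factor (default 1 = none).
#' @return object of class `modulation_spectrum`: `power` (centred,
#'   non-negative), `temporal_mod` (cycles/s), `spectral_mod` (cycles/kHz).
#' @export
modulation_power_spectrum <- function(map, bin_duration = 4096 / 2 / 250000,
                                      freq_bin_width = 65000 / 28,
                                      pad = 1L) {
  stopifnot(is.matrix(map))
  assert_finite(map, "map")
  nt <- nrow(map) * pad
  nf <- ncol(map) * pad
  padded <- matrix(0, nt, nf)
  padded[seq_len(nrow(map)), seq_len(ncol(map))] <- map
  F2 <- stats::fft(padded)
  power <- fft_shift2(Mod(F2)^2)
  structure(
    list(power = power,
         temporal_mod = fft_shift_freqs(nt) / bin_duration,
         spectral_mod = fft_shift_freqs(nf) / (freq_bin_width / 1000),
         pad = pad),
    class = "modulation_spectrum"
  )
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<modulation_spectrum> %d x %d; temporal up to %.1f cyc/s, spectral up to %.2f cyc/kHz\n",
    nrow(x$power), ncol(x$power), max(abs(x$temporal_mod)),
    max(abs(x$spectral_mod))))
  invisible(x)
}

# Rows of flattened modulation power, one per spectrum.
spectra_to_matrix <- function(spectra) {
  if (inherits(spectra, "modulation_spectrum")) spectra <- list(spectra)
  t(vapply(spectra, function(s) as.vector(s$power),
           numeric(length(spectra[[1]]$power))))
}

#' Embed modulation spectra (or any feature vectors) in two dimensions
#'
#' Plumbing around an established dimensionality-reduction backend, used to
#' inspect whether feature sets from two populations occupy separate
#' regions. The default backend is PCA (first two principal components),
#' which is deterministic; `method = "umap"` uses the uwot package when it
#' is installed (seeded, with the neighbor parameter auto-reduced with a
#' warning when there are too few points).
#'
#' @param spectra list of `modulation_spectrum` objects, or a numeric
#'   matrix with one row per item.
#' @param labels optional per-item population labels.
#' @param method `"pca"` (default) or `"umap"`.
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param seed integer seed (UMAP backend).
#' @return data frame with `dim1`, `dim2`, `label`.
#' @export
embed_features <- function(spectra, labels = NULL,
                           method = c("pca", "umap"),
                           n_neighbors = 15L, seed = 1L) {
  method <- match.arg(method)
  X <- if (is.matrix(spectra)) spectra else spectra_to_matrix(spectra)
  if (nrow(X) < 2) stop("need at least 2 items to embed", call. = FALSE)
  if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("method = \"umap\" requires the uwot package", call. = FALSE)
    }
    if (n_neighbors >= nrow(X)) {
      n_neighbors <- max(2L, nrow(X) - 1L)
      warning("n_neighbors reduced to ", n_neighbors,
              " (fewer points than neighbors)", call. = FALSE)
    }
    emb <- with_seed(seed, {
      uwot::umap(X, n_neighbors = n_neighbors, n_components = 2,
                 n_threads = 1, n_sgd_threads = 1)
    })
  } else {
    keep <- apply(X, 2, stats::sd) > 0
    if (!any(keep)) stop("all embedding inputs are constant", call. = FALSE)
    pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE)
    emb <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    if (ncol(emb) < 2) emb <- cbind(emb, 0)
  }
  data.frame(dim1 = emb[, 1], dim2 = emb[, 2],
             label = if (is.null(labels)) NA_character_ else as.character(labels),
             stringsAsFactors = FALSE)
}

#' Cluster calcium events by their morphological properties
#'
#' Each event is described by duration, area, rise time, fall time and
#' circularity (intensity-related properties are deliberately excluded to
#' avoid indicator-expression artifacts). Properties are z-scored, embedded
#' in two dimensions, and density-clustered with a Gaussian mixture model
#' (mclust, BIC-selected number of components). The label `-1` is reserved
#' for noise points in the interface; the mixture backend assigns every
#' point to a component, so an all-`-1` labeling can only arise from a
#' backend that supports noise.
#'
#' @param events data frame (or matrix) with one row per event; columns are
#'   the property vector. The canonical columns are `duration`, `area`,
#'   `rise_time`, `fall_time`, `circularity`.
#' @param max_clusters maximum number of mixture components tried
#'   (default 25).
#' @param method embedding backend passed to [embed_features()].
#' @param seed integer seed.
#' @return list with `labels` (integer, `-1` = noise), `embedding`
#'   (data frame), `n_clusters`.
#' @export
cluster_event_properties <- function(events, max_clusters = 25L,
                                     method = "pca", seed = 1L) {
  X <- as.matrix(events)
  stopifnot(is.numeric(X), nrow(X) >= 2)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  emb <- embed_features(Xs, method = method, seed = seed)
  fit <- with_seed(seed, {
    Mclust(as.matrix(emb[, c("dim1", "dim2")]),
           G = seq_len(max_clusters), verbose = FALSE)
  })
  list(labels = as.integer(fit$classification),
       embedding = emb, n_clusters = fit$G)
}

#' Pairwise Pearson correlations between units
#'
#' Correlation of the activity (or event-area) time series of every unit
#' pair, plus the pooled off-diagonal values for histogramming. Pairs
#' involving a zero-variance series are reported as `NA` and excluded from
#' the pooled distribution.
#'
#' @param series numeric matrix with one row per unit (equal-length series).
#' @return list with `correlation` (units x units, diagonal 1 where
#'   defined) and `pooled` (numeric vector of unique off-diagonal values).
#' @export
pairwise_unit_correlations <- function(series) {
  stopifnot(is.matrix(series), nrow(series) >= 2)
  sds <- apply(series, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(series)))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  d <- diag(cm)
  d[sds > 0] <- 1
  diag(cm) <- d
  pooled <- cm[upper.tri(cm)]
  list(correlation = cm, pooled = pooled[!is.na(pooled)])
}
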