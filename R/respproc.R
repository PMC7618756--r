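# Response processing: onset detection, binary rasters, and alignment of
# trial-averaged responses to stimulus patches with train/test/CV splits.

#' Binary event raster
#'
#' Trials x time-bins binary matrix for one unit (an astrocyte consensus
#' functional unit, a neuron, or a synthetic unit).
#'
#' @param binary matrix with entries in {0, 1}; rows are trials.
#' @param unit_id identifier.
#' @param population one of `"astro"`, `"neuro"`, `"synthetic"` (free-form
#'   labels are accepted).
#' @return object of class `event_raster`.
#' @export
event_raster <- function(binary, unit_id = "unit", population = "synthetic") {
  stopifnot(is.matrix(binary))
  if (!all(binary %in% c(0L, 1L))) {
    stop("raster entries must be 0 or 1", call. = FALSE)
  }
  structure(list(binary = binary, unit_id = unit_id, population = population),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %s (%s): %d trials x %d bins, %d events\n",
              x$unit_id, x$population, nrow(x$binary), ncol(x$binary),
              sum(x$binary)))
  invisible(x)
}

#' Detect event onsets at a fraction of each excursion's peak
#'
#' Segments the trace into contiguous excursions above `baseline` and, for
#' each excursion, marks the first bin at which the signal reaches
#' `threshold_fraction` of that excursion's peak (measured relative to the
#' baseline). The 10%-of-peak default is the standard onset rule for
#' calcium fluorescence events. An all-zero (or never-above-baseline) trace
#' yields no onsets.
#'
#' @param trace numeric vector, one sample per time bin.
#' @param threshold_fraction fraction of the excursion peak (default 0.10).
#' @param baseline scalar baseline level (default 0, appropriate for
#'   baseline-subtracted or synthetic traces; for raw traces pass e.g. a
#'   quantile of the trace).
#' @return sorted integer vector of onset bins (1-based).
#' @export
detect_onsets <- function(trace, threshold_fraction = 0.10, baseline = 0) {
  assert_finite(trace, "trace")
  above <- trace > baseline
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    peak <- max(trace[seg]) - baseline
    if (peak <= 0) next
    hit <- seg[which(trace[seg] - baseline >= threshold_fraction * peak)[1]]
    onsets <- c(onsets, hit)
  }
  sort(unique(onsets))
}

#' Build a binary activation raster from per-trial onsets
#'
#' @param onsets list with one integer vector of onset bins per trial
#'   (1-based). Duplicate onsets collapse to a single 1 (set semantics).
#' @param n_bins number of time bins T.
#' @param n_trials number of trials (default `length(onsets)`).
#' @param unit_id,population raster metadata.
#' @return an [event_raster()] of size n_trials x n_bins.
#' @export
binarize_raster <- function(onsets, n_bins, n_trials = length(onsets),
                            unit_id = "unit", population = "synthetic") {
  stopifnot(is.list(onsets), n_trials >= length(onsets))
  binary <- matrix(0L, nrow = n_trials, ncol = n_bins)
  for (tr in seq_along(onsets)) {
    o <- unique(as.integer(onsets[[tr]]))
    if (length(o) == 0) next
    if (any(o < 1L | o > n_bins)) {
      stop("onset outside [1, ", n_bins, "] in trial ", tr, call. = FALSE)
    }
    binary[tr, o] <- 1L
  }
  event_raster(binary, unit_id = unit_id, population = population)
}

# Contiguous partition of n items into k blocks, remainder to earliest blocks.
contiguous_folds <- function(idx, k) {
  n <- length(idx)
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Aligned stimulus-response dataset with train/test and CV splits
#'
#' Low-level constructor pairing reduced stimulus coordinates with a
#' trial-averaged response and computing the splits: a contiguous 70/30
#' train/test division and a contiguous `n_folds`-fold partition of the
#' train block (fold-size remainder assigned to the earliest folds).
#' Contiguous temporal blocks, rather than random rows, are used because
#' overlapping patch windows would otherwise leak stimulus history between
#' train and test.
#'
#' @param X N x K matrix of stimulus coordinates.
#' @param y length-N response vector in \[0, 1\].
#' @param train_fraction fraction of rows in the train block (default 0.70).
#' @param n_folds number of CV folds over the train block (default 3).
#' @param time_index optional per-row spectrogram bin index.
#' @param scale_sd optional per-column scale already applied to X.
#' @param unit_id,population metadata carried through to fitted models.
#' @return object of class `aligned_dataset`.
#' @export
aligned_dataset <- function(X, y, train_fraction = 0.70, n_folds = 3L,
                            time_index = seq_len(nrow(X)), scale_sd = NULL,
                            unit_id = "unit", population = "synthetic") {
  stopifnot(is.matrix(X), length(y) == nrow(X), n_folds >= 2)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  N <- nrow(X)
  n_train <- floor(train_fraction * N)
  if (n_train < n_folds || n_train >= N) {
    stop("train fraction leaves too few train or test rows", call. = FALSE)
  }
  train_idx <- seq_len(n_train)
  test_idx <- seq.int(n_train + 1L, N)
  structure(
    list(X = X, y = as.numeric(y), time_index = time_index,
         train_idx = train_idx, test_idx = test_idx,
         folds = contiguous_folds(train_idx, n_folds),
         scale_sd = scale_sd, unit_id = unit_id, population = population),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf(
    "<aligned_dataset> %s: %d rows x %d dims (%d train / %d test, %d folds)\n",
    x$unit_id, nrow(x$X), ncol(x$X), length(x$train_idx),
    length(x$test_idx), length(x$folds)))
  invisible(x)
}

#' Align an event raster to stimulus patches in reduced coordinates
#'
#' The regression target for bin `t` is the trial-averaged binary response
#' at `t`; the regressor is the reduced representation of the spectrogram
#' patch whose window ends at `t` (the current bin plus its 27 predecessors
#' for the default window). Bins without a full stimulus window are
#' dropped. Reduced coordinates are standardized to unit variance per
#' component using train-block standard deviations (`scale = TRUE`,
#' recommended: raw PCA coordinates of PSD patches span orders of magnitude
#' and condition the optimization poorly); fitted parameters are mapped
#' back through this scaling when features are extracted.
#'
#' @param raster an [event_raster()] with one column per spectrogram bin.
#' @param patches a `patch_set` from [extract_patches()].
#' @param pca a `pca_reduction` from [fit_pca()].
#' @param train_fraction,n_folds split parameters (defaults 0.70 and 3).
#' @param scale standardize reduced coordinates (default `TRUE`).
#' @return an [aligned_dataset()].
#' @export
align_responses <- function(raster, patches, pca, train_fraction = 0.70,
                            n_folds = 3L, scale = TRUE) {
  stopifnot(inherits(raster, "event_raster"), inherits(patches, "patch_set"),
            inherits(pca, "pca_reduction"))
  if (ncol(raster$binary) != patches$n_bins_total) {
    stop("raster has ", ncol(raster$binary), " bins but the spectrogram has ",
         patches$n_bins_total, call. = FALSE)
  }
  y <- colMeans(raster$binary)[patches$time_index]
  X <- pca_project(pca, patches$patches)
  N <- nrow(X)
  n_train <- floor(train_fraction * N)
  scale_sd <- NULL
  if (scale) {
    scale_sd <- apply(X[seq_len(n_train), , drop = FALSE], 2, stats::sd)
    scale_sd[scale_sd < 1e-12] <- 1
    X <- sweep(X, 2, scale_sd, `/`)
  }
  aligned_dataset(X, y, train_fraction = train_fraction, n_folds = n_folds,
                  time_index = patches$time_index, scale_sd = scale_sd,
                  unit_id = raster$unit_id, population = raster$population)
}
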