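# Synthetic data: USV-like stimuli, ground-truth encoding models, and event
# rasters with the statistical structure the downstream analysis assumes.

#' Specification of a synthetic USV-like stimulus
#'
#' Describes the stimulus layout used throughout: `n_segments` vocalization
#' segments of `segment_duration` seconds, each padded by `pad_silence`
#' seconds of silence on both sides, preceded by `lead_silence` seconds of
#' silence used for baseline estimation. The defaults reproduce the playback
#' regime of 8-s segments with 1-s pads, a 20-s lead, 250 kHz sampling and a
#' 45-110 kHz vocalization band; with `n_segments = 15` the total duration
#' is 20 + 15 x 10 = 170 s.
#'
#' @param n_segments number of vocalization segments (>= 1).
#' @param segment_duration seconds of vocalization per segment (default 8).
#' @param pad_silence seconds of silence on each side of a segment (default 1).
#' @param lead_silence seconds of leading silence (default 20).
#' @param sample_rate sampling rate in Hz (default 250000).
#' @param band numeric length-2, frequency band in Hz (default c(45000, 110000)).
#' @return object of class `usv_stimulus_spec`.
#' @export
usv_stimulus_spec <- function(n_segments, segment_duration = 8,
                              pad_silence = 1, lead_silence = 20,
                              sample_rate = 250000,
                              band = c(45000, 110000)) {
  stopifnot(n_segments >= 1, segment_duration > 0, pad_silence >= 0,
            lead_silence >= 0, length(band) == 2, band[1] < band[2])
  if (band[2] > sample_rate / 2) {
    stop(sprintf("band upper edge %g Hz exceeds the Nyquist frequency %g Hz",
                 band[2], sample_rate / 2), call. = FALSE)
  }
  structure(
    list(n_segments = as.integer(n_segments),
         segment_duration = segment_duration, pad_silence = pad_silence,
         lead_silence = lead_silence, sample_rate = sample_rate, band = band),
    class = "usv_stimulus_spec"
  )
}

# One frequency-modulated sweep (linear or sinusoidal FM), Hann-enveloped so
# energy stays inside the band up to windowing leakage.
synth_sweep <- function(duration, sample_rate, band) {
  n <- max(8L, round(duration * sample_rate))
  tt <- seq_len(n) / sample_rate
  extent <- runif(1, 0.15, 1) * min(30000, diff(band))
  if (runif(1) < 0.5) {
    # linear FM
    f0 <- runif(1, band[1], band[2])
    f1 <- f0 + sample(c(-1, 1), 1) * extent
    f1 <- min(max(f1, band[1]), band[2])
    f_inst <- seq(f0, f1, length.out = n)
  } else {
    # sinusoidal FM around a carrier kept inside the band
    fc <- runif(1, band[1] + extent / 2, band[2] - extent / 2)
    fm <- runif(1, 4, 20)
    f_inst <- fc + (extent / 2) * sin(2 * pi * fm * tt + runif(1, 0, 2 * pi))
  }
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  sin(phase) * signal::hanning(n)
}

#' Generate a synthetic USV-like stimulus waveform
#'
#' Each vocalization segment contains 2-6 frequency-modulated tone sweeps
#' per second (random start frequency, extent up to 30 kHz, duration
#' 30-150 ms, linear or sinusoidal FM) confined to the spec's band and
#' separated by short gaps. The active part of every segment is normalized
#' to a fixed RMS; all silences are exact zeros. Fully deterministic for a
#' fixed seed. The sweeps mimic mouse USV syllable statistics only
#' qualitatively; no bioacoustic fidelity is claimed.
#'
#' @param spec a [usv_stimulus_spec()].
#' @param seed integer RNG seed.
#' @param rms target root-mean-square amplitude of active samples (default 0.1).
#' @return object of class `usv_stimulus`: list with `waveform` (numeric),
#'   `sample_rate`, `spec`, and `segment_onsets` (s).
#' @export
generate_usv_stimulus <- function(spec, seed = 1L, rms = 0.1) {
  stopifnot(inherits(spec, "usv_stimulus_spec"))
  fs <- spec$sample_rate
  seg_len <- round(spec$segment_duration * fs)
  pad_len <- round(spec$pad_silence * fs)
  lead_len <- round(spec$lead_silence * fs)
  total <- lead_len + spec$n_segments * (seg_len + 2 * pad_len)
  wave <- numeric(total)
  onsets <- numeric(spec$n_segments)
  with_seed(seed, {
    for (seg in seq_len(spec$n_segments)) {
      buf <- numeric(seg_len)
      rate <- runif(1, 2, 6)                       # sweeps per second
      n_sweeps <- max(1L, round(rate * spec$segment_duration))
      durations <- runif(n_sweeps, 0.03, 0.15)
      starts <- sort(runif(n_sweeps, 0, spec$segment_duration - max(durations)))
      for (k in seq_len(n_sweeps)) {
        s <- synth_sweep(durations[k], fs, spec$band)
        i0 <- round(starts[k] * fs) + 1L
        i1 <- min(i0 + length(s) - 1L, seg_len)
        buf[i0:i1] <- buf[i0:i1] + s[seq_len(i1 - i0 + 1L)]
      }
      active <- buf != 0
      if (any(active)) buf <- buf * (rms / sqrt(mean(buf[active]^2)))
      at <- lead_len + (seg - 1L) * (seg_len + 2L * pad_len) + pad_len
      wave[(at + 1L):(at + seg_len)] <- buf
      onsets[seg] <- at / fs
    }
  })
  structure(
    list(waveform = wave, sample_rate = fs, spec = spec,
         segment_onsets = onsets),
    class = "usv_stimulus"
  )
}

#' @export
print.usv_stimulus <- function(x, ...) {
  cat(sprintf("<usv_stimulus> %.1f s at %g Hz (%d segments)\n",
              length(x$waveform) / x$sample_rate, x$sample_rate,
              x$spec$n_segments))
  invisible(x)
}

#' Gabor-like spectrotemporal map
#'
#' Localized time-frequency blob: a 2-D Gaussian envelope multiplied by an
#' oriented cosine carrier. Used as the canonical shape of ground-truth
#' receptive-field features because localized features make visual and
#' quantitative recovery checks straightforward.
#'
#' @param n_time,n_freq map size in bins (defaults 28 x 28).
#' @param center_t,center_f blob centre in bins (defaults: random-ish middle).
#' @param sigma_t,sigma_f envelope widths in bins.
#' @param freq_t,freq_f carrier frequencies in cycles per bin.
#' @param phase carrier phase in radians.
#' @return n_time x n_freq numeric matrix with unit Frobenius norm.
#' @export
gabor_map <- function(n_time = 28L, n_freq = 28L,
                      center_t = n_time / 2, center_f = n_freq / 2,
                      sigma_t = 3, sigma_f = 3,
                      freq_t = 0.1, freq_f = 0.1, phase = 0) {
  tg <- matrix(seq_len(n_time), n_time, n_freq)
  fg <- matrix(seq_len(n_freq), n_time, n_freq, byrow = TRUE)
  env <- exp(-((tg - center_t)^2 / (2 * sigma_t^2) +
                 (fg - center_f)^2 / (2 * sigma_f^2)))
  carrier <- cos(2 * pi * (freq_t * (tg - center_t) + freq_f * (fg - center_f)) +
                   phase)
  m <- env * carrier
  m / sqrt(sum(m^2))
}

random_gabor_map <- function(n_time = 28L, n_freq = 28L) {
  gabor_map(n_time, n_freq,
            center_t = runif(1, 6, n_time - 5),
            center_f = runif(1, 6, n_freq - 5),
            sigma_t = runif(1, 2, 5), sigma_f = runif(1, 2, 5),
            freq_t = runif(1, 0.03, 0.2), freq_f = runif(1, 0.03, 0.2),
            phase = runif(1, 0, 2 * pi))
}

#' Build a ground-truth MNE encoding model from spectrotemporal maps
#'
#' Constructs the generative twin of the fitted encoding model: event
#' probability per bin is `P(event|s) = 1 / (1 + exp(a + s.h + s'Js))` in
#' the PCA-reduced stimulus coordinates. The quadratic kernel is
#' `J = sum_i lambda_i v_i v_i'` where the `v_i` are the feature maps
#' projected through the PCA basis and re-orthonormalized (Gram-Schmidt via
#' QR); `h` is the projection of an optional linear map.
#'
#' When `patches` (reduced coordinates) and `target_sd` are supplied, each
#' eigenvalue is rescaled so that the standard deviation over patches of
#' `lambda_i * (s.v_i)^2` equals `|eigenvalues[i]| * target_sd`; the
#' supplied eigenvalues then act as signed relative weights. This keeps
#' probabilities well inside (0, 1) for stimulus statistics of any scale.
#'
#' @param pca a `pca_reduction` defining the reduced coordinates.
#' @param feature_maps list of spectrotemporal matrices (may be empty).
#' @param eigenvalues numeric, one finite value per feature map.
#' @param a scalar offset; the baseline rate at `s = 0` is `plogis(-a)`.
#' @param linear_map optional spectrotemporal matrix for the linear term.
#' @param patches optional N x K matrix of reduced patch coordinates used
#'   for eigenvalue calibration.
#' @param target_sd optional calibration scale (see Details).
#' @return object of class `ground_truth_model`: `a`, `h` (K), `J` (K x K
#'   symmetric), `eigenvalues` (final, possibly rescaled), `feature_maps`
#'   (784 x m matrix of orthonormalized ambient features), `base_rate`.
#' @export
make_ground_truth <- function(pca, feature_maps = list(),
                              eigenvalues = numeric(), a = log(9),
                              linear_map = NULL, patches = NULL,
                              target_sd = NULL) {
  stopifnot(inherits(pca, "pca_reduction"),
            length(feature_maps) == length(eigenvalues))
  if (length(eigenvalues) && !all(is.finite(eigenvalues))) {
    stop("non-finite eigenvalues", call. = FALSE)
  }
  K <- pca$n_components
  p <- nrow(pca$basis)
  h <- numeric(K)
  J <- matrix(0, K, K)
  V <- NULL
  lam <- eigenvalues
  if (length(feature_maps)) {
    Vamb <- vapply(feature_maps, flatten_map, numeric(p))
    Vred <- crossprod(pca$basis, Vamb)              # K x m
    nrm <- sqrt(colSums(Vred^2))
    if (any(nrm < 1e-12)) {
      stop("a feature map has (near-)zero projection onto the PCA basis",
           call. = FALSE)
    }
    V <- qr.Q(qr(Vred))                             # re-orthonormalized
    if (!is.null(target_sd)) {
      if (is.null(patches)) stop("`patches` required for calibration",
                                 call. = FALSE)
      for (i in seq_along(lam)) {
        s2 <- stats::sd((patches %*% V[, i])^2)
        if (!is.finite(s2) || s2 <= 0) {
          stop("feature ", i, " has zero variance over the supplied ",
               "patches; cannot calibrate its eigenvalue", call. = FALSE)
        }
        lam[i] <- eigenvalues[i] * target_sd / s2
      }
    }
    J <- V %*% (lam * t(V))
    J <- (J + t(J)) / 2
  }
  if (!is.null(linear_map)) {
    hv <- crossprod(pca$basis, flatten_map(linear_map))[, 1]
    if (!is.null(target_sd) && !is.null(patches)) {
      hv <- hv * target_sd / stats::sd(patches %*% hv)
    }
    h <- hv
  }
  structure(
    list(a = a, h = h, J = J, eigenvalues = lam,
         feature_maps = if (is.null(V)) NULL else pca$basis %*% V,
         base_rate = stats::plogis(-a), n_components = K),
    class = "ground_truth_model"
  )
}

# Event probability of a (ground-truth or fitted) MNE parameter set.
mne_probability <- function(a, h, J, X) {
  z <- a + as.vector(X %*% h) + rowSums((X %*% J) * X)
  stats::plogis(-z)
}

#' Simulate an event raster from a ground-truth encoding model
#'
#' Each trial is an independent Bernoulli draw per time bin with
#' `p = 1 / (1 + exp(a + s.h + s'Js))`; the trial average converges to `p`
#' as the number of trials grows. Bins preceding the first full stimulus
#' window (if `n_lead_bins > 0`) are drawn at the model's baseline rate.
#'
#' @param model a `ground_truth_model`.
#' @param patches N x K matrix of reduced patch coordinates (same basis as
#'   the model).
#' @param n_trials number of stimulus repetitions (default 20).
#' @param seed integer RNG seed.
#' @param n_lead_bins bins without stimulus history, prepended at the
#'   baseline rate (default 0).
#' @param unit_id,population raster metadata.
#' @return an [event_raster()].
#' @export
simulate_event_raster <- function(model, patches, n_trials = 20L, seed = 1L,
                                  n_lead_bins = 0L, unit_id = "synth",
                                  population = "synthetic") {
  stopifnot(inherits(model, "ground_truth_model"), is.matrix(patches))
  if (ncol(patches) != model$n_components) {
    stop("patches have ", ncol(patches), " columns; model expects ",
         model$n_components, call. = FALSE)
  }
  p <- mne_probability(model$a, model$h, model$J, patches)
  p_all <- c(rep(model$base_rate, n_lead_bins), p)
  T_bins <- length(p_all)
  binary <- with_seed(seed, {
    matrix(stats::rbinom(n_trials * T_bins, 1L, rep(p_all, each = n_trials)),
           nrow = n_trials, ncol = T_bins)
  })
  event_raster(binary, unit_id = unit_id, population = population)
}

#' Generate two synthetic populations with controlled subspace overlap
#'
#' Builds ground-truth quadratic feature maps for two populations ("A" and
#' "B") such that their feature subspaces share exactly `shared_dim` basis
#' directions while all remaining directions are mutually orthogonal. The
#' construction takes random Gabor-like maps, projects them into the PCA
#' space and applies Gram-Schmidt (QR), giving exact control over the true
#' principal angles: `shared_dim` angles of 0 degrees, all others 90.
#'
#' Each unit carries one quadratic feature with a positive eigenvalue
#' (event-probability-decreasing, i.e. inhibitory, the dominant class in
#' calcium event data), calibrated so the quadratic term has standard
#' deviation `quad_sd` over the supplied patches; rasters are Bernoulli
#' draws from the resulting model.
#'
#' @param patches N x K matrix of reduced patch coordinates (or a
#'   `patch_set` together with `pca`).
#' @param pca the `pca_reduction` the coordinates come from.
#' @param shared_dim number of directions shared by the populations.
#' @param n_private_a,n_private_b private directions per population.
#' @param n_trials stimulus repetitions per unit (default 20).
#' @param base_rate baseline event probability per bin (default 0.3; kept
#'   <= 0.3 so rasters resemble sparse calcium event trains).
#' @param quad_sd calibration scale of the quadratic term (default 2.5).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_dataset`: `rasters` (list of
#'   [event_raster()]), `truth` (list of `ground_truth_model`),
#'   `population_labels`, `true_features` (list `A`/`B` of 784 x d ambient
#'   feature matrices), `shared_dim`, `private_dims`.
#' @export
generate_population <- function(patches, pca, shared_dim = 1L,
                                n_private_a = 1L, n_private_b = 1L,
                                n_trials = 20L, base_rate = 0.3,
                                quad_sd = 2.5, seed = 1L) {
  if (inherits(patches, "patch_set")) patches <- pca_project(pca, patches)
  stopifnot(is.matrix(patches), shared_dim >= 0,
            n_private_a >= 0, n_private_b >= 0)
  d_a <- shared_dim + n_private_a
  d_b <- shared_dim + n_private_b
  if (shared_dim > min(d_a, d_b)) {
    stop("shared_dim exceeds a population's total dimension", call. = FALSE)
  }
  m <- shared_dim + n_private_a + n_private_b
  K <- pca$n_components
  if (m > K) {
    stop("requested ", m, " orthogonal directions but only ", K,
         " reduced dimensions are available", call. = FALSE)
  }
  n_time <- if (!is.null(pca$basis)) round(sqrt(nrow(pca$basis))) else 28L
  a <- log(1 / base_rate - 1)
  with_seed(seed, {
    maps <- replicate(m, random_gabor_map(n_time, nrow(pca$basis) / n_time),
                      simplify = FALSE)
    Vred <- vapply(maps, function(mp) {
      crossprod(pca$basis, flatten_map(mp))[, 1]
    }, numeric(K))
    Q <- qr.Q(qr(Vred))                   # exact Gram-Schmidt orthonormality
    take <- function(cols) Q[, cols, drop = FALSE]
    cols_a <- c(seq_len(shared_dim),
                shared_dim + seq_len(n_private_a))
    cols_b <- c(seq_len(shared_dim),
                shared_dim + n_private_a + seq_len(n_private_b))
    V_a <- take(cols_a); V_b <- take(cols_b)
    build_unit <- function(v) {
      lam <- quad_sd / stats::sd((patches %*% v)^2)
      J <- lam * tcrossprod(v)
      structure(
        list(a = a, h = numeric(K), J = (J + t(J)) / 2, eigenvalues = lam,
             feature_maps = pca$basis %*% v, base_rate = base_rate,
             n_components = K),
        class = "ground_truth_model")
    }
    truth <- c(lapply(seq_len(ncol(V_a)), function(i) build_unit(V_a[, i])),
               lapply(seq_len(ncol(V_b)), function(i) build_unit(V_b[, i])))
    labels <- c(rep("popA", ncol(V_a)), rep("popB", ncol(V_b)))
    rasters <- lapply(seq_along(truth), function(i) {
      simulate_event_raster(truth[[i]], patches, n_trials = n_trials,
                            seed = seed + i,
                            unit_id = sprintf("%s_unit%02d", labels[i], i),
                            population = labels[i])
    })
    structure(
      list(rasters = rasters, truth = truth, population_labels = labels,
           true_features = list(A = pca$basis %*% V_a, B = pca$basis %*% V_b),
           shared_dim = as.integer(shared_dim),
           private_dims = c(A = as.integer(n_private_a),
                            B = as.integer(n_private_b)),
           n_trials = as.integer(n_trials)),
      class = "synthetic_dataset")
  })
}
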