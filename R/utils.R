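# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten a spectrotemporal map to a row-major vector
#'
#' Maps are matrices with rows = time lags (oldest first) and columns =
#' frequency bins. Flattening is row-major: lag 1 frequencies first, then
#' lag 2, and so on. This is the layout used for stimulus patches and for
#' receptive-field features, so flattened maps, patch rows and PCA basis
#' vectors all live in the same coordinate system.
#'
#' @param map numeric matrix (time lags x frequency bins).
#' @return numeric vector of length `nrow(map) * ncol(map)`.
#' @seealso [unflatten_map()]
#' @export
flatten_map <- function(map) {
  stopifnot(is.matrix(map))
  as.vector(t(map))
}

#' Restore a flattened map to matrix form
#'
#' Inverse of [flatten_map()].
#'
#' @param v numeric vector.
#' @param n_time,n_freq dimensions of the map; defaults 28 x 28.
#' @return matrix (n_time x n_freq).
#' @export
unflatten_map <- function(v, n_time = 28L, n_freq = 28L) {
  stopifnot(length(v) == n_time * n_freq)
  matrix(v, nrow = n_time, ncol = n_freq, byrow = TRUE)
}

# Centre the zero-frequency component of a 2-D DFT power matrix.
fft_shift2 <- function(m) {
  i <- seq_len(nrow(m))
  j <- seq_len(ncol(m))
  si <- c(i[i > ceiling(nrow(m) / 2)], i[i <= ceiling(nrow(m) / 2)])
  sj <- c(j[j > ceiling(ncol(m) / 2)], j[j <= ceiling(ncol(m) / 2)])
  m[si, sj, drop = FALSE]
}

# Shifted DFT index frequencies (cycles per sample), matching fft_shift2.
fft_shift_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  sort(k) / n
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in `%s`", name), call. = FALSE)
  }
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' Used to score encoding-model predictions against held-out responses.
#' Returns `NA` when either vector has zero norm (the similarity is then
#' undefined and the corresponding model evaluation is reported as failed).
#'
#' @param a,b numeric vectors of equal length.
#' @param center subtract means before comparing (default `FALSE`, i.e. the
#'   raw-vector convention).
#' @return scalar in \[-1, 1\], or `NA_real_`.
#' @export
cosine_similarity <- function(a, b, center = FALSE) {
  stopifnot(length(a) == length(b))
  if (center) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
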