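# Second-order Maximum Noise Entropy encoding model:
#   P(event | s) = 1 / (1 + exp(a + s.h + s'Js))
# fit by penalized cross-entropy with cross-validated early stopping,
# evaluated by held-out cosine similarity against a shuffle null.

#' Construct an MNE model object
#'
#' Containers for the logistic encoding model parameters. `J` must be
#' symmetric (it is symmetrized internally during fitting by optimizing
#' only its upper triangle).
#'
#' @param a scalar offset.
#' @param h length-K linear kernel.
#' @param J K x K symmetric quadratic kernel.
#' @param fit_meta optional list of fit diagnostics/settings.
#' @return object of class `mne_model`.
#' @export
mne_model <- function(a, h, J, fit_meta = list()) {
  stopifnot(length(a) == 1, is.matrix(J), nrow(J) == ncol(J),
            length(h) == nrow(J))
  if (max(abs(J - t(J))) > 1e-8 * max(1, max(abs(J)))) {
    stop("J must be symmetric", call. = FALSE)
  }
  if (!all(is.finite(c(a, h, J)))) stop("non-finite parameters", call. = FALSE)
  structure(list(a = a, h = as.numeric(h), J = (J + t(J)) / 2,
                 n_components = length(h), fit_meta = fit_meta),
            class = "mne_model")
}

#' @export
print.mne_model <- function(x, ...) {
  cat(sprintf("<mne_model> K = %d; a = %.3f, |h| = %.3f, |J|_F = %.3f\n",
              x$n_components, x$a, sqrt(sum(x$h^2)), sqrt(sum(x$J^2))))
  invisible(x)
}

#' Predict event probabilities from an MNE model
#'
#' Computes `p_i = 1 / (1 + exp(a + x_i.h + x_i' J x_i))` row-wise,
#' overflow-safely (via `plogis`).
#'
#' @param model an `mne_model` (or `ground_truth_model`).
#' @param X N x K matrix of stimulus coordinates.
#' @return numeric vector of probabilities in (0, 1).
#' @export
mne_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == model$n_components)
  assert_finite(X, "X")
  mne_probability(model$a, model$h, model$J, X)
}

#' Pack MNE parameters into an optimization vector
#'
#' Layout: `c(a, h, upper-triangle of J including the diagonal,
#' column-major)`. Only the upper triangle is optimized; `J` is
#' reconstructed symmetric by [mne_unpack()].
#'
#' @param a,h,J model parameters.
#' @return numeric vector of length `1 + K + K(K+1)/2`.
#' @export
mne_pack <- function(a, h, J) {
  c(a, h, J[upper.tri(J, diag = TRUE)])
}

#' Unpack an optimization vector into MNE parameters
#'
#' @param par numeric vector from [mne_pack()].
#' @param K reduced stimulus dimension.
#' @return list with `a`, `h`, `J` (symmetric).
#' @export
mne_unpack <- function(par, K) {
  stopifnot(length(par) == 1 + K + K * (K + 1) / 2)
  a <- par[1]
  h <- par[2:(K + 1)]
  J <- matrix(0, K, K)
  J[upper.tri(J, diag = TRUE)] <- par[-seq_len(K + 1)]
  J <- J + t(J)
  diag(J) <- diag(J) / 2
  list(a = a, h = h, J = J)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x < 33
  out[lo] <- log1p(exp(x[lo]))
  out
}

#' Average cross-entropy loss and its exact gradient
#'
#' The objective of the MNE fit: mean cross-entropy between the (possibly
#' fractional, trial-averaged) target `y` and the model probabilities, plus
#' an optional ridge penalty `ridge * (|h|^2 + |J|_F^2)`. At a stationary
#' point with binary targets the model-expected mean rate, event-triggered
#' average and event-triggered covariance match their empirical
#' counterparts — the MNE moment conditions (the `a`, `h` and `J` gradient
#' components are exactly those moment mismatches at `ridge = 0`).
#'
#' @param par packed parameter vector (see [mne_pack()]).
#' @param X N x K stimulus matrix.
#' @param y length-N response in \[0, 1\].
#' @param ridge penalty weight (default 0).
#' @return list with `value` (scalar) and `gradient` (same layout as `par`).
#' @export
mne_nll_grad <- function(par, X, y, ridge = 0) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  K <- ncol(X)
  pr <- mne_unpack(par, K)
  N <- nrow(X)
  z <- pr$a + as.vector(X %*% pr$h) + rowSums((X %*% pr$J) * X)
  value <- mean(y * log1pexp(z) + (1 - y) * log1pexp(-z)) +
    ridge * (sum(pr$h^2) + sum(pr$J^2))
  p <- stats::plogis(-z)
  g <- (y - p) / N                       # d(mean CE)/dz_i
  grad_a <- sum(g)
  grad_h <- as.vector(crossprod(X, g)) + 2 * ridge * pr$h
  G <- crossprod(X, X * g)               # symmetric K x K
  ut <- upper.tri(G, diag = TRUE)
  rc <- which(ut, arr.ind = TRUE)
  is_diag <- rc[, 1] == rc[, 2]
  Gut <- G[ut]; Jut <- pr$J[ut]
  grad_u <- ifelse(is_diag, Gut + 2 * ridge * Jut, 2 * Gut + 4 * ridge * Jut)
  list(value = value, gradient = c(grad_a, grad_h, grad_u))
}

# One L-BFGS "round" continuing from par; returns updated par.
lbfgs_round <- function(par, X, y, ridge, maxit) {
  res <- stats::optim(
    par,
    fn = function(p) mne_nll_grad(p, X, y, ridge)$value,
    gr = function(p) mne_nll_grad(p, X, y, ridge)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = maxit)
  )
  if (!is.finite(res$value)) {
    stop("MNE optimization diverged (non-finite loss); reduce the step ",
         "budget or increase the ridge penalty", call. = FALSE)
  }
  res$par
}

plain_nll <- function(par, X, y) mne_nll_grad(par, X, y, ridge = 0)$value

#' Fit the MNE encoding model
#'
#' Minimizes the penalized cross-entropy on the training block of an
#' [aligned_dataset()] with an L-BFGS quasi-Newton optimizer. With
#' `cv = TRUE` (default) training proceeds in rounds of `iters_per_round`
#' iterations and, for each of the dataset's folds, the held-out fold's
#' unpenalized loss selects the best stopping round (with `patience` rounds
#' of grace); the final model is refit on the full training block for the
#' mean best round count. This early stopping, together with the small
#' ridge penalty, keeps the fit stable even when the number of parameters
#' `1 + K + K(K+1)/2` exceeds the number of training rows.
#'
#' @param data an [aligned_dataset()].
#' @param ridge ridge penalty on `h` and `J` (default 1e-4).
#' @param cv use fold-based early stopping (default `TRUE`).
#' @param max_rounds,iters_per_round,patience early-stopping schedule.
#' @param max_iter L-BFGS iteration budget when `cv = FALSE` (default 300).
#' @param init optional packed starting vector; default is `a` at the
#'   logit of the mean training response, `h = 0`, `J = 0`.
#' @return an [mne_model()] with `fit_meta` recording settings, per-fold
#'   best rounds and validation losses, and the dataset's coordinate
#'   scaling (used later by [extract_features()]).
#' @export
fit_mne <- function(data, ridge = 1e-4, cv = TRUE, max_rounds = 40L,
                    iters_per_round = 10L, patience = 3L, max_iter = 300L,
                    init = NULL) {
  stopifnot(inherits(data, "aligned_dataset"))
  K <- ncol(data$X)
  Xtr <- data$X[data$train_idx, , drop = FALSE]
  ytr <- data$y[data$train_idx]
  ybar <- min(max(mean(ytr), 1e-4), 1 - 1e-4)
  par0 <- init %||% mne_pack(log(1 / ybar - 1), numeric(K), matrix(0, K, K))

  fold_best <- integer(0)
  fold_val <- numeric(0)
  if (cv) {
    for (f in seq_along(data$folds)) {
      val_rows <- match(data$folds[[f]], data$train_idx)
      Xf <- Xtr[-val_rows, , drop = FALSE]; yf <- ytr[-val_rows]
      Xv <- Xtr[val_rows, , drop = FALSE]; yv <- ytr[val_rows]
      par <- par0
      best <- Inf; best_round <- 0L
      for (r in seq_len(max_rounds)) {
        par <- lbfgs_round(par, Xf, yf, ridge, iters_per_round)
        v <- plain_nll(par, Xv, yv)
        if (v < best - 1e-10) {
          best <- v; best_round <- r
        } else if (r - best_round >= patience) break
      }
      fold_best <- c(fold_best, max(best_round, 1L))
      fold_val <- c(fold_val, best)
    }
    rounds_used <- max(1L, as.integer(round(mean(fold_best))))
    par <- par0
    for (r in seq_len(rounds_used)) {
      par <- lbfgs_round(par, Xtr, ytr, ridge, iters_per_round)
    }
  } else {
    rounds_used <- NA_integer_
    par <- lbfgs_round(par0, Xtr, ytr, ridge, max_iter)
  }
  pr <- mne_unpack(par, K)
  mne_model(pr$a, pr$h, pr$J, fit_meta = list(
    ridge = ridge, cv = cv, iters_per_round = iters_per_round,
    max_iter = max_iter, rounds_used = rounds_used, fold_best = fold_best,
    fold_val_nll = fold_val, train_nll = plain_nll(par, Xtr, ytr),
    scale_sd = data$scale_sd, unit_id = data$unit_id,
    population = data$population))
}

# Refit with the budget the original fit ended up using (the "identical
# settings" applied to every shuffled model).
refit_like <- function(model, X, y) {
  K <- ncol(X)
  meta <- model$fit_meta
  ybar <- min(max(mean(y), 1e-4), 1 - 1e-4)
  par <- mne_pack(log(1 / ybar - 1), numeric(K), matrix(0, K, K))
  if (isTRUE(meta$cv)) {
    for (r in seq_len(meta$rounds_used)) {
      par <- lbfgs_round(par, X, y, meta$ridge, meta$iters_per_round)
    }
  } else {
    par <- lbfgs_round(par, X, y, meta$ridge, meta$max_iter)
  }
  mne_unpack(par, K)
}

#' Evaluate an MNE model against a shuffle null
#'
#' Performance is the cosine similarity between the model's predictions and
#' the true trial-averaged response on the held-out test block. The null
#' distribution is built by permuting the response over the rows of the
#' training block (the test pairing is untouched), refitting with the same
#' optimizer budget, and predicting the unshuffled test stimuli; with the
#' default 200 shuffles the model is called significant when the proportion
#' of null similarities at or above the observed one is below 0.05. Both
#' the literal proportion and the `(r + 1) / (n + 1)` convention are
#' reported.
#'
#' @param model a fitted [mne_model()].
#' @param data the [aligned_dataset()] the model was fit on.
#' @param n_shuffles number of shuffled refits (default 200; smaller values
#'   trigger a warning since the null becomes coarse, `0` disables
#'   significance).
#' @param seed integer RNG seed for the permutations.
#' @param alpha significance level (default 0.05).
#' @param keep_null_models keep the shuffled parameter sets (default
#'   `TRUE`; required by [extract_features()] for the eigenvalue null).
#' @return object of class `mne_evaluation`: `cosine_similarity`,
#'   `null_similarities`, `p_value` (proportion rule), `p_value_plus1`,
#'   `significant`, `failed`, `null_models`.
#' @export
evaluate_mne <- function(model, data, n_shuffles = 200L, seed = 1L,
                         alpha = 0.05, keep_null_models = TRUE) {
  stopifnot(inherits(model, "mne_model"), inherits(data, "aligned_dataset"))
  if (length(data$test_idx) == 0) stop("empty test set", call. = FALSE)
  Xte <- data$X[data$test_idx, , drop = FALSE]
  yte <- data$y[data$test_idx]
  obs <- cosine_similarity(mne_predict(model, Xte), yte)
  failed <- is.na(obs)
  if (n_shuffles > 0 && n_shuffles < 200) {
    warning("n_shuffles = ", n_shuffles,
            " is below the standard 200; the null distribution is coarse",
            call. = FALSE)
  }
  nulls <- numeric(0)
  null_models <- list()
  if (n_shuffles > 0 && !failed) {
    Xtr <- data$X[data$train_idx, , drop = FALSE]
    ytr <- data$y[data$train_idx]
    nulls <- with_seed(seed, {
      vapply(seq_len(n_shuffles), function(k) {
        pr <- refit_like(model, Xtr, ytr[sample.int(length(ytr))])
        if (keep_null_models) null_models[[k]] <<- pr
        cosine_similarity(mne_probability(pr$a, pr$h, pr$J, Xte), yte)
      }, numeric(1))
    })
  }
  if (n_shuffles > 0 && !failed) {
    r <- sum(nulls >= obs, na.rm = TRUE)
    p_lit <- r / n_shuffles
    p_plus1 <- (r + 1) / (n_shuffles + 1)
    signif_flag <- p_lit < alpha
  } else {
    p_lit <- NA_real_; p_plus1 <- NA_real_; signif_flag <- NA
  }
  structure(
    list(cosine_similarity = obs, null_similarities = nulls,
         p_value = p_lit, p_value_plus1 = p_plus1,
         significant = signif_flag, failed = failed, alpha = alpha,
         null_models = null_models, unit_id = data$unit_id),
    class = "mne_evaluation"
  )
}

#' @export
print.mne_evaluation <- function(x, ...) {
  cat(sprintf("<mne_evaluation> %s: cosine = %.3f, p = %s (%d shuffles)%s\n",
              x$unit_id %||% "unit",
              x$cosine_similarity,
              if (is.na(x$p_value)) "NA" else sprintf("%.4g", x$p_value),
              length(x$null_similarities),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

# Map a direction from the fitted (possibly standardized) reduced
# coordinates back to the raw reduced coordinates: if the model was fit on
# X / sd, a direction u in fitted coordinates corresponds to u / sd in raw
# PCA coordinates (the quadratic form in raw coordinates is D^-1 J D^-1).
unscale_direction <- function(u, scale_sd) {
  if (!is.null(scale_sd)) u <- u / scale_sd
  n <- sqrt(sum(u^2))
  if (n > 0) u / n else u
}

#' Extract receptive-field features from a fitted MNE model
#'
#' The model's features are (1) the linear kernel `h` and (2) the
#' eigenvectors of the quadratic kernel `J`, both defined in the reduced
#' stimulus space and back-projected through the PCA basis into the
#' time-frequency plane. A quadratic feature with a positive eigenvalue
#' increases the argument of the exponential and therefore decreases event
#' probability ("inhibitory"); a negative eigenvalue is "excitatory".
#'
#' Significance calls reuse the shuffled fits from [evaluate_mne()] as a
#' null: a quadratic feature is significant when its eigenvalue falls
#' outside the central `level` band of the rank-matched null eigenvalue
#' distribution (eigenvalues of each shuffled `J`, sorted); the linear
#' feature is significant when `|h|` exceeds the corresponding upper null
#' quantile. This eigenvalue-null criterion is a stated convention of this
#' package, recorded in the output, not a published rule.
#'
#' Eigen-analysis and the null comparison are carried out in the
#' coordinates the model was fitted in (i.e. the standardized reduced
#' coordinates when the dataset was scaled), where rank-matching across
#' shuffles is well calibrated; extracted directions are then mapped back
#' through the inverse scaling and the PCA basis into the time-frequency
#' plane.
#'
#' @param model a fitted [mne_model()].
#' @param pca the `pca_reduction` used to build the stimulus coordinates.
#' @param null_models list of shuffled parameter sets (from
#'   `evaluate_mne(..., keep_null_models = TRUE)`); `NULL` leaves
#'   significance as `NA`.
#' @param level width of the null band (default 0.95).
#' @param n_time number of time bins per map (default inferred as the
#'   square root of the ambient dimension).
#' @return object of class `rf_features`: a list of features, each with
#'   `map` (time x frequency matrix, sign fixed so the largest-magnitude
#'   element is positive), `kind` ("linear"/"quadratic"), `eigenvalue`,
#'   `rank`, `sign_class`, `significant`; plus the null bands used.
#' @export
extract_features <- function(model, pca, null_models = NULL, level = 0.95,
                             n_time = NULL) {
  stopifnot(inherits(model, "mne_model"), inherits(pca, "pca_reduction"))
  if (max(abs(model$J - t(model$J))) > 1e-8 * max(1, max(abs(model$J)))) {
    stop("asymmetric J", call. = FALSE)
  }
  p_amb <- nrow(pca$basis)
  n_time <- n_time %||% round(sqrt(p_amb))
  n_freq <- p_amb / n_time
  sds <- model$fit_meta$scale_sd
  eg <- eigen(model$J, symmetric = TRUE)     # values in decreasing order
  K <- model$n_components

  have_null <- length(null_models) > 0
  if (have_null) {
    null_eigs <- t(vapply(null_models, function(nm) {
      eigen(nm$J, symmetric = TRUE, only.values = TRUE)$values
    }, numeric(K)))
    lo <- apply(null_eigs, 2, stats::quantile, probs = (1 - level) / 2)
    hi <- apply(null_eigs, 2, stats::quantile, probs = 1 - (1 - level) / 2)
    null_hnorm <- vapply(null_models, function(nm) sqrt(sum(nm$h^2)),
                         numeric(1))
    h_thresh <- stats::quantile(null_hnorm, 1 - (1 - level) / 2)
  } else {
    lo <- hi <- rep(NA_real_, K)
    h_thresh <- NA_real_
  }

  sign_fix <- function(v_amb) if (v_amb[which.max(abs(v_amb))] < 0) -v_amb else v_amb

  features <- list()
  h_norm <- sqrt(sum(model$h^2))
  if (h_norm > 0) {
    amb <- sign_fix(as.vector(pca$basis %*% unscale_direction(model$h, sds)))
    features[[length(features) + 1L]] <- list(
      map = unflatten_map(amb, n_time, n_freq), kind = "linear",
      eigenvalue = NA_real_, rank = NA_integer_, sign_class = NA_character_,
      norm = h_norm,
      significant = if (have_null) h_norm > h_thresh else NA)
  }
  eig_floor <- 1e-10 * max(abs(eg$values), 1e-300)
  for (r in seq_len(K)) {
    val <- eg$values[r]
    if (abs(val) <= eig_floor) next      # numerically zero: not a candidate
    amb <- sign_fix(as.vector(pca$basis %*%
                                unscale_direction(eg$vectors[, r], sds)))
    features[[length(features) + 1L]] <- list(
      map = unflatten_map(amb, n_time, n_freq), kind = "quadratic",
      eigenvalue = val, rank = r,
      sign_class = if (val > 0) "inhibitory" else "excitatory",
      norm = NA_real_,
      significant = if (have_null) (val < lo[r] | val > hi[r]) else NA)
  }
  structure(
    list(features = features, eigenvalue_band = cbind(lo = lo, hi = hi),
         h_norm_threshold = h_thresh, level = level,
         significance_convention = "rank-matched shuffle eigenvalue null",
         unit_id = model$fit_meta$unit_id %||% "unit",
         population = model$fit_meta$population %||% NA_character_),
    class = "rf_features"
  )
}

#' @export
print.rf_features <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  sig <- vapply(x$features, function(f) isTRUE(f$significant), logical(1))
  cat(sprintf("<rf_features> %s: %d candidates (%d linear), %d significant\n",
              x$unit_id, length(x$features), sum(kinds == "linear"),
              sum(sig)))
  invisible(x)
}

#' Summarize extracted features as a data frame
#'
#' @param x an `rf_features` object.
#' @param ... unused.
#' @return data frame with one row per candidate feature.
#' @export
as.data.frame.rf_features <- function(x, ...) {
  data.frame(
    unit_id = x$unit_id,
    population = x$population,
    kind = vapply(x$features, `[[`, character(1), "kind"),
    rank = vapply(x$features, function(f) f$rank %||% NA_integer_, integer(1)),
    eigenvalue = vapply(x$features, `[[`, numeric(1), "eigenvalue"),
    sign_class = vapply(x$features, function(f) f$sign_class %||% NA_character_,
                        character(1)),
    significant = vapply(x$features, function(f) {
      if (is.na(f$significant)) NA else isTRUE(f$significant)
    }, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Collect feature maps into an ambient-space matrix
#'
#' Flattens the selected features of one or more `rf_features` objects into
#' the columns of a matrix, ready for [orthonormal_basis()] and
#' [principal_angles()].
#'
#' @param x an `rf_features` object or a list of them.
#' @param significant_only keep only features flagged significant
#'   (default `TRUE`).
#' @param kind which feature kinds to keep (default quadratic only, the
#'   dominant receptive-field class).
#' @return p x m numeric matrix (possibly with zero columns).
#' @export
feature_matrix <- function(x, significant_only = TRUE,
                           kind = c("quadratic", "linear")) {
  if (inherits(x, "rf_features")) x <- list(x)
  kind <- match.arg(kind, several.ok = TRUE)
  cols <- list()
  for (ff in x) {
    for (f in ff$features) {
      if (!(f$kind %in% kind)) next
      if (significant_only && !isTRUE(f$significant)) next
      cols[[length(cols) + 1L]] <- flatten_map(f$map)
    }
  }
  if (length(cols) == 0) {
    p <- if (length(x)) length(flatten_map(x[[1]]$features[[1]]$map)) else 0
    return(matrix(numeric(0), nrow = p, ncol = 0))
  }
  do.call(cbind, cols)
}
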