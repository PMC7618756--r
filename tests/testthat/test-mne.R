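make_gaussian_dataset <- function(K, N, model_fun = NULL, n_trials = 20,
                                  seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * K), N, K)
  p <- if (is.null(model_fun)) rep(0.3, N) else model_fun(X)
  y <- colMeans(matrix(rbinom(n_trials * N, 1, rep(p, each = n_trials)),
                       n_trials, N))
  list(data = aligned_dataset(X, y), p = p, X = X)
}

test_that("model predictions evaluate the logistic form exactly", {
  m0 <- mne_model(0, numeric(3), matrix(0, 3, 3))
  expect_equal(mne_predict(m0, matrix(rnorm(15), 5, 3)), rep(0.5, 5))
  m1 <- mne_model(log(9), numeric(2), matrix(0, 2, 2))
  expect_equal(mne_predict(m1, matrix(1, 1, 2)), 0.1)
  m2 <- mne_model(0, 1, matrix(1, 1, 1))
  expect_equal(mne_predict(m2, matrix(1, 1, 1)), 1 / (1 + exp(2)))
  # overflow safety
  m3 <- mne_model(1000, numeric(1), matrix(0, 1, 1))
  expect_equal(mne_predict(m3, matrix(0)), 0)
  expect_error(mne_predict(m0, matrix(c(1, NA, 1), 1)), "non-finite")
  expect_error(mne_model(0, c(1, 2), matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(5)
  K <- 4; N <- 50
  X <- matrix(rnorm(N * K), N, K)
  y <- runif(N)
  A <- matrix(rnorm(K * K), K) / 10
  par <- mne_pack(0.3, rnorm(K) / 5, (A + t(A)) / 2)
  for (ridge in c(0, 1e-3)) {
    g <- mne_nll_grad(par, X, y, ridge)$gradient
    fd <- fd_gradient(par, X, y, ridge)
    expect_lt(max(abs(fd - g) / (abs(g) + 1e-8)), 1e-6)
  }
})

test_that("the gradient vanishes when predictions already match the targets", {
  set.seed(6)
  X <- scale(matrix(rnorm(200), 50, 4), scale = FALSE)
  par <- mne_pack(0, numeric(4), matrix(0, 4, 4))
  g <- mne_nll_grad(par, X, rep(0.5, 50))$gradient
  expect_equal(max(abs(g)), 0, tolerance = 1e-12)
})

test_that("parameter packing round-trips and keeps J symmetric", {
  set.seed(2)
  A <- matrix(rnorm(25), 5)
  J <- (A + t(A)) / 2
  h <- rnorm(5)
  pr <- mne_unpack(mne_pack(1.5, h, J), 5)
  expect_equal(pr$a, 1.5)
  expect_equal(pr$h, h)
  expect_equal(pr$J, J)
})

test_that("a constant-rate unit is fit by an intercept-only model", {
  gd <- make_gaussian_dataset(6, 1500, seed = 3)
  m <- fit_mne(gd$data)
  expect_equal(m$a, log(1 / 0.3 - 1), tolerance = 0.15)
  expect_lt(sqrt(sum(m$h^2)), 0.1)
  expect_lt(sqrt(sum(m$J^2)), 0.1)
})

test_that("a single-quadratic-feature model is recovered from simulated rasters", {
  K <- 8
  set.seed(31)
  v <- rnorm(K); v <- v / sqrt(sum(v^2))
  Jt <- 1.5 * tcrossprod(v)
  gd <- make_gaussian_dataset(K, 4000, seed = 31, model_fun = function(X) {
    plogis(-(0.5 + rowSums((X %*% Jt) * X)))
  })
  m <- fit_mne(gd$data)
  eg <- eigen(m$J, symmetric = TRUE)
  expect_gt(abs(sum(eg$vectors[, 1] * v)), 0.9)
  expect_gt(eg$values[1], 5 * abs(eg$values[2]))
})

test_that("predictions are invariant under consistent linear reparameterization", {
  set.seed(12)
  K <- 5
  X <- matrix(rnorm(100 * K), 100, K)
  A <- matrix(rnorm(K * K), K) + diag(K)     # invertible
  S <- matrix(rnorm(K * K), K); J <- (S + t(S)) / 4
  h <- rnorm(K)
  m <- mne_model(0.3, h, J)
  Ainv <- solve(A)
  m2 <- mne_model(0.3, as.vector(Ainv %*% h), Ainv %*% J %*% t(Ainv))
  expect_equal(mne_predict(m2, X %*% A), mne_predict(m, X), tolerance = 1e-10)
})

test_that("cosine similarity handles collinear, orthogonal and degenerate inputs", {
  y <- c(0.2, 0.5, 0.9)
  expect_equal(cosine_similarity(3 * y, y), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_true(is.na(cosine_similarity(c(0, 0), y[1:2])))
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
})

test_that("shuffle evaluation counts exceedances by both p-value conventions", {
  # strong signal, tiny null: the observed similarity should beat every null
  K <- 4
  set.seed(41)
  v <- rnorm(K); v <- v / sqrt(sum(v^2))
  Jt <- 2 * tcrossprod(v)
  gd <- make_gaussian_dataset(K, 800, seed = 41, model_fun = function(X) {
    plogis(-(0.5 + rowSums((X %*% Jt) * X)))
  })
  m <- fit_mne(gd$data)
  ev <- suppressWarnings(evaluate_mne(m, gd$data, n_shuffles = 5, seed = 2))
  expect_length(ev$null_similarities, 5)
  expect_true(all(ev$null_similarities < ev$cosine_similarity))
  expect_equal(ev$p_value, 0)
  expect_equal(ev$p_value_plus1, 1 / 6)
  expect_true(ev$significant)
  expect_length(ev$null_models, 5)
  expect_warning(evaluate_mne(m, gd$data, n_shuffles = 2, seed = 1),
                 "below the standard 200")
})

test_that("evaluation without shuffles reports significance as unavailable", {
  gd <- make_gaussian_dataset(4, 400, seed = 9)
  m <- fit_mne(gd$data, cv = FALSE, max_iter = 30)
  ev <- evaluate_mne(m, gd$data, n_shuffles = 0)
  expect_false(is.na(ev$cosine_similarity))
  expect_true(is.na(ev$p_value))
  expect_true(is.na(ev$significant))
})

test_that("moment mismatches shrink as the optimization budget grows", {
  # binary targets: the gradient components in a and h are exactly the
  # mean-rate and event-triggered-average mismatches
  K <- 6
  set.seed(17)
  v <- rnorm(K); v <- v / sqrt(sum(v^2))
  Jt <- tcrossprod(v)
  gd <- make_gaussian_dataset(K, 2000, n_trials = 1, seed = 17,
                              model_fun = function(X) {
                                plogis(-(0.4 + rowSums((X %*% Jt) * X)))
                              })
  stopifnot(all(gd$data$y %in% c(0, 1)))
  Xtr <- gd$data$X[gd$data$train_idx, ]
  ytr <- gd$data$y[gd$data$train_idx]
  errs <- sapply(c(3, 30, 300), function(budget) {
    m <- fit_mne(gd$data, ridge = 0, cv = FALSE, max_iter = budget)
    p <- mne_predict(m, Xtr)
    c(mean_rate = abs(mean(p) - mean(ytr)),
      sta = sqrt(sum((crossprod(Xtr, ytr - p) / length(ytr))^2)))
  })
  expect_true(all(diff(errs["mean_rate", ]) <= 1e-12))
  expect_true(all(diff(errs["sta", ]) <= 1e-12))
  expect_lt(errs["mean_rate", 3], 1e-5)
})

test_that("extracted features expose the eigenstructure with the sign convention", {
  # diagonal J in an identity-like reduced basis: candidates are the
  # nonzero eigenvalues only, classified by sign
  K <- 4; p_amb <- 16
  pca <- structure(list(mean = numeric(p_amb),
                        basis = diag(p_amb)[, 1:K],
                        sdev = rep(1, p_amb), n_components = K,
                        explained_variance_fraction = 0.25),
                   class = "pca_reduction")
  m <- mne_model(0, numeric(K), diag(c(2, -1, 0, 0)))
  ft <- extract_features(m, pca, n_time = 4)
  kinds <- vapply(ft$features, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "quadratic"), 2L)
  expect_equal(sum(kinds == "linear"), 0L)        # h is zero
  vals <- vapply(ft$features, `[[`, numeric(1), "eigenvalue")
  expect_equal(sort(vals), c(-1, 2))
  cls <- vapply(ft$features, `[[`, character(1), "sign_class")
  expect_equal(cls[vals == 2], "inhibitory")
  expect_equal(cls[vals == -1], "excitatory")
  expect_true(all(is.na(vapply(ft$features, function(f) f$significant,
                               logical(1)))))
  # feature maps are unit-norm and sign-fixed
  mp <- ft$features[[1]]$map
  expect_equal(sum(mp^2), 1)
  expect_gt(mp[which.max(abs(mp))], 0)
  # without a null, significant-only pooling yields an empty matrix
  expect_equal(ncol(feature_matrix(ft)), 0L)
})

test_that("feature recovery through the stimulus pipeline finds the planted map", {
  su <- scaled_setup()
  gt <- make_ground_truth(su$pca, list(gabor_map(center_t = 20, center_f = 14)),
                          eigenvalues = 1, a = log(1 / 0.3 - 1),
                          patches = su$X, target_sd = 2.5)
  ra <- simulate_event_raster(gt, su$X, n_trials = 20, seed = 5)
  ad <- align_simulated(ra, su)
  m <- fit_mne(ad)
  ev <- suppressWarnings(evaluate_mne(m, ad, n_shuffles = 8, seed = 3))
  ft <- extract_features(m, su$pca, ev$null_models)
  quads <- Filter(function(f) f$kind == "quadratic", ft$features)
  lead <- quads[[which.max(vapply(quads, function(q) abs(q$eigenvalue),
                                  numeric(1)))]]
  rec <- abs(cosine_similarity(flatten_map(lead$map), gt$feature_maps[, 1]))
  expect_gt(rec, 0.9)
  expect_equal(lead$sign_class, "inhibitory")
  expect_true(lead$significant)
})
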