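# Principal-angle quantification of the overlap between receptive-field
# feature subspaces, and of each against the retained stimulus subspace.

#' Orthonormal basis of a feature set
#'
#' Rank-revealing orthonormalization of the columns of a feature matrix via
#' the pivoted QR decomposition. Numerically dependent columns (relative
#' tolerance `tol` on the diagonal of R) are dropped, so the returned basis
#' has exactly the numerical rank of the input and spans the same space.
#'
#' @param features p x m numeric matrix, columns are flattened features.
#' @param label optional population name carried through comparisons.
#' @param tol relative rank tolerance (default 1e-10).
#' @return object of class `feature_subspace`: `features`, `basis`
#'   (p x r, orthonormal columns), `rank`, `label`.
#' @export
orthonormal_basis <- function(features, label = NULL, tol = 1e-10) {
  stopifnot(is.matrix(features))
  nz <- colSums(features^2) > 0
  if (!any(nz)) stop("all feature columns are zero", call. = FALSE)
  U <- features[, nz, drop = FALSE]
  qrd <- qr(U, LAPACK = TRUE)
  d <- abs(diag(qr.R(qrd)))
  r <- sum(d > tol * max(d))
  structure(
    list(features = features,
         basis = qr.Q(qrd)[, seq_len(r), drop = FALSE],
         rank = as.integer(r), label = label),
    class = "feature_subspace"
  )
}

#' @export
print.feature_subspace <- function(x, ...) {
  cat(sprintf("<feature_subspace> %s: rank %d in %d dimensions (%d features)\n",
              x$label %||% "unnamed", x$rank, nrow(x$basis),
              ncol(x$features)))
  invisible(x)
}

as_subspace <- function(x, label = NULL) {
  if (inherits(x, "feature_subspace")) return(x)
  orthonormal_basis(as.matrix(x), label = label)
}

#' Principal angles between two subspaces
#'
#' The k-th principal angle is the recursive maximum of the cosine between
#' unit vectors of the two subspaces, orthogonal to the previously chosen
#' directions. It is computed here from the singular values of
#' `t(Qa) %*% Qb` (cosines), supplemented by the sine-based formulation
#' (singular values of `Qb - Qa (t(Qa) Qb)`) for the small-angle half of
#' the spectrum, where the arc-cosine of a near-unit singular value loses
#' all precision. The combined estimate is accurate across the full
#' 0-90 degree range.
#'
#' @param A,B `feature_subspace` objects (or feature matrices, which are
#'   orthonormalized first) in the same ambient space.
#' @return object of class `principal_angle_result`: `angles_deg`
#'   (ascending, length `min(rank(A), rank(B))`, each in \[0, 90\]) and
#'   `pair`.
#' @export
principal_angles <- function(A, B) {
  A <- as_subspace(A, "A")
  B <- as_subspace(B, "B")
  if (nrow(A$basis) != nrow(B$basis)) {
    stop("subspaces live in different ambient dimensions", call. = FALSE)
  }
  Qa <- A$basis; Qb <- B$basis
  M <- crossprod(Qa, Qb)
  cosines <- pmin(pmax(svd(M)$d, 0), 1)            # descending
  k <- length(cosines)
  theta_cos <- acos(cosines)                        # ascending
  # Sine route: singular values of the component of Qb orthogonal to
  # span(Qa) are sin(theta_k); ascending after sorting.
  S <- Qb - Qa %*% M
  sines <- sort(pmin(pmax(svd(S)$d, 0), 1))
  sines <- sines[seq_len(k)]
  theta_sin <- asin(sines)
  theta <- ifelse(theta_cos < pi / 4, theta_sin, theta_cos)
  structure(
    list(angles_deg = sort(theta * 180 / pi),
         pair = c(A$label %||% "A", B$label %||% "B")),
    class = "principal_angle_result"
  )
}

#' @export
print.principal_angle_result <- function(x, ...) {
  cat(sprintf("<principal_angles> %s vs %s: %s deg\n",
              x$pair[1], x$pair[2],
              paste(sprintf("%.2f", x$angles_deg), collapse = ", ")))
  invisible(x)
}

#' Compare two feature populations and the full stimulus space
#'
#' Computes three principal-angle vectors: between the pooled feature
#' subspaces of the two populations, and between each population and the
#' retained stimulus subspace. The "full stimulus space" is the span of the
#' PCA basis vectors back-projected into the ambient (time x frequency)
#' space — the subspace the features live in by construction — following
#' the convention that the retained components stand in for the stimulus
#' ensemble.
#'
#' @param astro_features,neuro_features p x m feature matrices (columns are
#'   flattened maps), e.g. from [feature_matrix()]. An empty matrix skips
#'   that population's comparisons with a warning.
#' @param pca the `pca_reduction` whose basis defines the stimulus
#'   subspace; `NULL` skips the stimulus comparisons.
#' @param labels length-2 population labels.
#' @return named list of `principal_angle_result` (entries `astro_neuro`,
#'   `astro_stimulus`, `neuro_stimulus`; missing comparisons are `NULL`).
#' @export
compare_populations <- function(astro_features, neuro_features, pca = NULL,
                                labels = c("astro", "neuro")) {
  subs <- list(NULL, NULL)
  mats <- list(astro_features, neuro_features)
  for (i in 1:2) {
    if (is.null(mats[[i]]) || ncol(as.matrix(mats[[i]])) == 0) {
      warning("no features for population '", labels[i],
              "'; its comparisons are skipped", call. = FALSE)
    } else {
      subs[[i]] <- orthonormal_basis(as.matrix(mats[[i]]), label = labels[i])
    }
  }
  stim <- if (!is.null(pca)) {
    structure(list(features = pca$basis, basis = pca$basis,
                   rank = ncol(pca$basis), label = "stimulus"),
              class = "feature_subspace")
  }
  out <- list(astro_neuro = NULL, astro_stimulus = NULL,
              neuro_stimulus = NULL)
  if (!is.null(subs[[1]]) && !is.null(subs[[2]])) {
    out$astro_neuro <- principal_angles(subs[[1]], subs[[2]])
  }
  if (!is.null(subs[[1]]) && !is.null(stim)) {
    out$astro_stimulus <- principal_angles(subs[[1]], stim)
  }
  if (!is.null(subs[[2]]) && !is.null(stim)) {
    out$neuro_stimulus <- principal_angles(subs[[2]], stim)
  }
  out
}
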