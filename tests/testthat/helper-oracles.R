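# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Central finite differences of the MNE objective.
fd_gradient <- function(par, X, y, ridge = 0, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (mne_nll_grad(up, X, y, ridge)$value -
       mne_nll_grad(dn, X, y, ridge)$value) / (2 * h)
  }, numeric(1))
}

# Basis of span(Q) orthogonal to the unit vector u (SVD used only for the
# complement bookkeeping; the angle search itself is direct maximization).
deflate_subspace <- function(Q, u) {
  P <- Q - u %*% crossprod(u, Q)
  sv <- svd(P)
  sv$u[, sv$d > 1e-10, drop = FALSE]
}

# Principal angles by the literal recursive definition: at each step,
# numerically maximize the cosine between unit vectors of the two
# subspaces orthogonal to all previously selected directions.
brute_force_angles <- function(Qa, Qb, n_restarts = 40) {
  k <- min(ncol(Qa), ncol(Qb))
  angles <- numeric(k)
  for (step in seq_len(k)) {
    M <- crossprod(Qa, Qb)
    ra <- ncol(Qa)
    obj <- function(par) {
      al <- par[seq_len(ra)]; be <- par[-seq_len(ra)]
      na <- sqrt(sum(al^2)); nb <- sqrt(sum(be^2))
      if (na < 1e-12 || nb < 1e-12) return(0)
      -abs(sum(al * (M %*% be)) / (na * nb))
    }
    best <- 0; best_par <- NULL
    for (r in seq_len(n_restarts)) {
      o <- stats::optim(stats::rnorm(ra + ncol(Qb)), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
      if (o$value < best) { best <- o$value; best_par <- o$par }
    }
    angles[step] <- acos(min(max(-best, 0), 1)) * 180 / pi
    if (step < k) {
      al <- best_par[seq_len(ra)]; be <- best_par[-seq_len(ra)]
      u <- Qa %*% al; u <- u / sqrt(sum(u^2))
      v <- Qb %*% be; v <- v / sqrt(sum(v^2))
      Qa <- deflate_subspace(Qa, u)
      Qb <- deflate_subspace(Qb, v)
    }
  }
  sort(angles)
}

# Mean silhouette of a labelled 2-D point set (direct definition).
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}
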