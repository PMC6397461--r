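# Video-wide aggregation of frame-pair dynamic features by compact encoding:
# Fisher vector under a diagonal GMM, VLAD-k under a k-means codebook, and
# higher-order VLAD (first/second/third-order residuals per visual word),
# with signed-square-root, intra- and l2 normalizations and optional
# temporal pyramid pooling.

#' Fit a PCA projection
#'
#' Mean-centred orthonormal projection to `d` dimensions (no scaling), for
#' optional pre-processing of frame-pair features before codebook learning.
#'
#' @param x training feature matrix (rows = observations).
#' @param d target dimension, `d <= ncol(x)`.
#' @return list of class `pca_projection` with `mean`, `rotation` and `d`.
#' @export
fit_pca <- function(x, d) {
  x <- as.matrix(x)
  if (d > ncol(x)) stop("d must not exceed the feature dimension")
  if (nrow(x) < d + 1) stop("need at least d + 1 training vectors")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(mean = pc$center,
                 rotation = pc$rotation[, seq_len(d), drop = FALSE],
                 sdev = pc$sdev, d = as.integer(d)),
            class = "pca_projection")
}

#' @rdname fit_pca
#' @param pca a fitted `pca_projection`.
#' @export
project_pca <- function(pca, x) {
  sweep(as.matrix(x), 2, pca$mean) %*% pca$rotation
}

# log density of each row of x under each diagonal Gaussian component
gmm_log_density <- function(x, means, vars) {
  K <- nrow(means); n <- nrow(x)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    z <- sweep(x, 2, means[k, ])
    out[, k] <- -0.5 * (sum(log(2 * pi * vars[k, ])) +
                          rowSums(sweep(z^2, 2, vars[k, ], "/")))
  }
  out
}

#' Fit a diagonal-covariance Gaussian mixture codebook
#'
#' EM with k-means initialization under a fixed seed. Component variances
#' are shrunk toward the global per-dimension variance with `tau` pseudo-
#' observations (a normal-inverse-gamma MAP update): without shrinkage, a
#' component that captures a nearly constant feature dimension gets a
#' near-zero variance, and the Fisher-vector standardization then amplifies
#' that dimension's noise until it dominates the encoding. A hard floor of
#' `1e-6` of the global variance remains as a last guard. The log-likelihood
#' trace is non-decreasing.
#'
#' @param x training feature matrix (`N x D`), `N >= K`.
#' @param K number of mixture components.
#' @param seed integer seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule.
#' @param tau pseudo-observations of the global variance per component.
#' @return object of class `gmm_codebook`: `K`, `weights`, `means` (`K x D`),
#'   `variances` (`K x D`), and `loglik`, the trace of the (shrinkage-
#'   penalized) log-likelihood maximized by the EM iterations.
#' @export
fit_gmm <- function(x, K, seed = 1L, max_iter = 100L, tol = 1e-8, tau = 1) {
  x <- as.matrix(x)
  N <- nrow(x); D <- ncol(x)
  if (K > N) stop("K must not exceed the number of training vectors")
  gvar <- apply(x, 2, stats::var)
  gvar[!is.finite(gvar) | gvar <= 0] <- 1
  floor_var <- 1e-6 * gvar
  km <- with_seed(seed, stats::kmeans(x, centers = K, nstart = 5, iter.max = 50))
  means <- km$centers
  weights <- pmax(tabulate(km$cluster, K), 1) / sum(pmax(tabulate(km$cluster, K), 1))
  vars <- t(vapply(seq_len(K), function(k) {
    pts <- x[km$cluster == k, , drop = FALSE]
    v <- if (nrow(pts) > 1) apply(pts, 2, stats::var) else gvar
    pmax((nrow(pts) * v + tau * gvar) / (nrow(pts) + tau), floor_var)
  }, numeric(D)))
  # shrinkage penalty, maximized when every variance equals the global one;
  # the EM objective (log-likelihood + penalty) is non-decreasing
  penalty <- function(v) {
    -0.5 * tau * sum(sweep(log(v), 2, log(gvar)) +
                       sweep(1 / v, 2, gvar, "*") - 1)
  }
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- sweep(gmm_log_density(x, means, vars), 2, log(weights), "+")
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse) + penalty(vars)
    loglik <- c(loglik, ll)
    if (it > 1 && ll - loglik[it - 1] < tol * abs(ll)) break
    q <- exp(lp - lse)
    nk <- colSums(q)
    nk <- pmax(nk, 1e-12)
    weights <- nk / N
    means <- sweep(t(q) %*% x, 1, nk, "/")
    for (k in seq_len(K)) {
      z <- sweep(x, 2, means[k, ])
      vars[k, ] <- pmax((colSums(q[, k] * z^2) + tau * gvar) / (nk[k] + tau),
                        floor_var)
    }
  }
  structure(list(K = as.integer(K), weights = as.numeric(weights),
                 means = unname(as.matrix(means)),
                 variances = unname(as.matrix(vars)),
                 loglik = loglik),
            class = "gmm_codebook")
}

#' Posterior responsibilities under a GMM codebook
#'
#' @param gmm `gmm_codebook`.
#' @param x feature matrix.
#' @return `N x K` matrix of soft assignments (rows sum to 1).
#' @export
gmm_posterior <- function(gmm, x) {
  lp <- sweep(gmm_log_density(as.matrix(x), gmm$means, gmm$variances),
              2, log(gmm$weights), "+")
  mx <- apply(lp, 1, max)
  exp(lp - (mx + log(rowSums(exp(lp - mx)))))
}

#' Fit a k-means codebook with per-word training statistics
#'
#' Learns `K` visual words by k-means and records, for the training vectors
#' assigned to each word, the mean, the (biased) per-dimension standard
#' deviation, and the (biased) per-dimension skewness used as reference
#' statistics by the higher-order VLAD encoding.
#'
#' @param x training feature matrix.
#' @param K number of visual words.
#' @param seed integer seed.
#' @return object of class `kmeans_codebook`: `K`, `centers`, `mu`, `sigma`,
#'   `gamma` (`K x D` each), `sizes`.
#' @export
fit_kmeans_codebook <- function(x, K, seed = 1L) {
  x <- as.matrix(x)
  if (K > nrow(x)) stop("K must not exceed the number of training vectors")
  km <- with_seed(seed, stats::kmeans(x, centers = K, nstart = 5, iter.max = 50))
  D <- ncol(x)
  mu <- matrix(0, K, D); sg <- matrix(0, K, D); gm <- matrix(0, K, D)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    pts <- x[km$cluster == k, , drop = FALSE]
    sizes[k] <- nrow(pts)
    if (nrow(pts) == 0) next
    mu[k, ] <- colMeans(pts)
    z <- sweep(pts, 2, mu[k, ])
    m2 <- colMeans(z^2)
    sg[k, ] <- sqrt(m2)
    m3 <- colMeans(z^3)
    ok <- m2 > 0 & nrow(pts) > 2
    gm[k, ok] <- m3[ok] / m2[ok]^1.5
  }
  structure(list(K = as.integer(K), centers = unname(as.matrix(km$centers)),
                 mu = mu, sigma = sg, gamma = gm, sizes = sizes),
            class = "kmeans_codebook")
}

finalize_encoding <- function(v, scheme, tpp = FALSE) {
  structure(v, scheme = scheme, tpp = tpp,
            zero_encoding = all(v == 0))
}

#' Fisher vector encoding of a feature sequence
#'
#' For a diagonal GMM with parameters `(mu_k, sigma_k, pi_k)` and soft
#' assignments `q_ki`, concatenates per component the first-order residual
#' `u_k = 1/(N sqrt(pi_k)) * sum_i q_ki (x_i - mu_k)/sigma_k` and the
#' second-order residual
#' `v_k = 1/(N sqrt(2 pi_k)) * sum_i q_ki [((x_i - mu_k)/sigma_k)^2 - 1]`
#' in the order `(u_1, v_1, ..., u_K, v_K)`, then applies signed-square-root
#' power normalization and global l2 normalization. Length `2 D K`.
#'
#' @param x feature sequence matrix (`N x D`, rows in temporal order).
#' @param gmm `gmm_codebook`.
#' @return encoded numeric vector with attributes `scheme` and
#'   `zero_encoding`.
#' @export
encode_fv <- function(x, gmm) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty feature sequence")
  N <- nrow(x); D <- ncol(x); K <- gmm$K
  q <- gmm_posterior(gmm, x)
  out <- numeric(2 * D * K)
  for (k in seq_len(K)) {
    z <- sweep(sweep(x, 2, gmm$means[k, ]), 2, sqrt(gmm$variances[k, ]), "/")
    u <- colSums(q[, k] * z) / (N * sqrt(gmm$weights[k]))
    v <- colSums(q[, k] * (z^2 - 1)) / (N * sqrt(2 * gmm$weights[k]))
    out[(2 * (k - 1) * D) + seq_len(D)] <- u
    out[(2 * (k - 1) * D + D) + seq_len(D)] <- v
  }
  finalize_encoding(l2_normalize(ssr(out)), "fv")
}

#' VLAD-k encoding of a feature sequence
#'
#' Each feature contributes its residual `x_i - c_k` to its `k_nn` nearest
#' centers. Per-word blocks are intra-l2-normalized, then signed-square-root
#' and global l2 normalization are applied. Length `D K`. An all-zero
#' accumulation (every feature exactly on its centers) is returned
#' unnormalized and flagged via the `zero_encoding` attribute.
#'
#' @param x feature sequence matrix.
#' @param codebook `kmeans_codebook`.
#' @param k_nn number of nearest centers each feature contributes to.
#' @return encoded numeric vector.
#' @export
encode_vlad <- function(x, codebook, k_nn = 5L) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty feature sequence")
  K <- codebook$K
  if (k_nn < 1 || k_nn > K) stop("k_nn must be in 1..K")
  D <- ncol(x)
  d2 <- outer(rowSums(x^2), rep(1, K)) - 2 * x %*% t(codebook$centers) +
    outer(rep(1, nrow(x)), rowSums(codebook$centers^2))
  blocks <- matrix(0, K, D)
  for (i in seq_len(nrow(x))) {
    nn <- order(d2[i, ])[seq_len(k_nn)]
    for (k in nn) blocks[k, ] <- blocks[k, ] + (x[i, ] - codebook$centers[k, ])
  }
  for (k in seq_len(K)) blocks[k, ] <- l2_normalize(blocks[k, ])
  finalize_encoding(l2_normalize(ssr(as.vector(t(blocks)))), "vlad")
}

#' Higher-order VLAD encoding of a feature sequence
#'
#' Features are hard-assigned to their nearest visual word. Word `k` with
#' `N_k` assigned features of mean `m_k` contributes the first-order residual
#' `u_k = N_k (m_k - mu_k)`, the second-order residual
#' `v_k = 1/N_k sum (x_i - m_k)^2 - sigma_k^2`, and the third-order residual
#' `s_k = skewness - gamma_k` (set to 0 when `N_k <= 2` or the variance is
#' zero), against the codebook's training statistics. Blocks are ordered
#' `(u_1, v_1, s_1, ..., u_K, v_K, s_K)`; empty words contribute zero
#' blocks. Intra-, power- and global l2 normalization as for VLAD. Length
#' `3 D K`.
#'
#' @param x feature sequence matrix.
#' @param codebook `kmeans_codebook` (with `mu`, `sigma`, `gamma`).
#' @return encoded numeric vector.
#' @export
encode_hvlad <- function(x, codebook) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty feature sequence")
  K <- codebook$K; D <- ncol(x)
  d2 <- outer(rowSums(x^2), rep(1, K)) - 2 * x %*% t(codebook$centers) +
    outer(rep(1, nrow(x)), rowSums(codebook$centers^2))
  assign <- max.col(-d2, ties.method = "first")
  out <- numeric(3 * K * D)
  for (k in seq_len(K)) {
    pts <- x[assign == k, , drop = FALSE]
    nk <- nrow(pts)
    u <- numeric(D); v <- numeric(D); s <- numeric(D)
    if (nk > 0) {
      mk <- colMeans(pts)
      u <- nk * (mk - codebook$mu[k, ])
      z <- sweep(pts, 2, mk)
      m2 <- colMeans(z^2)
      v <- m2 - codebook$sigma[k, ]^2
      if (nk > 2) {
        m3 <- colMeans(z^3)
        ok <- m2 > 0
        s[ok] <- m3[ok] / m2[ok]^1.5 - codebook$gamma[k, ok]
      }
    }
    base <- 3 * (k - 1) * D
    out[base + seq_len(D)] <- l2_normalize(u)
    out[base + D + seq_len(D)] <- l2_normalize(v)
    out[base + 2 * D + seq_len(D)] <- l2_normalize(s)
  }
  finalize_encoding(l2_normalize(ssr(out)), "hvlad")
}

#' Encode a feature sequence with a chosen scheme
#'
#' Dispatcher over [encode_fv()], [encode_vlad()] and [encode_hvlad()], with
#' optional PCA projection and temporal pyramid pooling.
#'
#' @param x feature sequence matrix (rows in temporal order).
#' @param codebook `gmm_codebook` (fv) or `kmeans_codebook` (vlad, hvlad).
#' @param scheme one of `"fv"`, `"vlad"`, `"hvlad"`.
#' @param k_nn VLAD-k neighborhood size.
#' @param tpp apply temporal pyramid pooling.
#' @param pca optional `pca_projection` applied to `x` first.
#' @return encoded numeric vector.
#' @export
encode_video <- function(x, codebook, scheme = c("fv", "vlad", "hvlad"),
                         k_nn = 5L, tpp = FALSE, pca = NULL) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  if (!is.null(pca)) x <- project_pca(pca, x)
  enc <- switch(scheme,
                fv = function(z) encode_fv(z, codebook),
                vlad = function(z) encode_vlad(z, codebook, k_nn),
                hvlad = function(z) encode_hvlad(z, codebook))
  if (!tpp) return(enc(x))
  tpp_encode(x, enc)
}

#' Temporal pyramid pooling windows
#'
#' Contiguous near-equal partitions of `1..N` into `j` windows; when `N` is
#' not divisible by `j` the earlier windows receive the extra frames.
#'
#' @param N sequence length.
#' @param j number of windows.
#' @return list of index vectors.
#' @export
tpp_windows <- function(N, j) {
  sizes <- rep(N %/% j, j)
  extra <- N %% j
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-j] + 1L)
  Map(seq, starts, ends)
}

#' Temporal pyramid pooling of a feature sequence
#'
#' Encodes the whole sequence, its two halves and its three thirds
#' (contiguous near-equal windows) and concatenates the six encodings; the
#' concatenation is l2-normalized. Requires `N >= 3` so every level-3 window
#' is nonempty.
#'
#' @param x feature sequence matrix.
#' @param encoder function mapping a feature matrix to an encoding vector.
#' @return concatenated encoding (6x the single-encoding length).
#' @export
tpp_encode <- function(x, encoder) {
  N <- nrow(x)
  if (N < 3) stop("temporal pyramid pooling needs at least N = 3 feature rows")
  wins <- c(tpp_windows(N, 1L), tpp_windows(N, 2L), tpp_windows(N, 3L))
  parts <- lapply(wins, function(idx) as.numeric(encoder(x[idx, , drop = FALSE])))
  finalize_encoding(l2_normalize(unlist(parts)), "tpp", tpp = TRUE)
}

#' Serialize a codebook to JSON
#'
#' @param codebook `gmm_codebook` or `kmeans_codebook`.
#' @param path output path.
#' @return `read_codebook` returns the codebook object.
#' @export
write_codebook <- function(codebook, path) {
  kind <- class(codebook)[1]
  obj <- c(list(kind = kind), unclass(codebook))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  for (f in c("means", "variances", "centers", "mu", "sigma", "gamma")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  }
  structure(obj, class = kind)
}
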