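test_that("PCA projections are lossless at full rank and exact on planar data", {
  set.seed(1)
  x <- matrix(rnorm(200), 40, 5)
  p <- fit_pca(x, 5)
  rec <- project_pca(p, x) %*% t(p$rotation)
  rec <- sweep(rec, 2, -p$mean)
  expect_lt(max(abs(rec - x)), 1e-9)

  basis <- matrix(rnorm(10), 5, 2)
  planar <- matrix(rnorm(60), 30, 2) %*% t(basis)
  p2 <- fit_pca(planar, 2)
  rec2 <- sweep(project_pca(p2, planar) %*% t(p2$rotation), 2, -p2$mean)
  expect_lt(max(abs(rec2 - planar)), 1e-9)
  expect_true(all(diff(p2$sdev) <= 1e-12))
  expect_error(fit_pca(x, 6), "exceed")
  expect_error(fit_pca(x[1:3, ], 5), "at least")
})

test_that("GMM fitting recovers separated components deterministically", {
  set.seed(2)
  x <- rbind(matrix(rnorm(300, 0, 0.5), 150, 2),
             matrix(rnorm(300, 8, 0.5), 150, 2))
  g <- fit_gmm(x, 2, seed = 5)
  expect_equal(sum(g$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(g$loglik) >= -1e-6))
  mu_sorted <- g$means[order(g$means[, 1]), ]
  expect_lt(max(abs(mu_sorted[1, ] - 0)), 3 * 0.5 / sqrt(150))
  expect_lt(max(abs(mu_sorted[2, ] - 8)), 3 * 0.5 / sqrt(150))
  expect_identical(fit_gmm(x, 2, seed = 5), g)
  expect_error(fit_gmm(x[1:3, ], 5), "exceed")
  # posteriors are proper responsibilities
  q <- gmm_posterior(g, x)
  expect_equal(rowSums(q), rep(1, 300), tolerance = 1e-9)
})

test_that("GMM log-likelihood is competitive with an independent EM fit", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
             matrix(rnorm(200, 4, 1.5), 100, 2))
  g <- fit_gmm(x, 2, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  # plain (unpenalized) log-likelihood of the fitted parameters
  lp <- sweep(cellvfa:::gmm_log_density(x, g$means, g$variances), 2,
              log(g$weights), "+")
  mx <- apply(lp, 1, max)
  ll <- sum(mx + log(rowSums(exp(lp - mx))))
  expect_gt(ll, mc$loglik - abs(mc$loglik) * 0.01)
})

test_that("Fisher vector matches its closed form and literal evaluation", {
  D <- 3
  gmm <- make_gmm(1, matrix(2, 1, D), matrix(1.5, 1, D))
  x <- matrix(2, 5, D)  # every vector at the mean
  enc <- encode_fv(x, gmm)
  expect_length(enc, 2 * D)
  expect_true(all(enc[1:D] == 0))
  expect_equal(unname(enc[(D + 1):(2 * D)]), rep(-1 / sqrt(D), D),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(enc^2)), 1, tolerance = 1e-12)

  set.seed(4)
  for (trial in 1:20) {
    K <- sample(1:3, 1); D <- sample(2:4, 1); N <- sample(2:6, 1)
    w <- runif(K); w <- w / sum(w)
    gmm <- make_gmm(w, matrix(rnorm(K * D), K, D),
                    matrix(runif(K * D, 0.5, 2), K, D))
    x <- matrix(rnorm(N * D), N, D)
    expect_equal(unname(as.numeric(encode_fv(x, gmm))), literal_fv(x, gmm),
                 tolerance = 1e-9)
  }
  expect_error(encode_fv(matrix(numeric(0), 0, 2), gmm), "empty")
})

test_that("VLAD accumulates residuals to nearest centers", {
  cb <- structure(list(K = 2L, centers = matrix(c(0, 10), 2, 1),
                       mu = matrix(c(0, 10), 2, 1), sigma = matrix(1, 2, 1),
                       gamma = matrix(0, 2, 1), sizes = c(1L, 1L)),
                  class = "kmeans_codebook")
  x <- matrix(c(1, 9), 2, 1)
  enc <- encode_vlad(x, cb, k_nn = 1)
  # pre-normalization blocks (1, -1); intra + SSR + l2 keep signs and symmetry
  expect_equal(unname(as.numeric(enc)), c(1, -1) / sqrt(2), tolerance = 1e-12)

  # every point on a center: zero encoding, flagged, left unnormalized
  enc0 <- encode_vlad(matrix(c(0, 10), 2, 1), cb, k_nn = 1)
  expect_true(all(enc0 == 0))
  expect_true(attr(enc0, "zero_encoding"))
  expect_error(encode_vlad(x, cb, k_nn = 3), "1..K")

  set.seed(5)
  K <- 4; D <- 3
  cb2 <- fit_kmeans_codebook(matrix(rnorm(200 * D), 200, D), K, seed = 2)
  x <- matrix(rnorm(100 * D), 100, D)
  # brute-force nearest-center accumulation
  blocks <- matrix(0, K, D)
  for (i in seq_len(100)) {
    dd <- colSums((t(cb2$centers) - x[i, ])^2)
    k <- which.min(dd)
    blocks[k, ] <- blocks[k, ] + (x[i, ] - cb2$centers[k, ])
  }
  for (k in seq_len(K)) {
    nb <- sqrt(sum(blocks[k, ]^2)); if (nb > 0) blocks[k, ] <- blocks[k, ] / nb
  }
  ref <- as.vector(t(blocks)); ref <- sign(ref) * sqrt(abs(ref))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(unname(as.numeric(encode_vlad(x, cb2, k_nn = 1))), ref,
               tolerance = 1e-9)
})

test_that("higher-order VLAD residuals vanish on matched statistics", {
  # codebook word statistics computed from a symmetric two-point set
  cb <- structure(list(K = 1L, centers = matrix(0, 1, 2),
                       mu = matrix(0, 1, 2), sigma = matrix(1, 1, 2),
                       gamma = matrix(0, 1, 2), sizes = 2L),
                  class = "kmeans_codebook")
  x <- rbind(c(1, 1), c(-1, -1))  # mean 0, biased sd 1, skewness 0
  enc <- encode_hvlad(x, cb)
  expect_length(enc, 3 * 2)
  expect_true(all(enc == 0))

  # single descriptor: u = x - mu, v = -sigma^2, s = 0
  x1 <- matrix(c(2, 3), 1, 2)
  e1 <- encode_hvlad(x1, cb)
  u <- c(2, 3); v <- c(-1, -1); s <- c(0, 0)
  raw <- c(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)), s)
  raw <- sign(raw) * sqrt(abs(raw)); raw <- raw / sqrt(sum(raw^2))
  expect_equal(unname(as.numeric(e1)), raw, tolerance = 1e-12)
})

test_that("encodings have unit norm and the documented dimensions", {
  set.seed(6)
  D <- 4
  xtr <- matrix(rnorm(300 * D), 300, D)
  x <- matrix(rnorm(30 * D), 30, D)
  gmm <- fit_gmm(xtr, 3, seed = 1)
  cb <- fit_kmeans_codebook(xtr, 3, seed = 1)
  for (enc in list(encode_fv(x, gmm), encode_vlad(x, cb, 2), encode_hvlad(x, cb))) {
    expect_equal(sqrt(sum(enc^2)), 1, tolerance = 1e-9)
  }
  expect_length(encode_fv(x, gmm), 2 * D * 3)
  expect_length(encode_vlad(x, cb, 2), D * 3)
  expect_length(encode_hvlad(x, cb), 3 * D * 3)
})

test_that("temporal pyramid pooling partitions windows deterministically", {
  expect_equal(tpp_windows(6, 1), list(1:6))
  expect_equal(tpp_windows(6, 2), list(1:3, 4:6))
  expect_equal(tpp_windows(6, 3), list(1:2, 3:4, 5:6))
  expect_equal(tpp_windows(7, 3), list(1:3, 4:5, 6:7))  # earlier windows get extras
  set.seed(7)
  x <- matrix(rnorm(6 * 3), 6, 3)
  gmm <- fit_gmm(matrix(rnorm(150), 50, 3), 2, seed = 1)
  enc <- tpp_encode(x, function(z) encode_fv(z, gmm))
  expect_length(enc, 6 * 2 * 3 * 2)
  expect_equal(sqrt(sum(enc^2)), 1, tolerance = 1e-9)
  # constant sequence: all six blocks identical before the final normalization
  xc <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  encc <- tpp_encode(xc, function(z) encode_fv(z, gmm))
  m <- matrix(encc, ncol = 6)
  expect_lt(max(abs(m - m[, 1])), 1e-12)
  expect_error(tpp_encode(x[1:2, , drop = FALSE], function(z) encode_fv(z, gmm)),
               "N = 3")
})

test_that("pooled encodings ignore temporal order without TPP but not with it", {
  set.seed(8)
  x <- matrix(rnorm(9 * 3), 9, 3)
  perm <- sample(9)
  xtr <- matrix(rnorm(150), 50, 3)
  gmm <- fit_gmm(xtr, 2, seed = 1)
  cb <- fit_kmeans_codebook(xtr, 2, seed = 1)
  expect_equal(encode_fv(x, gmm), encode_fv(x[perm, ], gmm), tolerance = 1e-12)
  expect_equal(encode_vlad(x, cb, 1), encode_vlad(x[perm, ], cb, 1),
               tolerance = 1e-12)
  expect_equal(encode_hvlad(x, cb), encode_hvlad(x[perm, ], cb), tolerance = 1e-12)
  t1 <- tpp_encode(x, function(z) encode_fv(z, gmm))
  t2 <- tpp_encode(x[perm, ], function(z) encode_fv(z, gmm))
  expect_gt(max(abs(t1 - t2)), 1e-6)
})

test_that("codebooks round-trip through JSON", {
  set.seed(9)
  xtr <- matrix(rnorm(120), 40, 3)
  g <- fit_gmm(xtr, 2, seed = 1)
  k <- fit_kmeans_codebook(xtr, 2, seed = 1)
  pg <- withr::local_tempfile(fileext = ".json")
  pk <- withr::local_tempfile(fileext = ".json")
  write_codebook(g, pg); write_codebook(k, pk)
  g2 <- read_codebook(pg); k2 <- read_codebook(pk)
  expect_s3_class(g2, "gmm_codebook")
  expect_equal(g2$means, g$means, tolerance = 1e-12)
  expect_equal(g2$weights, g$weights, tolerance = 1e-12)
  expect_s3_class(k2, "kmeans_codebook")
  expect_equal(k2$centers, k$centers, tolerance = 1e-12)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(as.numeric(encode_fv(x, g2)), as.numeric(encode_fv(x, g)),
               tolerance = 1e-12)
})
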