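test_that("contour resampling places points at equal arc length with canonical start", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ps <- resample_contour(sq, 4)
  # start vertex is the one with the smallest centroid angle: (1, 1) at 45 deg
  expect_equal(ps[1, ], c(1, 1), ignore_attr = TRUE)
  # arc positions 0, 1, 2, 3 along the perimeter from the start vertex
  expect_equal(unname(ps), rbind(c(1, 1), c(0, 1), c(0, 0), c(1, 0)))

  set.seed(1)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  blob <- cbind(5 + 3 * (1 + 0.1 * cos(3 * th)) * cos(th),
                5 + 3 * (1 + 0.1 * cos(3 * th)) * sin(th))
  ps2 <- resample_contour(blob, 50)
  gaps <- sqrt(rowSums((ps2[c(2:50, 1), ] - ps2)^2))
  # equal arc gaps imply near-equal chord gaps on a smooth convex outline
  expect_lt(diff(range(gaps)) / mean(gaps), 0.05)

  th2 <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(10 * cos(th2), 10 * sin(th2))
  ps3 <- resample_contour(circ, 100)
  expect_lt(max(abs(sqrt(rowSums(ps3^2)) - 10)), 1e-3)
  expect_error(resample_contour(rbind(c(0, 0), c(0, 0), c(0, 0)), 10),
               "degenerate|at least 3")
})

test_that("shape contexts count all neighbors, are scale invariant, and bin by angle", {
  set.seed(2)
  # jittered ring: the max/mean pairwise distance ratio stays below the outer
  # radial edge (2x the mean), so no point is dropped from any histogram
  ang <- sort(runif(15, 0, 2 * pi))
  rad <- 1 + runif(15, -0.05, 0.05)
  pts <- cbind(rad * cos(ang), rad * sin(ang))
  H <- shape_context(pts)
  expect_true(all(rowSums(H) == 14))
  expect_identical(unname(c(shape_context(pts * 7.3))), unname(c(H)))

  coll <- rbind(c(0, 0), c(1, 0), c(2, 0))
  Hc <- shape_context(coll)
  # from (0, 0) both other points lie at angle 0: a single angular column
  h1 <- matrix(Hc[1, ], nrow = 5)
  expect_equal(sum(h1), 2)
  expect_equal(sum(h1[, 1]), 2)  # angular bin containing 0 rad
})

test_that("chi-squared cost matches direct evaluation and is symmetric", {
  h <- c(3, 1, 0, 2)
  expect_equal(chi2_cost(h, h), 0)
  expect_equal(chi2_cost(c(2, 0), c(0, 2)), 2.0)
  set.seed(3)
  a <- rpois(10, 3); b <- rpois(10, 3)
  expect_equal(chi2_cost(a, b), chi2_cost(b, a))
  expect_error(chi2_cost(1:3, 1:4), "mismatch")
  # matrix form agrees with scalar form
  A <- rbind(a, b); B <- rbind(b, a, a)
  C <- chi2_cost_matrix(A, B)
  expect_equal(C[1, 2], 0)
  expect_equal(C[1, 1], chi2_cost(a, b))
})

test_that("hungarian matching equals exhaustive search", {
  m <- hungarian(matrix(c(1, 2, 2, 1), 2, 2))
  expect_identical(m$permutation, 1:2)
  expect_equal(m$total_cost, 2)
  d <- diag(0, 4); d[d == 0] <- 5; diag(d) <- 0
  expect_identical(hungarian(d)$permutation, 1:4)
  expect_error(hungarian(matrix(1, 2, 3)), "square")
  set.seed(4)
  for (trial in 1:100) {
    n <- sample(2:7, 1)
    C <- matrix(runif(n * n), n, n)
    expect_equal(hungarian(C)$total_cost, brute_force_assignment(C),
                 tolerance = 1e-12)
  }
})

test_that("TPS recovers affine maps exactly and interpolates with zero regularization", {
  set.seed(5)
  src <- cbind(runif(12), runif(12))
  tid <- fit_tps(src, src, 0)
  expect_lt(max(abs(apply_tps(tid, src) - src)), 1e-8)
  expect_lt(max(abs(tid$weights)), 1e-8)

  tgt <- sweep(src, 2, c(5, -2), "+")
  ttr <- fit_tps(src, tgt, 0)
  probe <- cbind(runif(20, -3, 3), runif(20, -3, 3))
  expect_lt(max(abs(apply_tps(ttr, probe) - sweep(probe, 2, c(5, -2), "+"))), 1e-6)

  warp_tgt <- src + 0.3 * cbind(sin(src[, 2] * 3), cos(src[, 1] * 2))
  tw <- fit_tps(src, warp_tgt, 0)
  expect_lt(max(abs(apply_tps(tw, src) - warp_tgt)), 1e-8)
  # side conditions: warp coefficients orthogonal to (1, x, y)
  expect_lt(max(abs(t(cbind(1, src)) %*% tw$weights)), 1e-8)

  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_tps(coll, coll + 1, 0), "singular")
})

test_that("shape distance is the symmetric mean of minimal context costs", {
  set.seed(6)
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  P <- cbind(cos(th), sin(th)) * (1 + 0.2 * runif(10))
  Q <- cbind(cos(th + 0.3), sin(th + 0.3)) * (1 + 0.2 * runif(10))
  expect_equal(shape_distance(P, P), 0)
  d <- shape_distance(P, Q)
  expect_gte(d, 0)
  C <- chi2_cost_matrix(shape_context(P), shape_context(Q))
  brute <- mean(apply(C, 1, min)) + mean(apply(C, 2, min))
  expect_equal(d, brute, tolerance = 1e-12)
})

test_that("deformation feature is zero for identical contours and near-zero under scaling", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- cbind(10 + 5 * cos(th), 10 + 5 * sin(th))
  expect_identical(unname(contour_deformation_feature(circ, circ, n = 40, L = 4)),
                   rep(0, 4))
  dil <- cbind(10 + 10 * cos(th), 10 + 10 * sin(th))
  expect_true(all(contour_deformation_feature(circ, dil, n = 40, L = 3) < 1e-3))
})

test_that("deformation feature is invariant to joint translation and scaling", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  c1 <- cbind(10 + 5 * (1 + 0.2 * cos(3 * th)) * cos(th),
              10 + 5 * (1 + 0.2 * cos(3 * th)) * sin(th))
  c2 <- cbind(10 + 5 * (1 + 0.15 * cos(2 * th + 1)) * cos(th),
              10 + 5 * (1 + 0.15 * cos(2 * th + 1)) * sin(th))
  fA <- contour_deformation_feature(c1, c2, n = 40, L = 3)
  fB <- contour_deformation_feature(c1 * 3.7 + 100, c2 * 3.7 + 100, n = 40, L = 3)
  expect_lt(max(abs(fA - fB)), 1e-6)
  fC <- contour_deformation_feature(sweep(c1, 2, c(40, -7), "+"),
                                    sweep(c2, 2, c(40, -7), "+"), n = 40, L = 3)
  expect_lt(max(abs(fA - fC)), 1e-6)
  expect_true(all(fA >= 0))
})
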