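test_that("dense SIFT handles constant images, intensity offsets, and size limits", {
  expect_error(dense_sift(matrix(0, 10, 20)), "16")
  s <- dense_sift(matrix(77, 24, 24))
  expect_true(all(s$desc == 0))
  img <- textured_image(24, 1)
  expect_lt(max(abs(dense_sift(img)$desc - dense_sift(img + 50)$desc)), 1e-9)
  expect_equal(ncol(dense_sift(img)$desc), 128L)
})

test_that("dense SIFT descriptors are translation equivariant in the interior", {
  img <- textured_image(32, 2)
  img2 <- shift_img(img, 8, 0)
  sA <- dense_sift(img); sB <- dense_sift(img2)
  idx <- function(y, x) y + (x - 1) * 32
  for (y in seq(11, 22, by = 3)) for (x in seq(11, 16, by = 2)) {
    expect_lt(max(abs(sA$desc[idx(y, x), ] - sB$desc[idx(y, x + 8), ])), 1e-9)
  }
})

test_that("flow energy matches closed forms and a literal loop evaluation", {
  s <- random_sift_image(6, 6, d = 8, seed = 3)
  z <- matrix(0, 6, 6)
  p <- flow_params(t = 5, d = 3, eta = 0.1, alpha = 0.7)
  expect_equal(flow_energy(s, s, list(u = z, v = z), p), 0)

  # constant field (1, 0) between identical images: eta per pixel plus the
  # self-shift data term; smoothness vanishes
  u1 <- z + 1
  e <- flow_energy(s, s, list(u = u1, v = z), p)
  dat <- 0
  for (x in 1:5) for (y in 1:6) {
    dat <- dat + min(sum(abs(s$desc[y + (x - 1) * 6, ] - s$desc[y + x * 6, ])), p$t)
  }
  dat <- dat + 6 * p$t  # last column out of bounds
  expect_equal(e, dat + p$eta * 36, tolerance = 1e-9)

  set.seed(4)
  s2 <- random_sift_image(6, 6, d = 8, seed = 5)
  for (trial in 1:5) {
    u <- matrix(sample(-2:2, 36, TRUE), 6, 6)
    v <- matrix(sample(-2:2, 36, TRUE), 6, 6)
    expect_equal(flow_energy(s, s2, list(u = u, v = v), p),
                 loop_flow_energy(s, s2, u, v, p), tolerance = 1e-9)
  }
})

test_that("identical inputs give the zero field with zero energy", {
  s <- dense_sift(textured_image(32, 7))
  fl <- estimate_flow(s, s)
  expect_true(all(fl$u == 0) && all(fl$v == 0))
  expect_equal(fl$energy, 0)
})

test_that("estimated flow recovers a known translation on a textured image", {
  base <- textured_image(32, 1)
  sh <- shift_img(base, 3, 1)
  fl <- estimate_flow(dense_sift(base), dense_sift(sh),
                      flow_params(search_radius = 4))
  interior <- matrix(FALSE, 32, 32); interior[9:24, 9:24] <- TRUE
  expect_gte(mean(fl$u[interior] == 3 & fl$v[interior] == 1), 0.95)
})

test_that("reported energy audits against flow_energy and decreases over sweeps", {
  s1 <- dense_sift(textured_image(32, 20))
  s2 <- dense_sift(textured_image(32, 21))
  fl <- estimate_flow(s1, s2)
  expect_equal(fl$energy, flow_energy(s1, s2, fl), tolerance = 1e-9)
  expect_true(all(diff(fl$energy_trace) <= 1e-9))
  # displacement bound: radius * 2^(levels - 1); 32 px -> 3 levels
  expect_true(all(abs(fl$u) <= 2 * 2^(3 - 1)))
  expect_true(all(abs(fl$v) <= 2 * 2^(3 - 1)))
})

test_that("small-instance energies are near the ICM oracle optimum", {
  p <- flow_params(t = 40, d = 20, eta = 0.05, alpha = 1, search_radius = 2,
                   pyramid_levels = 1)
  for (sd in 1:5) {
    s1 <- random_sift_image(8, 8, d = 8, seed = sd, scale = 10)
    s2 <- random_sift_image(8, 8, d = 8, seed = sd + 50, scale = 10)
    fl <- estimate_flow(s1, s2, p)
    orc <- icm_oracle_flow(s1, s2, p, 2)
    e_orc <- flow_energy(s1, s2, orc, p)
    expect_lte(fl$energy, 1.05 * e_orc)
  }
})

test_that("appearance change field vanishes under perfect correspondence", {
  s <- dense_sift(textured_image(32, 9))
  z <- matrix(0, 32, 32)
  acf0 <- appearance_change_field(s, s, list(u = z, v = z))
  expect_true(all(acf0$values == 0))

  base <- textured_image(32, 10)
  sh <- shift_img(base, 3, 1)
  sA <- dense_sift(base); sB <- dense_sift(sh)
  acf <- appearance_change_field(sA, sB, list(u = z + 3, v = z + 1))
  # exact descriptor equality needs both 16x16 windows clear of the wrap seam
  interior <- matrix(FALSE, 32, 32); interior[11:22, 11:21] <- TRUE
  expect_lt(max(acf$values[interior]), 1e-6)
  # out-of-bounds targets masked with zero value
  expect_true(all(acf$values[!acf$valid] == 0))
})

test_that("appearance field is invariant to a shared intensity offset", {
  i1 <- textured_image(32, 12); i2 <- textured_image(32, 13)
  s1 <- dense_sift(i1); s2 <- dense_sift(i2)
  fl <- estimate_flow(s1, s2)
  a <- appearance_change_field(s1, s2, fl)
  b <- appearance_change_field(dense_sift(i1 + 30), dense_sift(i2 + 30), fl)
  expect_lt(max(abs(a$values - b$values)), 1e-9)
})

test_that("appearance events raise the mean appearance discrepancy", {
  pe <- cell_video_params(appearance_event_rate = 1, noise_sigma = 1)
  p0 <- cell_video_params(appearance_event_rate = 0, noise_sigma = 1)
  se <- make_streaming_pair(pe, 4); s0 <- make_streaming_pair(p0, 4)
  fp <- flow_params()
  mean_acf <- function(sp) {
    s1 <- dense_sift(sp$frame1); s2 <- dense_sift(sp$frame2)
    fl <- estimate_flow(s1, s2, fp)
    a <- appearance_change_field(s1, s2, fl)
    mean(a$values[sp$mask])
  }
  expect_gt(mean_acf(se), mean_acf(s0))
})

test_that("flow visualization writes a color-wheel PNG with white still pixels", {
  u <- matrix(0, 8, 8); v <- matrix(0, 8, 8)
  u[1:4, ] <- 2
  path <- withr::local_tempfile(fileext = ".png")
  flow_to_png(list(u = u, v = v), path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(8L, 8L))
  expect_true(all(img[5:8, , ] > 0.99))   # zero flow renders white
  expect_lt(min(img[1:4, , 2]), 0.5)      # moving pixels are saturated
})

test_that("flow fields round-trip through the .flo format", {
  u <- matrix(rnorm(12), 3, 4); v <- matrix(rnorm(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".flo")
  write_flo(list(u = u, v = v), path)
  back <- read_flo(path)
  expect_equal(back$u, u, tolerance = 1e-6)
  expect_equal(back$v, v, tolerance = 1e-6)
})
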