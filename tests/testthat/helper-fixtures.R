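# Shared fixtures: all generated in code at test time.

# cyclic shift: content moves dx right, dy down
shift_img <- function(m, dx, dy) {
  roll <- function(n, k) if (k == 0) seq_len(n) else c((n - k + 1):n, 1:(n - k))
  m[roll(nrow(m), dy), roll(ncol(m), dx)]
}

# mildly smoothed random texture (rich enough for descriptor matching)
textured_image <- function(n, seed) {
  set.seed(seed)
  cellvfa:::gaussian_blur(matrix(runif(n * n, 0, 255), n, n), 0.8)
}

# sift_image with random descriptors, for optimizer tests on tiny grids
random_sift_image <- function(h, w, d = 8, seed = 1, scale = 10) {
  set.seed(seed)
  structure(list(desc = matrix(runif(h * w * d, 0, scale), h * w, d), h = h, w = w),
            class = "sift_image")
}

# exhaustive minimal assignment cost for small square matrices
brute_force_assignment <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  min(vapply(perms(seq_len(n)), function(p) sum(C[cbind(seq_len(n), p)]),
             numeric(1)))
}

# polygon area by the shoelace formula
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# literal per-pixel evaluation of the flow energy (independent of the
# vectorized implementation)
loop_flow_energy <- function(s1, s2, u, v, p) {
  h <- s1$h; w <- s1$w
  E <- 0
  for (x in seq_len(w)) for (y in seq_len(h)) {
    tx <- x + u[y, x]; ty <- y + v[y, x]
    E <- E + if (tx >= 1 && tx <= w && ty >= 1 && ty <= h) {
      min(sum(abs(s1$desc[y + (x - 1) * h, ] - s2$desc[ty + (tx - 1) * h, ])), p$t)
    } else p$t
    E <- E + p$eta * (abs(u[y, x]) + abs(v[y, x]))
    if (x < w) E <- E + min(p$alpha * abs(u[y, x] - u[y, x + 1]), p$d) +
        min(p$alpha * abs(v[y, x] - v[y, x + 1]), p$d)
    if (y < h) E <- E + min(p$alpha * abs(u[y, x] - u[y + 1, x]), p$d) +
        min(p$alpha * abs(v[y, x] - v[y + 1, x]), p$d)
  }
  E
}

# independent literal evaluation of the Fisher vector (first/second order
# residuals, SSR, l2), used as the oracle for encode_fv
literal_fv <- function(x, gmm) {
  N <- nrow(x); D <- ncol(x); K <- gmm$K
  q <- matrix(0, N, K)
  for (i in seq_len(N)) {
    dens <- vapply(seq_len(K), function(k) {
      gmm$weights[k] * prod(stats::dnorm(x[i, ], gmm$means[k, ],
                                         sqrt(gmm$variances[k, ])))
    }, numeric(1))
    q[i, ] <- dens / sum(dens)
  }
  out <- numeric(0)
  for (k in seq_len(K)) {
    u <- numeric(D); v <- numeric(D)
    for (i in seq_len(N)) {
      z <- (x[i, ] - gmm$means[k, ]) / sqrt(gmm$variances[k, ])
      u <- u + q[i, k] * z
      v <- v + q[i, k] * (z^2 - 1)
    }
    out <- c(out, u / (N * sqrt(gmm$weights[k])), v / (N * sqrt(2 * gmm$weights[k])))
  }
  out <- sign(out) * sqrt(abs(out))
  out / sqrt(sum(out^2))
}

make_gmm <- function(weights, means, vars) {
  structure(list(K = length(weights), weights = weights, means = means,
                 variances = vars, loglik = numeric(0)), class = "gmm_codebook")
}

# independent ICM oracle: start from the exhaustive per-pixel best data
# match, then sequential ICM sweeps to convergence
icm_oracle_flow <- function(s1, s2, p, radius) {
  h <- s1$h; w <- s1$w
  offs <- expand.grid(du = -radius:radius, dv = -radius:radius)
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (x in seq_len(w)) for (y in seq_len(h)) {
    best <- Inf
    for (k in seq_len(nrow(offs))) {
      du <- offs$du[k]; dv <- offs$dv[k]
      tx <- x + du; ty <- y + dv
      dc <- if (tx >= 1 && tx <= w && ty >= 1 && ty <= h) {
        min(sum(abs(s1$desc[y + (x - 1) * h, ] - s2$desc[ty + (tx - 1) * h, ])), p$t)
      } else p$t
      cost <- dc + p$eta * (abs(du) + abs(dv))
      if (cost < best) { best <- cost; u[y, x] <- du; v[y, x] <- dv }
    }
  }
  sm <- function(a, b) min(p$alpha * abs(a - b), p$d)
  repeat {
    changed <- FALSE
    for (x in seq_len(w)) for (y in seq_len(h)) {
      best <- Inf; bu <- u[y, x]; bv <- v[y, x]
      for (k in seq_len(nrow(offs))) {
        du <- offs$du[k]; dv <- offs$dv[k]
        tx <- x + du; ty <- y + dv
        dc <- if (tx >= 1 && tx <= w && ty >= 1 && ty <= h) {
          min(sum(abs(s1$desc[y + (x - 1) * h, ] - s2$desc[ty + (tx - 1) * h, ])), p$t)
        } else p$t
        cost <- dc + p$eta * (abs(du) + abs(dv))
        for (nb in list(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))) {
          if (nb[1] >= 1 && nb[1] <= h && nb[2] >= 1 && nb[2] <= w) {
            cost <- cost + sm(du, u[nb[1], nb[2]]) + sm(dv, v[nb[1], nb[2]])
          }
        }
        if (cost < best - 1e-12) { best <- cost; bu <- du; bv <- dv }
      }
      if (bu != u[y, x] || bv != v[y, x]) { u[y, x] <- bu; v[y, x] <- bv; changed <- TRUE }
    }
    if (!changed) break
  }
  list(u = u, v = v)
}
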