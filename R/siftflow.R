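# Dense SIFT descriptors, discrete SIFT-flow estimation and the appearance
# change field. The movement field w_p = (u_p, v_p) minimizes a truncated
# energy
#   E(w) = sum_p min(||s1_p - s2_{p+w_p}||_1, t)
#        + sum_p eta * (|u_p| + |v_p|)
#        + sum_{(p,q) in 4-neighborhoods} min(alpha|u_p-u_q|, d) + min(alpha|v_p-v_q|, d)
# with the smoothness truncation applied per component.

#' Dense SIFT image
#'
#' Computes one 128-dimensional SIFT descriptor per pixel: gradient
#' orientations over a 16x16 neighborhood are hard-assigned to 8 orientation
#' bins and pooled over a 4x4 grid of 4x4-pixel cells (cell-major, then
#' orientation ordering). Borders are mirror-padded. Each descriptor is
#' l2-normalized and scaled to `[0, 255]`; descriptors of constant regions
#' are all-zero. Descriptors are invariant to adding a constant to the image
#' and equivariant under translation.
#'
#' @param image numeric grayscale matrix, at least 16 x 16.
#' @return object of class `sift_image`: list with `desc` (an `(h*w) x 128`
#'   matrix, pixels in column-major order), `h`, `w`.
#' @export
dense_sift <- function(image) {
  image <- as.matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 16 || w < 16) stop("image must be at least 16 x 16")
  m <- 9L  # pad margin: 8 px window reach + 1 px for gradients
  ridx <- c(rev(seq_len(m) + 1L), seq_len(h), h - seq_len(m))
  cidx <- c(rev(seq_len(m) + 1L), seq_len(w), w - seq_len(m))
  pad <- image[ridx, cidx, drop = FALSE]
  ph <- nrow(pad); pw <- ncol(pad)
  # central-difference gradients on the padded image
  gx <- (pad[, c(2:pw, pw)] - pad[, c(1, 1:(pw - 1))]) / 2
  gy <- (pad[c(2:ph, ph), ] - pad[c(1, 1:(ph - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ori / (pi / 4)) + 1L, 8L)
  desc <- matrix(0, h * w, 128L)
  for (b in 1:8) {
    plane <- mag * (obin == b)
    # 4x4 box sums, top-left anchored: B[r, c] = sum plane[r..r+3, c..c+3]
    cs <- apply(plane, 2, cumsum)
    B <- cs[4:ph, ] - rbind(0, cs[1:(ph - 4), ])
    cs2 <- t(apply(B, 1, cumsum))
    B <- cs2[, 4:pw] - cbind(0, cs2[, 1:(pw - 4)])
    # pixel (y, x) in original coords sits at (y + m, x + m) in pad coords;
    # its 16x16 window starts at offset -8, cells start every 4 px
    for (i in 0:3) for (j in 0:3) {
      col <- (j * 4L + i) * 8L + b
      desc[, col] <- as.vector(B[(1:h) + (m - 8L) + 4L * i,
                                 (1:w) + (m - 8L) + 4L * j])
    }
  }
  # stabilized l2 normalization: the constant (half the 8-bit range) keeps
  # low-contrast, noise-dominated descriptors small instead of amplifying
  # them to full scale, so flat regions carry no spurious matching signal
  nrm <- sqrt(rowSums(desc^2))
  desc <- desc / (nrm + 128) * 255
  structure(list(desc = desc, h = h, w = w), class = "sift_image")
}

#' SIFT-flow parameters
#'
#' Truncations and the displacement weight follow common SIFT-flow practice
#' for descriptors scaled to `[0, 255]` (`eta = 0.005*255`,
#' `t = d = 40*255`). The smoothness weight default `alpha = 0.25*255` is
#' calibrated to this package's stabilized descriptor normalization (which
#' yields smaller typical descriptor distances than unnormalized SIFT
#' images): it minimizes the mean endpoint error against ground-truth
#' synthetic streaming fields. `pyramid_levels = NULL` selects enough levels
#' that the coarsest grid side is at least 8.
#'
#' @param t,d truncation thresholds of the data and smoothness terms.
#' @param eta weight of the displacement magnitude term.
#' @param alpha smoothness weight.
#' @param search_radius per-level search radius in pixels.
#' @param pyramid_levels number of pyramid levels, or `NULL` for automatic.
#' @param iterations ICM sweeps per pyramid level.
#' @return list of class `flow_params`.
#' @export
flow_params <- function(t = 40 * 255, d = 40 * 255, eta = 0.005 * 255,
                        alpha = 0.25 * 255, search_radius = 2L,
                        pyramid_levels = NULL, iterations = 2L) {
  if (t < 0 || d < 0 || eta < 0 || alpha < 0) stop("t, d, eta, alpha must be >= 0")
  if (search_radius < 1) stop("search_radius must be >= 1")
  structure(list(t = t, d = d, eta = eta, alpha = alpha,
                 search_radius = as.integer(search_radius),
                 pyramid_levels = pyramid_levels,
                 iterations = as.integer(iterations)),
            class = "flow_params")
}

# Construct a sift_image directly from a descriptor array (for tests and
# pyramid levels).
#' @keywords internal
sift_image_from_desc <- function(desc, h, w) {
  structure(list(desc = desc, h = h, w = w), class = "sift_image")
}

# L1 data cost of matching pixel p in s1 to p + (u, v) in s2, truncated at t;
# out-of-bounds targets cost t.
flow_data_cost <- function(s1, s2, u, v, t) {
  flow_data_cost_cpp(s1$desc, s2$desc, as.numeric(u), as.numeric(v),
                     s1$h, s1$w, t)
}

#' Evaluate the SIFT-flow energy of a displacement field
#'
#' Exact evaluation of the truncated data term (out-of-bounds targets are
#' charged the truncation `t`), the displacement magnitude term, and the
#' per-component truncated smoothness term over spatial 4-neighborhoods
#' (each edge counted once).
#'
#' @param s1,s2 `sift_image` objects of equal size.
#' @param flow list with integer matrices `u`, `v` (h x w).
#' @param params `flow_params`.
#' @return scalar energy.
#' @export
flow_energy <- function(s1, s2, flow, params = flow_params()) {
  h <- s1$h; w <- s1$w
  stopifnot(s2$h == h, s2$w == w, all(dim(flow$u) == c(h, w)),
            all(dim(flow$v) == c(h, w)))
  u <- flow$u; v <- flow$v
  e_data <- sum(flow_data_cost(s1, s2, u, v, params$t))
  e_disp <- params$eta * sum(abs(u) + abs(v))
  e_smooth <- 0
  if (h > 1) {
    e_smooth <- e_smooth +
      sum(pmin(params$alpha * abs(u[-1, ] - u[-h, ]), params$d)) +
      sum(pmin(params$alpha * abs(v[-1, ] - v[-h, ]), params$d))
  }
  if (w > 1) {
    e_smooth <- e_smooth +
      sum(pmin(params$alpha * abs(u[, -1] - u[, -w]), params$d)) +
      sum(pmin(params$alpha * abs(v[, -1] - v[, -w]), params$d))
  }
  e_data + e_disp + e_smooth
}

# 2x2 block-average downsampling of a descriptor grid.
downsample_sift <- function(s) {
  h2 <- floor(s$h / 2); w2 <- floor(s$w / 2)
  idx <- function(y, x) y + (x - 1L) * s$h
  y <- rep(seq_len(h2) * 2L - 1L, times = w2)
  x <- rep(seq_len(w2) * 2L - 1L, each = h2)
  desc <- (s$desc[idx(y, x), , drop = FALSE] + s$desc[idx(y + 1L, x), , drop = FALSE] +
             s$desc[idx(y, x + 1L), , drop = FALSE] +
             s$desc[idx(y + 1L, x + 1L), , drop = FALSE]) / 4
  sift_image_from_desc(desc, h2, w2)
}

# uniform fusion proposals: offsets within the search radius around the (up
# to two) most frequent displacements of the current field
fusion_candidates <- function(u, v, r, bound) {
  key <- paste(u, v)
  modes <- names(sort(table(key), decreasing = TRUE))
  modes <- utils::head(modes, 2)
  cand <- do.call(rbind, lapply(modes, function(m) {
    base <- as.numeric(strsplit(m, " ")[[1]])
    as.matrix(expand.grid(du = base[1] + (-r:r), dv = base[2] + (-r:r)))
  }))
  cand[, 1] <- pmin(pmax(cand[, 1], -bound), bound)
  cand[, 2] <- pmin(pmax(cand[, 2], -bound), bound)
  unique(cand)
}

# exact binary fusion of the current field with the uniform proposal (cu, cv);
# u0 caches the data + displacement cost of the current field
fuse_uniform <- function(a, b, u, v, cu, cv, params, u0) {
  h <- a$h; w <- a$w
  u1 <- flow_data_cost(a, b, matrix(cu, h, w), matrix(cv, h, w), params$t) +
    params$eta * (abs(cu) + abs(cv))
  if (!any(u1 < u0)) return(list(u = u, v = v, u0 = u0))
  sm <- function(ua, va, ub, vb) {
    pmin(params$alpha * abs(ua - ub), params$d) +
      pmin(params$alpha * abs(va - vb), params$d)
  }
  pa <- integer(0); pb <- integer(0); A <- numeric(0); B <- numeric(0); C <- numeric(0)
  if (h > 1) {
    # vertical edges: (y, x) -- (y + 1, x)
    y <- rep(seq_len(h - 1), times = w); x <- rep(seq_len(w), each = h - 1)
    p <- y + (x - 1L) * h; q <- p + 1L
    pa <- c(pa, p); pb <- c(pb, q)
    A <- c(A, sm(u[p], v[p], u[q], v[q]))
    B <- c(B, sm(u[p], v[p], cu, cv))
    C <- c(C, sm(cu, cv, u[q], v[q]))
  }
  if (w > 1) {
    # horizontal edges: (y, x) -- (y, x + 1)
    y <- rep(seq_len(h), times = w - 1); x <- rep(seq_len(w - 1), each = h)
    p <- y + (x - 1L) * h; q <- p + h
    pa <- c(pa, p); pb <- c(pb, q)
    A <- c(A, sm(u[p], v[p], u[q], v[q]))
    B <- c(B, sm(u[p], v[p], cu, cv))
    C <- c(C, sm(cu, cv, u[q], v[q]))
  }
  x1 <- fusion_move_cpp(u0, u1, pa - 1L, pb - 1L, A, B, C, numeric(length(A)))
  take <- matrix(x1 == 1L, h, w)
  u[take] <- cu; v[take] <- cv
  u0[take] <- u1[take]
  list(u = u, v = v, u0 = u0)
}

# smoothness cost of assigning (cu, cv) at every pixel given the current
# neighbor flow (per component, truncated); missing neighbors contribute 0
smooth_cost_maps <- function(u, v, cu, cv, alpha, d) {
  h <- nrow(u); w <- ncol(u)
  total <- matrix(0, h, w)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nu <- shift_matrix(u, sh[1], sh[2], fill = NA)
    nv <- shift_matrix(v, sh[1], sh[2], fill = NA)
    cst <- pmin(alpha * abs(cu - nu), d) + pmin(alpha * abs(cv - nv), d)
    cst[is.na(cst)] <- 0
    total <- total + cst
  }
  total
}

#' Estimate SIFT flow between two descriptor grids
#'
#' Coarse-to-fine discrete optimization of the SIFT-flow energy: descriptor
#' pyramids are built by 2x2 block averaging (coarsest side >= 8), and at
#' each level iterated conditional modes sweeps over a red-black checkerboard
#' update every pixel's displacement over candidates within `search_radius`
#' of its current value. Updates are accepted only on strict improvement, so
#' identical inputs return the (globally optimal) zero field, and the energy
#' recorded after each sweep at the finest level is non-increasing. Candidate
#' displacements are clamped to `search_radius * 2^(levels-1)` per component.
#'
#' @param s1,s2 `sift_image` objects of equal size.
#' @param params `flow_params`.
#' @return list of class `flow_field`: integer matrices `u`, `v`, the final
#'   `energy` (equal to `flow_energy()` of the returned field), the per-sweep
#'   `energy_trace` at the finest level, and `valid` (logical matrix marking
#'   pixels whose target stays in bounds).
#' @export
estimate_flow <- function(s1, s2, params = flow_params()) {
  stopifnot(inherits(s1, "sift_image"), inherits(s2, "sift_image"),
            s1$h == s2$h, s1$w == s2$w)
  levels <- params$pyramid_levels
  if (is.null(levels)) levels <- max(1L, floor(log2(min(s1$h, s1$w) / 8)) + 1L)
  levels <- max(1L, as.integer(levels))
  pyr1 <- list(s1); pyr2 <- list(s2)
  for (l in seq_len(levels - 1L)) {
    if (min(pyr1[[l]]$h, pyr1[[l]]$w) < 4) { levels <- l; break }
    pyr1[[l + 1L]] <- downsample_sift(pyr1[[l]])
    pyr2[[l + 1L]] <- downsample_sift(pyr2[[l]])
  }
  max_disp <- params$search_radius * 2^(levels - 1L)
  r <- params$search_radius
  offsets <- expand.grid(du = -r:r, dv = -r:r)
  # current displacement (offset 0) first: ties keep the current label
  offsets <- offsets[order(offsets$du != 0 | offsets$dv != 0), , drop = FALSE]
  u <- matrix(0, pyr1[[levels]]$h, pyr1[[levels]]$w)
  v <- matrix(0, pyr1[[levels]]$h, pyr1[[levels]]$w)
  trace <- NULL
  for (lev in levels:1) {
    a <- pyr1[[lev]]; b <- pyr2[[lev]]
    h <- a$h; w <- a$w
    disp_bound <- ceiling(max_disp / 2^(lev - 1))
    if (lev == levels) {
      # uniform-field initialization: scan constant displacements (cheap at
      # the coarsest grid; a constant field has zero smoothness cost)
      scan_r <- min(disp_bound, 4L * r)
      best_e <- flow_energy(a, b, list(u = u, v = v), params)
      for (du in -scan_r:scan_r) for (dv in -scan_r:scan_r) {
        cu <- matrix(du, h, w); cv <- matrix(dv, h, w)
        e <- sum(flow_data_cost(a, b, cu, cv, params$t)) +
          params$eta * h * w * (abs(du) + abs(dv))
        if (e < best_e) { best_e <- e; u <- cu; v <- cv }
      }
    }
    # fusion moves: fuse the current field with uniform proposals around its
    # dominant displacements; each binary fusion is solved exactly by min-cut
    # (the truncated-linear smoothness makes it submodular), so the energy
    # never increases and coherent regions can switch displacement jointly
    for (round in seq_len(if (lev == 1L) 2L else 1L)) {
      cand <- fusion_candidates(u, v, r, disp_bound)
      u0 <- flow_data_cost(a, b, u, v, params$t) +
        params$eta * as.vector(abs(u) + abs(v))
      changed <- FALSE
      for (ci in seq_len(nrow(cand))) {
        fused <- fuse_uniform(a, b, u, v, cand[ci, 1], cand[ci, 2], params, u0)
        if (!identical(fused$u, u) || !identical(fused$v, v)) changed <- TRUE
        u <- fused$u; v <- fused$v; u0 <- fused$u0
      }
      if (!changed) break
    }
    if (lev == 1L) trace <- c(trace, flow_energy(a, b, list(u = u, v = v), params))
    parity <- (matrix(rep(seq_len(w), each = h), h, w) +
                 matrix(rep(seq_len(h), times = w), h, w)) %% 2
    # full sweep count at the finest level; one sweep at coarse levels, where
    # the uniform scan and fusion moves do most of the work
    n_sweeps <- params$iterations
    for (sweep in seq_len(n_sweeps)) {
      nk <- nrow(offsets)
      cand_u <- vector("list", nk); cand_v <- vector("list", nk)
      base_cost <- vector("list", nk)
      for (k in seq_len(nk)) {
        cu <- pmin(pmax(u + offsets$du[k], -max_disp), max_disp)
        cv <- pmin(pmax(v + offsets$dv[k], -max_disp), max_disp)
        cand_u[[k]] <- cu; cand_v[[k]] <- cv
        base_cost[[k]] <- matrix(flow_data_cost(a, b, cu, cv, params$t), h, w) +
          params$eta * (abs(cu) + abs(cv))
      }
      for (col in c(0, 1)) {
        best <- matrix(Inf, h, w); bu <- u; bv <- v
        for (k in seq_len(nk)) {
          cst <- base_cost[[k]] +
            smooth_cost_maps(u, v, cand_u[[k]], cand_v[[k]], params$alpha, params$d)
          better <- cst < best & parity == col
          best[better] <- cst[better]
          bu[better] <- cand_u[[k]][better]
          bv[better] <- cand_v[[k]][better]
        }
        sel <- parity == col
        u[sel] <- bu[sel]; v[sel] <- bv[sel]
      }
      if (lev == 1L) {
        trace <- c(trace, flow_energy(a, b, list(u = u, v = v), params))
      }
    }
    if (lev > 1L) {
      hf <- pyr1[[lev - 1L]]$h; wf <- pyr1[[lev - 1L]]$w
      ui <- pmin(ceiling(seq_len(hf) / 2), h); xi <- pmin(ceiling(seq_len(wf) / 2), w)
      u <- 2 * u[ui, xi, drop = FALSE]
      v <- 2 * v[ui, xi, drop = FALSE]
    }
  }
  h <- s1$h; w <- s1$w
  gx <- matrix(rep(seq_len(w), each = h), h, w)
  gy <- matrix(rep(seq_len(h), times = w), h, w)
  valid <- (gx + u) >= 1 & (gx + u) <= w & (gy + v) >= 1 & (gy + v) <= h
  structure(list(u = u, v = v,
                 energy = trace[length(trace)],
                 energy_trace = trace, valid = valid),
            class = "flow_field")
}

#' Appearance change field
#'
#' Per-pixel discrepancy between corresponding SIFT descriptors: at pixel p
#' the norm of `s1_p - s2_{p + w_p}`, with the correspondence taken through
#' the estimated flow. Pixels whose target falls out of bounds get 0 and are
#' marked invalid.
#'
#' @param s1,s2 `sift_image` objects.
#' @param flow `flow_field` estimated between them.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return list of class `appearance_field`: `values` (h x w matrix, >= 0)
#'   and `valid` (logical matrix).
#' @export
appearance_change_field <- function(s1, s2, flow, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  h <- s1$h; w <- s1$w
  x <- rep(seq_len(w), each = h) + as.vector(flow$u)
  y <- rep(seq_len(h), times = w) + as.vector(flow$v)
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  vals <- numeric(h * w)
  if (any(ok)) {
    ti <- y[ok] + (x[ok] - 1) * h
    diff <- s1$desc[which(ok), , drop = FALSE] - s2$desc[ti, , drop = FALSE]
    vals[ok] <- if (norm == "l2") sqrt(rowSums(diff^2)) else rowSums(abs(diff))
  }
  structure(list(values = matrix(vals, h, w), valid = matrix(ok, h, w)),
            class = "appearance_field")
}

#' Render a flow field as an HSV color-wheel PNG
#'
#' Hue encodes the flow direction, saturation the magnitude (white = still).
#'
#' @param flow list with matrices `u`, `v`.
#' @param path output PNG path.
#' @param max_magnitude magnitude mapped to full saturation; defaults to the
#'   field's maximum.
#' @return `path`, invisibly.
#' @export
flow_to_png <- function(flow, path, max_magnitude = NULL) {
  u <- flow$u; v <- flow$v
  mag <- sqrt(u^2 + v^2)
  if (is.null(max_magnitude)) max_magnitude <- max(mag, 1e-9)
  hue <- (atan2(v, u) %% (2 * pi)) / (2 * pi)
  sat <- pmin(mag / max_magnitude, 1)
  rgb <- grDevices::col2rgb(grDevices::hsv(hue, sat, 1)) / 255
  arr <- array(0, c(nrow(u), ncol(u), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nrow(u), ncol(u))
  png::writePNG(arr, path)
  invisible(path)
}

#' Read or write a flow field in Middlebury .flo format
#'
#' @param flow list with matrices `u`, `v`.
#' @param path file path.
#' @return `read_flo` returns a list with `u` and `v`.
#' @export
write_flo <- function(flow, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("PIEH", con, 4, eos = NULL)
  writeBin(as.integer(c(ncol(flow$u), nrow(flow$u))), con, size = 4)
  inter <- rbind(as.vector(t(flow$u)), as.vector(t(flow$v)))  # row-major u,v interleaved
  writeBin(as.numeric(inter), con, size = 4)
  invisible(path)
}

#' @rdname write_flo
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- readChar(con, 4)
  if (!identical(tag, "PIEH")) stop("not a .flo file")
  wh <- readBin(con, "integer", 2, size = 4)
  dat <- readBin(con, "numeric", 2 * wh[1] * wh[2], size = 4)
  inter <- matrix(dat, nrow = 2)
  list(u = matrix(inter[1, ], wh[2], wh[1], byrow = TRUE),
       v = matrix(inter[2, ], wh[2], wh[1], byrow = TRUE))
}
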