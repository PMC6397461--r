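# Internal image and geometry helpers shared across modules.
#
# Convention: images are numeric matrices indexed [row = y, col = x], with the
# pixel at row r, column c having centre coordinates (x = c, y = r). Point
# sets use (x, y) in these pixel units.

#' @keywords internal
shift_matrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h
  ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

# 1-D Gaussian kernel, truncated at 3 sigma
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-m:m)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding, via shifted sums.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  m <- (length(k) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  # rows (vertical) pass with replicate padding
  padded <- img[c(rep(1L, m), seq_len(h), rep(h, m)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padded[(i - 1L) + seq_len(h), , drop = FALSE]
  # columns (horizontal) pass
  padded <- out[, c(rep(1L, m), seq_len(w), rep(w, m)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padded[, (i - 1L) + seq_len(w), drop = FALSE]
  out
}

# Vectorised even-odd (ray casting) point-in-polygon test.
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterise a closed polygon onto an h x w pixel grid (centres at integers).
#' @keywords internal
rasterize_polygon <- function(vx, vy, h, w) {
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), times = w)
  matrix(point_in_polygon(gx, gy, vx, vy), h, w)
}

# Binary dilation by a disk of radius r (in pixels).
#' @keywords internal
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx <= r * r && (dy != 0 || dx != 0)) {
      out <- out | shift_matrix(mask, dy, dx, fill = FALSE)
    }
  }
  out
}

# Bilinear sampling at real coordinates (x, y), clamped to the image domain.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + (x0 - 1) * h
  img[i00] * (1 - fx) * (1 - fy) + img[i00 + h] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy + img[i00 + h + 1] * fx * fy
}

#' Warp an image through a displacement field
#'
#' Resamples `img` so that output pixel p takes the value of `img` at
#' p - (u(p), v(p)) (backward warping with bilinear interpolation). This is
#' the convention under which the synthetic generator's ground-truth fields
#' exactly reproduce the next frame.
#'
#' @param img numeric matrix.
#' @param u,v numeric matrices of per-pixel x and y displacements.
#' @return warped numeric matrix of the same size.
#' @export
warp_image <- function(img, u, v) {
  stopifnot(all(dim(img) == dim(u)), all(dim(img) == dim(v)))
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(rep(seq_len(w), each = h), h, w)
  gy <- matrix(rep(seq_len(h), times = w), h, w)
  matrix(bilinear_sample(img, gx - u, gy - v), h, w)
}

#' @keywords internal
l2_normalize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x)
  x / nrm
}

# Signed square root (power normalisation)
#' @keywords internal
ssr <- function(x) sign(x) * sqrt(abs(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
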