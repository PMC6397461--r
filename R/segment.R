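# Minimal segmentation fallback for demos: the pipeline's contract is that
# contours are supplied (segmentation and stabilization are replaceable
# preprocessing), but a simple Otsu threshold + largest-component contour
# estimate makes the package usable on raw frames of a bright cell.

# Otsu's threshold on an 8-bit-range image
otsu_threshold <- function(img) {
  counts <- tabulate(pmin(pmax(floor(img) + 1L, 1L), 256L), 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1
}

# largest 4-connected TRUE component of a logical matrix (flood fill)
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(mask & labels == 0L)) {
    cur <- cur + 1L
    stack <- start
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labels[p] != 0L || !mask[p]) next
      labels[p] <- cur
      size <- size + 1L
      y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
      if (y > 1) stack <- c(stack, p - 1L)
      if (y < h) stack <- c(stack, p + 1L)
      if (x > 1) stack <- c(stack, p - h)
      if (x < w) stack <- c(stack, p + h)
    }
    sizes[cur] <- size
  }
  if (cur == 0L) stop("no foreground component found")
  labels == which.max(sizes)
}

#' Estimate a cell contour from a single frame
#'
#' Demo-grade segmentation fallback: Gaussian smoothing, Otsu thresholding,
#' largest connected component, and boundary extraction at the 0.5 level.
#' Intended for quick exploration when no contours are supplied; analysis
#' pipelines should provide contours from a dedicated segmentation/tracking
#' method.
#'
#' @param frame grayscale matrix on a 0-255 scale, cell brighter than
#'   background.
#' @param blur Gaussian smoothing sigma applied before thresholding.
#' @return closed contour matrix with columns (x, y).
#' @export
estimate_contour <- function(frame, blur = 1) {
  img <- gaussian_blur(as.matrix(frame), blur)
  mask <- largest_component(img > otsu_threshold(img))
  h <- nrow(mask); w <- ncol(mask)
  cl <- grDevices::contourLines(x = seq_len(h), y = seq_len(w),
                                z = mask * 1, levels = 0.5)
  if (length(cl) == 0) stop("no contour found")
  polys <- lapply(cl, function(cc) cbind(x = cc$y, y = cc$x))
  areas <- vapply(polys, function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  polys[[which.max(areas)]]
}
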