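# Contour deformation feature: shape context matching, Hungarian assignment
# and iterated thin-plate-spline (TPS) re-estimation between two cell
# contours. The per-iteration shape-context distances are concatenated into
# the deformation feature F_DCS.

#' Resample a closed contour to n equally spaced points
#'
#' Points are placed at equal arc-length intervals along the polygon,
#' starting at the vertex with the smallest angle (in `[0, 2*pi)`, measured
#' from the positive x-axis) around the centroid, which gives a canonical
#' start point so that identical shapes resample identically.
#'
#' @param contour numeric matrix with columns (x, y); closed polygon (the
#'   closing edge back to the first vertex is implicit; a duplicated last
#'   vertex is tolerated).
#' @param n number of output points.
#' @return an `n x 2` matrix of (x, y) coordinates.
#' @export
resample_contour <- function(contour, n) {
  contour <- as.matrix(contour)
  if (nrow(contour) >= 2 && all(contour[1, ] == contour[nrow(contour), ])) {
    contour <- contour[-nrow(contour), , drop = FALSE]
  }
  if (nrow(contour) < 3) stop("contour must have at least 3 distinct vertices")
  if (n < 3) stop("n must be at least 3")
  centroid <- colMeans(contour)
  ang <- atan2(contour[, 2] - centroid[2], contour[, 1] - centroid[1]) %% (2 * pi)
  start <- which.min(ang)
  idx <- c(start:nrow(contour), seq_len(start - 1))
  v <- contour[idx, , drop = FALSE]
  seg <- sqrt(rowSums((v[c(2:nrow(v), 1), , drop = FALSE] - v)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate (zero-length) contour")
  cum <- c(0, cumsum(seg))            # arc length at each vertex (and closure)
  s <- (seq_len(n) - 1) / n * per     # target arc positions
  # locate segment for each target position
  j <- findInterval(s, cum, rightmost.closed = TRUE)
  j[j > nrow(v)] <- nrow(v)
  frac <- (s - cum[j]) / seg[j]
  frac[!is.finite(frac)] <- 0
  nxt <- c(2:nrow(v), 1)
  v[j, , drop = FALSE] + frac * (v[nxt[j], , drop = FALSE] - v[j, , drop = FALSE])
}

#' Shape contexts of a point set
#'
#' For each point, counts the remaining points in a log-polar histogram:
#' radial bins are log-spaced between `r_inner` and `r_outer` times the mean
#' pairwise distance of the set (which makes the histograms scale invariant),
#' and angular bins divide `[0, 2*pi)` (angles from the positive x-axis) into
#' equal sectors. Points at or beyond the outermost radial edge are dropped.
#'
#' @param pts `n x 2` point matrix, `n >= 3`.
#' @param radial_bins,angular_bins histogram geometry (5 x 12 by default).
#' @param r_inner,r_outer radial range relative to the mean pairwise distance.
#' @return an `n x (radial_bins*angular_bins)` count matrix with attributes
#'   `radial_bins`, `angular_bins` and `radial_edges`.
#' @export
shape_context <- function(pts, radial_bins = 5L, angular_bins = 12L,
                          r_inner = 1 / 8, r_outer = 2) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  dx <- outer(pts[, 1], pts[, 1], "-")   # dx[i, j] = x_i - x_j
  dy <- outer(pts[, 2], pts[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  mean_d <- sum(d) / (n * (n - 1))       # mean over ordered pairs, i != j
  if (mean_d <= 0) stop("degenerate point set (all points coincide)")
  edges <- exp(seq(log(r_inner), log(r_outer), length.out = radial_bins))
  rn <- d / mean_d
  # log-domain radial bin with boundary snapping (9 decimals), so points that
  # sit numerically on a bin edge bin identically at any image scale
  step <- (log(r_outer) - log(r_inner)) / (radial_bins - 1)
  tt <- round((log(pmax(rn, 1e-300)) - log(r_inner)) / step, 9)
  rbin <- matrix(ifelse(tt < 0, 1L, floor(tt) + 2L), n, n)
  # angle of q_j as seen from p_i: atan2(y_j - y_i, x_j - x_i)
  theta <- atan2(-dy, -dx) %% (2 * pi)
  au <- round(theta / (2 * pi / angular_bins), 9)
  abin <- floor(au) + 1L
  abin[abin > angular_bins] <- 1L
  K <- radial_bins * angular_bins
  keep <- row(d) != col(d) & rbin <= radial_bins
  k <- rbin[keep] + (abin[keep] - 1L) * radial_bins
  i <- row(d)[keep]
  counts <- matrix(tabulate(i + (k - 1L) * n, nbins = n * K), n, K)
  structure(counts, radial_bins = radial_bins, angular_bins = angular_bins,
            radial_edges = edges * mean_d)
}

#' Chi-squared matching cost between two shape-context histograms
#'
#' `C = 1/2 * sum_k (h_i(k) - h_j(k))^2 / (h_i(k) + h_j(k))`, with
#' zero-denominator terms contributing 0.
#'
#' @param h_i,h_j histogram count vectors with the same binning.
#' @return a non-negative scalar.
#' @export
chi2_cost <- function(h_i, h_j) {
  if (length(h_i) != length(h_j)) stop("histogram binning mismatch")
  num <- (h_i - h_j)^2
  den <- h_i + h_j
  ok <- den > 0
  0.5 * sum(num[ok] / den[ok])
}

# Chi-squared cost matrix between two sets of shape contexts (rows).
#' @export
#' @rdname chi2_cost
#' @param H_i,H_j matrices of histograms (one per row, same binning).
chi2_cost_matrix <- function(H_i, H_j) {
  if (ncol(H_i) != ncol(H_j)) stop("histogram binning mismatch")
  chi2_cost_matrix_cpp(matrix(as.numeric(H_i), nrow(H_i)),
                       matrix(as.numeric(H_j), nrow(H_j)))
}

#' Optimal assignment by the Hungarian algorithm
#'
#' Finds the permutation `pi` minimizing `sum_i cost[i, pi(i)]` by shortest
#' augmenting paths (O(n^3)).
#'
#' @param cost square numeric cost matrix.
#' @return list with `permutation` (integer vector, row i is matched to column
#'   `permutation[i]`) and `total_cost`.
#' @export
hungarian <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be square")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  solve_assignment_cpp(cost)
}

# TPS radial basis: U(r) = r^2 log(r^2), U(0) = 0
tps_u <- function(r2) {
  out <- r2 * log(r2)
  out[r2 == 0] <- 0
  out
}

#' Fit a thin-plate-spline transform
#'
#' Solves the regularized TPS system mapping `source` points onto `target`
#' points: affine part plus radial-basis warp with kernel `U(r) = r^2 log r^2`
#' and bending-energy regularization `lambda`. With `regularization = 0` the
#' transform interpolates the control points exactly; the warping coefficients
#' satisfy the usual side conditions (orthogonal to 1, x and y).
#'
#' @param source,target `n x 2` point matrices, equal n.
#' @param regularization non-negative scalar added to the kernel diagonal.
#' @return object of class `tps_transform` with `affine` (3 x 2: intercept, x,
#'   y coefficients per output dimension), `weights` (n x 2), `control`
#'   (source points) and `regularization`.
#' @export
fit_tps <- function(source, target, regularization = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (nrow(target) != n) stop("source and target must have the same number of points")
  if (regularization < 0) stop("regularization must be >= 0")
  d2 <- outer(source[, 1], source[, 1], "-")^2 + outer(source[, 2], source[, 2], "-")^2
  K <- tps_u(d2) + diag(regularization, n)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular TPS system (collinear control points with zero regularization?)")
  })
  structure(list(weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:3, , drop = FALSE],
                 control = source,
                 regularization = regularization),
            class = "tps_transform")
}

#' Apply a fitted TPS transform to points
#'
#' @param tps a `tps_transform` from [fit_tps()].
#' @param pts `m x 2` point matrix.
#' @return transformed `m x 2` matrix.
#' @export
apply_tps <- function(tps, pts) {
  pts <- as.matrix(pts)
  d2 <- outer(pts[, 1], tps$control[, 1], "-")^2 +
    outer(pts[, 2], tps$control[, 2], "-")^2
  cbind(1, pts) %*% tps$affine + tps_u(d2) %*% tps$weights
}

#' Shape-context distance between two point sets
#'
#' Symmetric sum of per-point minimal chi-squared costs between the shape
#' contexts of `P` and of `T(Q)`:
#' `1/n * sum_p min_q C(p, T(q)) + 1/m * sum_q min_p C(p, T(q))`.
#'
#' @param P,Q point matrices.
#' @param tps optional `tps_transform` applied to `Q` first.
#' @param ... binning arguments forwarded to [shape_context()].
#' @return non-negative scalar distance.
#' @export
shape_distance <- function(P, Q, tps = NULL, ...) {
  TQ <- if (is.null(tps)) as.matrix(Q) else apply_tps(tps, Q)
  C <- chi2_cost_matrix(shape_context(P, ...), shape_context(TQ, ...))
  mean(apply(C, 1, min)) + mean(apply(C, 2, min))
}

#' Contour deformation feature between two contours
#'
#' Both contours are resampled to `n` points and jointly normalized for
#' location and scale. For `L` iterations: shape contexts are computed, the
#' chi-squared cost matrix is matched by the Hungarian algorithm, a
#' regularized TPS is fitted from the matched points of Q onto P, Q is warped,
#' and the shape-context distance `D_SC^l` between P and the warped Q is
#' recorded. The concatenation `(D_SC^1, ..., D_SC^L)` is the contour
#' deformation feature.
#'
#' The TPS uses `lambda0 * (mean pairwise distance)^2` regularization in every
#' iteration: with equal point counts the match is a bijection, so an exactly
#' interpolating fit would collapse Q onto P and make every distance zero;
#' the regularized warp absorbs smooth (in particular affine) shape change
#' while leaving genuine local deformation visible.
#'
#' @param p_contour,q_contour closed contours (matrices of (x, y) vertices).
#' @param n number of resampled points per contour (default 100).
#' @param L number of matching/TPS iterations (default 10; 30 when the
#'   contour feature is used standalone).
#' @param lambda0 TPS regularization scale (default 1).
#' @param ... binning arguments forwarded to [shape_context()].
#' @return numeric vector of length `L`, named `D_SC_1 ... D_SC_L`.
#' @export
contour_deformation_feature <- function(p_contour, q_contour, n = 100L,
                                        L = 10L, lambda0 = 1, ...) {
  if (L < 1) stop("L must be >= 1")
  P <- resample_contour(p_contour, n)
  Qc <- resample_contour(q_contour, n)
  # joint location/scale normalization: makes the feature exactly invariant
  # to rigid translation and uniform scaling of both contours
  ctr <- colMeans(rbind(P, Qc))
  P <- sweep(P, 2, ctr); Qc <- sweep(Qc, 2, ctr)
  scl <- mean(stats::dist(rbind(P, Qc)))
  if (scl <= 0) stop("degenerate contours")
  P <- P / scl; Qc <- Qc / scl
  # deterministic tie-break: among (near-)equal-cost assignments prefer the
  # order-preserving one, so symmetric shapes (where many permutations have
  # identical chi-squared cost) match rigidly instead of arbitrarily
  idx <- seq_len(n) - 1L
  circ <- abs(outer(idx, idx, "-"))
  tie_bias <- 1e-8 * pmin(circ, n - circ) / n
  out <- numeric(L)
  for (l in seq_len(L)) {
    HP <- shape_context(P, ...)
    HQ <- shape_context(Qc, ...)
    C <- chi2_cost_matrix(HP, HQ)
    m <- hungarian(C + tie_bias)
    if (sum(C[cbind(seq_len(n), m$permutation)]) <= 1e-9) {
      # contexts already agree point-for-point: no warp needed
      out[l] <- shape_distance(P, Qc, ...)
      next
    }
    src <- Qc[m$permutation, , drop = FALSE]
    lambda <- lambda0 * mean(stats::dist(src))^2
    tps <- tryCatch(fit_tps(src, P, regularization = lambda),
                    error = function(e) stop(sprintf("TPS fit failed at iteration %d: %s",
                                                     l, conditionMessage(e))))
    Qc <- apply_tps(tps, Qc)
    out[l] <- shape_distance(P, Qc, ...)
  }
  names(out) <- paste0("D_SC_", seq_len(L))
  out
}
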