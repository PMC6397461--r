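# Histograms of oriented SIFT flow: the movement field and the appearance
# change field are binned by flow angle over R equal sectors of [0, 2*pi)
# and weighted by flow magnitude (movement) or descriptor discrepancy
# (appearance). Together with the contour deformation feature they form the
# per-frame-pair dynamic feature F_i = {F_DCS, F_MDF, F_ACF}.

# angle -> bin over R half-open sectors [2*pi*(r-1)/R, 2*pi*r/R), with
# boundary snapping (9 decimals) so sector edges bin deterministically
flow_angle_bin <- function(u, v, R) {
  ang <- atan2(v, u) %% (2 * pi)
  b <- floor(round(ang / (2 * pi / R), 9)) + 1L
  b[b > R] <- 1L
  b
}

#' Movement field orientation histogram (F_MDF)
#'
#' Each masked pixel with a nonzero displacement is assigned to the sector of
#' `[0, 2*pi)` containing its flow angle `atan2(v, u)` and contributes its
#' magnitude `sqrt(u^2 + v^2)` to that bin. Zero-displacement pixels are
#' skipped (their angle is undefined); sector boundaries belong to the bin
#' they open (half-open sectors).
#'
#' @param flow `flow_field` (or any list with matrices `u`, `v`).
#' @param R number of orientation bins (>= 2); 36 by default.
#' @param mask optional logical matrix selecting cell pixels.
#' @return numeric vector of length `R`; its sum equals the total flow
#'   magnitude of the contributing pixels.
#' @export
orient_histogram_mdf <- function(flow, R = 36L, mask = NULL) {
  if (R < 2) stop("R must be >= 2")
  u <- flow$u; v <- flow$v
  sel <- (u != 0 | v != 0)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(u)))
    sel <- sel & mask
  }
  h <- numeric(R)
  if (any(sel)) {
    bins <- flow_angle_bin(u[sel], v[sel], R)
    wts <- sqrt(u[sel]^2 + v[sel]^2)
    s <- rowsum(wts, bins)
    h[as.integer(rownames(s))] <- s
  }
  h
}

#' Appearance change field orientation histogram (F_ACF)
#'
#' Same sector assignment as [orient_histogram_mdf()] (by flow angle), but
#' each pixel contributes its appearance discrepancy instead of the flow
#' magnitude.
#'
#' @param flow `flow_field`.
#' @param acf `appearance_field` (or list with `values` matrix), aligned with
#'   the flow.
#' @param R number of orientation bins.
#' @param mask optional logical matrix selecting cell pixels.
#' @return numeric vector of length `R`; its sum equals the summed
#'   discrepancy of the contributing pixels.
#' @export
orient_histogram_acf <- function(flow, acf, R = 36L, mask = NULL) {
  if (R < 2) stop("R must be >= 2")
  u <- flow$u; v <- flow$v
  vals <- acf$values
  if (!all(dim(vals) == dim(u))) stop("flow and appearance field shape mismatch")
  sel <- (u != 0 | v != 0)
  if (!is.null(acf$valid)) sel <- sel & acf$valid
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(u)))
    sel <- sel & mask
  }
  h <- numeric(R)
  if (any(sel)) {
    bins <- flow_angle_bin(u[sel], v[sel], R)
    s <- rowsum(vals[sel], bins)
    h[as.integer(rownames(s))] <- s
  }
  h
}

#' Combine the per-frame-pair dynamic features
#'
#' Concatenates the contour deformation feature, the movement histogram and
#' the appearance histogram, in that order, into the frame-pair feature
#' vector of length `L + 2R`.
#'
#' @param f_dcs contour deformation feature (length L).
#' @param f_mdf movement orientation histogram (length R).
#' @param f_acf appearance orientation histogram (length R).
#' @return named numeric vector of length `L + 2R`.
#' @export
combine_features <- function(f_dcs, f_mdf, f_acf) {
  if (is.null(f_dcs) || is.null(f_mdf) || is.null(f_acf)) {
    stop("all three components (f_dcs, f_mdf, f_acf) are required")
  }
  if (length(f_mdf) != length(f_acf)) {
    stop("f_mdf and f_acf must use the same number of orientation bins")
  }
  out <- c(f_dcs, f_mdf, f_acf)
  if (any(!is.finite(out))) stop("non-finite feature entries")
  names(out) <- c(paste0("D_SC_", seq_along(f_dcs)),
                  paste0("MDF_", seq_along(f_mdf)),
                  paste0("ACF_", seq_along(f_acf)))
  out
}
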