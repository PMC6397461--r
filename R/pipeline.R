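# End-to-end orchestration: per-video feature extraction with a fixed frame
# interval, codebook learning on training splits only, compact encoding,
# linear SVM with fivefold cross-validated penalty, and evaluation over
# random splits (macro precision / recall / F-score, mean +/- sd).

#' Experiment configuration
#'
#' Defaults reproduce the reference protocol: frame interval 30, combined
#' frame-pair feature with `L = 10` shape-context iterations and `R = 10`
#' orientation bins (dimension 30; `R = 36` is the standalone histogram
#' default), Fisher vector encoding with `K = 64` words and temporal pyramid
#' pooling, VLAD-k neighborhood 5, 30 random splits with 20 training videos
#' per class, and an SVM penalty grid `2^-5 ... 2^15` (steps of 4x) chosen
#' by fivefold cross-validation on the training split.
#'
#' @param interval frame interval between the two frames of a pair.
#' @param n_points contour resampling size.
#' @param L shape-context iterations per pair.
#' @param R orientation bins per field histogram.
#' @param scheme `"fv"`, `"vlad"` or `"hvlad"`.
#' @param K vocabulary size.
#' @param k_nn VLAD-k neighborhood.
#' @param tpp apply temporal pyramid pooling.
#' @param d_prime PCA target dimension, or `NULL` to use features as-is.
#' @param aggregation `"encoding"` (compact encoding) or `"average"`
#'   (average pooling of frame-pair features, the baseline aggregation).
#' @param n_splits number of random train/test splits.
#' @param n_train_per_class training videos sampled per class in each split.
#' @param cost_grid SVM penalty candidates.
#' @param cv_folds folds of the penalty cross-validation.
#' @param flow `flow_params` for the SIFT-flow stage.
#' @param crop_pad padding (pixels) around the cell bounding box for the
#'   cytoplasm features.
#' @param lambda0 TPS regularization scale.
#' @param stride pair stride; defaults to `interval` (non-overlapping pairs).
#' @param upsample integer up-sampling factor applied to the cropped frames
#'   before the cytoplasm features (default 1, i.e. none).
#' @param seed master seed controlling splits, codebooks and the SVM.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(interval = 30L, n_points = 100L, L = 10L,
                              R = 10L, scheme = "fv", K = 64L, k_nn = 5L,
                              tpp = TRUE, d_prime = NULL,
                              aggregation = c("encoding", "average"),
                              n_splits = 30L, n_train_per_class = 20L,
                              cost_grid = 2^seq(-5, 15, by = 2),
                              cv_folds = 5L, flow = flow_params(),
                              crop_pad = 16L, lambda0 = 1, stride = NULL,
                              upsample = 1L, seed = 1L) {
  aggregation <- match.arg(aggregation)
  structure(list(interval = as.integer(interval), n_points = as.integer(n_points),
                 L = as.integer(L), R = as.integer(R), scheme = scheme,
                 K = as.integer(K), k_nn = as.integer(k_nn), tpp = tpp,
                 d_prime = d_prime, aggregation = aggregation,
                 n_splits = as.integer(n_splits),
                 n_train_per_class = as.integer(n_train_per_class),
                 cost_grid = cost_grid, cv_folds = as.integer(cv_folds),
                 flow = flow, crop_pad = as.integer(crop_pad),
                 lambda0 = lambda0, stride = stride,
                 upsample = as.integer(upsample), seed = as.integer(seed)),
            class = "experiment_config")
}

# union bounding box of two contours, padded and clipped to the frame
pair_crop <- function(ct1, ct2, h, w, pad) {
  xs <- c(ct1[, 1], ct2[, 1]); ys <- c(ct1[, 2], ct2[, 2])
  x0 <- max(1L, floor(min(xs)) - pad); x1 <- min(w, ceiling(max(xs)) + pad)
  y0 <- max(1L, floor(min(ys)) - pad); y1 <- min(h, ceiling(max(ys)) + pad)
  # dense SIFT needs at least 16 px a side
  while (x1 - x0 + 1 < 16) { x0 <- max(1L, x0 - 1L); x1 <- min(w, x1 + 1L) }
  while (y1 - y0 + 1 < 16) { y0 <- max(1L, y0 - 1L); y1 <- min(h, y1 + 1L) }
  list(x = x0:x1, y = y0:y1)
}

#' Extract the frame-pair feature sequence of a video
#'
#' For each frame pair `(i, i + interval)` (stride `interval` by default):
#' the contour deformation feature between the two ground-truth contours, and
#' the movement / appearance-change histograms from SIFT flow computed on the
#' cell's padded bounding box, restricted to the cell mask dilated by 2 px.
#' Pairs with a missing contour are skipped with a warning; an error is
#' raised if no pair survives.
#'
#' @param video a `synthetic_video`, or any list with `frames` (matrices) and
#'   `contours` (one closed contour per frame), or a frame directory path.
#' @param config `experiment_config`.
#' @return matrix with one row per frame pair (temporal order) and
#'   `L + 2R` named columns; attribute `pairs` records the frame indices.
#' @export
extract_video_features <- function(video, config = experiment_config()) {
  if (is.character(video)) video <- load_video(video)
  frames <- video$frames; contours <- video$contours
  T_ <- length(frames)
  delta <- config$interval
  if (T_ < delta + 1) stop("video has fewer than interval + 1 frames")
  stride <- if (is.null(config$stride)) delta else config$stride
  starts <- seq(1L, T_ - delta, by = stride)
  rows <- list(); pairs <- list()
  for (i in starts) {
    j <- i + delta
    ct1 <- contours[[i]]; ct2 <- contours[[j]]
    if (is.null(ct1) || is.null(ct2) || anyNA(ct1) || anyNA(ct2)) {
      warning(sprintf("missing contour for pair (%d, %d); skipped", i, j))
      next
    }
    f_dcs <- contour_deformation_feature(ct1, ct2, n = config$n_points,
                                         L = config$L, lambda0 = config$lambda0)
    h <- nrow(frames[[i]]); w <- ncol(frames[[i]])
    cr <- pair_crop(ct1, ct2, h, w, config$crop_pad)
    up <- max(1L, config$upsample %||% 1L)
    crop1 <- frames[[i]][cr$y, cr$x, drop = FALSE]
    crop2 <- frames[[j]][cr$y, cr$x, drop = FALSE]
    if (up > 1L) {
      crop1 <- crop1[rep(seq_len(nrow(crop1)), each = up),
                     rep(seq_len(ncol(crop1)), each = up), drop = FALSE]
      crop2 <- crop2[rep(seq_len(nrow(crop2)), each = up),
                     rep(seq_len(ncol(crop2)), each = up), drop = FALSE]
    }
    s1 <- dense_sift(crop1)
    s2 <- dense_sift(crop2)
    fl <- estimate_flow(s1, s2, config$flow)
    acf <- appearance_change_field(s1, s2, fl)
    mask <- dilate_mask(rasterize_polygon((ct1[, 1] - cr$x[1]) * up + 1,
                                          (ct1[, 2] - cr$y[1]) * up + 1,
                                          nrow(crop1), ncol(crop1)), 2L)
    f_mdf <- orient_histogram_mdf(fl, R = config$R, mask = mask)
    f_acf <- orient_histogram_acf(fl, acf, R = config$R, mask = mask)
    rows[[length(rows) + 1L]] <- combine_features(f_dcs, f_mdf, f_acf)
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(rows) == 0) stop("no usable frame pairs in video")
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- do.call(rbind, pairs)
  out
}

#' Extract features for every video of a dataset
#'
#' @param videos a `synthetic_dataset`, a list of videos, or a manifest data
#'   frame with `path` entries.
#' @param config `experiment_config`.
#' @param verbose print progress.
#' @return list of feature matrices, one per video.
#' @export
extract_dataset_features <- function(videos, config = experiment_config(),
                                     verbose = FALSE) {
  vids <- if (inherits(videos, "synthetic_dataset")) videos$videos
  else if (is.data.frame(videos)) lapply(videos$path, identity)
  else videos
  lapply(seq_along(vids), function(i) {
    if (verbose) message("extracting video ", i, "/", length(vids))
    extract_video_features(vids[[i]], config)
  })
}

# stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# penalty selection by stratified CV, then final linear SVM fit
fit_linear_svm <- function(x, y, cost_grid, cv_folds, seed) {
  y <- factor(y)
  best_cost <- cost_grid[1]
  if (length(cost_grid) > 1) {
    acc <- with_seed(seed, {
      fold <- stratified_folds(y, cv_folds)
      vapply(cost_grid, function(cst) {
        hits <- 0L
        for (f in seq_len(cv_folds)) {
          tr <- fold != f
          if (all(tr) || length(unique(y[tr])) < 2) next
          m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                          cost = cst, scale = FALSE)
          hits <- hits + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
        }
        hits / length(y)
      }, numeric(1))
    })
    best_cost <- cost_grid[which.max(acc)]
  }
  model <- e1071::svm(x, y, kernel = "linear", cost = best_cost, scale = FALSE)
  list(model = model, cost = best_cost)
}

# per-class precision/recall/F from a confusion matrix (true x predicted)
confusion_metrics <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = prec, recall = rec, f_score = f,
       accuracy = sum(tp) / sum(cm))
}

#' Run the random-split classification experiment
#'
#' For each split: sample `n_train_per_class` training videos per class, fit
#' the codebook (and optional PCA) on training frame-pair features only,
#' encode every video, select the SVM penalty by stratified cross-validation
#' on the training encodings, and evaluate on the held-out videos. With
#' `aggregation = "average"` videos are represented by the temporal mean of
#' their frame-pair features instead (the baseline aggregation).
#'
#' @param x a `synthetic_dataset`, a list of videos, or a precomputed list of
#'   per-video feature matrices (as from [extract_dataset_features()]).
#' @param labels class labels (taken from the dataset when `x` is one).
#' @param config `experiment_config`.
#' @param verbose print progress.
#' @return object of class `eval_report`: `per_split` data frame (accuracy,
#'   macro precision/recall/F in percent), `per_class` (per-split per-class
#'   precision/recall/F and accuracy), `confusions`, `summary` (mean and sd
#'   per metric), and `mAP` (mean per-class accuracy, percent).
#' @export
run_experiment <- function(x, labels = NULL, config = experiment_config(),
                           verbose = FALSE) {
  if (inherits(x, "synthetic_dataset")) {
    labels <- x$labels
    x <- x$videos
  }
  if (is.null(labels)) stop("labels are required")
  feats <- if (is.matrix(x[[1]])) x else extract_dataset_features(x, config, verbose)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(labels)
  small <- names(counts)[counts <= config$n_train_per_class]
  if (length(small) > 0) {
    stop("class(es) with too few videos for ", config$n_train_per_class,
         " training samples: ", paste(small, collapse = ", "))
  }
  n_video <- length(feats)
  split_rows <- list(); per_class <- list(); confusions <- list()
  class_acc <- matrix(NA_real_, config$n_splits, length(classes),
                      dimnames = list(NULL, classes))
  for (s in seq_len(config$n_splits)) {
    train_idx <- with_seed(config$seed + 101L * s, {
      unlist(lapply(classes, function(cl) {
        sample(which(labels == cl), config$n_train_per_class)
      }))
    })
    test_idx <- setdiff(seq_len(n_video), train_idx)
    if (config$aggregation == "average") {
      enc <- t(vapply(feats, colMeans, numeric(ncol(feats[[1]]))))
      svm_x_scale <- TRUE
    } else {
      xtrain <- do.call(rbind, feats[train_idx])
      pca <- NULL
      if (!is.null(config$d_prime) && config$d_prime < ncol(xtrain)) {
        pca <- fit_pca(xtrain, config$d_prime)
        xtrain <- project_pca(pca, xtrain)
      }
      cb_seed <- (config$seed + 997L * s) %% 2147483647L
      codebook <- if (config$scheme == "fv") {
        fit_gmm(xtrain, config$K, seed = cb_seed)
      } else {
        fit_kmeans_codebook(xtrain, config$K, seed = cb_seed)
      }
      enc <- t(vapply(feats, function(f) {
        as.numeric(encode_video(f, codebook, scheme = config$scheme,
                                k_nn = config$k_nn, tpp = config$tpp, pca = pca))
      }, numeric(encoding_length(config, ncol(feats[[1]])))))
      svm_x_scale <- FALSE
    }
    fit <- fit_linear_svm(enc[train_idx, , drop = FALSE], labels[train_idx],
                          config$cost_grid, config$cv_folds,
                          seed = (config$seed + 499L * s) %% 2147483647L)
    pred <- as.character(predict(fit$model, enc[test_idx, , drop = FALSE]))
    cm <- table(factor(labels[test_idx], levels = classes),
                factor(pred, levels = classes))
    met <- confusion_metrics(cm)
    split_rows[[s]] <- data.frame(split = s,
                                  accuracy = 100 * met$accuracy,
                                  precision = 100 * mean(met$precision),
                                  recall = 100 * mean(met$recall),
                                  f_score = 100 * mean(met$f_score),
                                  cost = fit$cost)
    per_class[[s]] <- data.frame(split = s, class = classes,
                                 precision = 100 * as.numeric(met$precision),
                                 recall = 100 * as.numeric(met$recall),
                                 f_score = 100 * as.numeric(met$f_score))
    class_acc[s, ] <- 100 * as.numeric(met$recall)
    confusions[[s]] <- cm
    if (verbose) message(sprintf("split %d: accuracy %.1f%%", s,
                                 100 * met$accuracy))
  }
  per_split <- do.call(rbind, split_rows)
  summ <- data.frame(
    metric = c("accuracy", "precision", "recall", "f_score"),
    mean = vapply(c("accuracy", "precision", "recall", "f_score"),
                  function(m) mean(per_split[[m]]), numeric(1)),
    sd = vapply(c("accuracy", "precision", "recall", "f_score"),
                function(m) stats::sd(per_split[[m]]), numeric(1)))
  structure(list(per_split = per_split,
                 per_class = do.call(rbind, per_class),
                 class_accuracy = class_acc,
                 confusions = confusions,
                 summary = summ,
                 mAP = mean(colMeans(class_acc))),
            class = "eval_report")
}

# dimension of a single encoded video under a config
encoding_length <- function(config, D) {
  d <- if (!is.null(config$d_prime)) min(config$d_prime, D) else D
  base <- switch(config$scheme,
                 fv = 2L * d * config$K,
                 vlad = d * config$K,
                 hvlad = 3L * d * config$K)
  if (isTRUE(config$tpp)) 6L * base else base
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation over", nrow(x$per_split), "random splits\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.2f +/- %.2f %%\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  cat(sprintf("  mAP       %.2f %%\n", x$mAP))
  invisible(x)
}

#' Histogram overlap of classification scores
#'
#' Bins two score samples on a shared grid, normalizes each histogram to unit
#' mass, and returns the summed bin-wise minimum: 1 for identical score
#' distributions, 0 for disjoint supports. The diagnostic used to compare the
#' discrimination of encoding schemes on a binary problem.
#'
#' @param scores_pos,scores_neg decision values of the two classes.
#' @param n_bins number of shared bins (ignored when `binwidth` given).
#' @param binwidth optional fixed bin width anchored at
#'   `floor(min / binwidth) * binwidth`.
#' @return overlap in `[0, 1]`, with attributes `breaks`, `hist_pos`,
#'   `hist_neg`.
#' @export
score_overlap <- function(scores_pos, scores_neg, n_bins = 20L, binwidth = NULL) {
  all_s <- c(scores_pos, scores_neg)
  if (is.null(binwidth)) {
    rng <- range(all_s)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    lo <- floor(min(all_s) / binwidth) * binwidth
    breaks <- seq(lo, max(all_s) + binwidth, by = binwidth)
  }
  bin <- function(s) {
    idx <- findInterval(s, breaks, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)
    tabulate(idx, length(breaks) - 1L)
  }
  hp <- bin(scores_pos); hn <- bin(scores_neg)
  ov <- sum(pmin(hp / sum(hp), hn / sum(hn)))
  structure(ov, breaks = breaks, hist_pos = hp, hist_neg = hn)
}

#' Score-overlap diagnostic for a binary training set
#'
#' Fits a linear SVM on the encoded training exemplars of a two-class
#' problem and computes the [score_overlap()] of the decision values of the
#' two classes (smaller overlap = better discrimination).
#'
#' @param encodings matrix of encoded videos (rows).
#' @param labels two-class labels.
#' @param cost SVM penalty.
#' @param ... passed to [score_overlap()].
#' @return list with `overlap`, `scores_pos`, `scores_neg` (positive class =
#'   first factor level).
#' @export
svm_score_overlap <- function(encodings, labels, cost = 1, ...) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("score overlap diagnostic requires a binary problem")
  m <- e1071::svm(encodings, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(predict(m, encodings, decision.values = TRUE), "decision.values")[, 1]
  pos <- levels(y)[1]
  sp <- dv[y == pos]; sn <- dv[y != pos]
  ov <- score_overlap(sp, sn, ...)
  list(overlap = as.numeric(ov), scores_pos = sp, scores_neg = sn,
       breaks = attr(ov, "breaks"))
}
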