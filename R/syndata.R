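# Synthetic single-cell videos with controllable contour deformation and
# intracellular streaming. One target cell per field: a closed star-shaped
# contour with smoothly time-varying radial Fourier modes, an interior
# brighter than background, and Gaussian-blob particles advected by a smooth
# velocity field, with optional split/merge/disappear appearance events.
# Ground-truth contours and displacement fields make every downstream stage
# testable.

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of a synthetic cell video
#'
#' @param frame_count number of frames (>= 2).
#' @param frame_size square frame side in pixels.
#' @param contour_base_radius mean cell radius in pixels.
#' @param deform_amplitude total relative radial perturbation, in `[0, 1)`;
#'   0 gives a static circle.
#' @param deform_n_modes number of angular Fourier modes of the deformation.
#' @param stream_speed mean intracellular displacement per frame, in pixels.
#' @param appearance_event_rate per-particle per-frame probability of a
#'   split/merge/disappear intensity event.
#' @param particle_count number of intracellular particles.
#' @param noise_sigma additive Gaussian noise, in 8-bit intensity units.
#' @param distractor_count dim bystander blobs (emulating red blood cells)
#'   placed strictly outside the target contour; 0 by default.
#' @param class_label label attached to videos generated with these params.
#' @return list of class `cell_video_params`.
#' @export
cell_video_params <- function(frame_count = 24L, frame_size = 64L,
                              contour_base_radius = frame_size * 0.28,
                              deform_amplitude = 0.1, deform_n_modes = 3L,
                              stream_speed = 1, appearance_event_rate = 0.02,
                              particle_count = 12L, noise_sigma = 2,
                              distractor_count = 0L,
                              class_label = "class1") {
  if (frame_count < 2) stop("frame_count must be >= 2")
  if (deform_amplitude < 0 || deform_amplitude >= 1) {
    stop("deform_amplitude must be in [0, 1) (self-intersection risk)")
  }
  if (stream_speed < 0) stop("stream_speed must be >= 0")
  if (particle_count < 1) stop("particle_count must be >= 1")
  if (appearance_event_rate < 0 || appearance_event_rate > 1) {
    stop("appearance_event_rate must be in [0, 1]")
  }
  structure(list(frame_count = as.integer(frame_count),
                 frame_size = as.integer(frame_size),
                 contour_base_radius = contour_base_radius,
                 deform_amplitude = deform_amplitude,
                 deform_n_modes = as.integer(deform_n_modes),
                 stream_speed = stream_speed,
                 appearance_event_rate = appearance_event_rate,
                 particle_count = as.integer(particle_count),
                 noise_sigma = noise_sigma,
                 distractor_count = as.integer(distractor_count %||% 0L),
                 class_label = class_label),
            class = "cell_video_params")
}

#' Generate a deforming closed contour sequence
#'
#' Star-shaped contour `r(theta, t) = R0 * (1 + sum_m a_m(t) cos(m*theta +
#' phi_m))` centred in the frame, with per-mode amplitudes varying
#' sinusoidally in time, each bounded by `deform_amplitude / deform_n_modes`
#' so the total perturbation never exceeds `deform_amplitude` and the contour
#' stays simple. With `deform_amplitude = 0` every contour is the same circle.
#'
#' @param params `cell_video_params`.
#' @param seed integer seed; identical (params, seed) give identical output.
#' @param n_vertices polygon vertices per contour.
#' @return list of `frame_count` closed contours (`n_vertices x 2` matrices).
#' @export
make_contour_sequence <- function(params, seed, n_vertices = 72L) {
  stopifnot(inherits(params, "cell_video_params"))
  with_seed(seed, {
    M <- params$deform_n_modes
    modes <- seq_len(M) + 1L               # m = 2, 3, ... (m = 1 looks like translation)
    freq <- sample(1:3, M, replace = TRUE) # temporal cycles over the clip
    psi <- stats::runif(M, 0, 2 * pi)      # temporal phases
    phi <- stats::runif(M, 0, 2 * pi)      # angular phases
    amp <- params$deform_amplitude / max(1L, M)
    cx <- (params$frame_size + 1) / 2
    theta <- (seq_len(n_vertices) - 1) / n_vertices * 2 * pi
    lapply(seq_len(params$frame_count), function(t) {
      a <- amp * sin(2 * pi * freq * (t - 1) / params$frame_count + psi)
      pert <- rep(0, n_vertices)
      for (j in seq_len(M)) pert <- pert + a[j] * cos(modes[j] * theta + phi[j])
      r <- params$contour_base_radius * (1 + pert)
      cbind(x = cx + r * cos(theta), y = cx + r * sin(theta))
    })
  })
}

# rejection-sample k points inside the polygon, shrunk toward its centroid
sample_points_in_polygon <- function(contour, k, shrink = 0.85) {
  ctr <- colMeans(contour)
  poly <- sweep(sweep(contour, 2, ctr) * shrink, 2, ctr, "+")
  lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < k) {
    need <- 4 * (k - nrow(out))
    cand <- cbind(stats::runif(need, lo[1], hi[1]), stats::runif(need, lo[2], hi[2]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], poly[, 1], poly[, 2])
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(k), , drop = FALSE]
}

# smooth taper: 1 well inside the mask, 0 at and outside the boundary
mask_taper <- function(mask, sigma = 4) {
  t <- pmax(0, (gaussian_blur(mask * 1, sigma) - 0.5) / 0.5)
  t * mask
}

# smooth random velocity field with mean magnitude `speed` inside the mask
random_velocity_field <- function(mask, speed, sigma = 6) {
  h <- nrow(mask); w <- ncol(mask)
  if (speed <= 0) return(list(u = matrix(0, h, w), v = matrix(0, h, w)))
  taper <- mask_taper(mask)
  u <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), sigma) * taper
  v <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), sigma) * taper
  mag <- sqrt(u^2 + v^2)
  mm <- mean(mag[mask])
  if (mm > 0) { u <- u * speed / mm; v <- v * speed / mm }
  list(u = u, v = v)
}

# analytic Gaussian blob accumulation on the pixel grid
render_particles <- function(particles, h, w) {
  img <- matrix(0, h, w)
  if (nrow(particles) == 0) return(img)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    if (p$amp == 0) next
    img <- img + p$amp * exp(-((X - p$x)^2 + (Y - p$y)^2) / (2 * p$sigma^2))
  }
  img
}

render_cell_frame <- function(contour, particles, frame_size,
                              background = 30, cell_intensity = 60) {
  mask <- rasterize_polygon(contour[, 1], contour[, 2], frame_size, frame_size)
  img <- background + cell_intensity * gaussian_blur(mask * 1, 1) +
    render_particles(particles, frame_size, frame_size)
  pmin(pmax(img, 0), 255)
}

# dim bystander blobs strictly outside the cell (no overlap with the target):
# sampled in the ring between 1.35x the cell radius and the frame border
sample_distractors <- function(params, contour) {
  k <- params$distractor_count %||% 0L
  if (is.null(k) || k < 1) return(NULL)
  ctr <- colMeans(contour)
  r_min <- 1.35 * max(sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2))
  out <- matrix(numeric(0), 0, 2)
  n <- params$frame_size
  tries <- 0
  while (nrow(out) < k && tries < 200) {
    tries <- tries + 1
    cand <- c(stats::runif(1, 2, n - 1), stats::runif(1, 2, n - 1))
    if (sqrt(sum((cand - ctr)^2)) >= r_min + 3) out <- rbind(out, cand)
  }
  if (nrow(out) == 0) return(NULL)
  data.frame(x = out[, 1], y = out[, 2],
             amp = stats::runif(nrow(out), 15, 30),
             sigma = stats::runif(nrow(out), 2, 3.5))
}

new_particles <- function(pos) {
  data.frame(x = pos[, 1], y = pos[, 2],
             amp = stats::runif(nrow(pos), 40, 90),
             sigma = stats::runif(nrow(pos), 1.5, 3))
}

# field value at (possibly fractional) positions, by nearest pixel
field_at <- function(field, x, y) {
  h <- nrow(field$u); w <- ncol(field$u)
  xi <- pmin(pmax(round(x), 1), w)
  yi <- pmin(pmax(round(y), 1), h)
  idx <- yi + (xi - 1) * h
  cbind(field$u[idx], field$v[idx])
}

#' Generate a streaming frame pair with exact ground-truth flow
#'
#' Renders a single static-contour frame with intracellular particles, draws
#' a smooth random velocity field (zero outside the cell) of mean interior
#' magnitude `stream_speed`, and produces the second frame by backward
#' warping: `frame2(p) = frame1(p - w(p))`, so warping frame 1 through the
#' returned field reproduces frame 2 exactly up to appearance events and
#' noise. With probability `appearance_event_rate` a particle additionally
#' splits into two half-amplitude blobs, merges (doubles), or disappears in
#' frame 2. `uniform_motion = c(dx, dy)` replaces the random field by a
#' global translation (exact under both flow conventions).
#'
#' @param params `cell_video_params`.
#' @param seed integer seed.
#' @param uniform_motion optional length-2 displacement for the global
#'   translation mode.
#' @return list with `frame1`, `frame2` (matrices), `flow` (list `u`, `v`),
#'   `mask` (cell interior) and `contour`.
#' @export
make_streaming_pair <- function(params, seed, uniform_motion = NULL) {
  stopifnot(inherits(params, "cell_video_params"))
  n <- params$frame_size
  with_seed(seed, {
    theta <- (0:71) / 72 * 2 * pi
    cx <- (n + 1) / 2
    contour <- cbind(cx + params$contour_base_radius * cos(theta),
                     cx + params$contour_base_radius * sin(theta))
    mask <- rasterize_polygon(contour[, 1], contour[, 2], n, n)
    particles <- new_particles(sample_points_in_polygon(contour, params$particle_count))
    distractors <- sample_distractors(params, contour)
    field <- if (is.null(uniform_motion)) {
      random_velocity_field(mask, params$stream_speed)
    } else {
      list(u = matrix(uniform_motion[1], n, n), v = matrix(uniform_motion[2], n, n))
    }
    clean1 <- 30 + 60 * gaussian_blur(mask * 1, 1) + render_particles(particles, n, n)
    if (!is.null(distractors)) clean1 <- clean1 + render_particles(distractors, n, n)
    # noise drawn before event sampling so event-rate settings share it
    noise1 <- matrix(stats::rnorm(n * n, 0, params$noise_sigma), n, n)
    noise2 <- matrix(stats::rnorm(n * n, 0, params$noise_sigma), n, n)
    clean2 <- warp_image(clean1, field$u, field$v)
    if (params$appearance_event_rate > 0) {
      hit <- stats::runif(nrow(particles)) < params$appearance_event_rate
      adv <- cbind(particles$x, particles$y) + field_at(field, particles$x, particles$y)
      for (i in which(hit)) {
        type <- sample(c("split", "merge", "vanish"), 1)
        p <- particles[i, ]
        blob <- function(x0, y0, a) {
          X <- matrix(rep(seq_len(n), each = n), n, n)
          Y <- matrix(rep(seq_len(n), times = n), n, n)
          a * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * p$sigma^2))
        }
        if (type == "vanish") {
          clean2 <- clean2 - blob(adv[i, 1], adv[i, 2], p$amp)
        } else if (type == "split") {
          dir <- stats::runif(1, 0, 2 * pi)
          off <- 2.5 * c(cos(dir), sin(dir))
          clean2 <- clean2 - blob(adv[i, 1], adv[i, 2], p$amp) +
            blob(adv[i, 1] + off[1], adv[i, 2] + off[2], p$amp / 2) +
            blob(adv[i, 1] - off[1], adv[i, 2] - off[2], p$amp / 2)
        } else {
          clean2 <- clean2 + blob(adv[i, 1], adv[i, 2], p$amp)
        }
      }
    }
    list(frame1 = pmin(pmax(clean1 + noise1, 0), 255),
         frame2 = pmin(pmax(clean2 + noise2, 0), 255),
         flow = field, mask = mask, contour = contour)
  })
}

#' Generate a full synthetic cell video
#'
#' Combines a deforming contour sequence with particle streaming: each frame
#' renders the cell body from its ground-truth contour plus the current
#' particle configuration; between frames, particles are advected by a fresh
#' smooth velocity field (mean interior magnitude `stream_speed`) and undergo
#' appearance events at `appearance_event_rate`. The per-step velocity fields
#' are returned as ground-truth flows; they describe the interior streaming
#' (contour deformation is encoded in the contours themselves).
#'
#' @param params `cell_video_params`.
#' @param seed integer seed.
#' @return object of class `synthetic_video`: `frames` (list of matrices),
#'   `contours` (one closed contour per frame), `true_flows` (length
#'   `frame_count - 1` list of `u`/`v` matrices), `params`, `seed`.
#' @export
make_synthetic_video <- function(params, seed) {
  stopifnot(inherits(params, "cell_video_params"))
  n <- params$frame_size
  contours <- make_contour_sequence(params, seed)
  with_seed(seed + 1L, {
    particles <- new_particles(sample_points_in_polygon(contours[[1]],
                                                        params$particle_count))
    distractors <- sample_distractors(params, contours[[1]])
    bg_extra <- if (is.null(distractors)) 0 else render_particles(distractors, n, n)
    frames <- vector("list", params$frame_count)
    flows <- vector("list", params$frame_count - 1L)
    for (t in seq_len(params$frame_count)) {
      noise <- matrix(stats::rnorm(n * n, 0, params$noise_sigma), n, n)
      frames[[t]] <- pmin(pmax(
        render_cell_frame(contours[[t]], particles, n) + bg_extra + noise, 0), 255)
      if (t == params$frame_count) break
      mask <- rasterize_polygon(contours[[t]][, 1], contours[[t]][, 2], n, n)
      field <- random_velocity_field(mask, params$stream_speed)
      flows[[t]] <- field
      shift <- field_at(field, particles$x, particles$y)
      particles$x <- particles$x + shift[, 1]
      particles$y <- particles$y + shift[, 2]
      if (params$appearance_event_rate > 0) {
        hit <- stats::runif(nrow(particles)) < params$appearance_event_rate
        for (i in which(hit)) {
          type <- sample(c("split", "merge", "vanish"), 1)
          if (type == "vanish") {
            particles$amp[i] <- 0
          } else if (type == "merge") {
            particles$amp[i] <- particles$amp[i] * 2
          } else {
            dir <- stats::runif(1, 0, 2 * pi)
            twin <- particles[i, ]
            particles$amp[i] <- particles$amp[i] / 2
            particles$x[i] <- particles$x[i] + 2.5 * cos(dir)
            particles$y[i] <- particles$y[i] + 2.5 * sin(dir)
            twin$amp <- particles$amp[i]
            twin$x <- twin$x - 2.5 * cos(dir)
            twin$y <- twin$y - 2.5 * sin(dir)
            particles <- rbind(particles, twin)
          }
        }
      }
    }
    structure(list(frames = frames, contours = contours, true_flows = flows,
                   params = params, seed = seed),
              class = "synthetic_video")
  })
}

#' Write a synthetic video to disk
#'
#' Frames become zero-padded grayscale PNGs, contours a `contours.csv` with
#' columns frame, point_index, x, y; ground-truth flows are optionally
#' written in Middlebury .flo format.
#'
#' @param video `synthetic_video`.
#' @param dir output directory (created if needed).
#' @param write_flows also write `flow_###.flo` files.
#' @return `dir`, invisibly.
#' @export
write_synthetic_video <- function(video, dir, write_flows = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(video$frames)) {
    png::writePNG(pmin(pmax(video$frames[[t]] / 255, 0), 1),
                  file.path(dir, sprintf("frame_%03d.png", t)))
  }
  rows <- do.call(rbind, lapply(seq_along(video$contours), function(t) {
    ct <- video$contours[[t]]
    data.frame(frame = t, point_index = seq_len(nrow(ct)),
               x = ct[, 1], y = ct[, 2])
  }))
  utils::write.csv(rows, file.path(dir, "contours.csv"), row.names = FALSE)
  if (write_flows) {
    for (t in seq_along(video$true_flows)) {
      write_flo(video$true_flows[[t]], file.path(dir, sprintf("flow_%03d.flo", t)))
    }
  }
  invisible(dir)
}

#' Load a video from a frame directory and contour CSV
#'
#' @param path directory of PNG frames (sorted by name).
#' @param contours path to a contours CSV (frame, point_index, x, y);
#'   defaults to `contours.csv` inside `path`.
#' @return list with `frames` (matrices, 0-255 scale) and `contours`.
#' @export
load_video <- function(path, contours = file.path(path, "contours.csv")) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", path)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255
  })
  tab <- utils::read.csv(contours)
  cts <- lapply(split(tab, tab$frame), function(d) {
    d <- d[order(d$point_index), ]
    cbind(x = d$x, y = d$y)
  })
  cts <- cts[order(as.integer(names(cts)))]
  list(frames = frames, contours = cts)
}

#' Generate a labeled synthetic dataset
#'
#' Builds a balanced collection of `videos_per_class` videos for each class
#' parameter set. Classes must differ in `deform_amplitude` and/or
#' `stream_speed` (identical dynamics would make them indistinguishable by
#' construction). With `dir` given, every video is written to its own
#' subdirectory and a `manifest.csv` (video_id, path, contours, label) is
#' written; generation is fully determined by `seed`.
#'
#' @param class_params list of `cell_video_params`, one per class (>= 2).
#' @param videos_per_class videos to generate per class.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return list of class `synthetic_dataset`: `videos` (list of
#'   `synthetic_video`), `labels` (character vector), `manifest` (data frame).
#' @export
make_dataset <- function(class_params, videos_per_class, seed, dir = NULL) {
  if (length(class_params) < 2) stop("need at least 2 classes")
  key <- vapply(class_params, function(p) {
    paste(p$deform_amplitude, p$stream_speed)
  }, character(1))
  if (anyDuplicated(key)) {
    stop("two classes share identical deform_amplitude and stream_speed; ",
         "they would be indistinguishable by construction")
  }
  videos <- list(); labels <- character(0); rows <- list()
  idx <- 0L
  for (c_i in seq_along(class_params)) {
    p <- class_params[[c_i]]
    for (j in seq_len(videos_per_class)) {
      idx <- idx + 1L
      vid_seed <- (seed + 7919L * idx) %% 2147483647L
      v <- make_synthetic_video(p, vid_seed)
      id <- sprintf("video_%03d", idx)
      vpath <- if (is.null(dir)) NA_character_ else file.path(dir, id)
      if (!is.null(dir)) write_synthetic_video(v, vpath)
      videos[[idx]] <- v
      labels[idx] <- p$class_label
      rows[[idx]] <- data.frame(video_id = id, path = vpath,
                                contours = if (is.null(dir)) NA_character_ else
                                  file.path(vpath, "contours.csv"),
                                label = p$class_label)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(videos = videos, labels = labels, manifest = manifest),
            class = "synthetic_dataset")
}
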