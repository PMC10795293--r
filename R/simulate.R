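#' Configuration for the synthetic rosette simulator
#'
#' Defines a top-view rosette time series: leaves emerge in phyllotactic
#' arrangement around a fixed center, grow along a logistic curve, and
#' move slightly between frames. Defaults mirror the scale of a
#' chlorophyll-fluorescence phenotyping run: 57 timepoints per plant, a
#' handful of leaves present in the first frame and new leaves emerging
#' throughout, 137.5 degree divergence as in Arabidopsis.
#'
#' @param image_shape Image dimensions `c(height, width)` in pixels.
#' @param n_frames Number of timepoints, default 57.
#' @param n_leaves_final Total leaves by the end of the series, default 15.
#' @param emergence 0-based frame of first appearance per leaf; default:
#'   4 leaves at frame 0 (cotyledons plus first true leaves), the rest
#'   evenly spaced through the series.
#' @param phyllotaxis_deg Divergence angle between successive leaves,
#'   default 137.5.
#' @param initial_length,max_length Leaf length (major axis, pixels) at
#'   emergence asymptote and at maturity.
#' @param growth_rate,growth_midpoint Logistic growth parameters: length
#'   follows `L0 + (Lmax - L0) / (1 + exp(-rate * (age - midpoint)))` with
#'   age in frames.
#' @param width_ratio Leaf width as a fraction of its length, default 0.5.
#' @param center_offset Gap (pixels) between rosette center and the leaf
#'   blade's inner end, default 4.
#' @param angle_jitter_sd_deg Per-frame angular jitter sd (diel leaf
#'   movement), default 1.5 degrees.
#' @param night_every Every `night_every`-th frame gets an extra large
#'   angular jitter (`night_jitter_sd_deg`), emulating strong day-night
#'   transition movement; `NA` (default) disables it.
#' @param night_jitter_sd_deg Sd of the extra night-transition jitter.
#' @param dropout Probability that a leaf's detection is missing in a
#'   frame, default 0.05.
#' @param boundary_jitter Maximum morphological dilation/erosion radius
#'   (pixels) applied to surviving detections, default 1.
#' @param fp_rate Expected false-positive blobs per frame (Poisson),
#'   default 0.05.
#' @param trait_models Named list of per-trait generative models, each a
#'   list with `baseline` (mean of the per-leaf baseline), `baseline_sd`
#'   (between-leaf sd), `amp` and `tau` (saturating age trend
#'   `baseline + amp * (1 - exp(-age / tau))`). Defaults provide `FvFm`
#'   around 0.75 and `PhiPSII` around 0.55, in normalized `[0, 1]` units.
#' @param pixel_noise_sd Per-pixel Gaussian noise sd on trait images,
#'   default 0.02.
#' @param traits Generate trait image stacks (default `TRUE`); disable for
#'   tracking-only benchmarks. Geometry and detection noise use RNG
#'   streams independent of the trait stream, so ground truth and
#'   detections are identical either way.
#' @param seed Integer seed; the full simulation output is deterministic
#'   given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(120L, 120L),
                       n_frames = 57L,
                       n_leaves_final = 15L,
                       emergence = NULL,
                       phyllotaxis_deg = 137.5,
                       initial_length = 3,
                       max_length = 30,
                       growth_rate = 0.3,
                       growth_midpoint = 12,
                       width_ratio = 0.5,
                       center_offset = 4,
                       angle_jitter_sd_deg = 1.5,
                       night_every = NA,
                       night_jitter_sd_deg = 10,
                       dropout = 0.05,
                       boundary_jitter = 1L,
                       fp_rate = 0.05,
                       trait_models = list(
                         FvFm = list(baseline = 0.75, baseline_sd = 0.02,
                                     amp = 0.04, tau = 10),
                         PhiPSII = list(baseline = 0.55, baseline_sd = 0.03,
                                        amp = 0.06, tau = 10)),
                       pixel_noise_sd = 0.02,
                       traits = TRUE,
                       seed = 1L) {
  if (is.null(emergence)) {
    n0 <- min(4L, n_leaves_final)
    later <- n_leaves_final - n0
    emergence <- c(rep(0L, n0),
                   if (later > 0) as.integer(round(
                     seq(5, max(6, n_frames - 2), length.out = later))))
  }
  stopifnot(length(emergence) == n_leaves_final, all(emergence < n_frames),
            dropout >= 0, dropout <= 1, fp_rate >= 0,
            initial_length > 0, max_length >= initial_length)
  structure(
    list(image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
         n_leaves_final = as.integer(n_leaves_final),
         emergence = as.integer(emergence),
         phyllotaxis_deg = phyllotaxis_deg,
         initial_length = initial_length, max_length = max_length,
         growth_rate = growth_rate, growth_midpoint = growth_midpoint,
         width_ratio = width_ratio, center_offset = center_offset,
         angle_jitter_sd_deg = angle_jitter_sd_deg,
         night_every = night_every, night_jitter_sd_deg = night_jitter_sd_deg,
         dropout = dropout, boundary_jitter = as.integer(boundary_jitter),
         fp_rate = fp_rate, trait_models = trait_models,
         pixel_noise_sd = pixel_noise_sd, traits = isTRUE(traits),
         seed = as.integer(seed)),
    class = "sim_config")
}

# Filled-ellipse rasterization: pixel centers (0-based row/col) inside
# x'^2/a^2 + y'^2/b^2 <= 1 after rotation by theta (x = col, y = row).
render_ellipse <- function(dim, ey, ex, theta, a, b) {
  h <- dim[1]; w <- dim[2]
  ext <- max(a, b) + 1
  r0 <- max(0, floor(ey - ext)); r1 <- min(h - 1, ceiling(ey + ext))
  c0 <- max(0, floor(ex - ext)); c1 <- min(w - 1, ceiling(ex + ext))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - ey, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - ex)
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  rc <- which(inside, arr.ind = TRUE)
  if (!nrow(rc)) return(integer(0))
  as.integer((rows[rc[, 1]] + 1L) + cols[rc[, 2]] * h)
}

leaf_length <- function(age, cfg) {
  cfg$initial_length + (cfg$max_length - cfg$initial_length) *
    stats::plogis(cfg$growth_rate * (age - cfg$growth_midpoint))
}

trait_value <- function(model, baseline, age) {
  min(1, max(0, baseline + model$amp * (1 - exp(-age / model$tau))))
}

#' Simulate a rosette time series with ground truth
#'
#' Renders each leaf as a filled ellipse radiating from the image center
#' at angle `k * phyllotaxis + jitter`, with logistic length growth and
#' width proportional to length. Younger leaves are drawn on top, so
#' overlapping regions belong to the younger leaf (occlusion). The
#' ground-truth label of a leaf equals its emergence order and is constant
#' over its lifetime; a leaf rendered with zero visible pixels in a frame
#' is omitted from that frame's ground truth.
#'
#' The output bundles the noise-free ground truth, detector-like noisy
#' detections (via [apply_detection_noise()]), per-trait image stacks, and
#' generating-value tables, and is byte-identical across runs with the
#' same seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `rosette_sim`: `config`; `gt_frames` (list
#'   of [label_frame()]); `gt_tracks` (`track_set`); `detections` (noisy
#'   per-frame lists of [instance_mask()]); `trait_stacks` (named list of
#'   per-frame [trait_image()] lists); `gt_track_table`; `gt_trait_table`
#'   (tibble `track_id, frame_index, trait_name, true_value`).
#' @export
simulate_rosette <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$image_shape[1]; w <- config$image_shape[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  n <- config$n_leaves_final
  base_angle <- (seq_len(n) - 1) * config$phyllotaxis_deg * pi / 180

  # pass 1 (geometry stream): angular jitter, rendered leaves, gt labels
  geom <- withr::with_seed(config$seed, {
    gt_frames <- vector("list", config$n_frames)
    pix_frames <- vector("list", config$n_frames)
    clipped <- FALSE
    for (f in seq_len(config$n_frames)) {
      t0 <- f - 1L
      labels <- matrix(0L, h, w)
      jit <- stats::rnorm(n, 0, config$angle_jitter_sd_deg * pi / 180)
      if (!is.na(config$night_every) && config$night_every > 0 &&
          t0 %% config$night_every == 0L && t0 > 0L) {
        jit <- jit + stats::rnorm(n, 0, config$night_jitter_sd_deg * pi / 180)
      }
      ages <- t0 - config$emergence
      pix <- vector("list", n)
      for (k in seq_len(n)) {
        if (ages[k] < 0) next
        len <- leaf_length(ages[k], config)
        a <- len / 2
        b <- config$width_ratio * len / 2
        theta <- base_angle[k] + jit[k]
        d <- config$center_offset + a
        full <- render_ellipse(c(h, w), cy + d * sin(theta), cx + d * cos(theta),
                               theta, a, b)
        if (length(full) < ceiling(pi * a * b) / 2) clipped <- TRUE
        pix[[k]] <- full
        labels[full] <- k  # ascending k: younger leaves painted on top
      }
      gt_frames[[f]] <- label_frame(labels, frame_index = t0)
      pix_frames[[f]] <- pix
    }
    list(gt_frames = gt_frames, pix_frames = pix_frames, clipped = clipped)
  })
  if (geom$clipped) {
    warning("some leaves were clipped at the image bounds", call. = FALSE)
  }
  gt_frames <- geom$gt_frames

  # pass 2 (trait stream): per-leaf baselines, trait images, true values
  trait_stacks <- list()
  trait_rows <- list()
  if (config$traits && length(config$trait_models)) {
    ts <- withr::with_seed(config$seed + 1L, {
      baselines <- lapply(config$trait_models, function(md) {
        stats::rnorm(n, md$baseline, md$baseline_sd)
      })
      stacks <- lapply(config$trait_models, function(md) {
        vector("list", config$n_frames)
      })
      rows <- list()
      for (f in seq_len(config$n_frames)) {
        t0 <- f - 1L
        ages <- t0 - config$emergence
        labels <- gt_frames[[f]]$labels
        pix <- geom$pix_frames[[f]]
        for (tn in names(config$trait_models)) {
          md <- config$trait_models[[tn]]
          vals <- matrix(0, h, w)
          for (k in seq_len(n)) {
            if (ages[k] < 0) next
            own <- pix[[k]][labels[pix[[k]]] == k]
            if (!length(own)) next
            v <- trait_value(md, baselines[[tn]][k], ages[k])
            vals[own] <- v + stats::rnorm(length(own), 0, config$pixel_noise_sd)
            rows[[length(rows) + 1L]] <-
              tibble::tibble(track_id = k, frame_index = t0, trait_name = tn,
                             true_value = v)
          }
          vals[vals < 0] <- 0; vals[vals > 1] <- 1
          stacks[[tn]][[f]] <- trait_image(vals, trait_name = tn,
                                           frame_index = t0)
        }
      }
      list(stacks = stacks, rows = rows)
    })
    trait_stacks <- ts$stacks
    trait_rows <- ts$rows
  }

  # pass 3 (detection-noise stream)
  detections <- apply_detection_noise(gt_frames, config,
                                      seed = config$seed + 2L)
  gt_tracks <- trackset_from_labels(gt_frames, plant_id = config$seed)

  structure(
    list(config = config,
         gt_frames = gt_frames,
         gt_tracks = gt_tracks,
         detections = detections,
         trait_stacks = trait_stacks,
         gt_track_table = track_table(gt_tracks),
         gt_trait_table = dplyr::bind_rows(trait_rows)),
    class = "rosette_sim")
}

#' @export
print.rosette_sim <- function(x, ...) {
  cat(sprintf("<rosette_sim> seed %d: %d frames, %d leaves, %dx%d px, traits %s\n",
              x$config$seed, x$config$n_frames, x$config$n_leaves_final,
              x$config$image_shape[1], x$config$image_shape[2],
              paste(names(x$trait_stacks), collapse = "/")))
  invisible(x)
}

#' Degrade ground-truth frames into detector-like detections
#'
#' Emulates the failure modes of an instance-segmentation detector: each
#' ground-truth instance is independently dropped with probability
#' `config$dropout` (false negatives, the dominant association hazard);
#' surviving masks are morphologically dilated or eroded by up to
#' `config$boundary_jitter` pixels; false-positive blobs (small discs at
#' random positions) are injected at Poisson rate `config$fp_rate` per
#' frame. Confidences: real detections draw from `[0.9, 1.0]`, false
#' positives from `[0.3, 0.95]` — the bands overlap at 0.9 so confidence
#' filtering is a meaningful stage.
#'
#' @param gt_frames List of [label_frame()] objects.
#' @param config A [sim_config()] supplying the noise parameters.
#' @param seed Optional seed for standalone calls; `NULL` (default)
#'   continues from the current RNG state, as when called inside
#'   [simulate_rosette()].
#' @return List with one element per frame, each a list of
#'   [instance_mask()] objects (surviving instances in label order, then
#'   false positives).
#' @export
apply_detection_noise <- function(gt_frames, config, seed = NULL) {
  run <- function() {
    lapply(gt_frames, function(fr) {
      ms <- masks_from_labels(fr)
      out <- list()
      for (m in ms) {
        if (stats::runif(1) < config$dropout) next
        idx <- jitter_mask_idx(m, config$boundary_jitter)
        out[[length(out) + 1L]] <-
          instance_mask(idx, dim = fr$dim,
                        confidence = stats::runif(1, 0.9, 1.0),
                        frame_index = fr$frame_index,
                        local_id = length(out) + 1L)
      }
      n_fp <- stats::rpois(1, config$fp_rate)
      for (i in seq_len(n_fp)) {
        r <- stats::runif(1, 2, 4)
        ey <- stats::runif(1, r, fr$dim[1] - 1 - r)
        ex <- stats::runif(1, r, fr$dim[2] - 1 - r)
        idx <- render_ellipse(fr$dim, ey, ex, 0, r, r)
        if (!length(idx)) next
        out[[length(out) + 1L]] <-
          instance_mask(idx, dim = fr$dim,
                        confidence = stats::runif(1, 0.3, 0.95),
                        frame_index = fr$frame_index,
                        local_id = length(out) + 1L)
      }
      out
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Random morphological jitter of a mask boundary: dilate or erode by a
# radius drawn from 0..max_radius. An erosion that would annihilate the
# mask is discarded (detections keep area >= 1).
jitter_mask_idx <- function(mask, max_radius) {
  if (max_radius < 1L) return(mask$idx)
  r <- sample(0:max_radius, 1)
  if (r == 0L) return(mask$idx)
  m <- mask_matrix(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "diamond")
  out <- if (sample(c(TRUE, FALSE), 1)) {
    EBImage::dilate(m, brush)
  } else {
    EBImage::erode(m, brush)
  }
  idx <- which(out != 0)
  if (!length(idx)) mask$idx else idx
}

#' Filter detections by confidence
#'
#' Drops masks whose confidence falls below the cutoff (masks without a
#' confidence are kept). Applied before tracking or evaluation; the 0.9
#' default matches the detection-evaluation protocol.
#'
#' @param frames Per-frame lists of [instance_mask()] objects.
#' @param min_confidence Cutoff, default 0.9.
#' @return Filtered per-frame lists.
#' @export
filter_confidence <- function(frames, min_confidence = 0.9) {
  lapply(frames, function(fr) {
    Filter(function(m) is.na(m$confidence) || m$confidence >= min_confidence,
           fr)
  })
}

#' Write simulator output to disk
#'
#' Writes ground-truth label images (16-bit TIFF), a COCO-style JSON of
#' the noisy detections (run-length encoded, with scores), per-trait
#' float-TIFF stacks, and the ground-truth track and trait CSV tables.
#'
#' @param sim A [simulate_rosette()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "rosette_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(dir, "gt_labels")
  dir.create(gt_dir, showWarnings = FALSE)
  for (fr in sim$gt_frames) {
    write_label_frame(fr, file.path(gt_dir, sprintf("frame_%03d.tif",
                                                    fr$frame_index)))
  }
  for (tn in names(sim$trait_stacks)) {
    tdir <- file.path(dir, paste0("trait_", tn))
    dir.create(tdir, showWarnings = FALSE)
    for (ti in sim$trait_stacks[[tn]]) {
      tiff::writeTIFF(ti$values, file.path(tdir, sprintf("frame_%03d.tif",
                                                         ti$frame_index)),
                      bits.per.sample = 32L)
    }
  }
  write_detections_json(sim$detections, file.path(dir, "detections.json"))
  utils::write.csv(sim$gt_track_table, file.path(dir, "gt_tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$gt_trait_table, file.path(dir, "gt_traits.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write per-frame detections as COCO-style JSON
#'
#' Masks are stored as uncompressed column-major run-length encodings with
#' their confidences in the `score` field; [read_annotations()] reads the
#' file back.
#'
#' @param frames Per-frame lists of [instance_mask()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detections_json <- function(frames, path) {
  dims <- NULL
  for (fr in frames) for (m in fr) dims <- m$dim
  if (is.null(dims)) dims <- c(0L, 0L)
  images <- lapply(seq_along(frames), function(f) {
    list(id = f, height = dims[1], width = dims[2], frame_index = f - 1L)
  })
  anns <- list()
  for (f in seq_along(frames)) {
    for (m in frames[[f]]) {
      bin <- integer(prod(m$dim))
      bin[m$idx] <- 1L
      runs <- rle(c(0L, bin))
      counts <- runs$lengths
      counts[1] <- counts[1] - 1L  # drop the prepended sentinel
      ann <- list(id = length(anns) + 1L, image_id = f,
                  segmentation = list(size = as.list(m$dim),
                                      counts = as.list(counts)))
      if (!is.na(m$confidence)) ann$score <- m$confidence
      anns[[length(anns) + 1L]] <- ann
    }
  }
  jsonlite::write_json(list(images = images, annotations = anns), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
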