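# a small, fast configuration used throughout these tests
small_cfg <- function(...) {
  sim_config(image_shape = c(64L, 64L), n_frames = 10L, n_leaves_final = 5L,
             emergence = c(0L, 0L, 3L, 5L, 8L), max_length = 18, ...)
}

test_that("equal seeds give identical output; traits do not perturb geometry", {
  s1 <- simulate_rosette(small_cfg(seed = 4L))
  s2 <- simulate_rosette(small_cfg(seed = 4L))
  expect_identical(s1$gt_frames, s2$gt_frames)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$trait_stacks, s2$trait_stacks)

  s3 <- simulate_rosette(small_cfg(seed = 4L, traits = FALSE))
  expect_identical(s1$gt_frames, s3$gt_frames)
  expect_identical(s1$detections, s3$detections)
  expect_length(s3$trait_stacks, 0)

  s4 <- simulate_rosette(small_cfg(seed = 5L))
  expect_false(identical(s1$gt_frames, s4$gt_frames))
})

test_that("a single jitter-free leaf grows monotonically as one stable track", {
  cfg <- sim_config(image_shape = c(64L, 64L), n_frames = 8L,
                    n_leaves_final = 1L, emergence = 0L,
                    angle_jitter_sd_deg = 0, dropout = 0, boundary_jitter = 0L,
                    fp_rate = 0, max_length = 18, seed = 2L)
  sim <- simulate_rosette(cfg)
  expect_length(sim$gt_tracks$tracks, 1)
  tab <- sim$gt_track_table
  expect_equal(nrow(tab), 8L)
  expect_true(all(diff(tab$area) >= 0))  # logistic growth, no shrinkage
  # ground-truth label constant over the leaf's lifetime
  labs <- vapply(sim$gt_frames, function(fr) {
    setdiff(unique(as.vector(fr$labels)), 0L)
  }, integer(1))
  expect_equal(labs, rep(1L, 8))
})

test_that("ground-truth leaf counts reproduce the emergence schedule", {
  sim <- simulate_rosette(small_cfg(seed = 9L, traits = FALSE))
  counts <- leaf_count_series(sim$gt_tracks)
  # emergence (0,0,3,5,8) -> 2 leaves until frame 2, then 3, 4, 5
  expect_equal(counts$n_leaves, c(2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L))
})

test_that("zero noise reproduces ground truth; full dropout empties frames", {
  clean <- simulate_rosette(small_cfg(seed = 3L, dropout = 0,
                                      boundary_jitter = 0L, fp_rate = 0,
                                      traits = FALSE))
  for (f in seq_along(clean$gt_frames)) {
    gt_masks <- masks_from_labels(clean$gt_frames[[f]])
    dets <- clean$detections[[f]]
    expect_length(dets, length(gt_masks))
    for (k in seq_along(dets)) {
      expect_identical(dets[[k]]$idx, gt_masks[[k]]$idx)
      expect_gte(dets[[k]]$confidence, 0.9)
    }
  }

  gone <- simulate_rosette(small_cfg(seed = 3L, dropout = 1, fp_rate = 0,
                                     traits = FALSE))
  expect_true(all(lengths(gone$detections) == 0))
})

test_that("empirical dropout frequency matches the configured probability", {
  base <- simulate_rosette(small_cfg(seed = 12L, traits = FALSE))
  n_gt <- sum(vapply(base$gt_frames, function(fr) {
    length(setdiff(unique(as.vector(fr$labels)), 0L))
  }, integer(1)))
  dropped <- 0
  n_seeds <- 20
  noise_cfg <- small_cfg(seed = 12L, dropout = 0.1, fp_rate = 0)
  for (s in seq_len(n_seeds)) {
    dets <- apply_detection_noise(base$gt_frames, noise_cfg,
                                  seed = 1000L + s)
    dropped <- dropped + (n_gt - sum(lengths(dets)))
  }
  expect_lt(abs(dropped / (n_seeds * n_gt) - 0.1), 0.03)
})

test_that("confidence bands separate real detections from false positives", {
  sim <- simulate_rosette(small_cfg(seed = 6L, dropout = 0, fp_rate = 2,
                                    traits = FALSE))
  n_real_per_frame <- vapply(sim$gt_frames, function(fr) {
    length(setdiff(unique(as.vector(fr$labels)), 0L))
  }, integer(1))
  fp_conf <- real_conf <- double(0)
  for (f in seq_along(sim$detections)) {
    confs <- vapply(sim$detections[[f]], `[[`, double(1), "confidence")
    real_conf <- c(real_conf, confs[seq_len(n_real_per_frame[f])])
    fp_conf <- c(fp_conf, confs[-seq_len(n_real_per_frame[f])])
  }
  expect_true(all(real_conf >= 0.9))
  expect_true(length(fp_conf) > 0)
  expect_true(all(fp_conf >= 0.3 & fp_conf <= 0.95))
  # the bands overlap at 0.9 by design, so filtering is a real stage
  kept <- filter_confidence(sim$detections, 0.9)
  expect_lt(sum(lengths(kept)), sum(lengths(sim$detections)))
})

test_that("simulator output writes to disk and reads back consistently", {
  sim <- simulate_rosette(small_cfg(seed = 10L))
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  back <- read_label_frame(file.path(dir, "gt_labels", "frame_003.tif"),
                           frame_index = 3L)
  expect_identical(back$labels, sim$gt_frames[[4]]$labels)
  dets <- read_annotations(file.path(dir, "detections.json"))
  expect_equal(lengths(dets), lengths(sim$detections))
  expect_identical(dets[[2]][[1]]$idx, sim$detections[[2]][[1]]$idx)
  ti <- read_trait_image(file.path(dir, "trait_FvFm", "frame_000.tif"))
  expect_equal(ti$values, sim$trait_stacks$FvFm[[1]]$values, tolerance = 1e-6)
})
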