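mask_at <- function(rows, cols, dim = c(8L, 8L)) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  instance_mask(m)
}

test_that("leaf trait means are masked-pixel means", {
  const <- matrix(0.42, 8, 8)
  frames <- list(list(mask_at(2:3, 2:3)))
  ts <- track_sequence(frames)
  out <- extract_leaf_traits(ts, list(const), trait_name = "FvFm")
  expect_equal(out$mean_value, 0.42)
  expect_equal(out$trait_name, "FvFm")
  expect_equal(out$area, 4L)

  # 2-pixel mask over {0.2, 0.4} -> 0.3
  vals <- matrix(0, 8, 8)
  vals[1, 1] <- 0.2; vals[2, 1] <- 0.4
  two <- list(list(mask_at(1:2, 1)))
  got <- extract_leaf_traits(track_sequence(two), list(vals))
  expect_equal(got$mean_value, 0.3)

  expect_error(extract_leaf_traits(ts, list()), "empty")
  expect_error(extract_leaf_traits(ts, list(matrix(0, 4, 4))), "shape")
})

test_that("carried entries are emitted but flagged for filtering", {
  m <- mask_at(2:4, 2:4)
  frames <- list(list(m), list(), list(m))
  ts <- track_sequence(frames)
  imgs <- lapply(1:3, function(f) matrix(f / 10, 8, 8))
  out <- extract_leaf_traits(ts, imgs)
  expect_equal(out$status, c("observed", "carried", "observed"))
  # the carried record measures the stale mask on the frame-1 image
  expect_equal(out$mean_value, c(0.1, 0.2, 0.3))
  # per-leaf means always lie within the pixel range under the mask
  expect_true(all(out$mean_value >= 0 & out$mean_value <= 1))
})

test_that("leaf counts follow the emergence schedule and dip on misses", {
  empty_ts <- track_sequence(list(list(), list(), list()))
  expect_equal(leaf_count_series(empty_ts)$n_leaves, c(0L, 0L, 0L))

  a <- mask_at(1:2, 1:2); b <- mask_at(5:6, 5:6)
  frames <- list(list(a), list(a), list(a, b), list(a), list(a, b))
  ts <- track_sequence(frames)
  counts <- leaf_count_series(ts)
  expect_equal(counts$n_leaves, c(1L, 1L, 2L, 1L, 2L))
  expect_equal(counts$frame_index, 0:4)
})

test_that("plant means use union-of-mask semantics", {
  vals <- matrix(0, 8, 8)
  a <- mask_at(1:2, 1:2)          # 4 px
  b <- mask_at(5:6, 5:6)          # 4 px
  vals[a$idx] <- 0.2
  vals[b$idx] <- 0.6
  one <- plant_mean_series(list(list(a)), list(vals))
  expect_equal(one$mean_value, 0.2)

  both <- plant_mean_series(list(list(a, b)), list(vals))
  expect_equal(both$mean_value, 0.4)  # equal areas -> midpoint
  expect_equal(both$area, 8L)

  # overlapping masks: each pixel counted once
  c1 <- mask_at(1:2, 1:3)
  overlap <- plant_mean_series(list(list(a, c1)), list(vals))
  expect_equal(overlap$area, length(union(a$idx, c1$idx)))

  none <- plant_mean_series(list(list()), list(vals))
  expect_true(is.na(none$mean_value))
  expect_equal(none$area, 0L)

  # disjoint masks: plant mean equals the area-weighted mean of leaf means
  big <- mask_at(3:6, 1:2)  # 8 px at 0
  w <- plant_mean_series(list(list(a, big)), list(vals))
  expect_equal(w$mean_value, (4 * 0.2 + 8 * 0) / 12)
})

test_that("per-frame Welch t-tests match the closed form and conventions", {
  sa <- tibble::tibble(frame_index = rep(0L, 3), plant_id = 1:3,
                       value = c(1, 2, 3))
  sb <- tibble::tibble(frame_index = rep(0L, 3), plant_id = 4:6,
                       value = c(4, 5, 6))
  cmp <- group_compare(sa, sb)
  # closed-form Welch: means 2 and 5, each variance 1, n = 3
  t_hand <- (2 - 5) / sqrt(1 / 3 + 1 / 3)
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(t_hand, df_hand)
  expect_equal(cmp$t, t_hand)
  expect_equal(cmp$p, p_hand)

  same <- group_compare(sa, sa)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- tibble::tibble(frame_index = rep(0L, 3), value = rep(2, 3))
  degen <- group_compare(flat, flat)
  expect_equal(degen$t, 0)
  expect_equal(degen$p, 1)
  expect_match(degen$flag, "zero variance")

  diffc <- tibble::tibble(frame_index = rep(0L, 3), value = rep(5, 3))
  inf_t <- group_compare(flat, diffc)
  expect_true(is.infinite(inf_t$t))
  expect_equal(inf_t$p, 0)

  expect_warning(
    group_compare(sa[1, ], sb),
    "<2 replicates")
})

test_that("Benjamini-Hochberg adjustment is available across frames", {
  withr::with_seed(2, {
    sa <- tibble::tibble(frame_index = rep(0:4, each = 4),
                         value = stats::rnorm(20))
    sb <- tibble::tibble(frame_index = rep(0:4, each = 4),
                         value = stats::rnorm(20, mean = 1))
  })
  raw <- group_compare(sa, sb)
  adj <- group_compare(sa, sb, p_adjust = "BH")
  expect_equal(adj$p, stats::p.adjust(raw$p, method = "BH"))
  expect_true(all(adj$p >= raw$p))
})
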