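fake_pair <- function(red, green = NULL, remote = TRUE) {
  green <- green %||% matrix(1000, nrow(red), ncol(red))
  structure(list(red_channel = red, green_channel = green, is_remote = remote,
                 true_coverage = NA_real_, tissue_mask_true = NULL, seed = NULL),
            class = "if_image_pair")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("threshold calibration follows the order-statistic convention", {
  red <- matrix(c(1:100, rep(0, 28)), 8, 16)
  expect_equal(as.numeric(calibrate_threshold(fake_pair(red), 0.95)), 95)
  # percentile 1 returns the maximum: zero remote pixels survive a strict cut
  thr1 <- calibrate_threshold(fake_pair(red), 1.0)
  expect_equal(as.numeric(thr1), 100)
  expect_equal(sum(red > thr1), 0)
  expect_error(calibrate_threshold(fake_pair(matrix(0, 4, 4))),
               class = "ironmap_no_signal")
})

test_that("pooled remote images calibrate like one concatenated image", {
  r1 <- matrix(c(1:50, rep(0, 14)), 8, 8)
  r2 <- matrix(c(51:100, rep(0, 14)), 8, 8)
  pooled <- calibrate_threshold(list(fake_pair(r1), fake_pair(r2)), 0.95)
  concat <- calibrate_threshold(fake_pair(rbind(r1, r2)), 0.95)
  expect_equal(as.numeric(pooled), as.numeric(concat))
})

test_that("calibrated threshold eliminates the stated fraction of remote signal", {
  remotes <- lapply(1:3, function(s) make_if_pair(coverage = 0, is_remote = TRUE,
                                                  seed = s))
  thr <- calibrate_threshold(remotes, 0.95)
  pooled <- unlist(lapply(remotes, function(p) p$red_channel[p$red_channel > 0]))
  frac <- mean(pooled > thr)
  expect_lte(frac, 0.05 + 1 / length(pooled))
})

test_that("tissue mask reproduces a two-level image and supports a fixed rule", {
  g <- matrix(50, 64, 64); g[20:40, 20:40] <- 1000
  expect_equal(tissue_mask(g), g > 500, ignore_attr = TRUE)
  expect_equal(tissue_mask(g, "fixed", value = 70), g > 70)
  expect_error(tissue_mask(matrix(0, 8, 8)), class = "ironmap_no_signal")
})

test_that("coverage obeys its defining formula in the limiting cases", {
  g <- matrix(50, 64, 64); g[11:50, 11:50] <- 1000
  pair0 <- fake_pair(matrix(0, 64, 64), g)
  cv0 <- coverage(pair0, threshold = 100)
  expect_equal(cv0$coverage, 0)
  # red identical to green, threshold below tissue intensity: full coverage
  cv1 <- coverage(fake_pair(g, g), threshold = 600)
  expect_equal(cv1$coverage, 1)
  expect_equal(cv1$positive_pixels, cv1$tissue_pixels)
})

test_that("synthetic coverage is recovered within the speckle tolerance", {
  remotes <- lapply(1:2, function(s) make_if_pair(coverage = 0, is_remote = TRUE,
                                                  seed = 100 + s))
  thr <- calibrate_threshold(remotes)
  for (s in 1:5) {
    truecov <- c(0.05, 0.15, 0.3, 0.45, 0.6)[s]
    pair <- make_if_pair(coverage = truecov, seed = 200 + s)
    cv <- coverage(pair, thr)
    expect_lt(abs(cv$coverage - pair$true_coverage), 0.02)
  }
})

test_that("spot counting is exact on non-overlapping fields and scale invariant", {
  for (s in 1:3) {
    n <- c(12, 37, 0)[s]
    sf <- make_spot_field(n_spots = n, seed = 300 + s)
    expect_equal(count_spots(sf)$count, n)
    scaled <- count_spots(sf$image * 3.7, expected_radius_px = sf$radius_px)
    expect_equal(scaled$count, n)
  }
})

test_that("spot counts are invariant under toroidal translation", {
  sf <- make_spot_field(n_spots = 15, texture_sd = 0, seed = 11)
  img <- sf$image
  shifted <- img[c(33:nrow(img), 1:32), c(17:ncol(img), 1:16)]
  expect_equal(count_spots(shifted, expected_radius_px = sf$radius_px)$count,
               count_spots(img, expected_radius_px = sf$radius_px)$count)
})

test_that("touching spots split under watershed and merge without it", {
  img <- matrix(180, 96, 96)
  g <- list(x = matrix(rep(0:95, 96), 96, 96),
            y = matrix(rep(0:95, each = 96), 96, 96))
  r <- 5
  for (cx in c(40, 40 + 2 * r - 1)) {
    disc <- (g$x - cx)^2 + (g$y - 48)^2 <= r^2
    img[disc] <- 40
  }
  merged <- count_spots(img, expected_radius_px = r, max_area = 10 * pi * r^2)
  split <- count_spots(img, expected_radius_px = r, split_touching = TRUE)
  expect_equal(merged$count, 1)
  expect_equal(split$count, 2)
})

test_that("proximity binding rule matches the pairwise-distance oracle", {
  mask <- matrix(FALSE, 100, 100)
  mask[30:60, 30:60] <- TRUE
  inside <- data.frame(x = 45, y = 45)
  expect_true(incubation_bound_count(inside, mask, 2)$bound)
  away <- data.frame(x = 29 - 4, y = 45)   # 2 radii outside the mask edge
  expect_false(incubation_bound_count(away, mask, 2)$bound)

  withr::with_seed(13, {
    mask2 <- matrix(FALSE, 120, 120)
    for (i in 1:6) {
      cx <- sample(20:100, 1); cy <- sample(20:100, 1)
      mask2[max(1, cx - 8):min(120, cx + 8), max(1, cy - 5):min(120, cy + 5)] <- TRUE
    }
    spots <- data.frame(x = runif(100, 0, 119), y = runif(100, 0, 119))
    res <- incubation_bound_count(spots, mask2, adjacency_radius_px = 3)
    expect_equal(res$bound, bound_oracle(spots, mask2, 3))
  })
})

test_that("per-region aggregation sums its fields", {
  counts <- c(5, 7, 0, 3, 2, 1)
  region <- rep(c("LCX", "LAD", "RCA"), each = 2)
  agg <- aggregate_spot_counts(counts, region)
  expect_equal(agg$total[agg$region == "LCX"], 12)
  expect_equal(sum(agg$total), sum(counts))
  expect_equal(agg$n_fields, rep(2L, 3))
})
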