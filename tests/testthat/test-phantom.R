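test_that("territory labels partition the myocardium exactly", {
  ph <- make_phantom(c(64, 64), seed = 1)
  lv <- territory_levels()
  expect_true(all(ph$territory_labels[ph$myocardium_mask] %in% lv[c("LCX", "LAD", "RCA")]))
  expect_true(all(ph$territory_labels[!ph$myocardium_mask] == lv[["background"]]))
  areas <- table(ph$territory_labels[ph$territory_labels > 0])
  expect_equal(sum(areas), sum(ph$myocardium_mask))
})

test_that("phantom tissue maps respect their physical ordering", {
  ph <- make_phantom(c(64, 64), r2star_variation_sd = 5,
                     t1_variation_frac = 0.1, t2_variation_frac = 0.1, seed = 7)
  m <- ph$myocardium_mask
  expect_true(all(ph$r2star_map[m] > 0))
  expect_true(all(ph$t1_map[m] > ph$t2_map[m]))
  expect_true(all(ph$t2_map[m] > 0))
})

test_that("no-lesion phantom is symmetric across territories and the lesion increment is exact", {
  ph0 <- make_phantom(c(64, 64), lesion = "none", seed = 2)
  r0 <- ph0$r2star_map
  means0 <- sapply(c("LCX", "LAD", "RCA"), function(tn)
    mean(r0[ph0$territory_labels == territory_levels()[[tn]]]))
  expect_true(max(means0) - min(means0) == 0)

  ph <- make_phantom(c(64, 64), lesion = "LCX", mpio_delta_r2star = 40, seed = 2)
  lcx <- mean(ph$r2star_map[ph$territory_labels == 1L])
  lad <- mean(ph$r2star_map[ph$territory_labels == 2L])
  expect_equal(lcx - lad, 40)

  # patchy deposition elevates exactly the requested fraction of lesion pixels
  php <- make_phantom(c(64, 64), lesion = "LCX", mpio_delta_r2star = 40,
                      mpio_fraction = 0.3, seed = 2)
  lesion_vals <- php$r2star_map[php$territory_labels == 1L]
  n_hot <- sum(lesion_vals > 100 / 3 + 1)
  expect_equal(n_hot, round(0.3 * length(lesion_vals)))
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(make_phantom(c(64, 64), r2star_variation_sd = 4, seed = 9),
                   make_phantom(c(64, 64), r2star_variation_sd = 4, seed = 9))
  expect_identical(make_tracks(3, 4, seed = 5), make_tracks(3, 4, seed = 5))
  expect_identical(make_if_pair(coverage = 0.2, seed = 5),
                   make_if_pair(coverage = 0.2, seed = 5))
  expect_identical(make_spot_field(n_spots = 10, seed = 5),
                   make_spot_field(n_spots = 10, seed = 5))
  ph <- make_phantom(c(48, 48), seed = 1)
  sch <- schedule_multi_echo_invivo(noise_sigma = 2)
  expect_identical(simulate_series(ph, sch, seed = 3),
                   simulate_series(ph, sch, seed = 3))
})

test_that("noiseless signal models match their closed forms", {
  ph <- make_phantom(c(64, 64), r2star = 50, s0 = 100, t1_ms = 1000, seed = 1)
  i <- which(ph$myocardium_mask)[1]

  ser <- simulate_series(ph, schedule_multi_echo_invivo())
  S <- matrix(ser$images, 64 * 64, 4)
  expect_equal(S[i, 4], 100 * exp(-0.65), tolerance = 1e-12)
  # strictly decreasing in TE for positive decay rate
  expect_true(all(apply(S[ph$myocardium_mask, ], 1, function(r) all(diff(r) < 0))))

  # inversion-recovery null point at TI = T1 * ln 2
  sch_ir <- acquisition_schedule("inversion_recovery",
                                 c(100, 1000 * log(2), 4500))
  S_ir <- matrix(simulate_series(ph, sch_ir)$images, 64 * 64, 3)
  expect_equal(S_ir[i, 2], 0, tolerance = 1e-9)
  expect_equal(S_ir[i, 1], abs(100 * (1 - 2 * exp(-0.1))), tolerance = 1e-9)

  S_t2 <- matrix(simulate_series(ph, schedule_t2prep())$images, 64 * 64, 3)
  expect_equal(S_t2[i, 2], 100 * exp(-30 / 45), tolerance = 1e-12)
})

test_that("background magnitude noise has the Rayleigh floor", {
  ph <- make_phantom(c(150, 150), seed = 3)
  n_bg <- sum(!ph$myocardium_mask)
  expect_gte(n_bg, 1e4)
  sigma <- 5
  ser <- simulate_series(ph, schedule_multi_echo_invivo(noise_sigma = sigma),
                         seed = 11)
  bg <- matrix(ser$images, 150 * 150, 4)[!ph$myocardium_mask, 1]
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.03)
})

test_that("phantom and schedule constructors reject invalid input", {
  expect_error(make_phantom(c(16, 16)), class = "ironmap_bad_grid")
  expect_error(make_phantom(c(64, 64), lesion = "LMCA"))
  expect_error(acquisition_schedule("multi_echo", c(5, 3)),
               class = "ironmap_bad_schedule")
  expect_error(acquisition_schedule("multi_echo", 5),
               class = "ironmap_bad_schedule")
  expect_error(acquisition_schedule("inversion_recovery", c(100, 200)),
               class = "ironmap_bad_schedule")
  expect_error(acquisition_schedule("multi_echo", c(1, 2), noise_sigma = -1),
               class = "ironmap_bad_schedule")
})

test_that("synthetic IF pairs hit the requested coverage by construction", {
  p0 <- make_if_pair(coverage = 0, seed = 1)
  expect_equal(p0$true_coverage, 0)
  p1 <- make_if_pair(coverage = 1, seed = 1)
  expect_equal(p1$true_coverage, 1)
  p3 <- make_if_pair(shape = c(256, 256), coverage = 0.30, seed = 1)
  n_tissue <- sum(p3$tissue_mask_true)
  expect_equal(p3$true_coverage, round(0.30 * n_tissue) / n_tissue)
  # every marked pixel lies inside tissue and is bright
  expect_lte(abs(p3$true_coverage - 0.30), 1 / n_tissue * 2)
  expect_error(make_if_pair(coverage = 1.2), class = "ironmap_bad_coverage")
})

test_that("synthetic tracks carry recoverable ground truth within the field", {
  tr <- make_tracks(5, 7, seed = 4)
  expect_equal(length(unique(tr$track_id)), 12)
  truth <- attr(tr, "truth")
  expect_equal(sum(truth$bound), 5)
  expect_true(all(truth$dwell_s[truth$bound] >= 10))
  fe <- attr(tr, "field_extent")
  expect_true(all(tr$x_um >= 0 & tr$x_um <= fe[1]))
  expect_true(all(tr$y_um >= 0 & tr$y_um <= fe[2]))
  for (id in unique(tr$track_id))
    expect_true(all(diff(tr$t_s[tr$track_id == id]) > 0))
})

test_that("spot fields place the requested number of non-overlapping spots", {
  sf <- make_spot_field(n_spots = 25, seed = 6)
  expect_equal(nrow(sf$centers), 25)
  d <- as.matrix(stats::dist(sf$centers))
  diag(d) <- Inf
  expect_gte(min(d), 2 * sf$radius_px)
  sf0 <- make_spot_field(n_spots = 0, texture_sd = 0, noise_sd = 0, seed = 1)
  expect_equal(length(unique(as.numeric(sf0$image))), 1L)
  expect_error(make_spot_field(shape = c(64, 64), n_spots = 500, seed = 1),
               class = "ironmap_spot_placement")
})
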