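test_that("log-linear fit recovers an exact exponential decay", {
  ph <- make_phantom(c(64, 64), r2star = 50, seed = 1)
  ser <- simulate_series(ph, schedule_multi_echo_invivo())
  m <- fit_t2star(ser)
  expect_true(all(m$valid[ph$myocardium_mask]))
  rel <- abs(m$values - 50) / 50
  expect_lt(max(rel[ph$myocardium_mask]), 1e-9)
  expect_true(all(m$quality[ph$myocardium_mask] > 1 - 1e-9))
  expect_equal(m$extra$s0[which(ph$myocardium_mask)[1]], 100, tolerance = 1e-9)
})

test_that("pixels with fewer than two usable echoes are invalid", {
  sch <- schedule_multi_echo_invivo()
  img <- array(0, c(1, 1, 4))
  img[1, 1, ] <- c(100, 0, 0, 0)
  ser <- echo_series(img, sch)
  m <- fit_t2star(ser, min_signal = 1)
  expect_false(m$valid[1, 1])
  expect_true(is.na(m$values[1, 1]))
})

test_that("log-linear fit equals the normal-equations OLS oracle per pixel", {
  ph <- make_phantom(c(48, 48), r2star_variation_sd = 4, seed = 3)
  ser <- simulate_series(ph, schedule_multi_echo_invivo(noise_sigma = 2),
                         seed = 4)
  m <- fit_t2star(ser, min_signal = 0)
  S <- matrix(ser$images, 48 * 48, 4)
  px <- which(ph$myocardium_mask & m$valid)
  for (i in px[seq(1, length(px), by = 5)]) {
    co <- ols_loglinear_oracle(ser$schedule$times_ms, S[i, ])
    expect_lt(abs(m$values[i] - (-co["slope"] * 1000)) / abs(m$values[i]), 1e-10)
  }
})

test_that("noisy R2* estimates are accurate at 2% noise and cross-check a nonlinear fit", {
  n <- 100L
  truth <- 50
  sch <- schedule_multi_echo_invivo(noise_sigma = 2)
  img <- array(0, c(n, n, 4))
  for (k in 1:4) img[, , k] <- 100 * exp(-sch$times_ms[k] / 1000 * truth)
  ser <- withr::with_seed(42, {
    noisy <- sqrt((img + array(rnorm(n * n * 4, 0, 2), dim(img)))^2 +
                  array(rnorm(n * n * 4, 0, 2), dim(img))^2)
    echo_series(noisy, sch)
  })
  m <- fit_t2star(ser, min_signal = 0)  # no background in this fixture
  med <- median(m$values[m$valid])
  expect_lt(abs(med - truth) / truth, 0.02)

  # independent nonlinear least-squares cross-check on a pixel subset
  S <- matrix(ser$images, n * n, 4)
  idx <- which(m$valid)[seq_len(50)]
  nls_est <- vapply(idx, function(i) {
    df <- data.frame(te = sch$times_ms, s = S[i, ])
    fit <- minpack.lm::nlsLM(s ~ a * exp(-te / 1000 * r), data = df,
                             start = list(a = 100, r = 40))
    coef(fit)[["r"]]
  }, 1)
  expect_equal(median(nls_est), median(m$values[idx]), tolerance = 0.02)
})

test_that("fits are invariant to echo ordering", {
  ph <- make_phantom(c(48, 48), seed = 5)
  ser <- simulate_series(ph, schedule_multi_echo_invivo(noise_sigma = 1),
                         seed = 6)
  perm <- c(3, 1, 4, 2)
  ser_perm <- ser
  ser_perm$schedule$times_ms <- ser$schedule$times_ms[perm]
  ser_perm$images <- ser$images[, , perm]
  m1 <- fit_t2star(ser, min_signal = 0)
  m2 <- fit_t2star(ser_perm, min_signal = 0)
  expect_equal(m1$values, m2$values)
  expect_equal(m1$valid, m2$valid)
})

test_that("inversion-recovery fit round-trips noiseless T1 and flags degenerate pixels", {
  ph <- roundtrip_phantom(seed = 2)
  ser <- simulate_series(ph, schedule_inversion_recovery())
  m <- fit_t1_ir(ser, mask = ph$myocardium_mask)
  expect_true(all(m$valid[ph$myocardium_mask]))
  rel <- abs(m$values - ph$t1_map) / ph$t1_map
  expect_lt(max(rel[ph$myocardium_mask]), 1e-6)
  # all-zero pixels (background) are invalid, not garbage
  m_all <- fit_t1_ir(ser)
  expect_false(any(m_all$valid[!ph$myocardium_mask]))
})

test_that("apparent-T1 three-parameter model recovers T1 after readout correction", {
  # ideal IR data has B/A = 2, so the corrected T1 equals the apparent one
  ti <- c(100, 200, 400, 800, 1200, 1800, 2800, 4500)
  img <- array(abs(100 * (1 - 2 * exp(-ti / 1350))), c(1, 1, 8))
  ser <- echo_series(img, acquisition_schedule("inversion_recovery", ti))
  m <- fit_t1_ir(ser, model = "ir3")
  expect_true(m$valid[1, 1])
  expect_equal(m$values[1, 1], 1350, tolerance = 1e-4)
})

test_that("noisy T1 estimates stay within a few percent", {
  ti <- c(100, 200, 400, 800, 1200, 1800, 2800, 4500)
  n <- 50L
  truth <- 1200
  clean <- abs(100 * (1 - 2 * exp(-rep(ti, each = n * n) / truth)))
  img <- withr::with_seed(7, {
    sqrt((clean + rnorm(n * n * 8, 0, 2))^2 + rnorm(n * n * 8, 0, 2)^2)
  })
  ser <- echo_series(array(img, c(n, n, 8)),
                     acquisition_schedule("inversion_recovery", ti, noise_sigma = 2))
  m <- fit_t1_ir(ser)
  err <- abs(m$values[m$valid] - truth) / truth
  expect_lt(median(err), 0.03)
})

test_that("T2-prep fit round-trips noiseless T2 and flags zero-signal pixels", {
  ph <- roundtrip_phantom(seed = 3)
  ser <- simulate_series(ph, schedule_t2prep())
  m <- fit_t2prep(ser, mask = ph$myocardium_mask)
  rel <- abs(m$values - ph$t2_map) / ph$t2_map
  expect_lt(max(rel[ph$myocardium_mask]), 1e-6)

  img <- array(0, c(1, 1, 3))
  ser0 <- echo_series(img, schedule_t2prep())
  expect_error(fit_t2prep(ser0), class = "ironmap_all_background")
})

test_that("noisy T2 estimates stay within a few percent", {
  tau <- c(0, 30, 40)
  n <- 100L
  truth <- 45
  clean <- 100 * exp(-rep(tau, each = n * n) / truth)
  img <- withr::with_seed(8, {
    sqrt((clean + rnorm(n * n * 3, 0, 2))^2 + rnorm(n * n * 3, 0, 2)^2)
  })
  ser <- echo_series(array(img, c(n, n, 3)),
                     acquisition_schedule("t2_prep", tau, noise_sigma = 2))
  m <- fit_t2prep(ser)
  expect_lt(abs(median(m$values[m$valid]) - truth) / truth, 0.03)
})

test_that("map inversion converts units, propagates invalids, and is an involution", {
  vals <- matrix(c(20, 10, NA, 40), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  m <- parameter_map(vals, valid = valid, kind = "T2star")
  inv <- invert_map(m)
  expect_equal(inv$kind, "R2star")
  expect_equal(inv$values[1, 1], 50)
  expect_false(inv$valid[1, 2])
  expect_true(is.na(inv$values[1, 2]))
  back <- invert_map(inv)
  expect_equal(back$values[valid], m$values[valid])
  expect_error(invert_map(parameter_map(vals, valid = valid, kind = "T1")),
               class = "ironmap_bad_map")
})

test_that("Rician-floor background yields invalid or low-quality fits, never silent garbage", {
  ph <- make_phantom(c(64, 64), seed = 9)
  ser <- simulate_series(ph, schedule_multi_echo_invivo(noise_sigma = 3),
                         seed = 10)
  m <- fit_t2star(ser)   # min_signal from corner-estimated background sigma
  bg <- !ph$myocardium_mask
  bad <- !m$valid[bg] | m$quality[bg] < 0.5
  expect_true(all(bad))
})
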