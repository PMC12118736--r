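#' Per-pixel parameter map
#'
#' Container for a fitted relaxometry map: per-pixel parameter values,
#' a per-pixel goodness-of-fit (coefficient of determination, in \[0, 1\]),
#' and a validity mask. Units are s^-1 for R2* and ms for T1/T2/T2*.
#'
#' @param values Numeric array of fitted values.
#' @param quality Numeric array of per-pixel R^2, same shape.
#' @param valid Logical array: where the fit is usable.
#' @param kind One of `"R2star"`, `"T2star"`, `"T1"`, `"T2"`.
#' @param schedule The [acquisition_schedule()] used, or `NULL`.
#' @param pixel_size_mm Pixel size, mm.
#' @param extra Optional list of auxiliary maps (e.g. fitted S0).
#' @return A `parameter_map` object.
#' @export
parameter_map <- function(values, quality = NULL, valid = NULL,
                          kind = c("R2star", "T2star", "T1", "T2"),
                          schedule = NULL, pixel_size_mm = 1, extra = list()) {
  kind <- match.arg(kind)
  values <- as.array(values)
  valid <- if (is.null(valid)) is.finite(values) else as.array(valid)
  quality <- if (is.null(quality)) array(1, dim(values)) else as.array(quality)
  stopifnot(identical(dim(values), dim(valid)),
            identical(dim(values), dim(quality)))
  if (any(valid & !is.finite(values)))
    stop_ironmap("values must be finite wherever valid", "ironmap_bad_map")
  structure(
    list(values = values, quality = quality, valid = valid, kind = kind,
         schedule = schedule, pixel_size_mm = pixel_size_mm, extra = extra),
    class = "parameter_map"
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid]
  unit <- if (x$kind == "R2star") "1/s" else "ms"
  cat(sprintf("<parameter_map> %s [%s], %s px, %d valid; median %.3g\n",
              x$kind, unit, paste(dim(x$values), collapse = "x"),
              sum(x$valid), if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

# Estimate the background noise sigma from the four image corners, assuming
# pure-noise (Rayleigh) magnitude there: E[S] = sigma * sqrt(pi/2).
estimate_background_sigma <- function(series, patch_frac = 0.1) {
  d <- series_spatial_dim(series)
  p <- max(2L, floor(min(d[1:2]) * patch_frac))
  img1 <- if (length(d) == 2) series$images[, , 1] else series$images[, , 1, 1]
  ix <- c(seq_len(p), d[1] - seq_len(p) + 1)
  iy <- c(seq_len(p), d[2] - seq_len(p) + 1)
  corners <- img1[ix, iy]
  mean(corners) / sqrt(pi / 2)
}

# Shared vectorized weighted least squares of y = a + b*x per pixel, with
# per-pixel, per-time weights (0 drops a point). Returns slope, intercept,
# R^2 and the usable-point count.
loglinear_fit <- function(S, times, usable, weights = NULL) {
  W <- usable * (if (is.null(weights)) 1 else weights)
  Y <- log(S)
  Y[!usable] <- 0          # masked out by zero weight
  X <- matrix(times, nrow(S), length(times), byrow = TRUE)
  sw <- rowSums(W)
  sx <- rowSums(W * X); sy <- rowSums(W * Y)
  sxx <- rowSums(W * X * X); sxy <- rowSums(W * X * Y)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / sw
  fitted <- intercept + slope * X
  ss_res <- rowSums(W * (Y - fitted)^2)
  ybar <- sy / sw
  ss_tot <- rowSums(W * (Y - ybar)^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, pmin(1, 1 - ss_res / ss_tot)),
               ifelse(ss_res <= .Machine$double.eps * 100, 1, 0))
  # with only two usable points the line is saturated (zero residual dof):
  # R^2 carries no goodness information, so report 0 rather than a perfect 1
  n_usable <- rowSums(usable)
  r2[n_usable <= 2] <- 0
  list(slope = slope, intercept = intercept, r2 = r2, n_usable = n_usable)
}

#' Pixel-wise R2* mapping by log-linear fit
#'
#' Fits, at every pixel, an ordinary least-squares line to the logarithm of
#' the multi-echo signal against echo time, using only echoes whose signal
#' exceeds `min_signal`; the decay rate is `R2* = -slope` (converted from
#' per-ms to s^-1). Pixels with fewer than two usable echoes, or with a
#' non-positive fitted R2*, are marked invalid. The per-pixel quality is the
#' coefficient of determination of the line.
#'
#' @param series Multi-echo [echo_series()].
#' @param mask Optional logical array restricting the fit.
#' @param min_signal Signal floor below which an echo is excluded from the
#'   log fit. Default: 3x the background sigma estimated from the image
#'   corners (excludes Rician-floor echoes). Non-positive signals are always
#'   excluded.
#' @param weighted If `TRUE`, weight each echo by its squared signal
#'   (first-order variance stabilization of the log transform). The default
#'   is the plain unweighted log-linear fit.
#'
#' With exactly two usable echoes the line is saturated, so its R^2 carries
#' no information; such pixels keep their fitted value but report quality 0.
#' @return A `parameter_map` of kind `"R2star"`; the fitted `ln S0`
#'   intercept is available as `extra$s0` (signal units).
#' @examples
#' ph <- make_phantom(c(64, 64), seed = 1)
#' ser <- simulate_series(ph, schedule_multi_echo_invivo())
#' m <- fit_t2star(ser)
#' @export
fit_t2star <- function(series, mask = NULL, min_signal = NULL, weighted = FALSE) {
  stopifnot(inherits(series, "echo_series"))
  if (series$schedule$kind != "multi_echo")
    stop_ironmap("fit_t2star requires a multi_echo series", "ironmap_bad_series")
  res <- fit_logdecay(series, mask, min_signal, weighted)
  r2star <- -res$slope * 1000          # per ms -> per s
  valid <- res$valid & is.finite(r2star) & r2star > 0
  r2star[!valid] <- NA_real_
  d <- series_spatial_dim(series)
  parameter_map(array(r2star, d), array(res$r2, d), array(valid, d),
                kind = "R2star", schedule = series$schedule,
                pixel_size_mm = series$pixel_size_mm,
                extra = list(s0 = array(exp(res$intercept), d)))
}

#' Pixel-wise T2 mapping from a T2-prepared series
#'
#' Log-linear fit of signal against T2-preparation time; `T2 = -1/slope`
#' (ms). Pixels with non-positive signals at too many preparation times, or
#' a non-negative slope, are invalid.
#'
#' @inheritParams fit_t2star
#' @return A `parameter_map` of kind `"T2"` (ms).
#' @export
fit_t2prep <- function(series, mask = NULL, min_signal = 0, weighted = FALSE) {
  stopifnot(inherits(series, "echo_series"))
  if (series$schedule$kind != "t2_prep")
    stop_ironmap("fit_t2prep requires a t2_prep series", "ironmap_bad_series")
  if (length(unique(series$schedule$times_ms)) < 2)
    stop_ironmap("need >= 2 distinct preparation times", "ironmap_bad_series")
  res <- fit_logdecay(series, mask, min_signal, weighted)
  t2 <- -1 / res$slope                 # slope per ms -> T2 in ms
  valid <- res$valid & is.finite(t2) & t2 > 0
  t2[!valid] <- NA_real_
  d <- series_spatial_dim(series)
  parameter_map(array(t2, d), array(res$r2, d), array(valid, d),
                kind = "T2", schedule = series$schedule,
                pixel_size_mm = series$pixel_size_mm,
                extra = list(s0 = array(exp(res$intercept), d)))
}

# Common log-linear machinery for fit_t2star / fit_t2prep.
fit_logdecay <- function(series, mask, min_signal, weighted) {
  S <- series_matrix(series)
  times <- series$schedule$times_ms
  ord <- order(times)
  times <- times[ord]; S <- S[, ord, drop = FALSE]

  d <- series_spatial_dim(series)
  mask_v <- if (is.null(mask)) rep(TRUE, nrow(S)) else as.logical(as.array(mask))
  if (!any(mask_v))
    stop_ironmap("mask is empty", "ironmap_empty_mask")
  if (is.null(min_signal)) min_signal <- 3 * estimate_background_sigma(series)

  usable <- S > pmax(min_signal, 0) & S > 0
  usable[!mask_v, ] <- FALSE
  if (!any(usable))
    stop_ironmap("no usable signal above min_signal anywhere in the mask",
                 "ironmap_all_background")
  weights <- if (weighted) S^2 else NULL
  fit <- loglinear_fit(S, times, usable, weights)
  fit$valid <- mask_v & fit$n_usable >= 2 & is.finite(fit$slope)
  fit
}

#' Pixel-wise T1 mapping from an inversion-recovery series
#'
#' Fits the magnitude inversion-recovery model per pixel by nonlinear least
#' squares. Two models are available: the ideal two-parameter form
#' `|A * (1 - 2*exp(-TI/T1))|`, and a three-parameter apparent-T1 form
#' `|A - B*exp(-TI/T1star)|` with the readout-corrected
#' `T1 = T1star * (B/A - 1)`. Signal polarity (lost by the magnitude
#' operation) is restored by trying every restoration point around the
#' signal minimum and keeping the lowest residual; the 1-D profile over T1
#' (amplitudes solved in closed form) is minimized on a log-spaced grid and
#' refined with golden-section search.
#'
#' @param series Inversion-recovery [echo_series()] with >= 3 TIs.
#' @param mask Optional logical array restricting the fit.
#' @param model `"ir2"` (default) or `"ir3"` (apparent-T1 correction).
#' @param t1_range Search range for T1 (ms).
#' @param grid_n Number of log-spaced grid points for the coarse search.
#' @return A `parameter_map` of kind `"T1"` (ms). Pixels where the fit
#'   degenerates (all-zero signal, negative amplitude) are invalid.
#' @export
fit_t1_ir <- function(series, mask = NULL, model = c("ir2", "ir3"),
                      t1_range = c(50, 6000), grid_n = 120) {
  stopifnot(inherits(series, "echo_series"))
  model <- match.arg(model)
  if (series$schedule$kind != "inversion_recovery")
    stop_ironmap("fit_t1_ir requires an inversion_recovery series",
                 "ironmap_bad_series")
  ti <- series$schedule$times_ms
  if (length(ti) < 3)
    stop_ironmap("need >= 3 inversion times", "ironmap_bad_series")
  S <- series_matrix(series)
  ord <- order(ti); ti <- ti[ord]; S <- S[, ord, drop = FALSE]
  nt <- length(ti)

  d <- series_spatial_dim(series)
  mask_v <- if (is.null(mask)) rep(TRUE, nrow(S)) else as.logical(as.array(mask))
  if (!any(mask_v)) stop_ironmap("mask is empty", "ironmap_empty_mask")

  idx <- which(mask_v & rowSums(S) > 0)
  t1 <- rep(NA_real_, nrow(S))
  qual <- rep(NA_real_, nrow(S))
  valid <- rep(FALSE, nrow(S))
  if (length(idx)) {
    t1grid <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = grid_n))
    Ssub <- S[idx, , drop = FALSE]
    # Polarity candidates: flip the sign of the first k samples, k = 0..nt.
    # Coarse pass, fully vectorized across pixels: for each grid T1 and each
    # k, the best amplitude has a closed form, so the residual reduces to
    # sum(S^2) - (s.f)^2 / (f.f).
    ss2 <- rowSums(Ssub^2)
    best_res <- rep(Inf, length(idx))
    best_k <- rep(0L, length(idx))
    best_g <- rep(1L, length(idx))
    if (model == "ir2") {
      for (g in seq_along(t1grid)) {
        f <- 1 - 2 * exp(-ti / t1grid[g])
        ff <- sum(f * f)
        M <- Ssub * matrix(f, length(idx), nt, byrow = TRUE)
        prefix <- 0
        tot <- rowSums(M)
        for (k in 0:nt) {
          if (k > 0) prefix <- prefix + M[, k]
          dot <- tot - 2 * prefix
          ok <- dot > 0                       # amplitude must be positive
          res <- ifelse(ok, ss2 - dot^2 / ff, Inf)
          upd <- res < best_res
          best_res[upd] <- res[upd]; best_k[upd] <- k; best_g[upd] <- g
        }
      }
    } else {
      for (g in seq_along(t1grid)) {
        e <- exp(-ti / t1grid[g])
        for (k in 0:nt) {
          sgn <- c(rep(-1, k), rep(1, nt - k))
          res <- ir3_residual_vec(Ssub, sgn, e)
          upd <- res < best_res
          best_res[upd] <- res[upd]; best_k[upd] <- k; best_g[upd] <- g
        }
      }
    }

    # Per-pixel refinement of T1; the polarity point chosen on the coarse
    # grid can be off by one near the signal null, so neighbouring
    # candidates are refined as well and the lowest residual kept.
    for (j in seq_along(idx)) {
      if (!is.finite(best_res[j])) next
      lo <- t1grid[max(best_g[j] - 2, 1)]
      hi <- t1grid[min(best_g[j] + 2, grid_n)]
      opt <- NULL; opt_k <- NA_integer_
      for (k in intersect(best_k[j] + (-1:1), 0:nt)) {
        sgn <- c(rep(-1, k), rep(1, nt - k))
        s_k <- sgn * Ssub[j, ]
        obj <- if (model == "ir2") {
          function(T1) {
            f <- 1 - 2 * exp(-ti / T1)
            dot <- sum(s_k * f)
            if (dot <= 0) return(sum(s_k^2))
            sum(s_k^2) - dot^2 / sum(f * f)
          }
        } else {
          function(T1s) ir3_residual_one(s_k, exp(-ti / T1s))
        }
        cand <- stats::optimize(obj, c(lo, hi), tol = 1e-7)
        if (is.null(opt) || cand$objective < opt$objective) {
          opt <- cand; opt_k <- k
        }
      }
      sgn <- c(rep(-1, opt_k), rep(1, nt - opt_k))
      s <- sgn * Ssub[j, ]
      t1_hat <- opt$minimum
      if (model == "ir3") {
        e <- exp(-ti / t1_hat)
        ab <- ir3_coef(s, e)
        if (is.null(ab) || ab[1] <= 0 || ab[2] / ab[1] <= 1) next
        t1_hat <- t1_hat * (ab[2] / ab[1] - 1)
      }
      sst <- sum((s - mean(s))^2)
      q <- if (sst > 0) max(0, min(1, 1 - opt$objective / sst)) else
        as.numeric(opt$objective <= 1e-12)
      if (is.finite(t1_hat) && t1_hat > 0) {
        t1[idx[j]] <- t1_hat
        qual[idx[j]] <- q
        valid[idx[j]] <- TRUE
      }
    }
  }
  parameter_map(array(t1, d), array(qual, d), array(valid, d),
                kind = "T1", schedule = series$schedule,
                pixel_size_mm = series$pixel_size_mm,
                extra = list(model = model))
}

# Linear coefficients (A, B) of s ~ A - B*e for one pixel; NULL if singular.
ir3_coef <- function(s, e) {
  n <- length(s)
  se <- sum(e); see <- sum(e * e)
  den <- n * see - se^2
  if (abs(den) < 1e-12) return(NULL)
  ss <- sum(s); sse <- sum(s * e)
  B <- -(n * sse - se * ss) / den
  A <- (ss + B * se) / n
  c(A, B)
}

ir3_residual_one <- function(s, e) {
  ab <- ir3_coef(s, e)
  if (is.null(ab) || ab[1] <= 0 || ab[2] <= 0) return(sum(s^2))
  sum((s - (ab[1] - ab[2] * e))^2)
}

# Vectorized over pixels for the coarse grid pass of the ir3 model.
ir3_residual_vec <- function(S, sgn, e) {
  Ssigned <- S * matrix(sgn, nrow(S), ncol(S), byrow = TRUE)
  n <- length(e)
  se <- sum(e); see <- sum(e * e)
  den <- n * see - se^2
  if (abs(den) < 1e-12) return(rep(Inf, nrow(S)))
  ss <- rowSums(Ssigned)
  sse <- rowSums(Ssigned * matrix(e, nrow(S), n, byrow = TRUE))
  B <- -(n * sse - se * ss) / den
  A <- (ss + B * se) / n
  fitted_res <- rowSums((Ssigned - (matrix(A, nrow(S), n) -
    B * matrix(e, nrow(S), n, byrow = TRUE)))^2)
  ifelse(A > 0 & B > 0, fitted_res, Inf)
}

#' Convert between T2* and R2* maps
#'
#' Reciprocal with unit conversion, `T2*[ms] = 1000 / R2*[1/s]`; invalid
#' pixels propagate, quality is carried over, and a double inversion is the
#' identity.
#'
#' @param map A `parameter_map` of kind `"T2star"` or `"R2star"`.
#' @return The map of the complementary kind.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "parameter_map"))
  if (!map$kind %in% c("T2star", "R2star"))
    stop_ironmap("invert_map applies to T2star/R2star maps only",
                 "ironmap_bad_map")
  out_kind <- if (map$kind == "R2star") "T2star" else "R2star"
  vals <- 1000 / map$values
  vals[!map$valid] <- NA_real_
  parameter_map(vals, map$quality, map$valid, kind = out_kind,
                schedule = map$schedule, pixel_size_mm = map$pixel_size_mm,
                extra = map$extra)
}
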