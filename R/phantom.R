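#' Coronary territory label codes
#'
#' Territory maps are integer arrays using these codes: background 0, LCX 1,
#' LAD 2, RCA 3. The LCX is the lesion territory in the
#' ischemia/reperfusion setting this package models; the LAD is perfused but
#' uninjured and the RCA serves as a non-perfused internal control.
#'
#' @return Named integer vector of label codes.
#' @export
territory_levels <- function() {
  c(background = 0L, LCX = 1L, LAD = 2L, RCA = 3L)
}

territory_code <- function(name) {
  lv <- territory_levels()
  if (!name %in% names(lv))
    stop_ironmap(sprintf("unknown territory '%s'", name), "ironmap_bad_territory")
  lv[[name]]
}

# Smooth zero-mean random field with unit sd over `mask`, built by Gaussian
# smoothing of white noise. 2D only; 3D callers smooth slice-wise.
smooth_field <- function(shape, mask, smooth_sigma = 6) {
  noise <- matrix(stats::rnorm(prod(shape[1:2])), shape[1], shape[2])
  sm <- EBImage::gblur(noise, sigma = smooth_sigma)
  sm <- as.matrix(sm)
  mu <- mean(sm[mask]); s <- stats::sd(sm[mask])
  if (!is.finite(s) || s == 0) s <- 1
  (sm - mu) / s
}

#' Generate a digital left-ventricle phantom with ground truth
#'
#' Builds a ring-shaped LV myocardium on a square pixel grid, partitions it
#' into three contiguous angular coronary territories (LCX, LAD, RCA), and
#' attaches ground-truth tissue parameter maps (proton-density-like S0, T1,
#' T2, R2*). An iron-oxide (MPIO) contrast deposition is modelled as a
#' uniform R2* increment confined to one territory. All randomness (the
#' optional smooth within-tissue variation) is governed by `seed`.
#'
#' @param grid_shape Integer pair or triple of pixel dimensions (min 32 in
#'   plane). A third element replicates the ring over that many slices.
#' @param pixel_size_mm Isotropic pixel size, mm.
#' @param lesion Territory receiving the MPIO increment:
#'   `"LCX"`, `"LAD"`, `"RCA"` or `"none"`.
#' @param mpio_delta_r2star R2* increment (s^-1, >= 0) applied inside the
#'   lesion territory.
#' @param mpio_fraction Fraction of lesion-territory pixels carrying the
#'   increment (1 = uniform deposition over the territory; smaller values
#'   model patchy, focal particle binding as seen ex vivo).
#' @param s0,t1_ms,t2_ms,r2star Base tissue values: signal units, ms, ms,
#'   s^-1. Defaults approximate healthy myocardium at 3 T.
#' @param r2star_variation_sd Standard deviation (s^-1) of a smooth
#'   within-tissue R2* variation field (0 = piecewise constant).
#' @param t1_variation_frac,t2_variation_frac Fractional smooth variation of
#'   T1 and T2 (0 = constant).
#' @param field_offset_amplitude Amplitude (s^-1) of a slowly varying
#'   macroscopic field-inhomogeneity contribution to the effective decay
#'   rate (an R2' term); identical pre/post contrast.
#' @param inner_radius_frac,outer_radius_frac Ring radii as fractions of the
#'   smaller in-plane dimension.
#' @param sector_offset_deg Rotation of the three 120-degree territory
#'   sectors, degrees.
#' @param seed Integer seed; identical inputs give bit-identical phantoms.
#' @return A `phantom_truth` object: masks, territory labels, parameter maps
#'   (R2* including the MPIO increment), the increment itself, the field
#'   offset map and the seed.
#' @examples
#' ph <- make_phantom(c(64, 64), lesion = "LCX", mpio_delta_r2star = 40, seed = 1)
#' table(ph$territory_labels[ph$myocardium_mask])
#' @export
make_phantom <- function(grid_shape = c(64, 64), pixel_size_mm = 1,
                         lesion = c("none", "LCX", "LAD", "RCA"),
                         mpio_delta_r2star = 0, mpio_fraction = 1,
                         s0 = 100, t1_ms = 1200, t2_ms = 45, r2star = 100 / 3,
                         r2star_variation_sd = 0,
                         t1_variation_frac = 0, t2_variation_frac = 0,
                         field_offset_amplitude = 0,
                         inner_radius_frac = 0.22, outer_radius_frac = 0.42,
                         sector_offset_deg = 0, seed = NULL) {
  lesion <- match.arg(lesion)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) < 2 || length(grid_shape) > 3)
    stop_ironmap("grid_shape must have 2 or 3 elements", "ironmap_bad_grid")
  if (any(grid_shape[1:2] < 32))
    stop_ironmap("grid too small to contain the myocardial ring (min 32x32)",
                 "ironmap_bad_grid")
  if (mpio_delta_r2star < 0)
    stop_ironmap("mpio_delta_r2star must be >= 0", "ironmap_bad_phantom")
  if (mpio_fraction <= 0 || mpio_fraction > 1)
    stop_ironmap("mpio_fraction must be in (0, 1]", "ironmap_bad_phantom")
  if (t1_ms <= t2_ms || t2_ms <= 0 || r2star <= 0 || s0 < 0)
    stop_ironmap("tissue parameters must satisfy t1 > t2 > 0, r2star > 0, s0 >= 0",
                 "ironmap_bad_phantom")

  nx <- grid_shape[1]; ny <- grid_shape[2]
  nz <- if (length(grid_shape) == 3) grid_shape[3] else 1L
  g <- pixel_grid(c(nx, ny))
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  rmin <- inner_radius_frac * min(nx, ny)
  rmax <- outer_radius_frac * min(nx, ny)
  ring <- r >= rmin & r <= rmax

  # Angular 120-degree sectors; boundaries half-open so labels partition
  # the ring exactly.
  ang <- (atan2(g$y - cy, g$x - cx) * 180 / pi - sector_offset_deg) %% 360
  labels2d <- matrix(0L, nx, ny)
  labels2d[ring & ang < 120] <- territory_code("LCX")
  labels2d[ring & ang >= 120 & ang < 240] <- territory_code("LAD")
  labels2d[ring & ang >= 240] <- territory_code("RCA")

  mk <- function(base2d) {
    if (nz == 1L) matrix(base2d, nx, ny)
    else array(rep(base2d, nz), dim = c(nx, ny, nz))
  }

  run_seeded(seed, {
    v_r2 <- if (r2star_variation_sd > 0)
      smooth_field(c(nx, ny), ring) * r2star_variation_sd else 0
    v_t1 <- if (t1_variation_frac > 0)
      smooth_field(c(nx, ny), ring) * t1_variation_frac * t1_ms else 0
    v_t2 <- if (t2_variation_frac > 0)
      smooth_field(c(nx, ny), ring) * t2_variation_frac * t2_ms else 0

    s0_2d <- ifelse(ring, s0, 0)
    t1_2d <- ifelse(ring, pmax(t1_ms + v_t1, 1), 0)
    t2_2d <- ifelse(ring, pmax(t2_ms + v_t2, 0.5), 0)
    # keep T1 > T2 even under variation
    t1_2d <- ifelse(ring, pmax(t1_2d, t2_2d + 1), 0)
    r2_2d <- ifelse(ring, pmax(r2star + v_r2, 0.5), 0)
    if (lesion != "none" && mpio_delta_r2star > 0) {
      les_idx <- which(labels2d == territory_code(lesion))
      if (mpio_fraction < 1)
        les_idx <- sample(les_idx, round(mpio_fraction * length(les_idx)))
      r2_2d[les_idx] <- r2_2d[les_idx] + mpio_delta_r2star
    }

    fo_2d <- if (field_offset_amplitude != 0)
      field_offset_amplitude *
        sin(2 * pi * g$x / nx) * cos(2 * pi * g$y / ny) else
      matrix(0, nx, ny)

    structure(
      list(
        grid_shape = c(nx, ny, nz)[seq_len(if (nz > 1) 3 else 2)],
        pixel_size_mm = pixel_size_mm,
        myocardium_mask = mk(ring) > 0,
        territory_labels = mk(labels2d),
        s0_map = mk(s0_2d),
        t1_map = mk(t1_2d),
        t2_map = mk(t2_2d),
        r2star_map = mk(r2_2d),
        field_offset_map = mk(fo_2d),
        mpio_delta_r2star = mpio_delta_r2star,
        lesion_territory = lesion,
        seed = seed
      ),
      class = "phantom_truth"
    )
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %s px, %g mm; myocardium %d px; lesion %s (dR2* = %g 1/s)\n",
    paste(dim(x$myocardium_mask), collapse = "x"), x$pixel_size_mm,
    sum(x$myocardium_mask), x$lesion_territory, x$mpio_delta_r2star))
  invisible(x)
}

#' Simulate a magnitude MR image series over a phantom
#'
#' Evaluates the noiseless signal model of the schedule at every pixel and
#' adds Rician noise: independent Gaussian noise of standard deviation
#' `schedule$noise_sigma` is added to each of the two complex channels and
#' the modulus taken, as on vendor magnitude images. With zero noise the
#' exact model values are returned.
#'
#' Signal models (times in ms, rates in 1/s):
#' \itemize{
#'   \item multi-echo: `S(TE) = S0 * exp(-TE/1000 * (R2* + field_offset))`
#'   \item inversion recovery: `S(TI) = |S0 * (1 - 2 * exp(-TI/T1))|`
#'   \item T2 preparation: `S(tau) = S0 * exp(-tau/T2)`
#' }
#'
#' @param truth A `phantom_truth`.
#' @param schedule An [acquisition_schedule()].
#' @param seed Integer seed for the noise draw.
#' @return An [echo_series()].
#' @export
simulate_series <- function(truth, schedule, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(schedule, "acquisition_schedule"))
  if (any(!is.finite(truth$s0_map)))
    stop_ironmap("phantom maps must be finite", "ironmap_bad_phantom")
  sd_spatial <- dim(truth$myocardium_mask)
  npix <- prod(sd_spatial)
  times <- schedule$times_ms
  s0 <- as.numeric(truth$s0_map)

  signal <- matrix(0, npix, length(times))
  inside <- s0 > 0
  for (k in seq_along(times)) {
    tk <- times[k]
    sk <- numeric(npix)
    if (schedule$kind == "multi_echo") {
      rate <- as.numeric(truth$r2star_map) + as.numeric(truth$field_offset_map)
      sk[inside] <- s0[inside] * exp(-tk / 1000 * rate[inside])
    } else if (schedule$kind == "inversion_recovery") {
      t1 <- as.numeric(truth$t1_map)
      sk[inside] <- abs(s0[inside] * (1 - 2 * exp(-tk / t1[inside])))
    } else {
      t2 <- as.numeric(truth$t2_map)
      sk[inside] <- s0[inside] * exp(-tk / t2[inside])
    }
    signal[, k] <- sk
  }

  sigma <- schedule$noise_sigma
  if (sigma > 0) {
    signal <- run_seeded(seed, {
      re <- signal + matrix(stats::rnorm(length(signal), 0, sigma),
                            nrow(signal), ncol(signal))
      im <- matrix(stats::rnorm(length(signal), 0, sigma),
                   nrow(signal), ncol(signal))
      sqrt(re^2 + im^2)
    })
  }

  echo_series(array(signal, dim = c(sd_spatial, length(times))), schedule,
              pixel_size_mm = truth$pixel_size_mm,
              provenance = list(seed = seed, phantom_seed = truth$seed,
                                lesion = truth$lesion_territory))
}

#' Generate a synthetic two-channel immunofluorescence image pair
#'
#' Emulates a P-selectin stained cryosection: the green channel carries
#' tissue autofluorescence on a connected region occupying approximately
#' `tissue_fraction` of the image; the red channel carries supra-threshold
#' staining on an exact `coverage` fraction of tissue pixels plus
#' sub-threshold speckle elsewhere. The realized coverage is recorded as
#' ground truth.
#'
#' @param shape Image dimensions (pixels).
#' @param tissue_fraction Fraction of pixels covered by tissue, in (0, 1].
#' @param coverage Target stained fraction of tissue pixels, in \[0, 1\].
#' @param is_remote Flag the pair as a remote (uninjured control) section,
#'   used for threshold calibration.
#' @param intensity List of intensity parameters: `pos_mean`, `pos_sd`
#'   (stained pixels), `speckle_mean`, `speckle_sd`, `speckle_density`
#'   (background speckle), `green_tissue_mean`, `green_tissue_sd`,
#'   `green_bg_mean`, `green_bg_sd`.
#' @param seed Integer seed.
#' @return An `if_image_pair`: `red_channel`, `green_channel`, `is_remote`,
#'   `true_coverage`, `tissue_mask_true`.
#' @export
make_if_pair <- function(shape = c(256, 256), tissue_fraction = 0.6,
                         coverage = 0, is_remote = FALSE,
                         intensity = list(), seed = NULL) {
  if (coverage < 0 || coverage > 1)
    stop_ironmap("coverage must be in [0, 1]", "ironmap_bad_coverage")
  if (tissue_fraction <= 0 || tissue_fraction > 1)
    stop_ironmap("tissue_fraction must be in (0, 1]", "ironmap_bad_coverage")
  p <- utils::modifyList(list(
    pos_mean = 3000, pos_sd = 100,
    speckle_mean = 300, speckle_sd = 100, speckle_density = 0.3,
    green_tissue_mean = 1000, green_tissue_sd = 80,
    green_bg_mean = 60, green_bg_sd = 20
  ), intensity)

  nx <- shape[1]; ny <- shape[2]
  npix <- nx * ny
  g <- pixel_grid(shape)
  # connected tissue region: the round(frac * npix) pixels closest to centre
  d <- (g$x - (nx - 1) / 2)^2 + (g$y - (ny - 1) / 2)^2
  n_tissue <- max(1L, round(tissue_fraction * npix))
  ord <- order(as.numeric(d))
  tissue <- matrix(FALSE, nx, ny)
  tissue[ord[seq_len(n_tissue)]] <- TRUE

  run_seeded(seed, {
    green <- matrix(pmax(stats::rnorm(npix, p$green_bg_mean, p$green_bg_sd), 0),
                    nx, ny)
    green[tissue] <- pmax(stats::rnorm(n_tissue, p$green_tissue_mean,
                                       p$green_tissue_sd), 0)

    red <- matrix(0, nx, ny)
    tissue_idx <- which(tissue)
    n_pos <- round(coverage * n_tissue)
    pos_idx <- if (n_pos > 0) sample(tissue_idx, n_pos) else integer(0)
    speckle_pool <- setdiff(seq_len(npix), pos_idx)
    n_speck <- round(p$speckle_density * length(speckle_pool))
    speck_idx <- if (n_speck > 0) sample(speckle_pool, n_speck) else integer(0)
    if (n_speck > 0)
      red[speck_idx] <- pmax(stats::rnorm(n_speck, p$speckle_mean, p$speckle_sd), 0)
    if (n_pos > 0)
      red[pos_idx] <- pmax(stats::rnorm(n_pos, p$pos_mean, p$pos_sd),
                           p$pos_mean / 2)

    structure(
      list(red_channel = red, green_channel = green, is_remote = is_remote,
           true_coverage = n_pos / n_tissue, tissue_mask_true = tissue,
           seed = seed),
      class = "if_image_pair"
    )
  })
}

#' Generate synthetic flow-chamber particle tracks
#'
#' Emulates video tracking of iron-oxide microparticles over a platelet
#' monolayer in a parallel-plate flow chamber (field 450 x 350 um observed
#' for 60 s). Bound particles are stationary, with sub-pixel jitter, for a
#' dwell drawn from `dwell_range` (default at least 11 s, i.e. above the
#' 10 s binding rule). Transient particles either sweep across the field
#' with the flow or pause for less than 10 s.
#'
#' @param n_bound,n_transient Numbers of tracks of each class.
#' @param dwell_range Bound dwell times, s (uniform draw).
#' @param transient_dwell_range Pause durations of stationary transients, s.
#' @param field_extent Field of view, um (width, height).
#' @param frame_interval Sampling interval, s.
#' @param duration Observation duration, s.
#' @param jitter_sd Positional jitter of stationary particles, um.
#' @param speed_um_s Flow speed of moving transients, um/s.
#' @param seed Integer seed.
#' @return A `track_table` data frame (`track_id`, `t_s`, `x_um`, `y_um`)
#'   with attributes `field_extent`, `duration` and `truth` (a data frame of
#'   per-track ground-truth labels and dwells).
#' @export
make_tracks <- function(n_bound, n_transient, dwell_range = c(11, 20),
                        transient_dwell_range = c(2, 8),
                        field_extent = c(450, 350), frame_interval = 0.2,
                        duration = 60, jitter_sd = 0.15, speed_um_s = 60,
                        seed = NULL) {
  stopifnot(n_bound >= 0, n_transient >= 0, frame_interval > 0,
            all(dwell_range > 0), all(transient_dwell_range > 0))
  run_seeded(seed, {
    rows <- list()
    truth <- list()
    id <- 0L
    clamp <- function(v, hi) pmin(pmax(v, 0), hi)

    stationary_track <- function(id, dwell) {
      t0 <- stats::runif(1, 0, max(duration - dwell, 0))
      tt <- seq(t0, min(t0 + dwell, duration), by = frame_interval)
      x0 <- stats::runif(1, 5, field_extent[1] - 5)
      y0 <- stats::runif(1, 5, field_extent[2] - 5)
      data.frame(
        track_id = id, t_s = tt,
        x_um = clamp(x0 + stats::rnorm(length(tt), 0, jitter_sd), field_extent[1]),
        y_um = clamp(y0 + stats::rnorm(length(tt), 0, jitter_sd), field_extent[2])
      )
    }

    for (i in seq_len(n_bound)) {
      id <- id + 1L
      dwell <- stats::runif(1, dwell_range[1], dwell_range[2])
      rows[[id]] <- stationary_track(id, dwell)
      truth[[id]] <- data.frame(track_id = id, bound = TRUE,
                                dwell_s = diff(range(rows[[id]]$t_s)))
    }
    for (i in seq_len(n_transient)) {
      id <- id + 1L
      if (i %% 2 == 0) {
        dwell <- stats::runif(1, transient_dwell_range[1],
                              min(transient_dwell_range[2], 9.5))
        rows[[id]] <- stationary_track(id, dwell)
      } else {
        crossing <- field_extent[1] / speed_um_s
        t0 <- stats::runif(1, 0, max(duration - crossing, 0))
        tt <- seq(t0, min(t0 + crossing, duration), by = frame_interval)
        y0 <- stats::runif(1, 5, field_extent[2] - 5)
        rows[[id]] <- data.frame(
          track_id = id, t_s = tt,
          x_um = clamp((tt - t0) * speed_um_s, field_extent[1]),
          y_um = clamp(y0 + stats::rnorm(length(tt), 0, jitter_sd), field_extent[2])
        )
      }
      truth[[id]] <- data.frame(track_id = id, bound = FALSE,
                                dwell_s = diff(range(rows[[id]]$t_s)))
    }

    out <- do.call(rbind, rows) %||% data.frame(
      track_id = integer(0), t_s = numeric(0), x_um = numeric(0), y_um = numeric(0))
    rownames(out) <- NULL
    attr(out, "field_extent") <- field_extent
    attr(out, "duration") <- duration
    attr(out, "truth") <- do.call(rbind, truth) %||% data.frame(
      track_id = integer(0), bound = logical(0), dwell_s = numeric(0))
    class(out) <- c("track_table", "data.frame")
    out
  })
}

#' Generate a synthetic bright-field spot field
#'
#' Emulates a hematoxylin-stained high-power field: dark circular particles
#' (iron-oxide microbeads) on a brighter, smoothly textured background.
#' Spot centres are rejection-sampled to be non-overlapping and their true
#' positions recorded.
#'
#' @param shape Image dimensions (pixels).
#' @param n_spots Number of spots to place (>= 0).
#' @param spot_radius_px Spot radius in pixels.
#' @param background_mean Background intensity.
#' @param texture_sd Standard deviation of the smooth background texture.
#' @param spot_intensity Intensity inside spots (darker than background).
#' @param noise_sd Per-pixel sensor noise.
#' @param min_separation Minimum centre-to-centre distance; default keeps
#'   spots disjoint with a 2-pixel margin.
#' @param max_tries Rejection-sampling budget per spot before failing.
#' @param seed Integer seed.
#' @return A `spot_field`: `image`, `centers` (data frame `x`, `y`, 0-based
#'   pixel coordinates), `radius_px`.
#' @export
make_spot_field <- function(shape = c(256, 256), n_spots = 0,
                            spot_radius_px = 4, background_mean = 180,
                            texture_sd = 6, spot_intensity = 40, noise_sd = 2,
                            min_separation = NULL, max_tries = 500,
                            seed = NULL) {
  stopifnot(n_spots >= 0)
  min_separation <- min_separation %||% (2 * spot_radius_px + 2)
  nx <- shape[1]; ny <- shape[2]
  margin <- spot_radius_px + 2

  run_seeded(seed, {
    img <- matrix(background_mean, nx, ny)
    if (texture_sd > 0)
      img <- img + smooth_field(shape, matrix(TRUE, nx, ny), 10) * texture_sd

    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_spots)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(stats::runif(1, margin, nx - 1 - margin),
                  stats::runif(1, margin, ny - 1 - margin))
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                               byrow = TRUE))^2))) >= min_separation) {
          centers <- rbind(centers, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_ironmap(sprintf(
          "could not place %d non-overlapping spots in %dx%d after %d tries",
          n_spots, nx, ny, max_tries), "ironmap_spot_placement")
    }

    g <- pixel_grid(shape)
    for (i in seq_len(nrow(centers))) {
      disc <- (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 <= spot_radius_px^2
      img[disc] <- spot_intensity
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    img <- pmax(img, 0)

    structure(
      list(image = img,
           centers = data.frame(x = centers[, 1] %||% numeric(0),
                                y = centers[, 2] %||% numeric(0)),
           radius_px = spot_radius_px, seed = seed),
      class = "spot_field"
    )
  })
}
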