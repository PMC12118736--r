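#' Calibrate a fluorescence threshold on remote control images
#'
#' Pools the nonzero red-channel (P-selectin) intensities of the remote
#' (uninjured) sections and returns the given quantile, so that applying the
#' threshold as a strict `>` cut eliminates approximately that fraction of
#' remote signal. The quantile uses linear interpolation of the empirical
#' distribution function (`type = 4` in [stats::quantile()]), so pooled
#' values `1..100` at `percentile = 0.95` give exactly 95.
#'
#' @param remote_pairs A list of `if_image_pair` objects (or a single one)
#'   from remote tissue.
#' @param percentile Fraction of remote nonzero pixels to eliminate
#'   (default 0.95).
#' @return The intensity threshold (single number) with attribute
#'   `n_pixels_pooled`.
#' @export
calibrate_threshold <- function(remote_pairs, percentile = 0.95) {
  if (inherits(remote_pairs, "if_image_pair")) remote_pairs <- list(remote_pairs)
  stopifnot(length(remote_pairs) >= 1, percentile > 0, percentile <= 1)
  pooled <- unlist(lapply(remote_pairs, function(p) {
    stopifnot(inherits(p, "if_image_pair"))
    v <- as.numeric(p$red_channel)
    v[v > 0]
  }))
  if (length(pooled) == 0)
    stop_ironmap("remote images contain no nonzero red pixels",
                 "ironmap_no_signal")
  thr <- unname(stats::quantile(pooled, percentile, type = 4, names = FALSE))
  attr(thr, "n_pixels_pooled") <- length(pooled)
  thr
}

#' Tissue mask from green-channel autofluorescence
#'
#' The total tissue area is defined by the green autofluorescence channel.
#' By default the threshold is found by Otsu's method; a fixed threshold can
#' be supplied instead.
#'
#' @param green_channel Non-negative intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold when `method = "fixed"` (strict `>` rule).
#' @return Logical matrix: above-threshold pixels.
#' @export
tissue_mask <- function(green_channel, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  green_channel <- as.matrix(green_channel)
  if (all(green_channel == 0))
    stop_ironmap("green channel is identically zero", "ironmap_no_signal")
  thr <- if (method == "fixed") {
    if (is.null(value)) stop_ironmap("fixed method needs 'value'", "ironmap_bad_threshold")
    value
  } else {
    mx <- max(green_channel)
    EBImage::otsu(EBImage::Image(green_channel / mx), range = c(0, 1)) * mx
  }
  green_channel > thr
}

#' Immunofluorescence coverage of a stained marker
#'
#' The fraction of tissue pixels (green autofluorescence positive) that are
#' also positive for the stained marker (red channel strictly above the
#' calibrated threshold): positive-for-both divided by all tissue pixels.
#'
#' @param pair An `if_image_pair`.
#' @param threshold Red-channel intensity threshold, typically from
#'   [calibrate_threshold()].
#' @param tissue Optional precomputed logical tissue mask; default
#'   `tissue_mask(pair$green_channel)`.
#' @return A `coverage_result`: `threshold`, `tissue_pixels`,
#'   `positive_pixels`, `coverage`.
#' @export
coverage <- function(pair, threshold, tissue = NULL) {
  stopifnot(inherits(pair, "if_image_pair"), is.numeric(threshold))
  tissue <- tissue %||% tissue_mask(pair$green_channel)
  positive <- (pair$red_channel > as.numeric(threshold)) & tissue
  structure(
    list(threshold = as.numeric(threshold),
         tissue_pixels = sum(tissue),
         positive_pixels = sum(positive),
         coverage = sum(positive) / sum(tissue)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %d / %d tissue px positive (coverage %.4f) at threshold %.4g\n",
              x$positive_pixels, x$tissue_pixels, x$coverage, x$threshold))
  invisible(x)
}

#' Count dark spots in a bright-field high-power field
#'
#' Detects dark circular particles on a brighter background: the image is
#' inverted, a median-filter background estimate is subtracted, the residual
#' is thresholded robustly (median + `k_mad` median absolute deviations, so
#' counts are invariant to global intensity scaling), connected components
#' are labelled, and components within an area band around the expected spot
#' size are counted. Touching spots can optionally be separated by a
#' distance-transform watershed.
#'
#' @param image Intensity matrix, or a `spot_field`.
#' @param expected_radius_px Expected spot radius (pixels).
#' @param min_area,max_area Component area band (pixels); defaults derived
#'   from the expected radius.
#' @param k_mad Robust threshold multiplier.
#' @param split_touching If `TRUE`, watershed-split touching spots.
#' @return A `spot_count_result`: `count`, `areas`, `centroids`, and the
#'   detection parameters used.
#' @export
count_spots <- function(image, expected_radius_px = 4, min_area = NULL,
                        max_area = NULL, k_mad = 8, split_touching = FALSE) {
  if (inherits(image, "spot_field")) {
    expected_radius_px <- image$radius_px
    image <- image$image
  }
  image <- as.matrix(image)
  spot_area <- pi * expected_radius_px^2
  min_area <- min_area %||% max(3, floor(0.3 * spot_area))
  max_area <- max_area %||% ceiling(3 * spot_area)

  inv <- max(image) - image
  sz <- 2L * as.integer(expected_radius_px) * 2L + 1L
  mx <- max(inv)
  bg <- if (mx > 0)
    as.matrix(EBImage::medianFilter(EBImage::Image(inv / mx), size = sz)) * mx
  else inv
  resid <- inv - bg
  thr <- stats::median(resid) + k_mad * max(stats::mad(resid),
                                            1e-8 * max(abs(resid), 1))
  binary <- resid > thr

  lab <- if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(binary * 1))
    EBImage::watershed(dm)
  } else {
    EBImage::bwlabel(EBImage::Image(binary * 1))
  }
  lab <- as.matrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)

  centroids <- if (length(keep)) {
    t(vapply(keep, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(x = mean(idx[, 1]) - 1, y = mean(idx[, 2]) - 1)
    }, c(x = 0, y = 0)))
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))

  structure(
    list(count = length(keep), areas = areas[keep],
         centroids = as.data.frame(centroids),
         params = list(expected_radius_px = expected_radius_px,
                       min_area = min_area, max_area = max_area,
                       k_mad = k_mad, split_touching = split_touching)),
    class = "spot_count_result"
  )
}

#' Aggregate per-field spot counts per region
#'
#' Sums high-power-field counts per slide/region; by convention 20 fields
#' are recorded per slide.
#'
#' @param counts Integer vector of per-field counts.
#' @param region Optional region labels (same length), e.g. RCA/LCX/LAD.
#' @return Data frame with per-region total, mean and field count.
#' @export
aggregate_spot_counts <- function(counts, region = NULL) {
  stopifnot(all(counts >= 0))
  region <- region %||% rep("all", length(counts))
  out <- do.call(rbind, lapply(split(counts, region), function(v)
    data.frame(total = sum(v), mean_per_field = mean(v), n_fields = length(v))))
  out$region <- rownames(out)
  rownames(out) <- NULL
  out[, c("region", "total", "mean_per_field", "n_fields")]
}

#' Count particles bound to a cell layer by the proximity rule
#'
#' A particle is bound if it sits on top of or exactly next to a cell: its
#' centre must lie inside the cell mask dilated by the adjacency radius
#' (default one particle radius). Implemented via the Euclidean distance
#' transform of the cell mask.
#'
#' @param spot_centers Data frame with `x`, `y` (0-based pixel coordinates).
#' @param cell_mask Logical matrix of cell-covered pixels.
#' @param adjacency_radius_px Adjacency radius in pixels (>= 0).
#' @return List: `bound_count`, `bound` (logical per spot), `distances_px`.
#' @export
incubation_bound_count <- function(spot_centers, cell_mask,
                                   adjacency_radius_px = 1) {
  stopifnot(adjacency_radius_px >= 0)
  cell_mask <- as.matrix(cell_mask) > 0
  if (nrow(spot_centers) == 0)
    return(list(bound_count = 0L, bound = logical(0), distances_px = numeric(0)))
  # distance of every pixel to the nearest cell pixel: distance transform of
  # the complement (cell pixels are that map's background, distance 0).
  dt <- as.matrix(EBImage::distmap(EBImage::Image((!cell_mask) * 1)))
  i <- pmin(pmax(round(spot_centers$x) + 1, 1), nrow(cell_mask))
  j <- pmin(pmax(round(spot_centers$y) + 1, 1), ncol(cell_mask))
  d <- dt[cbind(i, j)]
  bound <- d <= adjacency_radius_px
  list(bound_count = sum(bound), bound = bound, distances_px = d)
}
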