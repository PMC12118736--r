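#' Acquisition schedule for a synthetic MR image series
#'
#' An acquisition schedule pairs a signal-evolution model with the ordered
#' acquisition times at which magnitude images are produced: echo times (TE)
#' for multi-echo gradient-echo T2* mapping, inversion times (TI) for
#' inversion-recovery T1 mapping, or T2-preparation times for T2 mapping.
#'
#' @param kind One of `"multi_echo"`, `"inversion_recovery"`, `"t2_prep"`.
#' @param times_ms Strictly increasing acquisition times in milliseconds,
#'   at least 2 (3 for inversion recovery). All times must be `>= 0`.
#' @param noise_sigma Standard deviation (signal units) of the complex
#'   Gaussian noise added per channel before the magnitude operation.
#' @param model_name Free-text label for provenance (e.g. the pulse sequence).
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(kind = c("multi_echo", "inversion_recovery", "t2_prep"),
                                 times_ms, noise_sigma = 0, model_name = kind) {
  kind <- match.arg(kind)
  times_ms <- as.numeric(times_ms)
  min_n <- if (kind == "inversion_recovery") 3L else 2L
  if (length(times_ms) < min_n)
    stop_ironmap(sprintf("'%s' schedule needs at least %d times", kind, min_n),
                 "ironmap_bad_schedule")
  if (any(!is.finite(times_ms)) || any(times_ms < 0))
    stop_ironmap("schedule times must be finite and >= 0", "ironmap_bad_schedule")
  if (any(diff(times_ms) <= 0))
    stop_ironmap("schedule times must be strictly increasing", "ironmap_bad_schedule")
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 || noise_sigma < 0)
    stop_ironmap("noise_sigma must be a single non-negative number", "ironmap_bad_schedule")
  structure(
    list(kind = kind, times_ms = times_ms, noise_sigma = noise_sigma,
         model_name = model_name[1]),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("<acquisition_schedule> %s (%s)\n  times [ms]: %s\n  noise sigma: %g\n",
              x$kind, x$model_name, paste(x$times_ms, collapse = ", "),
              x$noise_sigma))
  invisible(x)
}

#' Stock acquisition schedules
#'
#' Convenience constructors for the schedules used throughout the package:
#' the in vivo four-echo FLASH TE list (2.4, 6.0, 9.5, 13.0 ms), the ex vivo
#' three-echo list (3.4, 9.8, 17.1 ms), an eight-point inversion-recovery TI
#' ladder spanning 100-4500 ms, and the three T2-preparation times
#' (0, 30, 40 ms).
#'
#' @param noise_sigma Complex-channel noise standard deviation (signal units).
#' @param times_ms Optional override of the inversion-time ladder.
#' @return An [acquisition_schedule()].
#' @export
schedule_multi_echo_invivo <- function(noise_sigma = 0) {
  acquisition_schedule("multi_echo", c(2.4, 6.0, 9.5, 13.0), noise_sigma,
                       "multi-echo FLASH (in vivo)")
}

#' @rdname schedule_multi_echo_invivo
#' @export
schedule_multi_echo_exvivo <- function(noise_sigma = 0) {
  acquisition_schedule("multi_echo", c(3.4, 9.8, 17.1), noise_sigma,
                       "multi-echo spoiled GRE (ex vivo)")
}

#' @rdname schedule_multi_echo_invivo
#' @export
schedule_inversion_recovery <- function(noise_sigma = 0,
                                        times_ms = c(100, 200, 400, 800, 1200, 1800, 2800, 4500)) {
  acquisition_schedule("inversion_recovery", times_ms, noise_sigma, "IR bSSFP")
}

#' @rdname schedule_multi_echo_invivo
#' @export
schedule_t2prep <- function(noise_sigma = 0) {
  acquisition_schedule("t2_prep", c(0, 30, 40), noise_sigma, "T2-prepared FLASH")
}

#' Magnitude image series container
#'
#' Bundles a stack of non-negative magnitude images with the acquisition
#' schedule that produced them. Images are stored as an array whose last
#' dimension indexes schedule times; spatial dimensions may be 2D or 3D.
#' If the supplied schedule times are unsorted the series is reordered into
#' increasing time so fits are invariant to acquisition order.
#'
#' @param images Numeric array, last dimension of length `length(schedule$times_ms)`.
#' @param schedule An [acquisition_schedule()].
#' @param pixel_size_mm Isotropic pixel size in mm.
#' @param provenance Optional list (seed, phantom id, ...) carried along.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(images, schedule, pixel_size_mm = 1, provenance = list()) {
  if (!inherits(schedule, "acquisition_schedule"))
    stop_ironmap("schedule must be an acquisition_schedule", "ironmap_bad_series")
  images <- as.array(images)
  nd <- length(dim(images))
  nt <- dim(images)[nd]
  if (nt != length(schedule$times_ms))
    stop_ironmap("number of images must equal number of schedule times",
                 "ironmap_bad_series")
  if (any(images < 0, na.rm = TRUE))
    stop_ironmap("magnitude images must be non-negative", "ironmap_bad_series")
  structure(
    list(images = images, schedule = schedule, pixel_size_mm = pixel_size_mm,
         provenance = provenance),
    class = "echo_series"
  )
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<echo_series> %s, %s images of %s px, pixel %g mm\n",
              x$schedule$kind, d[length(d)],
              paste(d[-length(d)], collapse = "x"), x$pixel_size_mm))
  invisible(x)
}

# Flatten the spatial dimensions of a series to a pixels-by-times matrix.
series_matrix <- function(series) {
  d <- dim(series$images)
  nd <- length(d)
  matrix(series$images, prod(d[-nd]), d[nd])
}

series_spatial_dim <- function(series) {
  d <- dim(series$images)
  d[-length(d)]
}
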