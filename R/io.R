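# File-format frontends: NIfTI-1 for MR series and maps (with a JSON
# sidecar carrying the acquisition schedule), 16-bit TIFF for microscopy
# channels, CSV for track tables.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read and write magnitude image series as NIfTI + JSON sidecar
#'
#' The image stack is stored as one NIfTI-1 volume (last dimension =
#' acquisition times) and the schedule as a JSON sidecar
#' `{kind, times_ms, noise_sigma, model_name, seed}` next to it.
#'
#' @param series An [echo_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_series` returns `path` invisibly; `read_series` returns an
#'   [echo_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  RNifti::writeNifti(RNifti::asNifti(series$images,
                                     pixdim = rep(series$pixel_size_mm, 3)),
                     path)
  meta <- c(series$schedule[c("kind", "times_ms", "noise_sigma", "model_name")],
            list(pixel_size_mm = series$pixel_size_mm,
                 provenance = series$provenance))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sched <- acquisition_schedule(meta$kind, meta$times_ms,
                                meta$noise_sigma %||% 0,
                                meta$model_name %||% meta$kind)
  echo_series(array(as.numeric(img), dim = dim(img)), sched,
              pixel_size_mm = meta$pixel_size_mm %||% 1,
              provenance = as.list(meta$provenance %||% list()))
}

#' Read and write parameter maps as NIfTI volumes
#'
#' Writes three aligned volumes (`<stem>_values.nii.gz`,
#' `<stem>_quality.nii.gz`, `<stem>_valid.nii.gz`) plus a JSON sidecar with
#' the kind and pixel size. Invalid pixels are stored as NaN in the values
#' volume.
#'
#' @param map A `parameter_map`.
#' @param stem Output path stem (no extension).
#' @return `write_map` returns `stem` invisibly; `read_map` a `parameter_map`.
#' @export
write_map <- function(map, stem) {
  stopifnot(inherits(map, "parameter_map"))
  vals <- map$values
  vals[!map$valid] <- NaN
  RNifti::writeNifti(RNifti::asNifti(vals), paste0(stem, "_values.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$quality), paste0(stem, "_quality.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$valid * 1), paste0(stem, "_valid.nii.gz"))
  jsonlite::write_json(list(kind = map$kind, pixel_size_mm = map$pixel_size_mm),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_map
#' @export
read_map <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  vals <- RNifti::readNifti(paste0(stem, "_values.nii.gz"))
  qual <- RNifti::readNifti(paste0(stem, "_quality.nii.gz"))
  valid <- RNifti::readNifti(paste0(stem, "_valid.nii.gz"))
  vals <- array(as.numeric(vals), dim = dim(vals))
  vals[is.nan(vals)] <- NA_real_
  parameter_map(vals, array(as.numeric(qual), dim = dim(qual)),
                array(as.numeric(valid) > 0, dim = dim(valid)),
                kind = meta$kind, pixel_size_mm = meta$pixel_size_mm %||% 1)
}

#' Read and write immunofluorescence channel pairs as 16-bit TIFF
#'
#' Each channel is one single-channel 16-bit TIFF; intensities are stored
#' relative to `scale_max` (full 16-bit range). Metadata (remote flag, true
#' coverage when synthetic) goes to a JSON sidecar.
#'
#' @param pair An `if_image_pair`.
#' @param stem Output path stem; writes `<stem>_red.tif`, `<stem>_green.tif`,
#'   `<stem>.json`.
#' @param scale_max Intensity mapped to the top of the 16-bit range.
#' @return `write_if_pair` returns `stem` invisibly; `read_if_pair` an
#'   `if_image_pair`.
#' @export
write_if_pair <- function(pair, stem, scale_max = 65535) {
  stopifnot(inherits(pair, "if_image_pair"))
  wr <- function(ch, p) tiff::writeTIFF(pmin(pmax(ch / scale_max, 0), 1), p,
                                        bits.per.sample = 16L)
  wr(pair$red_channel, paste0(stem, "_red.tif"))
  wr(pair$green_channel, paste0(stem, "_green.tif"))
  jsonlite::write_json(list(is_remote = pair$is_remote,
                            true_coverage = pair$true_coverage,
                            scale_max = scale_max),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_if_pair
#' @export
read_if_pair <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  scale_max <- meta$scale_max %||% 65535
  rd <- function(p) as.matrix(tiff::readTIFF(p)) * scale_max
  structure(
    list(red_channel = rd(paste0(stem, "_red.tif")),
         green_channel = rd(paste0(stem, "_green.tif")),
         is_remote = isTRUE(meta$is_remote),
         true_coverage = meta$true_coverage %||% NA_real_,
         tissue_mask_true = NULL, seed = NULL),
    class = "if_image_pair"
  )
}

#' Read and write particle track tables as CSV
#'
#' CSV with header `track_id,t_s,x_um,y_um`; the field extent and duration
#' are kept in a JSON sidecar when written by this package.
#'
#' @param tracks A `track_table` (or compatible data frame).
#' @param path Output `.csv` path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `track_table`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "t_s", "x_um", "y_um")], path,
                   row.names = FALSE)
  meta <- list(field_extent = attr(tracks, "field_extent"),
               duration = attr(tracks, "duration"))
  if (!is.null(meta$field_extent))
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  req <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(req %in% names(out)))
    stop_ironmap("track CSV must have columns track_id,t_s,x_um,y_um",
                 "ironmap_bad_tracks")
  side <- sub("\\.csv$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "field_extent") <- meta$field_extent
    attr(out, "duration") <- meta$duration
  }
  class(out) <- c("track_table", "data.frame")
  out
}
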