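#' Classify flow-chamber particle tracks by the dwell-time rule
#'
#' Applies the binding rule used for flow-chamber recordings: a particle is
#' bound to the platelet monolayer only if it stays adherent for at least
#' `min_dwell` seconds within the observation window. Adhesion is
#' operationalized spatially: for each track, the dwell is the longest time
#' interval during which every position remains within `stationary_radius`
#' of the interval's first position (the anchor). Tracks still stationary at
#' the window end count their observed dwell. Timestamps are taken relative
#' to the start of the recording, so the classification is invariant to a
#' constant time shift.
#'
#' @param tracks A `track_table` (from [make_tracks()] or [read_tracks()]),
#'   or any data frame with `track_id`, `t_s`, `x_um`, `y_um`.
#' @param min_dwell Minimum dwell for binding, s (default 10).
#' @param stationary_radius Maximum displacement from the anchor still
#'   counted as stationary, um (default 2, about two particle diameters).
#' @param observation_window Observation duration, s (default 60); samples
#'   after the window are ignored.
#' @return A `binding_result`: data frame with `track_id`, `dwell_s`,
#'   `max_displacement_um` (within the best interval), `bound`; attribute
#'   `summary` holds the bound count for the field.
#' @export
classify_tracks <- function(tracks, min_dwell = 10, stationary_radius = 2,
                            observation_window = 60) {
  stopifnot(stationary_radius > 0, min_dwell >= 0, observation_window > 0)
  req <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(req %in% names(tracks)))
    stop_ironmap("tracks must have columns track_id, t_s, x_um, y_um",
                 "ironmap_bad_tracks")
  if (nrow(tracks) == 0) {
    out <- data.frame(track_id = integer(0), dwell_s = numeric(0),
                      max_displacement_um = numeric(0), bound = logical(0))
    attr(out, "summary") <- list(bound_count = 0L, n_tracks = 0L,
                                 observation_window = observation_window)
    class(out) <- c("binding_result", "data.frame")
    return(out)
  }
  t0 <- min(tracks$t_s)
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    tt <- tr$t_s - t0
    if (any(diff(tr$t_s) <= 0))
      stop_ironmap(sprintf("non-monotone timestamps in track %s",
                           tr$track_id[1]), "ironmap_bad_tracks")
    keep <- tt <= observation_window
    tt <- tt[keep]; x <- tr$x_um[keep]; y <- tr$y_um[keep]
    n <- length(tt)
    best_dwell <- -1; best_disp <- 0
    if (n > 0) {
      for (i in seq_len(n)) {
        # first sample after i that leaves the radius around anchor i
        d2 <- (x - x[i])^2 + (y - y[i])^2
        out_idx <- which(d2[i:n] > stationary_radius^2)
        j <- if (length(out_idx)) i + out_idx[1] - 2L else n
        dwell <- tt[j] - tt[i]
        if (dwell > best_dwell) {
          best_dwell <- dwell
          best_disp <- sqrt(max(d2[i:j]))
        }
        if (tt[n] - tt[i] <= best_dwell) break  # no longer interval possible
      }
    }
    best_dwell <- max(best_dwell, 0)
    data.frame(track_id = tr$track_id[1], dwell_s = best_dwell,
               max_displacement_um = best_disp,
               bound = best_dwell >= min_dwell)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(bound_count = sum(out$bound),
                               n_tracks = nrow(out),
                               observation_window = observation_window,
                               min_dwell = min_dwell,
                               stationary_radius = stationary_radius)
  class(out) <- c("binding_result", "data.frame")
  out
}

#' Summarize and compare binding counts across fields and groups
#'
#' Collects the bound-particle count of each field and compares groups with
#' the Mann-Whitney U test (via [compare_groups()]).
#'
#' @param results Named list of groups; each group is a list of
#'   `binding_result` objects (one per field) or a numeric vector of bound
#'   counts.
#' @return List: `per_group` (data frame of counts), `comparison` (test
#'   table, `NULL` for a single group).
#' @export
binding_rate <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (any(vapply(results, function(g) length(g) == 0, TRUE)))
    stop_ironmap("empty group in binding_rate", "ironmap_bad_groups")
  counts <- lapply(results, function(g) {
    if (is.numeric(g)) as.numeric(g)
    else vapply(g, function(r) {
      stopifnot(inherits(r, "binding_result"))
      as.numeric(attr(r, "summary")$bound_count)
    }, 1)
  })
  nm <- names(counts) %||% paste0("group", seq_along(counts))
  per_group <- do.call(rbind, lapply(seq_along(counts), function(i)
    data.frame(group = nm[i], field = seq_along(counts[[i]]),
               bound_count = counts[[i]])))
  comparison <- if (length(counts) == 2)
    compare_groups(stats::setNames(counts, nm), "mann_whitney") else NULL
  list(per_group = per_group, comparison = comparison)
}
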