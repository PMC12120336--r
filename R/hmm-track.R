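#' Extract a position track from a posterior stack
#'
#' Per hour, the mean position is the probability-weighted centroid of
#' the sea-cell centres and the mode position is the highest-probability
#' cell centre (ties broken towards the lowest latitude index, then the
#' lowest longitude index). The positional spread is the
#' root-mean-square great-circle distance (km) of the posterior around
#' the mean position.
#'
#' @param post Posterior `tt_stack` from [forward_backward()].
#' @return Tibble `time, lon_mean, lat_mean, lon_mode, lat_mode, sd_km`.
#' @export
extract_track <- function(post) {
  grid <- post$grid
  nla <- length(grid$lat); nlo <- length(grid$lon)
  lonm <- matrix(grid$lon, nla, nlo, byrow = TRUE)
  latm <- matrix(grid$lat, nla, nlo)
  purrr::map_dfr(seq_along(post$times), function(t) {
    p <- post$values[, , t]
    s <- sum(p)
    p <- p / s
    lon_mean <- sum(p * lonm)
    lat_mean <- sum(p * latm)
    mx <- max(p)
    cand <- which(p >= mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    sd_km <- sqrt(sum(p * haversine_km(lonm, latm, lon_mean, lat_mean)^2))
    tibble::tibble(time = post$times[t],
                   lon_mean = lon_mean, lat_mean = lat_mean,
                   lon_mode = grid$lon[j], lat_mode = grid$lat[i],
                   sd_km = sd_km)
  })
}

#' Reduce an hourly track to daily mean positions
#'
#' @param track Hourly track tibble from [extract_track()].
#' @return Tibble `date, lon_mean, lat_mean`, the per-calendar-day mean
#'   of the hourly mean positions.
#' @export
daily_track <- function(track) {
  track |>
    dplyr::group_by(date = as.Date(.data$time)) |>
    dplyr::summarise(lon_mean = mean(.data$lon_mean),
                     lat_mean = mean(.data$lat_mean),
                     .groups = "drop")
}

#' Total distance travelled along a track
#'
#' Sum of great-circle distances between consecutive mean positions, at
#' daily (default; hourly positional jitter inflates path length) or
#' hourly resolution.
#'
#' @param track Hourly track tibble.
#' @param resolution `"daily"` or `"hourly"`.
#' @return Distance in km.
#' @export
track_distance <- function(track, resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  pos <- if (resolution == "daily") daily_track(track) else track
  n <- nrow(pos)
  if (n < 2) return(0)
  sum(haversine_km(pos$lon_mean[-n], pos$lat_mean[-n],
                   pos$lon_mean[-1], pos$lat_mean[-1]))
}

#' Track sensitivity to the acoustic constraint
#'
#' Per-hour great-circle distance between two mean tracks estimated for
#' the same tag with and without acoustic detections; the summary
#' (mean, min, max) is the model-consistency diagnostic reported per
#' fish.
#'
#' @param track_with,track_without Hourly track tibbles on the same time
#'   axis.
#' @return List `mean_km, min_km, max_km, per_step` (tibble
#'   `time, distance_km`).
#' @export
track_sensitivity <- function(track_with, track_without) {
  if (!identical(as.numeric(track_with$time),
                 as.numeric(track_without$time))) {
    stop("tracks are on different time axes", call. = FALSE)
  }
  d <- haversine_km(track_with$lon_mean, track_with$lat_mean,
                    track_without$lon_mean, track_without$lat_mean)
  list(mean_km = mean(d), min_km = min(d), max_km = max(d),
       per_step = tibble::tibble(time = track_with$time, distance_km = d))
}

#' Detect tag death from a sustained surface signature
#'
#' A dead fish's tag that floats ashore records sustained near-zero
#' depth. Returns the first instant from which the depth stays below
#' `depth_m` for at least `window_h` hours, or `NA` if no such window
#' exists.
#'
#' @param series Sensor-series tibble.
#' @param depth_m Surface threshold, metres.
#' @param window_h Minimum sustained duration, hours.
#' @return POSIXct death time or `NA`.
#' @export
detect_tag_death <- function(series, depth_m = 1, window_h = 24) {
  shallow <- series$depth_m < depth_m
  ts <- as.numeric(series$timestamp)
  r <- rle(shallow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    span_h <- (ts[ends[k]] - ts[starts[k]]) / 3600
    runs_to_end <- ends[k] == length(ts)
    if (span_h >= window_h || (runs_to_end && span_h >= window_h)) {
      return(series$timestamp[starts[k]])
    }
  }
  as.POSIXct(NA, tz = "UTC")
}
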