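#' Analysis configuration
#'
#' Collects the tunable tolerances and thresholds of the pipeline in one
#' list. All values are strictly positive.
#'
#' @param sigma_T Temperature-likelihood standard deviation, degrees C.
#' @param sigma_z Depth slack for the bathymetric feasibility test, metres.
#' @param residency_threshold Residency gap threshold, hours.
#' @param survival_week Long-term survival horizon, days.
#' @param vmax Maximum plausible sustained swimming speed, m/s.
#' @param isolation_window Isolation window for detection QC, hours.
#' @param snr_min Minimum acceptable signal-to-noise ratio, dB.
#' @param kernel_truncation Movement-kernel truncation, multiples of sigma.
#' @param nondetection_value Likelihood value outside receiver ranges in
#'   hours without a detection (unitless).
#' @return A list of class `tt_config`.
#' @export
analysis_config <- function(sigma_T = 1.0, sigma_z = 5.0,
                            residency_threshold = 24, survival_week = 7,
                            vmax = 2.0, isolation_window = 24,
                            snr_min = 6, kernel_truncation = 4,
                            nondetection_value = 1) {
  cfg <- list(sigma_T = sigma_T, sigma_z = sigma_z,
              residency_threshold = residency_threshold,
              survival_week = survival_week, vmax = vmax,
              isolation_window = isolation_window, snr_min = snr_min,
              kernel_truncation = kernel_truncation,
              nondetection_value = nondetection_value)
  if (any(unlist(cfg) <= 0)) {
    stop("all configuration values must be strictly positive", call. = FALSE)
  }
  structure(cfg, class = "tt_config")
}

det_cols <- c("tag_id", "timestamp", "receiver_id", "station", "lon", "lat")

#' Read an acoustic detection table
#'
#' Parses a detection CSV with columns
#' `tag_id,timestamp,receiver_id,station,lon,lat[,snr]`, sorts by
#' `(tag_id, timestamp)` and reports malformed rows (unparseable timestamp
#' or coordinates, coordinates outside `bbox`) with their line numbers in
#' the `rejects` attribute.
#'
#' @param path CSV file path.
#' @param bbox Optional numeric `c(lon_min, lon_max, lat_min, lat_max)`
#'   declaring the plausible coordinate bounding box.
#' @return A tibble of detections; attribute `rejects` is a tibble of
#'   rejected rows with `line` and `reason`.
#' @export
read_detections <- function(path, bbox = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  missing <- setdiff(det_cols, names(raw))
  if (length(missing)) {
    stop("detections file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ts <- parse_utc(raw$timestamp)
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  snr <- if ("snr" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$snr))
  } else {
    rep(NA_real_, nrow(raw))
  }
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(lon) | is.na(lat))] <- "unparseable coordinates"
  if (!is.null(bbox)) {
    out <- !is.na(lon) & !is.na(lat) &
      (lon < bbox[1] | lon > bbox[2] | lat < bbox[3] | lat > bbox[4])
    reason[is.na(reason) & out] <- "coordinates outside bounding box"
  }
  ok <- is.na(reason)
  dets <- tibble::tibble(
    tag_id = raw$tag_id[ok], timestamp = ts[ok],
    receiver_id = raw$receiver_id[ok], station = raw$station[ok],
    lon = lon[ok], lat = lat[ok], snr = snr[ok]
  ) |>
    dplyr::arrange(.data$tag_id, .data$timestamp)
  rejects <- tibble::tibble(line = which(!ok) + 1L, reason = reason[!ok])
  attr(dets, "rejects") <- rejects
  dets
}

#' Write a detection table
#'
#' Inverse of [read_detections()]; timestamps are written as ISO-8601 UTC
#' (1 s precision) and coordinates at 1e-6 degrees so that a write/read
#' round trip is lossless at that precision.
#'
#' @param dets Detection tibble.
#' @param path Output path.
#' @export
write_detections <- function(dets, path) {
  out <- dets |>
    dplyr::mutate(timestamp = fmt_utc(.data$timestamp),
                  lon = sprintf("%.6f", .data$lon),
                  lat = sprintf("%.6f", .data$lat)) |>
    dplyr::select(dplyr::all_of(det_cols), "snr")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read receiver deployment metadata
#'
#' Columns: `receiver_id,station,lon,lat,start,end,detection_range_m,protocol`.
#' Deployments must satisfy `start < end` and `detection_range_m > 0`.
#'
#' @param path CSV file path.
#' @return A tibble of deployments.
#' @export
read_receivers <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           receiver_id = "c", station = "c",
                           lon = "d", lat = "d", start = "c", end = "c",
                           detection_range_m = "d", protocol = "c"))
  rec <- rec |>
    dplyr::mutate(start = parse_utc(.data$start), end = parse_utc(.data$end),
                  protocol = ifelse(.data$protocol %in% c("OPi", "R64K"),
                                    .data$protocol, "other"))
  if (any(rec$start >= rec$end)) {
    stop("receiver deployment with start >= end", call. = FALSE)
  }
  if (any(rec$detection_range_m <= 0)) {
    stop("detection_range_m must be positive", call. = FALSE)
  }
  rec
}

#' @rdname read_receivers
#' @param recv Receiver deployment tibble.
#' @export
write_receivers <- function(recv, path) {
  out <- recv |>
    dplyr::mutate(start = fmt_utc(.data$start), end = fmt_utc(.data$end),
                  lon = sprintf("%.6f", .data$lon),
                  lat = sprintf("%.6f", .data$lat))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an archival-tag (DST) sensor series
#'
#' Columns: `timestamp,depth_m,temperature_c`. The series is checked for
#' monotone timestamps; depth readings in `(-1, 0)` m (surface sensor
#' noise) are clipped to 0, values below -1 m are an error. The attribute
#' `cadence_s` reports the median sampling interval.
#'
#' @param path CSV file path.
#' @param tag_id Optional tag identifier attached to the series.
#' @return A tibble `tag_id,timestamp,depth_m,temperature_c`.
#' @export
read_sensor_series <- function(path, tag_id = NA_character_) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(timestamp = "c",
                                                 depth_m = "d",
                                                 temperature_c = "d"))
  ts <- parse_utc(raw$timestamp)
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1], call. = FALSE)
  }
  bad <- which(diff(as.numeric(ts)) <= 0)
  if (length(bad)) {
    stop("non-monotone timestamps starting at record ", bad[1] + 1,
         call. = FALSE)
  }
  if (any(raw$depth_m < -1, na.rm = TRUE)) {
    stop("depth below -1 m: sensor series invalid", call. = FALSE)
  }
  out <- tibble::tibble(
    tag_id = tag_id, timestamp = ts,
    depth_m = pmax(raw$depth_m, 0), temperature_c = raw$temperature_c
  )
  attr(out, "cadence_s") <-
    if (nrow(out) > 1) median(diff(as.numeric(ts))) else NA_real_
  out
}

#' @rdname read_sensor_series
#' @param series Sensor-series tibble.
#' @export
write_sensor_series <- function(series, path) {
  out <- series |>
    dplyr::transmute(timestamp = fmt_utc(.data$timestamp),
                     depth_m = .data$depth_m,
                     temperature_c = .data$temperature_c)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read fish (tagging) metadata
#'
#' Columns: `acoustic_tag_id,archival_tag_id,total_length_mm,release_time,
#' release_lon,release_lat,recapture_time,recapture_lon,recapture_lat`.
#' Maturity is derived from total length against the length at 50%
#' maturity (43.7 cm for pollack).
#'
#' @param path CSV file path.
#' @param lmat50_mm Length at 50% maturity, mm.
#' @return A tibble with a derived `maturity` column
#'   (`immature`/`mature`).
#' @export
read_fish <- function(path, lmat50_mm = LMAT50_MM) {
  fish <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            acoustic_tag_id = "c", archival_tag_id = "c",
                            total_length_mm = "d", release_time = "c",
                            release_lon = "d", release_lat = "d",
                            recapture_time = "c", recapture_lon = "d",
                            recapture_lat = "d"))
  fish <- fish |>
    dplyr::mutate(
      release_time = parse_utc(.data$release_time),
      recapture_time = parse_utc(.data$recapture_time),
      maturity = factor(
        ifelse(.data$total_length_mm >= lmat50_mm, "mature", "immature"),
        levels = c("immature", "mature"))
    )
  bad <- !is.na(fish$recapture_time) & fish$recapture_time <= fish$release_time
  if (any(bad)) {
    stop("recapture precedes release for tag ",
         fish$acoustic_tag_id[which(bad)[1]], call. = FALSE)
  }
  fish
}

#' @rdname read_fish
#' @param fish Fish-metadata tibble.
#' @export
write_fish <- function(fish, path) {
  out <- fish |>
    dplyr::mutate(release_time = fmt_utc(.data$release_time),
                  recapture_time = ifelse(is.na(.data$recapture_time), NA,
                                          fmt_utc(.data$recapture_time))) |>
    dplyr::select(-dplyr::any_of("maturity"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Aggregate a 90-s sensor series to hourly observations
#'
#' Bins records into clock-aligned UTC hours `[h, h+1)` and reduces each
#' occupied hour to the maximum depth (the most constraining value against
#' bathymetry), the mean depth, and the mean temperature. Empty hours are
#' skipped.
#'
#' @param series Sensor-series tibble from [read_sensor_series()].
#' @return A tibble `hour,z_max,z_mean,t_mean,n_records`.
#' @export
aggregate_hourly <- function(series) {
  stopifnot(nrow(series) > 0)
  series |>
    dplyr::group_by(hour = hour_floor(.data$timestamp)) |>
    dplyr::summarise(
      z_max = max(.data$depth_m),
      z_mean = mean(.data$depth_m),
      t_mean = mean(.data$temperature_c),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$hour)
}
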