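#' Geolocate one double-tagged fish
#'
#' End-to-end geolocation of a single tag: aggregates the 90-s sensor
#' series to hourly observations, builds depth, temperature and
#' (optionally) acoustic emission likelihoods against the reference
#' fields, anchors the track at the release (and recapture, when known)
#' position, estimates the diffusion coefficient by maximum marginal
#' likelihood (unless `sigma` is supplied), smooths with the
#' forward-backward recursions and extracts the mean/mode track.
#'
#' @param series Sensor-series tibble ([read_sensor_series()]).
#' @param fields [reference_fields()].
#' @param fish_row One-row fish-metadata tibble for this tag.
#' @param dets Filtered detections of this tag (ignored when
#'   `use_acoustic = FALSE`).
#' @param recv Receiver deployments.
#' @param cfg [analysis_config()].
#' @param use_acoustic Include the acoustic likelihood?
#' @param sigma Fix the diffusion coefficient (cells per square-root
#'   hour) instead of estimating it.
#' @param sigma_bounds Search bounds for the diffusion coefficient.
#' @param death_time Optional POSIXct at which the fish is presumed dead;
#'   the run is truncated there. `"auto"` applies
#'   [detect_tag_death()].
#' @param keep_posterior Keep the full posterior stack in the result?
#' @return An object of class `tt_geofit`: list with `track` (hourly
#'   tibble), `daily` (daily tibble), `sigma_hat` (cells and km units),
#'   `log_lik`, `distance_km`, `posterior` (optional), `profile`,
#'   `tag_id`, `use_acoustic`, `n_hours`.
#' @export
geolocate <- function(series, fields, fish_row, dets = NULL, recv = NULL,
                      cfg = analysis_config(), use_acoustic = TRUE,
                      sigma = NULL, sigma_bounds = c(0.05, 5),
                      death_time = NULL, keep_posterior = FALSE) {
  stopifnot(nrow(fish_row) == 1)
  if (identical(death_time, "auto")) death_time <- detect_tag_death(series)
  if (!is.null(death_time) && !is.na(death_time)) {
    series <- series[series$timestamp < death_time, ]
  }
  obs <- aggregate_hourly(series)
  obs <- obs[obs$hour %in% fields$time, ]
  if (nrow(obs) < 2) stop("fewer than two observable hours", call. = FALSE)

  Ld <- depth_likelihood(obs, fields, cfg$sigma_z)
  Lt <- temperature_likelihood(obs, fields, cfg$sigma_T)
  stacks <- list(Ld, Lt)
  if (use_acoustic) {
    if (is.null(dets) || is.null(recv)) {
      stop("use_acoustic = TRUE needs detections and receivers",
           call. = FALSE)
    }
    d <- dets[dets$tag_id == fish_row$acoustic_tag_id, ]
    La <- acoustic_likelihood(d, recv, fields$grid, obs$hour,
                              cfg$nondetection_value)
    # consistency screen: a detection whose hour has no cell compatible
    # with the sensor likelihoods is a residual false detection that
    # slipped past QC; drop it rather than declare the track infeasible
    mass <- vapply(seq_along(obs$hour), function(t) {
      sum(Ld$values[, , t] * Lt$values[, , t] * La$values[, , t])
    }, numeric(1))
    det_hours <- unique(hour_floor(d$timestamp))
    bad_hours <- obs$hour[mass == 0][obs$hour[mass == 0] %in% det_hours]
    if (length(bad_hours)) {
      message("dropping ", sum(hour_floor(d$timestamp) %in% bad_hours),
              " detection(s) in ", length(bad_hours),
              " hour(s) inconsistent with the sensor likelihoods")
      d <- d[!hour_floor(d$timestamp) %in% bad_hours, ]
      La <- acoustic_likelihood(d, recv, fields$grid, obs$hour,
                                cfg$nondetection_value)
    }
    stacks <- c(stacks, list(La))
  }
  recapture <- NULL
  if (!is.na(fish_row$recapture_time) &&
      !is.na(fish_row$recapture_lon) &&
      hour_floor(fish_row$recapture_time) >= obs$hour[nrow(obs)]) {
    recapture <- c(fish_row$recapture_lon, fish_row$recapture_lat)
  }
  L <- do.call(combine_likelihoods, c(stacks, list(
    release = c(fish_row$release_lon, fish_row$release_lat),
    recapture = recapture)))

  if (is.null(sigma)) {
    est <- estimate_sigma(L, sigma_bounds, truncation = cfg$kernel_truncation)
    sigma_hat <- est$sigma_hat
    profile <- est$profile
  } else {
    sigma_hat <- sigma
    profile <- NULL
  }
  kern <- movement_kernel(sigma_hat, fields$grid, cfg$kernel_truncation)
  fb <- forward_backward(L, kern)
  track <- extract_track(fb$posterior)
  structure(
    list(tag_id = fish_row$acoustic_tag_id,
         track = track, daily = daily_track(track),
         sigma_hat = sigma_hat,
         sigma_hat_km = sigma_hat * grid_cell_km(fields$grid),
         log_lik = fb$log_lik,
         distance_km = track_distance(track, "daily"),
         posterior = if (keep_posterior) fb$posterior else NULL,
         profile = profile, use_acoustic = use_acoustic,
         n_hours = nrow(obs)),
    class = "tt_geofit"
  )
}

#' @export
print.tt_geofit <- function(x, ...) {
  cat(sprintf(
    "<tt_geofit> tag %s: %d hours, sigma_hat %.3f cells/sqrt(h) (%.2f km), logLik %.1f, %s acoustic\n",
    x$tag_id, x$n_hours, x$sigma_hat, x$sigma_hat_km, x$log_lik,
    if (x$use_acoustic) "with" else "without"))
  invisible(x)
}

#' Tidy the hourly track of a geolocation fit
#'
#' @param x A `tt_geofit`.
#' @param ... Unused.
#' @return The hourly track tibble with a `tag_id` column.
#' @export
tidy.tt_geofit <- function(x, ...) {
  dplyr::mutate(x$track, tag_id = x$tag_id, .before = 1)
}

#' One-row summary of a geolocation fit
#'
#' @param x A `tt_geofit`.
#' @param ... Unused.
#' @return Tibble `tag_id, n_hours, sigma_hat, sigma_hat_km, log_lik,
#'   distance_km, use_acoustic`.
#' @export
glance.tt_geofit <- function(x, ...) {
  tibble::tibble(tag_id = x$tag_id, n_hours = x$n_hours,
                 sigma_hat = x$sigma_hat, sigma_hat_km = x$sigma_hat_km,
                 log_lik = x$log_lik, distance_km = x$distance_km,
                 use_acoustic = x$use_acoustic)
}

#' Write and read a track as CSV
#'
#' Columns `time,lon_mean,lat_mean,lon_mode,lat_mode,sd_km`.
#'
#' @param track Hourly track tibble.
#' @param path File path.
#' @export
write_track <- function(track, path) {
  out <- dplyr::mutate(track, time = fmt_utc(.data$time))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(time = "c", .default = "d")) |>
    dplyr::mutate(time = parse_utc(.data$time))
}
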