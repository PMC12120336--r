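#' Scenario configuration for the synthetic-data generator
#'
#' Defines a complete simulated study: a coastal shelf domain at ~2 x 2
#' km resolution, an M2 tide, a zonally graded temperature field with
#' seasonal and diel cycles, Brownian fish tracks, 90-s archival-tag
#' records, a line of acoustic receivers along the coast (3-min mean
#' ping interval, ~400 m detection range) and a configurable rate of
#' injected false detections. All defaults describe the study
#' conditions the generator emulates; a fixed seed makes every output
#' reproducible.
#'
#' @param lon_min,lon_max,lon_step,lat_min,lat_max,lat_step Grid extent
#'   and step, decimal degrees (~2 km cells at the defaults).
#' @param coast_lat Latitude of the straight coastline; cells north of
#'   it are land.
#' @param depth_slope Bathymetric slope, metres per degree of latitude
#'   south of the coast.
#' @param n_days Scenario duration, days.
#' @param origin First hour of the scenario (UTC).
#' @param n_fish Number of tagged fish.
#' @param sigma_true True per-hour displacement sd, grid cells.
#' @param beta_shape1,beta_shape2 Beta parameters of the hourly
#'   depth-behaviour fraction (fraction of the local water column).
#' @param temp_surface Mean sea-surface temperature, degrees C.
#' @param temp_gradient Zonal temperature gradient, degrees C per degree
#'   of longitude.
#' @param temp_lapse Vertical temperature decrease, degrees C per metre.
#' @param temp_shallow_amp Extra warming of shallow water columns,
#'   degrees C at the coast, decaying with bathymetry over
#'   `temp_shallow_scale` metres (summer coastal warming).
#' @param temp_shallow_scale E-folding bathymetry of the coastal
#'   warming, metres.
#' @param seasonal_amp,diel_amp Seasonal and diel temperature
#'   amplitudes, degrees C.
#' @param tide_amp M2 tidal amplitude, metres (period 12.42 h).
#' @param level_depths Depths of the temperature levels, metres.
#' @param n_receivers Number of acoustic stations (evenly spaced line).
#' @param detection_range_m Hard-disk detection range, metres.
#' @param ping_interval_s Mean transmitter ping interval, seconds.
#' @param false_rate_per_day Expected false detections per receiver-day.
#' @param depth_noise_sd,temp_noise_sd Sensor noise sds (m, degrees C).
#' @param snr_true_mean,snr_true_sd,snr_false_mean,snr_false_sd
#'   Signal-to-noise distributions (dB) of genuine and false detections.
#' @param seed Random seed.
#' @return A list of class `tt_scenario_config`.
#' @export
scenario_config <- function(lon_min = -5.9, lon_max = -4.5, lon_step = 0.03,
                            lat_min = 47.9, lat_max = 48.7, lat_step = 0.02,
                            coast_lat = 48.6, depth_slope = 130,
                            n_days = 14,
                            origin = as.POSIXct("2022-06-15 00:00:00",
                                                tz = "UTC"),
                            n_fish = 6, sigma_true = 1.2,
                            beta_shape1 = 4, beta_shape2 = 2,
                            temp_surface = 16, temp_gradient = 0.5,
                            temp_lapse = 0.04,
                            temp_shallow_amp = 1.5,
                            temp_shallow_scale = 40,
                            seasonal_amp = 2, diel_amp = 0.3,
                            tide_amp = 2, level_depths = c(0, 15, 40, 80),
                            n_receivers = 6, detection_range_m = 400,
                            ping_interval_s = 180,
                            false_rate_per_day = 0.5,
                            depth_noise_sd = 0.3, temp_noise_sd = 0.05,
                            snr_true_mean = 12, snr_true_sd = 3,
                            snr_false_mean = 4, snr_false_sd = 1.5,
                            seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$false_rate_per_day, cfg$depth_noise_sd, cfg$temp_noise_sd,
             cfg$sigma_true)
  if (any(rates < 0)) stop("rates and sds must be >= 0", call. = FALSE)
  structure(cfg, class = "tt_scenario_config")
}

#' Build the synthetic environment
#'
#' Bathymetry deepens linearly away from a straight coast with a gentle
#' longitudinal ripple; sea-surface height is a sinusoidal M2 tide;
#' temperature has a zonal gradient, seasonal and diel cycles and a
#' linear decrease with depth, on the configured vertical levels
#' (missing below the local seabed).
#'
#' @param cfg [scenario_config()].
#' @return List `grid` ([grid_spec()]) and `fields`
#'   ([reference_fields()]).
#' @export
make_environment <- function(cfg) {
  lon <- seq(cfg$lon_min, cfg$lon_max, by = cfg$lon_step)
  lat <- seq(cfg$lat_min, cfg$lat_max, by = cfg$lat_step)
  nla <- length(lat); nlo <- length(lon)
  latm <- matrix(lat, nla, nlo)
  lonm <- matrix(lon, nla, nlo, byrow = TRUE)
  elev <- (latm - cfg$coast_lat) * cfg$depth_slope +
    5 * sin(2 * pi * (lonm - cfg$lon_min) / 0.7)
  sea <- elev < 0
  bathy <- ifelse(sea, pmax(-elev, 0), 0)
  grid <- grid_spec(lon, lat, sea)

  nt <- cfg$n_days * 24
  time <- cfg$origin + 3600 * (seq_len(nt) - 1)
  th <- as.numeric(time - cfg$origin, units = "hours")
  ssh_t <- cfg$tide_amp * sin(2 * pi * th / 12.42)
  ssh <- array(rep(ssh_t, nla * nlo), c(nt, nla, nlo))

  doy <- lubridate::yday(time)
  hod <- lubridate::hour(time)
  t_time <- cfg$seasonal_amp * sin(2 * pi * (doy - 105) / 365) +
    cfg$diel_amp * sin(2 * pi * hod / 24)
  lev <- cfg$level_depths
  temp <- array(NA_real_, c(nt, length(lev), nla, nlo))
  base_cell <- cfg$temp_surface + cfg$temp_gradient * (lonm - cfg$lon_min) +
    cfg$temp_shallow_amp * exp(-bathy / cfg$temp_shallow_scale)
  for (l in seq_along(lev)) {
    cell <- base_cell - cfg$temp_lapse * lev[l]
    cell[!sea] <- NA
    cell[sea & bathy < lev[l]] <- NA  # level below the local seabed
    for (t in seq_len(nt)) temp[t, l, , ] <- cell + t_time[t]
  }
  fields <- reference_fields(grid, time, bathy, ssh, temp, lev)
  list(grid = grid, fields = fields)
}

#' Simulate a Brownian fish track on the grid
#'
#' Hourly Gaussian displacements with standard deviation `sigma_true`
#' grid cells per axis; steps landing on land (or off-grid) are
#' resampled (up to 200 tries, then the fish stays put).
#'
#' @param env Output of [make_environment()].
#' @param release_lon,release_lat Release position (must be at sea).
#' @param n_hours Track length, hours.
#' @param sigma_true Step sd, grid cells.
#' @param origin First hour (UTC).
#' @return Tibble `time, lon, lat`.
#' @export
simulate_track <- function(env, release_lon, release_lat, n_hours,
                           sigma_true, origin) {
  grid <- env$grid
  step <- grid_step(grid)
  ij <- cell_index(grid, release_lon, release_lat)
  if (is.na(ij$row) || !grid$sea_mask[ij$row, ij$col]) {
    stop("release position is on land or outside the grid", call. = FALSE)
  }
  lon <- numeric(n_hours); lat <- numeric(n_hours)
  lon[1] <- release_lon; lat[1] <- release_lat
  at_sea <- function(x, y) {
    ij <- cell_index(grid, x, y)
    !is.na(ij$row) && grid$sea_mask[ij$row, ij$col]
  }
  for (t in seq_len(n_hours)[-1]) {
    ok <- FALSE
    for (try in seq_len(200)) {
      nx <- lon[t - 1] + rnorm(1, 0, sigma_true) * step[["lon"]]
      ny <- lat[t - 1] + rnorm(1, 0, sigma_true) * step[["lat"]]
      if (at_sea(nx, ny)) { ok <- TRUE; break }
    }
    if (!ok) { nx <- lon[t - 1]; ny <- lat[t - 1] }
    lon[t] <- nx; lat[t] <- ny
  }
  tibble::tibble(time = origin + 3600 * (seq_len(n_hours) - 1),
                 lon = lon, lat = lat)
}

#' Simulate a 90-s archival-tag record along a track
#'
#' Each hour the fish holds a depth equal to a Beta-distributed fraction
#' of the local water column; 90-s depth and temperature records add
#' Gaussian sensor noise. Depth never exceeds the local water column.
#' An optional death time switches the record to a near-surface
#' (floating tag) signature afterwards.
#'
#' @param track Tibble from [simulate_track()].
#' @param env Output of [make_environment()].
#' @param cfg [scenario_config()].
#' @param death_time Optional POSIXct of death.
#' @param behaviour_frac Optional fixed depth-behaviour fraction (scalar
#'   or one value per track hour) overriding the Beta draw.
#' @return Sensor-series tibble `tag_id, timestamp, depth_m,
#'   temperature_c` (tag_id `NA`, set by the caller).
#' @export
simulate_dst <- function(track, env, cfg, death_time = NULL,
                         behaviour_frac = NULL) {
  grid <- env$grid; fields <- env$fields
  per_hour <- 3600 / 90
  n <- nrow(track) * per_hour
  ts <- track$time[1] + 90 * (seq_len(n) - 1)
  hidx <- rep(seq_len(nrow(track)), each = per_hour)
  ij <- cell_index(grid, track$lon, track$lat)
  ti <- hour_index(fields, track$time)
  frac <- if (is.null(behaviour_frac)) {
    rbeta(nrow(track), cfg$beta_shape1, cfg$beta_shape2)
  } else {
    rep_len(behaviour_frac, nrow(track))
  }
  lev <- fields$level_depths
  depth <- numeric(n); temp <- numeric(n)
  for (h in seq_len(nrow(track))) {
    r <- ij$row[h]; c <- ij$col[h]
    water <- fields$bathymetry[r, c] + fields$ssh[ti[h], r, c]
    rows <- which(hidx == h)
    z <- frac[h] * water + rnorm(length(rows), 0, cfg$depth_noise_sd)
    z <- pmin(pmax(z, 0), water)
    prof <- fields$temperature[ti[h], , r, c]
    fin <- which(is.finite(prof))
    tz <- if (length(fin) == 1) {
      rep(prof[fin], length(rows))
    } else {
      stats::approx(lev[fin], prof[fin], xout = pmin(pmax(z, min(lev[fin])),
                                                     max(lev[fin])))$y
    }
    depth[rows] <- z
    temp[rows] <- tz + rnorm(length(rows), 0, cfg$temp_noise_sd)
  }
  if (!is.null(death_time) && !is.na(death_time)) {
    dead <- ts >= death_time
    depth[dead] <- pmax(rnorm(sum(dead), 0.2, 0.05), 0)
  }
  tibble::tibble(tag_id = NA_character_, timestamp = ts,
                 depth_m = depth, temperature_c = temp)
}

#' Lay out a line of acoustic receivers along the coast
#'
#' Evenly spaced stations one cell seaward of the coastline, deployed
#' for the whole scenario.
#'
#' @param env Output of [make_environment()].
#' @param cfg [scenario_config()].
#' @return Receiver-deployment tibble.
#' @export
make_receivers <- function(env, cfg) {
  grid <- env$grid
  lon <- seq(cfg$lon_min + 0.1, cfg$lon_max - 0.1,
             length.out = cfg$n_receivers)
  lat <- vapply(lon, function(x) {
    j <- cell_index(grid, x, mean(grid$lat))$col
    sea_rows <- which(grid$sea_mask[, j])
    grid$lat[max(sea_rows) - 2]
  }, numeric(1))
  nt <- cfg$n_days * 24
  tibble::tibble(
    receiver_id = sprintf("R%02d", seq_along(lon)),
    station = sprintf("Station_%02d", seq_along(lon)),
    lon = lon, lat = lat,
    start = cfg$origin, end = cfg$origin + 3600 * nt,
    detection_range_m = cfg$detection_range_m,
    protocol = "OPi"
  )
}

#' Simulate acoustic detections of a track
#'
#' While the fish is within detection range of an active,
#' protocol-compatible receiver, pings arrive with exponential gaps
#' (mean `ping_interval_s`) and are detected (hard-disk range model).
#' False detections carrying this tag's id are injected uniformly over
#' each receiver's deployment at `false_rate_per_day`. The ground-truth
#' label is kept in the `genuine` column.
#'
#' @param track Tibble from [simulate_track()].
#' @param recv Receiver deployments.
#' @param cfg [scenario_config()].
#' @param tag_id Acoustic tag id to stamp on the rows.
#' @param tag_protocol Transmitter protocol; receivers with a different
#'   protocol never detect it.
#' @return Detection tibble with `genuine` logical column.
#' @export
simulate_detections <- function(track, recv, cfg, tag_id,
                                tag_protocol = "OPi") {
  out <- list()
  for (h in seq_len(nrow(track))) {
    h0 <- track$time[h]
    act <- recv[recv$start < h0 + 3600 & recv$end > h0 &
                  recv$protocol == tag_protocol, ]
    if (!nrow(act)) next
    d_m <- haversine_km(act$lon, act$lat, track$lon[h], track$lat[h]) * 1000
    inr <- which(d_m <= act$detection_range_m)
    if (!length(inr)) next
    gaps <- rexp(ceiling(3600 / cfg$ping_interval_s * 3),
                 1 / cfg$ping_interval_s)
    ping_t <- cumsum(gaps)
    ping_t <- ping_t[ping_t < 3600]
    if (!length(ping_t)) next
    for (k in inr) {
      out[[length(out) + 1]] <- tibble::tibble(
        tag_id = tag_id, timestamp = h0 + ping_t,
        receiver_id = act$receiver_id[k], station = act$station[k],
        lon = act$lon[k], lat = act$lat[k],
        snr = rnorm(length(ping_t), cfg$snr_true_mean, cfg$snr_true_sd),
        genuine = TRUE)
    }
  }
  # injected false detections, uniform over each deployment
  for (k in seq_len(nrow(recv))) {
    days <- as.numeric(recv$end[k] - recv$start[k], units = "days")
    nf <- rpois(1, cfg$false_rate_per_day * days)
    if (!nf) next
    out[[length(out) + 1]] <- tibble::tibble(
      tag_id = tag_id,
      timestamp = recv$start[k] +
        runif(nf) * as.numeric(recv$end[k] - recv$start[k], units = "secs"),
      receiver_id = recv$receiver_id[k], station = recv$station[k],
      lon = recv$lon[k], lat = recv$lat[k],
      snr = rnorm(nf, cfg$snr_false_mean, cfg$snr_false_sd),
      genuine = FALSE)
  }
  if (!length(out)) {
    return(tibble::tibble(tag_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          receiver_id = character(), station = character(),
                          lon = numeric(), lat = numeric(), snr = numeric(),
                          genuine = logical()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$tag_id, .data$timestamp)
}

#' Simulate a complete tagging scenario
#'
#' Generates, under the configured seed, the environment, the receiver
#' network, fish metadata (release positions at sea, lengths spanning
#' the immature/mature range), true Brownian tracks, 90-s archival-tag
#' series and the labelled detection table.
#'
#' @param cfg [scenario_config()].
#' @return List `cfg, grid, fields, recv, fish, tracks (named list),
#'   series (named list), dets` (all fish combined, `genuine` label
#'   kept).
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  set.seed(cfg$seed)
  env <- make_environment(cfg)
  recv <- make_receivers(env, cfg)
  n_hours <- cfg$n_days * 24
  # fish are released at the tagging sites, i.e. near acoustic stations
  st <- sample(nrow(recv), cfg$n_fish, replace = TRUE)
  fish <- tibble::tibble(
    acoustic_tag_id = sprintf("T%04d", seq_len(cfg$n_fish)),
    archival_tag_id = sprintf("A%04d", seq_len(cfg$n_fish)),
    total_length_mm = round(runif(cfg$n_fish, 350, 620)),
    release_time = cfg$origin,
    release_lon = recv$lon[st] + runif(cfg$n_fish, -5e-4, 5e-4),
    release_lat = recv$lat[st] + runif(cfg$n_fish, -5e-4, 5e-4),
    recapture_time = as.POSIXct(NA, tz = "UTC"),
    recapture_lon = NA_real_, recapture_lat = NA_real_
  ) |>
    dplyr::mutate(maturity = factor(
      ifelse(.data$total_length_mm >= LMAT50_MM, "mature", "immature"),
      levels = c("immature", "mature")))
  tracks <- list(); series <- list(); dets <- list()
  for (i in seq_len(cfg$n_fish)) {
    tr <- simulate_track(env, fish$release_lon[i], fish$release_lat[i],
                         n_hours, cfg$sigma_true, cfg$origin)
    sr <- simulate_dst(tr, env, cfg)
    sr$tag_id <- fish$acoustic_tag_id[i]
    dd <- simulate_detections(tr, recv, cfg, fish$acoustic_tag_id[i])
    tracks[[fish$acoustic_tag_id[i]]] <- tr
    series[[fish$acoustic_tag_id[i]]] <- sr
    dets[[i]] <- dd
  }
  list(cfg = cfg, grid = env$grid, fields = env$fields, recv = recv,
       fish = fish, tracks = tracks, series = series,
       dets = dplyr::bind_rows(dets) |>
         dplyr::arrange(.data$tag_id, .data$timestamp))
}

#' Write a simulated scenario to a directory of plain-text inputs
#'
#' Writes `detections.csv`, `receivers.csv`, `fish.csv`,
#' `dst_<tagid>.csv`, `fields.csv` and a `truth/` subdirectory with the
#' true tracks and detection labels, all readable by the package's
#' readers.
#'
#' @param scen Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_detections(scen$dets, file.path(dir, "detections.csv"))
  readr::write_csv(
    scen$dets |> dplyr::mutate(timestamp = fmt_utc(.data$timestamp)) |>
      dplyr::select("tag_id", "timestamp", "receiver_id", "genuine"),
    file.path(dir, "truth", "detection_labels.csv"))
  write_receivers(scen$recv, file.path(dir, "receivers.csv"))
  write_fish(scen$fish, file.path(dir, "fish.csv"))
  for (tg in names(scen$series)) {
    write_sensor_series(scen$series[[tg]],
                        file.path(dir, paste0("dst_", tg, ".csv")))
  }
  for (tg in names(scen$tracks)) {
    readr::write_csv(
      scen$tracks[[tg]] |> dplyr::mutate(time = fmt_utc(.data$time)),
      file.path(dir, "truth", paste0("track_", tg, ".csv")))
  }
  write_fields(scen$fields, file.path(dir, "fields.csv"))
  invisible(dir)
}
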