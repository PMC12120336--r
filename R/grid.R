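#' Regular longitude/latitude grid with a sea mask
#'
#' The discretised sea domain on which the geolocation model operates.
#' Axes are cell centres in decimal degrees, strictly increasing with a
#' uniform step; the sea mask marks water cells.
#'
#' @param lon_axis,lat_axis Numeric vectors of cell-centre coordinates,
#'   strictly increasing, regular step (uniform to 1e-9 degrees).
#' @param sea_mask Logical matrix of dimension `(n_lat, n_lon)`; `TRUE`
#'   marks a water cell. At least one cell must be sea.
#' @return An object of class `tt_grid`.
#' @export
grid_spec <- function(lon_axis, lat_axis, sea_mask) {
  check_axis(lon_axis, "lon_axis")
  check_axis(lat_axis, "lat_axis")
  sea_mask <- as.matrix(sea_mask)
  stopifnot(is.logical(sea_mask))
  if (!identical(dim(sea_mask), c(length(lat_axis), length(lon_axis)))) {
    stop("sea_mask must have dimension (n_lat, n_lon) = (",
         length(lat_axis), ", ", length(lon_axis), ")", call. = FALSE)
  }
  if (!any(sea_mask)) stop("sea_mask has no sea cell", call. = FALSE)
  structure(
    list(lon = as.numeric(lon_axis), lat = as.numeric(lat_axis),
         sea_mask = sea_mask),
    class = "tt_grid"
  )
}

check_axis <- function(x, name) {
  if (length(x) < 2) stop(name, " needs at least 2 values", call. = FALSE)
  d <- diff(x)
  if (any(d <= 0)) stop(name, " must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-9) {
    stop(name, " step is not uniform (tolerance 1e-9)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.tt_grid <- function(x, ...) {
  cat(sprintf(
    "<tt_grid> %d x %d cells, lon [%.3f, %.3f], lat [%.3f, %.3f], %d sea cells\n",
    length(x$lat), length(x$lon), min(x$lon), max(x$lon),
    min(x$lat), max(x$lat), sum(x$sea_mask)))
  invisible(x)
}

grid_step <- function(grid) {
  c(lon = mean(diff(grid$lon)), lat = mean(diff(grid$lat)))
}

# Mean cell size in km (used to convert sigma from cell units to km).
grid_cell_km <- function(grid) {
  step <- grid_step(grid)
  mid_lat <- mean(range(grid$lat))
  dx <- haversine_km(0, mid_lat, step[["lon"]], mid_lat)
  dy <- haversine_km(0, mid_lat - step[["lat"]] / 2, 0, mid_lat + step[["lat"]] / 2)
  mean(c(dx, dy))
}

# Row (lat) and column (lon) index of the cell containing each point.
# Points outside the grid bounding box get NA.
cell_index <- function(grid, lon, lat) {
  step <- grid_step(grid)
  i <- round((lat - grid$lat[1]) / step[["lat"]]) + 1
  j <- round((lon - grid$lon[1]) / step[["lon"]]) + 1
  i[i < 1 | i > length(grid$lat)] <- NA_integer_
  j[j < 1 | j > length(grid$lon)] <- NA_integer_
  bad <- is.na(i) | is.na(j)
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  list(row = as.integer(i), col = as.integer(j))
}

#' Gridded environmental reference fields
#'
#' Bathymetry, hourly sea-surface height and hourly temperature profiles on
#' a regular grid; the observation models compare archival-tag records
#' against these fields. Depth is positive down everywhere.
#'
#' @param grid A [grid_spec()] object.
#' @param time POSIXct vector of hour starts (UTC), hourly and contiguous.
#' @param bathymetry Matrix `(n_lat, n_lon)`, metres positive down;
#'   must be `>= 0` on sea cells.
#' @param ssh Array `(n_time, n_lat, n_lon)` of sea-surface height, metres.
#' @param temperature Array `(n_time, n_level, n_lat, n_lon)`, degrees C.
#'   May be `NA` at levels deeper than the local bathymetry.
#' @param level_depths Depths of the temperature levels, metres positive
#'   down, strictly increasing.
#' @return An object of class `tt_fields`.
#' @export
reference_fields <- function(grid, time, bathymetry, ssh, temperature,
                             level_depths) {
  stopifnot(inherits(grid, "tt_grid"))
  nt <- length(time); nla <- length(grid$lat); nlo <- length(grid$lon)
  if (nt > 1) {
    dt <- as.numeric(diff(time), units = "secs")
    if (any(abs(dt - 3600) > 1e-6)) {
      stop("time axis must be hourly and contiguous", call. = FALSE)
    }
  }
  stopifnot(identical(dim(bathymetry), c(nla, nlo)),
            identical(dim(ssh), c(nt, nla, nlo)),
            identical(dim(temperature),
                      c(nt, length(level_depths), nla, nlo)))
  if (any(diff(level_depths) <= 0)) {
    stop("level_depths must be strictly increasing", call. = FALSE)
  }
  if (any(bathymetry[grid$sea_mask] < 0, na.rm = TRUE)) {
    stop("bathymetry must be >= 0 on sea cells", call. = FALSE)
  }
  structure(
    list(grid = grid, time = time, bathymetry = bathymetry, ssh = ssh,
         temperature = temperature, level_depths = as.numeric(level_depths)),
    class = "tt_fields"
  )
}

#' @export
print.tt_fields <- function(x, ...) {
  cat(sprintf("<tt_fields> %d hours from %s, %d levels, grid %d x %d\n",
              length(x$time), fmt_utc(x$time[1]), length(x$level_depths),
              length(x$grid$lat), length(x$grid$lon)))
  invisible(x)
}

#' Validate reference-field invariants
#'
#' Checks that temperature is finite on every sea cell at all levels
#' shallower than the local bathymetry, that the time axis is hourly, and
#' that bathymetry is non-negative at sea.
#'
#' @param fields A [reference_fields()] object.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_fields <- function(fields) {
  stopifnot(inherits(fields, "tt_fields"))
  g <- fields$grid
  sea <- which(g$sea_mask)
  for (l in seq_along(fields$level_depths)) {
    shallow <- sea[fields$bathymetry[sea] > fields$level_depths[l]]
    if (!length(shallow)) next
    sl <- fields$temperature[, l, , , drop = FALSE]
    dim(sl) <- c(length(fields$time), length(g$lat) * length(g$lon))
    if (any(!is.finite(sl[, shallow]))) {
      stop("temperature not finite on sea cells at level ", l, call. = FALSE)
    }
  }
  invisible(TRUE)
}

hour_index <- function(fields, hours) {
  idx <- match(as.numeric(hours), as.numeric(fields$time))
  if (anyNA(idx)) {
    stop("hour ", fmt_utc(hours[which(is.na(idx))[1]]),
         " not covered by the reference fields", call. = FALSE)
  }
  idx
}

#' Write and read reference fields as plain-text CSV
#'
#' Long-format text serialisation of the gridded fields (one file), used
#' for portable fixtures and pipeline intermediates. Coordinates round-trip
#' at 1e-6 degrees, values at ~1e-6 of their magnitude.
#'
#' @param fields A [reference_fields()] object.
#' @param path Output/input file path.
#' @return `read_fields()` returns the reconstructed `tt_fields`.
#' @export
write_fields <- function(fields, path) {
  g <- fields$grid
  nla <- length(g$lat); nlo <- length(g$lon); nt <- length(fields$time)
  nlev <- length(fields$level_depths)
  hdr <- tibble::tibble(
    record = "meta",
    key = c("lon", "lat", "time", "level_depths"),
    value = c(paste(sprintf("%.6f", g$lon), collapse = ";"),
              paste(sprintf("%.6f", g$lat), collapse = ";"),
              paste(fmt_utc(fields$time), collapse = ";"),
              paste(fields$level_depths, collapse = ";"))
  )
  flat <- function(x) paste(signif(as.vector(x), 9), collapse = ";")
  dat <- tibble::tibble(
    record = "data",
    key = c("sea_mask", "bathymetry", "ssh", "temperature"),
    value = c(paste(as.integer(as.vector(g$sea_mask)), collapse = ";"),
              flat(fields$bathymetry), flat(fields$ssh),
              flat(fields$temperature))
  )
  readr::write_csv(dplyr::bind_rows(hdr, dat), path)
  invisible(path)
}

#' @rdname write_fields
#' @export
read_fields <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  get <- function(k) strsplit(raw$value[raw$key == k], ";", fixed = TRUE)[[1]]
  lon <- as.numeric(get("lon")); lat <- as.numeric(get("lat"))
  time <- parse_utc(get("time"))
  lev <- as.numeric(get("level_depths"))
  nla <- length(lat); nlo <- length(lon); nt <- length(time)
  sea <- matrix(as.integer(get("sea_mask")) == 1L, nla, nlo)
  g <- grid_spec(lon, lat, sea)
  num <- function(k) suppressWarnings(as.numeric(get(k)))
  reference_fields(
    g, time,
    bathymetry = matrix(num("bathymetry"), nla, nlo),
    ssh = array(num("ssh"), c(nt, nla, nlo)),
    temperature = array(num("temperature"), c(nt, length(lev), nla, nlo)),
    level_depths = lev
  )
}
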