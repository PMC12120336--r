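#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of mean radius 6371.0 km.
#' Inputs are WGS84 decimal degrees (longitude west-negative). All arguments
#' are vectorised and recycled.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # ~111.195 km, one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(sqrt(a), 1))
}

#' Meteorological season of a timestamp
#'
#' Winter = December-February, Spring = March-May, Summer = June-August,
#' Fall = September-November.
#'
#' @param time POSIXct vector.
#' @return Factor with levels Winter, Spring, Summer, Fall.
#' @export
season_of <- function(time) {
  m <- lubridate::month(time)
  s <- dplyr::case_when(
    m %in% c(12, 1, 2) ~ "Winter",
    m %in% 3:5 ~ "Spring",
    m %in% 6:8 ~ "Summer",
    TRUE ~ "Fall"
  )
  factor(s, levels = c("Winter", "Spring", "Summer", "Fall"))
}

# Clock-aligned hour floor (UTC); hour bins are half-open [h, h + 1h).
hour_floor <- function(time) {
  lubridate::floor_date(time, "hour")
}

# Round half-up to integer (the reporting convention for percentages).
round_half_up <- function(x) floor(x + 0.5)

# Parse ISO-8601 UTC timestamps strictly; NA for unparseable values.
parse_utc <- function(x) {
  suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", truncated = 3))
}

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
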