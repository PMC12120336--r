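#' Residency periods at acoustic stations
#'
#' For each (tag, station) pair, detections sorted in time are split into
#' residency periods wherever the gap between consecutive detections is at
#' least `threshold_h` hours; consecutive detections closer than the
#' threshold belong to the same period. A single detection forms a period
#' of duration zero. Detections during a flagged mortality run and at
#' excluded (temporary) stations are dropped first.
#'
#' @param dets Filtered detection tibble.
#' @param threshold_h Residency gap threshold, hours.
#' @param exclude_stations Stations excluded from the analysis (e.g. the
#'   temporary tagging-site receivers).
#' @param mortality Optional output of [flag_stationary_mortality()]; the
#'   flagged terminal runs are excluded.
#' @return Tibble `tag_id, station, start, end, n_detections, duration_h`.
#' @export
compute_residency_periods <- function(dets, threshold_h = 24,
                                      exclude_stations = character(),
                                      mortality = NULL) {
  d <- dets[!dets$station %in% exclude_stations, ]
  if (!is.null(mortality)) {
    dead <- mortality[mortality$presumed_dead, ]
    for (i in seq_len(nrow(dead))) {
      drop <- d$tag_id == dead$tag_id[i] & d$station == dead$station[i] &
        d$timestamp >= dead$dead_from[i]
      d <- d[!drop, ]
    }
  }
  if (nrow(d) == 0) {
    return(tibble::tibble(tag_id = character(), station = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          n_detections = integer(), duration_h = numeric()))
  }
  d |>
    dplyr::group_by(.data$tag_id, .data$station) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::mutate(
      gap_h = c(Inf, diff(as.numeric(.data$timestamp)) / 3600),
      period = cumsum(.data$gap_h >= threshold_h)
    ) |>
    dplyr::group_by(.data$tag_id, .data$station, .data$period) |>
    dplyr::summarise(
      start = min(.data$timestamp), end = max(.data$timestamp),
      n_detections = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(duration_h =
                    as.numeric(.data$end - .data$start, units = "hours")) |>
    dplyr::select(-"period") |>
    dplyr::arrange(.data$tag_id, .data$station, .data$start)
}

#' Summarise residency periods per fish, with a threshold sweep
#'
#' Per-fish number of residency periods and mean period duration, with
#' maturity classification from total length (immature below the length
#' at 50% maturity), plus a sensitivity table of per-fish period counts
#' over a range of thresholds. Counts are non-increasing in the
#' threshold.
#'
#' @param dets Filtered detections (same filtering as
#'   [compute_residency_periods()] inputs).
#' @param fish Fish metadata (for total length).
#' @param threshold_h Threshold for the headline summary, hours.
#' @param sweep_h Thresholds for the sensitivity table, hours.
#' @param ... Passed on to [compute_residency_periods()].
#' @return List with elements `per_fish` (tibble `tag_id, total_length_mm,
#'   maturity, n_periods, mean_duration_h`) and `sensitivity` (tibble
#'   `threshold_h, tag_id, n_periods`).
#' @export
residency_summary <- function(dets, fish, threshold_h = 24,
                              sweep_h = 1:24, ...) {
  per_fish_at <- function(th) {
    p <- compute_residency_periods(dets, th, ...)
    if (nrow(p) == 0) {
      return(tibble::tibble(tag_id = character(), n_periods = integer(),
                            mean_duration_h = numeric()))
    }
    p |>
      dplyr::group_by(.data$tag_id) |>
      dplyr::summarise(n_periods = dplyr::n(),
                       mean_duration_h = mean(.data$duration_h),
                       .groups = "drop")
  }
  headline <- per_fish_at(threshold_h) |>
    dplyr::left_join(
      fish |> dplyr::select("acoustic_tag_id", "total_length_mm",
                            "maturity"),
      by = c(tag_id = "acoustic_tag_id")
    ) |>
    dplyr::select("tag_id", "total_length_mm", "maturity", "n_periods",
                  "mean_duration_h")
  sweep <- purrr::map_dfr(sweep_h, function(th) {
    per_fish_at(th) |>
      dplyr::mutate(threshold_h = th, .before = 1) |>
      dplyr::select("threshold_h", "tag_id", "n_periods")
  })
  list(per_fish = headline, sensitivity = sweep)
}
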