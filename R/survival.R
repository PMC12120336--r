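#' Flag tags whose terminal detections indicate a dead fish
#'
#' A transmitter lying within range of a single receiver pings at the
#' nominal random-delay rate (about one ping every 3 min) indefinitely. A
#' tag is flagged presumed-dead-at-station when its final run of
#' detections is confined to one station, spans at least `min_days`
#' through the end of its series, and has a median inter-detection gap of
#' at most `2 * ping_interval`. The flagged run should be excluded from
#' residency analyses.
#'
#' @param dets Filtered detection tibble.
#' @param ping_interval Nominal mean transmitter ping interval, seconds.
#' @param min_days Minimum duration of the terminal run, days.
#' @return A tibble per tag: `tag_id`, `presumed_dead`, `station`
#'   (terminal station), `dead_from` (start of the flagged run, `NA` when
#'   not flagged).
#' @export
flag_stationary_mortality <- function(dets, ping_interval = 180,
                                      min_days = 7) {
  dets |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::summarise(res = list(terminal_run(.data$timestamp, .data$station,
                                             ping_interval, min_days)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
}

terminal_run <- function(ts, station, ping_interval, min_days) {
  n <- length(ts)
  last_st <- station[n]
  # maximal suffix at a single station
  i0 <- n
  while (i0 > 1 && station[i0 - 1] == last_st) i0 <- i0 - 1
  run_ts <- as.numeric(ts[i0:n])
  span_d <- (run_ts[length(run_ts)] - run_ts[1]) / 86400
  med_gap <- if (length(run_ts) > 1) median(diff(run_ts)) else Inf
  dead <- span_d >= min_days && med_gap <= 2 * ping_interval
  list(presumed_dead = dead, station = last_st,
       dead_from = if (dead) ts[i0] else as.POSIXct(NA, tz = "UTC"))
}

#' Short-term post-tagging survival from a two-station gate
#'
#' Fish released inside a monitored bay pass two temporary receivers in
#' sequence on their way out. A fish is `presumed_dead` if its detections
#' are a continuous terminal run at one temporary station (a transmitter
#' pinging from a carcass; see [flag_stationary_mortality()]). Otherwise
#' it is a `survivor` if it was detected at all -- sequentially at A then
#' B, at the gate before leaving, or anywhere else in the network later
#' (a fish in post-tagging distress would die at the release site, so any
#' non-continuous detection history implies recovery). Fish never
#' detected are `unassessed`.
#'
#' @param dets Filtered detections (all stations).
#' @param fish Fish metadata; only fish whose `acoustic_tag_id` is in
#'   `assessed_tags` are classified, others are `unassessed`.
#' @param station_a,station_b The two temporary gate stations, in passage
#'   order.
#' @param assessed_tags Tags released within range of the gate; defaults
#'   to all fish.
#' @param ping_interval,min_days Passed to [flag_stationary_mortality()].
#' @return Tibble `tag_id, short_term, evidence`.
#' @export
classify_short_term <- function(dets, fish, station_a, station_b,
                                assessed_tags = fish$acoustic_tag_id,
                                ping_interval = 180, min_days = 2) {
  mort <- flag_stationary_mortality(dets, ping_interval, min_days)
  purrr::map_dfr(fish$acoustic_tag_id, function(tg) {
    if (!tg %in% assessed_tags) {
      return(tibble::tibble(tag_id = tg, short_term = "unassessed",
                            evidence = "released outside the gate"))
    }
    d <- dets[dets$tag_id == tg, ] |> dplyr::arrange(.data$timestamp)
    m <- mort[mort$tag_id == tg, ]
    dead_here <- nrow(m) == 1 && isTRUE(m$presumed_dead) &&
      m$station %in% c(station_a, station_b)
    t_a <- suppressWarnings(min(d$timestamp[d$station == station_a]))
    b_after_a <- any(d$station == station_b & d$timestamp > t_a)
    elsewhere <- any(!d$station %in% c(station_a, station_b))
    st <- if (dead_here) {
      "presumed_dead"
    } else if (nrow(d) > 0) {
      "survivor"
    } else {
      "unassessed"
    }
    ev <- dplyr::case_when(
      dead_here ~ paste0("continuous terminal detections at ", m$station),
      is.finite(t_a) && b_after_a ~ "sequential passage A then B",
      elsewhere ~ "detected later elsewhere in the network",
      nrow(d) > 0 ~ "detected at the gate before leaving",
      TRUE ~ "never detected"
    )
    tibble::tibble(tag_id = tg, short_term = st, evidence = ev)
  }) |>
    dplyr::mutate(short_term = factor(.data$short_term,
                                      levels = c("survivor", "presumed_dead",
                                                 "unassessed")))
}

#' Long-term post-tagging survival
#'
#' A fish is a long-term `survivor` if it was detected by the permanent
#' network at least `survival_week` days after release, or recaptured at
#' least `survival_week` days after release; otherwise its long-term fate
#' is `unknown`. Temporary gate stations are excluded from the permanent
#' network.
#'
#' @param dets Filtered detections.
#' @param fish Fish metadata with `release_time` and optional
#'   `recapture_time`.
#' @param survival_week Survival horizon, days.
#' @param temporary_stations Stations excluded from the permanent network.
#' @return Tibble `tag_id, long_term, evidence`.
#' @export
classify_long_term <- function(dets, fish, survival_week = 7,
                               temporary_stations = character()) {
  perm <- dets[!dets$station %in% temporary_stations, ]
  horizon <- survival_week * 86400
  purrr::map_dfr(seq_len(nrow(fish)), function(i) {
    tg <- fish$acoustic_tag_id[i]
    rel <- fish$release_time[i]
    d <- perm[perm$tag_id == tg, ]
    det_late <- any(as.numeric(d$timestamp) - as.numeric(rel) >= horizon)
    rec_late <- !is.na(fish$recapture_time[i]) &&
      as.numeric(fish$recapture_time[i]) - as.numeric(rel) >= horizon
    tibble::tibble(
      tag_id = tg,
      long_term = if (det_late || rec_late) "survivor" else "unknown",
      evidence = dplyr::case_when(
        det_late ~ "permanent-network detection after the survival horizon",
        rec_late ~ "recaptured after the survival horizon",
        TRUE ~ "no late detection or recapture"
      )
    )
  }) |>
    dplyr::mutate(long_term = factor(.data$long_term,
                                     levels = c("survivor", "unknown")))
}

#' Survival rates by cohort
#'
#' Percentage of survivors per cohort, rounded half-up to the nearest
#' integer (the field's reporting convention). Cohorts are: all fish,
#' fish grouped by any columns named in `by` (e.g. country, tag
#' configuration). Empty cohorts are omitted.
#'
#' @param records Classification tibble with `tag_id` and a status column.
#' @param fish Fish metadata joined by `tag_id = acoustic_tag_id`; must
#'   contain the `by` columns.
#' @param status Name of the status column in `records`.
#' @param survivor_level Status value counted as survival.
#' @param by Character vector of grouping columns in `fish`.
#' @return Tibble `cohort, group, n, survivors, rate_pct`.
#' @export
survival_rates <- function(records, fish, status = "long_term",
                           survivor_level = "survivor", by = character()) {
  joined <- records |>
    dplyr::left_join(fish, by = c(tag_id = "acoustic_tag_id"))
  one <- function(df, cohort, group) {
    n <- nrow(df)
    if (n == 0) return(NULL)
    s <- sum(df[[status]] == survivor_level)
    tibble::tibble(cohort = cohort, group = group, n = n, survivors = s,
                   rate_pct = round_half_up(100 * s / n))
  }
  out <- list(one(joined, "all", "all"))
  for (col in by) {
    for (g in unique(joined[[col]][!is.na(joined[[col]])])) {
      out <- c(out, list(one(joined[joined[[col]] %in% g, ], col,
                             as.character(g))))
    }
  }
  dplyr::bind_rows(out)
}
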