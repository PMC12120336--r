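#' Cumulative listening effort per calendar month
#'
#' For each calendar month, sums over receivers the number of days their
#' deployment interval overlaps the month. Effort normalises raw
#' detection counts so that seasonal patterns are not artefacts of
#' network growth.
#'
#' @param recv Receiver deployments ([read_receivers()]).
#' @return Tibble `month` (first day of month, Date), `listening_days`.
#' @export
listening_effort <- function(recv) {
  purrr::map_dfr(seq_len(nrow(recv)), function(k) {
    s <- recv$start[k]; e <- recv$end[k]
    months <- seq(lubridate::floor_date(as.Date(s), "month"),
                  lubridate::floor_date(as.Date(e), "month"), by = "month")
    purrr::map_dfr(months, function(m0) {
      m1 <- lubridate::add_with_rollback(m0, months(1))
      ov <- min(as.numeric(e), as.numeric(as.POSIXct(m1, tz = "UTC"))) -
        max(as.numeric(s), as.numeric(as.POSIXct(m0, tz = "UTC")))
      tibble::tibble(month = m0, listening_days = max(ov, 0) / 86400)
    })
  }) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(listening_days = sum(.data$listening_days),
                     .groups = "drop") |>
    dplyr::arrange(.data$month)
}

#' Detections and individuals per listening day
#'
#' Normalises monthly detection counts and distinct-fish counts by the
#' network's cumulative listening days that month, optionally stratified
#' by fish length class (immature/mature at the length at 50% maturity).
#'
#' @param dets Filtered detection tibble.
#' @param effort Output of [listening_effort()].
#' @param fish Optional fish metadata for the maturity stratification.
#' @return Tibble `month[, maturity], n_detections, n_fish,
#'   detections_per_day, fish_per_day`.
#' @export
detections_per_listening_day <- function(dets, effort, fish = NULL) {
  d <- dets |>
    dplyr::mutate(month = lubridate::floor_date(as.Date(.data$timestamp),
                                                "month"))
  if (!is.null(fish)) {
    d <- d |>
      dplyr::left_join(fish |> dplyr::select("acoustic_tag_id", "maturity"),
                       by = c(tag_id = "acoustic_tag_id"))
    grp <- c("month", "maturity")
  } else {
    grp <- "month"
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_detections = dplyr::n(),
                     n_fish = dplyr::n_distinct(.data$tag_id),
                     .groups = "drop") |>
    dplyr::left_join(effort, by = "month") |>
    dplyr::mutate(detections_per_day = .data$n_detections / .data$listening_days,
                  fish_per_day = .data$n_fish / .data$listening_days)
}

#' Seasonal movement graph between stations
#'
#' Builds the per-fish ordered sequence of located events (release,
#' station detections, recapture), collapses consecutive duplicates, and
#' counts, for each season and maturity class, the number of distinct
#' fish moving between each ordered pair of locations. Each movement is
#' attributed to the season of the later event. Seasons: Winter = DJF,
#' Spring = MAM, Summer = JJA, Fall = SON.
#'
#' @param dets Filtered detection tibble.
#' @param fish Fish metadata (release/recapture positions and maturity).
#' @param release_site,recapture_site Node-name generators: functions of
#'   a fish-metadata row returning the site label; defaults label by
#'   rounded release/recapture position.
#' @return Tibble of directed edges
#'   `from, to, season, maturity, n_fish`.
#' @export
build_movement_graph <- function(dets, fish,
                                 release_site = NULL, recapture_site = NULL) {
  if (is.null(release_site)) {
    release_site <- function(f) sprintf("release_%.2f_%.2f",
                                        f$release_lon, f$release_lat)
  }
  if (is.null(recapture_site)) {
    recapture_site <- function(f) sprintf("recapture_%.2f_%.2f",
                                          f$recapture_lon, f$recapture_lat)
  }
  moves <- purrr::map_dfr(seq_len(nrow(fish)), function(i) {
    f <- fish[i, ]
    ev <- tibble::tibble(loc = release_site(f), time = f$release_time)
    d <- dets[dets$tag_id == f$acoustic_tag_id, ] |>
      dplyr::arrange(.data$timestamp)
    if (nrow(d)) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(loc = d$station,
                                                time = d$timestamp))
    }
    if (!is.na(f$recapture_time)) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(loc = recapture_site(f),
                                                time = f$recapture_time))
    }
    ev <- ev[order(ev$time), ]
    keep <- c(TRUE, ev$loc[-1] != ev$loc[-nrow(ev)])
    ev <- ev[keep, ]
    if (nrow(ev) < 2) return(NULL)
    tibble::tibble(
      tag_id = f$acoustic_tag_id,
      maturity = f$maturity,
      from = ev$loc[-nrow(ev)], to = ev$loc[-1],
      season = season_of(ev$time[-1])
    )
  })
  if (is.null(moves) || nrow(moves) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          season = factor(character(),
                                          levels = levels(season_of(Sys.time()))),
                          maturity = factor(character(),
                                            levels = c("immature", "mature")),
                          n_fish = integer()))
  }
  moves |>
    dplyr::distinct(.data$tag_id, .data$from, .data$to, .data$season,
                    .data$maturity) |>
    dplyr::count(.data$from, .data$to, .data$season, .data$maturity,
                 name = "n_fish")
}

#' Convert a movement-edge table to an igraph object
#'
#' @param edges Edge tibble from [build_movement_graph()].
#' @return An `igraph` directed graph with `season`, `maturity` and
#'   `n_fish` edge attributes; export with [igraph::write_graph()]
#'   (GraphML/DOT).
#' @export
movement_igraph <- function(edges) {
  igraph::graph_from_data_frame(edges, directed = TRUE)
}
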