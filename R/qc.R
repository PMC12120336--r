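#' Score acoustic detections against quality-control criteria
#'
#' Each detection is scored, per tag in timestamp order, on six criteria:
#' two hard flags (`pre_release`: detected before the fish was released;
#' `outside_deployment`: detected outside the receiver's deployment
#' interval, or at an unknown receiver) and four soft flags (`isolated`:
#' no other same-tag detection within the isolation window at any
#' station; `excess_velocity`: implied speed to the nearest-in-time
#' neighbouring detection above `vmax`; `implausible_release_distance`:
#' farther from the release point than the fish could have swum at
#' `vmax`; `low_snr`: signal-to-noise ratio present and below `snr_min`).
#'
#' Verdicts: any hard flag, or two or more soft flags, give `invalid`;
#' exactly one soft flag gives `suspect` (retained but marked); otherwise
#' `valid`. Implied velocity uses great-circle distance between station
#' positions; consecutive detections at the same station imply zero
#' velocity.
#'
#' @param dets Detection tibble ([read_detections()]).
#' @param recv Receiver deployments ([read_receivers()]).
#' @param fish Fish metadata ([read_fish()]); every detected tag must be
#'   present (unknown tags are a hard error).
#' @param cfg [analysis_config()].
#' @return A tibble aligned to `dets` (column `detection_ref` is the row
#'   index in `dets`) with the six logical flags and a `verdict` factor.
#' @export
score_detections <- function(dets, recv, fish, cfg = analysis_config()) {
  unknown <- setdiff(unique(dets$tag_id), fish$acoustic_tag_id)
  if (length(unknown)) {
    stop("detections for unknown tag id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(dets)
  rel <- fish$release_time[match(dets$tag_id, fish$acoustic_tag_id)]
  rlon <- fish$release_lon[match(dets$tag_id, fish$acoustic_tag_id)]
  rlat <- fish$release_lat[match(dets$tag_id, fish$acoustic_tag_id)]

  pre_release <- dets$timestamp < rel

  # a detection is inside deployment if ANY deployment of that receiver
  # covers the timestamp
  inside <- rep(FALSE, n)
  known_recv <- dets$receiver_id %in% recv$receiver_id
  if (any(!known_recv)) {
    message(sum(!known_recv), " detection(s) at unknown receiver(s); ",
            "flagged outside_deployment")
  }
  for (k in seq_len(nrow(recv))) {
    hit <- dets$receiver_id == recv$receiver_id[k] &
      dets$timestamp >= recv$start[k] & dets$timestamp <= recv$end[k]
    inside <- inside | hit
  }
  outside_deployment <- !inside

  win_s <- cfg$isolation_window * 3600
  isolated <- rep(FALSE, n)
  excess_velocity <- rep(FALSE, n)
  for (tg in unique(dets$tag_id)) {
    idx <- which(dets$tag_id == tg)
    o <- idx[order(dets$timestamp[idx])]
    ts <- as.numeric(dets$timestamp[o])
    m <- length(o)
    if (m == 1) {
      isolated[o] <- TRUE
      next
    }
    gap_prev <- c(Inf, diff(ts))
    gap_next <- c(diff(ts), Inf)
    isolated[o] <- gap_prev > win_s & gap_next > win_s
    d_prev <- c(Inf, haversine_km(dets$lon[o][-m], dets$lat[o][-m],
                                  dets$lon[o][-1], dets$lat[o][-1]) * 1000)
    d_next <- c(d_prev[-1], Inf)
    same_prev <- c(FALSE, dets$station[o][-m] == dets$station[o][-1])
    same_next <- c(same_prev[-1], FALSE)
    v_prev <- ifelse(same_prev, 0, d_prev / pmax(gap_prev, 1e-9))
    v_next <- ifelse(same_next, 0, d_next / pmax(gap_next, 1e-9))
    # speed to the nearest-in-time neighbour
    v_near <- ifelse(gap_prev <= gap_next, v_prev, v_next)
    excess_velocity[o] <- is.finite(v_near) & v_near > cfg$vmax
  }

  elapsed_s <- pmax(as.numeric(dets$timestamp) - as.numeric(rel), 0)
  d_rel_m <- haversine_km(rlon, rlat, dets$lon, dets$lat) * 1000
  implausible_release_distance <- !pre_release &
    d_rel_m > cfg$vmax * elapsed_s

  low_snr <- !is.na(dets$snr) & dets$snr < cfg$snr_min

  soft <- isolated + excess_velocity + implausible_release_distance + low_snr
  hard <- pre_release | outside_deployment
  verdict <- dplyr::case_when(
    hard ~ "invalid",
    soft >= 2 ~ "invalid",
    soft == 1 ~ "suspect",
    TRUE ~ "valid"
  )
  tibble::tibble(
    detection_ref = seq_len(n),
    pre_release = pre_release,
    outside_deployment = outside_deployment,
    isolated = isolated,
    excess_velocity = excess_velocity,
    implausible_release_distance = implausible_release_distance,
    low_snr = low_snr,
    verdict = factor(verdict, levels = c("valid", "suspect", "invalid"))
  )
}

#' Remove detections judged invalid
#'
#' Keeps the rows whose verdict is `valid` or `suspect`, preserving order.
#' Filtering is idempotent and the output is always a subset of the input.
#'
#' @param dets Detection tibble.
#' @param scores Score tibble from [score_detections()], aligned to `dets`.
#' @param keep `"non-invalid"` (default) retains valid and suspect rows;
#'   `"valid"` retains only unflagged rows (use this strict setting when
#'   detections feed a hard constraint such as the acoustic geolocation
#'   likelihood).
#' @return The retained detections.
#' @export
filter_detections <- function(dets, scores,
                              keep = c("non-invalid", "valid")) {
  keep <- match.arg(keep)
  stopifnot(nrow(scores) == nrow(dets),
            identical(scores$detection_ref, seq_len(nrow(dets))))
  sel <- if (keep == "valid") {
    scores$verdict == "valid"
  } else {
    scores$verdict != "invalid"
  }
  dets[sel, , drop = FALSE]
}
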