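#' Depth (bathymetric) emission likelihood
#'
#' A fish recording a maximum depth `z_max` in an hour cannot be in a
#' cell whose total water depth (bathymetry plus sea-surface height) is
#' shallower than that. Cells at least as deep as `z_max - sigma_z` get
#' weight 1; shallower cells get a Gaussian penalty on the shortfall,
#' `exp(-(z_max - D)^2 / (2 sigma_z^2))` with `D` the local water depth.
#'
#' @param obs Hourly observations from [aggregate_hourly()].
#' @param fields [reference_fields()].
#' @param sigma_z Depth slack, metres.
#' @return A `tt_stack` over the observation hours.
#' @export
depth_likelihood <- function(obs, fields, sigma_z = 5) {
  g <- fields$grid
  ti <- hour_index(fields, obs$hour)
  nla <- length(g$lat); nlo <- length(g$lon)
  vals <- array(0, c(nla, nlo, nrow(obs)))
  for (k in seq_len(nrow(obs))) {
    depth_tot <- fields$bathymetry + fields$ssh[ti[k], , ]
    short <- obs$z_max[k] - depth_tot
    w <- ifelse(short <= sigma_z, 1, exp(-short^2 / (2 * sigma_z^2)))
    w[!g$sea_mask] <- 0
    vals[, , k] <- w
  }
  likelihood_stack(obs$hour, vals, g)
}

#' Temperature emission likelihood
#'
#' Compares the hourly mean tag temperature with the reference
#' temperature profile interpolated linearly in depth to the hour's mean
#' tag depth, cell by cell, under an unnormalised Gaussian with standard
#' deviation `sigma_T`. In cells whose water column is shallower than
#' the tag's mean depth the deepest available level is used.
#'
#' @param obs Hourly observations from [aggregate_hourly()].
#' @param fields [reference_fields()].
#' @param sigma_T Temperature tolerance, degrees C.
#' @return A `tt_stack` over the observation hours.
#' @export
temperature_likelihood <- function(obs, fields, sigma_T = 1) {
  g <- fields$grid
  ti <- hour_index(fields, obs$hour)
  lev <- fields$level_depths
  nla <- length(g$lat); nlo <- length(g$lon); nlev <- length(lev)
  vals <- array(0, c(nla, nlo, nrow(obs)))
  for (k in seq_len(nrow(obs))) {
    z <- obs$z_mean[k]
    prof <- fields$temperature[ti[k], , , ]
    dim(prof) <- c(nlev, nla * nlo)
    if (z <= lev[1]) {
      tref <- prof[1, ]
    } else if (z >= lev[nlev]) {
      tref <- prof[nlev, ]
    } else {
      l <- findInterval(z, lev)
      a <- (lev[l + 1] - z) / (lev[l + 1] - lev[l])
      tref <- a * prof[l, ] + (1 - a) * prof[l + 1, ]
    }
    # shallow cells: deepest finite level stands in
    if (anyNA(tref)) {
      deepest <- prof[1, ]
      for (l in seq_len(nlev)[-1]) {
        ok <- is.finite(prof[l, ])
        deepest[ok] <- prof[l, ok]
      }
      tref[is.na(tref)] <- deepest[is.na(tref)]
    }
    w <- exp(-(obs$t_mean[k] - tref)^2 / (2 * sigma_T^2))
    w <- matrix(w, nla, nlo)
    w[!g$sea_mask] <- 0
    if (!any(w > 0)) {
      dt_min <- min(abs(obs$t_mean[k] - tref), na.rm = TRUE)
      stop("temperature likelihood infeasible at ", fmt_utc(obs$hour[k]),
           ": min |dT| = ", signif(dt_min, 4), " degC", call. = FALSE)
    }
    vals[, , k] <- w
  }
  likelihood_stack(obs$hour, vals, g)
}

# Cells whose centre lies within detection range of a receiver; with
# include_containing the cell holding the receiver is added (needed for
# the detection indicator, which must never be empty on a valid grid).
receiver_footprint <- function(grid, lon, lat, range_m,
                               include_containing = FALSE) {
  lonm <- matrix(grid$lon, length(grid$lat), length(grid$lon), byrow = TRUE)
  latm <- matrix(grid$lat, length(grid$lat), length(grid$lon))
  d <- haversine_km(lonm, latm, lon, lat) * 1000
  fp <- d <= range_m
  if (include_containing) {
    ij <- cell_index(grid, lon, lat)
    if (!is.na(ij$row)) fp[ij$row, ij$col] <- TRUE
  }
  fp
}

#' Acoustic detection/non-detection likelihood
#'
#' In an hour with one or more detections the likelihood is an indicator:
#' 1 on the cells within detection range of every detecting receiver
#' (their intersection, always including the cell holding the receiver),
#' 0 elsewhere; conflicting simultaneous detections at distant receivers
#' make the hour infeasible. In an hour without detections the
#' likelihood is 0 on cells whose centre is within range of a receiver
#' active that hour and `nondetection_value` elsewhere at sea; with no
#' active receiver the slice is uniform 1. Because the detection range
#' (hundreds of metres) is smaller than a grid cell, a non-detection
#' only rules out a cell when the receiver effectively covers it.
#'
#' @param dets Filtered detections of one tag.
#' @param recv Receiver deployments (already restricted to receivers able
#'   to hear this tag's protocol, if relevant).
#' @param grid [grid_spec()].
#' @param times Hourly POSIXct axis for the stack.
#' @param nondetection_value Likelihood outside receiver ranges in hours
#'   without detections.
#' @return A `tt_stack` over `times`.
#' @export
acoustic_likelihood <- function(dets, recv, grid, times,
                                nondetection_value = 1) {
  nla <- length(grid$lat); nlo <- length(grid$lon)
  fp_det <- lapply(seq_len(nrow(recv)), function(k) {
    receiver_footprint(grid, recv$lon[k], recv$lat[k],
                       recv$detection_range_m[k],
                       include_containing = TRUE)
  })
  fp_nd <- lapply(seq_len(nrow(recv)), function(k) {
    receiver_footprint(grid, recv$lon[k], recv$lat[k],
                       recv$detection_range_m[k])
  })
  det_hour <- hour_floor(dets$timestamp)
  vals <- array(0, c(nla, nlo, length(times)))
  for (t in seq_along(times)) {
    h0 <- times[t]; h1 <- h0 + 3600
    active <- which(recv$start < h1 & recv$end > h0)
    hit <- which(det_hour == h0)
    if (length(hit)) {
      rids <- unique(dets$receiver_id[hit])
      kk <- match(rids, recv$receiver_id)
      if (anyNA(kk)) {
        stop("detection at receiver ", rids[which(is.na(kk))[1]],
             " with no deployment record", call. = FALSE)
      }
      for (i in seq_along(hit)) {
        k <- match(dets$receiver_id[hit[i]], recv$receiver_id)
        tdet <- dets$timestamp[hit[i]]
        if (tdet < recv$start[k] || tdet > recv$end[k]) {
          stop("detection at ", fmt_utc(tdet), " outside deployment of ",
               recv$receiver_id[k], " (should have been filtered)",
               call. = FALSE)
        }
      }
      sl <- Reduce(`&`, fp_det[kk])
      sl <- sl & grid$sea_mask
      if (!any(sl)) {
        stop("infeasible acoustic slice at ", fmt_utc(h0),
             ": simultaneous detections have no common cell",
             call. = FALSE)
      }
      vals[, , t] <- sl * 1
    } else {
      sl <- matrix(nondetection_value, nla, nlo)
      for (k in active) sl[fp_nd[[k]]] <- 0
      sl[!grid$sea_mask] <- 0
      vals[, , t] <- sl
    }
  }
  likelihood_stack(times, vals, grid)
}
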