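mk_fields <- function(grid, n_hours, bathy, temp_fun = NULL,
                      levels = c(0, 20, 60), ssh = 0,
                      origin = utc("2022-06-01")) {
  nla <- length(grid$lat); nlo <- length(grid$lon)
  time <- origin + 3600 * (seq_len(n_hours) - 1)
  ssh_arr <- array(ssh, c(n_hours, nla, nlo))
  temp <- array(NA_real_, c(n_hours, length(levels), nla, nlo))
  for (t in seq_len(n_hours)) {
    for (l in seq_along(levels)) {
      sl <- if (is.null(temp_fun)) matrix(14, nla, nlo) else
        temp_fun(levels[l], t)
      sl[!grid$sea_mask] <- NA
      sl[bathy < levels[l]] <- NA  # level below the local seabed
      temp[t, l, , ] <- sl
    }
  }
  reference_fields(grid, time, bathy, ssh_arr, temp, levels)
}

obs_row <- function(hour, z_max, z_mean = z_max / 2, t_mean = 14) {
  tibble::tibble(hour = hour, z_max = z_max, z_mean = z_mean,
                 t_mean = t_mean, n_records = 40L)
}

test_that("depth likelihood applies the feasibility rule and slack", {
  g <- small_grid(3, 2)
  bathy <- matrix(c(100, 10, 49), 2, 3, byrow = TRUE)
  f <- mk_fields(g, 1, bathy)
  L <- depth_likelihood(obs_row(f$time[1], z_max = 50), f, sigma_z = 5)
  expect_equal(L$values[1, 1, 1], 1)                   # deep enough
  expect_equal(L$values[1, 2, 1], exp(-40^2 / 50))     # shortfall 40 m
  expect_equal(L$values[1, 3, 1], 1)                   # within the slack
})

test_that("posterior stays in water deeper than the recorded maximum", {
  # deep channel in column 3 of a shallow shelf
  g <- small_grid(5, 4)
  bathy <- matrix(10, 4, 5); bathy[, 3] <- 100
  f <- mk_fields(g, 6, bathy)
  obs <- purrr::map_dfr(1:6, function(t) obs_row(f$time[t], z_max = 50))
  L <- depth_likelihood(obs, f, sigma_z = 5)
  fb <- forward_backward(L, movement_kernel(1, g))
  deep_mass <- sum(fb$posterior$values[, 3, ])
  expect_gte(deep_mass / length(obs$hour), 0.95)
})

test_that("temperature likelihood is Gaussian in the mismatch", {
  g <- small_grid(2, 2)
  bathy <- matrix(50, 2, 2)
  # 15 degC everywhere at every level in column 1; 16 degC in column 2
  tf <- function(level, t) matrix(c(15, 16), 2, 2, byrow = TRUE)
  f <- mk_fields(g, 1, bathy, temp_fun = tf)
  L <- temperature_likelihood(obs_row(f$time[1], 20, 10, t_mean = 15),
                              f, sigma_T = 1)
  expect_equal(L$values[1, 1, 1], 1)           # exact match
  expect_equal(L$values[1, 2, 1], exp(-0.5))   # off by one sigma
})

test_that("temperature interpolates in depth and falls back when shallow", {
  g <- small_grid(2, 2)
  bathy <- matrix(c(60, 25), 2, 2, byrow = TRUE)  # column 2 shallow
  tf <- function(level, t) matrix(14 - 0.1 * level, 2, 2)
  f <- mk_fields(g, 1, bathy, temp_fun = tf, levels = c(0, 20, 60))
  # interpolated reference at z_mean = 30 m: 14 - 3 = 11
  L <- temperature_likelihood(obs_row(f$time[1], 40, 30, t_mean = 11),
                              f, sigma_T = 1)
  expect_equal(L$values[1, 1, 1], 1)
  # the shallow cell uses its deepest finite level (20 m -> 12 degC)
  L2 <- temperature_likelihood(obs_row(f$time[1], 40, 30, t_mean = 12),
                               f, sigma_T = 1)
  expect_equal(L2$values[1, 2, 1], 1)
})

test_that("a zonal gradient localises longitude to the expected scale", {
  lon <- seq(-6, -4, by = 0.04)
  lat <- seq(48, 48.2, by = 0.02)
  g <- grid_spec(lon, lat, matrix(TRUE, length(lat), length(lon)))
  bathy <- matrix(80, length(lat), length(lon))
  grad <- 2  # degC per degree of longitude
  tf <- function(level, t) {
    matrix(12 + grad * (matrix(g$lon, length(lat), length(lon),
                               byrow = TRUE) - -6), length(lat),
           length(lon))
  }
  f <- mk_fields(g, 48, bathy, temp_fun = tf)
  set.seed(31)
  true_lon <- -5 + cumsum(rnorm(48, 0, 0.01))
  sigma_T <- 0.2
  obs <- purrr::map_dfr(1:48, function(t) {
    obs_row(f$time[t], 40, 20,
            t_mean = 12 + grad * (true_lon[t] - -6) +
              rnorm(1, 0, sigma_T / 2))
  })
  L <- temperature_likelihood(obs, f, sigma_T = sigma_T)
  fb <- forward_backward(L, movement_kernel(0.5, g))
  tr <- extract_track(fb$posterior)
  rmse_lon <- sqrt(mean((tr$lon_mean - true_lon)^2))
  # gradient length scale: sigma_T / grad degrees of longitude
  expect_lt(rmse_lon, 0.5 * sigma_T / grad)
})

test_that("acoustic likelihood is an indicator on detection hours", {
  g <- small_grid(10, 6)
  recv <- tibble::tibble(
    receiver_id = c("R1", "R2"), station = c("S1", "S2"),
    lon = c(g$lon[2], g$lon[9]), lat = c(g$lat[2], g$lat[5]),
    start = utc("2022-06-01"), end = utc("2022-06-10"),
    detection_range_m = 400, protocol = "OPi")
  times <- utc("2022-06-02") + 3600 * (0:2)
  dets <- tibble::tibble(tag_id = "T1",
                         timestamp = utc("2022-06-02 01:10:00"),
                         receiver_id = "R1", station = "S1",
                         lon = recv$lon[1], lat = recv$lat[1],
                         snr = 10)
  L <- acoustic_likelihood(dets, recv, g, times)
  # hour 2: positive exactly on the detecting receiver's footprint
  fp <- L$values[, , 2] > 0
  expect_true(fp[2, 2])
  expect_equal(sum(fp), 1)  # 400 m range inside one ~2 km cell
  # hours without detections: zero near both active receivers, 1 elsewhere
  expect_equal(L$values[2, 2, 1], 0)
  expect_equal(L$values[5, 9, 1], 0)
  expect_equal(L$values[3, 5, 1], 1)
  # with no receiver active, the slice is uniform over sea
  late <- acoustic_likelihood(dets[0, ], recv, g,
                              utc("2022-06-20") + 3600 * (0:1))
  expect_true(all(late$values == 1))
})

test_that("conflicting simultaneous detections are infeasible", {
  g <- small_grid(10, 6)
  # stations ~50 km apart
  recv <- tibble::tibble(
    receiver_id = c("R1", "R2"), station = c("S1", "S2"),
    lon = c(g$lon[1], g$lon[10]), lat = c(g$lat[1], g$lat[6]),
    start = utc("2022-06-01"), end = utc("2022-06-10"),
    detection_range_m = 400, protocol = "OPi")
  dets <- tibble::tibble(
    tag_id = "T1",
    timestamp = utc("2022-06-02 01:10:00") + c(0, 60),
    receiver_id = c("R1", "R2"), station = c("S1", "S2"),
    lon = recv$lon, lat = recv$lat, snr = 10)
  expect_error(
    acoustic_likelihood(dets, recv, g, utc("2022-06-02 01:00:00")),
    "no common cell")
  # detection outside its receiver's deployment is a contract violation
  late_det <- dets[1, ]
  late_det$timestamp <- utc("2022-06-12 01:10:00")
  expect_error(
    acoustic_likelihood(late_det, recv, g, utc("2022-06-12 01:00:00")),
    "outside deployment")
})

test_that("combining likelihoods multiplies slices and anchors ends", {
  set.seed(32)
  g <- small_grid(4, 3, land_cells = cbind(1, 1))
  A <- random_stack(g, 4); B <- random_stack(g, 4); C <- random_stack(g, 4)
  ones <- uniform_stack(g, 4)
  expect_equal(combine_likelihoods(A, ones)$values, A$values)
  # associative and commutative
  expect_equal(combine_likelihoods(A, B, C)$values,
               combine_likelihoods(C, A, B)$values)
  expect_equal(combine_likelihoods(combine_likelihoods(A, B), C)$values,
               combine_likelihoods(A, B, C)$values, tolerance = 1e-12)
  # release anchor one-hot
  anch <- combine_likelihoods(A, release = c(g$lon[2], g$lat[2]))
  expect_equal(sum(anch$values[, , 1] > 0), 1)
  expect_equal(anch$values[2, 2, 1], 1)
  # recapture multiplies the last slice
  anch2 <- combine_likelihoods(A, recapture = c(g$lon[3], g$lat[3]))
  expect_equal(sum(anch2$values[, , 4] > 0), 1)
  # an all-zero slice is infeasible and names the culprit
  Z <- A; Z$values[, , 2] <- 0
  Z <- likelihood_stack(A$times, Z$values, g)
  expect_error(combine_likelihoods(B, Z), "slice 2")
})

test_that("movement kernel is normalised and has the right spread", {
  g <- small_grid(41, 41)
  k <- movement_kernel(1.5, g)
  expect_equal(sum(outer(k$g, k$g)), 1, tolerance = 1e-12)
  # one application to a central point mass spreads by sigma^2 per axis
  x <- matrix(0, 41, 41); x[21, 21] <- 1
  y <- tagtrack:::kern_apply(k, x)
  idx <- seq_len(41)
  var_lat <- sum(y * outer((idx - 21)^2, rep(1, 41)))
  var_lon <- sum(y * outer(rep(1, 41), (idx - 21)^2))
  expect_equal(var_lat, 1.5^2, tolerance = 0.05)
  expect_equal(var_lon, 1.5^2, tolerance = 0.05)
  # tiny sigma degenerates to the identity
  k0 <- movement_kernel(1e-4, g)
  expect_equal(tagtrack:::kern_apply(k0, x), x, tolerance = 1e-12)
})

test_that("one-step smoothing is prior times likelihood", {
  set.seed(33)
  g <- small_grid(4, 3)
  L <- random_stack(g, 1)
  fb <- forward_backward(L, movement_kernel(1, g))
  manual <- L$values[, , 1] / sum(L$values[, , 1])
  expect_equal(fb$posterior$values[, , 1], manual, tolerance = 1e-12)
})

test_that("smoothed marginals equal exhaustive path enumeration", {
  set.seed(34)
  # 3 x 3 grid with one land cell, 4 steps
  g <- small_grid(3, 3, land_cells = cbind(2, 2))
  L <- random_stack(g, 4)
  sigma <- 0.8
  fb <- forward_backward(L, movement_kernel(sigma, g))
  bf <- brute_force_smoother(L, sigma)
  expect_equal(fb$posterior$values, bf$marginals, tolerance = 1e-10)
  expect_equal(fb$log_lik, bf$log_lik, tolerance = 1e-10)
  # all-sea 3 x 3, different sigma, 5 steps
  g2 <- small_grid(3, 3)
  L2 <- random_stack(g2, 5)
  fb2 <- forward_backward(L2, movement_kernel(1.4, g2))
  bf2 <- brute_force_smoother(L2, 1.4)
  expect_equal(fb2$posterior$values, bf2$marginals, tolerance = 1e-10)
  expect_equal(fb2$log_lik, bf2$log_lik, tolerance = 1e-10)
})

test_that("posterior slices are normalised and land carries no mass", {
  scen <- one_fish_scenario(41, n_days = 4)
  f <- scen$fish[1, ]
  fit <- geolocate(scen$series[[1]], scen$fields, f,
                   cfg = synthetic_acfg(), use_acoustic = FALSE,
                   sigma = 1.2, keep_posterior = TRUE)
  sums <- apply(fit$posterior$values, 3, sum)
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  land <- !scen$grid$sea_mask
  expect_true(all(apply(fit$posterior$values, 3,
                        function(m) sum(m[land])) == 0))
  # anchored start: one-hot at the release cell
  expect_equal(sum(fit$posterior$values[, , 1] > 0), 1)
})

test_that("an infeasible slice names its time step", {
  g <- small_grid(3, 3)
  L <- uniform_stack(g, 3)
  vals <- L$values; vals[, , 2] <- 0
  expect_error(likelihood_stack(L$times, vals, g) |>
                 forward_backward(movement_kernel(1, g)),
               "slice 2")
})

test_that("sigma estimation is scale-invariant and flags flat profiles", {
  set.seed(35)
  g <- small_grid(12, 10)
  nla <- 10; nlo <- 12
  lonm <- matrix(g$lon, nla, nlo, byrow = TRUE)
  latm <- matrix(g$lat, nla, nlo)
  n <- 40
  x <- -5 + cumsum(rnorm(n, 0, 0.03)); y <- 48.06 + cumsum(rnorm(n, 0, 0.02))
  vals <- array(0, c(nla, nlo, n))
  for (t in 1:n) {
    vals[, , t] <- exp(-((lonm - x[t])^2 / (2 * 0.06^2) +
                           (latm - y[t])^2 / (2 * 0.04^2)))
  }
  L <- likelihood_stack(utc("2022-06-01") + 3600 * (0:(n - 1)), vals, g)
  e1 <- estimate_sigma(L, c(0.2, 4))
  L7 <- likelihood_stack(L$times, vals * 7, g)
  e2 <- estimate_sigma(L7, c(0.2, 4))
  expect_equal(e1$sigma_hat, e2$sigma_hat, tolerance = 1e-6)
  # uninformative likelihood: flat profile, boundary warning
  expect_warning(eu <- estimate_sigma(uniform_stack(g, 5), c(0.5, 2)),
                 "flat|monotone")
  expect_true(eu$boundary)
})

test_that("track extraction handles point masses and ties", {
  g <- small_grid(3, 3)
  vals <- array(0, c(3, 3, 1)); vals[2, 3, 1] <- 1
  post <- likelihood_stack(utc("2022-06-01"), vals, g)
  tr <- extract_track(post)
  expect_equal(tr$lon_mean, g$lon[3])
  expect_equal(tr$lat_mean, g$lat[2])
  expect_equal(tr$sd_km, 0)
  # symmetric two-cell posterior: mean midway, mode at the tie-break cell
  vals2 <- array(0, c(3, 3, 1)); vals2[1, 1, 1] <- 0.5; vals2[3, 1, 1] <- 0.5
  tr2 <- extract_track(likelihood_stack(utc("2022-06-01"), vals2, g))
  expect_equal(tr2$lat_mean, mean(g$lat[c(1, 3)]))
  expect_equal(tr2$lat_mode, g$lat[1])  # lowest latitude index wins
  expect_gt(tr2$sd_km, 0)
})

test_that("track distances: stationary zero, hourly at least daily", {
  tr0 <- tibble::tibble(time = utc("2022-06-01") + 3600 * (0:47),
                        lon_mean = -5, lat_mean = 48,
                        lon_mode = -5, lat_mode = 48, sd_km = 0)
  expect_equal(track_distance(tr0), 0)
  set.seed(36)
  tr <- tibble::tibble(time = utc("2022-06-01") + 3600 * (0:95),
                       lon_mean = -5 + cumsum(rnorm(96, 0, 0.01)),
                       lat_mean = 48 + cumsum(rnorm(96, 0, 0.01)),
                       lon_mode = 0, lat_mode = 0, sd_km = 0)
  expect_gte(track_distance(tr, "hourly"), track_distance(tr, "daily"))
})

test_that("track sensitivity is zero for identical tracks and errors on
           mismatched axes", {
  tr <- tibble::tibble(time = utc("2022-06-01") + 3600 * (0:5),
                       lon_mean = -5 + (0:5) / 100, lat_mean = 48,
                       lon_mode = 0, lat_mode = 0, sd_km = 0)
  s <- track_sensitivity(tr, tr)
  expect_equal(c(s$mean_km, s$min_km, s$max_km), c(0, 0, 0))
  tr2 <- tr; tr2$time <- tr2$time + 3600
  expect_error(track_sensitivity(tr, tr2), "time axes")
})

test_that("tag death is detected from a sustained surface signature", {
  ts <- utc("2022-06-01") + 90 * (0:(40 * 40 - 1))
  depth <- c(runif(600, 5, 20), rep(0.2, 40 * 40 - 600))
  s <- tibble::tibble(tag_id = "A1", timestamp = ts, depth_m = depth,
                      temperature_c = 14)
  d <- detect_tag_death(s)
  expect_equal(d, ts[601])
  s2 <- s; s2$depth_m <- runif(nrow(s2), 5, 20)
  expect_true(is.na(detect_tag_death(s2)))
})
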