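# Shared fixture builders. Everything is generated in code.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Small all-sea (or partly land) grid centred on the Iroise Sea.
small_grid <- function(nlon = 3, nlat = 3, land_cells = NULL,
                       lon0 = -5, lat0 = 48, step_lon = 0.03,
                       step_lat = 0.02) {
  lon <- lon0 + step_lon * (seq_len(nlon) - 1)
  lat <- lat0 + step_lat * (seq_len(nlat) - 1)
  sea <- matrix(TRUE, nlat, nlon)
  if (!is.null(land_cells)) sea[land_cells] <- FALSE
  grid_spec(lon, lat, sea)
}

# Uniform-1 likelihood stack over n hourly slices.
uniform_stack <- function(grid, n, origin = utc("2022-06-01")) {
  nla <- length(grid$lat); nlo <- length(grid$lon)
  likelihood_stack(origin + 3600 * (seq_len(n) - 1),
                   array(1, c(nla, nlo, n)), grid)
}

random_stack <- function(grid, n, origin = utc("2022-06-01")) {
  nla <- length(grid$lat); nlo <- length(grid$lon)
  likelihood_stack(origin + 3600 * (seq_len(n) - 1),
                   array(runif(nla * nlo * n, 0.1, 1), c(nla, nlo, n)),
                   grid)
}

# Independent brute-force smoother: explicit transition matrix and full
# path enumeration. Used as the oracle for forward_backward.
brute_force_smoother <- function(L, sigma, truncation = 4, prior = NULL) {
  grid <- L$grid
  nla <- length(grid$lat); nlo <- length(grid$lon)
  n_cell <- nla * nlo
  nt <- length(L$times)
  cell_i <- rep(seq_len(nla), nlo)
  cell_j <- rep(seq_len(nlo), each = nla)
  sea <- as.vector(grid$sea_mask)
  r <- ceiling(truncation * sigma)
  kw <- function(d) if (abs(d) > r) 0 else exp(-d^2 / (2 * sigma^2))
  g1 <- vapply(-r:r, kw, numeric(1)); g1 <- g1 / sum(g1)
  K <- function(di, dj) {
    if (abs(di) > r || abs(dj) > r) return(0)
    g1[di + r + 1] * g1[dj + r + 1]
  }
  P <- matrix(0, n_cell, n_cell)
  for (a in seq_len(n_cell)) {
    if (!sea[a]) next
    for (b in seq_len(n_cell)) {
      if (!sea[b]) next
      P[a, b] <- K(cell_i[b] - cell_i[a], cell_j[b] - cell_j[a])
    }
    P[a, ] <- P[a, ] / sum(P[a, ])
  }
  if (is.null(prior)) prior <- sea / sum(sea)
  prior <- as.vector(prior) * sea; prior <- prior / sum(prior)
  Lv <- matrix(L$values, n_cell, nt)  # column t = slice t
  paths <- as.matrix(expand.grid(rep(list(which(sea)), nt)))
  w <- prior[paths[, 1]] * Lv[cbind(paths[, 1], 1)]
  if (nt > 1) {
    for (t in 2:nt) {
      w <- w * P[cbind(paths[, t - 1], paths[, t])] *
        Lv[cbind(paths[, t], t)]
    }
  }
  marg <- array(0, c(nla, nlo, nt))
  for (t in seq_len(nt)) {
    m <- tapply(w, paths[, t], sum)
    v <- numeric(n_cell)
    v[as.integer(names(m))] <- m
    marg[, , t] <- matrix(v / sum(w), nla, nlo)
  }
  list(marginals = marg, log_lik = log(sum(w)))
}

# Analysis configuration matched to the synthetic generator's sensor
# noise (the correct observation model for simulated data).
synthetic_acfg <- function() analysis_config(sigma_T = 0.05, sigma_z = 2)

# One-fish scenario used by several geolocation tests.
one_fish_scenario <- function(seed, n_days = 9) {
  simulate_scenario(scenario_config(n_fish = 1, n_days = n_days,
                                    seed = seed))
}
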