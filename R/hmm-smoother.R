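#' Forward-backward smoothing of the gridded hidden Markov model
#'
#' Runs the scaled HMM filter and smoother over the hourly likelihood
#' stack. The transition law moves probability by the Brownian kernel,
#' zeroes land, and renormalises per source cell (so no probability is
#' lost at coasts or grid edges):
#' `P(j | i) = K(j - i) sea(j) / sum_j' K(j' - i) sea(j')`.
#' The forward pass accumulates the log marginal likelihood; the
#' backward pass yields smoothed per-hour state probabilities that sum
#' to one over sea cells.
#'
#' @param L A `tt_stack` of combined emission likelihoods.
#' @param kernel A [movement_kernel()].
#' @param prior Optional `(n_lat, n_lon)` matrix of initial-state
#'   weights; defaults to uniform over sea.
#' @return List with `posterior` (a `tt_stack` of smoothed
#'   probabilities), `log_lik`, and `filtered` (the filtered
#'   probabilities, same shape).
#' @export
forward_backward <- function(L, kernel, prior = NULL) {
  grid <- L$grid
  nla <- length(grid$lat); nlo <- length(grid$lon)
  nt <- length(L$times)
  sea <- grid$sea_mask * 1
  if (is.null(prior)) prior <- sea / sum(sea)
  prior <- prior * sea
  prior <- prior / sum(prior)
  check_feasible(L)

  # per-source normaliser of the land-masked kernel
  cnorm <- kern_apply(kernel, sea)
  cnorm[cnorm <= 0] <- 1  # land-only sources; never used with mass

  alpha <- array(0, c(nla, nlo, nt))
  log_lik <- 0
  a_prev <- prior
  for (t in seq_len(nt)) {
    pred <- if (t == 1) prior else sea * kern_apply(kernel, a_prev / cnorm)
    a <- pred * L$values[, , t]
    z <- sum(a)
    if (!(z > 0) || !is.finite(z)) {
      stop("forward normaliser vanished at step ", t, " (",
           fmt_utc(L$times[t]), "): track infeasible", call. = FALSE)
    }
    a <- a / z
    log_lik <- log_lik + log(z)
    alpha[, , t] <- a
    a_prev <- a
  }

  gamma <- array(0, c(nla, nlo, nt))
  beta <- matrix(1, nla, nlo)
  gamma[, , nt] <- alpha[, , nt]
  if (nt > 1) {
    for (t in (nt - 1):1) {
      w <- sea * L$values[, , t + 1] * beta
      beta <- kern_apply(kernel, w) / cnorm
      beta <- beta / max(beta)  # scale freely; gamma is renormalised
      g <- alpha[, , t] * beta
      gamma[, , t] <- g / sum(g)
    }
  }
  list(posterior = likelihood_stack(L$times, gamma, grid),
       log_lik = log_lik,
       filtered = likelihood_stack(L$times, alpha, grid))
}

#' Maximum-likelihood estimation of the diffusion coefficient
#'
#' Maximises the HMM log marginal likelihood over the per-hour
#' displacement standard deviation `sigma` by bounded scalar search
#' (Brent, tolerance 1e-3 cell units), and evaluates a coarse
#' likelihood profile. A profile that is monotone onto a bound
#' triggers a warning and returns the boundary value.
#'
#' @param L Combined emission `tt_stack`.
#' @param bounds Numeric `c(lower, upper)` for `sigma`, cells per
#'   square-root hour.
#' @param prior Optional initial-state matrix (see
#'   [forward_backward()]).
#' @param truncation Kernel truncation, multiples of `sigma`.
#' @param n_profile Number of profile evaluation points.
#' @return List `sigma_hat`, `log_lik`, `profile` (tibble
#'   `sigma, log_lik`), `boundary` (logical).
#' @export
estimate_sigma <- function(L, bounds = c(0.05, 5), prior = NULL,
                           truncation = 4, n_profile = 5) {
  ll <- function(s) {
    k <- movement_kernel(s, L$grid, truncation)
    forward_backward_loglik(L, k, prior)
  }
  prof_sigma <- seq(bounds[1], bounds[2], length.out = n_profile)
  prof_ll <- vapply(prof_sigma, ll, numeric(1))
  profile <- tibble::tibble(sigma = prof_sigma, log_lik = prof_ll)
  flat <- diff(range(prof_ll)) < 1e-9
  mono_up <- all(diff(prof_ll) >= -1e-9)
  mono_down <- all(diff(prof_ll) <= 1e-9)
  if (flat || mono_up || mono_down) {
    boundary_sigma <- if (mono_up && !flat) bounds[2] else bounds[1]
    warning("log-likelihood is ",
            if (flat) "flat" else "monotone", " on the sigma bounds; ",
            "returning the boundary value ", boundary_sigma, call. = FALSE)
    return(list(sigma_hat = boundary_sigma, log_lik = ll(boundary_sigma),
                profile = profile, boundary = TRUE))
  }
  opt <- optimize(ll, interval = bounds, maximum = TRUE, tol = 1e-3)
  list(sigma_hat = opt$maximum, log_lik = opt$objective, profile = profile,
       boundary = FALSE)
}

# Forward pass only (no smoothing): the log marginal likelihood.
forward_backward_loglik <- function(L, kernel, prior = NULL) {
  grid <- L$grid
  sea <- grid$sea_mask * 1
  if (is.null(prior)) prior <- sea / sum(sea)
  prior <- prior * sea; prior <- prior / sum(prior)
  cnorm <- kern_apply(kernel, sea)
  cnorm[cnorm <= 0] <- 1
  nt <- length(L$times)
  log_lik <- 0
  a_prev <- prior
  for (t in seq_len(nt)) {
    pred <- if (t == 1) prior else sea * kern_apply(kernel, a_prev / cnorm)
    a <- pred * L$values[, , t]
    z <- sum(a)
    if (!(z > 0) || !is.finite(z)) return(-Inf)
    a_prev <- a / z
    log_lik <- log_lik + log(z)
  }
  log_lik
}
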