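#' Hourly gridded likelihood stack
#'
#' Container for per-hour emission likelihoods (or posterior
#' probabilities) on a [grid_spec()] grid: an array of dimension
#' `(n_lat, n_lon, n_hour)` plus its hourly time axis. Land cells are
#' always zero; every slice must retain at least one strictly positive
#' sea cell, otherwise the track is infeasible.
#'
#' @param times POSIXct vector of hour starts.
#' @param values Numeric array `(n_lat, n_lon, n_hour)`, non-negative.
#' @param grid The [grid_spec()] the values live on.
#' @return An object of class `tt_stack`.
#' @export
likelihood_stack <- function(times, values, grid) {
  stopifnot(inherits(grid, "tt_grid"))
  nla <- length(grid$lat); nlo <- length(grid$lon)
  if (length(times) == 1 && length(dim(values)) == 2) {
    dim(values) <- c(nla, nlo, 1)
  }
  stopifnot(identical(dim(values), c(nla, nlo, length(times))))
  if (any(values < 0, na.rm = TRUE)) {
    stop("likelihood values must be non-negative", call. = FALSE)
  }
  land <- !grid$sea_mask
  for (t in seq_along(times)) values[, , t][land] <- 0
  structure(list(times = times, values = values, grid = grid),
            class = "tt_stack")
}

#' @export
print.tt_stack <- function(x, ...) {
  cat(sprintf("<tt_stack> %d hourly slices on a %d x %d grid\n",
              length(x$times), length(x$grid$lat), length(x$grid$lon)))
  invisible(x)
}

# Error if any slice carries no positive sea mass; returns indices checked.
check_feasible <- function(stack, what = "likelihood") {
  mass <- apply(stack$values, 3, sum)
  bad <- which(!(mass > 0) | !is.finite(mass))
  if (length(bad)) {
    stop("infeasible ", what, ": slice ", bad[1], " (",
         fmt_utc(stack$times[bad[1]]), ") has no positive sea cell",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Combine likelihood stacks and anchor the end points
#'
#' Elementwise product of aligned stacks. When a release position is
#' given the first slice is replaced by a one-hot indicator at the
#' release cell; when a recapture position is given the last slice is
#' multiplied by a one-hot indicator at the recapture cell. Any
#' resulting all-zero slice is an infeasibility error naming the slice
#' and the contributing stacks with zero mass there.
#'
#' @param ... Two or more `tt_stack`s on identical grids and time axes.
#' @param release Optional `c(lon, lat)` of the release position.
#' @param recapture Optional `c(lon, lat)` of the recapture position.
#' @return The combined `tt_stack`.
#' @export
combine_likelihoods <- function(..., release = NULL, recapture = NULL) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 1)
  base <- stacks[[1]]
  for (s in stacks[-1]) {
    stopifnot(identical(as.numeric(s$times), as.numeric(base$times)))
  }
  vals <- Reduce(`*`, lapply(stacks, `[[`, "values"))
  grid <- base$grid
  nt <- length(base$times)
  one_hot <- function(lonlat) {
    ij <- cell_index(grid, lonlat[1], lonlat[2])
    if (is.na(ij$row)) stop("anchor position outside the grid", call. = FALSE)
    m <- matrix(0, length(grid$lat), length(grid$lon))
    m[ij$row, ij$col] <- 1
    m
  }
  if (!is.null(release)) vals[, , 1] <- one_hot(release)
  if (!is.null(recapture)) vals[, , nt] <- vals[, , nt] * one_hot(recapture)
  mass <- apply(vals, 3, sum)
  bad <- which(!(mass > 0))
  if (length(bad)) {
    t0 <- bad[1]
    zero_in <- which(vapply(stacks, function(s) sum(s$values[, , t0]) == 0,
                            logical(1)))
    stop("infeasible combination at slice ", t0,
         if (length(zero_in)) paste0(" (stack ",
                                     paste(zero_in, collapse = ","),
                                     " contributes zero mass)"),
         call. = FALSE)
  }
  likelihood_stack(base$times, vals, grid)
}
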