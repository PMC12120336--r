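#' Brownian movement kernel on the grid
#'
#' Discrete isotropic Gaussian displacement kernel with standard
#' deviation `sigma` grid cells per square-root hour, truncated at
#' `truncation * sigma` cells (square support, so the kernel is
#' separable) and renormalised to unit mass before land masking. The
#' kernel is applied by separable convolution; land cells are zeroed and
#' each transition is renormalised per source cell, which conserves
#' probability at coasts and grid edges.
#'
#' @param sigma Per-hour displacement standard deviation, grid cells.
#' @param grid [grid_spec()].
#' @param truncation Truncation radius in multiples of `sigma`.
#' @return An object of class `tt_kernel` with the 1-D weights and the
#'   banded convolution matrices for this grid.
#' @export
movement_kernel <- function(sigma, grid, truncation = 4) {
  stopifnot(sigma > 0)
  r <- ceiling(truncation * sigma)
  if (r < 1) {
    message("movement kernel truncates to a delta (sigma = ", sigma, ")")
    r <- 0
  }
  d <- -r:r
  g <- exp(-d^2 / (2 * sigma^2))
  g[!is.finite(g)] <- 0
  if (sum(g) == 0) g[d == 0] <- 1
  g <- g / sum(g)
  band <- function(n) {
    A <- matrix(0, n, n)
    for (k in seq_along(d)) {
      idx <- which(seq_len(n) + d[k] >= 1 & seq_len(n) + d[k] <= n)
      A[cbind(idx, idx + d[k])] <- g[k]
    }
    A
  }
  structure(
    list(sigma = sigma, truncation_radius = r, g = g,
         A_lat = band(length(grid$lat)), A_lon = band(length(grid$lon)),
         sigma_km = sigma * grid_cell_km(grid)),
    class = "tt_kernel"
  )
}

#' @export
print.tt_kernel <- function(x, ...) {
  cat(sprintf("<tt_kernel> sigma %.3f cells/sqrt(h) (%.2f km/sqrt(h)), radius %d\n",
              x$sigma, x$sigma_km, x$truncation_radius))
  invisible(x)
}

# Separable convolution of a (n_lat, n_lon) field with the kernel.
kern_apply <- function(kernel, x) {
  kernel$A_lat %*% x %*% t(kernel$A_lon)
}

# Dense 2-D kernel (outer product of the 1-D weights); mass 1 by
# construction.
kernel_matrix <- function(kernel) {
  outer(kernel$g, kernel$g)
}
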