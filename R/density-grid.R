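#' Map a 2D projection of a data subset onto the unit square
#'
#' Rescales two selected columns of an event matrix to `[0, 1]` per axis using
#' the subset-local min/max (recomputed at every recursion step of the
#' clustering, so projections are always full-range for the current subset).
#'
#' @param subset numeric matrix (events x features), at least one row.
#' @param dim_x,dim_y distinct column indices of the projection axes.
#'
#' @return A list of class `"unit_square_projection"` with elements
#'   `dim_x`, `dim_y`, `x_min`, `x_max`, `y_min`, `y_max`, `degenerate`
#'   (logical; `TRUE` when an axis has zero range, in which case `coords` is
#'   `NULL`) and `coords` (n x 2 matrix of mapped coordinates in `[0,1]^2`).
#'
#' @details Degenerate projections (a constant axis) are flagged rather than
#'   raised as errors: upstream code simply skips them. Non-finite values are
#'   an error because they indicate a malformed input matrix.
#' @export
normalize_projection <- function(subset, dim_x, dim_y) {
  stopifnot(is.matrix(subset), nrow(subset) >= 1L, dim_x != dim_y)
  x <- subset[, dim_x]
  y <- subset[, dim_y]
  if (any(!is.finite(x))) {
    stop("non-finite values in projection column ", dim_x)
  }
  if (any(!is.finite(y))) {
    stop("non-finite values in projection column ", dim_y)
  }
  rx <- range(x)
  ry <- range(y)
  out <- list(
    dim_x = dim_x, dim_y = dim_y,
    x_min = rx[1L], x_max = rx[2L],
    y_min = ry[1L], y_max = ry[2L],
    degenerate = FALSE, coords = NULL
  )
  if (rx[1L] == rx[2L] || ry[1L] == ry[2L]) {
    out$degenerate <- TRUE
    class(out) <- "unit_square_projection"
    return(out)
  }
  out$coords <- cbind(
    (x - rx[1L]) / (rx[2L] - rx[1L]),
    (y - ry[1L]) / (ry[2L] - ry[1L])
  )
  class(out) <- "unit_square_projection"
  out
}

#' Per-axis histogram bin count from sample size (Mann's rule)
#'
#' The per-axis bin count N of the 2D histogram is the square root of the
#' total bin number given by Mann's formula, scaled by the Gaussian smoothing
#' width: N = 4 * sigma * (3 * (n - 1)^2 / 4)^0.1. The result is rounded half
#' away from zero and clamped to a floor of 4 (a smaller grid cannot host a
#' boundary path).
#'
#' @param n_points number of events in the current projection (>= 2).
#' @param sigma Gaussian smoothing width in bin units (> 0).
#' @return integer bin count per axis, >= 4.
#' @export
mann_bin_count <- function(n_points, sigma = 1) {
  stopifnot(sigma > 0)
  if (n_points < 2) {
    stop("mann_bin_count() needs at least 2 points; recursion should have stopped")
  }
  raw <- 4 * sigma * (3 * (n_points - 1)^2 / 4)^0.1
  max(4L, as.integer(floor(raw + 0.5)))  # round half away from zero
}

# 0-based bin index for coordinates in [0,1]: half-open bins, last bin closed.
bin_index <- function(v, n_bins) {
  pmin(as.integer(floor(v * n_bins)), n_bins - 1L)
}

# N x N column-normalised Gaussian transfer matrix: entry [i, j] is the share
# of bin j's mass deposited into bin i. Column normalisation implements the
# renormalised truncated-kernel boundary rule, so total mass is conserved.
gaussian_transfer_matrix <- function(n_bins, sigma) {
  idx <- seq_len(n_bins)
  k <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  sweep(k, 2L, colSums(k), "/")
}

#' Build the Gaussian-smoothed 2D density histogram of a projection
#'
#' Bins the unit-square coordinates on an N x N grid (half-open bins, final
#' bin closed) and convolves with an isotropic Gaussian kernel of standard
#' deviation `sigma` bin units. The kernel is truncated at the grid edges and
#' renormalised there, so the smoothed histogram's total mass equals the
#' number of points exactly.
#'
#' @param proj a non-degenerate [normalize_projection()] result.
#' @param n_bins bins per axis (>= 2); typically [mann_bin_count()].
#' @param sigma smoothing width in bin units; `0` skips smoothing.
#' @return A list of class `"density_grid"`: `H` (N x N smoothed density,
#'   rows = y bins, cols = x bins), `N`, `sigma`, `n_points`, `bin_edges`.
#' @export
build_smoothed_histogram <- function(proj, n_bins, sigma = 1) {
  stopifnot(inherits(proj, "unit_square_projection"), !proj$degenerate,
            n_bins >= 2)
  n <- nrow(proj$coords)
  ix <- bin_index(proj$coords[, 1L], n_bins)
  iy <- bin_index(proj$coords[, 2L], n_bins)
  h <- matrix(0, n_bins, n_bins)  # [y bin, x bin]
  # tabulate over the flattened (iy, ix) pair
  flat <- tabulate(iy + n_bins * ix + 1L, nbins = n_bins * n_bins)
  h[] <- flat
  if (sigma > 0) {
    k <- gaussian_transfer_matrix(n_bins, sigma)
    h <- k %*% h %*% t(k)  # smooth along y (rows), then along x (cols)
  }
  structure(
    list(H = h, N = as.integer(n_bins), sigma = sigma, n_points = n,
         bin_edges = seq(0, 1, length.out = n_bins + 1L)),
    class = "density_grid"
  )
}

# Debug helper: dump a grid's H as TSV for inspection.
write_density_grid <- function(grid, path) {
  utils::write.table(grid$H, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
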