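# Candidate split construction and ranking for one 2D projection.

#' Calinski-Harabasz index of a two-group split
#'
#' CH = [B / (K - 1)] / [W / (n - K)] with K = 2, where B is the
#' between-group dispersion (size-weighted squared distances of group
#' centroids to the overall centroid) and W the within-group dispersion.
#' Computed here in the 2D unit-square projection coordinates where the
#' candidate boundary lives. A split with zero within-group dispersion
#' returns `Inf`, ranking above every finite score.
#'
#' @param points2d n x 2 numeric matrix.
#' @param below logical vector: group membership (both groups nonempty).
#' @return scalar CH score.
#' @export
calinski_harabasz <- function(points2d, below) {
  stopifnot(nrow(points2d) == length(below))
  n <- nrow(points2d)
  n1 <- sum(below)
  if (n1 == 0L || n1 == n) stop("both groups must be nonempty")
  c_all <- colMeans(points2d)
  c1 <- colMeans(points2d[below, , drop = FALSE])
  c2 <- colMeans(points2d[!below, , drop = FALSE])
  b <- n1 * sum((c1 - c_all)^2) + (n - n1) * sum((c2 - c_all)^2)
  w <- sum(sweep(points2d[below, , drop = FALSE], 2L, c1)^2) +
       sum(sweep(points2d[!below, , drop = FALSE], 2L, c2)^2)
  if (w == 0) return(Inf)
  (b / 1) / (w / (n - 2))
}

# Assign unit-square points to the two sides of a boundary path.
# orientation "x": boundary is y = f(x); an event in x-column c is "below"
# iff its y <= boundary_y[c] (on-boundary points go below). orientation "y":
# axes transposed, boundary is x = f(y).
split_assignment <- function(coords, boundary_y, n_bins, orientation = "x") {
  if (orientation == "x") {
    cc <- bin_index(coords[, 1L], n_bins) + 1L
    coords[, 2L] <= boundary_y[cc]
  } else {
    cc <- bin_index(coords[, 2L], n_bins) + 1L
    coords[, 1L] <= boundary_y[cc]
  }
}

# Best admissible split for one (dim_x, dim_y) projection of a subset, or
# NULL. Scans gravity levels in both orientations (boundary as a function of
# x on H, then as a function of y on t(H)), drops candidates violating the
# min-cluster-size filter, and keeps the survivor with maximal CH.
# Tie-break: orientation "x" before "y", then lower q0.
candidates_for_projection <- function(subset, dim_x, dim_y, config) {
  proj <- normalize_projection(subset, dim_x, dim_y)
  if (proj$degenerate) return(NULL)
  n <- nrow(proj$coords)
  n_bins <- if (!is.null(config$bins)) config$bins else
    mann_bin_count(n, config$sigma)
  grid <- build_smoothed_histogram(proj, n_bins, config$sigma)
  best <- NULL
  for (orientation in c("x", "y")) {
    g <- grid
    if (orientation == "y") g$H <- t(g$H)
    cands <- scan_gravity_levels(g, beta = config$beta, dq = config$dq,
                                 step_limit = config$step_limit)
    for (cand in cands) {
      below <- split_assignment(proj$coords, cand$boundary_y, n_bins,
                                orientation)
      n1 <- sum(below)
      if (n1 < config$min_cluster_size || n - n1 < config$min_cluster_size)
        next
      ch <- calinski_harabasz(proj$coords, below)
      rec <- list(dim_x = dim_x, dim_y = dim_y, orientation = orientation,
                  q0 = cand$q0, rows = cand$rows, action = cand$action,
                  boundary_y = cand$boundary_y, ch = ch, below = below,
                  n_bins = n_bins,
                  x_min = proj$x_min, x_max = proj$x_max,
                  y_min = proj$y_min, y_max = proj$y_max)
      if (is.null(best) || ch > best$ch) best <- rec
      # equal CH: keep the earlier orientation / lower q0 (loop order)
    }
  }
  best
}
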