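# Minimum-density boundary search on one density grid.
#
# A candidate decision boundary is an extremal path through the smoothed
# histogram H augmented with a parabolic "gravity" potential anchored at the
# level y0 = q. Scanning q over a lattice and keeping strict local minima of
# the path action S(q) (the integral of the raw density along the path)
# yields the true density valleys.

#' Parabolic gravity potential for a density grid
#'
#' Builds Hg(y) = (y - y0)^2 at the grid's y-bin centers, with the anchor
#' y0 = q in unit-square coordinates (q interpolates between the subset-local
#' y minimum, q = 0, and maximum, q = 1). Adding k * Hg to the density
#' partially straightens candidate boundaries along y0.
#'
#' @param grid a [build_smoothed_histogram()] result.
#' @param q gravity level in `[0, 1]`.
#' @return list of class `"gravity_field"`: `q`, `y0`, `Hg` (N x N matrix,
#'   constant along x), `start_row` (1-based y bin containing y0).
#' @export
gravity_potential <- function(grid, q) {
  stopifnot(q >= 0, q <= 1)
  n <- grid$N
  y0 <- q  # unit coordinates: y_min -> 0, y_max -> 1
  centers <- (seq_len(n) - 0.5) / n
  hg_col <- (centers - y0)^2
  structure(
    list(q = q, y0 = y0,
         Hg = matrix(hg_col, nrow = n, ncol = n),
         start_row = min(as.integer(floor(y0 * n)) + 1L, n)),
    class = "gravity_field"
  )
}

#' Coupling constant balancing density and gravity
#'
#' k = beta * (max(H) - min(H)) / max(Hg). Zero when the density is constant
#' (nothing to straighten against) or the gravity potential is identically
#' zero.
#'
#' @param grid a density grid.
#' @param field a [gravity_potential()] result.
#' @param beta gravity strength multiplier (>= 0; default 0.1, i.e. 10%
#'   gravity, which works well in practice).
#' @return scalar k >= 0.
#' @export
coupling_constant <- function(grid, field, beta = 0.1) {
  stopifnot(beta >= 0)
  rng <- max(grid$H) - min(grid$H)
  mg <- max(field$Hg)
  if (mg == 0 || rng == 0) return(0)
  beta * rng / mg
}

#' Gravity-augmented density H1 = H + k * Hg
#' @inheritParams coupling_constant
#' @return N x N matrix, elementwise >= H.
#' @export
combined_density <- function(grid, field, beta = 0.1) {
  k <- coupling_constant(grid, field, beta)
  grid$H + k * field$Hg
}

#' Minimum-cost extremal path across a grid by dynamic programming
#'
#' Finds the row sequence (one y bin per x column, left to right) that
#' minimises the column sum of `H1`, starting at `start_row` with per-column
#' row moves bounded by `step_limit`; the end row is free. This is the
#' discrete analogue of the variational extremal: a trajectory of least
#' integrated (gravity-augmented) density.
#'
#' @param H1 N x N cost matrix (rows = y bins, cols = x columns).
#' @param start_row 1-based starting row (the bin containing y0).
#' @param step_limit maximum |row change| between adjacent columns.
#' @return integer vector of N row indices; ties in cost are broken toward
#'   the row nearest `start_row`, then toward the lower row index.
#' @export
find_extremal_path <- function(H1, start_row, step_limit = 1L) {
  n <- nrow(H1)
  stopifnot(ncol(H1) == n, start_row >= 1L, start_row <= n)
  if (n == 1L) return(rep(1L, ncol(H1)))
  # backward value function: V[r, c] = cost of the best path from (r, c) on
  v <- matrix(0, n, n)
  v[, n] <- H1[, n]
  for (cc in (n - 1L):1L) {
    for (r in seq_len(n)) {
      lo <- max(1L, r - step_limit)
      hi <- min(n, r + step_limit)
      v[r, cc] <- H1[r, cc] + min(v[lo:hi, cc + 1L])
    }
  }
  rows <- integer(n)
  rows[1L] <- start_row
  for (cc in 2L:n) {
    prev <- rows[cc - 1L]
    cand <- max(1L, prev - step_limit):min(n, prev + step_limit)
    val <- v[cand, cc]
    best <- cand[val == min(val)]
    if (length(best) > 1L) {
      d <- abs(best - start_row)
      best <- best[d == min(d)]
      best <- min(best)  # remaining tie: lower row index
    }
    rows[cc] <- best
  }
  rows
}

#' Action of a boundary path: integrated raw density along the path
#'
#' S = (1/N) * sum_c H[rows[c], c], evaluated on the raw smoothed density H
#' (not the gravity-augmented H1): the gravity term guides the path search
#' but must not contaminate the valley score.
#'
#' @param grid a density grid.
#' @param rows integer vector of N row indices (a path).
#' @return scalar S >= 0.
#' @export
path_action <- function(grid, rows) {
  n <- grid$N
  stopifnot(length(rows) == n)
  sum(grid$H[cbind(rows, seq_len(n))]) / n
}

#' Scan gravity levels and keep boundaries at local minima of the action
#'
#' For each q on the lattice `{0, dq, 2 dq, ..., 1}` this builds the gravity
#' field, solves the extremal path, and records the action S(q). Only strict
#' interior local minima, S(q - dq) > S(q) < S(q + dq), are returned: those
#' q0 mark true density valleys. A monotone action profile yields an empty
#' candidate list.
#'
#' @param grid a density grid.
#' @param beta gravity multiplier (default 0.1).
#' @param dq lattice step in `(0, 1)` (default 0.1).
#' @param step_limit DP move bound per column.
#' @return list of candidates, each a list `q0`, `rows` (path), `action`,
#'   `boundary_y` (bin-center ordinate per column, used for assignment);
#'   plus attribute `"scan"` with the full (q, S) table.
#' @export
scan_gravity_levels <- function(grid, beta = 0.1, dq = 0.1, step_limit = 1L) {
  stopifnot(dq > 0, dq < 1)
  qs <- seq(0, 1, by = dq)
  if (qs[length(qs)] < 1) qs <- c(qs, 1)
  m <- length(qs)
  s <- numeric(m)
  paths <- vector("list", m)
  for (i in seq_len(m)) {
    field <- gravity_potential(grid, qs[i])
    h1 <- grid$H + coupling_constant(grid, field, beta) * field$Hg
    paths[[i]] <- find_extremal_path(h1, field$start_row, step_limit)
    s[i] <- path_action(grid, paths[[i]])
  }
  keep <- which(vapply(seq_len(m), function(i) {
    i > 1L && i < m && s[i - 1L] > s[i] && s[i] < s[i + 1L]
  }, logical(1L)))
  out <- lapply(keep, function(i) {
    list(q0 = qs[i], rows = paths[[i]], action = s[i],
         boundary_y = (paths[[i]] - 0.5) / grid$N)
  })
  attr(out, "scan") <- data.frame(q = qs, S = s)
  out
}
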