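# Independent oracles and small fixture builders shared across tests.

# Exhaustive enumeration of all admissible paths (start fixed, end free,
# per-column row moves bounded by step_limit): the brute-force oracle for
# the dynamic-programming extremal search.
brute_force_path_cost <- function(H1, start_row, step_limit = 1L) {
  n <- nrow(H1)
  best <- Inf
  rec <- function(r, cc, cost) {
    cost <- cost + H1[r, cc]
    if (cc == n) {
      if (cost < best) best <<- cost
      return(invisible())
    }
    for (nr in max(1L, r - step_limit):min(n, r + step_limit)) {
      rec(nr, cc + 1L, cost)
    }
  }
  rec(start_row, 1L, 0)
  best
}

dp_path_cost <- function(H1, start_row, step_limit = 1L) {
  rows <- find_extremal_path(H1, start_row, step_limit)
  sum(H1[cbind(rows, seq_len(ncol(H1)))])
}

# Loop-based textbook Calinski-Harabasz for K groups, written independently
# of the package's vectorised implementation.
ch_oracle <- function(points, groups) {
  lv <- unique(groups)
  k <- length(lv)
  n <- nrow(points)
  c_all <- colMeans(points)
  b <- 0
  w <- 0
  for (g in lv) {
    p <- points[groups == g, , drop = FALSE]
    cg <- colMeans(p)
    b <- b + nrow(p) * sum((cg - c_all)^2)
    for (i in seq_len(nrow(p))) w <- w + sum((p[i, ] - cg)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# Brute-force maximum-overlap one-to-one assignment over all permutations
# (square contingency tables only).
brute_force_match_value <- function(tab) {
  stopifnot(nrow(tab) == ncol(tab))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(ncol(tab)))) {
    val <- sum(tab[cbind(seq_len(nrow(tab)), p)])
    if (val > best) best <- val
  }
  best
}

# Two well-separated 3D Gaussian blobs (>= 10 sd between means).
two_blob_data <- function(n_per = 200L, seed = 42L) {
  spec <- mixture_spec(means = rbind(c(0, 0, 0), c(12, 0, 0)),
                       scales = 1, n_total = 2L * n_per, seed = seed)
  make_blobs(spec)
}

# Mean intra-label minus mean inter-label pairwise distance (negated gap:
# larger value = tighter labels). Used to check label-aware embeddings.
intra_inter_gap <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(d[!same & !is.na(same)]) - mean(d[same & !is.na(same)])
}
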