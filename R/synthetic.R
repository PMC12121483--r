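# Synthetic mixture generators used to exercise the clustering and transfer
# pipelines: Gaussian blob mixtures, imbalanced mixtures with a rare
# population, and the uniform-hypercube empty-space demonstration.

#' Specify a Gaussian mixture of labelled components
#'
#' @param means numeric matrix, one row per component (component mean in d
#'   dimensions).
#' @param scales per-axis standard deviations: a single number, a vector of
#'   length d, or a matrix matching `means`.
#' @param proportions component mixing proportions (must sum to 1).
#' @param n_total total number of events.
#' @param seed RNG seed; generation is a pure function of spec + seed.
#' @return list of class `"mixture_spec"`.
#' @export
mixture_spec <- function(means, scales = 1, proportions = NULL,
                         n_total = 1000L, seed = 1L) {
  means <- as.matrix(means)
  k <- nrow(means)
  d <- ncol(means)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  stopifnot(length(proportions) == k, all(proportions > 0))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (is.matrix(scales)) {
    stopifnot(all(dim(scales) == dim(means)))
  } else {
    scales <- matrix(scales, nrow = k, ncol = d, byrow = TRUE)
  }
  stopifnot(all(scales > 0))
  counts <- allocate_counts(n_total, proportions)
  if (any(counts < 1L)) stop("every component needs proportion * n_total >= 1")
  structure(list(means = means, scales = scales, proportions = proportions,
                 n_total = as.integer(n_total), counts = counts,
                 d = d, k = k, seed = as.integer(seed)),
            class = "mixture_spec")
}

# Exact component allocation: floor each share, hand out the remainder
# round-robin by largest fractional part (ties to the earlier component).
# Deterministic sizes make test fixtures stable.
allocate_counts <- function(n_total, proportions) {
  raw <- n_total * proportions
  counts <- floor(raw)
  rem <- n_total - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    ord <- order(-frac, seq_along(frac))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Sample a labelled Gaussian mixture
#'
#' @param spec a [mixture_spec()].
#' @return list with `x` (n x d matrix) and `label` (0-based integer
#'   component IDs). Rows are grouped by component in spec order.
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  parts <- lapply(seq_len(spec$k), function(j) {
    nj <- spec$counts[j]
    sweep(matrix(stats::rnorm(nj * spec$d), nj, spec$d) *
            matrix(spec$scales[j, ], nj, spec$d, byrow = TRUE),
          2L, spec$means[j, ], "+")
  })
  list(x = do.call(rbind, parts),
       label = rep(seq_len(spec$k) - 1L, spec$counts))
}

#' Imbalanced mixture with a rare population separable along one axis
#'
#' The abundant mass is a standard Gaussian in all `d` dimensions; the rare
#' component overlaps it everywhere except along `sep_dim`, where its mean
#' sits `sep` standard deviations away, leaving a clear 1D density valley.
#' This is the regime where projection pursuit has the advantage: the rare
#' population is invisible to the joint high-dimensional density but cleanly
#' separated in one projection.
#'
#' @param abundant,rare event counts of the two components.
#' @param d dimensionality.
#' @param sep_dim the axis carrying the separation.
#' @param sep separation in standard-deviation units (default 8).
#' @param seed RNG seed.
#' @return list with `x` and `label` (0 = abundant, 1 = rare).
#' @export
make_rare_mixture <- function(abundant, rare, d = 7L, sep_dim = 1L,
                              sep = 8, seed = 1L) {
  stopifnot(rare >= 1, abundant >= 1, sep_dim >= 1, sep_dim <= d)
  set.seed(seed)
  xa <- matrix(stats::rnorm(abundant * d), abundant, d)
  xr <- matrix(stats::rnorm(rare * d), rare, d)
  xr[, sep_dim] <- xr[, sep_dim] + sep
  list(x = rbind(xa, xr),
       label = rep(c(0L, 1L), c(abundant, rare)))
}

#' Empty-space demonstration: mass of an inner hypercube
#'
#' Monte-Carlo estimate of the probability that a point uniform on
#' `[-1, 1]^d` satisfies `|x_i| <= t` for all axes, together with the closed
#' form `t^d`. In 10 dimensions with `t = 0.63` only about 1% of the data
#' falls in the inner cube — the sparsity that breaks local density
#' estimators in high dimensions.
#'
#' @param d dimensionality.
#' @param t inner cube half-width, in `(0, 1)`.
#' @param n Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return list with `estimate` (MC fraction), `exact` (`t^d`), `n`.
#' @export
hypercube_fraction <- function(d = 10L, t = 0.63, n = 1e6, seed = 1L) {
  stopifnot(t > 0, t < 1, d >= 1, n >= 1)
  set.seed(seed)
  inside <- rep(TRUE, n)
  for (j in seq_len(d)) {  # column-at-a-time keeps memory flat
    inside <- inside & (abs(stats::runif(n, -1, 1)) <= t)
  }
  list(estimate = mean(inside), exact = t^d, n = as.integer(n))
}
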