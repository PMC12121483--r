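# Evaluation metrics: misclassification after optimal label matching,
# per-cluster F1, mean silhouette, adjusted Rand.

# Translate predicted IDs through a matching (a cluster_matching object or a
# named vector pred -> truth); unmatched predictions become NA.
translate_labels <- function(pred, matching) {
  map <- if (inherits(matching, "cluster_matching")) matching$map else matching
  out <- unname(map[as.character(pred)])
  out
}

#' Total misclassification rate after label matching
#'
#' Fraction of events whose matched-and-translated predicted label differs
#' from the ground truth; events in unmatched predicted clusters count as
#' misclassified.
#'
#' @param pred,truth aligned label vectors.
#' @param matching a [match_cluster_labels()] result (computed from
#'   `pred`/`truth` when omitted).
#' @return scalar rate in `[0, 1]`.
#' @export
total_misclassification <- function(pred, truth, matching = NULL) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  if (is.null(matching)) matching <- match_cluster_labels(pred, truth)
  tr <- translate_labels(pred, matching)
  mean(is.na(tr) | tr != truth)
}

#' Per-cluster F1 after label matching
#'
#' Standard harmonic mean of precision and recall for each ground-truth
#' cluster against its matched predicted cluster; truth clusters with no
#' match get F1 = 0.
#'
#' @inheritParams total_misclassification
#' @return list with `f1` (named per-truth-cluster vector) and `macro`
#'   (unweighted mean).
#' @export
f1_per_cluster <- function(pred, truth, matching = NULL) {
  if (is.null(matching)) matching <- match_cluster_labels(pred, truth)
  tr <- translate_labels(pred, matching)
  lv <- sort(unique(truth))
  f1 <- vapply(lv, function(g) {
    tp <- sum(!is.na(tr) & tr == g & truth == g)
    fp <- sum(!is.na(tr) & tr == g & truth != g)
    fn <- sum(truth == g) - tp
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1L))
  names(f1) <- lv
  list(f1 = f1, macro = mean(f1))
}

#' Mean silhouette coefficient of a labelling
#'
#' Mean of `(b - a) / max(a, b)` over events, with `a` the mean Euclidean
#' distance to the event's own cluster and `b` the smallest mean distance to
#' any other cluster. Events in singleton clusters contribute 0. Above
#' `max_n` events a fixed-seed subsample is scored instead (the full
#' pairwise-distance matrix is quadratic in n).
#'
#' @param x numeric matrix of coordinates in the clustered space.
#' @param ids cluster labels (at least 2 distinct).
#' @param max_n subsample cap (default 10000).
#' @param seed subsampling seed.
#' @return scalar mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, ids, max_n = 10000L, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(ids)) < 2L) stop("silhouette needs at least 2 clusters")
  n <- nrow(x)
  if (n > max_n) {
    set.seed(seed)
    keep <- sort(sample.int(n, max_n))
    x <- x[keep, , drop = FALSE]
    ids <- ids[keep]
    n <- max_n
  }
  d <- as.matrix(stats::dist(x))
  f <- factor(ids)
  lv <- levels(f)
  # mean distance from every event to every cluster, via group column sums
  sums <- rowsum(t(d), f)                    # |levels| x n
  cnt <- as.vector(table(f))
  s <- vapply(seq_len(n), function(i) {
    gi <- as.integer(f[i])
    if (cnt[gi] == 1L) return(0)
    a <- sums[gi, i] / (cnt[gi] - 1L)
    others <- sums[, i] / cnt
    b <- min(others[-gi])
    (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to relabelling), about 0 for independent ones.
#'
#' @param a,b aligned label vectors.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == e) return(1)  # degenerate: both partitions trivial
  (sij - e) / (mx - e)
}
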