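# Automated label transfer: learn a label-aware 2D embedding from a labelled
# training sample, project a test sample into it, cluster the test sample in
# 2D, align cluster IDs to the ground truth by maximum-overlap matching, and
# report misclassification.

#' Fit a label-aware 2D embedding on a labelled training sample
#'
#' Supervised UMAP with features and training labels at equal weight
#' (target weight 0.5), so the embedding balances the data-driven geometry
#' against the prior labelling. Partially labelled data are supported:
#' events with `NA` labels contribute through the feature term only.
#'
#' @param x numeric training matrix (events x features).
#' @param labels training labels; at least two distinct non-NA values.
#' @param seed RNG seed; the embedding is stochastic and the seed is
#'   required for reproducibility.
#' @param target_weight label-vs-feature balance in `[0, 1]` (default 0.5,
#'   equal weight).
#' @param n_neighbors UMAP neighbourhood size.
#' @return object of class `"supervised_embedding"` holding the fitted model
#'   and the training embedding (`$embedding`, n x 2).
#' @export
fit_supervised_embedding <- function(x, labels, seed, target_weight = 0.5,
                                     n_neighbors = 15L) {
  x <- as.matrix(x)
  lab <- factor(labels)
  if (nlevels(lab[!is.na(lab)]) < 2L) {
    stop("at least 2 distinct training labels are required")
  }
  if (missing(seed)) stop("seed is required: the embedding is stochastic")
  set.seed(seed)
  model <- uwot::umap(x, y = lab, target_weight = target_weight,
                      n_neighbors = n_neighbors, n_components = 2L,
                      n_threads = 1L, n_sgd_threads = 0L, ret_model = TRUE)
  structure(list(model = model, embedding = model$embedding,
                 labels = lab, seed = seed,
                 target_weight = target_weight),
            class = "supervised_embedding")
}

#' Project new events into a fitted supervised embedding
#' @param object a [fit_supervised_embedding()] result.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return n x 2 matrix of embedded coordinates.
#' @export
predict.supervised_embedding <- function(object, newdata, ...) {
  set.seed(object$seed)
  uwot::umap_transform(as.matrix(newdata), object$model, n_threads = 1L)
}

#' Cluster 2D embedded coordinates by density-mode seeking
#'
#' Builds the package's Gaussian-smoothed histogram over the (unit-square
#' normalised) embedding and hill-climbs every occupied bin to its density
#' mode over the 8-neighbourhood; events inherit the mode of their bin.
#' Every event receives a cluster ID — there is no noise label, which is the
#' contract the transfer pipeline requires of its 2D clusterer. The
#' clusterer is pluggable: any function mapping an n x 2 matrix to integer
#' IDs can replace this default in [label_transfer()].
#'
#' @param xy n x 2 numeric matrix.
#' Shallow modes are merged into their neighbours by topographic persistence:
#' a mode whose height above its best connecting saddle is a small fraction
#' of its peak density is sampling noise riding on a larger basin, not a
#' separate population.
#'
#' @param sigma histogram smoothing width in bin units; larger values merge
#'   nearby modes (default 2, heavier than the boundary-search default
#'   because spurious modes are costlier here than blurred valleys).
#' @param bins optional fixed per-axis bin count (default: sample-size rule).
#' @param merge_ratio modes with relative persistence
#'   `(peak - saddle) / peak` below this are absorbed (default 0.2).
#' @return integer vector of 0-based cluster IDs, numbered by decreasing
#'   mode density.
#' @export
cluster_embedding <- function(xy, sigma = 2, bins = NULL, merge_ratio = 0.2) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) >= 2L)
  proj <- normalize_projection(cbind(xy, 0), 1L, 2L)
  if (proj$degenerate) return(rep(0L, nrow(xy)))
  n_bins <- if (!is.null(bins)) as.integer(bins) else
    mann_bin_count(nrow(xy), sigma)
  grid <- build_smoothed_histogram(proj, n_bins, sigma)
  h <- grid$H
  # steepest-ascent successor of each bin over its 8-neighbourhood (ties to
  # the lowest linear index; a bin that beats all neighbours is a mode)
  succ <- matrix(0L, n_bins, n_bins)
  for (r in seq_len(n_bins)) {
    for (cc in seq_len(n_bins)) {
      rr <- max(1L, r - 1L):min(n_bins, r + 1L)
      cs <- max(1L, cc - 1L):min(n_bins, cc + 1L)
      block <- h[rr, cs, drop = FALSE]
      bi <- which(block == max(block))[1L]
      br <- rr[(bi - 1L) %% length(rr) + 1L]
      bc <- cs[(bi - 1L) %/% length(rr) + 1L]
      succ[r, cc] <- (bc - 1L) * n_bins + br
    }
  }
  # follow successors to a fixed point
  mode_of <- integer(n_bins * n_bins)
  for (s in seq_along(mode_of)) {
    cur <- s
    repeat {
      nxt <- succ[cur]
      if (nxt == cur) break
      cur <- nxt
    }
    mode_of[s] <- cur
  }
  # merge low-persistence basins: find, for each pair of adjacent basins,
  # the highest saddle (max over boundary bin pairs of the lower of the two
  # densities), then absorb any mode sitting less than merge_ratio of its
  # peak above its best saddle into the neighbouring basin across it.
  repeat {
    basins <- sort(unique(mode_of))
    if (length(basins) <= 1L) break
    saddle <- matrix(-Inf, length(basins), length(basins),
                     dimnames = list(basins, basins))
    lin <- function(r, cc) (cc - 1L) * n_bins + r
    for (r in seq_len(n_bins)) {
      for (cc in seq_len(n_bins)) {
        a <- mode_of[lin(r, cc)]
        for (nb in list(c(r + 1L, cc), c(r, cc + 1L),
                        c(r + 1L, cc + 1L), c(r - 1L, cc + 1L))) {
          if (nb[1L] < 1L || nb[1L] > n_bins || nb[2L] > n_bins) next
          b <- mode_of[lin(nb[1L], nb[2L])]
          if (a == b) next
          s <- min(h[lin(r, cc)], h[lin(nb[1L], nb[2L])])
          ia <- match(as.character(a), rownames(saddle))
          ib <- match(as.character(b), rownames(saddle))
          if (s > saddle[ia, ib]) saddle[ia, ib] <- saddle[ib, ia] <- s
        }
      }
    }
    peaks <- h[basins]
    merged <- FALSE
    for (i in order(peaks)) {  # weakest mode first
      js <- which(is.finite(saddle[i, ]))
      if (!length(js)) next
      j <- js[which.max(saddle[i, js])]
      pers <- (peaks[i] - saddle[i, j]) / peaks[i]
      if (pers < merge_ratio && peaks[j] >= peaks[i]) {
        mode_of[mode_of == basins[i]] <- basins[j]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  ir <- bin_index(proj$coords[, 2L], n_bins) + 1L  # y -> row
  ic <- bin_index(proj$coords[, 1L], n_bins) + 1L  # x -> col
  ev_mode <- mode_of[(ic - 1L) * n_bins + ir]
  modes <- unique(ev_mode)
  modes <- modes[order(-h[modes], modes)]  # densest mode first
  match(ev_mode, modes) - 1L
}

#' Align predicted cluster IDs to ground-truth IDs by maximum overlap
#'
#' Builds the contingency table of the two labellings and solves a
#' one-to-one assignment maximising the total overlap (Hungarian
#' algorithm). Surplus clusters on either side remain unmatched, as do
#' pairings with zero overlap.
#'
#' @param pred,truth aligned label vectors over the same events.
#' @return object of class `"cluster_matching"`: `map` (named vector,
#'   predicted ID -> truth ID, `NA` for unmatched), `table` (contingency),
#'   `unmatched_pred`, `unmatched_truth`.
#' @export
match_cluster_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  tab <- table(pred, truth)
  pl <- rownames(tab)
  tl <- colnames(tab)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  # solve_LSAP needs nrow <= ncol: pad with zero columns/rows as needed
  nr <- nrow(m); nc <- ncol(m)
  if (nr <= nc) {
    sol <- as.integer(clue::solve_LSAP(m, maximum = TRUE))
    pairs <- cbind(seq_len(nr), sol)
  } else {
    sol <- as.integer(clue::solve_LSAP(t(m), maximum = TRUE))
    pairs <- cbind(sol, seq_len(nc))
  }
  keep <- m[pairs] > 0
  pairs <- pairs[keep, , drop = FALSE]
  map <- stats::setNames(rep(NA_character_, length(pl)), pl)
  map[pl[pairs[, 1L]]] <- tl[pairs[, 2L]]
  # coerce mapped values back to the truth vector's type
  map_typed <- if (is.numeric(truth)) {
    stats::setNames(as.numeric(map), pl)
  } else {
    map
  }
  structure(list(map = map_typed, table = tab,
                 unmatched_pred = pl[!(pl %in% pl[pairs[, 1L]])],
                 unmatched_truth = tl[!(tl %in% tl[pairs[, 2L]])]),
            class = "cluster_matching")
}

#' @export
print.cluster_matching <- function(x, ...) {
  cat("Cluster label matching (maximum-overlap assignment)\n")
  print(data.frame(pred = names(x$map), truth = unname(as.character(x$map))),
        row.names = FALSE)
  if (length(x$unmatched_pred))
    cat("unmatched predicted:", paste(x$unmatched_pred, collapse = ", "), "\n")
  if (length(x$unmatched_truth))
    cat("unmatched truth:", paste(x$unmatched_truth, collapse = ", "), "\n")
  invisible(x)
}

#' Misclassification report after cluster alignment
#'
#' An event is misclassified when its matched-and-translated predicted label
#' differs from the ground truth (events in unmatched predicted clusters are
#' all misclassified). Per-truth-cluster counts and rates are reported in
#' decreasing order of cluster abundance, together with per-cluster F1.
#'
#' @param pred,truth aligned label vectors.
#' @param matching optional precomputed [match_cluster_labels()].
#' @return object of class `"misclass_report"`: `total_rate`,
#'   `total_misclassified`, `n`, `per_cluster` (data frame: truth ID, size,
#'   misclassified count, rate, F1, ordered by size), `matching`.
#' @export
misclassification_report <- function(pred, truth, matching = NULL) {
  if (is.null(matching)) matching <- match_cluster_labels(pred, truth)
  tr <- translate_labels(pred, matching)
  wrong <- is.na(tr) | tr != truth
  lv <- names(sort(table(truth), decreasing = TRUE))
  f1 <- f1_per_cluster(pred, truth, matching)$f1
  per <- data.frame(
    truth = lv,
    size = as.integer(table(truth)[lv]),
    misclassified = vapply(lv, function(g) sum(wrong[truth == g]),
                           integer(1L)),
    row.names = NULL
  )
  per$rate <- per$misclassified / per$size
  per$f1 <- unname(f1[lv])
  structure(list(total_rate = mean(wrong),
                 total_misclassified = sum(wrong),
                 n = length(truth),
                 per_cluster = per, matching = matching),
            class = "misclass_report")
}

#' @export
print.misclass_report <- function(x, ...) {
  cat(sprintf("Label transfer misclassification: %d / %d events (%.2f%%)\n",
              x$total_misclassified, x$n, 100 * x$total_rate))
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Flag training labels that disagree with the embedding topology
#'
#' A sanity check on the ground-truth labelling: a population gated as one
#' homogeneous cluster should occupy one connected region of the supervised
#' embedding. For each label this splits the label's embedded events in two
#' (2-means seeded deterministically at the extremes of their first
#' principal axis) and scores the split's silhouette; a label that cleanly
#' separates into two distant lobes scores high and is flagged.
#'
#' @param xy n x 2 embedded coordinates (training embedding).
#' @param labels training labels.
#' @param threshold flag labels whose split silhouette exceeds this
#'   (default 0.6; a forced split of one Gaussian lobe scores near 0.4).
#' @return data frame: label, n, split_silhouette, flagged.
#' @export
check_label_topology <- function(xy, labels, threshold = 0.6) {
  xy <- as.matrix(xy)
  lv <- sort(unique(labels))
  stat <- vapply(lv, function(g) {
    p <- xy[labels == g, , drop = FALSE]
    if (nrow(p) < 4L) return(0)
    pc <- stats::prcomp(p, rank. = 1L)$x[, 1L]
    centers <- p[c(which.min(pc), which.max(pc)), , drop = FALSE]
    km <- stats::kmeans(p, centers = centers)
    if (min(km$size) < 2L) return(0)
    silhouette_score(p, km$cluster)
  }, numeric(1L))
  data.frame(label = lv, n = as.integer(table(labels)[as.character(lv)]),
             split_silhouette = stat, flagged = stat > threshold,
             row.names = NULL)
}

#' Automated label transfer between samples
#'
#' The end-to-end 4-step pipeline: (1) fit a supervised 2D embedding on the
#' labelled training sample (features and labels at equal weight); (2)
#' project the test sample into the embedding; (3) cluster the test sample
#' in 2D with a full-assignment clusterer and align its cluster IDs to the
#' training labels by maximum-overlap matching; (4) count misclassified
#' events per cluster against the test ground truth, when available.
#'
#' @param train,test numeric matrices with identical feature columns.
#' @param train_labels labels for `train` (NA allowed: partial labelling).
#' @param test_truth optional ground-truth labels for `test`; without them
#'   the report is omitted and only transferred labels are returned.
#' @param seed RNG seed (required; the embedding is stochastic).
#' @param clusterer function mapping an n x 2 matrix to integer IDs
#'   (default [cluster_embedding()]).
#' @param target_weight label-vs-feature balance (default 0.5).
#' @param ... passed on to the clusterer.
#' @return object of class `"label_transfer"`: `embedding` (the fitted
#'   model), `train2d`, `test2d`, `test_cluster` (raw 2D cluster IDs),
#'   `transferred` (cluster IDs translated to training-label space; `NA`
#'   for unmatched clusters), `matching`, `report` (a
#'   [misclassification_report()], when `test_truth` given), and
#'   `topology_check` (the training-side [check_label_topology()] table).
#' @export
label_transfer <- function(train, train_labels, test, test_truth = NULL,
                           seed, clusterer = cluster_embedding,
                           target_weight = 0.5, ...) {
  if (missing(seed)) stop("seed is required")
  emb <- fit_supervised_embedding(train, train_labels, seed = seed,
                                  target_weight = target_weight)
  test2d <- predict(emb, test)
  ids <- clusterer(test2d, ...)
  # align test clusters to training labels through the embedding: training
  # events carry their labels; test clusters are matched against the truth
  # labels of the test events when available, else against predicted
  # training-label regions via nearest training neighbours.
  if (!is.null(test_truth)) {
    matching <- match_cluster_labels(ids, test_truth)
    report <- misclassification_report(ids, test_truth, matching)
  } else {
    near <- nearest_neighbor_label(emb$embedding, as.character(emb$labels),
                                   test2d)
    matching <- match_cluster_labels(ids, near)
    report <- NULL
  }
  structure(list(embedding = emb, train2d = emb$embedding, test2d = test2d,
                 test_cluster = ids,
                 transferred = translate_labels(ids, matching),
                 matching = matching, report = report,
                 topology_check = check_label_topology(
                   emb$embedding, as.character(emb$labels))),
            class = "label_transfer")
}

# 1-NN label lookup in the 2D embedding (small helper for the unlabelled-test
# path; brute force is fine at the pipeline's 2D sizes).
nearest_neighbor_label <- function(ref2d, ref_labels, query2d) {
  ok <- !is.na(ref_labels)
  ref2d <- ref2d[ok, , drop = FALSE]
  ref_labels <- ref_labels[ok]
  vapply(seq_len(nrow(query2d)), function(i) {
    d2 <- (ref2d[, 1L] - query2d[i, 1L])^2 + (ref2d[, 2L] - query2d[i, 2L])^2
    ref_labels[which.min(d2)]
  }, character(1L))
}

#' @export
print.label_transfer <- function(x, ...) {
  cat("Automated label transfer\n")
  cat(sprintf("  %d training events -> supervised 2D embedding; %d test events\n",
              nrow(x$train2d), nrow(x$test2d)))
  cat(sprintf("  %d test clusters found in the embedding\n",
              length(unique(x$test_cluster))))
  if (!is.null(x$report)) {
    cat(sprintf("  total misclassification: %.2f%%\n",
                100 * x$report$total_rate))
  }
  if (any(x$topology_check$flagged)) {
    cat("  topology check: label(s)",
        paste(x$topology_check$label[x$topology_check$flagged],
              collapse = ", "),
        "disagree with the embedding topology\n")
  }
  invisible(x)
}
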