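#' Automated projection pursuit clustering
#'
#' Recursively partitions a numeric event matrix by scanning every orthogonal
#' 2D projection for a minimum-density decision boundary and splitting along
#' the boundary with the highest Calinski-Harabasz score. A branch becomes a
#' final cluster when it holds fewer than `2 * min_cluster_size` events or
#' when no projection offers a boundary leaving at least `min_cluster_size`
#' events on each side.
#'
#' @param x numeric matrix or data frame, events in rows, at least two
#'   feature columns, all values finite.
#' @param min_cluster_size the single required parameter: the smallest
#'   population expected in the data. No final cluster is smaller.
#' @param sigma Gaussian smoothing width of the 2D density histogram, in bin
#'   units (default 1).
#' @param beta gravity strength multiplier (default 0.1, i.e. 10% gravity).
#' @param dq gravity-level scan step (default 0.1).
#' @param bins optional fixed per-axis bin count; when supplied it replaces
#'   the sample-size (Mann) rule entirely (e.g. 50 for large cytometry
#'   samples).
#' @param step_limit maximum per-column row move of the boundary path
#'   (default 1).
#' @param max_depth optional safety cap on recursion depth; the size rule
#'   alone already guarantees termination.
#' @param keep_data store `x` in the result (needed by [plot.app()]).
#'
#' @return An object of class `"app"`: a list with components
#'   \item{cluster}{integer vector of 0-based cluster IDs, one per row of
#'     `x`, numbered in depth-first discovery order (below side first).}
#'   \item{k}{number of clusters.}
#'   \item{sizes}{cluster sizes, ordered by ID.}
#'   \item{tree}{the recursive split record (nested list; internal nodes
#'     carry the projection dims, orientation, gravity level q0, CH score,
#'     boundary path and subset-local axis bounds).}
#'   \item{config}{the parameters used.}
#'   \item{data}{the input matrix, when `keep_data = TRUE`.}
#'
#' @details The algorithm is fully deterministic: repeated runs on the same
#'   input give identical labels. Ties between candidate boundaries are
#'   broken by (CH score, dimension pair in lexicographic order, orientation,
#'   lower gravity level).
#'
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200), ncol = 2),
#'            matrix(rnorm(200, mean = 12), ncol = 2))
#' fit <- app(x, min_cluster_size = 25)
#' table(fit$cluster)
#' @export
app <- function(x, min_cluster_size, sigma = 1, beta = 0.1, dq = 0.1,
                bins = NULL, step_limit = 1L, max_depth = Inf,
                keep_data = TRUE) {
  if (missing(min_cluster_size)) {
    stop("min_cluster_size is required (the smallest population you expect)")
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("at least 2 feature columns are required")
  if (any(!is.finite(x))) stop("all feature values must be finite")
  stopifnot(min_cluster_size >= 1, dq > 0, dq < 1, beta >= 0, sigma > 0)
  config <- list(min_cluster_size = as.integer(min_cluster_size),
                 sigma = sigma, beta = beta, dq = dq,
                 bins = if (is.null(bins)) NULL else as.integer(bins),
                 step_limit = as.integer(step_limit), max_depth = max_depth)

  labels <- integer(nrow(x))
  next_id <- 0L
  pairs <- utils::combn(ncol(x), 2L)

  recurse <- function(idx, depth) {
    n <- length(idx)
    make_leaf <- function() {
      id <- next_id
      next_id <<- next_id + 1L
      labels[idx] <<- id
      list(leaf = TRUE, id = id, size = n)
    }
    if (n < 2L * config$min_cluster_size || depth >= config$max_depth) {
      return(make_leaf())
    }
    sub <- x[idx, , drop = FALSE]
    best <- NULL
    for (p in seq_len(ncol(pairs))) {
      cand <- candidates_for_projection(sub, pairs[1L, p], pairs[2L, p],
                                        config)
      if (!is.null(cand) && (is.null(best) || cand$ch > best$ch)) best <- cand
    }
    if (is.null(best)) return(make_leaf())
    below_idx <- idx[best$below]
    above_idx <- idx[!best$below]
    node <- list(
      leaf = FALSE, size = n,
      dim_x = best$dim_x, dim_y = best$dim_y,
      orientation = best$orientation, q0 = best$q0, ch = best$ch,
      action = best$action, n_bins = best$n_bins,
      boundary_y = best$boundary_y,
      x_min = best$x_min, x_max = best$x_max,
      y_min = best$y_min, y_max = best$y_max,
      n_below = length(below_idx), n_above = length(above_idx)
    )
    node$below <- recurse(below_idx, depth + 1L)
    node$above <- recurse(above_idx, depth + 1L)
    node
  }

  tree <- recurse(seq_len(nrow(x)), 0L)
  out <- list(cluster = labels, k = next_id,
              sizes = as.integer(table(factor(labels, levels = 0:(next_id - 1L)))),
              tree = tree, config = config, call = match.call(),
              data = if (keep_data) x else NULL)
  class(out) <- "app"
  out
}

#' @export
print.app <- function(x, ...) {
  cat("Automated projection pursuit clustering\n")
  cat(sprintf("  %d events, %d clusters (min cluster size %d)\n",
              length(x$cluster), x$k, x$config$min_cluster_size))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.app <- function(object, ...) {
  splits <- list()
  walk <- function(node, depth) {
    if (node$leaf) return(invisible())
    splits[[length(splits) + 1L]] <<- data.frame(
      depth = depth, dim_x = node$dim_x, dim_y = node$dim_y,
      orientation = node$orientation, q0 = node$q0, ch = node$ch,
      n_below = node$n_below, n_above = node$n_above
    )
    walk(node$below, depth + 1L)
    walk(node$above, depth + 1L)
  }
  walk(object$tree, 0L)
  structure(list(k = object$k, sizes = object$sizes,
                 splits = do.call(rbind, splits),
                 config = object$config),
            class = "summary.app")
}

#' @export
print.summary.app <- function(x, ...) {
  cat(sprintf("APP clustering: %d clusters\n", x$k))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$splits)) {
    cat("splits (depth-first):\n")
    print(x$splits, row.names = FALSE)
  } else {
    cat("no splits (single cluster)\n")
  }
  invisible(x)
}

#' Assign new events to the clusters of a fitted APP model
#'
#' Routes each new event down the split tree: at every internal node the
#' event's two projection coordinates are rescaled with that node's stored
#' subset-local bounds (values outside the training range are clamped to the
#' unit square) and compared against the stored boundary path.
#'
#' @param object an `"app"` fit.
#' @param newdata numeric matrix with the same feature columns as the
#'   training data.
#' @param ... unused.
#' @return integer vector of 0-based cluster IDs.
#' @export
predict.app <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  route <- function(node, row) {
    if (node$leaf) return(node$id)
    u <- (row[node$dim_x] - node$x_min) / (node$x_max - node$x_min)
    v <- (row[node$dim_y] - node$y_min) / (node$y_max - node$y_min)
    u <- min(max(u, 0), 1)
    v <- min(max(v, 0), 1)
    below <- if (node$orientation == "x") {
      v <= node$boundary_y[bin_index(u, node$n_bins) + 1L]
    } else {
      u <= node$boundary_y[bin_index(v, node$n_bins) + 1L]
    }
    if (below) route(node$below, row) else route(node$above, row)
  }
  vapply(seq_len(nrow(newdata)), function(i) route(object$tree, newdata[i, ]),
         integer(1L))
}

#' Plot the first split of an APP fit
#'
#' Scatter plot of the projection chosen at the root split, colored by final
#' cluster ID, with the decision boundary overlaid.
#'
#' @param x an `"app"` fit created with `keep_data = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.app <- function(x, ...) {
  if (is.null(x$data)) stop("refit with keep_data = TRUE to plot")
  node <- x$tree
  if (node$leaf) {
    graphics::plot(x$data[, 1:2], col = x$cluster + 1L,
                   xlab = "dim 1", ylab = "dim 2", ...)
    return(invisible(x))
  }
  graphics::plot(x$data[, c(node$dim_x, node$dim_y)],
                 col = grDevices::hcl.colors(max(x$k, 2L), "Dark 3")[x$cluster + 1L],
                 xlab = paste("dim", node$dim_x),
                 ylab = paste("dim", node$dim_y), ...)
  centers <- (seq_len(node$n_bins) - 0.5) / node$n_bins
  if (node$orientation == "x") {
    bx <- node$x_min + centers * (node$x_max - node$x_min)
    by <- node$y_min + node$boundary_y * (node$y_max - node$y_min)
  } else {
    bx <- node$x_min + node$boundary_y * (node$x_max - node$x_min)
    by <- node$y_min + centers * (node$y_max - node$y_min)
  }
  graphics::lines(bx, by, lwd = 2)
  invisible(x)
}
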