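# Delimited-text event tables, label/tree writers, and the CLI entry points
# wrapped by the Rscript front ends under inst/cli/.

#' Read an event table from delimited text
#'
#' Reads a CSV or TSV (chosen by file extension, overridable) event table
#' into a numeric matrix with stable row order. Rows containing non-finite
#' feature values are dropped with a message stating how many.
#'
#' @param path file path.
#' @param feature_columns character vector of feature column names, or NULL
#'   for every numeric column except the label column.
#' @param label_column optional name of a ground-truth label column.
#' @param sep field separator; default inferred from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return list with `x` (numeric matrix), `label` (vector or NULL),
#'   `dropped` (number of excluded rows).
#' @export
read_events <- function(path, feature_columns = NULL, label_column = NULL,
                        sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty event table: ", path)
  if (!is.null(label_column) && !(label_column %in% names(df))) {
    stop("label column not found: ", label_column)
  }
  if (is.null(feature_columns)) {
    feature_columns <- setdiff(names(df)[vapply(df, is.numeric, logical(1L))],
                               label_column)
  } else {
    missing_cols <- setdiff(feature_columns, names(df))
    if (length(missing_cols)) {
      stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
    }
  }
  x <- as.matrix(df[, feature_columns, drop = FALSE])
  storage.mode(x) <- "double"
  ok <- rowSums(!is.finite(x)) == 0L
  if (any(!ok)) {
    message(sum(!ok), " row(s) with non-finite features excluded")
  }
  list(x = x[ok, , drop = FALSE],
       label = if (is.null(label_column)) NULL else df[[label_column]][ok],
       dropped = sum(!ok))
}

#' Write cluster labels as a single-column TSV aligned to input row order
#' @param labels integer vector of 0-based cluster IDs.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(cluster = labels), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the split tree of an APP fit as JSON
#' @param fit an `"app"` object.
#' @param path output file.
#' @export
write_split_tree <- function(fit, path) {
  stopifnot(inherits(fit, "app"))
  prune <- function(node) {
    if (node$leaf) {
      return(list(leaf = TRUE, id = node$id, size = node$size))
    }
    list(leaf = FALSE, size = node$size,
         dim_x = node$dim_x, dim_y = node$dim_y,
         orientation = node$orientation, q0 = node$q0, ch = node$ch,
         n_below = node$n_below, n_above = node$n_above,
         below = prune(node$below), above = prune(node$above))
  }
  jsonlite::write_json(prune(fit$tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

cli_fail <- function(msg) {
  message("error: ", msg)
  1L
}

#' Command-line clustering entry point
#'
#' Implements `app-cluster --input X.csv --min-cluster-size 100 --out
#' labels.tsv [--features a,b,c --tree tree.json --bins N --sigma S --beta B
#' --dq D --step-limit L --arcsinh COFACTOR --seed N --verbose]`. Invoked by
#' `inst/cli/app-cluster.R`; exposed as a function so the flag handling is
#' testable in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 on success).
#' @export
run_app_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--features", type = "character", default = NULL),
    optparse::make_option("--min-cluster-size", type = "integer",
                          dest = "min_cluster_size"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--tree", type = "character", default = NULL),
    optparse::make_option("--bins", type = "integer", default = NULL),
    optparse::make_option("--sigma", type = "double", default = 1),
    optparse::make_option("--beta", type = "double", default = 0.1),
    optparse::make_option("--dq", type = "double", default = 0.1),
    optparse::make_option("--step-limit", type = "integer", default = 1L,
                          dest = "step_limit"),
    optparse::make_option("--arcsinh", type = "double", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--verbose", action = "store_true", default = FALSE)
  )
  parsed <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = argv),
    error = function(e) NULL)
  if (is.null(parsed)) return(cli_fail("could not parse arguments"))
  if (is.null(parsed$input) || is.null(parsed$out)) {
    return(cli_fail("--input and --out are required"))
  }
  if (is.null(parsed$min_cluster_size)) {
    return(cli_fail("--min-cluster-size is required"))
  }
  res <- tryCatch({
    feats <- if (is.null(parsed$features)) NULL else
      strsplit(parsed$features, ",")[[1L]]
    ev <- read_events(parsed$input, feature_columns = feats)
    x <- ev$x
    if (!is.null(parsed$arcsinh)) x <- asinh(x / parsed$arcsinh)
    set.seed(parsed$seed)  # the fit is deterministic; seed kept for parity
    fit <- app(x, min_cluster_size = parsed$min_cluster_size,
               sigma = parsed$sigma, beta = parsed$beta, dq = parsed$dq,
               bins = parsed$bins, step_limit = parsed$step_limit,
               keep_data = FALSE)
    write_labels(fit$cluster, parsed$out)
    if (!is.null(parsed$tree)) write_split_tree(fit, parsed$tree)
    if (parsed$verbose) {
      message(sprintf("clustered %d events into %d clusters",
                      length(fit$cluster), fit$k))
    }
    0L
  }, error = function(e) cli_fail(conditionMessage(e)))
  res
}

#' Command-line label-transfer entry point
#'
#' Implements `app-transfer --train train.csv --train-labels col --test
#' test.csv --seed 7 --out report.json [--test-labels col --features a,b,c
#' --coords coords.csv]`. The JSON report carries the total and per-cluster
#' misclassification (when test ground truth is given), the matching, and
#' the topology check.
#'
#' @inheritParams run_app_cli
#' @return integer exit code.
#' @export
run_transfer_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- list(
    optparse::make_option("--train", type = "character"),
    optparse::make_option("--train-labels", type = "character",
                          dest = "train_labels"),
    optparse::make_option("--test", type = "character"),
    optparse::make_option("--test-labels", type = "character",
                          dest = "test_labels", default = NULL),
    optparse::make_option("--features", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--coords", type = "character", default = NULL)
  )
  parsed <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = argv),
    error = function(e) NULL)
  if (is.null(parsed)) return(cli_fail("could not parse arguments"))
  need <- c("train", "train_labels", "test", "out", "seed")
  for (f in need) {
    if (is.null(parsed[[f]])) {
      return(cli_fail(paste0("--", gsub("_", "-", f), " is required")))
    }
  }
  tryCatch({
    feats <- if (is.null(parsed$features)) NULL else
      strsplit(parsed$features, ",")[[1L]]
    tr <- read_events(parsed$train, feature_columns = feats,
                      label_column = parsed$train_labels)
    te <- read_events(parsed$test, feature_columns = colnames(tr$x),
                      label_column = parsed$test_labels)
    lt <- label_transfer(tr$x, tr$label, te$x, test_truth = te$label,
                         seed = parsed$seed)
    out <- list(
      n_train = nrow(tr$x), n_test = nrow(te$x),
      test_clusters = length(unique(lt$test_cluster)),
      matching = as.list(lt$matching$map),
      topology_check = lt$topology_check
    )
    if (!is.null(lt$report)) {
      out$total_misclassification <- lt$report$total_rate
      out$total_misclassified <- lt$report$total_misclassified
      out$per_cluster <- lt$report$per_cluster
    }
    jsonlite::write_json(out, parsed$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    if (!is.null(parsed$coords)) {
      utils::write.csv(data.frame(umap_x = lt$test2d[, 1L],
                                  umap_y = lt$test2d[, 2L],
                                  cluster = lt$test_cluster,
                                  transferred = lt$transferred),
                       parsed$coords, row.names = FALSE)
    }
    0L
  }, error = function(e) cli_fail(conditionMessage(e)))
}

#' Materialise the standard synthetic fixtures as CSV files
#'
#' Implements `make-fixtures --dir DIR [--seed N]`: writes the four-blob 3D
#' mixture, the rare-population mixture, and an 8-component labelled mixture
#' (train/test pair), each with a `label` column.
#'
#' @inheritParams run_app_cli
#' @return integer exit code.
#' @export
run_fixtures_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- list(
    optparse::make_option("--dir", type = "character"),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  parsed <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = argv),
    error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed$dir)) {
    return(cli_fail("--dir is required"))
  }
  tryCatch({
    dir.create(parsed$dir, showWarnings = FALSE, recursive = TRUE)
    save_one <- function(gen, name) {
      df <- data.frame(gen$x)
      names(df) <- paste0("f", seq_len(ncol(gen$x)))
      df$label <- gen$label
      utils::write.csv(df, file.path(parsed$dir, name), row.names = FALSE)
    }
    save_one(make_blobs(four_blob_spec(seed = parsed$seed)),
             "four_blobs.csv")
    save_one(make_rare_mixture(9800, 200, d = 7, sep_dim = 3,
                               seed = parsed$seed), "rare_mixture.csv")
    save_one(make_blobs(eight_component_spec(seed = parsed$seed)),
             "transfer_train.csv")
    save_one(make_blobs(eight_component_spec(seed = parsed$seed + 1L)),
             "transfer_test.csv")
    0L
  }, error = function(e) cli_fail(conditionMessage(e)))
}

#' Standard four-blob 3D mixture specification
#'
#' Four well-separated Gaussian components in 3D (10 standard deviations
#' between neighbouring means), 2000 events in equal proportions: the
#' canonical fixture on which the recursion should recover exactly four
#' clusters.
#'
#' @param n_total total events (default 2000).
#' @param seed RNG seed.
#' @return a [mixture_spec()].
#' @export
four_blob_spec <- function(n_total = 2000L, seed = 1L) {
  mixture_spec(
    means = rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 10)),
    scales = 1, n_total = n_total, seed = seed
  )
}

#' Standard 8-component labelled mixture for the transfer pipeline
#'
#' Eight unit-variance Gaussian components in 5 dimensions with at least 8
#' standard deviations between any two means, equal proportions.
#'
#' @param n_total total events (default 4000).
#' @param seed RNG seed.
#' @return a [mixture_spec()].
#' @export
eight_component_spec <- function(n_total = 4000L, seed = 1L) {
  means <- rbind(
    c(0, 0, 0, 0, 0), c(8, 0, 0, 0, 0), c(0, 8, 0, 0, 0), c(0, 0, 8, 0, 0),
    c(0, 0, 0, 8, 0), c(0, 0, 0, 0, 8), c(8, 8, 0, 0, 0), c(0, 0, 8, 8, 0)
  )
  mixture_spec(means = means, scales = 1, n_total = n_total, seed = seed)
}
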