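# Smaller mixtures than the end-to-end acceptance run keep these unit tests
# fast; the UMAP fits dominate the runtime.

three_blob_train <- function(seed = 100L, n = 600L) {
  make_blobs(mixture_spec(
    means = rbind(c(0, 0, 0, 0), c(10, 0, 0, 0), c(0, 10, 0, 0)),
    scales = 1, n_total = n, seed = seed
  ))
}

test_that("the supervised embedding separates labelled components", {
  tr <- three_blob_train(seed = 100L)
  emb <- fit_supervised_embedding(tr$x, tr$label, seed = 1)
  expect_identical(ncol(emb$embedding), 2L)
  expect_gte(silhouette_score(emb$embedding, tr$label), 0.5)
  # same-label events are closer on average than different-label events
  expect_gt(intra_inter_gap(emb$embedding, tr$label), 0)
  expect_error(fit_supervised_embedding(tr$x, rep(1, nrow(tr$x)), seed = 1),
               "2 distinct")
  expect_error(fit_supervised_embedding(tr$x, tr$label), "seed")
})

test_that("embedding topology is reproducible under a fixed seed", {
  tr <- three_blob_train(seed = 101L, n = 300L)
  e1 <- fit_supervised_embedding(tr$x, tr$label, seed = 9)
  e2 <- fit_supervised_embedding(tr$x, tr$label, seed = 9)
  d1 <- as.vector(dist(e1$embedding))
  d2 <- as.vector(dist(e2$embedding))
  expect_gte(cor(d1, d2, method = "spearman"), 0.95)
  # transform of new points is deterministic for a fixed fitted model
  q <- three_blob_train(seed = 102L, n = 90L)
  expect_equal(predict(e1, q$x), predict(e1, q$x), tolerance = 1e-12)
})

test_that("shuffled training labels destroy the intra/inter distance gap", {
  tr <- three_blob_train(seed = 103L, n = 300L)
  emb <- fit_supervised_embedding(tr$x, tr$label, seed = 2)
  gap_true <- intra_inter_gap(emb$embedding, tr$label)
  set.seed(11)
  shuffled <- sample(tr$label)
  emb_s <- fit_supervised_embedding(tr$x, shuffled, seed = 2)
  gap_shuf <- intra_inter_gap(emb_s$embedding, shuffled)
  expect_lt(gap_shuf, 0.5 * gap_true)
})

test_that("the 2D mode-seeking clusterer assigns every event, never noise", {
  set.seed(20)
  xy <- rbind(matrix(rnorm(400, sd = 0.5), ncol = 2),
              matrix(rnorm(400, mean = 15, sd = 0.5), ncol = 2))
  ids <- cluster_embedding(xy)
  expect_identical(length(ids), 400L)
  expect_false(anyNA(ids))
  expect_true(all(ids >= 0L))
  expect_identical(sort(unique(ids)), 0:1)
  # each side pure
  expect_identical(length(unique(ids[1:200])), 1L)
  expect_identical(length(unique(ids[201:400])), 1L)

  # a single blob collapses to one mode
  one <- matrix(rnorm(600), ncol = 2)
  expect_identical(unique(cluster_embedding(one)), 0L)
})

test_that("maximum-overlap matching recovers permutations and flags surplus", {
  truth <- rep(0:2, each = 50)
  renamed <- c(2L, 0L, 1L)[truth + 1L]
  m <- match_cluster_labels(renamed, truth)
  expect_identical(unname(m$map[c("2", "0", "1")]), c(0, 1, 2))
  expect_equal(total_misclassification(renamed, truth, m), 0)
  expect_length(m$unmatched_pred, 0L)

  # brute-force optimum on random square contingency tables
  set.seed(314)
  for (i in 1:30) {
    k <- sample(2:4, 1L)
    pred <- sample(seq_len(k), 120, replace = TRUE)
    tru <- sample(seq_len(k), 120, replace = TRUE)
    mm <- match_cluster_labels(pred, tru)
    tab <- table(pred, tru)
    got <- sum(vapply(names(mm$map)[!is.na(mm$map)], function(p) {
      tab[p, as.character(mm$map[[p]])]
    }, numeric(1L)))
    expect_equal(got, brute_force_match_value(tab))
  }

  # an extra predicted cluster stays unmatched
  pred <- truth
  pred[1:10] <- 7L
  m2 <- match_cluster_labels(pred, truth)
  expect_identical(m2$unmatched_pred, "7")
  expect_output(print(m2), "unmatched predicted: 7")
})

test_that("misclassification reports tally per cluster and in total", {
  truth <- rep(0:1, each = 100)
  pred <- truth
  pred[c(1:10, 101:110)] <- 1 - pred[c(1:10, 101:110)]
  rep_ <- misclassification_report(pred, truth)
  expect_equal(rep_$total_rate, 0.10)
  expect_identical(rep_$total_misclassified, 20L)
  expect_identical(sum(rep_$per_cluster$misclassified),
                   rep_$total_misclassified)
  expect_true(all(rep_$per_cluster$rate >= 0 & rep_$per_cluster$rate <= 1))
  # abundance ordering
  expect_true(!is.unsorted(rev(rep_$per_cluster$size)))
  expect_output(print(rep_), "10.00%")

  perfect <- misclassification_report(truth, truth)
  expect_equal(perfect$total_rate, 0)
  expect_true(all(perfect$per_cluster$f1 == 1))
})

test_that("label transfer works end to end on a labelled mixture", {
  tr <- three_blob_train(seed = 104L)
  te <- three_blob_train(seed = 105L)
  lt <- label_transfer(tr$x, tr$label, te$x, test_truth = te$label, seed = 5)
  expect_s3_class(lt, "label_transfer")
  expect_lte(lt$report$total_rate, 0.01)
  expect_false(anyNA(lt$test_cluster))
  expect_output(print(lt), "test clusters")
  # no topology complaints for clean labels
  expect_false(any(lt$topology_check$flagged))

  # unlabelled test path still returns transferred labels
  lt2 <- label_transfer(tr$x, tr$label, te$x, seed = 5)
  expect_null(lt2$report)
  expect_lte(mean(lt2$transferred != te$label), 0.01)
})

test_that("labels contradicting the topology are flagged", {
  tr <- three_blob_train(seed = 106L)
  lab <- tr$label
  lab[lab == 2L] <- 0L  # one "population" spans two separated blobs
  emb <- fit_supervised_embedding(tr$x, lab, seed = 3)
  chk <- check_label_topology(emb$embedding, as.character(lab))
  expect_true(chk$flagged[chk$label == "0"])
  expect_false(any(chk$flagged[chk$label != "0"]))
})
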