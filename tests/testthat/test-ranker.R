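rand_feature_lists <- function(n_lists, n_items, labeller, seed) {
  set.seed(seed)
  lapply(seq_len(n_lists), function(i) {
    X <- matrix(stats::runif(n_items * 11), n_items, 11,
                dimnames = list(sprintf("D%03d", seq_len(n_items)),
                                feature_schema()))
    list(features = X, labels = labeller(X))
  })
}

ndcg10 <- function(model, lists) {
  mean(vapply(lists, function(l) {
    s <- predict_lambdamart(model, l$features)
    ndcg_at(l$labels[order(-s, seq_along(s))], 10)
  }, 0))
}

test_that("ndcg_at matches hand values and the exhaustive-permutation property", {
  expect_equal(ndcg_at(c(1, 0, 0), 3), 1)
  expect_equal(ndcg_at(c(0, 1), 2), 1 / log2(3), tolerance = 1e-12)
  expect_equal(ndcg_at(c(0, 0), 2), 1)
  expect_equal(ndcg_at(numeric(0)), 1)
  # every binary labelling of lists up to length 6: range and "1 iff ideal"
  for (n in 2:6) {
    grid <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (r in seq_len(nrow(grid))) {
      lab <- as.numeric(grid[r, ])
      v <- ndcg_at(lab)
      expect_gte(v, 0); expect_lte(v, 1)
      ideal <- identical(sort(lab, decreasing = TRUE), lab) || sum(lab) == 0
      expect_identical(v == 1, ideal)
    }
  }
})

test_that("lambda gradients: single-pair case, zero cases and the swap oracle", {
  # two items, equal scores: rho = 1/2, |dNDCG| = (1 - 1/log2(3)) / 1
  gr <- lambda_gradients(c(0, 0), c(1, 0))
  cval <- 0.5 * (1 - 1 / log2(3))
  expect_equal(gr$lambdas, c(cval, -cval), tolerance = 1e-12)
  expect_equal(gr$hessians, rep(0.25 * (1 - 1 / log2(3)), 2),
               tolerance = 1e-12)
  expect_identical(lambda_gradients(c(1, 2), c(1, 1))$lambdas, c(0, 0))
  expect_identical(lambda_gradients(c(1, 2), c(0, 0))$lambdas, c(0, 0))

  # brute-force swap-recomputation oracle on random 6-item lists
  for (seed in 1:6) {
    set.seed(seed)
    scores <- stats::rnorm(6)
    labels <- stats::rbinom(6, 1, 0.4)
    got <- lambda_gradients(scores, labels, sigma = 1)
    expect_equal(sum(got$lambdas), 0, tolerance = 1e-12)

    ord <- order(-scores, seq_along(scores))
    lab_ord <- labels[ord]
    base_ndcg <- ndcg_at(lab_ord)
    lam <- numeric(6)
    for (i in which(labels == 1)) for (j in which(labels == 0)) {
      pi <- which(ord == i); pj <- which(ord == j)
      swapped <- lab_ord
      swapped[c(pi, pj)] <- swapped[c(pj, pi)]
      delta <- abs(ndcg_at(swapped) - base_ndcg)
      rho <- 1 / (1 + exp(scores[i] - scores[j]))
      lam[i] <- lam[i] + rho * delta
      lam[j] <- lam[j] - rho * delta
    }
    expect_equal(got$lambdas, lam, tolerance = 1e-10)
  }
})

test_that("boosting masters a single separating feature and ignores constants", {
  lists <- rand_feature_lists(25, 12, function(X)
    as.integer(X[, 3] > 0.5), seed = 5)
  # make one feature constant: no split can ever use it
  lists <- lapply(lists, function(l) {
    l$features[, 5] <- 0.7
    l
  })
  model <- train_lambdamart(lists, n_trees = 50, max_leaves = 10,
                            learning_rate = 0.1)
  expect_equal(ndcg10(model, lists), 1)
  split_feats <- unlist(lapply(model$trees, function(nodes)
    vapply(nodes, function(nd) if (nd$is_leaf) NA_integer_ else nd$feature,
           1L)))
  expect_false(5L %in% split_feats)
  # scores invariant under a strictly monotone transform of the unused feature
  lists2 <- lapply(lists, function(l) {
    l$features[, 5] <- exp(l$features[, 5]) + 3
    l
  })
  expect_equal(lapply(lists2, function(l) predict_lambdamart(model, l$features)),
               lapply(lists, function(l) predict_lambdamart(model, l$features)))
})

test_that("training NDCG is non-decreasing (with plateaus) on synthetic lists", {
  lists <- rand_feature_lists(15, 10, function(X)
    as.integer(X[, 1] + X[, 2] > 1), seed = 9)
  model <- train_lambdamart(lists, n_trees = 40, max_leaves = 8,
                            learning_rate = 0.1)
  expect_true(all(diff(model$train_ndcg) >= -1e-6))
})

test_that("held-out ranking of a noiseless two-feature signal is near-perfect", {
  labeller <- function(X) as.integer(X[, 1] + X[, 2] > 1)
  train <- rand_feature_lists(60, 12, labeller, seed = 101)
  test <- rand_feature_lists(30, 12, labeller, seed = 202)
  model <- train_lambdamart(train, n_trees = 80, max_leaves = 10,
                            learning_rate = 0.1)
  expect_gte(ndcg10(model, test), 0.95)
})

test_that("degenerate training data and schema mismatches are rejected", {
  lists <- rand_feature_lists(3, 5, function(X) rep(1L, nrow(X)), seed = 3)
  expect_error(train_lambdamart(lists, n_trees = 2), "degenerate")
  ok <- rand_feature_lists(4, 6, function(X) as.integer(X[, 2] > 0.5),
                           seed = 4)
  model <- train_lambdamart(ok, n_trees = 3)
  bad <- ok[[1]]$features
  colnames(bad)[1] <- "renamed"
  expect_error(predict_lambdamart(model, bad), "schema")
})

test_that("score_candidates orders by score with lexicographic ties and survives edges", {
  ok <- rand_feature_lists(4, 6, function(X) as.integer(X[, 2] > 0.5),
                           seed = 7)
  model <- train_lambdamart(ok, n_trees = 5)
  X <- ok[[1]]$features
  pred <- score_candidates(model, X, doc_id = "docX")
  expect_identical(pred$rank, seq_len(nrow(X)))
  expect_true(all(diff(pred$score) <= 1e-12))
  # identical feature rows tie and fall back to descriptor id order
  X2 <- X[c(1, 1), , drop = FALSE]
  rownames(X2) <- c("DZZ", "DAA")
  pred2 <- score_candidates(model, X2)
  expect_identical(pred2$descriptor_id, c("DAA", "DZZ"))
  empty <- X[0, , drop = FALSE]
  expect_identical(nrow(score_candidates(model, empty)), 0L)
  single <- score_candidates(model, X[3, , drop = FALSE])
  expect_identical(single$rank, 1L)
})

test_that("training is deterministic and models round-trip through JSON", {
  lists <- rand_feature_lists(10, 8, function(X) as.integer(X[, 4] > 0.6),
                              seed = 11)
  m1 <- train_lambdamart(lists, n_trees = 12, max_leaves = 6)
  m2 <- train_lambdamart(lists, n_trees = 12, max_leaves = 6)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ranker(m1, p1); write_ranker(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_ranker(p1)
  X <- lists[[1]]$features
  expect_equal(predict_lambdamart(back, X), predict_lambdamart(m1, X),
               tolerance = 1e-12)
})
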