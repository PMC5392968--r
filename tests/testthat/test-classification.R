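test_that("modified Huber loss matches its piecewise definition", {
  expect_identical(huber_loss(1), 0)
  expect_identical(huber_loss(-1), 4)
  expect_identical(huber_loss(0), 1)
  expect_identical(huber_loss(-2), 8)
  expect_identical(huber_loss(3), 0)
  z <- seq(-4, 4, by = 0.01)
  h <- huber_loss(z)
  expect_true(all(h >= 0))
  expect_true(all((h == 0) == (z >= 1)))        # zero iff margin >= 1
  # continuity at the breakpoints
  expect_equal(huber_loss(-1 + 1e-9), 4, tolerance = 1e-6)
  expect_equal(huber_loss(1 - 1e-9), 0, tolerance = 1e-6)
  # convexity on a grid: midpoint below chord
  for (i in seq(1, length(z) - 20, by = 7)) {
    a <- z[i]; b <- z[i + 20]
    expect_lte(huber_loss((a + b) / 2), (huber_loss(a) + huber_loss(b)) / 2 + 1e-12)
  }
})

test_that("the cost function evaluates the printed formula", {
  zero <- mk_label_model("L", w = stats::setNames(numeric(0), character(0)))
  x <- list(c(t1 = 1), c(t2 = 1))
  y <- c(1, -1)
  # lambda * 0 / 2 + C+ h(0) + C- h(0) = 1.5 + 1.0
  expect_equal(svm_cost(zero, x, y, svm_config()), 2.5)
  # doubling C- adds exactly the negative-sum contribution again
  c1 <- svm_cost(zero, x, y, svm_config(c_minus = 1))
  c2 <- svm_cost(zero, x, y, svm_config(c_minus = 2, cost_ratio_r = 0.75))
  expect_equal(c2 - c1, 1)   # same C+ (1.5), negative part 1 -> 2
  # perfectly separated data with margins >= 1 and no regularization
  m <- mk_label_model("L", w = c(sig = 2), theta = -1)
  xs <- list(c(sig = 1), c(oth = 1))
  expect_equal(svm_cost(m, xs, c(1, -1), svm_config(reg_lambda = 0)), 0)
})

make_separable <- function(n_pos = 12, n_neg = 30, seed = 4) {
  set.seed(seed)
  pool <- sprintf("w%02d", 1:15)
  docs <- c(
    lapply(seq_len(n_pos), function(i)
      mk_pdoc(c("sigtok", sample(pool, 5, TRUE)), sprintf("p%02d", i))),
    lapply(seq_len(n_neg), function(i)
      mk_pdoc(sample(pool, 6, TRUE), sprintf("n%02d", i))))
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  gold <- lapply(docs, function(d)
    if (startsWith(d$doc_id, "p")) "LBL" else character())
  list(docs = docs, gold = gold)
}

test_that("SGD reaches perfect training accuracy on separable data and is seed-deterministic", {
  d <- make_separable()
  cfg <- svm_config(epochs = 25, seed = 9)
  m <- train_label_model("LBL", d$docs, d$gold, cfg)
  scores <- vapply(d$docs, predict_score, 0, model = m)
  truth <- startsWith(names(d$docs), "p")
  expect_identical(unname(scores > 0), unname(truth))
  m2 <- train_label_model("LBL", d$docs, d$gold, cfg)
  expect_identical(m, m2)
  # single-class data errors, naming the label
  empty_gold <- lapply(d$gold, function(g) character())
  expect_error(train_label_model("LBL", d$docs, empty_gold, cfg), "LBL")
})

test_that("full-batch training never increases the cost across epochs", {
  d <- make_separable(seed = 6)
  cfg0 <- svm_config(seed = 2)
  y <- ifelse(startsWith(names(d$docs), "p"), 1, -1)
  x <- lapply(d$docs, doc_features)
  costs <- vapply(c(1, 3, 6, 12), function(ep) {
    m <- train_label_model("LBL", d$docs, d$gold,
                           svm_config(epochs = ep, seed = 2),
                           method = "batch")
    svm_cost(m, x, y, cfg0)
  }, 0)
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("the analytic cost gradient matches finite differences", {
  d <- make_separable(n_pos = 5, n_neg = 8, seed = 13)
  x <- lapply(d$docs, doc_features)
  y <- ifelse(startsWith(names(d$docs), "p"), 1, -1)
  cfg <- svm_config(reg_lambda = 0.05)
  tokens <- sort(unique(unlist(lapply(x, names))))
  set.seed(31)
  w <- stats::setNames(stats::rnorm(length(tokens), sd = 0.3), tokens)
  theta <- 0.2
  model <- mk_label_model("LBL", w, theta)
  margins <- function(w, theta) y * (theta + vapply(x, function(xi)
    sum(w[names(xi)] * xi), 0))
  hgrad <- function(z) ifelse(z <= -1, -4, ifelse(z < 1, -2 * (1 - z), 0))
  cy <- ifelse(y > 0, cfg$c_plus, cfg$c_minus)
  g <- cy * hgrad(margins(w, theta)) * y
  grad_w <- cfg$reg_lambda * w
  for (i in seq_along(x))
    grad_w[names(x[[i]])] <- grad_w[names(x[[i]])] + g[i] * x[[i]]
  grad_theta <- sum(g)
  eps <- 1e-6
  for (tk in sample(tokens, 6)) {
    wp <- w; wp[tk] <- wp[tk] + eps
    wm <- w; wm[tk] <- wm[tk] - eps
    fd <- (svm_cost(mk_label_model("LBL", wp, theta), x, y, cfg) -
           svm_cost(mk_label_model("LBL", wm, theta), x, y, cfg)) / (2 * eps)
    expect_equal(unname(grad_w[tk]), fd, tolerance = 1e-5)
  }
  fd_t <- (svm_cost(mk_label_model("LBL", w, theta + eps), x, y, cfg) -
           svm_cost(mk_label_model("LBL", w, theta - eps), x, y, cfg)) / (2 * eps)
  expect_equal(grad_theta, fd_t, tolerance = 1e-5)
})

test_that("raising the cost ratio r does not lose positive-class recall", {
  # imbalanced, noisy data: the marker token is only probabilistically present
  set.seed(17)
  pool <- sprintf("w%02d", 1:20)
  n_pos <- 15; n_neg <- 150
  docs <- c(
    lapply(seq_len(n_pos), function(i) {
      toks <- sample(pool, 8, TRUE)
      if (stats::runif(1) < 0.7) toks <- c(toks, "marker")
      mk_pdoc(toks, sprintf("p%03d", i))
    }),
    lapply(seq_len(n_neg), function(i) {
      toks <- sample(pool, 8, TRUE)
      if (stats::runif(1) < 0.1) toks <- c(toks, "marker")
      mk_pdoc(toks, sprintf("n%03d", i))
    }))
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  gold <- lapply(docs, function(d)
    if (startsWith(d$doc_id, "p")) "LBL" else character())
  recalls <- vapply(c(1, 1.5, 3, 10), function(r) {
    m <- train_label_model("LBL", docs, gold,
                           svm_config(cost_ratio_r = r, epochs = 15,
                                      seed = 3, neg_cap_ratio = Inf),
                           method = "batch")
    pos_scores <- vapply(docs[startsWith(names(docs), "p")],
                         predict_score, 0, model = m)
    mean(pos_scores > 0)
  }, 0)
  expect_true(all(diff(recalls) >= -0.08))   # monotone trend, small tolerance
  expect_gte(recalls[4], recalls[1])
})

test_that("train_all trains every frequent label with positives and reports skips", {
  spec <- fixture_spec(n_docs = 60, seed = 5)
  vocab <- make_vocabulary(spec)
  corpus <- make_corpus(spec, vocab)
  pdocs <- preprocess_corpus(corpus)
  gold <- lapply(corpus, `[[`, "gold_terms")
  vocab <- set_label_frequencies(vocab, corpus)
  cfg <- svm_config(epochs = 4, seed = 8)
  battery <- train_all(pdocs, gold, vocab, n_labels = 50, cfg)
  used <- sort(unique(unlist(gold)))
  expect_setequal(c(names(battery$models), battery$skipped$label),
                  names(vocab$descriptors))
  expect_setequal(battery$skipped$label, setdiff(names(vocab$descriptors), used))
  # per-label streams: the battery model equals the individually trained one
  lb <- names(battery$models)[1]
  solo <- train_label_model(lb, pdocs, gold, cfg)
  expect_identical(battery$models[[lb]], solo)
})

test_that("classifier batteries round-trip through the directory artifact", {
  d <- make_separable()
  m <- train_label_model("LBL", d$docs, d$gold, svm_config(epochs = 5))
  battery <- mk_battery(list(m))
  dir <- withr::local_tempdir()
  write_classifiers(battery, dir)
  back <- read_classifiers(dir)
  expect_equal(back$models$LBL$w, m$w)
  expect_equal(back$models$LBL$theta, m$theta)
})
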