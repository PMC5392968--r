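# Per-label cost-sensitive linear classifiers (candidate source #2).
# One binary model per frequent label, minimizing
#   lambda/2 ||w||^2 + C+ sum_{y=+1} h(y(theta + w.x))
#                    + C- sum_{y=-1} h(y(theta + w.x))
# with h the modified Huber loss and C+ = r * C- (r = 1.5 by default) to
# counter the dominance of negative examples.

#' Modified Huber loss
#'
#' Piecewise loss: `-4 z` for `z <= -1`; `(1 - z)^2` for `-1 < z < 1`;
#' `0` for `z >= 1`. Continuous and convex, quadratic near the margin and
#' linear for large negative margins (robust to label noise).
#'
#' @param z numeric vector of margins `y * (theta + w . x)`.
#' @return non-negative numeric vector.
#' @export
huber_loss <- function(z) {
  ifelse(z <= -1, -4 * z, ifelse(z < 1, (1 - z)^2, 0))
}

.huber_grad <- function(z) {
  ifelse(z <= -1, -4, ifelse(z < 1, -2 * (1 - z), 0))
}

#' Classifier training configuration
#'
#' @param reg_lambda L2 regularization strength (lambda in the cost
#'   function).
#' @param cost_ratio_r ratio r with `C+ = r * C-`; the reference setting
#'   is 1.5.
#' @param c_minus misclassification cost of the negative class.
#' @param epochs SGD passes over the training set.
#' @param learning_rate initial SGD step size (decayed as
#'   `eta0 / (1 + eta0 * reg_lambda * t)`, the inverse-t schedule).
#' @param neg_cap_ratio cap on sampled negatives as a multiple of the
#'   positive count (`Inf` disables subsampling).
#' @param seed base seed; each label derives its own stream from it so
#'   results do not depend on training order.
#' @return an `svm_config` list.
#' @export
svm_config <- function(reg_lambda = 1e-4, cost_ratio_r = 1.5, c_minus = 1.0,
                       epochs = 20, learning_rate = 0.5,
                       neg_cap_ratio = 10, seed = 1) {
  stopifnot(reg_lambda >= 0, cost_ratio_r > 0, c_minus > 0, epochs >= 1,
            learning_rate > 0, neg_cap_ratio > 0)
  structure(list(reg_lambda = reg_lambda, cost_ratio_r = cost_ratio_r,
                 c_minus = c_minus, c_plus = cost_ratio_r * c_minus,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 schedule = "inv-t", neg_cap_ratio = neg_cap_ratio,
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' L2-normalized term-frequency features of a document
#'
#' @param pdoc a `processed_doc`.
#' @return named numeric vector (unit L2 norm; empty for empty docs).
#' @export
doc_features <- function(pdoc) {
  x <- as.numeric(pdoc$tf)
  names(x) <- names(pdoc$tf)
  nrm <- sqrt(sum(x^2))
  if (nrm > 0) x / nrm else x
}

#' Cost function of a label model on labelled data
#'
#' Evaluates `lambda/2 ||w||^2 + C+ sum_{y=+1} h(z) + C- sum_{y=-1} h(z)`
#' with `z = y (theta + w . x)`.
#'
#' @param model a `label_model` (see [train_label_model()]).
#' @param x list of named numeric feature vectors.
#' @param y labels in `{-1, +1}`.
#' @param cfg an [svm_config()].
#' @return non-negative scalar.
#' @export
svm_cost <- function(model, x, y, cfg = svm_config()) {
  stopifnot(all(y %in% c(-1, 1)), length(x) == length(y))
  z <- y * vapply(x, function(xi) {
    model$theta + sum(model$w[names(xi)] * xi, na.rm = TRUE)
  }, 0)
  h <- huber_loss(z)
  cfg$reg_lambda / 2 * sum(model$w^2) +
    cfg$c_plus * sum(h[y == 1]) + cfg$c_minus * sum(h[y == -1])
}

# deterministic small hash of a string, for order-independent per-label seeds
.str_seed <- function(s, base_seed) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 1000003
  as.integer((base_seed + h) %% .Machine$integer.max)
}

# internal: docs as index/value pairs over a shared token vector
.cls_data <- function(pdocs) {
  tokens <- sort(unique(unlist(lapply(pdocs, function(p) names(p$tf)),
                               use.names = FALSE)))
  docs <- lapply(pdocs, function(p) {
    x <- doc_features(p)
    list(idx = match(names(x), tokens), val = unname(x))
  })
  list(tokens = tokens, docs = docs,
       doc_ids = vapply(pdocs, `[[`, "", "doc_id"))
}

.sgd_fit <- function(data, sel, y, cfg) {
  nw <- length(data$tokens)
  w <- numeric(nw)
  scale <- 1            # lazily applied L2 shrinkage: effective w = scale * w
  theta <- 0
  eta0 <- cfg$learning_rate
  lam <- cfg$reg_lambda
  t <- 0L
  n <- length(sel)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      t <- t + 1L
      eta <- eta0 / (1 + eta0 * lam * t)
      d <- data$docs[[sel[i]]]
      z <- y[i] * (theta + scale * sum(w[d$idx] * d$val))
      if (lam > 0) {
        scale <- scale * (1 - eta * lam)
        if (scale < 1e-9) { w <- w * scale; scale <- 1 }
      }
      if (z < 1) {
        cy <- if (y[i] > 0) cfg$c_plus else cfg$c_minus
        coef <- eta * cy * .huber_grad(z) * y[i]
        w[d$idx] <- w[d$idx] - coef * d$val / scale
        theta <- theta - coef
      }
    }
  }
  list(w = w * scale, theta = theta)
}

.batch_fit <- function(data, sel, y, cfg) {
  nw <- length(data$tokens)
  w <- numeric(nw)
  theta <- 0
  docs <- data$docs[sel]
  cy <- ifelse(y > 0, cfg$c_plus, cfg$c_minus)
  cost_at <- function(w, theta) {
    z <- y * (theta + vapply(docs, function(d) sum(w[d$idx] * d$val), 0))
    cfg$reg_lambda / 2 * sum(w^2) + sum(cy * huber_loss(z))
  }
  step <- cfg$learning_rate
  cur <- cost_at(w, theta)
  for (ep in seq_len(cfg$epochs)) {
    z <- y * (theta + vapply(docs, function(d) sum(w[d$idx] * d$val), 0))
    g <- cy * .huber_grad(z) * y
    gw <- cfg$reg_lambda * w
    for (i in seq_along(docs))
      if (g[i] != 0) gw[docs[[i]]$idx] <- gw[docs[[i]]$idx] + g[i] * docs[[i]]$val
    gt <- sum(g)
    repeat {                       # backtracking: never increase the cost
      nw2 <- w - step * gw
      nt2 <- theta - step * gt
      nxt <- cost_at(nw2, nt2)
      if (nxt <= cur || step < 1e-12) break
      step <- step / 2
    }
    if (nxt <= cur) { w <- nw2; theta <- nt2; cur <- nxt }
  }
  list(w = w, theta = theta)
}

#' Train one label's cost-sensitive classifier
#'
#' Minimizes the class-weighted modified-Huber cost by stochastic gradient
#' descent (default) or deterministic full-batch gradient descent with
#' backtracking (`method = "batch"`). Features are L2-normalized stemmed
#' unigram counts. Deterministic given the seed.
#'
#' @param label descriptor id being trained; positives are the documents
#'   annotated with it.
#' @param pdocs named list of `processed_doc` (training documents).
#' @param gold named list: doc_id -> character vector of gold descriptor
#'   ids.
#' @param cfg an [svm_config()].
#' @param method `"sgd"` or `"batch"`.
#' @param subsample_negatives logical; cap negatives at
#'   `neg_cap_ratio * n_positives` (seeded per label).
#' @return object of class `label_model`: `descriptor_id`, `w` (named
#'   sparse weights, zero entries dropped), `theta`.
#' @export
train_label_model <- function(label, pdocs, gold, cfg = svm_config(),
                              method = c("sgd", "batch"),
                              subsample_negatives = TRUE) {
  method <- match.arg(method)
  data <- .cls_data(pdocs)
  ids <- data$doc_ids
  pos <- which(vapply(ids, function(i) label %in% gold[[i]], TRUE))
  neg <- setdiff(seq_along(ids), pos)
  if (!length(pos) || !length(neg))
    stop("label ", label, ": needs at least one positive and one negative example")
  set.seed(.str_seed(label, cfg$seed))
  if (subsample_negatives && is.finite(cfg$neg_cap_ratio)) {
    cap <- ceiling(cfg$neg_cap_ratio * length(pos))
    if (length(neg) > cap) neg <- sort(sample(neg, cap))
  }
  sel <- c(pos, neg)
  y <- c(rep(1, length(pos)), rep(-1, length(neg)))
  perm <- sample.int(length(sel))      # mix classes before epoch shuffling
  sel <- sel[perm]; y <- y[perm]
  fit <- switch(method,
                sgd = .sgd_fit(data, sel, y, cfg),
                batch = .batch_fit(data, sel, y, cfg))
  keep <- fit$w != 0
  structure(list(descriptor_id = label,
                 w = stats::setNames(fit$w[keep], data$tokens[keep]),
                 theta = fit$theta),
            class = "label_model")
}

#' Decision score of a label model on a document
#'
#' Returns `theta + w . x` with x the L2-normalized tf vector; positive
#' scores classify the label as present. Scores are retained downstream as
#' ranking features.
#'
#' @param model a `label_model`.
#' @param pdoc a `processed_doc`.
#' @return numeric scalar.
#' @export
predict_score <- function(model, pdoc) {
  x <- doc_features(pdoc)
  common <- intersect(names(x), names(model$w))
  model$theta + sum(model$w[common] * x[common])
}

#' Train classifiers for the most frequent labels
#'
#' Trains one model per label among the `n_labels` most frequently
#' annotated descriptors (the reference configuration uses the 20,000 most
#' frequent headings, the remaining ones being rarely used). Labels with
#' no positive (or no negative) training document are skipped and
#' reported. Each label's sampling stream is derived from its id, so the
#' result is independent of training order or worker count.
#'
#' @param pdocs named list of `processed_doc`.
#' @param gold named list doc_id -> gold descriptor ids.
#' @param vocab a `mesh_vocabulary` with populated label frequencies.
#' @param n_labels number of frequent labels to train.
#' @param cfg an [svm_config()].
#' @param method passed to [train_label_model()].
#' @return object of class `classifier_battery`: `models` (named list of
#'   `label_model`), `skipped` (data.frame label/reason), `config`.
#' @export
train_all <- function(pdocs, gold, vocab, n_labels, cfg = svm_config(),
                      method = "sgd") {
  labels <- top_frequent_labels(vocab, n_labels)
  n_pos <- vapply(labels, function(lb)
    sum(vapply(gold[names(pdocs)], function(g) lb %in% g, TRUE)), 0)
  models <- list()
  skipped <- data.frame(label = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (n_pos[i] == 0) {
      skipped <- rbind(skipped, data.frame(label = lb, reason = "no positives"))
      next
    }
    if (n_pos[i] == length(pdocs)) {
      skipped <- rbind(skipped, data.frame(label = lb, reason = "no negatives"))
      next
    }
    models[[lb]] <- train_label_model(lb, pdocs, gold, cfg, method = method)
  }
  structure(list(models = models, skipped = skipped, config = cfg),
            class = "classifier_battery")
}

#' @export
print.classifier_battery <- function(x, ...) {
  cat("classifier_battery:", length(x$models), "models,",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}

#' Persist a classifier battery as a directory artifact
#'
#' One sparse-weight TSV per label (`<label>.tsv`: token, weight) plus a
#' `manifest.json` holding thetas, the skip list and the configuration.
#'
#' @param battery a `classifier_battery`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_classifiers <- function(battery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lb in names(battery$models)) {
    m <- battery$models[[lb]]
    con <- file.path(dir, paste0(lb, ".tsv"))
    writeLines(c("token\tweight",
                 sprintf("%s\t%.17g", names(m$w), unname(m$w))), con)
  }
  manifest <- list(
    labels = names(battery$models),
    theta = lapply(battery$models, `[[`, "theta"),
    skipped = battery$skipped,
    config = unclass(battery$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a classifier battery written by [write_classifiers()]
#'
#' @param dir directory path.
#' @return a `classifier_battery` (without the original training data).
#' @export
read_classifiers <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  models <- lapply(mf$labels, function(lb) {
    tab <- utils::read.delim(file.path(dir, paste0(lb, ".tsv")),
                             colClasses = c("character", "numeric"))
    structure(list(descriptor_id = lb,
                   w = stats::setNames(tab$weight, tab$token),
                   theta = mf$theta[[lb]]),
              class = "label_model")
  })
  names(models) <- mf$labels
  skipped <- if (length(mf$skipped)) as.data.frame(mf$skipped)
             else data.frame(label = character(), reason = character())
  structure(list(models = models, skipped = skipped, config = mf$config),
            class = "classifier_battery")
}
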