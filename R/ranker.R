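# LambdaMART learning to rank: gradient-boosted limited-depth regression
# trees driven by NDCG-weighted pairwise lambda gradients, with Newton-step
# leaf values. Candidate lists {M_1..M_N} carry binary relevance labels
# (y = 1 iff the descriptor was manually assigned to the document).

#' Normalized discounted cumulative gain at k
#'
#' Gain `2^label - 1`, discount `1/log2(position + 1)`, normalized by the
#' ideal DCG. 1 when every relevant item precedes every irrelevant one;
#' defined as 1 for lists with no relevant item (empty-ideal convention).
#'
#' @param ranking labels (0/1) in ranked order.
#' @param k truncation depth (defaults to the list length).
#' @return numeric in `[0, 1]`.
#' @export
ndcg_at <- function(ranking, k = length(ranking)) {
  if (!length(ranking)) return(1)
  stopifnot(k >= 1)
  g <- 2^ranking - 1
  disc <- 1 / log2(seq_along(ranking) + 1)
  kk <- min(k, length(ranking))
  dcg <- sum((g * disc)[seq_len(kk)])
  ideal <- sum((sort(g, decreasing = TRUE) * disc)[seq_len(kk)])
  if (ideal == 0) 1 else dcg / ideal
}

#' Lambda gradients and hessians for one candidate list
#'
#' For every pair (i, j) with `label_i > label_j`:
#' `rho = 1 / (1 + exp(sigma (s_i - s_j)))`, and
#' `lambda_i += sigma * rho * |dNDCG_ij|`, `lambda_j -=` the same, where
#' `|dNDCG_ij|` is the NDCG change from swapping i and j in the ordering
#' induced by the current scores (ties broken by position). Hessians
#' accumulate `sigma^2 * rho (1 - rho) * |dNDCG_ij|`. Lambdas sum to zero
#' over a list; lists with all-equal labels yield zero vectors.
#'
#' @param scores current model scores.
#' @param labels 0/1 relevance labels (same length, >= 2).
#' @param sigma sigmoid steepness (default 1).
#' @return `list(lambdas, hessians)` of numeric vectors.
#' @export
lambda_gradients <- function(scores, labels, sigma = 1) {
  n <- length(scores)
  stopifnot(n == length(labels), n >= 2)
  lam <- numeric(n); hes <- numeric(n)
  pos <- which(labels > 0); neg <- which(labels == 0)
  if (!length(pos) || !length(neg))
    return(list(lambdas = lam, hessians = hes))
  r <- integer(n)
  r[order(-scores, seq_len(n))] <- seq_len(n)
  g <- 2^labels - 1
  disc <- 1 / log2(r + 1)
  idcg <- sum(sort(g, decreasing = TRUE) / log2(seq_len(n) + 1))
  if (idcg == 0) return(list(lambdas = lam, hessians = hes))
  sdiff <- outer(scores[pos], scores[neg], "-")
  rho <- 1 / (1 + exp(sigma * sdiff))
  delta <- abs(outer(g[pos], g[neg], "-") * outer(disc[pos], disc[neg], "-")) /
    idcg
  lam[pos] <- lam[pos] + sigma * rowSums(rho * delta)
  lam[neg] <- lam[neg] - sigma * colSums(rho * delta)
  h <- sigma^2 * rho * (1 - rho) * delta
  hes[pos] <- hes[pos] + rowSums(h)
  hes[neg] <- hes[neg] + colSums(h)
  list(lambdas = lam, hessians = hes)
}

# ---- regression trees -------------------------------------------------------

# best variance-reducing split of the rows of X[rows,]; ties broken by the
# lowest feature index, then the lowest threshold
.best_split <- function(X, target, rows, min_leaf_obs) {
  n <- length(rows)
  if (n < 2 * min_leaf_obs) return(NULL)
  y <- target[rows]
  total <- sum(y)
  base <- total^2 / n
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xv <- X[rows, f]
    ord <- order(xv)
    xs <- xv[ord]; ys <- y[ord]
    cs <- cumsum(ys)
    nl <- seq_len(n - 1)
    valid <- xs[-n] < xs[-1] & nl >= min_leaf_obs & (n - nl) >= min_leaf_obs
    if (!any(valid)) next
    gain <- cs[-n]^2 / nl + (total - cs[-n])^2 / (n - nl) - base
    gain[!valid] <- -Inf
    i <- which.max(gain)
    if (gain[i] <= 1e-12) next
    thr <- (xs[i] + xs[i + 1]) / 2
    if (is.null(best) || gain[i] > best$gain + 1e-12 ||
        (abs(gain[i] - best$gain) <= 1e-12 && thr < best$threshold)) {
      best <- list(feature = f, threshold = thr, gain = gain[i],
                   left = rows[ord[seq_len(i)]], right = rows[ord[-seq_len(i)]])
    }
  }
  best
}

# grow a tree best-first up to max_leaves; returns a node table
.fit_tree <- function(X, lambdas, hessians, max_leaves, min_leaf_obs) {
  nodes <- list(list(id = 1L, rows = seq_len(nrow(X)), is_leaf = TRUE,
                     feature = NA_integer_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_, value = 0))
  frontier <- list(list(id = 1L,
                        split = .best_split(X, lambdas, nodes[[1]]$rows,
                                            min_leaf_obs)))
  n_leaves <- 1L
  while (n_leaves < max_leaves) {
    gains <- vapply(frontier, function(fr)
      if (is.null(fr$split)) -Inf else fr$split$gain, 0)
    if (!length(gains) || all(!is.finite(gains))) break
    pick <- which.max(gains)
    fr <- frontier[[pick]]
    frontier <- frontier[-pick]
    sp <- fr$split
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[fr$id]]$is_leaf <- FALSE
    nodes[[fr$id]]$feature <- sp$feature
    nodes[[fr$id]]$threshold <- sp$threshold
    nodes[[fr$id]]$left <- lid
    nodes[[fr$id]]$right <- rid
    nodes[[lid]] <- list(id = lid, rows = sp$left, is_leaf = TRUE,
                         feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_, value = 0)
    nodes[[rid]] <- list(id = rid, rows = sp$right, is_leaf = TRUE,
                         feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_, value = 0)
    frontier <- c(frontier,
                  list(list(id = lid,
                            split = .best_split(X, lambdas, sp$left,
                                                min_leaf_obs)),
                       list(id = rid,
                            split = .best_split(X, lambdas, sp$right,
                                                min_leaf_obs))))
    n_leaves <- n_leaves + 1L
  }
  # Newton leaf values: sum(lambda) / sum(hessian)
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$is_leaf) {
      sl <- sum(lambdas[nodes[[i]]$rows])
      sh <- sum(hessians[nodes[[i]]$rows])
      nodes[[i]]$value <- if (sh > 1e-12) sl / sh else 0
      nodes[[i]]$rows <- NULL
    } else {
      nodes[[i]]$rows <- NULL
    }
  }
  nodes
}

.tree_predict <- function(nodes, X) {
  n <- nrow(X)
  out <- numeric(n)
  assign_node <- integer(n) + 1L
  todo <- list(list(id = 1L, rows = seq_len(n)))
  while (length(todo)) {
    cur <- todo[[1]]; todo <- todo[-1]
    node <- nodes[[cur$id]]
    if (node$is_leaf) {
      out[cur$rows] <- node$value
    } else {
      goleft <- X[cur$rows, node$feature] < node$threshold
      if (any(goleft))
        todo <- c(todo, list(list(id = node$left, rows = cur$rows[goleft])))
      if (any(!goleft))
        todo <- c(todo, list(list(id = node$right, rows = cur$rows[!goleft])))
    }
  }
  out
}

#' Train a LambdaMART ranking model
#'
#' Sequential gradient boosting: at each iteration the lambda gradients
#' and hessians of every training list are computed under the current
#' model, a limited-depth regression tree is fitted to the lambdas by
#' greedy variance-reduction splits, its leaf values are set by a Newton
#' step (`sum(lambda) / sum(hessian)`), and the tree is added with the
#' learning rate. Deterministic given the data (the seed is recorded in
#' the metadata; the reference defaults mirror common boosted-ranker
#' toolkit conventions).
#'
#' @param lists list of `list(features = <matrix with feature_schema()
#'   columns>, labels = <0/1 vector>)`; at least one list must contain
#'   both a positive and a negative label.
#' @param n_trees number of boosting rounds (default 300).
#' @param max_leaves maximum leaves per tree (default 10).
#' @param learning_rate shrinkage (default 0.1).
#' @param min_leaf_obs minimum observations per leaf (default 1).
#' @param sigma lambda sigmoid steepness.
#' @param seed recorded in metadata (training itself is deterministic).
#' @return object of class `lambdamart`: `trees`, `learning_rate`,
#'   `schema` (feature schema string), `meta`, `train_ndcg` (mean
#'   training NDCG trace).
#' @export
train_lambdamart <- function(lists, n_trees = 300, max_leaves = 10,
                             learning_rate = 0.1, min_leaf_obs = 1,
                             sigma = 1, seed = 1) {
  stopifnot(length(lists) >= 1, n_trees >= 1, max_leaves >= 2)
  mixed <- vapply(lists, function(l)
    any(l$labels > 0) && any(l$labels == 0), TRUE)
  if (!any(mixed))
    stop("degenerate training data: no list with both a positive and a negative label")
  schema <- feature_schema()
  for (l in lists)
    if (!identical(colnames(l$features), schema))
      stop("training features do not match the feature schema")
  X <- do.call(rbind, lapply(lists, `[[`, "features"))
  sizes <- vapply(lists, function(l) nrow(l$features), 0L)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  labels <- lapply(lists, `[[`, "labels")
  scores <- numeric(nrow(X))
  trees <- vector("list", n_trees)
  trace <- numeric(n_trees)
  for (tr in seq_len(n_trees)) {
    lam <- numeric(nrow(X)); hes <- numeric(nrow(X))
    for (li in seq_along(lists)) {
      if (sizes[li] < 2) next
      idx <- offsets[li] + seq_len(sizes[li])
      gr <- lambda_gradients(scores[idx], labels[[li]], sigma)
      lam[idx] <- gr$lambdas
      hes[idx] <- gr$hessians
    }
    nodes <- .fit_tree(X, lam, hes, max_leaves, min_leaf_obs)
    trees[[tr]] <- nodes
    scores <- scores + learning_rate * .tree_predict(nodes, X)
    trace[tr] <- mean(vapply(seq_along(lists), function(li) {
      idx <- offsets[li] + seq_len(sizes[li])
      ndcg_at(labels[[li]][order(-scores[idx], idx - offsets[li])])
    }, 0))
  }
  structure(list(trees = trees, learning_rate = learning_rate,
                 schema = feature_schema_hash(),
                 meta = list(n_trees = n_trees, max_leaves = max_leaves,
                             min_leaf_obs = min_leaf_obs, sigma = sigma,
                             seed = seed),
                 train_ndcg = trace),
            class = "lambdamart")
}

#' @export
print.lambdamart <- function(x, ...) {
  cat("lambdamart:", length(x$trees), "trees, learning rate",
      x$learning_rate, "\n")
  if (length(x$train_ndcg))
    cat("  final training NDCG:",
        sprintf("%.4f", x$train_ndcg[length(x$train_ndcg)]), "\n")
  invisible(x)
}

#' Score a feature matrix with a LambdaMART model
#'
#' @param model a `lambdamart`.
#' @param X numeric matrix with [feature_schema()] columns.
#' @return numeric scores (`sum learning_rate * tree(x)`).
#' @export
predict_lambdamart <- function(model, X) {
  if (!identical(colnames(X), feature_schema()) ||
      !identical(model$schema, feature_schema_hash()))
    stop("feature schema mismatch between model and input")
  s <- numeric(nrow(X))
  if (!nrow(X)) return(s)
  for (nodes in model$trees)
    s <- s + model$learning_rate * .tree_predict(nodes, X)
  s
}

#' Rank a candidate list
#'
#' Scores every candidate and returns the ordered prediction list
#' (non-increasing score, ties broken lexicographically by descriptor
#' id).
#'
#' @param model a `lambdamart`.
#' @param features numeric matrix (rownames = descriptor ids, columns =
#'   [feature_schema()]).
#' @param doc_id optional document id carried on the result.
#' @return a `prediction_list` data.frame: `rank`, `descriptor_id`,
#'   `score`.
#' @export
score_candidates <- function(model, features, doc_id = NA_character_) {
  s <- predict_lambdamart(model, features)
  ids <- rownames(features) %||% character(0)
  ord <- order(-s, ids)
  out <- data.frame(rank = seq_along(ord), descriptor_id = ids[ord],
                    score = s[ord], stringsAsFactors = FALSE)
  attr(out, "doc_id") <- doc_id
  class(out) <- c("prediction_list", "data.frame")
  out
}

.as_prediction_list <- function(ids, scores, doc_id = NA_character_) {
  ord <- order(-scores, ids)
  out <- data.frame(rank = seq_along(ord), descriptor_id = ids[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  attr(out, "doc_id") <- doc_id
  class(out) <- c("prediction_list", "data.frame")
  out
}

# ---- serialization ----------------------------------------------------------

#' Serialize a LambdaMART model to JSON
#'
#' Trees are written as flat node records (split feature/threshold or
#' leaf value) plus metadata and the feature schema string.
#'
#' @param model a `lambdamart`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranker <- function(model, path) {
  trees <- lapply(model$trees, function(nodes) {
    lapply(nodes, function(nd) {
      if (nd$is_leaf) list(leaf = TRUE, value = nd$value)
      else list(leaf = FALSE, feature = nd$feature,
                threshold = nd$threshold, left = nd$left, right = nd$right)
    })
  })
  jsonlite::write_json(
    list(model = "lambdamart", schema = model$schema,
         learning_rate = model$learning_rate, meta = model$meta,
         trees = trees),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a LambdaMART model written by [write_ranker()]
#'
#' @param path file path.
#' @return a `lambdamart`.
#' @export
read_ranker <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$model, "lambdamart"))
    stop("not a lambdamart model file: ", path)
  trees <- lapply(obj$trees, function(nodes) {
    lapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      if (isTRUE(nd$leaf))
        list(id = i, is_leaf = TRUE, feature = NA_integer_,
             threshold = NA_real_, left = NA_integer_, right = NA_integer_,
             value = as.numeric(nd$value))
      else
        list(id = i, is_leaf = FALSE, feature = as.integer(nd$feature),
             threshold = as.numeric(nd$threshold),
             left = as.integer(nd$left), right = as.integer(nd$right),
             value = 0)
    })
  })
  structure(list(trees = trees,
                 learning_rate = as.numeric(obj$learning_rate),
                 schema = obj$schema,
                 meta = obj$meta, train_ndcg = numeric(0)),
            class = "lambdamart")
}
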