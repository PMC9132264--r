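# Adaptive boosting (SAMME) over depth-limited CART base learners, with
# cross-validated sigmoid calibration of the ensemble margin.
#
# For two classes SAMME reduces to discrete AdaBoost: at each round a
# weighted depth-2 tree is fit, its weighted training error e determines
# the round weight alpha = lr * log((1 - e) / e), and misclassified sample
# weights are multiplied by exp(alpha). Rounds stop early when a tree fits
# perfectly (e = 0) or does no better than chance (e >= 0.5).
#
# Fitted trees are converted to a compact parameter form (split variable,
# threshold, branch direction, leaf class) so that models contain no
# fitted-object environments and serialise as plain data.

# Convert an rpart classification fit into nested split/leaf lists.
# Assumes numeric predictors only (continuous splits), maxcompete = 0 and
# maxsurrogate = 0 so $splits holds exactly one row per internal node in
# frame order.
compact_tree <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  split_row <- cumsum(!is_leaf)
  build <- function(node) {
    i <- match(node, nodes)
    if (is_leaf[i]) {
      return(list(leaf = TRUE, class = as.integer(frame$yval[i]) - 1L))
    }
    s <- fit$splits[split_row[i], ]
    list(leaf = FALSE,
         var = as.character(frame$var[i]),
         thresh = unname(s["index"]),
         lt_left = unname(s["ncat"]) < 0,
         left = build(2L * node),
         right = build(2L * node + 1L))
  }
  build(1L)
}

# Vectorised routing of a compact tree; X is a numeric matrix with column
# names matching split variables. Returns 0/1 class predictions.
predict_compact <- function(tree, X) {
  out <- integer(nrow(X))
  walk <- function(node, mask) {
    if (!any(mask)) return(invisible(NULL))
    if (node$leaf) {
      out[mask] <<- node$class
      return(invisible(NULL))
    }
    x <- X[, node$var]
    goleft <- if (node$lt_left) x < node$thresh else x >= node$thresh
    walk(node$left, mask & goleft)
    walk(node$right, mask & !goleft)
  }
  walk(tree, rep(TRUE, nrow(X)))
  out
}

samme_fit <- function(X, y, n_estimators = 500, learning_rate = 1,
                      max_depth = 2) {
  n <- nrow(X)
  stopifnot(n == length(y), all(y %in% c(0L, 1L)))
  dat <- data.frame(.label = factor(y, levels = c(0L, 1L)), X,
                    check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    wv <- w * n
    fit <- rpart::rpart(.label ~ ., data = dat, weights = wv,
                        method = "class", control = ctrl)
    tr <- compact_tree(fit)
    pred <- predict_compact(tr, X)
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 0) {
      trees <- c(trees, list(tr))
      alphas <- c(alphas, 1)
      break
    }
    if (err >= 0.5) {
      if (!length(trees)) {
        data_error("boosting failed: first base learner is no better than chance")
      }
      break
    }
    alpha <- learning_rate * log((1 - err) / err)
    trees <- c(trees, list(tr))
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

# Ensemble margin in [-1, 1]: alpha-weighted vote with predictions mapped
# to {-1, +1}, normalised by the total alpha.
samme_decision <- function(boost, X) {
  total <- sum(boost$alphas)
  s <- numeric(nrow(X))
  for (m in seq_along(boost$trees)) {
    s <- s + boost$alphas[m] * (2 * predict_compact(boost$trees[[m]], X) - 1)
  }
  s / total
}

# Platt scaling: logistic fit of the labels on the margin. Degenerate
# held-out folds (one class, or constant margin) fall back to a
# margin-independent Laplace-smoothed intercept.
platt_fit <- function(s, y) {
  fallback <- c(a = stats::qlogis((sum(y) + 1) / (length(y) + 2)), b = 0)
  if (length(unique(y)) < 2 || stats::sd(s) == 0) return(fallback)
  fit <- try(suppressWarnings(
    stats::glm(y ~ s, family = stats::binomial())), silent = TRUE)
  if (inherits(fit, "try-error")) return(fallback)
  cf <- stats::coef(fit)
  if (anyNA(cf)) return(fallback)
  c(a = unname(cf[1]), b = unname(cf[2]))
}

platt_apply <- function(coefs, s) {
  stats::plogis(coefs["a"] + coefs["b"] * s)
}

# Calibrated boosted classifier for one namespace: k (boost, calibration)
# pairs, each boost trained on k-1 folds and calibrated on the held-out
# fold; prediction averages the k calibrated probabilities.
calibrated_boost_fit <- function(X, y, n_estimators, learning_rate,
                                 max_depth, n_folds) {
  n <- nrow(X)
  if (n < n_folds) {
    data_error("need at least %d rows for %d-fold calibration, have %d",
               n_folds, n_folds, n)
  }
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  members <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    boost <- samme_fit(X[tr, , drop = FALSE], y[tr],
                       n_estimators = n_estimators,
                       learning_rate = learning_rate, max_depth = max_depth)
    s_out <- samme_decision(boost, X[!tr, , drop = FALSE])
    members[[k]] <- list(boost = boost, calib = platt_fit(s_out, y[!tr]))
  }
  list(members = members)
}

calibrated_boost_predict <- function(model, X) {
  probs <- vapply(model$members, function(m) {
    as.numeric(platt_apply(m$calib, samme_decision(m$boost, X)))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}
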