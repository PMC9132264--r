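#' Method registry
#'
#' An ordered list of predictor names. The order fixes the feature-slot
#' layout of the model input, so a trained model refuses feature tables
#' built with a different registry.
#'
#' @param methods character vector of unique predictor names (at least 2).
#' @return character vector of class `method_registry`.
#' @export
method_registry <- function(methods) {
  methods <- as.character(methods)
  if (anyDuplicated(methods)) usage_error("predictor names must be unique")
  if (length(methods) < 2) {
    usage_error("a consensus needs at least 2 methods, got %d", length(methods))
  }
  structure(methods, class = "method_registry")
}

slot_name <- function(method) gsub("[^A-Za-z0-9]", "_", method)

feature_columns <- function(registry) {
  slots <- slot_name(registry)
  c(paste0("src_is_", slots), "source_score", "source_ic",
    as.vector(t(outer(paste0("sup_", slots),
                      c("present", "score", "ic", "sim"), paste, sep = "_"))))
}

#' Build support-feature rows for candidate annotations
#'
#' Every unique (protein, term) predicted by any registered method becomes
#' one feature row. The row's source is the predicting method with the
#' highest probability score (ties resolved by registry order); methods
#' that co-predicted the identical term appear as supports with similarity
#' 1 and their own score. Every other method contributes its most similar
#' term for the same protein, provided the Lin similarity reaches `floor`
#' (0.5 by default); methods with no qualifying term get an all-zero
#' support slot.
#'
#' Inputs are the predictors' own (leaf-level) term sets; do not propagate
#' them first, or supports would be flooded with shared ancestors.
#'
#' @param inputs an [annotation_set] or list of them; all predictor names
#'   must appear in `registry`.
#' @param ic_table an `ic_table` from [compute_ic()].
#' @param ontology a [go_ontology].
#' @param registry a [method_registry].
#' @param floor similarity floor for support (default 0.5).
#' @return A `feature_table`: data.frame with identifier columns
#'   (`protein`, `term`, `namespace`, `source_method`, `label`) followed by
#'   the numeric feature block; the registry, feature column names and IC
#'   fingerprint are carried as attributes.
#' @export
build_features <- function(inputs, ic_table, ontology, registry,
                           floor = 0.5) {
  stopifnot(inherits(registry, "method_registry"))
  if (inherits(inputs, "annotation_set")) inputs <- list(inputs)
  for (x in inputs) {
    stopifnot(inherits(x, "annotation_set"))
    if (is_propagated(x)) {
      usage_error("build_features() expects unpropagated predictor outputs")
    }
  }
  all_rec <- do.call(rbind, lapply(inputs, as.data.frame))
  if (is.null(all_rec) || nrow(all_rec) == 0) {
    return(empty_feature_table(registry, ic_table))
  }
  unknown <- setdiff(unique(all_rec$predictor), unclass(registry))
  if (length(unknown)) {
    usage_error("unregistered predictor name(s): %s",
                paste(unknown, collapse = ", "))
  }

  all_rec$namespace <- unname(ontology$namespaces[all_rec$term])
  methods <- unclass(registry)
  slots <- slot_name(methods)
  cols <- feature_columns(registry)
  sim_cache <- new.env(parent = emptyenv())

  ids <- list()
  feats <- list()
  groups <- split(seq_len(nrow(all_rec)),
                  paste(all_rec$protein, all_rec$namespace, sep = "\r"))
  for (g in groups) {
    rec <- all_rec[g, , drop = FALSE]
    prot <- rec$protein[1]
    ns <- rec$namespace[1]
    # per-method term -> score lookup for this protein/namespace
    by_m <- lapply(methods, function(m) {
      r <- rec[rec$predictor == m, , drop = FALSE]
      stats::setNames(r$score, r$term)
    })
    names(by_m) <- methods
    uterms <- sort(unique(rec$term))
    term_ic <- stats::setNames(ic_of(ic_table, uterms, ontology), uterms)
    for (t in uterms) {
      have <- which(vapply(by_m, function(s) t %in% names(s), TRUE))
      src_scores <- vapply(methods[have], function(m) by_m[[m]][[t]], 0)
      src_i <- have[which.max(src_scores)]  # ties -> earliest registry order
      src <- methods[src_i]
      row <- stats::setNames(numeric(length(cols)), cols)
      row[paste0("src_is_", slots[src_i])] <- 1
      row["source_score"] <- by_m[[src]][[t]]
      row["source_ic"] <- term_ic[[t]]
      for (j in seq_along(methods)) {
        if (j == src_i) next
        m <- methods[j]
        pre <- paste0("sup_", slots[j], "_")
        if (t %in% names(by_m[[m]])) {
          row[paste0(pre, c("present", "score", "ic", "sim"))] <-
            c(1, by_m[[m]][[t]], term_ic[[t]], 1)
          next
        }
        cands <- names(by_m[[m]])
        if (!length(cands)) next
        sims <- lin_many(t, cands, ic_table, ontology, sim_cache)
        best <- max(sims)
        if (best < floor) next
        top <- cands[sims >= best - 1e-12]
        if (length(top) > 1) {
          ics <- ic_of(ic_table, top, ontology)
          top <- sort(top[ics >= max(ics) - 1e-12])
        }
        chosen <- top[1]
        row[paste0(pre, c("present", "score", "ic", "sim"))] <-
          c(1, by_m[[m]][[chosen]],
            ic_of(ic_table, chosen, ontology), min(1, best))
      }
      ids[[length(ids) + 1L]] <- data.frame(
        protein = prot, term = t, namespace = ns, source_method = src,
        stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- row
    }
  }
  id_df <- do.call(rbind, ids)
  feat_mat <- do.call(rbind, feats)
  out <- cbind(id_df, label = NA_integer_,
               as.data.frame(feat_mat, check.names = FALSE))
  o <- order(out$protein, out$namespace, out$term)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            registry = registry, feature_cols = cols,
            ic_fingerprint = ic_fingerprint(ic_table))
}

empty_feature_table <- function(registry, ic_table) {
  cols <- feature_columns(registry)
  out <- cbind(
    data.frame(protein = character(0), term = character(0),
               namespace = character(0), source_method = character(0),
               label = integer(0), stringsAsFactors = FALSE),
    as.data.frame(matrix(numeric(0), 0, length(cols),
                         dimnames = list(NULL, cols)), check.names = FALSE))
  structure(out, class = c("feature_table", "data.frame"),
            registry = registry, feature_cols = cols,
            ic_fingerprint = ic_fingerprint(ic_table))
}

#' @export
`[.feature_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(attr(x, "feature_cols") %in% names(out))) {
    attr(out, "registry") <- attr(x, "registry")
    attr(out, "feature_cols") <- attr(x, "feature_cols")
    attr(out, "ic_fingerprint") <- attr(x, "ic_fingerprint")
    class(out) <- class(x)
  }
  out
}

ic_fingerprint <- function(ic_table) {
  sprintf("%d|%.10g|%.10g|%g|%s", length(ic_table$ic), sum(ic_table$ic),
          sum(ic_table$ic^2), ic_table$base, ic_table$denominator)
}

#' Label feature rows against a propagated gold standard
#'
#' A row is positive when its term lies in the propagated gold annotation
#' set of its protein. Rows for proteins absent from the gold standard are
#' dropped (nothing is known about them).
#'
#' @param features a `feature_table` from [build_features()].
#' @param gold a propagated [annotation_set].
#' @param ontology a [go_ontology].
#' @return The labelled `feature_table`.
#' @export
label_features <- function(features, gold, ontology) {
  if (nrow(gold) == 0) data_error("gold standard is empty")
  if (!is_propagated(gold)) {
    data_error("gold standard must be propagated; call propagate_annotations() first")
  }
  gold_sets <- split(gold$term, gold$protein)
  keep <- features$protein %in% names(gold_sets)
  out <- features[keep, , drop = FALSE]
  out$label <- as.integer(mapply(function(p, t) t %in% gold_sets[[p]],
                                 out$protein, out$term))
  rownames(out) <- NULL
  attrs <- attributes(features)
  attr(out, "registry") <- attrs$registry
  attr(out, "feature_cols") <- attrs$feature_cols
  attr(out, "ic_fingerprint") <- attrs$ic_fingerprint
  class(out) <- class(features)
  out
}

feature_matrix <- function(features) {
  cols <- attr(features, "feature_cols")
  as.matrix(as.data.frame(features)[, cols, drop = FALSE])
}

#' Train the consensus model
#'
#' One calibrated boosted-tree classifier per ontology namespace: adaptive
#' boosting (SAMME) with depth-2 decision trees as base learners and
#' learning rate 1, probability-calibrated by k-fold cross-validated
#' sigmoid (Platt) scaling. The iteration cap defaults to 500 rounds,
#' sized for desk-scale corpora; raising it (up to the 100,000 rounds the
#' method tolerates) is a configuration choice, not a code change.
#'
#' @param features a labelled `feature_table` (see [label_features()]).
#' @param n_estimators maximum boosting rounds per model (default 500).
#' @param learning_rate boosting learning rate (default 1).
#' @param max_depth base-learner tree depth (default 2).
#' @param n_folds calibration folds (default 10).
#' @param seed integer seed controlling fold assignment (default 1).
#' @return An object of class `consensus_model`.
#' @export
train_consensus <- function(features, n_estimators = 500, learning_rate = 1,
                            max_depth = 2, n_folds = 10, seed = 1) {
  if (!inherits(features, "feature_table")) {
    usage_error("features must come from build_features()")
  }
  if (anyNA(features$label)) {
    data_error("features are unlabelled; call label_features() first")
  }
  registry <- attr(features, "registry")
  cols <- attr(features, "feature_cols")
  X_all <- feature_matrix(features)
  models <- list()
  with_seed(seed, {
    for (ns in sort(unique(features$namespace))) {
      sel <- features$namespace == ns
      y <- features$label[sel]
      if (length(unique(y)) < 2) {
        data_error("namespace '%s' has a single label class; cannot train", ns)
      }
      models[[ns]] <- calibrated_boost_fit(
        X_all[sel, , drop = FALSE], y,
        n_estimators = n_estimators, learning_rate = learning_rate,
        max_depth = max_depth, n_folds = n_folds)
    }
  })
  structure(
    list(version = 1L,
         registry = registry,
         feature_cols = cols,
         ic_fingerprint = attr(features, "ic_fingerprint"),
         params = list(n_estimators = n_estimators,
                       learning_rate = learning_rate,
                       max_depth = max_depth, n_folds = n_folds,
                       seed = seed),
         trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         n_rows = stats::setNames(
           as.integer(table(features$namespace)[names(models)]),
           names(models)),
         models = models),
    class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %d namespace model(s), registry [%s]\n",
              length(x$models), paste(x$registry, collapse = ", ")))
  cat(sprintf("  params: %d estimators, lr %g, depth %d, %d-fold calibration, seed %d\n",
              x$params$n_estimators, x$params$learning_rate,
              x$params$max_depth, x$params$n_folds, x$params$seed))
  invisible(x)
}

#' Score candidate annotations and split them at a threshold
#'
#' Every feature row receives a calibrated consensus probability; rows at
#' or above the threshold are confident, the rest rejected. Per-namespace
#' threshold overrides are supported (Fmax-optimal cutoffs per ontology
#' typically sit near, but not exactly at, 0.5).
#'
#' @param object a `consensus_model`.
#' @param features a `feature_table` built with the model's registry.
#' @param threshold default confident/rejected split point (default 0.5).
#' @param namespace_thresholds optional named numeric vector of
#'   per-namespace overrides.
#' @param ... unused.
#' @return A `consensus_result` data.frame with columns `protein`, `term`,
#'   `namespace`, `source_method`, `consensus_score`, `verdict`.
#' @export
predict.consensus_model <- function(object, features, threshold = 0.5,
                                    namespace_thresholds = NULL, ...) {
  if (!inherits(features, "feature_table")) {
    usage_error("features must come from build_features()")
  }
  freg <- attr(features, "registry")
  if (!identical(unclass(object$registry), unclass(freg))) {
    data_error("method registry mismatch: model [%s] vs features [%s]",
               paste(object$registry, collapse = ", "),
               paste(freg, collapse = ", "))
  }
  ffp <- attr(features, "ic_fingerprint")
  if (!is.null(ffp) && !identical(ffp, object$ic_fingerprint)) {
    warning("features were built with a different IC table than the model was trained with")
  }
  score <- rep(NA_real_, nrow(features))
  if (nrow(features)) {
    X <- feature_matrix(features)
    for (ns in unique(features$namespace)) {
      if (is.null(object$models[[ns]])) {
        data_error("model has no classifier for namespace '%s'", ns)
      }
      sel <- features$namespace == ns
      score[sel] <- calibrated_boost_predict(object$models[[ns]],
                                             X[sel, , drop = FALSE])
    }
  }
  thr <- rep(threshold, nrow(features))
  if (!is.null(namespace_thresholds) && nrow(features)) {
    ov <- namespace_thresholds[features$namespace]
    thr[!is.na(ov)] <- ov[!is.na(ov)]
  }
  out <- data.frame(protein = features$protein, term = features$term,
                    namespace = features$namespace,
                    source_method = features$source_method,
                    consensus_score = score,
                    verdict = ifelse(score >= thr, "confident", "rejected"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("consensus_result", "data.frame"),
            threshold = threshold,
            namespace_thresholds = namespace_thresholds)
}

#' Convert a consensus result to an annotation set
#'
#' @param result a `consensus_result`.
#' @param which `"all"`, `"confident"` or `"rejected"`.
#' @param predictor predictor name for the records (default `"consensus"`).
#' @return An [annotation_set].
#' @export
consensus_annotations <- function(result, which = c("all", "confident", "rejected"),
                                  predictor = "consensus") {
  which <- match.arg(which)
  if (which != "all") result <- result[result$verdict == which, , drop = FALSE]
  annotation_set(predictor, result$protein, result$term,
                 result$consensus_score)
}

#' Save / load a consensus model
#'
#' The model is a versioned plain-parameter archive (tree splits and
#' leaves, boosting weights, calibration coefficients, registry, IC
#' fingerprint, hyperparameters); loading reconstructs predictions exactly.
#'
#' @param model a `consensus_model`.
#' @param path file path.
#' @return `path` (save) or the `consensus_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "consensus_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) data_error("model file not found: %s", path)
  model <- readRDS(path)
  if (!inherits(model, "consensus_model")) {
    data_error("file does not contain a consensus model: %s", path)
  }
  if (is.null(model$version) || model$version > 1L) {
    data_error("unsupported model version: %s", model$version %||% "none")
  }
  model
}
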