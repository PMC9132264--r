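#' Consensus recovery experiment on a synthetic benchmark
#'
#' Runs the full pipeline at desk scale: simulate a benchmark, split the
#' proteins into training and held-out halves, estimate IC from the
#' training gold standard, build and label features, train the calibrated
#' boosted consensus model, score the held-out candidates, and evaluate
#' the consensus against every input method per namespace. Also aggregates
#' confusion-transition flows (each input method re-evaluated at its own
#' Fmax-optimal threshold against the consensus 0.5 split) and bins the
#' held-out consensus scores against their empirical positive rates for a
#' calibration check.
#'
#' @param config a [simulation_config()]; its seed drives everything.
#' @param train_fraction fraction of proteins used for training
#'   (default 0.5).
#' @param n_estimators boosting rounds for [train_consensus()].
#' @param step threshold step for evaluation (default 0.01).
#' @param floor support similarity floor (default 0.5).
#' @return A list of class `consensus_experiment` with elements
#'   `fmax` (data.frame: namespace x method, consensus last),
#'   `transitions` (per-namespace flow tables summed over input methods),
#'   `calibration` (per-bin counts and positive rates on held-out rows),
#'   plus the fitted `model`, the benchmark and the split.
#' @export
consensus_experiment <- function(config, train_fraction = 0.5,
                                 n_estimators = 500, step = 0.01,
                                 floor = 0.5) {
  bench <- simulate_benchmark(config)
  ontology <- bench$ontology
  proteins <- sort(unique(bench$gold$protein))
  n_train <- max(2L, as.integer(length(proteins) * train_fraction))
  train_prot <- with_seed(config$seed + 15485863L,
                          sample(proteins, n_train))
  test_prot <- setdiff(proteins, train_prot)

  gold_train <- filter_annotations(bench$gold, proteins = train_prot)
  gold_test <- filter_annotations(bench$gold, proteins = test_prot)
  ic <- compute_ic(gold_train, ontology)
  registry <- method_registry(vapply(config$methods, `[[`, "", "name"))

  inputs_train <- lapply(bench$predictions, filter_annotations,
                         proteins = train_prot)
  inputs_test <- lapply(bench$predictions, filter_annotations,
                        proteins = test_prot)

  features_train <- build_features(inputs_train, ic, ontology, registry,
                                   floor = floor)
  features_train <- label_features(features_train, gold_train, ontology)
  model <- train_consensus(features_train, n_estimators = n_estimators,
                           seed = config$seed)

  features_test <- build_features(inputs_test, ic, ontology, registry,
                                  floor = floor)
  result <- predict(model, features_test, threshold = 0.5)
  cons_set <- consensus_annotations(result)

  namespaces <- sort(unique(ontology$terms$namespace))
  fmax_rows <- list()
  transitions <- list()
  input_thresholds <- list()
  for (ns in namespaces) {
    row <- list(namespace = ns)
    for (m in unclass(registry)) {
      cv <- pr_curve(inputs_test[[m]], gold_test, ontology, step = step,
                     namespace = ns)
      fm <- fmax(cv)
      row[[m]] <- fm[["fmax"]]
      input_thresholds[[ns]][[m]] <- fm[["threshold"]]
    }
    cvc <- pr_curve(cons_set, gold_test, ontology, step = step,
                    namespace = ns)
    row$consensus <- fmax(cvc)[["fmax"]]
    fmax_rows[[ns]] <- as.data.frame(row, stringsAsFactors = FALSE)

    flow_sum <- NULL
    for (m in unclass(registry)) {
      fl <- transition_counts(
        inputs_test[[m]], result, gold_test, ontology,
        baseline_threshold = input_thresholds[[ns]][[m]],
        consensus_threshold = 0.5, namespace = ns)
      if (is.null(flow_sum)) {
        flow_sum <- as.data.frame(fl)
      } else {
        flow_sum$count <- flow_sum$count + fl$count
      }
    }
    transitions[[ns]] <- flow_sum
  }

  labelled_test <- label_features(features_test, gold_test, ontology)
  key_f <- paste(labelled_test$protein, labelled_test$term, sep = "\r")
  key_r <- paste(result$protein, result$term, sep = "\r")
  score <- result$consensus_score[match(key_f, key_r)]
  bin <- pmin(as.integer(score * 10), 9L) + 1L
  calibration <- data.frame(
    bin_mid = seq(0.05, 0.95, by = 0.1),
    n = as.integer(tabulate(bin, 10)),
    positive_rate = vapply(1:10, function(b) {
      if (!sum(bin == b)) NA_real_ else mean(labelled_test$label[bin == b])
    }, 0))

  structure(
    list(fmax = do.call(rbind, fmax_rows),
         transitions = transitions,
         calibration = calibration,
         input_thresholds = input_thresholds,
         model = model, result = result,
         benchmark = bench, ic = ic,
         train_proteins = train_prot, test_proteins = test_prot),
    class = "consensus_experiment")
}

#' @export
print.consensus_experiment <- function(x, ...) {
  cat("consensus_experiment\n")
  cat("held-out Fmax per namespace:\n")
  print.data.frame(x$fmax, row.names = FALSE, digits = 3)
  for (ns in names(x$transitions)) {
    fl <- x$transitions[[ns]]
    cat(sprintf("%s: FP->TN %d, TN->FP %d\n", ns,
                fl$count[fl$from == "FP" & fl$to == "TN"],
                fl$count[fl$from == "TN" & fl$to == "FP"]))
  }
  invisible(x)
}
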