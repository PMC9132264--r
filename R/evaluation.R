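# Protein-centric evaluation in the CAFA style: precision is averaged over
# proteins with at least one prediction at the threshold, recall over all
# benchmark proteins; predictions and gold standard are compared after DAG
# propagation with namespace roots excluded.

# Shared preprocessing: per-protein, per-threshold true-positive and
# prediction counts (and IC masses when an IC table is supplied).
eval_matrices <- function(pred, gold, ontology, step = 0.01,
                          namespace = NULL, ic_table = NULL) {
  stopifnot(inherits(pred, "annotation_set"), inherits(gold, "annotation_set"))
  if (nrow(gold) == 0) data_error("gold standard is empty")
  if (!is_propagated(gold)) {
    data_error("gold standard must be propagated; call propagate_annotations() first")
  }
  if (!is_propagated(pred)) pred <- propagate_annotations(pred, ontology)
  if (!is.null(namespace)) {
    pred <- filter_annotations(pred, namespace = namespace, ontology = ontology)
    gold <- filter_annotations(gold, namespace = namespace, ontology = ontology)
  }
  ns_seen <- unique(ontology$namespaces[c(pred$term, gold$term)])
  if (length(ns_seen) > 1) {
    usage_error("evaluation spans %d namespaces; pass `namespace` to pick one",
                length(ns_seen))
  }
  roots <- unname(ontology$roots)
  pred <- pred[!(pred$term %in% roots), , drop = FALSE]
  gold <- gold[!(gold$term %in% roots), , drop = FALSE]
  if (nrow(gold) == 0) data_error("gold standard has no non-root terms")

  proteins <- sort(unique(gold$protein))
  extra <- setdiff(unique(pred$protein), proteins)
  if (length(extra)) {
    message(sprintf("evaluation: ignoring predictions for %d protein(s) absent from the gold standard",
                    length(extra)))
  }
  gold_sets <- split(gold$term, gold$protein)

  tau <- round(seq(0, 1, by = step), 10)
  if (tau[length(tau)] < 1) tau <- c(tau, 1)
  tau <- rev(tau)  # descending grid including both endpoints

  n <- length(proteins)
  ntp <- matrix(0, n, length(tau))
  npred <- matrix(0, n, length(tau))
  goldn <- vapply(gold_sets[proteins], length, 1L)
  want_ic <- !is.null(ic_table)
  if (want_ic) {
    ru <- matrix(0, n, length(tau))
    mi <- matrix(0, n, length(tau))
    gold_ic_sum <- vapply(proteins, function(p)
      sum(ic_of(ic_table, gold_sets[[p]], ontology)), 0)
  }
  pred_by_prot <- split(pred[c("term", "score")], pred$protein)
  for (i in seq_len(n)) {
    p <- proteins[i]
    pp <- pred_by_prot[[p]]
    if (want_ic) { ru[i, ] <- gold_ic_sum[i] }
    if (is.null(pp) || nrow(pp) == 0) next
    at <- outer(pp$score, tau, `>=`)           # terms x thresholds
    in_gold <- pp$term %in% gold_sets[[p]]
    npred[i, ] <- colSums(at)
    ntp[i, ] <- colSums(at & in_gold)
    if (want_ic) {
      term_ics <- ic_of(ic_table, pp$term, ontology)
      ru[i, ] <- gold_ic_sum[i] - colSums(at * (in_gold * term_ics))
      mi[i, ] <- colSums(at * ((!in_gold) * term_ics))
    }
  }
  out <- list(tau = tau, proteins = proteins, ntp = ntp, npred = npred,
              goldn = goldn)
  if (want_ic) { out$ru <- ru; out$mi <- mi }
  out
}

curve_from_matrices <- function(mat, idx = NULL) {
  ntp <- mat$ntp; npred <- mat$npred; goldn <- mat$goldn
  if (!is.null(idx)) {
    ntp <- ntp[idx, , drop = FALSE]
    npred <- npred[idx, , drop = FALSE]
    goldn <- goldn[idx]
  }
  covered <- npred > 0
  n_cov <- colSums(covered)
  pr_ratio <- ntp / npred
  pr_ratio[!covered] <- NA
  precision <- suppressWarnings(colMeans(pr_ratio, na.rm = TRUE))
  precision[n_cov == 0] <- NA
  recall <- colMeans(ntp / goldn)
  data.frame(threshold = mat$tau, precision = precision, recall = recall,
             n_proteins_covered = n_cov)
}

#' Protein-centric precision-recall curve
#'
#' At each threshold of a descending grid (step 0.01 by default, endpoints
#' 0 and 1 included), per-protein precision is averaged over proteins with
#' at least one prediction at that threshold and per-protein recall over
#' all benchmark proteins. Both sets are propagated and namespace roots
#' are excluded. Constant-score predictors yield a single distinct
#' curve point.
#'
#' @param pred an [annotation_set] of predictions (propagated internally
#'   when needed).
#' @param gold a propagated [annotation_set] gold standard.
#' @param ontology a [go_ontology].
#' @param step threshold step (default 0.01).
#' @param namespace namespace to evaluate (required when the sets span
#'   more than one).
#' @return A `pr_curve` data.frame with columns `threshold`, `precision`,
#'   `recall`, `n_proteins_covered`.
#' @export
pr_curve <- function(pred, gold, ontology, step = 0.01, namespace = NULL) {
  mat <- eval_matrices(pred, gold, ontology, step = step, namespace = namespace)
  out <- curve_from_matrices(mat)
  structure(out, class = c("pr_curve", "data.frame"),
            n_benchmark = length(mat$proteins))
}

fmax_from_curve <- function(precision, recall, threshold) {
  f <- 2 * precision * recall / (precision + recall)
  f[is.na(f) | !is.finite(f)] <- 0
  best <- max(f)
  # ties resolved at the lowest threshold
  at <- threshold[f >= best - 1e-15]
  c(fmax = best, threshold = min(at))
}

#' Maximum protein-centric F-measure
#'
#' @param curve a `pr_curve`.
#' @return Named numeric vector: `fmax` and the `threshold` attaining it
#'   (ties resolved at the lowest threshold).
#' @export
fmax <- function(curve) {
  stopifnot(nrow(curve) > 0)
  fmax_from_curve(curve$precision, curve$recall, curve$threshold)
}

#' Minimum semantic distance between predicted and true annotations
#'
#' `S(tau) = sqrt(ru(tau)^2 + mi(tau)^2)` where remaining uncertainty
#' `ru` is the IC mass of missed gold terms and misinformation `mi` the IC
#' mass of spurious predicted terms, each averaged over all benchmark
#' proteins. Reported in the IC table's log units (bits by default).
#'
#' @inheritParams pr_curve
#' @param ic_table an `ic_table`.
#' @return Named numeric vector: `smin` and the `threshold` attaining it.
#' @export
smin <- function(pred, gold, ic_table, ontology, step = 0.01,
                 namespace = NULL) {
  mat <- eval_matrices(pred, gold, ontology, step = step,
                       namespace = namespace, ic_table = ic_table)
  s <- sqrt(colMeans(mat$ru)^2 + colMeans(mat$mi)^2)
  best <- min(s)
  at <- mat$tau[s <= best + 1e-15]
  c(smin = best, threshold = min(at))
}

aupr_from_curve <- function(precision, recall, covered) {
  keep <- covered > 0 & !is.na(precision)
  if (!any(keep)) return(0)
  pr <- precision[keep]; rc <- recall[keep]
  # anchor at zero recall with the precision of the highest covered
  # threshold (grid is descending, so the first kept point)
  rc <- c(0, rc); pr <- c(pr[1], pr)
  o <- order(rc)
  rc <- rc[o]; pr <- pr[o]
  sum(diff(rc) * (utils::head(pr, -1) + utils::tail(pr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal area over recall-sorted curve points, anchored at recall 0
#' with the precision of the highest threshold that covers at least one
#' protein. A constant-score predictor (single curve point) is treated as
#' a horizontal line from zero recall, i.e. a rectangle.
#'
#' @param curve a `pr_curve`.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(curve) {
  aupr_from_curve(curve$precision, curve$recall, curve$n_proteins_covered)
}

#' Bootstrap confidence interval for an evaluation metric
#'
#' Resamples benchmark proteins with replacement (metrics are
#' protein-centric, so the protein is the sampling unit), recomputes the
#' metric on each replicate, and returns the 2.5/97.5 percentiles.
#' Deterministic given the seed.
#'
#' @inheritParams pr_curve
#' @param metric `"fmax"`, `"aupr"` or `"smin"`.
#' @param iterations bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param ic_table required when `metric = "smin"`.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(pred, gold, ontology, metric = c("fmax", "aupr", "smin"),
                         iterations = 10000, seed = 1, step = 0.01,
                         namespace = NULL, ic_table = NULL) {
  metric <- match.arg(metric)
  if (metric == "smin" && is.null(ic_table)) {
    usage_error("metric 'smin' needs an ic_table")
  }
  mat <- eval_matrices(pred, gold, ontology, step = step,
                       namespace = namespace, ic_table = ic_table)
  n <- length(mat$proteins)
  if (n < 2) usage_error("bootstrap needs at least 2 benchmark proteins")
  stat_one <- function(idx) {
    if (metric == "smin") {
      s <- sqrt(colMeans(mat$ru[idx, , drop = FALSE])^2 +
                colMeans(mat$mi[idx, , drop = FALSE])^2)
      return(min(s))
    }
    cv <- curve_from_matrices(mat, idx)
    if (metric == "fmax") {
      fmax_from_curve(cv$precision, cv$recall, cv$threshold)[["fmax"]]
    } else {
      aupr_from_curve(cv$precision, cv$recall, cv$n_proteins_covered)
    }
  }
  stats_vec <- with_seed(seed, {
    vapply(seq_len(iterations), function(b)
      stat_one(sample.int(n, n, replace = TRUE)), 0)
  })
  q <- stats::quantile(stats_vec, c(0.025, 0.975), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Full evaluation report for one namespace
#'
#' @inheritParams pr_curve
#' @param ic_table optional `ic_table`; when given, Smin is included.
#' @param bootstrap bootstrap iterations for the Fmax confidence interval
#'   (0 disables).
#' @param seed seed for the bootstrap.
#' @return A list of class `evaluation_report` with the curve, `fmax` (and
#'   threshold), `aupr`, optional `smin` and `fmax_ci`.
#' @export
evaluation_report <- function(pred, gold, ontology, ic_table = NULL,
                              namespace = NULL, step = 0.01,
                              bootstrap = 0, seed = 1) {
  curve <- pr_curve(pred, gold, ontology, step = step, namespace = namespace)
  fm <- fmax(curve)
  out <- list(namespace = namespace %||% "all",
              curve = curve,
              fmax = fm[["fmax"]], fmax_threshold = fm[["threshold"]],
              aupr = aupr(curve))
  if (!is.null(ic_table)) {
    sm <- smin(pred, gold, ic_table, ontology, step = step,
               namespace = namespace)
    out$smin <- sm[["smin"]]
    out$smin_threshold <- sm[["threshold"]]
  }
  if (bootstrap > 0) {
    out$fmax_ci <- bootstrap_ci(pred, gold, ontology, metric = "fmax",
                                iterations = bootstrap, seed = seed,
                                step = step, namespace = namespace)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s]\n", x$namespace))
  cat(sprintf("  Fmax %.4f at threshold %.2f\n", x$fmax, x$fmax_threshold))
  if (!is.null(x$smin)) {
    cat(sprintf("  Smin %.4f at threshold %.2f\n", x$smin, x$smin_threshold))
  }
  cat(sprintf("  AUPR %.4f\n", x$aupr))
  if (!is.null(x$fmax_ci)) {
    cat(sprintf("  Fmax 95%% bootstrap CI [%.4f, %.4f]\n",
                x$fmax_ci[["lo"]], x$fmax_ci[["hi"]]))
  }
  invisible(x)
}

#' Confusion-transition accounting between baseline and consensus scoring
#'
#' Each candidate annotation of one input method is classified TP / FP /
#' TN / FN against the propagated gold standard at the method's own
#' threshold (typically its Fmax-optimal cutoff), then re-classified at the
#' consensus threshold after re-scoring. Truth is fixed, so each class can
#' only flow within its truth stratum: TP->TP/FN, FN->FN/TP, FP->FP/TN,
#' TN->TN/FP. Flows out of each baseline class sum to that class's
#' baseline count.
#'
#' @param baseline an [annotation_set] scored by one input method.
#' @param consensus a `consensus_result` (or any data.frame with `protein`,
#'   `term` and `consensus_score`) covering all baseline candidates.
#' @param gold a propagated [annotation_set].
#' @param ontology a [go_ontology].
#' @param baseline_threshold positive-call threshold for the baseline
#'   scores.
#' @param consensus_threshold positive-call threshold for the consensus
#'   scores (default 0.5).
#' @param namespace optional namespace restriction.
#' @return A `transition_counts` data.frame with columns `from`, `to`,
#'   `count` (8 rows).
#' @export
transition_counts <- function(baseline, consensus, gold, ontology,
                              baseline_threshold, consensus_threshold = 0.5,
                              namespace = NULL) {
  stopifnot(inherits(baseline, "annotation_set"))
  if (!is_propagated(gold)) {
    data_error("gold standard must be propagated; call propagate_annotations() first")
  }
  if (!is.null(namespace)) {
    baseline <- filter_annotations(baseline, namespace = namespace,
                                   ontology = ontology)
    consensus <- consensus[ontology$namespaces[consensus$term] %in% namespace, ,
                           drop = FALSE]
    gold <- filter_annotations(gold, namespace = namespace, ontology = ontology)
  }
  roots <- unname(ontology$roots)
  baseline <- baseline[!(baseline$term %in% roots), , drop = FALSE]
  gold_sets <- split(gold$term, gold$protein)
  known <- baseline$protein %in% names(gold_sets)
  if (any(!known)) {
    message(sprintf("transition_counts: dropping %d candidate(s) for proteins absent from the gold standard",
                    sum(!known)))
    baseline <- baseline[known, , drop = FALSE]
  }
  key_b <- paste(baseline$protein, baseline$term, sep = "\r")
  key_c <- paste(consensus$protein, consensus$term, sep = "\r")
  hit <- match(key_b, key_c)
  if (anyNA(hit)) {
    data_error("annotation universes mismatch: %d baseline candidate(s) missing a consensus score",
               sum(is.na(hit)))
  }
  truth <- mapply(function(p, t) t %in% gold_sets[[p]],
                  baseline$protein, baseline$term)
  before_pos <- baseline$score >= baseline_threshold
  after_pos <- consensus$consensus_score[hit] >= consensus_threshold
  cls <- function(truth, pos) {
    ifelse(truth & pos, "TP",
           ifelse(!truth & pos, "FP", ifelse(truth & !pos, "FN", "TN")))
  }
  from <- cls(truth, before_pos)
  to <- cls(truth, after_pos)
  flows <- data.frame(
    from = c("TP", "TP", "FP", "FP", "TN", "TN", "FN", "FN"),
    to   = c("TP", "FN", "FP", "TN", "TN", "FP", "FN", "TP"),
    stringsAsFactors = FALSE)
  flows$count <- mapply(function(f, t) sum(from == f & to == t),
                        flows$from, flows$to)
  structure(flows, class = c("transition_counts", "data.frame"),
            baseline_totals = table(factor(from, levels = c("TP", "FP", "TN", "FN"))))
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("transition_counts (baseline -> consensus re-evaluation):\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}
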