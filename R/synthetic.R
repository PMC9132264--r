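#' Simulation configuration for the synthetic benchmark
#'
#' Defines a desk-scale stand-in for a real annotation study: a small
#' rooted DAG per ontology namespace, a gold-standard corpus of
#' protein-term annotations (which doubles as the IC reference), and k
#' simulated predictors with controllable recall, precision, score noise
#' and term-specificity bias. A constant-score profile emulates
#' domain-scan methods that emit probability 1 for every prediction.
#'
#' @param seed integer master seed.
#' @param n_terms terms per namespace (>= 4).
#' @param depth number of DAG levels below each root.
#' @param branching mean number of children spawned per term when growing
#'   levels.
#' @param part_of_prob probability that a term gains an extra `part_of`
#'   parent from a shallower level.
#' @param n_proteins number of proteins (>= 2).
#' @param terms_per_protein mean gold leaf terms per protein per namespace.
#' @param methods list of [method_profile()]s.
#' @param fp_mode `"easy"` (uniform false-positive terms) or `"hard"`
#'   (false positives drawn from the semantic neighbourhood of the true
#'   terms, Lin >= 0.2).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_terms = 150, depth = 6,
                              branching = 2, part_of_prob = 0.1,
                              n_proteins = 1000, terms_per_protein = 4,
                              methods = default_method_profiles(),
                              fp_mode = c("easy", "hard")) {
  fp_mode <- match.arg(fp_mode)
  stopifnot(n_terms >= 4, n_proteins >= 2, depth >= 1, branching >= 1,
            part_of_prob >= 0, part_of_prob <= 1, terms_per_protein >= 1)
  if (depth + 1 > n_terms) usage_error("depth %d infeasible with %d terms", depth, n_terms)
  structure(list(seed = seed, n_terms = n_terms, depth = depth,
                 branching = branching, part_of_prob = part_of_prob,
                 n_proteins = n_proteins,
                 terms_per_protein = terms_per_protein,
                 methods = methods, fp_mode = fp_mode),
            class = "simulation_config")
}

#' Simulated predictor profile
#'
#' @param name predictor name.
#' @param recall probability that a true gold leaf term is emitted.
#' @param precision expected fraction of emitted terms that are correct;
#'   controls the false-positive rate.
#' @param noise_sd standard deviation of the Gaussian score noise.
#' @param specificity_bias in \[-1, 1\]: negative values swap emitted true
#'   terms for an ancestor (shallower, less specific) with probability
#'   `|bias|`; positive values swap for a child (deeper, possibly wrong)
#'   with probability `bias`.
#' @param constant_score when `TRUE` every emitted score is 1.
#' @return A list of class `method_profile`.
#' @export
method_profile <- function(name, recall, precision, noise_sd = 0.1,
                           specificity_bias = 0, constant_score = FALSE) {
  stopifnot(recall >= 0, recall <= 1, precision > 0, precision <= 1,
            noise_sd >= 0, specificity_bias >= -1, specificity_bias <= 1)
  structure(list(name = name, recall = recall, precision = precision,
                 noise_sd = noise_sd, specificity_bias = specificity_bias,
                 constant_score = constant_score),
            class = "method_profile")
}

#' Default four-method benchmark profiles
#'
#' Two reliable methods, one noisy method, and one constant-score
#' domain-style method.
#'
#' @return list of [method_profile()]s.
#' @export
default_method_profiles <- function() {
  list(method_profile("deeplearner", recall = 0.8, precision = 0.8),
       method_profile("seqsim", recall = 0.7, precision = 0.6),
       method_profile("noisy", recall = 0.5, precision = 0.3),
       method_profile("domainscan", recall = 0.4, precision = 0.5,
                      constant_score = TRUE))
}

synthetic_namespaces <- function() {
  c(molecular_function = "GO:0003674",
    biological_process = "GO:0008150",
    cellular_component = "GO:0005575")
}

#' Generate a random rooted DAG ontology
#'
#' One DAG per GO namespace, each with the requested number of terms:
#' levels are grown from the root with ~`branching` children per term, each
#' non-root term receives one `is_a` parent from the previous level, and
#' extra `part_of` edges to strictly shallower terms are added with
#' probability `part_of_prob`. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return A [go_ontology].
#' @export
make_ontology <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  roots <- synthetic_namespaces()
  with_seed(config$seed, {
    acc <- name <- ns <- character(0)
    ec <- er <- ep <- character(0)
    counter <- 0L
    for (k in seq_along(roots)) {
      nsname <- names(roots)[k]
      root <- roots[[k]]
      acc <- c(acc, root); name <- c(name, nsname); ns <- c(ns, nsname)
      levels <- list(root)
      made <- 1L
      depth_sizes <- level_sizes(config$n_terms - 1L, config$depth,
                                 config$branching)
      for (d in seq_along(depth_sizes)) {
        sz <- depth_sizes[d]
        if (sz == 0L) next
        lv <- character(sz)
        for (j in seq_len(sz)) {
          counter <- counter + 1L
          t <- sprintf("GO:%07d", 1000000L + counter)
          lv[j] <- t
          acc <- c(acc, t)
          name <- c(name, sprintf("%s term %d", nsname, counter))
          ns <- c(ns, nsname)
          parent <- sample(levels[[d]], 1L)
          ec <- c(ec, t); er <- c(er, "is_a"); ep <- c(ep, parent)
          if (stats::runif(1) < config$part_of_prob) {
            shallow <- setdiff(unlist(levels[seq_len(d)], use.names = FALSE),
                               parent)
            if (length(shallow)) {
              extra <- sample(shallow, 1L)
              ec <- c(ec, t); er <- c(er, "part_of"); ep <- c(ep, extra)
            }
          }
          made <- made + 1L
        }
        levels[[d + 1L]] <- lv
      }
    }
    terms <- data.frame(accession = acc, name = name, namespace = ns,
                        is_obsolete = FALSE, stringsAsFactors = FALSE)
    edges <- data.frame(child = ec, relation = er, parent = ep,
                        stringsAsFactors = FALSE)
    go_ontology(terms, edges)
  })
}

# Split n terms over `depth` levels with geometric growth at rate
# `branching`, clamping so that every level gets at least one term.
level_sizes <- function(n, depth, branching) {
  raw <- branching^seq_len(depth)
  sizes <- pmax(1, round(raw / sum(raw) * n))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) sizes[which.max(raw)] <- sizes[which.max(raw)] + 1L
  sizes
}

term_depths <- function(ontology) {
  live <- ontology_terms(ontology)
  vapply(live, function(t) length(anc_memo(ontology, t)) - 1L, 1L)
}

#' Sample a gold-standard annotation corpus
#'
#' Per protein and namespace, draws 1 + Poisson(`terms_per_protein` - 1)
#' deep-leaning terms (sampling weight grows with DAG depth squared, so
#' specific terms dominate as in curated corpora) and propagates them.
#' Serves as both the gold standard and the IC reference corpus.
#'
#' @param ontology a [go_ontology] from [make_ontology()].
#' @param config the same [simulation_config()].
#' @return A propagated [annotation_set] with predictor `"reference"`.
#' @export
make_gold <- function(ontology, config) {
  with_seed(config$seed + 104729L, {
    depths <- term_depths(ontology)
    proteins <- sprintf("P%05d", seq_len(config$n_proteins))
    prot <- term <- character(0)
    for (ns in names(ontology$roots)) {
      terms_ns <- ontology_terms(ontology, ns)
      terms_ns <- setdiff(terms_ns, ontology$roots[[ns]])
      w <- (depths[terms_ns] + 1)^2
      k <- 1L + stats::rpois(config$n_proteins, config$terms_per_protein - 1)
      k <- pmin(k, length(terms_ns))
      picked <- lapply(k, function(ki)
        sample(terms_ns, ki, prob = w))
      prot <- c(prot, rep(proteins, k))
      term <- c(term, unlist(picked, use.names = FALSE))
    }
    leaves <- annotation_set("reference", prot, term, 1.0)
    propagate_annotations(leaves, ontology)
  })
}

#' Simulate one predictor's annotation set
#'
#' Emits each gold leaf term with probability `profile$recall`
#' (specificity bias may swap it for an ancestor or child), then adds
#' false-positive terms at the rate implied by `profile$precision`. True
#' records score around 0.85 and false records around 0.2 before Gaussian
#' noise and clipping to \[0, 1\], approximating a calibrated predictor;
#' `constant_score` forces every score to 1.
#'
#' @param gold propagated gold standard from [make_gold()].
#' @param ontology the [go_ontology].
#' @param profile a [method_profile()].
#' @param seed integer seed for this predictor.
#' @param fp_mode `"easy"` or `"hard"` (see [simulation_config()]).
#' @param ic_table required for `fp_mode = "hard"`.
#' @return An [annotation_set] (unpropagated, leaf-level).
#' @export
simulate_predictor <- function(gold, ontology, profile, seed,
                               fp_mode = "easy", ic_table = NULL) {
  stopifnot(inherits(profile, "method_profile"))
  if (fp_mode == "hard" && is.null(ic_table)) {
    usage_error("fp_mode 'hard' needs an ic_table")
  }
  gold_leaves <- leaves_only(gold, ontology)
  gold_sets <- split(gold$term, gold$protein)
  roots <- unname(ontology$roots)
  with_seed(seed, {
    prot <- term <- character(0)
    truth <- logical(0)
    by_prot <- split(gold_leaves$term, gold_leaves$protein)
    all_terms_by_ns <- lapply(names(ontology$roots), function(ns)
      setdiff(ontology_terms(ontology, ns), ontology$roots[[ns]]))
    names(all_terms_by_ns) <- names(ontology$roots)
    for (p in names(by_prot)) {
      leaves <- by_prot[[p]]
      emit <- leaves[stats::runif(length(leaves)) < profile$recall]
      if (length(emit) && profile$specificity_bias != 0) {
        swap <- stats::runif(length(emit)) < abs(profile$specificity_bias)
        for (i in which(swap)) {
          if (profile$specificity_bias < 0) {
            anc <- setdiff(anc_memo(ontology, emit[i]), c(emit[i], roots))
            if (length(anc)) emit[i] <- sample(anc, 1L)
          } else {
            kids <- names(ontology$parents)[vapply(ontology$parents,
              function(ps) emit[i] %in% ps, TRUE)]
            if (length(kids)) emit[i] <- sample(kids, 1L)
          }
        }
        emit <- unique(emit)
      }
      n_true <- length(emit)
      # expected FP count tracks the realised TP count so that the
      # set-level precision matches the profile; a recall-0 method still
      # emits false calls at unit base rate
      fp_base <- if (profile$recall == 0) 1 else n_true
      n_fp <- stats::rpois(1, fp_base * (1 - profile$precision) / profile$precision)
      fps <- character(0)
      if (n_fp > 0) {
        gold_p <- gold_sets[[p]]
        pool <- character(0)
        for (ns in names(all_terms_by_ns)) {
          cand <- setdiff(all_terms_by_ns[[ns]], gold_p)
          if (fp_mode == "hard" && length(emit)) {
            emit_ns <- emit[ontology$namespaces[emit] == ns]
            if (length(emit_ns)) {
              cache <- new.env(parent = emptyenv())
              near <- vapply(cand, function(cc)
                max(lin_many(cc, emit_ns, ic_table, ontology, cache)), 0)
              hard_pool <- cand[near >= 0.2]
              if (length(hard_pool)) cand <- hard_pool
            }
          }
          pool <- c(pool, cand)
        }
        if (length(pool)) {
          fps <- sample(pool, min(n_fp, length(pool)))
        }
      }
      prot <- c(prot, rep(p, length(emit) + length(fps)))
      term <- c(term, emit, fps)
      truth <- c(truth, rep(TRUE, length(emit)), rep(FALSE, length(fps)))
    }
    score <- if (profile$constant_score) {
      rep(1, length(term))
    } else {
      # roughly calibrated two-level scores centred on the method's
      # positive predictive value: a perfect noise-free method scores 1
      base <- ifelse(truth, (1 + profile$precision) / 2,
                     (1 - profile$precision) / 2)
      clip01(base + stats::rnorm(length(term), 0, profile$noise_sd))
    }
    annotation_set(profile$name, prot, term, score)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Ontology, gold standard (doubling as the IC reference) and one
#' annotation set per configured method profile, all deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `ontology`, `gold` (propagated), `gold_leaves`,
#'   `predictions` (named list of [annotation_set]s) and `config`.
#' @export
simulate_benchmark <- function(config) {
  ontology <- make_ontology(config)
  gold <- make_gold(ontology, config)
  ic_table <- if (config$fp_mode == "hard") compute_ic(gold, ontology) else NULL
  predictions <- list()
  for (i in seq_along(config$methods)) {
    prof <- config$methods[[i]]
    predictions[[prof$name]] <- simulate_predictor(
      gold, ontology, prof, seed = config$seed + 7919L * i,
      fp_mode = config$fp_mode, ic_table = ic_table)
  }
  list(ontology = ontology, gold = gold,
       gold_leaves = leaves_only(gold, ontology),
       predictions = predictions, config = config)
}
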