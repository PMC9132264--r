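# Shared fixtures and independent brute-force oracles.

# Toy DAG: root R; A is_a R; B is_a R; A1 is_a A; A part_of B; C is_a B.
toy_terms <- function() {
  data.frame(
    accession = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
                  "GO:0000005"),
    name = c("R", "A", "B", "A1", "C"),
    namespace = "molecular_function",
    is_obsolete = FALSE,
    stringsAsFactors = FALSE)
}

toy_edges <- function() {
  data.frame(
    child = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000002",
              "GO:0000005"),
    relation = c("is_a", "is_a", "is_a", "part_of", "is_a"),
    parent = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000003",
               "GO:0000003"),
    stringsAsFactors = FALSE)
}

toy_ontology <- function() go_ontology(toy_terms(), toy_edges())

# Accession shorthands for readability in tests.
R_ <- "GO:0000001"; A_ <- "GO:0000002"; B_ <- "GO:0000003"
A1_ <- "GO:0000004"; C_ <- "GO:0000005"

# Propagated toy corpus on the toy DAG with term counts
# R:10, B:10, A:5, A1:2 (27 pairs): proteins 1-10 carry B and R,
# 1-5 also A, 1-2 also A1. Closed under ancestors by construction.
# Under root-normalised IC: ic(R)=ic(B)=0, ic(A)=1, ic(A1)=log2(5).
toy_corpus <- function() {
  prot <- sprintf("P%02d", 1:10)
  annotation_set(
    "reference",
    c(rep(prot, 2), prot[1:5], prot[1:2]),
    c(rep(R_, 10), rep(B_, 10), rep(A_, 5), rep(A1_, 2)),
    1.0, propagated = TRUE)
}

toy_obo_text <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: R", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: A", "namespace: molecular_function",
    "alt_id: GO:0000099",
    "is_a: GO:0000001 ! R", "relationship: part_of GO:0000003", "",
    "[Term]", "id: GO:0000003", "name: B", "namespace: molecular_function",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: A1", "namespace: molecular_function",
    "is_a: GO:0000002", "relationship: regulates GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: C", "namespace: molecular_function",
    "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000006", "name: old", "namespace: molecular_function",
    "is_obsolete: true", "replaced_by: GO:0000002", "",
    "[Typedef]", "id: part_of", "name: part of", "")
}

write_toy_obo <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(toy_obo_text(), path)
  path
}

# Naive repeated-BFS ancestor closure (reflexive), the oracle for
# term_ancestors().
oracle_ancestors <- function(ontology, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$parents[frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

# Brute-force Lin similarity: explicit double loop over the two ancestor
# closures to find common ancestors, then the max-IC ratio.
oracle_lin <- function(t1, t2, ic_table, ontology) {
  a1 <- oracle_ancestors(ontology, t1)
  a2 <- oracle_ancestors(ontology, t2)
  common <- character(0)
  for (x in a1) for (y in a2) if (identical(x, y)) common <- c(common, x)
  denom <- ic_of(ic_table, t1, ontology) + ic_of(ic_table, t2, ontology)
  if (denom <= 0 || !length(common)) {
    # same boundary convention as the measure itself: identical non-root
    # terms match perfectly, roots compare at 0
    if (identical(t1, t2) && !(t1 %in% ontology$roots)) return(1)
    return(0)
  }
  best <- -Inf
  for (g in common) best <- max(best, ic_of(ic_table, g, ontology))
  min(1, 2 * best / denom)
}

# Quadratic brute-force feature builder: for every candidate (protein,
# term), scan every other method's records one by one.
oracle_build_features <- function(inputs, ic_table, ontology, registry,
                                  floor = 0.5) {
  rec <- do.call(rbind, lapply(inputs, as.data.frame))
  rec$namespace <- unname(ontology$namespaces[rec$term])
  methods <- unclass(registry)
  cand <- unique(rec[c("protein", "term", "namespace")])
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    p <- cand$protein[i]; t <- cand$term[i]; ns <- cand$namespace[i]
    here <- rec[rec$protein == p & rec$term == t, ]
    src <- NULL; src_score <- -Inf
    for (m in methods) {       # registry order; strict > keeps first on ties
      sc <- here$score[here$predictor == m]
      if (length(sc) && sc > src_score) { src <- m; src_score <- sc }
    }
    row <- list(protein = p, term = t, namespace = ns, source_method = src,
                source_score = src_score,
                source_ic = ic_of(ic_table, t, ontology))
    for (m in methods) {
      slot <- c(present = 0, score = 0, ic = 0, sim = 0)
      if (m != src) {
        mrec <- rec[rec$protein == p & rec$predictor == m, ]
        if (t %in% mrec$term) {
          # a co-predicting method supports with the identical term
          row[[paste0("sup_", m)]] <- c(
            present = 1, score = mrec$score[mrec$term == t][1],
            ic = ic_of(ic_table, t, ontology), sim = 1)
          next
        }
        best_sim <- -Inf; best_term <- NULL
        for (j in seq_len(nrow(mrec))) {
          s <- oracle_lin(t, mrec$term[j], ic_table, ontology)
          ic_j <- ic_of(ic_table, mrec$term[j], ontology)
          better <- s > best_sim + 1e-12 ||
            (abs(s - best_sim) <= 1e-12 &&
               (ic_j > ic_of(ic_table, best_term, ontology) + 1e-12 ||
                  (abs(ic_j - ic_of(ic_table, best_term, ontology)) <= 1e-12 &&
                     mrec$term[j] < best_term)))
          if (is.null(best_term) || better) {
            best_sim <- s; best_term <- mrec$term[j]
          }
        }
        if (!is.null(best_term) && best_sim >= floor) {
          slot <- c(present = 1,
                    score = mrec$score[mrec$term == best_term][1],
                    ic = ic_of(ic_table, best_term, ontology),
                    sim = best_sim)
        }
      }
      row[[paste0("sup_", m)]] <- slot
    }
    rows[[i]] <- row
  }
  rows
}

# Per-protein set-arithmetic evaluation oracle at one explicit threshold.
# pred_sets / pred_scores are per-protein parallel lists of propagated,
# root-free terms and their scores; gold_sets are propagated root-free.
oracle_pr_point <- function(pred_sets, pred_scores, gold_sets, tau) {
  prots <- names(gold_sets)
  precisions <- c()
  for (p in prots) {
    pt <- pred_sets[[p]][pred_scores[[p]] >= tau]
    if (length(pt)) {
      precisions <- c(precisions,
                      length(intersect(pt, gold_sets[[p]])) / length(pt))
    }
  }
  recalls <- vapply(prots, function(p) {
    pt <- pred_sets[[p]][pred_scores[[p]] >= tau]
    length(intersect(pt, gold_sets[[p]])) / length(gold_sets[[p]])
  }, 0)
  list(precision = if (length(precisions)) mean(precisions) else NA_real_,
       recall = mean(recalls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic random DAG via the synthetic generator, for
# property tests.
fixture_config <- function(seed = 42, n_terms = 60, n_proteins = 40,
                           terms_per_protein = 3, depth = 5) {
  simulation_config(seed = seed, n_terms = n_terms, depth = depth,
                    n_proteins = n_proteins,
                    terms_per_protein = terms_per_protein)
}
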