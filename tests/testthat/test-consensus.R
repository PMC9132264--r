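# Separable two-method scenario: both methods agree on every gold term
# (support present, sim 1), and each method's false calls are unsupported.
# Used for the trainable-signal tests below.
separable_scenario <- function(n_proteins = 60, seed = 7) {
  cfg <- fixture_config(seed = seed, n_terms = 60, n_proteins = n_proteins,
                        terms_per_protein = 2)
  ont <- make_ontology(cfg)
  gold <- make_gold(ont, cfg)
  leaves <- leaves_only(gold, ont)
  gold_sets <- split(gold$term, gold$protein)
  # false term per (protein, true term): any term far from everything the
  # other method predicted for that protein (Lin < 0.5 guaranteed by
  # construction check below)
  ic <- compute_ic(gold, ont)
  all_terms <- ontology_terms(ont)
  roots <- unname(ont$roots)
  rec1 <- list(); rec2 <- list()
  set.seed(seed)
  for (p in unique(leaves$protein)) {
    ts <- leaves$term[leaves$protein == p]
    rec1[[p]] <- data.frame(protein = p, term = ts, true = TRUE)
    rec2[[p]] <- data.frame(protein = p, term = ts, true = TRUE)
    # one unsupported false term per method, checked to be dissimilar to
    # every term the other method predicts for this protein
    pool <- setdiff(all_terms, c(gold_sets[[p]], roots))
    for (m in 1:2) {
      for (cand in sample(pool)) {
        same_ns <- ont$namespaces[ts] == ont$namespaces[cand]
        sims_ns <- vapply(ts[same_ns], function(t)
          lin_similarity(cand, t, ic, ont)$value, 0)
        if (!length(sims_ns) || all(sims_ns < 0.45)) {
          if (m == 1) {
            rec1[[p]] <- rbind(rec1[[p]],
                               data.frame(protein = p, term = cand, true = FALSE))
          } else {
            rec2[[p]] <- rbind(rec2[[p]],
                               data.frame(protein = p, term = cand, true = FALSE))
          }
          break
        }
      }
    }
  }
  r1 <- do.call(rbind, rec1); r2 <- do.call(rbind, rec2)
  list(ontology = ont, gold = gold, ic = ic,
       m1 = annotation_set("m1", r1$protein, r1$term, 0.9),
       m2 = annotation_set("m2", r2$protein, r2$term, 0.9))
}

test_that("feature rows carry cross-method support with floored similarity", {
  ont <- toy_ontology()
  ic <- compute_ic(toy_corpus(), ont)
  reg <- method_registry(c("m1", "m2"))

  # Sim(A1, A) = 0.602 >= 0.5: mutual support
  f <- build_features(list(annotation_set("m1", "P1", A1_, 0.9),
                           annotation_set("m2", "P1", A_, 0.8)),
                      ic, ont, reg)
  expect_equal(nrow(f), 2)
  rA1 <- f[f$term == A1_, ]; rA <- f[f$term == A_, ]
  expect_equal(rA1$source_method, "m1")
  expect_equal(rA1$sup_m2_present, 1)
  expect_equal(rA1$sup_m2_score, 0.8)
  expect_equal(rA1$sup_m2_ic, 1)           # ic(A)
  expect_equal(rA1$sup_m2_sim, 2 / (log2(5) + 1), tolerance = 1e-10)
  expect_equal(rA1$sup_m1_present, 0)      # own slot stays zero
  expect_equal(rA$source_method, "m2")
  expect_equal(rA$sup_m1_score, 0.9)
  expect_equal(rA$sup_m1_ic, unname(ic$ic[A1_]))

  # Sim(A1, B) = 0: below the floor, slot zeroed entirely
  g <- build_features(list(annotation_set("m1", "P1", A1_, 0.9),
                           annotation_set("m2", "P1", B_, 0.8)),
                      ic, ont, reg)
  gA1 <- g[g$term == A1_, ]
  expect_equal(gA1$sup_m2_present, 0)
  expect_equal(gA1$sup_m2_score, 0)
  expect_equal(gA1$sup_m2_ic, 0)
  expect_equal(gA1$sup_m2_sim, 0)

  # lone method, others silent: all support slots zero
  h <- build_features(annotation_set("m1", "P1", A1_, 0.9), ic, ont, reg)
  expect_equal(nrow(h), 1)
  expect_equal(h$sup_m2_present, 0)
  expect_equal(h$sup_m1_present, 0)
})

test_that("co-predicted terms collapse to one row with identity supports", {
  ont <- toy_ontology()
  ic <- compute_ic(toy_corpus(), ont)
  reg <- method_registry(c("m1", "m2", "m3"))
  f <- build_features(list(annotation_set("m1", "P1", A1_, 0.7),
                           annotation_set("m2", "P1", A1_, 0.9),
                           annotation_set("m3", "P1", A_, 0.4)),
                      ic, ont, reg)
  expect_equal(nrow(f), 2)
  r <- f[f$term == A1_, ]
  expect_equal(r$source_method, "m2")      # highest score wins
  expect_equal(r$source_score, 0.9)
  expect_equal(r$sup_m1_present, 1)        # co-predictor becomes support
  expect_equal(r$sup_m1_score, 0.7)
  expect_equal(r$sup_m1_sim, 1)
  expect_equal(r$sup_m1_ic, unname(ic$ic[A1_]))
  expect_equal(r$sup_m3_sim, 2 / (log2(5) + 1), tolerance = 1e-10)

  expect_error(
    build_features(annotation_set("other", "P1", A1_, 0.5), ic, ont, reg),
    "unregistered")
  expect_error(
    build_features(propagate_annotations(annotation_set("m1", "P1", A1_, 1), ont),
                   ic, ont, reg),
    "unpropagated")
})

test_that("the feature builder matches the quadratic brute-force oracle", {
  cfg <- fixture_config(seed = 11, n_terms = 50, n_proteins = 4,
                        terms_per_protein = 1)
  bench <- simulate_benchmark(cfg)
  ic <- compute_ic(bench$gold, bench$ontology)
  reg <- method_registry(names(bench$predictions))
  inputs <- bench$predictions
  stopifnot(sum(vapply(inputs, nrow, 1L)) <= 80)

  f <- build_features(inputs, ic, bench$ontology, reg)
  oracle <- oracle_build_features(inputs, ic, bench$ontology, reg)
  expect_equal(nrow(f), length(oracle))
  okey <- vapply(oracle, function(r) paste(r$protein, r$term), "")
  for (i in seq_len(nrow(f))) {
    o <- oracle[[match(paste(f$protein[i], f$term[i]), okey)]]
    expect_equal(f$source_method[i], o$source_method)
    expect_equal(f$source_score[i], o$source_score)
    expect_equal(f$source_ic[i], o$source_ic, tolerance = 1e-10)
    for (m in unclass(reg)) {
      slot <- o[[paste0("sup_", m)]]
      sm <- slot_names <- paste0("sup_", gsub("[^A-Za-z0-9]", "_", m),
                                 c("_present", "_score", "_ic", "_sim"))
      got <- as.numeric(f[i, slot_names])
      expect_equal(got, unname(slot), tolerance = 1e-10)
    }
  }
})

test_that("feature building is invariant to input record order", {
  cfg <- fixture_config(seed = 3, n_terms = 50, n_proteins = 8)
  bench <- simulate_benchmark(cfg)
  ic <- compute_ic(bench$gold, bench$ontology)
  reg <- method_registry(names(bench$predictions))
  f1 <- build_features(bench$predictions, ic, bench$ontology, reg)
  shuffled <- lapply(bench$predictions, function(x) {
    y <- x[rev(seq_len(nrow(x))), ]
    annotation_set(y$predictor, y$protein, y$term, y$score)
  })
  f2 <- build_features(rev(shuffled), ic, bench$ontology, reg)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("labelling uses propagated gold membership and drops unknown proteins", {
  ont <- toy_ontology()
  ic <- compute_ic(toy_corpus(), ont)
  reg <- method_registry(c("m1", "m2"))
  f <- build_features(list(annotation_set("m1", c("P1", "P1", "P9"),
                                          c(A_, C_, A_), 0.9),
                           annotation_set("m2", "P1", A1_, 0.8)),
                      ic, ont, reg)
  gold <- propagate_annotations(annotation_set("gold", "P1", A1_, 1), ont)
  lf <- label_features(f, gold, ont)
  expect_false("P9" %in% lf$protein)          # protein absent from gold
  expect_equal(lf$label[lf$term == A_], 1L)   # ancestor of the gold leaf
  expect_equal(lf$label[lf$term == A1_], 1L)
  expect_equal(lf$label[lf$term == C_], 0L)
  expect_error(label_features(f, annotation_set(propagated = TRUE), ont), "empty")
  expect_error(
    label_features(f, annotation_set("g", "P1", A1_, 1), ont), "propagated")
})

test_that("training learns a separable support signal and refuses degenerate input", {
  sc <- separable_scenario()
  reg <- method_registry(c("m1", "m2"))
  f <- build_features(list(sc$m1, sc$m2), sc$ic, sc$ontology, reg)
  f <- label_features(f, sc$gold, sc$ontology)
  prot <- unique(f$protein)
  train_p <- prot[seq_len(40)]
  ftr <- f[f$protein %in% train_p, ]
  fte <- f[!(f$protein %in% train_p), ]

  model <- train_consensus(ftr, n_estimators = 30, seed = 1)
  pred <- predict(model, fte)
  acc <- mean((pred$consensus_score >= 0.5) == (fte$label == 1))
  expect_equal(acc, 1)   # perfectly separable by support presence

  # supported rows outscore the same rows with supports zeroed
  fz <- fte
  zcols <- grep("^sup_", attr(f, "feature_cols"), value = TRUE)
  fz[zcols] <- 0
  predz <- predict(model, fz)
  has_sup <- fte[[paste0("sup_m1_present")]] +
    fte[[paste0("sup_m2_present")]] > 0
  expect_gt(mean(pred$consensus_score[has_sup]),
            mean(predz$consensus_score[has_sup]))

  # single-class namespace refuses to train
  expect_error(train_consensus(ftr[ftr$label == 1, ], n_estimators = 5),
               "single label class")

  # fewer rows than calibration folds (both classes present, 9 rows)
  ns1 <- ftr[ftr$namespace == ftr$namespace[1], ]
  tiny <- ns1[c(which(ns1$label == 1)[1:5], which(ns1$label == 0)[1:4]), ]
  expect_error(train_consensus(tiny, n_estimators = 5, n_folds = 10),
               "fold")
})

test_that("shuffled labels give chance-level discrimination", {
  sc <- separable_scenario(n_proteins = 80, seed = 19)
  reg <- method_registry(c("m1", "m2"))
  f <- build_features(list(sc$m1, sc$m2), sc$ic, sc$ontology, reg)
  f <- label_features(f, sc$gold, sc$ontology)
  set.seed(5)
  f$label <- sample(f$label)
  prot <- unique(f$protein)
  ftr <- f[f$protein %in% prot[1:55], ]
  fte <- f[!(f$protein %in% prot[1:55]), ]
  model <- train_consensus(ftr, n_estimators = 20, seed = 2)
  pred <- predict(model, fte)
  pos <- pred$consensus_score[fte$label == 1]
  neg <- pred$consensus_score[fte$label == 0]
  auroc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(auroc, 0.3)
  expect_lt(auroc, 0.7)
})

test_that("prediction handles boundaries, determinism, and registry guards", {
  sc <- separable_scenario(n_proteins = 20, seed = 23)
  reg <- method_registry(c("m1", "m2"))
  f <- build_features(list(sc$m1, sc$m2), sc$ic, sc$ontology, reg)
  lf <- label_features(f, sc$gold, sc$ontology)
  model <- train_consensus(lf, n_estimators = 10, seed = 1)

  # empty feature table scores to an empty result
  empty <- build_features(list(), compute_ic(sc$gold, sc$ontology),
                          sc$ontology, reg)
  expect_equal(nrow(predict(model, empty)), 0)

  p0 <- predict(model, f, threshold = 0)
  expect_true(all(p0$verdict == "confident"))
  p2 <- predict(model, f, threshold = 1.001)
  expect_true(all(p2$verdict == "rejected"))

  # identical inputs scored twice give identical scores
  expect_identical(predict(model, f)$consensus_score,
                   predict(model, f)$consensus_score)

  # confident and rejected partition the scored set
  p <- predict(model, f)
  expect_equal(nrow(consensus_annotations(p, "confident")) +
                 nrow(consensus_annotations(p, "rejected")),
               nrow(p))

  # a registry mismatch is refused
  reg3 <- method_registry(c("m1", "m2", "m3"))
  f3 <- build_features(list(sc$m1, sc$m2), sc$ic, sc$ontology, reg3)
  expect_error(predict(model, f3), "registry mismatch")
})

test_that("models round-trip through save/load with identical predictions", {
  sc <- separable_scenario(n_proteins = 20, seed = 31)
  reg <- method_registry(c("m1", "m2"))
  f <- build_features(list(sc$m1, sc$m2), sc$ic, sc$ontology, reg)
  lf <- label_features(f, sc$gold, sc$ontology)
  model <- train_consensus(lf, n_estimators = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict(back, f)$consensus_score,
                   predict(model, f)$consensus_score)
  expect_error(load_model(tempfile()), "not found")

  # scoring with features from a different IC table warns via fingerprint
  ic2 <- compute_ic(sc$gold, sc$ontology, base = exp(1))
  f2 <- build_features(list(sc$m1, sc$m2), ic2, sc$ontology, reg)
  expect_warning(predict(model, f2), "IC table")
})

test_that("a method registry needs at least two uniquely named methods", {
  expect_error(method_registry("only"), "at least 2")
  expect_error(method_registry(c("a", "a")), "unique")
})
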