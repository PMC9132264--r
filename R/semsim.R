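#' Information content of GO terms from a reference corpus
#'
#' IC of a term is the negative log of its relative annotation frequency in
#' a propagated reference corpus. Counts are taken after DAG propagation,
#' which makes IC monotone non-increasing toward the root and keeps Lin
#' similarity bounded by 1.
#'
#' Two denominators are supported. The default, `"root"`, normalises each
#' term's propagated protein count by the propagated count of its namespace
#' root (the standard Resnik/Lin construction): `ic(t) =
#' -log(count(t)/count(root))`, so every root has IC 0. The `"corpus"`
#' variant divides by the total number of annotation pairs in the corpus
#' instead, reading the relative-frequency definition literally; under it
#' root ICs are positive.
#'
#' Terms absent from the reference receive the maximal IC of a
#' single-count pseudo-observation, `-log(1/denominator)`, so similarities
#' stay defined for novel predictor terms.
#'
#' @param reference a propagated [annotation_set] (use
#'   [propagate_annotations()] first).
#' @param ontology a [go_ontology].
#' @param base logarithm base; 2 by default, giving ICs in bits.
#' @param denominator `"root"` (per-namespace root count, default) or
#'   `"corpus"` (total annotation pairs).
#' @return An object of class `ic_table`.
#' @export
compute_ic <- function(reference, ontology, base = 2,
                       denominator = c("root", "corpus")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(reference, "annotation_set"))
  if (nrow(reference) == 0) data_error("reference corpus is empty")
  if (!is_propagated(reference)) {
    data_error("reference must be propagated; call propagate_annotations() first")
  }
  pairs <- unique(data.frame(protein = reference$protein,
                             term = reference$term,
                             stringsAsFactors = FALSE))
  counts <- table(pairs$term)
  n_pairs <- nrow(pairs)
  term_ns <- ontology$namespaces[names(counts)]
  root_counts <- numeric(0)
  for (ns in names(ontology$roots)) {
    rc <- counts[ontology$roots[[ns]]]
    root_counts[ns] <- if (is.na(rc)) 0 else as.numeric(rc)
  }
  denom <- switch(denominator,
                  root = root_counts[term_ns],
                  corpus = rep(n_pairs, length(counts)))
  ic <- -log(as.numeric(counts) / as.numeric(denom)) / log(base)
  ic[ic < 0] <- 0  # guard against counts above the root count (cannot occur
                   # in a propagated corpus; kept for numerical safety)
  structure(
    list(ic = stats::setNames(ic, names(counts)),
         n_pairs = n_pairs,
         root_counts = root_counts,
         base = base,
         denominator = denominator,
         propagated_counts = TRUE),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ic_table: %d terms, base %g (%s), denominator '%s', %d annotation pairs\n",
              length(x$ic), x$base, if (x$base == 2) "bits" else "log units",
              x$denominator, x$n_pairs))
  invisible(x)
}

# Smoothing value for a term unseen in the reference: one pseudo-count
# over the applicable denominator.
ic_smoothing <- function(ic_table, ns) {
  denom <- switch(ic_table$denominator,
                  root = ic_table$root_counts[ns],
                  corpus = rep(ic_table$n_pairs, length(ns)))
  denom[is.na(denom) | denom < 1] <- 1
  log(as.numeric(denom)) / log(ic_table$base)
}

#' Look up information content with smoothing
#'
#' @param ic_table an `ic_table` from [compute_ic()].
#' @param terms character vector of accessions.
#' @param ontology a [go_ontology] (needed to attribute unseen terms to a
#'   namespace for the smoothing value).
#' @return numeric vector of ICs.
#' @export
ic_of <- function(ic_table, terms, ontology) {
  out <- unname(ic_table$ic[terms])
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- ic_smoothing(ic_table, ontology$namespaces[terms[miss]])
  }
  out
}

#' Serialise an IC table to TSV
#'
#' Header comment lines record the corpus size, log base, denominator
#' convention and propagation flag, so a trained model can be re-used with
#' exactly the IC table that produced its features.
#'
#' @param ic_table an `ic_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(ic_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_pairs=%d", ic_table$n_pairs),
    sprintf("# base=%.10g", ic_table$base),
    sprintf("# denominator=%s", ic_table$denominator),
    sprintf("# propagated_counts=%s", ic_table$propagated_counts),
    sprintf("# root_counts=%s",
            paste(sprintf("%s:%d", names(ic_table$root_counts),
                          as.integer(ic_table$root_counts)), collapse = ","))
  ), con)
  utils::write.table(
    data.frame(term = names(ic_table$ic), ic = sprintf("%.12g", ic_table$ic)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an IC table written by [write_ic_table()]
#'
#' @param path path to the TSV file.
#' @return An `ic_table`.
#' @export
read_ic_table <- function(path) {
  if (!file.exists(path)) data_error("IC table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & lines != ""]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (!length(ln)) data_error("IC table header missing '%s'", key)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  rc_str <- strsplit(get_field("root_counts"), ",", fixed = TRUE)[[1]]
  rc_parts <- strsplit(rc_str, ":", fixed = TRUE)
  root_counts <- stats::setNames(
    vapply(rc_parts, function(p) as.numeric(p[2]), 0),
    vapply(rc_parts, `[[`, "", 1))
  parts <- strsplit(body, "\t", fixed = TRUE)
  structure(
    list(ic = stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                              vapply(parts, `[[`, "", 1)),
         n_pairs = as.integer(get_field("n_pairs")),
         root_counts = root_counts,
         base = as.numeric(get_field("base")),
         denominator = get_field("denominator"),
         propagated_counts = identical(get_field("propagated_counts"), "TRUE")),
    class = "ic_table"
  )
}

#' Lin semantic similarity between two terms
#'
#' `Sim(a, b) = 2 * IC(MICA) / (IC(a) + IC(b))`, where the MICA is the most
#' informative common ancestor over the reflexive `is_a`/`part_of` closure.
#' Self-similarity of any non-root term is 1 (for positive IC this follows
#' from the formula; at the 0/0 boundary it is taken as the convention,
#' since an identical term is a perfect match however common it is).
#' Comparisons whose IC sum is 0 otherwise — root against root, or two
#' distinct zero-IC terms — score 0. The value is invariant to the IC log
#' base.
#'
#' @param t1,t2 accessions in the same namespace.
#' @param ic_table an `ic_table`.
#' @param ontology a [go_ontology].
#' @return list with `value` (in \[0, 1\]) and `mica` (accession attaining
#'   the maximum; ties broken by lexicographically smallest accession).
#' @export
lin_similarity <- function(t1, t2, ic_table, ontology) {
  r1 <- resolve_terms(ontology, t1)
  r2 <- resolve_terms(ontology, t2)
  if (is.na(r1) || is.na(r2)) {
    data_error("unknown accession(s): %s",
               paste(c(t1, t2)[c(is.na(r1), is.na(r2))], collapse = ", "))
  }
  ns1 <- ontology$namespaces[r1]; ns2 <- ontology$namespaces[r2]
  if (!identical(unname(ns1), unname(ns2))) {
    data_error("similarity undefined across namespaces (%s vs %s)", ns1, ns2)
  }
  shared <- intersect(anc_memo(ontology, r1), anc_memo(ontology, r2))
  lin_from_shared(r1, r2, shared, ic_table, ontology)
}

lin_from_shared <- function(r1, r2, shared, ic_table, ontology) {
  denom <- sum(ic_of(ic_table, c(r1, r2), ontology))
  if (denom <= 0 || !length(shared)) {
    # 0/0 boundary: an identical non-root term is still a perfect match
    # (zero IC just means the corpus cannot distinguish it from its
    # namespace); roots compare at 0
    if (identical(r1, r2) && !(r1 %in% ontology$roots)) {
      return(list(value = 1, mica = r1))
    }
    return(list(value = 0, mica = NA_character_))
  }
  ics <- ic_of(ic_table, shared, ontology)
  mx <- max(ics)
  cand <- sort(shared[ics == mx])
  list(value = min(1, 2 * mx / denom), mica = cand[1])
}

#' Most similar supporting term from a candidate set
#'
#' Given a query annotation's term and the term set another method
#' predicted for the same protein, returns the candidate with the highest
#' Lin similarity to the query, provided that similarity reaches the floor
#' (0.5 by default). Ties break by higher similarity, then higher candidate
#' IC, then lexicographically smallest accession.
#'
#' @param query accession of the annotation being supported.
#' @param candidates character vector of accessions from the other method
#'   (same namespace as `query`).
#' @param ic_table an `ic_table`.
#' @param ontology a [go_ontology].
#' @param floor minimum similarity for support to count (default 0.5).
#' @return `NULL` when no candidate qualifies, else a list with `term`,
#'   `similarity` and `mica`.
#' @export
best_support_term <- function(query, candidates, ic_table, ontology,
                              floor = 0.5) {
  if (!length(candidates)) return(NULL)
  sims <- vapply(candidates, function(cand)
    lin_similarity(query, cand, ic_table, ontology)$value, 0)
  best <- max(sims)
  if (best < floor) return(NULL)
  top <- candidates[sims >= best - 1e-12]
  if (length(top) > 1) {
    ics <- ic_of(ic_table, top, ontology)
    top <- top[ics >= max(ics) - 1e-12]
    top <- sort(top)
  }
  chosen <- top[1]
  list(term = chosen,
       similarity = best,
       mica = lin_similarity(query, chosen, ic_table, ontology)$mica)
}

# Fast path used by the feature builder: similarity of one query term to
# many candidates, with precomputed ancestor sets and a pair cache.
lin_many <- function(query, candidates, ic_table, ontology, cache) {
  vapply(candidates, function(cand) {
    key <- if (query < cand) paste(query, cand) else paste(cand, query)
    hit <- get0(key, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    shared <- intersect(anc_memo(ontology, query), anc_memo(ontology, cand))
    v <- lin_from_shared(query, cand, shared, ic_table, ontology)$value
    assign(key, v, envir = cache)
    v
  }, 0)
}
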