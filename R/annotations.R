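#' Construct an annotation set
#'
#' An `annotation_set` is a data.frame with columns `predictor`, `protein`,
#' `term`, `score` and an attribute recording whether ancestors have been
#' propagated. Duplicate (predictor, protein, term) rows collapse to the
#' maximum score, which keeps construction order-independent.
#'
#' @param predictor,protein,term character vectors (recycled to a common
#'   length).
#' @param score numeric vector of probabilities in \[0, 1\].
#' @param propagated logical; has the set already been closed under
#'   ancestors?
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(predictor = character(0), protein = character(0),
                           term = character(0), score = numeric(0),
                           propagated = FALSE) {
  n <- max(length(predictor), length(protein), length(term), length(score))
  if (n > 0) {
    predictor <- rep_len(as.character(predictor), n)
    protein <- rep_len(as.character(protein), n)
    term <- rep_len(as.character(term), n)
    score <- rep_len(as.numeric(score), n)
  }
  bad <- is.na(score) | score < 0 | score > 1
  if (any(bad)) {
    data_error("score(s) outside [0,1]: %s",
               paste(utils::head(format(score[bad]), 5), collapse = ", "))
  }
  df <- data.frame(predictor = predictor, protein = protein, term = term,
                   score = score, stringsAsFactors = FALSE)
  df <- collapse_max(df)
  structure(df, class = c("annotation_set", "data.frame"),
            propagated = propagated)
}

# max-collapse duplicate (predictor, protein, term) keys
collapse_max <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$predictor, df$protein, df$term, sep = "\r")
  if (!anyDuplicated(key)) {
    o <- order(df$predictor, df$protein, df$term)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    return(df)
  }
  mx <- tapply(df$score, key, max)
  first <- df[!duplicated(key), , drop = FALSE]
  first$score <- as.numeric(mx[paste(first$predictor, first$protein,
                                     first$term, sep = "\r")])
  o <- order(first$predictor, first$protein, first$term)
  first <- first[o, , drop = FALSE]
  rownames(first) <- NULL
  first
}

is_propagated <- function(x) isTRUE(attr(x, "propagated"))

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d records, %d protein(s), %d predictor(s)%s\n",
              nrow(x), length(unique(x$protein)), length(unique(x$predictor)),
              if (is_propagated(x)) " [propagated]" else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a 4-column predictor table
#'
#' The expected layout is tab-separated with columns predictor name, protein
#' identifier, GO term accession and probability score. Lines starting with
#' `#` (and an optional header written that way) are skipped. Scores outside
#' \[0, 1\] raise an error naming the offending line; constant-score inputs
#' (e.g. domain-scan methods that emit probability 1 for everything) are
#' valid.
#'
#' @param path path to the TSV file.
#' @param ontology optional [go_ontology]; when supplied, accessions are
#'   resolved (alt ids, `replaced_by`) and unresolvable records are skipped
#'   with a message reporting the count.
#' @return An [annotation_set].
#' @export
read_predictions <- function(path, ontology = NULL) {
  if (!file.exists(path)) data_error("prediction table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(grepl("^\\s*$", lines) | startsWith(lines, "#"))
  idx <- which(keep)
  if (!length(idx)) {
    return(annotation_set())
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing 5th column (the consensus verdict) is tolerated on re-read
  if (any(nf != nf[1]) || !(nf[1] %in% c(4L, 5L))) {
    bad <- which(!(nf %in% c(4L, 5L)) | nf != nf[1])[1]
    data_error("line %d: expected 4 tab-separated columns, found %d",
               idx[bad], nf[bad])
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad)) {
    data_error("line %d: score '%s' is not a probability in [0,1]",
               idx[bad[1]], m[bad[1], 4])
  }
  predictor <- m[, 1]; protein <- m[, 2]; term <- m[, 3]
  if (!is.null(ontology)) {
    resolved <- resolve_terms(ontology, term)
    drop <- is.na(resolved)
    if (any(drop)) {
      message(sprintf("read_predictions: skipped %d record(s) with unresolvable accessions",
                      sum(drop)))
    }
    predictor <- predictor[!drop]; protein <- protein[!drop]
    score <- score[!drop]; term <- resolved[!drop]
  }
  annotation_set(predictor, protein, term, score)
}

#' Write an annotation set as a 4-column TSV
#'
#' @param x an [annotation_set] (or a consensus result; any data.frame with
#'   the four columns).
#' @param path output path.
#' @param verdict optional character vector (e.g. confident/rejected)
#'   appended as a fifth column.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(x, path, verdict = NULL) {
  df <- data.frame(predictor = x$predictor, protein = x$protein,
                   term = x$term, score = sprintf("%.6f", x$score),
                   stringsAsFactors = FALSE)
  if (!is.null(verdict)) df$verdict <- verdict
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GAF 2.x reference annotation file
#'
#' Comment lines start with `!`. Rows with a `NOT` qualifier are excluded;
#' an optional evidence-code exclusion list (e.g. `"IEA"`) filters on
#' column 7. All records are stored under the sentinel predictor name
#' `"reference"` with score 1.
#'
#' @param path path to the GAF file.
#' @param ontology a [go_ontology] used to resolve accessions; unresolvable
#'   records are skipped with a reported count.
#' @param exclude_evidence character vector of evidence codes to drop
#'   (default none).
#' @return An [annotation_set].
#' @export
read_gaf <- function(path, ontology, exclude_evidence = character(0)) {
  if (!file.exists(path)) data_error("GAF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & !grepl("^\\s*$", lines)]
  if (!length(lines)) return(annotation_set(propagated = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 15L)) {
    data_error("not a GAF 2.x layout: row with %d column(s), expected >= 15",
               min(nf))
  }
  protein <- vapply(parts, `[[`, "", 2L)
  qualifier <- vapply(parts, `[[`, "", 4L)
  term <- vapply(parts, `[[`, "", 5L)
  evidence <- vapply(parts, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (length(exclude_evidence)) keep <- keep & !(evidence %in% exclude_evidence)
  protein <- protein[keep]; term <- term[keep]
  resolved <- resolve_terms(ontology, term)
  drop <- is.na(resolved)
  if (any(drop)) {
    message(sprintf("read_gaf: skipped %d record(s) with unresolvable accessions",
                    sum(drop)))
  }
  annotation_set(predictor = "reference", protein = protein[!drop],
                 term = resolved[!drop], score = 1.0)
}

#' Propagate annotations up the DAG
#'
#' Adds every `is_a`/`part_of` ancestor of each annotated term, carrying
#' the maximum score over the descendants already present for that protein
#' (max-propagation keeps scores interpretable as probabilities and matches
#' the CAFA convention). The operation is idempotent.
#'
#' @param x an [annotation_set].
#' @param ontology a [go_ontology].
#' @return A propagated [annotation_set].
#' @export
propagate_annotations <- function(x, ontology) {
  stopifnot(inherits(x, "annotation_set"))
  if (nrow(x) == 0) {
    return(annotation_set(propagated = TRUE))
  }
  anc <- ancestors_list(ontology, x$term)
  nrep <- lengths(anc[x$term])
  out <- annotation_set(
    predictor = rep(x$predictor, nrep),
    protein = rep(x$protein, nrep),
    term = unlist(anc[x$term], use.names = FALSE),
    score = rep(x$score, nrep),
    propagated = TRUE
  )
  out
}

#' Reduce an annotation set to its leaf terms
#'
#' Keeps, per predictor and protein, only terms with no annotated
#' descendant for that same protein (a term is dropped when it is a proper
#' ancestor of another annotated term).
#'
#' @param x an [annotation_set].
#' @param ontology a [go_ontology].
#' @return An [annotation_set] with `propagated = FALSE`.
#' @export
leaves_only <- function(x, ontology) {
  stopifnot(inherits(x, "annotation_set"))
  if (nrow(x) == 0) return(annotation_set())
  anc <- ancestors_list(ontology, x$term)
  grp <- paste(x$predictor, x$protein, sep = "\r")
  keep <- logical(nrow(x))
  for (g in split(seq_len(nrow(x)), grp)) {
    terms_g <- x$term[g]
    covered <- unique(unlist(lapply(terms_g, function(t) setdiff(anc[[t]], t)),
                             use.names = FALSE))
    keep[g] <- !(terms_g %in% covered)
  }
  out <- x[keep, , drop = FALSE]
  annotation_set(out$predictor, out$protein, out$term, out$score)
}

#' Restrict an annotation set
#'
#' @param x an [annotation_set].
#' @param proteins optional protein identifiers to keep.
#' @param namespace optional namespace (terms are mapped through the
#'   ontology).
#' @param ontology required when `namespace` is given.
#' @param predictors optional predictor names to keep.
#' @return An [annotation_set] with the original `propagated` flag.
#' @export
filter_annotations <- function(x, proteins = NULL, namespace = NULL,
                               ontology = NULL, predictors = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(proteins)) keep <- keep & x$protein %in% proteins
  if (!is.null(predictors)) keep <- keep & x$predictor %in% predictors
  if (!is.null(namespace)) {
    stopifnot(!is.null(ontology))
    keep <- keep & ontology$namespaces[x$term] %in% namespace
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- attr(x, "propagated")
  class(out) <- class(x)
  out
}
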