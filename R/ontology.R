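#' Gene Ontology DAG container
#'
#' An `go_ontology` object holds the parsed term table, the relation edges,
#' and the propagation graph restricted to the `is_a` and `part_of`
#' relations. Every other module queries the DAG through [term_ancestors()].
#'
#' @details
#' The propagation graph keeps only `is_a` and `part_of` edges between
#' non-obsolete terms of the same namespace; other relation types (the
#' `regulates` family and friends) are parsed and stored in `$edges` but
#' never traversed. Each namespace must have exactly one root (a term with
#' no propagating parents) and the propagating edge set must be acyclic;
#' both conditions are verified at construction time.
#'
#' Alternate identifiers (`alt_id`) resolve to their primary accession.
#' Obsolete terms are excluded from the propagation graph; annotations that
#' cite them are remapped through `replaced_by` when available and dropped
#' otherwise.
#'
#' @param terms data.frame with columns `accession`, `name`, `namespace`,
#'   `is_obsolete`.
#' @param edges data.frame with columns `child`, `relation`, `parent`.
#' @param alt_ids named character vector mapping alternate accession to
#'   primary accession.
#' @param replaced_by named character vector mapping obsolete accession to
#'   its replacement.
#' @return An object of class `go_ontology`.
#' @export
go_ontology <- function(terms, edges,
                        alt_ids = character(0),
                        replaced_by = character(0)) {
  stopifnot(all(c("accession", "name", "namespace", "is_obsolete") %in% names(terms)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("child", "relation", "parent") %in% names(edges)))
  } else {
    edges <- data.frame(child = character(0), relation = character(0),
                        parent = character(0), stringsAsFactors = FALSE)
  }
  terms <- terms[!duplicated(terms$accession), , drop = FALSE]
  rownames(terms) <- NULL
  namespaces <- stats::setNames(terms$namespace, terms$accession)
  obsolete <- terms$accession[terms$is_obsolete]

  known <- terms$accession
  bad <- !(edges$child %in% known & edges$parent %in% known)
  if (any(bad)) {
    warning(sprintf("dropping %d edge(s) referencing unknown terms", sum(bad)))
    edges <- edges[!bad, , drop = FALSE]
  }

  # propagation graph: is_a / part_of, non-obsolete, same namespace
  prop <- edges[edges$relation %in% c("is_a", "part_of"), , drop = FALSE]
  prop <- prop[!(prop$child %in% obsolete) & !(prop$parent %in% obsolete), , drop = FALSE]
  prop <- prop[namespaces[prop$child] == namespaces[prop$parent], , drop = FALSE]
  prop <- prop[!duplicated(prop[c("child", "parent")]), , drop = FALSE]

  live <- setdiff(known, obsolete)
  parents <- split(prop$parent, factor(prop$child, levels = live))

  check_acyclic(parents, live)

  roots <- character(0)
  for (ns in unique(namespaces[live])) {
    ns_terms <- live[namespaces[live] == ns]
    parentless <- ns_terms[vapply(parents[ns_terms], length, 1L) == 0L]
    if (length(parentless) != 1L) {
      data_error("namespace '%s' must have exactly one root; found %d (%s)",
                 ns, length(parentless),
                 paste(utils::head(parentless, 5), collapse = ", "))
    }
    roots[ns] <- parentless
  }

  if (length(alt_ids)) {
    bad_alt <- alt_ids[!(alt_ids %in% live)]
    if (length(bad_alt)) {
      data_error("alt_id target(s) not primary live terms: %s",
                 paste(utils::head(unique(bad_alt), 5), collapse = ", "))
    }
  }

  structure(
    list(terms = terms, edges = edges, parents = parents,
         namespaces = namespaces, roots = roots,
         alt_ids = alt_ids, replaced_by = replaced_by,
         obsolete = obsolete, cache = new.env(parent = emptyenv())),
    class = "go_ontology"
  )
}

# Kahn's algorithm on the propagating edges; stops with an integrity error
# when a cycle exists.
check_acyclic <- function(parents, nodes) {
  indeg <- vapply(parents, length, 1L)
  children <- new.env(parent = emptyenv())
  for (ch in names(parents)) {
    for (p in parents[[ch]]) {
      assign(p, c(get0(p, envir = children, ifnotfound = character(0)), ch),
             envir = children)
    }
  }
  # process from parentless terms downward: remove edges child -> parent by
  # peeling nodes whose parents are all removed. Equivalent: Kahn on the
  # reversed graph (parent -> child), indegree = number of parents.
  queue <- nodes[indeg[nodes] == 0L]
  seen <- 0L
  indeg_env <- as.list(indeg)
  while (length(queue)) {
    n <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in get0(n, envir = children, ifnotfound = character(0))) {
      indeg_env[[ch]] <- indeg_env[[ch]] - 1L
      if (indeg_env[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(nodes)) {
    data_error("is_a/part_of graph contains a cycle (%d term(s) unreachable from roots)",
               length(nodes) - seen)
  }
  invisible(TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  live <- setdiff(x$terms$accession, x$obsolete)
  cat(sprintf("go_ontology: %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), length(x$obsolete), nrow(x$edges)))
  for (ns in names(x$roots)) {
    cat(sprintf("  %s: %d terms, root %s\n", ns,
                sum(x$namespaces[live] == ns), x$roots[[ns]]))
  }
  invisible(x)
}

#' Parse an OBO 1.2/1.4 flat file
#'
#' Reads `[Term]` stanzas: accession, name, namespace, `is_a` and
#' `relationship` lines, `alt_id`, `is_obsolete` and `replaced_by`. All
#' relation types are stored, but only `is_a` and `part_of` enter the
#' propagation graph.
#'
#' @param path path to an OBO file.
#' @return A [go_ontology] object.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) data_error("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  acc <- name <- ns <- character(0)
  obs <- logical(0)
  ec <- er <- ep <- character(0)   # edge child / relation / parent
  alt <- repl <- character(0)

  flush_term <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    acc <<- c(acc, cur$id)
    name <<- c(name, cur$name %||% "")
    ns <<- c(ns, cur$namespace %||% NA_character_)
    obs <<- c(obs, isTRUE(cur$obsolete))
    if (length(cur$edges)) {
      for (e in cur$edges) {
        ec <<- c(ec, cur$id); er <<- c(er, e[1]); ep <<- c(ep, e[2])
      }
    }
    for (a in cur$alt_ids) alt[a] <<- cur$id
    if (!is.null(cur$replaced_by)) repl[cur$id] <<- cur$replaced_by
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      flush_term()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(edges = list(), alt_ids = character(0))
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) {
      data_error("malformed OBO stanza line %d: '%s'", i, line)
    }
    key <- m[2]
    val <- sub("\\s*!.*$", "", m[3])  # strip trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "replaced_by") cur$replaced_by <- val
    else if (key == "is_a") cur$edges <- c(cur$edges, list(c("is_a", val)))
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) data_error("malformed relationship at line %d: '%s'", i, line)
      cur$edges <- c(cur$edges, list(c(parts[1], parts[2])))
    }
    # other keys (def, synonym, xref, subset, ...) ignored
  }
  flush_term()

  if (!length(acc)) data_error("no [Term] stanzas found in %s", path)
  if (anyNA(ns)) {
    data_error("term(s) missing a namespace: %s",
               paste(utils::head(acc[is.na(ns)], 5), collapse = ", "))
  }
  terms <- data.frame(accession = acc, name = name, namespace = ns,
                      is_obsolete = obs, stringsAsFactors = FALSE)
  edges <- data.frame(child = ec, relation = er, parent = ep,
                      stringsAsFactors = FALSE)
  go_ontology(terms, edges, alt_ids = alt, replaced_by = repl)
}

#' Write an ontology back to OBO format
#'
#' @param ontology a [go_ontology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "go_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  alt_by_primary <- if (length(ontology$alt_ids)) {
    split(names(ontology$alt_ids), ontology$alt_ids)
  } else {
    list()
  }
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    out <- c("[Term]",
             paste0("id: ", t$accession),
             paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    for (a in alt_by_primary[[t$accession]] %||% character(0)) {
      out <- c(out, paste0("alt_id: ", a))
    }
    e <- ontology$edges[ontology$edges$child == t$accession, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out,
               if (e$relation[j] == "is_a") paste0("is_a: ", e$parent[j])
               else paste0("relationship: ", e$relation[j], " ", e$parent[j]))
    }
    if (t$is_obsolete) {
      out <- c(out, "is_obsolete: true")
      rb <- ontology$replaced_by[t$accession]
      if (!is.na(rb)) out <- c(out, paste0("replaced_by: ", rb))
    }
    writeLines(c(out, ""), con)
  }
  writeLines(c("[Typedef]", "id: part_of", "name: part of", ""), con)
  invisible(path)
}

#' Resolve accessions to primary, live terms
#'
#' Alternate accessions map to their primary accession; obsolete terms map
#' through `replaced_by` when present and to `NA` otherwise; unknown
#' accessions map to `NA`.
#'
#' @param ontology a [go_ontology].
#' @param terms character vector of accessions.
#' @return character vector of resolved accessions (`NA` where unresolvable).
#' @export
resolve_terms <- function(ontology, terms) {
  out <- terms
  is_alt <- out %in% names(ontology$alt_ids)
  out[is_alt] <- ontology$alt_ids[out[is_alt]]
  is_obs <- out %in% ontology$obsolete
  if (any(is_obs)) {
    rb <- ontology$replaced_by[out[is_obs]]
    out[is_obs] <- ifelse(is.na(rb), NA_character_, rb)
    # a replacement could itself be an alt_id
    again <- !is.na(out) & out %in% names(ontology$alt_ids)
    out[again] <- ontology$alt_ids[out[again]]
  }
  live <- setdiff(ontology$terms$accession, ontology$obsolete)
  out[!(out %in% live)] <- NA_character_
  out
}

#' Ancestor closure of a term
#'
#' Reflexive-transitive closure over the `is_a`/`part_of` propagation graph:
#' the result contains the query term itself and its namespace root.
#' Closures are memoised on the ontology object, so repeated queries are
#' cheap.
#'
#' @param ontology a [go_ontology].
#' @param term a single accession (alternate ids are resolved first).
#' @return character vector of accessions.
#' @export
term_ancestors <- function(ontology, term) {
  stopifnot(inherits(ontology, "go_ontology"), length(term) == 1L)
  resolved <- resolve_terms(ontology, term)
  if (is.na(resolved)) {
    data_error("unknown or unresolvable accession: %s", term)
  }
  anc_memo(ontology, resolved)
}

anc_memo <- function(ontology, term) {
  cached <- get0(term, envir = ontology$cache, ifnotfound = NULL)
  if (!is.null(cached)) return(cached)
  # iterative DFS with memoisation (post-order)
  stack <- term
  while (length(stack)) {
    top <- stack[[length(stack)]]
    if (!is.null(get0(top, envir = ontology$cache, ifnotfound = NULL))) {
      stack <- stack[-length(stack)]
      next
    }
    ps <- ontology$parents[[top]] %||% character(0)
    pending <- ps[vapply(ps, function(p)
      is.null(get0(p, envir = ontology$cache, ifnotfound = NULL)), TRUE)]
    if (length(pending)) {
      stack <- c(stack, pending)
    } else {
      anc <- unique(c(top, unlist(lapply(ps, get, envir = ontology$cache),
                                  use.names = FALSE)))
      assign(top, anc, envir = ontology$cache)
      stack <- stack[-length(stack)]
    }
  }
  get(term, envir = ontology$cache)
}

# Ancestor sets for many (already resolved) terms; returns a named list.
ancestors_list <- function(ontology, terms) {
  terms <- unique(terms)
  stats::setNames(lapply(terms, anc_memo, ontology = ontology), terms)
}

#' Live (non-obsolete) terms of an ontology, optionally by namespace
#'
#' @param ontology a [go_ontology].
#' @param namespace optional namespace filter.
#' @return character vector of accessions.
#' @export
ontology_terms <- function(ontology, namespace = NULL) {
  live <- setdiff(ontology$terms$accession, ontology$obsolete)
  if (!is.null(namespace)) live <- live[ontology$namespaces[live] == namespace]
  live
}
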