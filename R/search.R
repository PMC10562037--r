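#' Search options
#'
#' @param include_synonyms match q-terms against synonyms as well as
#'   preferred labels.
#' @param child_levels how many child levels to include in the expansion
#'   (0 = matched classes only).
#' @param include_parents also include ancestor classes.
#' @param parent_levels how many parent levels when `include_parents`.
#' @param max_levels documented upper bound on either level parameter.
#' @return list of class `search_options`.
#' @export
search_options <- function(include_synonyms = TRUE, child_levels = 1L,
                           include_parents = FALSE, parent_levels = 1L,
                           max_levels = 10L) {
  stopifnot(child_levels >= 0, parent_levels >= 0)
  if (child_levels > max_levels || parent_levels > max_levels)
    stop("level parameters bounded by max_levels = ", max_levels,
         call. = FALSE)
  structure(list(include_synonyms = include_synonyms,
                 child_levels = as.integer(child_levels),
                 include_parents = include_parents,
                 parent_levels = as.integer(parent_levels)),
            class = "search_options")
}

bfs_hops <- function(ont, code, levels, index_fun) {
  out <- data.frame(code = character(0), hop = integer(0),
                    stringsAsFactors = FALSE)
  frontier <- code
  seen <- code
  hop <- 0L
  while (hop < levels && length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, index_fun))), seen)
    if (!length(nxt)) break
    hop <- hop + 1L
    out <- rbind(out, data.frame(code = nxt, hop = hop,
                                 stringsAsFactors = FALSE))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

#' Expand q-terms to ontology classes
#'
#' For each q-term: exact/synonym label matches, their descendants up to
#' `child_levels`, and (optionally) their ancestors up to `parent_levels`.
#' Provenance (`exact`, `synonym`, `child`, `parent`) and hop distance are
#' recorded; duplicates keep the smallest hop (and direct matches beat
#' expansions).
#'
#' @param ont an `ontology`.
#' @param q_terms character vector of at least one query term.
#' @param opts a [search_options()] list.
#' @return data.frame `q_term`, `code`, `label`, `provenance`, `hop`,
#'   ordered by (q_term, hop, code).
#' @export
expand_terms <- function(ont, q_terms, opts = search_options()) {
  stopifnot(length(q_terms) >= 1L)
  out <- list()
  for (q in q_terms) {
    seeds <- find_classes(ont, q, include_synonyms = opts$include_synonyms)
    rows <- if (nrow(seeds))
      data.frame(q_term = q, code = seeds$code, provenance = seeds$provenance,
                 hop = 0L, stringsAsFactors = FALSE)
    else data.frame(q_term = character(0), code = character(0),
                    provenance = character(0), hop = integer(0),
                    stringsAsFactors = FALSE)
    for (s in seeds$code) {
      kids <- bfs_hops(ont, s, opts$child_levels,
                       function(k) ont$child_index[[k]])
      if (nrow(kids))
        rows <- rbind(rows, data.frame(q_term = q, code = kids$code,
                                       provenance = "child", hop = kids$hop,
                                       stringsAsFactors = FALSE))
      if (opts$include_parents) {
        pars <- bfs_hops(ont, s, opts$parent_levels,
                         function(k) ont$classes[[k]]$parents)
        if (nrow(pars))
          rows <- rbind(rows, data.frame(q_term = q, code = pars$code,
                                         provenance = "parent",
                                         hop = pars$hop,
                                         stringsAsFactors = FALSE))
      }
    }
    # dedupe: smallest hop wins; at equal hop, direct match provenance wins
    prio <- match(rows$provenance, c("exact", "synonym", "child", "parent"))
    rows <- rows[order(rows$hop, prio), , drop = FALSE]
    rows <- rows[!duplicated(rows$code), , drop = FALSE]
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  res$label <- vapply(res$code, function(k) ont$classes[[k]]$label,
                      character(1), USE.NAMES = FALSE)
  res <- res[order(res$q_term, res$hop, res$code),
             c("q_term", "code", "label", "provenance", "hop")]
  rownames(res) <- NULL
  res
}

patient_uris <- function(store) {
  rdf_type <- rdf_type_uri(store$prefixes)
  tr <- store$triples
  patient_cls <- curie_to_uri("NCIT:C16960", store$prefixes)
  sort(unique(tr$subject[tr$predicate == rdf_type &
                           tr$object == patient_cls]))
}

#' Ontology-expanded cohort search
#'
#' Resolves q-terms to expanded class sets and returns every patient whose
#' knowledge-graph neighbourhood (forward subgraph within `depth` hops)
#' contains one of the expanded class URIs in object position — i.e. the
#' patient, or one of its attribute nodes, is typed or valued with the
#' class. Multiple q-terms combine as a conjunction (each term must match)
#' unless `combine = "or"`; within one term's expansion, matching any
#' class suffices.
#'
#' @param store a compiled `triple_store`.
#' @param ont the `ontology` the store was compiled against.
#' @param q_terms character vector of query terms.
#' @param opts a [search_options()] list.
#' @param combine `"and"` (cohort-definition conjunction, default) or
#'   `"or"`.
#' @param depth forward hop bound for the per-patient neighbourhood.
#' @return list of class `search_result`: `expanded_classes` (as
#'   [expand_terms()]) and `patient_hits` (data.frame `patient`,
#'   `matched_code`, `q_term`, `attributes` — the matched node's outgoing
#'   literal values), hits unique per (patient, class) and ordered by
#'   patient URI.
#' @export
search <- function(store, ont, q_terms, opts = search_options(),
                   combine = c("and", "or"), depth = 3L) {
  combine <- match.arg(combine)
  expanded <- expand_terms(ont, q_terms, opts)
  patients <- patient_uris(store)
  tr <- store$triples
  hits <- list()
  per_term_sets <- list()
  for (p in patients) {
    sub <- patient_subgraph(store, p, max_depth = depth)$triples
    for (q in unique(expanded$q_term)) {
      codes <- expanded$code[expanded$q_term == q]
      uris <- vapply(codes, function(k) ont$classes[[k]]$uri, character(1))
      m <- sub$is_uri & sub$object %in% uris
      if (any(m)) {
        per_term_sets[[q]] <- union(per_term_sets[[q]], p)
        mrows <- sub[m, , drop = FALSE]
        for (i in seq_len(nrow(mrows))) {
          node <- mrows$subject[i]
          lits <- sub[sub$subject == node & !sub$is_uri, , drop = FALSE]
          hits[[length(hits) + 1L]] <- data.frame(
            patient = p,
            matched_code = uri_to_curie(mrows$object[i], store$prefixes),
            q_term = q,
            attributes = paste(
              paste0(uri_to_curie(lits$predicate, store$prefixes), "=",
                     lits$object), collapse = "; "),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sets <- per_term_sets[unique(expanded$q_term)]
  matched <- if (!length(sets) || any(vapply(sets, is.null, logical(1)))) {
    if (combine == "and") character(0) else
      sort(unique(as.character(unlist(sets))))
  } else if (combine == "and") sort(Reduce(intersect, sets)) else
    sort(unique(as.character(unlist(sets))))
  ph <- if (length(hits)) do.call(rbind, hits) else
    data.frame(patient = character(0), matched_code = character(0),
               q_term = character(0), attributes = character(0),
               stringsAsFactors = FALSE)
  ph <- ph[ph$patient %in% matched, , drop = FALSE]
  ph <- unique(ph)
  ph <- ph[order(ph$patient, ph$q_term, ph$matched_code), , drop = FALSE]
  rownames(ph) <- NULL
  structure(list(expanded_classes = expanded, patient_hits = ph,
                 patients = matched),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$expanded_classes), " expanded classes; ",
      length(x$patients), " matching patients\n", sep = "")
  invisible(x)
}

#' Serialize a search result to JSON
#' @param result a `search_result`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path) {
  jsonlite::write_json(
    list(expanded_classes = result$expanded_classes,
         patients = result$patients,
         patient_hits = result$patient_hits),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
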