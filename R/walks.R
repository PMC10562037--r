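#' Tokenize an RDF term for the walk corpus
#'
#' Class URIs become CURIEs (e.g. `NCIT:C48720`), instance URIs under the
#' store's base become path tokens (`patient_P0001`), and literals are
#' lower-cased with non-alphanumerics collapsed to underscores.
#' @keywords internal
token_of <- function(value, is_uri, prefixes) {
  if (is_uri) {
    c <- uri_to_curie(value, prefixes)
    if (c != value) return(c)
    tok <- sub("^https?://[^/]+/", "", value)
    return(gsub("/", "_", tok))
  }
  tok <- tolower(value)
  tok <- gsub("[^a-z0-9]+", "_", tok)
  gsub("^_+|_+$", "", tok)
}

#' Build a breadth-first random-walk corpus
#'
#' For each patient, performs `walks_per_patient` truncated breadth-first
#' traversals of the patient's individual knowledge graph (forward
#' subgraph within `depth` hops): traversal starts at the patient node,
#' explores nodes breadth-first with the outgoing-edge order of every
#' node shuffled under the seeded RNG, and the token sequence (visited
#' nodes and literals, in visit order) is truncated at `max_walk_length`
#' tokens. A patient with no outgoing triples contributes its
#' patient-ID-only sentence and is flagged.
#'
#' @param store a compiled `triple_store`.
#' @param patients character vector of patient URIs (default: all typed
#'   patients in the store).
#' @param walks_per_patient sentences per patient.
#' @param max_walk_length token cap per sentence.
#' @param seed integer RNG seed; corpora are reproducible given the seed.
#' @param depth subgraph hop bound.
#' @return object of class `walk_corpus`: `sentences` (list of token
#'   vectors), `doc` (patient URI per sentence), `vocab` (sorted unique
#'   tokens), `empty_patients` (flagged URIs).
#' @export
build_walk_corpus <- function(store, patients = NULL,
                              walks_per_patient = 10L,
                              max_walk_length = 20L, seed = 1L,
                              depth = 3L) {
  stopifnot(walks_per_patient >= 0, max_walk_length >= 1)
  if (is.null(patients)) patients <- patient_uris(store)
  set.seed(as.integer(seed))
  sentences <- list()
  doc <- character(0)
  empties <- character(0)
  for (p in patients) {
    has_out <- p %in% names(store$index$s)
    sub <- if (has_out) patient_subgraph(store, p, max_depth = depth)$triples
           else NULL
    if (is.null(sub) || !nrow(sub)) {
      empties <- c(empties, p)
      if (walks_per_patient > 0) {
        sentences <- c(sentences,
                       rep(list(token_of(p, TRUE, store$prefixes)),
                           walks_per_patient))
        doc <- c(doc, rep(p, walks_per_patient))
      }
      next
    }
    adj <- split(seq_len(nrow(sub)), sub$subject)
    for (w in seq_len(walks_per_patient)) {
      tokens <- token_of(p, TRUE, store$prefixes)
      queue <- p
      visited <- p
      while (length(queue) && length(tokens) < max_walk_length) {
        node <- queue[1]
        queue <- queue[-1]
        rows <- adj[[node]]
        if (is.null(rows)) next
        rows <- if (length(rows) > 1L) base::sample(rows) else rows
        for (r in rows) {
          if (length(tokens) >= max_walk_length) break
          obj <- sub$object[r]
          tokens <- c(tokens, token_of(obj, sub$is_uri[r], store$prefixes))
          if (sub$is_uri[r] && !obj %in% visited) {
            visited <- c(visited, obj)
            queue <- c(queue, obj)
          }
        }
      }
      sentences[[length(sentences) + 1L]] <- tokens
      doc <- c(doc, p)
    }
  }
  structure(list(sentences = sentences, doc = doc,
                 vocab = sort(unique(unlist(sentences))),
                 empty_patients = empties),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("<walk_corpus> ", length(x$sentences), " sentences, ",
      length(unique(x$doc)), " patients, vocab ", length(x$vocab), "\n",
      sep = "")
  invisible(x)
}

#' Ontology-derived background sentences
#'
#' One sentence per class: its code, the word tokens of its label and
#' synonyms, and its parent codes. Used as background training text so
#' class tokens acquire neighbourhood structure beyond the patient walks
#' (a desk-scale stand-in for training on a full terminology scrape).
#'
#' @param ont an `ontology`.
#' @return list of token vectors.
#' @export
ontology_corpus <- function(ont) {
  lapply(ont$classes, function(cl) {
    words <- function(x) {
      t <- tolower(x)
      t <- unlist(strsplit(gsub("[^a-z0-9]+", "_", t), "_"))
      t[nzchar(t)]
    }
    unname(c(cl$code, words(cl$label),
             unlist(lapply(cl$synonyms, words)), cl$parents))
  })
}

#' Write a corpus as one sentence per line
#' @param corpus a `walk_corpus`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$sentences, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}
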