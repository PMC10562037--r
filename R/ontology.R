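#' Coded concept hierarchies with synonyms
#'
#' An `ontology` object holds a set of coded classes (CURIE code, preferred
#' label, synonyms, optional definition, parent codes) forming a directed
#' acyclic graph, plus a prefix table used to expand CURIEs such as
#' `NCIT:C48720` into resolvable URIs. It is the local stand-in for a
#' terminology service: term matching, level-bounded descendant/ancestor
#' traversal and CURIE/URI expansion are all answered from it.
#'
#' @name ontology
NULL

#' Expand a CURIE to an absolute URI
#'
#' @param code CURIE string, `prefix:local`.
#' @param prefixes named character vector mapping prefix to URI base.
#' @return absolute URI string.
#' @export
curie_to_uri <- function(code, prefixes) {
  stopifnot(is.character(code))
  parts <- regmatches(code, regexpr(":", code), invert = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || !nzchar(p[1]) || !is.element(p[1], names(prefixes)))
      stop("cannot expand CURIE: unknown prefix in '", paste(p, collapse = ":"),
           "'", call. = FALSE)
    paste0(prefixes[[p[1]]], p[2])
  }, character(1), USE.NAMES = FALSE)
}

#' Contract an absolute URI back to a CURIE where a prefix matches
#'
#' Longest-match contraction; URIs outside the prefix table are returned
#' unchanged.
#' @inheritParams curie_to_uri
#' @param uri absolute URI string(s).
#' @return character vector of CURIEs (or the input URI when no prefix applies).
#' @export
uri_to_curie <- function(uri, prefixes) {
  bases <- unlist(prefixes)
  ord <- order(nchar(bases), decreasing = TRUE)
  bases <- bases[ord]
  vapply(uri, function(u) {
    for (i in seq_along(bases)) {
      b <- bases[[i]]
      if (startsWith(u, b)) return(paste0(names(bases)[i], ":", substring(u, nchar(b) + 1L)))
    }
    u
  }, character(1), USE.NAMES = FALSE)
}

norm_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Load and validate an ontology file
#'
#' Reads the JSON dialect
#' `{"prefixes": {...}, "classes": [{"code", "label", "synonyms",
#' "definition", "parents"}, ...]}` and validates structural invariants:
#' unique non-empty codes, non-empty labels, no self-parenting, every parent
#' resolvable, and an acyclic parent relation. The inverse child index is
#' built on load.
#'
#' @param path path to the ontology JSON file.
#' @return an object of class `ontology` with components `classes` (named
#'   list of class records, each with `code`, `uri`, `label`, `synonyms`,
#'   `definition`, `parents`), `prefixes`, and `child_index` (named list
#'   code -> character vector of direct children).
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed ontology file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  prefixes <- unlist(doc$prefixes %||% list())
  if (is.null(prefixes)) prefixes <- character(0)
  cls <- doc$classes %||% list()
  codes <- vapply(cls, function(c) as.character(c$code %||% ""), character(1))
  if (any(!nzchar(codes))) stop("ontology integrity failure: empty class code",
                                call. = FALSE)
  if (anyDuplicated(codes))
    stop("ontology integrity failure: duplicate codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)
  classes <- stats::setNames(lapply(cls, function(c) {
    code <- as.character(c$code)
    label <- as.character(c$label %||% "")
    if (!nzchar(label))
      stop("ontology integrity failure: class ", code, " has empty label",
           call. = FALSE)
    parents <- unique(as.character(unlist(c$parents %||% character(0))))
    if (code %in% parents)
      stop("ontology integrity failure: class ", code, " lists itself as parent",
           call. = FALSE)
    list(code = code,
         uri = curie_to_uri(code, prefixes),
         label = label,
         synonyms = unique(as.character(unlist(c$synonyms %||% character(0)))),
         definition = if (is.null(c$definition)) NA_character_ else as.character(c$definition),
         parents = parents)
  }), codes)

  dangling <- unique(unlist(lapply(classes, function(c)
    setdiff(c$parents, codes))))
  if (length(dangling))
    stop("ontology integrity failure: dangling parent codes: ",
         paste(dangling, collapse = ", "), call. = FALSE)

  # cycle check: repeatedly strip classes whose parents are all stripped
  remaining <- codes
  repeat {
    strippable <- remaining[vapply(remaining, function(k)
      !any(classes[[k]]$parents %in% remaining), logical(1))]
    if (!length(strippable)) break
    remaining <- setdiff(remaining, strippable)
  }
  if (length(remaining))
    stop("ontology integrity failure: parent cycle among: ",
         paste(sort(remaining), collapse = ", "), call. = FALSE)

  child_index <- stats::setNames(vector("list", length(codes)), codes)
  for (k in codes) child_index[[k]] <- character(0)
  for (c in classes) for (p in c$parents)
    child_index[[p]] <- c(child_index[[p]], c$code)

  structure(list(classes = classes, prefixes = prefixes,
                 child_index = child_index),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", length(x$classes), " classes, ",
      length(x$prefixes), " prefixes\n", sep = "")
  invisible(x)
}

#' Find classes by term
#'
#' Case-insensitive, whitespace-normalized exact matching of a query term
#' against class labels and (optionally) synonyms; no stemming or fuzzy
#' matching.
#'
#' @param ont an `ontology`.
#' @param q_term query term, non-empty string.
#' @param include_synonyms also match against synonym lists.
#' @return data.frame with columns `code`, `label`, `provenance`
#'   (`"exact"` for a label match, `"synonym"` for a synonym match); zero
#'   rows when nothing matches.
#' @export
find_classes <- function(ont, q_term, include_synonyms = TRUE) {
  stopifnot(inherits(ont, "ontology"))
  if (!is.character(q_term) || length(q_term) != 1L || !nzchar(trimws(q_term)))
    stop("q_term must be a non-empty string", call. = FALSE)
  q <- norm_term(q_term)
  hits <- list()
  for (c in ont$classes) {
    if (norm_term(c$label) == q) {
      hits[[length(hits) + 1L]] <- data.frame(
        code = c$code, label = c$label, provenance = "exact",
        stringsAsFactors = FALSE)
    } else if (include_synonyms && length(c$synonyms) &&
               any(norm_term(c$synonyms) == q)) {
      hits[[length(hits) + 1L]] <- data.frame(
        code = c$code, label = c$label, provenance = "synonym",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(code = character(0), label = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

traverse_levels <- function(ont, code, levels, index_fun) {
  if (!is.element(code, names(ont$classes)))
    stop("unknown ontology code: ", code, call. = FALSE)
  stopifnot(levels >= 0)
  seen <- character(0)
  frontier <- code
  lvl <- 0L
  while (lvl < levels && length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, index_fun)))
    nxt <- setdiff(nxt, c(seen, code))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
    lvl <- lvl + 1L
  }
  sort(seen)
}

#' Descendant codes within a bounded number of child steps
#'
#' @param ont an `ontology`.
#' @param code CURIE of the start class (must exist).
#' @param levels how many child levels to walk; `0` returns an empty set.
#'   The start class is never included.
#' @return sorted character vector of CURIEs.
#' @export
descendants <- function(ont, code, levels = 1L) {
  traverse_levels(ont, code, levels, function(k) ont$child_index[[k]])
}

#' Ancestor codes within a bounded number of parent steps
#'
#' Mirror of [descendants()] over the parent relation.
#' @inheritParams descendants
#' @export
ancestors <- function(ont, code, levels = 1L) {
  traverse_levels(ont, code, levels, function(k) ont$classes[[k]]$parents)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
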