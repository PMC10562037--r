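#' In-memory RDF triple store
#'
#' A `triple_store` is a deduplicated, deterministically ordered set of
#' (subject, predicate, object) statements. Subjects and predicates are
#' absolute URIs; objects are either URIs or typed literals (string,
#' integer, decimal, date). Three positional indexes (subject-, predicate-
#' and object-major) are kept alongside the triple set for lookups.
#'
#' @param df data.frame with columns `subject`, `predicate`, `object`,
#'   `is_uri` (logical), `datatype` (character; `NA` for URI objects, one
#'   of `"string"`, `"integer"`, `"decimal"`, `"date"` for literals).
#' @param prefixes named character vector used for CURIE contraction when
#'   serializing.
#' @return object of class `triple_store`.
#' @export
triple_store <- function(df = NULL, prefixes = .rolhs_prefixes) {
  if (is.null(df))
    df <- data.frame(subject = character(0), predicate = character(0),
                     object = character(0), is_uri = logical(0),
                     datatype = character(0), stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "predicate", "object", "is_uri",
                  "datatype") %in% names(df)))
  lit <- !df$is_uri
  ok <- rep(TRUE, nrow(df))
  ok[lit & df$datatype == "integer"] <-
    parses_int(df$object[lit & df$datatype == "integer"])
  ok[lit & df$datatype == "decimal"] <-
    parses_dec(df$object[lit & df$datatype == "decimal"])
  ok[lit & df$datatype == "date"] <-
    grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$",
          df$object[lit & df$datatype == "date"])
  if (any(!ok))
    stop("literal does not parse under its datatype: ",
         df$object[!ok][1], call. = FALSE)
  key <- paste(df$subject, df$predicate, df$object, df$is_uri, df$datatype,
               sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$subject, df$predicate, df$object), , drop = FALSE]
  rownames(df) <- NULL
  idx <- list(s = split(seq_len(nrow(df)), df$subject),
              p = split(seq_len(nrow(df)), df$predicate),
              o = split(seq_len(nrow(df)), df$object))
  structure(list(triples = df, prefixes = prefixes, index = idx),
            class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat("<triple_store> ", nrow(x$triples), " triples, ",
      length(x$index$s), " subjects\n", sep = "")
  invisible(x)
}

#' Number of triples in a store
#' @param store a `triple_store`.
#' @return integer count.
#' @export
n_triples <- function(store) nrow(store$triples)

rdf_type_uri <- function(prefixes) curie_to_uri("rdf:type", prefixes)

expand_term <- function(x, prefixes) {
  if (grepl("^https?://", x)) return(x)
  if (grepl("^[A-Za-z][A-Za-z0-9]*:", x)) return(curie_to_uri(x, prefixes))
  x
}

escape_ttl <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  gsub('"', '\\\\"', x)
}
unescape_ttl <- function(x) {
  x <- gsub('\\\\"', '"', x)
  gsub("\\\\\\\\", "\\\\", x)
}

term_ttl <- function(uri, prefixes) {
  c <- uri_to_curie(uri, prefixes)
  ifelse(c == uri, paste0("<", uri, ">"), c)
}

#' Serialize a store to Turtle
#'
#' Deterministic output: sorted prefix declarations, then one triple per
#' line in (subject, predicate, object) order, using prefixed names where
#' the prefix table allows. Literals carry explicit XSD datatypes except
#' plain strings.
#'
#' @param store a `triple_store`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
serialize_turtle <- function(store, path) {
  px <- store$prefixes[order(names(store$prefixes))]
  lines <- sprintf("@prefix %s: <%s> .", names(px), unname(px))
  tr <- store$triples
  if (nrow(tr)) {
    obj <- character(nrow(tr))
    u <- tr$is_uri
    obj[u] <- term_ttl(tr$object[u], store$prefixes)
    lit <- !u
    tag <- c(string = "", integer = "^^xsd:integer",
             decimal = "^^xsd:decimal", date = "^^xsd:date")
    obj[lit] <- paste0('"', escape_ttl(tr$object[lit]), '"',
                       tag[tr$datatype[lit]])
    lines <- c(lines, "",
               paste(term_ttl(tr$subject, store$prefixes),
                     term_ttl(tr$predicate, store$prefixes), obj, "."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_ttl_term <- function(tok, prefixes, lineno) {
  if (startsWith(tok, "<"))
    return(list(value = sub("^<(.*)>$", "\\1", tok), is_uri = TRUE,
                datatype = NA_character_))
  if (startsWith(tok, '"')) {
    mm <- regmatches(tok, regexec(
      '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^([A-Za-z]+:[A-Za-z]+))?$', tok))[[1]]
    if (!length(mm))
      stop("turtle parse failure at line ", lineno, ": bad literal ", tok,
           call. = FALSE)
    dt <- if (nzchar(mm[3]))
      c(`xsd:integer` = "integer", `xsd:decimal` = "decimal",
        `xsd:date` = "date")[[mm[3]]] else "string"
    return(list(value = unescape_ttl(mm[2]), is_uri = FALSE, datatype = dt))
  }
  if (grepl("^[A-Za-z][A-Za-z0-9]*:\\S*$", tok))
    return(list(value = curie_to_uri(tok, prefixes), is_uri = TRUE,
                datatype = NA_character_))
  stop("turtle parse failure at line ", lineno, ": unrecognized term ",
       tok, call. = FALSE)
}

#' Parse a Turtle file into a store
#'
#' Parses the line-oriented Turtle subset written by [serialize_turtle()]
#' (one triple per line, `@prefix` declarations, `<uri>` or prefixed-name
#' terms, quoted literals with optional `^^xsd:` datatype). Errors name
#' the offending line.
#'
#' @param path Turtle file.
#' @return a `triple_store`.
#' @export
parse_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prefixes <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      m <- regmatches(ln, regexec(
        "^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.$", ln))[[1]]
      if (!length(m))
        stop("turtle parse failure at line ", i, ": bad @prefix",
             call. = FALSE)
      prefixes[m[2]] <- m[3]
      next
    }
    if (!grepl("\\.\\s*$", ln))
      stop("turtle parse failure at line ", i, ": missing terminating '.'",
           call. = FALSE)
    body <- sub("\\s*\\.\\s*$", "", ln)
    # split into three terms; literals may contain spaces
    toks <- regmatches(body, gregexpr(
      '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^[A-Za-z]+:[A-Za-z]+)?|<[^>]*>|\\S+',
      body))[[1]]
    if (length(toks) != 3L)
      stop("turtle parse failure at line ", i, ": expected 3 terms, got ",
           length(toks), call. = FALSE)
    s <- parse_ttl_term(toks[1], prefixes, i)
    p <- parse_ttl_term(toks[2], prefixes, i)
    o <- parse_ttl_term(toks[3], prefixes, i)
    if (!s$is_uri || !p$is_uri)
      stop("turtle parse failure at line ", i,
           ": subject/predicate must be URIs", call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$value, predicate = p$value, object = o$value,
      is_uri = o$is_uri, datatype = o$datatype, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  triple_store(df, prefixes = prefixes)
}

#' Basic graph pattern query
#'
#' Exact BGP join semantics: a binding of the variables (tokens starting
#' with `?`) is returned iff substituting it into every pattern yields a
#' triple of the store. Constants may be absolute URIs, CURIEs (expanded
#' through the store's prefix table) or literal strings. Duplicate
#' bindings are eliminated and rows are ordered deterministically.
#'
#' @param store a `triple_store`.
#' @param patterns list of length-3 character vectors `(s, p, o)`.
#' @return data.frame with one column per variable (names without `?`);
#'   zero columns and one row for an all-constant match (boolean yes),
#'   zero rows when there is no match.
#' @export
query <- function(store, patterns) {
  stopifnot(length(patterns) >= 1L)
  tr <- store$triples
  empty_binding <- function(n) as.data.frame(matrix(NA, n, 0))
  binds <- NULL  # NULL = unconstrained single empty binding
  for (pat in patterns) {
    stopifnot(length(pat) == 3L)
    is_var <- startsWith(pat, "?")
    cand <- tr
    cols <- c("subject", "predicate", "object")
    for (j in 1:3) if (!is_var[j]) {
      val <- expand_term(pat[j], store$prefixes)
      cand <- cand[cand[[cols[j]]] == val |
                     (!cand$is_uri & cols[j] == "object" &
                        cand$object == pat[j]), , drop = FALSE]
    }
    vars <- sub("^\\?", "", pat[is_var])
    sel <- cand[, cols[is_var], drop = FALSE]
    names(sel) <- vars
    # a variable repeated inside one pattern must bind consistently
    if (anyDuplicated(vars)) {
      keep <- rep(TRUE, nrow(sel))
      for (v in unique(vars[duplicated(vars)])) {
        ix <- which(names(sel) == v)
        for (k in ix[-1]) keep <- keep & sel[[ix[1]]] == sel[[k]]
      }
      sel <- sel[keep, unique(names(sel)), drop = FALSE]
    }
    sel <- if (ncol(sel)) unique(sel) else
      empty_binding(min(nrow(cand), 1L))
    binds <- if (is.null(binds)) sel
    else if (ncol(sel) == 0L) { if (nrow(sel)) binds else sel }
    else if (ncol(binds) == 0L) { if (nrow(binds)) sel else binds[0, ] }
    else {
      common <- intersect(names(binds), names(sel))
      if (length(common)) merge(binds, sel, by = common)
      else merge(binds, sel, by = NULL)
    }
    if (!is.null(binds) && nrow(binds) == 0L && ncol(binds) > 0L) break
  }
  if (is.null(binds)) binds <- empty_binding(1L)
  if (ncol(binds) == 0L) {
    binds <- empty_binding(min(nrow(binds), 1L))
  } else {
    binds <- unique(binds)
    binds <- binds[do.call(order, binds), , drop = FALSE]
  }
  rownames(binds) <- NULL
  binds
}

#' Forward subgraph of a patient node
#'
#' All triples reachable from `node` within `max_depth` forward
#' (subject-to-object) hops.
#' @param store a `triple_store`.
#' @param node absolute URI (or CURIE) of the start node; must occur as a
#'   subject in the store.
#' @param max_depth non-negative hop bound; `0` yields an empty store.
#' @return a `triple_store` restricted to the reachable triples.
#' @export
patient_subgraph <- function(store, node, max_depth = 3L) {
  node <- expand_term(node, store$prefixes)
  if (!node %in% names(store$index$s))
    stop("unknown node (not a subject): ", node, call. = FALSE)
  stopifnot(max_depth >= 0)
  tr <- store$triples
  keep <- integer(0)
  frontier <- node
  seen <- character(0)
  depth <- 0L
  while (depth < max_depth && length(frontier)) {
    rows <- unlist(store$index$s[frontier], use.names = FALSE)
    keep <- union(keep, rows)
    nxt <- unique(tr$object[rows][tr$is_uri[rows]])
    seen <- c(seen, frontier)
    frontier <- setdiff(intersect(nxt, names(store$index$s)), seen)
    depth <- depth + 1L
  }
  triple_store(tr[sort(keep), , drop = FALSE], prefixes = store$prefixes)
}

graph_node_label <- function(uri, ont, prefixes) {
  code <- uri_to_curie(uri, prefixes)
  if (!is.null(ont) && code %in% names(ont$classes))
    return(ont$classes[[code]]$label)
  code
}

#' Export a store as DOT or GraphML
#'
#' One node per distinct URI or literal, one edge per triple. Node labels
#' resolve through the ontology when one is supplied, falling back to the
#' CURIE (or the literal value).
#'
#' @param store a `triple_store`.
#' @param path destination file.
#' @param format `"dot"` or `"graphml"`.
#' @param ont optional `ontology` used for node labels.
#' @return `path`, invisibly.
#' @export
export_graph <- function(store, path, format = c("dot", "graphml"),
                         ont = NULL) {
  format <- match.arg(format)
  tr <- store$triples
  terms <- unique(c(tr$subject, tr$object))
  lab <- vapply(seq_along(terms), function(i) {
    t <- terms[i]
    if (t %in% tr$object[!tr$is_uri] && !t %in% tr$subject &&
        !t %in% tr$object[tr$is_uri]) t
    else graph_node_label(t, ont, store$prefixes)
  }, character(1))
  ids <- paste0("n", seq_along(terms) - 1L)
  names(ids) <- terms
  esc <- function(x) gsub('"', '\\\\"', x)
  xml_esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  if (format == "dot") {
    lines <- c("digraph rolhs {",
               sprintf('  %s [label="%s"];', ids, esc(lab)),
               sprintf('  %s -> %s [label="%s"];',
                       ids[tr$subject], ids[tr$object],
                       esc(uri_to_curie(tr$predicate, store$prefixes))),
               "}")
  } else {
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="label" for="node" attr.name="label" attr.type="string"/>',
               '<key id="pred" for="edge" attr.name="predicate" attr.type="string"/>',
               '<graph id="G" edgedefault="directed">',
               sprintf('<node id="%s"><data key="label">%s</data></node>',
                       ids, xml_esc(lab)),
               sprintf('<edge source="%s" target="%s"><data key="pred">%s</data></edge>',
                       ids[tr$subject], ids[tr$object],
                       xml_esc(uri_to_curie(tr$predicate, store$prefixes))),
               '</graph>', '</graphml>')
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
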