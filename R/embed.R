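#' Train an embedding model on a walk corpus
#'
#' Four model kinds over the same token corpus:
#' * `word2vec` — skip-gram with negative sampling (window 5, 5 negative
#'   samples by default).
#' * `fasttext` — skip-gram with negative sampling where a word's input
#'   representation is the mean of its own vector and its character
#'   3-5-gram vectors, giving subword fallback for unseen tokens.
#' * `doc2vec` — PV-DBOW: one trained vector per patient document
#'   predicting its tokens.
#' * `glove` — AdaGrad factorization of the windowed, 1/distance-weighted
#'   co-occurrence matrix under the weighted least-squares objective.
#'
#' Training is single-threaded and fully deterministic given `seed`.
#'
#' @param corpus a `walk_corpus`.
#' @param kind one of `"word2vec"`, `"doc2vec"`, `"glove"`, `"fasttext"`.
#' @param dim embedding dimension (>= 2), default 100.
#' @param window context window size.
#' @param epochs training epochs, default 100.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate (SGNS/DBOW) ; GloVe uses AdaGrad
#'   with `eta = 0.05`.
#' @param seed integer RNG seed.
#' @param background optional list of extra token sentences (e.g.
#'   [ontology_corpus()]) included for training but not attributed to any
#'   patient.
#' @return object of class `embedding_model`: `kind`, `dim`, `vectors`
#'   (token matrix, rownames = tokens), `doc_vectors` (doc2vec only,
#'   rownames = patient URIs), `ngrams`/`ngram_vectors` (fasttext only),
#'   `params`.
#' @export
train_embedding <- function(corpus, kind = c("word2vec", "doc2vec",
                                             "glove", "fasttext"),
                            dim = 100L, window = 5L, epochs = 100L,
                            negative = 5L, alpha = 0.025, seed = 1L,
                            background = NULL) {
  if (is.character(kind) && length(kind) == 1L &&
      !kind %in% c("word2vec", "doc2vec", "glove", "fasttext"))
    stop("unknown embedding kind: ", kind, call. = FALSE)
  kind <- match.arg(kind)
  stopifnot(dim >= 2)
  sentences <- c(corpus$sentences, background %||% list())
  sentences <- Filter(length, sentences)
  if (!length(sentences)) stop("corpus is empty", call. = FALSE)
  vocab <- sort(unique(unlist(sentences)))
  ids <- lapply(sentences, function(s) match(s, vocab) - 1L)
  params <- list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed))

  model <- list(kind = kind, dim = as.integer(dim), params = params,
                doc_vectors = NULL, ngrams = NULL, ngram_vectors = NULL)
  if (kind == "word2vec") {
    fit <- train_sgns_cpp(ids, length(vocab), dim, window, epochs,
                          negative, alpha, seed, list(), 0L)
    v <- fit$word
  } else if (kind == "fasttext") {
    grams <- lapply(vocab, token_ngrams)
    gram_vocab <- sort(unique(unlist(grams)))
    gram_ids <- lapply(grams, function(g) match(g, gram_vocab) - 1L)
    fit <- train_sgns_cpp(ids, length(vocab), dim, window, epochs,
                          negative, alpha, seed, gram_ids,
                          length(gram_vocab))
    v <- fit$word
    gv <- fit$ngram
    rownames(gv) <- gram_vocab
    model$ngrams <- gram_vocab
    model$ngram_vectors <- gv
  } else if (kind == "doc2vec") {
    docs <- c(corpus$doc,
              if (length(sentences) > length(corpus$sentences))
                paste0("_bg", seq_len(length(sentences) -
                                        length(corpus$sentences))))
    docs <- docs[seq_along(sentences)]
    doc_levels <- unique(docs)
    fit <- train_dbow_cpp(ids, match(docs, doc_levels) - 1L,
                          length(doc_levels), length(vocab), dim, epochs,
                          negative, alpha, seed)
    v <- fit$word
    dv <- fit$doc
    rownames(dv) <- doc_levels
    model$doc_vectors <- dv[!startsWith(doc_levels, "_bg"), , drop = FALSE]
  } else {  # glove
    cc <- cooc_counts_cpp(ids, length(vocab), window)
    if (!length(cc$i)) stop("corpus has no co-occurrences", call. = FALSE)
    v <- train_glove_cpp(cc$i, cc$j, cc$x, length(vocab), dim, epochs,
                         x_max = 10, alpha_pow = 0.75, eta = 0.05,
                         seed = seed)
  }
  if (any(!is.finite(v))) stop("training produced non-finite vectors",
                               call. = FALSE)
  rownames(v) <- vocab
  model$vectors <- v
  class(model) <- "embedding_model"
  model
}

token_ngrams <- function(token, n_min = 3L, n_max = 5L) {
  t <- paste0("<", token, ">")
  nc <- nchar(t)
  out <- character(0)
  for (n in n_min:n_max) {
    if (nc < n) break
    out <- c(out, substring(t, 1:(nc - n + 1), n:nc))
  }
  unique(out)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> kind=", x$kind, " dim=", x$dim, " vocab=",
      nrow(x$vectors), "\n", sep = "")
  invisible(x)
}

#' Vector for a single token, with subword fallback for fasttext
#' @param model an `embedding_model`.
#' @param token token string.
#' @return numeric vector of length `model$dim`, or `NULL` for an
#'   unrepresentable token.
#' @export
token_vector <- function(model, token) {
  if (token %in% rownames(model$vectors))
    return(model$vectors[token, ])
  if (model$kind == "fasttext") {
    g <- intersect(token_ngrams(token), model$ngrams)
    if (length(g)) return(colMeans(model$ngram_vectors[g, , drop = FALSE]))
  }
  NULL
}

#' Aggregate a patient's embedding vector
#'
#' For `doc2vec` the trained document vector; for the word-level kinds the
#' unweighted mean of the patient's distinct token vectors (so the vector
#' is invariant to how many walks repeat a token). A patient whose tokens
#' are all unrepresentable gets a flagged zero vector.
#'
#' @param model an `embedding_model`.
#' @param corpus the `walk_corpus` the model was trained on.
#' @param patient patient URI present in the corpus.
#' @return numeric vector of length `model$dim`; attribute `empty` set
#'   TRUE when it is a flagged zero vector.
#' @export
patient_vector <- function(model, corpus, patient) {
  if (!patient %in% corpus$doc)
    stop("unknown patient in corpus: ", patient, call. = FALSE)
  if (model$kind == "doc2vec") {
    if (!patient %in% rownames(model$doc_vectors))
      stop("patient missing from document vectors: ", patient,
           call. = FALSE)
    return(model$doc_vectors[patient, ])
  }
  toks <- unique(unlist(corpus$sentences[corpus$doc == patient]))
  vs <- Filter(Negate(is.null), lapply(toks, token_vector, model = model))
  if (!length(vs)) {
    v <- numeric(model$dim)
    attr(v, "empty") <- TRUE
    return(v)
  }
  Reduce(`+`, vs) / length(vs)
}

#' Matrix of patient vectors
#'
#' @inheritParams patient_vector
#' @param patients patient URIs (default: all in the corpus).
#' @return numeric matrix, one row per patient.
#' @export
patient_vectors <- function(model, corpus, patients = NULL) {
  if (is.null(patients)) patients <- unique(corpus$doc)
  m <- t(vapply(patients, function(p) patient_vector(model, corpus, p),
                numeric(model$dim)))
  rownames(m) <- patients
  m
}

#' Similarity and distance metrics
#'
#' Standard definitions: cosine similarity in `[-1, 1]` (undefined for a
#' zero vector), Euclidean, Manhattan and Minkowski (order `p`, default 3)
#' distances.
#'
#' @param u,v numeric vectors of equal length.
#' @param metric one of `"cosine"`, `"euclidean"`, `"manhattan"`,
#'   `"minkowski"`.
#' @param p Minkowski order.
#' @return a number.
#' @export
similarity <- function(u, v, metric = c("cosine", "euclidean",
                                        "manhattan", "minkowski"),
                       p = 3) {
  metric <- match.arg(metric)
  if (length(u) != length(v))
    stop("vectors have different dimensions", call. = FALSE)
  switch(metric,
         cosine = {
           nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
           if (nu == 0 || nv == 0)
             stop("cosine similarity undefined for zero vector",
                  call. = FALSE)
           sum(u * v) / (nu * nv)
         },
         euclidean = sqrt(sum((u - v)^2)),
         manhattan = sum(abs(u - v)),
         minkowski = sum(abs(u - v)^p)^(1 / p))
}

#' Rank the most similar patients
#'
#' Top-k neighbours of `query` by descending cosine similarity or
#' ascending distance; ties broken by patient ID; the query is excluded
#' from its own ranking.
#'
#' @param vectors numeric matrix of patient vectors (rownames = patient
#'   IDs/URIs).
#' @param query rowname of the query patient.
#' @param metric see [similarity()].
#' @param k number of neighbours (> 0).
#' @param p Minkowski order.
#' @return data.frame `patient`, `score`, best first.
#' @export
rank_similar <- function(vectors, query, metric = "cosine", k = 10L,
                         p = 3) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (!query %in% rownames(vectors))
    stop("query patient not among vectors: ", query, call. = FALSE)
  others <- setdiff(rownames(vectors), query)
  qv <- vectors[query, ]
  score <- vapply(others, function(o)
    similarity(qv, vectors[o, ], metric, p = p), numeric(1))
  ord <- if (metric == "cosine") order(-score, others) else
    order(score, others)
  out <- data.frame(patient = others[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

pairwise_means <- function(vectors, metric, p = 3) {
  n <- nrow(vectors)
  if (n < 2L) return(NA_real_)
  if (metric == "cosine") {
    nv <- sqrt(rowSums(vectors^2))
    x <- vectors / nv
    cm <- tcrossprod(x)
    return(mean(cm[upper.tri(cm)]))
  }
  d <- if (metric == "euclidean") stats::dist(vectors)
  else if (metric == "manhattan") stats::dist(vectors, method = "manhattan")
  else stats::dist(vectors, method = "minkowski", p = p)
  mean(d)
}

#' Five-group cluster coherence report
#'
#' Mean pairwise cosine similarity within each diagnosis group (and the
#' pooled within-group mean), the between-group mean cosine, and the
#' overall mean pairwise Euclidean / Manhattan / Minkowski distances.
#' All means are over unordered distinct pairs. Singleton groups are
#' excluded with a warning.
#'
#' @param vectors numeric matrix of patient vectors (rownames = patients).
#' @param labels named character vector patient -> group.
#' @param p Minkowski order.
#' @return object of class `cluster_eval`: `per_group` (group, n,
#'   mean_cosine), `intra_mean_cosine`, `inter_mean_cosine`, `distances`
#'   (metric, mean).
#' @export
evaluate_clusters <- function(vectors, labels, p = 3) {
  labels <- labels[rownames(vectors)]
  if (any(is.na(labels))) stop("labels missing for some patients",
                               call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2)) {
    warning("excluding singleton group(s): ",
            paste(names(tab)[tab < 2], collapse = ", "))
    keep <- labels %in% names(tab)[tab >= 2]
    vectors <- vectors[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  nv <- sqrt(rowSums(vectors^2))
  if (any(nv == 0)) stop("zero vector in cluster evaluation", call. = FALSE)
  x <- vectors / nv
  cm <- tcrossprod(x)
  ut <- upper.tri(cm)
  same <- outer(labels, labels, `==`)
  groups <- sort(unique(labels))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sel <- labels == g
    block <- cm[sel, sel, drop = FALSE]
    data.frame(group = g, n = sum(sel),
               mean_cosine = mean(block[upper.tri(block)]),
               stringsAsFactors = FALSE)
  }))
  dists <- data.frame(
    metric = c("euclidean", "manhattan", "minkowski"),
    mean = c(pairwise_means(vectors, "euclidean"),
             pairwise_means(vectors, "manhattan"),
             pairwise_means(vectors, "minkowski", p = p)),
    stringsAsFactors = FALSE)
  structure(list(per_group = per_group,
                 intra_mean_cosine = mean(cm[ut & same]),
                 inter_mean_cosine = mean(cm[ut & !same]),
                 all_pairs_mean_cosine = mean(cm[ut]),
                 distances = dists),
            class = "cluster_eval")
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat("<cluster_eval> intra cosine ", round(x$intra_mean_cosine, 3),
      " vs inter ", round(x$inter_mean_cosine, 3), "\n", sep = "")
  print(x$per_group)
  invisible(x)
}

#' Write vectors in word2vec text format
#'
#' First line `vocab_size dim`, then one `token v1 ... vd` line per row.
#' @param vectors numeric matrix with rownames.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(vectors, path) {
  lines <- c(paste(nrow(vectors), ncol(vectors)),
             vapply(seq_len(nrow(vectors)), function(i)
               paste(rownames(vectors)[i],
                     paste(formatC(vectors[i, ], format = "g", digits = 8),
                           collapse = " ")), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a cluster report as JSON and TSV
#' @param report a `cluster_eval`.
#' @param json_path,tsv_path destination files (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
write_cluster_report <- function(report, json_path = NULL,
                                 tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(per_group = report$per_group,
           intra_mean_cosine = report$intra_mean_cosine,
           inter_mean_cosine = report$inter_mean_cosine,
           all_pairs_mean_cosine = report$all_pairs_mean_cosine,
           distances = report$distances),
      json_path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(report$distances, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
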