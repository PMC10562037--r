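# tiny star graph: patient -> 4 attribute classes
star_store <- function() {
  triple_store(data.frame(
    subject = c(rep("http://e.org/patient/p1", 4),
                "http://e.org/patient/p1"),
    predicate = c(rep("http://e.org/has", 4),
                  "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
    object = c(paste0("http://e.org/attr", 1:4),
               "http://purl.obolibrary.org/obo/NCIT_C16960"),
    is_uri = TRUE, datatype = NA_character_, stringsAsFactors = FALSE),
    prefixes = rolhs:::.rolhs_prefixes)
}

toy_corpus <- function(n_rep = 30, seed = 1) {
  set.seed(seed)
  sents <- c(replicate(n_rep, c("A", "B", sample(c("X", "Y", "Z"), 3, TRUE)),
                       simplify = FALSE),
             replicate(n_rep, c("C", sample(c("U", "V", "W"), 3, TRUE)),
                       simplify = FALSE))
  structure(list(sentences = sents, doc = rep(c("p1", "p2"), each = n_rep),
                 vocab = sort(unique(unlist(sents))),
                 empty_patients = character(0)),
            class = "walk_corpus")
}

test_that("star-graph walks visit the whole star in seeded order", {
  s <- star_store()
  # every walk = patient token followed by a permutation of the 5 objects
  perms <- lapply(1:24, function(i)
    build_walk_corpus(s, walks_per_patient = 1, max_walk_length = 10,
                      seed = i)$sentences[[1]])
  for (p in perms) {
    expect_identical(p[1], "patient_p1")
    expect_setequal(p[-1], c(paste0("attr", 1:4), "NCIT:C16960"))
  }
  # seeded randomization actually permutes
  expect_gt(length(unique(vapply(perms, paste, "", collapse = " "))), 1L)
  # truncation at L tokens
  short <- build_walk_corpus(s, walks_per_patient = 1, max_walk_length = 3,
                             seed = 2)$sentences[[1]]
  expect_length(short, 3L)
})

test_that("walk corpora are deterministic and flag empty subgraphs", {
  s <- test_store()
  c1 <- build_walk_corpus(s, walks_per_patient = 3, seed = 5)
  c2 <- build_walk_corpus(s, walks_per_patient = 3, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(
    c1$sentences,
    build_walk_corpus(s, walks_per_patient = 3, seed = 6)$sentences))
  # every patient contributes its sentences; provenance is recorded
  pats <- rolhs:::patient_uris(s)
  expect_identical(sort(unique(c1$doc)), pats)
  expect_true(all(table(c1$doc) == 3))
  expect_true(all(lengths(c1$sentences) >= 1))
  # n = 0 walks -> empty corpus
  c0 <- build_walk_corpus(s, walks_per_patient = 0, seed = 5)
  expect_length(c0$sentences, 0)
  # patient with no outgoing triples is flagged with an ID-only sentence
  iso <- triple_store(rbind(star_store()$triples, data.frame(
    subject = "http://e.org/patient/p9",
    predicate = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    object = "http://purl.obolibrary.org/obo/NCIT_C16960",
    is_uri = TRUE, datatype = NA_character_)),
    prefixes = rolhs:::.rolhs_prefixes)
  # p9 has only its type triple: subgraph exists but p1-style attributes
  # are absent; a truly isolated patient must still yield a sentence
  cc <- build_walk_corpus(iso, patients = c("http://e.org/patient/p9",
                                            "http://e.org/nowhere"),
                          walks_per_patient = 2, seed = 1)
  expect_identical(sum(cc$doc == "http://e.org/nowhere"), 2L)
  expect_identical(cc$sentences[[3]], "nowhere")
  expect_identical(cc$empty_patients, "http://e.org/nowhere")
})

test_that("co-occurring tokens embed closer than non-co-occurring ones", {
  corp <- toy_corpus()
  for (k in c("word2vec", "glove", "fasttext")) {
    m <- train_embedding(corp, k, dim = 16, epochs = 40, seed = 3)
    ab <- similarity(token_vector(m, "A"), token_vector(m, "B"), "cosine")
    ac <- similarity(token_vector(m, "A"), token_vector(m, "C"), "cosine")
    expect_gt(ab, ac)
  }
  m <- train_embedding(corp, "doc2vec", dim = 16, epochs = 40, seed = 3)
  expect_identical(rownames(m$doc_vectors), c("p1", "p2"))
})

test_that("training is deterministic given a seed and validates input", {
  corp <- toy_corpus()
  for (k in c("word2vec", "doc2vec", "glove", "fasttext")) {
    m1 <- train_embedding(corp, k, dim = 8, epochs = 10, seed = 4)
    m2 <- train_embedding(corp, k, dim = 8, epochs = 10, seed = 4)
    expect_identical(m1$vectors, m2$vectors, info = k)
    expect_true(all(is.finite(m1$vectors)))
    expect_identical(dim(m1$vectors), c(length(corp$vocab), 8L))
  }
  expect_error(train_embedding(corp, "bert"), "unknown embedding kind")
  empty <- structure(list(sentences = list(), doc = character(0),
                          vocab = character(0)), class = "walk_corpus")
  expect_error(train_embedding(empty, "word2vec"), "empty")
  # single-sentence corpus: vocabulary is exactly its tokens
  one <- structure(list(sentences = list(c("a", "b", "a")), doc = "p",
                        vocab = c("a", "b")), class = "walk_corpus")
  m <- train_embedding(one, "word2vec", dim = 4, epochs = 2, seed = 1)
  expect_identical(rownames(m$vectors), c("a", "b"))
})

test_that("fasttext composes subword vectors for unseen tokens", {
  corp <- toy_corpus()
  m <- train_embedding(corp, "fasttext", dim = 8, epochs = 5, seed = 1)
  expect_null(token_vector(m, "QQQQQ"))
  # token sharing n-grams with a known one gets a composed vector
  long <- structure(list(sentences = list(c("NCIT:C48720", "NCIT:C48721",
                                            "stage")),
                         doc = "p", vocab = NULL), class = "walk_corpus")
  ml <- train_embedding(long, "fasttext", dim = 8, epochs = 5, seed = 1)
  v <- token_vector(ml, "NCIT:C48722")
  expect_length(v, 8L)
  expect_true(all(is.finite(v)))
})

test_that("patient vectors aggregate distinct token vectors by the mean", {
  corp <- toy_corpus()
  m <- train_embedding(corp, "word2vec", dim = 8, epochs = 10, seed = 2)
  toks1 <- unique(unlist(corp$sentences[corp$doc == "p1"]))
  manual <- colMeans(m$vectors[toks1, , drop = FALSE])
  expect_equal(unname(patient_vector(m, corp, "p1")), unname(manual))
  # one-token and two-token closed forms
  c1 <- structure(list(sentences = list("A", c("A", "B")),
                       doc = c("q1", "q2"), vocab = c("A", "B")),
                  class = "walk_corpus")
  expect_equal(unname(patient_vector(m, c1, "q1")),
               unname(m$vectors["A", ]))
  expect_equal(unname(patient_vector(m, c1, "q2")),
               unname((m$vectors["A", ] + m$vectors["B", ]) / 2))
  expect_error(patient_vector(m, corp, "p99"), "unknown patient")
  # doc2vec returns the trained document vector itself
  md <- train_embedding(corp, "doc2vec", dim = 8, epochs = 10, seed = 2)
  expect_identical(patient_vector(md, corp, "p1"),
                   md$doc_vectors["p1", ])
  # aggregation linearity: scaling all token vectors scales the output
  m2 <- m
  m2$vectors <- m$vectors * 3
  expect_equal(patient_vector(m2, corp, "p1"),
               3 * patient_vector(m, corp, "p1"))
})

test_that("similarity metrics satisfy closed forms and axioms", {
  expect_equal(similarity(c(1, 2, 3), c(1, 2, 3), "cosine"), 1)
  expect_identical(similarity(c(0, 0), c(1, 1), "manhattan"), 2)
  expect_identical(similarity(c(0, 0), c(1, 1), "euclidean"), sqrt(2))
  expect_error(similarity(c(0, 0), c(1, 1), "cosine"), "zero vector")
  expect_error(similarity(1:3, 1:4, "cosine"), "dimensions")
  set.seed(8)
  for (i in 1:50) {
    u <- rnorm(12); v <- rnorm(12); w <- rnorm(12)
    expect_equal(similarity(u, v, "minkowski", p = 2),
                 similarity(u, v, "euclidean"), tolerance = 1e-12)
    expect_equal(similarity(u, v, "minkowski", p = 1),
                 similarity(u, v, "manhattan"), tolerance = 1e-12)
    for (mt in c("euclidean", "manhattan", "minkowski")) {
      expect_identical(similarity(u, v, mt), similarity(v, u, mt))
      expect_lte(similarity(u, w, mt),
                 similarity(u, v, mt) + similarity(v, w, mt) + 1e-12)
    }
    expect_gte(similarity(u, v, "cosine"), -1 - 1e-12)
    expect_lte(similarity(u, v, "cosine"), 1 + 1e-12)
  }
})

test_that("rank_similar orders by metric with deterministic ties", {
  set.seed(5)
  vec <- matrix(rnorm(6 * 4), 6, 4,
                dimnames = list(paste0("P", 1:6), NULL))
  vec["P4", ] <- vec["P1", ]  # duplicate of the query
  r <- rank_similar(vec, "P1", "cosine", k = 5)
  expect_identical(r$patient[1], "P4")
  expect_equal(r$score[1], 1)
  expect_false("P1" %in% r$patient)
  # full ordering equals brute-force sort for distances
  for (mt in c("euclidean", "manhattan", "minkowski")) {
    r <- rank_similar(vec, "P2", mt, k = 10)
    brute <- sort(vapply(setdiff(rownames(vec), "P2"), function(o)
      similarity(vec["P2", ], vec[o, ], mt), numeric(1)))
    expect_equal(r$score, unname(brute))
    expect_identical(r$patient, names(brute))
  }
  # ties broken by patient ID
  tied <- matrix(0, 3, 2, dimnames = list(c("PB", "PA", "PQ"), NULL))
  tied["PQ", ] <- c(1, 0)
  rt <- rank_similar(tied, "PQ", "euclidean", k = 2)
  expect_identical(rt$patient, c("PA", "PB"))
  expect_error(rank_similar(vec, "P1", k = 0), "positive")
  expect_error(rank_similar(vec, "PX"), "not among")
})

test_that("cluster evaluation matches brute-force pairwise loops", {
  set.seed(6)
  vec <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(paste0("P", 1:20), NULL))
  labels <- setNames(rep(c("g1", "g2", "g3", "g4"), each = 5),
                     rownames(vec))
  ev <- evaluate_clusters(vec, labels)
  # O(n^2) oracle
  pair_vals <- function(fun) {
    intra <- c(); inter <- c(); all <- c()
    for (i in 1:19) for (j in (i + 1):20) {
      v <- fun(vec[i, ], vec[j, ])
      all <- c(all, v)
      if (labels[i] == labels[j]) intra <- c(intra, v)
      else inter <- c(inter, v)
    }
    list(intra = mean(intra), inter = mean(inter), all = mean(all))
  }
  cos <- pair_vals(function(a, b) similarity(a, b, "cosine"))
  expect_equal(ev$intra_mean_cosine, cos$intra)
  expect_equal(ev$inter_mean_cosine, cos$inter)
  expect_equal(ev$all_pairs_mean_cosine, cos$all)
  euc <- pair_vals(function(a, b) similarity(a, b, "euclidean"))
  expect_equal(ev$distances$mean[ev$distances$metric == "euclidean"],
               euc$all)
  mink <- pair_vals(function(a, b) similarity(a, b, "minkowski", p = 3))
  expect_equal(ev$distances$mean[ev$distances$metric == "minkowski"],
               mink$all)
  expect_identical(ev$per_group$n, rep(5L, 4))
})

test_that("cluster evaluation handles degenerate inputs", {
  ident <- matrix(1, 4, 3, dimnames = list(paste0("P", 1:4), NULL))
  labels <- setNames(c("a", "a", "b", "b"), rownames(ident))
  ev <- evaluate_clusters(ident, labels)
  expect_equal(ev$intra_mean_cosine, 1)
  expect_equal(ev$distances$mean, rep(0, 3))
  # two orthogonal 2-patient groups: intra 1, inter 0
  orth <- rbind(P1 = c(1, 0), P2 = c(2, 0), P3 = c(0, 1), P4 = c(0, 3))
  ev2 <- evaluate_clusters(orth, setNames(c("a", "a", "b", "b"),
                                          rownames(orth)))
  expect_equal(ev2$intra_mean_cosine, 1)
  expect_equal(ev2$inter_mean_cosine, 0)
  # singleton group excluded with a warning
  expect_warning(
    ev3 <- evaluate_clusters(orth, setNames(c("a", "a", "b", "c"),
                                            rownames(orth))),
    "singleton")
  expect_identical(ev3$per_group$group, "a")
})

test_that("vectors and corpora serialize to their text formats", {
  corp <- toy_corpus(n_rep = 3)
  p <- write_corpus(corp, tempfile())
  expect_identical(length(readLines(p)), length(corp$sentences))
  m <- train_embedding(corp, "word2vec", dim = 4, epochs = 2, seed = 1)
  vp <- write_vectors(m$vectors, tempfile())
  lines <- readLines(vp)
  expect_identical(lines[1], paste(nrow(m$vectors), 4))
  expect_identical(length(lines), nrow(m$vectors) + 1L)
})
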