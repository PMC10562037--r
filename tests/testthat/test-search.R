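# independent oracle: reachable object URIs within k forward hops,
# computed by naive repeated scans over the raw triple data.frame
reachable_objects <- function(store, start, k = 3) {
  tr <- store$triples
  nodes <- start
  objs <- character(0)
  for (i in seq_len(k)) {
    rows <- tr[tr$subject %in% nodes, , drop = FALSE]
    objs <- union(objs, rows$object[rows$is_uri])
    nodes <- setdiff(unique(rows$object[rows$is_uri]), nodes)
    if (!length(nodes)) break
  }
  objs
}

naive_search <- function(store, ont, terms, opts) {
  exp <- expand_terms(ont, terms, opts)
  pats <- rolhs:::patient_uris(store)
  sets <- lapply(unique(exp$q_term), function(q) {
    uris <- vapply(exp$code[exp$q_term == q],
                   function(k) ont$classes[[k]]$uri, character(1))
    pats[vapply(pats, function(p)
      any(uris %in% reachable_objects(store, p)), logical(1))]
  })
  sort(Reduce(intersect, sets))
}

test_that("fatigue with one child level expands to exactly four classes", {
  ont <- shipped_ontology()
  e <- expand_terms(ont, "fatigue", search_options(child_levels = 1))
  expect_setequal(e$code, c("NCIT:C3036", "ROO:CTCF01", "ROO:CTCF02",
                            "ROO:CTCF03"))
  expect_identical(e$provenance[e$code == "NCIT:C3036"], "exact")
  expect_identical(sort(unique(e$provenance)), c("child", "exact"))
  expect_identical(e$hop[e$provenance == "child"], rep(1L, 3))
})

test_that("T1 with no expansion excludes its sub-stages", {
  ont <- shipped_ontology()
  e <- expand_terms(ont, "T1", search_options(include_synonyms = TRUE,
                                              child_levels = 0))
  expect_identical(e$code, "NCIT:C48720")
  e1 <- expand_terms(ont, "T1", search_options(child_levels = 1))
  expect_setequal(e1$code, c("NCIT:C48720", "NCIT:C48721", "NCIT:C48722",
                             "NCIT:C48723"))
  # parent inclusion
  ep <- expand_terms(ont, "T1", search_options(child_levels = 0,
                                               include_parents = TRUE))
  expect_true("NCIT:C48879" %in% ep$code)
  expect_identical(ep$provenance[ep$code == "NCIT:C48879"], "parent")
})

test_that("search hits match hand enumeration from the source tables", {
  t <- test_cohort()
  s <- test_store()
  ont <- shipped_ontology()
  res <- search(s, ont, "fatigue", search_options(child_levels = 1))
  expected <- sort(paste0("http://rolhs.local/patient/",
                          unique(t$toxicity$patient_id[
                            t$toxicity$toxicity_type == "fatigue"])))
  expect_identical(res$patients, expected)
  # with child_levels = 0 only the (unused) parent class remains: no hits
  res0 <- search(s, ont, "fatigue", search_options(child_levels = 0))
  expect_identical(res0$patients, character(0))
  # hits carry provenance into expanded classes
  expect_true(all(res$patient_hits$matched_code %in%
                    res$expanded_classes$code))
  expect_false(any(duplicated(
    res$patient_hits[, c("patient", "matched_code")])))
})

test_that("staged T1 search matches sub-staged patients only via children", {
  t <- test_cohort()
  s <- test_store()
  ont <- shipped_ontology()
  r0 <- search(s, ont, "T1", search_options(child_levels = 0))
  r1 <- search(s, ont, "T1", search_options(child_levels = 1))
  pid <- function(r) sort(sub(".*/patient/", "", r$patients))
  expect_identical(pid(r0),
                   sort(t$staging$patient_id[t$staging$t_stage == "T1"]))
  expect_identical(pid(r1),
                   sort(t$staging$patient_id[
                     t$staging$t_stage %in% c("T1", "T1a", "T1b", "T1c")]))
})

test_that("multi-term search is the intersection of single terms", {
  s <- test_store()
  ont <- shipped_ontology()
  opts <- search_options(child_levels = 1)
  both <- search(s, ont, c("fatigue", "prostate cancer"), opts)
  f <- search(s, ont, "fatigue", opts)
  p <- search(s, ont, "prostate cancer", opts)
  expect_identical(both$patients, sort(intersect(f$patients, p$patients)))
  either <- search(s, ont, c("fatigue", "prostate cancer"), opts,
                   combine = "or")
  expect_identical(either$patients, sort(union(f$patients, p$patients)))
  # empty expansion -> empty hits
  none <- search(s, ont, "zzz-nothing", opts)
  expect_identical(none$patients, character(0))
  expect_identical(nrow(none$patient_hits), 0L)
})

test_that("search equals the naive reachability scan; monotone and sound", {
  s <- test_store()
  ont <- shipped_ontology()
  labels <- unlist(lapply(ont$classes, function(c) c(c$label, c$synonyms)))
  set.seed(33)
  terms <- sample(unique(labels), 40)
  for (q in terms) {
    k <- sample(0:2, 1)
    o_off <- search_options(include_synonyms = FALSE, child_levels = k)
    o_on <- search_options(include_synonyms = TRUE, child_levels = k)
    o_deep <- search_options(include_synonyms = TRUE, child_levels = k + 1)
    r_off <- search(s, ont, q, o_off)$patients
    r_on <- search(s, ont, q, o_on)$patients
    r_deep <- search(s, ont, q, o_deep)$patients
    # synonym soundness and level monotonicity
    expect_true(all(r_off %in% r_on), info = q)
    expect_true(all(r_on %in% r_deep), info = q)
    # brute-force equivalence
    expect_identical(r_on, naive_search(s, ont, q, o_on), info = q)
  }
})

test_that("search options are validated and serialized", {
  expect_error(search_options(child_levels = 99), "max_levels")
  expect_error(search_options(child_levels = -1))
  r <- search(test_store(), shipped_ontology(), "fatigue",
              search_options(child_levels = 1))
  p <- write_search_result(r, tempfile(fileext = ".json"))
  parsed <- jsonlite::fromJSON(p)
  expect_identical(sort(parsed$patients), r$patients)
  expect_identical(nrow(parsed$expanded_classes), 4L)
})
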