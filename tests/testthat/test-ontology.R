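test_that("load_ontology validates structure and builds the child index", {
  ont <- shipped_ontology()
  expect_s3_class(ont, "ontology")
  expect_setequal(ont$child_index[["NCIT:C48720"]],
                  c("NCIT:C48721", "NCIT:C48722", "NCIT:C48723"))
  # child_index is the exact inverse of the parent lists
  for (cl in ont$classes)
    for (p in cl$parents)
      expect_true(cl$code %in% ont$child_index[[p]])
  n_links <- sum(vapply(ont$classes, function(c) length(c$parents),
                        integer(1)))
  expect_identical(sum(lengths(ont$child_index)), n_links)
  # uri is the deterministic prefix expansion of the code
  expect_identical(ont$classes[["NCIT:C48720"]]$uri,
                   "http://purl.obolibrary.org/obo/NCIT_C48720")
})

test_that("load_ontology accepts an empty class list", {
  ont <- load_ontology(write_ont_json(list()))
  expect_length(ont$classes, 0)
})

test_that("load_ontology rejects malformed and inconsistent files", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_ontology(bad), "malformed")
  expect_error(load_ontology(tempfile()), "not found")
  # two-class cycle names both offenders
  cyc <- write_ont_json(list(ont_cls("EX:A", "a", parents = "EX:B"),
                             ont_cls("EX:B", "b", parents = "EX:A")))
  expect_error(load_ontology(cyc), "cycle.*EX:A, EX:B")
  expect_error(load_ontology(write_ont_json(list(
    ont_cls("EX:A", "a", parents = "EX:Z")))), "dangling.*EX:Z")
  expect_error(load_ontology(write_ont_json(list(
    ont_cls("EX:A", "a"), ont_cls("EX:A", "b")))), "duplicate")
  expect_error(load_ontology(write_ont_json(list(
    ont_cls("EX:A", "a", parents = "EX:A")))), "itself")
  expect_error(load_ontology(write_ont_json(list(ont_cls("EX:A", "")))),
               "empty label")
})

test_that("find_classes does exact and synonym matching, normalized", {
  ont <- shipped_ontology()
  hit <- find_classes(ont, "heart attack", include_synonyms = TRUE)
  expect_identical(hit$code, "NCIT:C27996")
  expect_identical(hit$provenance, "synonym")
  expect_identical(find_classes(ont, "T1 Stage")$code, "NCIT:C48720")
  expect_identical(nrow(find_classes(ont, "zzz-nonexistent")), 0L)
  # case-insensitive, whitespace-normalized
  expect_identical(
    find_classes(ont, "  MYOCARDIAL   infarction ")$code, "NCIT:C27996")
  # synonyms off: synonym-only matches disappear
  expect_identical(nrow(find_classes(ont, "heart attack",
                                     include_synonyms = FALSE)), 0L)
  expect_error(find_classes(ont, "  "), "non-empty")
})

test_that("descendants and ancestors walk bounded levels on the DAG", {
  ont <- shipped_ontology()
  expect_setequal(descendants(ont, "NCIT:C48720", 1),
                  c("NCIT:C48721", "NCIT:C48722", "NCIT:C48723"))
  expect_identical(descendants(ont, "NCIT:C48721", 3), character(0))
  expect_identical(descendants(ont, "NCIT:C48720", 0), character(0))
  expect_setequal(ancestors(ont, "NCIT:C48721", 1), "NCIT:C48720")
  expect_identical(ancestors(ont, "ROO:ROOT0", 5), character(0))
  expect_error(descendants(ont, "EX:nope", 1), "unknown")

  tiny <- tiny_ontology()
  expect_setequal(descendants(tiny, "EX:A", 2), c("EX:B", "EX:C"))
  expect_identical(descendants(tiny, "EX:A", 1), "EX:B")
  # diamond: both parents and the shared grandparent
  expect_setequal(ancestors(tiny, "EX:D", 2), c("EX:B2", "EX:C2", "EX:A2"))
})

test_that("traversal agrees with a brute-force closure oracle", {
  ont <- shipped_ontology()
  codes <- names(ont$classes)
  # oracle: k-step reachability by repeated one-step expansion over the
  # raw parent lists, independent of the package's BFS
  parents_of <- lapply(ont$classes, `[[`, "parents")
  children_of <- lapply(codes, function(k)
    codes[vapply(codes, function(j) k %in% parents_of[[j]], logical(1))])
  names(children_of) <- codes
  oracle <- function(start, k, index) {
    reach <- character(0); frontier <- start
    for (i in seq_len(k)) {
      frontier <- setdiff(unique(unlist(index[frontier])), c(reach, start))
      if (!length(frontier)) break
      reach <- c(reach, frontier)
    }
    sort(reach)
  }
  set.seed(9)
  for (x in sample(codes, 40)) {
    for (k in c(1L, 2L, 4L)) {
      expect_identical(descendants(ont, x, k), oracle(x, k, children_of))
      expect_identical(ancestors(ont, x, k), oracle(x, k, parents_of))
    }
  }
  # duality: y in desc(x, k)  <=>  x in anc(y, k' <= k)
  for (x in sample(codes, 15)) {
    for (y in descendants(ont, x, 3))
      expect_true(x %in% ancestors(ont, y, 3))
  }
  # monotone in level
  for (x in sample(codes, 20))
    expect_true(all(descendants(ont, x, 1) %in% descendants(ont, x, 2)))
})

test_that("CURIE/URI expansion is a bijection over the prefix table", {
  px <- rolhs:::.rolhs_prefixes
  codes <- c("NCIT:C48720", "ROO:CTCF01", "roo:hasTStage")
  expect_identical(uri_to_curie(curie_to_uri(codes, px), px), codes)
  expect_error(curie_to_uri("NOPE:123", px), "unknown prefix")
  expect_identical(uri_to_curie("http://elsewhere.org/x", px),
                   "http://elsewhere.org/x")
})

test_that("shipped ontology file matches its in-code definition", {
  p <- write_fixture_ontology(tempfile(fileext = ".json"))
  expect_identical(readLines(p),
                   readLines(system.file("extdata",
                                         "synthetic_ontology.json",
                                         package = "rolhs")))
})
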