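test_that("mapping a 3-patient fixture yields the hand-enumerated triples", {
  ont <- shipped_ontology()
  store <- compile_mapping(mini_spec(), mini_tables(), ont)
  # per patient: 1 patient type + 1 diagnosis type + 2 lookups + 1 date
  # literal + 1 relationship = 6 -> 18 triples
  expect_identical(n_triples(store), 18L)
  tr <- store$triples
  expect_identical(
    tr$object[tr$subject == "http://rolhs.local/patient/P1" &
                grepl("hasSex", tr$predicate)],
    "http://purl.obolibrary.org/obo/NCIT_C20197")
  # date literal normalized to ISO with explicit datatype
  expect_identical(
    tr$datatype[grepl("hasDateOfDiagnosis", tr$predicate)][1], "date")
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$",
                        tr$object[tr$datatype %in% "date"])))
  st <- attr(store, "stats")
  expect_identical(st$applicable, 9L)  # 3 sex + 3 smoking + 3 dates
  expect_identical(st$mapped, 9L)
})

test_that("empty tables compile to an empty store", {
  t <- mini_tables()
  t$demographics <- t$demographics[0, ]
  t$diagnosis <- t$diagnosis[0, ]
  store <- compile_mapping(mini_spec(), t, shipped_ontology())
  expect_identical(n_triples(store), 0L)
})

test_that("blanked cells yield no triple; unknown lookup values are logged", {
  t <- mini_tables()
  t$demographics$sex[1] <- ""
  t$demographics$smoking_status[2] <- "vaping"   # not in lookup
  store <- compile_mapping(mini_spec(), t, shipped_ontology())
  st <- attr(store, "stats")
  expect_identical(st$applicable, 8L)
  expect_identical(st$mapped, 7L)
  expect_identical(st$skipped$value, "vaping")
  expect_identical(n_triples(store), 16L)
})

test_that("spec validation rejects broken mappings with names", {
  t <- mini_tables()
  ont <- shipped_ontology()
  sp <- mini_spec()
  sp$property_bridges[[1]]$lookup$male <- "NCIT:C000000"
  expect_error(compile_mapping(sp, t, ont), "unresolvable class code")
  sp <- mini_spec()
  sp$class_maps[[1]]$table <- "nope"
  expect_error(compile_mapping(sp, t, ont), "missing table")
  sp <- mini_spec()
  sp$property_bridges[[1]]$column <- "nope"
  expect_error(compile_mapping(sp, t, ont), "does not exist")
  sp <- mini_spec()
  sp$class_maps[[2]]$name <- "patient"
  expect_error(compile_mapping(sp, t, ont), "duplicate class-map")
})

test_that("turtle serialization round-trips random stores exactly", {
  set.seed(14)
  for (i in 1:20) {
    s <- random_store(n = sample(5:40, 1))
    f <- tempfile(fileext = ".ttl")
    serialize_turtle(s, f)
    s2 <- parse_turtle(f)
    expect_identical(s2$triples, s$triples)
  }
})

test_that("turtle output is deterministic, prefix-led, and countable", {
  s <- test_store()
  f1 <- tempfile(); f2 <- tempfile()
  serialize_turtle(s, f1); serialize_turtle(s, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  # independent count: non-prefix, non-blank lines each hold one triple
  body <- lines[!startsWith(lines, "@prefix") & nzchar(lines)]
  expect_identical(length(body), n_triples(s))
  expect_true(all(grepl(" \\.$", body)))
  # empty store -> prefixes only
  fe <- tempfile()
  serialize_turtle(triple_store(), fe)
  expect_true(all(startsWith(readLines(fe)[nzchar(readLines(fe))],
                             "@prefix")))
})

test_that("turtle parse failures name the line", {
  f <- tempfile()
  writeLines(c("@prefix ex: <http://e.org/> .",
               "ex:a ex:b ex:c ."," ex:broken ex:only"), f)
  expect_error(parse_turtle(f), "line 3")
})

test_that("BGP query matches the relational filter oracle", {
  t <- test_cohort()
  s <- test_store()
  pid_of <- function(uris) sort(sub(".*/patient/", "", uris))
  b <- query(s, list(c("?p", "roo:hasDiagnosis", "?d"),
                     c("?d", "roo:hasTStage", "NCIT:C48723")))
  expect_identical(pid_of(b$p),
                   sort(t$staging$patient_id[t$staging$t_stage == "T1c"]))
  b2 <- query(s, list(c("?p", "roo:hasSmokingStatus", "NCIT:C67147")))
  expect_identical(
    pid_of(b2$p),
    sort(t$demographics$patient_id[
      t$demographics$smoking_status == "current"]))
  # join of two patterns equals the intersection of single-pattern sets
  j <- query(s, list(c("?p", "roo:hasSmokingStatus", "NCIT:C67147"),
                     c("?p", "roo:hasSex", "NCIT:C20197")))
  m <- query(s, list(c("?p", "roo:hasSex", "NCIT:C20197")))
  expect_identical(sort(j$p), sort(intersect(b2$p, m$p)))
})

test_that("all-constant patterns have ask semantics", {
  s <- test_store()
  tr <- s$triples[1, ]
  yes <- query(s, list(c(tr$subject, tr$predicate, tr$object)))
  expect_identical(nrow(yes), 1L)
  expect_identical(ncol(yes), 0L)
  no <- query(s, list(c(tr$subject, tr$predicate,
                        "http://example.org/absent")))
  expect_identical(nrow(no), 0L)
})

test_that("literal objects are queryable as constants", {
  s <- test_store()
  t <- test_cohort()
  b <- query(s, list(c("?p", "roo:hasAge",
                       t$demographics$age[1])))
  expect_true(paste0("http://rolhs.local/patient/",
                     t$demographics$patient_id[1]) %in% b$p)
})

test_that("patient_subgraph bounds forward reachability", {
  s <- test_store()
  p <- "http://rolhs.local/patient/P0001"
  expect_identical(n_triples(patient_subgraph(s, p, 0)), 0L)
  d1 <- patient_subgraph(s, p, 1)
  expect_identical(sort(unique(d1$triples$subject)), p)
  expect_identical(n_triples(d1),
                   length(s$index$s[[p]]))
  d2 <- patient_subgraph(s, p, 2)
  expect_true(n_triples(d2) > n_triples(d1))
  expect_true(all(do.call(paste, d1$triples) %in% do.call(paste, d2$triples)))
  expect_error(patient_subgraph(s, "http://rolhs.local/patient/PX", 2),
               "unknown node")
})

test_that("graph exports enumerate nodes and edges exactly", {
  s <- patient_subgraph(test_store(), "http://rolhs.local/patient/P0002", 3)
  n_terms <- length(unique(c(s$triples$subject, s$triples$object)))
  fd <- tempfile(fileext = ".dot")
  export_graph(s, fd, "dot", ont = shipped_ontology())
  dot <- readLines(fd)
  expect_identical(sum(grepl("^  n\\d+ \\[label", dot)), n_terms)
  expect_identical(sum(grepl("->", dot, fixed = TRUE)), n_triples(s))
  # ontology labels resolve for class nodes
  expect_true(any(grepl("Stage|Carcinoma", dot)))
  fg <- tempfile(fileext = ".graphml")
  export_graph(s, fg, "graphml")
  xml <- xml2::read_xml(fg)
  expect_identical(length(xml2::xml_find_all(xml, ".//*[local-name()='node']")),
                   n_terms)
  expect_identical(length(xml2::xml_find_all(xml, ".//*[local-name()='edge']")),
                   n_triples(s))
  # diagnosis-to-toxicity relationship edge present for this patient
  expect_true(any(grepl("hasToxicity", readLines(fg))))
})

test_that("store size matches the cell-count oracle on the cohort", {
  t <- test_cohort()
  s <- test_store()
  st <- attr(s, "stats")
  # value-bearing cells + type triples + relationship triples + unit class
  nb <- function(x) sum(!rolhs:::is_blank(x))
  expected_types <- nrow(t$demographics) + nrow(t$diagnosis) +
    nrow(t$treatment_course) + nrow(t$toxicity) + nrow(t$labs) +
    nrow(t$dose_grid)
  expected_rel <- nrow(t$diagnosis) + 2 * nrow(t$treatment_course) +
    nrow(t$toxicity) + nrow(t$labs) + nrow(t$dose_grid)
  expected_unit <- nrow(t$dose_grid)
  expect_identical(n_triples(s),
                   as.integer(st$mapped + expected_types + expected_rel +
                                expected_unit))
  # every URI resolves through the prefix table or the subject base
  uris <- unique(c(s$triples$subject, s$triples$predicate,
                   s$triples$object[s$triples$is_uri]))
  contracted <- uri_to_curie(uris, s$prefixes)
  expect_true(all(contracted != uris | startsWith(uris, "http://rolhs.local")))
})
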