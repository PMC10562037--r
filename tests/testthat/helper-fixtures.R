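# Shared fixtures, built in code. Heavier objects are memoized per session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# write an ontology JSON file from a compact class list
write_ont_json <- function(classes,
                           prefixes = list(
                             NCIT = "http://purl.obolibrary.org/obo/NCIT_",
                             EX = "http://example.org/ex#")) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(prefixes = prefixes, classes = classes),
                       path, auto_unbox = TRUE, null = "null")
  path
}

ont_cls <- function(code, label, synonyms = character(0),
                    parents = character(0)) {
  list(code = code, label = label, synonyms = as.list(synonyms),
       parents = as.list(parents))
}

# chain A -> B -> C plus diamond D -> {B2, C2} -> A2
tiny_ontology <- function() {
  load_ontology(write_ont_json(list(
    ont_cls("EX:A", "Alpha"),
    ont_cls("EX:B", "Beta", parents = "EX:A"),
    ont_cls("EX:C", "Gamma", parents = "EX:B"),
    ont_cls("EX:A2", "Top"),
    ont_cls("EX:B2", "Left", parents = "EX:A2"),
    ont_cls("EX:C2", "Right", parents = "EX:A2"),
    ont_cls("EX:D", "Bottom", parents = c("EX:B2", "EX:C2")))))
}

shipped_ontology <- function() memo("ont", fixture_ontology())

# a small clean cohort and its compiled graph, shared across test files
test_cohort <- function() memo("cohort", generate_cohort(60, seed = 42))
test_store <- function() memo("store", {
  compile_mapping(default_mapping_spec(), test_cohort(), shipped_ontology())
})

# hand-specified 3-patient mini world used for exact triple enumeration
mini_tables <- function() {
  t <- list(
    demographics = data.frame(
      patient_id = c("P1", "P2", "P3"),
      sex = c("male", "female", "male"),
      smoking_status = c("never", "current", "former"),
      stringsAsFactors = FALSE),
    diagnosis = data.frame(
      patient_id = c("P1", "P2", "P3"),
      diagnosis_code = c("prostate_carcinoma", "nsclc", "sclc"),
      date_of_diagnosis = c("20200101", "20200215", "20200301"),
      stringsAsFactors = FALSE))
  class(t) <- c("cohort_tables", "list")
  t
}

mini_spec <- function() {
  L <- list(sex = list(male = "NCIT:C20197", female = "NCIT:C16576"),
            smoking = list(never = "NCIT:C65108", current = "NCIT:C67147",
                           former = "NCIT:C67148"),
            dx = list(prostate_carcinoma = "NCIT:C4863", nsclc = "NCIT:C2926",
                      sclc = "NCIT:C4917"))
  list(
    base = "http://rolhs.local",
    prefixes = unlist(list(
      NCIT = "http://purl.obolibrary.org/obo/NCIT_",
      roo = "http://www.cancerdata.org/roo/",
      rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
      xsd = "http://www.w3.org/2001/XMLSchema#")),
    class_maps = list(
      list(name = "patient", table = "demographics",
           uri_template = "{base}/patient/{patient_id}",
           type_class = "NCIT:C16960"),
      list(name = "diagnosis", table = "diagnosis",
           uri_template = "{base}/diagnosis/{patient_id}",
           type_column = "diagnosis_code", type_lookup = L$dx)),
    property_bridges = list(
      list(subject_map = "patient", predicate = "roo:hasSex",
           column = "sex", lookup = L$sex),
      list(subject_map = "patient", predicate = "roo:hasSmokingStatus",
           column = "smoking_status", lookup = L$smoking),
      list(subject_map = "diagnosis", predicate = "roo:hasDateOfDiagnosis",
           column = "date_of_diagnosis", datatype = "date"),
      list(subject_map = "patient", predicate = "roo:hasDiagnosis",
           object_map = "diagnosis")))
}

# random triple store for round-trip properties
random_store <- function(n = 20L) {
  subs <- paste0("http://example.org/s", sample(1:8, n, TRUE))
  preds <- paste0("http://example.org/p", sample(1:5, n, TRUE))
  lit <- runif(n) < 0.5
  obj <- ifelse(lit,
                paste0("lit \"q\" \\", sample(letters, n, TRUE),
                       sample(1:99, n, TRUE)),
                paste0("http://example.org/o", sample(1:9, n, TRUE)))
  dt <- ifelse(lit, sample(c("string", "integer", "decimal", "date"),
                           n, TRUE), NA_character_)
  obj[lit & dt == "integer"] <- as.character(sample(-50:50, sum(lit & dt == "integer"), TRUE))
  obj[lit & dt == "decimal"] <- sprintf("%.2f", runif(sum(lit & dt == "decimal"), -5, 5))
  obj[lit & dt == "date"] <- format(as.Date("2020-01-01") +
                                      sample(0:999, sum(lit & dt == "date"), TRUE))
  triple_store(data.frame(subject = subs, predicate = preds, object = obj,
                          is_uri = !lit, datatype = dt,
                          stringsAsFactors = FALSE),
               prefixes = c(ex = "http://example.org/"))
}

default_rate <- function(r = 0.05) {
  c(type = r, cross_field = r, mandatory = r, range = r, format = r)
}
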