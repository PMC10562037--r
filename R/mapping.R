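#' Declarative relational-to-RDF mapping
#'
#' A mapping spec is a JSON mirror of the D2RQ ClassMap / PropertyBridge /
#' refersToClassMap triad. Class maps mint one subject URI per table row
#' from a URI template (columns in `{braces}`), optionally asserting an
#' `rdf:type` triple from a fixed class or a per-row value-to-class
#' lookup. Property bridges attach, per row, either a literal column (with
#' a datatype), a value-to-class lookup, a fixed object class, or a
#' reference to another class map (the relational join implied by shared
#' template columns). Rows with a blank template column produce no subject
#' and cells blanked by the ETL step produce no triple; lookup values
#' missing from the lookup table are skipped and logged, never invented.
#'
#' @name mapping_spec
NULL

fill_template <- function(template, row, base) {
  template <- gsub("{base}", base, template, fixed = TRUE)
  cols <- regmatches(template,
                     gregexpr("\\{([A-Za-z0-9_]+)\\}", template))[[1]]
  cols <- gsub("[{}]", "", cols)
  n <- nrow(row)
  out <- rep(template, n)
  ok <- rep(TRUE, n)
  for (col in cols) {
    v <- row[[col]]
    ok <- ok & !is_blank(v)
    for (i in which(ok))
      out[i] <- gsub(paste0("{", col, "}"), v[i], out[i], fixed = TRUE)
  }
  out[!ok] <- NA_character_
  out
}

template_columns <- function(template) {
  cols <- regmatches(template,
                     gregexpr("\\{([A-Za-z0-9_]+)\\}", template))[[1]]
  setdiff(gsub("[{}]", "", cols), "base")
}

check_mapping_spec <- function(spec, tables, ont) {
  nm <- vapply(spec$class_maps, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("mapping failure: duplicate class-map names", call. = FALSE)
  for (cm in spec$class_maps) {
    if (!cm$table %in% names(tables))
      stop("mapping failure: class map '", cm$name,
           "' references missing table ", cm$table, call. = FALSE)
    miss <- setdiff(template_columns(cm$uri_template),
                    names(tables[[cm$table]]))
    if (length(miss))
      stop("mapping failure: class map '", cm$name,
           "' template references missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (code in c(cm$type_class,
                   unlist(cm$type_lookup, use.names = FALSE)))
      if (!code %in% names(ont$classes))
        stop("mapping failure: unresolvable class code ", code,
             " in class map '", cm$name, "'", call. = FALSE)
  }
  maps <- stats::setNames(spec$class_maps, nm)
  for (b in spec$property_bridges) {
    if (!b$subject_map %in% nm)
      stop("mapping failure: unknown subject map ", b$subject_map,
           call. = FALSE)
    curie_to_uri(b$predicate, spec$prefixes)  # must resolve
    tb <- maps[[b$subject_map]]$table
    if (!is.null(b$column) && !b$column %in% names(tables[[tb]]))
      stop("mapping failure: bridge column ", tb, ".", b$column,
           " does not exist", call. = FALSE)
    for (code in c(b$object_class, unlist(b$lookup, use.names = FALSE)))
      if (!code %in% names(ont$classes))
        stop("mapping failure: unresolvable class code ", code,
             " in bridge (", tb, ", ", b$column %||% "-", ")",
             call. = FALSE)
    if (!is.null(b$object_map)) {
      if (!b$object_map %in% nm)
        stop("mapping failure: unknown object map ", b$object_map,
             call. = FALSE)
      otbl <- tables[[maps[[b$object_map]]$table]]
      miss <- setdiff(template_columns(maps[[b$subject_map]]$uri_template),
                      names(otbl))
      if (length(miss))
        stop("mapping failure: reference bridge cannot join ",
             b$subject_map, " from table of ", b$object_map,
             ": missing columns ", paste(miss, collapse = ", "),
             call. = FALSE)
    }
  }
  maps
}

#' Compile a mapping spec over cohort tables into a triple store
#'
#' @param spec mapping spec (list, e.g. from [default_mapping_spec()] or
#'   [read_mapping_spec()]).
#' @param tables a (cleaned) `cohort_tables`.
#' @param ont the `ontology` the lookups must resolve against.
#' @return a `triple_store`; `attr(, "stats")` holds `applicable` (number
#'   of non-blank cells under value-bearing bridges), `mapped` (cells that
#'   produced a triple), and `skipped` (log of skipped lookup values).
#' @export
compile_mapping <- function(spec, tables, ont) {
  maps <- check_mapping_spec(spec, tables, ont)
  prefixes <- spec$prefixes
  base <- spec$base
  rdf_type <- rdf_type_uri(prefixes)
  rows <- list()
  skipped <- list()
  applicable <- 0L
  mapped <- 0L
  add <- function(s, p, o, is_uri, datatype = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o, is_uri = is_uri,
      datatype = datatype, stringsAsFactors = FALSE)
  }
  log_skip <- function(tb, col, vals) {
    if (length(vals))
      skipped[[length(skipped) + 1L]] <<- data.frame(
        table = tb, column = col, value = vals, stringsAsFactors = FALSE)
  }

  subj_uri <- lapply(maps, function(cm)
    fill_template(cm$uri_template, tables[[cm$table]], base))

  for (cm in maps) {
    s <- subj_uri[[cm$name]]
    tbl <- tables[[cm$table]]
    if (!is.null(cm$type_class)) {
      ok <- !is.na(s)
      if (any(ok)) add(s[ok], rdf_type,
                       curie_to_uri(cm$type_class, prefixes), TRUE)
    } else if (!is.null(cm$type_column)) {
      v <- tbl[[cm$type_column]]
      ok <- !is.na(s) & !is_blank(v)
      known <- ok & v %in% names(cm$type_lookup)
      log_skip(cm$table, cm$type_column, unique(v[ok & !known]))
      if (any(known)) {
        codes <- unlist(cm$type_lookup)[v[known]]
        add(s[known], rdf_type, curie_to_uri(codes, prefixes), TRUE)
      }
    }
  }

  for (b in spec$property_bridges) {
    cm <- maps[[b$subject_map]]
    tbl <- tables[[cm$table]]
    pred <- curie_to_uri(b$predicate, prefixes)
    if (!is.null(b$object_map)) {
      om <- maps[[b$object_map]]
      otbl <- tables[[om$table]]
      s <- fill_template(cm$uri_template, otbl, base)
      o <- fill_template(om$uri_template, otbl, base)
      ok <- !is.na(s) & !is.na(o)
      if (any(ok)) add(s[ok], pred, o[ok], TRUE)
    } else if (!is.null(b$object_class)) {
      s <- subj_uri[[cm$name]]
      ok <- !is.na(s)
      if (any(ok)) add(s[ok], pred, curie_to_uri(b$object_class, prefixes),
                       TRUE)
    } else {
      v <- tbl[[b$column]]
      s <- subj_uri[[cm$name]]
      nonblank <- !is_blank(v)
      applicable <- applicable + sum(nonblank)
      ok <- nonblank & !is.na(s)
      if (!is.null(b$lookup)) {
        known <- ok & v %in% names(b$lookup)
        log_skip(cm$table, b$column, unique(v[ok & !known]))
        if (any(known)) {
          codes <- unlist(b$lookup)[v[known]]
          add(s[known], pred, curie_to_uri(codes, prefixes), TRUE)
        }
        mapped <- mapped + sum(known)
      } else {
        dt <- b$datatype %||% "string"
        val <- v
        if (dt == "date") {
          parse_ok <- valid_yyyymmdd(v)
          bad <- ok & !parse_ok
          log_skip(cm$table, b$column, unique(v[bad]))
          ok <- ok & parse_ok
          val <- ifelse(parse_ok,
                        paste(substr(v, 1, 4), substr(v, 5, 6),
                              substr(v, 7, 8), sep = "-"), v)
        }
        if (any(ok)) add(s[ok], pred, val[ok], FALSE, dt)
        mapped <- mapped + sum(ok)
      }
    }
  }

  df <- if (length(rows)) do.call(rbind, rows) else NULL
  store <- triple_store(df, prefixes = prefixes)
  attr(store, "stats") <- list(
    applicable = applicable, mapped = mapped,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(table = character(0), column = character(0),
                 value = character(0), stringsAsFactors = FALSE))
  store
}

#' Default mapping spec for generated cohorts
#'
#' Mirrors the generator's schema: patient, diagnosis (augmented with the
#' staging columns, which share its URI template), treatment course,
#' per-row toxicity and lab nodes, and DVH summary nodes with an explicit
#' cGy unit class. Value-to-class lookups are inlined from the shared
#' vocabulary.
#'
#' @param base base URI for minted subjects.
#' @return mapping spec list.
#' @export
default_mapping_spec <- function(base = "http://rolhs.local") {
  L <- .rolhs_lookups
  lk <- function(x) as.list(L[[x]])
  cm <- function(name, table, uri_template, type_class = NULL,
                 type_column = NULL, type_lookup = NULL) {
    Filter(Negate(is.null),
           list(name = name, table = table, uri_template = uri_template,
                type_class = type_class, type_column = type_column,
                type_lookup = type_lookup))
  }
  br <- function(subject_map, predicate, column = NULL, lookup = NULL,
                 datatype = NULL, object_map = NULL, object_class = NULL) {
    Filter(Negate(is.null),
           list(subject_map = subject_map, predicate = predicate,
                column = column, lookup = lookup, datatype = datatype,
                object_map = object_map, object_class = object_class))
  }
  list(
    base = base,
    prefixes = as.list(.rolhs_prefixes),
    class_maps = list(
      cm("patient", "demographics", "{base}/patient/{patient_id}",
         type_class = "NCIT:C16960"),
      cm("diagnosis", "diagnosis", "{base}/diagnosis/{patient_id}",
         type_column = "diagnosis_code", type_lookup = lk("diagnosis_code")),
      cm("staging", "staging", "{base}/diagnosis/{patient_id}"),
      cm("course", "treatment_course", "{base}/course/{rt_course_id}",
         type_class = "ROO:RTC00"),
      cm("toxicity", "toxicity",
         "{base}/toxicity/{patient_id}-{toxicity_seq}",
         type_column = "ctcae_term", type_lookup = lk("ctcae_term")),
      cm("lab", "labs", "{base}/lab/{patient_id}-{lab_test}",
         type_column = "lab_term", type_lookup = lk("lab_term")),
      cm("dvh", "dose_grid", "{base}/dvh/{rt_course_id}-{structure}",
         type_class = "ROO:DVH00")),
    property_bridges = list(
      br("patient", "roo:hasSex", "sex", lk("sex")),
      br("patient", "roo:hasRace", "race", lk("race")),
      br("patient", "roo:hasEthnicity", "ethnicity", lk("ethnicity")),
      br("patient", "roo:hasSmokingStatus", "smoking_status",
         lk("smoking_status")),
      br("patient", "roo:hasPerformanceStatus", "performance_status",
         lk("performance_status")),
      br("patient", "roo:hasMaritalStatus", "marital_status",
         datatype = "integer"),
      br("patient", "roo:hasAge", "age", datatype = "integer"),
      br("diagnosis", "roo:hasHistology", "histology", lk("histology")),
      br("diagnosis", "roo:hasLaterality", "laterality", lk("laterality")),
      br("diagnosis", "roo:hasDateOfDiagnosis", "date_of_diagnosis",
         datatype = "date"),
      br("staging", "roo:hasTStage", "t_stage", lk("t_stage")),
      br("staging", "roo:hasNStage", "n_stage", lk("n_stage")),
      br("staging", "roo:hasMStage", "m_stage", lk("m_stage")),
      br("staging", "roo:hasStageGroup", "stage_group", lk("stage_group")),
      br("staging", "roo:hasGleasonGradeGroup", "gleason_grade_group",
         lk("gleason_grade_group")),
      br("staging", "roo:hasPSACategory", "psa_category",
         lk("psa_category")),
      br("staging", "roo:hasPSAValue", "psa_value", datatype = "decimal"),
      br("course", "roo:hasModality", "modality", lk("modality")),
      br("course", "roo:hasTechnique", "technique", lk("technique")),
      br("course", "roo:hasIntent", "intent", lk("intent")),
      br("course", "roo:hasFractionation", "fractionation",
         lk("fractionation")),
      br("course", "roo:hasRTStartDate", "rt_start_date",
         datatype = "date"),
      br("course", "roo:hasPrescriptionDose", "prescription_dose_cgy",
         datatype = "integer"),
      br("course", "roo:hasFractionCount", "fraction_count",
         datatype = "integer"),
      br("toxicity", "roo:hasToxicityGrade", "grade",
         datatype = "integer"),
      br("lab", "roo:hasLabValue", "lab_value", datatype = "decimal"),
      br("lab", "roo:hasLabDate", "lab_date", datatype = "date"),
      br("dvh", "roo:hasMeanDose", "mean_dose_cgy", datatype = "decimal"),
      br("dvh", "roo:hasMaxDose", "max_dose_cgy", datatype = "decimal"),
      br("dvh", "roo:hasD95", "d95_cgy", datatype = "decimal"),
      br("dvh", "roo:hasVRx", "v_rx_pct", datatype = "decimal"),
      br("dvh", "roo:hasUnit", object_class = "NCIT:C64557"),
      br("patient", "roo:hasDiagnosis", object_map = "diagnosis"),
      br("patient", "roo:hasTreatmentCourse", object_map = "course"),
      br("diagnosis", "roo:isTreatedBy", object_map = "course"),
      br("diagnosis", "roo:hasToxicity", object_map = "toxicity"),
      br("patient", "roo:hasLabResult", object_map = "lab"),
      br("course", "roo:hasDVH", object_map = "dvh"))
  )
}

#' Read / write a mapping spec as JSON
#' @param spec mapping spec list.
#' @param path JSON file path.
#' @return `write_mapping_spec` returns `path` invisibly;
#'   `read_mapping_spec` returns the spec list.
#' @export
write_mapping_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mapping_spec
#' @export
read_mapping_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spec$prefixes <- unlist(spec$prefixes)
  spec
}
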