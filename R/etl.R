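#' Validation rules for cohort tables
#'
#' A rule applies one of the five cleaning checks to a (table, column)
#' target: `type` (value parses as the expected scalar type), `cross_field`
#' (value consistent with another column, e.g. RT start not before the
#' diagnosis date, or a dependent element present), `mandatory` (cell not
#' empty), `range` (numeric value within `[lo, hi]`), `format` (date in
#' YYYYMMDD). Empty cells are skipped by all checks except `mandatory`,
#' and unparseable values are owned by `type`/`format` so a single faulty
#' cell violates exactly one rule.
#'
#' @param kind one of `"type"`, `"cross_field"`, `"mandatory"`, `"range"`,
#'   `"format"`.
#' @param table,column target cell coordinates.
#' @param params kind-specific parameters: `type` needs `expected`
#'   (`"integer"` or `"decimal"`); `range` needs `lo`, `hi`; `cross_field`
#'   needs `relation` (`"date_not_before"` with `other_table`,
#'   `other_column`, `join`, or `"requires"` with `other_column`).
#' @return object of class `validation_rule`.
#' @export
validation_rule <- function(kind, table, column, params = list()) {
  kinds <- c("type", "cross_field", "mandatory", "range", "format")
  if (!kind %in% kinds)
    stop("unknown rule kind: ", kind, call. = FALSE)
  if (kind == "range") {
    stopifnot(is.numeric(params$lo), is.numeric(params$hi))
    if (params$lo > params$hi) stop("range lower bound above upper",
                                    call. = FALSE)
  }
  structure(list(kind = kind, table = table, column = column,
                 params = params), class = "validation_rule")
}

#' Default validation rule set for generated cohorts
#'
#' Covers all five checks over the generator's schema, including the
#' dependent-element rules (T stage requires N and M stage; a prescription
#' dose requires a fraction count).
#' @return list of `validation_rule` objects.
#' @export
default_rules <- function() {
  r <- function(...) validation_rule(...)
  list(
    r("type", "demographics", "performance_status",
      list(expected = "integer")),
    r("type", "demographics", "age", list(expected = "integer")),
    r("type", "treatment_course", "fraction_count",
      list(expected = "integer")),
    r("type", "treatment_course", "prescription_dose_cgy",
      list(expected = "integer")),
    r("type", "labs", "lab_value", list(expected = "decimal")),
    r("range", "demographics", "marital_status", list(lo = 1, hi = 9)),
    r("range", "demographics", "performance_status", list(lo = 0, hi = 4)),
    r("range", "toxicity", "grade", list(lo = 1, hi = 5)),
    r("mandatory", "demographics", "patient_id"),
    r("mandatory", "treatment_course", "rt_course_id"),
    r("format", "diagnosis", "date_of_diagnosis"),
    r("format", "treatment_course", "rt_start_date"),
    r("format", "labs", "lab_date"),
    r("cross_field", "treatment_course", "rt_start_date",
      list(relation = "date_not_before", other_table = "diagnosis",
           other_column = "date_of_diagnosis", join = "patient_id")),
    r("cross_field", "staging", "t_stage",
      list(relation = "requires", other_column = "n_stage")),
    r("cross_field", "staging", "t_stage",
      list(relation = "requires", other_column = "m_stage")),
    r("cross_field", "treatment_course", "prescription_dose_cgy",
      list(relation = "requires", other_column = "fraction_count"))
  )
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(x))
parses_int <- function(x) grepl("^-?[0-9]+$", x)
parses_dec <- function(x) grepl("^-?[0-9]+(\\.[0-9]+)?$", x)
valid_yyyymmdd <- function(x) {
  ok <- grepl("^[0-9]{8}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], "%Y%m%d"))
  ok
}

#' Validate cohort tables against a rule set
#'
#' Evaluates every rule on every applicable row; the report is
#' deterministic and ordered by (table, row, column, check) regardless of
#' rule order.
#'
#' @param tables a `cohort_tables`.
#' @param rules list of `validation_rule`s (default [default_rules()]).
#' @return object of class `validation_report`: list with `violations`
#'   (data.frame `table`, `row`, `column`, `check`, `message`) and
#'   `summary` (counts per check).
#' @export
validate <- function(tables, rules = default_rules()) {
  for (rule in rules) {
    if (!rule$table %in% names(tables))
      stop("rule targets missing table: ", rule$table, call. = FALSE)
    if (!rule$column %in% names(tables[[rule$table]]))
      stop("rule targets missing column: ", rule$table, ".", rule$column,
           call. = FALSE)
  }
  out <- list()
  emit <- function(tb, rows, col, check, msg) {
    if (length(rows))
      out[[length(out) + 1L]] <<- data.frame(
        table = tb, row = as.integer(rows), column = col, check = check,
        message = msg, stringsAsFactors = FALSE)
  }
  for (rule in rules) {
    x <- tables[[rule$table]][[rule$column]]
    blank <- is_blank(x)
    if (rule$kind == "mandatory") {
      emit(rule$table, which(blank), rule$column, "mandatory",
           "mandatory element is empty")
    } else if (rule$kind == "type") {
      bad <- !blank & !(if (rule$params$expected == "integer")
        parses_int(x) else parses_dec(x))
      emit(rule$table, which(bad), rule$column, "type",
           paste("value is not of type", rule$params$expected))
    } else if (rule$kind == "range") {
      num <- suppressWarnings(as.numeric(x))
      bad <- !blank & !is.na(num) &
        (num < rule$params$lo | num > rule$params$hi)
      emit(rule$table, which(bad), rule$column, "range",
           sprintf("value outside [%s, %s]", rule$params$lo, rule$params$hi))
    } else if (rule$kind == "format") {
      bad <- !blank & !valid_yyyymmdd(x)
      emit(rule$table, which(bad), rule$column, "format",
           "date not in YYYYMMDD format")
    } else if (rule$kind == "cross_field") {
      p <- rule$params
      if (identical(p$relation, "date_not_before")) {
        other <- tables[[p$other_table]]
        oy <- other[[p$other_column]][
          match(tables[[rule$table]][[p$join]], other[[p$join]])]
        ok_pair <- valid_yyyymmdd(x) & !is.na(oy) & valid_yyyymmdd(oy)
        bad <- ok_pair &
          as.Date(x, "%Y%m%d") < as.Date(oy, "%Y%m%d")
        bad[is.na(bad)] <- FALSE
        emit(rule$table, which(bad), rule$column, "cross_field",
             paste0(rule$column, " earlier than ", p$other_table, ".",
                    p$other_column))
      } else if (identical(p$relation, "requires")) {
        oy <- tables[[rule$table]][[p$other_column]]
        bad <- !blank & is_blank(oy)
        emit(rule$table, which(bad), rule$column, "cross_field",
             paste0(rule$column, " present but supporting element ",
                    p$other_column, " missing"))
      } else stop("unknown cross_field relation", call. = FALSE)
    }
  }
  viol <- if (length(out)) do.call(rbind, out) else
    data.frame(table = character(0), row = integer(0),
               column = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  viol <- unique(viol[order(viol$table, viol$row, viol$column, viol$check),
                      , drop = FALSE])
  rownames(viol) <- NULL
  counts <- table(factor(viol$check, levels = c("type", "cross_field",
                                                "mandatory", "range",
                                                "format")))
  structure(list(violations = viol,
                 summary = data.frame(check = names(counts),
                                      count = as.integer(counts),
                                      stringsAsFactors = FALSE)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$violations), " violations\n", sep = "")
  if (nrow(x$violations)) print(x$summary)
  invisible(x)
}

#' Apply the drop-on-failure policy
#'
#' Every violating cell is blanked while its row is retained, except
#' `mandatory` failures: a row without its key cannot anchor triples, so
#' those rows are flagged for exclusion from downstream mapping (their key
#' cell is already empty, which the mapping compiler skips on its own).
#' Cleaned tables re-validate with zero violations for all cell-local
#' checks.
#'
#' @param tables the `cohort_tables` the report was computed from.
#' @param report a `validation_report`.
#' @return cleaned `cohort_tables`, with flagged mandatory rows in
#'   `attr(, "excluded_rows")`.
#' @export
clean <- function(tables, report) {
  stopifnot(inherits(report, "validation_report"))
  v <- report$violations
  out <- tables
  cellwise <- v[v$check != "mandatory", , drop = FALSE]
  for (i in seq_len(nrow(cellwise)))
    out[[cellwise$table[i]]][[cellwise$column[i]]][cellwise$row[i]] <- ""
  attr(out, "excluded_rows") <-
    v[v$check == "mandatory", c("table", "row"), drop = FALSE]
  out
}

#' Mapping-completeness percentage
#'
#' `100 * mapped / source`, reported to two decimals.
#' @param n_source_elements number of source data elements (> 0).
#' @param n_mapped_elements number successfully mapped
#'   (`0 <= mapped <= source`).
#' @return numeric percentage rounded to 2 decimals.
#' @export
mapping_completeness <- function(n_source_elements, n_mapped_elements) {
  if (n_source_elements <= 0)
    stop("undefined metric: no source elements", call. = FALSE)
  if (n_mapped_elements < 0 || n_mapped_elements > n_source_elements)
    stop("mapped element count outside [0, source]", call. = FALSE)
  round(100 * n_mapped_elements / n_source_elements, 2)
}

#' Read / write validation rules as JSON
#'
#' @param rules list of `validation_rule`s.
#' @param path JSON file path.
#' @return `write_rules` returns `path` invisibly; `read_rules` returns a
#'   list of `validation_rule`s.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(lapply(rules, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    p <- r$params %||% list()
    for (k in c("lo", "hi")) if (!is.null(p[[k]])) p[[k]] <- as.numeric(p[[k]])
    validation_rule(r$kind, r$table, r$column, p)
  })
}
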