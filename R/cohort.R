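#' Synthetic radiotherapy cohort tables
#'
#' Generates relational-style patient tables (demographics, diagnosis,
#' staging, treatment_course, toxicity, labs, dose_grid) with
#' group-conditional attribute distributions over five diagnosis groups
#' (prostate, NSCLC, SCLC, breast, head & neck). Each patient carries
#' 18-25 categorical attributes in total; clean output satisfies every
#' default validation rule by construction (dates in YYYYMMDD, diagnosis
#' date on or before RT start, coded values inside their ranges). All
#' columns are character, mirroring CSV ingestion from a clinical export.
#'
#' @param n_patients positive number of patients.
#' @param group_weights five non-negative sampling weights for the
#'   diagnosis groups (in the order `names(diagnosis_groups())`); not all
#'   zero.
#' @param seed integer RNG seed; output is reproducible given the seed.
#' @param dose_grid_shape dimensions of the per-patient synthetic dose
#'   grid used to derive the dose_grid summary table.
#' @return named list of data.frames of class `cohort_tables`, with
#'   metadata (seed, shape) in `attr(, "meta")`.
#' @export
generate_cohort <- function(n_patients, group_weights = rep(1, 5), seed = 1L,
                            dose_grid_shape = c(8L, 8L, 8L)) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  n <- as.integer(n_patients)
  stopifnot(length(group_weights) == 5L, all(group_weights >= 0))
  if (sum(group_weights) == 0)
    stop("group_weights must not all be zero", call. = FALSE)
  set.seed(as.integer(seed))
  gnames <- names(.rolhs_groups)
  group <- sample(gnames, n, replace = TRUE, prob = group_weights)
  pid <- sprintf("P%04d", seq_len(n))

  samp1 <- function(dist) sample(names(dist), 1L, prob = dist)
  by_group <- function(field) vapply(group, function(g)
    samp1(.rolhs_groups[[g]][[field]]), character(1), USE.NAMES = FALSE)
  shared <- function(field) sample(names(.rolhs_shared[[field]]), n,
                                   replace = TRUE,
                                   prob = .rolhs_shared[[field]])

  demographics <- data.frame(
    patient_id = pid,
    age = as.character(pmin(94L, pmax(32L, round(stats::rnorm(n, 66, 10))))),
    sex = by_group("sex"),
    race = shared("race"),
    ethnicity = shared("ethnicity"),
    marital_status = as.character(sample(1:6, n, replace = TRUE)),
    smoking_status = shared("smoking_status"),
    performance_status = shared("performance_status"),
    stringsAsFactors = FALSE)

  dx_date <- as.Date("2018-01-01") + sample(0:1825, n, replace = TRUE)
  diagnosis <- data.frame(
    patient_id = pid,
    diagnosis_group = group,
    diagnosis_code = vapply(group, function(g)
      .rolhs_groups[[g]]$diagnosis_code, character(1), USE.NAMES = FALSE),
    histology = by_group("histology"),
    laterality = by_group("laterality"),
    date_of_diagnosis = format(dx_date, "%Y%m%d"),
    stringsAsFactors = FALSE)

  t_stage <- by_group("t_stage")
  n_stage <- by_group("n_stage")
  m_stage <- by_group("m_stage")
  stage_group <- ifelse(m_stage == "M1", "stage_iv",
                 ifelse(n_stage %in% c("N2", "N3") |
                        t_stage %in% c("T3", "T4"), "stage_iii",
                 ifelse(n_stage == "N1" | grepl("^T2", t_stage), "stage_ii",
                        "stage_i")))
  is_prost <- group == "prostate"
  psa_value <- ifelse(is_prost,
                      round(exp(stats::rnorm(n, log(9), 0.8)), 1), NA)
  psa_category <- ifelse(!is_prost, "",
                  ifelse(psa_value < 10, "psa_low",
                  ifelse(psa_value <= 20, "psa_intermediate", "psa_high")))
  staging <- data.frame(
    patient_id = pid, t_stage = t_stage, n_stage = n_stage,
    m_stage = m_stage, stage_group = stage_group,
    gleason_grade_group = ifelse(is_prost,
      sample(paste0("gg", 1:5), n, replace = TRUE,
             prob = c(0.2, 0.3, 0.25, 0.15, 0.1)), ""),
    psa_category = psa_category,
    psa_value = ifelse(is_prost, as.character(psa_value), ""),
    stringsAsFactors = FALSE)

  fractionation <- by_group("fractionation")
  fx <- integer(n); dpf <- integer(n)
  for (i in seq_len(n)) {
    if (fractionation[i] == "conventional") {
      fx[i] <- sample(28:40, 1L); dpf[i] <- sample(c(180L, 200L), 1L)
    } else if (fractionation[i] == "hypofractionated") {
      fx[i] <- sample(15:20, 1L); dpf[i] <- sample(seq(250L, 300L, 10L), 1L)
    } else {
      fx[i] <- 5L; dpf[i] <- sample(c(700L, 725L, 750L, 800L), 1L)
    }
  }
  rt_start <- dx_date + sample(14:90, n, replace = TRUE)
  treatment_course <- data.frame(
    patient_id = pid,
    rt_course_id = paste0(pid, "-C1"),
    modality = by_group("modality"),
    technique = by_group("technique"),
    intent = shared("intent"),
    fractionation = fractionation,
    rt_start_date = format(rt_start, "%Y%m%d"),
    prescription_dose_cgy = as.character(fx * dpf),
    fraction_count = as.character(fx),
    stringsAsFactors = FALSE)

  n_tox <- sample(2:4, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  tox_rows <- lapply(seq_len(n), function(i) {
    pool <- .rolhs_groups[[group[i]]]$toxicity
    k <- min(n_tox[i], length(pool))
    types <- sample(names(pool), k, prob = pool)
    grades <- sample(1:3, k, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    data.frame(patient_id = pid[i], rt_course_id = paste0(pid[i], "-C1"),
               toxicity_seq = as.character(seq_len(k)),
               toxicity_type = types, grade = as.character(grades),
               ctcae_term = paste0(types, "_g", grades),
               stringsAsFactors = FALSE)
  })
  toxicity <- do.call(rbind, tox_rows)

  creat <- pmax(0.4, round(stats::rnorm(n, 1.05, 0.25), 2))
  hgb <- pmax(7, round(stats::rnorm(n, 13.5, 1.6), 1))
  lab_date <- format(dx_date + sample(0:13, n, replace = TRUE), "%Y%m%d")
  labs <- rbind(
    data.frame(patient_id = pid, lab_test = "creatinine",
               lab_value = as.character(creat),
               lab_flag = ifelse(creat > 1.3, "high", "normal"),
               lab_term = ifelse(creat > 1.3, "creatinine_high",
                                 "creatinine_normal"),
               lab_date = lab_date, stringsAsFactors = FALSE),
    data.frame(patient_id = pid, lab_test = "hemoglobin",
               lab_value = as.character(hgb),
               lab_flag = ifelse(hgb < 12, "low", "normal"),
               lab_term = ifelse(hgb < 12, "hemoglobin_low",
                                 "hemoglobin_normal"),
               lab_date = lab_date, stringsAsFactors = FALSE))
  labs <- labs[order(labs$patient_id, labs$lab_test), , drop = FALSE]
  rownames(labs) <- NULL

  rx <- fx * dpf
  dg_rows <- lapply(seq_len(n), function(i) {
    g <- generate_dose_grid(dose_grid_shape, prescription_cgy = rx[i],
                            seed = dose_grid_seed(seed, i))
    do.call(rbind, lapply(names(g$masks), function(s) {
      cv <- compute_dvh(g, s, bin_width_cgy = 50)
      m <- dvh_metrics(cv, c("mean", "max", "D95"))
      vrx <- 100 * mean(cv$doses >= rx[i])
      data.frame(patient_id = pid[i], rt_course_id = paste0(pid[i], "-C1"),
                 structure = s,
                 mean_dose_cgy = as.character(round(m[["mean"]], 1)),
                 max_dose_cgy = as.character(round(m[["max"]], 1)),
                 d95_cgy = as.character(round(m[["D95"]], 1)),
                 v_rx_pct = as.character(round(vrx, 1)),
                 stringsAsFactors = FALSE)
    }))
  })
  dose_grid_tbl <- do.call(rbind, dg_rows)
  rownames(dose_grid_tbl) <- NULL

  tables <- list(demographics = demographics, diagnosis = diagnosis,
                 staging = staging, treatment_course = treatment_course,
                 toxicity = toxicity, labs = labs,
                 dose_grid = dose_grid_tbl)
  attr(tables, "meta") <- list(seed = as.integer(seed),
                               dose_grid_shape = dose_grid_shape)
  class(tables) <- c("cohort_tables", "list")
  tables
}

dose_grid_seed <- function(seed, i) {
  (as.integer(seed) * 7919L + i * 13L) %% 214748329L
}

#' Regenerate a patient's full 3-D dose grid
#'
#' The dose_grid summary table is derived from per-patient synthetic
#' grids; this reproduces the grid for one patient exactly.
#' @param tables a `cohort_tables` object.
#' @param patient_id patient identifier, e.g. `"P0001"`.
#' @return a `dose_grid`.
#' @export
cohort_dose_grid <- function(tables, patient_id) {
  meta <- attr(tables, "meta")
  i <- match(patient_id, tables$demographics$patient_id)
  if (is.na(i)) stop("unknown patient: ", patient_id, call. = FALSE)
  row <- tables$treatment_course[
    tables$treatment_course$patient_id == patient_id, , drop = FALSE]
  rx <- as.numeric(row$prescription_dose_cgy[1])
  generate_dose_grid(meta$dose_grid_shape, prescription_cgy = rx,
                     seed = dose_grid_seed(meta$seed, i))
}

#' Per-patient categorical attribute counts
#'
#' Counts the categorical attributes each patient carries across tables
#' (demographics 6, diagnosis 3, staging 4 + 2 prostate-specific,
#' treatment 4, one per toxicity row, labs 2).
#' @param tables a `cohort_tables` object.
#' @return named integer vector, one count per patient.
#' @export
attribute_counts <- function(tables) {
  pid <- tables$demographics$patient_id
  base <- 6L + 3L + 4L + 4L + 2L
  extra <- ifelse(nzchar(tables$staging$gleason_grade_group) &
                    nzchar(tables$staging$psa_category), 2L, 0L)[
                      match(pid, tables$staging$patient_id)]
  ntox <- vapply(pid, function(p)
    sum(tables$toxicity$patient_id == p), integer(1))
  stats::setNames(base + extra + ntox, pid)
}

#' Diagnosis group names used by the generator
#' @return character vector of the five group names.
#' @export
diagnosis_groups <- function() names(.rolhs_groups)

#' Inject controlled data-quality errors
#'
#' Corrupts a clean cohort with violations of the five cleaning checks,
#' returning the corrupted copy and a ground-truth ledger of every
#' corrupted cell. Each injected fault violates exactly one check:
#' `type` writes a non-integer string into an integer column,
#' `cross_field` moves the RT start date before the diagnosis date
#' (keeping a valid YYYYMMDD), `mandatory` blanks a key column, `range`
#' writes an out-of-range code, and `format` rewrites a date with dashes.
#' Rows whose diagnosis date is format-corrupted are excluded from
#' cross-field corruption so checks never mask one another.
#'
#' @param tables a clean `cohort_tables`.
#' @param rate_per_check named fractions in `[0, 1]` for checks among
#'   `type`, `cross_field`, `mandatory`, `range`, `format`.
#' @param seed integer RNG seed.
#' @param mandatory_target `c(table, column)` for the mandatory-blanking
#'   fault (default `treatment_course.rt_course_id`).
#' @return list with `tables` (corrupted copy) and `ledger` (data.frame
#'   `table`, `row`, `column`, `check`).
#' @export
inject_errors <- function(tables, rate_per_check, seed = 1L,
                          mandatory_target = c("treatment_course",
                                               "rt_course_id")) {
  checks <- c("type", "cross_field", "mandatory", "range", "format")
  if (is.null(names(rate_per_check)) ||
      !all(names(rate_per_check) %in% checks))
    stop("unknown check name in rate_per_check; expected: ",
         paste(checks, collapse = ", "), call. = FALSE)
  stopifnot(all(rate_per_check >= 0), all(rate_per_check <= 1))
  rate <- function(ch) if (ch %in% names(rate_per_check))
    rate_per_check[[ch]] else 0
  set.seed(as.integer(seed))
  out <- tables
  ledger <- list()
  note <- function(tb, rows, col, ch) {
    if (length(rows))
      ledger[[length(ledger) + 1L]] <<- data.frame(
        table = tb, row = as.integer(rows), column = col, check = ch,
        stringsAsFactors = FALSE)
  }
  pick <- function(nr, r) which(stats::runif(nr) < r)

  # format: diagnosis date rewritten as dashed ISO
  fr <- pick(nrow(out$diagnosis), rate("format"))
  if (length(fr)) {
    d <- out$diagnosis$date_of_diagnosis[fr]
    out$diagnosis$date_of_diagnosis[fr] <-
      paste(substr(d, 1, 4), substr(d, 5, 6), substr(d, 7, 8), sep = "-")
    note("diagnosis", fr, "date_of_diagnosis", "format")
  }
  bad_dx_patients <- out$diagnosis$patient_id[fr]

  # cross_field: RT start moved 30 days before diagnosis
  eligible <- which(!(out$treatment_course$patient_id %in% bad_dx_patients))
  cr <- eligible[stats::runif(length(eligible)) < rate("cross_field")]
  if (length(cr)) {
    dx <- out$diagnosis$date_of_diagnosis[
      match(out$treatment_course$patient_id[cr], out$diagnosis$patient_id)]
    out$treatment_course$rt_start_date[cr] <-
      format(as.Date(dx, "%Y%m%d") - 30, "%Y%m%d")
    note("treatment_course", cr, "rt_start_date", "cross_field")
  }

  # type: non-integer performance status
  tr <- pick(nrow(out$demographics), rate("type"))
  if (length(tr)) {
    out$demographics$performance_status[tr] <- "good"
    note("demographics", tr, "performance_status", "type")
  }

  # range: marital status outside 1..9
  rr <- pick(nrow(out$demographics), rate("range"))
  if (length(rr)) {
    out$demographics$marital_status[rr] <- "12"
    note("demographics", rr, "marital_status", "range")
  }

  # mandatory: blank a key column
  tb <- mandatory_target[1]; col <- mandatory_target[2]
  if (!tb %in% names(out) || !col %in% names(out[[tb]]))
    stop("mandatory_target does not name an existing column", call. = FALSE)
  mr <- pick(nrow(out[[tb]]), rate("mandatory"))
  if (length(mr)) {
    out[[tb]][[col]][mr] <- ""
    note(tb, mr, col, "mandatory")
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(table = character(0), row = integer(0),
               column = character(0), check = character(0),
               stringsAsFactors = FALSE)
  ord <- order(ledger$table, ledger$row, ledger$column)
  ledger <- ledger[ord, , drop = FALSE]
  rownames(ledger) <- NULL
  list(tables = out, ledger = ledger)
}

#' Diff two cohorts cell-by-cell
#'
#' Independent oracle for the injection ledger: lists every cell whose
#' value differs between two table sets with identical shapes.
#' @param a,b `cohort_tables` with identical dimensions.
#' @return data.frame `table`, `row`, `column`.
#' @export
diff_cells <- function(a, b) {
  out <- list()
  for (tb in names(a)) {
    ta <- a[[tb]]; tbb <- b[[tb]]
    stopifnot(identical(dim(ta), dim(tbb)))
    for (col in names(ta)) {
      rows <- which(ta[[col]] != tbb[[col]])
      if (length(rows))
        out[[length(out) + 1L]] <- data.frame(
          table = tb, row = rows, column = col, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(table = character(0), row = integer(0),
                      column = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$table, res$row, res$column), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write cohort tables as CSV files (one per table)
#'
#' @param tables a `cohort_tables`.
#' @param dir destination directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort_csv <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(tb) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(tables[[tb]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read cohort tables from a directory of CSV files
#'
#' All columns are read as character, mirroring the generator's output.
#' @param dir directory containing `<table>.csv` files.
#' @return a `cohort_tables` object.
#' @export
read_cohort_csv <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no CSV tables found in ", dir, call. = FALSE)
  tables <- lapply(files, function(f)
    utils::read.csv(f, colClasses = "character"))
  names(tables) <- sub("\\.csv$", "", basename(files))
  class(tables) <- c("cohort_tables", "list")
  tables
}

#' Export the cohort as a single JSON document
#'
#' @param tables a `cohort_tables`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cohort_json <- function(tables, path) {
  jsonlite::write_json(lapply(tables, identity), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables> ", nrow(x$demographics), " patients; tables: ",
      paste(sprintf("%s[%d]", names(x),
                    vapply(x, nrow, integer(1))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
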