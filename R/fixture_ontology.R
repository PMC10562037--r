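# Synthetic ROO/NCIT-style fixture ontology, generated from the shared
# vocabulary so the generator, the mapping spec and the ontology can never
# drift apart. The file shipped in inst/extdata/ is a rendered copy of
# fixture_ontology_def() (a test asserts they agree).

cls_def <- function(code, label, synonyms = character(0),
                    parents = character(0), definition = NULL) {
  list(code = code, label = label, synonyms = as.list(synonyms),
       definition = definition, parents = as.list(parents))
}

#' Definition of the bundled synthetic fixture ontology
#'
#' Builds the class list for the synthetic radiation-oncology fixture
#' ontology: five diagnosis groups, TNM staging (including the T1 ->
#' T1a/T1b/T1c sub-stages), histology, smoking status, ECOG performance
#' status, treatment modality/technique/intent/fractionation, CTCAE-style
#' graded toxicities, lab findings, and supporting structural classes.
#' Codes under the `ROO:` prefix are synthetic; NCIT-style codes are used
#' for well-known concepts.
#'
#' @return list with `prefixes` and `classes` suitable for serialization
#'   to the ontology JSON dialect.
#' @export
fixture_ontology_def <- function() {
  L <- .rolhs_lookups
  k <- list()
  add <- function(...) k[[length(k) + 1L]] <<- cls_def(...)

  add("ROO:ROOT0", "Clinical Concept", "root concept")
  root <- "ROO:ROOT0"
  add("NCIT:C7057", "Disease", c("disorder", "condition"), root)
  add("NCIT:C3262", "Neoplasm", c("cancer", "tumor"), "NCIT:C7057")
  add("NCIT:C41331", "Adverse Event", "toxicity", root)
  add("NCIT:C48881", "Cancer Staging", "TNM staging", root)
  add("NCIT:C16960", "Patient", character(0), root)
  add("NCIT:C27996", "Myocardial Infarction",
      c("heart attack", "acute coronary syndrome"), "NCIT:C7057")
  add("ROO:UNIT0", "Unit of Measure", character(0), root)
  add("NCIT:C64557", "Centigray", "cGy", "ROO:UNIT0",
      "Unit of absorbed radiation dose equal to one hundredth of a gray.")
  add("ROO:DVH00", "Dose Volume Histogram", "DVH", root)
  add("ROO:RTC00", "Radiation Treatment Course", "RT course", root)

  add("NCIT:C28421", "Sex", character(0), root)
  add(L$sex[["male"]], "Male", character(0), "NCIT:C28421")
  add(L$sex[["female"]], "Female", character(0), "NCIT:C28421")

  add("NCIT:C17049", "Race", character(0), root)
  race_lab <- c(white = "White", black = "Black or African American",
                asian = "Asian", other = "Other Race")
  for (v in names(L$race)) add(L$race[[v]], race_lab[[v]], v, "NCIT:C17049")

  add("NCIT:C16564", "Ethnicity", character(0), root)
  add(L$ethnicity[["hispanic"]], "Hispanic or Latino", "hispanic",
      "NCIT:C16564")
  add(L$ethnicity[["non_hispanic"]], "Not Hispanic or Latino",
      "non-hispanic", "NCIT:C16564")

  add("NCIT:C17934", "Smoking Status", "tobacco use", root)
  smoke_lab <- c(current = "Current Smoker", former = "Former Smoker",
                 never = "Never Smoker")
  smoke_syn <- list(current = "active smoker", former = "ex-smoker",
                    never = "non-smoker")
  for (v in names(L$smoking_status))
    add(L$smoking_status[[v]], smoke_lab[[v]], smoke_syn[[v]], "NCIT:C17934")

  add("NCIT:C105721", "ECOG Performance Status",
      c("performance status", "ECOG scale"), root)
  for (v in names(L$performance_status))
    add(L$performance_status[[v]], paste("ECOG Performance Status", v),
        paste("ECOG", v), "NCIT:C105721")

  dx_lab <- c(prostate_carcinoma = "Prostate Carcinoma",
              nsclc = "Lung Non-Small Cell Carcinoma",
              sclc = "Lung Small Cell Carcinoma",
              breast_carcinoma = "Breast Carcinoma",
              hn_carcinoma = "Head and Neck Carcinoma")
  dx_syn <- list(prostate_carcinoma = c("prostate cancer",
                                        "carcinoma of the prostate"),
                 nsclc = c("NSCLC", "non-small cell lung cancer"),
                 sclc = c("SCLC", "small cell lung cancer"),
                 breast_carcinoma = "breast cancer",
                 hn_carcinoma = "head and neck cancer")
  for (v in names(L$diagnosis_code))
    add(L$diagnosis_code[[v]], dx_lab[[v]], dx_syn[[v]], "NCIT:C3262")

  add("ROO:H0000", "Histologic Type", "histology", root)
  hist_lab <- c(adenocarcinoma = "Adenocarcinoma",
                squamous_cell = "Squamous Cell Carcinoma",
                small_cell = "Small Cell Carcinoma",
                large_cell = "Large Cell Carcinoma",
                ductal = "Invasive Ductal Carcinoma",
                lobular = "Invasive Lobular Carcinoma")
  hist_syn <- list(adenocarcinoma = character(0),
                   squamous_cell = "epidermoid carcinoma",
                   small_cell = "oat cell carcinoma",
                   large_cell = character(0),
                   ductal = "ductal carcinoma",
                   lobular = "lobular carcinoma")
  for (v in names(L$histology))
    add(L$histology[[v]], hist_lab[[v]], hist_syn[[v]], "ROO:H0000")

  add("NCIT:C25185", "Laterality", character(0), root)
  lat_lab <- c(left = "Left", right = "Right", bilateral = "Bilateral",
               not_applicable = "Not Applicable")
  for (v in names(L$laterality))
    add(L$laterality[[v]], lat_lab[[v]], character(0), "NCIT:C25185")

  add("NCIT:C48879", "T Stage", "primary tumor stage", "NCIT:C48881")
  t_parent <- c(T1 = "NCIT:C48879", T2 = "NCIT:C48879", T3 = "NCIT:C48879",
                T4 = "NCIT:C48879", T1a = L$t_stage[["T1"]],
                T1b = L$t_stage[["T1"]], T1c = L$t_stage[["T1"]],
                T2a = L$t_stage[["T2"]], T2b = L$t_stage[["T2"]])
  for (v in names(L$t_stage))
    add(L$t_stage[[v]], paste(v, "Stage"), v, t_parent[[v]],
        paste("Primary tumor stage", v, "finding."))
  add("NCIT:C48884", "N Stage", "regional lymph node stage", "NCIT:C48881")
  for (v in names(L$n_stage))
    add(L$n_stage[[v]], paste(v, "Stage"), v, "NCIT:C48884")
  add("NCIT:C48883", "M Stage", "distant metastasis stage", "NCIT:C48881")
  for (v in names(L$m_stage))
    add(L$m_stage[[v]], paste(v, "Stage"), v, "NCIT:C48883")
  add("NCIT:C28108", "Stage Group", "overall stage group", "NCIT:C48881")
  sg_lab <- c(stage_i = "Stage I", stage_ii = "Stage II",
              stage_iii = "Stage III", stage_iv = "Stage IV")
  for (v in names(L$stage_group))
    add(L$stage_group[[v]], sg_lab[[v]], character(0), "NCIT:C28108")

  add("ROO:GLS00", "Gleason Grade Group", "gleason score group", root)
  for (i in 1:5)
    add(L$gleason_grade_group[[paste0("gg", i)]],
        paste("Gleason Grade Group", i), paste("gleason group", i),
        "ROO:GLS00")
  add("ROO:PSA00", "PSA Level Category",
      "prostate specific antigen category", root)
  psa_lab <- c(psa_low = "Low PSA Level",
               psa_intermediate = "Intermediate PSA Level",
               psa_high = "High PSA Level")
  for (v in names(L$psa_category))
    add(L$psa_category[[v]], psa_lab[[v]], character(0), "ROO:PSA00")

  add("ROO:MOD00", "Radiation Treatment Modality", "treatment modality", root)
  mod_lab <- c(photon = "Photon Beam Radiation Therapy",
               electron = "Electron Beam Radiation Therapy",
               proton = "Proton Beam Radiation Therapy",
               brachytherapy = "Brachytherapy")
  mod_syn <- list(photon = "photon therapy", electron = "electron therapy",
                  proton = "proton therapy",
                  brachytherapy = "internal radiation therapy")
  for (v in names(L$modality))
    add(L$modality[[v]], mod_lab[[v]], mod_syn[[v]], "ROO:MOD00")

  add("ROO:TEC00", "Radiation Treatment Technique", "treatment technique",
      root)
  tec_lab <- c(imrt = "Intensity-Modulated Radiation Therapy",
               vmat = "Volumetric Modulated Arc Therapy",
               threed_crt = "Three-Dimensional Conformal Radiation Therapy",
               sbrt = "Stereotactic Body Radiation Therapy")
  tec_syn <- list(imrt = "IMRT", vmat = "VMAT",
                  threed_crt = c("3D-CRT", "3D conformal"),
                  sbrt = c("SBRT", "stereotactic body radiotherapy"))
  for (v in names(L$technique))
    add(L$technique[[v]], tec_lab[[v]], tec_syn[[v]], "ROO:TEC00")

  add("ROO:INT00", "Treatment Intent", character(0), root)
  int_lab <- c(curative = "Curative Treatment Intent",
               palliative = "Palliative Treatment Intent",
               adjuvant = "Adjuvant Treatment Intent")
  int_syn <- list(curative = "curative intent",
                  palliative = "palliative intent",
                  adjuvant = "adjuvant intent")
  for (v in names(L$intent))
    add(L$intent[[v]], int_lab[[v]], int_syn[[v]], "ROO:INT00")

  add("ROO:FRX00", "Dose Fractionation Scheme", "fractionation", root)
  frx_lab <- c(conventional = "Conventional Fractionation",
               hypofractionated = "Hypofractionated Radiation Therapy",
               ultrahypofractionated = "Ultrahypofractionated Radiation Therapy")
  frx_syn <- list(conventional = "standard fractionation",
                  hypofractionated = "hypofractionation",
                  ultrahypofractionated = "ultrahypofractionation")
  for (v in names(L$fractionation))
    add(L$fractionation[[v]], frx_lab[[v]], frx_syn[[v]], "ROO:FRX00")

  add("ROO:CTC00", "CTCAE Toxicity", "graded adverse event", "NCIT:C41331")
  tox_lab <- c(fatigue = "Fatigue", dermatitis = "Radiation Dermatitis",
               esophagitis = "Esophagitis", cystitis = "Cystitis",
               xerostomia = "Xerostomia", pneumonitis = "Pneumonitis",
               nausea = "Nausea")
  tox_syn <- list(fatigue = c("tiredness", "lack of energy", "asthenia"),
                  dermatitis = "radiation skin reaction",
                  esophagitis = "esophageal inflammation",
                  cystitis = "bladder inflammation",
                  xerostomia = "dry mouth",
                  pneumonitis = "lung inflammation",
                  nausea = character(0))
  for (t in names(.rolhs_tox_parents)) {
    add(.rolhs_tox_parents[[t]], tox_lab[[t]], tox_syn[[t]], "ROO:CTC00")
    for (g in 1:3)
      add(L$ctcae_term[[paste0(t, "_g", g)]],
          paste0("Grade ", g, " ", tox_lab[[t]]),
          paste0(t, " grade ", g), .rolhs_tox_parents[[t]])
  }

  add("NCIT:C36292", "Laboratory Test Result", "lab result", root)
  lab_lab <- c(creatinine_normal = "Normal Creatinine",
               creatinine_high = "Elevated Creatinine",
               hemoglobin_normal = "Normal Hemoglobin",
               hemoglobin_low = "Low Hemoglobin")
  lab_syn <- list(creatinine_normal = character(0),
                  creatinine_high = "high creatinine",
                  hemoglobin_normal = character(0),
                  hemoglobin_low = "anemia")
  for (v in names(L$lab_term))
    add(L$lab_term[[v]], lab_lab[[v]], lab_syn[[v]], "NCIT:C36292")

  list(prefixes = as.list(.rolhs_prefixes), classes = k)
}

#' Write the synthetic fixture ontology to a JSON file
#'
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fixture_ontology <- function(path) {
  def <- fixture_ontology_def()
  jsonlite::write_json(def, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Load the bundled synthetic fixture ontology
#'
#' Convenience wrapper: loads the copy shipped under `inst/extdata/`.
#' @return an `ontology` object.
#' @export
fixture_ontology <- function() {
  load_ontology(system.file("extdata", "synthetic_ontology.json",
                            package = "rolhs", mustWork = TRUE))
}
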