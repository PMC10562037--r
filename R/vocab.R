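# Controlled vocabularies shared by the synthetic fixture ontology, the
# cohort generator and the default mapping spec. Codes in the ROO: namespace
# are synthetic stand-ins; NCIT-style codes are used for well-known concepts
# (e.g. NCIT:C48720 = T1 stage) but the fixture makes no claim of fidelity
# to the full published terminologies.

.rolhs_prefixes <- c(
  NCIT = "http://purl.obolibrary.org/obo/NCIT_",
  ROO  = "http://www.cancerdata.org/roo/ROO_",
  roo  = "http://www.cancerdata.org/roo/",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

# value -> CURIE lookups, one per coded cohort column
.rolhs_lookups <- list(
  sex = c(male = "NCIT:C20197", female = "NCIT:C16576"),
  race = c(white = "NCIT:C41261", black = "NCIT:C16352",
           asian = "NCIT:C41260", other = "ROO:RAC04"),
  ethnicity = c(hispanic = "NCIT:C17459", non_hispanic = "NCIT:C41222"),
  smoking_status = c(current = "NCIT:C67147", former = "NCIT:C67148",
                     never = "NCIT:C65108"),
  performance_status = c(`0` = "NCIT:C105722", `1` = "NCIT:C105723",
                         `2` = "NCIT:C105724", `3` = "NCIT:C105725",
                         `4` = "NCIT:C105726"),
  diagnosis_code = c(prostate_carcinoma = "NCIT:C4863",
                     nsclc = "NCIT:C2926",
                     sclc = "NCIT:C4917",
                     breast_carcinoma = "NCIT:C4872",
                     hn_carcinoma = "NCIT:C4013"),
  histology = c(adenocarcinoma = "NCIT:C2852",
                squamous_cell = "NCIT:C2929",
                small_cell = "NCIT:C2923",
                large_cell = "NCIT:C2920",
                ductal = "NCIT:C4017",
                lobular = "NCIT:C7950"),
  laterality = c(left = "NCIT:C25229", right = "NCIT:C25228",
                 bilateral = "NCIT:C13717", not_applicable = "ROO:LAT04"),
  t_stage = c(T1 = "NCIT:C48720", T1a = "NCIT:C48721", T1b = "NCIT:C48722",
              T1c = "NCIT:C48723", T2 = "NCIT:C48724", T2a = "NCIT:C48725",
              T2b = "NCIT:C48726", T3 = "NCIT:C48728", T4 = "NCIT:C48732"),
  n_stage = c(N0 = "NCIT:C48705", N1 = "NCIT:C48706",
              N2 = "NCIT:C48786", N3 = "NCIT:C48714"),
  m_stage = c(M0 = "NCIT:C48699", M1 = "NCIT:C48700"),
  stage_group = c(stage_i = "NCIT:C27966", stage_ii = "NCIT:C28054",
                  stage_iii = "NCIT:C27970", stage_iv = "NCIT:C27971"),
  gleason_grade_group = c(gg1 = "ROO:GLS01", gg2 = "ROO:GLS02",
                          gg3 = "ROO:GLS03", gg4 = "ROO:GLS04",
                          gg5 = "ROO:GLS05"),
  psa_category = c(psa_low = "ROO:PSA01", psa_intermediate = "ROO:PSA02",
                   psa_high = "ROO:PSA03"),
  modality = c(photon = "NCIT:C66897", electron = "ROO:MOD02",
               proton = "NCIT:C66898", brachytherapy = "NCIT:C15195"),
  technique = c(imrt = "NCIT:C16135", vmat = "ROO:TEC02",
                threed_crt = "ROO:TEC03", sbrt = "NCIT:C118286"),
  intent = c(curative = "NCIT:C62220", palliative = "NCIT:C15292",
             adjuvant = "ROO:INT03"),
  fractionation = c(conventional = "ROO:FRX01",
                    hypofractionated = "ROO:FRX02",
                    ultrahypofractionated = "ROO:FRX03"),
  ctcae_term = c(
    fatigue_g1 = "ROO:CTCF01", fatigue_g2 = "ROO:CTCF02", fatigue_g3 = "ROO:CTCF03",
    dermatitis_g1 = "ROO:CTCD01", dermatitis_g2 = "ROO:CTCD02", dermatitis_g3 = "ROO:CTCD03",
    esophagitis_g1 = "ROO:CTCE01", esophagitis_g2 = "ROO:CTCE02", esophagitis_g3 = "ROO:CTCE03",
    cystitis_g1 = "ROO:CTCC01", cystitis_g2 = "ROO:CTCC02", cystitis_g3 = "ROO:CTCC03",
    xerostomia_g1 = "ROO:CTCX01", xerostomia_g2 = "ROO:CTCX02", xerostomia_g3 = "ROO:CTCX03",
    pneumonitis_g1 = "ROO:CTCP01", pneumonitis_g2 = "ROO:CTCP02", pneumonitis_g3 = "ROO:CTCP03",
    nausea_g1 = "ROO:CTCN01", nausea_g2 = "ROO:CTCN02", nausea_g3 = "ROO:CTCN03"),
  lab_term = c(creatinine_normal = "ROO:LAB11", creatinine_high = "ROO:LAB12",
               hemoglobin_normal = "ROO:LAB21", hemoglobin_low = "ROO:LAB22")
)

.rolhs_tox_parents <- c(fatigue = "NCIT:C3036", dermatitis = "NCIT:C2983",
                        esophagitis = "NCIT:C9224", cystitis = "NCIT:C2998",
                        xerostomia = "NCIT:C26917", pneumonitis = "NCIT:C3333",
                        nausea = "NCIT:C3258")

# diagnosis groups and their conditional attribute distributions; weights
# are sampling probabilities within a group
.rolhs_groups <- list(
  prostate = list(
    diagnosis_code = "prostate_carcinoma",
    sex = c(male = 1),
    histology = c(adenocarcinoma = 0.92, small_cell = 0.08),
    laterality = c(not_applicable = 1),
    t_stage = c(T1c = 0.40, T2a = 0.25, T2b = 0.15, T3 = 0.15, T4 = 0.05),
    n_stage = c(N0 = 0.85, N1 = 0.15),
    m_stage = c(M0 = 0.92, M1 = 0.08),
    modality = c(photon = 0.6, brachytherapy = 0.3, proton = 0.1),
    technique = c(imrt = 0.45, vmat = 0.35, sbrt = 0.15, threed_crt = 0.05),
    fractionation = c(conventional = 0.5, hypofractionated = 0.35,
                      ultrahypofractionated = 0.15),
    toxicity = c(cystitis = 0.4, fatigue = 0.35, nausea = 0.25)),
  lung_nsclc = list(
    diagnosis_code = "nsclc",
    sex = c(male = 0.6, female = 0.4),
    histology = c(adenocarcinoma = 0.5, squamous_cell = 0.35, large_cell = 0.15),
    laterality = c(left = 0.45, right = 0.55),
    t_stage = c(T1a = 0.10, T1b = 0.15, T2a = 0.20, T2b = 0.15, T3 = 0.25, T4 = 0.15),
    n_stage = c(N0 = 0.35, N1 = 0.25, N2 = 0.30, N3 = 0.10),
    m_stage = c(M0 = 0.8, M1 = 0.2),
    modality = c(photon = 0.95, proton = 0.05),
    technique = c(imrt = 0.35, vmat = 0.30, sbrt = 0.25, threed_crt = 0.10),
    fractionation = c(conventional = 0.55, hypofractionated = 0.25,
                      ultrahypofractionated = 0.20),
    toxicity = c(esophagitis = 0.35, pneumonitis = 0.30, fatigue = 0.20,
                 nausea = 0.15)),
  lung_sclc = list(
    diagnosis_code = "sclc",
    sex = c(male = 0.55, female = 0.45),
    histology = c(small_cell = 1),
    laterality = c(left = 0.45, right = 0.55),
    t_stage = c(T1 = 0.10, T2 = 0.30, T3 = 0.30, T4 = 0.30),
    n_stage = c(N0 = 0.20, N1 = 0.25, N2 = 0.35, N3 = 0.20),
    m_stage = c(M0 = 0.6, M1 = 0.4),
    modality = c(photon = 1),
    technique = c(imrt = 0.40, vmat = 0.35, threed_crt = 0.25),
    fractionation = c(conventional = 0.7, hypofractionated = 0.3),
    toxicity = c(esophagitis = 0.40, pneumonitis = 0.25, fatigue = 0.20,
                 nausea = 0.15)),
  breast = list(
    diagnosis_code = "breast_carcinoma",
    sex = c(female = 0.99, male = 0.01),
    histology = c(ductal = 0.75, lobular = 0.25),
    laterality = c(left = 0.48, right = 0.48, bilateral = 0.04),
    t_stage = c(T1a = 0.10, T1b = 0.15, T1c = 0.25, T2 = 0.35, T3 = 0.15),
    n_stage = c(N0 = 0.55, N1 = 0.30, N2 = 0.10, N3 = 0.05),
    m_stage = c(M0 = 0.93, M1 = 0.07),
    modality = c(photon = 0.9, electron = 0.1),
    technique = c(threed_crt = 0.40, imrt = 0.30, vmat = 0.30),
    fractionation = c(hypofractionated = 0.6, conventional = 0.4),
    toxicity = c(dermatitis = 0.45, fatigue = 0.35, nausea = 0.20)),
  head_neck = list(
    diagnosis_code = "hn_carcinoma",
    sex = c(male = 0.7, female = 0.3),
    histology = c(squamous_cell = 0.9, adenocarcinoma = 0.1),
    laterality = c(not_applicable = 0.5, left = 0.25, right = 0.25),
    t_stage = c(T1 = 0.20, T2 = 0.30, T3 = 0.30, T4 = 0.20),
    n_stage = c(N0 = 0.30, N1 = 0.25, N2 = 0.35, N3 = 0.10),
    m_stage = c(M0 = 0.9, M1 = 0.1),
    modality = c(photon = 0.8, proton = 0.2),
    technique = c(imrt = 0.55, vmat = 0.40, threed_crt = 0.05),
    fractionation = c(conventional = 0.85, hypofractionated = 0.15),
    toxicity = c(xerostomia = 0.35, dermatitis = 0.25, fatigue = 0.25,
                 nausea = 0.15))
)

# distributions shared across groups (overlap keeps groups realistic)
.rolhs_shared <- list(
  race = c(white = 0.6, black = 0.25, asian = 0.1, other = 0.05),
  ethnicity = c(non_hispanic = 0.85, hispanic = 0.15),
  smoking_status = c(never = 0.35, former = 0.40, current = 0.25),
  performance_status = c(`0` = 0.35, `1` = 0.35, `2` = 0.20, `3` = 0.08,
                         `4` = 0.02),
  intent = c(curative = 0.75, palliative = 0.15, adjuvant = 0.10)
)
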