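# Synthetic EMR cohort generator with a planted latent subtype structure.
# Every downstream stage (phenotyping, featurization, clustering, profiling,
# survival, validation) is testable against the generator's hidden truth.

#' Subtype specification for the synthetic cohort
#'
#' Defines one latent patient subtype: its share of the cohort, the
#' Bernoulli prevalence of each clinical concept (diagnoses, medications,
#' abnormal labs, vitals, procedures), constant outcome hazards (events per
#' person-year) and the distribution of steatosis note mentions.
#'
#' @param label subtype identifier.
#' @param mixing_proportion fraction of the cohort in `[0, 1]`.
#' @param feature_prevalences named numeric vector, concept -> probability;
#'   concept names must appear in [concept_catalog()].
#' @param outcome_hazards named numeric vector over
#'   `death, cirrhosis, hcc, ckd, cvd, mi` (per person-year, >= 0).
#' @param note_mention_profile named probabilities over
#'   `positive, negated, family, absent` (must sum to 1): how the subtype's
#'   steatosis-evidence document is written.
#' @param demographics list with `age_mean`, `age_sd`, `p_female`,
#'   `p_hispanic`, `race_probs` (named over Asian, Black, White, Other),
#'   and optional `meld_mean` (NA = no MELD notes).
#' @return object of class `subtype_spec`.
#' @export
subtype_spec <- function(label, mixing_proportion, feature_prevalences,
                         outcome_hazards = c(death = 0.005, cirrhosis = 0.001,
                                             hcc = 0.0005, ckd = 0.003,
                                             cvd = 0.004, mi = 0.001),
                         note_mention_profile = c(positive = 0.85,
                                                  negated = 0.08,
                                                  family = 0.04,
                                                  absent = 0.03),
                         demographics = list()) {
  if (mixing_proportion < 0 || mixing_proportion > 1)
    stop_config("mixing_proportion must be in [0,1]")
  if (any(feature_prevalences < 0 | feature_prevalences > 1))
    stop_config("feature prevalences must be probabilities in [0,1]")
  if (any(outcome_hazards < 0))
    stop_config("outcome hazards must be >= 0")
  need <- c("death", "cirrhosis", "hcc", "ckd", "cvd", "mi")
  if (!all(need %in% names(outcome_hazards)))
    stop_config("outcome_hazards must name all of: ",
                paste(need, collapse = ", "))
  kinds <- c("positive", "negated", "family", "absent")
  if (!all(kinds %in% names(note_mention_profile)) ||
      abs(sum(note_mention_profile[kinds]) - 1) > 1e-8)
    stop_config("note_mention_profile must cover ",
                paste(kinds, collapse = "/"), " and sum to 1")
  demo <- utils::modifyList(list(
    age_mean = 55, age_sd = 12, p_female = 0.5, p_hispanic = 0.15,
    race_probs = c(Asian = 0.06, Black = 0.12, White = 0.55, Other = 0.27),
    meld_mean = NA_real_), demographics)
  structure(list(label = label,
                 mixing_proportion = mixing_proportion,
                 feature_prevalences = feature_prevalences,
                 outcome_hazards = outcome_hazards[need],
                 note_mention_profile = note_mention_profile[kinds],
                 demographics = demo),
            class = "subtype_spec")
}

#' Clinical concept catalog used by the generator
#'
#' Each concept names one plantable clinical signal together with the EMR
#' events that express it: a diagnosis code, a medication, an abnormal lab
#' value, an abnormal vital sign, or a procedure code.
#'
#' @return data.frame with columns `concept`, `domain`, `code`
#'   (ICD-10 / CPT / drug name / lab test / vital kind) and
#'   `abnormal_value` for labs and vitals.
#' @export
concept_catalog <- function() {
  dx <- function(concept, code)
    data.frame(concept = concept, domain = "diagnosis", code = code,
               abnormal_value = NA_real_, stringsAsFactors = FALSE)
  med <- function(drug)
    data.frame(concept = paste0("med_", gsub(" ", "_", drug)),
               domain = "medication", code = drug,
               abnormal_value = NA_real_, stringsAsFactors = FALSE)
  lab <- function(concept, test, value)
    data.frame(concept = concept, domain = "lab", code = test,
               abnormal_value = value, stringsAsFactors = FALSE)
  vit <- function(concept, kind, value)
    data.frame(concept = concept, domain = "vital", code = kind,
               abnormal_value = value, stringsAsFactors = FALSE)
  proc <- function(concept, cpt)
    data.frame(concept = concept, domain = "procedure", code = cpt,
               abnormal_value = NA_real_, stringsAsFactors = FALSE)
  rbind(
    dx("diabetes", "E11.9"), dx("hypertension", "I10"),
    dx("hyperlipidemia", "E78.5"), dx("obesity", "E66.9"),
    dx("sleep_apnea", "G47.33"), dx("gerd", "K21.9"),
    dx("tobacco_use", "Z72.0"), dx("asthma", "J45.909"),
    dx("anxiety", "F41.9"), dx("depression", "F32.9"),
    dx("uti", "N39.0"), dx("pneumonia", "J18.9"),
    dx("sepsis", "A41.9"), dx("atrial_fibrillation", "I48.91"),
    dx("malignancy", "C80.1"), dx("vitamin_d_deficiency", "E55.9"),
    med("metformin"), med("insulin"), med("aspirin"), med("lisinopril"),
    med("amlodipine"), med("metoprolol"), med("atorvastatin"),
    med("omeprazole"), med("acetaminophen"), med("oxycodone"),
    med("gabapentin"), med("furosemide"), med("albuterol"),
    med("fluticasone"), med("cholecalciferol"),
    lab("lab_platelets_low", "platelets", 90),
    lab("lab_bilirubin_high", "bilirubin total", 2.8),
    lab("lab_inr_high", "INR", 1.6),
    lab("lab_albumin_low", "albumin", 2.7),
    lab("lab_ast_high", "AST", 85),
    vit("vital_bp_abnormal", "sbp", 148),
    vit("vital_pain_severe", "pain", 9),
    vit("vital_tachycardia", "heart_rate", 142),
    proc("proc_digestive_surgery", "44950"),
    proc("proc_cardiovascular_surgery", "35001"),
    proc("proc_respiratory_surgery", "31600"))
}

#' Default five-subtype cohort structure
#'
#' A literature-motivated latent structure: two large lower-risk subtypes, one
#' metabolic/inflammatory subtype, one fibrosis-dominant subtype, and one
#' small severe multimorbid subtype with high death hazard.
#'
#' @return list of five [subtype_spec()] objects.
#' @export
default_subtype_specs <- function() {
  cc <- concept_catalog()$concept
  base <- stats::setNames(rep(0.03, length(cc)), cc)
  prev <- function(...) {
    p <- base
    upd <- c(...)
    p[names(upd)] <- upd
    p
  }
  list(
    # metabolic comorbidity, minimal fibrosis; largest group
    subtype_spec("S1", 0.47,
      prev(obesity = 0.60, hypertension = 0.58, hyperlipidemia = 0.30,
           diabetes = 0.25, gerd = 0.19, asthma = 0.11,
           vitamin_d_deficiency = 0.14, vital_bp_abnormal = 0.45,
           med_omeprazole = 0.25, med_metformin = 0.28,
           med_atorvastatin = 0.28, med_fluticasone = 0.12),
      c(death = 0.002, cirrhosis = 0.0008, hcc = 0.0004, ckd = 0.003,
        cvd = 0.006, mi = 0.001),
      demographics = list(age_mean = 54, age_sd = 12, p_female = 0.62,
                          p_hispanic = 0.25,
                          race_probs = c(Asian = 0.05, Black = 0.18,
                                         White = 0.45, Other = 0.32))),
    # metabolic syndrome with liver inflammation, high utilizers
    subtype_spec("S2", 0.06,
      prev(diabetes = 0.50, hypertension = 0.62, hyperlipidemia = 0.37,
           obesity = 0.45, sleep_apnea = 0.12, gerd = 0.27,
           tobacco_use = 0.20, asthma = 0.22, anxiety = 0.13,
           depression = 0.17, uti = 0.12,
           lab_platelets_low = 0.35, lab_bilirubin_high = 0.30,
           lab_inr_high = 0.25, lab_albumin_low = 0.25, lab_ast_high = 0.40,
           vital_bp_abnormal = 0.55, vital_pain_severe = 0.25,
           med_aspirin = 0.40, med_lisinopril = 0.35, med_amlodipine = 0.30,
           med_metoprolol = 0.30, med_atorvastatin = 0.35,
           med_metformin = 0.40, med_insulin = 0.25,
           med_acetaminophen = 0.40, med_gabapentin = 0.20,
           med_oxycodone = 0.20, med_albuterol = 0.25,
           med_omeprazole = 0.30, med_cholecalciferol = 0.20,
           proc_digestive_surgery = 0.40),
      c(death = 0.008, cirrhosis = 0.002, hcc = 0.001, ckd = 0.012,
        cvd = 0.012, mi = 0.007),
      demographics = list(age_mean = 56, age_sd = 12, p_female = 0.52,
                          p_hispanic = 0.30,
                          race_probs = c(Asian = 0.04, Black = 0.25,
                                         White = 0.35, Other = 0.36),
                          meld_mean = 9)),
    # younger, healthier patients
    subtype_spec("S3", 0.40,
      prev(obesity = 0.20, hypertension = 0.12, hyperlipidemia = 0.10,
           diabetes = 0.06, gerd = 0.08),
      c(death = 0.0004, cirrhosis = 0, hcc = 0, ckd = 0.0015,
        cvd = 0.001, mi = 0.0004),
      demographics = list(age_mean = 44, age_sd = 11, p_female = 0.48,
                          p_hispanic = 0.10,
                          race_probs = c(Asian = 0.07, Black = 0.07,
                                         White = 0.66, Other = 0.20))),
    # fibrosis at baseline, liver synthetic dysfunction
    subtype_spec("S4", 0.04,
      prev(diabetes = 0.40, hypertension = 0.60, obesity = 0.20,
           hyperlipidemia = 0.21,
           lab_platelets_low = 0.60, lab_inr_high = 0.50,
           lab_albumin_low = 0.50, lab_ast_high = 0.55,
           med_furosemide = 0.25, med_metoprolol = 0.25,
           vital_bp_abnormal = 0.50),
      c(death = 0.02, cirrhosis = 0.05, hcc = 0.035, ckd = 0.006,
        cvd = 0.010, mi = 0.002),
      demographics = list(age_mean = 64, age_sd = 10, p_female = 0.38,
                          p_hispanic = 0.10,
                          race_probs = c(Asian = 0.05, Black = 0.08,
                                         White = 0.62, Other = 0.25),
                          meld_mean = 13)),
    # severe multimorbid disease, high mortality
    subtype_spec("S5", 0.03,
      prev(diabetes = 0.55, hypertension = 0.65, obesity = 0.25,
           malignancy = 0.15, atrial_fibrillation = 0.11,
           tobacco_use = 0.29, depression = 0.17, uti = 0.17,
           pneumonia = 0.10, sepsis = 0.25,
           lab_platelets_low = 0.55, lab_bilirubin_high = 0.50,
           lab_inr_high = 0.50, lab_albumin_low = 0.55, lab_ast_high = 0.55,
           vital_pain_severe = 0.35, vital_tachycardia = 0.20,
           med_aspirin = 0.40, med_metoprolol = 0.35, med_furosemide = 0.40,
           med_acetaminophen = 0.45, med_oxycodone = 0.35,
           med_insulin = 0.35,
           proc_cardiovascular_surgery = 0.31,
           proc_respiratory_surgery = 0.17,
           proc_digestive_surgery = 0.50),
      c(death = 0.25, cirrhosis = 0.05, hcc = 0.025, ckd = 0.015,
        cvd = 0.015, mi = 0.006),
      demographics = list(age_mean = 66, age_sd = 11, p_female = 0.45,
                          p_hispanic = 0.28,
                          race_probs = c(Asian = 0.04, Black = 0.22,
                                         White = 0.40, Other = 0.34),
                          meld_mean = 18)))
}

#' Cohort-level configuration for the generator
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer RNG seed; identical configs and seeds yield
#'   byte-identical bundles.
#' @param index_window two dates: earliest and latest intended NAFLD index
#'   date (defaults to 2013-01-01 .. 2019-01-31).
#' @param subtype_specs list of [subtype_spec()]; mixing proportions must
#'   sum to 1.
#' @param p_alt_pathway probability a patient carries a qualifying
#'   ambulatory ALT pair.
#' @param p_icd_pathway probability a patient carries an inclusion
#'   diagnosis code.
#' @param exclusion_rate probability a patient carries an exclusion trigger
#'   (exclusion diagnosis, positive viral-hepatitis lab, or steatogenic
#'   medication).
#' @param prevalent_outcome_rate probability of planting pre-existing
#'   outcome evidence within 6 months of the index date (exercises the
#'   prevalent-case rule downstream).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          index_window = as.Date(c("2013-01-01",
                                                   "2019-01-31")),
                          subtype_specs = default_subtype_specs(),
                          p_alt_pathway = 0.80, p_icd_pathway = 0.50,
                          exclusion_rate = 0.04,
                          prevalent_outcome_rate = 0.01) {
  if (n_patients < 1) stop_config("n_patients must be >= 1")
  index_window <- as.Date(index_window)
  if (index_window[1L] >= index_window[2L])
    stop_config("index_window start must precede end")
  mix <- vapply(subtype_specs, function(s) s$mixing_proportion, numeric(1))
  if (abs(sum(mix) - 1) > 1e-8)
    stop_config("mixing proportions must sum to 1 (got ", sum(mix), ")")
  probs <- c(p_alt_pathway, p_icd_pathway, exclusion_rate,
             prevalent_outcome_rate)
  if (any(probs < 0 | probs > 1)) stop_config("rates must be in [0,1]")
  known <- concept_catalog()$concept
  for (s in subtype_specs) {
    bad <- setdiff(names(s$feature_prevalences), known)
    if (length(bad))
      stop_config("unknown concepts in subtype ", s$label, ": ",
                  paste(bad, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 index_window = index_window, subtype_specs = subtype_specs,
                 p_alt_pathway = p_alt_pathway, p_icd_pathway = p_icd_pathway,
                 exclusion_rate = exclusion_rate,
                 prevalent_outcome_rate = prevalent_outcome_rate),
            class = "cohort_config")
}

#' Generate a templated clinical note sentence
#'
#' Embeds `term` in one of at least three surface templates per mention
#' kind; `absent` returns filler text containing no lexicon term.
#'
#' @param mention_kind one of `positive`, `negated`, `family`, `absent`.
#' @param term surface form to embed.
#' @return a single sentence (character).
#' @export
generate_note_text <- function(mention_kind = c("positive", "negated",
                                                "family", "absent"),
                               term = "hepatic steatosis") {
  mention_kind <- match.arg(mention_kind)
  templates <- switch(mention_kind,
    positive = c(
      "Ultrasound of the abdomen demonstrates %s.",
      "Liver biopsy shows %s.",
      "Imaging findings are consistent with %s.",
      "Assessment: %s, advised lifestyle modification."),
    negated = c(
      "There is absence of %s.",
      "No evidence of %s on imaging.",
      "Patient is negative for %s.",
      "Findings not consistent with %s."),
    family = c(
      "Mother with %s.",
      "Family history of %s reported.",
      "Patient's father had %s diagnosed previously."),
    absent = c(
      "Routine follow up visit, chronic problems reviewed.",
      "Patient presents with knee pain, improving with physical therapy.",
      "Medication list reviewed and reconciled with patient."))
  tmpl <- sample(templates, 1L)
  if (mention_kind == "absent") tmpl else sprintf(tmpl, term)
}

#' Draw one constant-hazard event time with administrative censoring
#'
#' @param hazard event rate per person-year (>= 0).
#' @param horizon administrative horizon in years.
#' @return list with `time` (years, capped at `horizon`) and `observed`.
#' @export
generate_event_time <- function(hazard, horizon) {
  if (is.na(hazard) || hazard < 0) stop_config("hazard must be >= 0")
  if (hazard == 0) return(list(time = horizon, observed = FALSE))
  t <- stats::rexp(1L, rate = hazard)
  if (t > horizon) list(time = horizon, observed = FALSE)
  else list(time = t, observed = TRUE)
}

# column accumulator: grow lists of scalars cheaply, materialize once
new_acc <- function(cols) {
  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 256L)
  env$n <- 0L
  env$cols <- cols
  env
}
acc_add <- function(acc, ...) {
  acc$n <- acc$n + 1L
  if (acc$n > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
  acc$rows[[acc$n]] <- list(...)
}
acc_df <- function(acc) {
  rows <- acc$rows[seq_len(acc$n)]
  out <- lapply(seq_along(acc$cols), function(j)
    unlist(lapply(rows, `[[`, j), use.names = FALSE))
  names(out) <- acc$cols
  if (acc$n == 0L) out <- lapply(out, function(x) x %||% character(0))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic EMR cohort
#'
#' Samples each patient's latent subtype from the mixing proportions, then
#' emits demographics, coded events, medication orders, lab results
#' (including qualifying ambulatory ALT pairs), vitals and free-text
#' documents consistent with that subtype's specification. Outcome event
#' times are exponential draws from the subtype's constant hazards,
#' administratively censored at the index-window end; observed outcomes are
#' written back into the record as diagnosis codes, dialysis procedures,
#' cirrhosis notes, or a death date and death note.
#'
#' @param config a [cohort_config()].
#' @return list of class `emr_simulation` with elements `bundle` (class
#'   `emr_bundle`: `patients`, `code_events`, `med_orders`, `lab_results`,
#'   `vitals`, `documents`) and `truth` (hidden per-patient subtype label,
#'   intended index date, eligibility design flags, and latent outcome
#'   times in years). The truth table is never represented inside the
#'   bundle.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  specs <- config$subtype_specs
  mix <- vapply(specs, function(s) s$mixing_proportion, numeric(1))
  catalog <- concept_catalog()
  admin_end <- config$index_window[2L]
  steat_terms <- c("hepatic steatosis", "steatosis", "steatohepatitis",
                   "fatty liver", "NASH", "NAFLD")
  outcome_names <- c("death", "cirrhosis", "hcc", "ckd", "cvd", "mi")
  outcome_codes <- list(
    hcc = list(system = "ICD10", code = "C22.0"),
    ckd = list(system = "ICD10", code = "N18.3"),
    cvd = list(system = "ICD10", code = "I25.10"),
    mi  = list(system = "ICD10", code = "I21.0"))
  excl_codes <- read_csv_strict(pkg_extdata("exclusion_codes_synthetic.csv"))
  steato_meds <- read_csv_strict(
    pkg_extdata("steatogenic_medications_synthetic.csv"))$drug_name

  pat <- new_acc(c("patient_id", "birth_date", "sex", "race", "ethnicity",
                   "death_date"))
  cod <- new_acc(c("patient_id", "date", "system", "code", "setting"))
  med <- new_acc(c("patient_id", "date", "drug_name"))
  lab <- new_acc(c("patient_id", "date", "test_name", "value_text",
                   "value_num", "ref_low", "ref_high", "setting"))
  vit <- new_acc(c("patient_id", "date", "kind", "value", "unit"))
  doc <- new_acc(c("patient_id", "date", "doc_type", "text"))
  truth <- new_acc(c("patient_id", "subtype", "index_date",
                     "designed_eligible", "mention_kind", "excluded_design",
                     paste0("t_", outcome_names),
                     paste0("obs_", outcome_names)))

  z <- sample.int(length(specs), n, replace = TRUE, prob = mix)
  win_days <- as.integer(config$index_window[2L] - config$index_window[1L])
  lab_ref <- read_csv_strict(pkg_extdata("lab_reference_synthetic.csv"))
  ref_of <- function(test) lab_ref[lab_ref$test_name == test, , drop = FALSE]

  for (i in seq_len(n)) {
    pid <- sprintf("P%06d", i)
    sp <- specs[[z[i]]]
    dm <- sp$demographics
    index <- config$index_window[1L] + sample.int(win_days, 1L)
    age <- max(18.5, stats::rnorm(1L, dm$age_mean, dm$age_sd))
    birth <- index - round(age * 365.25)
    sex <- if (stats::runif(1L) < dm$p_female) "F" else "M"
    hispanic <- stats::runif(1L) < dm$p_hispanic
    race <- sample(names(dm$race_probs), 1L, prob = dm$race_probs)
    ethnicity <- if (hispanic) "Hispanic" else "Not Hispanic"

    # --- NAFLD evidence ------------------------------------------------
    has_alt <- stats::runif(1L) < config$p_alt_pathway
    has_icd <- stats::runif(1L) < config$p_icd_pathway
    mention_kind <- sample(names(sp$note_mention_profile), 1L,
                           prob = sp$note_mention_profile)
    excluded <- stats::runif(1L) < config$exclusion_rate
    alt_thr <- if (sex == "M") 40 else 31
    r <- ref_of("ALT")
    if (has_alt) {
      d2 <- index - sample.int(180L, 1L)
      d1 <- d2 - (184L + sample.int(300L, 1L))
      for (d in c(d1, d2)) {
        acc_add(lab, pid, as.numeric(d), "ALT", "",
                alt_thr + round(stats::runif(1L, 0, 60), 1),
                r$ref_low, r$ref_high, "ambulatory")
      }
    } else {
      # sub-threshold or single ALT only
      acc_add(lab, pid, as.numeric(index - sample.int(300L, 1L)), "ALT", "",
              round(stats::runif(1L, 10, alt_thr - 2), 1),
              r$ref_low, r$ref_high, "ambulatory")
    }
    if (has_icd) {
      code <- sample(c("K76.0", "K75.81", "K76.9"), 1L)
      acc_add(cod, pid, as.numeric(index - sample.int(180L, 1L)),
              "ICD10", code, "ambulatory")
    }
    # steatosis-evidence document (kind per subtype profile) at index
    term <- sample(steat_terms, 1L)
    kind <- if (mention_kind == "family") "family" else mention_kind
    acc_add(doc, pid, as.numeric(index),
            sample(c("imaging", "note", "pathology"), 1L),
            generate_note_text(kind, term))
    # background note without any lexicon term
    acc_add(doc, pid, as.numeric(index - sample.int(400L, 1L)), "note",
            generate_note_text("absent"))
    meld_day <- index + sample.int(60L, 1L)

    # --- exclusions ----------------------------------------------------
    if (excluded) {
      pick <- sample.int(3L, 1L)
      d <- as.numeric(index - sample.int(700L, 1L))
      if (pick == 1L) {
        row <- excl_codes[sample.int(nrow(excl_codes), 1L), ]
        acc_add(cod, pid, d, row$system, row$code, "ambulatory")
      } else if (pick == 2L) {
        test <- sample(c("HBV surface antigen", "HCV RNA"), 1L)
        acc_add(lab, pid, d, test,
                if (test == "HCV RNA") "detected" else "positive",
                NA_real_, NA_real_, NA_real_, "ambulatory")
        # value_num, ref_low, ref_high all missing for qualitative results
      } else {
        drug <- sample(steato_meds, 1L)
        acc_add(med, pid, d, drug)
        acc_add(med, pid, d + 200, drug)
      }
    }

    # --- latent outcome times (years from index) -----------------------
    horizon <- as.numeric(admin_end - index) / 365.25
    tt <- numeric(length(outcome_names)); ob <- logical(length(outcome_names))
    names(tt) <- names(ob) <- outcome_names
    for (k in outcome_names) {
      e <- generate_event_time(sp$outcome_hazards[[k]], horizon)
      tt[k] <- e$time; ob[k] <- e$observed
    }
    death_date <- as.Date(NA)
    if (ob["death"]) death_date <- index + round(tt["death"] * 365.25)
    # non-death outcomes truncated by death
    for (k in setdiff(outcome_names, "death")) {
      if (ob[k] && ob["death"] && tt[k] > tt["death"]) ob[k] <- FALSE
    }
    last_day <- if (!is.na(death_date)) death_date else admin_end

    emit_outcome <- function(k, at_date) {
      if (k == "cirrhosis") {
        acc_add(doc, pid, as.numeric(at_date),
                sample(c("imaging", "note", "pathology"), 1L),
                generate_note_text("positive", "cirrhosis"))
      } else if (k == "ckd" && stats::runif(1L) < 0.3) {
        acc_add(cod, pid, as.numeric(at_date), "CPT",
                as.character(90935L + sample.int(60L, 1L)), "inpatient")
      } else {
        oc <- outcome_codes[[k]]
        acc_add(cod, pid, as.numeric(at_date), oc$system, oc$code,
                sample(c("ambulatory", "inpatient"), 1L))
      }
    }
    for (k in setdiff(outcome_names, "death")) {
      if (ob[k]) emit_outcome(k, index + round(tt[k] * 365.25))
    }
    if (stats::runif(1L) < config$prevalent_outcome_rate) {
      k <- sample(setdiff(outcome_names, "death"), 1L)
      emit_outcome(k, min(index + sample.int(120L, 1L), last_day))
    }
    if (!is.na(dm$meld_mean)) {
      meld <- max(6L, min(40L, round(stats::rnorm(1L, dm$meld_mean, 3))))
      acc_add(doc, pid, as.numeric(min(meld_day, last_day)), "note",
              sprintf("Calculated MELD %d on admission.", meld))
    }
    if (ob["death"]) {
      acc_add(doc, pid, as.numeric(death_date), "note",
              "Patient expired during this admission.")
    }

    # --- subtype concept events ----------------------------------------
    draw_day <- function() {
      d <- index + sample(seq(-180L, 365L), 1L)
      min(d, last_day)
    }
    pv <- sp$feature_prevalences
    on <- names(pv)[stats::runif(length(pv)) < pv]
    for (cpt in on) {
      row <- catalog[catalog$concept == cpt, ]
      if (row$domain == "diagnosis") {
        acc_add(cod, pid, as.numeric(draw_day()), "ICD10", row$code,
                sample(c("ambulatory", "inpatient"), 1L))
      } else if (row$domain == "medication") {
        d1 <- draw_day()
        acc_add(med, pid, as.numeric(d1), row$code)
        acc_add(med, pid, as.numeric(min(d1 + 183L + sample.int(120L, 1L),
                                         last_day + 300L)), row$code)
      } else if (row$domain == "lab") {
        r <- ref_of(row$code)
        acc_add(lab, pid, as.numeric(draw_day()), row$code, "",
                row$abnormal_value, r$ref_low, r$ref_high, "ambulatory")
      } else if (row$domain == "vital") {
        acc_add(vit, pid, as.numeric(draw_day()), row$code,
                row$abnormal_value,
                switch(row$code, sbp = "mmHg", dbp = "mmHg",
                       heart_rate = "bpm", pain = "score", "unit"))
      } else if (row$domain == "procedure") {
        acc_add(cod, pid, as.numeric(draw_day()), "CPT", row$code,
                "inpatient")
      }
    }
    # baseline normal measurements for realism
    r <- ref_of("creatinine")
    acc_add(lab, pid, as.numeric(draw_day()), "creatinine", "",
            round(stats::runif(1L, r$ref_low, r$ref_high), 2),
            r$ref_low, r$ref_high, "ambulatory")
    vd <- as.numeric(draw_day())
    acc_add(vit, pid, vd, "sbp", round(stats::rnorm(1L, 118, 6)), "mmHg")
    acc_add(vit, pid, vd, "dbp", round(stats::rnorm(1L, 72, 5)), "mmHg")
    acc_add(vit, pid, vd, "heart_rate", round(stats::rnorm(1L, 78, 8)), "bpm")
    acc_add(vit, pid, vd, "temperature",
            round(stats::rnorm(1L, 36.8, 0.3), 1), "C")
    acc_add(cod, pid, as.numeric(draw_day()), "CPT", "99213", "ambulatory")

    acc_add(pat, pid, as.numeric(birth), sex, race, ethnicity,
            as.numeric(death_date))
    args <- c(list(truth, pid, specs[[z[i]]]$label, as.numeric(index),
                   (has_alt || has_icd) && mention_kind == "positive" &&
                     !excluded,
                   mention_kind, excluded),
              as.list(unname(tt)), as.list(unname(ob)))
    do.call(acc_add, args)
  }

  to_date <- function(df, cols) {
    for (cl in cols) df[[cl]] <- as.Date(df[[cl]], origin = "1970-01-01")
    df
  }
  bundle <- structure(list(
    patients = to_date(acc_df(pat), c("birth_date", "death_date")),
    code_events = to_date(acc_df(cod), "date"),
    med_orders = to_date(acc_df(med), "date"),
    lab_results = to_date(acc_df(lab), "date"),
    vitals = to_date(acc_df(vit), "date"),
    documents = to_date(acc_df(doc), "date")), class = "emr_bundle")
  truth_df <- to_date(acc_df(truth), "index_date")
  # clamp: no event after a recorded death (medication second fills can
  # exceed; drop those rows)
  dd <- bundle$patients$death_date[match(bundle$med_orders$patient_id,
                                         bundle$patients$patient_id)]
  keep <- is.na(dd) | bundle$med_orders$date <= dd
  bundle$med_orders <- bundle$med_orders[keep, , drop = FALSE]
  rownames(bundle$med_orders) <- NULL
  structure(list(bundle = bundle, truth = truth_df),
            class = "emr_simulation")
}

#' @export
print.emr_bundle <- function(x, ...) {
  cat("<emr_bundle>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' @export
print.emr_simulation <- function(x, ...) {
  cat("Synthetic EMR cohort:", nrow(x$bundle$patients), "patients,",
      length(unique(x$truth$subtype)), "latent subtypes\n")
  print(table(x$truth$subtype))
  invisible(x)
}
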