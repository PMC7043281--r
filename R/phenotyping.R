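# Rule-based NAFLD electronic phenotype: persistent ambulatory ALT
# elevation or chronic non-alcoholic liver disease codes, minus exclusions
# (viral hepatitis, alcoholic/other chronic liver disease, steatogenic
# medications), plus positive steatosis evidence in free text.

#' Configuration for the NAFLD electronic phenotype
#'
#' Defaults follow the published rule set: ALT >= 40 IU/mL (men) or
#' >= 31 IU/mL (women) twice in the ambulatory setting more than 6 months
#' (183 days) apart; inclusion diagnosis codes ICD-9 571.5/571.8/571.9 and
#' ICD-10 K75.81/K76.0/K76.9; exclusion of viral hepatitis, alcoholic and
#' other chronic liver disease (code lists and positive HBV surface
#' antigen / detectable HCV RNA labs) and of steatogenic medication users;
#' qualifying dates must fall after 2012-12-31 and up to 2019-01-31.
#'
#' @param alt_threshold_male,alt_threshold_female ALT cut-offs in IU/mL.
#' @param min_gap_days minimum day gap between the two qualifying ALT
#'   measurements (strictly greater than).
#' @param inclusion_codes data.frame (`system`, `code`).
#' @param exclusion_codes data.frame (`category`, `system`, `code`);
#'   defaults to the shipped synthetic stand-in for the eMerge lists.
#' @param exclusion_lab_tests lab test names whose positive/detected
#'   results exclude a patient.
#' @param steatogenic_medications character vector of drug names.
#' @param index_window two dates: window start (exclusive) and end
#'   (inclusive) for the NAFLD diagnosis date.
#' @param require_both if `TRUE`, require the ALT rule AND an inclusion
#'   code rather than either.
#' @param steatosis_lexicon lexicon used for the steatosis-evidence scan.
#' @return object of class `phenotype_config`.
#' @export
phenotype_config <- function(alt_threshold_male = 40,
                             alt_threshold_female = 31,
                             min_gap_days = 183L,
                             inclusion_codes = data.frame(
                               system = c("ICD9", "ICD9", "ICD9",
                                          "ICD10", "ICD10", "ICD10"),
                               code = c("571.5", "571.8", "571.9",
                                        "K75.81", "K76.0", "K76.9"),
                               stringsAsFactors = FALSE),
                             exclusion_codes = NULL,
                             exclusion_lab_tests = c("HBV surface antigen",
                                                     "HCV RNA"),
                             steatogenic_medications = NULL,
                             index_window = as.Date(c("2012-12-31",
                                                      "2019-01-31")),
                             require_both = FALSE,
                             steatosis_lexicon = default_lexicon("steatosis")) {
  if (alt_threshold_male <= 0 || alt_threshold_female <= 0 ||
      min_gap_days <= 0)
    stop_config("thresholds and gap must be positive")
  index_window <- as.Date(index_window)
  if (index_window[1L] >= index_window[2L])
    stop_config("index window start must precede end")
  if (is.null(exclusion_codes))
    exclusion_codes <- read_csv_strict(
      pkg_extdata("exclusion_codes_synthetic.csv"))
  if (is.null(steatogenic_medications))
    steatogenic_medications <- read_csv_strict(
      pkg_extdata("steatogenic_medications_synthetic.csv"))$drug_name
  if (nrow(exclusion_codes) == 0L ||
      length(steatogenic_medications) == 0L)
    stop_config("exclusion lists must be non-empty")
  structure(list(alt_threshold_male = alt_threshold_male,
                 alt_threshold_female = alt_threshold_female,
                 min_gap_days = as.integer(min_gap_days),
                 inclusion_codes = inclusion_codes,
                 exclusion_codes = exclusion_codes,
                 exclusion_lab_tests = exclusion_lab_tests,
                 steatogenic_medications = steatogenic_medications,
                 index_window = index_window,
                 require_both = require_both,
                 steatosis_lexicon = steatosis_lexicon),
            class = "phenotype_config")
}

#' Persistent ambulatory ALT elevation
#'
#' TRUE iff the patient has two ambulatory ALT results at or above the
#' sex-specific threshold whose dates are strictly more than
#' `min_gap_days` apart. The qualifying date is the second (later) date of
#' the earliest qualifying pair, i.e. the first day on which the rule is
#' satisfied.
#'
#' @param labs data.frame of one patient's lab rows (`date`, `test_name`,
#'   `value_num`, `setting`).
#' @param sex `"M"` or `"F"`; unknown values fall back to the (stricter)
#'   male threshold and are flagged.
#' @param config a [phenotype_config()].
#' @return list `met` (logical), `date` (Date or NA), `note` (character).
#' @export
persistent_alt_elevation <- function(labs, sex, config = phenotype_config()) {
  note <- ""
  if (!isTRUE(sex %in% c("M", "F"))) {
    note <- "unknown sex: male ALT threshold applied"
    thr <- config$alt_threshold_male
  } else {
    thr <- if (sex == "M") config$alt_threshold_male
           else config$alt_threshold_female
  }
  if (is.null(labs) || nrow(labs) == 0L)
    return(list(met = FALSE, date = as.Date(NA), note = note))
  alt <- labs[labs$test_name == "ALT" & !is.na(labs$value_num) &
              labs$setting == "ambulatory" & labs$value_num >= thr, ,
              drop = FALSE]
  if (nrow(alt) < 2L)
    return(list(met = FALSE, date = as.Date(NA), note = note))
  d <- sort(unique(as_date_strict(alt$date, "lab date")))
  first <- d[1L]
  for (j in seq_along(d)) {
    if (as.integer(d[j] - first) > config$min_gap_days)
      return(list(met = TRUE, date = d[j], note = note))
  }
  list(met = FALSE, date = as.Date(NA), note = note)
}

#' Chronic non-alcoholic liver disease inclusion codes
#'
#' @param code_events one patient's coded events (`date`, `system`,
#'   `code`).
#' @param config a [phenotype_config()].
#' @return list `met`, `date` (earliest matching event date).
#' @export
has_liver_disease_code <- function(code_events,
                                   config = phenotype_config()) {
  if (is.null(code_events) || nrow(code_events) == 0L)
    return(list(met = FALSE, date = as.Date(NA)))
  key <- paste(code_events$system, code_events$code)
  inc <- paste(config$inclusion_codes$system, config$inclusion_codes$code)
  hit <- key %in% inc
  if (!any(hit)) return(list(met = FALSE, date = as.Date(NA)))
  list(met = TRUE,
       date = min(as_date_strict(code_events$date[hit], "code date")))
}

#' Exclusion screen: other liver disease, viral labs, steatogenic drugs
#'
#' Evaluated over the patient's entire record. A patient is excluded if
#' any exclusion diagnosis code is present, any listed viral-hepatitis lab
#' is positive/detected/reactive, or any steatogenic medication was ever
#' ordered.
#'
#' @param code_events,labs,med_orders one patient's tables.
#' @param config a [phenotype_config()].
#' @return list `excluded` (logical), `reasons` (character vector naming
#'   every trigger).
#' @export
is_excluded <- function(code_events, labs, med_orders,
                        config = phenotype_config()) {
  reasons <- character()
  if (!is.null(code_events) && nrow(code_events)) {
    key <- paste(code_events$system, code_events$code)
    exc <- paste(config$exclusion_codes$system, config$exclusion_codes$code)
    hit <- key %in% exc
    if (any(hit)) {
      cats <- config$exclusion_codes$category[
        match(key[hit], exc)]
      reasons <- c(reasons,
                   paste0("code:", code_events$code[hit], " (",
                          cats, ")"))
    }
  }
  if (!is.null(labs) && nrow(labs)) {
    vir <- labs[labs$test_name %in% config$exclusion_lab_tests, ,
                drop = FALSE]
    if (nrow(vir)) {
      pos <- grepl("positive|detected|reactive", tolower(vir$value_text))
      if (any(pos))
        reasons <- c(reasons, paste0("lab:", vir$test_name[pos], "=",
                                     vir$value_text[pos]))
    }
  }
  if (!is.null(med_orders) && nrow(med_orders)) {
    hit <- tolower(med_orders$drug_name) %in%
      tolower(config$steatogenic_medications)
    if (any(hit))
      reasons <- c(reasons,
                   paste0("medication:", unique(med_orders$drug_name[hit])))
  }
  list(excluded = length(reasons) > 0L, reasons = unique(reasons))
}

# slice an emr_bundle down to one patient
bundle_slice <- function(bundle, pid) {
  out <- lapply(bundle, function(tab)
    tab[tab$patient_id == pid, , drop = FALSE])
  class(out) <- "emr_bundle"
  out
}

#' Phenotype decision for a single patient
#'
#' A patient is NAFLD-eligible iff (persistent ALT elevation OR an
#' inclusion liver-disease code; AND of the two under
#' `config$require_both`), no exclusion trigger, and at least one positive
#' steatosis mention in imaging/biopsy/clinical notes. The NAFLD diagnosis
#' date is the earliest day on which all required criteria hold
#' simultaneously (the latest of the per-criterion earliest-satisfaction
#' dates) and must fall inside the index window.
#'
#' @param slice an `emr_bundle` restricted to one patient
#'   (see [classify_cohort()] for the cohort-level driver).
#' @param config a [phenotype_config()].
#' @return list of class `phenotype_decision`: `patient_id`, `eligible`,
#'   `nafld_date`, `criteria` (per-rule pass/fail with evidence dates),
#'   `failed_rules`.
#' @export
decide_patient <- function(slice, config = phenotype_config()) {
  pid <- if (nrow(slice$patients)) slice$patients$patient_id[1L]
         else unique(unlist(lapply(slice, function(t) t$patient_id)))[1L]
  sex <- if (nrow(slice$patients)) slice$patients$sex[1L] else NA_character_
  alt <- persistent_alt_elevation(slice$lab_results, sex, config)
  icd <- has_liver_disease_code(slice$code_events, config)
  exc <- is_excluded(slice$code_events, slice$lab_results,
                     slice$med_orders, config)
  ste <- patient_has_concept(slice$documents, config$steatosis_lexicon)

  liver_met <- if (config$require_both) alt$met && icd$met
               else alt$met || icd$met
  liver_date <- if (!liver_met) as.Date(NA)
    else if (config$require_both) max(alt$date, icd$date)
    else suppressWarnings(min(c(alt$date, icd$date), na.rm = TRUE))

  criteria <- list(
    liver_disease = list(pass = liver_met, date = liver_date,
                         alt = alt, icd = icd),
    not_excluded = list(pass = !exc$excluded, reasons = exc$reasons),
    steatosis_evidence = list(pass = ste$present, date = ste$date))

  eligible <- liver_met && !exc$excluded && ste$present
  nafld_date <- as.Date(NA)
  in_window <- NA
  if (eligible) {
    nafld_date <- max(liver_date, ste$date)
    in_window <- nafld_date > config$index_window[1L] &&
      nafld_date <= config$index_window[2L]
    if (!in_window) {
      eligible <- FALSE
      nafld_date <- as.Date(NA)
    }
  }
  # the window rule only applies once the other criteria produced a date
  criteria$in_window <- list(pass = !identical(in_window, FALSE))
  failed <- names(criteria)[!vapply(criteria, function(cr)
    isTRUE(cr$pass), logical(1L))]
  if (eligible) failed <- character()
  structure(list(patient_id = pid, eligible = eligible,
                 nafld_date = nafld_date, criteria = criteria,
                 failed_rules = failed),
            class = "phenotype_decision")
}

#' Apply the NAFLD phenotype to every patient in a bundle
#'
#' @param bundle an `emr_bundle`.
#' @param config a [phenotype_config()].
#' @return data.frame of class `phenotype_decisions` with one row per
#'   patient: `patient_id`, `eligible`, `nafld_date`, `failed_rules`
#'   (semicolon-joined).
#' @export
classify_cohort <- function(bundle, config = phenotype_config()) {
  pids <- bundle$patients$patient_id
  if (length(pids) == 0L) {
    out <- data.frame(patient_id = character(), eligible = logical(),
                      nafld_date = as.Date(character()),
                      failed_rules = character(), stringsAsFactors = FALSE)
    class(out) <- c("phenotype_decisions", "data.frame")
    return(out)
  }
  # pre-split child tables once; per-patient slicing by id scan is O(n^2)
  split_tab <- function(tab) split(tab, factor(tab$patient_id, levels = pids))
  parts <- lapply(bundle, split_tab)
  res <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    slice <- structure(lapply(parts, `[[`, i), class = "emr_bundle")
    res[[i]] <- decide_patient(slice, config)
  }
  out <- data.frame(
    patient_id = pids,
    eligible = vapply(res, `[[`, logical(1L), "eligible"),
    nafld_date = as.Date(vapply(res, function(d)
      as.numeric(d$nafld_date), numeric(1L)), origin = "1970-01-01"),
    failed_rules = vapply(res, function(d)
      paste(d$failed_rules, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
  attr(out, "decisions") <- res
  class(out) <- c("phenotype_decisions", "data.frame")
  out
}

#' @export
print.phenotype_decision <- function(x, ...) {
  cat(sprintf("<phenotype_decision> %s: %s\n", x$patient_id,
              if (x$eligible) paste("NAFLD, diagnosis date",
                                    format(x$nafld_date))
              else paste("not eligible (failed:",
                         paste(x$failed_rules, collapse = ", "), ")")))
  invisible(x)
}

#' @export
print.phenotype_decisions <- function(x, ...) {
  cat(sprintf("NAFLD phenotype decisions: %d patients, %d eligible (%.1f%%)\n",
              nrow(x), sum(x$eligible), 100 * mean(x$eligible)))
  if (any(!x$eligible)) {
    tab <- sort(table(unlist(strsplit(x$failed_rules[!x$eligible], ";"))),
                decreasing = TRUE)
    cat("Failed rules among ineligible patients:\n")
    print(tab)
  }
  invisible(x)
}
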