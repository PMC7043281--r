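# Outcome construction and competing-risk survival analysis: death,
# cirrhosis, HCC, CKD, CVD and MI from NAFLD diagnosis; Kaplan-Meier and
# Cox (Efron ties) for overall survival; Aalen-Johansen cumulative
# incidence and Fine-Gray subdistribution-hazard regression with death as
# the competing hazard for non-death outcomes.

# ---- outcome definitions -------------------------------------------------

# ICD range membership, e.g. ICD-9 585-586 or ICD-10 N18-N19: compare the
# 3-character root (letter + 2 digits for ICD-10, 3 digits for ICD-9).
icd_root_in_range <- function(codes, start, end) {
  root <- toupper(substr(codes, 1L, nchar(start)))
  root >= toupper(start) & root <= toupper(end)
}

cpt_in_range <- function(codes, start, end) {
  num <- suppressWarnings(as.numeric(codes))
  !is.na(num) & num >= start & num <= end
}

#' Outcome definitions
#'
#' Default identification channels follow the published code lists:
#' HCC ICD-9 155.0/155.2, ICD-10 C22.0/C22.7-C22.9; CKD ICD-9 585-586,
#' ICD-10 N18-N19 plus dialysis CPT 90935-90999; CVD (any ischemic heart
#' disease) ICD-9 410-414, ICD-10 I20-I25; acute MI ICD-9 410,
#' ICD-10 I21-I22; cirrhosis from note/imaging/pathology mentions; death
#' from the patient record and death mentions in notes.
#'
#' @return named list of outcome definitions; each has `name`, optional
#'   `icd9`/`icd10` exact codes, `icd9_range`/`icd10_range`/`cpt_range`
#'   lists of `c(start, end)`, and optional `lexicon`.
#' @export
outcome_definitions <- function() {
  list(
    death = list(name = "death", lexicon = default_lexicon("death")),
    cirrhosis = list(name = "cirrhosis",
                     lexicon = default_lexicon("cirrhosis")),
    hcc = list(name = "hcc",
               icd9 = c("155.0", "155.2"),
               icd10 = c("C22.0"),
               icd10_range = list(c("C22.7", "C22.9"))),
    ckd = list(name = "ckd",
               icd9_range = list(c("585", "586")),
               icd10_range = list(c("N18", "N19")),
               cpt_range = list(c(90935, 90999))),
    cvd = list(name = "cvd",
               icd9_range = list(c("410", "414")),
               icd10_range = list(c("I20", "I25"))),
    mi = list(name = "mi",
              icd9_range = list(c("410", "410")),
              icd10_range = list(c("I21", "I22"))))
}

# earliest evidence date for one outcome over all channels; NA if none
outcome_evidence_date <- function(def, codes, documents, death_date) {
  dates <- as.Date(character())
  if (nrow(codes)) {
    hit <- rep(FALSE, nrow(codes))
    i9 <- codes$system == "ICD9"; i10 <- codes$system == "ICD10"
    cptt <- codes$system == "CPT"
    if (!is.null(def$icd9)) hit <- hit | (i9 & codes$code %in% def$icd9)
    if (!is.null(def$icd10)) hit <- hit | (i10 & codes$code %in% def$icd10)
    for (r in def$icd9_range %||% list())
      hit <- hit | (i9 & icd_root_in_range(codes$code, r[1], r[2]))
    for (r in def$icd10_range %||% list())
      hit <- hit | (i10 & icd_root_in_range(codes$code, r[1], r[2]))
    for (r in def$cpt_range %||% list())
      hit <- hit | (cptt & cpt_in_range(codes$code, as.numeric(r[1]),
                                        as.numeric(r[2])))
    if (any(hit)) dates <- c(dates, codes$date[hit])
  }
  if (!is.null(def$lexicon) && nrow(documents)) {
    res <- patient_has_concept(documents, def$lexicon)
    if (res$present) dates <- c(dates, res$date)
  }
  if (def$name == "death" && !is.na(death_date))
    dates <- c(dates, death_date)
  if (!length(dates)) as.Date(NA) else min(dates)
}

#' Build per-patient, per-outcome time-to-event rows
#'
#' Time runs from the NAFLD diagnosis date. For non-death outcomes,
#' evidence on or before diagnosis + 183 days marks the case prevalent
#' (excluded from model fitting); later evidence is an incident event
#' (code 1); death before the outcome is a competing event (code 2) at the
#' death date; otherwise the row is censored (code 0) at the
#' administrative end of follow-up. For death, code 1 at the death date,
#' else censored.
#'
#' @param bundle an `emr_bundle`.
#' @param decisions [classify_cohort()] output; only eligible patients
#'   contribute rows.
#' @param defs outcome definitions, see [outcome_definitions()].
#' @param admin_end administrative censoring date (default 2019-01-31,
#'   the index-window end).
#' @return data.frame of class `tte_table`: `patient_id`, `outcome`,
#'   `time` (days, >= 0), `event` (0/1/2), `prevalent`.
#' @export
build_outcome_table <- function(bundle, decisions,
                                defs = outcome_definitions(),
                                admin_end = as.Date("2019-01-31")) {
  elig <- decisions[decisions$eligible, , drop = FALSE]
  rows <- list()
  codes_by <- split(bundle$code_events,
                    factor(bundle$code_events$patient_id,
                           levels = elig$patient_id))
  docs_by <- split(bundle$documents,
                   factor(bundle$documents$patient_id,
                          levels = elig$patient_id))
  pt <- bundle$patients[match(elig$patient_id,
                              bundle$patients$patient_id), , drop = FALSE]
  for (i in seq_len(nrow(elig))) {
    pid <- elig$patient_id[i]
    nafld <- elig$nafld_date[i]
    codes <- codes_by[[i]]
    docs <- docs_by[[i]]
    rec_death <- pt$death_date[i]
    death_evd <- outcome_evidence_date(defs$death, codes, docs, rec_death)
    death_time <- if (is.na(death_evd)) NA_real_
                  else as.numeric(death_evd - nafld)
    for (def in defs) {
      if (def$name == "death") {
        if (!is.na(death_time)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, outcome = "death",
            time = max(death_time, 0), event = 1L, prevalent = FALSE,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, outcome = "death",
            time = as.numeric(admin_end - nafld), event = 0L,
            prevalent = FALSE, stringsAsFactors = FALSE)
        }
        next
      }
      evd <- outcome_evidence_date(def, codes, docs, as.Date(NA))
      if (!is.na(evd) && as.numeric(evd - nafld) <= 183) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, outcome = def$name,
          time = max(as.numeric(evd - nafld), 0), event = 1L,
          prevalent = TRUE, stringsAsFactors = FALSE)
        next
      }
      has_event <- !is.na(evd) &&
        (is.na(death_time) || as.numeric(evd - nafld) <= death_time)
      if (has_event) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, outcome = def$name,
          time = as.numeric(evd - nafld), event = 1L, prevalent = FALSE,
          stringsAsFactors = FALSE)
      } else if (!is.na(death_time)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, outcome = def$name,
          time = max(death_time, 0), event = 2L, prevalent = FALSE,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, outcome = def$name,
          time = as.numeric(admin_end - nafld), event = 0L,
          prevalent = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tte_table", "data.frame")
  out
}

# ---- estimators ----------------------------------------------------------

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via `survival::survfit` (events precede
#' censorings at tied times, the conventional handling).
#'
#' @param time follow-up times.
#' @param status 1 = event, 0 = censored.
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (right-
#'   continuous step function evaluated at event/censoring times).
#' @export
kaplan_meier <- function(time, status) {
  stopifnot(length(time) >= 1L, length(time) == length(status))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Aalen-Johansen cumulative incidence functions
#'
#' CIF_k(t) = sum over event times t_i <= t of S(t_i-) d_{k,i} / n_i,
#' with S the all-cause Kaplan-Meier. Computed with `cmprsk::cuminc`.
#'
#' @param time follow-up times.
#' @param event 0 censored, 1 event of interest, 2 competing death.
#' @param group optional grouping vector (one curve set per group).
#' @return data.frame `group`, `event_type`, `time`, `cif`.
#' @export
cumulative_incidence <- function(time, event, group = NULL) {
  stopifnot(all(event %in% 0:2))
  if (is.null(group)) group <- rep(1L, length(time))
  ci <- cmprsk::cuminc(ftime = time, fstatus = event, group = group,
                       cencode = 0)
  ci <- ci[setdiff(names(ci), "Tests")]
  out <- do.call(rbind, lapply(names(ci), function(nm) {
    parts <- strsplit(nm, " ")[[1L]]
    data.frame(group = paste(parts[-length(parts)], collapse = " "),
               event_type = as.integer(parts[length(parts)]),
               time = ci[[nm]]$time, cif = ci[[nm]]$est,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

tidy_fit <- function(coefs, se, model, converged = TRUE, n = NA_integer_,
                     nevent = NA_integer_) {
  z <- coefs / se
  structure(data.frame(
    term = names(coefs), log_hr = unname(coefs), se = unname(se),
    hr = exp(unname(coefs)),
    ci_low = exp(unname(coefs) - 1.96 * unname(se)),
    ci_high = exp(unname(coefs) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE),
    model = model, converged = converged, n = n, nevent = nevent,
    class = c("hazard_fit", "data.frame"))
}

#' Cox proportional hazards model
#'
#' Partial-likelihood fit via `survival::coxph` with Efron tie handling
#' (Breslow available), standard errors from the inverse observed
#' information, 95% CI on the log scale.
#'
#' @param time,status follow-up time and event indicator (1 = event).
#' @param covariates data.frame or matrix of covariates (factors allowed
#'   in data.frame form).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame of class `hazard_fit`: per term `log_hr`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p`; attributes `model`, `converged`,
#'   `n`, `nevent`.
#' @export
cox_ph <- function(time, status, covariates, ties = "efron") {
  df <- as.data.frame(covariates)
  df$.time <- time
  df$.status <- status
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", setdiff(names(df), c(".time", ".status"))),
          collapse = " + ")))
  conv <- TRUE
  notes <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|infinite|singular", msg)) {
        conv <<- FALSE
        notes <<- c(notes, msg)
        invokeRestart("muffleWarning")
      }
    })
  out <- tidy_fit(stats::coef(fit), sqrt(diag(stats::vcov(fit))), "cox",
                  converged = conv, n = fit$n, nevent = fit$nevent)
  attr(out, "notes") <- notes
  out
}

#' Fine-Gray subdistribution hazards model
#'
#' Proportional subdistribution-hazard regression with competing-event
#' subjects retained in the risk set under censoring-distribution
#' weighting, fitted with `cmprsk::crr` (death = competing code 2).
#' Without competing events it reduces to the Cox model on the same data.
#'
#' @param time follow-up time.
#' @param event 0 censored, 1 event of interest, 2 competing death.
#' @param covariates numeric data.frame/matrix (design matrix; expand
#'   factors beforehand).
#' @return data.frame of class `hazard_fit` (see [cox_ph()]).
#' @export
fine_gray <- function(time, event, covariates) {
  x <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(x)) stop("covariates must be numeric for fine_gray")
  fit <- cmprsk::crr(ftime = time, fstatus = event, cov1 = x,
                     failcode = 1, cencode = 0)
  coefs <- fit$coef
  names(coefs) <- colnames(x)
  tidy_fit(coefs, sqrt(diag(fit$var)), "fine_gray",
           converged = fit$converged, n = length(time),
           nevent = sum(event == 1))
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("%s model (%s; %s events / %s subjects)\n",
              switch(attr(x, "model"), cox = "Cox proportional hazards",
                     fine_gray = "Fine-Gray subdistribution hazards",
                     attr(x, "model")),
              if (isTRUE(attr(x, "converged"))) "converged"
              else "flagged: possible non-convergence or separation",
              attr(x, "nevent"), attr(x, "n")))
  out <- data.frame(term = x$term, HR = signif(x$hr, 3),
                    `95% CI` = sprintf("%.3g-%.3g", x$ci_low, x$ci_high),
                    p = signif(x$p, 2), check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

# ---- covariates ----------------------------------------------------------

#' FIB-4 fibrosis category
#'
#' FIB-4 = age x AST / (platelets x sqrt(ALT)); categories < 1.3 low,
#' 1.3-2.67 indeterminate, > 2.67 high (standard literature cut-offs; the
#' boundary values themselves fall in the indeterminate band). Any
#' missing or non-positive input yields `missing`.
#'
#' @param age years; `ast`,`alt` IU/mL; `platelets` 10^9/L. Vectorized.
#' @return factor with levels low, indeterminate, high, missing.
#' @export
fib4_category <- function(age, ast, alt, platelets) {
  n <- max(length(age), length(ast), length(alt), length(platelets))
  age <- rep_len(age, n); ast <- rep_len(ast, n)
  alt <- rep_len(alt, n); platelets <- rep_len(platelets, n)
  ok <- !is.na(age) & !is.na(ast) & !is.na(alt) & !is.na(platelets) &
    age > 0 & ast > 0 & alt > 0 & platelets > 0
  score <- rep(NA_real_, n)
  score[ok] <- age[ok] * ast[ok] / (platelets[ok] * sqrt(alt[ok]))
  out <- rep("missing", n)
  out[ok & score < 1.3] <- "low"
  out[ok & score >= 1.3 & score <= 2.67] <- "indeterminate"
  out[ok & score > 2.67] <- "high"
  factor(out, levels = c("low", "indeterminate", "high", "missing"))
}

#' Model covariates for the eligible cohort
#'
#' Subtype (factor, reference = subtype 1, the largest), age at NAFLD
#' diagnosis, gender, race combined with ethnicity (Hispanic ethnicity
#' takes precedence and maps to the Hispanic category), and baseline
#' FIB-4 category from the AST/ALT/platelet measurements closest to the
#' diagnosis date (within +/- 365 days).
#'
#' @param bundle an `emr_bundle`.
#' @param decisions [classify_cohort()] output.
#' @param assignment named subtype labels from [cluster_subtypes()].
#' @return data.frame keyed by `patient_id` with `subtype`, `age`,
#'   `gender`, `race`, `fib4`.
#' @export
build_covariates <- function(bundle, decisions, assignment) {
  elig <- decisions[decisions$eligible, , drop = FALSE]
  pt <- bundle$patients[match(elig$patient_id,
                              bundle$patients$patient_id), , drop = FALSE]
  age <- as.numeric(elig$nafld_date - pt$birth_date) / 365.25
  race <- ifelse(pt$ethnicity == "Hispanic", "Hispanic", pt$race)
  labs <- bundle$lab_results[bundle$lab_results$patient_id %in%
                               elig$patient_id, , drop = FALSE]
  baseline_lab <- function(pid, nafld, test) {
    rows <- labs[labs$patient_id == pid & labs$test_name == test &
                   !is.na(labs$value_num), , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    gap <- abs(as.numeric(rows$date - nafld))
    rows <- rows[gap <= 365, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    gap <- abs(as.numeric(rows$date - nafld))
    rows$value_num[which.min(gap)]
  }
  ast <- alt <- plt <- rep(NA_real_, nrow(elig))
  for (i in seq_len(nrow(elig))) {
    ast[i] <- baseline_lab(elig$patient_id[i], elig$nafld_date[i], "AST")
    alt[i] <- baseline_lab(elig$patient_id[i], elig$nafld_date[i], "ALT")
    plt[i] <- baseline_lab(elig$patient_id[i], elig$nafld_date[i],
                           "platelets")
  }
  sub <- assignment[match(elig$patient_id, names(assignment))]
  data.frame(patient_id = elig$patient_id,
             subtype = stats::relevel(factor(sub), ref = "1"),
             age = age,
             gender = factor(pt$sex),
             race = factor(race),
             fib4 = fib4_category(age, ast, alt, plt),
             stringsAsFactors = FALSE)
}

#' Subtype hazard models for every outcome
#'
#' Univariate (subtype only) and multivariate (subtype + age + gender +
#' race + FIB-4) models: Cox for overall survival, Fine-Gray with death
#' as the competing hazard for non-death outcomes; prevalent cases are
#' excluded.
#'
#' @param tte a `tte_table` from [build_outcome_table()].
#' @param covariates from [build_covariates()].
#' @param outcomes outcome names to fit (default all present).
#' @param multivariate include the secondary predictors.
#' @return named list of `hazard_fit` objects (one per outcome).
#' @export
fit_outcome_models <- function(tte, covariates, outcomes = NULL,
                               multivariate = FALSE) {
  outcomes <- outcomes %||% unique(tte$outcome)
  fits <- list()
  for (oc in outcomes) {
    rows <- tte[tte$outcome == oc & !tte$prevalent, , drop = FALSE]
    cov <- covariates[match(rows$patient_id, covariates$patient_id), ,
                      drop = FALSE]
    keep <- !is.na(cov$subtype)
    rows <- rows[keep, , drop = FALSE]; cov <- cov[keep, , drop = FALSE]
    X <- stats::model.matrix(
      if (multivariate) ~ subtype + age + gender + race + fib4
      else ~ subtype, data = cov)[, -1L, drop = FALSE]
    fits[[oc]] <- tryCatch({
      if (oc == "death")
        cox_ph(rows$time, as.integer(rows$event == 1L), X)
      else
        fine_gray(rows$time, rows$event, X)
    }, error = function(e) {
      structure(data.frame(), model = "failed", converged = FALSE,
                error = conditionMessage(e),
                class = c("hazard_fit", "data.frame"))
    })
  }
  fits
}
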