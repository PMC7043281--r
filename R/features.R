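# Binary clinical featurization of an eligible cohort: demographic bins,
# phecode diagnoses, CPT procedure groups, persistent medications,
# abnormal labs, abnormal vitals.

#' Mapping tables used by the featurizer
#'
#' @param icd_to_phecode data.frame (`system`, `code`, `phecode`,
#'   `phecode_label`).
#' @param cpt_groups data.frame of non-overlapping numeric ranges
#'   (`start`, `end`, `group`).
#' @param drug_to_ingredient data.frame (`drug_name`, `ingredient`).
#' @param lab_reference data.frame (`test_name`, `ref_low`, `ref_high`)
#'   used when a result row lacks its own range.
#' @return object of class `mapping_tables`. Defaults are the shipped
#'   synthetic fixtures (small editable stand-ins for the full PheWAS,
#'   CPT and RxNorm vocabularies).
#' @export
mapping_tables <- function(icd_to_phecode = NULL, cpt_groups = NULL,
                           drug_to_ingredient = NULL, lab_reference = NULL) {
  if (is.null(icd_to_phecode))
    icd_to_phecode <- read_csv_strict(
      pkg_extdata("icd_phecode_map_synthetic.csv"),
      colClasses = "character")
  if (is.null(cpt_groups))
    cpt_groups <- read_csv_strict(pkg_extdata("cpt_groups_synthetic.csv"))
  if (is.null(drug_to_ingredient))
    drug_to_ingredient <- read_csv_strict(
      pkg_extdata("drug_ingredient_map_synthetic.csv"))
  if (is.null(lab_reference))
    lab_reference <- read_csv_strict(
      pkg_extdata("lab_reference_synthetic.csv"))
  o <- order(cpt_groups$start)
  cpt_groups <- cpt_groups[o, , drop = FALSE]
  if (any(cpt_groups$start > cpt_groups$end))
    stop_config("CPT ranges must have start <= end")
  if (nrow(cpt_groups) > 1L &&
      any(cpt_groups$start[-1L] <= cpt_groups$end[-nrow(cpt_groups)]))
    stop_config("CPT ranges must not overlap")
  structure(list(icd_to_phecode = icd_to_phecode, cpt_groups = cpt_groups,
                 drug_to_ingredient = drug_to_ingredient,
                 lab_reference = lab_reference),
            class = "mapping_tables")
}

#' Age-group indicator features
#'
#' Ten mutually exclusive bins:
#' 18-20, 21-30, 31-40, 41-50, 51-60, 61-70, 71-80, 81-90, 91-100, 101+.
#'
#' @param age numeric vector of ages (years) at the NAFLD diagnosis date;
#'   all must be >= 18.
#' @return binary matrix, one row per age, one column per bin.
#' @export
age_bin_features <- function(age) {
  if (any(is.na(age)) || any(age < 18))
    stop("age must be known and >= 18 for age binning")
  breaks <- c(18, 21, 31, 41, 51, 61, 71, 81, 91, 101, Inf)
  labels <- c("age_18_20", "age_21_30", "age_31_40", "age_41_50",
              "age_51_60", "age_61_70", "age_71_80", "age_81_90",
              "age_91_100", "age_101_plus")
  idx <- findInterval(age, breaks)
  m <- matrix(0L, length(age), length(labels),
              dimnames = list(NULL, labels))
  m[cbind(seq_along(age), idx)] <- 1L
  m
}

# shared: binary patient x column matrix from (patient, column) pairs
binary_incidence <- function(pids, patients, cols) {
  if (length(pids) == 0L) cols <- character(0)  # paste0 pads empties to ""
  levels_c <- sort(unique(cols))
  m <- matrix(0L, length(patients), length(levels_c),
              dimnames = list(patients, levels_c))
  if (length(pids))
    m[cbind(match(pids, patients), match(cols, levels_c))] <- 1L
  m
}

prevalence_filter <- function(m, min_prevalence) {
  if (ncol(m) == 0L) return(m)
  keep <- colMeans(m) >= min_prevalence
  m[, keep, drop = FALSE]
}

#' Phecode diagnosis features
#'
#' Maps ICD-9/10 events to phecodes and flags a patient for every phecode
#' with at least one mapped event; phecode columns below the cohort
#' prevalence floor are dropped. Unmapped codes are reported via the
#' `unmapped` attribute, not an error.
#'
#' @param code_events coded events for the cohort (`patient_id`, `system`,
#'   `code`).
#' @param patients ordered patient ids defining the rows.
#' @param mappings a [mapping_tables()].
#' @param min_prevalence minimum column mean to keep (default 0.001, i.e.
#'   at least 0.1% prevalence).
#' @return binary matrix with `phecode_<code>` columns.
#' @export
phecode_features <- function(code_events, patients, mappings,
                             min_prevalence = 0.001) {
  icd <- code_events[code_events$system %in% c("ICD9", "ICD10"), ,
                     drop = FALSE]
  map <- mappings$icd_to_phecode
  idx <- match(paste(icd$system, icd$code),
               paste(map$system, map$code))
  unmapped <- sort(unique(paste(icd$system[is.na(idx)],
                                icd$code[is.na(idx)])))
  hit <- !is.na(idx)
  m <- binary_incidence(icd$patient_id[hit], patients,
                        paste0("phecode_", map$phecode[idx[hit]]))
  m <- prevalence_filter(m, min_prevalence)
  attr(m, "unmapped") <- unmapped
  m
}

#' CPT second-level procedure-group features
#'
#' Each CPT event is assigned to its numeric range group (e.g. codes
#' 33010-37799 are cardiovascular-system surgery); one binary column per
#' group observed in the cohort. Codes outside every range are reported
#' via the `ungrouped` attribute.
#'
#' @inheritParams phecode_features
#' @return binary matrix with `cpt_<group>` columns.
#' @export
cpt_group_features <- function(code_events, patients, mappings) {
  cpt <- code_events[code_events$system == "CPT", , drop = FALSE]
  num <- suppressWarnings(as.numeric(cpt$code))
  rng <- mappings$cpt_groups
  grp_i <- findInterval(num, rng$start)
  ok <- !is.na(num) & grp_i >= 1L & num <= rng$end[pmax(grp_i, 1L)]
  attr_out <- sort(unique(cpt$code[!ok]))
  m <- binary_incidence(cpt$patient_id[ok], patients,
                        paste0("cpt_", rng$group[grp_i[ok]]))
  attr(m, "ungrouped") <- attr_out
  m
}

#' Persistent-medication features
#'
#' Medication names are mapped to ingredient concepts; an ingredient is
#' flagged for a patient only when two or more orders are separated by at
#' least 183 days (6 months), discarding acutely-used drugs. Prevalence
#' filtering is applied to the resulting columns.
#'
#' @param med_orders medication orders (`patient_id`, `date`,
#'   `drug_name`).
#' @inheritParams phecode_features
#' @return binary matrix with `med_<ingredient>` columns; unmapped drug
#'   names in the `unmapped` attribute.
#' @export
medication_features <- function(med_orders, patients, mappings,
                                min_prevalence = 0.001) {
  map <- mappings$drug_to_ingredient
  ing <- map$ingredient[match(tolower(med_orders$drug_name),
                              tolower(map$drug_name))]
  unmapped <- sort(unique(med_orders$drug_name[is.na(ing)]))
  ok <- !is.na(ing)
  orders <- med_orders[ok, , drop = FALSE]
  orders$ingredient <- ing[ok]
  persistent <- pid_ing <- character()
  if (nrow(orders)) {
    key <- paste(orders$patient_id, orders$ingredient, sep = "\r")
    d <- as.integer(as_date_strict(orders$date, "medication date"))
    span <- tapply(d, key, function(x) diff(range(x)))
    persistent <- names(span)[span >= 183L]
  }
  parts <- strsplit(persistent, "\r", fixed = TRUE)
  m <- binary_incidence(vapply(parts, `[[`, character(1L), 1L), patients,
                        paste0("med_", vapply(parts, `[[`, character(1L),
                                              2L)))
  m <- prevalence_filter(m, min_prevalence)
  attr(m, "unmapped") <- unmapped
  m
}

#' Abnormal laboratory features
#'
#' One binary column per lab test: flagged when any qualitative result
#' matches an abnormal term (abnormal, low, below average, reactive, ...)
#' or any numeric value falls strictly outside the reference range (row
#' range first, then the reference map). A value exactly on a bound
#' counts as normal. Numeric tests with no range anywhere are omitted and
#' reported via the `omitted` attribute.
#'
#' @param lab_results lab rows (`patient_id`, `test_name`, `value_text`,
#'   `value_num`, `ref_low`, `ref_high`).
#' @inheritParams phecode_features
#' @param abnormal_terms character vector of qualitative abnormal terms;
#'   defaults to the shipped list.
#' @return binary matrix with `lab_<test>` columns.
#' @export
lab_abnormal_features <- function(lab_results, patients, mappings,
                                  abnormal_terms = NULL) {
  if (is.null(abnormal_terms))
    abnormal_terms <- read_csv_strict(
      pkg_extdata("abnormal_lab_terms.csv"))$term
  labs <- lab_results
  ref <- mappings$lab_reference
  mref <- match(labs$test_name, ref$test_name)
  low <- ifelse(is.na(labs$ref_low), ref$ref_low[mref], labs$ref_low)
  high <- ifelse(is.na(labs$ref_high), ref$ref_high[mref], labs$ref_high)
  pat <- paste0("\\b(", paste(escape_regex(tolower(abnormal_terms)),
                              collapse = "|"), ")\\b")
  qual_abn <- !is.na(labs$value_text) & nzchar(labs$value_text) &
    grepl(pat, tolower(labs$value_text), perl = TRUE)
  has_num <- !is.na(labs$value_num)
  has_rng <- !is.na(low) & !is.na(high)
  num_abn <- has_num & has_rng &
    (labs$value_num < low | labs$value_num > high)
  # numeric-only results with no range anywhere cannot be judged
  orphan <- has_num & !has_rng & !qual_abn
  omitted <- setdiff(unique(labs$test_name[orphan]),
                     unique(labs$test_name[(qual_abn | num_abn) |
                                           (has_num & has_rng)]))
  abn <- (qual_abn | num_abn) & !(labs$test_name %in% omitted)
  m <- binary_incidence(labs$patient_id[abn], patients,
                        paste0("lab_", gsub("[^[:alnum:]]+", "_",
                                            labs$test_name[abn])))
  attr(m, "omitted") <- sort(omitted)
  m
}

#' Abnormal vital-sign features
#'
#' Five binary flags: body temperature > 39 deg C (or > 102 deg F,
#' applied in the recorded unit); blood pressure abnormal when
#' SBP > 130 or DBP > 80; heart rate > 130 bpm; respiratory rate > 40;
#' pain score of 9 or 10. One abnormal measurement suffices.
#'
#' @param vitals vital rows (`patient_id`, `kind`, `value`, `unit`); kinds
#'   are `temperature`, `sbp`, `dbp`, `heart_rate`, `respiratory_rate`,
#'   `pain`.
#' @inheritParams phecode_features
#' @return binary matrix with columns `vital_temperature`, `vital_bp`,
#'   `vital_heart_rate`, `vital_respiratory_rate`, `vital_pain`.
#' @export
vital_abnormal_features <- function(vitals, patients) {
  v <- vitals
  abn <- rep(FALSE, nrow(v))
  is_temp <- v$kind == "temperature"
  abn[is_temp & v$unit == "C" & v$value > 39] <- TRUE
  abn[is_temp & v$unit == "F" & v$value > 102] <- TRUE
  abn[v$kind == "sbp" & v$value > 130] <- TRUE
  abn[v$kind == "dbp" & v$value > 80] <- TRUE
  abn[v$kind == "heart_rate" & v$value > 130] <- TRUE
  abn[v$kind == "respiratory_rate" & v$value > 40] <- TRUE
  abn[v$kind == "pain" & v$value %in% c(9, 10)] <- TRUE
  feature <- ifelse(v$kind %in% c("sbp", "dbp"), "vital_bp",
                    paste0("vital_", v$kind))
  cols <- c("vital_temperature", "vital_bp", "vital_heart_rate",
            "vital_respiratory_rate", "vital_pain")
  m <- matrix(0L, length(patients), length(cols),
              dimnames = list(patients, cols))
  hit <- abn & feature %in% cols
  if (any(hit))
    m[cbind(match(v$patient_id[hit], patients),
            match(feature[hit], cols))] <- 1L
  m
}

#' Assemble the cohort feature matrix
#'
#' Runs every feature block for the eligible patients and concatenates
#' them column-wise with provenance metadata, in deterministic order
#' (domain, then feature name).
#'
#' @param bundle an `emr_bundle`.
#' @param decisions output of [classify_cohort()]; only eligible patients
#'   enter the matrix.
#' @param mappings a [mapping_tables()].
#' @param min_prevalence prevalence floor for phecode and medication
#'   columns.
#' @return object of class `feature_matrix`: list with `values` (binary
#'   patients x features matrix), `patients`, `features` (data.frame
#'   `name`, `domain`), and a `log` of unmapped/omitted inputs.
#' @export
build_feature_matrix <- function(bundle, decisions,
                                 mappings = mapping_tables(),
                                 min_prevalence = 0.001) {
  elig <- decisions[decisions$eligible, , drop = FALSE]
  pids <- elig$patient_id
  if (length(pids) == 0L) stop("no eligible patients to featurize")
  sub <- function(tab) tab[tab$patient_id %in% pids, , drop = FALSE]

  pt <- bundle$patients[match(pids, bundle$patients$patient_id), ,
                        drop = FALSE]
  age <- as.numeric(elig$nafld_date - pt$birth_date) / 365.25
  demo_age <- age_bin_features(age)
  sexf <- cbind(sex_female = as.integer(pt$sex == "F"))
  race <- ifelse(pt$ethnicity == "Hispanic", "Hispanic", pt$race)
  race_m <- binary_incidence(pids, pids, paste0("race_", race))

  blocks <- list(
    demographic = cbind(demo_age, sexf, race_m),
    diagnosis = phecode_features(sub(bundle$code_events), pids, mappings,
                                 min_prevalence),
    procedure = cpt_group_features(sub(bundle$code_events), pids, mappings),
    medication = medication_features(sub(bundle$med_orders), pids, mappings,
                                     min_prevalence),
    lab = lab_abnormal_features(sub(bundle$lab_results), pids, mappings),
    vital = vital_abnormal_features(sub(bundle$vitals), pids))

  log <- list(
    unmapped_codes = attr(blocks$diagnosis, "unmapped"),
    ungrouped_cpt = attr(blocks$procedure, "ungrouped"),
    unmapped_drugs = attr(blocks$medication, "unmapped"),
    omitted_labs = attr(blocks$lab, "omitted"))

  feats <- do.call(rbind, lapply(names(blocks), function(dm)
    data.frame(name = colnames(blocks[[dm]]) %||% character(),
               domain = dm, stringsAsFactors = FALSE)))
  if (anyDuplicated(feats$name))
    stop("duplicate feature names across blocks: ",
         paste(feats$name[duplicated(feats$name)], collapse = ", "))
  values <- do.call(cbind, blocks)
  # deterministic order: domain then name
  o <- order(feats$domain, feats$name)
  feats <- feats[o, , drop = FALSE]
  values <- values[, feats$name, drop = FALSE]
  rownames(values) <- pids
  rownames(feats) <- NULL
  storage.mode(values) <- "integer"
  structure(list(values = values, patients = pids, features = feats,
                 log = log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d binary features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$features$domain))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write a feature matrix to disk
#'
#' Writes a dense CSV and a sparse Matrix-Market file with separate
#' row/column name files.
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- file.path(dir, "features_dense.csv")
  utils::write.csv(data.frame(patient_id = fm$patients, fm$values,
                              check.names = FALSE),
                   dense, row.names = FALSE)
  mtx <- file.path(dir, "features.mtx")
  Matrix::writeMM(Matrix::Matrix(fm$values, sparse = TRUE), mtx)
  writeLines(fm$patients, file.path(dir, "features_rows.txt"))
  writeLines(colnames(fm$values), file.path(dir, "features_cols.txt"))
  utils::write.csv(fm$features, file.path(dir, "features_meta.csv"),
                   row.names = FALSE)
  invisible(c(dense, mtx))
}
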