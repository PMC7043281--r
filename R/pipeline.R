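# Pipeline orchestration and shared readers/writers. Tables travel as
# CSV (ISO-8601 dates, UTF-8); documents as JSON-lines; configs and
# manifests as JSON.

#' Write an EMR bundle to a directory
#'
#' One CSV per table plus a JSON-lines `documents.jsonl`.
#'
#' @param bundle an `emr_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_emr_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(bundle), "documents")) {
    df <- bundle[[nm]]
    for (cl in names(df))
      if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]])
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  docs <- bundle$documents
  con <- file(file.path(dir, "documents.jsonl"), open = "w",
              encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = docs$patient_id[i], date = format(docs$date[i]),
      doc_type = docs$doc_type[i], text = docs$text[i]),
      auto_unbox = TRUE), con)
  }
  invisible(dir)
}

#' Read an EMR bundle from a directory
#'
#' Inverse of [write_emr_bundle()]; malformed dates raise an error naming
#' the offending row.
#'
#' @param dir directory containing the bundle files.
#' @return an `emr_bundle`.
#' @export
read_emr_bundle <- function(dir) {
  read_tab <- function(nm, date_cols, classes = NA) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing bundle table: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = classes)
    for (cl in date_cols)
      df[[cl]] <- as_date_strict(df[[cl]], paste0(nm, ".", cl))
    df
  }
  docs_path <- file.path(dir, "documents.jsonl")
  lines <- if (file.exists(docs_path)) readLines(docs_path,
                                                 encoding = "UTF-8")
           else character()
  docs <- if (length(lines)) {
    parsed <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("malformed documents.jsonl at line ", i,
                             call. = FALSE))
      data.frame(patient_id = rec$patient_id, date = rec$date,
                 doc_type = rec$doc_type, text = rec$text,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parsed)
    out$date <- as_date_strict(out$date, "documents.date")
    out
  } else {
    data.frame(patient_id = character(), date = as.Date(character()),
               doc_type = character(), text = character(),
               stringsAsFactors = FALSE)
  }
  bundle <- list(
    patients = read_tab("patients", c("birth_date", "death_date")),
    code_events = read_tab("code_events", "date",
                           classes = c(code = "character")),
    med_orders = read_tab("med_orders", "date"),
    lab_results = read_tab("lab_results", "date"),
    vitals = read_tab("vitals", "date"),
    documents = docs)
  class(bundle) <- "emr_bundle"
  bundle
}

stage_manifest <- function(dir, stage, seed, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage, seed = seed,
                   package_version =
                     as.character(utils::packageVersion("nafldsubtypes")),
                   input_md5 = hashes)
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Default pipeline configuration
#'
#' @param n_patients cohort size for the simulation stage.
#' @param master_seed master seed; every randomized stage uses a seed
#'   derived deterministically from it and the stage name.
#' @param k number of subtypes.
#' @param fdr_threshold profiling significance threshold.
#' @param stability_repeats,stability_fraction validation-stage protocol.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 500L, master_seed = 1L, k = 5L,
                            fdr_threshold = 0.001,
                            stability_repeats = 10L,
                            stability_fraction = 0.9) {
  if (k < 2L) stop_config("k must be >= 2")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_config("fdr_threshold must be in (0,1)")
  structure(list(n_patients = as.integer(n_patients),
                 master_seed = as.integer(master_seed), k = as.integer(k),
                 fdr_threshold = fdr_threshold,
                 stability_repeats = as.integer(stability_repeats),
                 stability_fraction = stability_fraction),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate -> phenotype -> featurize -> cluster -> profile -> survival ->
#' validate, writing each stage's artifacts and a manifest (stage, seed,
#' input hashes) under `out_dir`. Rerunning with the same configuration
#' and master seed reproduces the deterministic stage outputs exactly.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @param out_dir artifact directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_nafld_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # simulate
  sim_seed <- stage_seed(config$master_seed, "simulate")
  sim <- generate_cohort(cohort_config(config$n_patients, seed = sim_seed))
  bdir <- file.path(out_dir, "bundle")
  write_emr_bundle(sim$bundle, bdir)
  truth <- sim$truth
  truth$index_date <- format(truth$index_date)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  stage_manifest(out_dir, "simulate", sim_seed)

  # phenotype
  decisions <- classify_cohort(sim$bundle)
  dec_out <- as.data.frame(decisions)
  dec_out$nafld_date <- format(dec_out$nafld_date)
  utils::write.csv(dec_out, file.path(out_dir, "decisions.csv"),
                   row.names = FALSE, na = "")
  stage_manifest(out_dir, "phenotype", NA,
                 file.path(bdir, "patients.csv"))

  # featurize
  fm <- build_feature_matrix(sim$bundle, decisions)
  write_feature_matrix(fm, file.path(out_dir, "features"))
  stage_manifest(out_dir, "featurize", NA,
                 file.path(out_dir, "decisions.csv"))

  # cluster
  cl <- cluster_subtypes(fm, k = config$k)
  utils::write.csv(data.frame(patient_id = names(cl$assignment),
                              subtype = unname(cl$assignment)),
                   file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  export_dendrogram(cl$dendrogram,
                    newick_file = file.path(out_dir, "dendrogram.nwk"),
                    merge_file = file.path(out_dir, "dendrogram_merges.csv"))
  stage_manifest(out_dir, "cluster", NA,
                 file.path(out_dir, "features", "features_dense.csv"))

  # profile
  profile <- profile_subtypes(fm, cl$assignment, config$fdr_threshold)
  utils::write.csv(as.data.frame(profile),
                   file.path(out_dir, "subtype_profiles.csv"),
                   row.names = FALSE)
  stage_manifest(out_dir, "analyze", NA,
                 file.path(out_dir, "assignments.csv"))

  # survival
  tte <- build_outcome_table(sim$bundle, decisions)
  covs <- build_covariates(sim$bundle, decisions, cl$assignment)
  fits <- fit_outcome_models(tte, covs)
  utils::write.csv(as.data.frame(tte), file.path(out_dir, "tte_table.csv"),
                   row.names = FALSE)
  fit_rows <- do.call(rbind, lapply(names(fits), function(oc) {
    f <- fits[[oc]]
    if (!nrow(f)) return(NULL)
    cbind(outcome = oc, model = attr(f, "model"), as.data.frame(f))
  }))
  if (!is.null(fit_rows))
    utils::write.csv(fit_rows, file.path(out_dir, "hazard_fits.csv"),
                     row.names = FALSE)
  dth <- tte[tte$outcome == "death", , drop = FALSE]
  utils::write.csv(kaplan_meier(dth$time, as.integer(dth$event == 1L)),
                   file.path(out_dir, "km_death.csv"), row.names = FALSE)
  stage_manifest(out_dir, "survival", NA,
                 file.path(out_dir, "assignments.csv"))

  # validate
  val_seed <- stage_seed(config$master_seed, "validate")
  stability <- subsample_and_recluster(
    fm, k = config$k, fraction = config$stability_fraction,
    repeats = config$stability_repeats, seed = val_seed,
    fdr_threshold = config$fdr_threshold)
  utils::write.csv(as.data.frame(stability),
                   file.path(out_dir, "stability.csv"), row.names = FALSE)
  stage_manifest(out_dir, "validate", val_seed,
                 file.path(out_dir, "assignments.csv"))

  invisible(list(simulation = sim, decisions = decisions, features = fm,
                 clustering = cl, profile = profile, tte = tte,
                 covariates = covs, fits = fits, stability = stability))
}
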