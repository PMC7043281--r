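# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic per-stage seed derived from a master seed; keeps every
# randomized stage reproducible while decorrelating streams across stages.
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647L)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonmiss <- !is.na(x) & nzchar(as.character(x))
  parsed <- as.Date(as.character(x[nonmiss]), format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonmiss)[is.na(parsed)]
    stop(sprintf("malformed %s at row %d: '%s'", what, bad[1L],
                 as.character(x)[bad[1L]]), call. = FALSE)
  }
  out[nonmiss] <- parsed
  out
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "nafldsubtypes",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    # during development (pkgload) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("missing packaged resource: ", file)
  path
}

read_csv_strict <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("nafld_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
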