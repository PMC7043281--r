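# Descriptive subtype profiling: each subtype versus all remaining
# patients, chi-squared for binary features, ANOVA / Wilcoxon for
# continuous summaries, Benjamini-Hochberg FDR control.

#' Pearson chi-squared test for a 2x2 table
#'
#' No continuity correction; p-value from the upper tail of the
#' chi-squared distribution with 1 degree of freedom. Degenerate tables
#' (a zero row or column margin) return `NA` statistics with a flag.
#'
#' @param a,b,c,d cell counts: rows = group (in/out of subtype),
#'   columns = feature present/absent.
#' @return list `statistic`, `p`, `degenerate`.
#' @export
two_by_two_chi_squared <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       degenerate = FALSE)
}

#' One-way ANOVA F test
#'
#' Classical equal-variance one-way F statistic across groups.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 levels).
#' @return list `statistic`, `p`, `degenerate` (constant data).
#' @export
anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two groups")
  if (stats::var(values) == 0)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p = unname(ft$p.value),
       degenerate = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Normal approximation with tie correction (no continuity correction, so
#' the statistic matches direct rank computation exactly).
#'
#' @param x,y numeric samples (both non-empty).
#' @return list `statistic` (W, number of (x, y) pairs with x > y counting
#'   ties as 1/2), `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, capped at 1 and monotone non-decreasing in the
#' order of sorted p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Profile subtypes against the rest of the cohort
#'
#' For every binary feature and every subtype, compares feature prevalence
#' inside the subtype against all remaining patients with a 2x2
#' chi-squared test; q-values are Benjamini-Hochberg adjusted across all
#' tests in the run (all subtypes jointly). Constant features are excluded
#' from testing and reported in the `excluded` attribute.
#'
#' @param fm a `feature_matrix` or binary matrix.
#' @param assignment integer subtype labels, one per matrix row.
#' @param fdr_threshold significance threshold on the q-value
#'   (default 0.001).
#' @return object of class `subtype_profile`: data.frame with columns
#'   `subtype`, `feature`, `prop_in`, `prop_out`, `statistic`, `p`, `q`,
#'   `significant`.
#' @export
profile_subtypes <- function(fm, assignment, fdr_threshold = 0.001) {
  m <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (length(assignment) != nrow(m))
    stop("assignment must cover every matrix row")
  cm <- colMeans(m)
  constant <- colnames(m)[cm %in% c(0, 1)]
  test_cols <- setdiff(colnames(m), constant)
  subtypes <- sort(unique(assignment))
  rows <- list()
  for (s in subtypes) {
    inside <- assignment == s
    n_in <- sum(inside); n_out <- sum(!inside)
    cs_in <- colSums(m[inside, test_cols, drop = FALSE])
    cs_out <- colSums(m[!inside, test_cols, drop = FALSE])
    for (j in seq_along(test_cols)) {
      a <- cs_in[j]; b <- n_in - cs_in[j]
      cc <- cs_out[j]; dd <- n_out - cs_out[j]
      ct <- two_by_two_chi_squared(a, b, cc, dd)
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, feature = test_cols[j],
        prop_in = a / n_in, prop_out = cc / n_out,
        statistic = ct$statistic, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr_threshold
  attr(out, "excluded") <- constant
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("subtype_profile", "data.frame")
  out
}

#' @export
print.subtype_profile <- function(x, n = 5L, ...) {
  cat(sprintf("Subtype profile: %d tests, %d significant at q < %g\n",
              nrow(x), sum(x$significant, na.rm = TRUE),
              attr(x, "fdr_threshold")))
  for (s in sort(unique(x$subtype))) {
    sub <- x[x$subtype == s & x$significant, , drop = FALSE]
    sub <- sub[order(sub$q, -abs(sub$prop_in - sub$prop_out)), ,
               drop = FALSE]
    cat(sprintf("\nSubtype %s: %d enriched/depleted features; top %d:\n",
                s, nrow(sub), min(n, nrow(sub))))
    if (nrow(sub))
      print(utils::head(data.frame(feature = sub$feature,
                                   in_pct = round(100 * sub$prop_in, 1),
                                   out_pct = round(100 * sub$prop_out, 1),
                                   q = signif(sub$q, 3)), n),
            row.names = FALSE)
  }
  invisible(x)
}

#' Significant feature sets per subtype
#'
#' @param profile a `subtype_profile`.
#' @return named list: subtype -> character vector of significant features.
#' @export
enriched_features <- function(profile) {
  subtypes <- sort(unique(profile$subtype))
  stats::setNames(lapply(subtypes, function(s)
    sort(profile$feature[profile$subtype == s & profile$significant])),
    as.character(subtypes))
}
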