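# Internal cross-validation of clustering robustness: repeated 90%
# subsampling, reclustering, adjusted-Rand agreement with the full-cohort
# cut, and Jaccard overlap of the enriched-feature sets per subtype.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement, computed with
#' `mclust::adjustedRandIndex`.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]` (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# optimal matching of repeat clusters to full-run clusters by maximal
# overlap: exhaustive over permutations (k is small; the default is 5)
match_clusters <- function(labels_rep, labels_full) {
  ks <- sort(unique(labels_full))
  overlap <- table(factor(labels_rep, levels = ks),
                   factor(labels_full, levels = ks))
  perms <- all_permutations(length(ks))
  best <- NULL; best_score <- -Inf
  for (p in perms) {
    score <- sum(overlap[cbind(seq_along(ks), p)])
    if (score > best_score) { best_score <- score; best <- p }
  }
  stats::setNames(ks[best], ks)  # repeat label -> matched full label
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' Cluster-stability report by repeated subsampling
#'
#' Mirrors the internal cross-validation protocol: draw `repeats` random
#' subsamples of `fraction` of the cohort without replacement, rerun the
#' whole clustering stage (distances, Ward linkage, k-cut) and the
#' subtype profiling on each, and compare with the full-cohort run via
#' (i) the adjusted Rand index on the shared patients and (ii) the
#' Jaccard overlap of each subtype's significant-feature set after
#' optimal (maximum-overlap) cluster matching.
#'
#' @param fm a `feature_matrix` (or binary matrix with rownames).
#' @param k number of subtypes.
#' @param fraction subsample fraction (default 0.9).
#' @param repeats number of subsamples (default 10).
#' @param seed RNG seed for the subsample draws.
#' @param fdr_threshold profiling significance threshold.
#' @return object of class `stability_report`: data.frame with one row
#'   per repeat (`repeat_id`, `seed`, `n`, `ari`, `mean_jaccard`,
#'   `degenerate`), plus attributes `jaccard` (repeats x k matrix) and
#'   `summary` (means and sds).
#' @export
subsample_and_recluster <- function(fm, k = 5L, fraction = 0.9,
                                    repeats = 10L, seed = 1L,
                                    fdr_threshold = 0.001) {
  m <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(m)
  if (n * fraction < k) stop("subsample too small for k clusters")
  full <- cluster_subtypes(m, k)
  full_labels <- full$assignment
  full_profile <- profile_subtypes(m, full_labels, fdr_threshold)
  full_sets <- enriched_features(full_profile)

  rows <- vector("list", repeats)
  jac <- matrix(NA_real_, repeats, k,
                dimnames = list(NULL, paste0("subtype_", seq_len(k))))
  for (r in seq_len(repeats)) {
    rep_seed <- stage_seed(seed, paste0("stability_repeat_", r))
    idx <- with_seed(rep_seed,
                     sort(sample.int(n, size = round(fraction * n))))
    sub_m <- m[idx, , drop = FALSE]
    degenerate <- FALSE
    res <- tryCatch({
      cl <- cluster_subtypes(sub_m, k)
      ari <- adjusted_rand(cl$assignment, full_labels[idx])
      prof <- profile_subtypes(sub_m, cl$assignment, fdr_threshold)
      sets <- enriched_features(prof)
      mapping <- match_clusters(cl$assignment, full_labels[idx])
      jrow <- vapply(seq_len(k), function(s) {
        matched <- as.character(mapping[as.character(s)])
        jaccard(sets[[as.character(s)]], full_sets[[matched]])
      }, numeric(1L))
      list(ari = ari, jrow = jrow)
    }, error = function(e) {
      degenerate <<- TRUE
      list(ari = NA_real_, jrow = rep(NA_real_, k))
    })
    jac[r, ] <- res$jrow
    rows[[r]] <- data.frame(repeat_id = r, seed = rep_seed,
                            n = length(idx), ari = res$ari,
                            mean_jaccard = mean(res$jrow, na.rm = TRUE),
                            degenerate = degenerate)
  }
  out <- do.call(rbind, rows)
  attr(out, "jaccard") <- jac
  attr(out, "summary") <- list(
    ari_mean = mean(out$ari, na.rm = TRUE),
    ari_sd = stats::sd(out$ari, na.rm = TRUE),
    jaccard_mean = mean(jac, na.rm = TRUE),
    jaccard_sd = stats::sd(jac, na.rm = TRUE))
  class(out) <- c("stability_report", "data.frame")
  out
}

#' @export
print.stability_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Cluster stability over %d subsamples: ARI %.3f +/- %.3f, enriched-feature Jaccard %.3f +/- %.3f\n",
    nrow(x), s$ari_mean, s$ari_sd, s$jaccard_mean, s$jaccard_sd))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
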