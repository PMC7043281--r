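# Patient clustering: Manhattan distances + agglomerative Ward-criterion
# linkage (ward.D2 semantics: Lance-Williams recurrence on squared
# dissimilarities, merge heights reported as square roots), cut at k
# clusters labeled in decreasing size order.
#
# The linkage is implemented here rather than delegated so that the merge
# order under ties is fully specified (smallest (left, right) active-slot
# pair); binary-feature Manhattan distances tie constantly.

#' Manhattan distance matrix between patients
#'
#' On binary features the Manhattan distance is the Hamming count of
#' discordant features.
#'
#' @param x a `feature_matrix` or a numeric matrix (patients in rows).
#' @return a `stats::dist` object.
#' @export
manhattan_distances <- function(x) {
  m <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("cannot compute distances on an empty matrix")
  stats::dist(m, method = "manhattan")
}

#' Agglomerative clustering with the Ward criterion (D2 semantics)
#'
#' Applies the Lance-Williams recurrence with Ward coefficients
#' alpha_i = (n_i + n_k) / (n_i + n_j + n_k),
#' beta = -n_k / (n_i + n_j + n_k), gamma = 0 to the *squared* input
#' dissimilarities; reported merge heights are square roots of the updated
#' squared dissimilarities. With Euclidean input this minimizes the
#' within-cluster variance increase at every merge; here it is applied to
#' Manhattan distances, reproducing the published analysis choice rather
#' than correcting it. Ties are broken by the smallest (left, right)
#' active-slot index pair, making the merge order deterministic.
#'
#' @param d a `stats::dist` object (n >= 2).
#' @return an object of class `c("ward_clust", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components, so that
#'   [stats::cutree()] and `plot()` work.
#' @export
ward_linkage <- function(d) {
  if (!inherits(d, "dist")) stop("d must be a stats::dist object")
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need at least two observations")
  labels <- attr(d, "Labels")
  # squared dissimilarities in a full matrix; only the lower triangle
  # (row > col) is "active" so that column-major which.min scans pairs in
  # (left, right) lexicographic order: pair (i < j) is stored at [j, i].
  S <- as.matrix(d)^2
  S[upper.tri(S, diag = TRUE)] <- Inf
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  # slot -> merge-tree node id: negative = leaf, positive = merge row
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- which.min(S)   # column-major => smallest (col=left, row=right)
    j <- ((best - 1L) %% n) + 1L   # row (right slot)
    i <- ((best - 1L) %/% n) + 1L  # col (left slot)
    h2 <- S[j, i]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- sqrt(h2)
    ni <- sizes[i]; nj <- sizes[j]
    # Lance-Williams update for every other active slot k
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      dik <- S[cbind(pmax(ks, i), pmin(ks, i))]
      djk <- S[cbind(pmax(ks, j), pmin(ks, j))]
      nk <- sizes[ks]
      newd <- ((ni + nk) * dik + (nj + nk) * djk - nk * h2) /
        (ni + nj + nk)
      lo <- pmin(ks, i); hi <- pmax(ks, i)
      S[cbind(hi, lo)] <- newd
    }
    # deactivate slot j
    S[j, ] <- Inf; S[, j] <- Inf
    active[j] <- FALSE
    sizes[i] <- ni + nj
    node[i] <- step
  }
  order <- dendrogram_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "ward.D2 (package)",
                 dist.method = "manhattan",
                 call = match.call()),
            class = c("ward_clust", "hclust"))
}

# leaf ordering by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram into k clusters labeled by decreasing size
#'
#' Undoes the last k-1 merges; the connected leaf sets are the clusters,
#' relabeled 1..k in decreasing size order (ties broken by the smallest
#' member index), so that cluster 1 is always the largest subtype.
#'
#' @param dend a `ward_clust`/`hclust` object.
#' @param k number of clusters, 1 <= k <= n.
#' @return integer vector of cluster labels (named by patient labels when
#'   available).
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$height) + 1L
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  raw <- stats::cutree(stats::as.hclust(dend), k = k)
  relabel_by_size(raw)
}

relabel_by_size <- function(raw) {
  tab <- table(raw)
  first_member <- tapply(seq_along(raw), raw, min)
  o <- order(-as.integer(tab), as.integer(first_member))
  newlab <- integer(length(tab))
  newlab[o] <- seq_along(tab)
  out <- newlab[match(raw, as.integer(names(tab)))]
  names(out) <- names(raw)
  out
}

#' Cluster NAFLD patients into subtypes
#'
#' End-to-end clustering stage: Manhattan distances over the binary
#' feature matrix, Ward-criterion (D2) agglomeration, cut at `k`
#' subtypes labeled in decreasing size order.
#'
#' @param fm a `feature_matrix` (or plain binary matrix).
#' @param k number of subtypes (default 5).
#' @return object of class `nafld_subtypes`: list with `assignment`
#'   (named integer vector), `k`, `dendrogram` (`ward_clust`), `sizes`.
#' @export
cluster_subtypes <- function(fm, k = 5L) {
  d <- manhattan_distances(fm)
  dend <- ward_linkage(d)
  assignment <- cut_tree(dend, k)
  pats <- if (inherits(fm, "feature_matrix")) fm$patients
          else rownames(fm) %||% as.character(seq_len(nrow(as.matrix(fm))))
  names(assignment) <- pats
  structure(list(assignment = assignment, k = as.integer(k),
                 dendrogram = dend,
                 sizes = as.integer(table(assignment)),
                 call = match.call()),
            class = "nafld_subtypes")
}

#' @export
print.nafld_subtypes <- function(x, ...) {
  cat(sprintf("NAFLD subtype clustering: %d patients in %d subtypes\n",
              length(x$assignment), x$k))
  cat("Subtype sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nafld_subtypes <- function(object, ...) {
  cat(sprintf("Ward-criterion clustering (Manhattan distance), k = %d\n",
              object$k))
  print(data.frame(subtype = seq_along(object$sizes), n = object$sizes,
                   share = round(object$sizes / sum(object$sizes), 3)))
  invisible(object)
}

#' @export
plot.nafld_subtypes <- function(x, ...) {
  plot(stats::as.hclust(x$dendrogram),
       main = "Patient dendrogram (Ward criterion)",
       xlab = "", sub = "", labels = FALSE, ...)
  stats::rect.hclust(stats::as.hclust(x$dendrogram), k = x$k)
  invisible(x)
}

#' Serialize a dendrogram
#'
#' @param dend a `ward_clust`/`hclust`.
#' @param newick_file,merge_file optional output paths: Newick with branch
#'   lengths derived from merge heights, and a merge-table CSV.
#' @return invisibly the Newick string.
#' @export
export_dendrogram <- function(dend, newick_file = NULL, merge_file = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_file)) writeLines(nwk, newick_file)
  if (!is.null(merge_file))
    utils::write.csv(data.frame(left = dend$merge[, 1L],
                                right = dend$merge[, 2L],
                                height = dend$height),
                     merge_file, row.names = FALSE)
  invisible(nwk)
}
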