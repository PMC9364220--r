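# Multivariate exploration: PCA biplots with condition-averaged scores, and
# complete-linkage hierarchical clustering on 1 - Pearson correlation.

#' PCA biplot decomposition with condition-averaged scores
#'
#' Singular value decomposition of the preprocessed matrix (samples x
#' features, already z-scored upstream, so no re-centering is applied):
#' scores = U D, loadings = V (orthonormal), variance fraction of component
#' i = d_i^2 / sum d^2. Scores are additionally averaged within each
#' condition defined by \code{average_by} (e.g. treatment x age), which is
#' how group separation is read off a biplot. Component signs follow the
#' convention that the largest-magnitude loading of each component is
#' positive.
#'
#' @param pm a \code{preprocessed_matrix} or \code{feature_matrix}.
#' @param average_by character vector of sample columns defining conditions.
#' @param n_components number of components to keep.
#' @return object of class \code{pca_result}: \code{scores} (per sample),
#'   \code{condition_scores} (per condition average), \code{loadings},
#'   \code{var_fraction}.
#' @export
pca_biplot <- function(pm, average_by = c("treatment", "age"),
                       n_components = NULL) {
  x <- pm$values
  if (nrow(x) < 2) stop("PCA needs more than one sample")
  if (any(is.na(x))) stop("PCA input must have no missing values")
  if (all(abs(x - mean(x)) < 1e-14))
    stop("degenerate input: matrix is constant")
  sv <- svd(x)
  d2 <- sv$d^2
  var_fraction <- d2 / sum(d2)
  k <- n_components %||% min(dim(x))
  k <- min(k, length(sv$d))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(V) <- pm$feature_id
  colnames(V) <- paste0("PC", seq_len(k))

  cond_scores <- NULL
  av_cols <- intersect(average_by, names(pm$samples))
  if (length(av_cols)) {
    key <- interaction(pm$samples[av_cols], drop = TRUE, sep = ":")
    agg <- apply(scores, 2, function(col) tapply(col, key, mean))
    agg <- matrix(agg, nrow = nlevels(key),
                  dimnames = list(levels(key), colnames(scores)))
    cond_scores <- data.frame(condition = rownames(agg), agg,
                              row.names = NULL, check.names = FALSE)
  }
  structure(list(scores = data.frame(pm$samples, scores,
                                     check.names = FALSE),
                 condition_scores = cond_scores,
                 loadings = V,
                 var_fraction = var_fraction[seq_len(k)],
                 average_by = av_cols),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "features\n")
  vf <- round(100 * x$var_fraction[seq_len(min(3, length(x$var_fraction)))],
              1)
  cat("variance explained:", paste0("PC", seq_along(vf), " ", vf, "%",
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Complete-linkage clustering on 1 - Pearson correlation
#'
#' Items (features or annotated species) are clustered on the distance
#' 1 - Pearson correlation between their profiles across conditions, using
#' furthest-neighbor (complete-linkage) agglomeration. Items with zero
#' profile variance have no defined correlation; they are flagged, excluded
#' from the tree, and assigned the cluster of their nearest valid neighbor
#' by Euclidean distance, with a warning.
#'
#' @param profiles numeric matrix, items in rows, conditions in columns;
#'   row names identify the items.
#' @param k number of clusters to cut.
#' @return object of class \code{cluster_result}: \code{tree} (hclust),
#'   \code{labels} (cluster per item), \code{order} (leaf order for
#'   heatmaps), \code{flagged} (zero-variance items).
#' @export
hca_clusters <- function(profiles, k) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("item", seq_len(nrow(profiles)))
  vr <- apply(profiles, 1, stats::var)
  flagged <- rownames(profiles)[vr < 1e-18 | !is.finite(vr)]
  valid <- setdiff(rownames(profiles), flagged)
  if (length(valid) < k)
    stop("need at least k items with nonzero variance (have ",
         length(valid), ", k = ", k, ")")
  pv <- profiles[valid, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(pv)))
  tree <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(tree, k = k)
  if (length(flagged)) {
    warning("zero-variance item(s) assigned by nearest valid neighbor: ",
            paste(flagged, collapse = ", "))
    for (f in flagged) {
      dd <- colSums((t(pv) - profiles[f, ])^2)
      labels[f] <- labels[names(which.min(dd))]
    }
  }
  structure(list(tree = tree, labels = labels[rownames(profiles)],
                 order = valid[tree$order], k = k, flagged = flagged),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Complete-linkage HCA (1 - Pearson):", length(x$labels), "items,",
      x$k, "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Ordered correlation matrix for heatmap export
#'
#' @param profiles the matrix passed to \code{\link{hca_clusters}}.
#' @param cl the resulting \code{cluster_result}.
#' @return the Pearson correlation matrix of the valid items, reordered by
#'   the dendrogram leaf order.
#' @export
ordered_cor_matrix <- function(profiles, cl) {
  pv <- as.matrix(profiles)[cl$order, , drop = FALSE]
  stats::cor(t(pv))
}
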