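#' Row-wise z-score transformation of a region-by-sample matrix
#'
#' Standardizes each region (row) to mean 0 and SD 1 using the population SD,
#' the form used ahead of unsupervised hierarchical clustering of DMR
#' methylation. Rows with zero variance carry no clustering information and
#' are dropped with a message; their ids are kept in the `dropped` attribute.
#'
#' @param values numeric matrix, regions x samples (>= 2 samples).
#' @return matrix of class `zscore_matrix` with attribute `dropped`.
#' @examples
#' zscore_transform(matrix(c(1, 2, 3), 1, 3,
#'                         dimnames = list("r1", c("a", "b", "c"))))
#' @export
zscore_transform <- function(values) {
  if (is.null(dim(values)) || ncol(values) < 2)
    stop_msg("z-score transformation needs >= 2 samples")
  mu <- rowMeans(values)
  sd_pop <- sqrt(rowMeans((values - mu)^2))
  keep <- sd_pop > 0
  if (any(!keep)) {
    ids <- rownames(values)[!keep] %||% as.character(which(!keep))
    message(sprintf("dropping %d zero-variance row(s): %s",
                    sum(!keep), paste(head(ids, 5), collapse = ", ")))
  }
  z <- (values[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  structure(z, class = c("zscore_matrix", class(z)),
            dropped = rownames(values)[!keep] %||% character(0))
}

#' Hierarchical clustering order of samples or regions
#'
#' Agglomerative clustering of a z-score matrix along the chosen axis with a
#' configurable distance metric and linkage (defaults: Euclidean, average
#' linkage). Leaf order is deterministic; ties follow input order through
#' [stats::hclust()].
#'
#' @param z a `zscore_matrix` (or any numeric matrix with finite values).
#' @param axis `"samples"` (cluster columns) or `"regions"` (cluster rows).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list: `order` (leaf indices), `labels` (leaf labels in dendrogram
#'   order), `hclust` (the fitted tree), `metric`, `linkage`.
#' @export
hierarchical_order <- function(z, axis = c("samples", "regions"),
                               metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  m <- if (axis == "samples") t(z) else unclass(z)
  if (nrow(m) < 2) stop_msg("need >= 2 %s to cluster", axis)
  if (any(!is.finite(m))) stop_msg("non-finite values in the z-score matrix")
  h <- hclust(dist(m, method = metric), method = linkage)
  list(order = h$order, labels = h$labels[h$order], hclust = h,
       metric = metric, linkage = linkage)
}

#' Mean cophenetic distance between two sample groups
#'
#' Helper for ordering claims of the form "second-trimester samples sit
#' between first-trimester and term samples in the dendrogram": averages the
#' cophenetic (tree) distances between the members of two groups.
#'
#' @param clust result of [hierarchical_order()].
#' @param ids_a,ids_b label sets (must appear among the tree's leaf labels).
#' @return mean cophenetic distance (numeric scalar).
#' @export
cophenetic_group_distance <- function(clust, ids_a, ids_b) {
  cd <- as.matrix(cophenetic(clust$hclust))
  miss <- setdiff(c(ids_a, ids_b), rownames(cd))
  if (length(miss)) stop_msg("label '%s' not in the clustering", miss[1])
  mean(cd[ids_a, ids_b])
}
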