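#' Euclidean distance matrix between station feature vectors
#'
#' @param features Numeric matrix or data.frame, one row per station
#'   (rownames = station ids), equal-length feature vectors, no missing
#'   values.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(features) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite (no NaN/NA)")
  as.matrix(stats::dist(features, method = "euclidean"))
}

#' Agglomerative average-linkage clustering
#'
#' At every step, merges the pair of clusters with the smallest mean
#' inter-cluster distance (UPGMA). Leaves are processed in the order of the
#' distance matrix, so feeding stations alphabetically gives a reproducible
#' tree; with distinct merge heights (the typical case for the packaged
#' 1-D features) the tree is unique.
#'
#' @param dist_mat Symmetric distance matrix (from [distance_matrix()]).
#' @return An object of class `hclust` (merge history, heights, leaf order).
#' @export
average_linkage <- function(dist_mat) {
  if (nrow(dist_mat) < 2L) stop("at least two items are required")
  stats::hclust(stats::as.dist(dist_mat), method = "average")
}

#' Cut a linkage tree into k clusters
#'
#' @param tree `hclust` tree.
#' @param k Number of clusters, 1..n.
#' @return Integer vector of cluster labels (1..k) named by item.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  stats::cutree(tree, k = k)
}

#' Cluster stations on their operation counts
#'
#' Convenience wrapper reproducing the station grouping used for strategy
#' design: average-linkage clustering on the annual total of
#' non-time-critical operations (optionally augmented by the
#' without/with-transport ratio), cut at `k` clusters.
#'
#' @param registry `station_registry`.
#' @param k Cluster count (default 5).
#' @param features `"total"` (default; 1-D annual totals, unscaled) or
#'   `c("total", "ratio")` to add the without/with transport ratio.
#' @return List: `labels` (named by abbreviation), `tree` (`hclust`),
#'   `features` (matrix used).
#' @export
cluster_stations <- function(registry, k = 5L, features = "total") {
  known <- c("total", "ratio")
  bad <- setdiff(features, known)
  if (length(bad) > 0L) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  cols <- list(
    total = registry$ops_total,
    ratio = registry$ops_without / pmax(registry$ops_with, 1)
  )
  X <- do.call(cbind, cols[features])
  rownames(X) <- registry$abbr
  tree <- average_linkage(distance_matrix(X))
  list(labels = cut_tree(tree, k), tree = tree, features = X)
}
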