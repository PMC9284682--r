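#' Dunn index (dunn1)
#'
#' Minimum between-cluster separation divided by maximum within-cluster
#' diameter (Euclidean distance). A worst-case indicator: one scattered
#' cluster drags it down even when the others are tight. All-singleton
#' clusterings have zero diameter and return `Inf`; fully coincident points
#' return 0.
#'
#' @param points numeric matrix (samples x dims) or vector (1-D).
#' @param labels cluster labels, at least 2 clusters.
#' @return nonnegative real (possibly `Inf`).
#' @export
dunn_index <- function(points, labels) {
  pd <- pairwise_setup(points, labels)
  if (length(unique(pd$labels)) < 2)
    stop("dunn_index: need at least 2 clusters")
  within <- pd$d[pd$same]
  between <- pd$d[!pd$same]
  diam <- if (length(within)) max(within) else 0
  sep <- min(between)
  if (diam == 0) {
    if (sep == 0) return(0)  # coincident points across clusters
    return(Inf)
  }
  sep / diam
}

#' Within/between distance ratio (wb.ratio)
#'
#' Mean of all within-cluster pairwise distances divided by the mean of all
#' between-cluster pairwise distances; lower is better (the other indices
#' increase with clustering quality, this one decreases).
#'
#' @inheritParams dunn_index
#' @return positive real (NaN when all points coincide).
#' @export
wb_ratio <- function(points, labels) {
  pd <- pairwise_setup(points, labels)
  if (length(unique(pd$labels)) < 2)
    stop("wb_ratio: need at least 2 clusters")
  if (!any(pd$same))
    stop("wb_ratio: no within-cluster pair (all clusters are singletons)")
  mean(pd$d[pd$same]) / mean(pd$d[!pd$same])
}

pairwise_setup <- function(points, labels) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (nrow(points) != length(labels))
    stop("points and labels differ in length")
  list(d = as.numeric(stats::dist(points)),
       same = pair_same_cluster(labels), labels = labels)
}

#' Clustering metrics container
#'
#' Holds the three cluster validation indices for one embedding + labeling.
#' Mostly produced by [evaluate_clustering()]; the constructor is exported so
#' externally reported metric values can be compared with [metrics_delta()].
#'
#' @param pearson_gamma,dunn1,wb_ratio the three index values.
#' @param n_samples,n_clusters sizes of the evaluated clustering.
#' @param n_components number of embedding dimensions used.
#' @param degenerate `TRUE` when an index was undefined (coincident points)
#'   and reported as 0 by contract.
#' @return list of class `cluster_metrics`.
#' @export
cluster_metrics <- function(pearson_gamma, dunn1, wb_ratio,
                            n_samples = NA_integer_,
                            n_clusters = NA_integer_,
                            n_components = NA_integer_,
                            degenerate = FALSE) {
  structure(list(pearson_gamma = pearson_gamma, dunn1 = dunn1,
                 wb_ratio = wb_ratio, n_samples = n_samples,
                 n_clusters = n_clusters, n_components = n_components,
                 degenerate = degenerate),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(
    "cluster_metrics (n = %s, clusters = %s): gamma = %.3f, dunn1 = %.3g, wb_ratio = %.3f%s\n",
    x$n_samples, x$n_clusters, x$pearson_gamma, x$dunn1, x$wb_ratio,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Evaluate a clustering of component scores
#'
#' Computes Pearson gamma, the Dunn index and the within/between ratio on
#' the first `n_components` columns of a score matrix, with the biological
#' groups as clusters and Euclidean distances. When all points coincide the
#' gamma is undefined; by contract it is reported as 0 with `degenerate =
#' TRUE` so downstream reports stay machine-readable.
#'
#' @param scores an [acpca()] result or a samples x components numeric
#'   matrix with sample ids as rownames.
#' @param table a [sample_table()] covering those samples.
#' @param cluster_by metadata column holding the cluster labels (default
#'   `"group"`).
#' @param n_components embedding dimensions to use (default 2).
#' @return a [cluster_metrics()] object.
#' @export
evaluate_clustering <- function(scores, table, cluster_by = "group",
                                n_components = 2) {
  if (inherits(scores, "acpca_result")) scores <- scores$scores
  scores <- as.matrix(scores)
  stopifnot(inherits(table, "sample_table"))
  if (ncol(scores) < n_components)
    stop("evaluate_clustering: scores have ", ncol(scores),
         " components, need ", n_components)
  if (is.null(rownames(scores)))
    stop("evaluate_clustering: scores need sample ids as rownames")
  tab <- table[match(rownames(scores), table$sample_id), , drop = FALSE]
  if (any(is.na(tab$sample_id)))
    stop("evaluate_clustering: score samples missing from table")
  labels <- as.character(tab[[cluster_by]])
  pts <- scores[, seq_len(n_components), drop = FALSE]
  d <- as.numeric(stats::dist(pts))
  same <- pair_same_cluster(labels)
  g <- pearson_gamma(d, same)
  degenerate <- FALSE
  if (is.na(g)) {
    g <- 0
    degenerate <- TRUE
  }
  cluster_metrics(pearson_gamma = g,
                  dunn1 = dunn_index(pts, labels),
                  wb_ratio = wb_ratio(pts, labels),
                  n_samples = nrow(pts),
                  n_clusters = length(unique(labels)),
                  n_components = as.integer(n_components),
                  degenerate = degenerate)
}

#' Difference in clustering metrics between two runs
#'
#' Corrected minus uncorrected, per metric. Sample counts of both sides are
#' recorded because outlier removal changes n, and the indices are sensitive
#' to removing large proportions of samples.
#'
#' @param before,after [cluster_metrics()] objects computed with the same
#'   cluster labels and number of components.
#' @param label free-text label of the comparison (e.g. the correction
#'   variant).
#' @return list of class `metrics_delta` with per-metric differences and
#'   `n_before`/`n_after`.
#' @export
metrics_delta <- function(before, after, label = "") {
  stopifnot(inherits(before, "cluster_metrics"),
            inherits(after, "cluster_metrics"))
  if (!is.na(before$n_clusters) && !is.na(after$n_clusters) &&
      before$n_clusters != after$n_clusters)
    stop("metrics_delta: runs cluster by different labelings (",
         before$n_clusters, " vs ", after$n_clusters, " clusters)")
  if (!is.na(before$n_components) && !is.na(after$n_components) &&
      before$n_components != after$n_components)
    stop("metrics_delta: runs use different numbers of components")
  structure(list(label = label,
                 pearson_gamma = after$pearson_gamma - before$pearson_gamma,
                 dunn1 = after$dunn1 - before$dunn1,
                 wb_ratio = after$wb_ratio - before$wb_ratio,
                 n_before = before$n_samples, n_after = after$n_samples),
            class = "metrics_delta")
}

#' @export
print.metrics_delta <- function(x, ...) {
  cat(sprintf(
    "metrics_delta [%s]: gamma %+0.3f, dunn1 %+0.3g, wb_ratio %+0.3f (n %s -> %s)\n",
    x$label, x$pearson_gamma, x$dunn1, x$wb_ratio, x$n_before, x$n_after))
  invisible(x)
}
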