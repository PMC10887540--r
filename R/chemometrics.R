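#' Pairwise Pearson correlations with p-values
#'
#' Correlation matrix of the response table with two-sided p-values from the
#' t-transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#' Constant columns yield undefined correlations; their pairs are returned
#' as `NA` and flagged.
#'
#' @param x Numeric matrix (samples x variables), no missing values.
#' @return List with `r` (correlations), `p` (p-values), and
#'   `constant` (names of constant columns, if any).
#' @export
correlation_analysis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("correlation_analysis: need >= 3 samples")
  if (any(!is.finite(x))) stop("correlation_analysis: missing values")
  sds <- apply(x, 2, stats::sd)
  const <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  n <- nrow(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(r) <- 1
  if (length(const)) {
    r[const, ] <- NA; r[, const] <- NA
    p[const, ] <- NA; p[, const] <- NA
    warning("correlation_analysis: constant column(s): ",
            paste(const, collapse = ", "))
  }
  list(r = r, p = p, constant = const)
}

#' Principal component analysis with signed variable contributions
#'
#' PCA of the response table, by default on the correlation matrix
#' (variables standardized), since the sixteen responses carry
#' incommensurate units. Beyond scores, loadings and explained-variance
#' percentages, the result reports each variable's signed contribution to
#' each component: `sign(loading) * 100 * loading^2 / sum(loading^2)`, so
#' absolute contributions sum to 100% per component while the sign records
#' the direction of influence.
#'
#' @param x Numeric matrix (samples x variables).
#' @param standardize Scale variables to unit variance (default `TRUE`).
#' @return List with `scores`, `loadings`, `explained` (percent per
#'   component, summing to 100), `contributions` (variables x components,
#'   signed percent), `sdev`.
#' @export
pca_responses <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("pca_responses: need >= 2 samples and >= 2 variables")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("pca_responses: dropping constant column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  explained <- 100 * ev / sum(ev)
  contrib <- apply(pc$rotation, 2, function(l) sign(l) * 100 * l^2 / sum(l^2))
  list(scores = pc$x, loadings = pc$rotation, explained = explained,
       contributions = contrib, sdev = pc$sdev)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters sample rows (by default on standardized responses with
#' Euclidean distance and complete linkage) and returns the merge history
#' with utilities for cutting and export.
#'
#' @param x Numeric matrix (samples x variables).
#' @param metric Distance metric understood by [stats::dist()].
#' @param linkage Linkage method understood by [stats::hclust()].
#' @param standardize Standardize columns first (default `TRUE`).
#' @return Object of class `cluster_tree`: the `hclust` object plus tags.
#' @export
hierarchical_cluster <- function(x, metric = "euclidean",
                                 linkage = "complete", standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("hierarchical_cluster: need >= 2 samples")
  ok_metric <- c("euclidean", "maximum", "manhattan", "canberra", "minkowski")
  ok_link <- c("complete", "single", "average", "ward.D", "ward.D2",
               "mcquitty", "centroid", "median")
  if (!metric %in% ok_metric)
    stop("hierarchical_cluster: unknown metric: ", metric)
  if (!linkage %in% ok_link)
    stop("hierarchical_cluster: unknown linkage: ", linkage)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    keep <- sds > 0
    x <- sweep(sweep(x[, keep, drop = FALSE], 2,
                     colMeans(x[, keep, drop = FALSE]), "-"),
               2, sds[keep], "/")
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 labels = rownames(x)),
            class = "cluster_tree")
}

#' @rdname hierarchical_cluster
#' @param tree A `cluster_tree`.
#' @param k Number of clusters to cut into.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' @rdname hierarchical_cluster
#' @export
cluster_newick <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' @rdname hierarchical_cluster
#' @param path JSON file path for the merge-list serialization.
#' @export
write_cluster_tree <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  o <- list(merge = hc$merge, height = hc$height, labels = hc$labels,
            order = hc$order, metric = tree$metric, linkage = tree$linkage)
  jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
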