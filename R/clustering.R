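#' Hierarchical clustering of samples by Pearson correlation distance
#'
#' Distance between two samples is `1 - Pearson correlation` of their
#' expression vectors over the supplied probes; agglomeration is pairwise
#' complete linkage (via [stats::hclust()]), whose merge heights are
#' guaranteed non-decreasing. Correlation distance makes the tree invariant
#' to per-sample affine rescaling (`c * x + b`, `c > 0`).
#'
#' @param values probe x sample numeric matrix (>= 2 probes, >= 2 samples);
#'   typically `log2(x + 1)` values restricted to an abundant-probe panel
#'   such as [top_n_union()].
#' @return object of class `linkage_tree`: list with `merge`, `height`,
#'   `order`, `labels` (as in [stats::hclust()]) and the underlying `hclust`
#'   object.
#' @export
pearson_complete_linkage <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("validation error: need >= 2 probes and >= 2 samples")
  }
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("validation error: constant sample vector(s), correlation undefined: ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(values))
  hc <- stats::hclust(d, method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "linkage_tree")
}

#' Flat cluster labels from a linkage tree
#'
#' @param tree a [pearson_complete_linkage()] result.
#' @param k number of clusters.
#' @return named integer vector of cluster labels.
#' @export
cut_linkage <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree: %d leaves, merge heights %.3g-%.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Heatmap-ready log-ratio matrix
#'
#' Per probe row: `log2((value + 1) / (row mean + 1))`, centering each
#' probe's display values on its own average; all-zero rows come out as all
#' zeros.
#'
#' @param values non-negative probe x sample (or probe x cell-type-average)
#'   matrix.
#' @return matrix of the same shape.
#' @export
heatmap_logratio <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("validation error: values must be >= 0")
  log2(sweep(values + 1, 1, rowMeans(values) + 1, `/`))
}
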