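#' Select genes with high isoform diversity
#'
#' Genes expressing strictly more than `min_isoforms` distinct isoforms
#' (above the expression-call thresholds) in at least one tissue.
#'
#' @param per_gene gene x tissue matrix of expressed-isoform counts, as
#'   returned by [isoforms_per_gene()] in `"expressed_in_tissue"` mode
#' @param min_isoforms strict lower bound (default 5, i.e. > 5 isoforms)
#' @return character vector of gene ids
#' @export
select_diverse_genes <- function(per_gene, min_isoforms = 5) {
  per_gene <- as.matrix(per_gene)
  rownames(per_gene)[apply(per_gene, 1, max) > min_isoforms]
}

#' Hierarchically cluster a gene x tissue isoform-count matrix
#'
#' Clusters rows (genes) and columns (tissues) of the raw isoform-count
#' matrix — never a display-capped version — with Euclidean distance and a
#' configurable linkage. Rows are sorted by gene id before clustering so
#' the result is invariant to input row order, with ties broken by id.
#'
#' @param mat gene x tissue numeric matrix (non-negative counts)
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`; `"ward.D2"` and `"average"` are common alternatives)
#' @param k optional number of flat row clusters (via [stats::cutree()])
#' @param h optional dendrogram cut height (alternative to `k`)
#' @return list with `row_order`, `col_order` (leaf orders as ids),
#'   `row_clusters` (named integer vector, or NULL), `row_hclust`,
#'   `col_hclust`, and `matrix` (the id-sorted input)
#' @export
cluster_matrix <- function(mat, linkage = "complete", k = NULL, h = NULL) {
  mat <- as.matrix(mat)
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (nrow(mat) < 2) {
    return(list(row_order = rownames(mat), col_order = colnames(mat),
                row_clusters = if (nrow(mat)) stats::setNames(1L, rownames(mat)),
                row_hclust = NULL, col_hclust = NULL, matrix = mat))
  }
  hr <- stats::hclust(stats::dist(mat), method = linkage)
  hc <- if (ncol(mat) >= 2)
    stats::hclust(stats::dist(t(mat)), method = linkage) else NULL
  clusters <- NULL
  if (!is.null(k) || !is.null(h))
    clusters <- stats::cutree(hr, k = k, h = h)
  list(row_order = rownames(mat)[hr$order],
       col_order = if (is.null(hc)) colnames(mat) else colnames(mat)[hc$order],
       row_clusters = clusters,
       row_hclust = hr, col_hclust = hc, matrix = mat)
}

#' Cap a count matrix for heatmap display
#'
#' Rendering convention: counts at or above `cap` share the darkest bin.
#' The cap applies only to the displayed values; clustering always uses the
#' raw counts.
#'
#' @param mat numeric matrix
#' @param cap ceiling (default 7)
#' @return matrix with values truncated at `cap`
#' @export
display_matrix <- function(mat, cap = 7) pmin(as.matrix(mat), cap)
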