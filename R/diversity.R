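#' Expressed-isoform counts across a CPM threshold sweep
#'
#' For each tissue, counts the isoforms whose median CPM exceeds each
#' threshold on the grid (strict `>`), with the median-unique condition
#' (`>= unique_thresh`) held fixed — or dropped entirely with
#' `require_unique = FALSE`, which is what the "0 < CPM <= 1" tallies use.
#'
#' @param median_cpm,median_unique isoform x tissue median matrices
#' @param grid numeric vector of CPM thresholds (default 0 to 10.01 in 0.01
#'   steps)
#' @param unique_thresh minimum median unique counts (default 1)
#' @param require_unique apply the unique condition at every grid point
#' @return data.frame with columns `tissue`, `threshold`, `n_isoforms`
#' @export
sweep_counts <- function(median_cpm, median_unique = NULL,
                         grid = seq(0, 10.01, by = 0.01),
                         unique_thresh = 1, require_unique = TRUE) {
  if (require_unique) {
    if (is.null(median_unique))
      stop("median_unique needed unless require_unique = FALSE")
    pass_unique <- median_unique >= unique_thresh
  } else {
    pass_unique <- matrix(TRUE, nrow(median_cpm), ncol(median_cpm),
                          dimnames = dimnames(median_cpm))
  }
  tissues <- colnames(median_cpm)
  out <- lapply(tissues, function(t) {
    vals <- sort(median_cpm[pass_unique[, t], t])
    # count of vals strictly above each threshold
    n <- length(vals) - findInterval(grid, vals, left.open = FALSE)
    data.frame(tissue = t, threshold = grid, n_isoforms = n)
  })
  do.call(rbind, out)
}

#' Expressed isoforms per gene
#'
#' Two counting modes: `"any_sample"` counts, per gene, the isoforms whose
#' maximum unique count over *all* samples reaches `k` (k typically 1, 5,
#' 10 or 20); `"expressed_in_tissue"` counts, per gene and tissue, the
#' isoforms passing the standard expression call.
#'
#' @param x unique-counts matrix (mode `"any_sample"`) or logical expressed
#'   isoform x tissue matrix (mode `"expressed_in_tissue"`)
#' @param gene_ids gene id per isoform row (named vector or positional)
#' @param mode counting mode
#' @param k unique-count threshold for mode `"any_sample"`
#' @param biotypes optional named transcript_biotype vector; when given with
#'   `protein_coding_only = TRUE`, restricts to protein-coding isoforms
#' @param protein_coding_only restrict to `transcript_biotype ==
#'   "protein_coding"`
#' @return mode `"any_sample"`: named integer vector per gene; mode
#'   `"expressed_in_tissue"`: gene x tissue integer matrix
#' @export
isoforms_per_gene <- function(x, gene_ids,
                              mode = c("any_sample", "expressed_in_tissue"),
                              k = 1, biotypes = NULL,
                              protein_coding_only = FALSE) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.null(names(gene_ids))) gene_ids <- gene_ids[rownames(x)]
  keep <- rep(TRUE, nrow(x))
  if (protein_coding_only) {
    if (is.null(biotypes)) stop("biotypes needed for protein_coding_only")
    keep <- is_protein_coding(biotypes[rownames(x)])
  }
  x <- x[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]
  if (mode == "any_sample") {
    hit <- apply(x, 1, max) >= k
    counts <- tapply(hit, gene_ids, sum)
    stats::setNames(as.integer(counts), names(counts))
  } else {
    m <- rowsum(x * 1L, group = gene_ids, reorder = TRUE)
    storage.mode(m) <- "integer"
    m
  }
}

is_protein_coding <- function(biotypes) {
  norm <- gsub("[-_ ]", "_", tolower(biotypes))
  !is.na(norm) & norm == "protein_coding"
}

#' Exclusive tissue-overlap sets (upset semantics)
#'
#' Every isoform expressed in at least one tissue is assigned to exactly
#' one combination — its exact expressed-tissue set — so the combination
#' counts partition the expressed isoforms (the standard upset-plot
#' convention).
#'
#' @param expressed logical isoform x tissue matrix
#' @param sep separator used to encode a combination as a string
#' @return data.frame with `combination` (tissue names joined by `sep`),
#'   `n_tissues`, `n_isoforms`, sorted by descending count (the "top N
#'   interactions" order)
#' @export
tissue_overlap <- function(expressed, sep = "+") {
  expressed <- as.matrix(expressed)
  if (ncol(expressed) < 2) stop("need at least two tissues")
  any_t <- rowSums(expressed) > 0
  e <- expressed[any_t, , drop = FALSE]
  tn <- colnames(e)
  combo <- apply(e, 1, function(r) paste(tn[r], collapse = sep))
  tab <- table(combo)
  out <- data.frame(combination = names(tab),
                    n_isoforms = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$n_tissues <- lengths(strsplit(out$combination, sep, fixed = TRUE))
  out <- out[order(-out$n_isoforms, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("combination", "n_tissues", "n_isoforms")]
}

#' Isoforms unique to a single tissue
#'
#' Counts the singleton combinations of [tissue_overlap()], per tissue, and
#' the protein-coding share when biotypes are supplied.
#'
#' @param expressed logical isoform x tissue matrix
#' @param biotypes optional named transcript_biotype vector
#' @return data.frame `tissue`, `n_unique`, and (with biotypes)
#'   `n_protein_coding`, `pc_share`
#' @export
unique_to_tissue <- function(expressed, biotypes = NULL) {
  expressed <- as.matrix(expressed)
  single <- rowSums(expressed) == 1
  out <- data.frame(tissue = colnames(expressed),
                    n_unique = colSums(expressed & single),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(biotypes)) {
    pc <- is_protein_coding(biotypes[rownames(expressed)])
    out$n_protein_coding <- colSums(expressed & single & pc)
    out$pc_share <- ifelse(out$n_unique > 0,
                           out$n_protein_coding / out$n_unique, NA_real_)
  }
  out
}

#' Protein-coding proportion contrast between two tissues
#'
#' Builds the 2x2 table (protein-coding vs other) x (tissue1 vs tissue2)
#' over each tissue's expressed isoforms and runs a Pearson chi-square test
#' (1 df, no continuity correction by default).
#'
#' @param expressed logical isoform x tissue matrix
#' @param biotypes named transcript_biotype vector for the isoform rows
#' @param tissue1,tissue2 tissue column names
#' @param correct apply the Yates continuity correction (default FALSE)
#' @return list with `table` (2x2), `statistic`, `p`, `proportions`
#'   (protein-coding fraction per tissue)
#' @export
pc_proportion_test <- function(expressed, biotypes, tissue1, tissue2,
                               correct = FALSE) {
  expressed <- as.matrix(expressed)
  pc <- is_protein_coding(biotypes[rownames(expressed)])
  tab <- rbind(
    c(sum(expressed[, tissue1] & pc), sum(expressed[, tissue1] & !pc)),
    c(sum(expressed[, tissue2] & pc), sum(expressed[, tissue2] & !pc)))
  dimnames(tab) <- list(c(tissue1, tissue2), c("protein_coding", "other"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero row or column in the 2x2 table")
  ht <- stats::chisq.test(tab, correct = correct)
  list(table = tab, statistic = unname(ht$statistic), p = ht$p.value,
       proportions = tab[, 1] / rowSums(tab))
}
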