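#' Counts-per-million normalization
#'
#' `cpm()` scales each sample column of the total-counts matrix to a
#' library of one million: `cpm[i,s] = total[i,s] / libsize[s] * 1e6`, with
#' the library size the column sum over all isoforms retained in the matrix.
#'
#' @param x a [counts_bundle()] or a counts matrix (isoforms x samples)
#' @return numeric matrix of CPM values, same dimnames
#' @export
cpm <- function(x) {
  m <- if (inherits(x, "counts_bundle")) x$total else as.matrix(x)
  lib <- colSums(m)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  sweep(m, 2, lib, "/") * 1e6
}

#' Gene-level CPM
#'
#' Sums member-isoform CPM per gene, including isoforms below any
#' expression threshold.
#'
#' @param cpm_mat isoform x sample CPM matrix
#' @param gene_ids named or positional character vector of gene ids, one
#'   per row of `cpm_mat`
#' @return gene x sample matrix
#' @export
gene_cpm <- function(cpm_mat, gene_ids) {
  if (!is.null(names(gene_ids))) gene_ids <- gene_ids[rownames(cpm_mat)]
  rowsum(cpm_mat, group = gene_ids, reorder = TRUE)
}

#' Within-gene relative abundance
#'
#' Percent of a gene's total-count expression carried by each isoform, per
#' sample. Samples where the gene has zero total expression get 0 and are
#' flagged in the `undefined` attribute.
#'
#' @param total isoform x sample total-counts (or CPM) matrix
#' @param gene_ids gene id per row
#' @return matrix of percentages (isoform rows summing to 100 within each
#'   gene wherever the gene total is positive), with logical attribute
#'   `undefined` marking gene-zero cells
#' @export
relative_abundance <- function(total, gene_ids) {
  total <- as.matrix(total)
  if (!is.null(names(gene_ids))) gene_ids <- gene_ids[rownames(total)]
  gt <- rowsum(total, group = gene_ids, reorder = FALSE)
  denom <- gt[match(gene_ids, rownames(gt)), , drop = FALSE]
  undefined <- denom == 0
  denom[undefined] <- 1
  out <- 100 * total / denom
  out[undefined] <- 0
  dimnames(out) <- dimnames(total)
  attr(out, "undefined") <- undefined
  out
}

#' Per-tissue medians of an isoform x sample matrix
#'
#' @param mat isoform x sample matrix
#' @param meta sample metadata with `sample_id` and `tissue`
#' @return isoform x tissue matrix of medians over the tissue's samples
#'   (even n: mean of the central pair)
#' @export
tissue_medians <- function(mat, meta) {
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$tissue))
    stop("samples absent from metadata: ",
         paste(colnames(mat)[is.na(meta$tissue)], collapse = ", "))
  tissues <- sort(unique(meta$tissue))
  out <- vapply(tissues, function(t) {
    cols <- which(meta$tissue == t)
    apply(mat[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat),
                                       dimnames = list(rownames(mat), tissues))
  out
}

#' Expression calls per isoform and tissue
#'
#' The noise rule: an isoform counts as expressed in a tissue when its
#' median CPM across the tissue's samples is strictly greater than
#' `cpm_thresh` (default 1) *and* its median unique count is at least
#' `unique_thresh` (default 1).
#'
#' @param median_cpm,median_unique isoform x tissue matrices from
#'   [tissue_medians()]
#' @param cpm_thresh CPM threshold (strict `>`); raise to e.g. 10 for an
#'   ultra-conservative call
#' @param unique_thresh unique-count threshold (`>=`); set to `-Inf` to
#'   drop the unique condition
#' @return logical isoform x tissue matrix
#' @export
expressed_flags <- function(median_cpm, median_unique, cpm_thresh = 1,
                            unique_thresh = 1) {
  stopifnot(identical(dim(median_cpm), dim(median_unique)))
  (median_cpm > cpm_thresh) & (median_unique >= unique_thresh)
}

#' Per-tissue expression summary
#'
#' Convenience wrapper computing CPM, per-tissue median CPM and median
#' unique counts, and the expressed calls from a counts bundle.
#'
#' @param bundle a [counts_bundle()] with total and unique matrices
#' @param meta sample metadata (`sample_id`, `tissue`)
#' @inheritParams expressed_flags
#' @return list with `cpm` (isoform x sample), `median_cpm`,
#'   `median_unique`, `expressed` (isoform x tissue), and the thresholds
#' @export
tissue_expression_summary <- function(bundle, meta, cpm_thresh = 1,
                                      unique_thresh = 1) {
  if (is.null(bundle$unique))
    stop("expression calling needs the unique-counts matrix")
  cpm_mat <- cpm(bundle)
  med_cpm <- tissue_medians(cpm_mat, meta)
  med_unique <- tissue_medians(bundle$unique, meta)
  list(cpm = cpm_mat, median_cpm = med_cpm, median_unique = med_unique,
       expressed = expressed_flags(med_cpm, med_unique, cpm_thresh, unique_thresh),
       cpm_thresh = cpm_thresh, unique_thresh = unique_thresh)
}

#' Sample inclusion filter
#'
#' Applies, in order: (1) drop samples with an experimental condition;
#' (2) drop samples with fewer than `min_reads` total reads; (3) among
#' technical replicates keep the sample with the highest total reads that is
#' below the maximum total reads of the tissue's other samples (avoiding
#' replicate-driven outliers; falls back to the highest replicate when none
#' is below); (4) drop tissues represented by fewer than `min_subjects`
#' unique subjects; (5) optionally flag or drop principal-component
#' outliers (see [pca_outliers()]).
#'
#' @param meta sample metadata data.frame (`sample_id`, `subject_id`,
#'   `tissue`, `total_reads`, optional `replicate_group`,
#'   `experimental_condition`)
#' @param counts optional total-counts matrix, required for the PCA rule
#' @param min_subjects minimum unique subjects per tissue (default 5)
#' @param min_reads minimum total reads per sample (default 1e6)
#' @param pca `"off"` (default), `"flag"` (log only) or `"exclude"`
#' @param pca_k multiplier on the tissue's median centroid distance
#' @return list with `included` (character vector of sample ids) and
#'   `exclusions` (data.frame `sample_id`, `rule`, `detail`)
#' @export
filter_samples <- function(meta, counts = NULL, min_subjects = 5,
                           min_reads = 1e6, pca = c("off", "flag", "exclude"),
                           pca_k = 3) {
  pca <- match.arg(pca)
  meta <- as.data.frame(meta)
  if (is.null(meta$replicate_group)) meta$replicate_group <- NA_character_
  if (is.null(meta$experimental_condition))
    meta$experimental_condition <- NA_character_
  log <- data.frame(sample_id = character(0), rule = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  drop <- function(ids, rule, detail) {
    if (length(ids))
      log <<- rbind(log, data.frame(sample_id = ids, rule = rule,
                                    detail = detail, stringsAsFactors = FALSE))
    meta <<- meta[!meta$sample_id %in% ids, , drop = FALSE]
  }

  cond <- !is.na(meta$experimental_condition) &
    nzchar(meta$experimental_condition)
  drop(meta$sample_id[cond], "experimental_condition",
       "sample carries an experimental condition")
  drop(meta$sample_id[meta$total_reads < min_reads], "low_reads",
       sprintf("total reads < %d", as.integer(min_reads)))

  rep_groups <- unique(meta$replicate_group[!is.na(meta$replicate_group)])
  for (g in rep_groups) {
    in_g <- which(meta$replicate_group %in% g)
    if (length(in_g) < 2) next
    tissue <- meta$tissue[in_g[1]]
    others <- meta$total_reads[meta$tissue == tissue &
                                 !(meta$replicate_group %in% g)]
    cap <- if (length(others)) max(others) else Inf
    reads <- meta$total_reads[in_g]
    below <- reads < cap
    keep <- if (any(below)) in_g[below][which.max(reads[below])] else
      in_g[which.max(reads)]
    drop(meta$sample_id[setdiff(in_g, keep)], "technical_replicate",
         sprintf("replicate group %s: kept %s", g, meta$sample_id[keep]))
  }

  subj <- tapply(meta$subject_id, meta$tissue, function(s) length(unique(s)))
  small <- names(subj)[subj < min_subjects]
  drop(meta$sample_id[meta$tissue %in% small], "few_subjects",
       sprintf("tissue has < %d unique subjects", min_subjects))

  if (pca != "off") {
    if (is.null(counts)) stop("PCA outlier rule needs the counts matrix")
    out <- pca_outliers(counts[, meta$sample_id, drop = FALSE], meta, k = pca_k)
    if (pca == "exclude") {
      drop(out, "pca_outlier",
           sprintf("PC1-2 distance > %g x tissue median centroid distance", pca_k))
    } else if (length(out)) {
      log <- rbind(log, data.frame(sample_id = out, rule = "pca_outlier_flag",
                                   detail = "flagged, not excluded",
                                   stringsAsFactors = FALSE))
    }
  }
  list(included = meta$sample_id, exclusions = log)
}

#' Principal-component outlier detection
#'
#' Reproducible stand-in for a visual PCA screen: principal components are
#' computed on log2(size-factor-normalized counts + 1); a sample is flagged
#' when its Euclidean distance to its tissue centroid in PC1-2 exceeds `k`
#' times the tissue's median centroid distance.
#'
#' @param counts isoform x sample total-counts matrix
#' @param meta sample metadata (`sample_id`, `tissue`)
#' @param k distance multiplier (default 3)
#' @return character vector of flagged sample ids
#' @export
pca_outliers <- function(counts, meta, k = 3) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  sf <- suppressWarnings(size_factors(counts))
  lg <- log2(sweep(counts, 2, sf, "/") + 1)
  keep <- apply(lg, 1, stats::var) > 0
  pcs <- stats::prcomp(t(lg[keep, , drop = FALSE]), center = TRUE,
                       scale. = FALSE)$x[, 1:2, drop = FALSE]
  flagged <- character(0)
  for (t in unique(meta$tissue)) {
    idx <- which(meta$tissue == t)
    if (length(idx) < 3) next
    ctr <- colMeans(pcs[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(pcs[idx, , drop = FALSE], 2, ctr)^2))
    med <- stats::median(d)
    if (med > 0) flagged <- c(flagged, meta$sample_id[idx][d > k * med])
  }
  flagged
}
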