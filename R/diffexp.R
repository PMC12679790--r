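#' Median-of-ratios size factors
#'
#' The usual count-normalization for comparing samples: a pseudo-reference
#' is the per-isoform geometric mean over samples (isoforms with any zero
#' excluded), and each sample's size factor is the median over isoforms of
#' count/reference. When no isoform is positive in every sample the
#' estimator is undefined; with `fallback = TRUE` library-size factors
#' (column sums scaled to geometric mean 1) are returned with a warning.
#'
#' @param total isoform x sample total-counts matrix
#' @param fallback allow the library-size fallback (default TRUE)
#' @return named positive numeric vector, one per sample
#' @export
size_factors <- function(total, fallback = TRUE) {
  total <- as.matrix(total)
  pos <- rowSums(total <= 0) == 0
  if (!any(pos)) {
    if (!fallback)
      stop("no isoform with positive counts in all samples; size factors undefined")
    warning("no all-positive isoform; falling back to library-size factors")
    lib <- colSums(total)
    return(lib / exp(mean(log(lib))))
  }
  lg <- log(total[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, stats::median)
  stats::setNames(sf, colnames(total))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement and
#' preserved ties; input is validated to lie in \[0, 1\].
#'
#' @param pvals numeric vector of p-values
#' @return vector of BH-adjusted values (FDR), same order as input
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Pairwise negative binomial differential expression
#'
#' A Wald test on size-factor-normalized counts between two sample groups
#' (typically two tissues). Per isoform: group means of normalized counts;
#' `log2FC = log2((meanA + c) / (meanB + c))` with pseudo-count `c`; a
#' method-of-moments NB dispersion pooled over the two groups (variance
#' model `mu + dispersion * mu^2`, floored at `min_disp`); delta-method
#' standard error of the log fold change; two-sided p-value from a t
#' reference with `nA + nB - 2` degrees of freedom (the estimated standard
#' error carries that many degrees of freedom, and a normal reference is
#' visibly anticonservative at five samples per group); BH adjustment
#' across the isoforms tested.
#'
#' Callers following the published filtering should restrict `counts` to
#' isoforms with median CPM > 1 in at least one tissue before testing.
#'
#' @param counts isoform x sample raw total counts
#' @param sf size factors for the columns of `counts` (see
#'   [size_factors()]); typically computed once on the full matrix
#' @param samples_a,samples_b column ids of the two groups (each >= 2)
#' @param pseudo pseudo-count on the normalized-mean scale (default 0.5)
#' @param min_disp dispersion floor (default 1e-8)
#' @return data.frame `isoform_id`, `mean_a`, `mean_b`, `log2fc`, `se`,
#'   `p`, `fdr`
#' @export
pairwise_de <- function(counts, sf, samples_a, samples_b, pseudo = 0.5,
                        min_disp = 1e-8) {
  counts <- as.matrix(counts)
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs at least 2 samples")
  na <- length(samples_a); nb <- length(samples_b)
  A <- sweep(counts[, samples_a, drop = FALSE], 2, sf[samples_a], "/")
  B <- sweep(counts[, samples_b, drop = FALSE], 2, sf[samples_b], "/")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- row_vars(A); vb <- row_vars(B)

  disp_of <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  disp <- ((na - 1) * disp_of(va, ma) + (nb - 1) * disp_of(vb, mb)) /
    (na + nb - 2)
  disp <- pmax(disp, min_disp)

  log2fc <- log2((ma + pseudo) / (mb + pseudo))
  var_ma <- (ma + disp * ma^2) / na
  var_mb <- (mb + disp * mb^2) / nb
  se <- sqrt(var_ma / (ma + pseudo)^2 + var_mb / (mb + pseudo)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = na + nb - 2)
  data.frame(isoform_id = rownames(counts),
             mean_a = ma, mean_b = mb, log2fc = log2fc, se = se,
             p = p, fdr = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' All pairwise tissue comparisons
#'
#' Runs [pairwise_de()] for every unordered tissue pair (36 pairs for nine
#' tissues), with BH adjustment within each pair's test family. Fold
#' changes are reported as `tissue_a` over `tissue_b` with `tissue_a <
#' tissue_b` alphabetically; the reverse comparison is the negation.
#'
#' @param counts isoform x sample raw total counts (already filtered to
#'   the isoforms under test)
#' @param meta sample metadata (`sample_id`, `tissue`)
#' @param sf size factors; by default computed on `counts` — pass factors
#'   computed on the full unfiltered matrix to follow the published
#'   normalize-then-filter order
#' @inheritParams pairwise_de
#' @return long data.frame `tissue_a`, `tissue_b`, `isoform_id`, `log2fc`,
#'   `se`, `p`, `fdr`
#' @export
pairwise_de_all <- function(counts, meta, sf = NULL, pseudo = 0.5,
                            min_disp = 1e-8) {
  counts <- as.matrix(counts)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  tissues <- sort(unique(meta$tissue))
  if (length(tissues) < 2) stop("need at least two tissues")
  out <- list()
  for (i in seq_len(length(tissues) - 1)) {
    for (j in seq(i + 1, length(tissues))) {
      a <- meta$sample_id[meta$tissue == tissues[i]]
      b <- meta$sample_id[meta$tissue == tissues[j]]
      de <- pairwise_de(counts, sf, a, b, pseudo = pseudo,
                        min_disp = min_disp)
      de$tissue_a <- tissues[i]
      de$tissue_b <- tissues[j]
      out[[length(out) + 1]] <- de
    }
  }
  res <- do.call(rbind, out)
  res[, c("tissue_a", "tissue_b", "isoform_id", "mean_a", "mean_b",
          "log2fc", "se", "p", "fdr")]
}

#' Look up signed fold changes per isoform as tissue x tissue matrices
#'
#' Internal helper for the classifiers: converts the long pairwise table
#' into, per isoform, a `log2fc` matrix (entry \[s, t\] = log2 fold change
#' of s over t) and an `fdr` matrix (symmetric).
#'
#' @param de long table from [pairwise_de_all()]
#' @return named list per isoform of lists `lfc`, `fdr` (tissue x tissue
#'   matrices, diagonal NA)
#' @keywords internal
de_matrices <- function(de) {
  tissues <- sort(unique(c(de$tissue_a, de$tissue_b)))
  nt <- length(tissues)
  iso <- unique(de$isoform_id)
  ia <- match(de$tissue_a, tissues)
  ib <- match(de$tissue_b, tissues)
  ii <- match(de$isoform_id, iso)
  lfc <- array(NA_real_, dim = c(nt, nt, length(iso)),
               dimnames = list(tissues, tissues, iso))
  fdr <- lfc
  lfc[cbind(ia, ib, ii)] <- de$log2fc
  lfc[cbind(ib, ia, ii)] <- -de$log2fc
  fdr[cbind(ia, ib, ii)] <- de$fdr
  fdr[cbind(ib, ia, ii)] <- de$fdr
  list(tissues = tissues, isoforms = iso, lfc = lfc, fdr = fdr)
}
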