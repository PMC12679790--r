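#' Preferential-tissue-set assignment
#'
#' An isoform is preferentially expressed in a tissue set S (|S| <= 3) when
#' it is significantly upregulated in every tissue of S against every
#' tissue outside S: each (s in S) vs (t not in S) comparison must show
#' `log2FC >= lfc` in s's favor and `FDR < fdr`. Comparisons *within* S are
#' ignored. Sets are searched smallest first (k = 1, 2, 3 — 129 candidate
#' sets over nine tissues); among qualifying sets of the same size the one
#' with the largest total log2 fold change wins.
#'
#' @param de long pairwise table from [pairwise_de_all()], covering every
#'   tissue pair for every isoform under consideration
#' @param max_k largest allowed set size (default 3)
#' @param lfc fold-change threshold (default 1; `strict` switches `>=` to
#'   `>`)
#' @param fdr FDR threshold (default 0.1, strict `<`)
#' @param strict use a strict inequality on the fold change
#' @return data.frame `isoform_id`, `k` (set size, NA when unassigned),
#'   `preferential_set` (`+`-joined tissues or NA), `total_lfc`
#' @export
preferential_sets <- function(de, max_k = 3, lfc = 1, fdr = 0.1,
                              strict = FALSE) {
  dm <- de_matrices(de)
  nt <- length(dm$tissues)
  check_pairs_complete(dm)
  subsets <- unlist(lapply(seq_len(max_k), function(k)
    utils::combn(nt, k, simplify = FALSE)), recursive = FALSE)
  sizes <- lengths(subsets)

  res <- lapply(seq_along(dm$isoforms), function(ii) {
    L <- dm$lfc[, , ii]
    Fd <- dm$fdr[, , ii]
    pass <- if (strict) (L > lfc) else (L >= lfc)
    pass <- pass & (Fd < fdr)
    for (k in seq_len(max_k)) {
      cand <- subsets[sizes == k]
      ok <- vapply(cand, function(S) all(pass[S, -S, drop = FALSE]),
                   logical(1))
      if (any(ok)) {
        winners <- cand[ok]
        tot <- vapply(winners, function(S) sum(L[S, -S, drop = FALSE]),
                      numeric(1))
        S <- winners[[which.max(tot)]]
        return(data.frame(
          isoform_id = dm$isoforms[ii], k = k,
          preferential_set = paste(dm$tissues[S], collapse = "+"),
          total_lfc = max(tot), stringsAsFactors = FALSE))
      }
    }
    data.frame(isoform_id = dm$isoforms[ii], k = NA_integer_,
               preferential_set = NA_character_, total_lfc = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

check_pairs_complete <- function(dm) {
  nt <- length(dm$tissues)
  off <- upper.tri(matrix(TRUE, nt, nt))
  for (ii in seq_along(dm$isoforms)) {
    miss <- is.na(dm$lfc[, , ii][off])
    if (any(miss)) {
      pairs <- which(off, arr.ind = TRUE)[miss, , drop = FALSE]
      stop("missing pairwise comparison for isoform ", dm$isoforms[ii], ": ",
           paste(dm$tissues[pairs[1, 1]], "vs", dm$tissues[pairs[1, 2]]))
    }
  }
  invisible(TRUE)
}

#' Housekeeping expression-pattern flags
#'
#' An isoform shows a housekeeping pattern when it is expressed above the
#' noise threshold in *every* tissue and its expression is flat across
#' tissues: every pairwise |log2FC| within `window` (default 2,
#' inclusive).
#'
#' @param de long pairwise table from [pairwise_de_all()]
#' @param expressed logical isoform x tissue matrix of expression calls
#' @param window log2 fold-change window (default 2)
#' @param strict use `<` instead of `<=` on the window
#' @return named logical vector over the isoforms present in `de`
#' @export
housekeeping_flags <- function(de, expressed, window = 2, strict = FALSE) {
  dm <- de_matrices(de)
  check_pairs_complete(dm)
  if (!all(dm$tissues %in% colnames(expressed)))
    stop("expressed matrix lacks tissue(s): ",
         paste(setdiff(dm$tissues, colnames(expressed)), collapse = ", "))
  flags <- vapply(seq_along(dm$isoforms), function(ii) {
    id <- dm$isoforms[ii]
    if (!id %in% rownames(expressed)) return(FALSE)
    if (!all(expressed[id, dm$tissues])) return(FALSE)
    mx <- max(abs(dm$lfc[, , ii]), na.rm = TRUE)
    if (strict) mx < window else mx <= window
  }, logical(1))
  stats::setNames(flags, dm$isoforms)
}

#' Gini coefficient of expression inequality
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`: 0 for perfectly uniform
#' expression across tissues, approaching (n-1)/n when a single tissue
#' carries everything. Low values (< 0.3 is the conventional cutoff)
#' indicate housekeeping-like uniformity. Input is typically the nine
#' per-tissue median CPMs of an isoform.
#'
#' @param x non-negative values, not all zero
#' @param unbiased apply the small-sample correction `n/(n-1)`
#' @return the coefficient, in `[0, (n-1)/n]` (uncorrected)
#' @export
gini <- function(x, unbiased = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two values")
  if (any(is.na(x)) || any(x < 0)) stop("values must be non-negative")
  if (all(x == 0)) stop("Gini undefined for an all-zero vector")
  n <- length(x)
  g <- sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  if (unbiased) g <- g * n / (n - 1)
  g
}

#' Classify isoforms: preferential sets, housekeeping flags, Gini
#'
#' One-stop wrapper combining [preferential_sets()],
#' [housekeeping_flags()] and per-isoform [gini()] over tissue median CPM.
#'
#' @param de long pairwise table from [pairwise_de_all()]
#' @param expressed logical isoform x tissue expression calls
#' @param median_cpm isoform x tissue median CPM matrix (Gini input)
#' @param max_k,lfc,fdr see [preferential_sets()]
#' @param window see [housekeeping_flags()]
#' @param gini_unbiased small-sample Gini correction
#' @return data.frame per isoform: `isoform_id`, `k`, `preferential_set`,
#'   `housekeeping`, `gini`
#' @export
classify_isoforms <- function(de, expressed, median_cpm, max_k = 3, lfc = 1,
                              fdr = 0.1, window = 2, gini_unbiased = FALSE) {
  pref <- preferential_sets(de, max_k = max_k, lfc = lfc, fdr = fdr)
  hk <- housekeeping_flags(de, expressed, window = window)
  g <- vapply(pref$isoform_id, function(id) {
    if (!id %in% rownames(median_cpm)) return(NA_real_)
    v <- median_cpm[id, ]
    if (all(v == 0)) return(NA_real_)
    gini(v, unbiased = gini_unbiased)
  }, numeric(1))
  data.frame(pref[, c("isoform_id", "k", "preferential_set")],
             housekeeping = unname(hk[pref$isoform_id]),
             gini = unname(g), stringsAsFactors = FALSE)
}
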