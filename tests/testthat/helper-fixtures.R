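# Shared fixtures and independent oracles. Oracles are written from the
# definitions (direct enumeration / closed forms) and never call the code
# paths they check.

# --- toy annotations -------------------------------------------------------

# Three isoforms sharing a 3' terminal junction, plus a mono-exon isoform
# on the same gene's locus; plus-strand.
toy_shared_annotation <- function() {
  ex <- list(
    T1 = cbind(start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L)),
    T2 = cbind(start = c(300L, 500L, 900L), end = c(420L, 600L, 1000L)),
    T3 = cbind(start = c(500L, 900L), end = c(600L, 1000L)),
    M1 = cbind(start = 880L, end = 1050L)
  )
  tx <- data.frame(
    transcript_id = names(ex), gene_id = "G1", chrom = "chr1", strand = "+",
    transcript_biotype = c("protein_coding", "protein_coding", "lncRNA",
                           "protein_coding"),
    stringsAsFactors = FALSE)
  annotation(tx, ex)
}

# Five single-isoform genes of increasing exon count (2,4,...,10) and length.
ladder_annotation <- function() {
  tx <- list(); ex <- list(); off <- 1000L
  for (g in 1:5) {
    n_ex <- 2L * g
    starts <- off + seq(0L, by = 1200L, length.out = n_ex)
    e <- cbind(start = as.integer(starts), end = as.integer(starts + 200L))
    id <- sprintf("LAD%d.T1", g)
    ex[[id]] <- e
    tx[[g]] <- data.frame(transcript_id = id, gene_id = sprintf("LAD%d", g),
                          chrom = "chrL", strand = "+",
                          transcript_biotype = "protein_coding")
    off <- as.integer(max(e) + 20000L)
  }
  annotation(do.call(rbind, tx), ex)
}

# Gene A: two isoforms differing only in the 5' first exon (shared 4-exon
# body); gene B: two isoforms differing only in the 3' terminal exon.
pair_annotation <- function() {
  body <- function(off, n) {
    s <- as.integer(off + seq(0L, by = 1000L, length.out = n))
    cbind(start = s, end = s + 250L)
  }
  b <- body(5000L, 4)
  b2 <- body(50000L, 4)
  ex <- list(
    A.T1 = rbind(cbind(start = 3000L, end = 3250L), b),
    A.T2 = rbind(cbind(start = 3400L, end = 3700L), b),
    B.T1 = rbind(b2, cbind(start = 54500L, end = 54750L)),
    B.T2 = rbind(b2, cbind(start = 55200L, end = 55450L)))
  tx <- data.frame(transcript_id = names(ex),
                   gene_id = rep(c("A", "B"), each = 2),
                   chrom = "chrP", strand = "+",
                   transcript_biotype = "protein_coding",
                   stringsAsFactors = FALSE)
  annotation(tx, ex)
}

# --- independent oracles ---------------------------------------------------

# Brute-force read/transcript compatibility by direct sub-chain comparison.
bf_compatibility <- function(read, ann) {
  blocks <- as.matrix(read$blocks)
  compatible <- character(0); full_length <- character(0)
  for (id in ann$transcripts$transcript_id) {
    row <- ann$transcripts[id, ]
    if (row$chrom != read$chrom || row$strand != read$strand) next
    exons <- ann$exons[[id]]
    if (nrow(blocks) == 1) {
      inside <- FALSE
      for (i in seq_len(nrow(exons)))
        if (exons[i, 1] <= blocks[1, 1] && exons[i, 2] >= blocks[1, 2])
          inside <- TRUE
      if (inside) {
        compatible <- c(compatible, id)
        if (nrow(exons) == 1) full_length <- c(full_length, id)
      }
      next
    }
    rj <- junction_chain(blocks); tj <- junction_chain(exons)
    nr <- nrow(rj); nt <- nrow(tj)
    if (nt < nr) next
    found <- FALSE
    for (i in seq_len(nt - nr + 1))
      if (all(tj[i:(i + nr - 1), , drop = FALSE] == rj)) found <- TRUE
    if (!found) next
    contained <- TRUE
    for (b in seq_len(nrow(blocks))) {
      hit <- FALSE
      for (i in seq_len(nrow(exons)))
        if (exons[i, 1] <= blocks[b, 1] && exons[i, 2] >= blocks[b, 2])
          hit <- TRUE
      if (!hit) contained <- FALSE
    }
    if (!contained) next
    compatible <- c(compatible, id)
    if (nr == nt) full_length <- c(full_length, id)
  }
  list(compatible_ids = compatible, full_length_ids = full_length,
       unique = length(compatible) == 1L)
}

# Benjamini-Hochberg step-up, computed from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Pearson chi-square statistic from the closed form sum((O-E)^2 / E).
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Gini double sum, written out with explicit loops.
gini_oracle <- function(x) {
  n <- length(x); s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Exhaustive preferential-set search straight from the definition.
bf_preferential <- function(lfc_mat, fdr_mat, tissues, max_k = 3,
                            lfc = 1, fdr = 0.1) {
  nt <- length(tissues)
  for (k in seq_len(max_k)) {
    sets <- utils::combn(nt, k, simplify = FALSE)
    best <- NULL; best_tot <- -Inf
    for (S in sets) {
      ok <- TRUE; tot <- 0
      for (s in S) for (t in setdiff(seq_len(nt), S)) {
        if (!(lfc_mat[s, t] >= lfc && fdr_mat[s, t] < fdr)) ok <- FALSE
        tot <- tot + lfc_mat[s, t]
      }
      if (ok && tot > best_tot) { best <- S; best_tot <- tot }
    }
    if (!is.null(best))
      return(list(k = k, set = paste(tissues[best], collapse = "+")))
  }
  list(k = NA_integer_, set = NA_character_)
}

# Partial Spearman by a second, naive route: manual OLS on ranks, then
# Pearson correlation of the re-ranked residuals.
partial_spearman_oracle <- function(e, k, len) {
  re <- rank(e); rk <- rank(k); rl <- rank(len)
  resid_on <- function(y, x) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    y - mean(y) - b * (x - mean(x))
  }
  r1 <- rank(resid_on(re, rl)); r2 <- rank(resid_on(rk, rl))
  sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small counts bundle with random contents for round-trip tests.
random_bundle <- function(n_iso = 6, n_samp = 4, seed = 1) {
  set.seed(seed)
  tot <- matrix(runif(n_iso * n_samp, 0, 100), n_iso, n_samp,
                dimnames = list(sprintf("tx%d", seq_len(n_iso)),
                                sprintf("s%d", seq_len(n_samp))))
  u <- matrix(rbinom(n_iso * n_samp, 20, 0.3), n_iso, n_samp,
              dimnames = dimnames(tot))
  tot <- tot + u
  fl <- tot * matrix(runif(n_iso * n_samp), n_iso, n_samp)
  counts_bundle(tot, full_length = fl, unique = u,
                gene_ids = stats::setNames(rep(c("gA", "gB"), length.out = n_iso),
                                           rownames(tot)))
}
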