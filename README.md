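# isodiver

Surveying RNA isoform diversity across tissues from long-read RNA-seq
counts.

Long-read sequencing can observe whole RNA isoforms, but degradation
truncates cDNA from the 5′ end, so many reads carry only part of the
exon–junction structure that identifies their isoform. `isodiver`
implements the full analysis chain for this setting, for researchers
studying isoform-level expression across tissues:

- **Quantification** — reads are matched to isoforms by junction-chain
  compatibility (a spliced read is compatible with transcript *T* when its
  junction chain is a contiguous sub-chain of *T*'s), producing three
  metrics per isoform × sample: *total* counts (1/k credit over the k
  compatible isoforms), *full-length* counts (reads carrying some
  isoform's complete chain, 1/m over the m matches), and *unique* counts
  (reads compatible with exactly one isoform).
- **Expression calling** — CPM normalization; an isoform is *expressed* in
  a tissue when median CPM > 1 and median unique counts ≥ 1 across the
  tissue's samples; reproducible sample-inclusion rules (subject minimums,
  read-depth floor, replicate selection, PCA outlier flagging).
- **Diversity statistics** — expressed-isoform counts across a CPM
  threshold sweep, isoforms per gene at unique-count thresholds, exclusive
  (upset-style) tissue-overlap sets, protein-coding proportion contrasts
  (Pearson χ²).
- **Clustering** — hierarchical clustering of the gene × tissue
  isoform-count matrix for genes expressing > 5 isoforms somewhere.
- **Length-controlled correlation** — Spearman correlation of rank
  residuals of expression and isoform count after regressing out gene
  length ranks.
- **Differential expression** — pairwise per-isoform negative binomial
  Wald tests between tissues (median-of-ratios size factors,
  method-of-moments dispersion, BH correction per pair).
- **Classification** — *preferential* isoforms (log2FC ≥ 1 and FDR < 0.1
  versus every tissue outside a set of ≤ 3 tissues, exhaustive search over
  all 129 candidate sets), *housekeeping* isoforms (expressed everywhere,
  all pairwise |log2FC| ≤ 2), and the Gini coefficient
  G = Σᵢⱼ|xᵢ − xⱼ| / (2n²x̄) over per-tissue median CPM.
- **Synthetic data** — a seeded generator of annotations (GTF), truncated
  reads, and count matrices with planted preferential / housekeeping /
  noise isoforms, used to validate every stage end-to-end.

## Worked example

```r
library(isodiver)

sim  <- simulate_study(seed = 7)                       # planted 9-tissue design
summ <- tissue_expression_summary(sim$bundle, sim$meta)
colSums(summ$expressed)
#>      atrial_appendage cerebellar_hemisphere           fibroblasts
#>                   427                   427                   427
#>        frontal_cortex        left_ventricle                 liver
#>                   427                   427                   427
#>                  lung                muscle               putamen
#>                   427                   427                   427

keep <- rownames(summ$median_cpm)[apply(summ$median_cpm, 1, max) > 1]
de   <- pairwise_de_all(sim$bundle$total[keep, ], sim$meta,
                        sf = size_factors(sim$bundle$total))
cls  <- classify_isoforms(de, summ$expressed, summ$median_cpm)
table(k = cls$k, useNA = "ifany")
#> k
#>    1    2    3 <NA>
#>   34   10   10  373

head(subset(cls, !is.na(k)), 3)
#>    isoform_id k      preferential_set housekeeping      gini
#> 3 SYNG0002.T1 1 cerebellar_hemisphere        FALSE 0.3599036
#> 6 SYNG0003.T1 1                  lung        FALSE 0.4604288
#> 7 SYNG0003.T2 1                muscle        FALSE 0.3984181

ci <- correlation_input(summ, sim$meta, sim$annotation, "liver")
r  <- residual_rank_correlation(ci$expression, ci$isoform_count, ci$gene_length)
sprintf("rho = %.3f, p = %.3g, n = %d", r$rho, r$p, r$n)
#> [1] "rho = 0.413, p = 9.74e-09, n = 178"
```

Reading the output: every expressed isoform in this design passes the
call in all nine tissues (the planted background varies only mildly
across tissues), so each tissue reports the same 427 expressed isoforms.
The classifier recovers the 30 planted preferential isoforms (10 per set
size) plus the 20 planted single-tissue 8-fold "variable" isoforms, which
genuinely meet the one-tissue preferential criterion — 54 assignments at
k = 1–3, with a handful of background isoforms clearing the FDR 0.1 bar.
The liver correlation is positive: genes expressing more isoforms are
more highly expressed even after controlling for gene length, as the
shared-latent-factor construction of the background plants.

Real count matrices (e.g. transcript × sample TSVs from a long-read
quantifier, plus a sample metadata table) enter the same way through
`read_counts_tsv()` / `read_sample_meta()`, and annotations through
`read_gtf()`.

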