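---
title: "Methods: surveying RNA isoform diversity across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying RNA isoform diversity across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodiver)
```

# The problem

Long-read RNA sequencing makes it possible to observe individual RNA
isoforms rather than collapsed gene-level expression, but a large fraction
of reads still cannot be attributed to a single isoform: cDNA degradation
truncates molecules from the 5' end, so reads often carry only a suffix of
the junction structure that would identify their isoform. `isodiver`
implements a survey pipeline for this setting: a junction-chain quantifier
that produces three complementary count metrics, a noise-thresholded
expression caller, tissue-level diversity statistics, a
gene-length-controlled correlation between expression and isoform
diversity, pairwise negative binomial differential expression, and
preferential-tissue / housekeeping classifiers — all validated end-to-end
on synthetic multi-tissue data with planted ground truth.

# Quantification model

A transcript's **junction chain** is the ordered list of intron intervals
between consecutive exons; a spliced read's aligned blocks imply a chain
the same way. Compatibility is purely structural:

* a spliced read is compatible with transcript T when its junction chain
  is a contiguous sub-chain of T's chain at exact coordinates, on the same
  strand, with every block inside T's exons;
* a mono-block read is compatible with T when its span lies within a
  single exon of T (the minimal rule that lets single-exon genes be
  counted);
* a read is a **full-length** match for T when its chain equals T's entire
  chain — read ends need not reach the transcript ends;
* a read is **unique** when it is compatible with exactly one transcript.

From these, three matrices are accumulated per sample: `total` credits
each of a read's k compatible isoforms 1/k (a read equally likely to come
from two isoforms credits each 0.5); `full_length` credits 1/m over the m
full-length matches (nothing when m = 0); `unique` adds 1 only when k = 1.
Reads with no compatible isoform are tallied as unassigned, never dropped
silently. Splitting is uniform, not abundance-weighted: an
expectation-maximization reassignment would be a different method, and the
statistics downstream are designed around the uniform-split metrics.

One corner of this accounting is easy to miss: a truncated read can be
compatible with k isoforms yet full-length for only m < k of them, so the
full-length matrix is *not* elementwise bounded by the total matrix; the
bound holds per sample in the column sums, and that is what
`counts_bundle()` enforces.

Junction matching is exact by default. A tolerance parameter exists in the
matching key design for noisy real alignments but the package's simulated
reads are error-free, so the default is 0.

# Expression calling and sample inclusion

CPM is computed per sample against the column sum of the total-counts
matrix over all isoforms retained in the matrix — the library size is not
re-derived after filtering, which prevents threshold feedback. An isoform
counts as **expressed in a tissue** when its median CPM across the
tissue's samples is strictly greater than 1 *and* its median unique count
is at least 1. The unique-count condition guards against isoforms that are
never observed unambiguously; both thresholds are arguments (a CPM
threshold of 10 gives an ultra-conservative call). Medians over an even
number of samples are midpoint means, which matters exactly at the
boundary.

`filter_samples()` applies inclusion rules in a fixed order: drop samples
with an experimental condition, drop samples under one million reads, keep
one technical replicate per group (the highest-read replicate that stays
below the maximum read count among the tissue's other samples, so a
replicate cannot enter as an outlier), then drop tissues with fewer than
five unique subjects. Visual PCA screening is replaced by a reproducible
rule: principal components of log2(size-factor-normalized counts + 1),
flagging samples beyond 3 times their tissue's median centroid distance in
PC1–2. The rule is flag-only by default; exclusion is an explicit switch.

# Diversity statistics

`sweep_counts()` counts expressed isoforms per tissue over a CPM grid from
0 to 10.01 in 0.01 steps with the unique condition held fixed (or dropped,
for tallies of everything with positive expression). `isoforms_per_gene()`
counts either isoforms whose unique count reaches k in any sample
(k ∈ {1, 5, 10, 20}) or isoforms passing the per-tissue call.
`tissue_overlap()` uses exclusive (upset-style) semantics: each isoform
expressed anywhere belongs to exactly one combination — its exact
expressed-tissue set — so combination counts partition the expressed
isoforms, and singleton combinations define the isoforms unique to one
tissue. The protein-coding contrast between two tissues is a Pearson
chi-square on the 2×2 (protein-coding vs other) × (tissue vs tissue)
table, one degree of freedom, no continuity correction by default (counts
in this design are large; the correction is a switch). Biotype matching
normalizes hyphen/underscore variants of `protein_coding`.

# Clustering diverse genes

Genes expressing strictly more than five isoforms in at least one tissue
are selected, and the gene × tissue matrix of raw isoform counts is
clustered hierarchically (Euclidean distance, complete linkage by default;
ward and average linkage are options). Rows are sorted by gene id before
clustering, which makes leaf order deterministic and the result invariant
to input row order. The display cap (counts ≥ 7 share one color bin)
applies only to rendered values — clustering always sees raw counts.

# Length-controlled correlation

Total gene expression and the number of expressed isoforms are both
related to gene length, so the correlation between them is computed on
rank residuals: rank all three variables (average ranks on ties), regress
expression ranks and isoform-count ranks on length ranks by least squares,
and correlate the residuals. The default follows the stated procedure
literally — a Spearman test on the residual vectors (which re-ranks them);
the textbook partial-Spearman variant (Pearson on rank residuals) is
available via `method = "pearson"` and agrees within a few hundredths on
realistic inputs. Gene expression here is the per-tissue median gene CPM
*including* sub-threshold isoforms, and gene length is the genomic span of
the union of the gene's transcripts — the simplest reproducible choice
where several definitions are defensible; both choices are localized so
alternatives can be swapped in.

# Differential expression

Each tissue pair is tested independently: size factors by median-of-ratios
on the total-counts matrix, per-isoform negative binomial dispersion by
method of moments pooled over the two groups (variance model
μ + αμ², floored at 1e-8), log2 fold change with a pseudo-count of 0.5
normalized counts, a delta-method standard error, and a two-sided p-value.
The p-value uses a t reference with nA + nB − 2 degrees of freedom rather
than a normal: the standard error is estimated from that many degrees of
freedom, and with five samples per group a normal reference measurably
inflates the false positive rate (≈ 0.09 at nominal 0.05 in the package's
null simulations, versus ≈ 0.05 under the t reference). BH correction is
applied within each pair's family of tests (36 families for nine tissues);
a global correction across pairs is a defensible alternative and the
long-format output makes it a one-liner if wanted.

This is deliberately *not* a reimplementation of DESeq2 — no dispersion
shrinkage, no fold-change shrinkage, no independent filtering. The package
contribution is the classification layer over pairwise DE outputs;
absolute counts of classified isoforms on real data will differ from what
a DESeq2-based run produces, and that caveat travels with any attempt to
reproduce published classification tallies.

# Classification

**Preferential expression**: an isoform is preferentially expressed in a
tissue set S of size at most 3 when every in-set versus out-of-set
comparison shows log2FC ≥ 1 in the in-set tissue's favor with FDR < 0.1.
Comparisons within S are ignored. The search is exhaustive over the 129
subsets of size 1–3 of nine tissues, smallest size first; among equal-size
qualifying sets the largest total fold change wins. The fold-change
inequality is inclusive (≥ 1) by default with a strictness flag, since the
two natural readings differ only on the boundary.

**Housekeeping pattern**: expressed in every tissue and flat —
|log2FC| ≤ 2 for all 36 pairwise comparisons (inclusive, with a
strictness flag).

At these defaults the two labels are not logically exclusive: an isoform
expressed everywhere with all in-set fold changes between 1 and 2 can
satisfy both, and occasionally does. They become provably exclusive as
soon as the housekeeping window is smaller than the preferential
fold-change threshold, and the test suite asserts exclusivity in that
regime.

**Gini coefficient**: G = Σᵢⱼ|xᵢ − xⱼ| / (2n²x̄) over the nine per-tissue
median CPMs, uncorrected by default (the n/(n−1) small-sample correction
is a flag). Values below 0.3 conventionally indicate housekeeping-like
uniformity. The tissue-level summary (median CPM per tissue, n = 9) is
used rather than per-sample values, matching the tissue-level framing of
the classification.

# The synthetic-data generator

The generator is first-class, tested code — it defines the conditions
under which every downstream claim is checked.

`generate_annotation()` builds genes whose isoforms combine one of two
first exons, a subset of skippable internal exons, and one of two last
exons. The variant ordering is strand-aware so that every multi-isoform
gene contains a pair of isoforms whose chains differ only at the
transcriptional 5' end (indistinguishable once a read loses its 5'
junction) and a pair differing only in the terminal 3' exon
(distinguishable even under heavy truncation). A quarter of
single-isoform genes are mono-exonic, exercising the containment rule.

`simulate_reads()` models degradation as 3'-anchored truncation — the
orientation consequence of oligo-dT-primed, strand-oriented cDNA: with
probability `truncation_rate` (default 0.5) a read keeps only a uniform
(0.2, 1) fraction of its transcript, measured from the 3' end.

`simulate_counts()` draws total counts from a negative binomial with
variance μ + αμ² — the same parameterization the DE module fits, so
calibration checks are coherent — and thins them binomially into unique
and full-length counts.

`simulate_study()` fixes the default study conditions: nine tissues
matching a multi-tissue survey design (three brain regions, two heart
regions, fibroblasts, liver, lung, muscle), five samples from five unique
subjects per tissue (the minimum the inclusion rules accept), dispersion
0.1 (typical between-subject variability for bulk tissue), library sizes
uniform on 2–4 million reads (comfortably above the one-million inclusion
floor). Planted structure: 10 preferential isoforms per set size 1–3 at a
4-fold effect (log2FC 2 — above the detection threshold of 1 but near the
housekeeping window boundary, so recovery is a meaningful test), 20 flat
housekeeping isoforms, 20 "variable" isoforms with one tissue at 8-fold
(clear window violations for specificity measurement), 50 noise isoforms
with expected CPM below 0.5, and background isoforms rescaled per tissue
so expected CPM columns sum to one million — expected CPM then means what
it says. All draws are seeded; identical seeds give byte-identical
annotations and count matrices.

What the generator does *not* emulate: sequencing error and fuzzy junction
boundaries, abundance-dependent assignment ambiguity between
non-truncation-related isoform pairs, subject-level correlation across
tissues, batch effects, and the long-tailed isoform-per-gene distribution
of a real transcriptome. Passing recovery tests therefore demonstrates
that the statistical machinery is correct under its stated model, not that
real-data classification counts would be reproduced.

# Problem sizes and numerical choices

The validation suite uses deliberately desk-scale designs: null DE
calibration at 2,000 isoforms × 20 replicates (five samples per group),
planted-truth recovery on ~450 isoforms across nine tissues × 5 samples,
read-level bias checks at 1,500 reads × 3 seeds on purpose-built
five-gene ladders and two-gene pair annotations, and correlation checks
at n = 300–500 genes. Dispersion floors (1e-8), the fold-change
pseudo-count (0.5), and the zero-variance conventions (zero fold change
with zero spread gives p = 1) are all configurable and documented in the
function help.

Known limitations: uniform read splitting (no EM), no dispersion
moderation across isoforms, exact-coordinate junction matching, and a
span-based gene-length definition. Each is an explicit, localized choice
rather than an accident of implementation.
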