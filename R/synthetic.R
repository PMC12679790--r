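#' @importFrom stats rbinom rnbinom runif rlnorm setNames median
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' The nine-tissue panel used by the default synthetic design
#' @return character vector of nine tissue names
#' @export
default_tissues <- function() {
  c("atrial_appendage", "cerebellar_hemisphere", "fibroblasts",
    "frontal_cortex", "left_ventricle", "liver", "lung", "muscle",
    "putamen")
}

# Exon layout for one synthetic gene. Isoforms combine one of two
# genomically-first exons (different right boundaries, so the first
# junction differs), a subset of skippable internal exons, and one of two
# genomically-last exons (different left boundaries). Variant order is
# strand-aware so that the first two isoforms emitted always form a pair
# whose chains differ only at the transcriptional 5' end, and isoforms 1
# and 3 differ only in the terminal (UTR-like) 3' exon — together these
# exercise the truncation-driven unique-count degradation the quantifier
# is exposed to.
make_gene_isoforms <- function(k, offset, strand = "+") {
  m <- max(1L, ceiling(log2(max(k / 4, 1))))
  exon_len <- function() sample(150:350, 1)
  intron_len <- function() sample(500:1500, 1)

  f1 <- c(offset, offset + exon_len())
  f2 <- c(offset + 40, f1[2] + sample(60:120, 1))
  pos <- f2[2] + intron_len()
  internals <- vector("list", m)
  for (i in seq_len(m)) {
    internals[[i]] <- c(pos, pos + exon_len())
    pos <- internals[[i]][2] + intron_len()
  }
  l1 <- c(pos, pos + exon_len())
  l2 <- c(l1[2] + intron_len(), 0)
  l2[2] <- l2[1] + exon_len()

  firsts <- list(f1, f2)
  lasts <- list(l1, l2)
  combos <- list()
  # masks: full internal set first, then progressively sparser subsets
  masks <- order(-vapply(0:(2^m - 1), function(x) sum(bitwAnd(x, 2^(0:(m - 1))) > 0),
                         numeric(1)))
  masks <- (0:(2^m - 1))[masks]
  fl_order <- if (strand == "+")
    list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  else
    list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (mask in masks) {
    for (fl in fl_order) {
      keep <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      ex <- do.call(rbind, c(list(firsts[[fl[1]]]), internals[keep],
                             list(lasts[[fl[2]]])))
      combos[[length(combos) + 1]] <- ex
      if (length(combos) >= k) break
    }
    if (length(combos) >= k) break
  }
  list(exons = combos[seq_len(k)], end = l2[2])
}

#' Generate a synthetic transcript annotation
#'
#' Builds `n_genes` genes whose isoforms combine alternative first exons,
#' skippable internal exons and alternative last exons, so every gene with
#' two or more isoforms contains a pair whose junction chains differ only
#' at the 5' end (vulnerable to truncation-driven ambiguity) and a pair
#' differing only in the terminal exon. A configurable fraction of
#' single-isoform genes is emitted mono-exonic. Deterministic given `seed`.
#'
#' @param n_genes number of genes
#' @param isoforms_per_gene integer, vector of length `n_genes`, or the
#'   maximum of a uniform draw on 1..k (when length 1 and `sample_k =
#'   TRUE`)
#' @param sample_k draw per-gene isoform numbers uniformly from
#'   `1:isoforms_per_gene`
#' @param p_protein_coding probability a transcript is protein-coding
#' @param p_mono probability a single-isoform gene is mono-exonic
#' @param chrom chromosome name
#' @param seed RNG seed
#' @return an [annotation()]
#' @export
generate_annotation <- function(n_genes = 50, isoforms_per_gene = 4,
                                sample_k = TRUE, p_protein_coding = 0.7,
                                p_mono = 0.25, chrom = "chrS1", seed = 1) {
  with_seed(seed, {
    ks <- if (length(isoforms_per_gene) == n_genes) isoforms_per_gene
    else if (sample_k) sample(seq_len(isoforms_per_gene), n_genes, replace = TRUE)
    else rep(isoforms_per_gene, n_genes)
    offset <- 10000L
    tx_rows <- list(); exons <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("SYNG%04d", g)
      strand <- sample(c("+", "-"), 1)
      k <- ks[g]
      if (k == 1 && runif(1) < p_mono) {
        iso <- list(exons = list(cbind(offset, offset + sample(800:1500, 1))),
                    end = offset + 1500)
      } else {
        iso <- make_gene_isoforms(k, offset, strand)
      }
      for (t in seq_len(k)) {
        tid <- sprintf("%s.T%d", gid, t)
        ex <- matrix(as.integer(iso$exons[[t]]), ncol = 2)
        colnames(ex) <- c("start", "end")
        exons[[tid]] <- ex
        tx_rows[[length(tx_rows) + 1]] <- data.frame(
          transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
          transcript_biotype = if (runif(1) < p_protein_coding)
            "protein_coding" else "lncRNA",
          stringsAsFactors = FALSE)
      }
      offset <- as.integer(iso$end + sample(20000:50000, 1))
    }
    annotation(do.call(rbind, tx_rows), exons)
  })
}

tx_window_blocks <- function(exons, a, b) {
  # genomic blocks for the transcript-ascending coordinate window [a, b)
  w <- exons[, 2] - exons[, 1]
  cw <- cumsum(c(0, w))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(a, cw[i]); hi <- min(b, cw[i + 1])
    if (lo < hi)
      out[[length(out) + 1]] <- c(exons[i, 1] + (lo - cw[i]),
                                  exons[i, 1] + (hi - cw[i]))
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

#' Simulate truncated long reads from an annotation
#'
#' Reads are drawn isoform-proportionally to `abundance` and subjected to a
#' 5'-truncation degradation model: with probability `1 - truncation_rate`
#' a read retains its full transcript, otherwise it retains a 3'-anchored
#' suffix whose retained fraction is uniform on (`min_frac`, 1). Genomic
#' blocks follow from the retained transcript interval; reads inherit the
#' transcript strand.
#'
#' @param ann an [annotation()]
#' @param abundance named non-negative weights over transcript ids (one
#'   sample) or a transcripts x samples matrix
#' @param n_reads reads per sample
#' @param truncation_rate probability a read is truncated (default 0.5)
#' @param min_frac lower bound of the retained fraction (default 0.2)
#' @param seed RNG seed
#' @param sample_ids sample names (default `S1`, ...)
#' @return data.frame `read_id`, `sample_id`, `chrom`, `strand`, `blocks`
#'   (list-column), with attribute `source_isoform` giving each read's true
#'   isoform
#' @export
simulate_reads <- function(ann, abundance, n_reads, truncation_rate = 0.5,
                           min_frac = 0.2, seed = 1, sample_ids = NULL) {
  if (is.null(dim(abundance)))
    abundance <- matrix(abundance, ncol = 1,
                        dimnames = list(names(abundance), "S1"))
  if (!is.null(sample_ids)) colnames(abundance) <- sample_ids
  tx <- ann$transcripts
  with_seed(seed, {
    recs <- list()
    src <- character(0)
    for (s in colnames(abundance)) {
      w <- abundance[, s]
      ids <- sample(rownames(abundance), n_reads, replace = TRUE,
                    prob = w / sum(w))
      frac <- ifelse(runif(n_reads) < truncation_rate,
                     runif(n_reads, min_frac, 1), 1)
      for (r in seq_len(n_reads)) {
        id <- ids[r]
        ex <- ann$exons[[id]]
        L <- sum(ex[, 2] - ex[, 1])
        l <- max(1L, as.integer(round(frac[r] * L)))
        # 3'-anchored suffix: genomic-ascending window depends on strand
        win <- if (tx[id, "strand"] == "+") c(L - l, L) else c(0L, l)
        recs[[length(recs) + 1]] <- list(
          read_id = sprintf("%s_r%06d", s, r), sample_id = s,
          chrom = tx[id, "chrom"], strand = tx[id, "strand"],
          blocks = tx_window_blocks(ex, win[1], win[2]))
        src <- c(src, id)
      }
    }
    out <- data.frame(
      read_id = vapply(recs, `[[`, character(1), "read_id"),
      sample_id = vapply(recs, `[[`, character(1), "sample_id"),
      chrom = vapply(recs, `[[`, character(1), "chrom"),
      strand = vapply(recs, `[[`, character(1), "strand"),
      blocks = I(lapply(recs, `[[`, "blocks")),
      stringsAsFactors = FALSE)
    attr(out, "source_isoform") <- src
    out
  })
}

#' Simulate a counts bundle from per-tissue expected CPM
#'
#' Total counts are negative binomial with mean `cpm * libsize / 1e6` and
#' variance `mu + dispersion * mu^2`; unique and full-length counts are
#' binomial thinnings of the totals at per-isoform rates. Sample metadata
#' (one subject per sample) is generated alongside.
#'
#' @param mean_cpm isoform x tissue matrix of expected CPM
#' @param samples_per_tissue samples (= unique subjects) per tissue
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`)
#' @param libsize_range min/max of the uniform library-size draw
#' @param unique_rate,full_length_rate per-isoform thinning rates (scalar
#'   or named vector; defaults drawn uniform on (0.3, 0.9) / (0.3, 0.8))
#' @param gene_ids optional isoform -> gene map carried into the bundle
#' @param seed RNG seed
#' @return list with `bundle` (a [counts_bundle()]) and `meta` (sample
#'   metadata data.frame)
#' @export
simulate_counts <- function(mean_cpm, samples_per_tissue = 5,
                            dispersion = 0.1, libsize_range = c(2e6, 4e6),
                            unique_rate = NULL, full_length_rate = NULL,
                            gene_ids = NULL, seed = 1) {
  stopifnot(samples_per_tissue >= 2)
  mean_cpm <- as.matrix(mean_cpm)
  tissues <- colnames(mean_cpm)
  iso <- rownames(mean_cpm)
  ni <- length(iso)
  with_seed(seed, {
    if (is.null(unique_rate)) unique_rate <- runif(ni, 0.3, 0.9)
    if (is.null(full_length_rate)) full_length_rate <- runif(ni, 0.3, 0.8)
    unique_rate <- rep_len(unname(unique_rate), ni)
    full_length_rate <- rep_len(unname(full_length_rate), ni)
    samples <- as.vector(t(outer(tissues, seq_len(samples_per_tissue),
                                 function(t, i) sprintf("%s_s%d", t, i))))
    meta <- data.frame(
      sample_id = samples,
      subject_id = sprintf("subj_%s", samples),
      tissue = rep(tissues, each = samples_per_tissue),
      total_reads = as.integer(round(runif(length(samples),
                                           libsize_range[1], libsize_range[2]))),
      replicate_group = NA_character_,
      experimental_condition = NA_character_,
      stringsAsFactors = FALSE)
    total <- matrix(0, ni, length(samples), dimnames = list(iso, samples))
    uniq <- total; fl <- total
    for (j in seq_along(samples)) {
      mu <- mean_cpm[, meta$tissue[j]] * meta$total_reads[j] / 1e6
      tot <- rnbinom(ni, mu = mu, size = 1 / dispersion)
      total[, j] <- tot
      uniq[, j] <- rbinom(ni, tot, unique_rate)
      fl[, j] <- rbinom(ni, tot, full_length_rate)
    }
    list(bundle = counts_bundle(total, full_length = fl, unique = uniq,
                                gene_ids = gene_ids),
         meta = meta)
  })
}

#' Default multi-tissue study design with planted ground truth
#'
#' Emulates the statistical structure of a nine-tissue long-read survey:
#' isoforms are planted as *preferential* (upregulated `effect_fold`-fold
#' in a tissue set of size 1-3), *housekeeping* (flat across all tissues),
#' *variable* (flat except one tissue at `variable_fold`), *background*
#' (mildly varying profiles), or *noise* (below the expression threshold),
#' and counts are drawn with [simulate_counts()].
#'
#' @param n_genes genes in the synthetic annotation
#' @param max_isoforms maximum isoforms per gene
#' @param n_pref_per_k planted preferential isoforms per set size 1, 2, 3
#' @param n_housekeeping,n_variable,n_noise planted counts per label
#' @param effect_fold preferential in-set fold change (default 4, i.e.
#'   log2FC 2)
#' @param variable_fold single-tissue fold for the variable label
#' @param samples_per_tissue samples per tissue (default 5)
#' @param dispersion NB dispersion (default 0.1)
#' @param tissues tissue names (default the nine-tissue panel)
#' @param seed RNG seed
#' @return list with `annotation`, `truth` (data.frame `isoform_id`,
#'   `gene_id`, `label`, `pref_set`), `mean_cpm`, `bundle`, `meta`
#' @export
simulate_study <- function(n_genes = 180, max_isoforms = 4,
                           n_pref_per_k = 10, n_housekeeping = 20,
                           n_variable = 20, n_noise = 50,
                           effect_fold = 4, variable_fold = 8,
                           samples_per_tissue = 5, dispersion = 0.1,
                           tissues = default_tissues(), seed = 1) {
  ann <- generate_annotation(n_genes = n_genes,
                             isoforms_per_gene = max_isoforms, seed = seed)
  iso <- ann$transcripts$transcript_id
  nt <- length(tissues)
  n_pref <- 3 * n_pref_per_k
  need <- n_pref + n_housekeeping + n_variable + n_noise
  if (length(iso) < need + 50)
    stop("annotation too small for the planted design; increase n_genes")
  with_seed(seed + 1L, {
    shuffled <- sample(iso)
    take <- function(n) {
      out <- shuffled[seq_len(n)]
      shuffled <<- shuffled[-seq_len(n)]
      out
    }
    pref_ids <- take(n_pref)
    hk_ids <- take(n_housekeeping)
    var_ids <- take(n_variable)
    noise_ids <- take(n_noise)
    bg_ids <- shuffled

    mean_cpm <- matrix(0, length(iso), nt, dimnames = list(iso, tissues))
    truth <- data.frame(isoform_id = iso,
                        gene_id = unname(transcript_genes(ann)[iso]),
                        label = "background", pref_set = NA_character_,
                        stringsAsFactors = FALSE)
    rownames(truth) <- iso

    ks <- rep(1:3, each = n_pref_per_k)
    for (i in seq_along(pref_ids)) {
      id <- pref_ids[i]
      base <- rlnorm(1, log(20), 0.4)
      set <- sort(sample(tissues, ks[i]))
      mean_cpm[id, ] <- base
      mean_cpm[id, set] <- base * effect_fold
      truth[id, "label"] <- "preferential"
      truth[id, "pref_set"] <- paste(set, collapse = "+")
    }
    for (id in hk_ids) {
      mean_cpm[id, ] <- rlnorm(1, log(50), 0.5)
      truth[id, "label"] <- "housekeeping"
    }
    for (id in var_ids) {
      base <- rlnorm(1, log(30), 0.4)
      mean_cpm[id, ] <- base
      mean_cpm[id, sample(tissues, 1)] <- base * variable_fold
      truth[id, "label"] <- "variable"
    }
    for (id in noise_ids) {
      mean_cpm[id, ] <- runif(1, 0.05, 0.4)
      truth[id, "label"] <- "noise"
    }
    for (id in bg_ids) {
      base <- rlnorm(1, log(8), 1)
      mean_cpm[id, ] <- base * rlnorm(nt, 0, 0.3)
    }
    # expected CPM must behave like CPM: rescale the background so each
    # tissue's expected column sum is 1e6 without touching planted ratios
    planted <- c(pref_ids, hk_ids, var_ids, noise_ids)
    for (t in tissues) {
      spare <- 1e6 - sum(mean_cpm[planted, t])
      mean_cpm[bg_ids, t] <- mean_cpm[bg_ids, t] *
        spare / sum(mean_cpm[bg_ids, t])
    }
  })
  sim <- simulate_counts(mean_cpm, samples_per_tissue = samples_per_tissue,
                         dispersion = dispersion,
                         gene_ids = transcript_genes(ann), seed = seed + 2L)
  list(annotation = ann, truth = truth, mean_cpm = mean_cpm,
       bundle = sim$bundle, meta = sim$meta)
}
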