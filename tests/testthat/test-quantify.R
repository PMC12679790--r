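test_that("junction chains follow from the exon chain", {
  expect_equal(unname(junction_chain(cbind(c(100, 300), c(200, 400)))),
               matrix(c(200, 300), ncol = 2))
  expect_equal(nrow(junction_chain(cbind(0, 1000))), 0L)
  expect_equal(unname(junction_chain(cbind(c(0, 20, 40), c(10, 30, 50)))),
               matrix(c(10, 30, 20, 40), ncol = 2))
})

test_that("full-chain reads are unique and full-length", {
  ann <- toy_shared_annotation()
  read <- list(chrom = "chr1", strand = "+",
               blocks = cbind(c(150L, 500L, 900L), c(200L, 600L, 950L)))
  cm <- compatibility(read, ann)
  expect_equal(cm$compatible_ids, "T1")
  expect_equal(cm$full_length_ids, "T1")
  expect_true(cm$unique)
})

test_that("truncated reads over a shared terminal junction are ambiguous", {
  ann <- toy_shared_annotation()
  # covers only the shared (600,900) junction: compatible with T1, T2, T3;
  # full-length only for T3, whose whole chain is that one junction
  read <- list(chrom = "chr1", strand = "+",
               blocks = cbind(c(550L, 900L), c(600L, 980L)))
  cm <- compatibility(read, ann)
  expect_setequal(cm$compatible_ids, c("T1", "T2", "T3"))
  expect_equal(cm$full_length_ids, "T3")
  expect_false(cm$unique)
  expect_equal(bf_compatibility(read, ann)[c("compatible_ids", "full_length_ids")],
               cm[c("compatible_ids", "full_length_ids")])
})

test_that("mono-block reads match by containment in an exonic stretch", {
  ann <- toy_shared_annotation()
  # inside the last exon shared by T1, T2, T3 and inside mono-exon M1
  read <- list(chrom = "chr1", strand = "+",
               blocks = cbind(920L, 990L))
  cm <- compatibility(read, ann)
  expect_setequal(cm$compatible_ids, c("T1", "T2", "T3", "M1"))
  expect_equal(cm$full_length_ids, "M1")
  expect_false(cm$unique)
  # wrong strand: nothing
  cm2 <- compatibility(list(chrom = "chr1", strand = "-",
                            blocks = cbind(920L, 990L)), ann)
  expect_length(cm2$compatible_ids, 0)
  # unknown chromosome: unassigned, not an error
  cm3 <- compatibility(list(chrom = "chrZ", strand = "+",
                            blocks = cbind(920L, 990L)), ann)
  expect_length(cm3$compatible_ids, 0)
})

test_that("compatibility agrees with the brute-force oracle on random reads", {
  for (seed in 1:3) {
    ann <- generate_annotation(n_genes = 3, isoforms_per_gene = 4,
                               sample_k = FALSE, p_mono = 0, seed = seed)
    ab <- stats::setNames(rep(1, nrow(ann$transcripts)),
                          ann$transcripts$transcript_id)
    reads <- simulate_reads(ann, ab, n_reads = 60, truncation_rate = 0.7,
                            seed = seed + 50)
    for (r in seq_len(nrow(reads))) {
      read <- list(chrom = reads$chrom[r], strand = reads$strand[r],
                   blocks = reads$blocks[[r]])
      got <- compatibility(read, ann)
      want <- bf_compatibility(read, ann)
      expect_setequal(got$compatible_ids, want$compatible_ids)
      expect_setequal(got$full_length_ids, want$full_length_ids)
      expect_equal(got$unique, want$unique)
    }
  }
})

test_that("quantification splits credit 1/k and conserves reads", {
  ann <- toy_shared_annotation()
  full_T1 <- cbind(c(120L, 500L, 900L), c(200L, 600L, 1000L))
  reads10 <- data.frame(
    read_id = sprintf("r%d", 1:10), sample_id = "S1", chrom = "chr1",
    strand = "+", blocks = I(replicate(10, full_T1, simplify = FALSE)))
  b <- quantify_reads(reads10, ann)
  expect_equal(b$total["T1", "S1"], 10)
  expect_equal(b$full_length["T1", "S1"], 10)
  expect_equal(b$unique["T1", "S1"], 10)

  # one read compatible with T1 and T2 -> 0.5 each
  shared <- cbind(c(550L, 900L), c(600L, 960L))  # also T3-compatible
  amb <- list(chrom = "chr1", strand = "+", blocks = shared)
  k <- length(compatibility(amb, ann)$compatible_ids)
  one <- data.frame(read_id = "r", sample_id = "S1", chrom = "chr1",
                    strand = "+", blocks = I(list(shared)))
  b2 <- quantify_reads(one, ann)
  expect_equal(b2$total["T1", "S1"], 1 / k)
  expect_equal(b2$total["T2", "S1"], 1 / k)
  expect_equal(sum(b2$total), 1)

  # conservation on a simulated read set, per sample, exactly
  ab <- stats::setNames(rep(1, 4), c("T1", "T2", "T3", "M1"))
  sim <- simulate_reads(ann, cbind(S1 = ab, S2 = ab), n_reads = 150,
                        truncation_rate = 0.6, seed = 9)
  bs <- quantify_reads(sim, ann)
  assigned <- colSums(bs$total) + attr(bs, "unassigned")
  expect_equal(unname(assigned), c(150, 150))
  expect_true(all(bs$unique <= bs$total + 1e-9))
  expect_true(all(colSums(bs$full_length) <= colSums(bs$total) + 1e-9))
})

test_that("reads round-trip through the JSON-lines interchange", {
  ann <- toy_shared_annotation()
  ab <- stats::setNames(rep(1, 4), names(ann$exons))
  reads <- simulate_reads(ann, ab, n_reads = 20, truncation_rate = 0.5,
                          seed = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reads(reads, path)
  back <- read_reads(path)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sample_id, reads$sample_id)
  for (i in seq_len(nrow(reads)))
    expect_equal(unname(back$blocks[[i]]), unname(reads$blocks[[i]]))
})
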