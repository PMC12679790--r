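test_that("threshold sweep counts and monotonicity", {
  # constructed tissue: 40 isoforms with median CPM in (1,10], 10 above 10,
  # 5 in (0,1], all with median unique >= 1
  med_cpm <- matrix(c(seq(1.2, 9.9, length.out = 40),
                      seq(10.5, 50, length.out = 10),
                      seq(0.1, 0.9, length.out = 5)), ncol = 1,
                    dimnames = list(sprintf("i%02d", 1:55), "liver"))
  med_u <- matrix(1, 55, 1, dimnames = dimnames(med_cpm))
  sw <- sweep_counts(med_cpm, med_u, grid = c(0, 1, 10))
  expect_equal(sw$n_isoforms[sw$threshold == 1], 50)
  expect_equal(sw$n_isoforms[sw$threshold == 10], 10)
  expect_equal(sw$n_isoforms[sw$threshold == 0], 55)

  # unfiltered variant at threshold 0 counts every positive median CPM
  med_u0 <- med_u; med_u0[1:20, ] <- 0
  sw0 <- sweep_counts(med_cpm, grid = 0, require_unique = FALSE)
  expect_equal(sw0$n_isoforms, 55)
  swu <- sweep_counts(med_cpm, med_u0, grid = 0)
  expect_equal(swu$n_isoforms, 35)

  # full grid is non-increasing for every tissue
  set.seed(8)
  mc <- matrix(rexp(200 * 3, 1 / 3), 200, 3,
               dimnames = list(paste0("i", 1:200), c("a", "b", "c")))
  mu <- matrix(rbinom(600, 3, 0.7), 200, 3, dimnames = dimnames(mc))
  sw2 <- sweep_counts(mc, mu)
  for (t in c("a", "b", "c")) {
    curve <- sw2$n_isoforms[sw2$tissue == t]
    expect_true(all(diff(curve) <= 0))
  }
})

test_that("isoforms per gene honour unique-count thresholds", {
  u <- rbind(i1 = c(1, 0, 0), i2 = c(4, 2, 0), i3 = c(0, 0, 0))
  colnames(u) <- paste0("s", 1:3)
  g <- c(i1 = "g1", i2 = "g1", i3 = "g1")
  expect_equal(unname(isoforms_per_gene(u, g, k = 1)["g1"]), 2L)
  expect_equal(unname(isoforms_per_gene(u, g, k = 5)["g1"]), 0L)
  # monotone over k for random matrices
  set.seed(4)
  u2 <- matrix(rnbinom(300, mu = 4, size = 1), 60, 5,
               dimnames = list(paste0("i", 1:60), paste0("s", 1:5)))
  g2 <- stats::setNames(rep(paste0("g", 1:12), each = 5), rownames(u2))
  prev <- NULL
  for (k in c(1, 5, 10, 20)) {
    cnt <- isoforms_per_gene(u2, g2, k = k)
    if (!is.null(prev)) expect_true(all(cnt <= prev))
    prev <- cnt
  }
})

test_that("a planted 12-isoform gene is counted in full at k = 1", {
  ann <- generate_annotation(n_genes = 1, isoforms_per_gene = 12,
                             sample_k = FALSE, p_mono = 0, seed = 3)
  ids <- ann$transcripts$transcript_id
  expect_length(ids, 12)
  u <- matrix(0L, 12, 2, dimnames = list(ids, c("s1", "s2")))
  u[, 1] <- 1L
  cnt <- isoforms_per_gene(u, transcript_genes(ann), k = 1)
  expect_equal(unname(cnt["SYNG0001"]), 12L)
})

test_that("tissue overlap uses exclusive combinations that partition", {
  e <- rbind(i1 = c(TRUE, FALSE, FALSE), i2 = c(TRUE, FALSE, FALSE),
             i3 = c(TRUE, TRUE, FALSE), i4 = c(TRUE, TRUE, TRUE))
  colnames(e) <- c("A", "B", "C")
  ov <- tissue_overlap(e)
  expect_equal(ov$n_isoforms[ov$combination == "A"], 2L)
  expect_equal(ov$n_isoforms[ov$combination == "A+B"], 1L)
  expect_equal(ov$n_isoforms[ov$combination == "A+B+C"], 1L)
  ut <- unique_to_tissue(e)
  expect_equal(ut$n_unique, c(A = 2L, B = 0L, C = 0L), ignore_attr = TRUE)

  # partition property on random flag matrices
  for (seed in 1:3) {
    set.seed(seed)
    r <- matrix(runif(400) < 0.4, 100, 4,
                dimnames = list(paste0("i", 1:100), paste0("t", 1:4)))
    ov2 <- tissue_overlap(r)
    expect_equal(sum(ov2$n_isoforms), sum(rowSums(r) > 0))
    ut2 <- unique_to_tissue(r)
    singles <- ov2[ov2$n_tissues == 1, ]
    for (t in colnames(r))
      expect_equal(ut2$n_unique[ut2$tissue == t],
                   if (t %in% singles$combination)
                     singles$n_isoforms[singles$combination == t] else 0L)
  }
})

test_that("protein-coding proportion contrast matches the closed form", {
  # identical proportions -> statistic 0, p = 1
  e <- matrix(TRUE, 100, 2, dimnames = list(paste0("i", 1:100), c("A", "B")))
  bt <- stats::setNames(rep(c("protein_coding", "lncRNA"), 50), rownames(e))
  r0 <- pc_proportion_test(e, bt, "A", "B")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # hand-built 2x2: 30/70 protein-coding in A, 60/40 in B
  e2 <- rbind(matrix(c(TRUE, FALSE), 100, 2, byrow = TRUE,
                     dimnames = list(paste0("a", 1:100), c("A", "B"))),
              matrix(c(FALSE, TRUE), 100, 2, byrow = TRUE,
                     dimnames = list(paste0("b", 1:100), c("A", "B"))))
  bt2 <- stats::setNames(c(rep("protein_coding", 30), rep("lncRNA", 70),
                           rep("protein_coding", 60), rep("lncRNA", 40)),
                         rownames(e2))
  r <- pc_proportion_test(e2, bt2, "A", "B")
  expect_equal(r$table, rbind(A = c(30, 70), B = c(60, 40)),
               ignore_attr = TRUE)
  expect_equal(r$statistic, chisq_oracle(r$table))
  expect_equal(r$p, stats::pchisq(chisq_oracle(r$table), 1, lower.tail = FALSE))
  # symmetric in tissue order
  r_swap <- pc_proportion_test(e2, bt2, "B", "A")
  expect_equal(r_swap$statistic, r$statistic)

  # hyphen/underscore biotype variants normalize
  bt3 <- bt2
  bt3[1:30] <- "protein-coding"
  expect_equal(pc_proportion_test(e2, bt3, "A", "B")$statistic, r$statistic)

  # degenerate table errors
  e3 <- e2; bt4 <- stats::setNames(rep("lncRNA", 200), rownames(e2))
  expect_error(pc_proportion_test(e3, bt4, "A", "B"), "zero")
})
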