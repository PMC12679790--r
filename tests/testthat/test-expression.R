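make_meta <- function(tissues, n_per = 3) {
  samples <- as.vector(t(outer(tissues, seq_len(n_per), paste, sep = "_s")))
  data.frame(sample_id = samples,
             subject_id = paste0("subj_", samples),
             tissue = rep(tissues, each = n_per),
             total_reads = 2e6,
             stringsAsFactors = FALSE)
}

test_that("cpm normalizes columns to one million", {
  m <- matrix(c(100, 0, 25, 75), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cp <- cpm(m)
  expect_equal(cp["a", "s1"], 1e6)
  expect_equal(unname(cp[, "s2"]), c(250000, 750000))
  set.seed(3)
  r <- matrix(rpois(40, 50) + 1, 8, 5,
              dimnames = list(paste0("i", 1:8), paste0("s", 1:5)))
  expect_equal(unname(colSums(cpm(r))), rep(1e6, 5), tolerance = 1e-9)
  r[, 2] <- 0
  expect_error(cpm(r), "s2")
})

test_that("relative abundance sums to 100 within genes and flags zeros", {
  m <- matrix(c(25, 75, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ra <- relative_abundance(m, c(a = "g", b = "g"))
  expect_equal(unname(ra[, "s1"]), c(25, 75))
  expect_equal(unname(ra[, "s2"]), c(0, 0))
  expect_true(all(attr(ra, "undefined")[, "s2"]))
  gc <- gene_cpm(cpm(m[, "s1", drop = FALSE]), c(a = "g", b = "g"))
  expect_equal(unname(gc["g", "s1"]), 1e6)
})

test_that("expression calls apply strict CPM > and unique >= thresholds", {
  med_cpm <- matrix(c(1.2, 1.0, 5), 3, 1,
                    dimnames = list(c("a", "b", "c"), "liver"))
  med_u <- matrix(c(1, 3, 0.5), 3, 1, dimnames = dimnames(med_cpm))
  e <- expressed_flags(med_cpm, med_u)
  expect_equal(unname(e[, 1]), c(TRUE, FALSE, FALSE))
  # median over even n is the midpoint mean
  mat <- matrix(c(1, 2, 3, 4), 1, 4,
                dimnames = list("a", paste0("t_s", 1:4)))
  meta <- data.frame(sample_id = colnames(mat), tissue = "t")
  expect_equal(unname(tissue_medians(mat, meta)[1, 1]), 2.5)
})

test_that("example per-sample values produce the documented call", {
  cpm_mat <- matrix(c(1.2, 0.9, 1.5), 1, 3,
                    dimnames = list("iso", paste0("t_s", 1:3)))
  u_mat <- matrix(c(1, 1, 3), 1, 3, dimnames = dimnames(cpm_mat))
  meta <- data.frame(sample_id = colnames(cpm_mat), tissue = "t")
  mc <- tissue_medians(cpm_mat, meta)
  mu <- tissue_medians(u_mat, meta)
  expect_equal(unname(mc[1, 1]), 1.2)
  expect_equal(unname(mu[1, 1]), 1)
  expect_true(expressed_flags(mc, mu)[1, 1])
})

test_that("expression calls are monotone in the CPM threshold and order-invariant", {
  set.seed(5)
  meta <- make_meta(c("liver", "lung"), 5)
  tot <- matrix(rnbinom(40 * 10, mu = 60, size = 5), 40, 10,
                dimnames = list(paste0("i", 1:40), meta$sample_id))
  u <- matrix(rbinom(400, 10, 0.5), 40, 10, dimnames = dimnames(tot))
  b <- counts_bundle(tot + u, unique = u)
  s <- tissue_expression_summary(b, meta)
  prev <- Inf
  for (th in seq(0, 10, by = 0.5)) {
    n <- sum(expressed_flags(s$median_cpm, s$median_unique, cpm_thresh = th))
    expect_lte(n, prev)
    prev <- n
  }
  perm <- sample(ncol(tot))
  b2 <- counts_bundle(b$total[, perm], unique = u[, perm])
  s2 <- tissue_expression_summary(b2, meta)
  expect_equal(s2$expressed, s$expressed)
  rperm <- sample(nrow(tot))
  b3 <- counts_bundle(b$total[rperm, ], unique = u[rperm, ])
  s3 <- tissue_expression_summary(b3, meta)
  expect_equal(s3$expressed[rownames(s$expressed), ], s$expressed)
})

test_that("sample filter applies the inclusion rules in order", {
  meta <- data.frame(
    sample_id = c("l1", "l2", "l3", "l4", "l5", "k1", "k2", "k3", "k4",
                  "low", "cond"),
    subject_id = c(paste0("ls", 1:5), paste0("ks", 1:4), "ls1", "ls2"),
    tissue = c(rep("liver", 5), rep("kidney", 4), "liver", "liver"),
    total_reads = c(3e6, 2.5e6, 2.2e6, 2.8e6, 2.1e6, rep(2e6, 4),
                    999999, 5e6),
    replicate_group = NA_character_,
    experimental_condition = c(rep(NA, 10), "knockdown"),
    stringsAsFactors = FALSE)
  res <- filter_samples(meta)
  # condition sample and the 999,999-read sample go first
  expect_true(all(c("cond", "low") %in% res$exclusions$sample_id))
  expect_equal(res$exclusions$rule[res$exclusions$sample_id == "low"],
               "low_reads")
  # kidney has 4 unique subjects -> all dropped
  expect_false(any(startsWith(res$included, "k")))
  expect_setequal(res$included, c("l1", "l2", "l3", "l4", "l5"))
})

test_that("replicate selection keeps the highest below the tissue maximum", {
  meta <- data.frame(
    sample_id = c("r_lo", "r_hi", "other"),
    subject_id = c("subjA", "subjA", "subjB"),
    tissue = "liver",
    total_reads = c(2.0e6, 3.5e6, 3.0e6),
    replicate_group = c("rg1", "rg1", NA),
    experimental_condition = NA_character_,
    stringsAsFactors = FALSE)
  res <- filter_samples(meta, min_subjects = 1)
  expect_true("r_lo" %in% res$included)
  expect_false("r_hi" %in% res$included)
  expect_equal(res$exclusions$rule, "technical_replicate")
})

test_that("PCA outlier rule flags a sample far from its tissue centroid", {
  set.seed(11)
  meta <- make_meta(c("liver", "lung"), 6)
  tot <- matrix(rnbinom(200 * 12, mu = 100, size = 10), 200, 12,
                dimnames = list(paste0("i", 1:200), meta$sample_id))
  tot[, "lung_s6"] <- rnbinom(200, mu = 1000, size = 1)  # corrupted sample
  out <- pca_outliers(tot, meta, k = 3)
  expect_true("lung_s6" %in% out)
  res <- filter_samples(meta, counts = tot, min_subjects = 2, pca = "flag")
  expect_true("lung_s6" %in%
                res$exclusions$sample_id[res$exclusions$rule == "pca_outlier_flag"])
  expect_true("lung_s6" %in% res$included)  # flag-only by default
  res2 <- filter_samples(meta, counts = tot, min_subjects = 2,
                         pca = "exclude")
  expect_false("lung_s6" %in% res2$included)
})
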