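test_that("median-of-ratios size factors match hand and brute-force oracles", {
  m <- matrix(5L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(size_factors_median_ratios(m),
               c(s1 = 1, s2 = 1, s3 = 1))

  a <- c(2L, 8L, 5L, 100L, 41L)
  m2 <- cbind(A = a, B = 2L * a)
  rownames(m2) <- paste0("g", 1:5)
  expect_equal(size_factors_median_ratios(m2),
               c(A = 1 / sqrt(2), B = sqrt(2)))

  withr::with_seed(77, {
    for (i in 1:5) {
      m3 <- matrix(rpois(20, 30) + 1L, 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
      expect_equal(size_factors_median_ratios(m3), brute_size_factors(m3),
                   tolerance = 1e-12)
    }
  })

  expect_error(size_factors_median_ratios(diag(3)), "all-positive")
})

test_that("method-of-moments dispersion matches hand computation and clamps", {
  # one cell of 5 samples; sf = 1 so normalized counts = counts
  y <- matrix(c(5, 5, 10, 15, 15,   # mean 10, var 25 -> alpha = 0.15
                10, 10, 10, 10, 10), # var 0 -> clamps to the floor
              nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:5)))
  fit <- estimate_dispersions(y, setNames(rep(1, 5), colnames(y)),
                              cells = rep("c1", 5))
  expect_equal(fit$table$alpha_mom[1], (25 - 10) / 100)
  expect_equal(fit$table$alpha_mom[2], 1e-8)
  expect_error(estimate_dispersions(y, setNames(rep(1, 5), colnames(y)),
                                    cells = paste0("c", 1:5)), "singleton")
})

test_that("dispersion recovery from NB data at deep replication", {
  withr::with_seed(123, {
    y <- matrix(rnbinom(100 * 200, mu = 100, size = 1 / 0.1), 100, 200)
  })
  dimnames(y) <- list(paste0("g", 1:100), paste0("s", 1:200))
  fit <- estimate_dispersions(y, setNames(rep(1, 200), colnames(y)),
                              cells = rep("c1", 200))
  hit <- mean(fit$table$alpha_mom > 0.07 & fit$table$alpha_mom < 0.13)
  expect_gte(hit, 0.9)
})

test_that("Wald contrast behaves correctly on symmetric and planted inputs", {
  sf <- setNames(rep(1, 6), paste0("s", 1:6))
  y <- matrix(rep(c(7L, 30L, 0L), each = 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g0"), names(sf)))
  res <- nb_wald_contrast(y, sf, rep(0.05, 3), paste0("s", 4:6),
                          paste0("s", 1:3))
  expect_equal(res$log2FC[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(res$p[1:2], c(1, 1), tolerance = 1e-10)
  expect_true(is.na(res$log2FC[3]) && is.na(res$p[3]))  # all-zero gene

  withr::with_seed(43, {
    y16 <- cbind(matrix(rnbinom(150, mu = 200, size = 100), ncol = 3),
                 matrix(rnbinom(150, mu = 3200, size = 100), ncol = 3))
  })
  dimnames(y16) <- list(paste0("g", 1:50), paste0("s", 1:6))
  res16 <- nb_wald_contrast(y16, sf, rep(0.01, 50), paste0("s", 4:6),
                            paste0("s", 1:3))
  expect_true(all(abs(res16$log2FC - 4) < 3.5 * res16$SE))
  expect_equal(mean(res16$log2FC), 4, tolerance = 0.05)
})

test_that("swapping groups negates log2FC and preserves p", {
  cfg <- wt_config(n_genes = 80, seed = 21, treatments = c("N", "T"))
  sim <- simulate_counts(generate_truth(cfg))
  sf <- size_factors_median_ratios(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, sim$sheet$treatment)
  a <- sim$sheet$sample[sim$sheet$treatment == "T"]
  b <- sim$sheet$sample[sim$sheet$treatment == "N"]
  r1 <- nb_wald_contrast(sim$counts, sf, disp, a, b)
  r2 <- nb_wald_contrast(sim$counts, sf, disp, b, a)
  ok <- !is.na(r1$p)
  expect_equal(r1$log2FC[ok], -r2$log2FC[ok], tolerance = 1e-6)
  expect_equal(r1$p[ok], r2$p[ok], tolerance = 1e-6)
})

test_that("gene permutation permutes all outputs identically", {
  cfg <- wt_config(n_genes = 40, seed = 31, treatments = c("N", "T"))
  sim <- simulate_counts(generate_truth(cfg))
  sf <- size_factors_median_ratios(sim$counts)
  perm <- withr::with_seed(1, sample(nrow(sim$counts)))
  a <- sim$sheet$sample[sim$sheet$treatment == "T"]
  b <- sim$sheet$sample[sim$sheet$treatment == "N"]
  disp <- estimate_dispersions(sim$counts, sf, sim$sheet$treatment)
  r1 <- nb_wald_contrast(sim$counts, sf, disp, a, b)
  disp_p <- estimate_dispersions(sim$counts[perm, ], sf,
                                 sim$sheet$treatment)
  r2 <- nb_wald_contrast(sim$counts[perm, ], sf, disp_p, a, b)
  expect_equal(r2$gene, r1$gene[perm])
  expect_equal(r2$log2FC, r1$log2FC[perm])
  expect_equal(r2$p, r1$p[perm])
})

test_that("contrast statistics are invariant to a common size-factor rescale", {
  cfg <- wt_config(n_genes = 50, seed = 51, treatments = c("N", "T"))
  sim <- simulate_counts(generate_truth(cfg))
  sf <- size_factors_median_ratios(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, sim$sheet$treatment)
  a <- sim$sheet$sample[sim$sheet$treatment == "T"]
  b <- sim$sheet$sample[sim$sheet$treatment == "N"]
  r1 <- nb_wald_contrast(sim$counts, sf, disp, a, b)
  r2 <- nb_wald_contrast(sim$counts, sf * 7.3, disp, a, b)
  ok <- !is.na(r1$p)
  expect_equal(r1$log2FC[ok], r2$log2FC[ok], tolerance = 1e-8)
  expect_equal(r1$SE[ok], r2$SE[ok], tolerance = 1e-8)
  expect_equal(r1$p[ok], r2$p[ok], tolerance = 1e-8)
})

test_that("BH adjustment matches the hand step-up and propagates missing", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  withr::with_seed(8, {
    p <- runif(50)
    expect_equal(bh_adjust(p), brute_bh(p))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_all_contrasts follows the design and recovers planted genes", {
  cfg <- sim_config(n_genes = 300, seed = 61,
                    genotypes = c(GP = 1, `hsfa2-1` = 0.6),
                    treatments = c("N", "T", "PT"))
  sim <- simulate_counts(generate_truth(cfg))
  expect_message(res <- run_all_contrasts(sim$counts, sim$sheet),
                 "skipping contrast P/N")
  expect_setequal(unique(res$contrast), c("T/N", "PT/N", "PT/T"))
  expect_equal(nrow(res), 300 * 3 * 2)

  cfg_wt <- wt_config(n_genes = 200, seed = 62)
  truth <- generate_truth(cfg_wt)
  sim_wt <- simulate_counts(truth)
  res_wt <- run_all_contrasts(sim_wt$counts, sim_wt$sheet)
  expect_setequal(unique(res_wt$contrast), c("T/N", "P/N", "PT/N", "PT/T"))
  hs_up <- truth$genes$gene[truth$genes$archetype == "hs_up"]
  get <- function(ct) res_wt[res_wt$contrast == ct &
                               res_wt$gene %in% hs_up, ]
  expect_gt(mean(get("T/N")$padj < 0.05 & get("T/N")$log2FC > 1), 0.8)
  expect_gt(mean(get("PT/N")$padj < 0.05 & get("PT/N")$log2FC > 1), 0.8)
  expect_lt(mean(get("PT/T")$padj < 0.05, na.rm = TRUE), 0.2)

  expect_error(run_all_contrasts(sim_wt$counts, sim_wt$sheet,
                                 genotypes = "nope"), "absent")
})

test_that("log2 fold changes agree with an established NB engine", {
  cfg <- wt_config(n_genes = 250, seed = 71, treatments = c("N", "T"),
                   archetype_proportions = c(constitutive = 0.7,
                                             hs_up = 0.15, hs_down = 0.15))
  sim <- simulate_counts(generate_truth(cfg))
  res <- suppressMessages(run_all_contrasts(sim$counts, sim$sheet,
                                            contrasts = "T/N"))

  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  coldata <- data.frame(treatment = factor(sim$sheet$treatment,
                                           levels = c("N", "T")),
                        row.names = sim$sheet$sample)
  dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts, coldata, ~treatment)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds, contrast = c("treatment", "T", "N"))

  keep <- res$baseMean > 5 & !is.na(res$log2FC) & !is.na(dres$log2FoldChange)
  expect_gt(cor(res$log2FC[keep], dres$log2FoldChange[keep]), 0.95)
  strong <- keep & !is.na(dres$padj) & dres$padj < 0.01 &
    abs(dres$log2FoldChange) > 1
  expect_gt(mean(res$padj[strong] < 0.05), 0.9)
})
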