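# build named lfc/padj vectors for the three type II contrasts
tri <- function(ptn, ptt, tn) {
  list(lfc = c(`PT/N` = ptn[1], `PT/T` = ptt[1], `T/N` = tn[1],
               `P/N` = tn[1]),
       padj = c(`PT/N` = ptn[2], `PT/T` = ptt[2], `T/N` = tn[2],
                `P/N` = tn[2]))
}

test_that("type II classification follows the re-induction rule", {
  x <- tri(c(2.1, 0.001), c(1.4, 0.003), c(1.6, 0.002))
  expect_equal(classify_type_II(x$lfc, x$padj), "+/++")
  x <- tri(c(1.8, 0.001), c(1.2, 0.004), c(0.3, 0.60))
  expect_equal(classify_type_II(x$lfc, x$padj), "0/+")
  x <- tri(c(-1.5, 0.002), c(-1.2, 0.01), c(-1.4, 0.005))
  expect_equal(classify_type_II(x$lfc, x$padj), "-/--")
  x <- tri(c(-1.5, 0.002), c(-1.2, 0.01), c(0.1, 0.9))
  expect_equal(classify_type_II(x$lfc, x$padj), "0/-")
  x <- tri(c(2.1, 1), c(1.4, 1), c(1.6, 1))
  expect_equal(classify_type_II(x$lfc, x$padj), "none")
  x <- tri(c(2.1, 0.001), c(NA, NA), c(1.6, 0.002))
  expect_equal(classify_type_II(x$lfc, x$padj), "unclassifiable")
})

test_that("type I classification requires sustained response", {
  lfc <- c(`T/N` = 2.0, `P/N` = 1.5); padj <- c(`T/N` = 0.001, `P/N` = 0.01)
  expect_equal(classify_type_I(lfc, padj), "positive")
  lfc["P/N"] <- 0.2; padj["P/N"] <- 0.8
  expect_equal(classify_type_I(lfc, padj), "none")
  lfc <- c(`T/N` = -2.0, `P/N` = -1.2); padj <- c(`T/N` = 0.001, `P/N` = 0.02)
  expect_equal(classify_type_I(lfc, padj), "negative")
  expect_equal(classify_type_I(c(`T/N` = 1), c(`T/N` = 0.01)),
               "unclassifiable")
})

# the three sign/significance states per contrast used for enumeration
states <- list(up = c(2, 0.001), ns = c(0.2, 0.9), down = c(-2, 0.001))

test_that("decision table is total: one label per sign/significance pattern", {
  labels <- c("+/++", "0/+", "-/--", "0/-", "none")
  for (s1 in names(states)) for (s2 in names(states))
    for (s3 in names(states)) {
      x <- tri(states[[s1]], states[[s2]], states[[s3]])
      lab <- classify_type_II(x$lfc, x$padj)
      expect_true(lab %in% labels)
      expect_length(lab, 1)
    }
})

test_that("mirror symmetry: negating fold changes swaps the classes", {
  swap <- c("+/++" = "-/--", "0/+" = "0/-", "-/--" = "+/++",
            "0/-" = "0/+", none = "none")
  swap1 <- c(positive = "negative", negative = "positive", none = "none")
  for (s1 in names(states)) for (s2 in names(states))
    for (s3 in names(states)) {
      x <- tri(states[[s1]], states[[s2]], states[[s3]])
      lab <- classify_type_II(x$lfc, x$padj)
      neg <- classify_type_II(-x$lfc, x$padj)
      expect_equal(neg, unname(swap[lab]))
      lab1 <- classify_type_I(x$lfc, x$padj)
      neg1 <- classify_type_I(-x$lfc, x$padj)
      expect_equal(neg1, unname(swap1[lab1]))
    }
})

test_that("tightening thresholds never adds a gene to a union class", {
  withr::with_seed(99, {
    for (i in 1:200) {
      lfc <- setNames(rnorm(4, 0, 2), c("PT/N", "PT/T", "T/N", "P/N"))
      padj <- setNames(runif(4), c("PT/N", "PT/T", "T/N", "P/N"))
      union2 <- function(t, a) {
        lab <- classify_type_II(lfc, padj, t, a)
        c(pos = lab %in% c("+/++", "0/+"), neg = lab %in% c("-/--", "0/-"))
      }
      loose <- union2(1, 0.05)
      expect_true(all(union2(1.5, 0.05) <= loose))
      expect_true(all(union2(1, 0.01) <= loose))
      t1 <- function(t, a) classify_type_I(lfc, padj, t, a) != "none"
      expect_true(t1(1.5, 0.05) <= t1(1, 0.05))
      expect_true(t1(1, 0.01) <= t1(1, 0.05))
    }
  })
})

test_that("classify_all recovers planted memory genes and respects nulls", {
  cfg <- wt_config(
    n_genes = 400, seed = 17,
    archetype_proportions = c(constitutive = 0.75, typeII_pp = 0.125,
                              typeII_0p = 0.125))
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  res <- run_all_contrasts(sim$counts, sim$sheet)
  calls <- classify_all(res)
  planted_pp <- truth$genes$gene[truth$genes$archetype == "typeII_pp"]
  planted_zp <- truth$genes$gene[truth$genes$archetype == "typeII_0p"]
  expect_gt(mean(calls$typeII[match(planted_pp, calls$gene)] %in%
                   c("+/++", "0/+")), 0.8)
  expect_gt(mean(calls$typeII[match(planted_zp, calls$gene)] %in%
                   c("+/++", "0/+")), 0.8)

  # degenerate threshold: everything is none
  calls_inf <- classify_all(res, lfc_threshold = Inf)
  expect_true(all(calls_inf$typeII %in% c("none", "unclassifiable")))
  expect_true(all(calls_inf$typeI %in% c("none", "unclassifiable")))
})

# minimal hand-built contrast table covering two genotypes
mini_results <- function(mut_ptt = c(0.4, 0.7)) {
  rows <- list(
    c("g1", "GP", "T/N", 1.6, 0.002), c("g1", "GP", "P/N", 0.1, 0.9),
    c("g1", "GP", "PT/N", 2.1, 0.001), c("g1", "GP", "PT/T", 1.4, 0.003),
    c("g1", "mut", "T/N", 1.6, 0.002), c("g1", "mut", "P/N", 0.1, 0.9),
    c("g1", "mut", "PT/N", 2.1, 0.001),
    c("g1", "mut", "PT/T", mut_ptt[1], mut_ptt[2]))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[1], genotype = r[2], contrast = r[3],
               baseMean = 100, log2FC = as.numeric(r[4]), SE = 0.1,
               stat = 1, p = as.numeric(r[5]), padj = as.numeric(r[5]))))
  class(df) <- c("contrast_results", class(df))
  df
}

test_that("dependence calls: loss iff a defining criterion fails in the mutant", {
  calls <- classify_all(mini_results())
  dep <- dependence_on_genotype(calls, "GP", "mut")
  expect_equal(dep$table$class, "+/++")
  expect_equal(dep$table$mut, "lost")
  expect_equal(unname(dep$sets$lost_in_each["mut"]), 1)

  calls_same <- classify_all(mini_results(mut_ptt = c(1.4, 0.003)))
  dep_same <- dependence_on_genotype(calls_same, "GP", "mut")
  expect_equal(dep_same$table$mut, "retained")

  expect_error(dependence_on_genotype(calls, "GP", "missing"), "absent")
})

test_that("attenuated mutants lose more planted memory genes than null mutants", {
  run_loss <- function(gam, seed) {
    cfg <- sim_config(
      n_genes = 300, seed = seed,
      genotypes = c(GP = 1, mut = gam),
      archetype_proportions = c(constitutive = 0.8, typeII_pp = 0.1,
                                typeII_0p = 0.1))
    sim <- simulate_counts(generate_truth(cfg))
    calls <- classify_all(run_all_contrasts(sim$counts, sim$sheet))
    dep <- dependence_on_genotype(calls, "GP", "mut")
    if (nrow(dep$table) == 0) return(NA_real_)
    mean(dep$table$mut == "lost")
  }
  expect_gt(run_loss(0.4, 23), run_loss(1, 23))
})

test_that("hyper-induction counting uses the fold threshold correctly", {
  df <- mini_results(mut_ptt = c(1.4, 0.003))
  calls <- classify_all(df)
  gp <- hyper_induction_stats(calls, "GP", fold = 3)
  # PT/T log2FC = 1.4 < log2(3): not hyper-induced
  expect_equal(gp$count, 0)
  expect_equal(gp$n_positive, 1)
  gp2 <- hyper_induction_stats(calls, "GP", fold = 1)
  expect_equal(gp2$count, 1)  # fold = 1 subsumes every positive gene
  # 2^1.8 > 3 counts; rebuild with a high ratio
  df$log2FC[df$genotype == "GP" & df$contrast == "PT/T"] <- 1.8
  calls_hi <- classify_all(df)
  expect_equal(hyper_induction_stats(calls_hi, "GP", fold = 3)$count, 1)
  # empty positive set -> undefined fraction (mutant lost PT/T significance)
  none <- hyper_induction_stats(classify_all(mini_results()), "mut",
                                fold = 3)
  expect_true(is.na(none$fraction))
})

test_that("responsive-set overlap matches exhaustive set algebra", {
  genes <- paste0("g", 1:9)
  mk <- function(gt, up_genes) {
    data.frame(gene = genes, genotype = gt, contrast = "PT/N",
               baseMean = 10, log2FC = ifelse(genes %in% up_genes, 2, 0),
               SE = 0.1, stat = 1,
               p = ifelse(genes %in% up_genes, 1e-4, 0.9),
               padj = ifelse(genes %in% up_genes, 1e-4, 0.9))
  }
  setA <- c("g1", "g2", "g3", "g4")
  setB <- c("g3", "g4", "g5")
  setC <- c("g4", "g5", "g6")
  df <- rbind(mk("A", setA), mk("B", setB), mk("C", setC))
  class(df) <- c("contrast_results", class(df))
  ov <- responsive_set_overlap(df, "PT/N", "up")
  expect_equal(sort(ov$sets$A), sort(setA))
  # exhaustive enumeration of exclusive cells
  expect_equal(ov$cells[["A"]], 2)        # g1, g2
  expect_equal(ov$cells[["A+B"]], 1)      # g3
  expect_equal(ov$cells[["A+B+C"]], 1)    # g4
  expect_equal(ov$cells[["B+C"]], 1)      # g5
  expect_equal(ov$cells[["C"]], 1)        # g6

  ident <- responsive_set_overlap(rbind(mk("A", setA), mk("B", setA)),
                                  "PT/N", "up")
  expect_equal(sort(ident$cells[["A+B"]]), 4)
  disj <- responsive_set_overlap(rbind(mk("A", c("g1")), mk("B", c("g2"))),
                                 "PT/N", "up")
  expect_false("A+B" %in% names(disj$cells))
})
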