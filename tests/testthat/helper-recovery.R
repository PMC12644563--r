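# Shared pipeline-recovery runs used by the acceptance-style tests.

# Planted type II recovery: simulate, run the full pipeline on wild type,
# and compare calls against the planted archetypes.
typeII_recovery <- function(seed, n_genes = 2000) {
  cfg <- sim_config(
    n_genes = n_genes, seed = seed, genotypes = c(GP = 1),
    archetype_proportions = c(constitutive = 0.78, hs_up = 0.05,
                              hs_down = 0.05, typeII_pp = 0.03,
                              typeII_0p = 0.03, typeII_mm = 0.03,
                              typeII_0m = 0.03))
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  res <- run_all_contrasts(sim$counts, sim$sheet)
  calls <- classify_all(res)
  arch <- truth$genes$archetype[match(calls$gene, truth$genes$gene)]
  planted_pos <- arch %in% c("typeII_pp", "typeII_0p")
  planted_neg <- arch %in% c("typeII_mm", "typeII_0m")
  called_pos <- calls$typeII %in% c("+/++", "0/+")
  called_neg <- calls$typeII %in% c("-/--", "0/-")
  correct <- (planted_pos & called_pos) | (planted_neg & called_neg)
  list(
    n_planted = sum(planted_pos | planted_neg),
    n_called = sum(called_pos | called_neg),
    tp = sum(correct),
    fp = sum((called_pos | called_neg) & !(planted_pos | planted_neg)))
}

# All-constitutive null run: raw Wald rejection fraction and type II calls.
null_calibration <- function(seed, n_genes = 2000) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, genotypes = c(GP = 1),
                    treatments = c("N", "T", "PT"),
                    archetype_proportions = c(constitutive = 1))
  sim <- simulate_counts(generate_truth(cfg))
  res <- suppressMessages(
    run_all_contrasts(sim$counts, sim$sheet,
                      contrasts = c("T/N", "PT/N", "PT/T")))
  calls <- classify_all(res)
  list(reject = mean(res$p < 0.05, na.rm = TRUE),
       n_typeII = sum(!calls$typeII %in% c("none", "unclassifiable")))
}

# Amplifier-shift run: a 500-gene planted up-set within a mostly
# non-responsive genome (so median-of-ratios normalization stays valid),
# PT/N ratio ECDF wild type vs mutant.
amplifier_shift <- function(seed, gamma, n_genes = 2500) {
  cfg <- sim_config(
    n_genes = n_genes, seed = seed,
    genotypes = c(GP = 1, mut = gamma), treatments = c("N", "PT"),
    archetype_proportions = c(constitutive = 0.8, hs_up = 0.2))
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  res <- suppressMessages(
    run_all_contrasts(sim$counts, sim$sheet, contrasts = "PT/N"))
  up <- truth$genes$gene[truth$genes$archetype == "hs_up"]
  sh <- gene_set_ratio_ecdf(res, up, ratio = "PT/N", reference = "GP")
  shared <- length(intersect(strsplit(sh$letters[["GP"]], "")[[1]],
                             strsplit(sh$letters[["mut"]], "")[[1]])) > 0
  list(p = sh$ks$p["GP", "mut"],
       shift = sh$median_shift[["mut"]],
       letters_shared = shared)
}

# Reference-gene ranking run on a simulate_cq fixture.
refgene_recovery <- function(seed, noise_sd = 0.1) {
  sim <- simulate_cq(sim_config(n_genes = 8, seed = seed,
                                genotypes = c(GP = 1), n_reps = 4L),
                     n_stable = 4, n_unstable = 4, noise_sd = noise_sd)
  rep_ <- stability_report(sim$cq, sim$truth$gene)
  stable <- sim$truth$gene[sim$truth$stable]
  agg <- setNames(rep_$ranking$aggregate, rep_$ranking$gene)
  list(
    separated = max(agg[stable]) < min(agg[setdiff(names(agg), stable)]),
    genorm_eq_dct = identical(
      order(rep_$values$genorm[sim$truth$gene]),
      order(rep_$values$delta_ct[sim$truth$gene])))
}
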