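#' Simulation configuration for the priming/triggering design
#'
#' Describes the study conditions the generators emulate: a gene panel with
#' planted expression archetypes, a factorial design of genotypes (wild type
#' plus mutants with attenuated heat responses) and treatments drawn from
#' \code{N} (untreated), \code{T} (triggered), \code{P} (primed) and \code{PT}
#' (primed then triggered), negative-binomial counts with a dispersion trend,
#' and lognormal library depths.
#'
#' The archetypes encode, on the log2 scale relative to \code{N}:
#' \describe{
#'   \item{constitutive}{no response in any treatment.}
#'   \item{hs_up / hs_down}{the same response after each heat treatment
#'     (\code{T} and \code{PT}), no memory.}
#'   \item{typeI_pos / typeI_neg}{sustained (de)induction: responsive in
#'     \code{T} and still shifted in \code{P}.}
#'   \item{typeII_pp / typeII_mm}{"+/++" / "-/--" memory: responsive after one
#'     treatment (\code{e_T}) and more strongly after two (extra
#'     \code{delta} on \code{PT} vs \code{T}).}
#'   \item{typeII_0p / typeII_0m}{"0/+" / "0/-" memory: no response after one
#'     treatment, a response of \code{delta} only after two.}
#' }
#' Mutant genotypes carry an attenuation factor \eqn{\gamma \in (0, 1]} that
#' multiplies every heat-responsive log2 effect (the "amplifier" model of the
#' memory transcription factors); the wild type has \eqn{\gamma = 1}.
#'
#' @param n_genes number of genes.
#' @param n_reps biological replicates per genotype x treatment cell.
#' @param genotypes named numeric vector of attenuation factors
#'   \eqn{\gamma}; names are genotype labels, first entry is treated as the
#'   wild type/reference.
#' @param treatments subset of \code{c("N","T","P","PT")}; must contain
#'   \code{"N"}.
#' @param archetype_proportions named fractions over the nine archetypes,
#'   summing to 1.
#' @param effect_sizes named list of per-archetype log2 effect sizes (see
#'   Details / defaults).
#' @param baseline_log_mean_mu,baseline_log_mean_sd lognormal (natural-log)
#'   parameters of baseline expression means.
#' @param dispersion_trend numeric \code{c(a0, a1)} of the dispersion trend
#'   \eqn{\alpha(\mu) = a1/\mu + a0}.
#' @param library_size_sd log-scale SD of per-sample depth multipliers
#'   (median-centred).
#' @param seed root integer seed; all generators derive fixed, independent
#'   substreams from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_reps = 3L,
                       genotypes = c(GP = 1, `hsfa2-1` = 0.6, `hsfa3-1` = 0.6),
                       treatments = c("N", "T", "P", "PT"),
                       archetype_proportions = c(
                         constitutive = 0.76, hs_up = 0.05, hs_down = 0.05,
                         typeI_pos = 0.01, typeI_neg = 0.01,
                         typeII_pp = 0.03, typeII_0p = 0.03,
                         typeII_mm = 0.03, typeII_0m = 0.03),
                       effect_sizes = list(
                         hs_up = c(e = 3), hs_down = c(e = 3),
                         typeI_pos = c(e_T = 2, e_P = 1.5),
                         typeI_neg = c(e_T = 2, e_P = 1.5),
                         typeII_pp = c(e_T = 2, delta = 2),
                         typeII_0p = c(delta = 2),
                         typeII_mm = c(e_T = 2, delta = 2),
                         typeII_0m = c(delta = 2)),
                       baseline_log_mean_mu = 5,
                       baseline_log_mean_sd = 1.5,
                       dispersion_trend = c(a0 = 0.01, a1 = 2),
                       library_size_sd = 0.1,
                       seed = 1L) {
  archetypes <- c("constitutive", "hs_up", "hs_down", "typeI_pos", "typeI_neg",
                  "typeII_pp", "typeII_0p", "typeII_mm", "typeII_0m")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_reps < 2) stop("n_reps must be >= 2 (replication is required downstream)")
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named vector of attenuation factors")
  if (any(genotypes <= 0 | genotypes > 1))
    stop("attenuation factors must lie in (0, 1]")
  if (!all(treatments %in% TREATMENT_LEVELS))
    stop("unknown treatment code(s): ",
         paste(setdiff(treatments, TREATMENT_LEVELS), collapse = ", "))
  unknown <- setdiff(names(archetype_proportions), archetypes)
  if (length(unknown))
    stop("unknown archetype label(s): ", paste(unknown, collapse = ", "))
  props <- setNames(numeric(length(archetypes)), archetypes)
  props[names(archetype_proportions)] <- archetype_proportions
  if (abs(sum(props) - 1) > 1e-9)
    stop("archetype proportions must sum to 1 (got ", sum(props), ")")
  if (props[["typeII_pp"]] > 0) {
    es <- effect_sizes$typeII_pp
    if (es[["e_T"]] <= 1 || es[["delta"]] <= 1)
      stop("typeII_pp effect sizes must satisfy e_T > 1 and delta > 1")
  }
  if (any(dispersion_trend < 0)) stop("dispersion trend parameters must be >= 0")
  if (library_size_sd < 0) stop("library_size_sd must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
    genotypes = genotypes, treatments = treatments,
    archetype_proportions = props, effect_sizes = effect_sizes,
    baseline_log_mean_mu = baseline_log_mean_mu,
    baseline_log_mean_sd = baseline_log_mean_sd,
    dispersion_trend = dispersion_trend,
    library_size_sd = library_size_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# Wild-type log2 effects (T, P, PT vs N) for one archetype.
archetype_theta <- function(archetype, effect_sizes) {
  g <- function(a, nm) unname(effect_sizes[[a]][[nm]])
  switch(archetype,
    constitutive = c(0, 0, 0),
    hs_up   = c(g("hs_up", "e"), 0, g("hs_up", "e")),
    hs_down = c(-g("hs_down", "e"), 0, -g("hs_down", "e")),
    typeI_pos = c(g("typeI_pos", "e_T"), g("typeI_pos", "e_P"),
                  g("typeI_pos", "e_T")),
    typeI_neg = c(-g("typeI_neg", "e_T"), -g("typeI_neg", "e_P"),
                  -g("typeI_neg", "e_T")),
    typeII_pp = c(g("typeII_pp", "e_T"), 0,
                  g("typeII_pp", "e_T") + g("typeII_pp", "delta")),
    typeII_0p = c(0, 0, g("typeII_0p", "delta")),
    typeII_mm = c(-g("typeII_mm", "e_T"), 0,
                  -(g("typeII_mm", "e_T") + g("typeII_mm", "delta"))),
    typeII_0m = c(0, 0, -g("typeII_0m", "delta")),
    stop("unknown archetype label: ", archetype))
}

#' Generate ground truth for a simulation
#'
#' Assigns archetypes to genes by deterministic largest-remainder rounding of
#' the configured proportions, draws lognormal baseline means, evaluates the
#' dispersion trend at each baseline, and computes the true per-genotype log2
#' effects (mutant effects are the wild-type effects multiplied by the
#' genotype's attenuation factor \eqn{\gamma}).
#'
#' @param config a [sim_config()].
#' @return an object of class \code{sim_truth}: a list with \code{genes}
#'   (gene, archetype, baseline, dispersion), \code{effects} (long table of
#'   genotype, gene and log2 effects of T, P, PT vs N) and the config.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  props <- config$archetype_proportions
  # largest-remainder apportionment: deterministic, sums to n
  raw <- props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  archetype <- rep(names(props), times = cnt)
  gene <- sprintf("gene_%0*d", nchar(n), seq_len(n))
  baseline <- withr::with_seed(
    substream_seed(config$seed, "truth_baseline"),
    rlnorm(n, meanlog = config$baseline_log_mean_mu,
           sdlog = config$baseline_log_mean_sd))
  a0 <- config$dispersion_trend[["a0"]]
  a1 <- config$dispersion_trend[["a1"]]
  dispersion <- a1 / baseline + a0
  theta_wt <- t(vapply(archetype, archetype_theta, numeric(3),
                       effect_sizes = config$effect_sizes))
  colnames(theta_wt) <- c("T", "P", "PT")
  effects <- do.call(rbind, lapply(names(config$genotypes), function(gt) {
    gam <- config$genotypes[[gt]]
    data.frame(genotype = gt, gene = gene,
               T = gam * theta_wt[, "T"],
               P = gam * theta_wt[, "P"],
               PT = gam * theta_wt[, "PT"],
               row.names = NULL, check.names = FALSE)
  }))
  structure(list(
    genes = data.frame(gene = gene, archetype = archetype,
                       baseline = baseline, dispersion = dispersion,
                       row.names = NULL),
    effects = effects, config = config), class = "sim_truth")
}

#' True log2 fold changes per contrast
#'
#' @param truth a [generate_truth()] result.
#' @return data frame with genotype, gene and the true log2 effects of the
#'   four standard contrasts \code{T/N}, \code{P/N}, \code{PT/N}, \code{PT/T}.
#' @export
true_contrasts <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  e <- truth$effects
  data.frame(genotype = e$genotype, gene = e$gene,
             `T/N` = e$T, `P/N` = e$P, `PT/N` = e$PT, `PT/T` = e$PT - e$T,
             check.names = FALSE)
}

#' Simulate a count matrix and sample sheet
#'
#' Counts are drawn from a negative binomial (gamma-Poisson) with mean
#' \eqn{depth_j \times q_g \times 2^{\theta}} where \eqn{\theta} is the true
#' log2 effect of the sample's genotype and treatment, and gene-wise
#' dispersion from the configured trend.  Library-depth multipliers are
#' lognormal and median-centred.
#'
#' @param truth a [generate_truth()] result.
#' @param config the matching [sim_config()] (defaults to the one stored in
#'   \code{truth}).
#' @return list with \code{counts} (integer gene x sample matrix) and
#'   \code{sheet} (sample, genotype, treatment, replicate, experiment).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (!identical(nrow(truth$genes), config$n_genes))
    stop("truth and config disagree on the number of genes")
  if (!"N" %in% config$treatments)
    stop("treatment set must contain the untreated baseline 'N'")
  genotypes <- names(config$genotypes)
  sheet <- expand.grid(replicate = seq_len(config$n_reps),
                       treatment = config$treatments,
                       genotype = genotypes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("genotype", "treatment", "replicate")]
  sheet$sample <- paste(sheet$genotype, sheet$treatment, sheet$replicate,
                        sep = "_")
  sheet$experiment <- if ("P" %in% config$treatments) "Exp1" else "Exp2"
  sheet <- sheet[, c("sample", "genotype", "treatment", "replicate",
                     "experiment")]
  m <- nrow(sheet)
  n <- config$n_genes
  depth <- withr::with_seed(
    substream_seed(config$seed, "library_depth"),
    exp(rnorm(m, 0, config$library_size_sd)))
  depth <- depth / median(depth)
  # per-sample log2 effect column: 0 for N, else the stored genotype effect
  theta <- matrix(0, n, m)
  for (j in seq_len(m)) {
    if (sheet$treatment[j] != "N") {
      sel <- truth$effects$genotype == sheet$genotype[j]
      theta[, j] <- truth$effects[sel, sheet$treatment[j]]
    }
  }
  mu <- truth$genes$baseline * 2^theta
  mu <- sweep(mu, 2, depth, `*`)
  counts <- withr::with_seed(
    substream_seed(config$seed, "counts"),
    matrix(rnbinom(n * m, mu = mu, size = rep(1 / truth$genes$dispersion, m)),
           nrow = n, ncol = m))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth$genes$gene, sheet$sample)
  list(counts = counts, sheet = sheet)
}

#' Simulate a qPCR Cq table with planted stable and unstable genes
#'
#' Stable genes have condition-independent expression; unstable genes carry a
#' condition-dependent log2 shift, planted in magnitude-matched +/- pairs so
#' that sample-wise means stay balanced (as for a mix of up- and
#' down-regulated genes).  Cq values are \code{base - log2(expression) +}
#' Gaussian technical noise.
#'
#' @param config a [sim_config()] (supplies \code{n_reps} and the seed).
#' @param n_stable,n_unstable numbers of planted genes;
#'   \code{n_stable + n_unstable >= 3}.
#' @param conditions condition labels (default \code{c("N","T","PT")}).
#' @param noise_sd technical noise SD in cycles (>= 0).
#' @param shift base magnitude (log2) of the condition shift of unstable
#'   genes.
#' @return list with \code{cq} (sample, gene, Cq, condition) and
#'   \code{truth} (gene, stable flag, planted shift).
#' @export
simulate_cq <- function(config, n_stable = 4L, n_unstable = 4L,
                        conditions = c("N", "T", "PT"),
                        noise_sd = 0.1, shift = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (n_stable + n_unstable < 3)
    stop("need at least 3 candidate genes (n_stable + n_unstable >= 3)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- c(if (n_stable) paste0("stable_", seq_len(n_stable)),
             if (n_unstable) paste0("unstable_", seq_len(n_unstable)))
  stable <- rep(c(TRUE, FALSE), c(n_stable, n_unstable))
  # +/- pairs with growing magnitude: s, -s, 1.5s, -1.5s, ...
  sh <- if (n_unstable) {
    mag <- shift * (1 + 0.5 * (ceiling(seq_len(n_unstable) / 2) - 1))
    mag * (-1)^(seq_len(n_unstable) - 1)
  } else numeric(0)
  planted_shift <- c(rep(0, n_stable), sh)
  nc <- length(conditions)
  cond_level <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else 0
  samples <- expand.grid(replicate = seq_len(config$n_reps),
                         condition = conditions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- paste(samples$condition, samples$replicate, sep = "_")
  withr::with_seed(substream_seed(config$seed, "cq"), {
    base <- runif(length(genes), 18, 28)
    rows <- expand.grid(gene_i = seq_along(genes),
                        sample_i = seq_len(nrow(samples)),
                        KEEP.OUT.ATTRS = FALSE)
    log2expr <- planted_shift[rows$gene_i] *
      cond_level[match(samples$condition[rows$sample_i], conditions)]
    cq <- data.frame(
      sample = samples$sample[rows$sample_i],
      gene = genes[rows$gene_i],
      Cq = base[rows$gene_i] - log2expr + rnorm(nrow(rows), 0, noise_sd),
      condition = samples$condition[rows$sample_i],
      stringsAsFactors = FALSE)
  })
  list(cq = cq,
       truth = data.frame(gene = genes, stable = stable,
                          shift = planted_shift, stringsAsFactors = FALSE))
}

#' Simulate a leaf-growth table
#'
#' Each plant elongates linearly in two phases: before heat stress (NHS) at a
#' plant-specific base rate, and after heat stress (HS) at that rate times a
#' genotype-specific effect and lognormal noise, mirroring a
#' relative-growth-rate phenotyping assay.
#'
#' @param config a [sim_config()] (seed source).
#' @param effect positive growth-rate ratio (HS/NHS); either a scalar or a
#'   named vector per genotype.
#' @param n_plants plants per genotype.
#' @param base_rate NHS elongation rate (mm/day).
#' @param noise_sd lognormal SD of plant- and phase-level rate noise.
#' @param nhs_window,hs_window measurement days \code{c(t1, t2)} per phase.
#' @param start_length leaf length (mm) at the first NHS measurement.
#' @return list with \code{growth} (plant, genotype, phase, t1, t2, length1,
#'   length2) and \code{truth} (genotype, true effect).
#' @export
simulate_growth <- function(config, effect = 1, n_plants = 12L,
                            base_rate = 10, noise_sd = 0,
                            nhs_window = c(3, 5), hs_window = c(7, 10),
                            start_length = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (any(effect <= 0)) stop("growth-rate effect must be > 0")
  if (diff(nhs_window) <= 0 || diff(hs_window) <= 0)
    stop("measurement windows must have t2 > t1")
  genotypes <- names(config$genotypes)
  eff <- if (length(effect) == 1 && is.null(names(effect)))
    setNames(rep(effect, length(genotypes)), genotypes)
  else {
    if (!all(genotypes %in% names(effect)))
      stop("effect must name every genotype")
    effect[genotypes]
  }
  withr::with_seed(substream_seed(config$seed, "growth"), {
    out <- do.call(rbind, lapply(genotypes, function(gt) {
      r_nhs <- base_rate * exp(rnorm(n_plants, 0, noise_sd))
      r_hs <- r_nhs * eff[[gt]] * exp(rnorm(n_plants, 0, noise_sd))
      plant <- paste(gt, "plant", seq_len(n_plants), sep = "_")
      l1 <- rep(start_length, n_plants)
      l2 <- l1 + r_nhs * diff(nhs_window)
      l3 <- l2 + r_hs * diff(hs_window)
      rbind(
        data.frame(plant = plant, genotype = gt, phase = "NHS",
                   t1 = nhs_window[1], t2 = nhs_window[2],
                   length1 = l1, length2 = l2, stringsAsFactors = FALSE),
        data.frame(plant = plant, genotype = gt, phase = "HS",
                   t1 = hs_window[1], t2 = hs_window[2],
                   length1 = l2, length2 = l3, stringsAsFactors = FALSE))
    }))
    row.names(out) <- NULL
    out
  }) -> growth
  list(growth = growth,
       truth = data.frame(genotype = genotypes, effect = unname(eff)))
}
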