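# Cq table -> samples x genes matrix, complete cases only (samples with a
# measurement for every candidate).
cq_matrix <- function(cq, candidates, require_complete = TRUE) {
  miss <- setdiff(candidates, unique(cq$gene))
  if (length(miss)) stop("candidate gene(s) absent from Cq table: ",
                         paste(miss, collapse = ", "))
  sub <- cq[cq$gene %in% candidates, ]
  samples <- unique(sub$sample)
  m <- matrix(NA_real_, length(samples), length(candidates),
              dimnames = list(samples, candidates))
  m[cbind(match(sub$sample, samples), match(sub$gene, candidates))] <- sub$Cq
  if (require_complete) {
    ok <- rowSums(is.na(m)) == 0
    if (!any(ok)) stop("no sample has complete Cq for all candidates")
    m <- m[ok, , drop = FALSE]
  }
  m
}

#' Candidate reference genes from RNA-seq contrasts
#'
#' Scores each gene by the cumulative absolute log2 fold change summed over
#' all (genotype, contrast) tables and returns the k least-varying genes.
#'
#' @param results a \code{contrast_results} table.
#' @param k number of candidates (default 8).
#' @return data frame (gene, score) of the k lowest scores, ascending.
#' @export
candidate_refs_from_rnaseq <- function(results, k = 8) {
  key <- paste(results$genotype, results$contrast)
  n_tables <- length(unique(key))
  ok <- !is.na(results$log2FC)
  score <- tapply(abs(results$log2FC[ok]), results$gene[ok], sum)
  complete <- tapply(rep(1, sum(ok)), results$gene[ok], sum) == n_tables
  score <- score[complete]
  if (length(score) < k)
    stop("fewer than k = ", k, " genes with complete contrasts")
  ord <- order(score, names(score))[seq_len(k)]
  data.frame(gene = names(score)[ord], score = unname(score[ord]),
             row.names = NULL)
}

#' geNorm stability measure M
#'
#' On expression \eqn{2^{-Cq}}, the M value of a candidate is the mean over
#' all partner candidates of the standard deviation across samples of their
#' pairwise log2 expression ratio (equivalently of the pairwise Cq
#' difference).  Lower is more stable.
#'
#' @param cq Cq table (sample, gene, Cq, condition).
#' @param candidates at least 3 candidate gene IDs.
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(cq, candidates) {
  if (length(candidates) < 3) stop("geNorm needs >= 3 candidates")
  m <- cq_matrix(cq, candidates)
  if (nrow(m) < 2) stop("need >= 2 samples with complete Cq")
  k <- length(candidates)
  pair_sd <- matrix(0, k, k, dimnames = list(candidates, candidates))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- sd(m[, i] - m[, j])  # log2 ratio = Cq_j - Cq_i up to sign
    pair_sd[i, j] <- pair_sd[j, i] <- s
  }
  setNames(rowSums(pair_sd) / (k - 1), candidates)
}

#' NormFinder-style stability
#'
#' Simplified variance-decomposition stability on two-way (gene- and
#' sample-) centred log2 expression (\eqn{-Cq}): with condition groups, the
#' square root of the between-group variance component plus the pooled
#' within-group variance per gene; with a single group this reduces to the
#' SD of the centred values.  Lower is more stable.
#'
#' @param cq Cq table.
#' @param candidates at least 2 candidate gene IDs.
#' @param groups optional named vector mapping sample -> group (e.g.
#'   condition); every group needs >= 2 samples.
#' @return named numeric vector of stability values.
#' @export
normfinder_stability <- function(cq, candidates, groups = NULL) {
  if (length(candidates) < 2) stop("NormFinder needs >= 2 candidates")
  m <- -cq_matrix(cq, candidates)  # log2 expression up to gene constants
  r <- m - rowMeans(m)             # remove sample effects
  r <- sweep(r, 2, colMeans(r))    # remove gene effects
  if (is.null(groups)) {
    return(setNames(apply(r, 2, sd), candidates))
  }
  g <- groups[rownames(m)]
  if (anyNA(g)) stop("groups must cover every retained sample")
  tab <- table(g)
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  vapply(setNames(candidates, candidates), function(cand) {
    x <- r[, cand]
    gm <- tapply(x, g, mean)
    within <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) /
      (length(x) - length(tab))
    between <- max(var(as.numeric(gm)), 0)
    sqrt(between + within)
  }, numeric(1))
}

#' BestKeeper SD
#'
#' The descriptive part of the BestKeeper criterion: the sample standard
#' deviation of each candidate's raw Cq values (cycles).  Lower is more
#' stable.
#'
#' @param cq Cq table.
#' @param candidates candidate gene IDs.
#' @return named numeric vector of SDs.
#' @export
bestkeeper_sd <- function(cq, candidates) {
  m <- cq_matrix(cq, candidates, require_complete = FALSE)
  out <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("BestKeeper needs >= 2 samples per gene")
    sd(x)
  })
  setNames(out, candidates)
}

#' Comparative delta-Ct stability
#'
#' For each candidate, the mean over partner candidates of the SD across
#' samples of the pairwise Cq difference.  Numerically identical to the
#' geNorm M value on a complete table (a pairwise Cq difference is a log2
#' expression ratio), and therefore produces the same ordering.
#'
#' @param cq Cq table.
#' @param candidates at least 3 candidate gene IDs.
#' @return named numeric vector of mean SDs.
#' @export
delta_ct_stability <- function(cq, candidates) {
  if (length(candidates) < 3)
    stop("comparative delta-Ct needs >= 3 candidates")
  genorm_m(cq, candidates)
}

#' RefFinder aggregate ranking
#'
#' Ranks candidates within each stability method (ascending value = better,
#' ties by average rank) and aggregates by the geometric mean of ranks.
#'
#' @param stabilities named list of >= 2 named numeric vectors (one per
#'   method, all covering the same genes).
#' @return data frame sorted by aggregate rank: gene, one rank column per
#'   method, aggregate.
#' @export
reffinder_rank <- function(stabilities) {
  if (length(stabilities) < 2) stop("need >= 2 stability methods")
  genes <- names(stabilities[[1]])
  for (s in stabilities) {
    if (!setequal(names(s), genes) || anyNA(s))
      stop("every method must provide a complete value for every gene")
  }
  ranks <- vapply(stabilities, function(s) rank(s[genes], ties.method =
                                                  "average"),
                  numeric(length(genes)))
  if (length(genes) == 1) ranks <- matrix(ranks, nrow = 1)
  aggregate_rank <- exp(rowMeans(log(ranks)))
  out <- data.frame(gene = genes, ranks, aggregate = aggregate_rank,
                    row.names = NULL, check.names = FALSE)
  out[order(out$aggregate, out$gene), , drop = FALSE]
}

#' Full stability report over a candidate panel
#'
#' Runs geNorm, NormFinder-style, BestKeeper and comparative delta-Ct on a
#' Cq table and aggregates with [reffinder_rank()].
#'
#' @param cq Cq table.
#' @param candidates candidate gene IDs (>= 3).
#' @param groups optional sample -> group mapping for NormFinder.
#' @return list of class \code{stability_report}: per-method values and the
#'   aggregate ranking.
#' @export
stability_report <- function(cq, candidates, groups = NULL) {
  vals <- list(
    genorm = genorm_m(cq, candidates),
    normfinder = normfinder_stability(cq, candidates, groups = groups),
    bestkeeper = bestkeeper_sd(cq, candidates),
    delta_ct = delta_ct_stability(cq, candidates))
  structure(list(values = vals, ranking = reffinder_rank(vals)),
            class = "stability_report")
}

#' Comparative-Ct (delta-delta-Ct) fold changes
#'
#' Per sample, \eqn{\Delta Ct = Cq_{target} - mean(Cq_{references})}; per
#' condition, \eqn{\Delta\Delta Ct} is the mean \eqn{\Delta Ct} minus the
#' control condition's mean, and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}} (amplification efficiency fixed at 2).  The
#' control condition's fold change is exactly 1 on means by construction.
#'
#' @param cq Cq table.
#' @param target target gene ID.
#' @param references reference gene IDs (averaged on the Cq scale).
#' @param control control condition label.
#' @return list of class \code{fold_change_result}: \code{by_condition}
#'   (condition, n, ddct, fold) and \code{per_sample} (sample, condition,
#'   dct, rel_fold).
#' @export
ddct_fold_change <- function(cq, target, references, control) {
  if (!control %in% cq$condition)
    stop("control condition absent from Cq table: ", control)
  m <- cq_matrix(cq, c(target, references))
  cond <- cq$condition[match(rownames(m), cq$sample)]
  dct <- m[, target] - rowMeans(m[, references, drop = FALSE])
  dct_control <- mean(dct[cond == control])
  per_sample <- data.frame(sample = rownames(m), condition = cond,
                           dct = dct, rel_fold = 2^(-(dct - dct_control)),
                           row.names = NULL)
  by_condition <- do.call(rbind, lapply(unique(cond), function(cc) {
    dd <- mean(dct[cond == cc]) - dct_control
    data.frame(condition = cc, n = sum(cond == cc), ddct = dd,
               fold = 2^(-dd), row.names = NULL)
  }))
  structure(list(by_condition = by_condition, per_sample = per_sample,
                 target = target, references = references,
                 control = control), class = "fold_change_result")
}

#' Relative growth rates from a two-phase growth table
#'
#' Per plant, the elongation rate (mm/day) in each phase and the relative
#' growth rate HS/NHS; plants with non-positive NHS rate are excluded with a
#' message.  When a genotype column is present, per-genotype summaries and
#' Welch comparisons against a reference genotype are added.
#'
#' @param growth growth table (as from [read_growth()] or
#'   [simulate_growth()]).
#' @param reference optional reference genotype for Welch comparisons.
#' @return list of class \code{growth_summary}: \code{per_plant},
#'   \code{by_genotype} (or NULL), \code{comparisons} (or NULL),
#'   \code{excluded}.
#' @export
relative_growth_rate <- function(growth, reference = NULL) {
  if (any(growth$t2 <= growth$t1)) stop("growth intervals must have t2 > t1")
  rate <- (growth$length2 - growth$length1) / (growth$t2 - growth$t1)
  wide <- data.frame(plant = unique(growth$plant))
  for (ph in c("NHS", "HS")) {
    sel <- growth$phase == ph
    idx <- match(wide$plant, growth$plant[sel])
    wide[[paste0("rate_", ph)]] <- rate[sel][idx]
  }
  if (anyNA(wide$rate_NHS) || anyNA(wide$rate_HS))
    stop("every plant needs both an NHS and an HS phase")
  if ("genotype" %in% names(growth))
    wide$genotype <- growth$genotype[match(wide$plant, growth$plant)]
  excluded <- wide$plant[wide$rate_NHS <= 0]
  if (length(excluded))
    message("excluding plant(s) with non-positive NHS growth rate: ",
            paste(excluded, collapse = ", "))
  wide <- wide[wide$rate_NHS > 0, , drop = FALSE]
  wide$relative <- wide$rate_HS / wide$rate_NHS
  by_genotype <- NULL; comparisons <- NULL
  if ("genotype" %in% names(wide)) {
    by_genotype <- do.call(rbind, lapply(split(wide, wide$genotype),
                                         function(d)
      data.frame(genotype = d$genotype[1], n = nrow(d),
                 mean_relative = mean(d$relative),
                 sd_relative = if (nrow(d) > 1) sd(d$relative) else NA_real_,
                 row.names = NULL)))
    if (!is.null(reference)) {
      if (!reference %in% wide$genotype)
        stop("reference genotype absent from growth table: ", reference)
      ref_vals <- wide$relative[wide$genotype == reference]
      others <- setdiff(unique(wide$genotype), reference)
      comparisons <- do.call(rbind, lapply(others, function(gt) {
        ht <- welch_t(wide$relative[wide$genotype == gt], ref_vals)
        data.frame(genotype = gt, reference = reference, t = ht$t,
                   df = ht$df, p = ht$p, row.names = NULL)
      }))
    }
  }
  structure(list(per_plant = wide, by_genotype = by_genotype,
                 comparisons = comparisons, excluded = excluded),
            class = "growth_summary")
}

#' Survival comparisons by Fisher's exact test
#'
#' For each group, a two-sided Fisher exact test of its alive/dead counts
#' against the reference group's.
#'
#' @param alive,dead named non-negative integer vectors (same names).
#' @param reference reference group name.
#' @return data frame: group, alive, dead, p (NA for the reference row).
#' @export
survival_comparison <- function(alive, dead, reference) {
  if (!identical(sort(names(alive)), sort(names(dead))))
    stop("alive and dead must cover the same groups")
  if (!reference %in% names(alive))
    stop("reference group absent: ", reference)
  if (any(alive + dead == 0)) stop("empty group(s) present")
  groups <- names(alive)
  p <- vapply(groups, function(g) {
    if (g == reference) return(NA_real_)
    fisher_exact_2x2(matrix(c(alive[[g]], dead[[g]],
                              alive[[reference]], dead[[reference]]),
                            nrow = 2, byrow = TRUE))
  }, numeric(1))
  data.frame(group = groups, alive = as.integer(alive[groups]),
             dead = as.integer(dead[groups]), p = p, row.names = NULL)
}
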