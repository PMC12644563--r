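#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of its count to the gene's geometric mean across samples; reference
#' genes are those with no zero count.  Factors are returned unscaled (no
#' re-centring), so they are meaningful up to a common scale.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors_median_ratios <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has all-positive counts; filter the matrix or add samples")
  lg <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(median(x - loggeo)))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor computed")
  sf
}

#' Dispersion estimation with trend shrinkage
#'
#' Per gene, a pooled within-cell method-of-moments estimate on normalized
#' counts, \eqn{\hat\alpha = \max((s^2 - \bar\mu)/\bar\mu^2,\ \alpha_{floor})},
#' where means and variances are pooled over design cells with at least two
#' replicates.  A trend \eqn{\alpha(\mu) = a_1/\mu + a_0} is fit by least
#' squares on genes whose estimate exceeds the floor, and the final value is
#' the log-space compromise
#' \eqn{\exp(w \log\hat\alpha + (1-w) \log\alpha_{trend})} with \eqn{w = 0.5};
#' genes whose method-of-moments estimate clamps at the floor (no usable
#' gene-wise signal at small replication) take the trend value directly.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors (named as the samples).
#' @param cells factor/character of design-cell membership per sample
#'   (e.g. genotype x treatment).
#' @param alpha_floor lower bound on all dispersions.
#' @param trend_weight weight \eqn{w} on the gene-wise estimate.
#' @return list of class \code{dispersion_fit}: per-gene table (gene, mu,
#'   alpha_mom, alpha_trend, alpha) and trend coefficients \code{c(a0, a1)}.
#' @export
estimate_dispersions <- function(counts, sf, cells, alpha_floor = 1e-8,
                                 trend_weight = 0.5) {
  cells <- as.factor(cells)
  if (length(cells) != ncol(counts))
    stop("cells must have one entry per sample")
  tab <- table(cells)
  use_cells <- names(tab)[tab >= 2]
  if (!length(use_cells))
    stop("all design cells are singletons; no within-cell variance available")
  norm <- sweep(counts, 2, sf, `/`)
  num_mu <- 0; den_mu <- 0; num_s2 <- 0; den_s2 <- 0
  for (cl in use_cells) {
    j <- which(cells == cl)
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, var)
    w <- length(j) - 1
    num_mu <- num_mu + length(j) * m; den_mu <- den_mu + length(j)
    num_s2 <- num_s2 + w * v; den_s2 <- den_s2 + w
  }
  mu <- num_mu / den_mu
  s2 <- num_s2 / den_s2
  alpha_mom <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, alpha_floor), NA_real_)
  fit_set <- which(!is.na(alpha_mom) & alpha_mom > alpha_floor & mu > 0)
  if (length(fit_set) >= 2) {
    co <- coef(lm(alpha_mom[fit_set] ~ I(1 / mu[fit_set])))
    a0 <- max(co[[1]], alpha_floor); a1 <- max(co[[2]], 0)
  } else {
    # too little signal above the floor: flat trend at the floor
    a0 <- alpha_floor; a1 <- 0
  }
  alpha_trend <- ifelse(mu > 0, pmax(a1 / mu + a0, alpha_floor), NA_real_)
  alpha <- exp(trend_weight * log(alpha_mom) +
                 (1 - trend_weight) * log(alpha_trend))
  # a clamped method-of-moments value carries no gene-wise signal: such genes
  # shrink all the way to the trend instead of averaging with the floor
  clamped <- !is.na(alpha_mom) & alpha_mom <= alpha_floor
  alpha[clamped] <- alpha_trend[clamped]
  alpha <- pmax(alpha, alpha_floor)
  structure(list(
    table = data.frame(gene = rownames(counts), mu = mu,
                       alpha_mom = alpha_mom, alpha_trend = alpha_trend,
                       alpha = alpha, row.names = NULL),
    trend = c(a0 = a0, a1 = a1),
    alpha_floor = alpha_floor), class = "dispersion_fit")
}

# Vectorised two-group NB IRLS with log link and log size-factor offsets.
# Returns per-gene intercept/coefficient fits plus Wald statistics for the
# numerator-vs-denominator contrast.
nb_irls_two_group <- function(y, sf, alpha, is_num, max_iter = 50L,
                              tol = 1e-8, beta_cap = 30) {
  G <- nrow(y); n <- ncol(y)
  o <- log(sf)
  x <- as.numeric(is_num)
  norm <- sweep(y, 2, sf, `/`)
  m0 <- rowMeans(norm[, !is_num, drop = FALSE])
  m1 <- rowMeans(norm[, is_num, drop = FALSE])
  all_zero <- m0 == 0 & m1 == 0
  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  O <- matrix(o, G, n, byrow = TRUE)
  dev_fun <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
    2 * rowSums(t1 - t2)
  }
  dev_old <- rep(Inf, G)
  converged <- all_zero  # nothing to fit for all-zero genes
  Sw <- Swx <- rep(NA_real_, G)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(b0 + tcrossprod(b1, x), -beta_cap), beta_cap) + O
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - O) + (y - mu) / mu
    wz <- w * z
    Sw <- rowSums(w)
    Swx <- rowSums(w[, is_num, drop = FALSE])
    Swz <- rowSums(wz)
    Swxz <- rowSums(wz[, is_num, drop = FALSE])
    b0_new <- (Swz - Swxz) / (Sw - Swx)
    b1_new <- (Sw * Swxz - Swx * Swz) / (Swx * (Sw - Swx))
    b0_new <- pmin(pmax(b0_new, -beta_cap), beta_cap)
    b1_new <- pmin(pmax(b1_new, -2 * beta_cap), 2 * beta_cap)
    upd <- !converged
    b0[upd] <- b0_new[upd]; b1[upd] <- b1_new[upd]
    dev <- dev_fun(exp(pmin(pmax(b0 + tcrossprod(b1, x), -beta_cap),
                            beta_cap) + O))
    newly <- !converged & abs(dev - dev_old) < tol * (1 + abs(dev))
    converged <- converged | newly
    dev_old <- dev
    if (all(converged)) break
  }
  # final weights at the fitted values, for the Wald variance
  eta <- pmin(pmax(b0 + tcrossprod(b1, x), -beta_cap), beta_cap) + O
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  Sw <- rowSums(w)
  Swx <- rowSums(w[, is_num, drop = FALSE])
  var_b1 <- Sw / (Swx * (Sw - Swx))
  list(b0 = b0, b1 = b1, var_b1 = var_b1,
       baseMean = rowMeans(norm), all_zero = all_zero,
       converged = converged)
}

#' Two-group negative-binomial Wald contrast
#'
#' Fits, per gene, a two-group NB GLM with log link and log size-factor
#' offsets by iteratively reweighted least squares at fixed gene-wise
#' dispersion, and tests the group coefficient with a two-sided Wald test
#' against the standard normal.  No fold-change shrinkage is applied.
#' Genes with zero counts in all samples of both groups, or whose fit fails
#' to converge, are reported with missing statistics.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors.
#' @param disp a \code{dispersion_fit} or a per-gene numeric vector of
#'   dispersions aligned with the rows of \code{counts}.
#' @param samples_num,samples_den sample IDs (or column indices) of the
#'   numerator and denominator groups of the fold change.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return data frame: gene, baseMean, log2FC, SE, stat, p, converged.
#' @export
nb_wald_contrast <- function(counts, sf, disp, samples_num, samples_den,
                             max_iter = 50L, tol = 1e-8) {
  if (length(samples_num) == 0 || length(samples_den) == 0)
    stop("both groups must be non-empty")
  alpha <- if (inherits(disp, "dispersion_fit")) disp$table$alpha
           else as.numeric(disp)
  if (length(alpha) != nrow(counts))
    stop("need one dispersion per gene")
  if (anyNA(alpha)) alpha[is.na(alpha)] <- 1e-8
  idx <- c(samples_den, samples_num)
  y <- counts[, idx, drop = FALSE]
  is_num <- rep(c(FALSE, TRUE), c(length(samples_den), length(samples_num)))
  fit <- nb_irls_two_group(y, sf[idx], alpha, is_num,
                           max_iter = max_iter, tol = tol)
  log2FC <- fit$b1 / log(2)
  SE <- sqrt(fit$var_b1) / log(2)
  stat <- log2FC / SE
  p <- 2 * pnorm(-abs(stat))
  bad <- fit$all_zero | !fit$converged
  log2FC[fit$all_zero] <- NA_real_
  SE[bad] <- NA_real_; stat[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(gene = rownames(counts), baseMean = fit$baseMean,
             log2FC = log2FC, SE = SE, stat = stat, p = p,
             converged = fit$converged & !fit$all_zero, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with missing-value propagation
#'
#' Step-up BH over the non-missing p values (missing entries are ignored and
#' propagate as missing), with the usual monotonicity enforcement.
#'
#' @param p numeric p values in \[0, 1\]; NA allowed.
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

parse_contrast <- function(contrast) {
  parts <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% TREATMENT_LEVELS))
    stop("contrast must be of the form 'T/N' over treatment codes: ", contrast)
  parts
}

#' Run all standard contrasts per genotype
#'
#' For each requested genotype, estimates one pooled dispersion fit across
#' its design cells and then fits each treatment contrast as a two-group NB
#' Wald test.  BH adjustment is applied within each (genotype, contrast)
#' table.  Contrasts whose treatments are absent from the design (e.g.
#' \code{P/N} in a reduced experiment) are skipped with a message.
#'
#' @param counts gene x sample count matrix.
#' @param sheet sample sheet matching the matrix.
#' @param genotypes genotypes to analyse (default: all in the sheet).
#' @param contrasts character contrasts \code{"NUM/DEN"} over treatment
#'   codes.
#' @param sf optional pre-computed size factors (default: median-of-ratios
#'   on the full matrix).
#' @return data frame of class \code{contrast_results} with columns gene,
#'   genotype, contrast, baseMean, log2FC, SE, stat, p, padj.
#' @export
run_all_contrasts <- function(counts, sheet, genotypes = NULL,
                              contrasts = c("T/N", "P/N", "PT/N", "PT/T"),
                              sf = NULL) {
  check_counts_sheet(counts, sheet)
  genotypes <- genotypes %||% unique(sheet$genotype)
  absent <- setdiff(genotypes, sheet$genotype)
  if (length(absent)) stop("genotype(s) absent from sheet: ",
                           paste(absent, collapse = ", "))
  sf <- sf %||% size_factors_median_ratios(counts)
  out <- list()
  for (gt in genotypes) {
    sub <- sheet[sheet$genotype == gt, ]
    disp <- estimate_dispersions(
      counts[, sub$sample, drop = FALSE], sf[sub$sample],
      cells = sub$treatment)
    for (ct in contrasts) {
      parts <- parse_contrast(ct)
      s_num <- sub$sample[sub$treatment == parts[1]]
      s_den <- sub$sample[sub$treatment == parts[2]]
      if (!length(s_num) || !length(s_den)) {
        message("skipping contrast ", ct, " for genotype ", gt,
                ": treatment not in design")
        next
      }
      tab <- nb_wald_contrast(counts[, sub$sample, drop = FALSE],
                              sf[sub$sample], disp, s_num, s_den)
      tab$padj <- bh_adjust(tab$p)
      tab$genotype <- gt
      tab$contrast <- ct
      out[[paste(gt, ct)]] <- tab[, c("gene", "genotype", "contrast",
                                      "baseMean", "log2FC", "SE", "stat",
                                      "p", "padj")]
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  class(res) <- c("contrast_results", class(res))
  res
}

#' Write contrast tables as TSV
#'
#' @param results a \code{contrast_results} table.
#' @param path output path.
#' @export
write_contrasts <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
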