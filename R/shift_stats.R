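#' ECDF evaluation points
#'
#' Convenience wrapper around [stats::ecdf()] returning the step-function
#' support: the sorted unique values and the cumulative fraction at each
#' (right-continuous, ties accumulate).
#'
#' @param values finite numeric values (>= 1).
#' @return data frame with columns \code{x} and \code{F}.
#' @export
ecdf_points <- function(values) {
  if (length(values) < 1) stop("ECDF needs at least one value")
  if (any(!is.finite(values))) stop("ECDF values must be finite")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  data.frame(x = x, F = f(x))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D = \sup_x |F_x - F_y|} with a p value from the exact distribution
#' when \eqn{n \cdot m \le} \code{exact_limit} (distribution-free
#' enumeration, via [stats::ks.test()]), else from the asymptotic Kolmogorov
#' formula.
#'
#' @param x,y numeric samples (each >= 1 finite value).
#' @param exact_limit product-size cutoff for the exact branch.
#' @param alternative passed to [stats::ks.test()] (default two-sided).
#' @return list: \code{D}, \code{p}, \code{exact} flag.
#' @export
ks_two_sample <- function(x, y, exact_limit = 10000,
                          alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  exact <- length(x) * length(y) <= exact_limit
  ht <- suppressWarnings(ks.test(x, y, alternative = alternative,
                                 exact = exact))
  list(D = unname(ht$statistic), p = min(1, unname(ht$p.value)),
       exact = exact)
}

#' Pairwise KS tests over named groups
#'
#' All unordered pairs are tested; no multiplicity correction is applied by
#' default (set \code{p_adjust = "holm"} to correct).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   non-empty).
#' @param alpha significance level stored with the matrix.
#' @param p_adjust \code{"none"} (default) or a [stats::p.adjust()] method.
#' @param exact_limit passed to [ks_two_sample()].
#' @return list of class \code{ks_matrix}: symmetric \code{D} and \code{p}
#'   matrices, \code{alpha}, and group medians.
#' @export
pairwise_ks <- function(groups, alpha = 0.05, p_adjust = "none",
                        exact_limit = 10000) {
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  if (any(vapply(groups, length, 1L) < 1)) stop("every group needs >= 1 value")
  k <- length(groups)
  nm <- names(groups)
  D <- matrix(0, k, k, dimnames = list(nm, nm))
  P <- matrix(1, k, k, dimnames = list(nm, nm))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pvec <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ht <- ks_two_sample(groups[[i]], groups[[j]], exact_limit = exact_limit)
    D[i, j] <- D[j, i] <- ht$D
    pvec[r] <- ht$p
  }
  if (p_adjust != "none") pvec <- p.adjust(pvec, method = p_adjust)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    P[i, j] <- P[j, i] <- pvec[r]
  }
  structure(list(D = D, p = P, alpha = alpha,
                 medians = vapply(groups, median, numeric(1))),
            class = "ks_matrix")
}

#' Compact letter display from a pairwise test matrix
#'
#' Insert-and-absorb algorithm over the non-significance relation: groups
#' sharing at least one letter are mutually non-significant at the matrix's
#' alpha, and every significant pair carries disjoint letters.  Letters are
#' assigned in order of descending group median (ties broken by label).
#'
#' @param km a \code{ks_matrix} (or any list with symmetric \code{p},
#'   \code{alpha} and \code{medians}).
#' @return named character vector of letter strings, one per group.
#' @export
cld_letters <- function(km) {
  p <- km$p
  alpha <- km$alpha
  nm <- rownames(p)
  ord <- nm[order(-km$medians[nm], nm)]
  sig <- p < alpha
  cols <- list(ord)  # letter columns, each a set of group labels
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      gi <- ord[i]; gj <- ord[j]
      if (!sig[gi, gj]) next
      hit <- which(vapply(cols, function(cl) gi %in% cl && gj %in% cl,
                          logical(1)))
      for (h in hit) {
        cl <- cols[[h]]
        cols[[h]] <- setdiff(cl, gj)
        cols[[length(cols) + 1]] <- setdiff(cl, gi)
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] %in% cols[[b]]) &&
            !(all(cols[[b]] %in% cols[[a]]) && a < b))
          keep[a] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  # stable letter order: columns by rank of their best (highest-median) member
  rank_of <- setNames(seq_along(ord), ord)
  cols <- cols[order(vapply(cols, function(cl) min(rank_of[cl]), numeric(1)))]
  alphabet <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- setNames(rep("", length(nm)), nm)
  for (k in seq_along(cols))
    for (g in cols[[k]]) out[g] <- paste0(out[g], alphabet[k])
  out[ord]
}

#' Verify the letter-display invariant
#'
#' Two groups share at least one letter iff their pairwise test is
#' non-significant at alpha.
#'
#' @param letters named letter strings from [cld_letters()].
#' @param km the \code{ks_matrix} they were derived from.
#' @return TRUE, or an error describing the violated pair.
#' @export
cld_check <- function(letters, km) {
  nm <- names(letters)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    share <- length(intersect(strsplit(letters[[i]], "")[[1]],
                              strsplit(letters[[j]], "")[[1]])) > 0
    sig <- km$p[nm[i], nm[j]] < km$alpha
    if (share == sig)
      stop("letter-display invariant violated for pair ", nm[i], "/", nm[j])
  }
  TRUE
}

#' Gene-set ratio ECDF shift analysis
#'
#' For a fixed gene set (defined on the reference genotype), collects each
#' genotype's log2 ratio values for one contrast, runs all pairwise KS tests
#' and the compact letter display, and reports each genotype's median shift
#' relative to the reference.
#'
#' @param results a \code{contrast_results} table.
#' @param genes gene set (character).
#' @param ratio contrast supplying the ratios (default \code{"PT/T"}).
#' @param genotypes genotypes to compare (default: all present).
#' @param reference reference genotype (default: first of
#'   \code{genotypes}).
#' @param alpha significance level for the letters.
#' @param p_adjust multiplicity correction across pairs (default none).
#' @return list of class \code{shift_analysis}: \code{values} (named list),
#'   \code{ks} (ks_matrix), \code{letters}, \code{median_shift} (vs
#'   reference), \code{n_genes}.
#' @export
gene_set_ratio_ecdf <- function(results, genes, ratio = "PT/T",
                                genotypes = NULL, reference = NULL,
                                alpha = 0.05, p_adjust = "none") {
  genotypes <- genotypes %||% unique(results$genotype)
  reference <- reference %||% genotypes[1]
  sub <- results[results$contrast == ratio &
                   results$genotype %in% genotypes, ]
  if (nrow(sub) == 0) stop("ratio contrast not present: ", ratio)
  values <- lapply(setNames(genotypes, genotypes), function(gt) {
    d <- sub[sub$genotype == gt & sub$gene %in% genes, ]
    v <- d$log2FC[is.finite(d$log2FC)]
    v
  })
  if (any(vapply(values, length, 1L) == 0))
    stop("empty gene set after intersection with available genes")
  km <- pairwise_ks(values, alpha = alpha, p_adjust = p_adjust)
  letters <- cld_letters(km)
  med <- vapply(values, median, numeric(1))
  structure(list(values = values, ks = km, letters = letters,
                 median_shift = med - med[[reference]],
                 reference = reference,
                 n_genes = vapply(values, length, 1L)),
            class = "shift_analysis")
}

#' EASE score (conservative one-sided Fisher test)
#'
#' The one-sided hypergeometric upper-tail p value computed after removing
#' one gene from the overlap cell (\eqn{k \to k - 1}); \eqn{k \le 1} returns
#' 1.  Always at least as large as the classical one-sided Fisher p for the
#' same table.
#'
#' @param k list hits for the term.
#' @param n list size.
#' @param K population hits for the term.
#' @param N population size.
#' @return p value.
#' @export
ease_score <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N)
    stop("inconsistent 2x2 table margins")
  if (k <= 1) return(1)
  phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

# classical one-sided Fisher p for the same margins (upper tail at k)
fisher_one_sided <- function(k, n, K, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO (term) enrichment by EASE score
#'
#' For every annotation term with at least one hit in the gene set, computes
#' the EASE p against the background universe and BH-adjusts across tested
#' terms.
#'
#' @param genes gene set (must be a subset of \code{background}).
#' @param background background gene universe.
#' @param annotation a named list gene -> terms, or the list returned by
#'   [read_go_map()].
#' @param term_names optional named term descriptions.
#' @return data frame sorted by adjusted p: term, name, k, n, K, N, p,
#'   padj.
#' @export
go_enrichment <- function(genes, background, annotation,
                          term_names = NULL) {
  if (length(background) == 0) stop("background must be non-empty")
  if (is.list(annotation) && !is.null(annotation$map)) {
    term_names <- term_names %||% annotation$term_names
    annotation <- annotation$map
  }
  out_genes <- setdiff(genes, background)
  if (length(out_genes))
    stop("gene set must be a subset of the background (offenders: ",
         paste(head(out_genes, 5), collapse = ", "), ")")
  ann <- annotation[names(annotation) %in% background]
  if (length(ann) == 0)
    return(data.frame(term = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0)))
  long <- data.frame(gene = rep(names(ann), lengths(ann)),
                     term = unlist(ann, use.names = FALSE))
  N <- length(unique(background))
  n <- length(unique(genes))
  hit_terms <- unique(long$term[long$gene %in% genes])
  if (length(hit_terms) == 0)
    return(data.frame(term = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0)))
  rows <- lapply(hit_terms, function(tm) {
    tg <- unique(long$gene[long$term == tm])
    k <- length(intersect(tg, genes))
    K <- length(tg)
    data.frame(term = tm,
               name = if (!is.null(term_names) && tm %in% names(term_names))
                 unname(term_names[tm]) else NA_character_,
               k = k, n = n, K = K, N = N,
               p = ease_score(k, n, K, N))
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$padj, res$p, res$term), ]
  row.names(res) <- NULL
  res
}

#' Ortholog-set overlap with hypergeometric enrichment
#'
#' Projects \code{set_b} through a one-to-one ortholog map into the A-space,
#' restricts both sets to the mapped universe, and reports the overlap with
#' an upper-tail hypergeometric p (probability of an overlap at least as
#' large under random draws from the mapped universe).
#'
#' @param set_a genes in species-A namespace.
#' @param set_b genes in species-B namespace.
#' @param map data frame with columns \code{a}, \code{b} (one-to-one, as
#'   from [read_ortholog_map()]).
#' @return list: sizes \code{n_a}, \code{n_b}, \code{overlap},
#'   \code{universe}, the overlapping genes (A-space), and \code{p}.
#' @export
ortholog_overlap <- function(set_a, set_b, map) {
  if (nrow(map) == 0) stop("empty ortholog universe")
  b_in_a <- map$a[match(set_b, map$b)]
  b_in_a <- b_in_a[!is.na(b_in_a)]
  a_in <- intersect(set_a, map$a)
  universe <- nrow(map)
  ov <- intersect(a_in, b_in_a)
  p <- if (length(ov) == 0) 1 else
    phyper(length(ov) - 1, length(a_in), universe - length(a_in),
           length(b_in_a), lower.tail = FALSE)
  list(n_a = length(a_in), n_b = length(b_in_a), overlap = length(ov),
       universe = universe, genes = ov, p = p)
}

#' Welch two-sample t test
#'
#' Two-sided Welch t test with Satterthwaite degrees of freedom.  When both
#' groups are constant: p = 1 if the means agree, 0 otherwise (by
#' convention).
#'
#' @param x,y numeric samples with >= 2 values each.
#' @return list: \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("Welch test needs >= 2 values per group")
  if (var(x) == 0 && var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (equal) 0 else Inf, df = NA_real_,
                p = if (equal) 1 else 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by summing tables with probability no larger than the
#' observed one (the standard convention); degenerate margins give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return p value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}
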