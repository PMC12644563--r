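# Pass/fail helpers for the global DE criterion (|log2FC| > t, padj < alpha).
pass_up <- function(lfc, padj, t, alpha) {
  !is.na(lfc) & !is.na(padj) & lfc > t & padj < alpha
}
pass_down <- function(lfc, padj, t, alpha) {
  !is.na(lfc) & !is.na(padj) & lfc < -t & padj < alpha
}

#' Classify one gene's type II memory behaviour
#'
#' A gene is a positive type II memory gene when it responds more strongly
#' after a second heat treatment: log2FC > threshold and padj < alpha in both
#' \code{PT/N} and \code{PT/T}.  The sub-class is \code{"+/++"} when the gene
#' is also induced after a single treatment (\code{T/N} passes the same
#' criterion) and \code{"0/+"} otherwise.  Negative classes \code{"-/--"} and
#' \code{"0/-"} mirror the rule with the down criterion.  A gene with any
#' required statistic missing is \code{"unclassifiable"} (distinct from
#' \code{"none"}).
#'
#' @param lfc,padj named numeric vectors carrying at least \code{PT/N},
#'   \code{PT/T} and \code{T/N} entries.
#' @param lfc_threshold,alpha DE thresholds (defaults 1 and 0.05).
#' @return one of \code{"+/++"}, \code{"0/+"}, \code{"-/--"}, \code{"0/-"},
#'   \code{"none"}, \code{"unclassifiable"}.
#' @export
classify_type_II <- function(lfc, padj, lfc_threshold = 1, alpha = 0.05) {
  need <- c("PT/N", "PT/T", "T/N")
  if (!all(need %in% names(lfc)) || !all(need %in% names(padj)) ||
      anyNA(lfc[need]) || anyNA(padj[need]))
    return("unclassifiable")
  t <- lfc_threshold
  pos <- pass_up(lfc[["PT/N"]], padj[["PT/N"]], t, alpha) &&
         pass_up(lfc[["PT/T"]], padj[["PT/T"]], t, alpha)
  neg <- pass_down(lfc[["PT/N"]], padj[["PT/N"]], t, alpha) &&
         pass_down(lfc[["PT/T"]], padj[["PT/T"]], t, alpha)
  if (pos) {
    if (pass_up(lfc[["T/N"]], padj[["T/N"]], t, alpha)) "+/++" else "0/+"
  } else if (neg) {
    if (pass_down(lfc[["T/N"]], padj[["T/N"]], t, alpha)) "-/--" else "0/-"
  } else "none"
}

#' Classify one gene's type I memory behaviour
#'
#' Positive (sustained induction) when both \code{T/N} and \code{P/N} pass
#' the up criterion; negative (sustained repression) when both pass the down
#' criterion; otherwise \code{"none"}.
#'
#' @inheritParams classify_type_II
#' @return one of \code{"positive"}, \code{"negative"}, \code{"none"},
#'   \code{"unclassifiable"}.
#' @export
classify_type_I <- function(lfc, padj, lfc_threshold = 1, alpha = 0.05) {
  need <- c("T/N", "P/N")
  if (!all(need %in% names(lfc)) || !all(need %in% names(padj)) ||
      anyNA(lfc[need]) || anyNA(padj[need]))
    return("unclassifiable")
  t <- lfc_threshold
  if (pass_up(lfc[["T/N"]], padj[["T/N"]], t, alpha) &&
      pass_up(lfc[["P/N"]], padj[["P/N"]], t, alpha)) "positive"
  else if (pass_down(lfc[["T/N"]], padj[["T/N"]], t, alpha) &&
           pass_down(lfc[["P/N"]], padj[["P/N"]], t, alpha)) "negative"
  else "none"
}

# Reshape a contrast_results table into wide per-(gene, genotype) columns
# lfc_<contrast> / padj_<contrast>.
contrasts_wide <- function(results) {
  key <- paste(results$gene, results$genotype, sep = "\r")
  if (anyDuplicated(paste(key, results$contrast)))
    stop("duplicated gene within a contrast table")
  base <- results[!duplicated(key), c("gene", "genotype")]
  rownames(base) <- unique(key)
  for (ct in unique(results$contrast)) {
    sub <- results[results$contrast == ct, ]
    k <- paste(sub$gene, sub$genotype, sep = "\r")
    base[[paste0("lfc_", ct)]] <- sub$log2FC[match(rownames(base), k)]
    base[[paste0("padj_", ct)]] <- sub$padj[match(rownames(base), k)]
  }
  rownames(base) <- NULL
  base
}

#' Classify all genes into memory categories per genotype
#'
#' Vectorised application of [classify_type_I()] and [classify_type_II()]
#' over a full contrast table.  Type I and type II flags are assigned
#' independently; a gene may carry both.
#'
#' @param results a \code{contrast_results} table from
#'   [run_all_contrasts()].
#' @param lfc_threshold,alpha DE thresholds.
#' @return data frame of class \code{memory_calls}: gene, genotype, typeI,
#'   typeII, plus the supporting \code{lfc_*} / \code{padj_*} columns; the
#'   per-class count summary is attached as attribute \code{"summary"}.
#' @export
classify_all <- function(results, lfc_threshold = 1, alpha = 0.05) {
  wide <- contrasts_wide(results)
  t <- lfc_threshold
  has2 <- all(c("lfc_PT/N", "lfc_PT/T", "lfc_T/N") %in% names(wide))
  if (has2) {
    up_ptn <- pass_up(wide$`lfc_PT/N`, wide$`padj_PT/N`, t, alpha)
    up_ptt <- pass_up(wide$`lfc_PT/T`, wide$`padj_PT/T`, t, alpha)
    up_tn <- pass_up(wide$`lfc_T/N`, wide$`padj_T/N`, t, alpha)
    dn_ptn <- pass_down(wide$`lfc_PT/N`, wide$`padj_PT/N`, t, alpha)
    dn_ptt <- pass_down(wide$`lfc_PT/T`, wide$`padj_PT/T`, t, alpha)
    dn_tn <- pass_down(wide$`lfc_T/N`, wide$`padj_T/N`, t, alpha)
    typeII <- ifelse(up_ptn & up_ptt, ifelse(up_tn, "+/++", "0/+"),
                     ifelse(dn_ptn & dn_ptt, ifelse(dn_tn, "-/--", "0/-"),
                            "none"))
    nas <- is.na(wide$`lfc_PT/N`) | is.na(wide$`padj_PT/N`) |
      is.na(wide$`lfc_PT/T`) | is.na(wide$`padj_PT/T`) |
      is.na(wide$`lfc_T/N`) | is.na(wide$`padj_T/N`)
    typeII[nas] <- "unclassifiable"
  } else typeII <- rep("unclassifiable", nrow(wide))
  has1 <- all(c("lfc_T/N", "lfc_P/N") %in% names(wide))
  if (has1) {
    u_tn <- pass_up(wide$`lfc_T/N`, wide$`padj_T/N`, t, alpha)
    u_pn <- pass_up(wide$`lfc_P/N`, wide$`padj_P/N`, t, alpha)
    d_tn <- pass_down(wide$`lfc_T/N`, wide$`padj_T/N`, t, alpha)
    d_pn <- pass_down(wide$`lfc_P/N`, wide$`padj_P/N`, t, alpha)
    typeI <- ifelse(u_tn & u_pn, "positive",
                    ifelse(d_tn & d_pn, "negative", "none"))
    nas <- is.na(wide$`lfc_T/N`) | is.na(wide$`padj_T/N`) |
      is.na(wide$`lfc_P/N`) | is.na(wide$`padj_P/N`)
    typeI[nas] <- "unclassifiable"
  } else typeI <- rep("unclassifiable", nrow(wide))
  out <- cbind(wide[, c("gene", "genotype")],
               data.frame(typeI = typeI, typeII = typeII,
                          stringsAsFactors = FALSE),
               wide[, setdiff(names(wide), c("gene", "genotype")),
                    drop = FALSE])
  smry <- do.call(rbind, lapply(split(out, out$genotype), function(d) {
    data.frame(genotype = d$genotype[1],
               typeI_positive = sum(d$typeI == "positive"),
               typeI_negative = sum(d$typeI == "negative"),
               typeII_pp = sum(d$typeII == "+/++"),
               typeII_0p = sum(d$typeII == "0/+"),
               typeII_mm = sum(d$typeII == "-/--"),
               typeII_0m = sum(d$typeII == "0/-"),
               row.names = NULL)
  }))
  attr(out, "summary") <- smry
  attr(out, "thresholds") <- c(lfc = t, alpha = alpha)
  class(out) <- c("memory_calls", class(out))
  out
}

# positive criteria defining a memory class; used for dependence calls
class_criteria <- function(call_type, label) {
  if (call_type == "typeII") {
    switch(label,
      "+/++" = list(up = c("PT/N", "PT/T", "T/N")),
      "0/+"  = list(up = c("PT/N", "PT/T")),
      "-/--" = list(down = c("PT/N", "PT/T", "T/N")),
      "0/-"  = list(down = c("PT/N", "PT/T")),
      NULL)
  } else {
    switch(label,
      positive = list(up = c("T/N", "P/N")),
      negative = list(down = c("T/N", "P/N")),
      NULL)
  }
}

#' Genotype dependence of memory calls
#'
#' For every gene carrying a memory call in the reference genotype, checks
#' whether the mutant still satisfies the criteria defining that call at
#' identical thresholds; a gene is \code{"lost"} in a mutant when at least
#' one defining criterion fails there.
#'
#' @param calls a \code{memory_calls} table covering the reference and
#'   mutant genotypes.
#' @param reference reference (wild-type) genotype label.
#' @param mutants mutant genotype labels.
#' @param call_type \code{"typeII"} (default) or \code{"typeI"}.
#' @return list of class \code{dependence_calls}: per-gene table (gene,
#'   reference class, one status column per mutant) and \code{sets} with the
#'   sizes lost-in-each, lost-in-either, lost-in-all, retained-in-all.
#' @export
dependence_on_genotype <- function(calls, reference, mutants,
                                   call_type = c("typeII", "typeI")) {
  call_type <- match.arg(call_type)
  if (!reference %in% calls$genotype)
    stop("reference genotype not present in calls: ", reference)
  absent <- setdiff(mutants, calls$genotype)
  if (length(absent)) stop("mutant genotype(s) absent: ",
                           paste(absent, collapse = ", "))
  th <- attr(calls, "thresholds") %||% c(lfc = 1, alpha = 0.05)
  ref <- calls[calls$genotype == reference, ]
  lab_col <- if (call_type == "typeII") "typeII" else "typeI"
  ref <- ref[!ref[[lab_col]] %in% c("none", "unclassifiable"), ]
  if (nrow(ref) == 0) {
    tab <- data.frame(gene = character(0), class = character(0))
    for (m in mutants) tab[[m]] <- character(0)
  } else {
    tab <- data.frame(gene = ref$gene, class = ref[[lab_col]],
                      stringsAsFactors = FALSE)
    for (m in mutants) {
      mut <- calls[calls$genotype == m, ]
      idx <- match(ref$gene, mut$gene)
      status <- vapply(seq_len(nrow(ref)), function(i) {
        crit <- class_criteria(call_type, ref[[lab_col]][i])
        j <- idx[i]
        if (is.na(j)) return("lost")
        ok <- TRUE
        for (ct in crit$up)
          ok <- ok && isTRUE(pass_up(mut[[paste0("lfc_", ct)]][j],
                                     mut[[paste0("padj_", ct)]][j],
                                     th[["lfc"]], th[["alpha"]]))
        for (ct in crit$down)
          ok <- ok && isTRUE(pass_down(mut[[paste0("lfc_", ct)]][j],
                                       mut[[paste0("padj_", ct)]][j],
                                       th[["lfc"]], th[["alpha"]]))
        if (ok) "retained" else "lost"
      }, character(1))
      tab[[m]] <- status
    }
  }
  lost_mat <- as.matrix(tab[, mutants, drop = FALSE]) == "lost"
  sets <- list(
    lost_in_each = setNames(colSums(lost_mat), mutants),
    lost_in_either = sum(rowSums(lost_mat) > 0),
    lost_in_all = sum(rowSums(lost_mat) == length(mutants)),
    retained_in_all = sum(rowSums(lost_mat) == 0))
  structure(list(table = tab, sets = sets, reference = reference,
                 call_type = call_type), class = "dependence_calls")
}

#' Hyper-induction among positive type II genes
#'
#' Among positive type II memory genes of one genotype, counts those whose
#' \code{PT/T} log2 fold change exceeds \code{log2(fold)} (default: more than
#' three-fold hyper-induction).
#'
#' @param calls a \code{memory_calls} table.
#' @param genotype genotype to evaluate (default: first in the table).
#' @param fold hyper-induction fold threshold.
#' @return list: n_positive, count, fraction (NA when no positive type II
#'   genes), genes.
#' @export
hyper_induction_stats <- function(calls, genotype = calls$genotype[1],
                                  fold = 3) {
  d <- calls[calls$genotype == genotype, ]
  pos <- d[d$typeII %in% c("+/++", "0/+"), ]
  if (nrow(pos) == 0)
    return(list(n_positive = 0L, count = 0L, fraction = NA_real_,
                genes = character(0)))
  hyper <- pos$`lfc_PT/T` > log2(fold)
  list(n_positive = nrow(pos), count = sum(hyper),
       fraction = mean(hyper), genes = pos$gene[hyper])
}

#' Per-genotype responsive sets and their intersection structure
#'
#' Computes, for one contrast and direction, the DE gene set of each
#' genotype and the sizes of all exclusive intersection cells (Venn/UpSet
#' structure).
#'
#' @param results a \code{contrast_results} table.
#' @param contrast contrast name, e.g. \code{"PT/N"}.
#' @param direction \code{"up"} or \code{"down"}.
#' @param genotypes genotypes to compare (default: all present).
#' @param lfc_threshold,alpha DE thresholds.
#' @return list: \code{sets} (named list of gene vectors), \code{cells}
#'   (named sizes of exclusive regions, keyed by \code{+}-joined genotype
#'   combinations).
#' @export
responsive_set_overlap <- function(results, contrast, direction = c("up",
                                   "down"), genotypes = NULL,
                                   lfc_threshold = 1, alpha = 0.05) {
  direction <- match.arg(direction)
  genotypes <- genotypes %||% unique(results$genotype)
  sub <- results[results$contrast == contrast &
                   results$genotype %in% genotypes, ]
  if (nrow(sub) == 0) stop("contrast not present: ", contrast)
  passes <- if (direction == "up")
    pass_up(sub$log2FC, sub$padj, lfc_threshold, alpha)
  else pass_down(sub$log2FC, sub$padj, lfc_threshold, alpha)
  sets <- lapply(setNames(genotypes, genotypes), function(gt)
    sub$gene[passes & sub$genotype == gt])
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(genotypes[row], collapse = "+"))
  cells <- table(pattern)
  list(sets = sets, cells = setNames(as.integer(cells), names(cells)))
}

#' Write memory calls as TSV
#' @param calls a \code{memory_calls} table.
#' @param path output path.
#' @export
write_memory_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
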