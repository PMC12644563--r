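#' Read a gene x sample count matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds sample IDs and whose
#' first column holds gene IDs.  Row and column order are preserved; counts
#' must be non-negative integers and IDs unique.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("count file needs a gene-ID column plus >= 1 sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  validate_counts(mat, genes, colnames(df)[-1])
}

# shared validation used by the reader and by in-memory inputs
validate_counts <- function(mat, genes = rownames(mat),
                            samples = colnames(mat)) {
  if (anyDuplicated(genes))
    stop("duplicate gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count for gene '", genes[bad[1, 1]],
         "', sample '", samples[bad[1, 2]], "'")
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample sheet (CSV)
#'
#' Columns: sample, genotype, treatment (one of N/T/P/PT, case-sensitive),
#' replicate (positive integer), experiment.
#'
#' @param path file path.
#' @return data frame with the five design columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "treatment", "replicate", "experiment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad)) stop("unknown treatment code(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample ID(s) in sheet: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (any(df$replicate < 1 | df$replicate != round(df$replicate)))
    stop("replicate must be a positive integer")
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a count matrix against a sample sheet
#'
#' @param counts count matrix.
#' @param sheet sample sheet.
#' @return invisibly TRUE; errors name any mismatched sample.
#' @export
check_counts_sheet <- function(counts, sheet) {
  miss <- setdiff(colnames(counts), sheet$sample)
  if (length(miss)) stop("samples in counts but not in sheet: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(sheet$sample, colnames(counts))
  if (length(extra)) stop("samples in sheet but not in counts: ",
                          paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Validate a priming/triggering design
#'
#' Tabulates replicate counts per genotype x treatment cell, flags genotypes
#' missing any required treatment, and flags cells with fewer than two
#' replicates.
#'
#' @param sheet sample sheet.
#' @param required treatments that every genotype must carry (default the
#'   full N/T/P/PT set).
#' @return list of class \code{design_report} with \code{cells} (genotype,
#'   treatment, n), \code{missing_treatments} and \code{low_replication}.
#' @export
validate_design <- function(sheet, required = TREATMENT_LEVELS) {
  bad <- setdiff(required, TREATMENT_LEVELS)
  if (length(bad)) stop("unknown treatment code(s): ",
                        paste(bad, collapse = ", "))
  cells <- aggregate(list(n = sheet$sample),
                     by = list(genotype = sheet$genotype,
                               treatment = sheet$treatment),
                     FUN = length)
  cells <- cells[order(cells$genotype, match(cells$treatment,
                                             TREATMENT_LEVELS)), ]
  row.names(cells) <- NULL
  missing <- do.call(rbind, lapply(unique(sheet$genotype), function(gt) {
    have <- cells$treatment[cells$genotype == gt]
    m <- setdiff(required, have)
    if (length(m)) data.frame(genotype = gt, treatment = m) else NULL
  }))
  low <- cells[cells$n < 2, , drop = FALSE]
  structure(list(cells = cells,
                 missing_treatments = missing,
                 low_replication = low),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design cells:\n")
  print(x$cells)
  if (!is.null(x$missing_treatments) && nrow(x$missing_treatments)) {
    cat("Missing required treatments:\n")
    print(x$missing_treatments)
  } else cat("No missing required treatments.\n")
  if (nrow(x$low_replication)) {
    cat("Cells with < 2 replicates:\n")
    print(x$low_replication)
  }
  invisible(x)
}

#' Read a one-to-one ortholog map (TSV)
#'
#' Two columns (species-A gene, species-B gene); any gene appearing more than
#' once in either column makes the map non one-to-one and is rejected.
#'
#' @param path file path.
#' @return data frame with columns \code{a} and \code{b}.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  out <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  dup_a <- unique(out$a[duplicated(out$a)])
  dup_b <- unique(out$b[duplicated(out$b)])
  if (length(dup_a) || length(dup_b))
    stop("ortholog map is not one-to-one: ",
         length(dup_a) + length(dup_b), " offending gene(s): ",
         paste(c(dup_a, dup_b), collapse = ", "))
  out
}

#' Read a GO (or other term) annotation map (TSV)
#'
#' Columns: gene, term, and optionally term_name.  Empty term sets are never
#' stored.
#'
#' @param path file path.
#' @return list with \code{map} (named list gene -> character vector of
#'   terms) and \code{term_names} (named character vector, possibly empty).
#' @export
read_go_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0)
    return(list(map = list(), term_names = character(0)))
  if (ncol(df) < 2) stop("annotation map needs gene and term columns")
  gene <- as.character(df[[1]]); term <- as.character(df[[2]])
  keep <- nzchar(gene) & nzchar(term)
  map <- lapply(split(term[keep], gene[keep]), unique)
  term_names <- character(0)
  if (ncol(df) >= 3) {
    tn <- as.character(df[[3]])
    term_names <- tn[keep][!duplicated(term[keep])]
    names(term_names) <- term[keep][!duplicated(term[keep])]
  }
  list(map = map, term_names = term_names)
}

#' Read a qPCR Cq table (CSV)
#'
#' Columns: sample, gene, Cq, condition.  At most one row per (sample, gene);
#' Cq must be finite.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_cq <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "Cq", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Cq table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  validate_cq(df)
}

validate_cq <- function(df) {
  if (!all(is.finite(df$Cq))) stop("Cq values must be finite")
  key <- paste(df$sample, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, gene) Cq row(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  df
}

#' Read a growth table (CSV)
#'
#' Columns: plant, phase (NHS or HS), t1, t2 (days), length1, length2 (mm);
#' an optional genotype column is carried through.  Requires t2 > t1 and
#' length2 >= length1 >= 0.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_growth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant", "phase", "t1", "t2", "length1", "length2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("growth table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$phase), c("NHS", "HS"))
  if (length(bad)) stop("unknown growth phase(s): ", paste(bad, collapse = ", "))
  if (any(df$t2 <= df$t1))
    stop("t2 <= t1 for plant(s): ",
         paste(unique(df$plant[df$t2 <= df$t1]), collapse = ", "))
  if (any(df$length1 < 0 | df$length2 < df$length1))
    stop("lengths must satisfy length2 >= length1 >= 0 (plant(s): ",
         paste(unique(df$plant[df$length1 < 0 | df$length2 < df$length1]),
               collapse = ", "), ")")
  df
}
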