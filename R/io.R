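# File formats
#
# genotype TSV : header row of SNP ids, first column the sample id, cells in
#                {0,1,2,NA}.
# phenotype TSV: two columns (sample id, 0/1 status), with header.
# counts TSV   : columns snp_id, r0, r1, r2, s0, s1, s2, is_active.
# VCF          : standard VCF, GT field only; genotype = number of ALT
#                alleles; multi-allelic records skipped, half-calls missing.

#' Genotype dataset (samples x SNPs plus binary phenotype)
#'
#' @param genotypes matrix of 0/1/2/`NA`, samples in rows (rownames = sample
#'   ids), SNPs in columns (colnames = SNP ids).
#' @param phenotype 0/1 vector (1 = case), one entry per sample, named by
#'   sample id or aligned with the rows.
#' @return Object of class `genotype_dataset` with fields `genotypes`,
#'   `phenotype`, `snp_ids`, `sample_ids`.
#' @export
genotype_dataset <- function(genotypes, phenotype) {
  if (!is.matrix(genotypes))
    stop("genotype_dataset: genotypes must be a matrix", call. = FALSE)
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok))
    stop("genotype_dataset: genotype entries must be 0, 1, 2 or NA",
         call. = FALSE)
  if (length(phenotype) != nrow(genotypes))
    stop("genotype_dataset: phenotype length (", length(phenotype),
         ") does not match sample count (", nrow(genotypes), ")",
         call. = FALSE)
  if (anyNA(phenotype) || !all(phenotype %in% c(0, 1)))
    stop("genotype_dataset: phenotype must be 0/1 and non-missing",
         call. = FALSE)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("sample", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  if (!is.null(names(phenotype))) {
    if (!setequal(names(phenotype), rownames(genotypes)))
      stop("genotype_dataset: phenotype names do not match sample ids",
           call. = FALSE)
    phenotype <- phenotype[rownames(genotypes)]
  }
  structure(list(genotypes = genotypes,
                 phenotype = as.integer(phenotype),
                 snp_ids = colnames(genotypes),
                 sample_ids = rownames(genotypes)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("Genotype dataset: %d samples (%d cases, %d controls) x %d SNPs\n",
              length(x$sample_ids), sum(x$phenotype == 1),
              sum(x$phenotype == 0), length(x$snp_ids)))
  cat(sprintf("  missing genotype entries: %d\n", sum(is.na(x$genotypes))))
  invisible(x)
}

#' Per-SNP genotype count tables from a dataset
#'
#' Complete-case tabulation per SNP (see [counts_from_genotypes()]).
#'
#' @param data a [genotype_dataset()].
#' @return A counts matrix (columns `r0,r1,r2,s0,s1,s2`, rownames SNP ids)
#'   accepted by [snp_statistics()] and [screen_counts()].
#' @export
dataset_counts <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  y <- data$phenotype
  tab <- t(apply(data$genotypes, 2, function(g) {
    ok <- !is.na(g)
    c(vapply(0:2, function(i) sum(g[ok] == i & y[ok] == 1), numeric(1)),
      vapply(0:2, function(i) sum(g[ok] == i & y[ok] == 0), numeric(1)))
  }))
  colnames(tab) <- c("r0", "r1", "r2", "s0", "s1", "s2")
  rownames(tab) <- data$snp_ids
  tab
}

#' Read genotype and phenotype data
#'
#' @param path genotype file (TSV dialect above, or VCF).
#' @param format `"tsv"` or `"vcf"`.
#' @param phenotype_path two-column TSV of sample id and 0/1 status; every
#'   genotyped sample must be phenotyped.
#' @return A [genotype_dataset()].  Samples are restricted to those present
#'   in both files; an empty intersection is an error.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), phenotype_path) {
  format <- match.arg(format)
  ph <- read.table(phenotype_path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer"))
  if (ncol(ph) != 2L)
    stop("read_genotypes: phenotype file must have two columns", call. = FALSE)
  if (anyDuplicated(ph[[1]]))
    stop("read_genotypes: duplicated sample ids in phenotype file",
         call. = FALSE)
  pheno <- setNames(ph[[2]], ph[[1]])

  g <- switch(format, tsv = read_genotype_tsv(path), vcf = read_vcf_gt(path))
  common <- intersect(rownames(g), names(pheno))
  if (length(common) == 0L)
    stop("read_genotypes: no samples shared between genotype and phenotype ",
         "files", call. = FALSE)
  extra <- setdiff(names(pheno), rownames(g))
  if (length(extra))
    message("read_genotypes: ", length(extra),
            " phenotyped sample(s) absent from genotype data; dropped")
  dropped <- setdiff(rownames(g), common)
  if (length(dropped))
    message("read_genotypes: ", length(dropped),
            " genotyped sample(s) lack phenotype; dropped")
  genotype_dataset(g[common, , drop = FALSE], pheno[common])
}

read_genotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  if (ncol(df) < 2L)
    stop("genotype TSV needs a sample-id column plus at least one SNP",
         call. = FALSE)
  ids <- df[[1]]
  g <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(g %in% c("0", "1", "2")) & !is.na(g)
  if (any(bad))
    stop("genotype TSV: malformed cell value '", g[bad][1], "'",
         call. = FALSE)
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  g
}

# GT-field-only VCF reader.  Biallelic records only; multi-allelic sites are
# skipped with a message.  Half-calls (./1) and missing GT are NA.
read_vcf_gt <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input needs the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1L
  if (any(multi))
    message("read_genotypes: skipped ", sum(multi), " multi-allelic record(s)")
  gt <- VariantAnnotation::geno(vcf)$GT[!multi, , drop = FALSE]
  ids <- rownames(gt)
  conv <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles))
  }
  g <- apply(gt, c(1, 2), conv)
  half <- gt != "./." & gt != ".|." & is.na(g)
  if (any(half))
    message("read_genotypes: ", sum(half),
            " half-call(s) treated as missing")
  out <- t(g)  # samples x SNPs
  colnames(out) <- ids
  out
}

#' Filter SNPs by missingness and observed genotype classes
#'
#' Applies the two standard pre-screening filters, in order: (1) drop SNPs
#' whose missing fraction exceeds `max_missing_ratio` (strictly greater;
#' exactly at the threshold is retained), (2) drop SNPs with fewer than three
#' distinct observed genotype values.  The surviving set does not depend on
#' the order of the two rules; the report attributes removals to the rule
#' applied first.
#'
#' @param data a [genotype_dataset()].
#' @param max_missing_ratio maximum tolerated missing fraction (default 1\%),
#'   with the denominator being the total sample count.
#' @return The filtered [genotype_dataset()], with attribute
#'   `"filter_report"`: list with `n_missing_removed`, `n_two_genotype_removed`,
#'   `kept`, `removed` (SNP ids).
#' @export
filter_snps <- function(data, max_missing_ratio = 0.01) {
  stopifnot(inherits(data, "genotype_dataset"))
  g <- data$genotypes
  miss_frac <- colMeans(is.na(g))
  drop1 <- miss_frac > max_missing_ratio
  classes <- apply(g, 2, function(col) length(unique(col[!is.na(col)])))
  drop2 <- !drop1 & classes < 3L
  keep <- !drop1 & !drop2
  if (!any(keep))
    stop("filter_snps: no SNPs survive filtering", call. = FALSE)
  out <- genotype_dataset(g[, keep, drop = FALSE], data$phenotype)
  attr(out, "filter_report") <- list(
    n_missing_removed = sum(drop1),
    n_two_genotype_removed = sum(drop2),
    kept = data$snp_ids[keep],
    removed = data$snp_ids[!keep])
  out
}

#' Orient each SNP so the minor allele is the risk allele
#'
#' Computes, per SNP, the frequency of the allele counted by the 0/1/2 coding
#' from the observed genotypes pooled over all samples.  SNPs where that
#' frequency exceeds 1/2 are recoded `g -> 2 - g`, so genotype 2 is always
#' homozygous for the minor allele.  A frequency of exactly 1/2 leaves the
#' coding unchanged.  The MAX statistic is invariant under this flip; the
#' signed recessive/dominant statistics swap (negated), which fixes their
#' interpretation across SNPs.
#'
#' @param data a [genotype_dataset()].
#' @return The reoriented [genotype_dataset()], with attribute `"flipped"`:
#'   logical vector per SNP.
#' @export
orient_minor_allele <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  g <- data$genotypes
  freq <- colMeans(g, na.rm = TRUE) / 2   # coded-allele frequency
  flip <- !is.na(freq) & freq > 0.5
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  out <- genotype_dataset(g, data$phenotype)
  attr(out, "flipped") <- setNames(flip, data$snp_ids)
  out
}

#' Write / read a genotype dataset as TSV
#'
#' @param data a [genotype_dataset()].
#' @param genotype_path,phenotype_path output files.
#' @return The paths, invisibly.
#' @export
write_genotype_tsv <- function(data, genotype_path, phenotype_path) {
  stopifnot(inherits(data, "genotype_dataset"))
  df <- data.frame(sample_id = data$sample_ids,
                   data$genotypes, check.names = FALSE)
  write.table(df, genotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ph <- data.frame(sample_id = data$sample_ids, status = data$phenotype)
  write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Write / read a counts table as TSV
#'
#' @param dataset a `simulated_dataset` from [simulate_counts()], or a counts
#'   matrix (then `active` supplies the truth column).
#' @param path output file.
#' @param active active index set when `dataset` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(dataset, path, active = integer(0)) {
  if (inherits(dataset, "simulated_dataset")) {
    tab <- dataset$tables
    active <- dataset$active
  } else {
    tab <- as_counts_matrix(dataset)
  }
  ids <- rownames(tab)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(tab)))
  df <- data.frame(snp_id = ids, tab,
                   is_active = as.integer(seq_len(nrow(tab)) %in% active))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @return `read_counts_tsv`: list with `tables` (counts matrix, rownames SNP
#'   ids) and `active` (index vector from the `is_active` column).
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", rep("numeric", 7)))
  need <- c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2", "is_active")
  if (!all(need %in% names(df)))
    stop("counts TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  tab <- as.matrix(df[, need[2:7]])
  rownames(tab) <- df$snp_id
  list(tables = tab, active = which(df$is_active == 1))
}

#' Ranked screening output table
#'
#' Long-format per-SNP summary of a screening run: all four adjusted
#' statistics (so methods can be compared downstream regardless of which one
#' drove the ranking), the method's statistic, its rank, and the selection
#' flag.
#'
#' @param result a `screening_result` from [screen_counts()].
#' @param snp_ids optional SNP identifiers.
#' @return data.frame with columns `snp_id`, `n_eff`, `omega_rec`,
#'   `omega_add`, `omega_dom`, `nu`, `method_stat`, `rank`, `selected`.
#' @export
screening_table <- function(result, snp_ids = NULL) {
  stopifnot(inherits(result, "screening_result"))
  m <- length(result$statistics)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  rank_of <- integer(m)
  rank_of[result$ranking] <- seq_len(m)
  data.frame(snp_id = snp_ids,
             n_eff = result$stats$n_eff,
             omega_rec = result$stats$omega_rec,
             omega_add = result$stats$omega_add,
             omega_dom = result$stats$omega_dom,
             nu = result$stats$nu,
             method_stat = result$statistics,
             rank = rank_of,
             selected = as.integer(seq_len(m) %in% result$selected))
}
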