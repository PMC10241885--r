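#' Genotype count table for one SNP
#'
#' Bundles the 2x3 case/control genotype counts of a single SNP.  Genotypes
#' are coded 0/1/2 = copies of the risk allele (labels aa/Aa/AA).
#'
#' @param r integer vector of length 3: case counts for genotypes 0, 1, 2.
#' @param s integer vector of length 3: control counts for genotypes 0, 1, 2.
#' @return An object of class `genotype_counts`: a list with fields `r`, `s`
#'   and the derived margins `n_i` (per-genotype totals), `r_tot`, `s_tot`,
#'   `n` (overall totals).
#' @examples
#' gc <- genotype_counts(r = c(10, 20, 30), s = c(30, 20, 10))
#' gc$n          # 120
#' @export
genotype_counts <- function(r, s) {
  r <- as.numeric(r)
  s <- as.numeric(s)
  if (length(r) != 3L || length(s) != 3L)
    stop("genotype_counts: 'r' and 's' must each have length 3", call. = FALSE)
  if (anyNA(r) || anyNA(s))
    stop("genotype_counts: counts must not be NA", call. = FALSE)
  if (any(r < 0) || any(s < 0))
    stop("genotype_counts: negative count in table r=(",
         paste(r, collapse = ","), "), s=(", paste(s, collapse = ","), ")",
         call. = FALSE)
  if (any(r != floor(r)) || any(s != floor(s)))
    stop("genotype_counts: counts must be integers", call. = FALSE)
  structure(
    list(r = r, s = s, n_i = r + s,
         r_tot = sum(r), s_tot = sum(s), n = sum(r) + sum(s)),
    class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  m <- rbind(cases = x$r, controls = x$s, total = x$n_i)
  colnames(m) <- c("aa(0)", "Aa(1)", "AA(2)")
  cat("Genotype count table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

# Require a table usable for association statistics: both groups present.
check_counts_usable <- function(counts) {
  if (counts$r_tot <= 0 || counts$s_tot <= 0)
    stop("genotype count table needs both cases and controls: r=(",
         paste(counts$r, collapse = ","), "), s=(",
         paste(counts$s, collapse = ","), ")", call. = FALSE)
  invisible(counts)
}

#' Tabulate a genotype count table from per-sample vectors
#'
#' Complete-case tabulation for one SNP: samples with a missing genotype are
#' dropped before counting, so the effective sample size is per-SNP.
#'
#' @param genotypes vector with values in \{0, 1, 2\} or `NA` (missing).
#' @param phenotypes vector of the same length with values in \{0, 1\}
#'   (1 = case, 0 = control); must be non-missing wherever the genotype is
#'   observed.
#' @return A [genotype_counts()] object over the non-missing samples.
#' @examples
#' counts_from_genotypes(c(0, 1, 2, 2), c(1, 1, 0, 0))
#' @export
counts_from_genotypes <- function(genotypes, phenotypes) {
  if (length(genotypes) != length(phenotypes))
    stop("counts_from_genotypes: genotype and phenotype lengths differ (",
         length(genotypes), " vs ", length(phenotypes), ")", call. = FALSE)
  ok <- !is.na(genotypes)
  g <- genotypes[ok]
  y <- phenotypes[ok]
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("counts_from_genotypes: phenotypes must be 0/1 and non-missing",
         call. = FALSE)
  if (!all(g %in% c(0, 1, 2)))
    stop("counts_from_genotypes: genotypes must be 0, 1, 2 or NA",
         call. = FALSE)
  r <- vapply(0:2, function(i) sum(g == i & y == 1), numeric(1))
  s <- vapply(0:2, function(i) sum(g == i & y == 0), numeric(1))
  genotype_counts(r, s)
}

# Coerce a list of genotype_counts (or a 6-column matrix/data.frame with
# columns r0,r1,r2,s0,s1,s2) to the internal m x 6 numeric matrix used by the
# vectorised statistic kernels.
as_counts_matrix <- function(tables) {
  cols <- c("r0", "r1", "r2", "s0", "s1", "s2")
  if (inherits(tables, "genotype_counts")) tables <- list(tables)
  if (is.list(tables) && !is.data.frame(tables)) {
    if (!all(vapply(tables, inherits, logical(1), "genotype_counts")))
      stop("expected genotype_counts objects", call. = FALSE)
    m <- t(vapply(tables, function(x) c(x$r, x$s), numeric(6)))
    colnames(m) <- cols
    return(m)
  }
  if (is.data.frame(tables)) tables <- as.matrix(tables[, cols])
  if (!is.matrix(tables) || ncol(tables) != 6L)
    stop("expected a list of genotype_counts or a 6-column counts matrix",
         call. = FALSE)
  colnames(tables) <- cols
  storage.mode(tables) <- "double"
  tables
}
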