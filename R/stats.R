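#' Statistic value with a definedness flag
#'
#' Association statistics are undefined when the score has zero variance over
#' the observed genotype margin (e.g. the recessive score on a SNP where
#' genotype AA is absent).  Rather than raising, such statistics carry
#' `defined = FALSE` and the conventional value 0, so that screening over
#' thousands of SNPs never aborts on a monomorphic site and an uninformative
#' SNP is simply never selected.
#'
#' @param value numeric scalar.
#' @param defined logical scalar; `FALSE` forces `value = 0`.
#' @return Object of class `stat_value` with fields `value` and `defined`.
#' @export
stat_value <- function(value, defined = TRUE) {
  if (!defined) value <- 0
  structure(list(value = as.numeric(value), defined = isTRUE(defined)),
            class = "stat_value")
}

#' @export
print.stat_value <- function(x, ...) {
  cat(format(x$value),
      if (!x$defined) "(undefined; value 0 by convention)" else "", "\n")
  invisible(x)
}

# ---- vectorised kernels -----------------------------------------------------
# `tab` is an m x 6 matrix with columns r0,r1,r2,s0,s1,s2 (see
# as_counts_matrix).  All kernels return list(value=, defined=) of length m.
# Counts are integers held in doubles, so the variance bracket is exact and
# "> 0" needs no tolerance.

omega_kernel <- function(tab, x) {
  r <- tab[, 1:3, drop = FALSE]
  s <- tab[, 4:6, drop = FALSE]
  rt <- rowSums(r); st <- rowSums(s); n <- rt + st
  ni <- r + s
  num <- (st * r - rt * s) %*% x                 # sum_i X_i (s r_i - r s_i)
  bracket <- n * (ni %*% (x^2)) - (ni %*% x)^2   # n sum X^2 n_i - (sum X n_i)^2
  den2 <- rt * st * as.numeric(bracket)
  defined <- den2 > 0 & rt > 0 & st > 0
  value <- numeric(nrow(tab))
  value[defined] <- as.numeric(num)[defined] / sqrt(den2[defined])
  list(value = value, defined = defined)
}

# omega for the three canonical scores plus their max; one pass over `tab`.
all_stats_kernel <- function(tab) {
  sc <- canonical_scores()
  rec <- omega_kernel(tab, sc$recessive$x)
  add <- omega_kernel(tab, sc$additive$x)
  dom <- omega_kernel(tab, sc$dominant$x)
  vals <- cbind(ifelse(rec$defined, abs(rec$value), -Inf),
                ifelse(add$defined, abs(add$value), -Inf),
                ifelse(dom$defined, abs(dom$value), -Inf))
  nu_def <- rec$defined | add$defined | dom$defined
  nu <- ifelse(nu_def, pmax(vals[, 1], vals[, 2], vals[, 3]), 0)
  list(rec = rec, add = add, dom = dom,
       nu = list(value = nu, defined = nu_def))
}

# Pearson phi^2 = chi^2 / n with empty genotype columns dropped (their 0/0
# cells contribute nothing, which is the same as reducing the table).
pc_kernel <- function(tab) {
  r <- tab[, 1:3, drop = FALSE]
  s <- tab[, 4:6, drop = FALSE]
  rt <- rowSums(r); st <- rowSums(s); n <- rt + st
  ni <- r + s
  chi2 <- numeric(nrow(tab))
  for (i in 1:3) {
    er <- rt * ni[, i] / n
    es <- st * ni[, i] / n
    term <- ifelse(ni[, i] > 0,
                   (r[, i] - er)^2 / pmax(er, .Machine$double.xmin) +
                   (s[, i] - es)^2 / pmax(es, .Machine$double.xmin),
                   0)
    chi2 <- chi2 + term
  }
  defined <- rt > 0 & st > 0
  list(value = ifelse(defined, chi2 / n, 0), defined = defined)
}

first_stat <- function(k) stat_value(k$value[1], k$defined[1])

# ---- scalar user-facing statistics ------------------------------------------

#' Cochran-Armitage trend test statistic
#'
#' Computes the trend statistic
#' \deqn{Z = \frac{\sqrt{n}\sum_i X_i (s r_i - r s_i)}
#'   {\sqrt{r s [\, n \sum_i X_i^2 n_i - (\sum_i X_i n_i)^2 ]}}}
#' for a 2x3 genotype count table under a given score vector.  Under the null
#' of no association Z is asymptotically standard normal.
#'
#' @param counts a [genotype_counts()] table with cases and controls present.
#' @param score a [score_vector()] or model label.
#' @return A [stat_value()]; `defined = FALSE` (value 0) when the variance
#'   bracket is not positive, i.e. the score is constant over the observed
#'   genotype margin.
#' @examples
#' catt_z(genotype_counts(c(0, 0, 50), c(50, 0, 0)), "recessive")  # Z = 10
#' @export
catt_z <- function(counts, score) {
  check_counts_usable(counts)
  k <- omega_kernel(as_counts_matrix(counts), as_score_vector(score)$x)
  stat_value(sqrt(counts$n) * k$value[1], k$defined[1])
}

#' Adjusted trend statistic (aCATT)
#'
#' The trend statistic without its \eqn{\sqrt{n}} factor:
#' \eqn{\hat\omega = Z/\sqrt{n}}.  This removes the sample-size dependence and
#' turns the statistic into a bounded association measure — it equals the
#' sample Pearson correlation between the score-coded genotype and the 0/1
#' phenotype, so \eqn{|\hat\omega| \le 1}.  Screening ranks SNPs by
#' \eqn{|\hat\omega|}.
#'
#' @inheritParams catt_z
#' @return A [stat_value()] in \[-1, 1\].
#' @seealso [amax()] for the model-robust maximum.
#' @export
adjusted_catt <- function(counts, score) {
  check_counts_usable(counts)
  first_stat(omega_kernel(as_counts_matrix(counts), as_score_vector(score)$x))
}

#' Adjusted MAX statistic (aMAX)
#'
#' \eqn{\hat\nu = \max(|\hat\omega_{rec}|, |\hat\omega_{add}|,
#' |\hat\omega_{dom}|)}, the maximum taken over the components whose score has
#' positive variance.  Robust when the true genetic model is unknown; the
#' basis of MAX-SIS screening.
#'
#' @inheritParams catt_z
#' @return A [stat_value()] in \[0, 1\]; `defined = FALSE` only if all three
#'   components are undefined.
#' @export
amax <- function(counts) {
  check_counts_usable(counts)
  first_stat(all_stats_kernel(as_counts_matrix(counts))$nu)
}

#' Pearson chi-square screening index (phi-square)
#'
#' \eqn{\phi^2 = \chi^2 / n} of the 2x3 table, with empty genotype columns
#' dropped.  A model-free comparator for the trend-based screeners: it stands
#' in for categorical Pearson-correlation screening and is documented as such,
#' not as a replication of any particular published index.  Zero exactly when
#' case and control genotype proportions coincide.
#'
#' @inheritParams catt_z
#' @return A [stat_value()] with nonnegative value.
#' @export
pc_index <- function(counts) {
  check_counts_usable(counts)
  first_stat(pc_kernel(as_counts_matrix(counts)))
}

#' All screening statistics for a set of count tables
#'
#' Vectorised one-pass computation of the per-SNP screening statistics.
#'
#' @param tables a list of [genotype_counts()] objects, a single table, or a
#'   matrix/data.frame with columns `r0,r1,r2,s0,s1,s2`.
#' @return A data.frame with one row per SNP: `n_eff`, the signed adjusted
#'   statistics `omega_rec`, `omega_add`, `omega_dom`, the maximum statistic
#'   `nu`, the chi-square index `pc`, and logical `*_defined` flags.
#' @export
snp_statistics <- function(tables) {
  tab <- as_counts_matrix(tables)
  ks <- all_stats_kernel(tab)
  pc <- pc_kernel(tab)
  data.frame(
    row.names = NULL,
    n_eff = unname(rowSums(tab)),
    omega_rec = ks$rec$value, omega_add = ks$add$value,
    omega_dom = ks$dom$value, nu = ks$nu$value, pc = pc$value,
    rec_defined = ks$rec$defined, add_defined = ks$add$defined,
    dom_defined = ks$dom$defined, nu_defined = ks$nu$defined,
    pc_defined = pc$defined)
}
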