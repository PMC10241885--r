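#' Screening configuration
#'
#' Bundles the choice of screening statistic and selection rule.  Methods:
#' `"rec"`, `"add"`, `"dom"` rank by the absolute adjusted trend statistic
#' under the corresponding score vector (REC-SIS, ADD-SIS, DOM-SIS); `"max"`
#' ranks by the adjusted MAX statistic (MAX-SIS); `"pc"` ranks by the
#' chi-square comparator index.  Rules: `"top_d"` keeps the `d` largest
#' statistics; `"threshold"` keeps statistics at least `c0 * n^(-tau)`.
#'
#' @param method one of `"rec"`, `"add"`, `"dom"`, `"max"`, `"pc"`.
#' @param rule `"top_d"` or `"threshold"`.
#' @param d positive integer, required for `rule = "top_d"`.
#' @param c0 positive constant, required for `rule = "threshold"`.
#' @param tau exponent in `[0, 0.5)`, required for `rule = "threshold"`.
#' @return Object of class `screening_config`.
#' @examples
#' screening_config("max", d = default_d(3000))
#' @export
screening_config <- function(method = c("rec", "add", "dom", "max", "pc"),
                             rule = c("top_d", "threshold"),
                             d = NULL, c0 = NULL, tau = NULL) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (rule == "top_d") {
    if (is.null(d) || length(d) != 1L || is.na(d) || d < 1 || d != floor(d))
      stop("screening_config: top_d rule needs a positive integer d",
           call. = FALSE)
    if (!is.null(c0) || !is.null(tau))
      stop("screening_config: c0/tau are threshold-rule parameters",
           call. = FALSE)
  } else {
    if (is.null(c0) || is.null(tau))
      stop("screening_config: threshold rule needs c0 and tau", call. = FALSE)
    if (!is.null(d))
      stop("screening_config: d is a top_d-rule parameter", call. = FALSE)
    check_threshold_params(c0, tau)
  }
  structure(list(method = method, rule = rule, d = d, c0 = c0, tau = tau),
            class = "screening_config")
}

check_threshold_params <- function(c0, tau) {
  if (!is.numeric(c0) || length(c0) != 1L || is.na(c0) || c0 <= 0)
    stop("threshold rule: c0 must be a positive number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau >= 0.5)
    stop("threshold rule: tau must lie in [0, 0.5)", call. = FALSE)
  invisible(TRUE)
}

#' Default screening size d = floor(n / log n)
#'
#' The conventional model-free choice for the number of SNPs to retain, with
#' the natural logarithm and the integer part taken as floor.
#'
#' @param n total sample size, `>= 2`.
#' @return Positive integer.
#' @examples
#' default_d(4901)  # 576
#' @export
default_d <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != floor(n))
    stop("default_d: n must be an integer >= 2", call. = FALSE)
  as.integer(floor(n / log(n)))
}

#' Rank statistics in stable decreasing order
#'
#' @param stats numeric vector of finite statistics.
#' @return An integer permutation of `seq_along(stats)`: the indices ordered
#'   by decreasing statistic, ties broken by smaller index first.
#' @examples
#' rank_statistics(c(0.1, 0.9, 0.5))  # 2 3 1
#' @export
rank_statistics <- function(stats) {
  if (anyNA(stats) || any(!is.finite(stats)))
    stop("rank_statistics: statistics must be finite", call. = FALSE)
  order(-stats, seq_along(stats))
}

#' Threshold selection of indices
#'
#' Keeps the indices whose statistic is at least `c0 * n^(-tau)`; the
#' truncated estimated active set of threshold-based sure screening.
#'
#' @param stats numeric vector of finite nonnegative screening statistics.
#' @param n sample size used in the threshold.
#' @param c0 positive constant.
#' @param tau exponent in `[0, 0.5)`.
#' @return Integer vector of selected indices (possibly empty), increasing.
#' @examples
#' threshold_select(c(0.5, 0.1, 0.3), n = 100, c0 = 2, tau = 0.4)  # 1
#' @export
threshold_select <- function(stats, n, c0, tau) {
  check_threshold_params(c0, tau)
  if (anyNA(stats) || any(!is.finite(stats)))
    stop("threshold_select: statistics must be finite", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("threshold_select: n must be a positive sample size", call. = FALSE)
  which(stats >= c0 * n^(-tau))
}

# Pick the method's statistic column (absolute value for signed omegas) and
# definedness flags from a snp_statistics() data.frame.
method_stat <- function(stats_df, method) {
  switch(method,
         rec = list(value = abs(stats_df$omega_rec),
                    defined = stats_df$rec_defined),
         add = list(value = abs(stats_df$omega_add),
                    defined = stats_df$add_defined),
         dom = list(value = abs(stats_df$omega_dom),
                    defined = stats_df$dom_defined),
         max = list(value = stats_df$nu, defined = stats_df$nu_defined),
         pc  = list(value = stats_df$pc, defined = stats_df$pc_defined),
         stop("unknown screening method '", method, "'", call. = FALSE))
}

# Ranking used by screen_counts: undefined statistics rank after every
# defined one, in index order.  Encoded by mapping undefined to -Inf (all
# screening statistics are >= 0) with the stable index tie-break.
rank_with_undefined <- function(value, defined) {
  v <- ifelse(defined, value, -Inf)
  order(-v, seq_along(v))
}

#' Screen a set of genotype count tables
#'
#' Computes the configured method's statistic for every SNP, ranks SNPs in
#' decreasing order and applies the selection rule.
#'
#' @param tables a list of [genotype_counts()] (or a 6-column counts
#'   matrix/data.frame, columns `r0,r1,r2,s0,s1,s2`), one table per SNP.
#' @param config a [screening_config()].
#' @param require_equal_margins all tables must share the same case and
#'   control totals (one fully observed study).  Set `FALSE` for per-SNP
#'   complete-case data, where the study-level `n` (the maximum effective
#'   sample size over SNPs) is used in the threshold rule.
#' @return Object of class `screening_result`: list with `statistics` (the
#'   method's per-SNP statistic), `defined`, `ranking` (permutation, best
#'   first), `selected` (increasing index vector), the full
#'   [snp_statistics()] table `stats`, and the `config`.
#' @examples
#' cfg <- simulation_config(model = "I", m = 50, n = 600, seed = 7)
#' sim <- simulate_counts(cfg)
#' res <- screen_counts(sim$tables, screening_config("max", d = 10))
#' res$selected
#' @export
screen_counts <- function(tables, config, require_equal_margins = TRUE) {
  if (!inherits(config, "screening_config"))
    stop("screen_counts: config must be a screening_config", call. = FALSE)
  tab <- as_counts_matrix(tables)
  m <- nrow(tab)
  if (m < 1L) stop("screen_counts: no tables supplied", call. = FALSE)
  rt <- rowSums(tab[, 1:3, drop = FALSE])
  st <- rowSums(tab[, 4:6, drop = FALSE])
  if (any(rt <= 0) || any(st <= 0))
    stop("screen_counts: table ", which(rt <= 0 | st <= 0)[1],
         " lacks cases or controls", call. = FALSE)
  if (require_equal_margins &&
      (length(unique(rt)) != 1L || length(unique(st)) != 1L))
    stop("screen_counts: tables have inconsistent case/control margins; ",
         "pass require_equal_margins = FALSE for per-SNP complete-case data",
         call. = FALSE)

  stats_df <- snp_statistics(tab)
  sel <- select_from_stats(stats_df, config, n_study = max(rt + st))
  structure(c(sel, list(stats = stats_df, config = config)),
            class = "screening_result")
}

# Shared by screen_counts and the replicated evaluation loop: apply a
# screening_config to an already computed snp_statistics() table.
select_from_stats <- function(stats_df, config, n_study) {
  m <- nrow(stats_df)
  ms <- method_stat(stats_df, config$method)
  ranking <- rank_with_undefined(ms$value, ms$defined)
  if (config$rule == "top_d") {
    if (config$d > m)
      stop("screening: d = ", config$d, " exceeds the number of SNPs m = ",
           m, call. = FALSE)
    selected <- sort(ranking[seq_len(config$d)])
  } else {
    selected <- threshold_select(ifelse(ms$defined, ms$value, 0),
                                 n_study, config$c0, config$tau)
  }
  list(statistics = ms$value, defined = ms$defined,
       ranking = ranking, selected = selected)
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening result: method=%s rule=%s, m=%d SNPs, %d selected\n",
              x$config$method, x$config$rule, length(x$statistics),
              length(x$selected)))
  top <- x$ranking[seq_len(min(5L, length(x$ranking)))]
  cat("Top SNPs:", paste(sprintf("#%d (%.4f)", top, x$statistics[top]),
                         collapse = ", "), "\n")
  invisible(x)
}
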