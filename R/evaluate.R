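# Replicated simulation x screening experiments and the two selection
# criteria: per-SNP selection proportion P_s^k (fraction of replications in
# which active SNP k is selected) and all-selected proportion P_a (fraction
# in which every active SNP is selected simultaneously).

# Derive per-replication seeds from a master seed; kept below 2^31.
replication_seeds <- function(seed, reps) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, reps))
}

# Core loop shared by evaluate_method and run_grid: all methods are screened
# against the SAME replication draws, so method differences are paired
# comparisons with reduced Monte-Carlo variance.
eval_cell <- function(config, configs_by_method, reps) {
  rep_seeds <- replication_seeds(config$seed, reps)
  a <- length(config$active)
  hits <- lapply(configs_by_method, function(.) {
    matrix(FALSE, nrow = reps, ncol = a)
  })
  all_sel <- lapply(configs_by_method, function(.) logical(reps))

  for (i in seq_len(reps)) {
    cfg_i <- config
    cfg_i$seed <- rep_seeds[i]
    sim <- simulate_counts(cfg_i)
    stats_df <- snp_statistics(sim$tables)
    for (meth in names(configs_by_method)) {
      sel <- select_from_stats(stats_df, configs_by_method[[meth]],
                               n_study = config$n)$selected
      inset <- config$active %in% sel
      if (a) hits[[meth]][i, ] <- inset
      all_sel[[meth]][i] <- all(inset)   # vacuously TRUE when active is empty
    }
  }

  lapply(names(configs_by_method), function(meth) {
    ps <- if (a) colMeans(hits[[meth]]) else numeric(0)
    names(ps) <- as.character(config$active)
    pa <- mean(all_sel[[meth]])
    structure(list(method = meth, per_snp = ps, all_selected = pa,
                   reps = reps,
                   mc_se = sqrt(pa * (1 - pa) / reps),
                   config = config,
                   screening = configs_by_method[[meth]]),
              class = "evaluation_summary")
  })
}

#' Replicated evaluation of one screening method
#'
#' Runs `reps` independent simulate-screen replications under `config` and
#' reports, for each active SNP, the proportion of replications in which it
#' was selected (`per_snp`, the criterion P_s^k) and the proportion in which
#' all active SNPs were selected simultaneously (`all_selected`, the
#' criterion P_a).  With an empty active set, P_a is 1 by convention (vacuous
#' conjunction) and `per_snp` is empty.
#'
#' @param config a [simulation_config()]; its seed drives the whole
#'   experiment (per-replication seeds are derived from it).
#' @param screening a [screening_config()], or `NULL` for MAX-SIS with
#'   `d = default_d(config$n)`.
#' @param reps number of replications (conventional full scale: 500; the
#'   desk-scale default is 100).
#' @return Object of class `evaluation_summary`: `per_snp` (named vector of
#'   P_s^k), `all_selected` (P_a), `reps`, `mc_se` (binomial Monte-Carlo
#'   standard error of P_a), `config`, `screening`.
#' @examples
#' cfg <- simulation_config(model = "I", m = 200, n = 1500, alpha = 0.45,
#'                          seed = 11)
#' evaluate_method(cfg, screening_config("max", d = 20), reps = 10)
#' @export
evaluate_method <- function(config, screening = NULL, reps = 100L) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(screening))
    screening <- screening_config("max", d = default_d(config$n))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("evaluate_method: reps must be a positive integer", call. = FALSE)
  eval_cell(config, setNames(list(screening), screening$method),
            as.integer(reps))[[1L]]
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(
    "Evaluation: %s-SIS, model %s, n=%d, w=%s, alpha=%s, %d reps\n",
    toupper(x$method), x$config$model, x$config$n, format(x$config$w),
    format(x$config$alpha), x$reps))
  if (length(x$per_snp)) {
    cat("  P_s^k:", paste(sprintf("%s=%.3f", names(x$per_snp), x$per_snp),
                          collapse = " "), "\n")
  }
  cat(sprintf("  P_a = %.3f (MC se %.3f)\n", x$all_selected, x$mc_se))
  invisible(x)
}

#' Evaluate a grid of simulation settings and screening methods
#'
#' Expands the cross product of `models`, `n`, `w` and `alpha`, evaluates
#' every requested method in every cell (methods within a cell share the same
#' replication draws), and returns a long-format results table.  Each cell
#' gets a deterministic seed derived from the master `seed` and the cell's
#' parameters, so results do not depend on the order in which cells are run.
#'
#' @param models character vector over \{"I","II","III","IV"\}.
#' @param n,w,alpha numeric vectors of sample sizes, case:control ratios and
#'   minor allele frequencies.
#' @param methods screening methods (see [screening_config()]).
#' @param reps replications per cell.
#' @param m number of SNPs per panel.
#' @param d number of SNPs to keep; `NULL` means `default_d(n)` per cell.
#' @param active active index set passed to every cell.
#' @param seed master seed.
#' @return data.frame with columns `model`, `n`, `w`, `alpha`, `method`, `d`,
#'   `reps`, `snp_index` (an active index, or `"all"` for P_a), `proportion`,
#'   `mc_se`.
#' @export
run_grid <- function(models = "I", n = 3000, w = 1, alpha = 0.3,
                     methods = c("rec", "add", "dom", "max", "pc"),
                     reps = 100L, m = 10000L, d = NULL, active = 1:6,
                     seed) {
  if (missing(seed))
    stop("run_grid: an explicit integer seed is required", call. = FALSE)
  grid <- expand.grid(model = models, n = n, w = w, alpha = alpha,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- simulation_config(model = g$model, m = m, n = g$n, w = g$w,
                             alpha = g$alpha, active = active,
                             seed = cell_seed(seed, g))
    d_cell <- if (is.null(d)) default_d(cfg$n) else d
    scfgs <- setNames(lapply(methods, screening_config, d = d_cell), methods)
    summaries <- eval_cell(cfg, scfgs, as.integer(reps))
    out[[i]] <- do.call(rbind, lapply(summaries, summary_rows, cell = g,
                                      d = d_cell))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Deterministic, order-independent per-cell seed: fold the cell parameters
# into the master seed with a small string hash.
cell_seed <- function(seed, g) {
  key <- paste(g$model, g$n, format(g$w, digits = 10),
               format(g$alpha, digits = 10), sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.double(seed) * 1009 + h) %% (.Machine$integer.max - 1) + 1)
}

summary_rows <- function(s, cell, d) {
  idx <- c(names(s$per_snp), "all")
  prop <- c(unname(s$per_snp), s$all_selected)
  data.frame(model = cell$model, n = cell$n, w = cell$w, alpha = cell$alpha,
             method = s$method, d = d, reps = s$reps,
             snp_index = idx, proportion = prop,
             mc_se = sqrt(prop * (1 - prop) / s$reps))
}

#' Write a grid results table as TSV
#'
#' @param results data.frame from [run_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
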