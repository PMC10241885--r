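#' Case/control sample sizes from total size and case:control ratio
#'
#' @param n total sample size.
#' @param w case:control ratio p:q (e.g. 1, 1/3, 1/5).
#' @return Integer vector `c(r, s)` with `r = round(n w / (1 + w))` cases and
#'   `s = n - r` controls.
#' @examples
#' case_control_sizes(3000, 1/5)  # 500 2500
#' @export
case_control_sizes <- function(n, w) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != floor(n))
    stop("case_control_sizes: n must be an integer >= 2", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0)
    stop("case_control_sizes: w must be a positive ratio", call. = FALSE)
  r <- round(n * w / (1 + w))
  s <- n - r
  if (r < 1 || s < 1)
    stop("case_control_sizes: degenerate design (r = ", r, ", s = ", s, ")",
         call. = FALSE)
  c(r = as.integer(r), s = as.integer(s))
}

#' Simulation configuration
#'
#' Describes one simulated case-control SNP panel.  Controls follow
#' Hardy-Weinberg genotype proportions at MAF `alpha`; active SNPs get their
#' case genotype distribution from the model's genotype-relative-risk
#' re-weighting (see [case_genotype_probs()]); all other SNPs are null
#' (case distribution = control distribution).
#'
#' Model `"IV"` mixes the three single-model laws over the active set: with
#' the default six active SNPs, SNPs 1-2 follow model I (`lambda = 1.8`),
#' 3-4 model II (`lambda = 1.4`) and 5-6 model III (`lambda = 1.6`).  A
#' general active set is split into three contiguous blocks, as even as
#' possible, in the same model order.
#'
#' @param model `"I"` (recessive), `"II"` (additive), `"III"` (dominant) or
#'   `"IV"` (mixture).
#' @param m number of SNPs.  Default 1e4 is the desk-scale setting; the
#'   full-scale panels of 1e5 SNPs are supported by setting `m` explicitly.
#' @param n total sample size.
#' @param w case:control ratio; cases `r = round(n w / (1+w))`.
#' @param alpha minor allele frequency in (0, 0.5].
#' @param lambda genotype relative risk of active SNPs.  `NULL` uses the
#'   model's conventional effect: 1.8 (I), 1.4 (II), 1.6 (III), and the
#'   per-block triple (1.8, 1.4, 1.6) for model IV.
#' @param active indices of the SNPs associated with the phenotype
#'   (default the first six); `integer(0)` for a fully null panel.
#' @param seed integer RNG seed; required so that every dataset is
#'   reproducible.
#' @return Object of class `simulation_config` (also carries the derived
#'   case/control sizes `r`, `s`).
#' @export
simulation_config <- function(model = c("I", "II", "III", "IV"),
                              m = 10000L, n = 3000L, w = 1, alpha = 0.3,
                              lambda = NULL, active = 1:6, seed) {
  model <- match.arg(model)
  if (missing(seed))
    stop("simulation_config: an explicit integer seed is required",
         call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m))
    stop("simulation_config: m must be a positive integer", call. = FALSE)
  rs <- case_control_sizes(n, w)
  control_genotype_probs(alpha)  # validates alpha
  active <- as.integer(active)
  if (length(active) && (any(active < 1) || any(active > m) ||
                         anyDuplicated(active)))
    stop("simulation_config: active must be distinct indices in 1..m",
         call. = FALSE)
  if (!is.null(lambda) && (!is.numeric(lambda) || any(lambda < 1)))
    stop("simulation_config: lambda must be >= 1", call. = FALSE)
  structure(list(model = model, m = as.integer(m), n = as.integer(n), w = w,
                 alpha = alpha, lambda = lambda, active = active,
                 seed = as.integer(seed), r = rs[["r"]], s = rs[["s"]]),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: model %s, m=%d SNPs, n=%d (r=%d cases, s=%d controls),\n  w=%s, alpha=%s, %d active SNPs, seed=%d\n",
    x$model, x$m, x$n, x$r, x$s, format(x$w), format(x$alpha),
    length(x$active), x$seed))
  invisible(x)
}

default_lambda <- function(model) {
  switch(model, I = 1.8, II = 1.4, III = 1.6,
         IV = c(1.8, 1.4, 1.6))
}

# Per-active-SNP (model, lambda) assignment.  For models I-III every active
# SNP shares the single model; model IV splits the active set into three
# contiguous blocks (sizes as even as possible, remainder to earlier blocks)
# following models I, II, III.
active_model_map <- function(config) {
  a <- length(config$active)
  if (a == 0L)
    return(data.frame(index = integer(0), model = character(0),
                      lambda = numeric(0)))
  if (config$model != "IV") {
    lam <- if (is.null(config$lambda)) default_lambda(config$model)
           else config$lambda[1]
    return(data.frame(index = config$active, model = config$model,
                      lambda = lam))
  }
  lam <- if (is.null(config$lambda)) default_lambda("IV") else {
    if (length(config$lambda) != 3L)
      stop("model IV needs three lambdas (models I, II, III)", call. = FALSE)
    config$lambda
  }
  sizes <- rep(a %/% 3L, 3L)
  extra <- a %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  blocks <- rep(c("I", "II", "III"), times = sizes)
  data.frame(index = config$active, model = blocks, lambda = lam[
    match(blocks, c("I", "II", "III"))])
}

# Evaluate a thunk with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Conditional case genotype distributions for every active SNP.
active_case_probs <- function(config) {
  ctrl <- control_genotype_probs(config$alpha)
  map <- active_model_map(config)
  lapply(seq_len(nrow(map)), function(i)
    case_genotype_probs(map$model[i], map$lambda[i], ctrl))
}

#' Simulate per-SNP genotype count tables
#'
#' Draws, for every SNP, the case genotype counts from a trinomial
#' distribution with `r` trials and the SNP's case genotype distribution, and
#' the control counts from a trinomial with `s` trials and Hardy-Weinberg
#' probabilities at MAF `alpha`.  Null SNPs use the control distribution for
#' both groups.  Only counts are generated: the screening statistics depend on
#' the data through the 2x3 table alone, so sample-level genotypes are not
#' needed (see [simulate_genotype_matrix()] when they are).
#'
#' Deterministic given `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config a [simulation_config()].
#' @return Object of class `simulated_dataset`: list with `tables` (an
#'   `m x 6` counts matrix, columns `r0,r1,r2,s0,s1,s2`, directly accepted by
#'   [screen_counts()] and [snp_statistics()]), `active` (true active index
#'   set), `population` (per-active-SNP [population_snp_model()] plus the
#'   shared `null` model, for diagnostics) and the `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ctrl <- control_genotype_probs(config$alpha)
  case_probs <- active_case_probs(config)
  p <- config$r / config$n

  tab <- with_seed(config$seed, {
    # fixed draw order: active cases (SNP by SNP), null cases, all controls
    cases <- matrix(0, nrow = config$m, ncol = 3)
    for (i in seq_along(config$active))
      cases[config$active[i], ] <- rmultinom(1, config$r, case_probs[[i]])
    nulls <- setdiff(seq_len(config$m), config$active)
    if (length(nulls))
      cases[nulls, ] <- t(rmultinom(length(nulls), config$r, ctrl))
    controls <- t(rmultinom(config$m, config$s, ctrl))
    cbind(cases, controls)
  })
  colnames(tab) <- c("r0", "r1", "r2", "s0", "s1", "s2")

  map <- active_model_map(config)
  population <- lapply(seq_len(nrow(map)), function(i)
    snp_population_model(map$model[i], map$lambda[i], config$alpha, p = p))
  names(population) <- as.character(map$index)
  population$null <- null_population_model(config$alpha, p = p)

  structure(list(tables = tab, active = config$active,
                 population = population, config = config),
            class = "simulated_dataset")
}

#' Simulate a sample-level genotype matrix
#'
#' Expands the same generative law as [simulate_counts()] to per-sample
#' genotypes: phenotype 1 for the first `r` samples and 0 for the remaining
#' `s`, genotypes drawn independently per SNP from the group's genotype
#' distribution.  Exists to exercise the real-data code path (tabulation,
#' filtering, file IO); for screening alone the count-level simulation is
#' sufficient and far cheaper.
#'
#' @param config a [simulation_config()] with `m * n <= 1e8`.
#' @return List with `genotypes` (an `n x m` integer matrix, samples in rows,
#'   values 0/1/2, rownames sample ids, colnames SNP ids), `phenotype`
#'   (named 0/1 vector), `active`, `config`.
#' @export
simulate_genotype_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (as.double(config$m) * config$n > 1e8)
    stop("simulate_genotype_matrix: m * n exceeds the 1e8-entry guard; ",
         "use simulate_counts() for large panels", call. = FALSE)
  ctrl <- control_genotype_probs(config$alpha)
  case_probs <- active_case_probs(config)
  pos <- match(seq_len(config$m), config$active)  # NA for null SNPs

  g <- with_seed(config$seed, {
    vapply(seq_len(config$m), function(k) {
      pc <- if (is.na(pos[k])) ctrl else case_probs[[pos[k]]]
      c(sample(0:2, config$r, replace = TRUE, prob = pc),
        sample(0:2, config$s, replace = TRUE, prob = ctrl))
    }, integer(config$n))
  })
  dimnames(g) <- list(paste0("sample", seq_len(config$n)),
                      paste0("snp", seq_len(config$m)))
  phenotype <- setNames(rep(c(1L, 0L), c(config$r, config$s)), rownames(g))
  list(genotypes = g, phenotype = phenotype, active = config$active,
       config = config)
}
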