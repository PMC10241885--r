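test_that("control genotype distribution is Hardy-Weinberg", {
  expect_equal(control_genotype_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(control_genotype_probs(0.2), c(0.64, 0.32, 0.04))
  for (a in c(0.01, 0.15, 0.37, 0.5))
    expect_equal(sum(control_genotype_probs(a)), 1)
  expect_error(control_genotype_probs(0), "alpha")
  expect_error(control_genotype_probs(0.6), "alpha")
})

test_that("case genotype distributions follow the model weight vectors", {
  ctrl <- control_genotype_probs(0.3)
  # lambda = 1: null, case = control for every model
  for (mod in c("I", "II", "III"))
    expect_equal(case_genotype_probs(mod, 1, ctrl), ctrl, tolerance = 1e-14)

  # Model I at the printed setting vs the transcription oracle
  pj <- oracle_model_case_joint("I", 1.8, 0.45, 0.5)
  expect_equal(case_genotype_probs("I", 1.8, control_genotype_probs(0.45)),
               pj / sum(pj), tolerance = 1e-12)

  # Model II: genotype-2 weight is 2*lambda - 1 relative to genotype 0
  cs <- case_genotype_probs("II", 1.4, ctrl)
  expect_equal((cs[3] / cs[1]) / (ctrl[3] / ctrl[1]), 2 * 1.4 - 1,
               tolerance = 1e-12)
  expect_equal(sum(cs), 1)

  expect_error(case_genotype_probs("V", 1.5, ctrl), "unknown genetic model")
  expect_error(case_genotype_probs("I", 0.5, ctrl), "lambda")
})

test_that("simulation_config derives case/control sizes from n and w", {
  expect_identical(case_control_sizes(3000, 1 / 5), c(r = 500L, s = 2500L))
  expect_identical(case_control_sizes(3000, 1 / 3), c(r = 750L, s = 2250L))
  expect_identical(case_control_sizes(4500, 1), c(r = 2250L, s = 2250L))
  cfg <- simulation_config(model = "I", m = 100, n = 3000, w = 1 / 5, seed = 1)
  expect_identical(c(cfg$r, cfg$s), c(500L, 2500L))
  expect_error(simulation_config(model = "I", m = 10, active = 1:20, seed = 1),
               "active")
  expect_error(simulation_config(model = "I", m = 10), "seed")
})

test_that("model IV assigns active blocks to models I, II, III", {
  cfg <- simulation_config(model = "IV", m = 100, seed = 2)
  map <- trendscreen:::active_model_map(cfg)
  expect_identical(map$model, rep(c("I", "II", "III"), each = 2))
  expect_identical(map$lambda, rep(c(1.8, 1.4, 1.6), each = 2))
})

test_that("simulate_counts draws trinomials with the configured margins", {
  cfg <- simulation_config(model = "II", m = 500, n = 1200, w = 1 / 3,
                           alpha = 0.25, seed = 31)
  sim <- simulate_counts(cfg)
  expect_identical(dim(sim$tables), c(500L, 6L))
  expect_true(all(rowSums(sim$tables[, 1:3]) == cfg$r))
  expect_true(all(rowSums(sim$tables[, 4:6]) == cfg$s))
  expect_identical(sim$active, 1:6)

  # identical seeds give identical datasets; different seeds differ
  sim2 <- simulate_counts(cfg)
  expect_identical(sim$tables, sim2$tables)
  cfg3 <- simulation_config(model = "II", m = 500, n = 1200, w = 1 / 3,
                            alpha = 0.25, seed = 32)
  expect_false(identical(sim$tables, simulate_counts(cfg3)$tables))

  # the caller's RNG stream is not disturbed
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(simulate_counts(cfg)); b <- runif(3)
  expect_identical(a, b)
})

test_that("null panels reproduce Hardy-Weinberg genotype frequencies", {
  alpha <- 0.3
  cfg <- simulation_config(model = "I", m = 1, n = 1e5, alpha = alpha,
                           active = integer(0), seed = 33)
  sim <- simulate_counts(cfg)
  f_hat <- (sim$tables[1, 1:3] + sim$tables[1, 4:6]) / cfg$n
  hwe <- control_genotype_probs(alpha)
  se <- sqrt(hwe * (1 - hwe) / cfg$n)
  expect_true(all(abs(f_hat - hwe) < 3 * se))

  # null SNPs are independent of Y at the population level
  mod <- sim$population$null
  for (sc in the_scores)
    expect_equal(population_omega(mod, sc)$value, 0, tolerance = 1e-14)
  # active SNPs have positive population nu
  cfg2 <- simulation_config(model = "IV", m = 10, alpha = 0.3, seed = 34)
  pop <- simulate_counts(cfg2)$population
  for (k in as.character(1:6))
    expect_gt(population_nu(pop[[k]])$value, 0)
})

test_that("active-SNP statistics concentrate on the population measure", {
  # Model I, printed settings: mean omega_rec over replicate draws lands
  # within 3 Monte-Carlo standard errors of the population value
  cfg <- simulation_config(model = "I", m = 1, n = 4500, w = 1, alpha = 0.45,
                           active = 1L, seed = 35)
  mod <- snp_population_model("I", 1.8, 0.45, p = 0.5)
  omega <- population_omega(mod, "recessive")$value
  reps <- 300
  seeds <- trendscreen:::replication_seeds(cfg$seed, reps)
  vals <- vapply(seq_len(reps), function(i) {
    cfg$seed <- seeds[i]
    snp_statistics(simulate_counts(cfg)$tables)$omega_rec[1]
  }, numeric(1))
  expect_lt(abs(mean(vals) - omega), 3 * stats::sd(vals) / sqrt(reps))
})

test_that("simulate_genotype_matrix expands the same generative law", {
  cfg <- simulation_config(model = "I", m = 50, n = 400, w = 1, alpha = 0.35,
                           seed = 36)
  sim <- simulate_genotype_matrix(cfg)
  expect_identical(dim(sim$genotypes), c(400L, 50L))
  # phenotype has exactly r ones then s zeros
  expect_identical(sum(sim$phenotype == 1), cfg$r)
  expect_identical(sum(sim$phenotype == 0), cfg$s)

  # tabulation reproduces the count-level distribution (goodness of fit on
  # the pooled genotype margin of every null SNP; a few rejections at the
  # 0.01 level are expected by chance among 44 tests)
  hwe <- control_genotype_probs(0.35)
  pvals <- vapply(setdiff(seq_len(50), cfg$active), function(k) {
    gc <- counts_from_genotypes(sim$genotypes[, k], sim$phenotype)
    suppressWarnings(stats::chisq.test(gc$n_i, p = hwe))$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 3)

  # round trip: matrix -> counts -> statistics equals direct tabulation
  gc <- counts_from_genotypes(sim$genotypes[, 3], sim$phenotype)
  tab <- dataset_counts(genotype_dataset(sim$genotypes, sim$phenotype))
  expect_equal(unname(tab[3, ]), c(gc$r, gc$s))

  expect_error(
    simulate_genotype_matrix(
      simulation_config(model = "I", m = 1e6, n = 1000, seed = 1)),
    "guard")
})
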