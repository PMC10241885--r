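test_that("catt_z matches the brute-force oracle and handles edge cases", {
  # identical case/control distributions: all s*r_i - r*s_i terms vanish
  z <- catt_z(genotype_counts(c(10, 20, 30), c(10, 20, 30)), "additive")
  expect_true(z$defined)
  expect_identical(z$value, 0)

  # perfectly separated table, recessive score: strongly positive
  gc <- genotype_counts(c(0, 0, 50), c(50, 0, 0))
  z <- catt_z(gc, "recessive")
  expect_equal(z$value, oracle_catt_z(gc$r, gc$s, c(0, 0, 1)), tolerance = 1e-12)
  expect_gt(z$value, 5)

  # zero-variance recessive score (genotype AA absent): undefined, value 0
  z <- catt_z(genotype_counts(c(25, 25, 0), c(25, 25, 0)), "recessive")
  expect_false(z$defined)
  expect_identical(z$value, 0)

  # fuzz against the oracle over all three scores
  set.seed(41)
  for (i in 1:200) {
    gc <- rand_table()
    for (sc in the_scores) {
      zo <- oracle_catt_z(gc$r, gc$s, score_vector(sc)$x)
      zp <- catt_z(gc, sc)
      if (is.na(zo)) expect_false(zp$defined)
      else expect_equal(zp$value, zo, tolerance = 1e-10)
    }
  }
})

test_that("catt_z rejects invalid tables", {
  expect_error(genotype_counts(c(-1, 2, 3), c(1, 1, 1)), "negative")
  expect_error(catt_z(genotype_counts(c(0, 0, 0), c(1, 1, 1)), "additive"),
               "cases and controls")
  expect_error(catt_z(genotype_counts(c(1, 1, 1), c(0, 0, 0)), "additive"),
               "cases and controls")
})

test_that("adjusted_catt is Z/sqrt(n) and the per-sample Pearson correlation", {
  # the printed worked table: dominant score vs expanded-vector correlation
  gc <- genotype_counts(c(10, 20, 30), c(30, 20, 10))
  om <- adjusted_catt(gc, "dominant")
  expect_equal(om$value, oracle_corr(gc$r, gc$s, c(0, 1, 1)),
               tolerance = 1e-10)

  # independence gives exactly zero
  expect_identical(
    adjusted_catt(genotype_counts(c(6, 10, 4), c(12, 20, 8)), "additive")$value,
    0)

  set.seed(42)
  for (i in 1:300) {
    gc <- rand_table()
    n <- gc$n
    for (sc in the_scores) {
      om <- adjusted_catt(gc, sc)
      z <- catt_z(gc, sc)
      expect_identical(om$defined, z$defined)
      if (!om$defined) next
      # identity with the unadjusted statistic
      expect_equal(om$value * sqrt(n), z$value, tolerance = 1e-10)
      # bounded correlation
      expect_lte(abs(om$value), 1 + 1e-12)
      # equals the sample correlation on expanded vectors
      expect_equal(om$value, oracle_corr(gc$r, gc$s, score_vector(sc)$x),
                   tolerance = 1e-10)
    }
  }
})

test_that("amax is the max of defined |omega| components", {
  expect_identical(
    amax(genotype_counts(c(10, 20, 30), c(10, 20, 30)))$value, 0)

  gc <- genotype_counts(c(10, 20, 30), c(30, 20, 10))
  comps <- sapply(the_scores, function(sc)
    abs(oracle_corr(gc$r, gc$s, score_vector(sc)$x)))
  expect_equal(amax(gc)$value, max(comps), tolerance = 1e-10)

  # genotype AA never observed: recessive component undefined and excluded
  gc <- genotype_counts(c(10, 40, 0), c(30, 20, 0))
  expect_false(adjusted_catt(gc, "recessive")$defined)
  comps <- sapply(c("additive", "dominant"), function(sc)
    abs(oracle_corr(gc$r, gc$s, score_vector(sc)$x)))
  expect_equal(amax(gc)$value, max(comps), tolerance = 1e-10)

  # monomorphic SNP: all components undefined, never selected
  mono <- amax(genotype_counts(c(10, 0, 0), c(20, 0, 0)))
  expect_false(mono$defined)
  expect_identical(mono$value, 0)
})

test_that("population measures match their oracles and definitions", {
  # independence: all omegas and nu are zero
  null <- null_population_model(alpha = 0.3, p = 0.4)
  for (sc in the_scores)
    expect_equal(population_omega(null, sc)$value, 0, tolerance = 1e-14)
  expect_equal(population_nu(null)$value, 0, tolerance = 1e-14)

  # Model I population via the transcription oracle
  pj <- oracle_model_case_joint("I", 1.8, 0.45, 0.5)
  qj <- 0.5 * c(0.55^2, 2 * 0.45 * 0.55, 0.45^2)
  mod <- snp_population_model("I", 1.8, 0.45, p = 0.5)
  for (sc in the_scores)
    expect_equal(population_omega(mod, sc)$value,
                 oracle_population_omega(pj, qj, score_vector(sc)$x),
                 tolerance = 1e-12)

  # nu is the max of the three components
  expect_equal(population_nu(mod)$value,
               max(sapply(the_scores, function(sc)
                 abs(population_omega(mod, sc)$value))),
               tolerance = 1e-14)

  # Model III: the dominant component attains the maximum
  mod3 <- snp_population_model("III", 1.6, 0.25, p = 0.5)
  vals <- sapply(the_scores, function(sc)
    abs(population_omega(mod3, sc)$value))
  expect_identical(names(which.max(vals)), "dominant")
  expect_equal(population_nu(mod3)$value, vals[["dominant"]],
               tolerance = 1e-14)
})

test_that("adjusted_catt is consistent for the population measure", {
  # law of large numbers: one huge draw lands within 0.01 of omega
  mod <- snp_population_model("I", 1.8, 0.45, p = 0.5)
  n <- 1e6
  set.seed(7)
  r <- as.numeric(rmultinom(1, n / 2, mod$p_joint / mod$p))
  s <- as.numeric(rmultinom(1, n / 2, mod$q_joint / mod$q))
  gc <- genotype_counts(r, s)
  for (sc in the_scores)
    expect_lt(abs(adjusted_catt(gc, sc)$value -
                  population_omega(mod, sc)$value), 0.01)

  # mean absolute error decreases with n
  set.seed(8)
  omega <- population_omega(mod, "recessive")$value
  mae <- sapply(c(500, 5000, 50000), function(n) {
    errs <- replicate(40, {
      r <- as.numeric(rmultinom(1, n / 2, mod$p_joint / mod$p))
      s <- as.numeric(rmultinom(1, n / 2, mod$q_joint / mod$q))
      abs(adjusted_catt(genotype_counts(r, s), "recessive")$value - omega)
    })
    mean(errs)
  })
  expect_true(all(diff(mae) < 0))
})

test_that("pc_index matches the chi-square oracle and column dropping", {
  expect_identical(
    pc_index(genotype_counts(c(10, 20, 30), c(10, 20, 30)))$value, 0)

  gc <- genotype_counts(c(10, 20, 30), c(30, 20, 10))
  chi <- suppressWarnings(
    stats::chisq.test(rbind(gc$r, gc$s), correct = FALSE))$statistic
  expect_equal(pc_index(gc)$value, unname(chi) / gc$n, tolerance = 1e-12)

  # an empty genotype column reduces to the 2x2 table
  gc <- genotype_counts(c(10, 0, 30), c(25, 0, 15))
  chi22 <- suppressWarnings(stats::chisq.test(
    rbind(gc$r[c(1, 3)], gc$s[c(1, 3)]), correct = FALSE))$statistic
  expect_equal(pc_index(gc)$value, unname(chi22) / gc$n, tolerance = 1e-12)

  # nonnegative on random tables, zero iff identical proportions
  set.seed(43)
  for (i in 1:100) {
    gc <- rand_table()
    expect_gte(pc_index(gc)$value, 0)
  }
})

test_that("allele-flip symmetry holds", {
  set.seed(44)
  for (i in 1:200) {
    gc <- rand_table()
    fl <- flip_table(gc)
    rec <- adjusted_catt(gc, "recessive"); dom <- adjusted_catt(gc, "dominant")
    add <- adjusted_catt(gc, "additive")
    # rec <-> -dom, add -> -add; hence nu is flip-invariant
    frec <- adjusted_catt(fl, "recessive"); fdom <- adjusted_catt(fl, "dominant")
    fadd <- adjusted_catt(fl, "additive")
    if (rec$defined || fdom$defined)
      expect_equal(frec$value, -dom$value, tolerance = 1e-10)
    if (add$defined || fadd$defined)
      expect_equal(fadd$value, -add$value, tolerance = 1e-10)
    if (dom$defined || frec$defined)
      expect_equal(fdom$value, -rec$value, tolerance = 1e-10)
    expect_equal(amax(fl)$value, amax(gc)$value, tolerance = 1e-10)
  }
})

test_that("counts_from_genotypes tabulates with per-SNP complete cases", {
  gc <- counts_from_genotypes(c(0, 1, 2, 2), c(1, 1, 0, 0))
  expect_identical(gc$r, c(1, 1, 0))
  expect_identical(gc$s, c(0, 0, 2))

  gc <- counts_from_genotypes(c(0, NA, 2), c(1, 0, 0))
  expect_identical(gc$r, c(1, 0, 0))
  expect_identical(gc$s, c(0, 0, 1))
  expect_identical(gc$n, 2)

  set.seed(45)
  g <- sample(c(0:2, NA), 120, replace = TRUE)
  y <- rbinom(120, 1, 0.5)
  expect_equal(counts_from_genotypes(g, y)$n, sum(!is.na(g)))

  expect_error(counts_from_genotypes(c(0, 1), c(1)), "lengths differ")
  expect_error(counts_from_genotypes(c(0, 1), c(1, 2)), "0/1")
})
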