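# Independent brute-force oracles used across the suite.  These deliberately
# transcribe the defining formulas with plain scalar loops (or defer to
# stats::cor / stats::chisq.test) and stay independent of the package's
# vectorised kernels.

# Trend statistic, direct scalar transcription of the defining ratio.
oracle_catt_z <- function(r, s, x) {
  rt <- sum(r); st <- sum(s); n <- rt + st; ni <- r + s
  num <- 0; sx2n <- 0; sxn <- 0
  for (i in 1:3) {
    num <- num + x[i] * (st * r[i] - rt * s[i])
    sx2n <- sx2n + x[i]^2 * ni[i]
    sxn <- sxn + x[i] * ni[i]
  }
  bracket <- n * sx2n - sxn^2
  if (rt * st * bracket <= 0) return(NA_real_)
  sqrt(n) * num / sqrt(rt * st * bracket)
}

# Per-sample Pearson correlation between the score-coded genotype and the
# phenotype, on the expanded vectors.
oracle_corr <- function(r, s, x) {
  xv <- c(rep(x, times = r), rep(x, times = s))
  yv <- c(rep(1, sum(r)), rep(0, sum(s)))
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NA_real_)
  stats::cor(xv, yv)
}

# Population trend measure from joint probabilities, scalar transcription.
oracle_population_omega <- function(p_joint, q_joint, x) {
  p <- sum(p_joint); q <- sum(q_joint); f <- p_joint + q_joint
  num <- sum(x * (q * p_joint - p * q_joint))
  bracket <- sum(x^2 * f) - sum(x * f)^2
  if (p * q * bracket <= 0) return(NA_real_)
  num / sqrt(p * q * bracket)
}

# Joint case probabilities by direct transcription of the printed model
# fractions (control joints q_i = q * HWE_i).
oracle_model_case_joint <- function(model, lambda, alpha, p) {
  q <- 1 - p
  qj <- q * c((1 - alpha)^2, 2 * alpha * (1 - alpha), alpha^2)
  den <- switch(model,
                I   = qj[1] + qj[2] + lambda * qj[3],
                II  = qj[1] + lambda * qj[2] + (2 * lambda - 1) * qj[3],
                III = qj[1] + lambda * qj[2] + lambda * qj[3])
  wt <- switch(model,
               I   = c(1, 1, lambda),
               II  = c(1, lambda, 2 * lambda - 1),
               III = c(1, lambda, lambda))
  p * wt * qj / den
}

# Random valid count table: both groups nonempty, but structural degeneracy
# (zero genotype columns) is allowed and does occur.
rand_table <- function(n_max = 200) {
  rt <- sample(1:(n_max / 2), 1)
  st <- sample(1:(n_max / 2), 1)
  genotype_counts(as.numeric(stats::rmultinom(1, rt, runif(3) + 0.05)),
                  as.numeric(stats::rmultinom(1, st, runif(3) + 0.05)))
}

# Allele-label flip: reverse the genotype coding i -> 2 - i.
flip_table <- function(counts) {
  genotype_counts(rev(counts$r), rev(counts$s))
}

the_scores <- c("recessive", "additive", "dominant")
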