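#' Population joint genotype/phenotype distribution for one SNP
#'
#' Holds the joint probabilities of (genotype, case status) in the population:
#' `p_i = P(G = i, Y = 1)` and `q_i = P(G = i, Y = 0)`, with case prevalence
#' `p = sum(p_i)` and `q = 1 - p`.  The genotype margin is `f_i = p_i + q_i`.
#' This is the population analogue of a [genotype_counts()] table and the
#' generative law used by the simulator.
#'
#' @param p_joint numeric length 3: joint case probabilities (p0, p1, p2).
#' @param q_joint numeric length 3: joint control probabilities (q0, q1, q2).
#' @return Object of class `population_snp_model` with fields `p_joint`,
#'   `q_joint`, `p`, `q`, `f` (genotype margin).
#' @examples
#' m <- snp_population_model("I", lambda = 1.8, alpha = 0.45, p = 0.5)
#' population_nu(m)
#' @export
population_snp_model <- function(p_joint, q_joint) {
  p_joint <- as.numeric(p_joint)
  q_joint <- as.numeric(q_joint)
  if (length(p_joint) != 3L || length(q_joint) != 3L)
    stop("population_snp_model: joint probability vectors must have length 3",
         call. = FALSE)
  if (any(p_joint < 0) || any(q_joint < 0) ||
      any(p_joint > 1) || any(q_joint > 1))
    stop("population_snp_model: probabilities must lie in [0, 1]",
         call. = FALSE)
  p <- sum(p_joint); q <- sum(q_joint)
  if (abs(p + q - 1) > 1e-8)
    stop("population_snp_model: joint probabilities must sum to 1 (got ",
         format(p + q), ")", call. = FALSE)
  if (p <= 0 || q <= 0)
    stop("population_snp_model: both case and control mass must be positive",
         call. = FALSE)
  structure(list(p_joint = p_joint, q_joint = q_joint,
                 p = p, q = q, f = p_joint + q_joint),
            class = "population_snp_model")
}

#' @export
print.population_snp_model <- function(x, ...) {
  m <- rbind(`Y=1` = x$p_joint, `Y=0` = x$q_joint, total = x$f)
  colnames(m) <- paste0("G=", 0:2)
  cat("Population SNP model (p =", format(x$p), ")\n")
  print(m)
  invisible(x)
}

#' Population adjusted trend measure
#'
#' The population counterpart of [adjusted_catt()]:
#' \deqn{\omega = \frac{\sum_i X_i (q p_i - p q_i)}
#'   {\sqrt{p q [\, \sum_i X_i^2 f_i - (\sum_i X_i f_i)^2 ]}},}
#' the correlation between the score-coded genotype and the phenotype in the
#' population.  Zero for every score exactly when genotype and phenotype are
#' independent (`p_i / p = q_i / q`).
#'
#' @param model a [population_snp_model()].
#' @param score a [score_vector()] or model label.
#' @return A [stat_value()] in \[-1, 1\]; undefined when the score is constant
#'   over the support of the genotype margin.
#' @export
population_omega <- function(model, score) {
  x <- as_score_vector(score)$x
  num <- sum(x * (model$q * model$p_joint - model$p * model$q_joint))
  bracket <- sum(x^2 * model$f) - sum(x * model$f)^2
  den2 <- model$p * model$q * bracket
  if (den2 <= .Machine$double.eps) return(stat_value(0, defined = FALSE))
  stat_value(num / sqrt(den2))
}

#' Population MAX measure
#'
#' \eqn{\nu = \max(|\omega_{rec}|, |\omega_{add}|, |\omega_{dom}|)} over the
#' defined components; the population target of [amax()].
#'
#' @inheritParams population_omega
#' @return A [stat_value()] in \[0, 1\].
#' @export
population_nu <- function(model) {
  comps <- lapply(canonical_scores(), function(s) population_omega(model, s))
  def <- vapply(comps, `[[`, logical(1), "defined")
  if (!any(def)) return(stat_value(0, defined = FALSE))
  stat_value(max(abs(vapply(comps[def], `[[`, numeric(1), "value"))))
}

#' Hardy-Weinberg genotype distribution of the control population
#'
#' Controls are assumed to be in Hardy-Weinberg equilibrium at minor allele
#' frequency `alpha`, giving conditional genotype probabilities
#' \eqn{((1-\alpha)^2,\; 2\alpha(1-\alpha),\; \alpha^2)}.
#'
#' @param alpha minor allele frequency in (0, 0.5].
#' @return Numeric length-3 probability vector over genotypes 0, 1, 2.
#' @examples
#' control_genotype_probs(0.2)  # 0.64 0.32 0.04
#' @export
control_genotype_probs <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 0.5)
    stop("control_genotype_probs: alpha must lie in (0, 0.5]", call. = FALSE)
  c((1 - alpha)^2, 2 * alpha * (1 - alpha), alpha^2)
}

# Penetrance-style genotype weights for the case population under each model:
# the case joint probabilities are proportional to weight_i * q_i.  lambda is
# the genotype relative risk of the model.
model_weights <- function(model, lambda) {
  switch(model,
         I   = c(1, 1, lambda),               # recessive
         II  = c(1, lambda, 2 * lambda - 1),  # additive
         III = c(1, lambda, lambda),          # dominant
         stop("unknown genetic model '", model, "' (use I, II or III)",
              call. = FALSE))
}

#' Case genotype distribution under a penetrance model
#'
#' Re-weights the control genotype distribution by the model's genotype
#' relative risks and renormalises: with weights `(w0, w1, w2)` equal to
#' `(1, 1, lambda)` for the recessive model I, `(1, lambda, 2*lambda - 1)` for
#' the additive model II and `(1, lambda, lambda)` for the dominant model III,
#' the case conditional probabilities are
#' \eqn{p_i / p = w_i q_i' / \sum_j w_j q_j'} where `q_i'` is the control
#' conditional distribution.  `lambda = 1` gives the null (case = control).
#'
#' @param model `"I"`, `"II"` or `"III"`.
#' @param lambda genotype relative risk, `>= 1`.
#' @param control_probs conditional control genotype distribution, e.g.
#'   [control_genotype_probs()].
#' @return Numeric length-3 conditional case genotype distribution.
#' @export
case_genotype_probs <- function(model, lambda, control_probs) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 1)
    stop("case_genotype_probs: lambda must be a single number >= 1",
         call. = FALSE)
  if (length(control_probs) != 3L || any(control_probs < 0) ||
      abs(sum(control_probs) - 1) > 1e-8)
    stop("case_genotype_probs: control_probs must be a genotype distribution",
         call. = FALSE)
  w <- model_weights(model, lambda)
  wq <- w * control_probs
  wq / sum(wq)
}

#' Build the population model of an active SNP under models I-III
#'
#' Convenience constructor combining Hardy-Weinberg controls at MAF `alpha`
#' with the model-`lambda` case re-weighting and case prevalence `p`.
#'
#' @inheritParams case_genotype_probs
#' @param alpha minor allele frequency in (0, 0.5].
#' @param p case sampling proportion in (0, 1); `p = w/(1+w)` for a
#'   case:control ratio `w`.
#' @return A [population_snp_model()].
#' @export
snp_population_model <- function(model, lambda, alpha, p = 0.5) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("snp_population_model: p must lie in (0, 1)", call. = FALSE)
  ctrl <- control_genotype_probs(alpha)
  cas <- case_genotype_probs(model, lambda, ctrl)
  population_snp_model(p_joint = p * cas, q_joint = (1 - p) * ctrl)
}

#' Null population model (genotype independent of phenotype)
#'
#' @inheritParams snp_population_model
#' @return A [population_snp_model()] with identical case and control
#'   conditional genotype distributions.
#' @export
null_population_model <- function(alpha, p = 0.5) {
  ctrl <- control_genotype_probs(alpha)
  population_snp_model(p_joint = p * ctrl, q_joint = (1 - p) * ctrl)
}
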