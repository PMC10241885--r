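---
title: "Trend-test-based screening of case-control SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend-test-based screening of case-control SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendscreen)
```

## The problem

A genome-wide case-control study records, for each of $m$ SNPs, a genotype
$G_k \in \{0,1,2\}$ (copies of a candidate risk allele) and a binary phenotype
$Y$ (1 = case).  When $m$ is in the hundreds of thousands, multiple-testing
corrections that treat SNPs as independent are both conservative and fragile
under linkage disequilibrium.  *Feature screening* takes a different route:
rank all SNPs by a cheap marginal association statistic and keep only the top
$d$, so that downstream modelling works on a panel of manageable size.  The
property one wants is *sure screening*: with probability tending to one, no
truly associated SNP is discarded.

## Statistics

For one SNP, write the 2x3 table of genotype counts as $r_0,r_1,r_2$ (cases)
and $s_0,s_1,s_2$ (controls), with margins $r$, $s$, $n_i = r_i + s_i$ and
$n = r + s$.  Given a genotype score vector $(X_0,X_1,X_2)$ the
Cochran-Armitage trend statistic is

$$Z \;=\; \frac{\sqrt{n}\,\sum_i X_i\,(s\,r_i - r\,s_i)}
  {\sqrt{r\,s\,\bigl[\,n\sum_i X_i^2 n_i - (\sum_i X_i n_i)^2\bigr]}},$$

asymptotically $N(0,1)$ under independence.  The optimal scores under the
classical penetrance models are fixed: recessive $(0,0,1)$, additive
$(0,\tfrac12,1)$, dominant $(0,1,1)$.  Since the true genetic model is
unknown in practice, the MAX statistic
$Z_{\max} = \max(|Z_0|, |Z_{1/2}|, |Z_1|)$ is the standard robust choice.

$Z$ grows like $\sqrt{n}$, which makes it unsuitable as a ranking measure
whose population target should not depend on the design size.  The *adjusted*
statistics drop that factor:
$\hat\omega = Z/\sqrt{n}$ (aCATT) and
$\hat\nu = \max(|\hat\omega_0|,|\hat\omega_{1/2}|,|\hat\omega_1|)$ (aMAX).
A useful identity, asserted by the test suite to $10^{-10}$ relative
tolerance on fuzzed tables, is that $\hat\omega$ equals the plain Pearson
correlation between the score-coded genotype and the phenotype on the
expanded per-sample vectors; hence $|\hat\omega| \le 1$ and
$\hat\nu \in [0,1]$.  The population counterparts $\omega$ and $\nu$ replace
counts by the joint probabilities $p_i = P(G=i, Y=1)$, $q_i = P(G=i, Y=0)$;
both vanish exactly under independence.

Ranking by $|\hat\omega_j|$ gives REC-SIS, ADD-SIS and DOM-SIS; ranking by
$\hat\nu$ gives MAX-SIS.  `pc_index()` supplies a model-free comparator,
$\phi^2 = \chi^2/n$ of the 2x3 table with empty genotype columns dropped.  It
is a documented stand-in for published categorical Pearson-correlation
screeners, not a replication of any one of them: for fixed table shape any
monotone normalisation of $\chi^2$ produces the same ranking, which is all a
screener uses.

```{r}
gc <- genotype_counts(r = c(10, 20, 30), s = c(30, 20, 10))
c(rec = adjusted_catt(gc, "recessive")$value,
  add = adjusted_catt(gc, "additive")$value,
  dom = adjusted_catt(gc, "dominant")$value,
  max = amax(gc)$value)
```

## Selection rules and their parameters

Two rules turn ranked statistics into an estimated active set:

* **top-d** (`screening_config(method, d = ...)`): keep the $d$ largest
  statistics.  The conventional model-free default is
  $d = \lfloor n/\log n\rfloor$ (`default_d()`; natural logarithm — the
  base-10 reading fails to reproduce the worked value
  $\lfloor 4901/\log 4901\rfloor = 576$, giving 1328 instead).
* **threshold** (`rule = "threshold"`, `c0`, `tau`): keep statistics at least
  $c_0 n^{-\tau}$, $c_0 > 0$, $\tau \in [0, \tfrac12)$.  This is the form
  for which sure-screening guarantees are proved, but choosing $(c_0,\tau)$
  is hard in practice; since the statistics are ranked consistently, a top-d
  set with $d$ at least the threshold-set size contains it, which is why the
  top-d rule is the operational default.  Choosing an optimal $d$ is out of
  scope here, as it is in the screening literature generally.

## Numerical choices

* **Zero-variance scores.**  A score that is constant over the observed
  genotype margin (e.g. recessive when no AA is observed) has an undefined
  statistic.  We return `defined = FALSE` with conventional value 0 rather
  than raising: a score with no variation carries no trend information, and
  a screener over $10^5$ SNPs must not abort on a monomorphic site.  aMAX
  maximises over defined components only; an all-undefined SNP has
  $\hat\nu = 0$ and is effectively never selected.
* **Ties and undefined ranks.**  Ties at the top-d boundary are broken by
  smaller SNP index, and undefined statistics rank after all defined ones in
  index order.  Neither convention is forced by the method; both are chosen
  to make output deterministic across runs and platforms.
* **Exact arithmetic where possible.**  Counts are integers held in doubles,
  so the variance bracket is computed exactly and the `> 0` definedness test
  needs no tolerance.  Equality assertions in the tests use relative
  tolerance $10^{-10}$.
* **Heterogeneous sample sizes.**  With per-SNP missingness the effective
  $n$ varies across SNPs (complete-case tabulation per SNP).  The threshold
  rule then uses the study-level $n$, taken as the maximum effective sample
  size over SNPs.

## What the simulator states, and what a green test establishes

`simulate_counts()` draws, for each SNP, case counts from a trinomial
$\mathrm{Mul}(r,\, p_0/p, p_1/p, p_2/p)$ and control counts from
$\mathrm{Mul}(s,\, q_0/q, q_1/q, q_2/q)$.  Controls are Hardy-Weinberg at
minor allele frequency $\alpha$:
$(q_0,q_1,q_2)/q = ((1-\alpha)^2,\, 2\alpha(1-\alpha),\, \alpha^2)$.  Active
SNPs reweight the control distribution by genotype relative risks and
renormalise:

| model | weights $(w_0,w_1,w_2)$ | default $\lambda$ |
|---|---|---|
| I (recessive) | $(1, 1, \lambda)$ | 1.8 |
| II (additive) | $(1, \lambda, 2\lambda - 1)$ | 1.4 |
| III (dominant) | $(1, \lambda, \lambda)$ | 1.6 |

Model IV mixes the three: the default six active SNPs are assigned in pairs
to models I, II and III with their default effects (a general active set is
split into three contiguous, as-even-as-possible blocks in the same order).
Null SNPs use the control law for both groups, so their population measures
are exactly zero.  Case/control sizes come from the total $n$ and the
case:control ratio $w$ as $r = \mathrm{round}(n w/(1+w))$, $s = n - r$;
every conventional grid combination ($n \in \{1500,3000,4500\}$,
$w \in \{1, 1/3, 1/5\}$) is an exact integer split.

The stated experimental world is: $m = 10^5$ SNPs, the first six active,
$\alpha \in \{0.15,\dots,0.45\}$, 500 replications, $d = \lfloor n/\log
n\rfloor$.  Desk-scale defaults in this package reduce replications to 100
and (where a test says so explicitly) $m$ to $10^4$.  One scaling fact is
worth stating because it is easy to get wrong: reducing $m$ at fixed $d$
multiplies the retained fraction $d/m$ and makes every cell easier, so
orderings between methods can compress toward the ceiling.  The acceptance
test for the mixed-model cell therefore keeps the full $m = 10^5$ (at 100
replications it still runs in well under a minute); the single-model
"best cell" check uses $m = 10^4$ as specified and passes with a wide margin.

What the simulator does **not** emulate: linkage disequilibrium between SNPs
(all SNPs are drawn independently; LD is motivation for screening, not part
of the generative law), covariates, genotyping error, departures from
Hardy-Weinberg in controls, and case-control sampling of a finite population.
A green evaluation therefore establishes that the statistics, the ranking
machinery and the selection rules behave as the theory predicts under the
stated law — not that any particular real panel will be screened correctly.

## Replicated evaluation

`evaluate_method()` and `run_grid()` report the two standard criteria over
replications: $\mathcal P_s^k$, the fraction of replications in which active
SNP $k$ is selected, and $\mathcal P_a$, the fraction in which *all* active
SNPs are selected simultaneously ($\mathcal P_a = 1$ vacuously for an empty
active set).  Within a grid cell all methods are screened against the same
replication draws, so method comparisons are paired.  Monte-Carlo standard
errors are the binomial $\sqrt{P(1-P)/\mathrm{reps}}$, and statistical
assertions in the tests use a 3-SE slack.

Reproducibility: every randomised entry point takes an explicit seed; a
master seed spawns per-replication seeds, and `run_grid()` derives each
cell's seed from the master seed and the cell's parameters, so results are
independent of the order in which cells are evaluated.  Within one dataset
the draw order is fixed (active cases, then null cases, then controls).  The
original experiments did not state their RNG, so reproduction of their
figures is statistical, not bitwise.

```{r}
cfg <- simulation_config(model = "I", m = 1000, n = 3000, w = 1,
                         alpha = 0.45, seed = 42)
evaluate_method(cfg, screening_config("max", d = default_d(3000)), reps = 20)
```

## Real-data pathway

`read_genotypes()` accepts a genotype TSV (samples x SNPs, cells 0/1/2/NA)
or a VCF (GT field; genotype = ALT-allele count; multi-allelic records are
skipped and half-calls treated as missing, both logged), joined to a
two-column phenotype file by sample id.  The case-study preprocessing is:

1. `filter_snps()`: drop SNPs with missing fraction strictly above 1%
   (exactly 1% is retained), then SNPs with fewer than three observed
   genotype classes.  The surviving set is order-independent; the report
   attributes removals to the first rule applied.  The missing-fraction
   denominator is the total sample count (the alternative — phenotyped
   samples only — is not distinguished by our sources; totals are the
   conservative reading).
2. `orient_minor_allele()`: per SNP, if the coded allele's pooled frequency
   exceeds 1/2, recode $g \to 2 - g$ so genotype 2 is homozygous minor.
   A frequency of exactly 1/2 leaves the coding unchanged (the tie gives no
   basis to prefer either orientation, and aMAX is invariant either way).
   Under this flip $\hat\omega_{rec} \leftrightarrow -\hat\omega_{dom}$ and
   $\hat\omega_{add} \to -\hat\omega_{add}$, so $\hat\nu$ is unchanged —
   orientation standardises interpretation, not ranking by MAX-SIS.

The `cli_main()` subcommands `simulate`, `screen` and `evaluate` wrap these
pathways for shell use; all randomised commands require `--seed`.

## Known limitations

* No p-values for the MAX statistic (its trivariate-normal asymptotics are
  not implemented); screening uses ranks only.
* No covariate adjustment; the statistics are marginal.
* No LD-aware simulation and no data-driven choice of $d$, $c_0$ or $\tau$.
* PLINK binary formats are not read; use VCF or the TSV dialect.
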