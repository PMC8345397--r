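---
title: "Methods: control-anchored wPRS analysis for familial colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-anchored wPRS analysis for familial colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcprs)
```

## The problem

A substantial fraction of familial and/or early-onset colorectal cancer
(fCRC) patients carry no pathogenic variant in a known high-penetrance gene.
One candidate explanation is polygenic: the accumulation of many common,
individually low-risk alleles. `crcprs` implements the analysis used to test
that hypothesis in a case-control design with four groups — fCRC cases,
serrated polyposis (SP) patients, sporadic CRC cases and CRC-free controls —
built around a weighted polygenic risk score (wPRS) over ~92 validated
common risk variants.

## The score

For individual $j$ with effect-allele dosages $g_{ij} \in [0,2]$ and
per-allele log-odds weights $w_i$, the raw scores over the non-missing,
quality-filtered variants are

$$S_j^{w} = \sum_{i \in \mathrm{obs}(j)} w_i\, g_{ij}, \qquad
  S_j^{u} = \sum_{i \in \mathrm{obs}(j)} g_{ij}.$$

Two rescalings produce the final wPRS:

1. **Control anchoring.** Every weighted score is multiplied by
   $r = \bar S^{u}_{\mathrm{ctrl}} / \bar S^{w}_{\mathrm{ctrl}}$, the ratio
   of the control means of the unweighted and weighted scores. The control
   mean wPRS then sits on the risk-allele-count scale (about 88 for a
   92-variant panel with typical frequencies), and one wPRS unit is a
   *risk-allele equivalent*: the per-unit OR from a logistic model is
   interpretable as a per-risk-allele OR. This is the only reading of
   "rescaled using the control mean (unweighted/weighted)" consistent with
   scores in the high-80s/low-90s alongside per-unit ORs near 1.1.
2. **Missingness correction.** Scores of individuals with missing genotypes
   are inflated by
   $\sum_{i} c_i \big/ \sum_{i \in \mathrm{obs}(j)} c_i$, where
   $c_i = w_i \bar g_{i,\mathrm{ctrl}}$ is variant $i$'s mean weighted
   contribution in controls. We use per-variant control-mean contributions
   rather than the bare count ratio $M/m$ because weights and allele
   frequencies vary across variants; the per-variant form is mean-preserving
   under missingness that is independent of genotype (checked by simulation
   in the test suite). Individuals with no missing variants satisfy
   $\mathrm{wPRS}_j = r\,S^w_j$ exactly.

Missing dosages are an explicit `NA`, never 0: the correction requires
knowing *which* variants were observed.

### Variant filtering and harmonization

Imputed variants with imputation $R^2 < 0.3$ (strictly less than) are
excluded; directly genotyped variants are always retained. The filter only
ever clears the inclusion flag, so it is idempotent and monotone in the
threshold. Genotype records are matched to panel variants by chromosome,
position and unordered allele pair — rsIDs are reporting metadata only,
which is robust to identifier drift. A record whose alleles match only
after strand complementation is accepted on the complemented strand;
strand-ambiguous pairs (A/T, C/G) are dropped by default (`ambiguity_policy
= "keep"` scores them assuming same-strand reporting). The source study does
not document its harmonization policy; dropping ambiguous pairs is the
conservative PRS convention. Anything irreconcilable degrades to missing
with a logged reason rather than an error.

### Winner's-curse correction

Discovery effect sizes selected at genome-wide significance
($\alpha = 5\times10^{-8}$) are biased away from zero. When enabled
(`winners_curse = TRUE`; off by default, since the upstream weights may
already be corrected), weights are replaced by the conditional
maximum-likelihood estimate: with $c = \Phi^{-1}(1-\alpha/2)$, the corrected
$\beta$ maximizes

$$\ell(\beta) = \log\phi\!\left(\frac{\hat\beta-\beta}{se}\right)
 - \log\!\left[\Phi\!\left(\frac{\beta}{se}-c\right)
 + \Phi\!\left(-\frac{\beta}{se}-c\right)\right].$$

The maximizer is found by golden-section search on
$[\min(0,\hat\beta)-se,\ \max(0,\hat\beta)+se]$, which brackets the optimum
because the conditional MLE shrinks toward zero; numerical overshoot past
$\hat\beta$ or past zero is clipped. The estimate is validated in tests
against a brute-force grid maximizer (step $se/1000$) and against simulated
discovery replicates, where it reduces the mean selected bias.

## The statistical battery

* **Group means** are compared with Welch's two-sided $t$-test (means, not
  medians: the source tables report means and SDs, and the unequal-variance
  form needs no homoscedasticity assumption).
* **Contingency tables** use Pearson's $\chi^2$ with 1 df and *no*
  continuity correction — the form that reproduces all seven published
  clinical p-values from their printed counts at four decimals; with the
  Yates correction they do not reproduce. The asymptotic test is used even
  at small expected counts, matching the published analysis, so the usual
  approximation warning is deliberately not surfaced.
* **Odds ratios** come from logistic regression (IRLS via `glm`) with age
  and sex as covariates, Wald 95% CIs with $z = 1.96$. Crude cross-product
  ORs with Woolf CIs are reported alongside adjusted ones in the clinical
  comparison, because published adjusted ORs cannot be reproduced without
  knowing the exact covariate set per row. Rank-deficient designs and
  (quasi-)separation raise explicit errors rather than returning degenerate
  estimates.
* **Quantile profile**: individuals in the pooled fCRC + control population
  are ranked into 20 equal bins (sizes differ by at most one; ties broken by
  stable input order). Each quantile's OR versus the median (10th) quantile
  is estimated by logistic regression on the two quantiles' members with the
  same covariates; the reference OR is fixed at 1. Quantiles with an empty
  case or control arm are marked `NA` — the Wald OR diverges there.
  Sporadic and SP individuals are scored but never enter the ranking.
* **High/low comparison**: fCRC cases in quantiles 17–20 versus 1–10; the
  intermediate band is reported but not compared.
* **Interactions** of the score with a binary modifier are Wald tests of
  the product term with main effects and covariates included.

## Discrimination and heritability

AUC is computed by the rank (Mann–Whitney) formulation with ties counting
one half, so it is invariant under strictly monotone transforms of the
score. Model AUC is the AUC of fitted probabilities from the logistic fit.

Observed-scale variance explained is linear-model $R^2$ of the 0/1 outcome
on the design — the convention the liability transformation expects (for a
single predictor it is the squared Pearson correlation). The liability-scale
transform uses the ascertainment-corrected form for case-control samples:
with prevalence $K$, sample case fraction $P$, threshold
$t = \Phi^{-1}(1-K)$, $z = \phi(t)$, $i = z/K$,

$$C = \frac{[K(1-K)]^2}{z^2 P(1-P)}, \quad
  u = i\,\frac{P-K}{1-K}, \quad \theta = u(u-t), \quad
  R^2_l = \frac{C R^2_o}{1 + C\theta R^2_o}.$$

At $K=P=0.5$ this collapses to $R^2_l = (\pi/2) R^2_o$ (a closed-form test
case). Ascertainment correction matters here because familial case
fractions in such studies (hundreds of cases against ~1.6k controls) far
exceed any plausible CRC prevalence. The prevalence is a configuration
parameter, default $K = 0.04$ (lifetime CRC risk of roughly 4%; the source
analysis does not state the value it assumed, which is one reason its
printed AUC/R² values are context, not reproducible targets).

Contribution decomposition is leave-one-covariate-out: for each variable in
the full model, the metric (AUC or liability $R^2$) is recomputed without
it; the contribution is the difference, reported in percentage points. A
duplicated or aliased column must contribute ~0, so metric evaluation
inside the decomposition tolerates aliased designs (predictions live on the
column span), while direct model fitting still errors on rank deficiency.

## The synthetic cohort generator

The generator exists so every pipeline stage is exercisable and testable
without the study's (undeposited) genotypes. Its defaults are the study's
conditions:

* 92 variants, effect-allele frequencies uniform on (0.05, 0.5), positive
  per-allele log-ORs of 0.02–0.18 (log-normal magnitudes, the range of
  common CRC GWAS effects); ~13/95 of variants flagged directly genotyped,
  the rest given Beta-shaped imputation $R^2$ on (0.3, 1) except for 3
  variants forced below the 0.3 cutoff, so the quality filter excludes
  3 of 95 as in the study;
* genotypes $\sim$ Binomial(2, EAF) per variant (Hardy–Weinberg, linkage
  equilibrium — the panel variants are independent association signals by
  construction, so no LD machinery is modelled);
* disease by a liability-threshold model, prevalence $K = 0.04$, with the
  score's liability variance share defaulting to $h^2 = 0.10$ (the scale of
  liability-scale variance such scores explain); a logistic alternative
  solves its intercept by bisection to hit the target prevalence within
  $10^{-4}$;
* familial cases ascertained by affected sibling: each case proband gets
  one sibling by Mendelian transmission (each transmitted allele shared
  with probability 1/2, otherwise a fresh population allele), the sibling's
  status drawn from the same disease model with the *population* intercept
  or threshold (re-solving on the enriched sibling set would erase the
  enrichment), and probands with an affected sibling retained;
* group sizes 417 fCRC / 80 SP / 1077 sporadic / 1642 controls by default,
  with group-specific age means/SDs, male fractions and clinical-flag rates
  set to the study's cohort table (e.g. fCRC age 48.7 (12.4), controls 62.4
  (10.25), control male fraction 0.51, control CRC family-history rate
  5.12%); SP individuals are drawn from the non-case pool, matching the
  null association the study observed for that group;
* the default population size is 250,000 because affected-sibling
  ascertainment at $K = 0.04$ retains only ~5% of case probands, and the
  full familial group of 417 must be fillable;
* independent genotype missingness (default 2%) and a mandatory seed: the
  same configuration reproduces byte-identical cohorts and reports.

What the generator does **not** emulate: linkage disequilibrium, population
structure, genotyping error, shared sibling environment, age-dependent
incidence, or any correlation between clinical flags and the score beyond
what ascertainment induces. Passing recovery tests therefore show the
pipeline is correct *under its own model assumptions*; they do not certify
performance on real genotype data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as follows:
OR-coverage replicates use a population of 16,000 with 500 cases/1600
controls sampled (50 replicates); $h^2$ recovery uses populations of 20,000
sampled to equal cases and controls at $K=0.04$ (50 replicates per $h^2$
value in $\{0.05, 0.10, 0.20\}$); familial-enrichment replicates run at the
generator's full default population of 250,000, where each replicate yields
a familial group comparable to the study's (the test compares retained
familial probands against non-retained case probands with a one-sided
Welch test); missingness-bias checks use 1000 individuals at 10%
missingness. Unit tests use much smaller fixtures built in code.

Numerical details worth knowing: logistic convergence uses `glm` with
epsilon $10^{-10}$ and up to 100 iterations; quantile bin boundaries are
$\lfloor kn/Q \rfloor$, which distributes the remainder deterministically;
the dosage text format serialises doubles with 17 significant digits so
write/read round-trips are bit-exact; the liability transform clamps to
$[0,1]$ with a warning.

One published-arithmetic caveat surfaced by the fixtures: the study's
control-group male/female ratio is printed as 1.04, but its own counts
(835/807) give 1.03 at two decimals; the packaged fixture carries the
recomputed value. All other packaged ratios, percentages and the seven
clinical $\chi^2$ p-values reproduce exactly.

## Known limitations

* The wPRS rescaling interpretation (control anchoring to the allele-count
  scale) is a reconstruction from the published score magnitudes; other
  readings of the one-sentence description are conceivable but inconsistent
  with the printed group means.
* The adjusted ORs of the clinical high/low table depend on an undocumented
  covariate set; only the $\chi^2$ p-values are treated as exactly
  reproducible.
* $h^2$ recovery at the upper end (0.20) with ~800 cases is intrinsically
  noisy: the observed-scale $R^2$ estimator's sampling SD (~0.019) makes a
  ±0.03 band a ~1.6-SD criterion, so seed-to-seed recovery rates near 86–92%
  are expected even though the estimator is unbiased.
* No LD-aware scoring, no cross-validated AUC, no DeLong CIs, no Fisher
  exact tests, no multiple-testing correction (the source analysis applied
  none).
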