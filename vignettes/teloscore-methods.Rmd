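---
title: "Genetically determined telomere length in myeloma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically determined telomere length in myeloma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Measured leukocyte telomere length (LTL) is a fragile epidemiological
exposure: it drifts with age, responds to chemotherapy and smoking, and is
sensitive to DNA extraction and storage. A genetic proxy sidesteps all of
this. Eleven GWAS-identified SNPs (in or near *ZNF676*, *TERT*, *CTC1*,
*DHX35*, *PXK*, *NAF1*, *ZNF208*, *OBFC1*, *ACYP2*, *TERC* and *ZBTB46*)
jointly explain about 2.28% of LTL variability, and counting their
long-telomere alleles yields a "teloscore" — a genetically determined
telomere length (gdTL) that is fixed at conception. This package implements
the full analysis built on that instrument for a multiple myeloma (MM)
case-control and survival study: score construction, genotype QC,
covariate-adjusted logistic and Cox models, and summary-statistic Mendelian
randomization (MR).

## The teloscore

For subject $i$ with effect-allele dosages $c_{ij} \in \{0,1,2\}$ over
$L = 11$ SNPs:

* **unweighted**: $u_i = \sum_j c_{ij}$, an integer in $[0, 2L] = [0, 22]$;
* **weighted**: $w_i = \sum_j c_{ij} w_j$, where $w_j$ is the per-allele
  effect on LTL in base pairs, so $w_i$ is the estimated bp difference in
  telomere length attributable to the panel;
* **scaled ("average") variants**: $u_i / m_i$ and
  $\sum_{j \in \mathrm{obs}} c_{ij} w_j / m_i$ over the $m_i$ non-missing
  calls, so subjects with incomplete genotyping remain comparable.

Raw scores are defined only for subjects with a 100% call rate; scaled
scores cover everyone with at least one call. We interpreted "average
values for each score" as the per-non-missing-SNP mean: it is the simplest
reading, and for complete data the scaled score is an order-preserving
rescaling of the raw score (so quintile assignments agree — a property the
test suite checks). An alternative "$\times L$" rescaling to 11-SNP
units would be monotone in the same statistic and would change nothing
downstream.

**Weights are configuration, not constants.** The per-allele bp effects
come from external GWAS estimates that are not part of this package's
sources, so `builtin_panel()` ships with `weight_bp = NA` and weights must
be supplied (`set_panel_weights()`). A clearly labelled *synthetic* weight
set (48–120 bp, the range typical of telomere GWAS loci) is bundled for
simulation and examples only.

### Quintile convention

Quintile cutpoints are empirical: cutpoint $k$ is the smallest reference
value whose empirical CDF reaches $k/5$, and a score tied with a cutpoint
falls in the *lower* quintile. This matters because the unweighted score is
a heavily tied integer; the visibly unequal quintile sizes of the published
occupancy table (780/594/553/473/576 for the raw unweighted score) confirm
that ties were not split there either. The reference stratum is
analysis-specific: controls for risk (complete-call-rate controls for the
raw scores, all controls for the scaled scores) and, for survival, cases
with complete stage, therapy and follow-up data, recomputed separately
under the Durie-Salmon and ISS staging systems since their completeness
differs.

## Association models

* **Risk**: unconditional logistic regression adjusted for age, sex and
  country (reference-coded indicators, first level alphabetically;
  p-values are invariant to the reference choice). Each SNP is tested under
  an allelic (rare-allele dosage) and a codominant (heterozygote +
  rare-homozygote indicator) model; the printed per-SNP ratios in the
  reference tables are per copy of the minor allele, and the package
  reports the same orientation. The two-model scan over 11 SNPs uses the
  Bonferroni threshold $0.05/22 \approx 0.0023$. Scores enter either as
  quintile indicators (2–5 vs 1) or as the quintile index 1–5, whose
  coefficient is the risk increase per quintile step.
* **Survival**: Cox proportional hazards on overall survival (diagnosis to
  death, censored at last follow-up), adjusted for age, sex, country,
  stage (DS or ISS) and first-line therapy class. Ties are handled with
  Breslow's approximation by default — follow-up is recorded in months, so
  ties are common — with Efron available by option.

Inference is Wald throughout (CI $=\exp(\hat\beta \pm 1.96\,\mathrm{se})$),
matching the ratio/CI/p triads of standard reports. Convergence tolerance
is $10^{-10}$ on the IRLS deviance (logistic) and $10^{-9}$ (Cox) with 100
iterations; non-convergence, perfect separation and rank deficiency are
errors at the fitting level, and the scan functions degrade per-SNP with a
warning (e.g. a rare-homozygote cell with a handful of subjects) rather
than aborting the whole analysis.

## Mendelian randomization

Inputs are per-SNP pairs: $b_{X,j}$ (LTL per effect allele, with the unit —
bp or kb — declared by the caller, kb by default so slopes are $O(1)$) and
$b_{Y,j}$ (log-OR or log-HR oriented to the same allele). When built from
printed tables, $b_Y$ is the log of the per-minor-allele ratio, negated
where the long-telomere allele is the common one, and its standard error is
recovered from the CI width: $(\log \mathrm{hi} - \log \mathrm{lo})/3.92$.
Rounding of printed ratios limits downstream agreement to roughly two
significant figures.

* **IVW**: weighted regression of $b_Y$ on $b_X$ through the origin,
  weights $b_{Y,\mathrm{se}}^{-2}$. Both the fixed-effect standard error
  and the multiplicative random-effects inflation
  $\max(1, \sqrt{Q/(K-1)})$ are reported side by side, since published
  reports rarely state which convention their software used.
* **MR-Egger**: the same regression with an intercept, after orienting all
  $b_X \ge 0$ (the standard formulation; it fixes the sign convention of
  the intercept, which estimates directional pleiotropy). Standard errors
  are inflated by $\max(1, \sqrt{Q_E/(K-2)})$.
* **Cochran's Q** about either fit, with $K-1$ or $K-2$ df, tests
  instrument heterogeneity.
* **Bowden's $I^2_{GX}$** measures instrument strength for Egger:
  $\max(0, (Q_{GX}-(K-1))/Q_{GX})$ with $Q_{GX}$ the weighted dispersion of
  the $b_X$. Because different software weights this statistic differently,
  both the exposure-weighted and an outcome-weighted variant are computed
  and labelled; neither is asserted to be "the" published value.

Exposure-side error is ignored in Wald ratios and IVW point estimates (the
standard first-order practice); $I^2_{GX}$ is the provided diagnostic for
when that matters. Point estimates are invariant to jointly negating any
instrument's $(b_X, b_Y)$ and equivariant under rescaling $b_X$ — both are
property-tested against brute-force weighted-least-squares oracles.

## The synthetic cohort generator

No individual-level data were deposited by the reference study, so the
package ships a generator whose *defaults are the study conditions*:

* 2407 cases / 1741 controls with the printed per-country margins;
* 11 independent biallelic SNPs in HWE at the printed MAFs (the panel SNPs
  sit on distinct chromosomes, so no LD is simulated);
* telomere length linear in the weighted score, noise calibrated so the
  score explains 2.28% of variance (baseline 7000 bp, a typical adult
  LTL);
* case status from a logistic liability on TL in kb, intercept root-solved
  to hit the case fraction; the default $\theta = 0.3$ per kb (OR
  $\approx 1.35$/kb) matches the published effect scale, and covariate
  effects default to zero so confounding is opt-in;
* overall survival from a Weibull proportional-hazards model (shape 1.2,
  scale 80 months) with $\gamma = -0.2$ per kb (longer gdTL, better OS),
  stage log-HR 0.4 per step, new-therapy log-HR $-0.3$, exponential
  censoring (mean 90 months) capped at 120 months — at these defaults
  roughly half of followed cases die, giving the survival models realistic
  information;
* a latent severity class drives both staging systems (ISS is the DS class
  jittered one step with probability 0.3) and the hazard, and
  availability masks reproduce the printed completeness fractions
  (DS 1235/2407, ISS 1022/2407 with 984 jointly, OS 1273/2407);
* ages are drawn per arm around the printed medians when no age effect is
  configured (cases $\sim N(61.5, 9.6)$, controls $\sim N(52.6, 17)$);
* genotype calls are masked MCAR at 3.7%, reproducing the 96.3% mean call
  rate and a ~66% complete-call-rate stratum.

What the generator does *not* emulate: linkage disequilibrium, population
stratification, genotyping batch effects, informative missingness, and
myeloma-specific mortality. Passing recovery tests therefore demonstrate
the estimators are correct under the stated model, not that real-data
confounding is handled.

A known subtlety the test suite documents: with a binary outcome, per-SNP
marginal log-ORs are attenuated by a few percent relative to the
conditional liability coefficient (non-collapsibility of the odds ratio),
so the IVW slope from simulated case-control data is not exactly unbiased
for $\theta$ even though its 95% CI coverage stays nominal at the study's
effect sizes.

## Problem sizes used by the test suite

Calibration and recovery checks run at sizes chosen to make Monte Carlo
noise negligible relative to the tested tolerances: HWE uniformity on
2,000 simulated SNPs of 500 subjects; type-I error on 500 replicates at
n = 2,000; parameter recovery and CI coverage on 500 replicates of
n = 20,000 cohorts; the score-variance calibration at n = 50,000. Binomial
3-SD bands accompany every rejection-rate check.

## Limitations

* Weights (and their standard errors, needed only for $I^2_{GX}$) must be
  supplied by the user from the GWAS literature; results scale with them.
* The HWE test is the 1-df Pearson chi-square; an exact test is future
  work and would matter only for very rare alleles.
* No imputation: subjects missing a call contribute to scaled-score
  analyses only, exactly as in the reference design.
* Summary-statistic MR only; individual-level (two-stage) MR is out of
  scope, as are weighted-median/modal and MR-PRESSO estimators.
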