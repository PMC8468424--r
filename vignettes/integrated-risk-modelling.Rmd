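---
title: "Integrated risk modelling with a 15-SNP polygenic score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated risk modelling with a 15-SNP polygenic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

## The model

`polyrisk` implements the standard small-panel polygenic risk score (PRS)
for a binary disease outcome and its combination with classical
epidemiological risk factors in a retrospective case-control design.

The score for individual $i$ is

$$\mathrm{PRS}_i = \sum_{k=1}^{15} \beta_k x_{ik},$$

where $x_{ik} \in \{0,1,2\}$ counts copies of the *minor* allele of SNP $k$
and $\beta_k$ is the natural log of the published per-allele odds ratio for
that allele. The packaged panel holds 15 GWAS-identified breast-cancer
susceptibility SNPs with iCOGS consortium effect sizes; minor-allele
orientation is fixed once and for all by the *published* control frequency
(all panel frequencies lie in $(0, 0.5]$), never by the analysis cohort.
One panel SNP illustrates why this matters: its effect allele is the minor
allele in the source study but the *major* allele in some cohorts, and the
weight must stay attached to the published minor allele for scores to be
comparable across cohorts. Betas are computed as `log(or_published)` at use
time rather than stored, so they carry exactly the precision of the
published table.

Association is modelled throughout with logistic regression,

$$\operatorname{logit} P(Y_i = 1) = \alpha + \gamma\,\mathrm{PRS}_i +
  \boldsymbol{\delta}^\top \mathbf{z}_i,$$

with $\mathbf{z}$ the ten classical risk factors: menopausal status, age at
menarche (years), parity, age at first full-term pregnancy (FFTP, 5-year
bands entering as indicator contrasts, with nulliparous women folded into
the reference band), breastfeeding among parous women (a structural 0 for
nulliparous women), height (cm), BMI (kg/m²), hormone-replacement therapy,
smoking, and first-degree family history. Continuous factors enter
linearly; no transformations are applied.

## Estimation and numerical choices

`fit_logistic()` is a from-scratch iteratively reweighted least squares
(IRLS) maximiser with a fixed numerical contract:

* convergence when the relative log-likelihood change drops below `tol`
  (default `1e-10`), at most 100 iterations;
* rank-deficient designs are a hard error naming the collinear columns;
* complete or quasi-complete separation (any coefficient passing 15 in
  absolute value) returns a *flagged, non-converged* fit rather than silent
  numbers — at case-control scale, transparency beats penalised regression;
* standard errors come from the inverse observed information at the
  optimum, and Wald intervals are used throughout
  ($\exp(b \pm z_{0.975}\,\mathrm{se})$). Profile-likelihood intervals are
  deliberately out of scope; the per-bin odds-ratio point estimates, which
  are the reproducible surface, are identical either way.

Two-by-two tables have the closed form
$\widehat{OR} = n_{11} n_{00} / (n_{10} n_{01})$ with
$\mathrm{se} = \sqrt{\sum 1/n_{ij}}$; tests assert that the IRLS route and
the closed form agree to $10^{-8}$ on expanded tables, which is the
package's strongest internal cross-check. Zero cells are rejected rather
than continuity-corrected.

## Stratification

Two different quantile rules coexist, on purpose:

* **PRS quantiles are control-anchored.** Cut-points are the type-7
  (linearly interpolated) quantiles of the *control* score distribution —
  the most widespread quantile convention and deterministic. Every
  individual falls into the half-open interval $[\text{lower},
  \text{upper})$ containing its score; the last bin is closed above, so a
  case scoring beyond every control lands in the top bin. Default:
  quartiles with the second quartile (25–50%) as reference.
* **Predicted-risk deciles are pooled.** The integrated model's fitted
  probabilities are binned by deciles of the whole analysis sample (cases
  plus controls), with the fifth decile as reference. The asymmetry is
  intentional: the score stratification describes where cases sit relative
  to the *control* distribution, while the risk-model stratification
  divides the *dataset*.

Because the per-decile odds ratios depend only on the per-bin case/control
counts, the published decile table is exactly reproducible from its printed
counts alone; `make_fixture("published_deciles")` rebuilds that 1780-row
dataset (900 controls, 880 cases) and the acceptance suite reproduces all
nine non-reference odds ratios to printed precision.

## Evaluation surface

* **Calibration** uses the Hosmer–Lemeshow statistic on groups of sorted
  predicted probability. Groups are near-equal in size, but tied
  probabilities never straddle a boundary (the boundary extends to the next
  distinct value, so heavy ties can reduce the group count). Degrees of
  freedom are fixed at `groups − 2`, the convention consistent with the
  printed $\chi^2 = 11.77$, $p = 0.162$ pair at ten groups, which the
  package reproduces to three decimals by construction of `pchisq`.
* **Discrimination** is the Mann–Whitney AUC with ties counted one half,
  with the DeLong placement-value variance
  $\widehat{\mathrm{var}} = s^2_{10}/m + s^2_{01}/n$ and a Wald interval
  clipped to $[0,1]$. A property test equates the implementation with
  brute-force pair enumeration on every random instance up to $n = 200$,
  and a separate test matches `pROC`'s DeLong interval to $10^{-9}$.
* **Classification** reports sensitivity and specificity at a probability
  threshold, default 0.5 on the predicted probability (no threshold is
  prescribed by the design; 0.5 is the neutral choice and is configurable).
* **Interaction screening** between the PRS and the risk factors uses
  pairwise Spearman correlations in the control group (mid-rank ties,
  pairwise-complete observations, two-sided $p$ from the $t$
  approximation). No product-term interaction test is fitted in the core
  pipeline, matching the screening-only design; no multiplicity correction
  is applied anywhere, matching nominal $p < 0.05$ usage.

## The synthetic cohort generator

Real individual-level genotype/phenotype data for this design are not
distributable, so the generator is a first-class module. It emulates the
retrospective design by rejection sampling from a prospective population
model, which is exact and fast at desk scale for prevalence $\ge 0.05$:

1. genotypes are drawn per SNP as Binomial(2, MAF) — Hardy–Weinberg at the
   published panel frequencies, with no linkage disequilibrium (the panel
   SNPs sit on distinct loci);
2. covariates are drawn independently from configurable marginals;
3. disease is assigned with probability
   $\operatorname{logit}^{-1}(\alpha + \sum_k \beta_k x_k +
   \boldsymbol{\delta}^\top \mathbf{z})$, with $\alpha$ either fixed or
   calibrated by root-finding so the population prevalence hits a target
   (default 0.1, a configurable convention — screening-age breast-cancer
   risk is of this order);
4. individuals are retained until the case and control quotas (defaults
   1109 and 1177, the sampling frame the analysis pipeline assumes) are
   both met, and the generating truth (intercept, betas, seed) is returned
   for recovery tests.

Default covariate marginals and effects are a documented plausible set —
e.g. height 162 (6) cm, BMI 27 (4.5) kg/m², menarche 13 (1.5) years,
parity 85%, family history 12% with log-OR ln 1.6 — chosen once as
realistic for a Mediterranean screening population; no published covariate
effect sizes were available to copy. Continuous covariates are centred at
their generating means inside the linear predictor so the intercept keeps
its prevalence meaning. Because the generating SNP effects equal the PRS
weights, the integrated model's PRS coefficient has generating truth
exactly 1, a convenient recovery target.

What the generator does *not* emulate: linkage disequilibrium,
genotype-covariate dependence (an explicit design choice, matching the
absence of PRS-by-factor interactions in this setting), age structure,
genotyping error, and informative missingness (injected missingness is
MCAR, independent per field, never on status, and only among parous women
for breastfeeding). Passing recovery tests therefore demonstrate that the
*estimators* are correct under the stated model, not that the model
captures every feature of real cohort data.

## Missing data

The analysis is complete-case on the ten risk factors, with one structural
subtlety: breastfeeding is defined only among parous women, so a missing
breastfeeding value with `parous = 0` does not exclude the row (it enters
the design as 0). Missing *genotypes* are handled by policy in
`compute_prs()`: the default `expected_dosage` fills twice the control
minor-allele frequency (computed from the supplied cohort's controls, or
the published frequency as fallback), which is unbiased under
Hardy–Weinberg and keeps the sample; `zero` and `drop_individual` are
available for sensitivity analyses. The scale of the PRS association is
reported both per raw score unit and per control-group standard deviation,
since either convention appears in this literature.

## Problem sizes and test design

The test suite runs its statistical properties at sizes chosen to keep the
whole suite under a minute while leaving comfortable Monte Carlo margins:
Hardy–Weinberg moments at $n = 10^5$ draws, per-SNP effect recovery at a
population of 50{,}000, DeLong coverage and Hosmer–Lemeshow type-I error at
500 replicates each (bands 95% ± 3% and 5% ± 3%), and 20-seed sign
properties for the case/control score ordering. One property required care:
the *apparent* AUC of the 14-term integrated model is optimism-biased even
under an all-null generating model (≈ 0.525 at $n = 2000$), so the
null-discrimination property is evaluated out-of-sample — coefficients
fitted on one simulated cohort score an independent one — where the mean
AUC is 0.5 as it should be. Relatedly, the pipeline reports apparent
(in-sample) evaluation metrics, as is conventional for this design; a
cross-validated mode is a possible extension but has no anchor in the core
design.

## Known limitations

* Wald intervals only; the upper bounds of extreme-decile intervals can
  differ slightly from profile-likelihood ones.
* No LD, shrinkage, or multi-ancestry reweighting of the panel weights.
* No absolute-risk projection (age-conditional incidence); the outputs are
  odds ratios, calibration and discrimination of a case-control model.
* The generator's covariate effects are conventions, not estimates; any
  quantity that depends on them is a property of the synthetic model only.
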