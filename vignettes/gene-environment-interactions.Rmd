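---
title: "Additive and multiplicative PRS × ACE interaction analysis: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and multiplicative PRS x ACE interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psygxe)
```

## The problem

Genetic liability to psychiatric disorders (summarized by polygenic risk
scores, PRS) and adverse childhood experiences (ACEs) each raise the risk of
psychopathological symptoms. Whether they *interact* — and on which scale —
is a different question with a different answer per symptom: two exposures
whose odds ratios multiply exactly (no multiplicative interaction) still
combine super-additively on the risk-difference scale whenever both have
effects, and vice versa. `psygxe` estimates both quantities from one
logistic model per phenotype and runs the multi-phenotype screening cascade
around them.

Because participant-level cohort data of this kind are access-restricted,
the package pairs the analysis machinery with a synthetic cohort generator
whose planted parameters live on exactly the scales the analysis estimates.
Every statistical claim the package makes is therefore checkable against
ground truth; what that does and does not imply about real data is discussed
at the end.

## The model

For one binary phenotype, let $G$ indicate high polygenic risk and $E$ any
ACE. The interaction model is

$$\operatorname{logit} P(Y=1) = \beta_0 + \beta_1 G + \beta_2 E + \beta_3 GE
+ \boldsymbol\gamma^\top \mathbf{c},$$

with covariates $\mathbf{c}$ (sex, birth year, employment, income, smoking,
education, deprivation index, 10 genetic principal components by default).
Writing $OR_{10}=e^{\beta_1}$, $OR_{01}=e^{\beta_2}$,
$OR_{11}=e^{\beta_1+\beta_2+\beta_3}$:

* **Multiplicative interaction** is $\beta_3 = \log\frac{OR_{11}}{OR_{10}\,
  OR_{01}}$, read directly off the fit with its Wald SE and p-value.
  Positive = synergistic (ACE effects amplified at high genetic risk),
  negative = antagonistic (a ceiling/threshold pattern).
* **Additive interaction** is the relative excess risk due to interaction,
  $\mathrm{RERI} = OR_{11}-OR_{10}-OR_{01}+1$, with the identity
  $OR_{11}-1 = (OR_{10}-1)+(OR_{01}-1)+\mathrm{RERI}$ giving the
  excess-risk decomposition the package also emits. The variance comes from
  the delta method: $se^2 = h^\top\Sigma h$ with
  $h = (OR_{11}-OR_{10},\, OR_{11}-OR_{01},\, OR_{11})$ over
  $(\beta_1,\beta_2,\beta_3)$. Covariate coefficients have zero gradient
  here, so using the $3\times3$ block of the covariance matrix is exact,
  not a truncation. The p-value is two-sided Wald on $\mathrm{RERI}/se$;
  a parametric-bootstrap alternative (`reri_bootstrap_se()`) draws
  coefficients from their estimated multivariate normal and is used as an
  independent check in the test suite (agreement within 10% at
  n = 20,000).
* **Classification**: the additive label is `"none"` when the 95% CI spans
  zero, otherwise synergistic/antagonistic by whether the RERI sign matches
  the sign of $OR_{11}-1$. Odds ratios are positive, so the sign rule is
  only meaningful on the excess-risk scale — this is how the otherwise
  ambiguous "consistent sign with $OR_{11}$" convention is implemented.

## Exposure derivation

**ACEs.** The five Childhood Trauma Screener items are ordinal (0 = "Never
true" … 4 = "Very often true"). The three abuse items endorse at codes
2–4; the two neglect items ("felt loved", "taken to doctor") are reverse
scored and endorse at codes 0–1. `any_ace` is 1 when at least one observed
item endorses; the count sums endorsed items. Three deliberate conventions
where the field's instruments leave room:

* Participants with *some* missing items are classified from observed items
  only (`any_ace = 0` requires every observed item non-endorsed); only
  all-five-missing rows are excluded, with an explicit exclusion record —
  this mirrors the usual inclusion rule of requiring at least one item.
* Out-of-range sentinel codes ("prefer not to answer" style) become
  missing, the standard questionnaire convention.
* Domain endorsement is missing only when *all* member symptoms are
  missing; an observed "yes" dominates. This maximizes sample retention and
  keeps the any-endorsement semantics monotone.

**PRS-PCA.** Raw per-threshold scores differ in scale by orders of
magnitude, so columns are standardized before the eigendecomposition
(correlation-matrix PCA); the first component is standardized to mean 0,
SD 1 over all rows with complete scores (once, before any per-model
complete-case restriction). The sign of a principal component is arbitrary,
so PC1 is aligned to correlate positively with the row-mean of the
standardized columns — a convention that never looks at any outcome.
Under this rule the score is invariant to any common positive affine
transform of the inputs and *flips* if every column is negated, which is
the scientifically correct behaviour: negated scores reverse the risk
direction. Dichotomization is strictly above the 75th percentile
(linear-interpolation quantile), deterministic and seedless; with heavy
ties at the threshold fewer than 25% can be flagged high.

## The screening cascade

1. **Univariate screen**: one covariate-adjusted logistic model per
   phenotype × exposure (ACE, PRS per disorder). The Bonferroni tier is
   $\alpha/(n_{\text{phenotypes}} \times n_{\text{exposures}})$, computed
   from the *realized* catalog (61 × 3 = 183 for the default catalog, giving
   $2.73\times10^{-4}$ at $\alpha=0.05$), never hard-coded, so reduced
   synthetic catalogs stay internally consistent.
2. **Selection**: a phenotype enters the joint/interaction stages for a
   given PRS only if both that PRS *and* ACE pass the corrected tier on it.
3. **Joint models**: both exposures together; reported next to the
   univariate ORs so attenuation is visible.
4. **Interaction models**: RERI and $\beta_3$ per selected pair, with a
   nominal tier at $\alpha$ and a per-PRS Bonferroni tier whose denominator
   is the realized selection count for that PRS. A phenotype selected for
   both disorders is tested in each family independently.
5. **Sensitivity**: (a) all covariate × PRS and covariate × ACE product
   terms added to the interaction model, so covariate confounding cannot
   masquerade as G×E interaction; (b) ACE-count (0–5) dose–response on the
   domain phenotypes, linear per-ACE coding by default with a categorical
   option (categorical coding uses the observed count levels, since top
   counts can be empty in realistic samples); (c) the five ACE-type flags,
   alone and jointly; plus an optional row filter (e.g. an ancestry subset
   column) applied before refitting.

Every attempted model appears exactly once in either a result table or the
exclusion log with its reason — degenerate outcomes and flagged fits are
recorded, never silently dropped.

## Model fitting and numerical choices

Fits use maximum-likelihood logistic regression (IRLS) run to a relative
deviance change below $10^{-8}$ with at most 100 iterations, on the
complete cases of each model's own columns (per-model listwise deletion,
so each phenotype keeps every participant with full information for that
model). Ordinal covariates (income, education, smoking, employment) enter
as unordered indicator terms by default — assuming nothing about spacing —
and p-values are Wald throughout, consistent with reporting ORs with normal
CIs.

Quasi-complete separation is detected as non-convergence, a missing
coefficient, or any non-intercept coefficient beyond ±15 on the log-odds
scale (odds ratios above $e^{15}\approx 3\times10^6$ have no
epidemiological interpretation and occur in practice only when a cell is
empty). Flagged fits carry no usable estimates: `tidy_fit()` emits zero
rows and the interaction extractors refuse them explicitly.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
structure the models assume, with ground truth for every downstream
estimate:

* **Threshold scores**: per disorder, 10 columns from a multivariate normal
  with exchangeable correlation (default 0.85, i.e. a leading eigenvalue
  share of $(1+9\rho)/10 \approx 0.87$; a `pc1_variance_target` can be
  supplied instead and is inverted through that identity), then per-column
  scale distortions spanning five orders of magnitude to mimic raw
  per-threshold scores.
* **Adversity items**: a Gaussian copula with exchangeable latent
  correlation (default 0.3) mapped through per-item category probabilities
  chosen so abuse items endorse at roughly 5–16% and the reverse-scored
  neglect items concentrate mass at the top codes. The default rates give
  an any-ACE prevalence near 40%, a realistic figure for retrospective
  adult self-report. Item-level missingness is optional,
  missing-completely-at-random, default 0; a participant always retains at
  least one observed item, mirroring the inclusion rule.
* **Outcomes**: Bernoulli draws whose logit is
  $\operatorname{logit}(\pi_0) + \beta_1 G + \beta_2 E + \beta_3 GE$ using
  the *dichotomized* exposures the pipeline reconstructs (the PRS-PCA top
  quartile and the derived any-ACE flag), so planted and estimated
  parameters live on the same scale. Interactions are planted either as
  $\beta_3$ directly (multiplicative scale) or as a target RERI inverted
  exactly through
  $\beta_3 = \log(\mathrm{RERI} + e^{\beta_1} + e^{\beta_2} - 1) -
  \beta_1 - \beta_2$ (`plant_additive_interaction()`, with an explicit
  infeasibility error when the log argument is non-positive). Dose-response
  and type-specific scenarios can put the ACE effect on the count or on one
  type flag instead. Cognition-style phenotypes are continuous scores
  (standard normal minus the planted linear predictor, so risk lowers the
  score) dichotomized downstream at an impairment quantile, by default the
  lowest quartile, configurable in the catalog.

Identical scenario + seed reproduces the cohort bit for bit; one seed set
at the top of `generate_cohort()` drives all draws in fixed order.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: symptoms are conditionally independent
given the exposures, so domain (any-endorsement) prevalences run higher
than in real questionnaires where symptoms cluster; there is no planted
gene–environment correlation (high PRS and ACEs are independent by
construction, whereas real cohorts show small correlations); covariates are
independent of exposures unless explicitly given effects; missingness is
MCAR only; and the default symptom prevalences are placeholders, not
calibrated to any published descriptive table. Parameter recovery on these
cohorts validates the estimators and the cascade logic, not robustness to
confounding structures the generator never produces.

## The default phenotype catalog

The catalog ships with 55 symptom-level phenotypes across 7 domains
(psychotic 7, mania 6, depression 14, anxiety 16, help-seeking 1,
self-harm/suicide 8, cognition 3) plus any-endorsement domain phenotypes.
Help-seeking has a single symptom, so its symptom and domain are one
phenotype and the catalog counts 61 distinct phenotypes — the figure the
183-test Bonferroni tier derives from. The per-domain split outside
cognition and help-seeking is a structural stand-in: the screening
machinery needs counts, membership and construction rules, and real
analyses supply their own catalog as JSON (`read_catalog()`). The three
cognition phenotypes are continuous test scores (numeric memory, fluid
intelligence, prospective memory) cut at the lowest quartile; the quartile
is a package default, configurable per entry, since instrument-specific
impairment cuts vary.

## Problem sizes used in the validation suite

The package's own validation uses: exact identities at 1,000 random
coefficient triples (tolerance $10^{-12}$); a 2,000-draw parametric
bootstrap against the delta-method SE on one n = 20,000 cohort; CI coverage
and Wald test size over 600 replicated cohorts of n = 5,000 at planted RERI
0 and 0.25 (coverage required in [0.92, 0.97], type-I in [3.5%, 6.5%]);
parameter recovery within 3 SE at n = 200,000 on each interaction scale;
and exact planted-set recovery of the screening cascade on a
five-phenotype catalog at n = 40,000. These sizes give the binomial and
Monte-Carlo error margins the assertions need while keeping the suite
routine to run.

## Known limitations

* RERI is computed on the odds-ratio scale, as is conventional when only
  logistic fits are available; for common outcomes ORs overstate risk
  ratios and the RERI inherits that distortion.
* No attributable proportion or synergy index; no likelihood-ratio or
  profile-likelihood intervals (Wald throughout).
* The delta-method CI is first-order; its coverage is verified by
  simulation at the sample sizes above, not guaranteed in tiny samples or
  for very rare phenotypes — where the separation flag will usually fire
  first.
* Ancestry handling is a row filter on a user-supplied column; the package
  does no ancestry inference, genotype QC, clumping or per-SNP scoring —
  it starts from precomputed per-threshold scores.
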