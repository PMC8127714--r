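---
title: "Methods: estimating and comparing selection in paired crop-proximity experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and comparing selection in paired crop-proximity experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selmosaic)
```

## The scientific question

When a wild plant grows beside a large planting of a closely related crop,
the two share pollinators and seed predators, and the crop's presence can
change the abundance and behavior of both. `selmosaic` implements the
statistical pipeline for a paired field design that asks whether such
proximity alters natural selection: replicated populations of a wild plant
are established near a crop field and ~2.5 km away ("far"), for every
combination of site, year and seed source, and per-plant fitness, floral
traits and interactor activity are measured.

Four analyses build on each other:

1. **Phenotypic selection analysis** per population (Lande–Arnold):
   selection differentials and gradients on standardized traits.
2. **Proximity ANCOVA**: mixed models asking whether those coefficients
   differ near versus far, consistently or context-dependently.
3. **Homogeneity of selection**: variance-ratio tests asking whether
   selection is more heterogeneous in one arm.
4. **Multigroup piecewise SEM**: whether mutualist- and
   antagonist-mediated causal paths differ between arms.

A synthetic-data generator with known ground truth makes every stage
testable without the field data.

## Derived variables

Fitness is whole-plant seed production, estimated as mean seeds per
(bagged) inflorescence times the number of inflorescences. Relative
fitness divides by the population mean, so it averages exactly 1 within
each population. Analyses use log-transformed relative fitness by default.
Because zero-seed plants occur in the field (inflorescence counts range
down to zero) and must stay in the analysis, the default log transform is
$\ln(w_{rel} + 1)$; the offset is configurable, and `log_offset = 0`
(defined when all plants set seed) recovers the exactly log-linear scale.

Plants whose inflorescence bags yielded no seed sample have no defensible
fitness value; whether they are excluded from fitness analyses or treated
as zero-seed plants is a genuine judgment call, so both behaviors are
exposed (`missing_fitness = "exclude"` by default, or `"zero"`) rather
than silently deciding.

Stem volume is the cylinder $\pi r^2 h$ from basal diameter (measured in
mm) and height (measured in cm). The two units are harmonized to mm, so
volume is in mm³ throughout.

The five disk-flower traits are derived per flower first — corolla lobe
size CS = CL×CW, proximal throat size PTS = PTL×PTW, corolla tube size
TS = TL×TW, with distal throat width/length as measured — and then
averaged across a plant's flowers. The mean-of-products order matters and
is asserted by tests: for heterogeneous flowers it differs from the
product of means.

Seed-predator attack is the proportion of examined seeds damaged by each
predator (moth ISO, midge NEO). Pollen deposition scales mean grains per
stigma by an assumed constant 100 flowers per inflorescence times the
inflorescence count.

Traits are standardized (mean 0, SD 1) within population. The optional
`transform_policy = "auto"` first applies $\ln(x+1)$ to variables with
|skewness| > 1 (arcsine-square-root for proportions); the applied
transforms are recorded in the output. The default is `"none"` because the
generator's traits are near-normal by construction.

## Selection differentials and gradients

For standardized trait $z$ and fitness $w$,
$s' = \mathrm{cov}(z, w)$ (total selection) with significance from the
Pearson correlation test, uncorrected for multiple comparisons — the
per-case tests are descriptive, and the summary layer counts significant
cases against the number expected by chance. Gradients
$\beta$ are the partial coefficients of the single OLS regression of $w$
on all eleven traits plus stem volume (direct selection). Two identities
pin the implementation: with a single covariate, or with exactly
orthogonal covariates, $\beta$ equals $s'$ to numerical precision; and
$s'$ equals $r \cdot \mathrm{SD}(w)$.

Collinearity diagnostics follow the usual regression practice: VIFs
$1/(1-R^2_j)$ with thresholds 5 (warn) and 10 (fail), and condition
indices $\sqrt{\lambda_{max}/\lambda_i}$ of the unit-length-scaled design
cross-product with threshold 30. When any VIF exceeds the warning level,
the model is refit without the worst covariate and the report records
whether the remaining gradients stay inside their original 95% CIs.
Populations are never excluded automatically; the diagnostics flag is
reported so exclusion stays an explicit, reproducible judgment.

## Proximity ANCOVA

Whether selection differs by proximity is tested with linear mixed models:
log-relative fitness on site × proximity × trait (total selection; one
model per trait) or on site × proximity × (all twelve covariates) (direct
selection), plus year and its interactions for multiyear data, with a
random intercept per population. A significant trait × proximity term
means selection on that trait differs consistently between arms; a
higher-order interaction involving proximity means the difference is
site- or year-dependent; `classify_effects()` encodes exactly that rule.

Terms are tested marginally (Type III) with sum-to-zero contrasts, because
interactions are interpreted in the presence of main effects. Denominator
degrees of freedom use the Satterthwaite approximation by default, with a
containment-style alternative (`ddf_method = "containment"`) that tests
design-factor terms against the population stratum. Because relative
fitness is centered within populations, the population variance component
is frequently near zero; singular fits fall back to the pooled Type III
ANCOVA with a warning, and the zero-variance limit is available directly
via `random = "none"` (the two agree exactly, which the tests assert).

## Homogeneity of selection

To compare the *dispersion* of selection between arms without letting
between-trait differences in its typical direction dominate, per-trait
means are subtracted from the population-level coefficients (pooled across
arms by default; per-arm recentering is a flag). The pooled test stacks
all recentered coefficients and compares
$F = s^2_{far} / s^2_{near}$ with df $(n_{far}-1,\, n_{near}-1)$; traits
are weighted equally. Two-sided p-values are
$2\min\{P(F \le f),\, P(F \ge f)\}$, capped at 1 — the convention that
reproduces reference variance-ratio results and matches `var.test`; a
one-sided variant is a flag. Per-trait tests run on the raw
(non-recentered) coefficients, and the suite also counts how many traits
have higher far-arm variance. Degrees of freedom are always derived from
the data at hand and printed, never hard-coded.

## Multigroup piecewise SEM

Floral traits are summarized by the first principal component of the
inflorescence traits and of the disk-flower traits separately, computed
per site-year combination (pairs at a site-year share the composite
definition) on the correlation matrix. Loadings are sign-aligned so every
constituent trait correlates nonnegatively with the scores — flips are
recorded, and the scores are invariant to the polarity of the input
columns, which makes "larger composite = larger traits" interpretable.
The default causal model sends both composites to seed-predator attack
(and to pollen deposition where measured), attack and pollen to relative
fitness, and stem volume and inflorescence number directly to fitness.
The DAG is overridable via `dag_spec()` ("A -> B" lines).

Model fit uses Shipley's d-separation test: one independence claim per
non-adjacent pair, conditioned on the union of both variables' parents,
with the response chosen so it is not an ancestor of its partner. Each
claim is tested by the linear regression of the response on the partner
plus conditioning set; Fisher's $C = -2\sum \ln p_i$ is compared to
$\chi^2_{2k}$, and $p > 0.05$ indicates the data are consistent with the
claimed structure. The test suite verifies the basis set against
brute-force path-enumeration d-separation on exhaustively enumerated
small DAGs.

The multigroup step visits paths in a canonical order (topological by
child, then by parent — the order is logged and configurable): for each
focal path the child is regressed on its parents, the group, interactions
of already-freed paths and the focal parent × group interaction; an
interaction p below 0.05 frees the path (per-arm coefficients), otherwise
it is constrained (pooled coefficient, group intercept retained). Fisher's
C in the multigroup setting is computed pooled for claims whose response
has no freed incoming path and per group otherwise; this rule is
documented and overridable (`fisher_groups`), since local-estimation SEM
admits either convention.

All endogenous responses are modeled linear-Gaussian on standardized
data; proportion-valued variables are transformed upstream by the
standardization policy rather than modeled with link functions, matching
the practice of standardizing and transforming before SEM.

## The synthetic generator

`generate_experiment()` emulates the design so that downstream estimates
have known targets:

* paired near/far populations for every site × year × seed-source cell
  (defaults 2 × 2 × 2 = 8 pairs, mirroring a two-site multiyear design),
  80–155 plants each;
* nine floral traits drawn multivariate normal with a configurable
  positive-definite correlation matrix (defaults: 0.4 within the
  inflorescence and flower blocks, 0.2 between);
* seed fates (moth-damaged, midge-damaged, intact out of ~80 examined
  seeds) drawn Dirichlet-multinomial with logit-scale trait linkage;
  far-arm attack rates elevated (default ×2) and pollinator activity
  depressed (default ×0.6), reflecting the field observation of more
  seed-predator attack away from the crop and more pollinators near it;
* pollen counts per stigma Poisson with log-scale floral-trait linkage,
  measured only at the focal site(s), as in the field protocol;
* fitness log-linear in the standardized *realized* traits with known
  gradients (defaults within ±0.3), a stem-volume term, per-proportion
  attack penalties and Gaussian noise, realized as negative-binomial seed
  counts (overdispersed counts being the natural model for seeds).

Two details matter for unbiased recovery. Flower-level measurements are
fabricated to reproduce the plant-level composite values exactly (product
splits with mean-one weights), and fitness is linked to the traits as
*realized* after rounding and truncation — so the estimand of the
downstream regression equals the stored truth. Effect sizes linking
traits to attack and pollen are not empirical (the study reports none);
they are chosen for testability and labeled as such.

Determinism: each population is generated from an RNG sub-stream keyed by
a stable hash of its id and the master seed, so populations are identical
regardless of which design cells are generated alongside them, and the
same seed yields byte-identical CSVs.

What the generator does *not* emulate: spatial structure within plots,
phenology, pollinator foraging behavior, trait measurement error
(flower-to-flower variation is present but integrates out exactly), or
environment–fitness covariance. Passing recovery and calibration tests on
these data therefore shows the estimators are correct under the assumed
model, not that field inference is free of those complications.

## Numerical choices and study sizes

* Covariances and variances use $n-1$ denominators, pairing with the
  correlation-test significance.
* Zero-variance fitness yields $s' = 0$, $p = 1$ (no evidence of
  selection, the conservative convention); zero-variance traits are
  excluded from standardization with a warning.
* Gradients require at least two more plants than covariates; singular
  designs are flagged, not silently dropped.
* Parameter-recovery runs measure gradients on `log_offset = 0`
  log-relative fitness because the generator's link is log-linear — the
  correct estimand pairing; the field-data default stays at offset 1 so
  zero-fitness plants remain.
* Simulation sizes used by the checks: 200 replicates at 120
  plants/population for recovery (bias ≤ 0.02, CI coverage 0.93–0.97);
  500 exchangeable-arm replicates for ANCOVA null calibration and 1000
  for the pooled homogeneity test (rejection 0.03–0.07 at nominal 0.05);
  200 replicates at 100 plants/group for multigroup power (a path
  differing by 0.5 freed ≥ 80% of the time, null paths constrained
  ≥ 90%). These sizes are the package's reproducibility contract and are
  re-run by `scripts/acceptance.R`.

## Known limitations

* Nonlinear (quadratic) and correlational selection are out of scope; the
  emulated per-population sample sizes do not support them.
* Only random intercepts are modeled in the ANCOVA; random slopes by
  population are not.
* The SEM layer is local-estimation piecewise modeling: no latent
  variables, correlated errors, or covariance-based global fit.
* The generator's interactor effect sizes are non-empirical defaults;
  conclusions about power at other effect sizes require configuring them.
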