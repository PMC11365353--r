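---
title: "Meta-analytic prediction equations for potassium excretion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic prediction equations for potassium excretion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Dairy cattle excrete most of their surplus dietary potassium in urine, and a
smaller share in feces. Because total collection of excreta is impractical on
farms, nutritionists rely on simple prediction equations that map routinely
measured quantities — potassium intake, dry-matter intake (DMI), water
intake, urine volume, milk yield — to daily urinary (`k_ur`) and fecal
(`k_fa`) potassium excretion in g/d. kexmeta implements the full workflow
for developing and evaluating such equations from published study-level
treatment means: database assembly and validation, outlier screening, a
weighted random-intercept mixed model, leave-one-study-out cross-validation
(LOSO-CV), and a model-adequacy suite.

```{r setup}
library(kexmeta)
```

## The unit of analysis and the model

The unit of analysis is the *treatment mean*: one published group-level
average (one diet in one study). Treatment means from the same publication
share husbandry, assay and cohort idiosyncrasies, so records are not
independent across a study. The model is therefore a random-intercept linear
mixed model,

$$y_{ij} = \beta_0 + \beta_1 x_{ij} + s_i + e_{ij}, \qquad
  s_i \sim N(0, \tau^2), \qquad
  e_{ij} \sim N(0, \sigma^2 / w_{ij}),$$

where $y_{ij}$ is the excretion response of mean $j$ in study $i$, $x_{ij}$
a single candidate predictor, $s_i$ the study effect and $w_{ij}$ the number
of animals behind the mean. Weighting by $w_{ij}$ treats each record as an
average of that many unit-variance observations — the canonical
treatment-mean weighting when replication is known — so better-replicated
means carry proportionally more information. $\sigma^2$ is reported on the
*unit-weight* scale: the residual variance of a record with $w = 1$.

Only simple (single-predictor) regressions are fitted. With a few dozen
treatment means per response, more complex fixed-effect structures are not
supported by the data, and candidate predictors (e.g. DMI and K intake) are
strongly collinear.

### Estimation

`kexmm()` estimates the model by restricted maximum likelihood (REML), the
standard choice when variance components matter: it corrects the downward
bias maximum likelihood incurs from estimating the fixed effects. Because
there is a single random intercept, the REML criterion can be *profiled
exactly* over the one variance ratio $\theta = \tau^2/\sigma^2$: at each
$\theta$ the fixed effects are generalized least squares and $\sigma^2$ has
a closed form, both computed blockwise by Sherman–Morrison (each study block
is a diagonal plus a rank-one term). The resulting one-dimensional criterion
is minimized by an 81-point log-spaced grid over $\theta \in [10^{-10},
10^{7}]$ followed by Brent refinement within the bracketing grid cells
(tolerance $10^{-9}$ on $\log\theta$, comfortably below the $10^{-8}$
relative movement at which we declare convergence). The criterion is also
evaluated at $\theta = 0$ exactly: a boundary estimate $\hat\tau^2 = 0$ is a
legal, reported outcome, not an error. This avoids general-purpose
mixed-model optimizers entirely, while the test suite verifies agreement
with one (lme4, same weighted REML objective) to $10^{-4}$ relative on
simulated datasets.

Standard errors come from $\hat\sigma^2 (X' V_0^{-1} X)^{-1}$ at the
optimum, slope significance from the Wald statistic with a normal reference
(with 15+ studies the difference from a t reference is immaterial at the
precision reported), and study BLUPs from the usual shrinkage formula
$\hat s_i = \theta \, (\sum_j w_{ij} r_{ij}) / (1 + \theta \sum_j w_{ij})$,
which sum exactly to zero by the intercept normal equation.

### Marginal R²

The marginal R² — variance explained by fixed effects alone — is

$$R^2_m = \frac{\mathrm{Var}_f}{\mathrm{Var}_f + \hat\tau^2 + \bar\sigma^2},$$

with $\mathrm{Var}_f$ the population variance of the fixed-effect
predictions over the complete cases. The textbook formula assumes a single
residual variance; under per-record weights we use the *mean* per-record
residual variance $\bar\sigma^2 = \hat\sigma^2 \cdot \mathrm{mean}(1/w)$.
This is a genuine design choice (the weighted case is not pinned down by the
usual citation), made because it reduces to the standard formula at equal
weights and keeps $R^2_m$ invariant to rescaling all weights. Simulation
checks in the test suite confirm the perfect-fit limit ($R^2_m \to 1$), the
null behaviour ($R^2_m$ near 0 when the slope is 0), and recovery of a
calibrated design value within ±0.05.

## Database rules

`read_kex_db()`/`kex_db()` validate every record: positive quantities, a
replication count of at least 1, at least one response present, and — when
DMI, dietary K concentration and K intake are all reported — internal
consistency of the identity

$$\text{K intake [g/d]} = \text{DMI [kg/d]} \times \text{dietary K [\% DM]}
  \times 10,$$

within a 5% relative tolerance (configurable; source papers round). Rows
failing validation are returned in a per-row rejection report, never
silently dropped. `derive_k_intake()` fills missing K intakes by the same
identity and never overwrites a reported value. Models use complete cases
per response–predictor pair, which is why each fitted equation can carry a
different n.

`kex_summarize()` reports per-variable n, mean, sample SD (n − 1), min,
max and CV, plus the excretion share of intake (mean response ÷ mean K
intake × 100). Sample SDs are the descriptive convention; the *population*
SDs used inside the error decomposition below are a separate, deliberate
choice.

## Outlier screening

`screen_outliers()` applies Tukey's interquartile-range rule with factor
1.5: a record strictly outside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
1.5\,\mathrm{IQR}]$ on *any* screened variable is removed whole. Quartiles
use the linear-interpolation convention (`quantile` type 7) — fence
membership depends on the quantile rule, so it is fixed and documented
rather than configurable. Screening is one pass over the incoming database:
re-screening a screened set tightens the fences and can flag new records,
so iterating would not terminate at a fixed point by construction; the
report records the fences actually used. Data-specific judgement calls
(e.g. a study with implausibly low urinary K at high intake, or a paper
reusing another paper's data) are handled by an explicit study blocklist in
the configuration, not by hard-coded names.

## Cross-validation and adequacy metrics

Generalization is assessed to *unseen studies*: `loso_cv()` holds out one
whole study per fold, refits on the rest, and predicts the held-out means
from fixed effects only — the random intercept of a new study has
expectation zero, and using its BLUP would leak the held-out data. Metrics
are computed unweighted over the pooled CV pairs (weights express fitting
precision, not evaluation importance).

`mspe_decompose()` computes the mean square prediction error and its exact
decomposition

$$\mathrm{MSPE} = \underbrace{(\bar P - \bar O)^2}_{\text{mean bias}}
 + \underbrace{(S_p - r S_o)^2}_{\text{slope bias}}
 + \underbrace{(1 - r^2) S_o^2}_{\text{random}},$$

where $S_o, S_p$ are population SDs (divide by n) and $r$ the Pearson
correlation. Population moments are what make the identity exact (so the
three bias percentages sum to 100); the RSR denominator, by the metric's
convention, uses the sample SD of the observed values. Also reported:
RMSPE as % of the observed mean, Lin's concordance correlation coefficient

$$\mathrm{CCC} = \frac{2 r S_o S_p}{S_o^2 + S_p^2 + (\bar O - \bar P)^2},$$

and bias-significance tests from regressing residuals $y - \hat y$ on
mean-centered predictions (intercept t-test = mean bias, slope t-test =
slope bias), the standard companion procedure to the decomposition.
Degenerate inputs are flagged rather than fatal where a defensible value
exists (constant predictions: $r$ treated as 0, CCC undefined); constant
observations are an error.

`rank_models()` orders candidates by ascending RSR — the headline selection
metric because it normalizes RMSPE by the observed spread and is comparable
across models fitted to different n — with ties broken by descending CCC,
then ascending RMSPE%, then predictor name, giving a deterministic total
order.

## The synthetic-data generator

The raw literature database behind the published equations is not public,
so `simulate_kex_db()` generates databases with the exact structure the
model assumes: study intercepts $s_i \sim N(0, \tau^2)$, predictors uniform
over the published min–max ranges, integer weights uniform over a
replication range, and residuals $N(0, \sigma^2/w)$. Defaults are the
urinary K-intake calibration: 17 studies of 2–4 means (the published
database size), $\beta_0 = 1.08$, $\beta_1 = 0.65$, K intake over
105.3–686.0 g/d, weights 4–12 cows per mean, $\tau = 30$ g/d and $\sigma =
25$ g/d. The variance components are not printed anywhere, so they were
chosen once to give residual spread of the order the published equation's
slope SE implies, and are exposed as parameters. Uniform predictor
marginals (rather than truncated normals) are a stated generator
convention: the published tables give ranges, and uniform spread maximizes
design information for slope recovery. One root seed derives per-study
substreams, so a study's draws do not depend on how many records other
studies contribute.

`simulate_kex_db_mv()` additionally draws DMI and dietary K jointly
(optionally rank-correlated through a Gaussian copula) and *derives* K
intake by the exact identity, so every record passes the database
consistency check; the response is driven by one designated predictor.
Planted multiplicative outliers on the response mimic the implausible
excretion records the screening stage exists for.

What the generator does *not* emulate: within-study predictor clustering
(real studies vary diets narrowly around a design point; true within-study
dispersion is unknowable from published summaries and is left as a
parameter), non-Gaussian study effects, correlated residuals across
responses, and any physiological K-balance mechanism. Passing tests
therefore demonstrate that the estimator and evaluation stack are correct
under the model's own assumptions — not that the published coefficients are
right for real cattle.

## A worked run

```{r, eval = FALSE}
db <- simulate_kex_db(kex_sim_config(seed = 5))
fit <- kexmm(k_ur ~ k_intake, db)
summary(fit)
cv <- loso_cv(db, k_ur ~ k_intake)
mspe_decompose(cv$observed, cv$predicted)
```

The end-to-end pipeline (`kex_pipeline()`) chains load → derive → screen →
fit → LOSO-CV → metrics → rank and writes CSV/JSON artifacts stamped with a
config hash and seed; identical config and seed give byte-identical
reports. One invocation handles one response; `kex_pipeline_both()` runs
urinary and fecal in sequence.

## Numerical and design choices, collected

- REML, not ML; single-ratio profiling with an exact boundary check at
  $\tau^2 = 0$.
- Grid-plus-Brent optimization; the test suite asserts no point on a dense
  $\theta$ grid beats the returned optimum.
- Doubling all weights leaves coefficients, $\hat\tau^2$, SEs and BLUPs
  unchanged and doubles unit-weight $\hat\sigma^2$ (per-record variances
  $\hat\sigma^2/w$ unchanged) — weights act only as relative precisions.
- Population SDs inside the MSPE decomposition; sample SDs for descriptive
  summaries and the RSR denominator.
- Wald normal test for slope significance; bias tests by
  residual-on-centered-prediction regression.
- IQR screening with type-7 quantiles, factor 1.5, one pass.
- CV predictions are fixed-effects-only; metrics unweighted.
- Problem sizes in the test suite (200 replicates for recovery studies,
  1,000 random pair sets for metric identities, 25 datasets for the
  mixed-model oracle) were chosen to keep Monte Carlo error an order of
  magnitude below the tolerances they check.

## Limitations

Simple regressions on treatment means cannot capture individual-animal
variation, and equations developed from cows milking roughly 20–42 kg/d
should not be extrapolated far outside that range. The evaluation stack
scores whole-study generalization, which is the right target for applying
an equation to a new herd, but with ~17 studies the CV metrics themselves
carry non-trivial sampling error. Where the published analysis made
data-specific exclusion judgements, this package provides the mechanism
(blocklists, audit trails) but deliberately not the judgements.
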