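---
title: "Dissecting hyperarousal into questionnaire-derived dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hyperarousal into questionnaire-derived dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Hyperarousal — the subjectively experienced cognitive, emotional and somatic
tension that cuts across insomnia, depression, anxiety, posttraumatic stress
and attention-deficit disorders — is usually measured with disorder-specific
questionnaires. `hyperdim` implements a complete pipeline for asking whether
a large battery of such ordinal items hides a small number of latent
dimensions, for building a short-form instrument that measures them, for
profiling how the dimensions relate to disorder severity, and for carrying
the dimensions into external cohorts whose items were never part of the
battery. Every stage can be exercised against synthetic data with known
ground truth.

## The measurement model

Responses to item $j$ are ordinal codes $1..c_j$ assumed to discretize a
latent standard-normal variable $y_j^*$ at thresholds
$\tau_{j1} < \dots < \tau_{j,c_j-1}$, with

$$y^* = \Lambda f + \varepsilon, \qquad f \sim N(0, \Phi), \qquad
\varepsilon \sim N(0, \operatorname{diag}\psi),$$

where $\Lambda$ holds item loadings on $k$ correlated factors and each
item's total latent variance is 1, so category probabilities are normal-CDF
increments between thresholds. All pipeline stages operate on the polychoric
correlation matrix of the battery, the maximum-likelihood estimate of
$\operatorname{cor}(y^*)$.

### Polychoric estimation

The two-step estimator fixes thresholds at the inverse-normal quantiles of
the observed cumulative margins and maximizes the bivariate-normal
multinomial likelihood over the single correlation by Brent search on
$(-0.999, 0.999)$ with tolerance $10^{-7}$. Choices worth knowing:

* **Continuity correction.** Zero cells of each pairwise table are replaced
  by 0.1 before the likelihood is evaluated; entirely empty categories are
  collapsed first (the correction is meant for sampling zeros, not for
  categories nobody can reach).
* **Local thresholds.** Each pair re-estimates thresholds from its own
  pairwise-complete margins, so missing data never distort other pairs.
* **Rectangle probabilities** come from a hybrid Gauss–Legendre bivariate
  normal CDF (absolute accuracy near machine precision, verified against an
  independent implementation in the tests).
* **Smoothing.** An assembled pairwise matrix can be indefinite; negative
  eigenvalues are clipped at $10^{-8}$, the matrix reconstructed and
  rescaled to unit diagonal, and the event flagged. The distortion is
  bounded by the magnitude of the most negative eigenvalue.

### Screening and redundancy reduction

Items with Kaiser–Meyer–Olkin per-item sampling adequacy below 0.7 are
dropped. Near-duplicate items are then pruned by a stepwise rule: walking
thresholds $0.90, 0.85, \dots, 0.50$, any surviving pair correlating beyond
the threshold loses the item with the *higher* absolute median correlation
with the other surviving items (it carries less unique variance), medians
being recomputed after every removal. Two readings of the original
procedure were open: medians are taken over the *surviving* set (not the
original battery), and passes iterate within a threshold until no pair
exceeds it. Exact ties consult an optional priority rank — the stand-in for
the human preference for trait-like over state-like wording — and fall back
to label order, recording the tie. The stop threshold is exposed because
stopping at $|0.5|$ was a pragmatic choice ("a workable number of items"),
not a statistical one.

### Dimensionality and rotation

Parallel analysis compares observed eigenvalues with the 95th percentile of
eigenvalues of standard-normal data of the same shape (200 replicates by
default); the suggested dimensionality is the length of the leading run of
observed eigenvalues exceeding their quantile. Because content
considerations can override the purely statistical suggestion (the
reference analysis retained 7 of a suggested 16), the extracted `k` is an
explicit parameter everywhere.

Extraction is principal-axis factoring: communalities start at squared
multiple correlations and the reduced matrix is re-eigendecomposed until
the largest communality change is below $10^{-6}$; Heywood cases are
clipped to 1 and flagged. Promax rotation follows: Kaiser-normalized
varimax, then an oblique least-squares transform to the powered target
$\operatorname{sign}(\Lambda_v)|\Lambda_v|^4$, scaled so $\Phi$ has unit
diagonal. Sign (largest loading positive) and order (descending structure
sum of squares) conventions make solutions reproducible.

**Variance explained.** With correlated factors the sum of squared
*structure* loadings over-counts shared variance (it can exceed 100%
cumulatively), so per-factor explained variance is reported as
$\sum_j P_{jf} S_{jf} / p$ — pattern times structure — whose total equals
the mean communality, reduces to the usual convention for orthogonal
solutions, and is recorded as metadata in the output.

### Scores, short form, confirmation

Full-battery dimension scores multiply responses by pattern loadings over
all items; a person missing an item whose loading reaches the salience
threshold $|0.32|$ on a factor gets a missing score for that factor. The
short form selects the highest-loading items per factor (counts
4, 5, 4, 4, 4, 2, 4 by default) whose cross-loadings stay at or below 0.32,
relaxing the cap in recorded 0.05 steps only if the pool runs dry; item
responses are rescaled to $[0, 4]$ as $(x - \min)/(\max - \min) \times 4$
and averaged within factor, so scores live on a 0–4 severity scale.

Confirmatory fits use normal-theory maximum likelihood on the covariance of
the 0–4 rescaled items — the original estimator is unstated, so the input
matrix is pluggable (a polychoric matrix can be supplied instead) and the
choice is recorded. The discrepancy
$F = \log|\Sigma| + \operatorname{tr}(S\Sigma^{-1}) - \log|S| - p$ is
minimized by quasi-Newton iteration with analytic gradients from a
deterministic start (loadings $0.7 \times$ the sign of the first principal
component, uniquenesses at 51% of item variances), with seeded jittered
restarts on failure. $\chi^2 = (n-1)F$; CFI and TLI are computed against
the independence baseline, RMSEA from the noncentrality estimate, SRMR from
standardized residuals. Factor correlations are free, or generated by a
single higher-order factor ($\Phi = \gamma\gamma' + \operatorname{diag}(1 -
\gamma^2)$, with $\gamma$ kept in $(-1,1)$ through a tanh
parameterization). Nested models compare by likelihood ratio. Cronbach's
$\alpha$ uses its defining covariance formula; McDonald's $\omega_t$ comes
from a one-factor ML fit; $\omega_h$ (experimental, method unstated in the
reference) projects a higher-order solution onto the general factor.

### Severity profiles and the partial-correlation network

Disorder-severity profiles are ordinary least squares of each screener
total on all (or one) dimension scores plus covariates, on listwise
complete rows; continuous variables are scaled to unit SD on the analysis
sample so coefficients are standardized betas, binary sex enters as 0/1,
and confidence intervals are t-based. Screener cut-points (ISI $\ge$ 10,
RMT20 depression $\ge$ 13, generalized anxiety $\ge$ 11, social anxiety
$\ge$ 12, panic $\ge$ 9, posttraumatic stress $\ge$ 8, ASRS $\ge$ 4)
classify probable disorders.

The network stage estimates a Gaussian graphical model over the 7 dimension
scores and 7 severities: graphical lasso along 100 log-spaced penalties
from $\lambda_{\max}$ (empty graph) down to $0.01\,\lambda_{\max}$, with
the Extended BIC ($\gamma = 0.5$) selecting the penalty; edges are the
regularized partial correlations $-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$.
Pearson correlations of the observed columns feed the estimator (the
original input type is unstated; any correlation matrix can be supplied).
Edge stability uses a nonparametric bootstrap (2000 resamples by default)
that *re-runs the entire selection* per resample; edges whose
$(\alpha/2, 1-\alpha/2)$ bootstrap interval covers zero are set to zero at
$\alpha = 0.05$. Note the semantics: a *smaller* $\alpha$ widens the
interval and removes more edges.

### Factor extension and indicator measures

To score the dimensions in a cohort that only shares some related items,
extension loadings for external items are computed from the
cross-correlation block $R_{eo}$ (polychoric, via the same machinery):

$$S_e = R_{eo} R_{oo}^{-1} (\Lambda\Phi), \qquad
\Lambda_e = S_e \Phi^{-1}.$$

The defining contract — adopted deliberately, since the source method is
named but not written out — is the duplicate-item identity: an external
item identical to a battery item reproduces that item's pattern row
exactly. A consequence users should expect: for a genuinely new item with
true loading $\lambda$, the extension estimate shrinks toward
$\lambda\,A/(1+A)$ with $A = \sum_j \lambda_j^2/\psi_j$ summed over the
battery items of that factor — the factor must be well determined by the
battery for extension loadings to be nearly unattenuated. External items
are selected as indicators when their primary $|\text{loading}|$ exceeds
0.45 with no cross-loading above 0.32; dimensions with at least 3 selected
items are "representable". Indicator scores average the 0–4 rescaled items
a person answered (item-wise exclusion, matching the handling of refusal
codes), unlike the stricter short-form rule.

## The synthetic-data generator

`battery_config()` fixes $\Lambda$, $\Phi$, thresholds, severity
coefficients, covariate distributions, and MCAR missingness;
`generate_battery()` draws factors, discretizes, and returns responses,
true factor scores, severities, covariates and an optional external item
block, all reproducible from one master seed via deterministic sub-streams.

Two frozen configurations ship with the package:

* `study_battery_config()` mirrors the full battery's composition: 221
  items (12 dichotomous, 91 four-level, 118 five-level) over 7 correlated
  factors, n = 467.
* `preset_study_like()` is the compact recovery benchmark used throughout
  the tests: 27 salient markers with the short-form counts
  (4, 5, 4, 4, 4, 2, 4), primary loadings 0.70–0.86, plus 21 sub-salient
  (0.31) distractors, n = 467. Free parameters the reference conditions do
  not pin down were chosen once so the preset *is* a valid benchmark: the
  two-item vigilant factor gets the strongest marker pair, most distractors,
  and the lowest factor correlations, because a two-indicator factor is
  otherwise not recoverable at congruence $\ge 0.95$ from 467 observations
  (method bias is zero: on the model-implied matrix the pipeline returns
  the generating loadings exactly). Factor correlations are generated from
  second-order loadings (range 0.23–0.52, median 0.38). Severity outcomes
  are linear in the factors with one dominant dimension per disorder
  (sleep-related for insomnia, anxious for depression/anxiety, somatic for
  panic, vigilant/sudomotor for posttraumatic stress) and residual SDs set
  for realistic $R^2$; the linear model is an assumption for testing, not a
  claim about any cohort. Sex is Bernoulli(0.776), age normal (58.3, 13.8)
  truncated to 18–90, missingness 0.0006 (the sporadic technical
  missingness scale).

What the generator deliberately does **not** emulate: item wording and
content judgments, non-MCAR missingness, acquiescence or other response
styles, and floor effects beyond what skewed thresholds induce. Passing
recovery tests therefore demonstrates the *estimators* work at the study's
size and measurement levels — not that any real battery has this structure.

## Numerical choices and degenerate inputs

* Polychoric estimates are clipped to $(-0.999, 0.999)$; single-category
  items and pairs with fewer than 3 complete observations are errors.
* Reduction tie-breaks are deterministic (priority rank, then label order).
* Parallel analysis with fewer than 20 replicates is refused.
* CFA optimizations failing to converge retry up to 5 times with seeded
  jitter; a merged-factor statistic coming out negative is clipped to 0 and
  flagged as a boundary issue.
* The graphical lasso special-cases $\lambda < 10^{-12}$ to the exact dense
  inverse; at every accepted penalty the precision matrix is checked
  positive definite before its EBIC is computed.
* All randomness in package functions flows through explicit seed
  arguments and never disturbs the caller's RNG state.

## Problem sizes in the test-suite

One interaction is worth flagging: the preset's marker items are
deliberately strongly loaded, so within-factor correlations reach ~0.7 and
the full reduction endpoint of |0.5| would prune genuine markers — on real
batteries the items pruned between |0.7| and |0.5| are near-duplicates from
overlapping questionnaires, which the compact preset does not contain. The
benchmark pipeline runs therefore stop the reduction at |0.7|; the endpoint
is an ordinary parameter everywhere.

The shipped tests run the full stack at the study scale: 25 replicates of
the 48-item battery at n = 467 for factor recovery and for the
7-versus-merged-6 model comparison; 100 replicates per condition for
polychoric bias; 200 replicates for regression-coverage; 25 chain-graph
replicates (14 nodes, n = 5000) with 250-resample bootstraps plus one full
2000-resample bootstrap at study scale for the network stage. These sizes
are the package's own choice of a thorough-but-repeatable benchmark; all
are plain `testthat` tests with fixed seeds.

## Known limitations

* Ordinal-specific CFA estimators (WLSMV-type) are not implemented; ML on
  rescaled scores is the default and the input matrix is pluggable.
* No measurement-invariance (multi-group) machinery, no oblimin/geomin
  rotations, no polyserial special cases.
* $\omega_h$ depends on the higher-order model being appropriate and is
  flagged experimental.
* Dwyer-type extension attenuates loadings of weakly determined factors,
  as derived above; indicator validity correlations inherit that ceiling.
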