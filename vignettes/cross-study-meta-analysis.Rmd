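---
title: "Cross-study synthesis of differential expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study synthesis of differential expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaexpr)
```

## The problem

Collections of small two-arm expression studies — a handful of biological
replicates per arm, assayed on a common platform — rarely agree gene by gene.
Per-study tests weight a two-replicate study as heavily as a twenty-replicate
one, and they cannot separate a gene's consistent response from study-specific
shifts caused by batch effects, tissue, or treatment protocol. `metaexpr`
synthesizes such collections the way quantitative research synthesis does:
each gene gets its own inverse-variance weighted random-effects meta-analysis
across studies, and study-level covariates (plant part, stress method) are
modeled by per-gene meta-regression.

The unit of synthesis is the *contrast*: one treated-vs-control comparison
within one study and plant part. A study that assayed both roots and shoots
contributes two contrasts, treated as if they were independent studies. This
is deliberately non-conservative — the replicates behind the two contrasts
share a batch — but it preserves scarce information; the alternative of
discarding one tissue per study was rejected.

## Effect sizes

For gene $g$ in contrast $i$, with treated arm mean $\bar Y_1$, control arm
mean $\bar Y_2$, arm variances $s_1^2, s_2^2$ (unbiased, $n-1$ denominator)
and replicate counts $n_1, n_2$, the effect size is the log expression ratio

$$\ln R_i = \ln(\bar Y_1 / \bar Y_2), \qquad
v_i = \frac{s_1^2}{n_1 \bar Y_1^2} + \frac{s_2^2}{n_2 \bar Y_2^2},$$

where $v_i$ is the delta-method sampling variance. Small-sample bias
corrections for ratio effect sizes exist but are not applied — the classical
formulation is used, matching the established practice this package follows.

**Analysis scale.** Expression matrices arrive on the log2 scale (GCRMA-style
output). By default (`effect_scale = "as_given"`) the ratio is taken over the
log2-scale arm means, i.e. the procedure is applied literally to the values
as provided. This makes effects dimensionless ratios of log-intensities
rather than log fold changes; a $\ln R$ of 0.05 at a baseline of
$\log_2 I = 8$ corresponds to roughly a 0.4 log2-unit shift. The arguably
more conventional alternative — back-transforming replicates with $2^x$
before averaging — is available as `effect_scale = "delog2"` but is not the
default, because the default reproduces the literal published procedure. The
choice is recorded in the configuration so results are never ambiguous.

Genes with a nonpositive arm mean on the analysis scale have no defined log
ratio; those records are excluded and reported. Zero sampling variances
(all replicates identical) are raised to a configurable floor
(`variance_floor`, default $10^{-8}$) so inverse-variance weights stay
finite; the count of floored records is logged.

## Random-effects meta-analysis

True effects are allowed to differ across contrasts beyond sampling noise:
$\theta_i \sim N(\mu, \tau^2)$, estimated per gene with weights

$$w_i = \frac{1}{v_i + \tau^2}, \qquad
\hat\mu = \frac{\sum w_i \hat\theta_i}{\sum w_i}, \qquad
s^2_{\hat\mu} = \frac{1}{\sum w_i},$$

and a 95% confidence interval $\hat\mu \pm t_{0.025}[K-1]\, s_{\hat\mu}$
(Student's t with $K-1$ degrees of freedom by default; the normal multiplier
is available via `ci_distribution`). Batch effects that shift both arms of a
study equally cancel in $\ln R$; batch effects that shift study outcomes are
absorbed into $\tau^2$ rather than modeled as covariates.

**Between-study variance.** The default estimator for the meta-analysis is
REML; the DerSimonian–Laird (DL) moment estimator

$$\hat\tau^2_{DL} = \max\!\left(0,\ \frac{Q - (K-1)}
{\sum w_i^{FE} - \sum (w_i^{FE})^2 / \sum w_i^{FE}}\right),
\quad w_i^{FE} = 1/v_i,$$

is provided both as a fast alternative and as the starting value for the
REML iteration. REML is maximized by an iterative scheme that takes the
observed-information (Newton) step where the curvature is negative and the
expected-information (Fisher scoring) step otherwise, truncating at zero;
convergence is declared when the step falls below $10^{-8}$, with a cap of
100 iterations and a DL fallback (flagged per gene) on non-convergence. The
Newton step matters: pure Fisher scoring converges only linearly on flat
restricted likelihoods and can exhaust the iteration budget.

**Single-contrast genes** ($K = 1$) are retained with $\tau^2 = 0$ and
flagged (`single_contrast`): their estimates pass through, their
$t$-interval is undefined (0 degrees of freedom, reported as `NA`).

**Test reference.** The published convention tests $z = \hat\mu/s_{\hat\mu}$
against the normal distribution while building the interval from Student's
t. Both are kept, independently selectable (`test_distribution`,
`ci_distribution`). The normal reference is *anticonservative* at the scale
of typical collections: when the $v_i$ are small relative to $\tau^2$ —
exactly the regime of well-measured arrays with real between-study
heterogeneity — $\hat\mu/s_{\hat\mu}$ is t-distributed with $K-1$ degrees of
freedom under the null, so a normal p-value at $K=8$ understates the tail by
a factor of several at genome-wide thresholds, and BH adjustment then no
longer controls the false discovery rate (the calibration stage of the
analysis workflow measures a realized FDP of roughly three times the nominal
level under the normal reference, and control restored under the matched t
reference). The package default remains the normal reference for fidelity to
the published method; the calibration studies and the acceptance script use
`test_distribution = "student_t"`, the configuration whose FDR-control claim
is actually true at small $K$. No Knapp–Hartung adjustment is applied
anywhere, since the synthesized method does not use it.

## Meta-regression

Each moderator is fitted separately (plant part; stress method) as a
per-gene mixed-effects regression $y_i = X_i\beta + \sigma_i + e_i$ with
*cell-means (no-intercept) coding*: one indicator column per level, so each
coefficient is directly the mean true effect of its level. For plant part
the levels are root and shoot, with seedling contrasts excluded; for method
the levels are water withholding, mannitol and deracination, with PEG
contrasts excluded. Residual heterogeneity uses the moderator-adjusted
(generalized) DL estimator by default — the published choice for the
regression — with REML available.

**The moderator test.** $Q_M$ is a Wald chi-square. Two conventions are
implemented because the natural omnibus test of a no-intercept model ("some
coefficient differs from zero", $m$ degrees of freedom) is not the test with
$m-1$ degrees of freedom that the published description names. The default,
`qm_df_convention = "m_minus_1"`, tests *equality of the level means* — the
scientifically relevant question "does the moderator change the response",
with the printed $m-1$ degrees of freedom; `"m"` gives the omnibus variant.
With one-hot designs the coefficients are independent and the equality test
reduces to the familiar heterogeneity-of-means chi-square.

The $\chi^2$ reference for $Q_M$ is asymptotic in the number of contrasts.
At a ten-contrast roster the test is anticonservative (the calibration stage
measures a type-I rate of roughly twice nominal at 0.05, driven by the
estimated $\tau^2$ in the denominator and the small per-level counts); at 80
balanced contrasts the p-values are uniform to the sensitivity of a
2000-gene KS test. Calibration of the implementation is therefore assessed
in the large-roster regime, and moderator p-values from small rosters should
be read as approximate.

**Labels.** Genes whose FDR-adjusted $Q_M$ is significant are labeled from
the signs and per-level FDR-adjusted significance of their level means:
`sign_reversal` (up in one level, down in another), `level_specific`
(exactly one significant level), `magnitude_difference` otherwise. These
rules are this package's own post-hoc convention, documented rather than
asserted as the original classification.

## Per-study moderated t-tests

The comparison baseline tests each gene within each contrast with an
empirical-Bayes moderated t: gene-wise residual variances $s^2_g$ (pooled
two-arm, $d = n_1+n_2-2$ df) are shrunk toward a genome-wide prior
$s_0^2$ with prior degrees of freedom $d_0$,

$$s^2_{post} = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
t_g = \frac{\bar Y_1 - \bar Y_2}{\sqrt{s^2_{post}(1/n_1 + 1/n_2)}}
\sim t_{d + d_0}.$$

$(d_0, s_0^2)$ are estimated by the method of moments on
$\log s^2_g$ under the scaled-F marginal model, inverting the trigamma
function by Newton iteration. When the spread of log variances does not
exceed what sampling alone implies, $d_0 = \infty$ (complete pooling) — the
generator's constant-noise data land in this branch by design, and the
limits $d_0 \to 0$ (ordinary t) and $d_0 \to \infty$ are exposed for
testing via `prior_df_override`. A genome of all-zero residual variances
makes the prior inestimable; the tests then fall back to ordinary t with a
warning. A contrast that yields zero discoveries is a legitimate outcome,
not an error. FDR adjustment is applied separately per analysis family:
genome-wide for the meta-analysis, per moderator for the meta-regressions,
per contrast for the t-tests.

## Filters

Before any statistics, probe sets must (i) reach a raw fluorescence of 100
— i.e. $\log_2 I \ge \log_2 100 \approx 6.64$ — in at least 10% of all
pooled samples, and (ii) show an interquartile range of at least 0.5 log2
units across all pooled arrays. The published phrase "log2 fluorescence
intensity of 100" is ambiguous; a log2 *value* of 100 is physically
impossible for array data, so the raw-scale reading is the default and the
literal log2-scale reading is available (`intensity_scale =
"log2_literal"`). Quantiles use the linear-interpolation (type 7)
convention so tie behavior is fully determined and the worked examples are
exact.

## The synthetic generator

`simulate_collection()` emulates the structure of a ten-study ATH1
water-stress collection (the default roster: two root studies, one
PEG-stressed seedling study, one deracination study, the rest shoot tissue;
3+3 replicates with two 2+2 studies, 56 arrays in all), so the exclusion
logic of both moderator models is exercised out of the box. Per gene: a
null indicator (80% nulls by default), a mean effect
$\mu_g \sim N(0, 0.5^2)$ for non-nulls, study-level true effects
$\theta_{gs} = \mu_g + \text{shift}(s) + N(0, \tau^2)$ with $\tau^2 = 0.05$,
and a log2 baseline $N(8, 0.8^2)$. Replicates are normal with sd 0.25
around the batch-shifted baseline (batch sd 0.2, equal in both arms so it
cancels in the expected effect; an arm-asymmetric option exists for
robustness checks); treated arms are placed at
$(\text{baseline}+\text{batch})\,e^{\theta}$ so the expected log expression
ratio equals $\theta$ exactly. The effect-size, null-fraction and
heterogeneity values are the calibration conditions this package is
evaluated under; the baseline and noise values were chosen once as
realistic for GCRMA-scale data and sit comfortably above the intensity
filter. Part moderation uses an opposing construction (+$\delta_g$ in
roots, $-\delta_g$ in shoots, so the genome-wide mean effect stays
centred); method moderation draws independent per-level shifts. Genes whose
implied treated mean would be nonpositive are redrawn and counted.

What the generator does *not* emulate: probe-level effects and
normalization artifacts, cross-hybridization, correlation between genes,
heavy-tailed replicate noise, or time-course structure. Calibration results
on this generator therefore validate the estimators and the pipeline
plumbing under the assumed model; they do not certify behavior under model
misspecification on real arrays.

## Problem sizes and numerical conventions

The calibration studies use 2000 genes per collection — large enough that a
Kolmogorov–Smirnov uniformity check and FDP averages are informative, small
enough that the whole suite runs in well under a minute per study. FDP
control is averaged over 20 replicate collections of 8 studies; coverage
uses directly simulated study-level effects with $v_i \in [0.01, 0.1]$.
Orderings break ties by gene identifier under C collation, so results are
locale-independent. Result tables are written as TSV at full double
precision and round-trip exactly to at least 12 significant digits.

## Known limitations

* The pseudo-independence of multi-tissue contrasts from one study
  understates within-study correlation; $\tau^2$ absorbs what a multivariate
  model would decompose.
* The normal test reference (the default, for fidelity) does not control
  FDR at small $K$; use `test_distribution = "student_t"` when control
  matters more than replication of the published convention.
* $Q_M$ p-values from rosters of ten contrasts are approximate
  (anticonservative); treat borderline moderation calls accordingly.
* Moderators are fitted one at a time; a joint design matrix is accepted by
  the machinery but has no calibration study behind it.
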