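---
title: "Methods: model-averaged RADS and the M4I combiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-averaged RADS and the M4I combiner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsmmi)
```

## The risk model

RADS — the radiation attributed decrease of survival — answers: given
survival to attained age $a$, what is the cumulative probability that a
radiation-attributed solid cancer has occurred? It is built from the
excess hazard

$$h(a, e, D) = \frac{w_{ERR}\,ERR(D,a,e)\,m(a) + w_{EAR}\,EAR(D,a,e)/10^4}{DDREF},$$

its integral $H(a\mid e, D) = \int_{e+l}^{a} h(u,e,D)\,du$, and the
transform $RADS = 1 - \exp(-H)$. The construction deliberately avoids
population life tables and competing-risk adjustments (as REID/REIC use);
only the baseline incidence rates $m(a)$ enter, which keeps the number of
transferred population quantities small.

Assumptions worth keeping in view:

* **Risk transfer.** The 0.5/0.5 split between multiplicative (ERR) and
  additive (EAR) transfer follows ICRP (2007) for all solid cancer; no
  uncertainty is attached to these weights, nor to DDREF or the neutron
  RBE — they are treated as fixed protection-system conventions.
* **Dose metric.** Doses are weighted colon doses (gamma + 10 × neutron,
  the Life Span Study convention). Mission doses of 0.17 Sv (lunar) and
  1 Sv (Mars) are treated numerically as this weighted dose; translating
  space-radiation quality factors into organ dose equivalents is out of
  scope here.
* **Small-hazard reading.** At mission doses $H \ll 1$, so
  $|RADS - H| \le H^2/2$ is tiny and RADS is nearly the integrated
  excess risk itself; the package asserts this bound as a test property.

## Candidate excess-risk models and model averaging

Eight published all-solid-cancer dose–response families are supported,
each in an ERR and an EAR variant with its own coefficients: BEIR VII
(sex-specific dose slopes, exposure-age transform active below age 30,
power-law attained-age modifier), Grant linear and linear–quadratic and
Preston linear (log-linear modifiers in exposure age and attained age, a
high-kerma indicator above 4 Gy, a $(1+\sigma s)$ sex factor), INWORKS
linear and linear–quadratic (piecewise attained-age coefficient with
breaks at 60 and 80 years), and UNSCEAR linear and linear–quadratic
(time-since-exposure and attained-age log-modifiers, $\exp(\sigma s)$ sex
factor). Sex is coded $s = -1$ (male), $+1$ (female) — the symmetric
convention common in LSS modelling; the source table does not state the
coding, and a 0/1 convention cannot be excluded, which users can emulate
by rescaling $\sigma$ and the dose coefficient.

Model averaging uses information-criterion weights
$w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ on the excess-risk
scale, per evaluation point. Two criteria (AIC, BIC) crossed with two
baseline-fitting conventions ("original" published baselines vs a common
"same" parametric baseline) give four method-level weight sets. The
packaged weight files under `inst/extdata/weights/` transcribe published
weights whose typeset column alignment is not fully unambiguous; they
are one consistent sum-to-one interpretation, shipped as editable
configuration rather than constants, and the test suite relies only on
the unambiguous anchors (BIC/original concentrated on the linear Grant
model; AIC/same split between the two UNSCEAR forms) plus synthetic
weight sets.

## Numerical choices

* **Quadrature.** Trapezoidal rule on a uniform age grid (default step
  1 year; the attained age is always included as a final, possibly
  shorter, step). Exact for piecewise-linear integrands, which also makes
  the test oracles closed-form; halving the step moves synthetic RADS
  values by less than $10^{-6}$.
* **Baseline interpolation.** Rate files carry per-100,000-person-year
  rates; conversion to per-person-year fractions happens once, at load.
  Age bands are `[start, next start)`; rates attach to band midpoints,
  are linearly interpolated between them and held flat beyond the table
  edges. A table that does not nominally span the integration range is a
  data error naming the missing ages.
* **DDREF grouping.** The published hazard formula's typesetting leaves
  ambiguous whether DDREF divides the whole bracketed sum or only the
  EAR term. The default divides the whole sum; `ddref_scope =
  "ear_only"` selects the alternative. At DDREF = 2 the choice rescales
  the ERR contribution by a factor 2, so it matters more than most
  settings.
* **Latency.** The latency $l$ is part of the method definition but has
  no published value in the source analysis; the default is 5 years, the
  conventional solid-cancer choice. It is prominently configurable
  (`rads_settings(latency = ...)`) because it directly truncates the
  integration window.
* **Degenerate inputs.** Zero dose gives exactly zero excess risk for
  every family; an empty integration window ($a \le e + l$) gives
  $H = 0$; UNSCEAR families reject non-positive time since exposure
  (logarithm of $(a-e)/40$).

## Monte Carlo uncertainty

Method-level 95% CIs come from Monte Carlo simulation (default 1000
realisations). Each realisation resamples every model's coefficient
vector from its asymptotic multivariate normal distribution
(`MASS::mvrnorm` with the model's covariance matrix) and Poisson-resamples
each baseline cell with a 100,000 person-year denominator (the
denominators behind registry rates are not published; 100,000 matches the
rate unit and is configurable). Draws are untruncated — a draw can turn a
risk coefficient negative — and the resulting negative excess hazards are
floored at zero per age step, with the flooring rate recorded on the
estimate. Models are resampled independently of one another, and the ERR
and EAR variants of a family independently, because no cross-model or
cross-endpoint covariances are available.

The interval is the 2.5th/97.5th percentile of the realisations; the
point estimate is the plug-in value at the mean coefficients (the source
does not state its estimator; plug-in keeps the point independent of the
simulation size). A single random stream per run is seeded from
`rads_settings(seed = ...)`, with coefficient draws first (registry
order) and baseline draws second (cells age-major, male before female),
so identical settings give bit-identical results.

## The M4I combiner

The four method-level estimates are combined by a weighted mean (equal
weights $v_k = 1/4$ by default) with Gaussian error propagation,
$\sigma = \sqrt{\sum_k v_k^2 \sigma_k^2}$, and a CI of
$\pm 1.96\sigma$ truncated to $[0, 1)$. Equal weights reproduce the
published general estimates exactly after two-decimal rounding, and no
unique alternative construction of criterion-dependent weights exists;
non-equal weights remain available. Method-level $\sigma_k$ defaults to
the Monte Carlo standard deviation of each method's realisations; when
replaying printed tables, the CI half-width divided by 1.96 is used
instead. The independence assumption across methods is an approximation
— all four derive from the same cohort — so the combined CI should be
read as indicative. Reproducing the published combined CIs exactly is
not attempted: the $\sigma$ inputs used there (internal Monte Carlo
standard deviations) are not recoverable from the printed tables.

## What the synthetic generator does and does not emulate

`synth_model_registry()` replaces fitting by calibration: every family's
sex-averaged excess risk at the reference covariates (1 Gy, exposure age
30, attained age 70 — the centering used when the original models were
fitted) is set exactly to a target scale, with fixed, field-plausible
effect-modifier values. Defaults were chosen once, as realistic orders
of magnitude: `err_scale = 0.5`/Gy and `ear_scale = 50` per 10⁴ PY/Gy
(the magnitude of LSS all-solid-cancer estimates), coefficient relative
standard deviation 0.2, common correlation 0.3 (covariances are
$\sigma\sigma^\top \circ R$, positive semi-definite by construction), and
a Gompertz-like baseline reaching a sex-averaged 3000 per 10⁵ PY at age
85 with a ±10% sex split. With these defaults a lunar-mission profile
lands at a RADS of a few tenths of a percent — the right order of
magnitude relative to the published method estimates.

The generator emulates the *structure* of the real inputs — eight
calibrated families per endpoint, monotone age-increasing baselines,
interchangeable file formats — not the statistics of real registries or
the actual fitted coefficients and covariances. Passing tests therefore
demonstrate correctness of the pipeline's arithmetic, invariants and
uncertainty propagation, not agreement of method-level RADS values with
the published per-mission table, which would require the unpublished
coefficient sets and the real European baseline average.

## Problem sizes used by the test suite

The suite runs end-to-end at the study's own scale where that is cheap —
the full pipeline test uses all six scenarios at 1000 realisations — and
at reduced scale where repetition dominates: most Monte Carlo unit tests
use 100–400 realisations, the moment checks 10,000 draws, and the
coverage study 500 trials of 10,000 realisations each with baseline
resampling disabled (the synthetic truth perturbs coefficients only, so
coefficient-only intervals are the construction whose coverage is
nominally 95%).

## Known limitations

* Endpoint scope is all-solid-cancer incidence; leukaemia (where model
  choice likely matters more), mortality endpoints, and REID/REIC-style
  competing-risk measures are out of scope.
* Only linear and linear–quadratic dose responses are represented.
* The M4I CI inherits the cross-method independence approximation.
* Space-radiation quality factors and organ dose equivalents are not
  modelled; doses enter as LSS-weighted colon dose.
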