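---
title: "Memory chain models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory chain models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorychain)
```

## The model

A memory for an item is represented by a collection of redundant *traces*
distributed over a chain of stores (working memory, hippocampus/medial
temporal lobe, neocortex). Two assumptions define the dynamics at every
time scale:

1. trace intensity in a store declines at a constant rate, and
2. while traces survive, they induce traces in the next, slower store.

Writing `r_i(t)` for the expected trace count (*intensity*) of store *i*
at memory age `t`, the cascade is linear:

$$ r_1'(t) = -a_1 r_1(t), \quad r_1(0) = \mu_1; \qquad
   r_i'(t) = \mu_i\, r_{i-1}(t) - a_i r_i(t), \quad r_i(0) = 0 \;(i>1). $$

Retrieval searches the stores with cue quality `q`; finding any single
trace suffices, and under Poisson-distributed trace counts the recall
probability is

$$ p(t) = 1 - e^{-q\, r(t)}, \qquad r(t) = \sum_i r_i(t). $$

With distinct decline rates the cascade has the classic
sequential-first-order-kinetics solution (a sum of exponentials); for the
workhorse two-store case with negligible neocortical decline
(`a2 = 0`),

$$ r_1(t) = \mu_1 e^{-a_1 t}, \qquad
   r_2(t) = \frac{\mu_1\mu_2}{a_1}\left(1 - e^{-a_1 t}\right). $$

### Parameters and units

| parameter | meaning | units | default bounds in fitting |
|---|---|---|---|
| `mu1` | intensity acquired per learning episode | traces | [0, 100] |
| `mu_i`, i>1 | induction (consolidation) rate into store i | 1/time per unit donor intensity | [0, 100] |
| `a_i` | decline rate of store i | 1/time | [0, 10] |
| `q` | cue quality | dimensionless, >0 | fixed (default 1) |
| `g` | guessing floor | probability | fixed (default 0) |
| `lambda_i` | fraction of store-i intensity destroyed | fraction | [0, 1] |
| induction scale | multiplier on `mu_i` (functional lesion) | fraction | [0, 1] |
| retrieval scale | multiplier on `q` (retrieval deficit) | fraction | (0, 1] |

Time is always the dataset's own unit (seconds, days, years); the package
never converts. The expected lifetime of a single MTL trace is `1/a1` in
that unit.

The guessing floor `g` is an extension beyond the bare link
`p = 1 - e^{-r}`: recognition tasks have chance levels of 1/4, 1/3 or 1/2,
and `p = g + (1-g)(1-e^{-r})` folds that floor in. The default `g = 0`
keeps the canonical equations as the default behaviour, because published
parameter values were obtained without an explicit chance correction.
Cue quality multiplies the chain total once (acquisition x decline x cue),
not per store.

## Lesions and pathologies

A `lesion_profile()` carries three mechanisms, reflecting how the model is
used across analyses:

* **intensity lesion** `lambda_i`: destroys a fraction of store *i*'s
  surviving traces at lesion time — the retrograde mechanism. The Ribot
  gradient is the lesioned retention curve; with `lambda_1 = 1`, `a2 = 0`
  it is `1 - \exp(-(\mu_1\mu_2/a_1)(1 - e^{-a_1 t}))`, increasing in
  memory age (Ribot's Law).
* **induction scaling**: reduces `mu_i` — the anterograde mechanism
  (e.g. a damaged working-memory-to-MTL pathway); the *functional lesion
  size* is reported as `1 - scale`.
* **retrieval scaling**: reduces cue quality — a pure retrieval deficit.

Named profiles encode standard clinical hypotheses: Korsakoff (partial
store-1 lesion), Alzheimer (store-1 lesion plus `(1-\lambda_2) r_2(t)`),
Huntington (intact storage, scaled retrieval). Lesions are "at test" by
default: after a lesion only the final store's decline applies
(`post_lesion_decay()`), and in the fitted data post-lesion forgetting is
treated as negligible.

The lesion fraction is purely functional — it need not coincide with
lesioned tissue volume and can vary with task difficulty.

## The relative retrograde gradient

Clinical tests of retrograde amnesia deliberately make remote-period items
easier, which distorts the shape of both the patient and control curves.
Because the cascade is linear in `mu1` and `q` multiplies the total, the
*intensity ratio*

$$ rr(t) = \frac{-\ln(1-p_{\text{lesioned}}(t))}{-\ln(1-p_{\text{control}}(t))} $$

cancels both, so any per-time-point difficulty manipulation applied to both
groups leaves it unchanged — a ratio of raw probabilities does not have
this property. The model curve rises from the ordinate intercept
`1 - lambda_1` (retrieval-scaled) toward 1; a pure retrieval deficit gives
a flat gradient at `q_H`.

Numerical choices: observed proportions of exactly 1 are clipped to
`1 - 1/(2n)` before the log transform (a standard continuity correction;
strict mode errors instead); points with zero control intensity are
dropped with a warning; empirical rr is computed from aggregate proportions
per time point, not per subject. Near floor or ceiling the transform
amplifies noise — no variance-stabilising weighting is applied, since none
is canonical.

## Repeated learning

Because the cascade is linear, intensities from separate learning episodes
superpose exactly: `accumulated_intensity()` sums the full-chain intensity
at each episode's lag, and with `mu2 = 0` reduces to the sum
`r_1(\text{lag}_1) + r_1(\text{lag}_2) + \dots`. A massed block of trials
is represented by an effective trial count (`massed_factor`) scaling that
episode's acquired intensity before decline — the only placement consistent
with "eight massed shocks as effective as 3.34 spaced ones". Learning
saturation is deliberately out of scope; superposition is exact here and
the package documents it as such.

## Fitting

`fit_memory_chain()` minimises, by default, the unweighted sum of squared
errors between observed proportions and model probabilities, pooled over
all groups fitted simultaneously; chain parameters are shared across
groups and lesion parameters may be free per group or shared across a
declared set. A binomial log-likelihood loss is available (published fits
report SSE and `R^2` but not the objective, so least squares on
proportions is the default). `R^2` is pooled: `1 - SSE/SST` with `SST`
about the grand mean of all fitted points — chosen because a single `R^2`
is conventionally reported per multi-curve fit; it is not a per-curve
average.

The optimiser is `nlminb` (bounded quasi-Newton) launched from a
latin-hypercube of starting points (default 32, seeded, hence bit-identical
results per seed). Rate parameters (`mu`, `a`) are drawn log-uniformly over
their bounds because their plausible values span decades (consolidation
rates of 0.001 to learning intensities of 5); fractions are drawn
uniformly. Estimates landing at a bound are flagged and a degeneracy
warning is raised — a temporally flat dataset, for example, identifies
only the combination `mu1 mu2 / a1`, not the rates separately.
Under-identified specifications (free parameters >= data points) error
before optimisation. The Pearson chi-square
`sum n_i (o_i - p_i)^2 / (p_i(1-p_i))` with `points - free` degrees of
freedom is reported alongside SSE/`R^2`; it grows more severe with trial
counts, which matters for high-n retention curves.

`fit_rr()` fits the model rr-gradient directly; `mu1` and `q` are
structurally absent from its objective (they cancel), so the estimable
parameters are `a1`, `mu2` and the lesion fractions. A flat fitted
gradient is flagged: the decline rate is then unidentifiable and the
curve is the retrieval-deficit signature.

## Numerical choices

* **Closed forms vs integration.** Exponential chains use the
  distinct-rate sum-of-exponentials solution. When two decline rates agree
  to within `1e-9` (relatively), that form divides by a vanishing rate
  difference, and the package switches to `lsoda` integration at
  `rtol = 1e-12`, `atol = 1e-14` — which also serves, via `ode_oracle()`,
  as the independent verification path for the closed forms (agreement to
  better than `1e-8` relative to the solution scale; component-wise
  relative error on near-zero intensities is not certifiable by any
  finite-tolerance integrator and is not claimed).
* **Power decline.** The alternative store-1 decline is
  `r_1(t) = mu1 (1+t)^{-a1}` — finite at `t = 0`, with the exponent as the
  shape parameter; downstream stores are computed by adaptive quadrature of
  the induction convolution. The exact functional form of a power decline
  is a documented package choice (only the decline *family* is canonical);
  it applies to store 1, where the decline function matters for the
  retrograde analyses, and higher stores remain exponential.
* **rr at t = 0.** Both intensities vanish at `t = 0`; `rr_model()`
  returns the analytic limit `retrieval * induction_1 * (1 - lambda_1)`.

## The synthetic-data generator

`simulate_retention()` draws `Binomial(n, p(t))` counts per point from the
exact model probabilities of each group's chain, optionally after
per-time-point difficulty multipliers on `mu1` (applied identically to all
groups, emulating non-counterbalanced items). It emulates the sampling
noise of retention experiments; it does *not* emulate subject-level
heterogeneity, item-level correlation, session effects, or drop-out — so
passing recovery tests show estimator correctness under binomial sampling,
not robustness to those real-data features.

The parameter-recovery study in the acceptance tests uses a published
two-store configuration (`mu1 = 1.5`, `a1 = 0.103`, `mu2 = 0.00325`,
`a2 = 0`, full lesion) at 4 log-spaced lags spanning the study's printed
3.5–56 day range, two groups (8 points), 30 trials per point and 200
replicates; the median estimate across replicates is required to land
within 15% of truth. At `n = 30` the lesioned curve carries only a few
expected successes in total, so individual-replicate errors on `mu2` are
intrinsically large (a Fisher-information floor near 25%); the median
estimate is nearly unbiased, which is the property the recovery study
checks. The original studies' `R^2` values are not reproducible because
their raw data points were published only as figures.

## The trace-level simulator

`simulate_traces()` is the package's internal-consistency bridge between
the trace narrative and the closed forms: it simulates the trace process
by exact event-time sampling (no time stepping) and compares recall
frequency with `1 - e^{-q r(t)}`.

Two induction mechanisms are provided, and the distinction is substantive:

* `"poisson"` (default): every store is a Poisson point process. Store-1
  counts are `Poisson(mu1)` with independent survival; store-2 formation
  is an inhomogeneous Poisson process whose rate follows the donor
  intensity, simulated exactly by thinning a homogeneous
  `mu1 mu2`-rate process against the store-1 survival law and the store-2
  survival to `t`. Only the primitive rates and survival laws enter —
  never the cascade solution — so agreement with the closed forms is a
  genuine check. Poisson counts are the unique distribution for which
  `P(\ge 1 \text{ trace}) = 1 - e^{-\text{intensity}}` holds exactly under
  superposition and thinning, so cue quality and intensity lesions are
  implemented as independent thinning.
* `"branching"`: each individual store-1 trace spawns store-2 traces at
  rate `mu2` while it lives. The means are identical, but parent–child
  clustering overdisperses the store-2 count (a Poisson *cluster* process),
  and recall frequency then falls measurably below `1 - e^{-r}` whenever
  `mu2/a1` is not small. The package treats the Poisson-flow reading as
  the one consistent with the exponential recall law, and keeps the
  branching variant because the difference is a testable prediction about
  what "traces generate traces" must mean for the law to hold.

The simulator covers one- and two-store chains (the configurations used in
the analyses); deeper chains would need the donor intensity of
intermediate stores as a thinning envelope, which would reintroduce the
closed forms and defeat the purpose.

## Problem sizes used in the test suite

Oracle-agreement properties run on 50 random two- and three-store chains;
the trace simulator is checked at `1e5` replicates on a 12-point grid of
published-scale parameters; the recovery study runs 200 replicate fits
with 8 multistarts each. These sizes give Monte-Carlo standard errors
small enough for the stated tolerances while keeping the default test run
brief.

## Known limitations

* No learning saturation or spacing effects: superposition is exact by
  construction.
* The rr transform amplifies noise near floor/ceiling; no
  variance-stabilising weighting is offered.
* Bootstrap confidence intervals are not built in; `simulate()` on a fit
  provides the parametric resampling primitive.
* Lesion fractions are functional quantities, not anatomical volumes.
* The power-decline cascade relies on quadrature and is slower than the
  exponential closed forms; it is provided for decline-shape robustness
  checks rather than large fitting campaigns.
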