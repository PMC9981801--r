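---
title: "Models and methods behind glycorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycorisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorisk)
```

`glycorisk` assembles four statistical components of a diabetes risk
evaluation system — longitudinal record aggregation, a calibrated margin
classifier, pedigree genetic coefficients, and an RBM glucose
forecaster — plus the rule-based clinical classifications that surround
them. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where the design was genuinely
open. Nothing here claims an empirical result beyond what the package's
own tests and `scripts/acceptance.R` compute.

## Decay-weighted record aggregation

A patient's history is the set of sub-records $(k_b, f_b)$,
$b = 1,\dots,l$, ordered by timestamp. The aggregation weight of the
record at rank offset $b$ (0 = most recent) is

$$Ph_b = \frac{e^{-\alpha b}}{\sum_{k=0}^{l-1} e^{-\alpha k}},$$

and the risk input is $x = \sum_{b=1}^{l} Ph_{\,l-b}\, f_b$. The index
shift means the newest record receives $Ph_0$, the largest weight; this
orientation is deliberate and documented because the rank subscripts
admit either reading. Two further choices:

* **Decay is per record rank, not per elapsed day.** The kernel depends
  only on the order of records; calendar-aware decay is out of scope.
  `decay_weights()` therefore needs only $l$ and $\alpha$.
* **$\alpha$ (config key `decay_rate`, CLI `--alpha`)** is unitless per
  rank step, default 0.5. $\alpha = 0$ recovers the arithmetic mean;
  $\alpha = \ln 2$ halves a record's weight per step. Weights always
  sum to 1, so adding a constant to every record adds exactly that
  constant to $x$ (translation equivariance — one of the property
  tests). In double precision $e^{-\alpha b}$ underflows to zero once
  $\alpha b \gtrsim 745$; the normalization is unaffected, but strict
  positivity of the tail weights is only meaningful inside that range.

Records with tied timestamps keep input order (stable sort). Missing
feature values are rejected rather than imputed.

## Margin classifier and the Diabetes Index

The classifier is the standard soft-margin linear machine
$$\min_{r,g,\zeta}\ \tfrac12 r^\top r + C\sum_a \zeta_a
\quad\text{s.t.}\quad y_a(r\cdot x_a + g) \ge 1-\zeta_a,\ \zeta_a \ge 0,$$
with the identity feature map: no kernel is specified by the design, and
the primal is stated in linear form, so the linear machine is the
faithful choice. `train_classifier()` solves the dual by sequential
minimal optimization with maximal-violating-pair working-set selection
and the analytic two-variable update, stopping when the KKT violation
gap falls below `tol` (default `1e-8`, giving primal–dual gaps around
`1e-7` on the small problems the package targets). The bias is the
midpoint of the converged KKT interval (equivalently the mean of
$y_a - r\cdot x_a$ over free support vectors). The test suite checks the
achieved primal objective against a generic quadratic-programming
solver (`kernlab::ipop`) to within $10^{-4}$ relative.

Decision values are mapped to the Diabetes Index
$$DI(x) = \frac{1}{1+\exp(S\,d(x)+F)} \in [0,1]$$
by maximizing the Bernoulli likelihood of $(S, F)$. Three details:

* **Sign convention.** $S$ is fitted freely; with the usual geometry
  (larger $d$ means the positive class) the fit lands on $S < 0$. The
  code never hard-codes the sign.
* **Smoothed targets.** Targets are $(N_+ + 1)/(N_+ + 2)$ for positives
  and $1/(N_- + 2)$ for negatives, the standard sigmoid-calibration
  smoothing; it keeps $(S, F)$ finite on perfectly separated data.
* **Out-of-fold fitting.** `fit_risk_model()` fits the calibration on
  decision values produced by 3-fold cross-training (round-robin fold
  assignment, deterministic), avoiding the optimism of in-sample
  calibration. The final classifier is refit on all training data.

The optimizer is BFGS with the analytic gradient and a tight relative
tolerance; an IRLS fit (`glm`, quasibinomial) on the same smoothed
targets reproduces the parameters to $10^{-6}$ in the tests. No DI
decision threshold is built in — the index is reported as a
probability.

## Pedigree genetic coefficients

For members in a direct line of descent,
$k(X,Y) = (1/2)^M$ with $M$ the number of parent–child links between
them, so parent–child = 1/2 and $k(X,X) = 1$. For collateral relatives
the coefficient sums over the most-recent common ancestors $N_i$ — the
common ancestors none of whose descendants are also common ancestors —
$$k(X,Y) = \sum_i k(X,N_i)\,k(Y,N_i),$$
which gives the two-term form (both parents) for full siblings: $1/4 +
1/4 = 1/2$. The implementation sums over however many MRCAs exist
rather than exactly two, which reduces to the sibling case and extends
correctly to half-siblings (one term). An invariant test verifies on
every generated pedigree up to four generations that this equals the
classic path-counting rule: the sum of $(1/2)^{\text{path length}}$
over all up-then-down ancestor paths whose legs share only the peak.

Inbred pedigrees (any member whose parents share a common ancestor) are
rejected at construction, because with overlapping ancestral paths the
MRCA form stops being well defined; identity-by-descent corrections are
a non-goal. Familial risk of a proband $R$ is defined as the plain sum
of $k(R,P)$ over affected relatives $P \ne R$ — the aggregation over
"diabetes-positive family members" is stated but never given a formula
in the design, so the minimal additive reading was chosen and is
documented here. No rule combines familial risk with the Diabetes
Index; the pipeline reports them side by side.

## RBM glucose model

The forecaster is a restricted Boltzmann machine over $m$ visible and
$n_h$ hidden binary units with energy
$$E(z,x) = -\sum_i b_i z_i - \sum_j c_j x_j - \sum_{i,j} z_i W_{ij} x_j$$
and Boltzmann joint $T(z,x) = e^{-E}/B(\theta)$. The conditionals are
the standard logistic forms
$P(x_j{=}1\mid z) = \sigma(c_j + \sum_i z_i W_{ij})$ and
$P(z_i{=}1\mid x) = \sigma(b_i + \sum_j W_{ij} x_j)$ — the hidden units
use the hidden bias and the visible units the visible bias, the pairing
fixed unambiguously by the energy. `partition_function()` enumerates
$B(\theta)$ exactly (guarded at $m+n_h \le 20$) and exists purely as a
test oracle: the suite verifies that the enumerated joint normalizes
and that both conditionals match enumeration to $10^{-10}$ on random
small machines, and that CD training does not decrease the exact
log-likelihood on data sampled from a planted 10-unit machine.

**Continuous glucose bridge.** Glucose in mmol/L is mapped to $[0,1]$
by a per-series min–max encoding (range padded by 5%, or by ±0.5
mmol/L for a constant series, so the map is always invertible) and
treated as Bernoulli mean-activations: the machine is binary, the data
are continuous, and this is the minimal faithful bridge.
Gaussian-Bernoulli units are a non-goal.

**Training.** Sliding windows of `lag` past values plus one target form
the visible layer ($m = \text{lag}+1$). Contrastive divergence CD-k
(default $k{=}1$) with mini-batches of 16, weights initialized
$N(0, 0.01^2)$, biases 0, fixed learning rate; hidden states are
sampled binary along the chain, visible reconstructions use means.
Training is fully seeded and reproducible.

**Forecasting.** Each step clamps the lag units to the encoded recent
values and reconstructs the single free target unit. Because exactly
one visible unit is free, its conditional under the model is exactly
computable by summing out the hidden layer:
$$\operatorname{logit} P(z_m{=}1 \mid z_{\text{lags}}) = b_m +
\sum_j\big[\operatorname{softplus}(a_j + W_{mj}) -
\operatorname{softplus}(a_j)\big],\qquad
a_j = c_j + \sum_{i \in \text{lags}} z_i W_{ij}.$$
This exact conditional is the default forecast rule; an approximate
mean-field iteration (`method = "mean_field"`) is retained for
comparison. The choice matters: on clean sinusoidal traces the exact
conditional roughly halves the one-step error of mean-field
reconstruction, and it is what lets the forecaster beat a
last-value-carried-forward baseline in the skill tests. Both rules are
deterministic — no sampling happens at forecast time — so repeated
forecasts are identical and the RMSE
$\sqrt{\tfrac1n\sum_a (x_a - \hat x_a)^2}$ is stable. Multi-step
horizons roll forward on the model's own predictions; `forecast()`
withholds the final `horizon` values of the supplied series as the
actuals it scores against.

**Defaults.** `lag = 24`, `n_hidden = 64`, 500 epochs, learning rate
0.3. With the default synthetic trace (period 48 samples) a lag of half
a period is what identifies the phase of the oscillation; fewer lags
leave the conditional genuinely ambiguous.

## Clinical rules and survey statistics

The diagnosis rule is diabetic iff fasting glucose $\ge 7.0$ mmol/L or
2-hour postprandial $\ge 11.1$ mmol/L, boundaries inclusive, and is
monotone in both measurements. The elderly type-2 glycemic-control
table maps health status to an HbA1c ceiling and fasting/bedtime ranges
(7.5/8.0/8.5% ceilings; the source table's garbled unit headers are
read as mmol/L, consistent with the diagnosis thresholds). Trend
changes are plain percentage-point differences between two years;
proportions are tabulated as count/total × 100. Printed-style rounding
is half-away-from-zero to two decimals (`round_half_up()`), since base
`round()` rounds half to even. No age standardization, confidence
intervals or significance tests are attached — the survey statistics
are descriptive by design.

## Synthetic data: what it does and does not emulate

The generators provide the statistical structure the pipeline assumes,
not realistic electronic health records:

* **Cohorts.** Labels are Bernoulli(`positive_fraction`, default 0.3);
  each patient has 3–8 records at strictly increasing integer-day
  timestamps (gaps uniform on 1–7 days); features are i.i.d. Gaussian
  with standard deviation `noise_sd` around a class mean shifted by
  `effect_size`·`noise_sd` (default 3) for positives. Anonymous
  continuous indicators with a mean shift are the simplest structure
  that exercises the aggregation and classification path; there are no
  ICD codes, missingness mechanisms, or within-patient correlation
  structure, so passing tests demonstrate correctness of the machinery,
  not clinical performance.
* **Pedigrees.** Founder couples (default $\max(4, 2^{g-1})$ for $g$
  generations) each produce 2–3 children; children are paired into
  next-generation couples only if they share no common ancestor, so
  generated pedigrees are loop-free by construction, matching the
  MRCA formula's domain. Affected flags are i.i.d.
  Bernoulli(`affected_fraction`).
* **Traces.** `baseline + amplitude·sin(2πt/period) + N(0, noise_sd)`,
  truncated at 0. The defaults — 288 samples (one day at the 5-minute
  ambulatory sampling interval), baseline 8 mmol/L, amplitude 3, period
  48 samples (4-hour, postprandial-scale cycles), noise 0.3 — were
  chosen once as a plausible stylized day of continuous glucose
  monitoring. Real CGM traces have meal/activity asymmetries and sensor
  artifacts that a sinusoid does not capture.

All generators draw from a temporarily seeded RNG and restore the
caller's RNG state, so equal seeds give identical outputs and no global
state leaks.

## Numerical choices and degenerate inputs

* SMO: kernel rows computed on the fly (linear kernel, small $d$);
  curvature floored at $10^{-12}$ for degenerate pairs; iteration cap
  $\max(20000, 200m)$.
* Calibration: BFGS from $(0,0)$ with analytic gradient, relative
  tolerance $10^{-14}$; degenerate single-label inputs are errors.
* Single-record histories return the record itself; $\alpha = 0$
  returns the mean. Dimension mismatches and non-finite values are
  errors naming the offending record.
* Constant glucose series get a ±0.5 mmol/L encoding pad; horizon 0
  returns an empty forecast with `NA` RMSE; series shorter than
  `lag + horizon` are errors.
* Ties in `mrca_pair` cannot occur in loop-free pedigrees; unknown
  members raise lookup errors naming the member.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise the methods meaningfully while keeping a full
run fast on one CPU: cohorts of 500 patients (five seeds) for accuracy
recovery, pedigrees to four generations for the path-counting
equivalence, RBM oracle machines with $m+n_h \le 12$, and five
288-sample traces for forecast skill with 48 walk-forward one-step
predictions each.

## Known limitations

* The linear classifier has no kernel, class weighting, or feature
  selection; strongly non-linear class boundaries will underfit.
* The Bernoulli-mean bridge quantizes continuous glucose; very
  low-amplitude variation within a wide encoding range is forecast
  coarsely.
* Familial risk is an unnormalized sum: it grows with family size and
  is not a probability.
* The MRCA formula excludes inbred pedigrees by design.
* Multi-step forecasts compound one-step errors; no uncertainty
  intervals are attached.
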