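# glycorisk

Tools for population-scale diabetes risk evaluation from longitudinal
clinical records, family history and ambulatory glucose monitoring.
`glycorisk` is aimed at biostatisticians and epidemiological modellers
who need the pieces of such an evaluation system as reusable,
individually testable components, together with seeded synthetic data so
every analysis is reproducible without access to protected health
records.

## What it computes

**Decay-weighted risk inputs.** A patient's history is a time-ordered
set of sub-records (timestamp, indicator vector *f<sub>b</sub>*). Records
are collapsed into one fixed-length input with normalized exponential
decay weights

&nbsp;&nbsp;*Ph<sub>b</sub>* = e^(−α·b) / Σ<sub>k=0..l−1</sub> e^(−α·k),
&nbsp;&nbsp;*x* = Σ<sub>b=1..l</sub> *Ph<sub>l−b</sub>* · *f<sub>b</sub>*,

so the most recent record carries the largest weight and α ≥ 0 tunes how
fast older records fade (α = 0 is the plain mean).

**Diabetes Index.** A soft-margin linear classifier — minimize
½‖r‖² + C Σ ζ<sub>a</sub> subject to y<sub>a</sub>(r·x<sub>a</sub> + g) ≥
1 − ζ<sub>a</sub> — is trained by an SMO dual solver written in the
package. Decision values d(x) = r·x + g are converted to a calibrated
probability DI(x) = 1 / (1 + exp(S·d(x) + F)) ∈ [0, 1] by a
maximum-likelihood sigmoid fit with Platt-style target smoothing,
fitted on out-of-fold decision values.

**Pedigree genetic coefficients.** Along a direct line of descent the
coefficient is k(X,Y) = (1/2)^M for M generation steps (parent–child =
1/2); otherwise it is the sum over most-recent common ancestors N of
k(X,N)·k(Y,N) (full siblings = 1/2, first cousins = 1/8). Familial risk
of a proband is the sum of coefficients to all affected relatives.

**RBM glucose forecasting.** Glucose series (mmol/L) are min-max encoded
to [0, 1], cut into lag windows, and modelled by a restricted Boltzmann
machine with energy E(z,x) = −b·z − c·x − zᵀWx, trained by
contrastive divergence. Forecasts clamp the lag units and decode the
exact model conditional of the single free target unit; accuracy is
scored by RMSE. Exact enumeration of the partition function on tiny
machines backs the test suite.

**Clinical rules and survey statistics.** The diagnosis rule (fasting
≥ 7.0 or 2-h postprandial ≥ 11.1 mmol/L), the elderly type-2
glycemic-control target table, percentage-point trend changes,
proportion tabulations and age/sex structure tables.

## Worked example

```r
library(glycorisk)

co  <- generate_cohort(cohort_spec(n_patients = 200, effect_size = 3, seed = 1))
ri  <- cohort_risk_inputs(co, alpha = 0.5)
train <- seq_len(200) %% 2 == 1
fit <- fit_risk_model(ri$inputs[train, ], ri$labels[train], C = 1)
di  <- diabetes_index(fit$model, fit$calibration, ri$inputs)
cat(sprintf("held-out accuracy: %.3f\n",
            mean(ifelse(di[!train] >= 0.5, 1, -1) == ri$labels[!train])))
cat(sprintf("mean DI  positives: %.3f   negatives: %.3f\n",
            mean(di[ri$labels > 0]), mean(di[ri$labels < 0])))

ped <- generate_pedigree(3, affected_fraction = 0.4, seed = 7)
id  <- ped$members$id[nrow(ped$members)]
cat(sprintf("familial risk of %s: %.3f\n", id, familial_risk(ped, id)))

tr  <- generate_trace(trace_spec(seed = 2))
rbm <- fit_glucose_rbm(tr, seed = 2)
fc  <- forecast(rbm$params, rbm$encoding, tr, horizon = 12)
cat(sprintf("12-step forecast RMSE: %.3f mmol/L\n", fc$rmse))
```

Output:

```
held-out accuracy: 1.000
mean DI  positives: 0.957   negatives: 0.012
familial risk of I031: 1.875
12-step forecast RMSE: 0.332 mmol/L
```

At effect size 3 the two classes are well separated, so the held-out
half is classified perfectly and the calibrated Diabetes Index averages
0.96 for positives versus 0.01 for negatives. Member I031's familial
risk of 1.875 is the sum of relatedness coefficients to its affected
relatives (e.g. an affected parent contributes 0.5, an affected
grandparent 0.25). The 12-step forecast RMSE of 0.33 mmol/L is the
roll-forward error on the withheld tail of a noisy synthetic day of
5-minute glucose samples.

`run_pipeline(run_config(...))` chains all stages and writes a report
directory (`patient_scores.csv`, `familial_risk.csv`, `forecast.csv`,
serialized models, resolved config, summary); reports are byte-identical
across runs with the same seeds. A command-line front end with the same
surface lives at `inst/scripts/glycorisk`.

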