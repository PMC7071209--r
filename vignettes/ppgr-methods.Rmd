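---
title: "Methods: predicting postprandial glycemic responses from meals and CGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting postprandial glycemic responses from meals and CGM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules, the parameters that matter, what the synthetic data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The problem

In free-living conditions, the glucose excursion after a meal (the
postprandial glycemic response, PPGR) varies widely between people and
between meals. For pregnant women with gestational diabetes mellitus
(GDM), predicting the PPGR of a planned meal from its composition and the
patient's characteristics is the basis of personalized dietary advice. The
pipeline here links three noisy, independently collected data streams —
continuous glucose monitoring (CGM) at ~5-min sampling, an electronic food
diary, and a paper protocol of meal start times — into a per-meal design
matrix, and asks a specific scientific question: *does adding glycemic
index (GI) and glycemic load (GL) to meal macronutrients improve PPGR
prediction?*

## GI assignment and mixed-meal arithmetic

Each food receives a dietary GI by the first applicable of five rules:
a published GI; GI 0 when carbohydrate is below 5 g/100 g; the GI of a
close match; a food-subgroup mean; an expert default (0, 50, or a
nominated value). The rule that fired is kept as a provenance tag
(`gi_rule`); foods where no rule applies keep an undefined GI and their
meals are later removed by a record filter rather than guessed at.

For a dish or meal of several items, the GI is the carbohydrate-weighted
mean of item GIs and the GL accumulates item contributions:

$$gi = \frac{\sum_i gi_i\,carbo_i}{\sum_i carbo_i},
\qquad gl = \frac{1}{100}\sum_i gi_i\,carbo_i .$$

`carbo_i` is interpreted as *grams of carbohydrate contributed by item i
in the consumed portion*. A literal mass-fraction reading would make GL
dimensionally inconsistent with its conventional scale (a GL near 28 for
80 g of white bread, not 0.28) and incomparable to the `carbo` regressor.
Under this reading the identity $gl = gi \cdot carbo / 100$ holds exactly,
and the tests assert it to 1e-9. A meal with zero carbohydrate has GI 0 by
convention, the same convention as assignment rule 2 (the 0/0 case of the
weighted mean).

GIs are validated to [0, 150]: published values above 100 exist, and no
renormalization is applied.

## Record linkage and timing exclusions

Protocol meal starts are matched to the nearest diary meal by absolute
time difference, greedily in ascending difference so a contested diary
meal goes to the closer protocol entry; entries with no diary meal within
`max_gap_min` (default 60) are dropped. The cap is not part of the
nearest-record rule itself but prevents pathological cross-day matches.

Four rules then exclude meals whose reported start is implausible against
the glucose trace, evaluated in fixed order with first-match-wins
labeling, on interpolated glucose values:

* **late_report** — BG(t) − BG(t−60 min) > 1.0 mmol/L: the reported start
  sits on the rising flank or peak, i.e. the meal began earlier.
* **falling_edge** — BG(t) ≥ BG(t+30) + 0.5 and BG(t) ≤ BG(t−30) − 0.5.
* **prior_meal** — another matched meal start in the open interval
  (t−60, t).
* **subsequent_meal** — another matched meal start in (t, t+60).

Single-label exclusion (rather than multi-labeling) is implied by the
non-overlapping counts such studies report per rule. Neighbor checks in
rules 3–4 run over protocol-matched meal starts of the same patient,
including meals that are themselves excluded: interference is a property
of the timeline, not of record quality. Meals for which any required BG
value falls in a sensor gap (> 20 min between samples) or outside the
trace get the separate label `cgm_unavailable`.

Interpolation is linear; queries within 2.5 min (half the nominal sampling
interval) of the trace ends take the edge sample's value, accommodating
protocol times between samples.

## PPGR outcomes

For each kept meal at start $t$: BG0 = BG(t), BG60 = BG(t+60), BGMax =
maximum over [t, t+180] (raw samples plus interpolated window edges),
BGRise = BGMax − BG0, trapezoidal AUC60/AUC120, and incremental
iAUC60/iAUC120 above the BG0 baseline. The iAUC uses the
positive-increment convention of standard GI methodology: baseline
crossings of the piecewise-linear trace are inserted exactly and area
below baseline contributes zero. All areas are in mmol/L·h; time is
internally minutes.

Two filters then drop records: meals containing an undefined-GI item, and
"flat" responses to carbohydrate-rich meals — more than 40 g of
carbohydrate with a mean incremental rate below 0.3 mmol/L/h. The rate is
computed as iauc120 / 2 h, the only reading of a mmol/L/h threshold
against an iAUC-based outcome; an alternative (peak-rise rate) reading
exists but has the wrong units against the stated threshold. Patients
whose diaries show systematic misreporting are removed wholesale first:
every meal a single item, or strictly more than 5 meals with all weights
multiples of 100 g.

## Features and design matrix

Patient features are declared in a YAML spec (name, block, type, levels)
rather than hard-coded: numeric anthropometrics/biochemistry, obstetric
counts, binary history variables (passed through as 0/1 — equivalent to
dummy coding up to the reference level), and ordinal questionnaire items
(0/1/2) which are dummy-encoded like unordered categoricals, producing
columns named `variable_value` (e.g. `fruits_1`). Encoding uses the
*declared* level set, keeping the column roster identical across data
subsets — necessary for applying one model to train and test splits.
Missing patient values are imputed by the column mean within the
patient's group (GDM or control); ordinal/binary imputations are rounded
to the nearest admissible level so the result stays encodable. The bundled
spec describes 44 variables expanding to 77 patient columns; counts are
configuration, not constants.

Each design row is one kept meal: the nine meal-composition features
(including gi and gl), the pre-meal glucose BG0 as a context feature, and
the encoded patient block; the seven outcomes (BG60, BGMax, BGRise,
AUC60, AUC120, iAUC60, iAUC120) ride along. The *without-GI/GL* arm drops
exactly the `gi` and `gl` columns (and, in polynomial designs, their
polynomial children).

## Modeling tracks

**Stepwise (descriptive, all records).** Forward selection maximizing R²,
stopping when the entering variable's partial-F p-value exceeds
`alpha_enter` (default 0.05). A pure "optimize R²" rule never stops, so a
stopping criterion must exist for a finite model; the partial-F at 0.05 is
the convention of mainstream statistics packages and is configurable.
There is no removal step. Ties are broken by column order so runs are
reproducible, and rank-deficient candidates (e.g. the last dummy of a
fully encoded variable, collinear with the intercept) are skipped.

**Regularized (predictive, held-out patients).** Patients — not rows —
are split 70/30, and grouped 10-fold cross-validation on the training
side scores a hyperparameter grid: support sizes 1–30 for orthogonal
matching pursuit (OMP), 20 log-spaced penalties in [1e-4, 10] for LARS
lasso / lasso / ridge, crossed with l1 ratios {0.1, 0.5, 0.9} for the
elastic net. Inside every fold the Spearman prefilter (|r| > 0.1 with the
outcome, computed on that fold's training part only) and the column
normalization (center by mean, divide by the centered column's l2 norm)
are refit, so no validation information leaks into feature selection or
scaling; whether the original analysis prefiltered on all data is
ambiguous, and the train-only choice is the conservative one. The grid
point with the largest mean validation r² (coefficient of determination,
possibly negative) wins and is refit on the full training split. OMP's
natural hyperparameter is its support size, so the "alpha" grid search
becomes a support-size search there.

OMP and the LARS-lasso path are implemented in the package (greedy
residual-correlation selection with OLS refits; the piecewise-linear
lasso path with the drop modification, solutions at arbitrary penalties
by exact interpolation between knots). Their correctness is pinned in
tests by two equivalences — OMP at full support and the lasso path end
both reproduce the least-squares solution to 1e-6 — and by agreement with
glmnet at interior penalties. Lasso/ridge/elastic-net fits themselves go
through glmnet.

**Evaluation.** Pearson R between predictions and observations, MAE, r²,
the coefficient count, and the fraction of test meals with absolute error
above 1.0 mmol/L·h (reported for every outcome, interpretable on the
iAUC120 scale).

## The synthetic cohort generator

No patient data ships with the package; the generator *is* the study
conditions for every test. Defaults: 30 GDM + 30 control patients, 6 days
of CGM at 5-min sampling, 4 diary meals/day — about 1,440 meals, the
scale of a real cohort of this design.

Each meal's incremental response is a gamma-shaped kernel
$(t/t_p)^a e^{a(1-t/t_p)}$ peaking at $t_p$ = 45 min (shape $a$ = 5,
support 4 h), normalized to unit iAUC120 so that a meal's amplitude *is*
its noiseless iAUC120 in mmol/L·h. The amplitude is planted linearly:

$$A = \beta_0 + \beta_{carbo}\,carbo + \beta_{gl}\,gl + \beta_{bg0}\,basal
      + u_{patient} + \varepsilon,$$

with defaults $\beta = (0.012, 0.016, -0.25)$, $\beta_0 = 2.07$,
meal noise sd 0.62, patient random effect sd 0.2 (clipped at a small
positive amplitude; the clip affects ~2% of meals). The trace is basal +
kernel sum + AR(1) sensor noise (stationary sd 0.10 mmol/L, per-sample
correlation 0.7 — smooth like a real sensor, so interpolation and the
timing rules face realistic inputs), clipped to 2–25 mmol/L.

Meals are structured the way diary meals are: one carbohydrate staple
whose portion is scaled to a satiety-driven carbohydrate target
(lognormal, median 33 g), plus 0–2 low-carbohydrate sides. This does two
jobs at once. It is realistic — people eat roughly similar amounts of
carbohydrate from dense and dilute staples — and it makes the planted
effects identifiable: portion-driven variance otherwise dominates both
`carbo` and `gl` and pushes their correlation toward 1. Under the default
food table (47 items across the GI strata, staple GIs from 18 to 100, two
rare unresolved-GI dishes) the meal-level carbo–gl correlation is ~0.82,
deliberately milder than the ~0.95 such studies report from real diaries;
passing recovery tests therefore does *not* show the pipeline could
separate GI/GL from carbohydrate in real data, where they are nearly
exchangeable — which is precisely the finding such comparisons probe.

A structural caveat the tests respect: `gl = gi × carbo / 100` makes the
predictor triple (gi, gl, carbo) functionally dependent, so *exact*
support recovery is only well-posed for estimators that keep correlated
partners (the lasso family). Greedy OMP legitimately represents the
planted signal by a minimal subset (e.g. carbo + gi instead of
carbo + gl) — the recovery tests therefore use the LARS-lasso estimator,
while OMP is held to prediction-equivalence standards instead.

Reporting errors are injected at configurable rates, calibrated to the
proportions such cohorts report: late reports (both streams shifted
35–50 min, landing the reported start near the peak; default 5%),
falling-edge reports (shift of peak + 28–35 min; 2%), interfering snack
insertions 20–40 min after a meal (3%), lost diary records (2%), and
misreporting patients (10%, half single-item, half 100 g-rounded). A late
report is only *detectable* when the meal produced a visible rise —
amplitudes below ~0.7 mmol/L·h cannot trip a 1.0 mmol/L threshold at any
delay — so the error-recovery test uses a raised-intercept regime where
nearly every response is visible, isolating the detector from the
amplitude distribution. Under first-match-wins ordering, an inserted
snack on a steep rising flank may be labeled `late_report` rather than
`prior_meal`; the labels are faithful to the rule order, and injected
cluster pairs are still both excluded.

`theoretical_r()` gives the attainable ceiling
$\sqrt{V_{signal}/(V_{signal}+V_{noise})}$: the signal variance of the
planted predictor is estimated by regenerating a large meal sample from
the configured distributions (Monte Carlo, 20,000 meals, deterministic
given the seed), and the noise adds the meal noise, the patient effect
(unpredictable for held-out patients), and an exact AR(1) term for sensor
noise propagated through the discrete trapezoidal iAUC with baseline
subtraction ($\sigma^2 w^\top R w$ with trapezoid-minus-baseline weights
$w$ and AR(1) correlation $R$); the positive-part clipping is ignored,
accurate while responses stay above baseline. Defaults put the ceiling
near 0.6, the regime reported for held-out-patient PPGR prediction.

## Numerical choices

* Glucose queries: linear interpolation; ±2.5-min edge tolerance;
  sensor gaps over 20 min are undefined rather than bridged.
* iAUC: exact crossing insertion before integration, so results are
  invariant to sampling-phase of the baseline crossings.
* Normalization constants are stored in the fitted model and reapplied
  verbatim at prediction time; constant columns are dropped with a
  warning.
* Stepwise ties broken by column order; candidate columns within 1e-10
  (relative) of the current span are skipped as rank-deficient.
* The LARS path recomputes residual correlations from the residual at
  each knot (no incremental drift) and treats active-set degeneracy by
  stopping; solutions above $\lambda_{max}$ are exactly zero.
* Grouped splits shuffle patients under a local RNG seed and restore the
  caller's RNG state; all generator draws derive from the mandatory
  config seed.

## Test problem sizes

The default test suite runs the full closed loop
(generate → match → exclude → filter → assemble → fit → evaluate) at the
default scenario's scale: 50 seeded replicates for signal recovery and
the performance-ceiling comparison, 20 seeds for the arm comparison under
an amplified independent GL signal, 10 under a null GL signal, 720-meal
cohorts for error-injection recovery, and 1,000-meal / 200-trace batches
for the arithmetic and integration oracles. These sizes were chosen so
the whole suite exercises every stage at cohort scale while staying
comfortably reproducible on a laptop.

## Known limitations

* The feature roster is a structural emulation, not the original
  instrument; real questionnaires and appendix feature lists differ.
* The generator's covariate shifts between GDM and control groups are
  directional only, not calibrated to a real cohort's distributions.
* Physiological glucose–insulin dynamics (e.g. minimal models), glycemic
  variability indices, and second-meal effects are out of scope; the
  response kernel is additive and meal-independent.
* `point_bg` fingerstick values are carried through the protocol reader
  but unused computationally (no sensor recalibration).
* Real CGM exports (proprietary formats) must be converted to the
  documented CSV layout first.
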