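---
title: "Methods: simulator, surrogates and the in-silico optimization loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulator, surrogates and the in-silico optimization loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choopt)
```

This vignette documents the models, assumptions and design choices behind
`choopt`, in the spirit of a methods section: what is computed, why the
defaults are what they are, and what the package's own tests do and do not
demonstrate.

## 1. The cultivation simulator

### Why a simulator

The workflow this package implements — learn a surrogate from historical
cultivation runs, screen a large candidate space, validate the proposals —
is normally closed by wet-lab experiments. Here the loop is closed by a
kinetic simulator instead. That choice makes the whole procedure
*testable*: the simulator is the ground truth, so we can measure whether
the surrogate's proposals genuinely improve the process rather than merely
fit the data.

### State and update rule

A run is a daily trajectory over days 0–12 (13 samples, one per day,
matching daily offline analytics). The state carries viable cell density
(VCD, 10⁶ cells/mL), glucose (g/L), glutamine (mM), lactate (g/L), product
titer (g/L), mean cell diameter (µm) and viability (%). We use daily
discrete difference equations rather than ODE integration: sampling is
daily, the downstream models only ever see daily points, and discrete
updates are exactly reproducible.

Each day, in order:

1. **Feeding.** From the feeding start day on, a fixed nutrient bolus is
   added (glucose `glc_bolus`, glutamine `gln_bolus`, emulating combined
   macro/micro nutrient feeds). From day 5 on, glucose is topped up to the
   condition's feed target if it is below it (target 0 = no glucose feed).
2. **Growth.** The specific growth rate is Monod-type with a Gaussian pH
   optimum and a logistic crowding term:

   µ = µ_max · exp(−((pH − pH_opt)/w_pH)²) · DO/(K_DO + DO) ·
       Glc/(K_Glc + Glc) · Gln/(K_Gln + Gln) · max(0, 1 − VCD/VCD_cap)

   The crowding term is essential: with daily feeding, pure Monod growth
   is unbounded, whereas real fed-batch cultures saturate near a
   system-specific peak density.
3. **Death.** k_d = k_d0 · (1 + a·day^1.5), plus a starvation boost while
   glucose < 0.5 g/L. The superlinear age term produces the
   characteristic late-phase VCD decline.
4. **Production.** Specific productivity has a growth-associated and a
   non-growth-associated term; the latter has its own pH optimum, placed
   *above* the growth optimum, and a saturating glutamine gain:

   q_P = (q_α·µ + q_β·exp(−((pH − pH_opt,q)/w_q)²)) · (1 + g·Gln/(K_q + Gln))

   Daily titer increment: Δtiter = q_P · VCD_avg / 1000 (units: pg/cell/day
   × 10⁶ cells/mL → g/L). Production is never negative, so titer is
   non-decreasing — product degradation is not modelled.
5. **Diameter** grows with culture age in proportion to how far growth has
   stalled (old, slow-growing CHO cells are larger); **viability** declines
   logistically with cumulative death pressure; **lactate** is produced as
   a glucose overflow metabolite and re-consumed when glucose is low.

The separation of the two pH optima (growth ≈ 7.20, production ≈ 7.45) is
what gives the process an interior titer optimum between them: mildly
alkaline setpoints sacrifice some growth for a disproportionate gain in
per-cell productivity. High starting glutamine and early feeding raise the
production gain; this is deliberately the structure the screening stage is
supposed to discover.

### Measurement noise

Measured quantities receive multiplicative lognormal noise with CV
`noise_cv` (default 0.05, a realistic day-to-day analytics scatter; at this
level the replicate CV of final titer stays well under 15 %). Titer noise
is applied to the daily *increments*, not the levels, so measured titer
remains non-decreasing — assays scatter, but product does not vanish.
Setting `noise_cv = 0` gives the deterministic trajectory; replicates are
then identical.

### Calibration

The defaults of `simulator_params()` were tuned once so that the
noise-free standard condition (pH 7.15, DO 60 %, VCD₀ 0.3, 6 g/L glucose,
6 mM glutamine, feed from day 3, glucose top-up to 5 g/L) lands on the
reference process's standard KPIs — peak VCD ≈ 23–24 ×10⁶ cells/mL, final
titer ≈ 3.0–3.1 g/L, maximum diameter ≈ 17 µm, mean Q_P ≈ 22–27
pg/cell/day — and then frozen. Qualitative behaviours built in and covered
by tests: batch runs (no feeding) produce clearly less antibody; very low
pH (≤ 6.9) cripples growth and titer; earlier feeding with high glutamine
never hurts; the titer-vs-pH curve has an interior maximum.

### What the generator emulates, and what it does not

`build_design("FULL_58")` reconstructs the *shape* of the historical
dataset: 3 standard replicates plus 55 varied runs — a two-factor central
composite (CCC) design over pH and DO, duplicated pH-shift runs
(7.1 → 7.3 on days 0/3/4/5), feed-timing and medium variations including
batch runs, four stressful high-pH/low-glutamine combinations, a duplicated
three-factor full factorial (feed day × VCD₀ × glutamine) and glucose-feed
variations — 754 daily points in total, of which a configurable fraction
(default 2.5 %, i.e. 19 points) receives QC flags to exercise cleaning.

Not emulated: glutamate, osmolality, pCO₂, antifoam, intra-day dynamics,
assay-specific error structure, or any correlation between nuisance events
and conditions (QC flags are assigned completely at random). Passing tests
therefore show the *workflow* is sound against a plausible ground truth;
they cannot certify performance on a real bioreactor, where the response
surface is rougher and noise is structured.

## 2. Storage

Runs are persisted as one JSON document per line, each validated against
the schema shipped in `inst/extdata/run_schema.json` (field names are
reconstructed from the measured quantities of the process; the schema
enforces required keys, types, physical bounds, and exactly 13 samples).
The package ships its own validator for the draft-07 keyword subset the
schema uses. Records round-trip load → save → load byte-identically
(modulo key order), and `flatten_to_points()` is lossless for the modelled
fields.

Per-point outputs are *running* statistics (max VCD and diameter up to day
t, titer at t, mean Q_P over days 1..t, defined as 0 at day 0). Process
time is a model input, so outputs must depend on it to carry information;
whole-run KPIs repeated on all 13 rows are available via
`outputs = "whole_run"` for comparison.

## 3. Preprocessing

* **Cleaning** drops flagged points only, never modifies survivors, and
  keeps an audit trail of removals.
* **Feature selection** iteratively fits a random forest (100 trees,
  `mtry` = all features, as in scikit-learn regression forests — this
  keeps the spurious importance of uninformative features low) and selects
  features whose normalized impurity importance strictly exceeds 0.1.
  Because each iteration's importances sum to 1 by construction, a pool
  with *no* informative feature left would still push some features above
  any threshold below 1/pool-size; importances are therefore only acted on
  while the forest retains out-of-bag predictive skill (OOB R² > 0).
  Selection is seeded and invariant to candidate ordering (candidates are
  sorted; ties broken lexicographically).
* **Splitting** defaults to run-level units (all 13 points of a run stay
  on one side), preventing trajectory leakage; a point-level split is
  available to mirror a plain random split of the table. The training side
  gets ⌊fraction · units⌋ units.
* **Scaling** removes the mean and divides by the *population* (ddof 0)
  standard deviation, fitted on training rows only; test data reuse the
  training scalers. Constant columns scale by 1 with a warning.

## 4. Surrogate models

Four families share one interface (`fit_surrogate()` / `predict_kpis()`),
all trained on scaled inputs and outputs with the scalers stored inside the
fitted object:

| family            | backend                  | default            |
|-------------------|--------------------------|--------------------|
| `linear`          | `stats::lm.fit`          | —                  |
| `latent_projection` | `mixOmics::pls`        | 4 components       |
| `tree_ensemble`   | `randomForest` (1/output)| 4 trees            |
| `feedforward_net` | own implementation       | see below          |

The feedforward network is implemented in plain matrix algebra (no
multi-hidden-layer regressor exists in the R dependency stack): ReLU hidden
layers, linear outputs, Glorot-uniform initialization, full-batch Adam on
the L2-regularized half-MSE loss L = ‖Ŷ−Y‖²/(2n) + α‖W‖²/(2n), α = 0.1.
The production architecture is (100, 50, 25, 50, 100); a lighter
(50, 25, 25, 50) network is the default for model comparison.

**Training controls.** Full-batch Adam with learning rate 0.01, an epoch
cap (8000 for the production net) and patience-based early stopping (stop
after 800 epochs without a loss improvement of 10⁻⁶). These values were
fixed during development by watching the loss and the learned response
surface: much shorter schedules leave the network visibly underfit, with
flat or even spurious structure in sparsely covered corners of the input
space (e.g. low pH), which then contaminates screening. Training is seeded
and bit-reproducible.

**Extrapolation.** Predictions for inputs outside the per-feature training
range are returned but flagged (`extrapolated`). The screening stage relies
on mild extrapolation — the interesting optima often sit at the edge of the
data — so the flag is a diagnostic, not a refusal. Note the flag is
per-feature: a candidate may be inside every marginal range yet far from
any training point in combination; such "interaction extrapolation" is
invisible to the flag and is precisely where surrogate artifacts live.

**Cross-validation unit.** `compare_models()` defaults to run-level folds
(consistent with the split default). Point-level folds mirror the common
practice of plain k-fold CV on the data table; with daily trajectories
they are more lenient, since sibling days of each run are always in
training. Run-level CV on 58-run data is harsher but high-variance: with
~19 runs per fold, an entire design region can land in one fold, where
tree ensembles degrade gracefully while neural networks can fail
catastrophically. Both units are exposed; the package's own family-ordering
check uses point-level folds because that is the convention of the
reference comparison it mirrors.

## 5. Screening and validation

* **Candidates** are sampled uniformly: continuous inputs within their
  training ranges (a data-driven surrogate cannot be trusted beyond its
  data; user-supplied bounds are clamped to the observed range), discrete
  inputs over their observed category sets. Uniform random sampling (not a
  grid) is dimension-robust; the count M is a parameter (10⁵ by default in
  the pipeline; 10⁶ is feasible, predictions are chunked).
* **Filter.** Candidates with predicted titer strictly above the threshold
  (default 4.6 g/L) survive; rankings per KPI break ties by candidate
  index, so results are independent of row order. Process time is sampled
  like any input; `day12_dominance()` reports the fraction of top-titer
  survivors at day 12 rather than assuming it.
* **Proposal selection** formalizes "pick good but dissimilar settings":
  from each KPI's top 10 survivors, picks are chosen greedily to maximize
  the minimum pairwise Euclidean distance in scaled input space, seeded by
  the top-ranked candidate (4 picks per KPI, 5 for titer as the primary
  target). Identical pools fall back to rank order with a warning.
* **Validation** simulates every proposal (plus standard-condition
  replicates) with the ground-truth simulator and tabulates predicted vs
  validated vs standard KPIs. The headline percent increase uses the
  validated standard titer as denominator; the prediction-accuracy percent
  uses the predicted value as denominator.

## 6. Numerical conventions

* "None" sentinels: feeding/shift day −1, keeping all feature tables
  numeric.
* Threshold comparisons are strict (`>`), both in feature selection and in
  the titer filter.
* Q_P generalizes the per-run statistic to any N ≥ 1 (running mean up to
  day t); the ×1000 factor converts g/L per 10⁶ cells/mL·day to
  pg/cell/day. Days with non-positive averaged VCD are an error, day 0 is
  defined as Q_P = 0.
* Tuning ties are broken by smaller parameter count, then lexicographic
  label.
* All seeds are derived from a single integer via a seeded draw, and every
  function that consumes randomness restores the caller's RNG state.

## 7. Problem sizes used by the test suite

The shipped tests run the loop at the scale of the emulated study: 58-run
datasets (754 points), 10⁵ screening candidates, threefold CV, and five
pipeline replicates under different global seeds for the end-to-end
property (proposals must beat the simulated standard process by a clear
margin, ground truth in hand). Metric implementations are checked against
brute-force transcriptions of their formulas on 1000 random instances, and
the screening filter against a per-row recomputation.

## 8. Known limitations

* The simulator's smooth, low-dimensional response surface is friendlier
  to surrogates than real bioprocess data; transfer of the *quantitative*
  improvements to a physical process is out of scope.
* The network's extrapolation flag cannot detect interaction
  extrapolation (see above).
* QC flags are missing-completely-at-random; cleaning under informative
  missingness is untested.
* One surrogate per pipeline run: no retraining/continuous-learning loop
  after validation, and no gradient-based or Bayesian optimization over
  the surrogate — the workflow screens, it does not optimize analytically.
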