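---
title: "Model, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcea)
```

## The model and its assumptions

`ppcea` implements a three-state Markov cohort model of chronic low back
pain used to compare pharmacopuncture (PPT, acupoint injection of herbal
solutions) with physiotherapy (PT). States are pain-severity categories on
the 0–10 numeric rating scale: mild (NRS < 4), moderate (4 ≤ NRS < 7),
severe (NRS ≥ 7). The cohort is closed and mortality is not modelled: the
target population is working-age (19–70) and no deaths occurred in the
source trial.

Assumptions baked into the engine:

* **Cycle and horizon.** 3-month cycles (Δt = 0.25 y), 12 cycles = 3
  years. The horizon is a DSA parameter (1–5 years → 4–20 cycles).
* **Initial distribution.** The source trial enrolled only moderate or
  severe patients, split 12% : 88%; `model_spec()` rejects any initial
  mild mass.
* **Constant transition probabilities.** The matrices estimated at the
  final trial follow-up apply unchanged to every cycle.
* **Pooled mild behaviour.** The mild row is a pooled (arm-independent)
  estimate; `load_config()` rejects configurations whose mild rows differ
  across arms, and the PSA draws the mild row once per iteration, shared
  by both arms.
* **Treatment only in moderate/severe.** Mild patients incur no medical,
  transport or time costs; they do contribute productivity losses (the
  inputs include an explicit mild productivity-loss value) and QALYs.
* **Currency.** All computation in USD. The only stored KRW quantity, the
  willingness-to-pay threshold (30.5 million KRW), is converted once at
  load with the fixed 2021 rate 1,144.61 KRW/USD, giving λ ≈ 26,646.8
  USD/QALY.

## The 2-cycle mild row and convention calibration

The published transition estimates label the mild row a **2-cycle**
quantity (mild patients were re-assessed over a 6-month interval) while
the moderate and severe rows are 1-cycle. How such a row enters a
per-cycle engine is genuinely under-determined, so `per_cycle_matrix()`
implements three conventions:

* **`tunnel`** — mild splits into two sequential sub-states; the first
  cycle in mild is a forced stay, the second exits with the 2-cycle row.
  This enforces the 2-cycle sojourn literally.
* **`matrix_root`** — solve for a per-cycle mild row whose two-cycle
  composition reproduces the printed row. For the published matrices no
  non-negative solution exists (any per-cycle mild row m forces the
  two-step mild→severe element ≥ m(moderate)·0.194 ≈ 0.05, far above the
  printed 0.001; the principal matrix square root is complex), so the
  solver returns the clipped fixed point — the projected best
  approximation — and falls back to `tunnel` only if the iteration
  degenerates.
* **`direct`** — use the printed row per cycle as-is, ignoring the
  2-cycle label. This is what a standard cohort-model package does with
  whatever row it is given, and plausibly what the original analysis did.

Combined with the cycle-correction (`none` / `half_cycle`) and
discount-timing (`cycle_start` / `cycle_end`) switches this gives 12
convention tuples. `calibrate_conventions()` scores all of them against
supplied target totals by mean absolute relative error and never
overwrites a user's choice. Against the published base-case totals the
winner is (`direct`, `half_cycle`, `cycle_start`) with a mean residual of
0.03% — effectively exact on all four cost totals and both QALY values —
while the best tunnel or exact-root tuple misses the PT arm by 6–8%. The
packaged default configuration therefore pins the calibrated tuple;
`model_spec()`'s own defaults remain the conservative (`tunnel`, `none`,
`cycle_start`).

## Accrual and discounting

Per cycle t (0-based), accrual weights are the occupancy entering the
cycle (`cycle_correction = "none"`) or the average of entering and leaving
occupancy (`"half_cycle"`, the calibrated default — the usual trapezoid
assumption that transitions happen mid-cycle on average). The discount
factor is (1 + r)^(−t·Δt) under `cycle_start` (cycle 0 undiscounted) or
(1 + r)^(−(t+1)·Δt) under `cycle_end`, with r = 4.5%/year. Totals sum
over cycles 0..T−1: twelve 3-month accruals equal the 3-year horizon.
Treatment costs are charged from cycle 0 — patients enrol in treated
states and treatment is re-administered each cycle.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| Discount rate | 0.045 | 1/year | DSA 0.035–0.06 |
| Horizon | 12 cycles | 3 months each | DSA 1–5 years |
| Initial moderate share | 0.12 | fraction | DSA ± 0.03 |
| PPT medical cost | 298.77 | USD/treated cycle | consultation 80.01 + syndrome differentiation 17.42 + therapy 201.34; fixed in PSA |
| PT medical cost | 156.0978 | USD/treated cycle | consultation 107.53 + scenario mix (weights 0.25/0.61/0.08/0.06 over 43.83/47.23/61.40/64.80) |
| Transport | 4.32 / 5.46 | USD/treated cycle | PPT / PT; PSA SE = 10% of mean |
| Time cost | 183.83 / 209.40 | USD/treated cycle | PSA SE 12.15 / 14.14 |
| Productivity loss | 1645.46 / 2585.98 / 3405.16 | USD/cycle | mild / moderate / severe, all states, full-societal only |
| Utility | 0.837 / 0.782 / 0.750 | — | per-cycle QALY weight = utility × 0.25 |
| WTP | 26,646.8 | USD/QALY | 30.5M KRW / 1,144.61 |

The published per-cycle QALY weights are printed rounded (0.209, 0.195,
0.187); the package computes them as utility × 0.25 at full precision
(0.20925, 0.1955, 0.1875) — note 0.1955 and 0.1875 round *up* under
round-half-even, so the printed 0.195/0.187 appear truncated. Computation
is always full-precision; rounding happens only in report writers.

## One-way sensitivity analysis

`run_one_way()` re-runs the complete base case at each range end. Design
choices:

* **Row perturbation.** A transition-row element moves by its published
  delta, clipped to [0, 1]; the remaining elements rescale
  proportionally (equal split of the freed mass when they are all zero).
  This preserves the row's relative structure and is standard practice.
* **Medical costs.** The input table marks medical unit costs "fixed" for
  the PSA and prints no one-way range, yet the narrative varies medical
  costs and ranks "cost of PPT" among the most influential parameters.
  The default ranges vary each arm's medical cycle cost by ±10%, the same
  convention the table's footnote applies where no distribution could be
  assumed.
* **Scenario weights.** The published range "100, respectively" is read
  as: each PT scenario weight pushed to 100% (the other weights rescale
  to zero), reproducing e.g. 107.53 + 43.83 = 151.36 for scenario 1.
* **Tornado metric.** Results are ordered by NMB spread at λ, not ICER
  spread: under dominance the ICER changes sign as ΔQALY crosses zero,
  so it is reported alongside but not used for ranking. Ties keep input
  order.

## Probabilistic sensitivity analysis

1,000 Monte-Carlo iterations by default. Distribution choices:

* **Per-cycle QALY weights** ~ Beta with the published concentration
  pairs, whose means (0.2092, 0.1954, 0.1874) match the per-cycle values
  — so draws are used as QALY weights directly, *not* re-multiplied by
  Δt (the source states the sensitivity analysis was conducted on the
  QALY values).
* **Costs** ~ Gamma parameterized by mean = base value and SD = published
  SE (shape = mean²/SE², scale = SE²/mean); transportation uses an SE
  fixed at 10% of the mean. Medical unit costs are fixed and never
  sampled.
* **Transition rows** ~ Dirichlet with the published concentrations; the
  pooled mild row is drawn once per iteration and shared by both arms.
* **Scenario weights** ~ per-scenario marginal Betas, renormalized onto
  the simplex (the source gives marginals only).
* **Independence.** No correlation structure is stated, so parameters are
  sampled independently.
* **Seeding.** One master seed generates a sub-seed per iteration, so
  results are bit-reproducible and independent of evaluation order.

**A known, honest discrepancy.** The published Dirichlet concentrations
imply row means that differ from the published probabilities — most
sharply for the PT arm, where the moderate-row concentrations
(0.125, 3.198, 0.954) imply means (0.029, 0.748, 0.223) versus printed
(0.052, 0.765, 0.183), and the severe-row concentrations imply
mild/severe means of 0.164/0.334 versus printed 0.209/0.222. Sampling
those concentrations faithfully keeps more of the PT cohort in treated
states, so the PSA mean PT healthcare cost comes out ≈ $1,470, about 8%
above the published PSA mean of $1,360.74, while the PPT mean (≈ $1,282
vs $1,299.99) and both cost-effectiveness probabilities (≈ 98.7% vs
97.7%; ≈ 99.7% vs 99.4%) reproduce well. The package does not re-center
the Dirichlet draws to force agreement; the corresponding acceptance
assertion is left failing by design, with the analysis above as its
explanation.

## The synthetic trial: what it does and does not establish

`simulate_trial()` emulates the statistical structure the analysis
assumes: enrollment restricted to moderate/severe (12:88), two follow-up
intervals generated by the arm's true transition matrix, truncated-normal
EQ-5D-5L utilities around state means, and per-state productivity-loss
amounts. The patient-level utility SD is not published; 0.1 is a
realistic within-stratum EQ-5D spread and is set once. Because a normal
truncated to [0, 1] with mean 0.837 and SD 0.1 loses upper-tail mass, the
observation mean sits ≈ 0.014 below the location parameter; recovery
tests therefore compare estimates to the analytic truncated mean.

The generator deliberately omits: continuous NRS scores (only the three
categories matter), dropout/missingness, arm-specific utilities, and any
time trend in transition behaviour. A green recovery test therefore
establishes that the estimators invert the generator — counts/row-totals
recover the matrices (within 0.02 at 10,000 patients/arm, pooling the two
intervals and pooling the mild row across arms, since a 12:88 enrollment
leaves single-interval mild/moderate rows with only ~2,000–3,000
observations), and the end-to-end pipeline reproduces base-case dominance
— not that the real trial data look like this.

## Numerical choices and degenerate inputs

* Row sums validated to 1e-6 on input (optional renormalization), 1e-9
  for conservation invariants.
* ICER with ΔQALY = 0 is undefined (`NA`); dominance then follows the
  cost sign. ΔCost = 0 with ΔQALY > 0 is classified `tradeoff` (with a
  zero ICER): strict dominance requires strictly lower cost.
* `perturb_probability_row()` with an all-zero complement splits the
  freed mass equally; an all-zero row after clipping is an error.
* `estimate_transitions()` never invents a row for an unobserved source
  state — it returns NA and leaves supplying a pooled row to the caller.
* `auc_qaly()` converts weeks to years at 52.18 weeks/year (the
  average-year convention, stated explicitly because 13 weeks is then
  0.2491 years, not 0.25).
* Zero-variance utility samples yield a fixed value; a method-of-moments
  Beta fit is attempted only when the variance is compatible with a Beta
  (v < m(1−m)).

## Known limitations

* The convention calibration targets four printed totals; other
  convention tuples reproduce single cells equally well (e.g. exact-root
  with cycle-end discounting matches the PPT healthcare total to $0.17)
  and the selection is only as sharp as those targets.
* The DSA parameter list reconstructs the published analysis from its
  ranges; the exact 20 parameters in the published tornado (supplementary
  material) are not available, so figure-level agreement is out of scope.
* PSA agreement for the PT arm is bounded by the concentration/probability
  inconsistency described above.
* Transition estimates come from a 100-patient trial observed for 6
  months and are extrapolated to 3 years as constants; the model cannot
  say anything about slow relapse dynamics beyond that window.
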