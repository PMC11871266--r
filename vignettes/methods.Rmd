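---
title: "Estimating causal effects of mechanical power on ventilation outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of mechanical power on ventilation outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventcausal)
```

## The problem

Mechanical power (MP) summarises the energy a ventilator delivers to the
respiratory system per minute and predicts ventilator-induced lung injury
(VILI). Whether, and by how much, *reducing* MP would improve outcomes is a
causal question: in observational ICU data clinicians titrate ventilation to
disease severity, so high MP is a marker of being sick as much as a cause of
harm. This package implements a DAG-guided causal workflow for that
question: exposure construction from hourly ventilator records, graphical
identification, adjusted and double-machine-learning estimation, a dynamic
hour-by-threshold effect surface on oxygenation, and counterfactual MP
trajectory simulation — all validated against a synthetic cohort generator
with known ground truth.

## Exposure, outcomes and conventions

The hourly exposure is

$$\mathrm{MP}\ (\mathrm{J/min}) = 0.098 \cdot V_t \cdot RR \cdot (\mathrm{PEEP} + P_{insp}),
\qquad P_{insp} = P_{peak} - \mathrm{PEEP},$$

with $V_t$ in litres (input files carry mL and are converted at read time,
consistent with typical charting around 480 mL). Because the bracket
collapses to $P_{peak}$, MP is computed from peak pressure directly; PEEP is
retained to reject inconsistent records ($P_{peak} < \mathrm{PEEP}$) and for
the driving-pressure covariate ($P_{peak} - \mathrm{PEEP}$; plateau pressure
is not in the data model). Per-admission treatments are the median, maximum
and minimum hourly MP over the first 24 h.

VFD28 (ventilator-free days at day 28) uses the standard composite
convention, which the source data do not pin down exactly: death on or
before day 28 scores 0; otherwise $\max(0,\ 28 - \lceil \text{hours
ventilated}/24 \rceil)$. A single continuous ventilation episode is assumed;
reintubation is out of scope. The oxygenation intermediary is
PaO$_2$/FiO$_2$ (P/F); FiO$_2$ values in $(1, 100]$ are read as percentages
(both dialects occur in exports), and SpO$_2$/FiO$_2$ is available as an
optional column but is not used by the models.

## Identification

The packaged graph (`default_vent_dag()`, an editable plain-text file)
encodes the clinical structure: labs and vitals (WBC, temperature, pH, MAP,
PaCO$_2$) and demographics feed a latent disease-severity score; severity
drives both the P/F trajectory and VFD28; clinicians titrate respiratory
rate and peak pressure to severity; those settings plus latent lung
compliance determine MP. Compliance is marked unobserved (it is not charted
in the admission-level data model) and is given no path to the outcomes
except through MP, so the effect remains backdoor-identifiable.

`d_separated()` uses the moralised ancestral graph construction (restrict to
ancestors of the query and conditioning sets, marry co-parents, drop
directions, delete the conditioning set, test connectivity).
`backdoor_sets()` enumerates subsets of observed non-descendants of the
exposure in increasing size and keeps those that d-separate exposure and
outcome after removing the exposure's outgoing edges; supersets of known
valid sets are pruned in minimal-only mode. Exhaustive enumeration is a
deliberate choice — the graphs involved have tens of nodes at most and no
heuristic should decide identifiability. When no observed set exists the
classed condition `ventcausal_not_identifiable` distinguishes "nothing can
block the backdoor" from "the empty set suffices". The test suite checks
both primitives against an independent path-enumeration oracle on hundreds
of random graphs.

## Estimators

**Backdoor linear regression.** The point estimate is the treatment
coefficient from the least-squares fit of outcome on treatment plus the
adjustment set, computed by QR factorisation of the design matrix (the
normal equations are solved by an orthogonal decomposition rather than
delegated to a modelling wrapper, and the test suite verifies agreement with
an explicit normal-equations solve to 1e-8). Confidence intervals are
percentile intervals from a nonparametric bootstrap over admissions — the
independent sampling units — with B = 500 by default. Exact rank deficiency
is an error naming the collinear columns; `drop_aliased = TRUE` instead
drops aliased *adjustment* columns (never the treatment), which the pipeline
enables because diagnosis groups nearly determine the admission arm and
small cohorts alias the dummies exactly.

**Double machine learning.** `dml_ate()` implements cross-fitted
partialling-out: admissions are split into $K = 5$ folds; outcome and
treatment are predicted from the adjustment variables by models fit on the
other folds; and

$$\hat\theta = \frac{\sum_i \tilde r_{T,i}\, \tilde r_{Y,i}}{\sum_i \tilde r_{T,i}^2}$$

over out-of-fold residuals. Nuisance learners are depth-limited random
forests (`ranger`, 200 trees, `min.node.size` 5, single-threaded and seeded
for determinism) for the forest variant, and linear least squares or a
user-supplied regressor for the generic variant. Two intervals are
reported: the influence-function (sandwich) variance of the orthogonal
score, and a bootstrap over the out-of-fold residual pairs at admission
level. The residual-pair bootstrap is a deliberate simplification — fully
re-fitting forests inside each of 500 resamples would dominate the runtime
while the cross-fitted residuals are already out-of-sample; the
influence-function interval is the default. A treatment explained
(numerically) completely by the confounders triggers a "no
overlap/variation" error rather than a huge unstable ratio, with tolerance
$\sum \tilde r_T^2 / n < 10^{-10}\,\mathrm{var}(T)$.

On a linear data-generating process the forest variant carries the usual
finite-sample regularisation bias of tree ensembles (visible as a modest
negative shift relative to the linear fits), while the generic/linear
variant matches the backdoor regression as $n$ grows — the suite asserts
agreement within 3 joint standard errors at $n = 10{,}000$. Under the
generator's nonlinear confounding mode the ordering reverses and the forest
variant is the consistent one; pick nuisance learners to match the
confounding structure you believe in, which is exactly the point of
exposing both.

"Causal-forest-style" estimation here means forest nuisances inside the
partialling-out score; honest generalized-random-forest splitting theory is
intentionally out of scope.

**Subgroups and thresholds.** `cate_by_subgroup()` re-runs the configured
estimator within cohort labels, passing the same seed to every subgroup (a
single-level grouping therefore reproduces the ATE call bit for bit);
groups under `min_n` (default 50 admissions) are reported as suppressed
rows, never silently dropped or zeroed. `binary_effect_at_threshold()`
recodes treatment as $1\{\mathrm{MP} > \theta\}$ and records the coding on
the estimate; a threshold leaving either arm under `min_arm_n` raises the
classed `ventcausal_degenerate_threshold` condition.

## The dynamic hour × threshold surface

`fit_cate_grid()` fits one model per cell over default axes of 0–40 hours
since intubation and 0–40 J/min thresholds (41 × 41 = 1681 models per
cohort): treatment $1\{\mathrm{MP}_h > \theta\}$, outcome P/F at $h + 1$
(the lead is configurable), adjustment covariates from hour $h-1$ (clamped
at 0) plus the admission covariates, and a horizon filter requiring
intubation at least `max(hours) + lead` hours so every cell sees the same
cohort. Cells are estimated by the same QR partialling-out as the backdoor
regression but with analytic standard errors — per-cell bootstraps across
~1700 models would be computationally disproportionate, and
`binary_effect_at_threshold()` remains available with bootstrap intervals
for any single threshold of interest. Cells with fewer than `min_cell_n`
(default 50) admissions per arm are masked and exported with an explicit
sentinel. Within an hour the adjustment projection is computed once and each
threshold's indicator is residualised against it, which keeps the full grid
under a few seconds at $n = 2000$.

Two facts about reading the surface. First, with a change-point
data-generating process the *binary* contrast peaks at the true threshold
and attenuates away from it (treated-arm dilution below, control-arm
contamination above); recovery of the change-point means the extremum of the
column profile, not a step in it. Second, because the per-cell propensity
$P(\mathrm{MP}_h > \theta \mid X)$ gets extreme at the axis edges, linear
adjustment there can produce small wrong-signed cells — they come with large
standard errors and the masking rule removes the worst, but the edges of the
surface deserve skepticism in any application.

`optimal_threshold_path()` returns, per hour, the threshold minimising the
estimated cell effect among unmasked cells, breaking ties toward the lowest
MP (least-energy principle) and returning `NA` for fully masked hours. The
argmin convention treats lower surface values as less injurious; on surfaces
where larger values mean better oxygenation the argmin is the pessimistic
reading, so the raw surface is always exported and the path is a
convenience, not a recommendation.

## Trajectory simulation

`simulate_trajectory()` follows the per-hour optimal path from a configured
initial MP (snapped to the grid axis): each hour after the first is
perturbed independently with probability `noise_level`, in which case the
realised MP is a uniform draw in `perturbation_range` (default 5–40 J/min,
snapped to the grid). Hour 0 always realises the initial MP, so the expected
perturbed fraction refers to the remaining hours. Undefined path hours carry
the previous ideal value forward with a warning. Noise is i.i.d. across
hours — autocorrelated event models are out of scope — and the surface is
never re-estimated from the simulated path. Since the ideal path is a
per-hour argmin, its cumulative effect is a lower bound for any fixed-MP
policy on the same surface; the suite asserts this on random surfaces.

## The synthetic cohort generator

`generate_cohort()` draws from structural equations that follow the packaged
DAG:

1. **Admission level.** Age band, admission type (medical fraction default
   0.417) and diagnosis group (per-arm mixes defaulting to a large mixed-ICU
   pattern) determine, with APACHE II (which carries its own noise), a
   *deterministic* severity score. Determinism here is the design point: the
   backdoor is closed exactly by the four observed admission covariates, so
   estimator validation is a test of the estimator, not of proxy quality.
2. **Hourly.** Clinician policy titrates respiratory rate, inspiratory
   pressure and PEEP to severity (strength `confounding_strength`); tidal
   volume varies around 0.48 L; MP follows from the formula. Labs and vitals
   are noisy children of severity. Defaults are loosely calibrated to
   large-ICU descriptive scales (MP mean ≈ 17, medical arm higher than
   surgical) without asserting exact marginals.
3. **P/F.** Next-hour P/F is a severity baseline plus a *hinge* in lagged
   MP: marginal effect `true_pf_effect` (default −2 ratio units per J/min)
   applied only to MP in excess of `mp_threshold_true` (default 17 J/min),
   zero below — a change-point whose recovery the grid tests.
4. **Outcome.** A latent ventilation course
   $18 - 2.4\,\mathrm{sev} + \beta \cdot \mathrm{MP}_{med} + \varepsilon$
   (slope from `true_ate_vfd` or the cohort-specific `true_cate_map`, plus
   an optional step `true_vfd_step` above the threshold) maps to intubation
   duration ($24(28-\text{latent})$ hours, floored at 24 h) and death when
   the course goes negative; VFD28 is then *derived* through `vfd28()`, so
   the composite logic is exercised end to end.

Two numerical choices deserve explanation. The intercept 18 keeps the
latent course clear of the 27-day ceiling implied by the 24-hour minimum
episode: a higher intercept top-censors low-severity/low-MP admissions and
the censoring leaks into the MP coefficient through its correlation with
severity, breaking the generator's own contract that the adjusted
regression recovers `true_ate_vfd`. The same margin keeps baseline 28-day
mortality near zero, because deaths (course < 0) would censor the composite
toward 0 and attenuate the linear truth; the `mortality_shift` knob lets
users trade exact linear recoverability for realistic mortality, and that
trade is theirs to make. The nonlinear confounding mode adds a smooth
quadratic severity term to both the ventilator policy and the outcome, the
structure under which flexible nuisance learners earn their keep.

What the generator does *not* emulate: physiologic waveforms, drugs and
fluids, autocorrelated measurement error (hourly noise is i.i.d. given
severity), reintubation, inter-ICU transfer, and informative missingness
(`inject_missingness()` knocks out ventilator fields completely at random).
Passing tests therefore demonstrate correctness of the estimators under the
stated structural assumptions — not robustness to everything real ICU data
can do.

All randomness flows from one integer seed; sub-streams (admission, hourly,
outcome, missingness, folds, bootstraps, trajectories) are derived from it
by fixed offsets, so equal configuration and seed reproduce every artifact
byte for byte.

## Inclusion filtering and descriptives

`apply_inclusion()` applies, in order: adults only (when a raw `age_years`
column exists — the closed age-band vocabulary otherwise implies
eligibility); at least `min_complete_hours` hours carrying all four MP
inputs (default 2 — one complete hour makes a median but no spread, and
downstream windows need at least a pair); and removal of spontaneous-mode
hours, dropping admissions left under the same minimum. Step counts are
returned and are non-increasing by construction. `table_one()` reports
mean (SD) with Student's t-test, median (IQR) with the Mann–Whitney U test,
and n (%) with the chi-square test over the first 24 h; p-values are
descriptive and deliberately uncorrected for multiplicity. Groups too small
to test are reported as `NA` with a reason, not guessed.

## Problem sizes and tolerances used by the test suite

The suite validates estimator recovery at $n = 5000$ admissions over 200
seeded replicates (mean bias under 0.02 days per J/min; bootstrap /
influence-function coverage at least 90% for nominal 95%), the nonlinear
contrast at $n = 1500$ over 100 paired replicates (forest DML beats linear
adjustment in at least 80%), the grid at $n = 2000$ on the full 41 × 41
axes, identification against brute-force oracles on 500 random DAGs of up to
8 nodes, and trajectory contracts over 100 random surfaces plus a
1000-hour synthetic horizon. These scales keep the whole suite in the
minutes range on a single CPU while leaving Monte-Carlo margins far from
the thresholds. Exact equalities (the MP formula, VFD28 conventions,
normal-equations agreement at 1e-8, byte-identical reruns) are asserted
exactly.

## Known limitations

- Estimation treats the admission as the unit and the early-window MP
  summary as the exposure; time-varying-treatment methods (g-computation,
  marginal structural models) are out of scope, with the per-hour grid as
  the dynamic approximation.
- The forest DML variant is a partialling-out estimator with forest
  nuisances, not a full generalized random forest; its finite-sample bias
  on smooth confounding is documented above.
- The grid fits independent cells: no smoothing across neighbouring cells
  and no formal change-point inference on the surface.
- Real-data use requires mapping to the package's schemas
  (`map_external_schema()` is a renaming/unit-conversion stub, not an ETL
  layer) and a DAG the analyst actually believes; the packaged graph is a
  starting point, not an oracle.
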