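---
title: "Modelling granulopoiesis under chemotherapy and G-CSF"
author: "granulosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling granulopoiesis under chemotherapy and G-CSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulosim)
```

# The model

## Cell kinetics

Granulopoiesis is represented by five well-mixed compartments —
haematopoietic stem cells (S), committed granulopoietic progenitors
(CG), proliferating precursors (PGB), maturing post-mitotic precursors
(MGB) and circulating granulocytes (GRA) — each normalized so that its
unperturbed steady state equals 1.  Every compartment obeys a balance of
influx, production, efflux and chemotherapy-induced loss:

$$\frac{dC_X}{dt} = C_{in}(t)\,A(t) - \frac{C_X(t)}{T_X(t)}
  - \Psi^X_{total}(t)\,C_X(t).$$

The influx of each compartment is the efflux of the one upstream,
multiplied by a derived amplification constant chosen at model build so
that all fluxes balance exactly at the steady state; the normalized
steady state is therefore 1 *by construction*, and the "steady-state
value 1" threshold used in myelotoxicity quantification is exact, not a
numerical artifact.

Stem-cell divisions self-renew with a fraction $a(S)$ that decreases
with the stem-cell content, exceeds $1/2$ for depleted marrow (net
regrowth) and equals exactly $1/2$ at $S = 1$.  The shipped shape is
logistic-like, $a(S) = a_{max} / (1 + (2a_{max}-1)S^\nu)$; any
decreasing shape with these anchor properties would serve, and the
package treats the choice as a calibration detail, not a claim.

## G-CSF regulation

Five quantities respond to the G-CSF serum concentration through Hill
curves: PGB amplification and PGB transit time increase with G-CSF,
while MGB transit time, MGB apoptosis and the stem-cell self-renewal
fraction decrease.  The PGB-transit direction is counter-intuitive
(stimulation slows mitotic exit while expanding the pool) but is taken
at face value from the model lineage this package follows; dynamically
it produces the familiar clinical pattern of a transiently deepened
trough followed by a strong rebound when G-CSF is high.

The stem-renewal coupling deserves a note.  With an autonomous stem-cell
compartment, damage restricted to downstream stages could never move
$S$; the qualitative behaviour this package reproduces, however,
includes a delayed reduction of *all* stages after a PGB-restricted
insult.  We therefore let G-CSF above its baseline tilt stem-cell
divisions from self-renewal towards differentiation (demand
mobilization): deep neutropenia raises endogenous G-CSF, which
transiently depletes $S$ and leaves a slowly recovering deficit.  This
single mechanism links the depth of peripheral toxicity to stem-cell
toxicity across drugs, which is what makes stem-cell AOC a good
predictor of overall toxicity in the correlation analysis.

Filgrastim is treated as indistinguishable from endogenous G-CSF: its
effect curves are anchored so that the endogenous steady-state
concentration (25 pg/ml by default) maps exactly onto the baseline value
of each regulated quantity.  Pegfilgrastim is a separate species,
anchored at concentration 0, whose effect adds as an increment; its
elimination is almost exclusively granulocyte-mediated, which yields the
characteristic self-limiting exposure (high when the patient is
neutropenic, rapidly cleared after recovery).  Endogenous production is
demand-regulated with a steep Hill response, so that severe neutropenia
raises the endogenous concentration by one to two orders of magnitude
while leukocytosis suppresses it.

## Chemotherapy toxicity

Each drug application contributes a normalized pulse (area exactly one
per injection, amplitude $1/t_{inf}$ during the infusion).  The pulse
feeds a chain of four identical first-order stages with rate
$k_{Delay}$; the chain output is the Erlang-4-smoothed damage signal,
peaking $3/k_{Delay}$ after an impulse and conserving area through every
stage.  Multiplying the output by the cell-stage specific toxicity
coefficient $K_X$ gives the loss rate; coefficients of simultaneously
applied drugs add (no interactions), the first-cycle factor
$f_{fc} \ge 1$ scales all coefficients until the drug's first
application of its second treated cycle, and leukocytes follow
$C_{WBC} = C_{ANC} + C_{LY}\,e^{-\Psi_{LY}}$ with a constant lymphocyte
baseline $C_{LY} = 3000/\mu l$.

One genuinely open point is the dimensional reading of $\Psi_{LY}$.
The marrow loss term needs a rate (1/h), and the chain output carries
exactly that unit, so $K_X$ is a clean dimensionless multiplier.
$\Psi_{LY}$, in contrast, sits inside an exponential and should be
dimensionless.  The package offers three couplings via the
`psi_ly_coupling` parameter: `"hour"` (default; $K_{WBC}$ times the
chain output in 1/h — the direct analogue of the marrow term),
`"day"` (output rescaled to 1/d) and `"state"` ($K_{WBC}$ times the
dimensionless fourth chain state).  With the reference coefficient
magnitudes the default gives mild lymphocyte dips (a few percent), while
`"state"` gives deep, weeks-long lymphopenia of clinical magnitude.  The
default was chosen because the cross-drug toxicity-correlation analysis
is only consistent with a mild lymphocyte perturbation of WBC ranks;
users fitting absolute clinical WBC nadirs may prefer `"state"`, and the
parameter-recovery tests use it because it makes $K_{WBC}$ well
identifiable.

Prednisone (and methylprednisolone) is non-cytotoxic: while any dose is
covering (24 h per application) the granulocyte clearance rate is
multiplied by `prednisone_factor` (default 0.7), producing the transient
granulocytosis seen at the start of CHOP-like cycles.

# Parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| $T_S$ | 360 | h | slow stem-cell turnover; with $a_{max}=0.7$ the linearized recovery time constant is roughly a month, so stem-cell deficits persist for weeks |
| $T_{CG}$, $T_{PGB}$, $T_{MGB}$ | 96, 96, 120 | h | transit of order days through progenitor, mitotic and maturation stages |
| $T_{GRA}$ | 7 | h | blood residence of neutrophils |
| steady-state ANC | 5000 | cells/ul | mid-normal neutrophil count; configurable |
| steady-state G-CSF | 25 | pg/ml | normal serum level |
| $C_{LY}$ | 3000 | cells/ul | normal lymphocyte concentration, constant |
| amplification max | 8 | – | maximal G-CSF-driven fold increase of PGB production |
| PGB transit max | 192 | h | mitotic pool expansion under stimulation |
| MGB transit min | 20 | h | accelerated marrow release under stimulation |
| stem-renewal min | 0.45 | – | maximal demand-driven suppression of self-renewal |
| production Hill, beta | 4, 0.05 | – | steep endogenous response: up to ~20-fold production in aplasia |
| Filgrastim $k_a$, CL | 0.35/h, linear + GRA-mediated | | absorption over hours, half-life of a few hours |
| Pegfilgrastim $k_a$, CL | 0.05/h, GRA-mediated | | slow absorption, neutrophil-dependent elimination |

All values live in `inst/extdata/kinetic_parameters.yaml` and can be
overridden per call (`kinetic_params(...)`) or replaced wholesale by a
user file.  They are package defaults calibrated to the qualitative
contracts below — they are not estimates of any published
pharmacokinetic parameter set.

The calibration targets were: exact steady-state persistence; return to
within 1% of baseline after any single perturbation; a stem-cell-only
insult depressing $S$ first with delayed, milder downstream dips and
mild oscillation; all-stage CHOP-like damage depleting CG most and
recovering slowest; an unsupported CHOP-14 WBC nadir near day 11; G-CSF
support removing most of the leukopenia; and early, short Filgrastim
(days 2–8) being clearly inferior to schedules that cover the trough
(days 3–12, days 5–13).

# Myelotoxicity quantification

`aoc()` integrates $\max(\text{threshold} - \text{curve}, 0)$ by exact
trapezoids with linear interpolation of threshold crossings.
Conventional thresholds are 2000/ul (ANC), 4000/ul (WBC) and 1
(normalized curves).  The per-drug toxicity correlation analysis
(`toxicity_correlation()`) simulates one injection of every shipped
parameter set without G-CSF, computes normalized AOCs of S, MGB, ANC and
WBC over 28 days, and reports Spearman correlations (average ranks for
ties) of S, MGB and ANC against WBC; one point per parameter-table row,
so the analysis is exactly reproducible.  `scripts/acceptance.R`
recomputes these three coefficients from scratch.

The G-CSF schedule analyses (`simulate_gcsf_variants()`,
`schedule_grid()`) compare leukopenia across schedules.  The test suite
evaluates the CHOP-14 schedule orderings on the normalized WBC curve
with threshold 1: under the default lymphotoxicity coupling the
simulated *median* curves with any G-CSF support do not cross the
absolute 4000/ul line, which would make absolute-threshold comparisons
degenerate (all zero), whereas the normalized threshold ranks schedules
by their full deficit.

# Parameter estimation

The cost of a candidate parameter set is
$\int_{t_0}^{t_1} |\log f_{model} - \log f_{data}|\,dt$ per scenario,
summed unweighted over scenarios; $f_{data}$ is the linear interpolation
of the observed medians (interpolated on the linear scale, logged
afterwards), the quadrature is trapezoidal on the union of the model
grid and the data days, and logs are natural (the argmin is scale-free).
Blood counts are approximately log-normal, which motivates the log
scale; the $L_1$ form is robust to single outlying medians.

Minimization uses a $(\mu+\lambda)$ evolutionary strategy in
log-parameter space with per-coordinate self-adaptive step sizes
(defaults $\mu = 5$, $\lambda = 35$, 200 generations; all hyperparameters
in `es_control()`).  Initial candidates are sampled log-uniformly within
the box bounds; bounds are enforced by projection, ordering constraints
between parameter sets ("escalated at least as toxic as baseline") by a
penalty, and step sizes are re-inflated after prolonged stagnation.  The
fit is a pure function of the seed.  `stepwise_protocol()` runs ordered
fitting steps, freezing every earlier result bit-identically —
`default_protocol()` ships the nine-step design used for the reference
table, with scenarios 12, 22 and 32 reserved for validation and never
fitted.

Identifiability caveat: toxicity on CG, PGB and MGB can partially
compensate each other in the peripheral counts, so recovery experiments
assert only the stem-cell and lymphocyte coefficients and the predicted
curves.  The shipped recovery experiments free $(K_S, K_{WBC})$, the two
best-determined coefficients.

# Synthetic data

`generate_observed()` samples a simulated count curve at clinic-visit
days (default three per week), multiplies by $e^{N(0,\sigma^2)}$ noise
and clips at a detection floor — a pure function of configuration and
seed.  It emulates the *median* curves of patient cohorts: multiplicative
log-normal scatter around a smooth model truth.  It does not emulate
inter-patient variability structure, correlated measurement error,
treatment modifications in response to cytopenia, or model
misspecification; passing recovery tests therefore demonstrate that the
estimation machinery works, not that real clinical series are fitted
this well.  `damage_experiment_suite()` packages the three simplified one-injection
experiments (stem-cell-only, PGB-only, all-stage damage).

# Numerical choices

* Integration: `deSolve::ode` (lsoda), relative tolerance $10^{-6}$,
  absolute $10^{-9}$; infusion starts/ends, injections and prednisone
  boundaries are integration restarts, so every right-hand side is
  smooth within a segment and injections are never stepped over.
  G-CSF injections enter as depot boluses at segment starts.
* Output: dense grid of 0.1 day plus all event times; compartment values
  are floored at 0 inside the right-hand side to avoid negative
  excursions at solver tolerance scale.
* The damage chains are integrated inside the coupled system (so
  arbitrary overlapping schedules work); the Erlang-4 closed form serves
  as an independent test oracle only.  The per-drug forcing trace
  attached to results is re-integrated from the chains alone on the
  regular grid, so G-CSF variants of one chemotherapy backbone carry
  identical traces.
* AOC quadrature is exact for piecewise-linear curves, including
  threshold crossings inside grid intervals.
* Ties in Spearman correlations use average ranks.

Problem sizes in the shipped tests were chosen to keep the default suite
in the minutes range: 28-day single-injection runs for the correlation
analysis (22 simulations), 84-day six-cycle runs for the CHOP-14
schedule comparisons, 100–250-day runs for homeostasis, and recovery
fits with $\mu = 4$, $\lambda = 10$ and 40–50 generations on daily
sampled series.

# Known limitations

* The model predicts cohort *medians*; individual trajectories and hard
  clinical endpoints (febrile neutropenia, antibiotics, hospitalization)
  are out of scope.
* Cell-kinetic and PK constants are package defaults calibrated to
  qualitative behaviour, not published estimates; absolute nadir depths
  under the default parameters are shallower than severe clinical
  courses.
* The lymphocyte sub-model is deliberately minimal (no lymphocyte
  kinetics, a single constant baseline) and its coupling strength is a
  documented convention (see above).
* Drug toxicity is phenomenological: no drug pharmacokinetics, no
  cell-cycle specificity, no distinction between cytostatic and
  cytotoxic action, and no interactions between drugs beyond additivity
  (fixed combinations that violate additivity, such as
  carboplatin/paclitaxel, carry their own joint parameter set).
* Parameter sets are specific to drug, dose and risk group; applying
  them to other doses requires re-estimation.
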