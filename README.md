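# granulosim

Simulation of human granulopoiesis under cytotoxic chemotherapy with
G-CSF support (Filgrastim / Pegfilgrastim).

Cytotoxic chemotherapy suppresses the production of neutrophil
granulocytes; the resulting neutropenia is the most common dose-limiting
side effect of dose-dense regimens such as CHOP-14 or BEACOPP.  The
growth factor G-CSF is routinely given to shorten neutropenia, but the
best derivative, dose, starting day and duration depend on the regimen
and the patient group, and cannot be screened exhaustively in trials.
`granulosim` implements a compartmental pharmacokinetic/pharmacodynamic
model of granulopoiesis coupled to a phenomenological chemotherapy
toxicity model, so that alternative G-CSF schedules can be simulated and
ranked by predicted myelotoxicity.  Its intended users are modellers and
quantitative clinical researchers working on chemotherapy-associated
neutropenia.

## The model

Five cell compartments are tracked, normalized so that the healthy
steady state of each is 1: haematopoietic stem cells (S), granulopoietic
progenitors (CG), proliferating precursors (PGB), maturing precursors
(MGB) and circulating granulocytes (GRA).  Each compartment obeys a
balance equation of influx, production and efflux,

    dC_X/dt = C_in(t) * A(t) - C_X(t) / T_X(t) - Psi_X(t) * C_X(t),

where `A` is the amplification of cell numbers, `T_X` the transit
(mean residence) time, and `Psi_X` a chemotherapy-induced loss rate.
G-CSF regulates PGB amplification and PGB transit time upward, and MGB
transit time, MGB apoptosis and the stem-cell self-renewal fraction
downward, through anchored Hill curves; endogenous G-CSF production is
demand-regulated.  Filgrastim pools with endogenous G-CSF, Pegfilgrastim
is a separate species with granulocyte-mediated elimination.

Chemotherapy enters as normalized injection pulses (unit area per
injection) smoothed by a four-stage delay chain (Erlang-4 kernel);
the delayed signal times a drug-, dose- and cell-stage-specific toxicity
coefficient `K_X` gives the first-order loss rate `Psi_X`, with a
first-cycle factor `f_fc >= 1` and additive combination of simultaneous
drugs.  Leukocytes are modelled as `WBC = ANC + 3000 * exp(-Psi_LY)`
cells/ul.  A reference table of toxicity parameter sets for 22
drugs/dose levels (CHOP, etoposide, procarbazine, bleomycin, taxanes,
anthracyclines, platinum drugs, cytarabine, ...) ships with the package,
as does a machine-readable library of the common regimens and 33
clinical G-CSF scenarios.

Myelotoxicity is summarized as the AOC: the area between a threshold and
the cell-count curve where the curve lies below the threshold
(2000/ul for ANC, 4000/ul for WBC, 1 for normalized counts).  Toxicity
parameters for new drugs are estimated from median blood-count series by
minimizing the integral of `|log model - log data|` with a
(mu+lambda) evolutionary strategy, optionally through a stepwise
protocol with frozen earlier estimates and ordering constraints.

## Worked example

Simulate dose-dense CHOP in elderly patients with and without Filgrastim
support (clinical scenario 21: 480 ug on days 4-13 of each 14-day
cycle, 6 cycles), and quantify the leukopenia:

```r
library(granulosim)

rg    <- scenario_regimen(21)          # CHOP-14 elderly + fil d4-13
sim_g <- simulate_therapy(rg)
sim_0 <- simulate_therapy(with_gcsf(rg, "none"))

round(min(sim_0$wbc))                  # WBC nadir without G-CSF, /ul
round(min(sim_g$wbc))                  # WBC nadir with support, /ul
aoc(sim_0$time_day, sim_0$wbc_norm, 1, c(0, 84), curve_id = "WBC, no G-CSF")
aoc(sim_g$time_day, sim_g$wbc_norm, 1, c(0, 84), curve_id = "WBC, fil d4-13")
```

which prints

```
[1] 5372
[1] 7853
<gs_aoc> WBC, no G-CSF: AOC = 13.8 (threshold 1, window 0-84 d)
<gs_aoc> WBC, fil d4-13: AOC = 0.0048195 (threshold 1, window 0-84 d)
```

The normalized AOC of 13.8 days without support means the cumulative
leukocyte deficit over six cycles equals 13.8 days of a complete count
loss; the supported schedule removes it almost entirely.  Alternative
schedules can be ranked with `simulate_gcsf_variants()` or on a
dose-by-duration grid with `schedule_grid()`; `toxicity_correlation()`
reproduces the per-drug comparison of stem-cell versus peripheral
toxicity, and `fit_toxicity()` / `stepwise_protocol()` estimate toxicity
parameters from observed median curves.

A command-line interface is provided as `inst/cli/granulosim.R` with
`simulate`, `fit`, `aoc`, `correlate` and `optimize` subcommands.

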