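# Default cell-kinetic and G-CSF PK/PD parameters of the granulopoiesis
# model.  Internal time unit is hours; concentrations are pg/ml; cell
# counts are cells/ul.  Effect curves are Hill functions; baselines are
# taken from `transit_times`/`apoptosis_base` (amplification baseline 1)
# and the Filgrastim curves are anchored so that the endogenous
# steady-state G-CSF concentration maps exactly to the baseline value of
# each regulated quantity.
version: 1
time_unit: hours
steady_state:
  anc: 5000.0          # absolute neutrophil count, cells/ul
  gcsf: 25.0           # endogenous G-CSF serum level, pg/ml
  lymphocytes: 3000.0  # constant lymphocyte concentration, cells/ul
transit_times:         # mean residence times, hours
  S: 360.0             # stem cells: slow turnover, recovery over weeks
  CG: 96.0
  PGB: 96.0
  MGB: 120.0
  GRA: 7.0             # blood residence of mature neutrophils
stem_cell:
  a_max: 0.7           # maximal self-renewal fraction as S -> 0
  shape: 2.0           # steepness of the self-renewal response
apoptosis_base: 0.004  # baseline MGB apoptosis/clearance rate, 1/h
effects:
  fil:                 # Filgrastim (pools with endogenous G-CSF)
    pgb_amplification: {max: 8.0,    ec50: 2000.0, hill: 1.2}
    pgb_transit:       {max: 192.0,  ec50: 200.0,  hill: 2.0}
    mgb_transit:       {min: 20.0,   ec50: 1200.0, hill: 1.3}
    apoptosis:         {min: 0.0004, ec50: 1200.0, hill: 1.3}
    stem_renewal:      {min: 0.45,   ec50: 300.0,  hill: 1.5}
  peg:                 # Pegfilgrastim (separate molecular species)
    pgb_amplification: {max: 8.0,    ec50: 4000.0, hill: 1.2}
    pgb_transit:       {max: 192.0,  ec50: 400.0,  hill: 2.0}
    mgb_transit:       {min: 20.0,   ec50: 2400.0, hill: 1.3}
    apoptosis:         {min: 0.0004, ec50: 2400.0, hill: 1.3}
    stem_renewal:      {min: 0.45,   ec50: 600.0,  hill: 1.5}
pk:
  fil: {ka: 0.35, bioavailability: 0.6, volume_ml: 2500.0, k_lin: 0.03,
        vmax: 900.0, km: 1500.0}
  peg: {ka: 0.05, bioavailability: 0.6, volume_ml: 2500.0, k_lin: 0.002,
        vmax: 800.0, km: 3000.0}
  production: {beta: 0.05, hill: 4.0}
# lymphotoxicity coupling: "hour" multiplies K_WBC by the WBC chain
# output in 1/h (the direct analogue of the marrow toxicity term);
# "day" rescales the output to 1/d; "state" uses the dimensionless
# 4th chain state and yields deep clinical-grade lymphopenia
psi_ly_coupling: hour
prednisone_factor: 0.7 # multiplier on GRA clearance while prednisone active
body: {mass_kg: 70.0, bsa_m2: 1.8}
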