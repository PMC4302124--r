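# Core granulopoiesis model: derived constants, steady state and the
# right-hand sides of the cell-kinetic and G-CSF pharmacokinetic ODEs.
#
# Compartments are normalized to a steady state of 1.  The derived influx
# amplifications phi_X balance influx and efflux exactly at baseline, so
# the normalized steady state is 1 by construction:
#   dS   = (2 a(S) - 1) S / T_S                        - psi_S S
#   dCG  = phi_CG  2 (1 - a(S)) S / T_S   - CG / T_CG  - psi_CG CG
#   dPGB = phi_PGB w_amp(G) CG / T_CG     - PGB / T_P(G) - psi_PGB PGB
#   dMGB = phi_MGB PGB / T_P(G) - MGB / T_M(G) - d_ap(G) MGB - psi_MGB MGB
#   dGRA = phi_GRA MGB / T_M(G) - m_pred GRA / T_GRA
# where a(S) is the stem-cell self-renewal fraction, w_amp, T_P, T_M and
# d_ap are the four G-CSF regulated quantities and m_pred <= 1 is the
# prednisone clearance multiplier.

# Precompute everything the right-hand side needs: effect-curve
# coefficients, influx amplifications and the endogenous production rate.
build_model <- function(params) {
  tt <- params$transit_times
  ap0 <- params$apoptosis_base
  phi <- c(CG = tt$S / tt$CG,
           PGB = tt$CG / tt$PGB,
           MGB = tt$PGB * (1 / tt$MGB + ap0),
           GRA = tt$MGB / tt$GRA)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("parameters admit no positive influx/efflux balance (",
         paste(names(phi)[!is.finite(phi) | phi <= 0], collapse = ", "),
         ")", call. = FALSE)
  curves <- list()
  for (deriv in c("fil", "peg"))
    for (q in names(params$effects[[deriv]]))
      curves[[deriv]][[q]] <- effect_curve(params, q, deriv)
  pkf <- params$pk$fil; pkp <- params$pk$peg
  css <- params$steady_state$gcsf
  # endogenous production balancing elimination at baseline (GRA = 1)
  p0 <- pkf$k_lin * css + pkf$vmax * css / (pkf$km + css)
  list(params = params, phi = phi, curves = curves, p0 = p0,
       css = css, tt = tt, ap0 = ap0,
       a_max = params$stem_cell$a_max, nu = params$stem_cell$shape,
       c_stem = 2 * params$stem_cell$a_max - 1,
       pkf = pkf, pkp = pkp, prod = params$pk$production,
       anc_ss = params$steady_state$anc,
       c_ly = params$steady_state$lymphocytes)
}

# Combined pharmacodynamic effect of Filgrastim/endogenous G-CSF (conc cf)
# and Pegfilgrastim (conc cp): the Filgrastim curve evaluated at cf plus
# the Pegfilgrastim increment relative to zero concentration, clipped to
# the admissible range of the quantity.
combined_effect <- function(model, quantity, cf, cp) {
  cv_f <- model$curves$fil[[quantity]]
  val <- eval_effect_curve(cv_f, cf)
  if (cp > 0) {
    cv_p <- model$curves$peg[[quantity]]
    val <- val + (eval_effect_curve(cv_p, cp) - cv_p$base)
    lo <- min(cv_f$lo, cv_p$lo); hi <- max(cv_f$hi, cv_p$hi)
    val <- min(max(val, lo), hi)
  }
  val
}

#' Unperturbed steady state of the model
#'
#' Returns the model state at which the right-hand side vanishes without
#' treatment: all normalized cell compartments equal 1 (by construction of
#' the derived influx amplifications), the G-CSF serum concentration
#' equals its endogenous steady-state value, depots and damage chains are
#' empty.
#'
#' @param params a `gs_params` object.
#' @return named numeric vector with components `S`, `CG`, `PGB`, `MGB`,
#'   `GRA` (normalized), `dep_fil`, `con_fil`, `dep_peg`, `con_peg`, and
#'   attribute `anc` (absolute steady-state ANC, cells/ul).
#' @export
steady_state <- function(params = kinetic_params()) {
  model <- build_model(params)
  structure(c(S = 1, CG = 1, PGB = 1, MGB = 1, GRA = 1,
              dep_fil = 0, con_fil = model$css, dep_peg = 0, con_peg = 0),
            anc = model$anc_ss)
}

#' Right-hand side of the cell-kinetic equations
#'
#' Balance of cell influx (amplified efflux of the upstream compartment),
#' cell efflux and a proportional chemotherapy cell-loss term, evaluated
#' at a given G-CSF concentration.  Exposed mainly for inspection and
#' testing; the simulation engine integrates the same kinetics jointly
#' with the PK and damage-chain states.
#'
#' @param state named vector with `S`, `CG`, `PGB`, `MGB`, `GRA`
#'   (normalized, >= 0).
#' @param gcsf_conc Filgrastim/endogenous G-CSF concentration, pg/ml.
#' @param toxicity named loss rates (1/h) per compartment; missing
#'   entries are 0.  `GRA` losses are admitted here for experimentation
#'   even though the shipped toxicity sets act on marrow stages only.
#' @param gcsf_conc_peg Pegfilgrastim concentration, pg/ml.
#' @param prednisone_mult multiplier on the GRA clearance rate, in (0, 1].
#' @param params a `gs_params` object.
#' @return named derivative vector (per hour).
#' @export
cell_kinetic_rhs <- function(state, gcsf_conc,
                             toxicity = c(S = 0, CG = 0, PGB = 0,
                                          MGB = 0, GRA = 0),
                             gcsf_conc_peg = 0, prednisone_mult = 1,
                             params = kinetic_params()) {
  if (any(is.na(state)) || any(state < 0))
    stop("state must be non-negative and free of NAs", call. = FALSE)
  model <- build_model(params)
  psi <- c(S = 0, CG = 0, PGB = 0, MGB = 0, GRA = 0)
  psi[names(toxicity)] <- toxicity
  cell_rhs_core(model, state[["S"]], state[["CG"]], state[["PGB"]],
                state[["MGB"]], state[["GRA"]], gcsf_conc, gcsf_conc_peg,
                psi, prednisone_mult)
}

cell_rhs_core <- function(model, S, CG, PGB, MGB, GRA, cf, cp, psi,
                          pred_mult) {
  a <- model$a_max / (1 + model$c_stem * S^model$nu)
  # demand regulation: G-CSF above its steady state tilts stem-cell
  # divisions from self-renewal towards differentiation (multiplier 1 at
  # the steady-state concentration), so downstream damage propagates
  # upstream as a transient stem-cell dip
  if (!is.null(model$curves$fil$stem_renewal))
    a <- min(a * combined_effect(model, "stem_renewal", cf, cp), 0.995)
  w_amp <- combined_effect(model, "pgb_amplification", cf, cp)
  Tp <- combined_effect(model, "pgb_transit", cf, cp)
  Tm <- combined_effect(model, "mgb_transit", cf, cp)
  ap <- combined_effect(model, "apoptosis", cf, cp)
  tt <- model$tt; phi <- model$phi
  flux_S <- S / tt$S
  flux_CG <- CG / tt$CG
  flux_PGB <- PGB / Tp
  flux_MGB <- MGB / Tm
  c(S = (2 * a - 1) * flux_S - psi[["S"]] * S,
    CG = phi[["CG"]] * 2 * (1 - a) * flux_S - flux_CG - psi[["CG"]] * CG,
    PGB = phi[["PGB"]] * w_amp * flux_CG - flux_PGB - psi[["PGB"]] * PGB,
    MGB = phi[["MGB"]] * flux_PGB - flux_MGB - ap * MGB - psi[["MGB"]] * MGB,
    GRA = phi[["GRA"]] * flux_MGB - pred_mult * GRA / tt$GRA -
      psi[["GRA"]] * GRA)
}

#' Right-hand side of the G-CSF pharmacokinetic sub-model
#'
#' Subcutaneous depot absorption into a central compartment, elimination
#' by linear clearance plus saturable granulocyte-mediated clearance
#' proportional to the current normalized granulocyte count, and
#' demand-regulated endogenous production (production rises when GRA falls
#' below 1).  Filgrastim pools with endogenous G-CSF; Pegfilgrastim is a
#' separate species with negligible linear clearance.  Injections enter as
#' depot boluses at event times and are therefore not part of this
#' continuous right-hand side.
#'
#' @param state named vector with `dep_fil` (pg), `con_fil` (pg/ml),
#'   `dep_peg` (pg), `con_peg` (pg/ml).
#' @param gra normalized granulocyte count, >= 0.
#' @param params a `gs_params` object.
#' @return named derivative vector (per hour).
#' @export
gcsf_pk_rhs <- function(state, gra, params = kinetic_params()) {
  model <- build_model(params)
  gcsf_rhs_core(model, state[["dep_fil"]], state[["con_fil"]],
                state[["dep_peg"]], state[["con_peg"]], gra)
}

gcsf_rhs_core <- function(model, df, cf, dp, cp, gra) {
  pkf <- model$pkf; pkp <- model$pkp; pr <- model$prod
  production <- model$p0 * (1 + pr$beta) / (pr$beta + gra^pr$hill)
  c(dep_fil = -pkf$ka * df,
    con_fil = pkf$ka * df / pkf$volume_ml + production -
      pkf$k_lin * cf - pkf$vmax * gra * cf / (pkf$km + cf),
    dep_peg = -pkp$ka * dp,
    con_peg = pkp$ka * dp / pkp$volume_ml -
      pkp$k_lin * cp - pkp$vmax * gra * cp / (pkp$km + cp))
}
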