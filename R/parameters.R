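# Cell-kinetic and PK/PD parameters of the granulopoiesis model.
#
# The model tracks five normalized cell compartments
#   S   - haematopoietic stem cells
#   CG  - granulopoietic progenitors
#   PGB - proliferating granulopoietic precursors (mitotic)
#   MGB - maturing granulopoietic precursors (post-mitotic)
#   GRA - mature granulocytes in peripheral blood
# normalized so that the unperturbed steady state of every compartment is 1.
# G-CSF regulates four quantities: PGB amplification and PGB transit time
# increase with the G-CSF serum concentration, while MGB transit time and
# the MGB apoptosis/clearance rate decrease.

.gs_env <- new.env(parent = emptyenv())

#' Cell-kinetic parameters of the granulopoiesis model
#'
#' Returns the model parameter set, by default the parameter file shipped
#' with the package (`inst/extdata/kinetic_parameters.yaml`).  Individual
#' entries can be overridden via `...` using the same nested structure,
#' e.g. `kinetic_params(steady_state = list(anc = 4000))` replaces the
#' steady-state ANC and keeps everything else.
#'
#' @param file optional path to a parameter file (YAML) replacing the
#'   shipped defaults.
#' @param ... named overrides, merged recursively into the parameter list.
#' @return an object of class `gs_params`: a named list with components
#'   `steady_state` (anc in cells/ul, gcsf in pg/ml, lymphocytes in
#'   cells/ul), `transit_times` (hours, one per compartment),
#'   `stem_cell` (self-renewal curve), `apoptosis_base` (1/h), `effects`
#'   (Hill effect-curve parameters per G-CSF derivative), `pk`
#'   (absorption/elimination constants per derivative and the endogenous
#'   production regulation), `prednisone_factor` and `body`.
#' @export
kinetic_params <- function(file = NULL, ...) {
  if (is.null(file)) {
    if (is.null(.gs_env$default_params)) {
      path <- system.file("extdata", "kinetic_parameters.yaml",
                          package = "granulosim", mustWork = TRUE)
      .gs_env$default_params <- yaml::read_yaml(path)
    }
    p <- .gs_env$default_params
  } else {
    p <- yaml::read_yaml(file)
  }
  dots <- list(...)
  if (length(dots)) p <- modifyList(p, dots)
  p <- structure(p, class = "gs_params")
  validate_params(p)
  p
}

#' Write a parameter set to a YAML file
#'
#' @param params a `gs_params` object.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_kinetic_params <- function(params, file) {
  stopifnot(inherits(params, "gs_params"))
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

validate_params <- function(p) {
  tt <- unlist(p$transit_times)
  if (length(tt) != 5L || any(!is.finite(tt)) || any(tt <= 0))
    stop("all transit times must be finite and > 0", call. = FALSE)
  if (p$stem_cell$a_max <= 0.5 || p$stem_cell$a_max > 1)
    stop("stem_cell a_max must lie in (0.5, 1]", call. = FALSE)
  if (p$stem_cell$shape <= 0)
    stop("stem_cell shape must be > 0", call. = FALSE)
  if (p$steady_state$anc <= 0 || p$steady_state$gcsf <= 0)
    stop("steady-state ANC and G-CSF must be > 0", call. = FALSE)
  if (p$apoptosis_base < 0)
    stop("apoptosis_base must be >= 0", call. = FALSE)
  for (deriv in names(p$effects)) {
    for (q in names(p$effects[[deriv]])) {
      e <- p$effects[[deriv]][[q]]
      base <- effect_baseline(p, q)
      if (e$hill <= 0) stop("Hill exponent must be > 0 (", q, ")", call. = FALSE)
      if (e$ec50 <= 0) stop("EC50 must be > 0 (", q, ")", call. = FALSE)
      if (!is.null(e$max) && e$max < base)
        stop("effect max below baseline for ", q, call. = FALSE)
      if (!is.null(e$min) && e$min > base)
        stop("effect min above baseline for ", q, call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.gs_params <- function(x, ...) {
  cat("<gs_params> granulopoiesis model parameters (version ",
      x$version, ")\n", sep = "")
  cat("  steady state: ANC ", x$steady_state$anc, "/ul, G-CSF ",
      x$steady_state$gcsf, " pg/ml, LY ", x$steady_state$lymphocytes,
      "/ul\n", sep = "")
  cat("  transit times (h):",
      paste(names(x$transit_times), unlist(x$transit_times),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Baseline (steady-state) value of a regulated quantity.
effect_baseline <- function(params, quantity) {
  switch(quantity,
    pgb_amplification = 1,
    pgb_transit       = params$transit_times$PGB,
    mgb_transit       = params$transit_times$MGB,
    apoptosis         = params$apoptosis_base,
    stem_renewal      = 1,
    stop("unknown G-CSF regulated quantity: ", quantity, call. = FALSE))
}

effect_direction <- function(quantity) {
  switch(quantity,
    pgb_amplification = 1, pgb_transit = 1,
    mgb_transit = -1, apoptosis = -1, stem_renewal = -1,
    stop("unknown G-CSF regulated quantity: ", quantity, call. = FALSE))
}

# Resolve the four Hill-curve coefficients (lo, hi, ec50, h) of a quantity
# for one derivative.  Filgrastim pools with endogenous G-CSF, so its curve
# is anchored at the endogenous steady-state concentration: the missing
# endpoint is solved such that E(gcsf_ss) equals the baseline exactly.
# Pegfilgrastim is absent at steady state, so its curve is anchored at
# concentration 0 and gcsf_effect() reports the increment-bearing curve.
effect_curve <- function(params, quantity, derivative) {
  e <- params$effects[[derivative]][[quantity]]
  if (is.null(e))
    stop("unknown quantity/derivative: ", quantity, "/", derivative,
         call. = FALSE)
  base <- effect_baseline(params, quantity)
  dir <- effect_direction(quantity)
  h <- e$hill; ec50 <- e$ec50
  if (derivative == "fil") {
    cs <- params$steady_state$gcsf
    Hs <- cs^h / (cs^h + ec50^h)
    if (dir > 0) {
      hi <- e$max
      lo <- (base - hi * Hs) / (1 - Hs)
      if (lo < 0) stop("effect curve for ", quantity,
                       " cannot be anchored (min < 0)", call. = FALSE)
    } else {
      lo <- e$min
      hi <- (base - lo * Hs) / (1 - Hs)
    }
  } else if (derivative == "peg") {
    if (dir > 0) { lo <- base; hi <- e$max } else { lo <- e$min; hi <- base }
  } else stop("unknown G-CSF derivative: ", derivative, call. = FALSE)
  list(lo = lo, hi = hi, ec50 = ec50, h = h, dir = dir, base = base)
}

eval_effect_curve <- function(curve, conc) {
  H <- conc^curve$h / (conc^curve$h + curve$ec50^curve$h)
  H[conc <= 0] <- 0
  if (curve$dir > 0) curve$lo + (curve$hi - curve$lo) * H
  else curve$hi - (curve$hi - curve$lo) * H
}

#' G-CSF concentration-effect curves
#'
#' Hill-type pharmacodynamic effect of a G-CSF serum concentration on one
#' of the four regulated quantities.  PGB amplification and PGB transit
#' time increase with concentration; MGB transit time and the MGB
#' apoptosis rate decrease.  For Filgrastim (which is indistinguishable
#' from endogenous G-CSF) the curve passes exactly through the baseline
#' value at the endogenous steady-state concentration; for Pegfilgrastim
#' (a distinct species, absent at steady state) it passes through the
#' baseline at concentration 0.
#'
#' @param concentration G-CSF serum concentration(s), pg/ml, >= 0.
#' @param quantity one of `"pgb_amplification"` (dimensionless multiplier),
#'   `"pgb_transit"` (hours), `"mgb_transit"` (hours), `"apoptosis"` (1/h).
#' @param derivative `"fil"` or `"peg"`.
#' @param params a `gs_params` object.
#' @return numeric vector of effect values, same length as `concentration`.
#' @export
gcsf_effect <- function(concentration, quantity,
                        derivative = c("fil", "peg"),
                        params = kinetic_params()) {
  derivative <- match.arg(derivative)
  if (any(is.na(concentration)) || any(concentration < 0))
    stop("concentration must be >= 0", call. = FALSE)
  curve <- effect_curve(params, quantity, derivative)
  out <- eval_effect_curve(curve, concentration)
  out[is.infinite(concentration)] <-
    if (curve$dir > 0) curve$hi else curve$lo
  out
}

#' Stem-cell self-renewal regulation
#'
#' Fraction of stem-cell divisions that self-renew, as a function of the
#' normalized stem-cell content.  The fraction decreases monotonically in
#' `S`, exceeds 1/2 for depleted marrow (`S < 1`, net regrowth) and equals
#' exactly 1/2 at the steady state `S = 1`, the fixed-point condition of
#' the stem-cell balance.
#'
#' @param S normalized stem-cell content(s), >= 0.
#' @param params a `gs_params` object.
#' @return self-renewal fraction(s) in (0, 1).
#' @export
stem_cell_regulation <- function(S, params = kinetic_params()) {
  if (any(S < 0, na.rm = TRUE)) stop("S must be >= 0", call. = FALSE)
  a_max <- params$stem_cell$a_max
  nu <- params$stem_cell$shape
  # a(1) = 1/2 by construction: a(S) = a_max / (1 + (2 a_max - 1) S^nu)
  a_max / (1 + (2 * a_max - 1) * S^nu)
}
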