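# Chemotherapy toxicity sub-model: injection pulses, four-stage delay
# chains, cell-stage specific toxicity coefficients, first-cycle effect,
# additive drug combination, the lymphocyte/WBC sub-model and the
# prednisone (non-cytotoxic) modifier.
#
# Each cytotoxic drug (or fixed drug combination) is characterized by
# eight parameters: a first-cycle factor f_fc >= 1, a delay rate k_delay
# (1/h) of the four-stage marrow damage chain, four toxicity coefficients
# K_S, K_CG, K_PGB, K_MGB, and a separate delay rate plus coefficient for
# the lymphocyte (WBC) chain.  The injection pulse has unit area per
# injection, so the chain output integrates to the number of injections
# and the K coefficients are dose-normalized.

#' Reference toxicity parameter table
#'
#' The packaged reference table of drug-specific toxicity parameter sets
#' (one row per drug, dose and risk group).  Columns: `label` (short
#' identifier used by the regimen library), `drug_label`, `description`,
#' `group` (protocol family), `risk_group` (`young`, `elderly` or `all`),
#' `f_fc`, `k_delay` (1/h), `K_S`, `K_CG`, `K_PGB`, `K_MGB`,
#' `k_delay_wbc` (1/h), `K_WBC` and the default `infusion_h`.  Drugs whose
#' estimation data were ANC-based carry `NA` in the WBC columns: no
#' lymphocyte toxicity is modelled for them.
#'
#' @return a data.frame with 22 rows.
#' @export
toxicity_table <- function() {
  if (is.null(.gs_env$tox_table)) {
    path <- system.file("extdata", "toxicity_parameters.csv",
                        package = "granulosim", mustWork = TRUE)
    .gs_env$tox_table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .gs_env$tox_table
}

#' Construct or look up a toxicity parameter set
#'
#' With a single character argument, looks the label up in
#' [toxicity_table()].  Alternatively a fully specified set can be built
#' from explicit values (for user-defined drugs or fitting).
#'
#' @param label set label (e.g. `"CHOPo"`), or `NULL` when building from
#'   explicit values.
#' @param f_fc first-cycle factor, >= 1.
#' @param k_delay delay rate of the marrow damage chain, 1/h, > 0.
#' @param K named numeric vector with entries `S`, `CG`, `PGB`, `MGB`
#'   (dimensionless toxicity coefficients, >= 0).
#' @param k_delay_wbc delay rate of the lymphocyte chain, 1/h (may be `NA`
#'   together with `K_WBC` for drugs without a modelled lymphocyte effect).
#' @param K_WBC lymphocyte toxicity coefficient.
#' @param infusion_h default infusion duration, hours.
#' @param risk_group,description metadata.
#' @return an object of class `gs_toxset`.
#' @export
toxicity_set <- function(label = NULL, f_fc = 1, k_delay = NULL,
                         K = c(S = 0, CG = 0, PGB = 0, MGB = 0),
                         k_delay_wbc = NA_real_, K_WBC = NA_real_,
                         infusion_h = 1, risk_group = "all",
                         description = "") {
  if (!is.null(label) && is.null(k_delay)) {
    tab <- toxicity_table()
    row <- tab[tab$label == label, ]
    if (nrow(row) != 1L)
      stop("unknown toxicity set label: ", label, call. = FALSE)
    return(toxicity_set(label = row$label, f_fc = row$f_fc,
                        k_delay = row$k_delay,
                        K = c(S = row$K_S, CG = row$K_CG,
                              PGB = row$K_PGB, MGB = row$K_MGB),
                        k_delay_wbc = row$k_delay_wbc, K_WBC = row$K_WBC,
                        infusion_h = row$infusion_h,
                        risk_group = row$risk_group,
                        description = row$description))
  }
  K <- K[c("S", "CG", "PGB", "MGB")]
  if (any(is.na(K)) || any(K < 0))
    stop("toxicity coefficients K must be named S/CG/PGB/MGB and >= 0",
         call. = FALSE)
  if (is.na(f_fc) || f_fc < 1)
    stop("first-cycle factor f_fc must be >= 1", call. = FALSE)
  if (is.null(k_delay) || is.na(k_delay) || k_delay <= 0)
    stop("delay rate k_delay must be > 0", call. = FALSE)
  wbc <- !is.na(K_WBC) && !is.na(k_delay_wbc)
  if (wbc && (k_delay_wbc <= 0 || K_WBC < 0))
    stop("WBC delay rate must be > 0 and K_WBC >= 0", call. = FALSE)
  structure(list(label = if (is.null(label)) "custom" else label,
                 f_fc = f_fc, k_delay = k_delay, K = K,
                 k_delay_wbc = if (wbc) k_delay_wbc else NA_real_,
                 K_WBC = if (wbc) K_WBC else 0,
                 wbc_modelled = wbc, infusion_h = infusion_h,
                 risk_group = risk_group, description = description),
            class = "gs_toxset")
}

#' @export
print.gs_toxset <- function(x, ...) {
  cat("<gs_toxset> ", x$label, " (", x$description, ")\n", sep = "")
  cat("  f_fc =", x$f_fc, " k_delay =", x$k_delay, "/h\n")
  cat("  K:", paste(names(x$K), signif(x$K, 3), sep = "=", collapse = " "),
      "\n")
  if (x$wbc_modelled)
    cat("  WBC: k_delay =", x$k_delay_wbc, "/h, K_WBC =", x$K_WBC, "\n")
  else cat("  WBC: no lymphocyte toxicity modelled\n")
  invisible(x)
}

#' Chemotherapy application of a single drug
#'
#' @param drug drug (or toxicity-set label) identifier.
#' @param times_day application start times in study days (day 1 is the
#'   first study day; the infusion starts at the configured clock time).
#' @param infusion_h infusion duration, hours, > 0.
#' @param dose dose label (metadata; pulses are dose-normalized).
#' @param cytotoxic `FALSE` for prednisone-like drugs.
#' @param clock_h time of day at which infusions start (hours after
#'   midnight, default 8).
#' @return an object of class `gs_application` with `times_h` (absolute
#'   start times in hours) and the remaining fields.
#' @export
drug_application <- function(drug, times_day, infusion_h = 1, dose = NA,
                             cytotoxic = TRUE, clock_h = 8) {
  if (infusion_h <= 0) stop("infusion_h must be > 0", call. = FALSE)
  times_day <- as.numeric(times_day)
  if (any(diff(times_day) <= 0))
    stop("application times must be strictly increasing", call. = FALSE)
  structure(list(drug = drug, times_day = times_day,
                 times_h = (times_day - 1) * 24 + clock_h,
                 infusion_h = infusion_h, dose = dose,
                 cytotoxic = isTRUE(cytotoxic)),
            class = "gs_application")
}

#' Normalized chemotherapy pulse function
#'
#' Piecewise-constant injection pulse: `1/infusion_h` while any infusion
#' of the application is running, 0 otherwise, so that the area under the
#' curve of every single injection equals one.
#'
#' @param application a `gs_application`.
#' @param t time(s) in hours.
#' @return pulse rate(s), 1/h.
#' @export
chemo_pulse <- function(application, t) {
  stopifnot(inherits(application, "gs_application"))
  out <- numeric(length(t))
  for (t0 in application$times_h)
    out <- out + (t >= t0 & t < t0 + application$infusion_h) /
      application$infusion_h
  out
}

#' Right-hand side of the four-stage damage delay chain
#'
#' Four concatenated first-order transitions turning the injection pulse
#' into a delayed, smoothed damage signal (the impulse response is the
#' Erlang-4 density with rate `k_delay`).  The chain input of the first
#' stage is the pulse itself, so area is conserved through every stage and
#' the output integrates to the number of injections.
#'
#' @param chain_state numeric vector of the four chain states.
#' @param input_rate chain input (the pulse rate), 1/h.
#' @param k_delay transition rate, 1/h, > 0.
#' @return list with `deriv` (length-4 derivative) and `output`
#'   (`k_delay * chain_state[4]`, the delayed damage rate in 1/h).
#' @export
delay_chain_rhs <- function(chain_state, input_rate, k_delay) {
  if (k_delay <= 0) stop("k_delay must be > 0", call. = FALSE)
  stopifnot(length(chain_state) == 4L)
  through <- k_delay * chain_state
  deriv <- c(input_rate, through[1:3]) - through
  list(deriv = deriv, output = through[4])
}

#' Cell-stage specific toxicity (loss rate)
#'
#' Multiplies the delayed damage signal by the compartment's toxicity
#' coefficient, applying the first-cycle factor `f_fc` while `t` lies
#' before the start of the drug's second treatment cycle
#' (`t_second_cycle`; `Inf`, the default, keeps the factor active over the
#' whole horizon, appropriate for drugs applied in a single cycle).
#'
#' @param set a `gs_toxset`.
#' @param compartment one of `"S"`, `"CG"`, `"PGB"`, `"MGB"`.
#' @param chain_output delayed damage rate(s) (1/h), >= 0.
#' @param t time(s), hours.
#' @param t_second_cycle first application time (hours) of the drug's
#'   second treated cycle.
#' @return loss rate(s), 1/h.
#' @export
toxicity_function <- function(set, compartment, chain_output, t,
                              t_second_cycle = Inf) {
  stopifnot(inherits(set, "gs_toxset"))
  if (!compartment %in% c("S", "CG", "PGB", "MGB"))
    stop("unknown compartment: ", compartment, call. = FALSE)
  if (any(chain_output < 0)) stop("chain output must be >= 0", call. = FALSE)
  K <- set$K[[compartment]]
  ifelse(t < t_second_cycle, set$f_fc * K, K) * chain_output
}

#' Combine toxicity functions of simultaneously applied drugs
#'
#' Drugs are assumed not to interact: the total loss rate is the pointwise
#' sum of the per-drug toxicity functions.
#'
#' @param per_drug list of numeric vectors (equal length), each >= 0.
#' @return pointwise sum; `0` for an empty list.
#' @export
combine_toxicities <- function(per_drug) {
  if (length(per_drug) == 0L) return(0)
  if (any(vapply(per_drug, function(x) any(x < 0), logical(1))))
    stop("toxicity functions must be >= 0", call. = FALSE)
  Reduce(`+`, per_drug)
}

#' Leukocyte count from neutrophils and the lymphocyte toxicity
#'
#' `WBC = ANC + C_LY * exp(-Psi_LY)` with a constant lymphocyte baseline
#' `C_LY` (3000/ul by default); `Psi_LY` is the dimensionless cumulative
#' lymphotoxicity built from the drug's WBC delay chain.
#'
#' @param anc absolute neutrophil count(s), cells/ul, >= 0.
#' @param psi_ly dimensionless lymphocyte toxicity, >= 0.
#' @param c_ly lymphocyte baseline, cells/ul.
#' @return WBC, cells/ul.
#' @export
wbc_from_anc <- function(anc, psi_ly, c_ly = 3000) {
  if (any(anc < 0) || any(psi_ly < 0))
    stop("anc and psi_ly must be >= 0", call. = FALSE)
  anc + c_ly * exp(-psi_ly)
}

#' Prednisone effect on granulocyte clearance
#'
#' Prednisone is non-cytotoxic but temporarily prolongs the granulocyte
#' half-life.  While any prednisone dose is covering (each application
#' covers 24 h from its start) the GRA clearance rate is multiplied by
#' `factor <= 1`; afterwards the multiplier returns to 1.
#'
#' @param application a non-cytotoxic `gs_application`.
#' @param t time(s), hours.
#' @param factor clearance multiplier during coverage, in (0, 1].
#' @return multiplier value(s).
#' @export
prednisone_effect <- function(application, t, factor = 0.7) {
  stopifnot(inherits(application, "gs_application"))
  if (application$cytotoxic)
    stop("prednisone_effect applies to non-cytotoxic applications only",
         call. = FALSE)
  if (factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]", call. = FALSE)
  covered <- rep(FALSE, length(t))
  for (t0 in application$times_h)
    covered <- covered | (t >= t0 & t < t0 + 24)
  ifelse(covered, factor, 1)
}
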