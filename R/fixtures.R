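# Synthetic clinic-like data: median time series sampled from simulated
# trajectories with multiplicative log-normal noise, plus the named suite
# of simplified single-injection toxicity experiments.

#' Noise model for synthetic observed series
#'
#' @param sigma log-scale standard deviation of the multiplicative
#'   log-normal noise (0 = noise-free).
#' @param floor detection floor, cells/ul (> 0); samples are clipped
#'   from below.
#' @param seed RNG seed.
#' @return a list of class `gs_noise`.
#' @export
noise_model <- function(sigma = 0.2, floor = 50, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (floor <= 0) stop("floor must be > 0", call. = FALSE)
  structure(list(sigma = sigma, floor = floor, seed = seed),
            class = "gs_noise")
}

#' Default clinic-visit sampling days
#'
#' Three visits per week (days 1, 3 and 5 of each week) over the horizon,
#' emulating the sampling density of trial median curves.
#'
#' @param horizon_days study horizon, days.
#' @return numeric vector of study days.
#' @export
clinic_days <- function(horizon_days) {
  d <- as.vector(outer(c(1, 3, 5), seq(0, horizon_days - 1, by = 7), `+`))
  sort(d[d <= horizon_days])
}

#' Generate a synthetic observed median series
#'
#' Simulates a regimen, samples the requested blood count at the given
#' days and applies multiplicative log-normal noise with clipping at the
#' detection floor.  A pure function of its inputs and the noise seed.
#'
#' @param regimen a `gs_regimen`.
#' @param noise a [noise_model()].
#' @param days sampling days (default [clinic_days()] over the horizon).
#' @param count_type `"wbc"` or `"anc"`.
#' @param toxicity,params,horizon_days,solver passed to
#'   [simulate_therapy()].
#' @return a `gs_observed` series.
#' @export
generate_observed <- function(regimen, noise = noise_model(),
                              days = NULL, count_type = c("wbc", "anc"),
                              toxicity = NULL, params = kinetic_params(),
                              horizon_days = NULL,
                              solver = solver_settings()) {
  count_type <- match.arg(count_type)
  sim <- simulate_therapy(regimen, params = params, toxicity = toxicity,
                          horizon_days = horizon_days, solver = solver)
  horizon <- max(sim$time_day)
  days <- days %||% clinic_days(horizon)
  if (any(days < 0) || any(days - 1 > horizon + 1e-9))
    stop("sampling days outside the simulated horizon", call. = FALSE)
  curve <- if (count_type == "wbc") sim$wbc else sim$anc
  # study day d corresponds to simulation time d - 1 (day 1 = t 0)
  vals <- stats::approx(sim$time_day, curve, xout = days - 1,
                        rule = 2)$y
  set.seed(noise$seed)
  if (noise$sigma > 0)
    vals <- vals * exp(stats::rnorm(length(vals), 0, noise$sigma))
  vals <- pmax(vals, noise$floor)
  observed_series(days, vals, count_type = count_type,
                  scenario_id = paste0("synthetic:", regimen$name))
}

#' Simplified single-injection toxicity experiments
#'
#' Three named experiments applying one injection of the elderly CHOP
#' toxicity set with the damage restricted to (a) stem cells only,
#' (b) PGB only, (c) all cell stages.  Each element carries a regimen and
#' a toxicity override ready for [simulate_therapy()].
#'
#' @param horizon_days simulation horizon, days.
#' @return named list (`s_only`, `pgb_only`, `all_stages`) of lists with
#'   `name`, `regimen`, `toxicity`.
#' @export
damage_experiment_suite <- function(horizon_days = 120) {
  base <- toxicity_set("CHOPo")
  mask <- function(set, keep) {
    set$K[setdiff(names(set$K), keep)] <- 0
    set
  }
  rg <- single_injection_regimen("CHOPo", horizon_days = horizon_days)
  list(
    s_only = list(name = "CHOP toxicity on stem cells only",
                  regimen = rg,
                  toxicity = list(CHOPo = mask(base, "S"))),
    pgb_only = list(name = "CHOP toxicity on PGB only",
                    regimen = rg,
                    toxicity = list(CHOPo = mask(base, "PGB"))),
    all_stages = list(name = "CHOP toxicity on all cell stages",
                      regimen = rg,
                      toxicity = list(CHOPo = base)))
}
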