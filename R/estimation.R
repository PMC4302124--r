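# Toxicity-parameter estimation: the log-scale cost integral, a
# (mu + lambda) evolutionary strategy with self-adaptive step sizes, and
# the stepwise constrained fitting protocol.

#' Observed median blood-count series
#'
#' @param day sampling days (study days, non-decreasing).
#' @param value median counts, cells/ul, > 0.
#' @param count_type `"wbc"` or `"anc"`.
#' @param scenario_id optional scenario identifier.
#' @param unit unit label (metadata).
#' @return an object of class `gs_observed` (a data.frame).
#' @export
observed_series <- function(day, value, count_type = c("wbc", "anc"),
                            scenario_id = NA, unit = "cells/ul") {
  count_type <- match.arg(count_type)
  if (any(value <= 0))
    stop("observed values must be > 0 (log scale)", call. = FALSE)
  if (any(diff(day) < 0))
    stop("days must be non-decreasing", call. = FALSE)
  structure(data.frame(day = day, value = value, unit = unit,
                       scenario_id = scenario_id,
                       count_type = count_type),
            class = c("gs_observed", "data.frame"))
}

#' Read / write observed series in CSV form
#'
#' Columns: `day`, `value`, `unit`, `scenario_id`, `count_type`.
#' @param file path.
#' @return a `gs_observed` (for `read_observed`).
#' @export
read_observed <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        comment.char = "#")
  observed_series(df$day, df$value, count_type = df$count_type[1],
                  scenario_id = df$scenario_id[1], unit = df$unit[1])
}

#' @rdname read_observed
#' @param series a `gs_observed`.
#' @export
write_observed <- function(series, file) {
  utils::write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}

#' Log-scale cost between a model curve and observed data
#'
#' The integral of `|log f_model(t) - log f_data(t)|` from the first to
#' the last data day, where `f_data` is the linear interpolation of the
#' data points (interpolated on the linear scale, logged afterwards).
#' Natural logarithms; trapezoidal quadrature on the union of the model
#' grid and the data days.  The log scale reflects the approximately
#' log-normal distribution of blood counts.
#'
#' @param model_time,model_value dense model curve (days, cells/ul).
#' @param series a `gs_observed` (or data.frame with `day`, `value`).
#' @return cost value (days, since log differences are dimensionless).
#' @export
fit_cost <- function(model_time, model_value, series) {
  day <- series$day; val <- series$value
  t0 <- min(day); t1 <- max(day)
  if (min(model_time) > t0 + 1e-9 || max(model_time) < t1 - 1e-9)
    stop("model curve does not span the data window [", t0, ", ", t1, "]",
         call. = FALSE)
  if (any(model_value <= 0))
    stop("model curve must be positive on the data window (log scale)",
         call. = FALSE)
  grid <- sort(unique(c(day, model_time[model_time >= t0 &
                                          model_time <= t1])))
  fm <- stats::approx(model_time, model_value, xout = grid,
                      ties = "ordered")$y
  fd <- stats::approx(day, val, xout = grid, ties = "ordered")$y
  integrand <- abs(log(fm) - log(fd))
  sum(diff(grid) * (integrand[-1] + integrand[-length(integrand)]) / 2)
}

#' Evolutionary-strategy control settings
#'
#' @param mu number of parents.
#' @param lambda number of offspring per generation.
#' @param generations number of generations.
#' @param sigma0 initial mutation step size, as a fraction of the
#'   log-space box width.
#' @param penalty weight of the ordering-constraint penalty.
#' @param stagnation generations without improvement before step sizes
#'   are re-inflated.
#' @return a list of settings.
#' @export
es_control <- function(mu = 5, lambda = 35, generations = 200,
                       sigma0 = 0.25, penalty = 1e3, stagnation = 30) {
  list(mu = mu, lambda = lambda, generations = generations,
       sigma0 = sigma0, penalty = penalty, stagnation = stagnation)
}

# Assemble toxicity sets from frozen sets plus the free-parameter vector.
assemble_sets <- function(free_spec, x, frozen) {
  sets <- frozen
  i <- 0L
  for (lab in names(free_spec)) {
    if (is.null(sets[[lab]])) sets[[lab]] <- toxicity_set(lab)
    s <- sets[[lab]]
    for (field in free_spec[[lab]]) {
      i <- i + 1L
      v <- exp(x[i])
      if (field %in% c("K_S", "K_CG", "K_PGB", "K_MGB")) {
        s$K[[sub("^K_", "", field)]] <- v
      } else if (field == "K_WBC") {
        s$K_WBC <- v; s$wbc_modelled <- TRUE
        if (is.na(s$k_delay_wbc)) s$k_delay_wbc <- 0.02
      } else if (field == "k_delay_wbc") {
        s$k_delay_wbc <- v; s$wbc_modelled <- TRUE
      } else if (field %in% c("f_fc", "k_delay")) {
        s[[field]] <- if (field == "f_fc") max(v, 1) else v
      } else stop("unknown free field: ", field, call. = FALSE)
    }
    sets[[lab]] <- s
  }
  sets
}

n_free <- function(free_spec) sum(lengths(free_spec))

ordering_penalty <- function(sets, constraints) {
  p <- 0
  for (cn in constraints) {
    hi <- sets[[cn$greater]] %||% toxicity_set(cn$greater)
    lo <- sets[[cn$less]] %||% toxicity_set(cn$less)
    for (field in cn$fields) {
      get <- function(s) if (grepl("^K_[SCPM]", field))
        s$K[[sub("^K_", "", field)]] else s[[field]]
      p <- p + max(0, get(lo) - get(hi))
    }
  }
  p
}

#' Fit toxicity parameters to observed median series
#'
#' Minimizes the summed log-scale cost ([fit_cost()]) over one or more
#' scenarios by a (mu + lambda) evolutionary strategy in log-parameter
#' space with per-coordinate self-adaptive step sizes, box constraints
#' (projection) and ordering constraints between parameter sets
#' (penalty).  Toxicity sets fitted earlier can be passed as `frozen` and
#' remain untouched.
#'
#' @param scenarios list; each element a list with `series` (a
#'   `gs_observed`) and `regimen` (a `gs_regimen`).  Costs are summed
#'   over scenarios (unweighted).
#' @param free named list: toxicity-set label -> character vector of free
#'   fields (`"K_S"`, `"K_CG"`, `"K_PGB"`, `"K_MGB"`, `"K_WBC"`,
#'   `"k_delay"`, `"k_delay_wbc"`, `"f_fc"`).
#' @param frozen named list of `gs_toxset` objects overriding the shipped
#'   table (kept constant).
#' @param bounds length-2 vector (or named list per `label.field`) of
#'   box bounds on the natural scale.
#' @param constraints list of ordering constraints, each
#'   `list(greater = <label>, less = <label>, fields = <character>)`
#'   demanding elementwise `greater >= less`.
#' @param seed RNG seed (the fit is deterministic given the seed).
#' @param control an [es_control()] list.
#' @param params,solver model parameters and solver settings.
#' @return an object of class `gs_fit`: list with `sets` (best-found
#'   toxicity sets), `cost`, `initial_cost`, `trace` (data.frame
#'   generation/best cost), `free`, `frozen_manifest`, `constraints_ok`,
#'   `converged`, `seed`.
#' @export
fit_toxicity <- function(scenarios, free, frozen = list(),
                         bounds = c(1e-6, 1e3), constraints = list(),
                         seed = 1, control = es_control(),
                         params = kinetic_params(),
                         solver = solver_settings()) {
  stopifnot(length(scenarios) >= 1)
  for (sc in scenarios)
    if (!inherits(sc$series, "gs_observed") ||
        !inherits(sc$regimen, "gs_regimen"))
      stop("each scenario needs a gs_observed series and a gs_regimen",
           call. = FALSE)

  objective <- function(x) {
    sets <- assemble_sets(free, x, frozen)
    total <- 0
    for (sc in scenarios) {
      sim <- simulate_therapy(sc$regimen, params = params,
                              toxicity = sets,
                              horizon_days = max(sc$series$day) + 1,
                              solver = solver)
      col <- if (sc$series$count_type[1] == "wbc") sim$wbc else sim$anc
      # simulation time 0 is study day 1
      total <- total + fit_cost(sim$time_day + 1, pmax(col, 1),
                                sc$series)
    }
    total + control$penalty * ordering_penalty(sets, constraints)
  }

  nf <- n_free(free)
  if (nf == 0L) {
    cost <- objective(numeric(0))
    return(structure(list(sets = frozen, cost = cost,
                          initial_cost = cost,
                          trace = data.frame(generation = 0, best = cost),
                          free = free,
                          frozen_manifest = names(frozen),
                          constraints_ok = ordering_penalty(
                            frozen, constraints) == 0,
                          converged = TRUE, seed = seed),
                     class = "gs_fit"))
  }

  keys <- unlist(lapply(names(free), function(l) paste(l, free[[l]],
                                                       sep = ".")))
  lb <- ub <- numeric(nf)
  for (i in seq_len(nf)) {
    b <- if (is.list(bounds)) bounds[[keys[i]]] %||% c(1e-6, 1e3) else
      bounds
    if (b[1] <= 0 || b[2] <= b[1])
      stop("infeasible bounds for ", keys[i], call. = FALSE)
    lb[i] <- log(b[1]); ub[i] <- log(b[2])
  }

  set.seed(seed)
  mu <- control$mu; lambda <- control$lambda
  tau <- 1 / sqrt(2 * nf); tau2 <- 1 / sqrt(2 * sqrt(nf))
  sig_init <- control$sigma0 * (ub - lb)
  pop_x <- t(vapply(seq_len(mu), function(i) stats::runif(nf, lb, ub),
                    numeric(nf)))
  dim(pop_x) <- c(mu, nf)
  pop_s <- matrix(rep(sig_init, each = mu), mu, nf)
  pop_f <- apply(pop_x, 1, objective)
  initial_cost <- min(pop_f)
  trace <- data.frame(generation = 0, best = initial_cost)
  stag <- 0
  for (g in seq_len(control$generations)) {
    par_idx <- sample.int(mu, lambda, replace = TRUE)
    off_x <- matrix(0, lambda, nf); off_s <- matrix(0, lambda, nf)
    for (o in seq_len(lambda)) {
      p <- par_idx[o]
      s <- pop_s[p, ] * exp(tau2 * stats::rnorm(1) +
                              tau * stats::rnorm(nf))
      s <- pmin(pmax(s, 1e-8), ub - lb)
      x <- pop_x[p, ] + s * stats::rnorm(nf)
      off_x[o, ] <- pmin(pmax(x, lb), ub)
      off_s[o, ] <- s
    }
    off_f <- apply(off_x, 1, objective)
    all_x <- rbind(pop_x, off_x); all_s <- rbind(pop_s, off_s)
    all_f <- c(pop_f, off_f)
    sel <- order(all_f)[seq_len(mu)]
    improved <- min(all_f) < min(pop_f) - 1e-12
    pop_x <- all_x[sel, , drop = FALSE]
    pop_s <- all_s[sel, , drop = FALSE]
    pop_f <- all_f[sel]
    stag <- if (improved) 0 else stag + 1
    if (stag >= control$stagnation) {   # re-inflate steps on stagnation
      pop_s <- matrix(rep(sig_init, each = mu), mu, nf)
      stag <- 0
    }
    trace <- rbind(trace, data.frame(generation = g, best = pop_f[1]))
  }
  best_sets <- assemble_sets(free, pop_x[1, ], frozen)
  structure(list(sets = best_sets, cost = pop_f[1],
                 initial_cost = initial_cost, trace = trace,
                 free = free, frozen_manifest = names(frozen),
                 constraints_ok = ordering_penalty(best_sets,
                                                   constraints) == 0,
                 converged = pop_f[1] < initial_cost,
                 best_x = stats::setNames(exp(pop_x[1, ]), keys),
                 seed = seed),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit> cost ", signif(x$cost, 5), " (from ",
      signif(x$initial_cost, 5), "), ",
      nrow(x$trace) - 1, " generations, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$best_x)) print(signif(x$best_x, 4))
  invisible(x)
}

#' Run a stepwise constrained fitting protocol
#'
#' Executes fitting steps in order; each step estimates the parameter
#' sets it declares free, on its own scenarios, with the results of all
#' earlier steps frozen.
#'
#' @param steps list of step definitions: each
#'   `list(name, scenarios = <names into data>, free, constraints)`.
#' @param data named list of scenario entries (each
#'   `list(series, regimen)`), keyed by the names the steps reference.
#' @param seed base RNG seed (step i uses `seed + i - 1`).
#' @param ... passed to [fit_toxicity()].
#' @return named list of `gs_fit` results, one per step; each records its
#'   frozen manifest.
#' @export
stepwise_protocol <- function(steps, data, seed = 1, ...) {
  frozen <- list()
  results <- list()
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    missing <- setdiff(st$scenarios, names(data))
    if (length(missing))
      stop("step '", st$name, "' references unknown data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    fit <- fit_toxicity(data[st$scenarios], free = st$free,
                        frozen = frozen,
                        constraints = st$constraints %||% list(),
                        seed = seed + i - 1, ...)
    frozen <- fit$sets
    results[[st$name]] <- fit
  }
  results
}

#' The shipped default estimation protocol
#'
#' The nine-step stepwise protocol used to estimate the shipped toxicity
#' table: simple chemotherapies first, then combinations with ordering
#' constraints, each step freezing all earlier results.  Scenarios 12, 22
#' and 32 are excluded from every step and reserved for validation.
#'
#' @return list with `steps` (step definitions referencing scenario ids)
#'   and `validation_scenarios`.
#' @export
default_protocol <- function() {
  step <- function(name, scen, free, constraints = list())
    list(name = name, scenarios = paste0("s", scen), free = free,
         constraints = constraints)
  list(steps = list(
    # CHOP parameters are estimated separately per risk group; the
    # scenarios of the two groups touch disjoint parameter sets, so they
    # form one step with both sets free.
    step("chop", c(13, 14, 15, 20, 21, 30, 31, 33),
         list(CHOPo = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              CHOPy = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC")),
         list(list(greater = "CHOPo", less = "CHOPy",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    step("etoposide100", c(16, 17, 23, 24),
         list(ETy = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              ETo = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"))),
    step("beacopp_basis", c(18, 26),
         list(CD = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              VB = c("K_S", "K_CG", "K_PGB", "K_MGB"),
              PROC = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC")),
         list(list(greater = "CHOPy", less = "CD",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    step("beacopp_escalated", 27,
         list(CDesk = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              ETesk = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC")),
         list(list(greater = "CDesk", less = "CD",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")),
              list(greater = "ETesk", less = "ETy",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    step("high_choep", c(3, 25),
         list(CDh = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              ETh = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC")),
         list(list(greater = "CDh", less = "CHOPy",
                   fields = c("K_CG", "K_PGB", "K_MGB")),
              list(greater = "ETh", less = "ETy",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    step("ta", c(1, 4, 5, 6, 7, 8),
         list(TA = c("K_S", "K_CG", "K_PGB", "K_MGB"))),
    step("carboplatin_paclitaxel", c(2, 9, 10, 11),
         list(CP = c("K_S", "K_CG", "K_PGB", "K_MGB"))),
    step("breast_sequential", c(19, 28),
         list(E90 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              E150 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              P175 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              P225 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              C600 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC"),
              C2500 = c("K_S", "K_CG", "K_PGB", "K_MGB", "K_WBC")),
         list(list(greater = "E150", less = "E90",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")),
              list(greater = "P225", less = "P175",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")),
              list(greater = "C2500", less = "C600",
                   fields = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    step("eshap", 29,
         list(ET40 = c("K_S", "K_CG", "K_PGB", "K_MGB"),
              Cyta = c("K_S", "K_CG", "K_PGB", "K_MGB"),
              Cisp = c("K_S", "K_CG", "K_PGB", "K_MGB")))),
    validation_scenarios = c(12, 22, 32))
}
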