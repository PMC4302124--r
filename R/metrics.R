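# Myelotoxicity quantification: area over the curve (AOC) below a
# threshold, the per-drug toxicity correlation analysis, and AOC grids
# over alternative G-CSF schedules.

#' Area between a threshold and a curve below the threshold (AOC)
#'
#' Integrates `max(threshold - curve, 0)` over the window by the
#' trapezoidal rule on the curve's grid, with exact linear-interpolation
#' handling of threshold crossings inside grid intervals.  The AOC
#' summarizes depth and duration of a cytopenia in one number; it is 0
#' exactly when the curve never falls below the threshold.
#'
#' Conventional thresholds: 2000/ul for absolute ANC, 4000/ul for
#' absolute WBC, and 1 for normalized cell counts.
#'
#' @param time time grid, days, strictly increasing.
#' @param value curve values on `time`.
#' @param threshold the threshold, same units as `value`.
#' @param window integration window `c(t0, t1)` in days (default: full
#'   curve support); must lie within the curve support.
#' @param curve_id label stored in the result.
#' @return an object of class `gs_aoc`: list with `value` (AOC;
#'   units of `value` times days), `threshold`, `window`, `curve_id`.
#' @export
aoc <- function(time, value, threshold, window = range(time),
                curve_id = "curve") {
  if (inherits(time, "gs_sim"))
    stop("pass time and value vectors, e.g. aoc(sim$time_day, sim$wbc, ...)",
         call. = FALSE)
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (any(diff(time) <= 0)) {
    keep <- !duplicated(time)
    time <- time[keep]; value <- value[keep]
  }
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] outside curve support [", min(time), ", ", max(time), "]",
         call. = FALSE)
  y0 <- stats::approx(time, value, xout = window)$y
  keep <- time > window[1] & time < window[2]
  tt <- c(window[1], time[keep], window[2])
  yy <- c(y0[1], value[keep], y0[2])
  d1 <- threshold - yy[-length(yy)]
  d2 <- threshold - yy[-1]
  dt <- diff(tt)
  seg <- numeric(length(dt))
  both_below <- d1 >= 0 & d2 >= 0            # curve below threshold
  seg[both_below] <- (d1[both_below] + d2[both_below]) / 2 * dt[both_below]
  cross <- xor(d1 > 0, d2 > 0) & !both_below
  if (any(cross)) {
    dpos <- pmax(d1[cross], d2[cross])
    frac <- dpos / (abs(d1[cross]) + abs(d2[cross]))
    seg[cross] <- dpos * frac * dt[cross] / 2
  }
  structure(list(value = sum(seg), threshold = threshold,
                 window = as.numeric(window), curve_id = curve_id),
            class = "gs_aoc")
}

#' @export
print.gs_aoc <- function(x, ...) {
  cat("<gs_aoc> ", x$curve_id, ": AOC = ", signif(x$value, 5),
      " (threshold ", x$threshold, ", window ", x$window[1], "-",
      x$window[2], " d)\n", sep = "")
  invisible(x)
}

# Ad-hoc regimen applying one injection of a single toxicity set.
single_injection_regimen <- function(label, horizon_days = 120) {
  as_regimen(list(name = paste0("single ", label),
                  protocol = "single injection",
                  cycle_length_days = horizon_days, n_cycles = 1,
                  applications = list(list(drug = label, days = 1,
                                           toxicity = label))))
}

#' Correlation of per-drug stem-cell, marrow and peripheral toxicities
#'
#' For each shipped toxicity parameter set, one chemotherapy injection is
#' simulated without G-CSF support and the AOC of the normalized
#' stem-cell (S), MGB, ANC and WBC curves (threshold 1) is computed over
#' a fixed horizon.  Spearman rank correlations across parameter sets
#' quantify how well marrow toxicity predicts peripheral toxicity.
#'
#' @param labels toxicity-set labels to include (default: all shipped
#'   sets).  Unknown labels are skipped with a warning.
#' @param params a `gs_params` object.
#' @param horizon_days AOC horizon, days.
#' @param solver a [solver_settings()] list.
#' @return an object of class `gs_cor`: list with `aoc` (data.frame of
#'   per-set AOC values, unit days) and `correlations` (named vector:
#'   `S_vs_WBC`, `MGB_vs_WBC`, `ANC_vs_WBC`; Spearman, average ranks for
#'   ties).
#' @export
toxicity_correlation <- function(labels = toxicity_table()$label,
                                 params = kinetic_params(),
                                 horizon_days = 28,
                                 solver = solver_settings()) {
  known <- labels %in% toxicity_table()$label
  if (any(!known)) {
    warning("skipping unknown toxicity sets: ",
            paste(labels[!known], collapse = ", "), call. = FALSE)
    labels <- labels[known]
  }
  rows <- lapply(labels, function(lab) {
    rg <- single_injection_regimen(lab, horizon_days = horizon_days)
    sim <- simulate_therapy(rg, params = params,
                            horizon_days = horizon_days, solver = solver)
    w <- c(0, horizon_days)
    data.frame(label = lab,
               S = aoc(sim$time_day, sim$S, 1, w)$value,
               MGB = aoc(sim$time_day, sim$MGB, 1, w)$value,
               ANC = aoc(sim$time_day, sim$GRA, 1, w)$value,
               WBC = aoc(sim$time_day, sim$wbc_norm, 1, w)$value)
  })
  tab <- do.call(rbind, rows)
  sp <- function(a, b) stats::cor(a, b, method = "spearman")
  structure(list(aoc = tab,
                 correlations = c(S_vs_WBC = sp(tab$S, tab$WBC),
                                  MGB_vs_WBC = sp(tab$MGB, tab$WBC),
                                  ANC_vs_WBC = sp(tab$ANC, tab$WBC)),
                 horizon_days = horizon_days),
            class = "gs_cor")
}

#' @export
print.gs_cor <- function(x, ...) {
  cat("<gs_cor> per-drug AOC correlations over ", x$horizon_days,
      " days (", nrow(x$aoc), " parameter sets)\n", sep = "")
  print(round(x$correlations, 3))
  invisible(x)
}

#' WBC AOC grid over G-CSF dose and injection count
#'
#' Evaluates the leukotoxicity (WBC AOC below `threshold`) of a
#' chemotherapy backbone for every combination of G-CSF dose and number
#' of daily injections starting at `start_day` of each cycle.
#'
#' @param regimen chemotherapy backbone (`gs_regimen`); its own G-CSF
#'   schedule is replaced.
#' @param start_day within-cycle day of the first injection.
#' @param doses_ug injection doses, micrograms (absolute).
#' @param n_injections vector of injection counts (consecutive days).
#' @param derivative G-CSF derivative.
#' @param threshold WBC threshold, cells/ul.
#' @param horizon_days AOC window end (default: full regimen).
#' @param params,solver model parameters and solver settings.
#' @return an object of class `gs_grid`: matrix of AOC values
#'   (rows = doses, columns = injection counts; unit cells/ul * days)
#'   with the evaluation settings as attributes.
#' @export
schedule_grid <- function(regimen, start_day, doses_ug, n_injections,
                          derivative = "fil", threshold = 4000,
                          horizon_days = NULL, params = kinetic_params(),
                          solver = solver_settings()) {
  stopifnot(length(doses_ug) >= 1, length(n_injections) >= 1)
  horizon_days <- horizon_days %||%
    (regimen$n_cycles * regimen$cycle_length_days)
  m <- matrix(NA_real_, length(doses_ug), length(n_injections),
              dimnames = list(dose_ug = doses_ug,
                              n_injections = n_injections))
  for (i in seq_along(doses_ug)) {
    for (j in seq_along(n_injections)) {
      days <- seq(start_day, length.out = n_injections[j])
      if (max(days) > regimen$cycle_length_days)
        stop("injection days exceed the cycle length", call. = FALSE)
      rg <- with_gcsf(regimen, derivative, dose_ug = doses_ug[i],
                      days = days)
      sim <- simulate_therapy(rg, params = params,
                              horizon_days = horizon_days,
                              solver = solver)
      m[i, j] <- aoc(sim$time_day, sim$wbc, threshold,
                     c(0, horizon_days))$value
    }
  }
  structure(m, class = c("gs_grid", "matrix"), start_day = start_day,
            threshold = threshold, horizon_days = horizon_days,
            regimen = regimen$name, derivative = derivative)
}

#' Long-format view of a schedule grid
#' @param grid a `gs_grid`.
#' @return data.frame with columns `dose_ug`, `n_injections`, `aoc`.
#' @export
grid_long <- function(grid) {
  stopifnot(inherits(grid, "gs_grid"))
  df <- expand.grid(dose_ug = as.numeric(rownames(grid)),
                    n_injections = as.numeric(colnames(grid)))
  df$aoc <- as.vector(grid)
  df
}
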