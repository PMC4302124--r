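# Machine-readable regimen library: chemotherapy protocols (drugs, doses,
# within-cycle days, cycle structure) plus G-CSF schedules, and the
# expansion of a regimen into an absolute event list for the simulator.
#
# Day convention: within-cycle days are 1-based ("days 4-13" means one
# injection on each of days 4..13); infusions and injections start at a
# fixed clock time (08:00 by default).  Study day d of cycle c maps to the
# absolute time ((c-1) * cycle_length + d - 1) * 24 + 8 hours.

GS_CLOCK_H <- 8

#' G-CSF injection schedule element
#'
#' @param derivative `"fil"` (Filgrastim) or `"peg"` (Pegfilgrastim).
#' @param dose_ug dose per injection, micrograms (absolute, or per kg
#'   body weight if `per_kg`).
#' @param days within-cycle days (1-based) of the injections.
#' @param per_kg whether `dose_ug` is per kg body weight.
#' @param cycles cycle indices covered (`NULL` = all cycles).
#' @return an object of class `gs_gcsf`.
#' @export
gcsf_injection <- function(derivative = c("fil", "peg"), dose_ug, days,
                           per_kg = FALSE, cycles = NULL) {
  derivative <- match.arg(derivative)
  if (dose_ug <= 0) stop("dose_ug must be > 0", call. = FALSE)
  if (length(days) == 0 || any(days < 1))
    stop("injection days must be >= 1", call. = FALSE)
  structure(list(derivative = derivative, dose_ug = dose_ug,
                 days = as.numeric(days), per_kg = isTRUE(per_kg),
                 cycles = cycles),
            class = "gs_gcsf")
}

#' Load a regimen definition
#'
#' Reads a regimen config (YAML).  `name` may be the file stem of a
#' shipped regimen (see [regimen_library()]) or a path to a user file.
#' Cytotoxic applications must carry either a toxicity label known to
#' [toxicity_table()] or an inline `toxicity_params` block.
#'
#' @param name regimen name or file path.
#' @param risk_group risk group to resolve per-group toxicity labels
#'   (`NULL` picks the regimen's first declared group).
#' @return an object of class `gs_regimen`.
#' @export
load_regimen <- function(name, risk_group = NULL) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "regimens", paste0(name, ".yaml"),
                package = "granulosim")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown regimen: ", name, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_regimen(raw, risk_group = risk_group, source = path)
}

as_regimen <- function(raw, risk_group = NULL, source = NA_character_) {
  for (field in c("name", "cycle_length_days", "n_cycles", "applications"))
    if (is.null(raw[[field]]))
      stop("regimen config misses required field '", field, "'",
           call. = FALSE)
  cl <- raw$cycle_length_days
  if (cl <= 0 || raw$n_cycles < 1)
    stop("invalid cycle structure in regimen '", raw$name, "'",
         call. = FALSE)
  groups <- raw$risk_groups %||% list("all")
  risk_group <- risk_group %||% groups[[1]]
  if (!risk_group %in% unlist(groups))
    stop("regimen '", raw$name, "' has no risk group '", risk_group, "'",
         call. = FALSE)
  apps <- lapply(seq_along(raw$applications), function(i) {
    a <- raw$applications[[i]]
    where <- paste0("applications[", i, "]")
    if (is.null(a$drug) || is.null(a$days))
      stop(where, ": 'drug' and 'days' are required", call. = FALSE)
    if (any(a$days < 1 | a$days > cl))
      stop(where, " (", a$drug, "): day outside cycle [1, ", cl, "]",
           call. = FALSE)
    cytotoxic <- a$cytotoxic %||% TRUE
    set <- NULL
    if (cytotoxic) {
      lab <- a$toxicity
      if (is.list(lab)) lab <- lab[[risk_group]]
      if (!is.null(a$toxicity_params)) {
        set <- do.call(toxicity_set, a$toxicity_params)
        lab <- set$label
      } else if (is.null(lab)) {
        stop(where, " (", a$drug, "): cytotoxic application without ",
             "toxicity label for risk group '", risk_group, "'",
             call. = FALSE)
      } else if (!lab %in% toxicity_table()$label) {
        stop(where, " (", a$drug, "): unknown toxicity label '", lab,
             "' and no inline toxicity_params", call. = FALSE)
      } else {
        set <- toxicity_set(lab)
      }
    } else {
      lab <- a$drug
    }
    # canonical field order so that save/load round trips exactly
    list(drug = a$drug, dose = a$dose, days = a$days, cycles = a$cycles,
         cytotoxic = cytotoxic, toxicity = a$toxicity,
         label = lab, set = set,
         infusion_h = a$infusion_h %||%
           (if (cytotoxic) set$infusion_h else 1))
  })
  gcsf <- lapply(raw$gcsf %||% list(), function(g)
    gcsf_injection(g$derivative, g$dose_ug, g$days,
                   per_kg = g$per_kg %||% FALSE, cycles = g$cycles))
  structure(list(name = raw$name, protocol = raw$protocol %||% raw$name,
                 cycle_length_days = cl, n_cycles = raw$n_cycles,
                 risk_groups = unlist(groups), risk_group = risk_group,
                 applications = apps, gcsf = gcsf,
                 notes = raw$notes %||% "",
                 external_knowledge_days =
                   isTRUE(raw$external_knowledge_days),
                 source = source),
            class = "gs_regimen")
}

#' Write a regimen definition to a YAML file
#'
#' Inverse of [load_regimen()]: `load_regimen(save_regimen(r, f))`
#' reproduces `r` (up to the resolved risk group).
#'
#' @param regimen a `gs_regimen`.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
save_regimen <- function(regimen, file) {
  stopifnot(inherits(regimen, "gs_regimen"))
  apps <- lapply(regimen$applications, function(a) {
    out <- list(drug = a$drug, dose = a$dose, days = a$days)
    if (!is.null(a$cycles)) out$cycles <- a$cycles
    if (!a$cytotoxic) out$cytotoxic <- FALSE
    else out$toxicity <- a$toxicity
    out$infusion_h <- a$infusion_h
    out
  })
  gcsf <- lapply(regimen$gcsf, function(g) {
    out <- list(derivative = g$derivative, dose_ug = g$dose_ug,
                days = g$days)
    if (g$per_kg) out$per_kg <- TRUE
    if (!is.null(g$cycles)) out$cycles <- g$cycles
    out
  })
  yaml::write_yaml(list(
    name = regimen$name, protocol = regimen$protocol,
    cycle_length_days = regimen$cycle_length_days,
    n_cycles = regimen$n_cycles,
    risk_groups = as.list(regimen$risk_groups),
    applications = apps, gcsf = gcsf, notes = regimen$notes,
    external_knowledge_days = regimen$external_knowledge_days), file)
  invisible(file)
}

#' Attach or replace the G-CSF schedule of a regimen
#'
#' @param regimen a `gs_regimen`.
#' @param derivative,dose_ug,days,per_kg,cycles see [gcsf_injection()];
#'   `derivative = "none"` removes G-CSF support.
#' @return the modified regimen.
#' @export
with_gcsf <- function(regimen, derivative, dose_ug = NULL, days = NULL,
                      per_kg = FALSE, cycles = NULL) {
  stopifnot(inherits(regimen, "gs_regimen"))
  regimen$gcsf <- if (identical(derivative, "none")) list() else
    list(gcsf_injection(derivative, dose_ug, days, per_kg = per_kg,
                        cycles = cycles))
  regimen
}

#' Names of the shipped regimen definitions
#' @return character vector of regimen file stems usable with
#'   [load_regimen()].
#' @export
regimen_library <- function() {
  dir_path <- system.file("extdata", "regimens", package = "granulosim")
  sort(sub("\\.yaml$", "", list.files(dir_path, pattern = "\\.yaml$")))
}

#' Clinical scenario table
#'
#' The 33 modelled scenarios (combinations of chemotherapy protocol, risk
#' group and G-CSF schedule).  Scenarios flagged `validation` were held
#' out of all parameter-estimation steps.
#'
#' @return a data.frame with one row per scenario.
#' @export
scenario_table <- function() {
  path <- system.file("extdata", "scenarios.csv", package = "granulosim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build the full regimen of a clinical scenario
#'
#' @param id scenario id (1..33).
#' @return a `gs_regimen` with the scenario's G-CSF schedule attached.
#' @export
scenario_regimen <- function(id) {
  tab <- scenario_table()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1L) stop("unknown scenario id: ", id, call. = FALSE)
  rg <- load_regimen(row$regimen, risk_group = row$risk_group)
  if (row$gcsf_derivative != "none")
    rg <- with_gcsf(rg, row$gcsf_derivative, dose_ug = row$gcsf_dose_ug,
                    days = parse_days(row$gcsf_days),
                    per_kg = row$gcsf_per_kg == 1)
  rg$name <- sprintf("%s [scenario %02d]", rg$name, id)
  rg
}

parse_days <- function(spec) {
  parts <- strsplit(as.character(spec), ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.numeric(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(ab[1], ab[2])
    } else as.numeric(p)
  }))
}

#' @export
print.gs_regimen <- function(x, ...) {
  cat("<gs_regimen> ", x$name, " (", x$protocol, "), ",
      x$n_cycles, " x ", x$cycle_length_days, " days, risk group ",
      x$risk_group, "\n", sep = "")
  for (a in x$applications)
    cat("  ", a$drug, if (!a$cytotoxic) " [non-cytotoxic]" else
        paste0(" -> ", a$label),
        ": days ", paste(a$days, collapse = ","),
        if (!is.null(a$cycles)) paste0(" (cycles ",
                                       paste(a$cycles, collapse = ","), ")"),
        "\n", sep = "")
  for (g in x$gcsf)
    cat("  G-CSF ", g$derivative, " ", g$dose_ug,
        if (g$per_kg) " ug/kg" else " ug", ", days ",
        paste(range(g$days), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Expand a regimen into an absolute event schedule
#'
#' Converts the within-cycle template into absolute-time lists: per
#' toxicity label the merged chemotherapy application (all cycles), the
#' merged prednisone-like coverage, G-CSF injection events with absolute
#' doses, and a sorted event table whose times serve as integration
#' breakpoints.
#'
#' @param regimen a `gs_regimen`.
#' @param body body parameters (list with `mass_kg`) used to convert
#'   per-kg G-CSF doses.
#' @return a list with components `drugs` (named list: `set`, `app`,
#'   `t_second_cycle` in hours), `prednisone` (a `gs_application` or
#'   `NULL`), `gcsf` (data.frame `time_h`, `derivative`, `dose_ug`),
#'   `events` (sorted data.frame `time_h`, `day`, `type`, `label`) and
#'   `horizon_days`.
#' @export
expand_schedule <- function(regimen, body = list(mass_kg = 70)) {
  stopifnot(inherits(regimen, "gs_regimen"))
  cl <- regimen$cycle_length_days
  abs_days <- function(days, cycles) {
    cycles <- cycles %||% seq_len(regimen$n_cycles)
    sort(unlist(lapply(cycles, function(c) (c - 1) * cl + days)))
  }
  drugs <- list(); pred_days <- numeric(0)
  ev <- list()
  for (a in regimen$applications) {
    d <- abs_days(a$days, a$cycles)
    if (!a$cytotoxic) {
      pred_days <- sort(c(pred_days, d))
      next
    }
    app <- drug_application(a$drug, times_day = d,
                            infusion_h = a$infusion_h, dose = a$dose,
                            clock_h = GS_CLOCK_H)
    # first-cycle window: until the drug's first application in its
    # second treated cycle (Inf if applied within a single cycle only)
    cyc <- (d - 1) %/% cl + 1
    later <- d[cyc > cyc[1]]
    t2 <- if (length(later)) (later[1] - 1) * 24 + GS_CLOCK_H else Inf
    lab <- a$label
    if (!is.null(drugs[[lab]])) {
      all_d <- sort(c(drugs[[lab]]$app$times_day, d))
      drugs[[lab]]$app <- drug_application(a$drug, all_d,
                                           infusion_h = a$infusion_h,
                                           dose = a$dose,
                                           clock_h = GS_CLOCK_H)
      cyc <- (all_d - 1) %/% cl + 1
      later <- all_d[cyc > cyc[1]]
      drugs[[lab]]$t_second_cycle <-
        if (length(later)) (later[1] - 1) * 24 + GS_CLOCK_H else Inf
    } else {
      drugs[[lab]] <- list(set = a$set, app = app, t_second_cycle = t2)
    }
    ev[[length(ev) + 1L]] <- data.frame(
      time_h = c(app$times_h, app$times_h + app$infusion_h),
      type = rep(c("chemo_start", "chemo_stop"), each = length(d)),
      label = lab)
  }
  pred <- NULL
  if (length(pred_days)) {
    pred <- drug_application("prednisone", pred_days, infusion_h = 1,
                             cytotoxic = FALSE, clock_h = GS_CLOCK_H)
    ev[[length(ev) + 1L]] <- data.frame(
      time_h = c(pred$times_h, pred$times_h + 24),
      type = rep(c("prednisone_start", "prednisone_stop"),
                 each = length(pred_days)),
      label = "prednisone")
  }
  gcsf <- data.frame(time_h = numeric(0), derivative = character(0),
                     dose_ug = numeric(0))
  for (g in regimen$gcsf) {
    d <- abs_days(g$days, g$cycles)
    dose <- if (g$per_kg) g$dose_ug * body$mass_kg else g$dose_ug
    gcsf <- rbind(gcsf, data.frame(time_h = (d - 1) * 24 + GS_CLOCK_H,
                                   derivative = g$derivative,
                                   dose_ug = dose))
    ev[[length(ev) + 1L]] <- data.frame(time_h = (d - 1) * 24 + GS_CLOCK_H,
                                        type = "gcsf",
                                        label = g$derivative)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time_h = numeric(0), type = character(0),
               label = character(0))
  events <- events[order(events$time_h, events$type), , drop = FALSE]
  events$day <- events$time_h / 24 + 1
  rownames(events) <- NULL
  list(drugs = drugs, prednisone = pred,
       gcsf = gcsf[order(gcsf$time_h), , drop = FALSE],
       events = events[, c("time_h", "day", "type", "label")],
       horizon_days = regimen$n_cycles * cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
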