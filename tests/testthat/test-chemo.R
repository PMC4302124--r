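test_that("the injection pulse has unit area and the stated support", {
  app <- drug_application("x", times_day = 1, infusion_h = 1, clock_h = 0)
  expect_equal(chemo_pulse(app, 0.5), 1)
  expect_equal(chemo_pulse(app, 2), 0)
  expect_equal(chemo_pulse(app, -0.1), 0)
  # unit area for several infusion durations, fine Riemann sum
  for (tinf in c(1, 3, 24)) {
    a <- drug_application("x", 1, infusion_h = tinf, clock_h = 0)
    tt <- seq(0, 48, by = 1e-3)
    area <- sum(chemo_pulse(a, tt[-length(tt)])) * 1e-3
    expect_equal(area, 1, tolerance = 1e-6)
  }
  # two injections -> total area 2
  a2 <- drug_application("x", c(1, 2), infusion_h = 1, clock_h = 0)
  tt <- seq(0, 72, by = 1e-3)
  expect_equal(sum(chemo_pulse(a2, tt[-length(tt)])) * 1e-3, 2,
               tolerance = 1e-6)
})

test_that("the delay chain impulse response is the Erlang-4 density", {
  # impulse into stage 1: output k (k t)^3 exp(-k t) / 3!
  for (k in c(0.01, 0.1, 1)) {
    out <- integrate_chain(k, function(t) 0, breaks = numeric(0),
                           t_end = 12 / k, init = c(1, 0, 0, 0))
    expect_lt(max(abs(k * out[, "m4"] - erlang4_output(out[, "t"], k))),
              1e-6)
  }
  # peak position 3/k with the closed-form peak value
  k <- 1
  out <- integrate_chain(k, function(t) 0, numeric(0), 12,
                         init = c(1, 0, 0, 0), pts_per_h = 100)
  tpk <- unname(out[which.max(out[, "m4"]), "t"])
  expect_equal(tpk, 3, tolerance = 0.02)
  expect_equal(max(k * out[, "m4"]), 27 * exp(-3) / 6, tolerance = 1e-4)
  # CHOP delay rate: peak at 3/k ~ 47.2 h
  k <- 6.35e-2
  out <- integrate_chain(k, function(t) 0, numeric(0), 300,
                         init = c(1, 0, 0, 0))
  expect_equal(unname(out[which.max(out[, "m4"]), "t"]), 3 / k,
               tolerance = 0.01)
})

test_that("delay-chain area is conserved for any pulse shape", {
  for (k in c(0.02, 0.3)) {
    for (tinf in c(1, 24)) {
      input <- function(t) (t >= 0 & t < tinf) / tinf
      out <- integrate_chain(k, input, breaks = c(0, tinf),
                             t_end = tinf + 30 / k)
      expect_equal(unname(out[nrow(out), "area"]), 1, tolerance = 1e-6)
    }
  }
  # two injections integrate to 2
  input2 <- function(t) ((t >= 0 & t < 1) + (t >= 24 & t < 25)) / 1
  out <- integrate_chain(0.1, input2, breaks = c(0, 1, 24, 25),
                         t_end = 400)
  expect_equal(unname(out[nrow(out), "area"]), 2, tolerance = 1e-6)
})

test_that("the delay chain is linear (superposition of injections)", {
  k <- 0.08
  brk <- c(0, 1, 24, 25)   # shared breakpoints align the output grids
  one <- function(t0) {
    input <- function(t) (t >= t0 & t < t0 + 1)
    integrate_chain(k, input, breaks = brk, t_end = 300)
  }
  both <- integrate_chain(k, function(t)
    (t >= 0 & t < 1) + (t >= 24 & t < 25), breaks = brk, t_end = 300)
  a <- one(0); b <- one(24)
  expect_equal(a[, "t"], both[, "t"])
  expect_lt(max(abs(both[, "m4"] - a[, "m4"] - b[, "m4"])), 1e-8)
})

test_that("toxicity coefficients scale the delayed signal, with first-cycle factor", {
  set <- toxicity_set(f_fc = 2, k_delay = 0.1,
                      K = c(S = 0.1, CG = 0, PGB = 0, MGB = 0))
  expect_equal(toxicity_function(set, "S", 0.05, t = 10,
                                 t_second_cycle = 100), 0.01)
  expect_equal(toxicity_function(set, "S", 0.05, t = 200,
                                 t_second_cycle = 100), 0.005)
  # f_fc applies throughout for single-cycle drugs (t_second = Inf)
  expect_equal(toxicity_function(set, "S", 0.05, t = 1e6), 0.01)
  set1 <- toxicity_set(f_fc = 1, k_delay = 0.1,
                       K = c(S = 0.1, CG = 0, PGB = 0, MGB = 0))
  expect_equal(toxicity_function(set1, "S", 0.05, 10, 100),
               toxicity_function(set1, "S", 0.05, 500, 100))
  expect_error(toxicity_function(set, "LY", 0.05, 1), "compartment")
  expect_error(toxicity_set(f_fc = 0.9, k_delay = 0.1), "f_fc")
  expect_error(toxicity_set(k_delay = -1), "k_delay")
})

test_that("drug combinations add without interaction", {
  expect_equal(combine_toxicities(list()), 0)
  x <- c(0, 0.1, 0.3)
  expect_equal(combine_toxicities(list(x)), x)
  expect_equal(combine_toxicities(list(x, x)), 2 * x)
  expect_error(combine_toxicities(list(c(-0.1, 0))), ">= 0")
})

test_that("leukocytes are neutrophils plus exponentially depleted lymphocytes", {
  expect_equal(wbc_from_anc(1500, 0), 4500)
  expect_equal(wbc_from_anc(1000, Inf), 1000)
  expect_equal(wbc_from_anc(1000, 1), 1000 + 3000 * exp(-1))
  expect_equal(wbc_from_anc(1000, 1), 2103.6, tolerance = 1e-4)
  expect_error(wbc_from_anc(-1, 0), ">= 0")
})

test_that("the packaged toxicity table reproduces the reference values", {
  tab <- toxicity_table()
  expect_equal(nrow(tab), 22)
  chop_o <- tab[tab$label == "CHOPo", ]
  expect_equal(chop_o$K_S, 2.16e-1)
  expect_equal(chop_o$f_fc, 1.11)
  expect_equal(chop_o$k_delay, 6.35e-2)
  expect_equal(chop_o$K_WBC, 1.27e1)
  expect_equal(tab[tab$label == "TA", "f_fc"], 2.01)
  expect_equal(tab[tab$label == "ETh", "K_PGB"], 6.41e-1)
  # ANC-based estimation data: no lymphocyte toxicity modelled
  blank <- c("VB", "CP", "TA", "Cyta", "Cisp", "ET40")
  expect_true(all(is.na(tab[tab$label %in% blank, "K_WBC"])))
  for (lab in blank)
    expect_false(toxicity_set(lab)$wbc_modelled)
  expect_equal(toxicity_set("C600")$infusion_h, 24)
  expect_equal(toxicity_set("P225")$infusion_h, 3)
  expect_error(toxicity_set("NOPE"), "unknown")
})

test_that("prednisone lowers granulocyte clearance only while covering", {
  app <- drug_application("prednisone", times_day = 1:5, infusion_h = 1,
                          cytotoxic = FALSE, clock_h = 0)
  expect_equal(prednisone_effect(app, 12, factor = 0.7), 0.7)
  expect_equal(prednisone_effect(app, 4 * 24 + 23, factor = 0.7), 0.7)
  expect_equal(prednisone_effect(app, 6 * 24, factor = 0.7), 1)
  cyt <- drug_application("x", 1, cytotoxic = TRUE)
  expect_error(prednisone_effect(cyt, 1), "non-cytotoxic")
  # paired simulation: prednisone keeps GRA at or above the untreated level
  pred_reg <- granulosim:::as_regimen(list(
    name = "pred", cycle_length_days = 30, n_cycles = 1,
    applications = list(list(drug = "prednisone", days = 1:5,
                             cytotoxic = FALSE))))
  simp <- simulate_therapy(pred_reg, horizon_days = 30)
  expect_gt(max(simp$GRA), 1.05)                   # transient granulocytosis
  expect_lt(max(abs(tail(simp$GRA, 20) - 1)), 0.01)  # temporary only
})
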