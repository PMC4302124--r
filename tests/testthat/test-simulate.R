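test_that("an empty regimen yields flat steady-state trajectories", {
  sim <- cached("ss100", simulate_therapy(empty_regimen(100)))
  expect_lt(max(abs(as.matrix(sim[, c("S", "CG", "PGB", "MGB", "GRA")]) -
                      1)), 1e-5)
  expect_equal(sim$wbc - sim$anc,
               rep(kinetic_params()$steady_state$lymphocytes, nrow(sim)))
})

test_that("simulations are deterministic and respect non-negativity", {
  rg <- single_shot("CHOPo", 60)
  s1 <- simulate_therapy(rg, horizon_days = 60)
  s2 <- simulate_therapy(rg, horizon_days = 60)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(as.matrix(s1[, c("S", "CG", "PGB", "MGB", "GRA")]) >= 0))
  expect_true(all(s1$wbc >= s1$anc))
})

test_that("zero toxicity coefficients reproduce the untreated steady state", {
  null_set <- toxicity_set(f_fc = 1, k_delay = 6.35e-2,
                           K = c(S = 0, CG = 0, PGB = 0, MGB = 0))
  sim <- simulate_therapy(single_shot("CHOPo", 40),
                          toxicity = list(CHOPo = null_set),
                          horizon_days = 40)
  expect_lt(max(abs(as.matrix(sim[, c("S", "CG", "PGB", "MGB", "GRA")]) -
                      1)), 1e-5)
})

test_that("stem-cell-only damage spreads downstream with delay and recovers", {
  suite <- damage_experiment_suite()
  sim <- cached("dmg_s", simulate_therapy(suite$s_only$regimen,
                                           toxicity = suite$s_only$toxicity,
                                           horizon_days = 120))
  expect_lt(min(sim$S), 0.9)
  # stem-cell nadir precedes the blood nadir
  expect_lt(sim$time_day[which.min(sim$S)],
            sim$time_day[which.min(sim$GRA)])
  # later stages decline with delay: GRA still near 1 when S has dropped 5%
  t5 <- min(sim$time_day[sim$S < 0.95])
  expect_gt(sim$GRA[max(which(sim$time_day <= t5))], 0.98)
})

test_that("full CHOP toxicity depletes CG most and prolongs recovery", {
  suite <- damage_experiment_suite()
  sims <- list(
    s = cached("dmg_s", simulate_therapy(suite$s_only$regimen,
                                          toxicity = suite$s_only$toxicity,
                                          horizon_days = 120)),
    pgb = cached("dmg_p", simulate_therapy(suite$pgb_only$regimen,
                                            toxicity = suite$pgb_only$toxicity,
                                            horizon_days = 120)),
    all = cached("dmg_a", simulate_therapy(suite$all_stages$regimen,
                                            toxicity = suite$all_stages$toxicity,
                                            horizon_days = 120)))
  mins <- sapply(sims$all[, c("S", "CG", "PGB", "MGB", "GRA")], min)
  expect_equal(names(which.min(mins)), "CG")
  # deeper blood nadir than either single-stage experiment
  expect_lt(min(sims$all$GRA), min(sims$s$GRA))
  expect_lt(min(sims$all$GRA), min(sims$pgb$GRA))
  # recovery takes longest for the all-stage damage: larger residual
  # deficit late in the run
  late_def <- sapply(sims, function(s)
    abs(1 - s$GRA[max(which(s$time_day <= 60))]))
  expect_gte(late_def[["all"]], late_def[["s"]])
  expect_gte(late_def[["all"]], late_def[["pgb"]])
})

test_that("G-CSF schedule variants share bitwise-identical chemotherapy forcing", {
  rg <- chop14_elderly()
  vars <- list(list(derivative = "fil", dose_ug = 480, days = 4:8),
               list(derivative = "none"),
               list(derivative = "fil", dose_ug = 480, days = 4:8))
  sims <- simulate_gcsf_variants(rg, vars, horizon_days = 30)
  expect_length(sims, 3)
  expect_identical(attr(sims[[1]], "psi_out"), attr(sims[[2]], "psi_out"))
  # duplicate variants give identical results
  expect_identical(as.data.frame(sims[[1]]), as.data.frame(sims[[3]]))
  expect_length(simulate_gcsf_variants(rg, list()), 0)
})

test_that("halving solver tolerances leaves the ANC trajectory unchanged", {
  rg <- chop14_elderly()
  s1 <- simulate_therapy(rg, horizon_days = 42,
                         solver = solver_settings(rtol = 1e-6,
                                                  atol = 1e-9))
  s2 <- simulate_therapy(rg, horizon_days = 42,
                         solver = solver_settings(rtol = 5e-7,
                                                  atol = 5e-10))
  expect_lt(max(abs(s1$anc - s2$anc) / max(s1$anc)), 1e-3)
})

test_that("scaling all toxicity coefficients up never eases the cytopenia", {
  base <- toxicity_set("CHOPy")
  lam <- 1.5
  harder <- base
  harder$K <- base$K * lam
  harder$K_WBC <- base$K_WBC * lam
  rg <- single_shot("CHOPy", 60)
  s1 <- simulate_therapy(rg, horizon_days = 60)
  s2 <- simulate_therapy(rg, toxicity = list(CHOPy = harder),
                         horizon_days = 60)
  expect_lte(min(s2$GRA), min(s1$GRA))
  expect_gte(aoc(s2$time_day, s2$GRA, 1, c(0, 60))$value,
             aoc(s1$time_day, s1$GRA, 1, c(0, 60))$value)
})

test_that("trajectories can be written as tidy CSV with provenance", {
  sim <- cached("ss100", simulate_therapy(empty_regimen(100)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, f)
  expect_match(readLines(f, n = 1), "granulosim trajectories")
  df <- utils::read.csv(f, comment.char = "#")
  expect_setequal(unique(df$variable),
                  c("S", "CG", "PGB", "MGB", "GRA", "anc", "wbc",
                    "wbc_norm", "psi_ly", "gcsf_fil", "gcsf_peg"))
})
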