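test_that("observed series validate their invariants and round-trip as CSV", {
  s <- observed_series(c(1, 3, 5), c(8000, 4000, 6000), "wbc",
                       scenario_id = "toy")
  expect_s3_class(s, "gs_observed")
  expect_error(observed_series(c(1, 2), c(1000, -5), "anc"), "> 0")
  expect_error(observed_series(c(3, 1), c(1, 1), "anc"),
               "non-decreasing")
  f <- withr::local_tempfile(fileext = ".csv")
  write_observed(s, f)
  s2 <- read_observed(f)
  expect_equal(s2$value, s$value)
  expect_equal(s2$count_type[1], "wbc")
})

test_that("the log-scale cost integral matches closed forms", {
  d <- observed_series(c(1, 11), c(4000, 4000), "wbc")
  t <- seq(0, 12, by = 0.1)
  expect_equal(fit_cost(t, rep(4000, length(t)), d), 0)
  # model = 2x data over 10 days: integral 10 * ln 2
  expect_equal(fit_cost(t, rep(8000, length(t)), d), 10 * log(2))
  expect_equal(fit_cost(t, rep(8000, length(t)), d), 6.931, tolerance = 1e-3)
  # deviation at an interior day increases the cost monotonically
  d2 <- observed_series(1:5, rep(4000, 5), "wbc")
  cost_dev <- function(delta) {
    m <- rep(4000, length(t)); m[t >= 2.5 & t <= 3.5] <- 4000 * (1 + delta)
    fit_cost(t, m, d2)
  }
  costs <- sapply(c(0.1, 0.3, 0.6), cost_dev)
  expect_true(all(diff(costs) > 0) && costs[1] > 0)
  expect_error(fit_cost(t, rep(-1, length(t)), d), "positive")
  expect_error(fit_cost(c(2, 3), c(1, 1), d), "span")
})

test_that("an empty free set returns the frozen parameters and their cost", {
  rg <- single_shot("CHOPo", 14)
  series <- generate_observed(rg, noise_model(sigma = 0, seed = 1),
                              days = c(3, 7, 10), count_type = "wbc")
  fit <- fit_toxicity(list(list(series = series, regimen = rg)),
                      free = list(),
                      frozen = list(CHOPo = toxicity_set("CHOPo")))
  expect_equal(fit$sets$CHOPo, toxicity_set("CHOPo"))
  expect_lt(fit$cost, 0.2)     # noise-free data from the same parameters
  expect_true(fit$constraints_ok)
})

test_that("the evolutionary strategy is deterministic given the seed", {
  rg <- single_shot("CHOPo", 14)
  series <- generate_observed(rg, noise_model(sigma = 0, seed = 1),
                              days = 1:14, count_type = "anc")
  scen <- list(list(series = series, regimen = rg))
  ctrl <- es_control(mu = 2, lambda = 4, generations = 3)
  f1 <- fit_toxicity(scen, free = list(CHOPo = "K_S"),
                     bounds = c(1e-3, 10), seed = 11, control = ctrl)
  f2 <- fit_toxicity(scen, free = list(CHOPo = "K_S"),
                     bounds = c(1e-3, 10), seed = 11, control = ctrl)
  expect_identical(f1$best_x, f2$best_x)
  expect_identical(f1$trace, f2$trace)
  expect_lte(f1$cost, f1$initial_cost)
  expect_error(fit_toxicity(scen, free = list(CHOPo = "K_S"),
                            bounds = c(5, 1), seed = 1, control = ctrl),
               "bounds")
})

test_that("ordering constraints are respected by the returned parameters", {
  rg <- single_shot("ETy", 14)
  series <- generate_observed(rg, noise_model(sigma = 0, seed = 2),
                              days = 1:14, count_type = "anc")
  scen <- list(list(series = series, regimen = rg))
  cons <- list(list(greater = "ETy", less = "ETo", fields = "K_PGB"))
  fit <- fit_toxicity(scen, free = list(ETy = "K_PGB"),
                      frozen = list(ETo = toxicity_set("ETo")),
                      bounds = c(1e-4, 50), constraints = cons,
                      seed = 5,
                      control = es_control(mu = 3, lambda = 8,
                                           generations = 8))
  expect_true(fit$constraints_ok)
  expect_gte(fit$sets$ETy$K[["PGB"]], toxicity_set("ETo")$K[["PGB"]])
})

test_that("the default stepwise protocol encodes the study design", {
  proto <- default_protocol()
  expect_length(proto$steps, 9)
  expect_equal(proto$validation_scenarios, c(12, 22, 32))
  used <- unlist(lapply(proto$steps, `[[`, "scenarios"))
  expect_false(any(paste0("s", proto$validation_scenarios) %in% used))
  # every referenced free label exists in the shipped table
  labs <- unlist(lapply(proto$steps, function(s) names(s$free)))
  expect_true(all(labs %in% toxicity_table()$label))
  # steps with constraints reference earlier-fitted or same-step sets
  expect_error(stepwise_protocol(
    list(list(name = "x", scenarios = "nope", free = list())),
    data = list()), "unknown data")
})

test_that("a two-step protocol freezes step-1 results bit-identically", {
  rg_chop <- single_shot("CHOPo", 14)
  rg_choep <- granulosim:::as_regimen(list(
    name = "choep-like", cycle_length_days = 14, n_cycles = 1,
    applications = list(list(drug = "chop", days = 1, toxicity = "CHOPo"),
                        list(drug = "eto", days = 1:3,
                             toxicity = "ETo"))))
  data <- list(
    chop = list(series = generate_observed(rg_chop,
                                           noise_model(sigma = 0, seed = 3),
                                           days = 1:14,
                                           count_type = "anc"),
                regimen = rg_chop),
    choep = list(series = generate_observed(rg_choep,
                                            noise_model(sigma = 0, seed = 4),
                                            days = 1:14,
                                            count_type = "anc"),
                 regimen = rg_choep))
  steps <- list(
    list(name = "step1", scenarios = "chop",
         free = list(CHOPo = "K_S")),
    list(name = "step2", scenarios = "choep",
         free = list(ETo = "K_PGB")))
  res <- stepwise_protocol(steps, data, seed = 9,
                           control = es_control(mu = 2, lambda = 6,
                                                generations = 6),
                           bounds = c(1e-4, 50))
  expect_named(res, c("step1", "step2"))
  # step-1 estimate frozen during step 2
  expect_identical(res$step2$sets$CHOPo, res$step1$sets$CHOPo)
  expect_equal(res$step2$frozen_manifest, "CHOPo")
  # single-step protocol is plain fit_toxicity
  res1 <- stepwise_protocol(steps[1], data, seed = 9,
                            control = es_control(mu = 2, lambda = 6,
                                                 generations = 6),
                            bounds = c(1e-4, 50))
  direct <- fit_toxicity(data["chop"], free = list(CHOPo = "K_S"),
                         seed = 9,
                         control = es_control(mu = 2, lambda = 6,
                                              generations = 6),
                         bounds = c(1e-4, 50))
  expect_equal(res1$step1$best_x, direct$best_x)
})
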