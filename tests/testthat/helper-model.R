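# Shared fixtures for the test suite.  Expensive simulations are computed
# lazily and cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A regimen with no drug applications (pure steady-state run).
empty_regimen <- function(horizon_days = 100) {
  granulosim:::as_regimen(list(name = "untreated",
                               cycle_length_days = horizon_days,
                               n_cycles = 1, applications = list()))
}

# One injection of a single toxicity set, no G-CSF.
single_shot <- function(label, horizon_days = 120) {
  granulosim:::single_injection_regimen(label, horizon_days = horizon_days)
}

# Integrate the 4-stage delay chain through the exported RHS with an
# arbitrary input function (piecewise constant per segment), plus a
# cumulative-area state.  Independent of the simulation engine.
integrate_chain <- function(k, input_fn, breaks, t_end, init = rep(0, 4),
                            rtol = 1e-10, atol = 1e-12, pts_per_h = 4) {
  rhs <- function(t, y, parms) {
    ch <- delay_chain_rhs(y[1:4], parms$u, k)
    list(c(ch$deriv, ch$output))
  }
  y <- c(init, 0)
  brk <- sort(unique(c(0, breaks, t_end)))
  brk <- brk[brk <= t_end]
  out <- NULL
  for (i in seq_len(length(brk) - 1)) {
    span <- brk[i + 1] - brk[i]
    tt <- seq(brk[i], brk[i + 1],
              length.out = max(20, ceiling(span * pts_per_h)))
    u <- input_fn((brk[i] + brk[i + 1]) / 2)
    sol <- deSolve::ode(y, tt, rhs, parms = list(u = u), rtol = rtol,
                        atol = atol)
    y <- sol[nrow(sol), -1]
    out <- rbind(out, if (i == 1) sol else sol[-1, ])
  }
  out <- unname(out)
  colnames(out) <- c("t", paste0("m", 1:4), "area")
  out
}

erlang4_output <- function(t, k) k * (k * t)^3 * exp(-k * t) / 6

chop14_elderly <- function() load_regimen("chop14", risk_group = "elderly")

aoc1 <- function(sim, var = "wbc_norm", window = c(0, 84))
  aoc(sim$time_day, sim[[var]], 1, window)$value
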