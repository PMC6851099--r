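test_that("the single-exponential model evaluates correctly", {
  expect_equal(model_mean(0.4107, 1.12, 0), 0)
  expect_equal(round(model_mean(0.4107, 1.12, 1 / 1.12), 4), 0.2596)
  expect_lt(abs(model_mean(0.4107, 1.12, 100) - 0.4107), 1e-10)
  expect_error(model_mean(0.4107, 1.12, -1), "non-negative")
  expect_error(model_mean(-1, 1.12, 1), "positive")
})

test_that("noise-free induction fits recover parameters to 1e-6", {
  times <- seq(0, 360, 10)
  for (a in c(0.2, 0.4107, 2)) {
    for (b in c(0.5, 1.12, 4)) {
      s <- data.frame(time_s = times, count = model_mean(a, b, times / 60))
      est <- fit_induction(s, 4500)
      expect_lt(abs(est$a - a) / a, 1e-6)
      expect_lt(abs(est$b - b) / b, 1e-6)
    }
  }
})

test_that("a series far from its plateau raises the warning flag", {
  times <- seq(0, 120, 10)
  s <- data.frame(time_s = times, count = model_mean(1, 0.15, times / 60))
  expect_warning(est <- fit_induction(s, 4500), "plateau")
  expect_true(est$plateau_warning)
})

test_that("derived rates reproduce the analytic identities", {
  e <- derive_rates(0.4107, 1.12, 4500)
  expect_equal(e$elongation_rate_bp_s, 84)
  expect_equal(round(e$elongation_time_s, 1), 53.6)
  expect_equal(e$k_on_per_min, 0.4107 * 1.12)
  # elongation rate x elongation time = gene length, exactly
  expect_equal(e$elongation_rate_bp_s * e$elongation_time_s, 4500)

  # shorter gene: 3300 bp traversed in 36 s
  e2 <- derive_rates(0.4, 60 / 36, 3300)
  expect_equal(round(e2$elongation_rate_bp_s), 92)

  # per-polymerase on-rate
  e3 <- derive_rates(0.4107, 1.12, 4500, rnap_total = 35)
  expect_equal(e3$kprime_on_per_min, 0.4107 * 1.12 / 35)
  expect_error(derive_rates(-1, 1, 100), "positive")
})

test_that("fitted off-rate is recovered from seeded simulations", {
  # parameter recovery at the strain's printed rates; dispersion shrinks
  # with the number of cells
  fit_b <- function(seed, n) {
    cfg <- sim_config(n_cells = n, duration_s = 360, seed = seed)
    tr <- simulate_transcription_counts(cfg)
    s <- data.frame(time_s = tr$times_s, count = colMeans(tr$counts))
    fit_induction(s, 4500)$b
  }
  b_small <- vapply(1:24, fit_b, numeric(1), n = 500)
  b_big <- vapply(1:24, fit_b, numeric(1), n = 3000)
  # unbiased within 3 standard errors at the larger size
  expect_lt(abs(mean(b_big) - 1.12), 3 * stats::sd(b_big) / sqrt(24))
  # dispersion shrinks as the cell count grows
  expect_lt(stats::sd(b_big), stats::sd(b_small))
})

test_that("decay fits recover half-lives on exact and noisy data", {
  d <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0)
  f <- fit_decay(d$time_min, d$abundance)
  expect_equal(f$half_life_min, 5.5)
  expect_equal(f$half_life_min, log(2) / f$decay_rate_per_min)

  # halving over tau: half-life tau (three exact points)
  f2 <- fit_decay(c(0, 3, 6), c(100, 50, 25))
  expect_equal(f2$half_life_min, 3)

  # 200 noisy replicates: mean recovered half-life within 2% of truth
  hl <- vapply(1:200, function(s) {
    d <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0.05, seed = s)
    fit_decay(d$time_min, d$abundance)$half_life_min
  }, numeric(1))
  expect_lt(abs(mean(hl) - 5.5) / 5.5, 0.02)

  expect_error(fit_decay(c(0, 2, 4), c(1, 2, 4)), "no decay")
  expect_error(fit_decay(c(0, 2), c(4, 2)), "3 time points")
  expect_error(fit_decay(c(0, 2, 4), c(1, -1, 0.5)), "positive")
})

test_that("degradation correction matches the steady-state ODE oracle", {
  expect_equal(round(corrected_production_ratio(36, 5.5, 2.4)), 16)
  expect_equal(corrected_production_ratio(10, 3, 3), 10)

  # brute-force oracle: integrate dm/dt = p - gamma m for both strains to
  # steady state; the abundance ratio then implies the production ratio
  p_ratio <- 36 * 2.4 / 5.5
  g1 <- log(2) / 5.5
  g2 <- log(2) / 2.4
  out <- deSolve::ode(
    y = c(m1 = 0, m2 = 0), times = seq(0, 500, 1),
    func = function(t, y, parms) {
      list(c(p_ratio - g1 * y[1], 1 - g2 * y[2]))
    }, parms = NULL)
  ab_ratio <- out[nrow(out), "m1"] / out[nrow(out), "m2"]
  expect_lt(abs(ab_ratio - 36), 1e-6)
  expect_lt(abs(corrected_production_ratio(ab_ratio, 5.5, 2.4) - p_ratio),
            1e-6)
  expect_error(corrected_production_ratio(-1, 1, 1), "positive")
})

test_that("two-probe onsets give the elongation rate", {
  expect_equal(elongation_rate_from_onsets(100, 110, 900), 90)
  expect_error(elongation_rate_from_onsets(100, 100, 900), "later")
  expect_error(elongation_rate_from_onsets(100, 110, -5), "positive")

  # round trip through simulated ramps at 101 bp/s, probes 1000 bp apart
  r <- simulate_probe_onsets(101, c(800, 1800), duration_s = 60,
                             sample_interval_s = 1)
  o1 <- estimate_onset(r$time_s[r$probe == 1], r$abundance[r$probe == 1])
  o2 <- estimate_onset(r$time_s[r$probe == 2], r$abundance[r$probe == 2])
  rate <- elongation_rate_from_onsets(o1, o2, 1000)
  expect_lt(abs(rate - 101) / 101, 0.05)
  # onset difference ~ 9.90 s
  expect_lt(abs((o2 - o1) - 9.90), 0.5)
})

test_that("Miller units follow the assay formula", {
  expect_equal(miller_units(1.0, 10, 0.01, 0.5), 20000)
  expect_equal(miller_units(0, 10, 0.01, 0.5), 0)
  expect_equal(miller_units(1.0, 10, 0.02, 0.5),
               miller_units(1.0, 10, 0.01, 0.5) / 2)
  expect_error(miller_units(1, 0, 0.01, 0.5), "positive")
})
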