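test_that("configuration rejects invalid parameters by name", {
  expect_error(sim_config(k_on_per_min = -1), "k_on_per_min")
  expect_error(sim_config(k_off_per_min = 0), "k_off_per_min")
  expect_error(sim_config(bleach_rate_per_frame = 1), "bleach_rate_per_frame")
  expect_error(sim_config(nucleoid_l = 0.7), "nucleoid_l")
  expect_error(sim_config(pixel_size_nm = 600), "pixel_size_nm")
})

test_that("population mean count follows the immigration-death closed form", {
  cfg <- sim_config(n_cells = 10000, k_on_per_min = 0.46,
                    k_off_per_min = 1.12, duration_s = 300, seed = 2)
  tr <- simulate_transcription_counts(cfg)

  # induction starts empty
  expect_equal(tr$counts[, 1], rep(0L, 10000))

  # closed-form mean of the M/M/inf-type process at every sampled time
  a <- 0.46 / 1.12
  for (j in c(4, 10, 19, 31)) {
    t_min <- tr$times_s[j] / 60
    expected <- a * (1 - exp(-1.12 * t_min))
    se <- stats::sd(tr$counts[, j]) / sqrt(10000)
    expect_lt(abs(mean(tr$counts[, j]) - expected), 3 * se)
  }
})

test_that("event logs are consistent and reproducible under a fixed seed", {
  cfg <- sim_config(n_cells = 50, duration_s = 200, seed = 31)
  tr1 <- simulate_transcription_counts(cfg)
  tr2 <- simulate_transcription_counts(cfg)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$counts, tr2$counts)

  # arrivals strictly increasing per cell; departures after arrivals
  expect_true(all(tr1$events$departure_s > tr1$events$arrival_s))
  by_cell <- split(tr1$events$arrival_s, tr1$events$cell)
  expect_true(all(vapply(by_cell, function(a) all(diff(a) > 0), logical(1))))

  # loci confined to the nucleoid disk
  r <- sqrt(tr1$cells$locus_x^2 + tr1$cells$locus_z^2)
  expect_true(all(r < cfg$nucleoid_l))
})

test_that("fixed-dwell mode keeps the same mean plateau", {
  cfg <- sim_config(n_cells = 4000, duration_s = 360, seed = 8)
  tr <- simulate_transcription_counts(cfg, dwell = "fixed")
  plateau <- mean(tr$counts[, tr$times_s >= 240])
  expect_lt(abs(plateau - 0.46 / 1.12), 0.03)
})

test_that("radial relocation displaces loci by the requested mean", {
  cfg <- sim_config(n_cells = 400, duration_s = 200, seed = 5)
  tr <- simulate_transcription_counts(cfg)

  # zero step leaves positions untouched
  tr0 <- simulate_radial_relocation(tr, 0, onset_s = 50)
  expect_equal(tr0$locus_x_t[, ncol(tr0$locus_x_t)], tr$cells$locus_x)

  # fixed magnitude: mean displacement is exactly the configured step
  tr61 <- simulate_radial_relocation(tr, 61, onset_s = 50)
  expect_equal(mean(tr61$relocation$displacement_nm), 61)
  # positions before onset unchanged, after onset radially further out
  before <- tr61$times_s < 50
  expect_equal(tr61$locus_x_t[, before],
               matrix(rep(tr$cells$locus_x, sum(before)), ncol = sum(before)))
  r0 <- sqrt(tr$cells$locus_x^2 + tr$cells$locus_z^2)
  r1 <- sqrt(tr61$locus_x_t[, 21]^2 + tr61$locus_z_t[, 21]^2)
  expect_true(all(r1 >= r0))

  # exponential magnitudes: mean within Monte Carlo error
  tre <- simulate_radial_relocation(tr, 61, onset_s = 50,
                                    magnitude = "exponential")
  se <- stats::sd(tre$relocation$displacement_nm) / sqrt(400)
  expect_lt(abs(mean(tre$relocation$displacement_nm) - 61), 3 * se)

  # reproducibility and rejection of negative steps
  tre2 <- simulate_radial_relocation(tr, 61, onset_s = 50,
                                     magnitude = "exponential")
  expect_identical(tre$relocation$displacement_nm,
                   tre2$relocation$displacement_nm)
  expect_error(simulate_radial_relocation(tr, -1, 50), "non-negative")
})

test_that("decay series follows 2^(-t/half-life) with lognormal noise", {
  # noiseless: exact half-life ratio and frozen table of 2^(-t/5.5)
  d <- simulate_decay_series(5.5, c(0, 5.5), noise_cv = 0)
  expect_equal(d$abundance[2] / d$abundance[1], 0.5)

  d6 <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0, a0 = 1)
  expect_equal(round(d6$abundance, 4),
               c(1, 0.7772, 0.6040, 0.4695, 0.3649, 0.2836))

  # noisy series reproducible and mean-preserving on average
  n1 <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0.05, seed = 3)
  n2 <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0.05, seed = 3)
  expect_identical(n1, n2)

  expect_error(simulate_decay_series(-1, 0:5), "half_life")
  expect_error(simulate_decay_series(5.5, 0:5, noise_cv = -0.1), "noise_cv")
})

test_that("probe onset ramps encode the elongation delay", {
  r <- simulate_probe_onsets(90, c(900, 2700))
  expect_equal(diff(attr(r, "onsets_s")), 20)
  # abundance zero before onset, linear after
  p2 <- r[r$probe == 2, ]
  expect_true(all(p2$abundance[p2$time_s <= 30] == 0))
  expect_equal(diff(p2$abundance[p2$time_s >= 40]),
               rep(2, sum(p2$time_s >= 40) - 1))

  expect_error(simulate_probe_onsets(90, c(900, 900)), "distinct")
  expect_error(simulate_probe_onsets(0, c(900, 2700)), "positive")
})
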