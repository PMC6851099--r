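test_that("confined spots have the uniform-disk moments", {
  m <- cylinder_model(l = 0.35, scale_nm = 860, n_spots = 100000, seed = 4)
  e <- sample_confined(m)
  r <- sqrt(e$x^2 + e$y^2)
  expect_true(all(r < 0.35))

  # first absolute moment 4l/(3pi) and variance l^2/4
  se_mean <- stats::sd(abs(e$x)) / sqrt(nrow(e))
  expect_lt(abs(mean(abs(e$x)) - 4 * 0.35 / (3 * pi)), 3 * se_mean)
  expect_lt(abs(stats::var(e$x) - 0.35^2 / 4) / (0.35^2 / 4), 0.02)

  # bit-reproducible under the model seed
  expect_identical(e, sample_confined(m))
})

test_that("model parameters are validated", {
  expect_error(cylinder_model(l = 0.6), "0.5")
  expect_error(cylinder_model(scale_nm = -1), "scale_nm")
  expect_error(cylinder_model(loc_error_nm = -1), "loc_error_nm")
})

test_that("localization blur adds the expected variance", {
  m <- cylinder_model(l = 0.35, scale_nm = 860, loc_error_nm = 70,
                      n_spots = 50000, seed = 6)
  e <- sample_confined(m)

  m0 <- m; m0$loc_error_nm <- 0
  expect_equal(blur(e, m0)$x, e$x)

  b <- blur(e, m, seed = 99)
  s2 <- (70 / 860)^2
  expect_lt(abs(stats::var(b$x) - (stats::var(e$x) + s2)) /
              (stats::var(e$x) + s2), 0.02)
  expect_identical(blur(e, m, seed = 99), b)
})

test_that("radial displacement moves spots outward by the requested mean", {
  m <- cylinder_model(l = 0.35, scale_nm = 860, n_spots = 30000, seed = 7)
  e <- sample_confined(m)

  expect_equal(radial_displace(e, 0, m)$x, e$x)
  expect_error(radial_displace(e, -5, m), "non-negative")

  d <- radial_displace(e, 61, m)
  dr <- (sqrt(d$x^2 + d$y^2) - sqrt(e$x^2 + e$y^2)) * m$scale_nm
  expect_lt(max(abs(dr - 61)), 1e-9)   # fixed mode: exactly 61 nm outward

  de <- radial_displace(e, 61, m, magnitude = "exponential", seed = 42)
  dre <- (sqrt(de$x^2 + de$y^2) - sqrt(e$x^2 + e$y^2)) * m$scale_nm
  expect_lt(abs(mean(dre) - 61), 3 * stats::sd(dre) / sqrt(length(dre)))

  # far from folding effects the mean |x| change is (2/pi) x step
  ring <- structure(data.frame(
    x = 0.3 * cos(seq(0, 2 * pi, length.out = 20001)[-1]),
    y = 0.3 * sin(seq(0, 2 * pi, length.out = 20001)[-1])),
    class = c("spot_ensemble", "data.frame"))
  step_nm <- 0.01 * m$scale_nm
  rd <- radial_displace(ring, step_nm, m)
  shift <- mean(abs(rd$x)) - mean(abs(ring$x))
  expect_lt(abs(shift - (2 / pi) * 0.01) / ((2 / pi) * 0.01), 0.01)
})

test_that("projected shift is a paired mean-|x| difference", {
  m <- cylinder_model(n_spots = 1000, seed = 8)
  e <- sample_confined(m)
  expect_equal(projected_shift(e, e), 0)

  # rigid outward translation along +x with no fold crossings
  pos <- e
  pos$x <- abs(pos$x) + 0.01
  moved <- pos
  moved$x <- moved$x + 0.02
  expect_equal(projected_shift(pos, moved), 0.02)

  short <- e[1:10, ]
  class(short) <- class(e)
  expect_error(projected_shift(e, short), "equal size")
})

test_that("blur without displacement produces no shift between measurements", {
  # both the before and after ensembles carry localization error, as in
  # the measurement pipeline; with no displacement in between, the
  # projected shift is zero in expectation
  m <- cylinder_model(l = 0.35, scale_nm = 860, loc_error_nm = 70,
                      n_spots = 100000, seed = 9)
  e <- sample_confined(m)
  b1 <- blur(e, m, seed = 10)
  b2 <- blur(e, m, seed = 20)
  diffs <- abs(b2$x) - abs(b1$x)
  shift <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(shift), 4 * se)
  # and the common-random-numbers pipeline is exactly zero at zero step
  expect_identical(relocation_shift(m, 0), 0)

  # blurring an unmeasured ensemble does inflate mean |x| (folding),
  # which is why both stages are measured with error
  expect_gt(mean(abs(b1$x)) - mean(abs(e$x)), 0)
})

test_that("shift inversion is the identity on imposed displacements", {
  m <- cylinder_model(l = 0.35, scale_nm = 860, loc_error_nm = 70,
                      n_spots = 40000, seed = 11)
  for (d in c(20, 61, 100)) {
    s <- relocation_shift(m, d)
    inv <- invert_shift(s, m, interval_nm = c(0, 300))
    expect_lt(abs(inv$displacement_nm - d), 1)
  }
  # monotonicity of the forward map
  shifts <- vapply(c(0, 20, 40, 61, 100, 150), function(d)
    relocation_shift(m, d), numeric(1))
  expect_true(all(diff(shifts) > 0))
  expect_equal(invert_shift(0, m)$displacement_nm, 0)
  expect_error(invert_shift(10, m, interval_nm = c(0, 1)), "bracket")
})

test_that("scale calibration reproduces the reference shift", {
  m <- cylinder_model(l = 0.35, loc_error_nm = 70, n_spots = 40000,
                      seed = 12)
  cal <- calibrate_scale(m, displacement_nm = 61, target_shift = 0.07)
  expect_lt(abs(cal$achieved_shift - 0.07), 1e-3)
  m$scale_nm <- cal$scale_nm
  expect_lt(abs(relocation_shift(m, 61) - 0.07), 1e-3)
})

test_that("nucleoid percentages and FWHM follow their definitions", {
  expect_equal(percent_of_nucleoid(81, 300), 27)
  expect_equal(percent_of_nucleoid(30, 300), 10)
  expect_equal(percent_of_nucleoid(0, 300), 0)
  expect_error(percent_of_nucleoid(30, 0), "positive")

  # Gaussian profile with sigma = 600 / 2.3548 has FWHM 600 nm
  x <- seq(-1500, 1500, 5)
  prof <- exp(-x^2 / (2 * (600 / 2.3548)^2))
  expect_lt(abs(nucleoid_fwhm(x, prof) - 600), 1)

  # boxcar keeps its width; scaling the axis scales the FWHM
  xb <- seq(0, 100, 1)
  box <- as.numeric(xb >= 30 & xb < 70)
  expect_equal(nucleoid_fwhm(xb, box), 40)
  expect_equal(nucleoid_fwhm(3 * xb, box), 120)

  expect_error(nucleoid_fwhm(xb, rep(1, length(xb))), "cross")
})
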