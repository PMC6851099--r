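test_that("noiseless Gaussian spots are localized to sub-0.01 px", {
  img <- gaussian_frame(21, 21, 10.30, 7.60, 1.3, 500)
  f <- fit_spot(img)
  expect_true(f$accepted)
  expect_lt(abs(f$x - 10.30), 0.01)
  expect_lt(abs(f$y - 7.60), 0.01)
  expect_lt(abs(f$sigma - 1.3), 0.05)
})

test_that("localization bias stays below 0.01 px across sub-pixel phases", {
  for (px in seq(0, 0.8, by = 0.2)) {
    for (py in c(0.1, 0.5, 0.9)) {
      img <- gaussian_frame(17, 17, 8 + px, 8 + py, 1.3, 400, offset = 10)
      f <- fit_spot(img, threshold_k = 3)
      expect_true(f$accepted)
      expect_lt(abs(f$x - (8 + px)), 0.01)
      expect_lt(abs(f$y - (8 + py)), 0.01)
    }
  }
})

test_that("featureless regions are rejected with a reason code", {
  f <- fit_spot(matrix(5, 15, 15))
  expect_false(f$accepted)
  expect_equal(f$reason, "below_threshold")

  set.seed(3)
  f2 <- fit_spot(matrix(rnorm(225, 100, 3), 15, 15))
  expect_false(f2$accepted)
})

test_that("localization scatter at the default photon budget is ~70 nm", {
  cfg <- sim_config(seed = 1)
  sig <- cfg$psf_sigma_nm / cfg$pixel_size_nm
  set.seed(9)
  err <- replicate(250, {
    x0 <- 7.5 + stats::runif(1, -0.5, 0.5)
    y0 <- 7.5 + stats::runif(1, -0.5, 0.5)
    img <- gaussian_frame(15, 15, x0, y0, sig, cfg$single_fluor_intensity,
                          offset = cfg$background_level)
    img[] <- stats::rpois(length(img), img)
    img <- img + stats::rnorm(length(img), 0, cfg$camera_noise_sd)
    f <- fit_spot(img)
    if (f$accepted) c(f$x - x0, f$y - y0) else c(NA, NA)
  })
  err <- stats::na.omit(as.vector(err))
  sd_nm <- stats::sd(err) * cfg$pixel_size_nm
  expect_gt(sd_nm, 40)
  expect_lt(sd_nm, 100)
})

test_that("cell axes from mask moments recover shape and orientation", {
  # axis-aligned 40 x 10 rectangle: ratio 4, orientation 0
  m <- matrix(FALSE, 30, 60); m[10:19, 10:49] <- TRUE
  g <- fit_cell_axes(m)
  expect_lt(abs(g$orientation), 0.01)
  expect_lt(abs(g$long_half / g$short_half - 4), 0.2)

  # rotated capsule: orientation recovered within 1 degree
  for (deg in c(30, -50)) {
    th <- deg * pi / 180
    mr <- capsule_mask(80, 80, 40, 40, th, 44, 10)
    gr <- fit_cell_axes(mr)
    expect_lt(abs(gr$orientation - th), 1 * pi / 180)
  }

  # disk: degenerate axes
  xy <- expand.grid(r = 1:41, c = 1:41)
  disk <- matrix((xy$r - 21)^2 + (xy$c - 21)^2 <= 15^2, 41, 41)
  gd <- fit_cell_axes(disk)
  expect_lt(gd$long_half / gd$short_half, 1.03)

  expect_error(fit_cell_axes(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[15:18, 15:18] <- TRUE
  expect_error(fit_cell_axes(two), "single connected")
})

test_that("relative positions follow the half-at-membrane convention", {
  g <- structure(list(centroid = c(x = 50, y = 30), long_half = 20,
                      short_half = 4, orientation = 0),
                 class = "cell_geometry")
  # centroid maps to the origin
  p0 <- relative_position(list(x = 50, y = 30), g)
  expect_equal(c(p0$x_rel, p0$y_rel), c(0, 0))
  # membrane at mid-length maps to x_rel = 0.5
  pm <- relative_position(list(x = 50, y = 34), g)
  expect_equal(c(pm$x_rel, pm$y_rel), c(0.5, 0))
  # worked offsets: (along, across) = (-5, 2) in half-axes (20, 4)
  pw <- relative_position(list(x = 45, y = 32), g)
  expect_equal(c(pw$x_rel, pw$y_rel), c(0.25, 0.125))
  # outside the ellipse beyond tolerance
  expect_error(relative_position(list(x = 50, y = 36), g), "outside")
})

test_that("relative positions are invariant under rigid motions", {
  len <- 44; wid <- 12
  along <- 8; across <- 2.5
  ref <- NULL
  for (th in c(0, 0.4, 1.1, -0.9)) {
    cx <- 60 + 5 * th; cy <- 60 - 3 * th   # translation varies too
    m <- capsule_mask(120, 120, cx, cy, th, len, wid)
    g <- fit_cell_axes(m)
    sx <- cx + along * cos(th) - across * sin(th)
    sy <- cy + along * sin(th) + across * cos(th)
    p <- relative_position(list(x = sx, y = sy), g)
    if (is.null(ref)) {
      ref <- p
    } else {
      expect_lt(abs(p$x_rel - ref$x_rel), 0.02)
      expect_lt(abs(p$y_rel - ref$y_rel), 0.02)
    }
  }
})

test_that("windowed mean positions and bootstrap intervals behave", {
  pos <- data.frame(x_rel = c(0.1, 0.3), time_s = c(10, 20))
  mp <- mean_position(pos)
  expect_equal(mp$mean, 0.2)
  expect_equal(mp$n, 2)
  expect_equal(mean_position(data.frame(x_rel = rep(0.2, 5),
                                        time_s = 1:5))$sd, 0)
  expect_error(mean_position(pos, window = c(100, 200)), "no foci")

  # constant sample: zero half-width
  expect_equal(bootstrap_mean_ci(rep(0.3, 20)), 0)

  # Gaussian n = 350: half-width ~ 1.96 sd / sqrt(350)
  set.seed(4)
  x <- stats::rnorm(350, 0.2, 0.1)
  hw <- bootstrap_mean_ci(x, n_boot = 4000, seed = 11)
  expect_lt(abs(hw - 1.96 * stats::sd(x) / sqrt(350)) /
              (1.96 * stats::sd(x) / sqrt(350)), 0.10)

  # expected shrink as n doubles (averaged over replicates)
  set.seed(6)
  hw_small <- mean(replicate(8, bootstrap_mean_ci(
    stats::rnorm(100, 0, 0.1), n_boot = 500,
    seed = sample.int(1e6, 1))))
  hw_big <- mean(replicate(8, bootstrap_mean_ci(
    stats::rnorm(400, 0, 0.1), n_boot = 500,
    seed = sample.int(1e6, 1))))
  expect_lt(hw_big, hw_small)

  expect_error(bootstrap_mean_ci(0.5), "two")
})
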