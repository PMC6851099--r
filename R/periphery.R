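#' Cylindrical nucleoid Monte Carlo model
#'
#' Parameters of the cross-section simulation of locus positions in a
#' rod-shaped cell: loci are confined to a disk of normalized radius `l`
#' (the nucleoid boundary; the membrane sits at 0.5 in these units, one
#' unit being the full cell width), each measured coordinate carries a
#' Gaussian localization error, and the physical scale converts
#' nanometres to normalized units.
#'
#' @param l normalized confinement radius, in (0, 0.5].
#' @param scale_nm nanometres per normalized unit (per full cell width);
#'   see [calibrate_scale()] for the calibration tying a 61-nm mean
#'   displacement to a 0.07 projected shift.
#' @param loc_error_nm localization error sigma per axis (nm, >= 0).
#' @param n_spots ensemble size.
#' @param seed integer seed.
#' @return A list of class `cylinder_model`.
#' @examples
#' m <- cylinder_model(l = 0.35, scale_nm = 860, n_spots = 1e4)
#' @export
cylinder_model <- function(l = 0.35, scale_nm = 860, loc_error_nm = 70,
                           n_spots = 100000, seed = 1L) {
  if (!(l > 0 && l <= 0.5)) stop("'l' must lie in (0, 0.5]")
  if (scale_nm <= 0) stop("'scale_nm' must be strictly positive")
  if (loc_error_nm < 0) stop("'loc_error_nm' must be non-negative")
  if (n_spots < 1) stop("'n_spots' must be at least 1")
  structure(list(l = l, scale_nm = scale_nm, loc_error_nm = loc_error_nm,
                 n_spots = as.integer(n_spots), seed = as.integer(seed)),
            class = "cylinder_model")
}

#' Sample spots uniformly inside the nucleoid cross-section
#'
#' Seeded rejection sampling of `n_spots` points uniform on the disk of
#' radius `l` in the cell cross-section plane, emulating gene loci
#' confined by nucleoid condensation before transcription begins.
#'
#' @param model a [cylinder_model()].
#' @return A data frame of class `spot_ensemble` with columns `x`, `y`
#'   (normalized cross-section coordinates) and attribute `stage =
#'   "initial"`.
#' @examples
#' e <- sample_confined(cylinder_model(n_spots = 1000))
#' mean(abs(e$x))   # ~ 4 l / (3 pi)
#' @export
sample_confined <- function(model) {
  stopifnot(inherits(model, "cylinder_model"))
  set.seed(model$seed)
  sample_confined_impl(model)
}

sample_confined_impl <- function(model) {
  pts <- runif_disk(model$n_spots, model$l)
  ens <- data.frame(x = pts$x, y = pts$z)
  attr(ens, "stage") <- "initial"
  class(ens) <- c("spot_ensemble", "data.frame")
  ens
}

#' Apply Gaussian localization error to an ensemble
#'
#' Adds independent Gaussian noise of sigma `loc_error_nm / scale_nm`
#' (normalized units) to each coordinate, emulating the measurement error
#' of single-spot localization.
#'
#' @param ensemble a `spot_ensemble`.
#' @param model a [cylinder_model()] supplying the error and scale.
#' @param seed optional integer; if given, seeds the RNG first (otherwise
#'   the current stream continues).
#' @return The blurred ensemble (stage `"blurred"`).
#' @export
blur <- function(ensemble, model, seed = NULL) {
  stopifnot(inherits(ensemble, "spot_ensemble"),
            inherits(model, "cylinder_model"))
  if (is.null(model$scale_nm) || !is.finite(model$scale_nm)) {
    stop("'scale_nm' must be set to apply a localization error in nm")
  }
  if (!is.null(seed)) set.seed(seed)
  s <- model$loc_error_nm / model$scale_nm
  if (s > 0) {
    n <- nrow(ensemble)
    ensemble$x <- ensemble$x + stats::rnorm(n, 0, s)
    ensemble$y <- ensemble$y + stats::rnorm(n, 0, s)
  }
  attr(ensemble, "stage") <- "blurred"
  ensemble
}

#' Displace spots radially outward
#'
#' Moves each spot along its radial unit vector in the cross-section by a
#' magnitude with the requested mean — the model of transcription-driven
#' relocation toward the nucleoid periphery. Spots exactly at the origin
#' receive a uniformly random direction.
#'
#' @param ensemble a `spot_ensemble`.
#' @param mean_step_nm mean displacement (nm, >= 0).
#' @param model a [cylinder_model()] (for the nm-to-normalized scale).
#' @param magnitude `"fixed"` (every spot moves exactly `mean_step_nm`,
#'   default) or `"exponential"` (exponential magnitudes with that mean).
#' @param seed optional integer seed (see [blur()]).
#' @return The displaced ensemble (stage `"displaced"`).
#' @export
radial_displace <- function(ensemble, mean_step_nm, model,
                            magnitude = c("fixed", "exponential"),
                            seed = NULL) {
  stopifnot(inherits(ensemble, "spot_ensemble"),
            inherits(model, "cylinder_model"))
  magnitude <- match.arg(magnitude)
  if (mean_step_nm < 0) stop("'mean_step_nm' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ensemble)
  step <- switch(magnitude,
    fixed = rep(mean_step_nm, n),
    exponential = if (mean_step_nm > 0) stats::rexp(n, 1 / mean_step_nm)
                  else rep(0, n)
  ) / model$scale_nm
  r <- sqrt(ensemble$x^2 + ensemble$y^2)
  phi <- ifelse(r > 0, atan2(ensemble$y, ensemble$x),
                stats::runif(n, 0, 2 * pi))
  ensemble$x <- ensemble$x + step * cos(phi)
  ensemble$y <- ensemble$y + step * sin(phi)
  attr(ensemble, "stage") <- "displaced"
  ensemble
}

#' Projected mean-|x| shift between two ensembles
#'
#' The observable of the relocation experiment: the change in the mean
#' folded position along the short (x) axis, `mean(|x|_after) -
#' mean(|x|_before)`, in normalized units.
#'
#' @param before,after `spot_ensemble`s of equal size.
#' @return The shift (normalized units).
#' @export
projected_shift <- function(before, after) {
  stopifnot(inherits(before, "spot_ensemble"),
            inherits(after, "spot_ensemble"))
  if (nrow(before) != nrow(after)) {
    stop("'before' and 'after' ensembles must have equal size")
  }
  mean(abs(after$x)) - mean(abs(before$x))
}

#' Forward relocation pipeline under common random numbers
#'
#' Runs the full measurement model once: sample confined spots, measure
#' them with localization error (before), displace them radially by
#' `step_nm` on average, and measure again with the *same* error draws
#' (after). Sharing the sample and the blur noise between the two stages
#' (common random numbers) makes the projected shift a smooth, exactly
#' zero-at-zero function of the step, which the inversion exploits.
#'
#' @param model a [cylinder_model()].
#' @param step_nm mean radial displacement (nm).
#' @param magnitude passed to [radial_displace()].
#' @return The projected mean-|x| shift (normalized units).
#' @export
relocation_shift <- function(model, step_nm, magnitude = "fixed") {
  set.seed(model$seed)
  ens <- sample_confined_impl(model)
  n <- nrow(ens)
  s <- model$loc_error_nm / model$scale_nm
  nx <- stats::rnorm(n, 0, s)
  ny <- stats::rnorm(n, 0, s)
  before <- ens
  before$x <- before$x + nx
  before$y <- before$y + ny
  after <- radial_displace(ens, step_nm, model, magnitude = magnitude)
  after$x <- after$x + nx
  after$y <- after$y + ny
  mean(abs(after$x)) - mean(abs(before$x))
}

#' Invert a projected shift into a physical displacement
#'
#' Solves, by bisection on the mean radial step under common random
#' numbers, for the displacement (nm) whose forward-simulated projected
#' shift matches the target. This is the inverse problem behind converting
#' an observed normalized shift along the short axis into a 3D radial
#' movement of the locus.
#'
#' @param target_shift target projected shift (normalized units, >= 0).
#' @param model a [cylinder_model()].
#' @param interval_nm search interval for the step (nm).
#' @param tol absolute tolerance on the achieved shift.
#' @param magnitude passed to [radial_displace()].
#' @return List with `displacement_nm`, `achieved_shift` and `iterations`.
#' @examples
#' m <- cylinder_model(n_spots = 20000, scale_nm = 860, seed = 3)
#' s <- relocation_shift(m, 61)
#' invert_shift(s, m)$displacement_nm   # ~61
#' @export
invert_shift <- function(target_shift, model, interval_nm = c(0, 500),
                         tol = 1e-4, magnitude = "fixed") {
  if (target_shift < 0) stop("'target_shift' must be non-negative")
  if (target_shift == 0) {
    return(list(displacement_nm = 0, achieved_shift = 0, iterations = 0L))
  }
  f <- function(step) relocation_shift(model, step, magnitude = magnitude)
  lo <- interval_nm[1]; hi <- interval_nm[2]
  flo <- f(lo); fhi <- f(hi)
  if ((flo - target_shift) * (fhi - target_shift) > 0) {
    stop("search interval does not bracket the target shift")
  }
  it <- 0L
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    it <- it + 1L
    if (abs(fm - target_shift) < tol || (hi - lo) < 1e-6) break
    if ((fm - target_shift) * (flo - target_shift) < 0) {
      hi <- mid
    } else {
      lo <- mid; flo <- fm
    }
    if (it > 200) stop("bisection failed to converge")
  }
  list(displacement_nm = mid, achieved_shift = fm, iterations = it)
}

#' Calibrate the physical scale of normalized units
#'
#' Solves for `scale_nm` (nanometres per normalized unit) such that a
#' given mean radial displacement produces a given projected mean-|x|
#' shift under the full pipeline (confinement, displacement and
#' localization blur). Ties the normalized-coordinate observable to a
#' physical distance without hard-coding the conversion.
#'
#' @param model a [cylinder_model()] whose `scale_nm` is to be solved for.
#' @param displacement_nm reference displacement (default 61 nm).
#' @param target_shift reference projected shift (default 0.07).
#' @param interval_nm search interval for the scale.
#' @return List with `scale_nm` and `achieved_shift`.
#' @export
calibrate_scale <- function(model, displacement_nm = 61, target_shift = 0.07,
                            interval_nm = c(100, 5000)) {
  g <- function(scale) {
    m <- model
    m$scale_nm <- scale
    relocation_shift(m, displacement_nm) - target_shift
  }
  sol <- stats::uniroot(g, interval_nm, tol = 1e-3)
  list(scale_nm = sol$root, achieved_shift = sol$f.root + target_shift)
}

#' Displacement as a percentage of the nucleoid half-width
#'
#' @param displacement_nm radial displacement (nm).
#' @param nucleoid_halfwidth_nm nucleoid half-width (nm, > 0); the
#'   half-width is half the full-width-at-half-maximum of the stained
#'   nucleoid's short-axis intensity profile.
#' @return Percentage `100 * displacement / halfwidth`.
#' @examples
#' percent_of_nucleoid(81, 300)   # 27
#' @export
percent_of_nucleoid <- function(displacement_nm, nucleoid_halfwidth_nm) {
  if (nucleoid_halfwidth_nm <= 0) {
    stop("'nucleoid_halfwidth_nm' must be strictly positive")
  }
  100 * displacement_nm / nucleoid_halfwidth_nm
}

#' Full width at half maximum of a 1D intensity profile
#'
#' Linear-interpolated width at half of (max - baseline), the standard
#' definition of nucleoid dimensions from stained-image intensity
#' profiles. The baseline is the profile minimum.
#'
#' @param position numeric axis (same units as the returned width),
#'   strictly increasing.
#' @param intensity profile values.
#' @return FWHM in the units of `position`.
#' @examples
#' x <- seq(-1000, 1000, 5)
#' nucleoid_fwhm(x, exp(-x^2 / (2 * 254.8^2)))   # ~600
#' @export
nucleoid_fwhm <- function(position, intensity) {
  stopifnot(length(position) == length(intensity), length(position) >= 3,
            all(diff(position) > 0))
  base <- min(intensity)
  half <- base + (max(intensity) - base) / 2
  imax <- which.max(intensity)
  above <- intensity >= half
  left <- which(!above[seq_len(imax)])
  right <- which(!above[imax:length(intensity)])
  if (!length(left) || !length(right)) {
    stop("profile does not cross half-maximum on both sides")
  }
  il <- max(left)                 # last below-half index left of the peak
  ir <- imax + min(right) - 1L    # first below-half index right of it
  xl <- position[il] + (half - intensity[il]) /
    (intensity[il + 1] - intensity[il]) * (position[il + 1] - position[il])
  xr <- position[ir - 1] + (half - intensity[ir - 1]) /
    (intensity[ir] - intensity[ir - 1]) * (position[ir] - position[ir - 1])
  xr - xl
}
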