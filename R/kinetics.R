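#' Mean number of transcribing polymerases under the kinetic model
#'
#' The immigration–death model of single-gene transcription: polymerases
#' enter elongation at constant rate `k_on` and each leaves at rate
#' `k_off`, so the population mean count after induction at t = 0 is
#' `a (1 - exp(-b t))` with plateau `a = k_on / k_off` and rate
#' `b = k_off`.
#'
#' @param a plateau (mean transcribing polymerases per cell), > 0.
#' @param b rate constant (per minute), > 0.
#' @param t time in minutes, >= 0 (vectorized).
#' @return Expected mean count at `t`.
#' @examples
#' model_mean(0.4107, 1.12, 5)
#' @export
model_mean <- function(a, b, t) {
  if (a <= 0 || b <= 0) stop("'a' and 'b' must be strictly positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  a * (1 - exp(-b * t))
}

#' Fit the induction curve and derive transcription kinetic parameters
#'
#' Weighted nonlinear least squares of `a (1 - exp(-b t))` to a
#' population-mean induction series (mean transcribing polymerases per
#' cell vs time after induction). Weights are `n / sd^2` (inverse squared
#' standard error) where dispersion columns are available, unweighted
#' otherwise. Derived rates follow [derive_rates()].
#'
#' @param series data frame with `time_s` and `count` columns (e.g. an
#'   `induction_series` from [count_transcribing()]), optionally `sd` and
#'   `n` for weighting.
#' @param gene_length_bp transcribed gene length (bp) for elongation-rate
#'   derivation; default 4500.
#' @param rnap_total optional average total polymerases per cell, used to
#'   derive the per-polymerase on-rate `k'_on = k_on / rnap_total`.
#' @return A `kinetic_estimate` (see [derive_rates()]) with standard
#'   errors `a_se`, `b_se` from the fit covariance, and a logical
#'   `plateau_warning` set when `b * t_max < 1` (curve far from plateau,
#'   so `a` and `b` are poorly separated).
#' @export
fit_induction <- function(series, gene_length_bp = 4500, rnap_total = NULL) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "count") %in% names(series)))
  if (nrow(series) < 5) stop("at least 5 time points are required")
  t_min <- series$time_s / 60
  y <- series$count
  w <- NULL
  if (all(c("sd", "n") %in% names(series)) &&
      all(is.finite(series$sd)) && all(series$sd > 0)) {
    w <- series$n / series$sd^2
  }
  a0 <- max(y, na.rm = TRUE)
  if (a0 <= 0) stop("induction series has no positive counts; cannot fit")
  # initial rate guess: time to reach ~63% of the apparent plateau
  i63 <- which(y >= 0.63 * a0)[1]
  b0 <- if (!is.na(i63) && t_min[i63] > 0) 1 / t_min[i63] else
    1 / max(t_min[t_min > 0][1], 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t_min)),
                      start = list(a = a0, b = b0),
                      weights = if (is.null(w)) rep(1, length(y)) else w,
                      lower = c(a = 1e-12, b = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("induction fit did not converge: ", conditionMessage(e))
    })
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  est <- derive_rates(p[["a"]], p[["b"]], gene_length_bp,
                      rnap_total = rnap_total)
  est$a_se <- unname(se[1])
  est$b_se <- unname(se[2])
  est$plateau_warning <- p[["b"]] * max(t_min) < 1
  if (est$plateau_warning) {
    warning("b * t_max < 1: the induction curve is far from its plateau; ",
            "fitted parameters are poorly constrained")
  }
  est$fit <- fit
  est
}

#' Derive transcription rates from the fitted plateau and rate constant
#'
#' From the single-exponential fit `a (1 - exp(-b t))`:
#' * `k_off = b` (per minute) — the transcriptional off-rate, set by the
#'   elongation duration;
#' * `k_on = a * b` (per minute) — the pseudo-first-order on-rate
#'   aggregating promoter search, complex formation and initiation;
#' * `elongation_rate = L * b / 60` (bp/s) for gene length `L`;
#' * `elongation_time = 60 / b` (s) and `search_time = 60 / k_on` (s).
#'
#' `elongation_rate * elongation_time = L` holds exactly.
#'
#' @param a plateau (mean transcribing polymerases/cell).
#' @param b rate constant (per minute).
#' @param gene_length_bp gene length in base pairs.
#' @param rnap_total optional total polymerases per cell for the
#'   per-polymerase on-rate `kprime_on = k_on / rnap_total`.
#' @return A list of class `kinetic_estimate`.
#' @examples
#' e <- derive_rates(0.41, 1.12, 4500)
#' e$elongation_rate_bp_s   # 84
#' @export
derive_rates <- function(a, b, gene_length_bp, rnap_total = NULL) {
  if (a <= 0 || b <= 0 || gene_length_bp <= 0) {
    stop("'a', 'b' and 'gene_length_bp' must be strictly positive")
  }
  k_on <- a * b
  est <- list(a = a, b = b,
              gene_length_bp = gene_length_bp,
              k_on_per_min = k_on,
              k_off_per_min = b,
              elongation_rate_bp_s = gene_length_bp * b / 60,
              elongation_time_s = 60 / b,
              search_time_s = 60 / k_on)
  if (!is.null(rnap_total)) est$kprime_on_per_min <- k_on / rnap_total
  class(est) <- "kinetic_estimate"
  est
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat("Transcription kinetic estimate\n")
  cat(sprintf("  a (plateau)      : %.4f polymerases/cell\n", x$a))
  cat(sprintf("  k_on             : %.3f /min  (search time %.0f s)\n",
              x$k_on_per_min, x$search_time_s))
  cat(sprintf("  k_off            : %.3f /min  (elongation time %.0f s)\n",
              x$k_off_per_min, x$elongation_time_s))
  cat(sprintf("  elongation rate  : %.0f bp/s over %d bp\n",
              x$elongation_rate_bp_s, round(x$gene_length_bp)))
  invisible(x)
}

#' Fit first-order mRNA decay on a log scale
#'
#' Ordinary least squares of `log(abundance)` against time; the half-life
#' is `ln 2 / |slope|`. Models a rifampicin run-off series in which
#' transcription is arrested at t = 0 and remaining mRNA decays
#' exponentially.
#'
#' @param times_min sampling times (min), length >= 3.
#' @param abundances positive abundances.
#' @return List of class `decay_fit`: `half_life_min`, `half_life_se_min`,
#'   `decay_rate_per_min` (natural-log slope magnitude), `intercept`
#'   (abundance at t = 0) and the underlying `lm` fit.
#' @examples
#' d <- simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0)
#' fit_decay(d$time_min, d$abundance)$half_life_min
#' @export
fit_decay <- function(times_min, abundances) {
  if (length(times_min) < 3) stop("at least 3 time points are required")
  if (any(abundances <= 0)) stop("abundances must be strictly positive")
  fit <- stats::lm(log(abundances) ~ times_min)
  slope <- stats::coef(fit)[["times_min"]]
  if (slope >= 0) stop("no decay: fitted slope of log abundance is not negative")
  # summary() warns on exact (noise-free) fits; the zero SE is fine
  se <- suppressWarnings(
    summary(fit)$coefficients["times_min", "Std. Error"])
  structure(list(half_life_min = log(2) / abs(slope),
                 half_life_se_min = log(2) * se / slope^2,
                 decay_rate_per_min = abs(slope),
                 intercept = exp(stats::coef(fit)[[1]]),
                 fit = fit),
            class = "decay_fit")
}

#' Degradation-corrected production (transcription) ratio
#'
#' At steady state, abundance = production rate x mean lifetime, so an
#' observed abundance ratio between two strains overstates the production
#' ratio when the numerator strain's mRNA is also longer-lived. The
#' corrected production ratio is
#' `abundance_ratio x half_life_den / half_life_num`.
#'
#' @param abundance_ratio steady-state abundance ratio (numerator strain /
#'   denominator strain).
#' @param half_life_num_min numerator strain's mRNA half-life (min).
#' @param half_life_den_min denominator strain's mRNA half-life (min).
#' @return Production-rate fold change.
#' @examples
#' corrected_production_ratio(36, 5.5, 2.4)   # ~16-fold
#' @export
corrected_production_ratio <- function(abundance_ratio, half_life_num_min,
                                       half_life_den_min) {
  if (abundance_ratio <= 0 || half_life_num_min <= 0 ||
      half_life_den_min <= 0) {
    stop("all arguments must be strictly positive")
  }
  abundance_ratio * half_life_den_min / half_life_num_min
}

#' Elongation rate from two probe onset times
#'
#' Two hybridization probes at known positions along the transcript start
#' reporting signal when the first polymerase passes them; the elongation
#' rate is the probe separation divided by the onset-time difference.
#'
#' @param onset_near_s,onset_far_s onset times (s) of the promoter-
#'   proximal and promoter-distal probes.
#' @param separation_bp distance between the probes (bp, > 0).
#' @return Elongation rate in bp/s.
#' @examples
#' elongation_rate_from_onsets(100, 110, 900)   # 90
#' @export
elongation_rate_from_onsets <- function(onset_near_s, onset_far_s,
                                        separation_bp) {
  if (separation_bp <= 0) stop("'separation_bp' must be strictly positive")
  dt <- onset_far_s - onset_near_s
  if (dt <= 0) {
    stop("the far probe must report later than the near probe")
  }
  separation_bp / dt
}

#' Estimate a ramp onset time by hinge regression
#'
#' Fits the piecewise-linear model `abundance = max(0, t - t0) * slope`
#' by least squares over the onset `t0`, recovering when the first
#' polymerase passed a probe from that probe's accumulation ramp.
#'
#' @param time_s sampling times (s).
#' @param abundance non-negative ramp values.
#' @return Estimated onset time `t0` (s).
#' @export
estimate_onset <- function(time_s, abundance) {
  stopifnot(length(time_s) == length(abundance), length(time_s) >= 3)
  rss <- function(t0) {
    x <- pmax(time_s - t0, 0)
    if (all(x == 0)) return(sum(abundance^2))
    slope <- sum(x * abundance) / sum(x^2)
    sum((abundance - slope * x)^2)
  }
  opt <- stats::optimize(rss, range(time_s))
  opt$minimum
}

#' Beta-galactosidase activity in Miller units
#'
#' `1000 * OD420 / (t * V * OD660)` for reaction time `t` (min), assay
#' culture volume `V` (mL) and cell density `OD660`.
#'
#' @param od420 reaction absorbance at 420 nm.
#' @param t_min reaction time in minutes (> 0).
#' @param volume_ml culture volume used, in millilitres (> 0).
#' @param od660 culture density at 660 nm (> 0).
#' @return Activity in Miller units.
#' @examples
#' miller_units(1.0, 10, 0.01, 0.5)   # 20000
#' @export
miller_units <- function(od420, t_min, volume_ml, od660) {
  if (t_min <= 0 || volume_ml <= 0 || od660 <= 0) {
    stop("'t_min', 'volume_ml' and 'od660' must be strictly positive")
  }
  1000 * od420 / (t_min * volume_ml * od660)
}
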