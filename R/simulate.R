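#' Simulate per-cell counts of transcribing polymerases
#'
#' Models transcription of a single gene copy as a continuous-time
#' immigration–death process: polymerases enter productive elongation at a
#' constant pseudo-first-order rate `k_on` and each terminates
#' independently at rate `k_off` (so the mean elongation duration is
#' `1/k_off`). The population mean count then follows
#' `a (1 - exp(-b t))` with `a = k_on/k_off` and `b = k_off`, the model the
#' induction-curve fit recovers.
#'
#' @param config a [sim_config()] object; rates are taken from
#'   `k_on_per_min` / `k_off_per_min` and the frame grid from
#'   `frame_interval_s` / `duration_s`.
#' @param dwell one of `"exponential"` (Markovian dwell, default) or
#'   `"fixed"` (every polymerase elongates for exactly `1/k_off`); the
#'   fixed mode is a sensitivity check with the same mean dwell.
#'
#' @return An object of class `transcription_truth`: a list with
#'   * `counts` — integer matrix, cells x frames, number of bound
#'     (transcribing) polymerases at each frame time;
#'   * `times_s` — frame times in seconds from induction (t = 0);
#'   * `events` — data frame of the full event log (`cell`, `arrival_s`,
#'     `departure_s`), arrivals strictly increasing within each cell;
#'   * `cells` — per-cell geometry (`length_um`, `width_um`) and initial
#'     locus position in normalized cross-section coordinates
#'     (`locus_x`, `locus_z`, uniform on the disk of radius `nucleoid_l`)
#'     plus `locus_axial`, the fractional position along the long axis;
#'   * `config` — the generating configuration (true parameters).
#' @examples
#' tr <- simulate_transcription_counts(sim_config(n_cells = 5, seed = 7))
#' dim(tr$counts)
#' @export
simulate_transcription_counts <- function(config,
                                          dwell = c("exponential", "fixed")) {
  stopifnot(inherits(config, "sim_config"))
  dwell <- match.arg(dwell)
  k_on_s <- config$k_on_per_min / 60
  k_off_s <- config$k_off_per_min / 60
  if (config$duration_s < 3 / k_off_s) {
    warning("duration_s covers less than 3 mean dwell times; ",
            "the plateau may not be reached")
  }
  set.seed(config$seed)
  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  n <- config$n_cells

  ev_cell <- ev_arr <- ev_dep <- vector("list", n)
  counts <- matrix(0L, nrow = n, ncol = length(times))
  for (i in seq_len(n)) {
    n_arr <- stats::rpois(1, k_on_s * config$duration_s)
    if (n_arr > 0) {
      arr <- sort(stats::runif(n_arr, 0, config$duration_s))
      dwell_s <- if (dwell == "exponential") {
        stats::rexp(n_arr, rate = k_off_s)
      } else {
        rep(1 / k_off_s, n_arr)
      }
      dep <- arr + dwell_s
      ev_cell[[i]] <- rep.int(i, n_arr)
      ev_arr[[i]] <- arr
      ev_dep[[i]] <- dep
      # right-continuous step function sampled on the frame grid
      counts[i, ] <- vapply(times, function(t) sum(arr <= t & dep > t),
                            integer(1))
    }
  }

  len <- pmax(stats::rnorm(n, config$cell_length_um[["mean"]],
                           config$cell_length_um[["sd"]]),
              config$cell_width_um[["mean"]] * 1.2)
  wid <- pmax(stats::rnorm(n, config$cell_width_um[["mean"]],
                           config$cell_width_um[["sd"]]),
              config$cell_width_um[["mean"]] * 0.5)
  locus <- runif_disk(n, config$nucleoid_l)

  truth <- list(
    counts = counts,
    times_s = times,
    events = data.frame(cell = unlist(ev_cell),
                        arrival_s = unlist(ev_arr),
                        departure_s = unlist(ev_dep)),
    cells = data.frame(cell = seq_len(n),
                       length_um = len,
                       width_um = wid,
                       locus_x = locus$x,
                       locus_z = locus$z,
                       locus_axial = stats::runif(n, -0.25, 0.25)),
    config = config
  )
  class(truth) <- "transcription_truth"
  truth
}

# Uniform points on the disk of radius l (rejection from the square),
# using the current RNG stream.
runif_disk <- function(n, l) {
  x <- z <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- 2L * (n - got) + 8L
    cx <- stats::runif(m, -l, l)
    cz <- stats::runif(m, -l, l)
    keep <- (cx^2 + cz^2) < l^2
    k <- min(sum(keep), n - got)
    if (k > 0) {
      idx <- which(keep)[seq_len(k)]
      x[got + seq_len(k)] <- cx[idx]
      z[got + seq_len(k)] <- cz[idx]
      got <- got + k
    }
  }
  list(x = x, z = z)
}

#' Impose a radial relocation of the gene locus after an onset time
#'
#' Adds time-dependent locus positions to a `transcription_truth` object:
#' before `onset_s` each locus sits at its initial confined position inside
#' the nucleoid; from `onset_s` onward it is displaced outward along its
#' radial direction in the cell cross-section by a magnitude with the
#' requested mean, emulating relocation toward the nucleoid periphery
#' driven by active transcription.
#'
#' @param truth a `transcription_truth` from
#'   [simulate_transcription_counts()].
#' @param mean_step_nm mean radial displacement in nanometres (>= 0).
#' @param onset_s time (s) at which the displacement is applied.
#' @param magnitude one of `"fixed"` (every locus moves exactly
#'   `mean_step_nm`; default) or `"exponential"` (exponentially distributed
#'   magnitudes with that mean).
#'
#' @return The input `truth` augmented with matrices `locus_x_t` /
#'   `locus_z_t` (cells x frames, normalized cross-section units) and a
#'   `relocation` record holding per-cell realized `displacement_nm`.
#' @examples
#' tr <- simulate_transcription_counts(sim_config(n_cells = 5, seed = 7))
#' tr <- simulate_radial_relocation(tr, mean_step_nm = 61, onset_s = 100)
#' mean(tr$relocation$displacement_nm)
#' @export
simulate_radial_relocation <- function(truth, mean_step_nm, onset_s,
                                       magnitude = c("fixed", "exponential")) {
  stopifnot(inherits(truth, "transcription_truth"))
  magnitude <- match.arg(magnitude)
  if (!is.numeric(mean_step_nm) || length(mean_step_nm) != 1 ||
      mean_step_nm < 0) {
    stop("'mean_step_nm' must be a single non-negative number")
  }
  cfg <- truth$config
  set.seed(cfg$seed + 1L)
  n <- nrow(truth$cells)
  nt <- length(truth$times_s)

  disp_nm <- switch(magnitude,
    fixed = rep(mean_step_nm, n),
    exponential = if (mean_step_nm > 0) stats::rexp(n, 1 / mean_step_nm)
                  else rep(0, n)
  )
  # one normalized unit = one full cell width
  scale_nm <- truth$cells$width_um * 1000
  disp_norm <- disp_nm / scale_nm

  x0 <- truth$cells$locus_x
  z0 <- truth$cells$locus_z
  r0 <- sqrt(x0^2 + z0^2)
  theta <- ifelse(r0 > 0, atan2(z0, x0), stats::runif(n, 0, 2 * pi))
  x1 <- x0 + disp_norm * cos(theta)
  z1 <- z0 + disp_norm * sin(theta)

  after <- truth$times_s >= onset_s
  truth$locus_x_t <- matrix(rep(x0, nt), nrow = n)
  truth$locus_z_t <- matrix(rep(z0, nt), nrow = n)
  truth$locus_x_t[, after] <- x1
  truth$locus_z_t[, after] <- z1
  truth$relocation <- list(mean_step_nm = mean_step_nm,
                           onset_s = onset_s,
                           magnitude = magnitude,
                           displacement_nm = disp_nm)
  truth
}

#' Simulate a first-order mRNA decay series
#'
#' Abundances follow `A0 * 2^(-t / half_life)` with optional multiplicative
#' lognormal noise, emulating a rifampicin run-off experiment in which
#' samples are withdrawn at fixed intervals after transcription arrest and
#' quantified by RT-PCR.
#'
#' @param half_life_min mRNA half-life in minutes (> 0).
#' @param sample_times_min sampling times in minutes (non-negative).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise; 0 gives the exact decay curve.
#' @param a0 initial abundance (arbitrary units).
#' @param seed integer seed.
#'
#' @return Data frame with columns `time_min` and `abundance`.
#' @examples
#' simulate_decay_series(5.5, seq(0, 10, 2), noise_cv = 0)
#' @export
simulate_decay_series <- function(half_life_min, sample_times_min,
                                  noise_cv = 0.05, a0 = 100, seed = 1L) {
  if (!is.numeric(half_life_min) || half_life_min <= 0) {
    stop("'half_life_min' must be strictly positive")
  }
  if (any(sample_times_min < 0)) stop("'sample_times_min' must be non-negative")
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("'noise_cv' must be non-negative")
  }
  mu <- a0 * 2^(-sample_times_min / half_life_min)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    # mean-preserving lognormal: E[exp(N(-s^2/2, s^2))] = 1
    mu <- mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(time_min = sample_times_min, abundance = mu)
}

#' Simulate two-probe amplicon onset ramps
#'
#' Emulates the two-TaqMan-probe RT-PCR design used to measure the
#' elongation rate: after induction, the amplicon covered by each probe
#' stays at zero abundance until the first polymerase reaches the probe
#' position (delay = position / elongation rate), then accumulates
#' linearly. The elongation rate is recoverable from the difference of the
#' two onset times and the probe separation.
#'
#' @param elongation_rate_bp_s elongation rate (bp/s, > 0).
#' @param probe_positions_bp two distinct positive probe positions (bp from
#'   the transcription start).
#' @param induction_time_s time of induction (s); onsets are offset by it.
#' @param sample_interval_s sampling interval of the ramps (s).
#' @param duration_s total sampled duration (s).
#' @param rate_au_s linear accumulation rate after onset (arbitrary
#'   units/s).
#'
#' @return Data frame with columns `time_s`, `probe` (1 or 2, ordered by
#'   position), and `abundance`; attribute `onsets_s` records the true
#'   onset times.
#' @examples
#' ramps <- simulate_probe_onsets(90, c(900, 2700))
#' diff(attr(ramps, "onsets_s"))   # 20 s
#' @export
simulate_probe_onsets <- function(elongation_rate_bp_s, probe_positions_bp,
                                  induction_time_s = 0,
                                  sample_interval_s = 2,
                                  duration_s = 120,
                                  rate_au_s = 1) {
  if (!is.numeric(elongation_rate_bp_s) || elongation_rate_bp_s <= 0) {
    stop("'elongation_rate_bp_s' must be strictly positive")
  }
  if (length(probe_positions_bp) != 2 || any(probe_positions_bp <= 0) ||
      probe_positions_bp[1] == probe_positions_bp[2]) {
    stop("'probe_positions_bp' must be two distinct positive positions")
  }
  pos <- sort(probe_positions_bp)
  onsets <- induction_time_s + pos / elongation_rate_bp_s
  times <- seq(0, duration_s, by = sample_interval_s)
  out <- do.call(rbind, lapply(1:2, function(j) {
    data.frame(time_s = times, probe = j,
               abundance = pmax(0, times - onsets[j]) * rate_au_s)
  }))
  attr(out, "onsets_s") <- onsets
  out
}
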