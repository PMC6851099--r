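#' Simulation configuration for synthetic transcription imaging
#'
#' Bundles every parameter of the synthetic-data generator: cell geometry,
#' optics, transcription kinetics, fluorophore photometry and camera noise.
#' Defaults reproduce the imaging conditions of the live-cell T7 RNA
#' polymerase system the package models: ~35 polymerases per cell, frames
#' every 10 s, 100-nm pixels (16-um camera pixel / 160x magnification),
#' 130-nm PSF sigma, and on/off rates of 0.46 and 1.12 per minute.
#'
#' @param n_cells number of cells to simulate.
#' @param cell_length_um,cell_width_um length-2 numeric `c(mean, sd)` of the
#'   cell dimensions in micrometres (total length including caps; width =
#'   diameter).
#' @param pixel_size_nm camera pixel size in the sample plane (nm).
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm).
#' @param k_on_per_min pseudo-first-order transcriptional on-rate
#'   (arrivals of transcribing polymerases per minute); aggregates promoter
#'   search, complex formation and initiation.
#' @param k_off_per_min transcriptional off-rate per bound polymerase
#'   (per minute); the reciprocal of the mean elongation duration.
#' @param rnap_total average total number of labelled polymerases per cell.
#' @param single_fluor_intensity integrated camera counts collected from a
#'   single fluorophore per frame.
#' @param background_level uniform background (counts/pixel).
#' @param camera_noise_sd Gaussian read-noise standard deviation (counts).
#' @param bleach_rate_per_frame per-frame photobleaching probability of a
#'   bound fluorophore, in `[0, 1)`; default 0 (off).
#' @param frame_interval_s time between frames (s).
#' @param duration_s total imaged duration after induction (s).
#' @param nucleoid_l confinement radius of the locus in normalized
#'   cross-section units (full cell width = 1, membrane at 0.5).
#' @param seed integer seed governing every random draw downstream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 10, seed = 42)
#' cfg$k_on_per_min
#' @export
sim_config <- function(n_cells = 200,
                       cell_length_um = c(3.0, 0.4),
                       cell_width_um = c(0.86, 0.05),
                       pixel_size_nm = 100,
                       psf_sigma_nm = 130,
                       k_on_per_min = 0.46,
                       k_off_per_min = 1.12,
                       rnap_total = 35,
                       single_fluor_intensity = 200,
                       background_level = 15,
                       camera_noise_sd = 2,
                       bleach_rate_per_frame = 0,
                       frame_interval_s = 10,
                       duration_s = 360,
                       nucleoid_l = 0.35,
                       seed = 1L) {
  cfg <- list(
    n_cells = n_cells,
    cell_length_um = as_mean_sd(cell_length_um, "cell_length_um"),
    cell_width_um = as_mean_sd(cell_width_um, "cell_width_um"),
    pixel_size_nm = pixel_size_nm,
    psf_sigma_nm = psf_sigma_nm,
    k_on_per_min = k_on_per_min,
    k_off_per_min = k_off_per_min,
    rnap_total = rnap_total,
    single_fluor_intensity = single_fluor_intensity,
    background_level = background_level,
    camera_noise_sd = camera_noise_sd,
    bleach_rate_per_frame = bleach_rate_per_frame,
    frame_interval_s = frame_interval_s,
    duration_s = duration_s,
    nucleoid_l = nucleoid_l,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

as_mean_sd <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L)) {
    stop(sprintf("'%s' must be numeric c(mean, sd) or a single mean", name),
         call. = FALSE)
  }
  if (length(x) == 1L) x <- c(x, 0)
  names(x) <- c("mean", "sd")
  x
}

validate_sim_config <- function(cfg) {
  pos <- c("n_cells", "pixel_size_nm", "psf_sigma_nm", "k_on_per_min",
           "k_off_per_min", "rnap_total", "single_fluor_intensity",
           "frame_interval_s", "duration_s", "nucleoid_l")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("configuration parameter '%s' must be strictly positive", p),
           call. = FALSE)
    }
  }
  for (p in c("cell_length_um", "cell_width_um")) {
    if (cfg[[p]][["mean"]] <= 0 || cfg[[p]][["sd"]] < 0) {
      stop(sprintf("configuration parameter '%s' must have positive mean and non-negative sd", p),
           call. = FALSE)
    }
  }
  for (p in c("background_level", "camera_noise_sd")) {
    if (cfg[[p]] < 0) {
      stop(sprintf("configuration parameter '%s' must be non-negative", p),
           call. = FALSE)
    }
  }
  b <- cfg$bleach_rate_per_frame
  if (!is.numeric(b) || b < 0 || b >= 1) {
    stop("configuration parameter 'bleach_rate_per_frame' must lie in [0, 1)",
         call. = FALSE)
  }
  if (cfg$nucleoid_l > 0.5) {
    stop("configuration parameter 'nucleoid_l' must be at most 0.5 (membrane)",
         call. = FALSE)
  }
  # Nyquist-style guard: the PSF must be sampled finely enough to fit
  if (cfg$pixel_size_nm >= cfg$psf_sigma_nm * 4) {
    stop("configuration parameter 'pixel_size_nm' must be below 4 x psf_sigma_nm",
         call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic transcription imaging configuration\n")
  cat(sprintf("  cells: %d  (%.2f +/- %.2f um x %.2f +/- %.2f um)\n",
              x$n_cells,
              x$cell_length_um[["mean"]], x$cell_length_um[["sd"]],
              x$cell_width_um[["mean"]], x$cell_width_um[["sd"]]))
  cat(sprintf("  kinetics: k_on %.3f /min, k_off %.3f /min, RNAP_total %g\n",
              x$k_on_per_min, x$k_off_per_min, x$rnap_total))
  cat(sprintf("  optics: %g nm/px, PSF sigma %g nm\n",
              x$pixel_size_nm, x$psf_sigma_nm))
  cat(sprintf("  frames: every %g s for %g s; seed %d\n",
              x$frame_interval_s, x$duration_s, x$seed))
  invisible(x)
}
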