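#' Validate a pipeline configuration
#'
#' Checks the nested configuration list (usually read from YAML) against
#' the documented schema before any stage runs. Units are embedded in key
#' names (`*_nm`, `*_min`, `*_s`).
#'
#' @param config nested list with blocks `simulate`, and optionally
#'   `relocation`, `quantify`, `kinetics`, `geometry`.
#' @return The validated config, with defaults filled in; errors list
#'   every offending key.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  bad <- character(0)
  sim <- config$simulate
  if (is.null(sim)) {
    bad <- c(bad, "simulate (missing block)")
  } else {
    for (k in c("k_on_per_min", "k_off_per_min", "n_cells")) {
      v <- sim[[k]]
      if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
        bad <- c(bad, sprintf("simulate.%s (must be > 0)", k))
      }
    }
  }
  rel <- config$relocation
  if (!is.null(rel) && !is.null(rel$mean_step_nm) && rel$mean_step_nm < 0) {
    bad <- c(bad, "relocation.mean_step_nm (must be >= 0)")
  }
  geo <- config$geometry
  if (!is.null(geo)) {
    if (!is.null(geo$l) && !(geo$l > 0 && geo$l <= 0.5)) {
      bad <- c(bad, "geometry.l (must be in (0, 0.5])")
    }
    if (!is.null(geo$loc_error_nm) && geo$loc_error_nm < 0) {
      bad <- c(bad, "geometry.loc_error_nm (must be >= 0)")
    }
  }
  if (length(bad)) {
    stop("invalid configuration: ", paste(bad, collapse = "; "))
  }
  config
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes, in order: **simulate** (immigration–death counts, locus
#' relocation, frame rendering), **quantify** (ROMIF intensities,
#' single-fluorophore calibration, polymerase counts), **localize**
#' (2D Gaussian spot fits, cell-normalized positions), **kinetics**
#' (induction-curve fit, derived rates) and **geometry** (cylindrical
#' Monte Carlo, projected shift, inversion). Every random draw derives
#' from `config$simulate$seed`. Intermediate tables are written as CSV
#' under `out_dir` and the summary as JSON.
#'
#' @param config nested configuration list (see
#'   [validate_pipeline_config()]); a path to a YAML file is also
#'   accepted.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param stages character subset of
#'   `c("simulate", "quantify", "localize", "kinetics", "geometry")`.
#' @return A list of class `pipeline_result` with per-stage results, a
#'   `summary` list and a `manifest` (config echo, seed registry, outputs,
#'   package version).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "quantify", "localize",
                                    "kinetics", "geometry")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list(config = config)
  outputs <- character(0)

  scfg <- do.call(sim_config, config$simulate)
  res$sim_config <- scfg

  if ("simulate" %in% stages) {
    truth <- simulate_transcription_counts(scfg)
    rel <- config$relocation
    if (!is.null(rel)) {
      truth <- simulate_radial_relocation(
        truth,
        mean_step_nm = rel$mean_step_nm %||% 61,
        onset_s = rel$onset_s %||% 100,
        magnitude = rel$magnitude %||% "fixed")
    }
    stack <- render_frames(scfg, truth)
    res$truth <- truth
    res$stack <- stack
    message(sprintf("simulate: %d cells, %d frames, %d polymerase events",
                    scfg$n_cells, length(stack$times_s),
                    nrow(truth$events)))
    if (!is.null(out_dir)) {
      outputs <- c(outputs,
                   write_truth_csv(truth, file.path(out_dir, "ground_truth.csv")),
                   write_stack_tiff(stack, out_dir))
    }
  }

  if ("quantify" %in% stages) {
    if (is.null(res$stack)) stop("quantify: missing upstream stage 'simulate'")
    res$quantify <- quantify_stack(res$stack, scfg)
    message(sprintf("quantify: %d cells kept of %d; plateau count %.3f",
                    sum(res$quantify$cells_kept), scfg$n_cells,
                    utils::tail(res$quantify$series$count, 1)))
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "induction_series.csv")
      utils::write.csv(res$quantify$series, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
  }

  if ("localize" %in% stages) {
    if (is.null(res$stack)) stop("localize: missing upstream stage 'simulate'")
    res$localize <- localize_stack(res$stack)
    message(sprintf("localize: %d foci accepted, %d rejected",
                    nrow(res$localize$foci), res$localize$n_rejected))
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "foci.csv")
      utils::write.csv(res$localize$foci, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
  }

  if ("kinetics" %in% stages) {
    series <- if (!is.null(res$quantify)) res$quantify$series else
      stop("kinetics: missing upstream stage 'quantify'")
    kcfg <- config$kinetics
    res$kinetics <- fit_induction(
      series,
      gene_length_bp = kcfg$gene_length_bp %||% 4500,
      rnap_total = scfg$rnap_total)
    message(sprintf("kinetics: a = %.3f, b = %.3f /min, elongation %.0f bp/s",
                    res$kinetics$a, res$kinetics$b,
                    res$kinetics$elongation_rate_bp_s))
  }

  if ("geometry" %in% stages) {
    gcfg <- config$geometry %||% list()
    model <- cylinder_model(
      l = gcfg$l %||% 0.35,
      scale_nm = gcfg$scale_nm %||% 860,
      loc_error_nm = gcfg$loc_error_nm %||% 70,
      n_spots = gcfg$n_spots %||% 100000,
      seed = scfg$seed + 10L)
    step <- gcfg$step_nm %||% 61
    shift <- relocation_shift(model, step)
    inv <- invert_shift(shift, model)
    res$geometry <- list(model = model, step_nm = step,
                         projected_shift = shift,
                         inverted = inv)
    if (isTRUE(gcfg$calibrate)) {
      res$geometry$calibration <- calibrate_scale(model)
    }
    message(sprintf("geometry: %g-nm step -> projected shift %.4f (inverted %.1f nm)",
                    step, shift, inv$displacement_nm))
  }

  res$summary <- pipeline_summary(res)
  res$manifest <- build_manifest(config, scfg$seed, outputs)
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  }
  class(res) <- "pipeline_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quantify_stack <- function(stack, scfg, bright_percentile = 0.95) {
  n <- nrow(stack$placement)
  nt <- length(stack$times_s)
  total <- vapply(seq_len(n), function(i)
    sum(stack$images[, , 1][stack$mask == i]), numeric(1))
  keep <- filter_bright_cells(total, bright_percentile)
  rows <- expand.grid(cell = which(keep), frame = seq_len(nt))
  imax <- mapply(function(i, j) {
    m <- stack$mask == i
    i_max(stack$images[, , j], m)
  }, rows$cell, rows$frame)
  df <- data.frame(cell = rows$cell,
                   time_s = stack$times_s[rows$frame],
                   i_max = imax)
  # pre-induction baseline group: frames at t = 0 exist in the stack
  series <- transcribing_intensity(df)
  cal <- calibrate_single_fluorophore(
    simulate_calibration_dots(scfg, n_dots = 50))
  list(series = count_transcribing(series, cal),
       per_cell = df, calibration = cal, cells_kept = keep)
}

#' Simulate single-fluorophore calibration dot intensities
#'
#' Renders isolated single-fluorophore spots over background with the
#' camera noise model of `config` and measures each by the integrated
#' intensity of the 5x5 window centred on the brightest pixel, minus the
#' local background — centring on the peak rather than on the maximal
#' window sum avoids the upward selection bias a max-sum search would
#' add to dim dots.
#'
#' @param config a [sim_config()].
#' @param n_dots number of dots.
#' @param seed integer seed (default derived from the config seed).
#' @return Numeric vector of background-corrected integrated intensities.
#' @export
simulate_calibration_dots <- function(config, n_dots = 50, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% (config$seed + 5L))
  sig <- config$psf_sigma_nm / config$pixel_size_nm
  side <- 2L * ceiling(6 * sig) + 9L
  out <- vapply(seq_len(n_dots), function(d) {
    x0 <- side / 2 + stats::runif(1, -0.5, 0.5)
    y0 <- side / 2 + stats::runif(1, -0.5, 0.5)
    img <- matrix(config$background_level, side, side)
    img <- add_gaussian_spot(img, x0, y0, sig, config$single_fluor_intensity)
    img[] <- stats::rpois(length(img), pmax(img, 0))
    if (config$camera_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$camera_noise_sd)
    }
    # centre the window on the fitted dot position; raw-peak centring
    # jitters by 1-2 px at this budget and clips flux
    sf <- fit_spot(img, threshold_k = 3)
    if (!isTRUE(sf$accepted)) return(NA_real_)  # undetected dot: skipped
    pk <- c(round(sf$y), round(sf$x))
    r0 <- min(max(pk[1] - 2L, 1L), side - 4L)
    c0 <- min(max(pk[2] - 2L, 1L), side - 4L)
    win <- img[r0:(r0 + 4L), c0:(c0 + 4L)]
    outside <- img
    outside[r0:(r0 + 4L), c0:(c0 + 4L)] <- NA
    sum(win) - 25 * mean(outside, na.rm = TRUE)
  }, numeric(1))
  out <- out[!is.na(out) & out > 0]
  if (!length(out)) stop("no calibration dot was detected")
  out
}

localize_stack <- function(stack, threshold_k = 5) {
  n <- nrow(stack$placement)
  nt <- length(stack$times_s)
  geoms <- lapply(seq_len(n), function(i) fit_cell_axes(stack$mask == i))
  out <- list(); rej <- 0L
  for (j in seq_len(nt)) {
    present <- which(stack$visible_counts[, j] > 0)
    for (i in present) {
      idx <- which(stack$mask == i, arr.ind = TRUE)
      roi <- list(rows = min(idx[, 1]):max(idx[, 1]),
                  cols = min(idx[, 2]):max(idx[, 2]))
      sf <- fit_spot(stack$images[, , j], roi, threshold_k = threshold_k)
      if (!sf$accepted) { rej <- rej + 1L; next }
      # assign to the cell whose mask contains the fitted centre
      rr <- round(sf$y); cc <- round(sf$x)
      if (rr < 1 || cc < 1 || rr > nrow(stack$mask) ||
          cc > ncol(stack$mask) || stack$mask[rr, cc] != i) {
        rej <- rej + 1L; next
      }
      rp <- tryCatch(relative_position(sf, geoms[[i]]), error = function(e) NULL)
      if (is.null(rp)) { rej <- rej + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        cell = i, time_s = stack$times_s[j],
        x_px = sf$x, y_px = sf$y, sigma_px = sf$sigma,
        amplitude = sf$amplitude,
        x_rel = rp$x_rel, y_rel = rp$y_rel)
    }
  }
  foci <- if (length(out)) do.call(rbind, out) else
    data.frame(cell = integer(0), time_s = numeric(0), x_px = numeric(0),
               y_px = numeric(0), sigma_px = numeric(0),
               amplitude = numeric(0), x_rel = numeric(0), y_rel = numeric(0))
  list(foci = foci, n_rejected = rej, geometries = geoms)
}

pipeline_summary <- function(res) {
  s <- list()
  if (!is.null(res$kinetics)) {
    k <- res$kinetics
    s$kinetics <- list(a = k$a, b = k$b,
                       a_se = k$a_se, b_se = k$b_se,
                       k_on_per_min = k$k_on_per_min,
                       k_off_per_min = k$k_off_per_min,
                       elongation_rate_bp_s = k$elongation_rate_bp_s,
                       elongation_time_s = k$elongation_time_s,
                       search_time_s = k$search_time_s)
  }
  if (!is.null(res$geometry)) {
    g <- res$geometry
    s$geometry <- list(l = g$model$l, scale_nm = g$model$scale_nm,
                       loc_error_nm = g$model$loc_error_nm,
                       step_nm = g$step_nm,
                       projected_shift = g$projected_shift,
                       inverted_displacement_nm = g$inverted$displacement_nm)
    if (!is.null(g$calibration)) s$geometry$calibrated_scale_nm <-
      g$calibration$scale_nm
  }
  if (!is.null(res$quantify)) {
    s$quantify <- list(n_cells_kept = sum(res$quantify$cells_kept),
                       calibration_unit = res$quantify$calibration$unit,
                       plateau_count =
                         utils::tail(res$quantify$series$count, 1))
  }
  if (!is.null(res$localize)) {
    s$localize <- list(n_foci = nrow(res$localize$foci),
                       n_rejected = res$localize$n_rejected)
  }
  s
}

build_manifest <- function(config, seed, outputs) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  checks <- if (length(outputs)) unname(tools::md5sum(outputs)) else character(0)
  list(config_md5 = h,
       seed_registry = list(root = seed,
                            relocation = seed + 1L,
                            render = seed + 2L,
                            calibration_dots = seed + 5L,
                            geometry = seed + 10L),
       outputs = if (length(outputs))
         data.frame(path = outputs, md5 = checks) else NULL,
       version = as.character(utils::packageVersion("periloc")))
}

write_truth_csv <- function(truth, path) {
  nt <- length(truth$times_s)
  n <- nrow(truth$cells)
  have_reloc <- !is.null(truth$locus_x_t)
  df <- data.frame(
    cell = rep(truth$cells$cell, times = nt),
    time_s = rep(truth$times_s, each = n),
    count = as.vector(truth$counts),
    locus_x_norm = if (have_reloc) as.vector(truth$locus_x_t) else
      rep(truth$cells$locus_x, times = nt)
  )
  df$locus_x_nm <- df$locus_x_norm *
    rep(truth$cells$width_um * 1000, times = nt)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_stack_tiff <- function(stack, out_dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) return(character(0))
  img_path <- file.path(out_dir, "frames.tiff")
  mx <- max(stack$images)
  pages <- lapply(seq_len(dim(stack$images)[3]),
                  function(j) pmin(pmax(stack$images[, , j] / mx, 0), 1))
  tiff::writeTIFF(pages, img_path, bits.per.sample = 16)
  mask_path <- file.path(out_dir, "masks.tiff")
  tiff::writeTIFF(stack$mask / 65535, mask_path, bits.per.sample = 16)
  c(img_path, mask_path)
}

#' Render report figures from a pipeline result
#'
#' Produces the three standard figures: the induction curve with its
#' exponential fit, histograms of folded short-axis positions in early and
#' late time windows, and the mean relative position over time. Requires
#' ggplot2; figures are written as PDF when `out_dir` is given.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param out_dir optional directory for PDF output.
#' @param early_s,late_s time windows (s) for the position histograms.
#' @return Invisibly, a list of ggplot objects (with warnings for any
#'   stage that is absent from the result).
#' @export
report <- function(result, out_dir = NULL,
                   early_s = c(0, 50), late_s = c(300, 350)) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("report() requires the ggplot2 package")
  }
  figs <- list()
  if (!is.null(result$quantify)) {
    ser <- result$quantify$series
    p <- ggplot2::ggplot(ser, ggplot2::aes(x = time_s, y = count)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "time after induction (s)",
                    y = "mean transcribing polymerases / cell")
    if (!is.null(result$kinetics)) {
      k <- result$kinetics
      tt <- seq(0, max(ser$time_s), length.out = 200)
      fitdf <- data.frame(time_s = tt, count = model_mean(k$a, k$b, tt / 60))
      p <- p + ggplot2::geom_line(data = fitdf, colour = "blue")
    }
    figs$induction <- p
  } else {
    warning("report: quantify stage absent; induction figure skipped")
  }
  if (!is.null(result$localize) && nrow(result$localize$foci) > 0) {
    foci <- result$localize$foci
    foci$window <- ifelse(foci$time_s >= early_s[1] & foci$time_s < early_s[2],
                          "early",
                   ifelse(foci$time_s >= late_s[1] & foci$time_s < late_s[2],
                          "late", NA))
    sub <- foci[!is.na(foci$window), ]
    if (nrow(sub)) {
      figs$histograms <- ggplot2::ggplot(sub, ggplot2::aes(x = x_rel)) +
        ggplot2::geom_histogram(binwidth = 0.025, boundary = 0) +
        ggplot2::facet_wrap(~window) +
        ggplot2::labs(x = "|x| (normalized)", y = "foci")
    }
    means <- stats::aggregate(x_rel ~ time_s, data = foci, FUN = mean)
    figs$time_course <- ggplot2::ggplot(means,
                                        ggplot2::aes(x = time_s, y = x_rel)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = "time after induction (s)",
                    y = "mean relative x position")
  } else {
    warning("report: localize stage absent; position figures skipped")
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(figs)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), figs[[nm]],
                      width = 6, height = 4)
    }
  }
  invisible(figs)
}
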