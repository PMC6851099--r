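#' Find the region of maximum integrated fluorescence (ROMIF)
#'
#' Scans every 5x5-pixel window lying fully inside the cell mask and
#' returns the one with the largest integrated (summed) intensity. The
#' ROMIF is the focus-intensity estimator: at most one transcription focus
#' per cell is expected, and its 25-pixel window captures essentially the
#' whole diffraction-limited spot. Ties are broken by the smallest
#' row-major window origin.
#'
#' @param frame numeric matrix (one fluorescence frame).
#' @param mask logical matrix of the same dimension (`TRUE` inside the
#'   cell).
#' @param window window side length in pixels (default 5).
#'
#' @return A list of class `romif` with `origin` (row, col of the window's
#'   top-left pixel), `integrated` (sum over the 25 pixels) and `mean`
#'   (`integrated / 25`).
#' @examples
#' f <- matrix(0, 9, 9); f[5, 5] <- 100
#' find_romif(f, matrix(TRUE, 9, 9))$integrated
#' @export
find_romif <- function(frame, mask, window = 5L) {
  stopifnot(is.matrix(frame), is.matrix(mask),
            all(dim(frame) == dim(mask)))
  w <- as.integer(window)
  sums <- window_sums(frame, w)
  cover <- window_sums(mask * 1, w)
  valid <- cover == w * w
  if (!any(valid)) {
    stop(sprintf("cell mask too small: no fully interior %dx%d window", w, w))
  }
  sums[!valid] <- -Inf
  # smallest row-major origin among ties: order by row, then column
  best <- max(sums)
  cand <- which(sums == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  origin <- cand[1, ]
  structure(list(origin = c(row = unname(origin[1]), col = unname(origin[2])),
                 integrated = best,
                 mean = best / (w * w),
                 window = w),
            class = "romif")
}

# Sums over all w x w windows; result[r, c] is the sum of the window with
# top-left pixel (r, c). Computed by a summed-area table.
window_sums <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  if (H < w || W < w) return(matrix(-Inf, 0, 0))
  sat <- matrix(0, H + 1, W + 1)
  cs <- apply(m, 2, cumsum)                  # cumsum down rows
  sat[-1, -1] <- t(apply(cs, 1, cumsum))     # then across columns
  r <- seq_len(H - w + 1)
  cl <- seq_len(W - w + 1)
  sat[r + w, cl + w, drop = FALSE] - sat[r, cl + w, drop = FALSE] -
    sat[r + w, cl, drop = FALSE] + sat[r, cl, drop = FALSE]
}

romif_pixels <- function(romif) {
  w <- romif$window
  rows <- romif$origin[["row"]] + 0:(w - 1)
  cols <- romif$origin[["col"]] + 0:(w - 1)
  list(rows = rows, cols = cols)
}

#' Cellular background excluding the ROMIF window
#'
#' Mean fluorescence over the whole cell mask excluding the 25 ROMIF
#' pixels, i.e. the diffuse signal from unbound fluorophores against which
#' the focus intensity is measured.
#'
#' @param frame,mask as in [find_romif()].
#' @param romif a `romif` result for this cell and frame.
#' @return Mean background in counts/pixel.
#' @export
cellular_background <- function(frame, mask, romif) {
  stopifnot(inherits(romif, "romif"))
  px <- romif_pixels(romif)
  excl <- matrix(FALSE, nrow(frame), ncol(frame))
  excl[px$rows, px$cols] <- TRUE
  keep <- mask & !excl
  if (!any(keep)) {
    stop("cell mask contains no pixels outside the ROMIF window")
  }
  mean(frame[keep])
}

#' Background-corrected maximum focus intensity per cell
#'
#' The per-pixel mean over the ROMIF window minus the per-pixel cellular
#' background. Near zero for cells without a focus; proportional to the
#' number of gene-bound fluorophores otherwise.
#'
#' @param frame,mask as in [find_romif()].
#' @param romif optional precomputed `romif` (recomputed if missing).
#' @return `I_max` in counts/pixel (may be slightly negative under noise).
#' @examples
#' f <- matrix(1, 20, 20)
#' i_max(f, matrix(TRUE, 20, 20))   # 0 for a uniform frame
#' @export
i_max <- function(frame, mask, romif = NULL) {
  if (is.null(romif)) romif <- find_romif(frame, mask)
  romif$mean - cellular_background(frame, mask, romif)
}

#' Population-average focus intensity above the pre-induction baseline
#'
#' Averages per-cell `I_max` within each time group and subtracts the
#' pre-induction (time 0) population mean, giving the mean fluorescence
#' contributed by transcribing polymerases per cell. Cells without a
#' visible focus are included — their `I_max` is simply near zero — so the
#' result is a population average, not a focus-conditional one.
#'
#' @param imax_by_time data frame with columns `time_s` and `i_max`
#'   (one row per cell per time point).
#' @return An `induction_series` data frame: `time_s`, `intensity`
#'   (counts/pixel above baseline), `n`, `sd`.
#' @export
transcribing_intensity <- function(imax_by_time) {
  stopifnot(is.data.frame(imax_by_time),
            all(c("time_s", "i_max") %in% names(imax_by_time)))
  if (!any(imax_by_time$time_s == 0)) {
    stop("no pre-induction (time_s == 0) group present")
  }
  agg <- stats::aggregate(i_max ~ time_s, data = imax_by_time,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(time_s = agg$time_s,
                    intensity = agg$i_max[, "mean"],
                    n = agg$i_max[, "n"],
                    sd = agg$i_max[, "sd"])
  baseline <- out$intensity[out$time_s == 0]
  out$intensity <- out$intensity - baseline
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  class(out) <- c("induction_series", "data.frame")
  out
}

#' Calibrate the single-fluorophore intensity unit
#'
#' From integrated 5x5-pixel intensities of isolated single-fluorophore
#' dots (e.g. sparse membrane-anchored fusions imaged under identical
#' conditions), computes the per-pixel unit `<I_single>/25` used to
#' convert focus intensity into a polymerase count.
#'
#' @param dot_intensities numeric vector of integrated dot intensities
#'   (counts over the 5x5 window); at least 10 recommended.
#' @param window window side used for integration (default 5).
#' @return List of class `single_fluor_calibration` with `intensities`,
#'   `mean_integrated` and `unit` (counts/pixel per fluorophore).
#' @examples
#' calibrate_single_fluorophore(c(2000, 3000))$unit   # 100
#' @export
calibrate_single_fluorophore <- function(dot_intensities, window = 5L) {
  if (!length(dot_intensities)) stop("no dot intensities supplied")
  if (any(dot_intensities <= 0)) {
    stop("all dot intensities must be positive")
  }
  if (length(dot_intensities) < 10) {
    warning("fewer than 10 calibration dots; the unit may be unstable")
  }
  m <- mean(dot_intensities)
  structure(list(intensities = dot_intensities,
                 mean_integrated = m,
                 unit = m / (window^2)),
            class = "single_fluor_calibration")
}

#' Convert an intensity induction series into polymerase counts
#'
#' Divides the population-mean transcribing intensity by the per-pixel
#' single-fluorophore unit, yielding the average number of transcribing
#' polymerases per cell at each time (fractional, being a population
#' mean).
#'
#' @param series an `induction_series` from [transcribing_intensity()].
#' @param calibration a `single_fluor_calibration`.
#' @return The series with an added `count` column (class
#'   `induction_series`).
#' @export
count_transcribing <- function(series, calibration) {
  stopifnot(inherits(calibration, "single_fluor_calibration"))
  if (!is.finite(calibration$unit) || calibration$unit <= 0) {
    stop("calibration unit must be strictly positive")
  }
  series$count <- series$intensity / calibration$unit
  if (!is.null(series$sd)) series$count_sd <- series$sd / calibration$unit
  series
}

#' Flag cells with excessive total fluorescence
#'
#' Cells expressing too many labelled polymerases are excluded from
#' quantification because specific binding cannot be discerned above their
#' high background. The threshold is a percentile of the per-cell total
#' fluorescence distribution.
#'
#' @param total_fluorescence numeric vector, per-cell summed intensity.
#' @param percentile exclusion percentile (default 0.95: the brightest 5%
#'   are flagged).
#' @return Logical vector, `TRUE` for cells to keep.
#' @export
filter_bright_cells <- function(total_fluorescence, percentile = 0.95) {
  stopifnot(percentile > 0, percentile <= 1)
  total_fluorescence <= stats::quantile(total_fluorescence, percentile)
}
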