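#' Render synthetic fluorescence frames and cell masks
#'
#' Turns a `transcription_truth` object into an image stack: each cell is
#' a spherocylinder mask placed without overlap on the field; the
#' polymerases bound at the gene locus are rendered as a single
#' diffraction-limited 2D Gaussian whose integrated intensity is
#' `count x single_fluor_intensity`; the remaining (free) fluorophores
#' contribute a uniform intra-cellular background; a constant extracellular
#' background, Poisson shot noise and Gaussian read noise complete the
#' camera model. Optional per-frame photobleaching removes bound
#' fluorophores with probability `bleach_rate_per_frame` per rendered
#' frame.
#'
#' @param config the [sim_config()] used to generate `truth`.
#' @param truth a `transcription_truth`, optionally carrying relocated
#'   locus positions from [simulate_radial_relocation()].
#' @param frames integer indices of frames to render (default all).
#' @param shot_noise,read_noise logical; disable to obtain the noise-free
#'   expected image (useful for flux-conservation checks).
#' @param free_fluor_background logical; render the uniform intra-cellular
#'   background contributed by the `rnap_total - count` unbound
#'   fluorophores (default `TRUE`; disable to image only bound spots).
#' @param orientation `"aligned"` (long axis along image columns, default)
#'   or `"random"` (uniform orientation per cell).
#'
#' @return An object of class `rendered_stack`: list with `images`
#'   (array height x width x frames), `mask` (integer label matrix, 0 =
#'   background, i = cell i), `placement` (per-cell centre, orientation and
#'   pixel dimensions), `visible_counts` (cells x frames, counts actually
#'   rendered after bleaching), `spot_px` (list of per-frame spot
#'   positions) and `times_s`.
#' @examples
#' cfg <- sim_config(n_cells = 3, duration_s = 30, seed = 11)
#' tr <- simulate_transcription_counts(cfg)
#' stack <- render_frames(cfg, tr, frames = 1:2)
#' dim(stack$images)
#' @export
render_frames <- function(config, truth, frames = NULL,
                          shot_noise = TRUE, read_noise = TRUE,
                          free_fluor_background = TRUE,
                          orientation = c("aligned", "random")) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "transcription_truth"))
  orientation <- match.arg(orientation)
  if (config$n_cells != nrow(truth$cells) ||
      !isTRUE(all.equal(config$frame_interval_s,
                        truth$config$frame_interval_s))) {
    stop("'config' and 'truth' are inconsistent (cell number or frame grid)")
  }
  n <- config$n_cells
  if (is.null(frames)) frames <- seq_along(truth$times_s)
  nt <- length(frames)
  set.seed(config$seed + 2L)

  px <- config$pixel_size_nm
  len_px <- truth$cells$length_um * 1000 / px
  wid_px <- truth$cells$width_um * 1000 / px
  theta <- if (orientation == "random") stats::runif(n, 0, pi) else rep(0, n)
  place <- place_cells(len_px, wid_px, theta)
  H <- place$height
  W <- place$width

  mask <- matrix(0L, nrow = H, ncol = W)
  cell_pixels <- vector("list", n)
  for (i in seq_len(n)) {
    pix <- spherocylinder_pixels(place$cx[i], place$cy[i], theta[i],
                                 len_px[i], wid_px[i], H, W)
    if (any(mask[pix] != 0L)) stop("internal error: overlapping cell masks")
    mask[pix] <- i
    cell_pixels[[i]] <- pix
  }

  # locus position (image pixels) per cell per frame
  have_reloc <- !is.null(truth$locus_x_t)
  spot_xy <- function(i, fr) {
    xs <- if (have_reloc) truth$locus_x_t[i, fr] else truth$cells$locus_x[i]
    along <- truth$cells$locus_axial[i] * len_px[i]
    across <- xs * wid_px[i]
    if (abs(across) >= wid_px[i] / 2) {
      stop(sprintf("locus of cell %d lies outside the cell mask", i))
    }
    c(x = place$cx[i] + along * cos(theta[i]) - across * sin(theta[i]),
      y = place$cy[i] + along * sin(theta[i]) + across * cos(theta[i]))
  }

  visible <- bleach_thin(truth, frames, config$bleach_rate_per_frame)

  sig <- config$psf_sigma_nm / px
  images <- array(0, dim = c(H, W, nt))
  spot_px <- vector("list", nt)
  for (j in seq_len(nt)) {
    fr <- frames[j]
    img <- matrix(config$background_level, nrow = H, ncol = W)
    sx <- sy <- cell <- numeric(0)
    for (i in seq_len(n)) {
      n_bound <- visible[i, j]
      if (free_fluor_background) {
        n_free <- max(config$rnap_total - truth$counts[i, fr], 0)
        img[cell_pixels[[i]]] <- img[cell_pixels[[i]]] +
          n_free * config$single_fluor_intensity / length(cell_pixels[[i]])
      }
      if (n_bound > 0) {
        pos <- spot_xy(i, fr)
        img <- add_gaussian_spot(img, pos[["x"]], pos[["y"]], sig,
                                 n_bound * config$single_fluor_intensity)
        sx <- c(sx, pos[["x"]]); sy <- c(sy, pos[["y"]]); cell <- c(cell, i)
      }
    }
    if (shot_noise) {
      img[] <- stats::rpois(length(img), pmax(img, 0))
    }
    if (read_noise && config$camera_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$camera_noise_sd)
    }
    images[, , j] <- img
    spot_px[[j]] <- data.frame(cell = cell, x = sx, y = sy)
  }

  structure(list(images = images, mask = mask,
                 placement = data.frame(cell = seq_len(n),
                                        cx = place$cx, cy = place$cy,
                                        theta = theta,
                                        length_px = len_px,
                                        width_px = wid_px),
                 visible_counts = visible,
                 spot_px = spot_px,
                 times_s = truth$times_s[frames],
                 frames = frames),
            class = "rendered_stack")
}

# Non-overlapping placement of axis-oriented bounding boxes by rejection
# sampling; the field grows until all cells fit.
place_cells <- function(len_px, wid_px, theta, margin = 4, max_tries = 2000) {
  n <- length(len_px)
  # half-extent of the rotated bounding box
  hx <- (len_px / 2) * abs(cos(theta)) + (wid_px / 2) * abs(sin(theta)) + margin
  hy <- (len_px / 2) * abs(sin(theta)) + (wid_px / 2) * abs(cos(theta)) + margin
  area <- sum((2 * hx) * (2 * hy))
  side <- ceiling(sqrt(2.5 * area))
  side <- max(side, ceiling(2 * max(hx)) + 2, ceiling(2 * max(hy)) + 2)
  repeat {
    cx <- cy <- numeric(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        x <- stats::runif(1, hx[i] + 1, side - hx[i])
        y <- stats::runif(1, hy[i] + 1, side - hy[i])
        if (i == 1 || all(abs(x - cx[seq_len(i - 1)]) >
                            hx[i] + hx[seq_len(i - 1)] |
                          abs(y - cy[seq_len(i - 1)]) >
                            hy[i] + hy[seq_len(i - 1)])) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(list(cx = cx, cy = cy, width = side, height = side))
    side <- ceiling(side * 1.3)
  }
}

# Linear indices of pixels inside a spherocylinder (capsule) of total
# length len_px and diameter wid_px centred at (cx, cy), long axis at
# angle theta. Pixel (row r, col c) has centre (x = c, y = r).
spherocylinder_pixels <- function(cx, cy, theta, len_px, wid_px, H, W) {
  r <- wid_px / 2
  h <- max(len_px / 2 - r, 0)
  ext <- len_px / 2 + 1
  rows <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  cc <- rep(cols, each = length(rows))
  rr <- rep(rows, times = length(cols))
  dx <- cc - cx
  dy <- rr - cy
  along <- dx * cos(theta) + dy * sin(theta)
  across <- -dx * sin(theta) + dy * cos(theta)
  da <- pmax(abs(along) - h, 0)
  inside <- (da^2 + across^2) <= r^2
  (cc[inside] - 1L) * H + rr[inside]
}

# Add a pixel-integrated isotropic 2D Gaussian of total flux `integrated`
# at sub-pixel position (x0, y0). Rendered within +/- 6 sigma.
add_gaussian_spot <- function(img, x0, y0, sigma, integrated) {
  H <- nrow(img); W <- ncol(img)
  ext <- ceiling(6 * sigma)
  rows <- max(1, floor(y0 - ext)):min(H, ceiling(y0 + ext))
  cols <- max(1, floor(x0 - ext)):min(W, ceiling(x0 + ext))
  fx <- stats::pnorm(cols + 0.5, x0, sigma) - stats::pnorm(cols - 0.5, x0, sigma)
  fy <- stats::pnorm(rows + 0.5, y0, sigma) - stats::pnorm(rows - 0.5, y0, sigma)
  img[rows, cols] <- img[rows, cols] + integrated * (fy %o% fx)
  img
}

# Per-frame visible bound counts after photobleaching. Each polymerase
# survives each rendered frame independently with probability
# 1 - bleach_rate; once bleached it stays dark while still bound.
bleach_thin <- function(truth, frames, bleach_rate) {
  n <- nrow(truth$cells)
  nt <- length(frames)
  if (bleach_rate <= 0 || nrow(truth$events) == 0) {
    return(truth$counts[, frames, drop = FALSE])
  }
  times <- truth$times_s[frames]
  visible <- matrix(0L, nrow = n, ncol = nt)
  ev <- truth$events
  for (e in seq_len(nrow(ev))) {
    bound <- which(ev$arrival_s[e] <= times & ev$departure_s[e] > times)
    if (!length(bound)) next
    # number of frames survived before bleaching (geometric)
    n_vis <- stats::rgeom(1, bleach_rate) + 1L
    vis <- bound[seq_len(min(n_vis, length(bound)))]
    visible[ev$cell[e], vis] <- visible[ev$cell[e], vis] + 1L
  }
  visible
}
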