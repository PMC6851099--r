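# Independent oracles and small fixture builders used across tests.

# Exhaustive scan over every w x w window fully inside the mask; the
# reference implementation find_romif must agree with.
brute_force_romif <- function(frame, mask, w = 5L) {
  best <- -Inf
  origin <- NULL
  for (r in seq_len(nrow(frame) - w + 1)) {
    for (cc in seq_len(ncol(frame) - w + 1)) {
      if (all(mask[r:(r + w - 1), cc:(cc + w - 1)])) {
        s <- sum(frame[r:(r + w - 1), cc:(cc + w - 1)])
        if (s > best) {
          best <- s
          origin <- c(row = r, col = cc)
        }
      }
    }
  }
  list(origin = origin, integrated = best)
}

# random blobby mask guaranteed to contain at least one interior 5x5 window
random_mask <- function(H, W) {
  m <- matrix(FALSE, H, W)
  r0 <- sample(3:(H - 7), 1)
  c0 <- sample(3:(W - 7), 1)
  m[r0:(r0 + 4), c0:(c0 + 4)] <- TRUE
  extra <- matrix(runif(H * W) < 0.4, H, W)
  m | extra
}

# capsule (spherocylinder) mask via the package's own rasterizer -- used
# only as geometry fixture, the property under test is coordinate algebra
capsule_mask <- function(H, W, cx, cy, theta, len_px, wid_px) {
  m <- matrix(FALSE, H, W)
  m[periloc:::spherocylinder_pixels(cx, cy, theta, len_px, wid_px, H, W)] <- TRUE
  m
}

# tiny noiseless Gaussian frame
gaussian_frame <- function(H, W, x0, y0, sigma, flux, offset = 0) {
  periloc:::add_gaussian_spot(matrix(offset, H, W), x0, y0, sigma, flux)
}
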