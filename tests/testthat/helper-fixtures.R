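# Shared fixtures, built in code at test time.

# A small, fast phantom: full default geometry but short duration.
quick_phantom <- function(duration = 30, fps = 2, seed = 1, ...) {
  render_phantom(phantom_config(duration = duration, fps = fps, seed = seed,
                                ...))
}

# Noiseless, motionless phantom for exact round-trip checks.
still_phantom <- function(duration = 30, fps = 2, seed = 1, ...) {
  quick_phantom(duration = duration, fps = fps, seed = seed,
                drift = c(0, 0), breathing_amplitude = 0,
                lesion = perfusion_spec(A = 100, t0 = 10, alpha = 2,
                                        beta = 30, b = 20, sigma = 0),
                parenchyma = perfusion_spec(A = 40, t0 = 12, alpha = 2,
                                            beta = 35, b = 15, sigma = 0),
                ...)
}

# A grayscale LUT on levels 0..255 for direct intensity bookkeeping.
gray_lut <- function(n = 256) {
  v <- seq(255, 0, length.out = n)
  structure(list(rgb = cbind(v, v, v), intensity = v), class = "ceus_lut")
}

# Hand-built frame sequence whose contrast panel is a uniform gray level
# per frame; used to unit-test the sampling/validity rule in isolation.
# Panels are 20 x 20; frame is 20 rows x 45 cols (b-mode 0-20, contrast
# 20-40, colorbar 40-45 unused because a LUT is passed explicitly).
stub_regions <- function() {
  list(b_mode   = region_spec("b_mode",   0, 20, 0, 20),
       contrast = region_spec("contrast", 20, 40, 0, 20),
       colorbar = region_spec("colorbar", 40, 45, 0, 10))
}

stub_frames <- function(levels, fps = 1) {
  get_frame <- function(i) {
    fr <- array(0, dim = c(20, 45, 3))
    fr[, 21:40, ] <- levels[i]
    fr
  }
  frame_sequence(get_frame, length(levels), fps, 45, 20)
}

# Provider marking a fixed central square as lesion.
stub_provider <- function() {
  m <- matrix(FALSE, 256, 256)
  m[97:160, 97:160] <- TRUE
  mask_provider(function(panel, i) m, name = "stub")
}

# A ceus_tic built directly from numeric series (bypasses video sampling).
make_tic <- function(time, lesion, parenchyma = lesion,
                     valid = rep(TRUE, length(time)), fps = 1) {
  structure(data.frame(time_s = time, lesion_intensity = lesion,
                       parenchyma_intensity = parenchyma, valid = valid,
                       frame = seq_along(time)),
            class = c("ceus_tic", "data.frame"), fps = fps,
            smoothed = FALSE)
}

# Literal per-pixel brute force of dilation as a union of translates.
brute_dilate <- function(mask, kernel) {
  k <- kernel$kernel; a <- kernel$anchor
  H <- nrow(mask); W <- ncol(mask)
  off <- which(k, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  ms <- which(mask, arr.ind = TRUE)
  if (nrow(ms) == 0) return(out)
  for (p in seq_len(nrow(ms))) {
    rr <- ms[p, 1] + off[, 1] - a[1]
    cc <- ms[p, 2] + off[, 2] - a[2]
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

# Independent N-class MCC oracle via the covariance form of the Gorodkin
# R_K statistic, computed from indicator matrices rather than marginals.
mcc_covariance_oracle <- function(cm) {
  n <- sum(cm)
  N <- nrow(cm)
  X <- matrix(0, n, N); Y <- matrix(0, n, N)
  r <- 1
  for (i in seq_len(N)) for (j in seq_len(N)) {
    cnt <- cm[i, j]
    if (cnt > 0) {
      X[r:(r + cnt - 1), i] <- 1  # truth
      Y[r:(r + cnt - 1), j] <- 1  # prediction
      r <- r + cnt
    }
  }
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  num <- sum(cx * cy)
  den <- sqrt(sum(cx * cx)) * sqrt(sum(cy * cy))
  if (den == 0) return(0)
  num / den
}
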