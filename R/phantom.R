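#' Default contrast colormap
#'
#' A 70-entry dark-to-bright "hot"-style ramp (black, red, yellow, white)
#' emulating a vendor contrast colormap. Adjacent entries are distinct so
#' nearest-colour decoding of the rendered colorbar is well-posed; with one
#' entry per colorbar row the encode/decode round trip is exact up to half
#' a quantisation step.
#'
#' @param n number of colours (>= 8).
#' @return `n` x 3 matrix of RGB values on 0--255.
#' @export
default_colormap <- function(n = 70) {
  stopifnot(n >= 8)
  x <- seq(0, 1, length.out = n)
  r <- clamp(x / 0.4, 0, 1)
  g <- clamp((x - 0.35) / 0.4, 0, 1)
  b <- clamp((x - 0.75) / 0.25, 0, 1)
  cm <- round(cbind(r, g, b) * 255)
  dimnames(cm) <- NULL
  if (any(rowSums(abs(diff(cm))) == 0))
    stop("colormap has duplicate adjacent colours", call. = FALSE)
  cm
}

# Map intensities (0-255) to colormap row indices.
colormap_index <- function(intensity, n_colors) {
  clamp(round(clamp(intensity, 0, 255) / 255 * (n_colors - 1)), 0,
        n_colors - 1) + 1L
}

#' Phantom configuration
#'
#' Describes a synthetic CEUS video: an 800 x 525 frame holding a B-mode
#' panel (left), a contrast panel (right) and a 5 x 70 px vertical colorbar,
#' the default panel geometry of the supported scanner layout. An
#' elliptical lesion drifts slowly and oscillates with breathing; its
#' contrast enhancement follows a gamma-variate lesion curve while the
#' surrounding tissue follows a parenchyma curve. Probe-lift intervals
#' render near-black frames (frame scaled by 0.02).
#'
#' @param width,height frame size in pixels. The default 800 x 525 matches
#'   the default region coordinates.
#' @param fps frame rate (frames/second).
#' @param duration video length in seconds.
#' @param lesion_center ellipse centre `c(x, y)` in B-mode panel-local
#'   pixel coordinates at t = 0.
#' @param lesion_axes ellipse semi-axes `c(ax, ay)` in pixels.
#' @param drift lesion drift velocity `c(vx, vy)` in pixels/second.
#' @param breathing_amplitude,breathing_period vertical sinusoidal motion
#'   (pixels, seconds).
#' @param lesion,parenchyma [perfusion_spec()] objects for the two tissue
#'   compartments.
#' @param probe_lift list of `c(start, end)` second intervals during which
#'   the probe loses contact; must be disjoint and within `[0, duration]`.
#' @param colormap dark-to-bright RGB matrix (>= 8 rows).
#' @param regions region coordinate list as from [default_regions()].
#' @param bmode_background,bmode_lesion mean B-mode gray levels of tissue
#'   and lesion; the high-contrast defaults make segmentation learnable at
#'   desk scale.
#' @param seed integer RNG seed; identical seeds give bit-identical frames.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width = 800, height = 525, fps = 2,
                           duration = 120,
                           lesion_center = c(200, 220),
                           lesion_axes = c(45, 30),
                           drift = c(0.3, 0.1),
                           breathing_amplitude = 4, breathing_period = 4,
                           lesion = perfusion_spec(A = 100, t0 = 10,
                                                   alpha = 2, beta = 30,
                                                   b = 20, sigma = 2),
                           parenchyma = perfusion_spec(A = 40, t0 = 12,
                                                       alpha = 2, beta = 35,
                                                       b = 15, sigma = 2),
                           probe_lift = list(),
                           colormap = default_colormap(),
                           regions = default_regions(),
                           bmode_background = 60, bmode_lesion = 200,
                           seed = 1L) {
  stopifnot(width > 0, height > 0, fps > 0, duration > 0,
            inherits(lesion, "perfusion_spec"),
            inherits(parenchyma, "perfusion_spec"),
            is.matrix(colormap), nrow(colormap) >= 8)
  cb <- regions$colorbar
  if (cb$x_max > width || cb$y_max > height || cb$x_min < 0 || cb$y_min < 0)
    stop("colorbar rectangle lies outside the frame", call. = FALSE)
  for (nm in c("b_mode", "contrast")) {
    r <- regions[[nm]]
    if (r$x_max > width || r$y_max > height)
      stop(nm, " panel lies outside the frame", call. = FALSE)
  }
  if (length(probe_lift)) {
    iv <- do.call(rbind, probe_lift)
    if (any(iv[, 1] >= iv[, 2]) || any(iv < 0) || any(iv > duration))
      stop("probe-lift intervals must be increasing and within [0, duration]",
           call. = FALSE)
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
      stop("probe-lift intervals must be disjoint", call. = FALSE)
  }
  cfg <- structure(
    list(width = width, height = height, fps = fps, duration = duration,
         lesion_center = lesion_center, lesion_axes = lesion_axes,
         drift = drift, breathing_amplitude = breathing_amplitude,
         breathing_period = breathing_period, lesion = lesion,
         parenchyma = parenchyma, probe_lift = probe_lift,
         colormap = colormap, regions = regions,
         bmode_background = bmode_background, bmode_lesion = bmode_lesion,
         seed = as.integer(seed)),
    class = "phantom_config")
  # lesion must stay inside the B-mode panel for the whole video
  pw <- region_width(regions$b_mode); ph <- region_height(regions$b_mode)
  tt <- seq(0, duration, by = 0.1)
  ctr <- lesion_trajectory(cfg, tt)
  if (any(ctr[, 1] - lesion_axes[1] < 0) || any(ctr[, 1] + lesion_axes[1] > pw - 1) ||
      any(ctr[, 2] - lesion_axes[2] < 0) || any(ctr[, 2] + lesion_axes[2] > ph - 1))
    stop("lesion ellipse leaves the B-mode panel during the video",
         call. = FALSE)
  cfg
}

# Lesion centre (x, y) in panel-local coordinates at times t.
lesion_trajectory <- function(config, t) {
  cbind(config$lesion_center[1] + config$drift[1] * t,
        config$lesion_center[2] + config$drift[2] * t +
          config$breathing_amplitude *
            sin(2 * pi * t / config$breathing_period))
}

in_probe_lift <- function(config, t) {
  for (iv in config$probe_lift) if (t >= iv[1] && t < iv[2]) return(TRUE)
  FALSE
}

ellipse_mask <- function(center, axes, nrow_, ncol_) {
  x <- (seq_len(ncol_) - 1 - center[1]) / axes[1]
  y <- (seq_len(nrow_) - 1 - center[2]) / axes[2]
  outer(y^2, x^2, `+`) <= 1
}

#' Render a synthetic CEUS phantom video
#'
#' Builds a lazily rendered frame sequence: frames are generated on demand
#' and deterministically from the seed, so large videos never have to be
#' held in memory. The returned object is a [frame_sequence()] augmented
#' with per-frame ground-truth lesion masks and the noiseless truth curves.
#'
#' @param config a [phantom_config()].
#' @return An object of classes `ceus_phantom` and `ceus_frames`, with
#'   elements `get_frame(i)` (H x W x 3 array, 0--255), `get_mask(i)`
#'   (logical matrix in B-mode panel coordinates), `lesion_truth(t)` and
#'   `parenchyma_truth(t)` (noiseless intensity functions), and `config`.
#' @examples
#' ph <- render_phantom(phantom_config(duration = 5, fps = 2))
#' dim(ph$get_frame(1))
#' @export
render_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- round(config$duration * config$fps)
  rg <- config$regions
  pw <- region_width(rg$b_mode); ph_ <- region_height(rg$b_mode)
  cw <- region_width(rg$contrast); ch <- region_height(rg$contrast)
  if (cw != pw || ch != ph_)
    stop("B-mode and contrast panels must have the same size", call. = FALSE)

  # static B-mode speckle textures, one draw per video
  tex <- with_seed(substream_seed(config$seed, 0), {
    list(bg = clamp(matrix(rnorm(ph_ * pw, config$bmode_background, 12),
                           ph_, pw), 0, 255),
         les = clamp(matrix(rnorm(ph_ * pw, config$bmode_lesion, 12),
                            ph_, pw), 0, 255))
  })
  K <- nrow(config$colormap)

  get_mask <- function(i) {
    t <- (i - 1) / config$fps
    ellipse_mask(lesion_trajectory(config, t)[1, ], config$lesion_axes,
                 ph_, pw)
  }

  # colorbar: dark at the bottom, bright at the top, one colour per row
  cbh <- region_height(rg$colorbar); cbw <- region_width(rg$colorbar)
  cb_int <- 255 * (1 - (seq_len(cbh) - 1) / (cbh - 1))
  cb_rgb <- config$colormap[colormap_index(cb_int, K), , drop = FALSE]

  get_frame <- function(i) {
    stopifnot(i >= 1, i <= n)
    t <- (i - 1) / config$fps
    frame <- array(10, dim = c(config$height, config$width, 3))
    mask <- get_mask(i)

    bpanel <- ifelse(mask, tex$les, tex$bg)
    les_i <- gamma_variate(t, config$lesion)
    par_i <- gamma_variate(t, config$parenchyma)
    cmat <- with_seed(substream_seed(config$seed, i), {
      m <- matrix(par_i + rnorm(ch * cw, 0, config$parenchyma$sigma), ch, cw)
      m[mask] <- les_i + rnorm(sum(mask), 0, config$lesion$sigma)
      m
    })
    cidx <- matrix(colormap_index(cmat, K), ch, cw)

    yb <- (rg$b_mode$y_min + 1):rg$b_mode$y_max
    xb <- (rg$b_mode$x_min + 1):rg$b_mode$x_max
    yc <- (rg$contrast$y_min + 1):rg$contrast$y_max
    xc <- (rg$contrast$x_min + 1):rg$contrast$x_max
    for (k in 1:3) {
      frame[yb, xb, k] <- bpanel
      frame[yc, xc, k] <- matrix(config$colormap[cidx, k], ch, cw)
    }
    ycb <- (rg$colorbar$y_min + 1):rg$colorbar$y_max
    xcb <- (rg$colorbar$x_min + 1):rg$colorbar$x_max
    for (k in 1:3)
      frame[ycb, xcb, k] <- matrix(cb_rgb[, k], cbh, cbw)

    if (in_probe_lift(config, t)) frame <- frame * 0.02
    frame
  }

  out <- frame_sequence(get_frame = get_frame, n = n, fps = config$fps,
                        width = config$width, height = config$height)
  out$get_mask <- get_mask
  out$lesion_truth <- function(t) gamma_variate(t, config$lesion)
  out$parenchyma_truth <- function(t) gamma_variate(t, config$parenchyma)
  out$config <- config
  class(out) <- c("ceus_phantom", class(out))
  out
}

#' @export
print.ceus_phantom <- function(x, ...) {
  cat(sprintf("CEUS phantom: %d frames at %g fps (%g s), %d x %d px\n",
              x$n, x$fps, x$n / x$fps, x$width, x$height))
  cat(sprintf("  lesion peak %g at t = %g s; %d probe-lift interval(s)\n",
              x$config$lesion$b + x$config$lesion$A,
              x$config$lesion$t0 + x$config$lesion$beta,
              length(x$config$probe_lift)))
  invisible(x)
}

#' Write a phantom to disk as numbered PNG frames
#'
#' Creates `frame_%05d.png` files, ground-truth masks `mask_%05d.png`
#' (0/255) and a `video.json` sidecar holding the frame rate, geometry,
#' probe-lift intervals and true perfusion parameters.
#'
#' @param phantom object from [render_phantom()].
#' @param dir output directory (created if missing).
#' @param masks write ground-truth masks as well?
#' @param frames optional subset of frame indices (default all).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, masks = TRUE, frames = NULL) {
  stopifnot(inherits(phantom, "ceus_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- frames %||% seq_len(phantom$n)
  for (i in frames) {
    png::writePNG(phantom$get_frame(i) / 255,
                  file.path(dir, sprintf("frame_%05d.png", i)))
    if (masks)
      png::writePNG(phantom$get_mask(i) * 1,
                    file.path(dir, sprintf("mask_%05d.png", i)))
  }
  cfg <- phantom$config
  sidecar <- list(
    fps = cfg$fps, n_frames = length(frames), width = cfg$width,
    height = cfg$height, probe_lift = cfg$probe_lift,
    lesion = unclass(cfg$lesion), parenchyma = unclass(cfg$parenchyma),
    seed = cfg$seed)
  jsonlite::write_json(sidecar, file.path(dir, "video.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
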