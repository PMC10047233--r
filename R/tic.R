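#' Structuring element for morphological dilation
#'
#' An all-true rectangular kernel by default (10 x 10, the pipeline
#' default for ringing the lesion with parenchyma). The anchor is the
#' kernel cell placed over each mask pixel; the default
#' `floor(size / 2) + 1` puts a 10 x 10 kernel's anchor so that a single
#' on-pixel dilates to a block extending 5 pixels up/left and 4 down/right.
#'
#' @param nrow,ncol kernel size in pixels.
#' @param kernel optional logical matrix for non-rectangular elements.
#' @param anchor `c(row, col)` anchor, 1-based.
#' @return An object of class `structuring_element`.
#' @export
structuring_element <- function(nrow = 10, ncol = nrow, kernel = NULL,
                                anchor = NULL) {
  k <- kernel %||% matrix(TRUE, nrow, ncol)
  storage.mode(k) <- "logical"
  if (!any(k)) stop("structuring element is empty", call. = FALSE)
  anchor <- anchor %||% (floor(dim(k) / 2) + 1L)
  structure(list(kernel = k, anchor = as.integer(anchor)),
            class = "structuring_element")
}

# Union of shifted copies of `mask`; offsets is a 2-column (dy, dx) matrix.
shift_union <- function(mask, offsets) {
  H <- nrow(mask); W <- ncol(mask)
  acc <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(offsets))) {
    dy <- offsets[i, 1]; dx <- offsets[i, 2]
    if (dy >= H || dy <= -H || dx >= W || dx <= -W) next
    tr <- max(1, 1 + dy):min(H, H + dy)
    tc <- max(1, 1 + dx):min(W, W + dx)
    acc[tr, tc] <- acc[tr, tc] | mask[tr - dy, tc - dx]
  }
  acc
}

#' Morphological dilation of a binary mask
#'
#' Dilation as the union of translates of the mask over every active cell
#' of the structuring element, clipped at the image border. For all-true
#' rectangular kernels the operation is separable and performed as a
#' vertical pass followed by a horizontal pass.
#'
#' @param mask logical matrix.
#' @param kernel a [structuring_element()] (default 10 x 10 all-true).
#' @return Dilated logical matrix; always a superset of `mask`.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
#' sum(dilate(m, structuring_element(3)))  # 3 x 3 block
#' @export
dilate <- function(mask, kernel = structuring_element(10)) {
  mask <- as_mask(mask)
  stopifnot(inherits(kernel, "structuring_element"))
  k <- kernel$kernel; a <- kernel$anchor
  if (all(k)) {
    dr <- cbind(seq_len(nrow(k)) - a[1], 0L)
    dc <- cbind(0L, seq_len(ncol(k)) - a[2])
    out <- shift_union(shift_union(mask, dr), dc)
  } else {
    act <- which(k, arr.ind = TRUE)
    out <- shift_union(mask, cbind(act[, 1] - a[1], act[, 2] - a[2]))
  }
  # anchor inside an active cell guarantees out >= mask; keep the attrs
  attributes(out) <- attributes(mask)
  out | mask
}

#' Parenchyma ring around a lesion mask
#'
#' The set difference between the dilated mask and the mask itself: the
#' band of normal tissue immediately surrounding the lesion, used as the
#' parenchyma reference region.
#'
#' @param mask lesion mask (logical matrix).
#' @param dilated its dilation; must be a superset of `mask`.
#' @return Logical matrix; disjoint from `mask`, and
#'   `ring | mask == dilated`.
#' @export
parenchyma_ring <- function(mask, dilated) {
  mask <- as_mask(mask); dilated <- as_mask(dilated)
  if (any(mask & !dilated))
    stop("dilated mask is not a superset of the mask", call. = FALSE)
  dilated & !mask
}

#' Build a colour lookup table from a colorbar strip
#'
#' Each row of the cropped vertical colorbar is averaged to a single RGB
#' colour; rows are assigned intensities linearly from 255 (top) to 0
#' (bottom). Runs of identical adjacent colours are collapsed, keeping the
#' brighter (upper) assignment.
#'
#' @param strip RGB array (rows x cols x 3, 0--255) of the colorbar crop.
#' @return An object of class `ceus_lut`: a list with `rgb` (n x 3 matrix)
#'   and `intensity` (strictly decreasing numeric vector).
#' @export
build_lut <- function(strip) {
  d <- dim(strip)
  if (is.null(d) || length(d) != 3 || d[1] < 2)
    stop("colorbar strip must be an RGB raster with at least 2 rows",
         call. = FALSE)
  rgb <- cbind(rowMeans(strip[, , 1, drop = FALSE]),
               rowMeans(strip[, , 2, drop = FALSE]),
               rowMeans(strip[, , 3, drop = FALSE]))
  intensity <- seq(255, 0, length.out = d[1])
  keep <- c(TRUE, rowSums(abs(diff(rgb))) > 0)
  if (sum(keep) < 2)
    stop("colorbar strip is a single colour; cannot build a monotone LUT",
         call. = FALSE)
  structure(list(rgb = rgb[keep, , drop = FALSE],
                 intensity = intensity[keep]), class = "ceus_lut")
}

#' @export
print.ceus_lut <- function(x, ...) {
  cat(sprintf("colorbar LUT: %d colours, intensities %g (top) to %g (bottom)\n",
              nrow(x$rgb), x$intensity[1], x$intensity[length(x$intensity)]))
  invisible(x)
}

# Decode an n x 3 RGB matrix to intensities via nearest LUT colour
# (Euclidean distance in RGB; ties resolved to the lower LUT index).
lut_decode <- function(px, lut) {
  d2 <- outer(rowSums(px^2), rowSums(lut$rgb^2), `+`) -
    2 * (px %*% t(lut$rgb))
  lut$intensity[max.col(-d2, ties.method = "first")]
}

#' Mean decoded intensity of masked pixels
#'
#' Maps every on-pixel of the contrast panel to the intensity of its
#' nearest LUT colour and returns the arithmetic mean.
#'
#' @param panel RGB raster (rows x cols x 3, 0--255).
#' @param mask logical matrix of the same rows x cols.
#' @param lut a [build_lut()] result.
#' @return Mean intensity on the 0--255 scale.
#' @export
mean_intensity <- function(panel, mask, lut) {
  mask <- as_mask(mask)
  d <- dim(panel)
  if (nrow(mask) != d[1] || ncol(mask) != d[2])
    stop("mask and panel sizes differ", call. = FALSE)
  n <- sum(mask)
  if (n == 0) stop("mask selects no pixels", call. = FALSE)
  px <- cbind(panel[, , 1][mask], panel[, , 2][mask], panel[, , 3][mask])
  mean(lut_decode(px, lut))
}

#' Extract lesion and parenchyma time-intensity curves
#'
#' Samples the video at 1 Hz. For each second the first frame with
#' timestamp >= s is decoded: the mask provider gives the lesion mask,
#' its 10 x 10 dilation minus itself gives the parenchyma ring, both are
#' applied to the contrast panel through the colorbar LUT, and the lesion
#' intensity is screened by the probe-lift rule: a value is valid when the
#' absolute difference from the previously accepted value is under
#' `reject_fraction` (default 75%) of that previous value. Rejected frames
#' are skipped frame by frame within the second; a second with no
#' acceptable frame is recorded as invalid. The parenchyma value is taken
#' from the same accepted frame so both series stay time-aligned.
#'
#' @param frames a [frame_sequence()].
#' @param provider a mask provider (see [mask_provider()]).
#' @param regions region list as from [default_regions()].
#' @param kernel dilation [structuring_element()].
#' @param reject_fraction relative-change validity threshold (default 0.75).
#' @param lut optional [build_lut()] result; by default built from the
#'   colorbar crop of `lut_frame`.
#' @param lut_frame frame index used to derive the LUT.
#' @return An object of class `ceus_tic`: a data frame with columns
#'   `time_s`, `lesion_intensity`, `parenchyma_intensity`, `valid`,
#'   `frame`.
#' @export
sample_tic <- function(frames, provider, regions = default_regions(),
                       kernel = structuring_element(10),
                       reject_fraction = 0.75, lut = NULL, lut_frame = 1) {
  stopifnot(inherits(frames, "ceus_frames"))
  if (frames$n / frames$fps < 1)
    stop("need at least one full second of frames", call. = FALSE)
  b_spec <- regions$b_mode; c_spec <- regions$contrast
  ph <- region_height(b_spec); pw <- region_width(b_spec)
  if (ph != region_height(c_spec) || pw != region_width(c_spec))
    stop("B-mode and contrast panels must have the same size", call. = FALSE)
  if (is.null(lut))
    lut <- build_lut(crop_region(frames$get_frame(lut_frame),
                                 regions$colorbar))

  seconds <- 0:floor(frames$timestamps[frames$n])
  rows <- vector("list", length(seconds))
  prev <- NULL
  for (si in seq_along(seconds)) {
    s <- seconds[si]
    cand <- which(frames$timestamps >= s & frames$timestamps < s + 1)
    accepted <- FALSE
    for (j in cand) {
      frame <- frames$get_frame(j)
      bpanel <- crop_region(frame, b_spec)
      m256 <- predict_mask(provider, bpanel, j)
      mask <- resize_nearest(m256, ph, pw)
      if (!any(mask)) next
      mask_c <- map_mask_between_panels(mask, b_spec, c_spec)
      cpanel <- crop_region(frame, c_spec)
      les <- mean_intensity(cpanel, mask_c, lut)
      if (!is.null(prev) && !(abs(les - prev) < reject_fraction * prev)) next
      ring <- parenchyma_ring(mask, dilate(mask, kernel))
      par_ <- if (any(ring)) {
        ring_c <- map_mask_between_panels(ring, b_spec, c_spec)
        mean_intensity(cpanel, ring_c, lut)
      } else NA_real_
      rows[[si]] <- data.frame(time_s = s, lesion_intensity = les,
                               parenchyma_intensity = par_, valid = TRUE,
                               frame = j)
      prev <- les
      accepted <- TRUE
      break
    }
    if (!accepted)
      rows[[si]] <- data.frame(time_s = s, lesion_intensity = NA_real_,
                               parenchyma_intensity = NA_real_,
                               valid = FALSE, frame = NA_integer_)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("ceus_tic", "data.frame"), fps = frames$fps,
            smoothed = FALSE)
}

#' Smooth a time-intensity curve
#'
#' Savitzky--Golay filtering (default window 51, polynomial order 3) of
#' the lesion and parenchyma series. Invalid seconds are filled by linear
#' interpolation before filtering and re-flagged as invalid afterwards;
#' endpoints are handled by the filter's polynomial fits to the terminal
#' windows, so polynomials up to the filter order pass through unchanged.
#' When the curve has fewer valid samples than the window, the window
#' shrinks to the largest odd number <= the valid length (minimum 5).
#'
#' @param curve a [sample_tic()] result.
#' @param window filter window length (odd; default 51).
#' @param polyorder polynomial order (default 3).
#' @return The curve with smoothed intensities, class `ceus_tic`.
#' @export
smooth_tic <- function(curve, window = 51, polyorder = 3) {
  stopifnot(inherits(curve, "ceus_tic"))
  ok <- curve$valid
  nv <- sum(ok)
  if (nv < polyorder + 2)
    stop("need at least ", polyorder + 2, " valid samples to smooth",
         call. = FALSE)
  w <- min(window, if (nv %% 2 == 1) nv else nv - 1)
  w <- max(w, 5)
  for (col in c("lesion_intensity", "parenchyma_intensity")) {
    v <- curve[[col]]
    vok <- ok & !is.na(v)
    if (sum(vok) < polyorder + 2) next
    filled <- approx(curve$time_s[vok], v[vok], xout = curve$time_s,
                     rule = 2)$y
    sm <- signal::sgolayfilt(filled, p = polyorder, n = w)
    sm[!ok] <- NA_real_
    curve[[col]] <- sm
  }
  attr(curve, "smoothed") <- TRUE
  curve
}

#' Summarise a time-intensity curve
#'
#' Computes the four perfusion descriptors from the (smoothed) curve:
#' maximum intensity, time to peak (earliest maximum), area under the
#' curve (trapezoidal integral over valid samples, no baseline
#' subtraction), and mean transit time defined as the first temporal
#' moment of the baseline-shifted curve,
#' \eqn{\mathrm{MTT} = \sum_t t (I(t) - I_{\min}) / \sum_t (I(t) - I_{\min})}.
#' A flat curve has no defined MTT and yields `NaN` with a warning.
#'
#' @param curve a `ceus_tic`, normally after [smooth_tic()].
#' @param series which series to summarise, `"lesion"` (default, the
#'   classifier features) or `"parenchyma"`.
#' @return An object of class `tic_params`: a list with `max_intensity`,
#'   `ttp`, `auc` and `mtt`.
#' @export
extract_params <- function(curve, series = c("lesion", "parenchyma")) {
  stopifnot(inherits(curve, "ceus_tic"))
  series <- match.arg(series)
  col <- paste0(series, "_intensity")
  ok <- curve$valid & !is.na(curve[[col]])
  if (sum(ok) < 3)
    stop("need at least 3 valid samples to extract parameters",
         call. = FALSE)
  t <- curve$time_s[ok]
  v <- curve[[col]][ok]
  imax <- which.max(v)
  wts <- v - min(v)
  mtt <- if (sum(wts) <= .Machine$double.eps * length(v) * max(abs(v), 1)) {
    warning("flat curve: mean transit time is undefined", call. = FALSE)
    NaN
  } else sum(t * wts) / sum(wts)
  structure(list(max_intensity = v[imax], ttp = t[imax],
                 auc = pracma::trapz(t, v), mtt = mtt),
            class = "tic_params")
}

#' @export
print.tic_params <- function(x, ...) {
  cat(sprintf(
    "TIC parameters: max intensity %.2f, TTP %.1f s, AUC %.1f, MTT %.2f s\n",
    x$max_intensity, x$ttp, x$auc, x$mtt))
  invisible(x)
}

#' Write a time-intensity curve (and its parameters) to CSV
#'
#' The curve file has one row per second with columns `time_s`,
#' `lesion_intensity`, `parenchyma_intensity`, `valid` (0/1) and `frame`;
#' invalid seconds have empty intensity cells. The optional companion
#' parameter file holds the four descriptors as `name,value` rows.
#'
#' @param curve a `ceus_tic`.
#' @param path output CSV path for the curve.
#' @param params optional [extract_params()] result.
#' @param params_path companion CSV path (default `<path>_params.csv`).
#' @return `path`, invisibly.
#' @export
write_tic_csv <- function(curve, path, params = NULL,
                          params_path = NULL) {
  stopifnot(inherits(curve, "ceus_tic"), nrow(curve) > 0)
  df <- as.data.frame(curve)
  df$valid <- as.integer(df$valid)
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(params)) {
    params_path <- params_path %||%
      paste0(sub("\\.csv$", "", path), "_params.csv")
    write.csv(data.frame(name = c("max_intensity", "ttp", "auc", "mtt"),
                         value = c(params$max_intensity, params$ttp,
                                   params$auc, params$mtt)),
              params_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a time-intensity curve written by [write_tic_csv()]
#' @param path CSV path.
#' @param fps original frame rate (stored only as an attribute).
#' @return A `ceus_tic`.
#' @export
read_tic_csv <- function(path, fps = NA_real_) {
  df <- read.csv(path)
  df$valid <- df$valid == 1
  df$frame <- as.integer(df$frame)
  structure(df, class = c("ceus_tic", "data.frame"), fps = fps,
            smoothed = FALSE)
}
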