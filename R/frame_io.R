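#' Rectangular region of a video frame
#'
#' Regions use image coordinates: `x` is the column, `y` the row, the
#' origin is the top-left corner and bounds are half-open `[min, max)`,
#' so the cropped width is `x_max - x_min` and the height `y_max - y_min`.
#'
#' @param name region label, one of `"b_mode"`, `"contrast"`, `"colorbar"`.
#' @param x_min,x_max,y_min,y_max integer pixel bounds.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, x_min, x_max, y_min, y_max) {
  stopifnot(x_min < x_max, y_min < y_max, x_min >= 0, y_min >= 0)
  structure(list(name = name, x_min = as.integer(x_min),
                 x_max = as.integer(x_max), y_min = as.integer(y_min),
                 y_max = as.integer(y_max)), class = "region_spec")
}

region_width <- function(spec) spec$x_max - spec$x_min
region_height <- function(spec) spec$y_max - spec$y_min

#' Default region coordinates
#'
#' Crop rectangles for the supported side-by-side scanner layout on an
#' 800 x 525 frame: B-mode panel on the left (x 0--400, y 78--525), the
#' contrast panel on the right (x 400--800) and a 5 x 70 px colorbar strip
#' at x 770--775, y 100--170. All are configurable; these are only
#' defaults.
#'
#' @return Named list of [region_spec()] objects
#'   (`b_mode`, `contrast`, `colorbar`).
#' @export
default_regions <- function() {
  list(b_mode   = region_spec("b_mode",   0,   400, 78,  525),
       contrast = region_spec("contrast", 400, 800, 78,  525),
       colorbar = region_spec("colorbar", 770, 775, 100, 170))
}

#' Ordered frame sequence
#'
#' A lazy container for video frames: frames are fetched through
#' `get_frame(i)` so phantom rendering and PNG decoding happen on demand.
#' Timestamps are `(i - 1) / fps`.
#'
#' @param get_frame function of a frame index returning an H x W x 3 array
#'   on the 0--255 scale.
#' @param n number of frames.
#' @param fps frame rate (frames/second).
#' @param width,height frame size in pixels.
#' @return An object of class `ceus_frames`.
#' @export
frame_sequence <- function(get_frame, n, fps, width, height) {
  stopifnot(is.function(get_frame), n >= 1, fps > 0)
  structure(list(get_frame = get_frame, n = n, fps = fps,
                 width = width, height = height,
                 timestamps = (seq_len(n) - 1) / fps),
            class = "ceus_frames")
}

#' @export
print.ceus_frames <- function(x, ...) {
  cat(sprintf("frame sequence: %d frames at %g fps, %d x %d px\n",
              x$n, x$fps, x$width, x$height))
  invisible(x)
}

#' Read a video as a frame sequence
#'
#' Reads a directory of numbered PNG frames (the phantom/export format,
#' with an optional `video.json` sidecar carrying the frame rate). Frames
#' are decoded lazily. Container formats (AVI/MP4) are not decoded by this
#' package; export such videos to PNG frames first.
#'
#' @param path directory containing `*.png` frames.
#' @param frame_rate_override frame rate to use when the sidecar is absent.
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, frame_rate_override = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop("container decoding is not supported; supply a directory of ",
           "PNG frames (with an optional video.json sidecar)", call. = FALSE)
    stop("path does not exist: ", path, call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (!length(files))
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  files <- files[!grepl("mask", basename(files))]
  if (!length(files)) stop("no PNG frames found in ", path, call. = FALSE)

  fps <- frame_rate_override
  sidecar <- file.path(path, "video.json")
  if (is.null(fps) && file.exists(sidecar))
    fps <- jsonlite::read_json(sidecar)$fps
  if (is.null(fps))
    stop("frame rate unknown: no video.json sidecar found, ",
         "pass frame_rate_override", call. = FALSE)

  first <- load_frame_png(files[1])
  h <- dim(first)[1]; w <- dim(first)[2]
  get_frame <- function(i) {
    fr <- load_frame_png(files[i])
    if (dim(fr)[1] != h || dim(fr)[2] != w)
      stop("frame ", i, " has inconsistent dimensions", call. = FALSE)
    fr
  }
  frame_sequence(get_frame, length(files), fps, w, h)
}

load_frame_png <- function(file) {
  img <- png::readPNG(file)
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Crop a rectangular region from a frame
#'
#' Uses the half-open `[min, max)` convention of [region_spec()]: the
#' output is `(y_max - y_min)` rows by `(x_max - x_min)` columns and its
#' top-left pixel is the frame pixel at `(x_min, y_min)`.
#'
#' @param frame H x W x 3 array or H x W matrix.
#' @param spec a [region_spec()].
#' @return The cropped raster.
#' @export
crop_region <- function(frame, spec) {
  stopifnot(inherits(spec, "region_spec"))
  d <- dim(frame)
  if (spec$x_max > d[2] || spec$y_max > d[1])
    stop("region '", spec$name, "' lies outside the frame bounds",
         call. = FALSE)
  rows <- (spec$y_min + 1):spec$y_max
  cols <- (spec$x_min + 1):spec$x_max
  if (length(d) == 2L) frame[rows, cols, drop = FALSE]
  else frame[rows, cols, , drop = FALSE]
}

#' Transfer a panel-local mask between the B-mode and contrast panels
#'
#' The two panels show the same anatomy at the same scale, so a mask drawn
#' in B-mode panel coordinates applies to the contrast panel pixel for
#' pixel; only the frame offset differs. Mask area is preserved exactly.
#'
#' @param mask logical matrix in source-panel coordinates.
#' @param from_spec,to_spec the two panel [region_spec()]s, which must have
#'   identical width and height.
#' @return The mask, tagged with the destination panel name.
#' @export
map_mask_between_panels <- function(mask, from_spec, to_spec) {
  mask <- as_mask(mask)
  if (region_width(from_spec) != region_width(to_spec) ||
      region_height(from_spec) != region_height(to_spec))
    stop("panel sizes differ; cannot transfer the mask", call. = FALSE)
  if (nrow(mask) != region_height(from_spec) ||
      ncol(mask) != region_width(from_spec))
    stop("mask size does not match the source panel", call. = FALSE)
  attr(mask, "space") <- to_spec$name
  mask
}

#' Read or write a binary mask as PNG
#'
#' Masks are stored as single-channel PNGs with values 0/255.
#' @param path PNG file path.
#' @param mask logical matrix.
#' @return `read_mask_png` returns a logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}
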