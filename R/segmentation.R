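#' Mask provider contract
#'
#' A mask provider turns a B-mode panel raster and a frame index into a
#' 256 x 256 binary lesion mask, regardless of backend. Two backends ship
#' with the package: [truth_mask_provider()] (phantom ground truth, the
#' reference backend for testing) and [unet_mask_provider()] (a trained
#' compact U-Net). Callers resize the 256 x 256 mask back to panel size
#' with nearest-neighbour sampling for geometry work.
#'
#' @param fun function `(panel, frame_index)` returning a logical matrix.
#' @param name backend label used in error messages.
#' @return An object of class `mask_provider`.
#' @export
mask_provider <- function(fun, name = "custom") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, name = name), class = "mask_provider")
}

#' Predict a lesion mask for one frame
#'
#' Dispatches to the provider backend and enforces the contract: output is
#' strictly binary and exactly 256 x 256. Backend errors are re-raised
#' with the frame index attached.
#'
#' @param provider a [mask_provider()].
#' @param bmode_panel cropped B-mode panel (matrix or RGB array).
#' @param frame_index 1-based frame index.
#' @return 256 x 256 logical matrix.
#' @export
predict_mask <- function(provider, bmode_panel, frame_index) {
  stopifnot(inherits(provider, "mask_provider"))
  if (length(bmode_panel) == 0) stop("empty panel", call. = FALSE)
  mask <- tryCatch(provider$fun(bmode_panel, frame_index),
                   error = function(e)
                     stop("mask provider '", provider$name,
                          "' failed at frame ", frame_index, ": ",
                          conditionMessage(e), call. = FALSE))
  mask <- as_mask(mask)
  if (!identical(dim(mask), c(256L, 256L)))
    stop("mask provider '", provider$name, "' returned a ",
         paste(dim(mask), collapse = "x"),
         " mask; the contract requires 256x256", call. = FALSE)
  mask
}

#' Ground-truth mask provider for a phantom
#'
#' Serves the generator's analytic lesion masks, resampled to the
#' 256 x 256 contract size. The primary backend for testing the curve
#' pipeline, since it is exact by construction.
#'
#' @param phantom a [render_phantom()] object.
#' @return A [mask_provider()].
#' @export
truth_mask_provider <- function(phantom) {
  stopifnot(inherits(phantom, "ceus_phantom"))
  mask_provider(function(panel, i) resize_nearest(phantom$get_mask(i),
                                                  256L, 256L),
                name = "ground-truth")
}

#' U-Net mask provider
#'
#' Wraps a trained [train_unet()] model: the panel is converted to
#' grayscale, bilinearly resized to the model's input size, passed through
#' the network, thresholded, and the binary mask is resized to 256 x 256
#' with nearest-neighbour sampling to preserve binarity.
#'
#' @param model a `ceus_unet` from [train_unet()].
#' @param threshold binarisation threshold on the sigmoid output
#'   (default the model spec's, normally 0.5). Predicted mask area is
#'   non-increasing in this threshold.
#' @return A [mask_provider()].
#' @export
unet_mask_provider <- function(model, threshold = NULL) {
  stopifnot(inherits(model, "ceus_unet"))
  threshold <- threshold %||% model$spec$threshold
  mask_provider(function(panel, i) {
    g <- to_gray(panel)
    s <- model$spec$input_size
    x <- resize_bilinear(g, s, s) / 255
    p <- unet_predict(model, x * 255)
    resize_nearest(p >= threshold, 256L, 256L)
  }, name = "unet")
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
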