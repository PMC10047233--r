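# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, runs `code` and
#' restores the previous state, so package internals never perturb the
#' user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-stream seed from a master seed; keeps results independent of
# the order in which lazily rendered frames are requested.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Nearest-neighbour resampling of a matrix or H x W x C array
#' @noRd
resize_nearest <- function(img, height, width) {
  d <- dim(img)
  src_h <- d[1]; src_w <- d[2]
  ri <- clamp(floor((seq_len(height) - 0.5) * src_h / height) + 1L, 1L, src_h)
  ci <- clamp(floor((seq_len(width) - 0.5) * src_w / width) + 1L, 1L, src_w)
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

# Row/column linear-interpolation matrix used by resize_bilinear: maps
# src samples to dst pixel centres (half-pixel convention, edges clamped).
interp_matrix <- function(src, dst) {
  pos <- clamp((seq_len(dst) - 0.5) * src / dst + 0.5, 1, src)
  lo <- pmin(floor(pos), src - 1L)
  w <- pos - lo
  m <- matrix(0, dst, src)
  m[cbind(seq_len(dst), lo)] <- 1 - w
  m[cbind(seq_len(dst), lo + 1L)] <- m[cbind(seq_len(dst), lo + 1L)] + w
  m
}

#' Bilinear resampling of a numeric matrix
#' @noRd
resize_bilinear <- function(img, height, width) {
  stopifnot(is.matrix(img))
  if (nrow(img) == 1L) img <- rbind(img, img)
  if (ncol(img) == 1L) img <- cbind(img, img)
  interp_matrix(nrow(img), height) %*% img %*% t(interp_matrix(ncol(img), width))
}

# Collapse an RGB array to grayscale (equal channel weights; phantom and
# B-mode content are already achromatic).
to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
}

assert_binary_mask <- function(mask, what = "mask") {
  if (is.logical(mask)) return(invisible(mask))
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop(what, " must be binary (logical or 0/1)", call. = FALSE)
  invisible(mask)
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  assert_binary_mask(x)
  array(as.logical(x), dim = dim(x))
}
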