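#' Compact U-Net specification
#'
#' A small encoder/decoder segmentation network: `depth - 1` encoder
#' levels of two 3 x 3 convolutions (ReLU) followed by 2 x 2 max pooling,
#' a two-convolution bottleneck, and a mirrored decoder using
#' nearest-neighbour upsampling, a channel-halving convolution and skip
#' concatenation, closed by a 1 x 1 convolution with sigmoid output.
#' Output spatial size equals input spatial size. The defaults (input
#' 256 x 256 grayscale, 4 levels, base 16 channels, threshold 0.5) are a
#' desk-scale architecture intended for synthetic phantoms, not a clinical
#' model.
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param depth number of resolution levels including the bottleneck.
#' @param base_channels channels of the first encoder level; doubled per
#'   level.
#' @param threshold default binarisation threshold on the sigmoid output.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(input_size = 256, depth = 4, base_channels = 16,
                      threshold = 0.5) {
  stopifnot(depth >= 2, base_channels >= 1, threshold > 0, threshold < 1)
  if (input_size %% 2^(depth - 1) != 0)
    stop("input_size must be divisible by 2^(depth - 1)", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 threshold = threshold), class = "unet_spec")
}

unet_channel_plan <- function(spec) {
  L <- spec$depth - 1
  ch <- spec$base_channels * 2^(seq_len(L) - 1)
  cb <- spec$base_channels * 2^L
  plan <- list()
  for (l in seq_len(L)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    plan[[paste0("enc", l, "_c1")]] <- c(cin, ch[l])
    plan[[paste0("enc", l, "_c2")]] <- c(ch[l], ch[l])
  }
  plan[["bott_c1"]] <- c(ch[L], cb)
  plan[["bott_c2"]] <- c(cb, cb)
  for (l in rev(seq_len(L))) {
    cbelow <- if (l == L) cb else ch[l + 1]
    plan[[paste0("dec", l, "_up")]] <- c(cbelow, ch[l])
    plan[[paste0("dec", l, "_c1")]] <- c(2L * ch[l], ch[l])
    plan[[paste0("dec", l, "_c2")]] <- c(ch[l], ch[l])
  }
  plan[["out"]] <- c(ch[1], 1L)
  plan
}

unet_init <- function(spec, seed = 1L) {
  plan <- unet_channel_plan(spec)
  with_seed(seed, {
    params <- lapply(names(plan), function(nm) {
      io <- plan[[nm]]
      fan_in <- if (nm == "out") io[1] else 9 * io[1]
      list(W = matrix(rnorm(fan_in * io[2], 0, sqrt(2 / fan_in)),
                      fan_in, io[2]),
           b = rep(0, io[2]))
    })
    names(params) <- names(plan)
    params
  })
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_relu_fwd <- function(x, p, cache, name) {
  pre <- conv3x3_fwd(x, p$W, p$b)
  act <- pre > 0
  out <- pre * act
  cache[[length(cache) + 1]] <- list(op = "conv", name = name, x = x,
                                     act = act)
  list(out = out, cache = cache)
}

unet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  L <- spec$depth - 1
  if (max(x) > 1.5) x <- x / 255
  a <- array(x, dim = c(nrow(x), ncol(x), 1))
  cache <- list()
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    r <- conv_relu_fwd(a, model$params[[paste0("enc", l, "_c1")]], cache,
                       paste0("enc", l, "_c1")); a <- r$out; cache <- r$cache
    r <- conv_relu_fwd(a, model$params[[paste0("enc", l, "_c2")]], cache,
                       paste0("enc", l, "_c2")); a <- r$out; cache <- r$cache
    skips[[l]] <- a
    mp <- maxpool2_fwd(a)
    cache[[length(cache) + 1]] <- list(op = "pool", idx = mp$idx)
    a <- mp$out
  }
  r <- conv_relu_fwd(a, model$params$bott_c1, cache, "bott_c1")
  a <- r$out; cache <- r$cache
  r <- conv_relu_fwd(a, model$params$bott_c2, cache, "bott_c2")
  a <- r$out; cache <- r$cache
  for (l in rev(seq_len(L))) {
    a <- upsample2_fwd(a)
    cache[[length(cache) + 1]] <- list(op = "up")
    r <- conv_relu_fwd(a, model$params[[paste0("dec", l, "_up")]], cache,
                       paste0("dec", l, "_up")); a <- r$out; cache <- r$cache
    nskip <- dim(skips[[l]])[3]
    cache[[length(cache) + 1]] <- list(op = "concat", nskip = nskip)
    d <- dim(a)
    cc <- array(0, dim = c(d[1], d[2], nskip + d[3]))
    cc[, , seq_len(nskip)] <- skips[[l]]
    cc[, , nskip + seq_len(d[3])] <- a
    a <- cc
    r <- conv_relu_fwd(a, model$params[[paste0("dec", l, "_c1")]], cache,
                       paste0("dec", l, "_c1")); a <- r$out; cache <- r$cache
    r <- conv_relu_fwd(a, model$params[[paste0("dec", l, "_c2")]], cache,
                       paste0("dec", l, "_c2")); a <- r$out; cache <- r$cache
  }
  d <- dim(a)
  am <- matrix(a, d[1] * d[2], d[3])
  logits <- matrix(am %*% model$params$out$W + model$params$out$b[1],
                   d[1], d[2])
  cache[[length(cache) + 1]] <- list(op = "out", x = a)
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# Reverse pass over the recorded op list. Skip-connection gradients are
# accumulated into the matching encoder activations through the concat ops.
unet_backward <- function(model, cache, dlogits) {
  grads <- list()
  k <- length(cache)
  stopifnot(cache[[k]]$op == "out")
  a <- cache[[k]]$x
  d <- dim(a)
  dm <- matrix(dlogits, d[1] * d[2], 1)
  am <- matrix(a, d[1] * d[2], d[3])
  grads$out <- list(W = crossprod(am, dm), b = sum(dm))
  da <- array(dm %*% t(model$params$out$W), dim = d)
  k <- k - 1
  skip_grads <- list()
  L <- model$spec$depth - 1
  lvl <- 1 # decoder level counter (ascending while walking backwards)
  while (k >= 1) {
    entry <- cache[[k]]
    if (entry$op == "conv") {
      dpre <- da * entry$act
      g <- conv3x3_bwd(entry$x, model$params[[entry$name]]$W, dpre)
      grads[[entry$name]] <- list(W = g$dw, b = as.numeric(g$db))
      da <- g$dx
    } else if (entry$op == "concat") {
      ns <- entry$nskip
      skip_grads[[length(skip_grads) + 1]] <-
        da[, , seq_len(ns), drop = FALSE]
      da <- da[, , ns + seq_len(dim(da)[3] - ns), drop = FALSE]
    } else if (entry$op == "up") {
      da <- upsample2_bwd(da)
    } else if (entry$op == "pool") {
      da <- maxpool2_bwd(da, entry$idx)
      # the encoder activation also fed a skip connection
      sg <- skip_grads[[length(skip_grads)]]
      skip_grads[[length(skip_grads)]] <- NULL
      da <- da + sg
    }
    k <- k - 1
  }
  grads
}

#' Forward prediction with a trained U-Net
#'
#' @param model a `ceus_unet`.
#' @param image numeric matrix, either on 0--255 or 0--1 scale; its side
#'   must be divisible by `2^(depth - 1)`.
#' @return Matrix of sigmoid probabilities, same size as `image`.
#' @export
unet_predict <- function(model, image) {
  stopifnot(inherits(model, "ceus_unet"))
  logits <- unet_forward(model, image)$logits
  1 / (1 + exp(-logits))
}

dice_bce_loss <- function(logits, y, eps = 1e-7) {
  p <- 1 / (1 + exp(-logits))
  n <- length(p)
  pc <- clamp(p, eps, 1 - eps)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  dice <- (2 * spy + 1) / (sp + sy + 1)
  # gradients w.r.t. logits
  dbce <- (p - y) / n
  ddice_dp <- (2 * y * (sp + sy + 1) - (2 * spy + 1)) / (sp + sy + 1)^2
  dlogits <- dbce + (-ddice_dp) * p * (1 - p)
  list(loss = bce + (1 - dice), dlogits = dlogits, dice = dice)
}

#' Train the compact U-Net on image/mask pairs
#'
#' Minimises Dice + binary cross-entropy with the Adam optimiser.
#' Training is deterministic given `seed`. Images may be any square size
#' divisible by `2^(depth - 1)`; the network is fully convolutional.
#'
#' @param images list of grayscale matrices (0--255 or 0--1).
#' @param masks list of logical matrices, same sizes as `images`.
#' @param spec a [unet_spec()].
#' @param epochs training epochs.
#' @param batch_size gradient-accumulation batch size.
#' @param lr Adam learning rate.
#' @param seed integer seed for initialisation and shuffling.
#' @param validation optional `list(images =, masks =)` held-out pairs;
#'   per-epoch validation Dice is recorded in the history.
#' @param verbose print per-epoch progress?
#' @return An object of class `ceus_unet` with elements `spec`, `params`
#'   and `history` (data frame of epoch, mean training loss, mean Dice,
#'   and validation Dice when supplied).
#' @export
train_unet <- function(images, masks, spec = unet_spec(), epochs = 10,
                       batch_size = 4, lr = 1e-3, seed = 1L,
                       validation = NULL, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  n <- length(images)
  for (i in seq_len(n)) {
    assert_binary_mask(masks[[i]], "training mask")
    if (!identical(dim(to_gray(images[[i]])), dim(masks[[i]])))
      stop("image/mask size mismatch at pair ", i, call. = FALSE)
  }
  xs <- lapply(images, function(im) {
    g <- to_gray(im); if (max(g) > 1.5) g / 255 else g
  })
  ys <- lapply(masks, function(m) array(as.numeric(m), dim = dim(m)))

  model <- structure(list(spec = spec, params = unet_init(spec, seed)),
                     class = "ceus_unet")
  mstate <- lapply(model$params, function(p)
    list(W = p$W * 0, b = p$b * 0))
  vstate <- mstate
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  step <- 0
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     dice = numeric(), val_dice = numeric())

  order_seeds <- with_seed(seed, sample.int(.Machine$integer.max, epochs))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(n))
    losses <- dices <- numeric(0)
    bstart <- seq(1, n, by = batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + batch_size - 1, n)]
      acc <- NULL
      for (i in idx) {
        fw <- unet_forward(model, xs[[i]], keep_cache = TRUE)
        lo <- dice_bce_loss(fw$logits, ys[[i]])
        losses <- c(losses, lo$loss); dices <- c(dices, lo$dice)
        g <- unet_backward(model, fw$cache, lo$dlogits)
        acc <- if (is.null(acc)) g else
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 acc, g, SIMPLIFY = FALSE)
      }
      step <- step + 1
      for (nm in names(model$params)) {
        gW <- acc[[nm]]$W / length(idx); gb <- acc[[nm]]$b / length(idx)
        mstate[[nm]]$W <- beta1 * mstate[[nm]]$W + (1 - beta1) * gW
        mstate[[nm]]$b <- beta1 * mstate[[nm]]$b + (1 - beta1) * gb
        vstate[[nm]]$W <- beta2 * vstate[[nm]]$W + (1 - beta2) * gW^2
        vstate[[nm]]$b <- beta2 * vstate[[nm]]$b + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        model$params[[nm]]$W <- model$params[[nm]]$W -
          lr * (mstate[[nm]]$W / corr1) /
            (sqrt(vstate[[nm]]$W / corr2) + aeps)
        model$params[[nm]]$b <- model$params[[nm]]$b -
          lr * (mstate[[nm]]$b / corr1) /
            (sqrt(vstate[[nm]]$b / corr2) + aeps)
      }
    }
    vd <- NA_real_
    if (!is.null(validation)) {
      vds <- mapply(function(im, m) {
        g <- to_gray(im); if (max(g) > 1.5) g <- g / 255
        dice_coefficient(unet_predict(model, g) >= spec$threshold,
                         as_mask(m))
      }, validation$images, validation$masks)
      vd <- mean(vds)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   dice = mean(dices), val_dice = vd))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f dice %.4f val_dice %s", ep,
                      mean(losses), mean(dices),
                      ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
  }
  model$history <- hist
  model
}

#' @export
print.ceus_unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                   numeric(1)))
  cat(sprintf("compact U-Net: depth %d, base %d channels, input %dx%d, %d parameters\n",
              x$spec$depth, x$spec$base_channels, x$spec$input_size,
              x$spec$input_size, np))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs; final loss %.4f, train dice %.4f\n",
                max(x$history$epoch), tail(x$history$loss, 1),
                tail(x$history$dice, 1)))
  invisible(x)
}

#' Save or load a U-Net checkpoint
#'
#' Checkpoints are plain JSON (spec, weights, history), portable across
#' platforms.
#' @param model a `ceus_unet`.
#' @param path file path.
#' @return `load_unet` returns the restored `ceus_unet`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "ceus_unet"))
  obj <- list(spec = unclass(model$spec),
              params = lapply(model$params, function(p)
                list(W = as.vector(p$W), dim = dim(p$W), b = p$b)),
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(unet_spec, as.list(obj$spec))
  params <- lapply(obj$params, function(p)
    list(W = matrix(p$W, p$dim[1], p$dim[2]), b = as.numeric(p$b)))
  structure(list(spec = spec, params = params,
                 history = as.data.frame(obj$history)),
            class = "ceus_unet")
}
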