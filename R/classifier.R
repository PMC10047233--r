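#' Feature and label schemas
#'
#' Column names of the clinical/perfusion feature table and the five
#' diagnostic classes. Gender is encoded 1 = male, 2 = female; the two
#' history fields are 0/1; the four perfusion descriptors come from the
#' lesion time-intensity curve.
#'
#' @return Character vector of column names.
#' @export
feature_names <- function() {
  c("Gender", "Age", "Cirrhosis History", "Hepatitis History",
    "Maximum Intensity", "Area Under the Curve", "Mean Transit Time",
    "Time to Peak")
}

#' @rdname feature_names
#' @export
label_names <- function() {
  c("Hepatocarcinoma", "Metastasis", "Other malignant lesions",
    "Hemangioma", "Other benign lesions")
}

# Extract the label factor from one-hot columns.
dataset_labels <- function(data) {
  oh <- as.matrix(data[, label_names(), drop = FALSE])
  if (any(rowSums(oh) != 1))
    stop("label columns must be one-hot (exactly one active class per row)",
         call. = FALSE)
  factor(label_names()[max.col(oh)], levels = label_names())
}

dataset_features <- function(data) {
  miss <- setdiff(feature_names(), names(data))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(data[, feature_names(), drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  x
}

#' Feed-forward classifier architecture
#'
#' Dense layer widths over the 8 clinical/perfusion features. The default
#' (8, 6, 6, 5) is a trainable 8-unit input layer, two 6-unit hidden
#' layers and a 5-unit softmax output — 203 trainable parameters in total.
#' All layers have biases; hidden activations are ReLU.
#'
#' @param widths integer vector of layer output widths.
#' @param n_features input dimension (default 8).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(widths = c(8, 6, 6, 5), n_features = 8) {
  stopifnot(length(widths) >= 1, all(widths >= 1))
  structure(list(widths = as.integer(widths),
                 n_features = as.integer(n_features)),
            class = "network_spec")
}

#' Count trainable parameters of a network
#'
#' Sums `in * out + out` over the dense layers; for a constructed
#' classifier the actual weight and bias arrays are walked instead.
#'
#' @param x a [network_spec()] or a fitted `ceus_classifier`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "ceus_classifier"))
    return(sum(vapply(x$weights, function(l) length(l$W) + length(l$b),
                      numeric(1))))
  stopifnot(inherits(x, "network_spec"))
  ins <- c(x$n_features, x$widths[-length(x$widths)])
  sum(ins * x$widths + x$widths)
}

#' Focal cross-entropy loss
#'
#' \deqn{FCE = -\sum_i \alpha (1 - p_i)^{\gamma} t_i \log p_i}
#' over the one-hot target `t`; with `gamma = 0`, `alpha = 1` it reduces
#' to the ordinary cross-entropy \eqn{-\log p_{true}}. Probabilities are
#' clipped at `eps` before the logarithm.
#'
#' @param p probability vector (non-negative, sums to 1) or a matrix with
#'   one row per sample.
#' @param target one-hot vector/matrix, or integer class index/vector.
#' @param alpha weighting factor in `(0, 1]` (default 0.25).
#' @param gamma focusing parameter >= 0 (default 2).
#' @param eps clipping floor for the probabilities.
#' @return Loss value (scalar for a vector input, mean over rows for a
#'   matrix).
#' @examples
#' focal_cross_entropy(c(.2, .2, .2, .2, .2), 1)           # ~0.2575
#' focal_cross_entropy(c(1, 0, 0, 0, 0), 1)                # 0
#' @export
focal_cross_entropy <- function(p, target, alpha = 0.25, gamma = 2,
                                eps = 1e-7) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0)
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-5))
    stop("p must be non-negative and sum to 1", call. = FALSE)
  idx <- if (is.matrix(target)) max.col(target)
         else if (length(target) == ncol(p) && nrow(p) == 1 &&
                  all(target %in% c(0, 1)) && sum(target) == 1)
           which(target == 1)
         else as.integer(target)
  pt <- clamp(p[cbind(seq_len(nrow(p)), idx)], eps, 1)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Oversample a dataset to balanced class counts
#'
#' Duplicates randomly chosen minority-class rows (with replacement) until
#' every class matches the majority count. All original rows are retained;
#' duplicates are exact copies. Deterministic given `seed`.
#'
#' @param data data frame with the one-hot label columns of
#'   [label_names()].
#' @param seed integer seed.
#' @return The balanced data frame.
#' @export
oversample <- function(data, seed = 1L) {
  y <- dataset_labels(data)
  counts <- table(y)
  if (any(counts == 0))
    stop("every class must have at least one sample", call. = FALSE)
  target <- max(counts)
  with_seed(seed, {
    extra <- unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      need <- target - length(rows)
      if (need > 0) sample(rows, need, replace = TRUE) else integer(0)
    }))
    data[c(seq_len(nrow(data)), extra), , drop = FALSE]
  })
}

#' Stratified train/validation split
#'
#' Splits per class: `ceiling(fraction * n_class)` rows to training, the
#' remainder to validation. Deterministic given `seed`.
#'
#' @param data data frame with one-hot label columns.
#' @param fraction training fraction in `(0, 1)` (default 0.70).
#' @param seed integer seed.
#' @return `list(train =, validation =)` of disjoint data frames.
#' @export
split_dataset <- function(data, fraction = 0.70, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  y <- dataset_labels(data)
  if (any(table(y) < 2))
    stop("every class needs at least 2 samples for a stratified split",
         call. = FALSE)
  with_seed(seed, {
    tr <- unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, ceiling(fraction * length(rows)))
    }))
    list(train = data[sort(tr), , drop = FALSE],
         validation = data[setdiff(seq_len(nrow(data)), tr), , drop = FALSE])
  })
}

#' Training configuration for the lesion classifier
#'
#' Defaults follow the reference protocol: focal cross-entropy with
#' `alpha = 0.25`, `gamma = 2`, RMSProp at learning rate 1e-4 (decay 0.9,
#' epsilon 1e-7), 100 epochs, batch size 50, features z-scored with
#' training-split statistics, and training-set oversampling to balance
#' classes.
#'
#' @param alpha,gamma focal-loss parameters.
#' @param learning_rate,rho,epsilon RMSProp hyperparameters.
#' @param epochs,batch_size training protocol.
#' @param standardize z-score features using training statistics?
#' @param oversample balance the training classes by duplication?
#' @param seed integer seed governing initialisation, oversampling and
#'   batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(alpha = 0.25, gamma = 2, learning_rate = 1e-4,
                         rho = 0.9, epsilon = 1e-7, epochs = 100,
                         batch_size = 50, standardize = TRUE,
                         oversample = TRUE, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, learning_rate > 0,
            epochs >= 1, batch_size >= 1)
  structure(list(alpha = alpha, gamma = gamma,
                 learning_rate = learning_rate, rho = rho,
                 epsilon = epsilon, epochs = epochs,
                 batch_size = batch_size, standardize = standardize,
                 oversample = oversample, seed = as.integer(seed)),
            class = "train_config")
}

classifier_forward <- function(weights, x) {
  acts <- list(x)
  a <- x
  nl <- length(weights)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, `+`)
    a <- if (l < nl) relu(z) else {
      zm <- z - apply(z, 1, max)
      ez <- exp(zm)
      ez / rowSums(ez)
    }
    acts[[l + 1]] <- a
  }
  acts
}

# Gradient of the mean focal loss w.r.t. the softmax logits.
focal_logit_grad <- function(p, idx, alpha, gamma, eps) {
  n <- nrow(p)
  pt <- clamp(p[cbind(seq_len(n), idx)], eps, 1)
  # dL/dpt, then chain through softmax: dL/dz_j = dL/dpt * pt (1[j=t] - p_j)
  dlp <- alpha * gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
    alpha * (1 - pt)^gamma / pt
  if (gamma == 0) dlp <- -alpha / pt
  g <- -p * (dlp * pt)
  g[cbind(seq_len(n), idx)] <- g[cbind(seq_len(n), idx)] + dlp * pt
  g / n
}

#' Train the five-class lesion classifier
#'
#' Fits the feed-forward network of [network_spec()] with focal
#' cross-entropy and RMSProp. Feature standardisation statistics are
#' computed from `train` before oversampling; oversampling (when enabled)
#' balances only the training rows, never the validation rows. Training is
#' deterministic given the config seed.
#'
#' @param train data frame with [feature_names()] and one-hot
#'   [label_names()] columns.
#' @param validation optional validation data frame; enables the
#'   per-epoch validation loss/accuracy history.
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @return An object of class `ceus_classifier` with elements `weights`,
#'   `spec`, `config`, `center`/`scale` and `history` (per-epoch train and
#'   validation loss and categorical accuracy).
#' @export
train_classifier <- function(train, validation = NULL,
                             spec = network_spec(),
                             config = train_config()) {
  x_raw <- dataset_features(train)
  center <- rep(0, ncol(x_raw)); scale_ <- rep(1, ncol(x_raw))
  if (config$standardize) {
    center <- colMeans(x_raw)
    scale_ <- apply(x_raw, 2, sd)
    scale_[scale_ < 1e-12] <- 1
  }
  if (config$oversample) train <- oversample(train, seed = config$seed)
  x <- sweep(sweep(dataset_features(train), 2, center), 2, scale_, `/`)
  yi <- as.integer(dataset_labels(train))
  xv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    xv <- sweep(sweep(dataset_features(validation), 2, center), 2, scale_,
                `/`)
    yv <- as.integer(dataset_labels(validation))
  }

  ins <- c(spec$n_features, spec$widths[-length(spec$widths)])
  # He-scaled weights; small positive biases keep every ReLU unit live at
  # the start, which matters in a network this small
  weights <- with_seed(config$seed, lapply(seq_along(spec$widths),
    function(l) list(
      W = matrix(rnorm(ins[l] * spec$widths[l], 0, sqrt(2 / ins[l])),
                 ins[l], spec$widths[l]),
      b = rep(0.1, spec$widths[l]))))
  vstate <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))

  n <- nrow(x)
  nl <- length(weights)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     train_accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  epoch_seeds <- with_seed(config$seed + 1L,
                           sample.int(.Machine$integer.max, config$epochs))
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    for (bs in seq(1, n, by = config$batch_size)) {
      idx <- ord[bs:min(bs + config$batch_size - 1, n)]
      acts <- classifier_forward(weights, x[idx, , drop = FALSE])
      p <- acts[[nl + 1]]
      if (any(!is.finite(p)))
        stop("training diverged (non-finite probabilities) at epoch ", ep,
             call. = FALSE)
      delta <- focal_logit_grad(p, yi[idx], config$alpha, config$gamma,
                                1e-7)
      for (l in rev(seq_len(nl))) {
        a_in <- acts[[l]]
        gW <- crossprod(a_in, delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(weights[[l]]$W)) * (acts[[l]] > 0)
        vstate[[l]]$W <- config$rho * vstate[[l]]$W +
          (1 - config$rho) * gW^2
        vstate[[l]]$b <- config$rho * vstate[[l]]$b +
          (1 - config$rho) * gb^2
        weights[[l]]$W <- weights[[l]]$W - config$learning_rate * gW /
          (sqrt(vstate[[l]]$W) + config$epsilon)
        weights[[l]]$b <- weights[[l]]$b - config$learning_rate * gb /
          (sqrt(vstate[[l]]$b) + config$epsilon)
      }
    }
    pfull <- classifier_forward(weights, x)[[nl + 1]]
    hist$train_loss[ep] <- focal_cross_entropy(pfull, yi, config$alpha,
                                               config$gamma)
    hist$train_accuracy[ep] <- mean(max.col(pfull) == yi)
    if (!is.null(xv)) {
      pv <- classifier_forward(weights, xv)[[nl + 1]]
      hist$val_loss[ep] <- focal_cross_entropy(pv, yv, config$alpha,
                                               config$gamma)
      hist$val_accuracy[ep] <- mean(max.col(pv) == yv)
    }
  }
  structure(list(weights = weights, spec = spec, config = config,
                 center = center, scale = scale_, history = hist),
            class = "ceus_classifier")
}

#' Predict class probabilities for patients
#'
#' @param object a fitted `ceus_classifier`.
#' @param newdata data frame with the [feature_names()] columns (or a
#'   single named numeric vector).
#' @param ... unused.
#' @return Matrix of class probabilities (rows sum to 1) with
#'   [label_names()] columns.
#' @export
predict.ceus_classifier <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata), check.names = FALSE)
  x <- dataset_features(newdata)
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  p <- classifier_forward(object$weights, x)[[length(object$weights) + 1]]
  colnames(p) <- label_names()
  p
}

#' @export
print.ceus_classifier <- function(x, ...) {
  cat(sprintf("lesion classifier: dense %s over %d features, %d parameters\n",
              paste(x$spec$widths, collapse = "-"), x$spec$n_features,
              count_parameters(x)))
  h <- x$history
  cat(sprintf("  final train loss %.4f, accuracy %.3f",
              tail(h$train_loss, 1), tail(h$train_accuracy, 1)))
  if (!all(is.na(h$val_accuracy)))
    cat(sprintf("; validation accuracy %.3f", tail(h$val_accuracy, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.ceus_classifier <- function(object, ...) {
  print(object)
  cat("layers:\n")
  ins <- c(object$spec$n_features,
           object$spec$widths[-length(object$spec$widths)])
  for (l in seq_along(object$weights))
    cat(sprintf("  dense %d -> %d (%d parameters)\n", ins[l],
                object$spec$widths[l],
                ins[l] * object$spec$widths[l] + object$spec$widths[l]))
  invisible(object)
}

#' @export
coef.ceus_classifier <- function(object, ...) object$weights

#' Plot the training history of a fitted classifier
#'
#' Loss evolution over epochs for the training and (when available)
#' validation splits.
#' @param x a `ceus_classifier`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ceus_classifier <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "focal cross-entropy", ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
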