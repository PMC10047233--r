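test_that("the network has exactly 203 trainable parameters", {
  spec <- network_spec()
  expect_identical(count_parameters(spec), 203L)
  # layer-wise: 8*8+8, 8*6+6, 6*6+6, 6*5+5
  ins <- c(8, 8, 6, 6)
  expect_equal(ins * spec$widths + spec$widths, c(72, 54, 42, 35))
  expect_identical(count_parameters(network_spec(widths = 1, n_features = 1)),
                   2L)
  # and the constructed model agrees, walking its actual weight arrays
  tab <- generate_patient_table(60, seed = 2)
  m <- train_classifier(tab, config = train_config(epochs = 1))
  expect_equal(count_parameters(m), 203)
})

test_that("focal cross-entropy matches hand-computed values", {
  p <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  expect_equal(focal_cross_entropy(p, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.8^2 * (-log(0.2)), tolerance = 1e-6)
  expect_equal(focal_cross_entropy(c(1, 0, 0, 0, 0), 1), 0)
  # gamma = 0, alpha = 1 reduces to plain cross-entropy
  q <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  expect_equal(focal_cross_entropy(q, 1, alpha = 1, gamma = 0), -log(0.7))
  # one-hot targets are equivalent to indices
  expect_equal(focal_cross_entropy(q, c(0, 0, 1, 0, 0)),
               focal_cross_entropy(q, 3))
  # zero probability is clipped, not infinite
  expect_true(is.finite(focal_cross_entropy(c(0, 1, 0, 0, 0), 1)))
  expect_error(focal_cross_entropy(c(0.5, 0.2, 0.1, 0.1, 0.2), 1), "sum")
})

test_that("focal loss is non-negative and decreasing in p_true", {
  pt <- seq(0.05, 0.99, by = 0.01)
  losses <- vapply(pt, function(p)
    focal_cross_entropy(c(p, (1 - p) / 4, (1 - p) / 4, (1 - p) / 4,
                          (1 - p) / 4), 1), numeric(1))
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))
})

test_that("focal gradient w.r.t. logits matches finite differences", {
  set.seed(2)
  z <- matrix(rnorm(10), 2, 5)
  yidx <- c(2, 4)
  soft <- function(z) { ez <- exp(z - apply(z, 1, max)); ez / rowSums(ez) }
  g <- ceustic:::focal_logit_grad(soft(z), yidx, 0.25, 2, 1e-7)
  eps <- 1e-6
  for (k in seq_along(z)) {
    z2 <- z; z2[k] <- z2[k] + eps
    z3 <- z; z3[k] <- z3[k] - eps
    num <- (focal_cross_entropy(soft(z2), yidx) -
              focal_cross_entropy(soft(z3), yidx)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("oversampling balances classes without losing or inventing rows", {
  tab <- generate_patient_table(69, class_proportions =
                                  c(24, 10, 10, 10, 15) / 69, seed = 5)
  bal <- oversample(tab, seed = 3)
  y <- ceustic:::dataset_labels(bal)
  expect_true(all(table(y) == max(table(ceustic:::dataset_labels(tab)))))
  # originals all retained
  orig <- bal[seq_len(nrow(tab)), ]
  rownames(orig) <- NULL
  expect_identical(orig, tab)
  # duplicates are exact copies of existing rows
  extra <- bal[-seq_len(nrow(tab)), ]
  key <- function(d) apply(d, 1, paste, collapse = "|")
  expect_true(all(key(extra) %in% key(tab)))
  # already balanced input is unchanged
  eq <- generate_patient_table(100, class_proportions = rep(0.2, 5),
                               seed = 11)
  yq <- ceustic:::dataset_labels(eq)
  if (length(unique(table(yq))) == 1)
    expect_identical(oversample(eq, 1), eq)
  expect_identical(oversample(tab, seed = 3), bal)
})

test_that("the stratified split is disjoint, sized and deterministic", {
  tab <- generate_patient_table(100, class_proportions = rep(0.2, 5),
                                seed = 8)
  counts <- table(ceustic:::dataset_labels(tab))
  sp <- split_dataset(tab, fraction = 0.7, seed = 2)
  expect_equal(nrow(sp$train), sum(ceiling(0.7 * counts)))
  expect_equal(nrow(sp$validation), 100 - sum(ceiling(0.7 * counts)))
  ytr <- table(ceustic:::dataset_labels(sp$train))
  expect_true(all(ytr == ceiling(0.7 * counts)))
  expect_equal(length(intersect(rownames(sp$train), rownames(sp$validation))),
               0)
  sp2 <- split_dataset(tab, fraction = 0.7, seed = 2)
  expect_identical(sp, sp2)
})

test_that("no oversampled training row leaks into validation", {
  tab <- generate_patient_table(200, seed = 13)
  sp <- split_dataset(tab, seed = 13)
  bal <- oversample(sp$train, seed = 13)
  key <- function(d) apply(d[, feature_names()], 1, paste, collapse = "|")
  expect_equal(length(intersect(key(bal), key(sp$validation))), 0)
})

test_that("training is deterministic and the history is well-formed", {
  tab <- generate_patient_table(150, seed = 21)
  sp <- split_dataset(tab, seed = 21)
  cfg <- train_config(epochs = 8, seed = 21)
  m1 <- train_classifier(sp$train, sp$validation, config = cfg)
  m2 <- train_classifier(sp$train, sp$validation, config = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 8)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_true(all(is.finite(m1$history$val_loss)))
})

test_that("predictions are proper probability vectors with schema names", {
  tab <- generate_patient_table(120, seed = 31)
  m <- train_classifier(tab, config = train_config(epochs = 3, seed = 1))
  p <- predict(m, tab)
  expect_equal(dim(p), c(120, 5))
  expect_equal(colnames(p), label_names())
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 120), tolerance = 1e-6)
  # single named-vector input works for one patient
  one <- predict(m, unlist(tab[1, feature_names()]))
  expect_equal(unname(one), unname(p[1, , drop = FALSE]), tolerance = 1e-12)
  expect_error(predict(m, tab[, -2]), "missing feature")
})
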