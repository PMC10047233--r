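test_that("mask providers honour the 256x256 binary contract", {
  ph <- quick_phantom(duration = 2)
  prov <- truth_mask_provider(ph)
  panel <- crop_region(ph$get_frame(1), default_regions()$b_mode)
  m <- predict_mask(prov, panel, 1)
  expect_equal(dim(m), c(256L, 256L))
  expect_type(m, "logical")
  # the resampled truth mask keeps the lesion area proportion
  expect_equal(sum(m) / (256^2), sum(ph$get_mask(1)) / (447 * 400),
               tolerance = 0.05)
  # an untrained network still satisfies the contract, even on zero input
  model <- structure(list(spec = unet_spec(input_size = 64),
                          params = ceustic:::unet_init(unet_spec(input_size = 64), 1)),
                     class = "ceus_unet")
  uprov <- unet_mask_provider(model)
  m2 <- predict_mask(uprov, matrix(0, 447, 400), 1)
  expect_equal(dim(m2), c(256L, 256L))
  expect_type(m2, "logical")
  # provider failures carry the frame index
  bad <- mask_provider(function(p, i) stop("boom"), name = "bad")
  expect_error(predict_mask(bad, panel, 17), "frame 17")
  wrong <- mask_provider(function(p, i) matrix(FALSE, 10, 10))
  expect_error(predict_mask(wrong, panel, 1), "256x256")
})

test_that("predicted mask area is non-increasing in the threshold", {
  model <- structure(list(spec = unet_spec(input_size = 32, depth = 3,
                                           base_channels = 4),
                          params = ceustic:::unet_init(
                            unet_spec(input_size = 32, depth = 3,
                                      base_channels = 4), 3)),
                     class = "ceus_unet")
  set.seed(5)
  panel <- matrix(runif(64 * 64) * 255, 64, 64)
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    sum(predict_mask(unet_mask_provider(model, threshold = th), panel, 1))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("dice coefficient identities", {
  m <- matrix(runif(100) > 0.5, 10, 10)
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(dice_coefficient(m, !m), 0)
  expect_equal(dice_coefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
})

test_that("analytic gradients match central finite differences", {
  spec <- unet_spec(input_size = 8, depth = 2, base_channels = 2)
  set.seed(42)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(as.numeric(matrix(runif(64), 8, 8) > 0.5), 8, 8)
  model <- structure(list(spec = spec, params = ceustic:::unet_init(spec, 7)),
                     class = "ceus_unet")
  # random non-zero biases keep pre-activations away from the ReLU kink,
  # where the finite difference would straddle the non-differentiability
  model$params <- lapply(model$params, function(p) {
    p$b <- rnorm(length(p$b), 0, 0.05); p
  })
  lossfn <- function(params) {
    m <- model; m$params <- params
    fw <- ceustic:::unet_forward(m, x, keep_cache = TRUE)
    ceustic:::dice_bce_loss(fw$logits, y)$loss
  }
  fw <- ceustic:::unet_forward(model, x, keep_cache = TRUE)
  lo <- ceustic:::dice_bce_loss(fw$logits, y)
  gr <- ceustic:::unet_backward(model, fw$cache, lo$dlogits)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(model$params)) {
    ks <- sample(length(model$params[[nm]]$W),
                 min(3, length(model$params[[nm]]$W)))
    for (k in ks) {
      p2 <- model$params; p2[[nm]]$W[k] <- p2[[nm]]$W[k] + eps
      p3 <- model$params; p3[[nm]]$W[k] <- p3[[nm]]$W[k] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_equal(gr[[nm]]$W[k], num, tolerance = 1e-4)
    }
    p2 <- model$params; p2[[nm]]$b[1] <- p2[[nm]]$b[1] + eps
    p3 <- model$params; p3[[nm]]$b[1] <- p3[[nm]]$b[1] - eps
    expect_equal(gr[[nm]]$b[1], (lossfn(p2) - lossfn(p3)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training is seeded-deterministic and tolerates one pair", {
  set.seed(1)
  img <- matrix(runif(32 * 32) * 255, 32, 32)
  msk <- matrix(FALSE, 32, 32); msk[10:20, 12:22] <- TRUE
  spec <- unet_spec(input_size = 32, depth = 2, base_channels = 2)
  m1 <- train_unet(list(img), list(msk), spec, epochs = 2, seed = 5)
  m2 <- train_unet(list(img), list(msk), spec, epochs = 2, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_error(train_unet(list(img), list(msk[1:10, ]), spec),
               "size mismatch")
  expect_error(train_unet(list(img), list(msk * 2), spec), "binary")
})

test_that("unet checkpoints survive a save/load round trip", {
  spec <- unet_spec(input_size = 16, depth = 2, base_channels = 2)
  m <- train_unet(list(matrix(runif(256), 16, 16)),
                  list(matrix(c(TRUE, FALSE), 16, 16)), spec, epochs = 1,
                  seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_unet(m, path)
  m2 <- load_unet(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  x <- matrix(runif(256), 16, 16)
  expect_equal(unet_predict(m2, x), unet_predict(m, x), tolerance = 1e-12)
})

test_that("the TIC pipeline is backend-agnostic for equivalent masks", {
  ph <- still_phantom(duration = 12)
  truth <- truth_mask_provider(ph)
  # a second provider that reproduces the same masks through the generic
  # provider interface (stands in for a converged network)
  clone <- mask_provider(function(panel, i)
    ceustic:::resize_nearest(ph$get_mask(i), 256L, 256L), name = "clone")
  t1 <- sample_tic(ph, truth)
  t2 <- sample_tic(ph, clone)
  expect_equal(t1$lesion_intensity, t2$lesion_intensity)
  expect_equal(t1$parenchyma_intensity, t2$parenchyma_intensity)
})
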