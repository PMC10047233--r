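test_that("dilation matches hand-derived cases", {
  # single on-pixel, all-true 10x10 kernel: a 10x10 block extending 5
  # up/left and 4 down/right of the pixel
  m <- matrix(FALSE, 100, 100)
  m[50, 50] <- TRUE
  d <- dilate(m, structuring_element(10))
  on <- which(d, arr.ind = TRUE)
  expect_equal(range(on[, 1]), c(45, 54))
  expect_equal(range(on[, 2]), c(45, 54))
  expect_equal(sum(d), 100)
  # empty mask stays empty; output is always a superset
  expect_equal(sum(dilate(matrix(FALSE, 8, 8), structuring_element(3))), 0)
  expect_error(structuring_element(kernel = matrix(FALSE, 2, 2)), "empty")
})

test_that("dilation equals the literal union-of-translates brute force", {
  set.seed(42)
  for (rep in 1:40) {
    H <- sample(10:40, 1); W <- sample(10:40, 1)
    m <- matrix(runif(H * W) < 0.15, H, W)
    kr <- sample(2:12, 1); kc <- sample(2:12, 1)
    k <- if (rep %% 3 == 0) {
      structuring_element(kr, kc)                        # separable path
    } else {
      kk <- matrix(runif(kr * kc) < 0.6, kr, kc)
      kk[ceiling(kr / 2), ceiling(kc / 2)] <- TRUE
      structuring_element(kernel = kk)                   # general path
    }
    expect_identical(unname(dilate(m, k)) | m, brute_dilate(m, k) | m)
  }
})

test_that("parenchyma ring partitions the dilated mask", {
  m <- matrix(FALSE, 100, 100)
  xy <- expand.grid(r = 1:100, c = 1:100)
  m[as.matrix(xy[(xy$r - 50)^2 + (xy$c - 50)^2 <= 25, ])] <- TRUE  # disc r=5
  d <- dilate(m, structuring_element(11))
  ring <- parenchyma_ring(m, d)
  expect_equal(sum(ring), sum(d) - sum(m))   # pixel-count identity
  expect_false(any(ring & m))
  expect_identical(ring | m, unname(d))
  expect_identical(parenchyma_ring(m, m), m & FALSE)    # mask == dilated
  expect_identical(parenchyma_ring(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4)),
                   matrix(TRUE, 4, 4))
  expect_error(parenchyma_ring(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4)),
               "superset")
})

test_that("LUT construction: ramps, two-colour strips, duplicates, errors", {
  ramp <- array(rep(seq(255, 0, length.out = 70), 15), dim = c(70, 5, 3))
  lut <- build_lut(ramp)
  expect_equal(nrow(lut$rgb), 70)
  expect_equal(lut$intensity, seq(255, 0, length.out = 70))
  two <- array(0, dim = c(2, 3, 3)); two[1, , ] <- 255
  lut2 <- build_lut(two)
  expect_equal(lut2$intensity, c(255, 0))
  expect_equal(lut2$rgb[1, ], rep(255, 3))
  # duplicate adjacent rows collapse to the brighter assignment
  dup <- array(0, dim = c(4, 2, 3))
  dup[1:2, , ] <- 200; dup[3:4, , ] <- 30
  lutd <- build_lut(dup)
  expect_equal(nrow(lutd$rgb), 2)
  expect_equal(lutd$intensity, c(255, 255 / 3))
  expect_error(build_lut(array(9, dim = c(5, 2, 3))), "single colour")
})

test_that("mean intensity equals a per-pixel nearest-colour brute force", {
  set.seed(7)
  lut <- build_lut(array(rep(seq(250, 5, length.out = 32), 3),
                         dim = c(32, 1, 3)))
  panel <- array(runif(20 * 20 * 3) * 255, dim = c(20, 20, 3))
  mask <- matrix(runif(400) < 0.4, 20, 20)
  got <- mean_intensity(panel, mask, lut)
  idxs <- which(mask)
  vals <- vapply(idxs, function(ii) {
    px <- c(panel[, , 1][ii], panel[, , 2][ii], panel[, , 3][ii])
    d2 <- colSums((t(lut$rgb) - px)^2)
    lut$intensity[which.min(d2)]
  }, numeric(1))
  expect_equal(got, mean(vals), tolerance = 1e-12)
  # uniform panel at a LUT colour decodes exactly; ties go to lower index
  uni <- array(0, dim = c(4, 4, 3))
  uni[, , 1] <- lut$rgb[5, 1]; uni[, , 2] <- lut$rgb[5, 2]
  uni[, , 3] <- lut$rgb[5, 3]
  expect_equal(mean_intensity(uni, matrix(TRUE, 4, 4), lut),
               lut$intensity[5])
  expect_error(mean_intensity(uni, matrix(FALSE, 4, 4), lut), "no pixels")
})

test_that("the 75% rule accepts and rejects per its arithmetic", {
  lut <- gray_lut()
  # against the previous ACCEPTED 100: a drop to 30 (|30-100| = 70 < 75)
  # is valid, a drop to 10 (90 > 75) is not
  t1 <- sample_tic(stub_frames(c(100, 30)), stub_provider(),
                   regions = stub_regions(),
                   kernel = structuring_element(3), lut = lut)
  expect_equal(t1$valid, c(TRUE, TRUE))
  expect_equal(t1$lesion_intensity, c(100, 30))
  t2 <- sample_tic(stub_frames(c(100, 10, 95)), stub_provider(),
                   regions = stub_regions(),
                   kernel = structuring_element(3), lut = lut)
  expect_equal(t2$valid, c(TRUE, FALSE, TRUE))
  # the invalid second carries no intensity; comparison stays anchored to
  # the last accepted value (100), so 95 is accepted afterwards
  expect_true(is.na(t2$lesion_intensity[2]))
  expect_equal(t2$lesion_intensity[3], 95)
})

test_that("rejected frames are retried within the second", {
  lut <- gray_lut()
  # 2 fps: second 1 has frames at levels 10 (rejected) then 80 (accepted)
  frames <- stub_frames(c(100, 100, 10, 80, 90, 90), fps = 2)
  tic <- sample_tic(frames, stub_provider(), regions = stub_regions(),
                    kernel = structuring_element(3), lut = lut)
  expect_true(all(tic$valid))
  expect_equal(tic$lesion_intensity, c(100, 80, 90))
  expect_equal(tic$frame, c(1, 4, 5))
})

test_that("raising the rejection threshold never loses valid seconds", {
  set.seed(11)
  levels <- pmax(5, 100 + cumsum(rnorm(30, 0, 45)))
  levels <- pmin(levels, 255)
  frames <- stub_frames(levels)
  nvalid <- vapply(c(0.3, 0.5, 0.75, 1, 2), function(f) {
    sum(sample_tic(frames, stub_provider(), regions = stub_regions(),
                   kernel = structuring_element(3), lut = gray_lut(),
                   reject_fraction = f)$valid)
  }, numeric(1))
  expect_true(all(diff(nvalid) >= 0))
})

test_that("probe-lift seconds are flagged invalid and the curve recovers", {
  ph <- still_phantom(duration = 30, probe_lift = list(c(20, 23)))
  tic <- sample_tic(ph, truth_mask_provider(ph))
  expect_equal(tic$time_s[!tic$valid], c(20, 21, 22))
  expect_true(tic$valid[tic$time_s == 23])
  expect_true(all(tic$valid[tic$time_s < 20]))
})

test_that("Savitzky-Golay smoothing is exact on cubics and constants", {
  t <- 0:89
  cubic <- 2 + 0.5 * t - 0.02 * t^2 + 1e-4 * t^3
  sm <- smooth_tic(make_tic(t, cubic), window = 51, polyorder = 3)
  expect_equal(sm$lesion_intensity, cubic, tolerance = 1e-8)
  const <- make_tic(0:59, rep(42, 60))
  expect_equal(smooth_tic(const)$lesion_intensity, rep(42, 60),
               tolerance = 1e-10)
})

test_that("the window shrinks to the largest odd length below 51", {
  t <- 0:29
  v <- 50 + 30 * sin(t / 5)
  sm <- smooth_tic(make_tic(t, v), window = 51, polyorder = 3)
  ref <- signal::sgolayfilt(v, p = 3, n = 29)
  expect_equal(sm$lesion_intensity, ref, tolerance = 1e-10)
  expect_error(smooth_tic(make_tic(0:3, rep(1, 4))), "at least 5")
})

test_that("invalid gaps are interpolated for filtering then re-flagged", {
  t <- 0:59
  v <- 20 + t
  valid <- rep(TRUE, 60); valid[25:28] <- FALSE
  tic <- make_tic(t, replace(v, 25:28, NA), valid = valid)
  sm <- smooth_tic(tic)
  expect_true(all(is.na(sm$lesion_intensity[25:28])))
  # a line is degree 1, so filtering after interpolation reproduces it
  expect_equal(sm$lesion_intensity[valid], v[valid], tolerance = 1e-8)
})

test_that("parameter extraction has the degenerate closed forms", {
  const <- make_tic(0:20, rep(7, 21))
  expect_warning(p <- extract_params(const), "flat")
  expect_equal(p$max_intensity, 7)
  expect_equal(p$ttp, 0)
  expect_equal(p$auc, 7 * 20)
  expect_true(is.nan(p$mtt))
  # symmetric triangle 0 -> 100 -> 0 over [0, 20]
  tri <- make_tic(0:20, c(seq(0, 100, by = 10), seq(90, 0, by = -10)))
  pt <- extract_params(tri)
  expect_equal(pt$ttp, 10)
  expect_equal(pt$mtt, 10)
  expect_equal(pt$max_intensity, 100)
  expect_error(extract_params(make_tic(0:1, c(1, 2))), "at least 3")
})

test_that("closed-form gamma-variate peak is recovered from sampled curves", {
  t <- 0:119
  sp <- perfusion_spec(A = 100, t0 = 10, alpha = 2, beta = 8, b = 20)
  tic <- make_tic(t, gamma_variate(t, sp))
  p <- extract_params(tic)
  expect_lt(abs(p$max_intensity - 120) / 120, 0.02)
  expect_lt(abs(p$ttp - 18), 1 + 1e-9)
  expect_gt(p$auc, 0)
  expect_true(p$mtt >= 0 && p$mtt <= 119)
})

test_that("curve CSVs round-trip losslessly and params file has 4 values", {
  dir <- withr::local_tempdir()
  t <- 0:39
  v <- 20 + 80 * exp(-(t - 15)^2 / 40)
  valid <- rep(TRUE, 40); valid[10:11] <- FALSE
  tic <- make_tic(t, replace(v, 10:11, NA), replace(v / 2, 10:11, NA),
                  valid = valid)
  tic$frame[10:11] <- NA
  params <- extract_params(tic)
  path <- file.path(dir, "tic.csv")
  write_tic_csv(tic, path, params = params)
  back <- read_tic_csv(path, fps = 1)
  expect_equal(as.data.frame(back), as.data.frame(tic), tolerance = 1e-12)
  pf <- read.csv(file.path(dir, "tic_params.csv"))
  expect_equal(pf$name, c("max_intensity", "ttp", "auc", "mtt"))
  expect_equal(pf$value[1], params$max_intensity, tolerance = 1e-12)
})
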