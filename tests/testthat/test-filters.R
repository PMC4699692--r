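set.seed(103)

test_that("slice normalization equalizes drifting stacks and fixes uniform ones", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 20), background = 125,
                                  noise_sd = 4, drift_sd = 15, seed = 3))
  dn <- normalize_slices(ph$ds)
  means <- apply(img3d(dn), 3, mean)
  expect_lt(diff(range(means)), 0.5)
  # already uniform stack: unchanged within rounding
  du <- layered_dataset(array(rnorm(30^2 * 6, 100, 5), c(30, 30, 6)))
  dn2 <- normalize_slices(du)
  expect_lt(max(abs(img3d(dn2) - img3d(du))), 1.5)
})

test_that("masked normalization equalizes background statistics across slices", {
  # two-region phantom: constant background plus slice-dependent bright
  # foreground content; masked mode must ignore the foreground
  d <- c(40, 40, 8)
  img <- array(rnorm(prod(d), 100, 5), d)
  for (z in seq_len(d[3])) img[1:(2 * z), 1:20, z] <- 220  # varying content
  for (z in seq_len(d[3])) img[, , z] <- img[, , z] + 4 * z  # drift
  ds <- layered_dataset(img)
  msk <- array(1L, d); msk[1:20, 1:20, ] <- 0L  # background-only mask
  ds <- set_layer(ds, "mask", msk)
  dn <- normalize_slices(ds, "masked-area")
  bg_means <- sapply(seq_len(d[3]), function(z)
    mean(img3d(dn)[, , z][msk[, , z] == 1]))
  expect_lt(diff(range(bg_means)), 0.5)
  # empty mask on a slice is a named error
  msk2 <- msk; msk2[, , 3] <- 0L
  expect_error(normalize_slices(set_layer(ds, "mask", msk2), "masked-area"),
               "3")
})

test_that("display adjustment is identity at defaults, fixes endpoints, and is monotone", {
  ds <- layered_dataset(array(sample(0:255, 1000, TRUE), c(10, 10, 10)))
  expect_identical(adjust_display(ds, 0, 1, 1)$image, ds$image)
  dg <- adjust_display(ds, 0, 1, 2.2)
  expect_equal(dg$image[ds$image == 0], rep(0, sum(ds$image == 0)))
  expect_equal(dg$image[ds$image == 255], rep(255, sum(ds$image == 255)))
  x <- sort(unique(as.vector(ds$image)))
  y <- dg$image[match(x, ds$image)]
  expect_true(all(diff(y) >= 0))
  expect_error(adjust_display(ds, gamma = 0), "gamma")
})

test_that("anisotropic diffusion denoises flat regions without moving edges", {
  img <- array(80, c(60, 60, 4)); img[31:60, , ] <- 180
  img <- img + array(rnorm(length(img), 0, 10), dim(img))
  ds <- layered_dataset(img)
  df <- anisotropic_diffusion(ds, iterations = 12, kappa = 25)
  v0 <- var(as.vector(img3d(ds)[5:25, 5:55, ]))
  v1 <- var(as.vector(img3d(df)[5:25, 5:55, ]))
  expect_gte(v0 / v1, 4)
  for (z in 1:4) {
    prof <- rowMeans(img3d(df)[, , z])
    expect_lte(abs(which(prof > 130)[1] - 31), 1)
  }
  # noise-free constant image is a fixed point
  cst <- layered_dataset(array(100, c(20, 20, 2)))
  expect_lt(max(abs(img3d(anisotropic_diffusion(cst, 5, 20)) - 100)), 1e-9)
  expect_error(anisotropic_diffusion(ds, lambda = 0.3), "lambda")
})

test_that("binary erosion-then-dilation equals opening and small specks vanish", {
  v <- array(runif(20 * 20 * 4), c(20, 20, 4))
  expect_identical(
    morphology_filter(v, "opening", radius = 2),
    morphology_filter(morphology_filter(v, "erosion", radius = 2),
                      "dilation", radius = 2))
  spot <- array(0, c(20, 20, 1)); spot[10, 10, 1] <- 1
  expect_true(all(morphology_filter(spot, "opening", radius = 2) == 0))
  expect_error(morphology_filter(spot, "erosion", radius = 2, dims = "3d"),
               "single-slice")
})

test_that("bottom-hat responds inside dark disks only", {
  img <- array(200, c(50, 50, 1))
  gx <- matrix(1:50, 50, 50); gy <- t(gx)
  disk <- (gx - 15)^2 + (gy - 15)^2 <= 9
  img[, , 1][disk] <- 60
  bh <- morphology_filter(img, "bottom-hat", radius = 6)
  expect_gt(mean(bh[, , 1][disk]), 100)
  far <- (gx - 40)^2 + (gy - 40)^2 <= 25
  expect_lt(max(bh[, , 1][far]), 1e-9)
})

test_that("gradient magnitude: zeros, closed-form ramp, and sphere shell maxima", {
  expect_true(all(gradient_magnitude(
    layered_dataset(array(7, c(10, 10, 3)))) == 0))
  ramp <- layered_dataset(array(rep(1:30, 20 * 4) * 0, c(30, 20, 4)))
  ramp$image[, , 1, ] <- array(rep((1:30) * 3, 20 * 4), c(30, 20, 4))
  g <- gradient_magnitude(ramp)
  expect_lt(max(abs(g[2:29, 5:15, 2] - 3)), 1e-9)
  # anisotropy: same values, doubled spacing halves the gradient
  ramp2 <- ramp; ramp2$geometry$voxel_size[1] <- 2
  expect_lt(max(abs(gradient_magnitude(ramp2)[2:29, 5:15, 2] - 1.5)), 1e-9)
  # sphere boundary produces a shell of maxima near the surface
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), noise_sd = 0,
    objects = list(list(kind = "sphere", n = 1, radius = c(10, 10),
                        intensity = 40)), seed = 5))
  gs <- gradient_magnitude(ph$ds)
  ctr <- as.numeric(ph$objects[1, c("cx", "cy", "cz")])
  w <- which(gs > 0.5 * max(gs), arr.ind = TRUE)
  rad <- sqrt(colSums((t(w) - ctr)^2))
  expect_true(all(abs(rad - 10) < 2.5))
})

test_that("vesselness prefers tubes over blobs and is rotation-tolerant", {
  img <- array(160, c(64, 64, 12))
  for (y in 5:60) {
    d2 <- outer((1:64 - 32)^2, ((1:12) - 6)^2, "+")
    img[, y, ][d2 <= 9] <- 220
  }
  gx <- array(rep(1:64, 64 * 12), c(64, 64, 12))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(array(rep(1:12, 64 * 64), c(12, 64, 64)), c(2, 3, 1))
  img[(gx - 16)^2 + (gy - 16)^2 + (gz - 6)^2 <= 36] <- 220
  ds <- layered_dataset(img)
  vess <- frangi_filter(ds, scales = c(1.5, 2.5), polarity = "bright")
  expect_gt(mean(vess[32, 10:55, 6]), 2 * mean(vess[16, 16, 6]))
  expect_true(all(vess >= 0 & vess <= 1))
  # constant image: zero response
  expect_true(all(frangi_filter(layered_dataset(array(50, c(32, 32, 8))),
                                scales = 2) == 0))
  # 90-degree in-plane rotation changes the mean axis response < 5%
  ds_r <- ds_transform(ds, "rotate90", k = 1)
  vess_r <- frangi_filter(ds_r, scales = c(1.5, 2.5), polarity = "bright")
  on_axis <- mean(vess[32, 10:55, 6])
  on_axis_r <- mean(vess_r[10:55, 32, 6])
  expect_lt(abs(on_axis - on_axis_r) / on_axis, 0.05)
})

test_that("tube response peaks near scale sigma = r/sqrt(2)", {
  r <- 3
  img <- array(160, c(48, 48, 8))
  for (y in 1:48) {
    d2 <- outer((1:48 - 24)^2, ((1:8) - 4)^2, "+")
    img[, y, ][d2 <= r^2] <- 220
  }
  ds <- layered_dataset(img)
  scales <- c(1, 1.5, 2.1, 3, 4.2)
  resp <- sapply(scales, function(s)
    mean(frangi_filter(ds, scales = s, polarity = "bright")[24, 10:38, 4]))
  best <- scales[which.max(resp)]
  target <- r / sqrt(2)
  ix <- which.min(abs(scales - target))
  expect_lte(abs(which.max(resp) - ix), 1)  # within one scale step
})

test_that("ROI-restricted filtering leaves the outside bit-identical", {
  img <- array(rnorm(50 * 50 * 4, 120, 15), c(50, 50, 4))
  ds <- layered_dataset(img)
  for (roi in list(roi_shape("rectangle", x = c(10, 30), y = c(12, 35)),
                   roi_shape("ellipse", center = c(25, 25), radii = c(10, 7)),
                   roi_shape("polygon",
                             vertices = cbind(c(10, 40, 25), c(10, 12, 40))))) {
    msk <- rasterize_roi(roi, ds_dim(ds))
    dr <- anisotropic_diffusion(ds, iterations = 4, kappa = 30, roi = roi)
    expect_identical(img3d(dr)[!msk], img3d(ds)[!msk])
    expect_false(identical(img3d(dr)[msk], img3d(ds)[msk]))
  }
})

test_that("ROI interior matches the globally filtered volume exactly", {
  img <- array(rnorm(40 * 40 * 3, 120, 15), c(40, 40, 3))
  ds <- layered_dataset(img)
  roi <- roi_shape("rectangle", x = c(8, 32), y = c(8, 32))
  it <- 4
  dg <- anisotropic_diffusion(ds, iterations = it, kappa = 30)
  dr <- anisotropic_diffusion(ds, iterations = it, kappa = 30, roi = roi)
  # interior eroded by the filter support
  core_x <- (8 + it + 1):(32 - it - 1)
  expect_equal(img3d(dr)[core_x, core_x, ], img3d(dg)[core_x, core_x, ])
  # ROI covering the whole image equals global application
  roi_all <- roi_shape("rectangle", x = c(1, 40), y = c(1, 40))
  expect_equal(img3d(anisotropic_diffusion(ds, iterations = it, kappa = 30,
                                           roi = roi_all)),
               img3d(dg))
})

test_that("filters are deterministic and log entries accumulate", {
  ds <- layered_dataset(array(rnorm(20^3, 100, 10), c(20, 20, 20)))
  a <- anisotropic_diffusion(ds, 3, 20)
  b <- anisotropic_diffusion(ds, 3, 20)
  expect_identical(a$image, b$image)
  expect_equal(nrow(action_log(anisotropic_diffusion(a, 3, 20))),
               nrow(action_log(a)) + 1)
})
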