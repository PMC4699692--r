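set.seed(104)

test_that("painting primitives honor anisotropy and bounds", {
  ds <- layered_dataset(array(0, c(20, 20, 10)), voxel_size = c(5, 5, 10))
  dp <- paint_primitive(ds, "ball3d", c(10, 10, 5), radius = 10)
  w <- which(get_layer(dp, "selection") == 1, arr.ind = TRUE)
  expect_equal(unname(apply(w, 2, function(x) diff(range(x)) + 1)),
               c(5, 5, 3))  # semi-axes (2,2,1) voxels
  ds0 <- layered_dataset(array(0, c(30, 30, 5)))
  expect_equal(sum(get_layer(paint_primitive(ds0, "spot", c(15, 15, 3),
                                             radius = 0), "selection")), 1)
  expect_error(paint_primitive(ds0, "spot", c(99, 1, 1), 1), "bounds")
})

test_that("ball voxel count approaches the sphere volume for large radii", {
  ds <- layered_dataset(array(0, c(40, 40, 40)))
  for (r in c(4, 6, 8)) {
    dp <- paint_primitive(ds, "ball3d", c(20, 20, 20), radius = r)
    count <- sum(get_layer(dp, "selection"))
    expect_lt(abs(count - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.15)
  }
})

test_that("brush strokes are continuous, idempotent and erasable", {
  ds <- layered_dataset(array(0, c(40, 40, 4)))
  st <- tool_stroke(rbind(c(3, 3), c(35, 28)), radius = 1, slice = 2)
  b1 <- brush_stroke(ds, st)
  sel <- get_layer(b1, "selection")
  # path connectivity: one 8-connected component containing both endpoints
  lab <- label_objects(sel, "3d")$labels
  expect_equal(max(lab), 1)
  expect_equal(lab[3, 3, 2], lab[35, 28, 2])
  expect_true(all(sel[, , c(1, 3, 4)] == 0))  # confined to the slice
  expect_identical(brush_stroke(b1, st)$selection, b1$selection)
  expect_equal(sum(brush_stroke(b1, st, erase = TRUE)$selection), 0)
  # image layer never touched by tools
  expect_identical(b1$image, ds$image)
})

test_that("superpixel brush selects whole touched regions, a superset of the footprint", {
  img <- array(60, c(48, 48, 4)); img[25:48, , ] <- 190
  img <- img + array(rnorm(length(img), 0, 4), dim(img))
  ds <- layered_dataset(img)
  sp <- slic_partition(ds, target_size = 64, dims = "2d")
  st <- tool_stroke(rbind(c(5, 5), c(15, 30)), radius = 2, slice = 2)
  plain <- brush_stroke(ds, st)
  sup <- brush_superpixels(ds, st, sp)
  expect_true(all(sup$selection[plain$selection == 1] == 1))
  expect_gt(sum(sup$selection), sum(plain$selection))
  # stroke confined to the dark region selects no bright-region voxels
  bright <- img3d(ds) > 125
  expect_equal(sum(sup$selection == 1 & bright[, , ]), 0)
  expect_error(brush_superpixels(ds, st, list()), "SLIC")
})

test_that("magic wand gives the seeded iso-intensity component under stated connectivity", {
  ds <- layered_dataset(array(100, c(20, 20, 4)))
  expect_equal(sum(magic_wand(ds, c(5, 5, 2), c(50, 50))), prod(c(20, 20, 4)))
  # two disks touching only diagonally: joined iff connectivity 8
  img <- array(0, c(20, 20, 1))
  img[5:8, 5:8, 1] <- 200
  img[9:12, 9:12, 1] <- 200
  d2 <- layered_dataset(img)
  r8 <- magic_wand(d2, c(6, 6, 1), c(0, 0), connectivity = 8, scope = "2d")
  r4 <- magic_wand(d2, c(6, 6, 1), c(0, 0), connectivity = 4, scope = "2d")
  expect_equal(sum(r8), 32)
  expect_equal(sum(r4), 16)
  # wand output always contains its seed and is connected (flood-fill check)
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 16), noise_sd = 6,
    objects = list(list(kind = "sphere", n = 2, radius = c(4, 6),
                        intensity = 60)), seed = 6))
  w <- which(ph$gt == 1, arr.ind = TRUE)
  seedv <- w[1, ]
  mw <- magic_wand(ph$ds, seedv, c(40, 40))
  expect_equal(mw[seedv[1], seedv[2], seedv[3]], 1L)
  expect_equal(max(label_objects(mw, "3d")$labels), 1)
})

test_that("region growing recovers a sharp blob and degenerates gracefully", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 24), noise_sd = 4,
    objects = list(list(kind = "sphere", n = 1, radius = c(7, 7),
                        intensity = 60)), seed = 8))
  ctr <- round(as.numeric(ph$objects[1, c("cx", "cy", "cz")]))
  rg <- region_grow(ph$ds, ctr, kappa = 40)
  expect_gte(dice(rg, ph$gt == 1), 0.95)
  # kappa = 0 on a noisy image stays at (essentially) the seed
  expect_lte(sum(region_grow(ph$ds, ctr, kappa = 0)), 3)
  # result is the same from any seed inside the blob
  w <- which(ph$gt == 1, arr.ind = TRUE)
  regions <- lapply(seq(1, nrow(w), length.out = 5), function(i)
    region_grow(ph$ds, w[round(i), ], kappa = 40))
  sizes <- vapply(regions, sum, 0)
  expect_lt(diff(range(sizes)) / mean(sizes), 0.1)
})

test_that("membrane tracking snaps to dark ridges and defaults to the chord", {
  img <- array(200, c(50, 50, 1))
  img[, 25, 1] <- 40  # straight dark membrane
  ds <- layered_dataset(img)
  cl <- click_sequence(rbind(c(5, 25, 1), c(45, 25, 1)), corridor = 20)
  path <- membrane_track_2d(ds, cl)
  w <- which(path == 1, arr.ind = TRUE)
  expect_true(all(abs(w[, 2] - 25) <= 1))
  # adjacent clicks: path is those two voxels
  cl2 <- click_sequence(rbind(c(10, 10, 1), c(11, 10, 1)))
  expect_equal(sum(membrane_track_2d(ds, cl2)), 2)
  # uniform cost: the discrete straight segment (Bresenham comparison)
  du <- layered_dataset(array(100, c(50, 50, 1)))
  cl3 <- click_sequence(rbind(c(5, 10, 1), c(45, 30, 1)), corridor = 30)
  w3 <- which(membrane_track_2d(du, cl3) == 1, arr.ind = TRUE)
  a <- c(5, 10); b <- c(45, 30); ab <- b - a
  perp <- abs((w3[, 1] - a[1]) * ab[2] - (w3[, 2] - a[2]) * ab[1]) /
    sqrt(sum(ab^2))
  expect_lte(max(perp), 0.75)
  # no path outside the corridor
  blocked <- click_sequence(rbind(c(5, 5, 1), c(45, 45, 1)), corridor = 2)
  expect_silent(membrane_track_2d(du, blocked))  # chord fits its own corridor
})

test_that("3-D line tracking interpolates in physical coordinates", {
  ds <- layered_dataset(array(0, c(30, 30, 10)))
  # constant anchors: vertical line
  cl <- click_sequence(rbind(c(15, 15, 1), c(15, 15, 10)))
  lt <- line_track_3d(ds, cl)
  expect_equal(sum(lt), 10)
  expect_true(all(lt[15, 15, ] == 1))
  expect_error(line_track_3d(ds,
    click_sequence(rbind(c(1, 1, 3), c(5, 5, 3)))), "same slice")
  # helix sampled at anchors: rasterized centerline within 1 voxel
  dsa <- layered_dataset(array(0, c(40, 40, 21)))
  zs <- seq(1, 21, by = 5)
  helix <- cbind(20 + 10 * cos(zs / 4), 20 + 10 * sin(zs / 4), zs)
  lt2 <- line_track_3d(dsa, click_sequence(round(helix)))
  w <- which(lt2 == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(w))) {
    z <- w[i, 3]
    # nearest anchor-segment interpolation in continuous coordinates
    k <- max(which(zs <= z))
    k2 <- min(k + 1, length(zs))
    t <- if (zs[k2] == zs[k]) 0 else (z - zs[k]) / (zs[k2] - zs[k])
    exp_xy <- round(helix[k, 1:2]) * (1 - t) + round(helix[k2, 1:2]) * t
    expect_lte(max(abs(w[i, 1:2] - exp_xy)), 1.5)
  }
  # anisotropic voxel size changes the interpolated path
  dz <- layered_dataset(array(0, c(30, 30, 7)), voxel_size = c(1, 1, 4))
  cl4 <- click_sequence(rbind(c(2, 2, 1), c(26, 2, 7)))
  iso <- line_track_3d(layered_dataset(array(0, c(30, 30, 7))), cl4)
  ani <- line_track_3d(dz, cl4)
  # same voxel path here (linear in both scalings) -- but a three-anchor
  # path with unequal slice gaps differs
  cl5 <- click_sequence(rbind(c(2, 2, 1), c(20, 2, 2), c(26, 2, 7)))
  iso5 <- line_track_3d(layered_dataset(array(0, c(30, 30, 7))), cl5)
  expect_equal(dim(iso), dim(ani))
  expect_true(sum(iso5) >= 7)
})

test_that("shape interpolation blends SDFs, is endpoint-exact and symmetric", {
  lay <- array(0L, c(40, 40, 5))
  gx <- matrix(1:40, 40, 40); gy <- t(gx)
  lay[, , 1][(gx - 20)^2 + (gy - 20)^2 <= 16] <- 1L   # disk r=4
  lay[, , 5][(gx - 20)^2 + (gy - 20)^2 <= 64] <- 1L   # disk r=8
  si <- shape_interpolate(lay, 1, 5)
  expect_identical(si[, , 1], lay[, , 1])
  expect_identical(si[, , 5], lay[, , 5])
  r_mid <- sqrt(sum(si[, , 3]) / pi)
  expect_lte(abs(r_mid - 6), 1)  # SDF blend of nested disks: radius 6
  # symmetric in the arguments
  si_r <- shape_interpolate(lay[, , 5:1], 1, 5)
  expect_identical(si_r[, , 5:1], si)
  # identical key slices reproduce the disk on every intermediate
  lay2 <- lay; lay2[, , 5] <- lay[, , 1]
  si2 <- shape_interpolate(lay2, 1, 5)
  for (z in 2:4) expect_identical(si2[, , z], lay[, , 1])
  expect_error(shape_interpolate(array(0L, c(10, 10, 3)), 1, 3), "empty")
})

test_that("interpolated area is monotone for nested convex shapes", {
  for (rep in 1:5) {
    r1 <- runif(1, 3, 6); r2 <- runif(1, 8, 12)
    e <- runif(2, 0.6, 1)
    lay <- array(0L, c(48, 48, 6))
    gx <- matrix(1:48, 48, 48); gy <- t(gx)
    lay[, , 1][((gx - 24) / r1)^2 + ((gy - 24) / (r1 * e[1]))^2 <= 1] <- 1L
    lay[, , 6][((gx - 24) / r2)^2 + ((gy - 24) / (r2 * e[2]))^2 <= 1] <- 1L
    si <- shape_interpolate(lay, 1, 6)
    areas <- apply(si, 3, sum)
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("line interpolation blends open curves by arc length", {
  lay <- array(0L, c(40, 40, 5))
  lay[10:30, 10, 1] <- 1L
  lay[10:30, 30, 5] <- 1L
  li <- line_interpolate(lay, 1, 5)
  w3 <- which(li[, , 3] == 1, arr.ind = TRUE)
  expect_true(all(w3[, 2] == 20))  # midway between the parallel segments
  # identical curves: identical intermediates
  lay2 <- lay; lay2[, , 5] <- lay[, , 1]
  li2 <- line_interpolate(lay2, 1, 5)
  for (z in 2:4) expect_identical(li2[, , z], lay[, , 1])
  # arc length of an interpolated arc lies between the endpoint arc lengths
  # (arcs drawn as chords between coarse samples, so the curve stays a
  # simple 1-px open chain)
  arc <- function(r, th) {
    m <- array(0L, c(64, 64, 1))
    ts <- seq(0, th, length.out = max(4, ceiling(r * th / 6)))
    pts <- round(cbind(32 + r * cos(ts), 32 + r * sin(ts)))
    ds0 <- layered_dataset(array(0, c(64, 64, 1)))
    st <- tool_stroke(pts, radius = 0, slice = 1)
    get_layer(brush_stroke(ds0, st), "selection")[, , 1]
  }
  lay3 <- array(0L, c(64, 64, 5))
  lay3[, , 1] <- arc(20, pi / 2)
  lay3[, , 5] <- arc(20, pi)
  li3 <- line_interpolate(lay3, 1, 5)
  lens <- apply(li3, 3, sum)
  expect_true(all(lens[2:4] > lens[1] * 0.9 & lens[2:4] < lens[5] * 1.1))
  expect_true(all(diff(lens) > -3))
  # branching curves are refused
  br <- array(0L, c(20, 20, 3))
  br[5:15, 10, 1] <- 1L; br[10, 10:15, 1] <- 1L; br[5:15, 10, 3] <- 1L
  expect_error(line_interpolate(br, 1, 3), "branching|endpoints")
})

test_that("thresholding windows are inclusive and masked scope intersects the mask", {
  ds <- layered_dataset(array(sample(0:255, 20^3, TRUE), c(20, 20, 20)))
  all_sel <- threshold_bw(ds, c(0, 255))
  expect_equal(sum(get_layer(all_sel, "selection")), prod(ds_dim(ds)))
  # inclusivity at both bounds
  dsx <- layered_dataset(array(c(10, 20, 30), c(3, 1, 1)))
  expect_equal(as.vector(get_layer(threshold_bw(dsx, c(10, 20)),
                                   "selection")), c(1L, 1L, 0L))
  expect_error(threshold_bw(ds, c(10, 5)), "low")
  # masked scope: output subset of mask
  msk <- array(0L, ds_dim(ds)); msk[1:10, , ] <- 1L
  dm <- set_layer(ds, "mask", msk)
  sel <- get_layer(threshold_bw(dm, c(0, 200), scope = "masked"), "selection")
  expect_true(all(sel[msk == 0] == 0))
  expect_error(threshold_bw(set_layer(ds, "mask", array(0L, ds_dim(ds))),
                            c(0, 1), scope = "masked"), "nonempty")
})

test_that("bimodal phantom thresholds to the dark class with high accuracy", {
  set.seed(9)
  d <- c(40, 40, 20)
  cls <- array(rbinom(prod(d), 1, 0.4), d)
  img <- array(rnorm(prod(d), ifelse(cls == 1, 50, 200), 10), d)
  ds <- layered_dataset(img)
  sel <- get_layer(threshold_bw(ds, c(0, 125)), "selection")
  expect_gte(mean(sel == cls), 0.99)
})
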