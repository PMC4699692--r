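set.seed(105)

test_that("SLIC partitions every voxel into near-target-size regions", {
  ds <- layered_dataset(array(100, c(36, 36, 18)))
  sp <- slic_partition(ds, target_size = 125)
  expect_equal(sort(unique(as.vector(sp$labels))), seq_len(sp$n_regions))
  n_expect <- prod(ds_dim(ds)) / 125
  expect_gte(sp$n_regions, n_expect / 2)
  expect_lte(sp$n_regions, n_expect * 2)
  # constant image: all region means equal
  expect_lt(diff(range(sp$stats$mean)), 1e-9)
  # adjacency is symmetric-unique and references live regions
  expect_true(all(sp$adjacency[, 1] < sp$adjacency[, 2]))
  expect_true(all(sp$adjacency <= sp$n_regions))
  # determinism
  sp2 <- slic_partition(ds, target_size = 125)
  expect_identical(sp$labels, sp2$labels)
})

test_that("SLIC respects a strong intensity boundary", {
  img <- array(60, c(60, 60, 20)); img[31:60, , ] <- 190
  img <- img + array(rnorm(length(img), 0, 5), dim(img))
  ds <- layered_dataset(img)
  sp <- slic_partition(ds, target_size = 125)
  lab <- sp$labels
  cross <- lab[-1, , ] != lab[-60, , ]
  edge <- abs(img3d(ds)[-1, , ] - img3d(ds)[-60, , ]) > 60
  expect_gte(sum(cross & edge) / sum(edge), 0.95)  # boundary recall
})

test_that("graph-cut equals exhaustive min-cut enumeration on small graphs", {
  set.seed(11)
  agree <- 0
  n_inst <- 100
  for (rep in seq_len(n_inst)) {
    n <- sample(4:12, 1)
    edges <- random_region_graph(n)
    means <- runif(n, 0, 255)
    sp <- make_toy_partition(n, edges, means)
    ob <- sample(n, 1); bg <- sample(setdiff(1:n, ob), 1)
    seeds <- seed_labels(matrix(c(ob, 1, 1), 1), matrix(c(bg, 1, 1), 1),
                         shape = c(n, 1, 1))
    sigma <- 12
    seg <- graphcut_segment(sp, seeds, sigma = sigma)
    w <- exp(-abs(means[edges[, 1]] - means[edges[, 2]]) / sigma)
    got <- cut_cost(as.integer(seg[, 1, 1]), edges, w)
    best <- min_cut_exhaustive(n, edges, w, ob, bg)
    if (abs(got - best) < 1e-9) agree <- agree + 1
    # seed sides always respected
    expect_equal(seg[ob, 1, 1], 1L)
    expect_equal(seg[bg, 1, 1], 0L)
  }
  expect_equal(agree, n_inst)
})

test_that("graph-cut recovers a seeded blob and honors degenerate seeds", {
  ph <- make_phantom(phantom_spec(shape = c(64, 64, 32), background = 50,
    noise_sd = 8, objects = list(list(kind = "sphere", n = 1,
      radius = c(10, 10), intensity = 200)), seed = 5))
  sp <- slic_partition(ph$ds, target_size = 27)
  w <- which(ph$gt == 1, arr.ind = TRUE)
  seeds <- seed_labels(w[round(nrow(w) / 2), , drop = FALSE],
                       rbind(c(3, 3, 3), c(60, 60, 30)),
                       shape = ds_dim(ph$ds))
  seg <- graphcut_segment(sp, seeds)
  expect_gte(dice(seg, ph$gt == 1), 0.95)
  # result stable across a sigma rescaling (cut topology unchanged)
  seg2 <- graphcut_segment(sp, seeds, sigma = 25)
  expect_gte(dice(seg2, seg), 0.98)
  # all supervoxels seeded object -> everything object
  all_ob <- seed_labels(array(1L, ds_dim(ph$ds)),
                        matrix(c(1, 1, 1), 1), shape = ds_dim(ph$ds))
  expect_error(graphcut_segment(sp, all_ob), "both classes")
})

test_that("watershed assignment equals the R priority-flood oracle on small grids", {
  set.seed(12)
  agree <- 0
  n_inst <- 100
  for (rep in seq_len(n_inst)) {
    nx <- sample(5:12, 1); ny <- sample(5:12, 1)
    relief <- matrix(sample(nx * ny), nx, ny)  # unique values: tie-free
    pos <- sample(nx * ny, 2)
    coords <- cbind(arrayInd(pos, c(nx, ny)), 1)
    got <- watershed_markered(array(relief, c(nx, ny, 1)),
      seed_labels(coords[1, , drop = FALSE], coords[2, , drop = FALSE],
                  shape = c(nx, ny, 1)))
    mk <- matrix(0L, nx, ny); mk[pos[1]] <- 1L; mk[pos[2]] <- 2L
    want <- flood_oracle_2d(relief, mk)
    if (identical(got$labels[, , 1], want)) agree <- agree + 1
  }
  expect_equal(agree, n_inst)
})

test_that("two seeded slice scribbles segment a membrane-bounded nucleus in 3-D", {
  np <- make_nucleus_phantom(shape = c(64, 64, 64), radius = 20, seed = 6)
  d3 <- ds_dim(np$ds)
  zc <- round(np$center[3])
  ob <- matrix(c(round(np$center[1]), round(np$center[2]), zc), 1)
  bg <- rbind(c(3, 3, zc), c(60, 60, zc), c(3, 60, zc), c(60, 3, zc))
  # the membrane provides the boundary: gradient relief from the image
  sw <- watershed_markered(np$ds, seed_labels(ob, bg, shape = d3),
                           use_gradient = TRUE)
  expect_gte(dice(sw$object, np$gt == 1), 0.9)
  expect_true(all(sw$labels %in% c(1L, 2L)))  # every voxel assigned
  # adding a background marker never enlarges the object
  bg2 <- rbind(bg, c(32, 3, zc))
  sw2 <- watershed_markered(np$ds, seed_labels(ob, bg2, shape = d3),
                            use_gradient = TRUE)
  expect_lte(sum(sw2$object), sum(sw$object))
  expect_error(watershed_markered(255 - img3d(np$ds),
    structure(list(object = integer(), background = 5L),
              class = "SeedLabels")), "marker")
})

test_that("object separation splits fused spheres at the analytic bisector", {
  fp <- make_fused_pair(radius = 10, center_distance = 14, seed = 7)
  bin <- (img3d(fp$ds) < 100) + 0L
  expect_equal(max(label_objects(bin, "3d")$labels), 1)  # rendered as one
  lab <- separate_objects(bin, min_depth = 2)
  expect_equal(max(lab), 2)
  a <- lab[-dim(lab)[1], , ]; b <- lab[-1, , ]
  bd <- which(a > 0 & b > 0 & a != b, arr.ind = TRUE)
  expect_lte(abs(mean(bd[, 1]) + 0.5 - fp$split_plane_x), 2)
  # single sphere is not oversplit at the default depth
  one <- make_phantom(phantom_spec(shape = c(40, 40, 40), noise_sd = 0,
    objects = list(list(kind = "sphere", n = 1, radius = c(9, 9),
                        intensity = 40)), seed = 9))
  expect_equal(max(separate_objects((img3d(one$ds) < 100) + 0L,
                                    min_depth = 2)), 1)
  expect_error(separate_objects(array(0L, c(5, 5, 5))), "empty")
})

test_that("anisotropy-aware separation succeeds where the naive one fails", {
  fpa <- make_fused_pair(radius = 50, center_distance = 70,
                         voxel_size = c(5, 5, 25), seed = 8)
  bina <- (img3d(fpa$ds) < 100) + 0L
  laba <- separate_objects(bina, voxel_size = c(5, 5, 25),
                           anisotropy_aware = TRUE, min_depth = 10)
  expect_equal(max(laba), 2)
  a <- laba[-dim(laba)[1], , ]; b <- laba[-1, , ]
  bd <- which(a > 0 & b > 0 & a != b, arr.ind = TRUE)
  expect_lte(abs((mean(bd[, 1]) + 0.5) * 5 - fpa$split_plane_x), 10)
  # voxel-unit distances at the same suppression depth miss the split
  lab0 <- separate_objects(bina, voxel_size = c(5, 5, 25),
                           anisotropy_aware = FALSE, min_depth = 10)
  expect_lt(max(lab0), 2)
})

test_that("separation never merges previously disconnected components", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 24), noise_sd = 0,
    objects = list(list(kind = "sphere", n = 4, radius = c(3, 5),
                        intensity = 40)), seed = 10))
  bin <- (ph$gt > 0) + 0L
  n_in <- max(label_objects(bin, "3d")$labels)
  lab <- separate_objects(bin, min_depth = 1)
  expect_gte(max(lab), n_in)
  # voxels of different input components never share an output label
  lin <- label_objects(bin, "3d")$labels
  tab <- table(lin[lin > 0], lab[lin > 0])
  expect_true(all(colSums(tab > 0) <= 1))
})

test_that("membrane feature stack has the documented schema and ridge polarity", {
  ds <- layered_dataset(array(90, c(20, 20, 2)))
  fx <- membrane_features(ds, context_radius = 4, scales = c(1, 2))
  expect_equal(ncol(fx$x), 2 * 4 + 1 + 8)
  expect_match(fx$schema, "membrane_v1")
  # derivative features of a constant image are all zero
  deriv_cols <- c(2, 3, 4, 6, 7, 8, 9)
  expect_lt(max(abs(fx$x[, deriv_cols])), 1e-9)
  # dark 2-px line: most-negative Hessian eigenvalue is NOT at the line --
  # dark ridge polarity means the largest positive eigenvalue sits there
  img <- array(200, c(30, 30, 1)); img[, 15:16, 1] <- 40
  dl <- layered_dataset(img)
  fl <- membrane_features(dl, scales = c(1, 2))
  lam_max <- matrix(fl$x[, 3], 30, 30)  # larger eigenvalue at scale 1
  expect_gt(mean(lam_max[, 15]), mean(lam_max[, 5]))
  expect_error(membrane_features(ds, scales = numeric()), "scales")
})

test_that("supervoxel features include ordered quantiles and neighbour context", {
  ds <- layered_dataset(array(77, c(24, 24, 12)))
  sp <- slic_partition(ds, target_size = 64)
  fx <- supervoxel_features(ds, sp)
  expect_equal(nrow(fx$x), sp$n_regions)
  # constant image: all rows identical
  expect_lt(max(apply(fx$x, 2, function(c) diff(range(c)))), 1e-9)
  # quantile columns are monotone within each row
  qcols <- grep("^q", colnames(fx$x))
  qm <- fx$x[, qcols, drop = FALSE]
  expect_true(all(apply(qm, 1, function(r) all(diff(r) >= 0))))
  # neighbour features fall back to own features without neighbours
  ds1 <- layered_dataset(array(50, c(4, 4, 2)))
  sp1 <- slic_partition(ds1, target_size = 32)
  if (sp1$n_regions == 1) {
    f1 <- supervoxel_features(ds1, sp1)
    own <- f1$x[, !grepl("^nbr_", colnames(f1$x))]
    nbr <- f1$x[, grepl("^nbr_", colnames(f1$x))]
    expect_equal(unname(nbr), unname(own))
  }
})

test_that("classifier training is seed-deterministic and robust to label noise", {
  set.seed(13)
  n <- 300
  X <- rbind(matrix(rnorm(n * 6, 0), n, 6), matrix(rnorm(n * 6, 3), n, 6))
  y <- rep(c(1L, 2L), each = n)
  m <- train_classifier(X, y, "supervoxel", n_trees = 50, seed = 9,
                        schema = "s")
  expect_equal(m$training_accuracy, 1)
  m2 <- train_classifier(X, y, "supervoxel", n_trees = 50, seed = 9,
                         schema = "s")
  Xn <- matrix(rnorm(200 * 6, 1.5), 200, 6)
  expect_identical(predict_classifier(m, Xn, schema = "s")$prob,
                   predict_classifier(m2, Xn, schema = "s")$prob)
  # 10% label noise on separable data: held-out accuracy >= 90%
  yn <- y
  flip <- sample(length(y), length(y) * 0.1)
  yn[flip] <- 3L - yn[flip]
  tr <- sample(length(y), 400)
  mnoise <- train_classifier(X[tr, ], yn[tr], "supervoxel", n_trees = 100,
                             seed = 4, schema = "s")
  pred <- predict_classifier(mnoise, X[-tr, ], schema = "s")
  held <- ifelse(pred$prob >= 0.5, 1L, 2L)
  expect_gte(mean(held == y[-tr]), 0.9)
  # single-class labels are an error
  expect_error(train_classifier(X, rep(1L, 2 * n), "supervoxel"),
               "single-class|>= 10")
  # persistence round trip enforces schema
  f <- tempfile(fileext = ".rds")
  save_classifier(m, f)
  ml <- load_classifier(f)
  expect_error(predict_classifier(ml, list(x = X, schema = "t")), "schema")
  expect_identical(predict_classifier(ml, X, schema = "s")$prob,
                   predict_classifier(m, X, schema = "s")$prob)
})

test_that("probabilities are in [0,1] and supervoxel painting is constant per region", {
  np <- make_network_phantom(shape = c(48, 48, 24), polarity = "bright",
                             seed = 10)
  sp <- slic_partition(np$ds, target_size = 12)
  fx <- supervoxel_features(np$ds, sp)
  reg_gt <- tapply(as.vector(np$gt > 0), as.vector(sp$labels), mean)
  y <- ifelse(reg_gt > 0.5, 1L, 2L)
  m <- train_classifier(fx, y, "supervoxel", n_trees = 60, seed = 2)
  pr <- predict_classifier(m, fx, sp = sp)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  rng <- tapply(as.vector(pr$prob), as.vector(sp$labels),
                function(v) diff(range(v)))
  expect_lt(max(rng), 1e-12)
})
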