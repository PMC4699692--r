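set.seed(101)

make_ds <- function(shape = c(24, 24, 12), voxel = c(5, 5, 10)) {
  layered_dataset(array(sample(0:255, prod(shape), TRUE), shape),
                  voxel_size = voxel)
}

test_that("crop shifts the bounding box and flip is an involution", {
  ds <- make_ds(c(30, 30, 30), c(5, 5, 5))
  dc <- ds_transform(ds, "crop", box = list(x = c(11, 20)))
  expect_equal(ds_dim(dc), c(10L, 30L, 30L))
  expect_equal(unname(dc$geometry$bbox_min[1]), 50)
  df <- ds_transform(ds_transform(ds, "flip", axis = "y"), "flip", axis = "y")
  expect_identical(df$image, ds$image)
  expect_error(ds_transform(ds, "crop", box = list(x = c(0, 40))), "crop box")
})

test_that("resize preserves the physical extent two ways", {
  ds <- layered_dataset(array(runif(40^3) * 255, c(40, 40, 40)),
                        voxel_size = c(3, 3, 3))
  before <- physical_extent(ds)
  dr <- ds_transform(ds, "resize", factor = 0.5)
  expect_equal(ds_dim(dr), c(20L, 20L, 20L))
  expect_equal(unname(dr$geometry$voxel_size), c(6, 6, 6))
  expect_equal(physical_extent(dr), before)
  # independent route: extent = shape * voxel_size recomputed from scratch
  expect_equal(unname(ds_dim(dr) * dr$geometry$voxel_size),
               unname(ds_dim(ds) * ds$geometry$voxel_size))
})

test_that("transforms move all four layers identically", {
  ds <- make_ds()
  sel <- array(0L, ds_dim(ds)); sel[3:6, 3:6, 2] <- 1L
  ds <- set_layer(ds, "selection", sel)
  ds <- add_material(ds, "m1")
  mod <- array(0L, ds_dim(ds)); mod[10:12, 10:12, 5] <- 1L
  ds <- set_layer(ds, "model", mod)
  for (args in list(list(mode = "flip", axis = "x"),
                    list(mode = "rotate90", k = 1L),
                    list(mode = "transpose", perm = c("y", "x", "z")),
                    list(mode = "crop", box = list(z = c(1, 8))))) {
    tr <- do.call(ds_transform, c(list(ds), args))
    expect_identical(dim(tr$selection), dim(tr$model))
    expect_identical(dim(tr$selection)[1:2], dim(tr$image)[1:2])
    expect_equal(sum(tr$selection), sum(ds$selection))
    expect_equal(sum(tr$model), sum(ds$model))
  }
})

test_that("physical center of a marked voxel is invariant under crop and rotate90 round trips", {
  ds <- make_ds(c(20, 16, 8), c(2, 3, 5))
  mark <- c(7, 9, 4)
  phys0 <- ds$geometry$bbox_min + (mark - 0.5) * ds$geometry$voxel_size
  dc <- ds_transform(ds, "crop", box = list(x = c(3, 18), y = c(2, 14)))
  mark_c <- mark - c(2, 1, 0)
  phys_c <- dc$geometry$bbox_min + (mark_c - 0.5) * dc$geometry$voxel_size
  expect_equal(unname(phys_c), unname(phys0))
  # four quarter turns restore the voxel grid exactly
  dr <- ds
  for (i in 1:4) dr <- ds_transform(dr, "rotate90", k = 1)
  expect_identical(dr$image, ds$image)
  expect_equal(dr$geometry$voxel_size, ds$geometry$voxel_size)
})

test_that("undo restores bit-exact state and stacks are bounded per scope", {
  ds <- layered_dataset(array(7, c(10, 10, 4)), depth_2d = 2, depth_3d = 2)
  ds <- set_layer(ds, "selection", array(0L, ds_dim(ds)))
  before <- get_layer(ds, "selection")
  edit_k <- function(k) function(d) {
    s <- get_layer(d, "selection"); s[k, k, 1] <- 1L; d$selection <- s; d
  }
  ds1 <- undoable_edit(ds, edit_k(1), "3d")
  expect_identical(get_layer(undo_edit(ds1, "3d"), "selection"), before)
  # depth 2: three edits, only two undos succeed
  d3 <- undoable_edit(undoable_edit(ds1, edit_k(2), "3d"), edit_k(3), "3d")
  u1 <- undo_edit(d3, "3d"); u2 <- undo_edit(u1, "3d")
  expect_warning(u3 <- undo_edit(u2, "3d"), "nothing to undo")
  expect_identical(u3$selection, u2$selection)
  expect_equal(sum(u2$selection), 1)  # oldest state evicted; edit 1 remains
  # undo then redo restores the exact pre-undo state
  r1 <- redo_edit(u2, "3d")
  expect_identical(r1$selection, u1$selection)
})

test_that("interleaved 2-D and 3-D edits undo independently per scope", {
  ds <- layered_dataset(array(0, c(8, 8, 4)))
  ds <- set_layer(ds, "selection", array(0L, ds_dim(ds)))
  e2 <- function(d) { s <- d$selection; s[1, 1, 2] <- 1L; d$selection <- s; d }
  e3 <- function(d) { s <- d$selection; s[5, 5, ] <- 1L; d$selection <- s; d }
  ds <- undoable_edit(ds, e2, "2d", slice = 2)
  ds <- undoable_edit(ds, e3, "3d")
  # undoing the 3-D edit leaves the 2-D edit in place
  u <- undo_edit(ds, "3d")
  expect_equal(u$selection[1, 1, 2], 1L)
  expect_equal(sum(u$selection[5, 5, ]), 0L)
  u2 <- undo_edit(u, "2d")
  expect_equal(sum(u2$selection), 0L)
})

test_that("chop tiles exactly, round-trips bit-exactly, and unions coordinates", {
  ds <- make_ds(c(30, 30, 16))
  ds <- add_material(ds, "blob")
  mod <- array(0L, ds_dim(ds)); mod[5:10, 5:10, 5:10] <- 1L
  ds <- set_layer(ds, "model", mod)
  for (grid in list(c(1, 1, 1), c(2, 2, 1), c(3, 2, 2))) {
    ch <- ds_chop(ds, grid)
    ra <- ds_reassemble(ch$blocks, ch$plan)
    expect_identical(ra$image, ds$image)
    expect_identical(ra$model, ds$model)
    # blocks' voxel coordinate union equals the original coordinate set
    pb <- ch$plan$blocks
    covered <- array(FALSE, ds_dim(ds))
    for (i in seq_len(nrow(pb)))
      covered[pb$x0[i]:pb$x1[i], pb$y0[i]:pb$y1[i], pb$z0[i]:pb$z1[i]] <- TRUE
    expect_true(all(covered))
  }
  # block geometry offsets
  ch <- ds_chop(ds, c(2, 1, 1))
  expect_equal(unname(ch$blocks[[2]]$geometry$bbox_min[1]),
               unname(ds$geometry$bbox_min[1] + 15 * 5))
  expect_error(ds_chop(ds, c(2, 1, 1), overlap = 20), "overlap")
})

test_that("chop with overlap round-trips and later block wins conflicts", {
  ds <- make_ds(c(24, 24, 8))
  ch <- ds_chop(ds, c(2, 2, 1), overlap = 3)
  expect_identical(ds_reassemble(ch$blocks, ch$plan)$image, ds$image)
  # edit overlap zone in block 1 only; block 2 (later) must win there
  b <- ch$blocks
  b[[1]]$image[] <- 0
  ra <- ds_reassemble(b, ch$plan)
  pb <- ch$plan$blocks
  ov_x <- pb$x0[2]:pb$x1[1]  # columns covered by both blocks 1 and 2
  expect_identical(ra$image[ov_x, pb$y0[1]:pb$y1[1], , ],
                   ds$image[ov_x, pb$y0[1]:pb$y1[1], , ])
})

test_that("reassembly reconciles material tables by name", {
  ds <- make_ds(c(16, 16, 4))
  ch <- ds_chop(ds, c(2, 1, 1))
  b <- ch$blocks
  b[[1]] <- add_material(b[[1]], "mito")
  m1 <- array(0L, ds_dim(b[[1]])); m1[1:2, 1:2, 1] <- 1L
  b[[1]] <- set_layer(b[[1]], "model", m1)
  b[[2]] <- add_material(b[[2]], "er")
  b[[2]] <- add_material(b[[2]], "mito")
  m2 <- array(0L, ds_dim(b[[2]])); m2[1:2, 1:2, 1] <- 1L; m2[3:4, 3:4, 1] <- 2L
  b[[2]] <- set_layer(b[[2]], "model", m2)
  ra <- ds_reassemble(b, ch$plan)
  expect_setequal(ra$materials$name, c("mito", "er"))
  mito_id <- ra$materials$id[ra$materials$name == "mito"]
  expect_equal(sum(ra$model == mito_id), 4 + 4)  # both blocks' mito voxels
  expect_error(ds_reassemble(b[1], ch$plan), "missing")
})

test_that("every mutating operation appends exactly one log entry", {
  ds <- make_ds()
  n0 <- nrow(action_log(ds))
  ds <- ds_transform(ds, "flip", axis = "x")
  ds <- adjust_display(ds, 10, 1.1, 1.2)
  ds <- threshold_bw(ds, c(0, 128))
  expect_equal(nrow(action_log(ds)), n0 + 3)
  expect_equal(tail(action_log(ds)$op, 3),
               c("transform", "adjust_display", "threshold_bw"))
})

test_that("layer-shape congruence holds after random op sequences", {
  ds <- make_ds(c(20, 18, 10))
  ds <- set_layer(ds, "selection", array(0L, ds_dim(ds)))
  ds <- set_layer(ds, "mask", array(1L, ds_dim(ds)))
  ops <- list(
    function(d) ds_transform(d, "flip", axis = sample(c("x", "y", "z"), 1)),
    function(d) ds_transform(d, "rotate90", k = sample(0:3, 1)),
    function(d) ds_transform(d, "transpose",
                             perm = sample(c("x", "y", "z"))),
    function(d) ds_transform(d, "crop",
                             box = list(x = sort(sample(ds_dim(d)[1], 2)))))
  for (rep in 1:10) {
    d <- ds
    for (k in 1:4) d <- ops[[sample(length(ops), 1)]](d)
    expect_identical(dim(d$selection), dim(d$mask))
    expect_identical(unname(dim(d$image)[c(1, 2, 4)]), dim(d$selection))
  }
})

test_that("model layer validation enforces the material table contract", {
  ds <- make_ds(c(8, 8, 2))
  bad <- array(0L, ds_dim(ds)); bad[1, 1, 1] <- 3L
  expect_error(set_layer(ds, "model", bad), "material")
  expect_error(add_material(add_material(ds, "a"), "a"), "already present")
})
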