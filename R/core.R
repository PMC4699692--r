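#' @useDynLib volseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm runif sd
#' @importFrom utils head tail write.table read.delim
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Volume geometry: voxel size and bounding box
#'
#' Describes the physical calibration of a dataset: the voxel (volume pixel)
#' dimensions, the length unit, and the physical coordinate of the dataset
#' origin.  Every spatial transform of a dataset adjusts the geometry so that
#' voxel indices can always be mapped to physical coordinates.  The physical
#' position of voxel `i` (0-based) along an axis is
#' `bbox_min + (i + 0.5) * voxel_size`.
#'
#' @param voxel_size numeric length-3, physical size of one voxel along
#'   x, y, z. Must be positive.
#' @param units length-unit name, e.g. `"nm"` or `"um"`.
#' @param bbox_min physical coordinate of the dataset origin (x0, y0, z0).
#' @param axis4 semantics of the fourth (stack) axis: `"Z"` for volumes or
#'   `"Time"` for time-lapse series.  The semantic axis order of a dataset is
#'   always X:Y:Color:Z or X:Y:Color:Time.
#' @return an object of class `VolumeGeometry`.
#' @export
volume_geometry <- function(voxel_size = c(1, 1, 1), units = "nm",
                            bbox_min = c(0, 0, 0), axis4 = c("Z", "Time")) {
  axis4 <- match.arg(axis4)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(bbox_min) == 3)
  structure(list(voxel_size = stats::setNames(voxel_size, c("x", "y", "z")),
                 units = units,
                 bbox_min = stats::setNames(as.numeric(bbox_min),
                                            c("x", "y", "z")),
                 axis4 = axis4),
            class = "VolumeGeometry")
}

#' @export
print.VolumeGeometry <- function(x, ...) {
  cat(sprintf("<VolumeGeometry> voxel %s %s, bbox_min (%s), axis4 %s\n",
              paste(signif(x$voxel_size, 6), collapse = "x"), x$units,
              paste(signif(x$bbox_min, 6), collapse = ", "), x$axis4))
  invisible(x)
}

#' Physical extent of a dataset along the spatial axes
#' @param ds a `LayeredDataset`
#' @return named numeric length-3: shape times voxel size per axis.
#' @export
physical_extent <- function(ds) {
  ds_dim(ds) * ds$geometry$voxel_size
}

#' Material table for model layers
#'
#' Ordered table of model materials.  Ids are unique and contiguous from 1;
#' label 0 always means background.
#'
#' @param names character vector of unique material names.
#' @param colors optional vector of colors (any R color); defaults to a
#'   distinct palette.
#' @return data.frame with columns `id`, `name`, `color`.
#' @export
material_table <- function(names = character(), colors = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("material names must be unique")
  n <- length(names)
  if (is.null(colors)) colors <- grDevices::hcl.colors(max(n, 2), "Dark 3")[seq_len(n)]
  data.frame(id = seq_len(n), name = names,
             color = grDevices::rgb(t(grDevices::col2rgb(colors)), maxColorValue = 255),
             stringsAsFactors = FALSE)
}

validate_materials <- function(mt) {
  stopifnot(is.data.frame(mt), all(c("id", "name", "color") %in% names(mt)))
  if (nrow(mt) && !identical(mt$id, seq_len(nrow(mt))))
    stop("material ids must be contiguous from 1")
  if (anyDuplicated(mt$name)) stop("material names must be unique")
  invisible(mt)
}

#' Four-layer volumetric dataset
#'
#' The central state object: a grayscale or multichannel image volume plus
#' three annotation layers sharing one geometry.
#' \itemize{
#'   \item \strong{Image}: the raw data, unsigned 8- or 16-bit values.
#'   \item \strong{Selection}: binary working layer written by segmentation
#'     tools.
#'   \item \strong{Mask}: optional binary layer for staging results and
#'     restricting operations.
#'   \item \strong{Model}: small-integer label layer holding the final
#'     segmentation, with a material table naming each label.
#' }
#' Annotation layers always have the same spatial shape as the image and are
#' allocated lazily (a missing layer reads as all zero).  Every mutating
#' operation appends one entry to the action log.
#'
#' @param image numeric array: 2-D (x, y), 3-D (x, y, z) or 4-D
#'   (x, y, color, z).
#' @param voxel_size,units,bbox_min,axis4 see [volume_geometry()].
#' @param bitdepth 8 or 16; values are clipped to this range by image ops.
#' @param depth_2d,depth_3d maximum undo history depth per scope.
#' @return an object of class `LayeredDataset`.
#' @export
layered_dataset <- function(image, voxel_size = c(1, 1, 1), units = "nm",
                            bbox_min = c(0, 0, 0), axis4 = "Z",
                            bitdepth = 8, depth_2d = 3, depth_3d = 3) {
  d <- dim(image)
  if (is.null(d)) stop("image must be an array")
  image <- if (length(d) == 2) array(image, c(d, 1, 1))
           else if (length(d) == 3) array(image, c(d[1], d[2], 1, d[3]))
           else if (length(d) == 4) image
           else stop("image must have 2-4 dimensions")
  if (!bitdepth %in% c(8, 16)) stop("bitdepth must be 8 or 16")
  storage.mode(image) <- "double"
  ds <- structure(list(
    image = image,
    selection = NULL, mask = NULL, model = NULL,
    materials = material_table(),
    geometry = volume_geometry(voxel_size, units, bbox_min, axis4),
    bitdepth = bitdepth,
    log = list(),
    history = list(depth_2d = depth_2d, depth_3d = depth_3d,
                   undo_2d = list(), undo_3d = list(),
                   redo_2d = list(), redo_3d = list())
  ), class = "LayeredDataset")
  log_action(ds, "create", list(shape = dim(image)))
}

#' @export
print.LayeredDataset <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<LayeredDataset> %dx%d, %d channel(s), %d %s slice(s), %d-bit\n",
              d[1], d[2], d[3], d[4], tolower(x$geometry$axis4), x$bitdepth))
  print(x$geometry)
  cat(sprintf("  layers: selection[%s] mask[%s] model[%s, %d material(s)]\n",
              if (is.null(x$selection)) "-" else "x",
              if (is.null(x$mask)) "-" else "x",
              if (is.null(x$model)) "-" else "x", nrow(x$materials)))
  cat(sprintf("  action log: %d entries\n", length(x$log)))
  invisible(x)
}

#' Spatial shape of a dataset
#' @param ds a `LayeredDataset`
#' @return integer length-3 (nx, ny, nz)
#' @export
ds_dim <- function(ds) {
  d <- dim(ds$image)
  as.integer(d[c(1, 2, 4)])
}

#' Grayscale view of the image layer
#' @param ds a `LayeredDataset`
#' @param channel color channel to extract
#' @return 3-D numeric array (x, y, z)
#' @export
img3d <- function(ds, channel = 1) {
  array(ds$image[, , channel, ], ds_dim(ds))
}

dtype_max <- function(ds) if (ds$bitdepth == 8) 255 else 65535

clip_dtype <- function(x, ds) {
  x[x < 0] <- 0
  m <- dtype_max(ds)
  x[x > m] <- m
  x
}

#' Read an annotation layer (zero-filled if not yet allocated)
#' @param ds a `LayeredDataset`
#' @param layer `"selection"`, `"mask"` or `"model"`
#' @return 3-D integer array
#' @export
get_layer <- function(ds, layer = c("selection", "mask", "model")) {
  layer <- match.arg(layer)
  ds[[layer]] %||% array(0L, ds_dim(ds))
}

#' Replace an annotation layer
#'
#' The replacement must match the spatial shape of the image; selection and
#' mask are coerced to 0/1, model labels must fit the material table.
#' @param ds a `LayeredDataset`
#' @param layer `"selection"`, `"mask"` or `"model"`
#' @param value 3-D array (or logical)
#' @param op log-entry operation name
#' @return the updated dataset
#' @export
set_layer <- function(ds, layer = c("selection", "mask", "model"), value,
                      op = paste0("set_", layer[1])) {
  layer <- match.arg(layer)
  value <- array(as.integer(value), dim(value) %||% length(value))
  if (!identical(as.integer(dim(value)), as.integer(unname(ds_dim(ds)))))
    stop("layer shape must match image spatial shape")
  if (layer != "model") {
    value[value != 0L] <- 1L
  } else {
    mx <- max(value)
    if (mx > 255) stop("model labels are 8-bit: at most 255 materials")
    if (mx > nrow(ds$materials))
      stop("model contains labels without a material table entry")
  }
  ds[[layer]] <- value
  log_action(ds, op, list(layer = layer))
}

#' Add a material to the model material table
#' @param ds a `LayeredDataset`
#' @param name unique material name
#' @param color material color
#' @return the updated dataset (new material id is `nrow(ds$materials)`)
#' @export
add_material <- function(ds, name, color = NULL) {
  if (name %in% ds$materials$name) stop("material name already present: ", name)
  if (nrow(ds$materials) >= 255) stop("at most 255 materials")
  id <- nrow(ds$materials) + 1L
  col <- if (is.null(color)) grDevices::hcl.colors(25, "Dark 3")[(id - 1L) %% 25 + 1L] else color
  ds$materials <- rbind(ds$materials,
                        data.frame(id = id, name = name,
                                   color = grDevices::rgb(t(grDevices::col2rgb(col)),
                                                          maxColorValue = 255)))
  log_action(ds, "add_material", list(id = id, name = name))
}

# -- action log --------------------------------------------------------------

#' Append an entry to the dataset action log
#'
#' Every image-processing manipulation is logged; logs are serialized with
#' the dataset so a processing history travels with the data.
#' @param ds a `LayeredDataset`
#' @param op operation name
#' @param params parameter record (list of simple values)
#' @return the updated dataset
#' @export
log_action <- function(ds, op, params = list()) {
  ds$log[[length(ds$log) + 1L]] <- list(
    time = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
    op = op, params = params)
  ds
}

#' The dataset action log as a data.frame
#' @param ds a `LayeredDataset`
#' @return data.frame with columns `time`, `op`, `params` (deparsed)
#' @export
action_log <- function(ds) {
  data.frame(
    time = vapply(ds$log, `[[`, "", "time"),
    op = vapply(ds$log, `[[`, "", "op"),
    params = vapply(ds$log, function(e)
      paste(deparse(e$params, width.cutoff = 500), collapse = ""), ""),
    stringsAsFactors = FALSE)
}

# -- undo history ------------------------------------------------------------

snapshot_layers <- function(ds) ds[c("image", "selection", "mask", "model", "materials")]

#' Apply a reversible edit with bounded undo
#'
#' Pushes the pre-edit state onto the history stack for the given scope, then
#' applies the edit.  2-D edits snapshot only the affected slice of every
#' layer; 3-D edits snapshot whole layers.  Each scope keeps its own bounded
#' stack (`depth_2d` / `depth_3d` of the dataset); pushing beyond the depth
#' evicts the oldest snapshot.
#'
#' @param ds a `LayeredDataset`
#' @param edit function taking and returning a `LayeredDataset`; it must not
#'   change the spatial shape (use [ds_transform()] for that).
#' @param scope `"2d"` (single-slice edit) or `"3d"`
#' @param slice 1-based slice index, required for scope `"2d"`
#' @return the edited dataset
#' @seealso [undo_edit()], [redo_edit()]
#' @export
undoable_edit <- function(ds, edit, scope = c("3d", "2d"), slice = NULL) {
  scope <- match.arg(scope)
  depth <- if (scope == "2d") ds$history$depth_2d else ds$history$depth_3d
  if (depth < 1) stop("history depth for scope ", scope, " is < 1")
  snap <- if (scope == "2d") {
    if (is.null(slice)) stop("2d scope requires a slice index")
    list(slice = slice,
         image = ds$image[, , , slice, drop = FALSE],
         selection = if (!is.null(ds$selection)) ds$selection[, , slice, drop = FALSE],
         mask = if (!is.null(ds$mask)) ds$mask[, , slice, drop = FALSE],
         model = if (!is.null(ds$model)) ds$model[, , slice, drop = FALSE],
         materials = ds$materials)
  } else snapshot_layers(ds)
  key <- paste0("undo_", scope)
  st <- ds$history[[key]]
  st[[length(st) + 1L]] <- snap
  if (length(st) > depth) st <- st[-1L]
  ds$history[[key]] <- st
  ds$history[[paste0("redo_", scope)]] <- list()
  out <- edit(ds)
  if (!identical(unname(ds_dim(out)), unname(ds_dim(ds))))
    stop("undoable_edit must not change the spatial shape")
  out
}

restore_snapshot <- function(ds, snap) {
  if (!is.null(snap$slice)) {
    s <- snap$slice
    ds$image[, , , s] <- snap$image
    if (!is.null(snap$selection)) {
      if (is.null(ds$selection)) ds$selection <- array(0L, ds_dim(ds))
      ds$selection[, , s] <- snap$selection
    }
    if (!is.null(snap$mask)) {
      if (is.null(ds$mask)) ds$mask <- array(0L, ds_dim(ds))
      ds$mask[, , s] <- snap$mask
    }
    if (!is.null(snap$model)) {
      if (is.null(ds$model)) ds$model <- array(0L, ds_dim(ds))
      ds$model[, , s] <- snap$model
    }
    ds$materials <- snap$materials
  } else {
    ds[c("image", "selection", "mask", "model", "materials")] <- snap
  }
  ds
}

take_snapshot_for <- function(ds, snap) {
  # mirror of restore: capture the current state of what snap covers
  if (!is.null(snap$slice)) {
    s <- snap$slice
    list(slice = s,
         image = ds$image[, , , s, drop = FALSE],
         selection = if (!is.null(ds$selection)) ds$selection[, , s, drop = FALSE],
         mask = if (!is.null(ds$mask)) ds$mask[, , s, drop = FALSE],
         model = if (!is.null(ds$model)) ds$model[, , s, drop = FALSE],
         materials = ds$materials)
  } else snapshot_layers(ds)
}

#' Undo the most recent edit in a scope
#'
#' 2-D and 3-D histories are independent.  Undoing on an empty stack is an
#' explicit no-op: the dataset is returned unchanged with a warning.
#' @param ds a `LayeredDataset`
#' @param scope `"2d"` or `"3d"`
#' @return the restored dataset
#' @export
undo_edit <- function(ds, scope = c("3d", "2d")) {
  scope <- match.arg(scope)
  key <- paste0("undo_", scope)
  st <- ds$history[[key]]
  if (!length(st)) {
    warning("nothing to undo in scope ", scope)
    return(ds)
  }
  snap <- st[[length(st)]]
  ds$history[[key]] <- st[-length(st)]
  rk <- paste0("redo_", scope)
  rst <- ds$history[[rk]]
  rst[[length(rst) + 1L]] <- take_snapshot_for(ds, snap)
  ds$history[[rk]] <- rst
  restore_snapshot(ds, snap)
}

#' Redo an undone edit in a scope
#' @inheritParams undo_edit
#' @return the restored dataset
#' @export
redo_edit <- function(ds, scope = c("3d", "2d")) {
  scope <- match.arg(scope)
  rk <- paste0("redo_", scope)
  rst <- ds$history[[rk]]
  if (!length(rst)) {
    warning("nothing to redo in scope ", scope)
    return(ds)
  }
  snap <- rst[[length(rst)]]
  ds$history[[rk]] <- rst[-length(rst)]
  uk <- paste0("undo_", scope)
  st <- ds$history[[uk]]
  st[[length(st) + 1L]] <- take_snapshot_for(ds, snap)
  ds$history[[uk]] <- st
  restore_snapshot(ds, snap)
}

# -- spatial transforms ------------------------------------------------------

apply_spatial <- function(ds, fimg, flayer) {
  # fimg acts on the 4-D image, flayer on 3-D annotation layers
  ds$image <- fimg(ds$image)
  for (ly in c("selection", "mask", "model"))
    if (!is.null(ds[[ly]])) ds[[ly]] <- flayer(ds[[ly]])
  ds
}

#' Spatial transforms with geometry bookkeeping
#'
#' Crop, resize, flip, rotate (multiples of 90 degrees in the XY plane) or
#' transpose a dataset.  All four layers are transformed identically and the
#' geometry is adjusted with respect to the performed action: cropping shifts
#' `bbox_min`, resizing rescales `voxel_size` so the physical extent is
#' preserved, rotation/transposition permute the voxel dimensions.
#' Annotation layers are always resampled nearest-neighbour; the image may
#' additionally use linear interpolation.
#'
#' @param ds a `LayeredDataset`
#' @param mode one of `"crop"`, `"resize"`, `"flip"`, `"rotate90"`,
#'   `"transpose"`
#' @param box for crop: list with 1-based inclusive index ranges
#'   `x = c(lo, hi)`, `y = ...`, `z = ...` (missing axes keep full range)
#' @param factor for resize: scalar or length-3 scale factor (> 0)
#' @param shape for resize: alternative target spatial shape
#' @param method for resize: `"nearest"` (default) or `"linear"`
#'   (image layer only)
#' @param axis for flip: `"x"`, `"y"` or `"z"`
#' @param k for rotate90: number of 90-degree counter-clockwise turns
#' @param perm for transpose: permutation of `c("x","y","z")`
#' @return the transformed dataset, with one action-log entry appended
#' @export
ds_transform <- function(ds, mode = c("crop", "resize", "flip", "rotate90",
                                      "transpose"),
                         box = NULL, factor = NULL, shape = NULL,
                         method = c("nearest", "linear"),
                         axis = "x", k = 1L, perm = c("y", "x", "z")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  d <- ds_dim(ds)
  g <- ds$geometry
  if (mode == "crop") {
    rng <- lapply(c(x = 1, y = 2, z = 3), function(a) c(1L, d[a]))
    for (a in names(box)) rng[[a]] <- as.integer(box[[a]])
    for (a in c("x", "y", "z")) {
      r <- rng[[a]]
      if (r[1] < 1 || r[2] > d[match(a, c("x", "y", "z"))] || r[1] > r[2])
        stop("crop box outside volume on axis ", a)
    }
    ix <- rng$x[1]:rng$x[2]; iy <- rng$y[1]:rng$y[2]; iz <- rng$z[1]:rng$z[2]
    ds <- apply_spatial(ds,
      function(im) im[ix, iy, , iz, drop = FALSE],
      function(la) la[ix, iy, iz, drop = FALSE])
    off <- c(rng$x[1], rng$y[1], rng$z[1]) - 1L
    g$bbox_min <- g$bbox_min + off * g$voxel_size
    ds$geometry <- g
    return(log_action(ds, "transform", list(mode = "crop", box = rng)))
  }
  if (mode == "resize") {
    if (is.null(shape)) {
      if (is.null(factor)) stop("resize needs factor or shape")
      factor <- rep(as.numeric(factor), length.out = 3)
      if (any(factor <= 0)) stop("resize factors must be > 0")
      shape <- pmax(1L, as.integer(round(d * factor)))
    }
    shape <- as.integer(rep(shape, length.out = 3))
    idx <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) / shape[a] * d[a] + 0.5)
    nn <- lapply(1:3, function(a) pmin(pmax(as.integer(round(idx[[a]])), 1L), d[a]))
    resize_nn <- function(la) la[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    resize_img <- function(im) {
      if (method == "nearest") return(im[nn[[1]], nn[[2]], , nn[[3]], drop = FALSE])
      out <- array(0, c(shape[1], shape[2], dim(im)[3], shape[3]))
      lo <- lapply(seq_along(idx), function(a)
        pmin(pmax(as.integer(floor(idx[[a]])), 1L), d[a]))
      hi <- lapply(seq_along(idx), function(a) pmin(lo[[a]] + 1L, d[a]))
      fr <- lapply(seq_along(idx), function(a) pmin(pmax(idx[[a]] - lo[[a]], 0), 1))
      for (ch in seq_len(dim(im)[3])) {
        v <- array(im[, , ch, ], d)
        # trilinear by successive 1-D blends
        a1 <- v[lo[[1]], , , drop = FALSE] * (1 - fr[[1]]) + v[hi[[1]], , , drop = FALSE] * fr[[1]]
        a2 <- a1[, lo[[2]], , drop = FALSE] * rep(1 - fr[[2]], each = shape[1]) +
              a1[, hi[[2]], , drop = FALSE] * rep(fr[[2]], each = shape[1])
        a3 <- a2[, , lo[[3]], drop = FALSE] * rep(1 - fr[[3]], each = shape[1] * shape[2]) +
              a2[, , hi[[3]], drop = FALSE] * rep(fr[[3]], each = shape[1] * shape[2])
        out[, , ch, ] <- a3
      }
      out
    }
    ds <- apply_spatial(ds, resize_img, resize_nn)
    g$voxel_size <- g$voxel_size * d / shape   # physical extent preserved
    ds$geometry <- g
    return(log_action(ds, "transform",
                      list(mode = "resize", shape = shape, method = method)))
  }
  if (mode == "flip") {
    a <- match(axis, c("x", "y", "z"))
    if (is.na(a)) stop("flip axis must be x, y or z")
    rev_idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    rev_idx[[a]] <- rev(rev_idx[[a]])
    ds <- apply_spatial(ds,
      function(im) im[rev_idx[[1]], rev_idx[[2]], , rev_idx[[3]], drop = FALSE],
      function(la) la[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]], drop = FALSE])
    return(log_action(ds, "transform", list(mode = "flip", axis = axis)))
  }
  if (mode == "rotate90") {
    k <- as.integer(k) %% 4L
    rot1 <- function(la) { # one CCW turn in the XY plane of a 3-D array
      aperm(la, c(2, 1, 3))[dim(la)[2]:1, , , drop = FALSE]
    }
    rot1_img <- function(im) {
      aperm(im, c(2, 1, 3, 4))[dim(im)[2]:1, , , , drop = FALSE]
    }
    for (i in seq_len(k)) {
      ds <- apply_spatial(ds, rot1_img, rot1)
      vs <- ds$geometry$voxel_size
      ds$geometry$voxel_size <- stats::setNames(vs[c(2, 1, 3)], c("x", "y", "z"))
    }
    return(log_action(ds, "transform", list(mode = "rotate90", k = k)))
  }
  # transpose
  pa <- match(perm, c("x", "y", "z"))
  if (any(is.na(pa)) || length(pa) != 3 || anyDuplicated(pa))
    stop("perm must be a permutation of x, y, z")
  map4 <- c(1L, 2L, 4L)  # spatial axis -> image array dimension
  ds <- apply_spatial(ds,
    function(im) aperm(im, c(map4[pa[1]], map4[pa[2]], 3L, map4[pa[3]])),
    function(la) aperm(la, pa))
  ds$geometry$voxel_size <- stats::setNames(ds$geometry$voxel_size[pa],
                                            c("x", "y", "z"))
  ds$geometry$bbox_min <- stats::setNames(ds$geometry$bbox_min[pa],
                                          c("x", "y", "z"))
  log_action(ds, "transform", list(mode = "transpose", perm = perm))
}

# -- chop / reassemble -------------------------------------------------------

block_ranges <- function(n, k, overlap) {
  # k contiguous core blocks tiling 1..n, each extended by `overlap`
  bounds <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) {
    core <- c(bounds[i] + 1L, bounds[i + 1L])
    c(max(1L, core[1] - overlap), min(n, core[2] + overlap),
      core[1], core[2])
  })
}

#' Divide a dataset into blocks for independent processing
#'
#' The volume is split into a `grid` of blocks whose cores tile the original
#' exactly; an optional symmetric overlap (in voxels) extends each block.
#' Each block carries offset geometry so it can be processed as a standalone
#' dataset and re-imported.
#'
#' @param ds a `LayeredDataset`
#' @param grid integer length-3: number of blocks along x, y, z
#' @param overlap overlap in voxels (default 0)
#' @return list with `blocks` (list of `LayeredDataset`) and `plan`
#'   (a `ChopPlan`)
#' @seealso [ds_reassemble()]
#' @export
ds_chop <- function(ds, grid, overlap = 0L) {
  d <- ds_dim(ds)
  grid <- as.integer(rep(grid, length.out = 3))
  if (any(grid < 1) || any(grid > d)) stop("grid counts must be in 1..shape")
  overlap <- as.integer(overlap)
  if (overlap < 0) stop("overlap must be >= 0")
  if (any(overlap >= floor(d / grid)))
    stop("overlap must be smaller than the block size")
  rx <- block_ranges(d[1], grid[1], overlap)
  ry <- block_ranges(d[2], grid[2], overlap)
  rz <- block_ranges(d[3], grid[3], overlap)
  blocks <- list()
  plan_rows <- list()
  bi <- 0L
  for (kz in seq_len(grid[3])) for (ky in seq_len(grid[2]))
    for (kx in seq_len(grid[1])) {
      bi <- bi + 1L
      bx <- rx[[kx]]; by <- ry[[ky]]; bz <- rz[[kz]]
      blk <- ds
      blk$log <- list()
      blk$history <- ds$history[c("depth_2d", "depth_3d")]
      blk$history[c("undo_2d", "undo_3d", "redo_2d", "redo_3d")] <-
        list(list(), list(), list(), list())
      blk <- apply_spatial(blk,
        function(im) im[bx[1]:bx[2], by[1]:by[2], , bz[1]:bz[2], drop = FALSE],
        function(la) la[bx[1]:bx[2], by[1]:by[2], bz[1]:bz[2], drop = FALSE])
      off <- c(bx[1], by[1], bz[1]) - 1L
      blk$geometry$bbox_min <- ds$geometry$bbox_min + off * ds$geometry$voxel_size
      blk <- log_action(blk, "chop_block", list(index = bi))
      blocks[[bi]] <- blk
      plan_rows[[bi]] <- data.frame(
        block = bi, kx = kx, ky = ky, kz = kz,
        x0 = bx[1], x1 = bx[2], y0 = by[1], y1 = by[2], z0 = bz[1], z1 = bz[2],
        cx0 = bx[3], cx1 = bx[4], cy0 = by[3], cy1 = by[4], cz0 = bz[3], cz1 = bz[4])
    }
  plan <- structure(list(grid = grid, overlap = overlap, shape = unname(d),
                         voxel_size = unname(ds$geometry$voxel_size),
                         units = ds$geometry$units,
                         bbox_min = unname(ds$geometry$bbox_min),
                         axis4 = ds$geometry$axis4,
                         blocks = do.call(rbind, plan_rows)),
                    class = "ChopPlan")
  list(blocks = blocks, plan = plan)
}

#' @export
print.ChopPlan <- function(x, ...) {
  cat(sprintf("<ChopPlan> %s grid, overlap %d, source %s\n",
              paste(x$grid, collapse = "x"), x$overlap,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Reassemble chopped blocks into one dataset
#'
#' Blocks are placed back at their plan offsets.  A chop followed by a
#' reassemble with no edits reproduces the source bit-exactly.  Where blocks
#' overlap and disagree, the later block in plan order wins (logged).
#' Material tables are reconciled by name: labels are remapped onto the
#' union table.
#'
#' @param blocks list of `LayeredDataset` from [ds_chop()]
#' @param plan the corresponding `ChopPlan`
#' @return the reassembled `LayeredDataset`
#' @export
ds_reassemble <- function(blocks, plan) {
  pb <- plan$blocks
  if (length(blocks) != nrow(pb))
    stop("missing block(s): expected ", nrow(pb), ", got ", length(blocks),
         " (missing indices ",
         paste(setdiff(seq_len(nrow(pb)), seq_along(blocks)), collapse = ", "), ")")
  for (i in seq_len(nrow(pb))) {
    ext <- c(pb$x1[i] - pb$x0[i] + 1L, pb$y1[i] - pb$y0[i] + 1L,
             pb$z1[i] - pb$z0[i] + 1L)
    if (!identical(unname(ds_dim(blocks[[i]])), as.integer(ext)))
      stop("block ", i, " does not match the plan extents")
  }
  # union material table by name, in first-appearance order
  mats <- material_table()
  remaps <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    bm <- blocks[[i]]$materials
    validate_materials(bm)
    remap <- integer(nrow(bm))
    for (j in seq_len(nrow(bm))) {
      hit <- match(bm$name[j], mats$name)
      if (is.na(hit)) {
        mats <- rbind(mats, data.frame(id = nrow(mats) + 1L, name = bm$name[j],
                                       color = bm$color[j]))
        hit <- nrow(mats)
      }
      remap[j] <- hit
    }
    remaps[[i]] <- remap
  }
  nch <- dim(blocks[[1]]$image)[3]
  out <- blocks[[1]]
  out$image <- array(0, c(plan$shape[1], plan$shape[2], nch, plan$shape[3]))
  out$selection <- NULL; out$mask <- NULL; out$model <- NULL
  need <- c(selection = FALSE, mask = FALSE, model = FALSE)
  for (b in blocks) for (ly in names(need)) if (!is.null(b[[ly]])) need[ly] <- TRUE
  for (ly in names(need)[need]) out[[ly]] <- array(0L, plan$shape)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ix <- pb$x0[i]:pb$x1[i]; iy <- pb$y0[i]:pb$y1[i]; iz <- pb$z0[i]:pb$z1[i]
    out$image[ix, iy, , iz] <- b$image
    for (ly in names(need)[need]) {
      la <- b[[ly]] %||% array(0L, ds_dim(b))
      if (ly == "model" && length(remaps[[i]])) {
        lut <- c(0L, remaps[[i]])
        la <- array(lut[la + 1L], dim(la))
      }
      out[[ly]][ix, iy, iz] <- la
    }
  }
  out$materials <- mats
  out$geometry <- volume_geometry(plan$voxel_size, plan$units, plan$bbox_min,
                                  plan$axis4)
  out$log <- list()
  out <- log_action(out, "reassemble",
                    list(grid = plan$grid, overlap = plan$overlap,
                         precedence = "later block wins"))
  out
}
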