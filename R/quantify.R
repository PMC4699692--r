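# Object labelling, shape/intensity properties in physical units,
# property-range filtering (segmentation polishing), model smoothing,
# manual geometric measurements with intensity profiles, and table export.

crofton_perimeter <- function(sl) {
  # Cauchy-Crofton estimate from fg/bg transition counts in 4 directions:
  # P ~ (pi/8) * (c0 + c90 + (c45 + c135)/sqrt(2)),
  # where the diagonal weight is the spacing of diagonal scan lines.
  nx <- nrow(sl); ny <- ncol(sl)
  f <- matrix(0L, nx + 2, ny + 2)
  f[2:(nx + 1), 2:(ny + 1)] <- (sl != 0) + 0L
  c0 <- sum(f[-1, ] != f[-(nx + 2), ])
  c90 <- sum(f[, -1] != f[, -(ny + 2)])
  c45 <- sum(f[-1, -1] != f[-(nx + 2), -(ny + 2)])
  c135 <- sum(f[-1, -(ny + 2)] != f[-(nx + 2), -1])
  (pi / 8) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

shape_props_2d <- function(pix, vs) {
  # pix: n x 2 voxel coords; second-moment ellipse properties
  n <- nrow(pix)
  xy <- sweep(pix, 2, colMeans(pix))
  xy <- sweep(xy, 2, vs[1:2], "*")
  mu20 <- mean(xy[, 1]^2) + vs[1]^2 / 12
  mu02 <- mean(xy[, 2]^2) + vs[2]^2 / 12
  mu11 <- mean(xy[, 1] * xy[, 2])
  tr <- mu20 + mu02
  disc <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  ori <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  list(eccentricity = min(ecc, 1 - 1e-12), orientation = ori)
}

shape_props_3d <- function(pix, vs) {
  xyz <- sweep(pix, 2, colMeans(pix))
  xyz <- sweep(xyz, 2, vs, "*")
  cv <- crossprod(xyz) / nrow(xyz) + diag(vs^2 / 12)
  ev <- eigen(cv, symmetric = TRUE)
  l <- pmax(ev$values, 0)
  ecc <- if (l[1] > 0) sqrt(pmax(1 - l[3] / l[1], 0)) else 0
  ax <- ev$vectors[, 1]
  ori <- atan2(ax[2], ax[1]) * 180 / pi
  if (ori < 0) ori <- ori + 180
  list(eccentricity = min(ecc, 1 - 1e-12), orientation = ori)
}

object_row <- function(id, slice, pix, vs, units, img) {
  vs <- unname(vs)
  nvox <- nrow(pix)
  cen <- unname(colMeans(pix))
  cen_phys <- (cen - 0.5) * vs[seq_along(cen)]
  if (is.na(slice)) {
    props <- shape_props_3d(pix, vs)
    vol <- nvox * prod(vs)
    per <- NA_real_
  } else {
    props <- shape_props_2d(pix[, 1:2, drop = FALSE], vs)
    vol <- nvox * vs[1] * vs[2]
    per <- NA_real_  # filled by caller (needs the full slice)
  }
  ints <- if (!is.null(img)) {
    iv <- img[pix]
    c(min(iv), max(iv), mean(iv))
  } else c(NA_real_, NA_real_, NA_real_)
  data.frame(id = id, slice = slice, n_voxels = nvox,
             volume = vol, perimeter = per,
             eccentricity = props$eccentricity,
             orientation = props$orientation,
             int_min = ints[1], int_max = ints[2], int_mean = ints[3],
             cx = cen_phys[1], cy = cen_phys[2],
             cz = if (length(cen_phys) > 2) cen_phys[3] else NA_real_)
}

#' Label connected components and quantify their properties
#'
#' Labels 2-D (per slice) or 3-D connected components of a binary volume
#' and computes shape properties (size, eccentricity, perimeter,
#' orientation) and intensity properties (minimum, maximum, average) per
#' object, in physical units honoring anisotropic voxel size.
#' Eccentricity and orientation come from the second-moment equivalent
#' ellipse; the 2-D perimeter is a four-direction Cauchy-Crofton estimate.
#'
#' @param bin binary 3-D array
#' @param dims `"3d"` or `"2d-per-slice"`
#' @param connectivity `"full"` (8/26) or `"face"` (4/6)
#' @param voxel_size physical voxel size
#' @param units unit name for documentation columns
#' @param image optional intensity volume for the intensity columns
#' @return list with `labels` (integer volume) and `table` (`ObjectTable`
#'   data.frame, one row per connected component)
#' @export
label_objects <- function(bin, dims = c("3d", "2d-per-slice"),
                          connectivity = "full", voxel_size = c(1, 1, 1),
                          units = "nm", image = NULL) {
  dims <- match.arg(dims)
  d <- dim(bin)
  vs <- rep(voxel_size, length.out = 3)
  full <- identical(connectivity, "full") || connectivity %in% c(8, 26)
  rows <- list()
  if (dims == "3d") {
    lab <- array(cpp_label_components(as.integer(bin != 0), d, full), d)
    ids <- seq_len(max(lab))
    if (length(ids)) {
      idx <- which(lab > 0)
      sp <- split(idx, lab[idx])
      for (i in ids) {
        pix <- arrayInd(sp[[as.character(i)]], d)
        rows[[i]] <- object_row(i, NA, pix, vs, units, image)
      }
    }
  } else {
    lab <- array(0L, d)
    nid <- 0L
    for (z in seq_len(d[3])) {
      lz <- array(cpp_label_components(as.integer(bin[, , z] != 0),
                                       c(d[1:2], 1L), full), d[1:2])
      kz <- max(lz)
      if (kz == 0) next
      for (i in seq_len(kz)) {
        pixm <- which(lz == i, arr.ind = TRUE)
        pix3 <- cbind(pixm, z)
        r <- object_row(nid + i, z, pix3, vs, units, image)
        r$perimeter <- crofton_perimeter(lz == i) * vs[1]
        rows[[nid + i]] <- r
      }
      lz[lz > 0] <- lz[lz > 0] + nid
      lab[, , z] <- lz
      nid <- nid + kz
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), slice = integer(), n_voxels = integer(),
               volume = numeric(), perimeter = numeric(),
               eccentricity = numeric(), orientation = numeric(),
               int_min = numeric(), int_max = numeric(),
               int_mean = numeric(), cx = numeric(), cy = numeric(),
               cz = numeric())
  attr(tab, "units") <- units
  attr(tab, "voxel_size") <- vs
  list(labels = lab, table = tab)
}

#' Filter labelled objects by property ranges
#'
#' Keeps only objects whose properties fall inside every given range;
#' everything else is removed from both the table and the label volume.
#' Used as a polishing stage after thresholding-style segmentation.
#' Applying the same filter twice is a no-op.
#'
#' @param labels label volume from [label_objects()]
#' @param table the matching `ObjectTable`
#' @param ... named ranges `property = c(min, max)` (use `Inf`); properties
#'   must be table columns
#' @return list with filtered `labels`, `table` and `removed` (count)
#' @export
filter_objects <- function(labels, table, ...) {
  pred <- list(...)
  if (length(pred) == 1 && is.list(pred[[1]]) && is.null(names(pred)[1]))
    pred <- pred[[1]]
  keep <- rep(TRUE, nrow(table))
  for (p in names(pred)) {
    if (!p %in% names(table)) stop("unknown property: ", p)
    rng <- pred[[p]]
    keep <- keep & table[[p]] >= rng[1] & table[[p]] <= rng[2]
  }
  drop_ids <- table$id[!keep]
  if (length(drop_ids)) labels[labels %in% drop_ids] <- 0L
  out_tab <- table[keep, , drop = FALSE]
  list(labels = labels, table = out_tab, removed = length(drop_ids))
}

#' Smooth a label (model) volume by per-material binary opening
#'
#' Erosion followed by dilation applied independently to each material's
#' binary mask; opening is anti-extensive, so smoothed materials can never
#' bleed into each other.  Removes small specks and ragged protrusions.
#' @param model integer label volume
#' @param radius structuring-element radius in voxels
#' @param dims `"3d"` (ball) or `"2d"` (disk per slice)
#' @return the smoothed label volume
#' @export
smooth_model <- function(model, radius = 2, dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  d <- dim(model)
  off <- element_offsets(if (dims == "3d") "ball" else "disk", radius)
  out <- array(0L, d)
  for (m in setdiff(sort(unique(as.vector(model))), 0L)) {
    bin <- (model == m) + 0
    sm <- morph_vol(bin, "opening", off)
    out[sm >= 0.5] <- m
  }
  out
}

#' Manual geometric measurement with intensity profile
#'
#' Physical-unit measurements between anchor points: point-to-point
#' distance, angle at the middle anchor, caliper (extent of the selected
#' object projected on the anchor direction), or least-squares circle
#' radius through >= 3 anchors.  Distance-like measurements sample an
#' intensity profile along the measured path at sub-voxel spacing.
#'
#' @param ds a `LayeredDataset`
#' @param kind `"distance"`, `"angle"`, `"caliper"` or `"radius"`
#' @param anchors matrix of physical coordinates, one row per anchor
#'   (2 rows for distance/caliper, 3 for angle, >= 3 for radius)
#' @return object of class `Measurement` with `value`, `units`, `profile`
#' @export
measure <- function(ds, kind = c("distance", "angle", "caliper", "radius"),
                    anchors) {
  kind <- match.arg(kind)
  anchors <- as.matrix(anchors)
  if (ncol(anchors) == 2) anchors <- cbind(anchors, 0)
  vs <- unname(ds$geometry$voxel_size)
  units <- ds$geometry$units
  profile <- NULL
  if (kind == "distance" || kind == "caliper") {
    if (nrow(anchors) != 2) stop(kind, " needs exactly 2 anchors")
    dirv <- anchors[2, ] - anchors[1, ]
    dist <- sqrt(sum(dirv^2))
    if (kind == "distance") {
      value <- dist
    } else {
      sel <- get_layer(ds, "selection")
      if (!any(sel != 0)) stop("caliper needs a nonempty selection layer")
      w <- which(sel != 0, arr.ind = TRUE)
      phys <- sweep(w - 0.5, 2, vs, "*")
      u <- dirv / dist
      proj <- phys %*% u
      value <- max(proj) - min(proj)
    }
    profile <- sample_profile(ds, anchors[1, ], anchors[2, ])
  } else if (kind == "angle") {
    if (nrow(anchors) != 3) stop("angle needs exactly 3 anchors")
    u <- anchors[1, ] - anchors[2, ]
    v <- anchors[3, ] - anchors[2, ]
    value <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) *
      180 / pi
  } else {
    if (nrow(anchors) < 3) stop("radius needs >= 3 anchors")
    value <- fit_circle_radius(anchors[, 1:2, drop = FALSE])
  }
  structure(list(kind = kind, anchors = anchors, value = value,
                 units = units, profile = profile), class = "Measurement")
}

#' @export
print.Measurement <- function(x, ...) {
  cat(sprintf("<Measurement> %s = %.4g %s%s\n", x$kind, x$value, x$units,
              if (x$kind == "angle") " degrees" else ""))
  invisible(x)
}

fit_circle_radius <- function(xy) {
  # Kasa least-squares circle fit; errors on collinear anchors
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  if (qr(A)$rank < 3) stop("anchors are collinear: no circle fit")
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

sample_profile <- function(ds, p0, p1) {
  vs <- unname(ds$geometry$voxel_size)
  len <- sqrt(sum((p1 - p0)^2))
  step <- min(vs) / 2
  n <- max(2, ceiling(len / step) + 1)
  tt <- seq(0, 1, length.out = n)
  v <- img3d(ds)
  d <- dim(v)
  vals <- vapply(tt, function(t) {
    p <- p0 + t * (p1 - p0)
    idx <- p / vs + 0.5   # physical -> voxel center coordinates
    trilinear(v, idx, d)
  }, 0)
  data.frame(position = tt * len, value = vals)
}

trilinear <- function(v, p, d) {
  lo <- pmin(pmax(floor(p), 1), d)
  hi <- pmin(lo + 1, d)
  f <- pmin(pmax(p - lo, 0), 1)
  acc <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    w <- (if (i) f[1] else 1 - f[1]) * (if (j) f[2] else 1 - f[2]) *
         (if (k) f[3] else 1 - f[3])
    acc <- acc + w * v[if (i) hi[1] else lo[1],
                       if (j) hi[2] else lo[2],
                       if (k) hi[3] else lo[3]]
  }
  acc
}

#' Export an object table or measurements as delimited text
#'
#' One row per object/measurement; physical columns carry a unit suffix in
#' the header, numeric cells keep 6 significant digits and parse losslessly
#' back.
#' @param table an `ObjectTable` data.frame or a `Measurement`
#' @param path output file
#' @param format `"csv"` or `"tsv"`
#' @return the path, invisibly
#' @export
export_table <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(table, "Measurement")) {
    table <- data.frame(kind = table$kind, value = table$value,
                        units = table$units)
  }
  units <- attr(table, "units") %||% "units"
  out <- table
  ren <- c(volume = paste0("volume_", units, "3"),
           perimeter = paste0("perimeter_", units),
           cx = paste0("cx_", units), cy = paste0("cy_", units),
           cz = paste0("cz_", units),
           orientation = "orientation_deg")
  for (nm in names(ren)) {
    hit <- match(nm, names(out))
    if (!is.na(hit)) names(out)[hit] <- ren[nm]
  }
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = if (format == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
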