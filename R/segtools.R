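# Scriptable equivalents of the interactive segmentation tools: painting
# primitives, brush strokes, magic wand / region growing, membrane and line
# tracking, shape/line interpolation, and black-and-white thresholding.
# Tools write only to their declared target layer; the image layer is never
# mutated by segmentation tools.

#' A brush/tool stroke
#' @param points matrix or data.frame with columns x, y (voxels) and a
#'   common `slice`; or 3 columns x, y, slice
#' @param radius brush radius in voxels (>= 0)
#' @param slice slice index if `points` has 2 columns
#' @param target_layer `"selection"` or `"mask"`
#' @export
tool_stroke <- function(points, radius = 1, slice = NULL,
                        target_layer = c("selection", "mask")) {
  target_layer <- match.arg(target_layer)
  points <- as.matrix(points)
  if (ncol(points) == 2) {
    if (is.null(slice)) stop("2-column points need a slice index")
    points <- cbind(points, slice)
  }
  if (radius < 0) stop("radius must be >= 0")
  structure(list(points = points, radius = radius,
                 target_layer = target_layer), class = "ToolStroke")
}

#' An ordered sequence of anchor clicks for tracking tools
#' @param points matrix with columns x, y, slice (>= 2 rows, consecutive
#'   points distinct)
#' @param corridor search-corridor width in voxels
#' @export
click_sequence <- function(points, corridor = 40) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 anchor points")
  if (any(rowSums(abs(diff(points))) == 0))
    stop("consecutive points must be distinct")
  structure(list(points = points, corridor = corridor),
            class = "ClickSequence")
}

bresenham <- function(p0, p1) {
  # integer 2-D line rasterization (8-connected)
  x0 <- p0[1]; y0 <- p0[2]; x1 <- p1[1]; y1 <- p1[2]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx - dy
  pts <- matrix(0L, dx + dy + 1L, 2)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(n), , drop = FALSE]
}

disk_mask_idx <- function(center, radius, nx, ny) {
  r <- max(0L, as.integer(radius))
  ix <- max(1, center[1] - r):min(nx, center[1] + r)
  iy <- max(1, center[2] - r):min(ny, center[2] + r)
  g <- expand.grid(x = ix, y = iy)
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  cbind(g$x[keep], g$y[keep])
}

#' Paint a spot (2-D disk) or a 3-D ball into an annotation layer
#'
#' The 3-D ball is anisotropy-corrected: its radius is interpreted in
#' physical units and the painted voxel region is an ellipsoid in voxel
#' space whose physical shape is a sphere.
#'
#' @param ds a `LayeredDataset`
#' @param kind `"spot"` or `"ball3d"`
#' @param center voxel coordinate `c(x, y, z)`
#' @param radius spot: radius in voxels; ball3d: physical radius
#' @param target `"selection"` or `"mask"`
#' @param erase remove instead of add
#' @return the updated dataset
#' @export
paint_primitive <- function(ds, kind = c("spot", "ball3d"), center, radius,
                            target = "selection", erase = FALSE) {
  kind <- match.arg(kind)
  d <- ds_dim(ds)
  center <- round(center)
  if (any(center < 1) || any(center > d)) stop("center out of bounds")
  layer <- get_layer(ds, target)
  val <- if (erase) 0L else 1L
  if (kind == "spot") {
    pix <- disk_mask_idx(center[1:2], radius, d[1], d[2])
    layer[cbind(pix, center[3])] <- val
  } else {
    vs <- unname(ds$geometry$voxel_size)
    rv <- pmax(radius / vs, 0)
    ix <- max(1, floor(center[1] - rv[1])):min(d[1], ceiling(center[1] + rv[1]))
    iy <- max(1, floor(center[2] - rv[2])):min(d[2], ceiling(center[2] + rv[2]))
    iz <- max(1, floor(center[3] - rv[3])):min(d[3], ceiling(center[3] + rv[3]))
    g <- expand.grid(x = ix, y = iy, z = iz)
    keep <- ((g$x - center[1]) * vs[1])^2 + ((g$y - center[2]) * vs[2])^2 +
            ((g$z - center[3]) * vs[3])^2 <= radius^2
    keep[g$x == center[1] & g$y == center[2] & g$z == center[3]] <- TRUE
    layer[as.matrix(g[keep, ])] <- val
  }
  ds[[target]] <- layer
  log_action(ds, "paint_primitive",
             list(kind = kind, center = center, radius = radius,
                  erase = erase))
}

stroke_footprint <- function(stroke, nx, ny) {
  pts <- stroke$points
  pix <- NULL
  for (i in seq_len(nrow(pts))) {
    if (i > 1) {
      seg <- bresenham(round(pts[i - 1, 1:2]), round(pts[i, 1:2]))
    } else seg <- matrix(round(pts[i, 1:2]), 1)
    pix <- rbind(pix, seg)
  }
  pix <- unique(pix)
  if (stroke$radius > 0) {
    out <- unique(do.call(rbind, lapply(seq_len(nrow(pix)), function(i)
      disk_mask_idx(pix[i, ], stroke$radius, nx, ny))))
  } else {
    out <- pix[pix[, 1] >= 1 & pix[, 1] <= nx & pix[, 2] >= 1 & pix[, 2] <= ny,
               , drop = FALSE]
  }
  out
}

#' Paint a brush stroke (union of disks along the path)
#'
#' The path is rasterized continuously, so arbitrarily spaced input points
#' yield a gap-free stroke.  Strokes are confined to one slice.
#' @param ds a `LayeredDataset`
#' @param stroke a [tool_stroke()]
#' @param erase remove instead of add
#' @return the updated dataset
#' @export
brush_stroke <- function(ds, stroke, erase = FALSE) {
  d <- ds_dim(ds)
  z <- stroke$points[1, 3]
  pix <- stroke_footprint(stroke, d[1], d[2])
  layer <- get_layer(ds, stroke$target_layer)
  layer[cbind(pix, z)] <- if (erase) 0L else 1L
  ds[[stroke$target_layer]] <- layer
  log_action(ds, "brush_stroke",
             list(n_points = nrow(stroke$points), radius = stroke$radius,
                  erase = erase))
}

#' Brush against superpixels: select every region the stroke touches
#'
#' Selects the union of all superpixels/supervoxels intersected by the
#' stroke footprint; the result is always a superset of the plain brush
#' footprint, which makes selection of homogeneous areas much faster.
#' @param ds a `LayeredDataset`
#' @param stroke a [tool_stroke()]
#' @param sp a `SupervoxelPartition` from [slic_partition()]
#' @return the updated dataset
#' @export
brush_superpixels <- function(ds, stroke, sp) {
  if (!inherits(sp, "SupervoxelPartition"))
    stop("compute a SLIC partition first (slic_partition)")
  d <- ds_dim(ds)
  z <- stroke$points[1, 3]
  pix <- stroke_footprint(stroke, d[1], d[2])
  touched <- unique(sp$labels[cbind(pix, z)])
  sel <- array(sp$labels %in% touched, d)
  if (sp$dims == "2d") {
    keep <- array(FALSE, d)
    keep[, , z] <- TRUE
    sel <- sel & keep
  }
  layer <- get_layer(ds, stroke$target_layer)
  layer[sel] <- 1L
  layer[cbind(pix, z)] <- 1L
  ds[[stroke$target_layer]] <- layer
  log_action(ds, "brush_superpixels", list(n_regions = length(touched)))
}

conn_full <- function(connectivity, dims) {
  if (is.character(connectivity)) return(connectivity == "full")
  connectivity %in% c(8, 26)
}

#' Magic wand: connected region within an intensity window around a seed
#'
#' Selects the connected component containing the seed among voxels whose
#' intensity lies in `[I(seed) - tolerance[1], I(seed) + tolerance[2]]`.
#' @param ds a `LayeredDataset`
#' @param seed voxel coordinate `c(x, y, z)`
#' @param tolerance `c(low, high)` intensity window half-widths
#' @param connectivity 4/8 (2-D) or 6/26 (3-D); default 8/26
#' @param scope `"3d"` or `"2d"` (seed slice only)
#' @return binary 3-D array (the selected region)
#' @export
magic_wand <- function(ds, seed, tolerance = c(10, 10), connectivity = NULL,
                       scope = c("3d", "2d")) {
  scope <- match.arg(scope)
  d <- ds_dim(ds)
  seed <- round(seed)
  if (any(seed < 1) || any(seed > d)) stop("seed out of bounds")
  v <- img3d(ds)
  i0 <- v[seed[1], seed[2], seed[3]]
  mask <- v >= i0 - tolerance[1] & v <= i0 + tolerance[2]
  if (scope == "2d") {
    m2 <- array(FALSE, d)
    m2[, , seed[3]] <- mask[, , seed[3]]
    mask <- m2
  }
  full <- if (is.null(connectivity)) TRUE else conn_full(connectivity, scope)
  lab <- array(cpp_label_components(as.integer(mask), d, full), d)
  (lab == lab[seed[1], seed[2], seed[3]]) + 0L
}

#' Region growing from a seed with an evolving-mean criterion
#'
#' Iteratively admits frontier voxels whose intensity is within `kappa` of
#' the running region mean; the frontier is processed in deterministic
#' linear-index order, so results are reproducible.
#' @param ds a `LayeredDataset`
#' @param seed voxel coordinate `c(x, y, z)`
#' @param max_iter maximum number of growth sweeps
#' @param kappa admission tolerance in intensity units
#' @param connectivity 6 or 26
#' @return binary 3-D array
#' @export
region_grow <- function(ds, seed, max_iter = 1000, kappa = 10,
                        connectivity = 26) {
  d <- ds_dim(ds)
  seed <- round(seed)
  if (any(seed < 1) || any(seed > d)) stop("seed out of bounds")
  v <- img3d(ds)
  n <- prod(d)
  lin <- function(x, y, z) x + d[1] * (y - 1L + d[2] * (z - 1L))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = if (d[3] > 1) -1:1 else 0)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity %in% c(6, 4)) offs <- offs[rowSums(abs(offs)) == 1, ]
  region <- logical(n)
  s0 <- lin(seed[1], seed[2], seed[3])
  region[s0] <- TRUE
  total <- v[s0]; cnt <- 1
  frontier <- s0
  coords <- arrayInd(s0, d)
  for (it in seq_len(max_iter)) {
    # candidate neighbors of the current frontier
    cand <- integer(0)
    cc <- arrayInd(frontier, d)
    for (r in seq_len(nrow(offs))) {
      nx <- cc[, 1] + offs$dx[r]; ny <- cc[, 2] + offs$dy[r]
      nz <- cc[, 3] + offs$dz[r]
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
      cand <- c(cand, lin(nx[ok], ny[ok], nz[ok]))
    }
    cand <- sort(unique(cand))
    cand <- cand[!region[cand]]
    if (!length(cand)) break
    admit <- cand[abs(v[cand] - total / cnt) <= kappa]
    if (!length(admit)) break
    region[admit] <- TRUE
    total <- total + sum(v[admit]); cnt <- cnt + length(admit)
    frontier <- admit
  }
  array(region + 0L, d)
}

#' Trace a membrane profile between clicks by minimal-cost path search
#'
#' For each consecutive click pair, finds the cheapest 8-connected path on
#' the slice inside a corridor around the straight chord.  Voxel cost
#' decreases with membrane evidence (dark-ridge intensity after smoothing),
#' so the path snaps onto dark membrane profiles.  Ties are broken by
#' preferring shorter paths closer to the chord, making the uniform-cost
#' result the discrete straight segment.
#' @param ds a `LayeredDataset`
#' @param clicks a [click_sequence()] with all points on one slice
#' @param smooth_sigma Gaussian smoothing of the evidence, voxels
#' @return binary 3-D array with the 1-px wide concatenated path
#' @export
membrane_track_2d <- function(ds, clicks, smooth_sigma = 1) {
  d <- ds_dim(ds)
  pts <- clicks$points
  if (length(unique(pts[, 3])) != 1)
    stop("membrane_track_2d expects clicks on one slice")
  z <- pts[1, 3]
  sl <- img3d(ds)[, , z]
  evid <- gauss_smooth(array(max(sl) - sl, c(dim(sl), 1)),
                       c(smooth_sigma, smooth_sigma, 0))[, , 1]
  cost <- (max(evid) - evid) + 1e-3
  out <- array(0L, d)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- round(pts[i, 1:2]); b <- round(pts[i + 1, 1:2])
    path <- corridor_shortest_path(cost, a, b, clicks$corridor)
    if (is.null(path))
      stop("no path within corridor for segment ", i)
    out[cbind(path, z)] <- 1L
  }
  out
}

corridor_shortest_path <- function(cost, a, b, corridor) {
  nx <- nrow(cost); ny <- ncol(cost)
  gx <- matrix(seq_len(nx), nx, ny)
  gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(matrix(a, 1))
  t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len^2
  t <- pmin(pmax(t, 0), 1)
  perp <- sqrt((gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2)
  inside <- perp <= corridor / 2
  inside[a[1], a[2]] <- TRUE
  inside[b[1], b[2]] <- TRUE
  idx <- which(inside)
  node_of <- rep(NA_integer_, nx * ny)
  node_of[idx] <- seq_along(idx)
  # 8-neighbor edges inside corridor; weight = step * mean endpoint cost,
  # plus a tiny chord-distance penalty as deterministic tie-break
  tie <- perp * 1e-9
  edges <- NULL; w <- NULL
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    pr <- arrayInd(idx, c(nx, ny))
    qx <- pr[, 1] + o[1]; qy <- pr[, 2] + o[2]
    ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
    qi <- (qy - 1) * nx + qx
    ok[ok] <- !is.na(node_of[qi[ok]])
    if (!any(ok)) next
    pnode <- node_of[idx[ok]]
    qnode <- node_of[qi[ok]]
    step <- sqrt(sum(o^2))
    wseg <- step * (cost[idx[ok]] + cost[qi[ok]] +
                    tie[idx[ok]] + tie[qi[ok]]) / 2
    edges <- rbind(edges, cbind(pnode, qnode))
    w <- c(w, wseg)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  na <- node_of[(a[2] - 1) * nx + a[1]]
  nb <- node_of[(b[2] - 1) * nx + b[1]]
  sp <- suppressWarnings(igraph::shortest_paths(g, from = na, to = nb,
                                                weights = igraph::E(g)$weight))
  vp <- sp$vpath[[1]]
  if (!length(vp)) return(NULL)
  arrayInd(idx[as.integer(vp)], c(nx, ny))
}

#' Track a 3-D polyline (microtubule-style centerline) across slices
#'
#' Interpolates linearly between anchors in physical coordinates (so
#' anisotropic voxel sizes are honored), rasterizing one node per
#' intersected slice, optionally dilated to a radius.
#' @param ds a `LayeredDataset`
#' @param clicks a [click_sequence()] with anchors ordered in slice index
#' @param radius dilation radius in voxels (0 = single-voxel line)
#' @return binary 3-D array
#' @export
line_track_3d <- function(ds, clicks, radius = 0) {
  d <- ds_dim(ds)
  vs <- unname(ds$geometry$voxel_size)
  pts <- clicks$points
  out <- array(0L, d)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    if (a[3] == b[3])
      stop("two clicks on the same slice in segment ", i)
    zs <- a[3]:b[3]
    pa <- a * vs; pb <- b * vs
    for (z in zs) {
      t <- (z * vs[3] - pa[3]) / (pb[3] - pa[3])
      xy <- (pa[1:2] + t * (pb[1:2] - pa[1:2])) / vs[1:2]
      cx <- min(max(round(xy[1]), 1), d[1])
      cy <- min(max(round(xy[2]), 1), d[2])
      if (radius > 0) {
        pix <- disk_mask_idx(c(cx, cy), radius, d[1], d[2])
        out[cbind(pix, z)] <- 1L
      } else out[cx, cy, z] <- 1L
    }
  }
  out
}

slice_sdf <- function(sl) {
  # signed distance: positive inside, negative outside, in pixels
  d3 <- c(dim(sl), 1L)
  fg <- as.integer(sl != 0)
  din <- sqrt(cpp_edt_sq(fg, d3, c(1, 1, 1)))
  dout <- sqrt(cpp_edt_sq(1L - fg, d3, c(1, 1, 1)))
  array(din - dout, dim(sl))
}

match_objects_2d <- function(la, lb) {
  # greedy centroid matching between labelled slices
  ca <- centroids_2d(la); cb <- centroids_2d(lb)
  na <- nrow(ca); nb <- nrow(cb)
  if (!na || !nb) return(list(pairs = NULL, ua = seq_len(na), ub = seq_len(nb)))
  dm <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j)
    sqrt(sum((ca[i, ] - cb[j, ])^2))))
  pairs <- NULL
  while (any(is.finite(dm))) {
    k <- arrayInd(which.min(dm), dim(dm))
    pairs <- rbind(pairs, k)
    dm[k[1], ] <- Inf; dm[, k[2]] <- Inf
  }
  list(pairs = pairs,
       ua = setdiff(seq_len(na), pairs[, 1]),
       ub = setdiff(seq_len(nb), pairs[, 2]))
}

centroids_2d <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
}

#' Morphological shape interpolation between two key slices
#'
#' Fills the gap between objects drawn on two separated slices by blending
#' signed distance transforms: the intermediate slice at fraction `t` is the
#' zero superlevel set of `(1-t)*SDF_a + t*SDF_b`.  Endpoints are
#' reproduced exactly, and the operation is symmetric in its arguments.
#' With several objects per key slice, objects are matched by centroid
#' proximity and blended pairwise; unmatched objects are copied unchanged
#' with a warning.
#'
#' @param layer binary 3-D array (e.g. a selection layer)
#' @param slice_a,slice_b key slice indices (both must contain foreground)
#' @param overwrite replace nonempty intermediate slices (default requires
#'   them empty)
#' @return the layer with intermediate slices filled
#' @export
shape_interpolate <- function(layer, slice_a, slice_b, overwrite = FALSE) {
  if (slice_a > slice_b) { tmp <- slice_a; slice_a <- slice_b; slice_b <- tmp }
  sa <- layer[, , slice_a]; sb <- layer[, , slice_b]
  if (!any(sa != 0) || !any(sb != 0)) stop("empty key slice")
  mids <- setdiff(seq(slice_a, slice_b), c(slice_a, slice_b))
  if (!length(mids)) return(layer)
  if (!overwrite && any(layer[, , mids] != 0))
    stop("intermediate slices are not empty (use overwrite = TRUE)")
  la <- array(cpp_label_components(as.integer(sa != 0), c(dim(sa), 1L), TRUE),
              dim(sa))
  lb <- array(cpp_label_components(as.integer(sb != 0), c(dim(sb), 1L), TRUE),
              dim(sb))
  mm <- match_objects_2d(la, lb)
  if (length(mm$ua) || length(mm$ub))
    warning("unmatched object(s) copied unchanged across the gap")
  sdfs <- lapply(seq_len(nrow(mm$pairs %||% matrix(0, 0, 2))), function(k) {
    i <- mm$pairs[k, 1]; j <- mm$pairs[k, 2]
    list(a = slice_sdf(la == i), b = slice_sdf(lb == j))
  })
  for (z in mids) {
    # integer slice-distance weights keep the blend exactly symmetric
    wa <- slice_b - z
    wb <- z - slice_a
    acc <- matrix(0L, nrow(sa), ncol(sa))
    for (sd2 in sdfs)
      acc[wa * sd2$a + wb * sd2$b > 0] <- 1L
    for (i in mm$ua) acc[la == i] <- 1L
    for (j in mm$ub) acc[lb == j] <- 1L
    layer[, , z] <- acc
  }
  layer
}

trace_open_curve <- function(sl) {
  # ordered pixel list of a 1-px-wide simple open curve (8-connected)
  pix <- which(sl != 0, arr.ind = TRUE)
  if (!nrow(pix)) stop("empty curve slice")
  key <- paste(pix[, 1], pix[, 2])
  lookup <- new.env()
  for (i in seq_len(nrow(pix))) assign(key[i], i, envir = lookup)
  nbrs <- function(i) {
    out <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      k <- paste(pix[i, 1] + dx, pix[i, 2] + dy)
      j <- lookup[[k]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(nrow(pix)), function(i) length(nbrs(i)), 0L)
  if (any(deg > 2)) stop("branching curve: only simple open curves supported")
  ends <- which(deg == 1)
  if (length(ends) != 2) stop("curve must be open with two endpoints")
  ord <- integer(nrow(pix))
  ord[1] <- ends[1]
  visited <- logical(nrow(pix))
  visited[ends[1]] <- TRUE
  for (i in seq_len(nrow(pix) - 1)) {
    nx <- setdiff(nbrs(ord[i]), which(visited))
    if (!length(nx)) break
    ord[i + 1] <- nx[1]
    visited[nx[1]] <- TRUE
  }
  pix[ord[ord > 0], , drop = FALSE]
}

resample_curve <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n)
  t(vapply(tgt, function(si) {
    k <- max(which(s <= si + 1e-12))
    if (k >= nrow(pts)) return(as.numeric(pts[nrow(pts), ]))
    f <- (si - s[k]) / (s[k + 1] - s[k])
    as.numeric(pts[k, ] * (1 - f) + pts[k + 1, ] * f)
  }, numeric(2)))
}

#' Interpolate open contours (line interpolation) between two key slices
#'
#' Each key slice must contain one simple open 1-px curve.  Curves are
#' resampled to equal arc-length point counts, endpoints are matched by
#' proximity, blended point-wise linearly and re-rasterized on each
#' intermediate slice.
#' @inheritParams shape_interpolate
#' @return the layer with intermediate curves drawn
#' @export
line_interpolate <- function(layer, slice_a, slice_b) {
  if (slice_a > slice_b) { tmp <- slice_a; slice_a <- slice_b; slice_b <- tmp }
  ca <- trace_open_curve(layer[, , slice_a])
  cb <- trace_open_curve(layer[, , slice_b])
  n <- max(nrow(ca), nrow(cb), 2)
  ra <- resample_curve(ca, n)
  rb <- resample_curve(cb, n)
  straight <- sum((ra[1, ] - rb[1, ])^2) + sum((ra[n, ] - rb[n, ])^2)
  crossed <- sum((ra[1, ] - rb[n, ])^2) + sum((ra[n, ] - rb[1, ])^2)
  if (crossed < straight) rb <- rb[n:1, ]
  mids <- setdiff(seq(slice_a, slice_b), c(slice_a, slice_b))
  for (z in mids) {
    t <- (z - slice_a) / (slice_b - slice_a)
    pts <- round(ra * (1 - t) + rb * t)
    sl <- matrix(0L, dim(layer)[1], dim(layer)[2])
    for (i in seq_len(n - 1)) {
      seg <- bresenham(pts[i, ], pts[i + 1, ])
      sl[seg] <- 1L
    }
    sl[pts] <- 1L
    layer[, , z] <- sl
  }
  layer
}

#' Black-and-white thresholding into the selection layer
#'
#' Selects voxels with `low <= I <= high` (inclusive at both bounds), over
#' the whole dataset or only within the mask layer.
#' @param ds a `LayeredDataset`
#' @param window `c(low, high)` intensity window
#' @param scope `"whole"` or `"masked"` (intersects with the mask layer)
#' @param slices optional slice subset to threshold (others left empty)
#' @return the dataset with the selection layer replaced
#' @export
threshold_bw <- function(ds, window, scope = c("whole", "masked"),
                         slices = NULL) {
  scope <- match.arg(scope)
  if (window[1] > window[2]) stop("window low must be <= high")
  v <- img3d(ds)
  sel <- (v >= window[1] & v <= window[2])
  if (!is.null(slices)) {
    keep <- array(FALSE, dim(sel))
    keep[, , slices] <- TRUE
    sel <- sel & keep
  }
  if (scope == "masked") {
    m <- get_layer(ds, "mask")
    if (!any(m != 0)) stop("masked scope requires a nonempty mask")
    sel <- sel & (m != 0)
  }
  ds$selection <- array(as.integer(sel), ds_dim(ds))
  log_action(ds, "threshold_bw",
             list(window = window, scope = scope))
}
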