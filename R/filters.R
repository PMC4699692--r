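# Preprocessing and enhancement filters.  Separable Gaussian smoothing is
# implemented as banded-matrix multiplication along each axis, which keeps
# whole-volume filtering in BLAS.

gauss_kernel_mat <- function(n, sigma) {
  # n x n convolution matrix for a truncated, renormalized Gaussian
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  sweep(K, 1, rowSums(K), "/")
}

blur_axis <- function(vol, sigma, axis) {
  d <- dim(vol)
  if (sigma <= 0) return(vol)
  K <- gauss_kernel_mat(d[axis], sigma)
  if (axis == 1) {
    array(K %*% matrix(vol, d[1]), d)
  } else if (axis == 2) {
    p <- aperm(vol, c(2, 1, 3))
    aperm(array(K %*% matrix(p, d[2]), c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    p <- aperm(vol, c(3, 1, 2))
    aperm(array(K %*% matrix(p, d[3]), c(d[3], d[1], d[2])), c(2, 3, 1))
  }
}

gauss_smooth <- function(vol, sigma) {
  # sigma: scalar or length-3, in voxels
  sigma <- rep(sigma, length.out = 3)
  for (a in 1:3) if (dim(vol)[a] > 1) vol <- blur_axis(vol, sigma[a], a)
  vol
}

shift_arr <- function(vol, dx = 0, dy = 0, dz = 0) {
  # shift with edge replication
  d <- dim(vol)
  ix <- pmin(pmax(seq_len(d[1]) - dx, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - dy, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3]) - dz, 1), d[3])
  vol[ix, iy, iz, drop = FALSE]
}

# -- normalization & display -------------------------------------------------

#' Normalize slice intensities across a stack
#'
#' Rescales every slice linearly so its mean and standard deviation match the
#' dataset-wide target, computed either over whole slices or only over masked
#' voxels (useful when slice content differs but a common background is
#' present).  Output is clipped to the dataset bit depth.
#'
#' @param ds a `LayeredDataset`
#' @param mode `"whole-slice"` or `"masked-area"` (requires a nonempty mask
#'   on every slice)
#' @return the normalized dataset
#' @export
normalize_slices <- function(ds, mode = c("whole-slice", "masked-area")) {
  mode <- match.arg(mode)
  v <- img3d(ds)
  d <- dim(v)
  msk <- if (mode == "masked-area") {
    m <- get_layer(ds, "mask")
    per <- apply(m, 3, sum)
    if (any(per == 0))
      stop("empty mask on slice(s): ",
           paste(which(per == 0), collapse = ", "))
    m > 0
  } else array(TRUE, d)
  M <- mean(v[msk]); S <- sd(v[msk])
  for (z in seq_len(d[3])) {
    sel <- msk[, , z]
    mk <- mean(v[, , z][sel]); sk <- sd(v[, , z][sel])
    v[, , z] <- if (is.finite(sk) && sk > 0) (v[, , z] - mk) / sk * S + M
                else v[, , z] - mk + M
  }
  ds$image[, , 1, ] <- clip_dtype(v, ds)
  log_action(ds, "normalize_slices", list(mode = mode))
}

#' Brightness / contrast / gamma adjustment
#'
#' Monotone point-wise mapping of the image layer:
#' `y = clip(x * contrast + brightness)^(1/gamma)` on the unit-scaled
#' intensity.  Annotation layers are untouched.  Defaults are the identity.
#'
#' @param ds a `LayeredDataset`
#' @param brightness additive offset in gray levels
#' @param contrast multiplicative gain (>= 0)
#' @param gamma gamma exponent (> 0); endpoints 0 and the dtype maximum are
#'   fixed points
#' @export
adjust_display <- function(ds, brightness = 0, contrast = 1, gamma = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  mx <- dtype_max(ds)
  if (!(brightness == 0 && contrast == 1 && gamma == 1)) {
    x <- ds$image / mx
    y <- pmin(pmax(x * contrast + brightness / mx, 0), 1)^(1 / gamma)
    ds$image <- y * mx
  }
  log_action(ds, "adjust_display",
             list(brightness = brightness, contrast = contrast, gamma = gamma))
}

# -- anisotropic diffusion ---------------------------------------------------

#' Edge-preserving Perona-Malik anisotropic diffusion
#'
#' Iterative diffusion with an edge-stopping conductance: gradients larger
#' than `kappa` diffuse little, so noise in flat regions is removed while
#' object edges stay put.  The default operates per 2-D slice; `dims = "3d"`
#' couples the slices.
#'
#' @param ds a `LayeredDataset` (grayscale)
#' @param iterations number of diffusion steps (>= 1)
#' @param kappa conductance threshold, in intensity units
#' @param lambda integration step, in (0, 0.25] for 2-D stability
#' @param conduction `"exponential"` (`exp(-(g/kappa)^2)`, favors
#'   high-contrast edges) or `"rational"` (`1/(1+(g/kappa)^2)`)
#' @param dims `"2d"` (per slice) or `"3d"`
#' @param roi optional [roi_shape()]: voxels outside are left bit-identical
#' @export
anisotropic_diffusion <- function(ds, iterations = 10, kappa = 20,
                                  lambda = 0.25,
                                  conduction = c("exponential", "rational"),
                                  dims = c("2d", "3d"), roi = NULL) {
  conduction <- match.arg(conduction)
  dims <- match.arg(dims)
  if (lambda <= 0 || lambda > 0.25) stop("lambda must be in (0, 0.25]")
  if (iterations < 1) stop("iterations must be >= 1")
  g <- if (conduction == "exponential") function(d) exp(-(d / kappa)^2)
       else function(d) 1 / (1 + (d / kappa)^2)
  run <- function(v) {
    nbrs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    if (dims == "3d" && dim(v)[3] > 1)
      nbrs <- c(nbrs, list(c(0, 0, 1), c(0, 0, -1)))
    for (it in seq_len(iterations)) {
      acc <- 0
      for (o in nbrs) {
        dd <- shift_arr(v, o[1], o[2], o[3]) - v
        acc <- acc + g(dd) * dd
      }
      v <- v + lambda * acc
    }
    v
  }
  if (is.null(roi)) {
    out <- run(img3d(ds))
  } else {
    out <- roi_apply_volume(img3d(ds), run, roi, pad = iterations + 1L)
  }
  ds$image[, , 1, ] <- clip_dtype(out, ds)
  log_action(ds, "anisotropic_diffusion",
             list(iterations = iterations, kappa = kappa, lambda = lambda,
                  conduction = conduction, dims = dims))
}

# -- morphology --------------------------------------------------------------

element_offsets <- function(shape = c("disk", "ball", "square", "cube"),
                            radius) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  if (r < 1) stop("element radius must be >= 1")
  g <- expand.grid(dx = -r:r, dy = -r:r,
                   dz = if (shape %in% c("ball", "cube")) -r:r else 0L)
  keep <- switch(shape,
    disk = , ball = g$dx^2 + g$dy^2 + g$dz^2 <= r^2,
    square = , cube = rep(TRUE, nrow(g)))
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

morph_vol <- function(vol, operator, offsets) {
  d <- dim(vol)
  dil <- function(v) array(cpp_minmax_filter(v, d, offsets, TRUE), d)
  ero <- function(v) array(cpp_minmax_filter(v, d, offsets, FALSE), d)
  switch(operator,
    dilation = dil(vol),
    erosion = ero(vol),
    opening = dil(ero(vol)),
    closing = ero(dil(vol)),
    `top-hat` = vol - dil(ero(vol)),
    `bottom-hat` = ero(dil(vol)) - vol,
    stop("unknown operator: ", operator))
}

#' Grayscale / binary morphological filtering
#'
#' Standard flat-structuring-element morphology.  The bottom-hat (closing
#' minus image) highlights dark structures smaller than the element; the
#' top-hat highlights bright ones.  Binary layers can be passed directly as
#' arrays.
#'
#' @param x a `LayeredDataset` (image layer is filtered) or a 3-D array
#' @param operator `"erosion"`, `"dilation"`, `"opening"`, `"closing"`,
#'   `"top-hat"` or `"bottom-hat"`
#' @param radius structuring-element radius in voxels (>= 1)
#' @param dims `"2d"` (disk, per slice) or `"3d"` (ball)
#' @param shape optional element shape override
#' @param roi optional [roi_shape()] restriction
#' @return object of the same kind as `x`
#' @export
morphology_filter <- function(x, operator, radius = 2, dims = c("2d", "3d"),
                              shape = NULL, roi = NULL) {
  dims <- match.arg(dims)
  is_ds <- inherits(x, "LayeredDataset")
  vol <- if (is_ds) img3d(x) else x
  if (dims == "3d" && dim(vol)[3] == 1)
    stop("3-D structuring element on single-slice data")
  shape <- shape %||% if (dims == "3d") "ball" else "disk"
  off <- element_offsets(shape, radius)
  run <- function(v) morph_vol(v, operator, off)
  out <- if (is.null(roi)) run(vol)
         else roi_apply_volume(vol, run, roi, pad = as.integer(radius) * 2L)
  if (!is_ds) return(out)
  x$image[, , 1, ] <- clip_dtype(out, x)
  log_action(x, "morphology_filter",
             list(operator = operator, radius = radius, dims = dims,
                  shape = shape))
}

#' Spacing-aware gradient magnitude
#'
#' Central-difference gradient magnitude in physical units per voxel size,
#' so anisotropic data get correct per-axis weighting.  Often used to create
#' boundary relief for watershed segmentation of objects without stained
#' boundaries.
#'
#' @param ds a `LayeredDataset`
#' @return 3-D array of gradient magnitudes
#' @export
gradient_magnitude <- function(ds) {
  v <- img3d(ds)
  vs <- unname(ds$geometry$voxel_size)
  gx <- (shift_arr(v, -1, 0, 0) - shift_arr(v, 1, 0, 0)) / (2 * vs[1])
  gy <- (shift_arr(v, 0, -1, 0) - shift_arr(v, 0, 1, 0)) / (2 * vs[2])
  g2 <- gx^2 + gy^2
  if (dim(v)[3] > 1) {
    gz <- (shift_arr(v, 0, 0, -1) - shift_arr(v, 0, 0, 1)) / (2 * vs[3])
    g2 <- g2 + gz^2
  }
  sqrt(g2)
}

# -- Frangi vesselness -------------------------------------------------------

hessian_2d <- function(sl, sigma) {
  # scale-normalized Hessian of one 2-D slice (as nx x ny x 1 array ops)
  v <- array(sl, c(dim(sl), 1))
  s <- gauss_smooth(v, c(sigma, sigma, 0))
  dxx <- shift_arr(s, -1, 0, 0) - 2 * s + shift_arr(s, 1, 0, 0)
  dyy <- shift_arr(s, 0, -1, 0) - 2 * s + shift_arr(s, 0, 1, 0)
  dx <- (shift_arr(s, -1, 0, 0) - shift_arr(s, 1, 0, 0)) / 2
  dxy <- (shift_arr(dx, 0, -1, 0) - shift_arr(dx, 0, 1, 0)) / 2
  n <- sigma^2
  list(xx = n * dxx[, , 1], yy = n * dyy[, , 1], xy = n * dxy[, , 1])
}

frangi_slice <- function(sl, scales, beta, cpar, polarity) {
  best <- array(0, dim(sl))
  for (sg in scales) {
    H <- hessian_2d(sl, sg)
    tr <- H$xx + H$yy
    disc <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
    l1 <- (tr + disc) / 2
    l2 <- (tr - disc) / 2
    swap <- abs(l1) > abs(l2)  # ensure |l1| <= |l2|
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    S2 <- l1^2 + l2^2
    c2 <- if (is.null(cpar)) pmax(max(sqrt(S2)) / 2, .Machine$double.eps)^2
          else cpar^2
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    V <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    V[if (polarity == "dark") l2 < 0 else l2 > 0] <- 0
    V[l2 == 0 | S2 < 1e-12] <- 0
    best <- pmax(best, V)
  }
  best
}

#' Multiscale Frangi vesselness filter
#'
#' Hessian-eigenvalue measure of how tube-like the local structure is,
#' maximized over Gaussian scales, for detection of elongated tubular
#' structures (membrane profiles, ER tubules, vessels).  Modes: per-XY-slice
#' 2-D, full 3-D, or sequential 2-D in the XY then ZX planes combined by
#' voxel-wise maximum (union of tubular evidence across orientations).
#'
#' @param ds a `LayeredDataset`
#' @param scales Gaussian sigmas in voxels, ascending; a tube of radius `r`
#'   responds most strongly near `sigma = r/sqrt(2)`
#' @param alpha plate/line discrimination weight (3-D only)
#' @param beta blob discrimination weight
#' @param c structureness weight; default half the maximum Hessian norm per
#'   slice/volume
#' @param polarity `"dark"` (EM-style dark structures) or `"bright"`
#' @param planes `"2d-per-slice"`, `"3d"` or `"sequential-planes"`
#' @return vesselness volume normalized to [0, 1]
#' @export
frangi_filter <- function(ds, scales = c(1, 2, 3), alpha = 0.5, beta = 0.5,
                          c = NULL, polarity = c("dark", "bright"),
                          planes = c("2d-per-slice", "3d",
                                     "sequential-planes")) {
  polarity <- match.arg(polarity)
  planes <- match.arg(planes)
  if (!length(scales)) stop("at least one scale required")
  if (is.unsorted(scales) || any(scales <= 0))
    stop("scales must be ascending and > 0")
  v <- img3d(ds)
  slicewise <- function(vol) {
    out <- array(0, dim(vol))
    for (z in seq_len(dim(vol)[3]))
      out[, , z] <- frangi_slice(vol[, , z], scales, beta, c, polarity)
    out
  }
  if (planes == "2d-per-slice") {
    out <- slicewise(v)
  } else if (planes == "sequential-planes") {
    xy <- slicewise(v)
    zx <- aperm(slicewise(aperm(v, c(1, 3, 2))), c(1, 3, 2))
    out <- pmax(xy, zx)
  } else {
    if (dim(v)[3] < 5) stop("3-D vesselness needs >= 5 slices")
    out <- frangi_3d(v, scales, alpha, beta, c, polarity)
  }
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

frangi_3d <- function(v, scales, alpha, beta, cpar, polarity) {
  best <- array(0, dim(v))
  for (sg in scales) {
    s <- gauss_smooth(v, sg)
    d1 <- function(a) (shift_arr(s, -(a == 1), -(a == 2), -(a == 3)) -
                       shift_arr(s, (a == 1), (a == 2), (a == 3))) / 2
    d2 <- function(a) shift_arr(s, -(a == 1), -(a == 2), -(a == 3)) - 2 * s +
                      shift_arr(s, (a == 1), (a == 2), (a == 3))
    n <- sg^2
    hxx <- n * d2(1); hyy <- n * d2(2); hzz <- n * d2(3)
    gx <- d1(1); gy <- d1(2)
    hxy <- n * (shift_arr(gx, 0, -1, 0) - shift_arr(gx, 0, 1, 0)) / 2
    hxz <- n * (shift_arr(gx, 0, 0, -1) - shift_arr(gx, 0, 0, 1)) / 2
    hyz <- n * (shift_arr(gy, 0, 0, -1) - shift_arr(gy, 0, 0, 1)) / 2
    ev <- eig_sym3(hxx, hxy, hxz, hyy, hyz, hzz)   # sorted by |.| ascending
    l1 <- ev[[1]]; l2 <- ev[[2]]; l3 <- ev[[3]]
    S2 <- l1^2 + l2^2 + l3^2
    c2 <- if (is.null(cpar)) pmax(max(sqrt(S2)) / 2, .Machine$double.eps)^2
          else cpar^2
    Ra2 <- ifelse(l3 != 0, (l2 / l3)^2, 0)
    Rb2 <- ifelse(l2 * l3 != 0, l1^2 / abs(l2 * l3), 0)
    V <- (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
         (1 - exp(-S2 / (2 * c2)))
    bad <- if (polarity == "dark") (l2 <= 0 | l3 <= 0) else (l2 >= 0 | l3 >= 0)
    V[bad | S2 < 1e-12] <- 0
    best <- pmax(best, V)
  }
  best
}

eig_sym3 <- function(a11, a12, a13, a22, a23, a33) {
  # vectorized closed-form eigenvalues of symmetric 3x3 fields,
  # returned sorted by absolute value (ascending)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 1e-12
  if (any(nz)) {
    b11 <- (a11 - q) / p; b12 <- a12 / p; b13 <- a13 / p
    b22 <- (a22 - q) / p; b23 <- a23 / p; b33 <- (a33 - q) / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    l1 <- ifelse(nz, e1, q); l2 <- ifelse(nz, e2, q); l3 <- ifelse(nz, e3, q)
  }
  # sort triple by |.|
  d <- dim(a11)
  M <- cbind(as.vector(l1), as.vector(l2), as.vector(l3))
  A <- abs(M)
  o1 <- max.col(-A, ties.method = "first")
  o3 <- max.col(A, ties.method = "last")
  pick <- function(o) M[cbind(seq_len(nrow(M)), o)]
  s1 <- pick(o1); s3 <- pick(o3)
  s2 <- rowSums(M) - s1 - s3
  list(array(s1, d), array(s2, d), array(s3, d))
}

# -- region-of-interest machinery --------------------------------------------

#' Describe an arbitrarily shaped region of interest
#'
#' Filters can be applied to rectangular, ellipsoidal or polygonal regions of
#' interest; the ROI is rasterized deterministically per slice.
#'
#' @param kind `"rectangle"`, `"ellipse"` or `"polygon"`
#' @param x,y for rectangle: inclusive index ranges `c(lo, hi)`
#' @param center,radii for ellipse: center and semi-axes in voxels
#' @param vertices for polygon: 2-column matrix of (x, y) vertices
#' @param slices slice range (default: all)
#' @return object of class `ROIShape`
#' @export
roi_shape <- function(kind = c("rectangle", "ellipse", "polygon"),
                      x = NULL, y = NULL, center = NULL, radii = NULL,
                      vertices = NULL, slices = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, x = x, y = y, center = center, radii = radii,
                 vertices = vertices, slices = slices), class = "ROIShape")
}

#' Rasterize an ROI to a binary volume
#' @param roi an [roi_shape()]
#' @param dim3 spatial shape (nx, ny, nz)
#' @return 3-D logical array
#' @export
rasterize_roi <- function(roi, dim3) {
  nx <- dim3[1]; ny <- dim3[2]; nz <- dim3[3]
  m <- matrix(FALSE, nx, ny)
  if (roi$kind == "rectangle") {
    m[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2]] <- TRUE
  } else if (roi$kind == "ellipse") {
    gx <- matrix(seq_len(nx), nx, ny)
    gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    m <- ((gx - roi$center[1]) / roi$radii[1])^2 +
         ((gy - roi$center[2]) / roi$radii[2])^2 <= 1
  } else {
    vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
    nv <- length(vx)
    gx <- as.vector(matrix(seq_len(nx), nx, ny))
    gy <- as.vector(matrix(seq_len(ny), nx, ny, byrow = TRUE))
    inside <- rep(FALSE, nx * ny)
    j <- nv
    for (i in seq_len(nv)) {  # even-odd crossing rule
      cross <- ((vy[i] > gy) != (vy[j] > gy)) &
        (gx < (vx[j] - vx[i]) * (gy - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, cross)
      j <- i
    }
    m <- matrix(inside, nx, ny)
  }
  if (!any(m)) stop("ROI rasterizes to an empty region")
  sl <- roi$slices %||% c(1, nz)
  out <- array(FALSE, dim3)
  out[, , sl[1]:sl[2]] <- m
  out
}

roi_apply_volume <- function(vol, fun, roi, pad) {
  d <- dim(vol)
  mask <- rasterize_roi(roi, d)
  idx <- which(mask, arr.ind = TRUE)
  roi_min <- apply(idx, 2, min)
  roi_max <- apply(idx, 2, max)
  lo <- pmax(roi_min - pad, 1)
  hi <- pmin(roi_max + pad, d)
  if (any((roi_max - roi_min + 1)[1:2] < pad))
    warning("ROI smaller than the filter support; boundary effects possible")
  crop <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  res <- fun(crop)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- vol
  tgt <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  tgt[sub] <- res[sub]
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- tgt
  out
}

#' Apply any volume filter inside an ROI only
#'
#' Voxels outside the ROI stay bit-identical to the input; inside, the
#' result equals the filter run on a crop padded by the filter support.
#' @param vol 3-D array
#' @param fun function from 3-D array to 3-D array of the same shape
#' @param roi an [roi_shape()]
#' @param pad padding in voxels (the filter support)
#' @return filtered volume
#' @export
apply_in_roi <- function(vol, fun, roi, pad = 4L) {
  roi_apply_volume(vol, fun, roi, pad)
}
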