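# Synthetic phantom generators.  Phantoms emulate the contrast situations of
# EM/LM organelle datasets (dark-stained structures on a bright background,
# or fluorescent bright-on-dark), with partial-volume antialiased rendering,
# Gaussian noise and optional slice-wise intensity drift.  Ground truth is
# the pre-noise ideal label field.

# coverage of one ellipsoid (physical semi-axes) into vol/gt, in place style
render_ellipsoid <- function(state, center, semiaxes, intensity, label,
                             overwrite = TRUE) {
  d <- dim(state$img)
  vs <- state$vs
  rvox <- semiaxes / vs
  lo <- pmax(floor(center - rvox - 2), 1)
  hi <- pmin(ceiling(center + rvox + 2), d)
  if (any(lo > hi)) return(state)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- (ix - center[1]) * vs[1] / semiaxes[1]
  gy <- (iy - center[2]) * vs[2] / semiaxes[2]
  gz <- (iz - center[3]) * vs[3] / semiaxes[3]
  r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  # approximate signed distance to the surface in physical units
  rr <- sqrt(r2)
  sd_phys <- (rr - 1) * min(semiaxes)
  w <- min(vs)
  cov <- pmin(pmax(0.5 - sd_phys / w, 0), 1)
  sub_img <- state$img[ix, iy, iz]
  sub_gt <- state$gt[ix, iy, iz]
  blend <- cov > 0 & (overwrite | sub_gt == 0L)
  sub_img[blend] <- sub_img[blend] * (1 - cov[blend]) +
    intensity * cov[blend]
  core <- cov >= 0.5 & (overwrite | sub_gt == 0L)
  sub_gt[core] <- label
  state$img[ix, iy, iz] <- sub_img
  state$gt[ix, iy, iz] <- sub_gt
  state
}

render_tube_segment <- function(state, p0, p1, radius, intensity, label) {
  # p0, p1, radius in physical units; voxel coords derived from state$vs
  d <- dim(state$img)
  vs <- state$vs
  v0 <- p0 / vs; v1 <- p1 / vs
  rvox <- radius / vs
  lo <- pmax(floor(pmin(v0, v1) - rvox - 2), 1)
  hi <- pmin(ceiling(pmax(v0, v1) + rvox + 2), d)
  if (any(lo > hi)) return(state)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  px <- ix * vs[1]; py <- iy * vs[2]; pz <- iz * vs[3]
  g <- expand.grid(x = px, y = py, z = pz)
  ab <- p1 - p0
  len2 <- sum(ab^2)
  ap <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
  t <- if (len2 > 0) pmin(pmax((ap %*% ab) / len2, 0), 1) else 0
  dx <- ap[, 1] - t * ab[1]; dy <- ap[, 2] - t * ab[2]; dz <- ap[, 3] - t * ab[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  w <- min(vs)
  cov <- array(pmin(pmax(0.5 - (dist - radius) / w, 0), 1),
               c(length(ix), length(iy), length(iz)))
  sub_img <- state$img[ix, iy, iz]
  sub_gt <- state$gt[ix, iy, iz]
  blend <- cov > 0 & sub_gt == 0L | cov > 0 & sub_gt == label
  sub_img[blend] <- sub_img[blend] * (1 - cov[blend]) + intensity * cov[blend]
  core <- cov >= 0.5 & (sub_gt == 0L | sub_gt == label)
  sub_gt[core] <- label
  state$img[ix, iy, iz] <- sub_img
  state$gt[ix, iy, iz] <- sub_gt
  state
}

new_render_state <- function(shape, vs, background) {
  list(img = array(background, shape), gt = array(0L, shape), vs = vs)
}

finish_phantom <- function(state, voxel_size, units, noise_sd, drift_sd,
                           bitdepth = 8, seed_done = TRUE) {
  img <- state$img
  d <- dim(img)
  if (drift_sd > 0) {
    drift <- seq(-drift_sd, drift_sd, length.out = d[3]) * sqrt(3)
    for (z in seq_len(d[3])) img[, , z] <- img[, , z] + drift[z]
  }
  if (noise_sd > 0) img <- img + array(rnorm(length(img), 0, noise_sd), d)
  mx <- if (bitdepth == 8) 255 else 65535
  img[img < 0] <- 0; img[img > mx] <- mx
  ds <- layered_dataset(img, voxel_size = voxel_size, units = units,
                        bitdepth = bitdepth)
  list(ds = ds, gt = state$gt)
}

#' Specification for a synthetic phantom
#'
#' @param shape spatial shape (nx, ny, nz)
#' @param voxel_size physical voxel size
#' @param units length unit
#' @param background background intensity (8-bit scale)
#' @param noise_sd Gaussian noise standard deviation (default 5% of the
#'   8-bit dynamic range)
#' @param drift_sd slice-wise linear intensity drift amplitude (standard
#'   deviation across the stack), exercising slice normalization
#' @param objects list of object groups; each a list with `kind`
#'   (`"sphere"`, `"tube"`, `"sheet"`), `n`, `radius = c(min, max)` (voxels),
#'   `intensity`, optional `class` name
#' @param seed RNG seed: the same seed yields a bit-identical phantom
#' @return object of class `PhantomSpec`
#' @export
phantom_spec <- function(shape = c(64, 64, 32), voxel_size = c(1, 1, 1),
                         units = "nm", background = 170, noise_sd = 12.75,
                         drift_sd = 0, objects = list(), seed = 1) {
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 units = units, background = background, noise_sd = noise_sd,
                 drift_sd = drift_sd, objects = objects, seed = seed),
            class = "PhantomSpec")
}

#' Generate a phantom dataset with ground truth
#'
#' Objects are rendered with partial-volume antialiasing, then noise and
#' drift are added; the ground truth is the pre-noise ideal label field.
#' Object classes get consecutive class labels in the order given; the
#' per-object table records kind, center and size.
#'
#' @param spec a [phantom_spec()]
#' @return list with `ds` (a `LayeredDataset`), `gt` (class label volume),
#'   `objects` (per-object data.frame), `classes` (class names)
#' @export
make_phantom <- function(spec) {
  set.seed(spec$seed)
  d <- spec$shape
  vs <- rep(spec$voxel_size, length.out = 3)
  st <- new_render_state(d, vs, spec$background)
  rows <- list()
  placed <- matrix(numeric(0), 0, 4)  # physical center + radius
  classes <- character()
  for (ci in seq_along(spec$objects)) {
    ob <- spec$objects[[ci]]
    cls <- ob$class %||% paste0(ob$kind, ci)
    classes <- c(classes, cls)
    for (k in seq_len(ob$n)) {
      r <- runif(1, ob$radius[1], ob$radius[2]) * min(vs)
      if (ob$kind == "sphere") {
        if (any((r / vs) + 2 >= d - (r / vs) - 1)) {
          warning("sphere of radius ", signif(r, 3), " does not fit; skipped")
          next
        }
        ctr <- NULL
        for (try in 1:200) {
          cand <- sapply(1:3, function(a)
            runif(1, (r / vs[a]) + 2, d[a] - (r / vs[a]) - 1))
          cph <- cand * vs
          if (!nrow(placed) ||
              all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cph)^2)) >
                  placed[, 4] + r + 2 * min(vs))) {
            ctr <- cand
            break
          }
        }
        if (is.null(ctr)) next
        placed <- rbind(placed, c(ctr * vs, r))
        st <- render_ellipsoid(st, ctr, rep(r, 3), ob$intensity, ci)
        rows[[length(rows) + 1]] <- data.frame(class = cls, kind = "sphere",
          cx = ctr[1], cy = ctr[2], cz = ctr[3], size = r)
      } else if (ob$kind == "tube") {
        npts <- ob$points %||% 6
        p <- sapply(1:3, function(a) runif(1, 0.15, 0.85) * d[a] * vs[a])
        for (s in seq_len(npts)) {
          q <- p + rnorm(3, 0, mean(d * vs) * 0.12)
          q <- pmin(pmax(q, 2 * vs), (d - 2) * vs)
          st <- render_tube_segment(st, p, q, r, ob$intensity, ci)
          p <- q
        }
        rows[[length(rows) + 1]] <- data.frame(class = cls, kind = "tube",
          cx = NA, cy = NA, cz = NA, size = r)
      } else if (ob$kind == "sheet") {
        # axis-aligned thin slab at a random x position
        x0 <- round(runif(1, 0.2, 0.8) * d[1])
        th <- max(1, round(r / vs[1]))
        ix <- max(1, x0 - th):min(d[1], x0 + th)
        st$img[ix, , ] <- ob$intensity
        st$gt[ix, , ] <- ci
        rows[[length(rows) + 1]] <- data.frame(class = cls, kind = "sheet",
          cx = x0, cy = NA, cz = NA, size = th)
      }
    }
  }
  out <- finish_phantom(st, vs, spec$units, spec$noise_sd, spec$drift_sd)
  out$objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), kind = character())
  out$classes <- classes
  out
}

#' Two partially fused spheres with ground truth kept separate
#'
#' Emulates clustered lipid droplets that appear merged in a binary
#' rendering: two spheres of equal radius with center distance below their
#' diameter form a single connected component, while the ground truth keeps
#' them as two objects.  The analytic split plane (perpendicular bisector of
#' the centers) is recorded for validating object separation.
#'
#' @param radius sphere radius, physical units
#' @param center_distance distance between centers (0 < d < 2 radius)
#' @param voxel_size physical voxel size (use e.g. `c(5, 5, 25)` for a 5:1
#'   anisotropic grid)
#' @param intensity,background object/background gray levels
#' @param noise_sd Gaussian noise level
#' @param seed RNG seed
#' @return list with `ds`, `gt` (labels 1 and 2), `split_plane_x` (physical
#'   x of the bisector plane), `centers`
#' @export
make_fused_pair <- function(radius = 10, center_distance = 14,
                            voxel_size = c(1, 1, 1), intensity = 40,
                            background = 170, noise_sd = 6, seed = 1) {
  if (center_distance <= 0 || center_distance >= 2 * radius)
    stop("need 0 < center_distance < 2*radius")
  set.seed(seed)
  vs <- rep(voxel_size, length.out = 3)
  margin <- radius * 1.6
  nx <- ceiling((center_distance + 2 * margin) / vs[1])
  ny <- ceiling(2 * margin / vs[2])
  nz <- ceiling(2 * margin / vs[3])
  d <- c(nx, ny, nz)
  st <- new_render_state(d, vs, background)
  cy <- d[2] / 2; cz <- d[3] / 2
  c1 <- c((margin) / vs[1], cy, cz)
  c2 <- c((margin + center_distance) / vs[1], cy, cz)
  st <- render_ellipsoid(st, c1, rep(radius, 3), intensity, 1L)
  st <- render_ellipsoid(st, c2, rep(radius, 3), intensity, 2L, overwrite = FALSE)
  out <- finish_phantom(st, vs, "nm", noise_sd, 0)
  out$split_plane_x <- (c1[1] + c2[1]) / 2 * vs[1]
  out$centers <- rbind(c1 * vs, c2 * vs)
  out
}

#' Nucleus phantom: membrane-bounded sphere
#'
#' A large sphere with a dark bounding membrane on a brighter background,
#' the classic situation where two marker scribbles on a single slice
#' suffice to segment the whole organelle in 3-D with marker-controlled
#' watershed.
#' @param shape spatial shape
#' @param radius nucleus radius in voxels
#' @param seed RNG seed
#' @param noise_sd noise level
#' @return list with `ds`, `gt` (1 = nucleus interior incl. membrane)
#' @export
make_nucleus_phantom <- function(shape = c(96, 96, 96), radius = 30,
                                 noise_sd = 8, seed = 1) {
  set.seed(seed)
  d <- as.integer(shape)
  st <- new_render_state(d, c(1, 1, 1), 165)
  ctr <- d / 2 + runif(3, -2, 2)
  st <- render_ellipsoid(st, ctr, rep(radius, 3), 45, 1L)        # membrane
  st <- render_ellipsoid(st, ctr, rep(radius - 2.5, 3), 120, 1L) # interior
  out <- finish_phantom(st, c(1, 1, 1), "nm", noise_sd, 0)
  out$center <- ctr
  out$radius <- radius
  out
}

#' Tubular-network phantom (ER-style)
#'
#' Random-walk tubular network, rendered dark on bright (EM, cytochemical
#' stain) or bright on dark (LM, fluorescence), plus optional small speckle
#' objects emulating spurious stained dots that quantification filtering
#' should remove.
#' @param shape spatial shape
#' @param n_tubes number of random-walk tubes
#' @param tube_radius tube radius in voxels
#' @param polarity `"dark"` or `"bright"`
#' @param n_speckles number of small spurious objects
#' @param noise_sd noise level
#' @param seed RNG seed
#' @return list with `ds`, `gt` (1 = network, 2 = speckles)
#' @export
make_network_phantom <- function(shape = c(96, 96, 48), n_tubes = 12,
                                 tube_radius = 2.5,
                                 polarity = c("dark", "bright"),
                                 n_speckles = 0, noise_sd = 8, seed = 1) {
  polarity <- match.arg(polarity)
  set.seed(seed)
  d <- as.integer(shape)
  bg <- if (polarity == "dark") 170 else 30
  fg <- if (polarity == "dark") 60 else 200
  st <- new_render_state(d, c(1, 1, 1), bg)
  for (k in seq_len(n_tubes)) {
    p <- sapply(1:3, function(a) runif(1, 0.15, 0.85) * d[a])
    for (s in 1:6) {
      q <- p + rnorm(3, 0, mean(d) * 0.15)
      q <- pmin(pmax(q, 3), d - 3)
      st <- render_tube_segment(st, p, q, tube_radius, fg, 1L)
      p <- q
    }
  }
  if (n_speckles > 0) {
    for (k in seq_len(n_speckles)) {
      ctr <- round(sapply(1:3, function(a) runif(1, 5, d[a] - 5)))
      # speckles stay clear of the network so they remain isolated objects
      nb <- st$gt[max(1, ctr[1] - 4):min(d[1], ctr[1] + 4),
                  max(1, ctr[2] - 4):min(d[2], ctr[2] + 4),
                  max(1, ctr[3] - 4):min(d[3], ctr[3] + 4)]
      if (any(nb != 0)) next
      st <- render_ellipsoid(st, ctr, rep(runif(1, 1, 1.6), 3), fg, 2L,
                             overwrite = FALSE)
    }
  }
  finish_phantom(st, c(1, 1, 1), "nm", noise_sd, 0)
}

#' Membrane phantom: thin dark sheets for the membrane classifier
#' @param shape spatial shape
#' @param n_membranes number of sheets
#' @param thickness full sheet thickness in voxels
#' @param noise_sd noise level
#' @param seed RNG seed
#' @return list with `ds`, `gt` (1 = membrane)
#' @export
make_membrane_phantom <- function(shape = c(96, 96, 8), n_membranes = 4,
                                  thickness = 3, noise_sd = 7, seed = 1) {
  set.seed(seed)
  d <- as.integer(shape)
  st <- new_render_state(d, c(1, 1, 1), 165)
  for (k in seq_len(n_membranes)) {
    # gently curved sheet: x = x0 + a*sin(w*y), spanning y and z
    x0 <- runif(1, 0.15, 0.85) * d[1]
    a <- runif(1, 2, 6)
    w <- runif(1, 1, 2) * pi / d[2]
    ph <- runif(1, 0, 2 * pi)
    for (z in seq_len(d[3])) {
      prev <- NULL
      for (y in seq_len(d[2])) {
        xc <- x0 + a * sin(w * y + ph)
        p0 <- c(if (is.null(prev)) xc else prev, y - 1, z)
        p1 <- c(xc, y, z)
        st <- render_tube_segment(st, p0, p1, thickness / 2, 55, 1L)
        prev <- xc
      }
    }
  }
  finish_phantom(st, c(1, 1, 1), "nm", noise_sd, 0)
}

#' Composite mitotic-cell phantom
#'
#' A densely packed cell volume emulating the organelle contrasts of a
#' cytochemically stained metaphase cell: a dark tubular ER network, very
#' dark singular organelles of three size classes (lipid droplets,
#' lysosomes, peroxisomes), a central irregular chromosome mass with an
#' intensity close to the mitochondria (so that global thresholding cannot
#' discriminate them), and medium-dark mitochondria.  The chromosome mass
#' contains dark mottling so that a threshold tuned for singular organelles
#' also catches part of it.  Class mean darkness ordering:
#' singular organelles > ER lumen > chromosomes ~ mitochondria > background.
#'
#' @param seed RNG seed
#' @param shape spatial shape (default 192^3)
#' @param noise_sd Gaussian noise level
#' @return list with `ds`, `gt` (labels 1..6 in the order ER, lysosome,
#'   peroxisome, LD, chromosome, mitochondrion), `classes`, `intensities`
#' @export
make_mitotic_phantom <- function(seed = 1, shape = c(192, 192, 192),
                                 noise_sd = 8) {
  set.seed(seed)
  d <- as.integer(rep(shape, length.out = 3))
  classes <- c("ER", "lysosome", "peroxisome", "LD", "chromosome",
               "mitochondrion")
  ints <- c(ER = 85, lysosome = 35, peroxisome = 32, LD = 30,
            chromosome = 112, mitochondrion = 118)
  bg <- 170
  st <- new_render_state(d, c(1, 1, 1), bg)
  ctr <- d / 2

  # 1: ER — tubular network threading the cytoplasm (rendered first; other
  # organelles displace it, as they do in a crowded cell)
  n_tubes <- max(8, round(prod(d) / 3e5))
  for (k in seq_len(n_tubes)) {
    p <- sapply(1:3, function(a) runif(1, 0.1, 0.9) * d[a])
    for (s in 1:7) {
      q <- p + rnorm(3, 0, mean(d) * 0.13)
      q <- pmin(pmax(q, 4), d - 4)
      st <- render_tube_segment(st, p, q, 2.2, ints["ER"], 1L)
      p <- q
    }
  }

  # 5: chromosome — central irregular mass of overlapping ellipsoids
  chrom_r <- mean(d) * 0.11
  for (k in 1:7) {
    cc <- ctr + rnorm(3, 0, chrom_r * 0.5)
    ax <- chrom_r * runif(3, 0.55, 1.0)
    st <- render_ellipsoid(st, cc, ax, ints["chromosome"], 5L)
  }

  # singular organelles + mitochondria in the cytoplasm, kept off the
  # chromosome region and off each other
  placed <- matrix(numeric(0), 0, 4)
  chrom_excl <- chrom_r * 1.8
  place_sphere <- function(r) {
    for (try in 1:300) {
      cand <- sapply(1:3, function(a) runif(1, r + 3, d[a] - r - 3))
      if (sqrt(sum((cand - ctr)^2)) < chrom_excl + r) next
      if (nrow(placed) &&
          any(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cand)^2)) <
              placed[, 4] + r + 3)) next
      return(cand)
    }
    NULL
  }
  scale_n <- prod(d) / 192^3
  spec_sing <- list(
    list(lab = 4L, n = max(4, round(8 * scale_n)), r = c(7, 9), cls = "LD"),
    list(lab = 2L, n = max(4, round(8 * scale_n)), r = c(4.5, 5.5), cls = "lysosome"),
    list(lab = 3L, n = max(4, round(8 * scale_n)), r = c(2.8, 3.5), cls = "peroxisome"))
  for (sp in spec_sing) {
    for (k in seq_len(sp$n)) {
      r <- runif(1, sp$r[1], sp$r[2])
      cand <- place_sphere(r)
      if (is.null(cand)) next
      placed <- rbind(placed, c(cand, r))
      st <- render_ellipsoid(st, cand, rep(r, 3), ints[sp$cls], sp$lab)
    }
  }
  # 6: mitochondria — ellipsoids with ~2:1 aspect, axis-aligned random axis
  n_mito <- max(6, round(12 * scale_n))
  for (k in seq_len(n_mito)) {
    ax <- c(runif(1, 9, 12), runif(1, 4.5, 6), runif(1, 4.5, 6))
    ax <- ax[sample(3)]
    r <- max(ax)
    cand <- place_sphere(r)
    if (is.null(cand)) next
    placed <- rbind(placed, c(cand, r))
    st <- render_ellipsoid(st, cand, ax, ints["mitochondrion"], 6L)
  }

  # dark mottling inside the chromosome: a singular-organelle threshold
  # also catches these, which is why chromosomes need local masking
  chrom_idx <- which(st$gt == 5L)
  n_spots <- max(20, round(length(chrom_idx) / 400))
  spots <- sample(chrom_idx, min(n_spots, length(chrom_idx)))
  ar <- arrayInd(spots, d)
  for (i in seq_len(nrow(ar))) {
    sub <- st$img
    ix <- max(1, ar[i, 1] - 1):min(d[1], ar[i, 1] + 1)
    iy <- max(1, ar[i, 2] - 1):min(d[2], ar[i, 2] + 1)
    iz <- ar[i, 3]
    msk <- st$gt[ix, iy, iz] == 5L
    tmp <- st$img[ix, iy, iz]
    tmp[msk] <- 50
    st$img[ix, iy, iz] <- tmp
  }

  out <- finish_phantom(st, c(1, 1, 1), "nm", noise_sd, 0)
  out$classes <- classes
  out$intensities <- ints
  out$chrom_center <- ctr
  out
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`, the standard overlap score for comparing a
#' segmentation with ground truth.
#' @param a,b binary arrays (nonzero = foreground)
#' @return Dice coefficient in [0, 1] (1 when both are empty)
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
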