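# Semiautomatic segmentation engines: SLIC superpixels/supervoxels with a
# region adjacency graph, interactive graph-cut (max-flow/min-cut) over
# supervoxels, marker-controlled watershed, distance-transform object
# separation, and the two random-forest classifiers (per-voxel membrane
# detection and per-supervoxel intensity classification).

#' Cluster voxels into SLIC superpixels / supervoxels
#'
#' Simple linear iterative clustering in physical coordinates: on
#' anisotropic grids the spatial distance term uses the voxel size, so
#' supervoxels stay approximately isotropic in physical space.  The
#' partition carries per-region intensity statistics and the region
#' adjacency (face-touching) used by the graph-cut and the supervoxel
#' classifier.
#'
#' @param ds a `LayeredDataset`
#' @param target_size target region size in voxels (>= 8)
#' @param compactness spatial regularization weight in intensity units;
#'   default 5% of the dataset dynamic range
#' @param dims `"3d"` (supervoxels) or `"2d"` (per-slice superpixels)
#' @param iters SLIC iterations
#' @return object of class `SupervoxelPartition` with fields `labels`
#'   (1-based 3-D array), `n_regions`, `stats` (mean/min/max/size per
#'   region), `adjacency` (2-column matrix), `dims`
#' @export
slic_partition <- function(ds, target_size = 125, compactness = NULL,
                           dims = c("3d", "2d"), iters = 8) {
  dims <- match.arg(dims)
  if (target_size < 8) stop("target_size must be >= 8")
  d <- ds_dim(ds)
  v <- img3d(ds)
  vs <- unname(ds$geometry$voxel_size)
  if (is.null(compactness)) compactness <- 0.05 * dtype_max(ds)
  if (target_size > prod(d))
    warning("target_size exceeds the volume: single region")
  if (dims == "3d") {
    step <- (target_size * prod(vs))^(1 / 3)
    lab <- array(cpp_slic(v, d, vs, step, compactness, as.integer(iters)),
                 d) + 1L
  } else {
    step <- sqrt(target_size * vs[1] * vs[2])
    lab <- array(0L, d)
    off <- 0L
    for (z in seq_len(d[3])) {
      lz <- cpp_slic(array(v[, , z], c(d[1], d[2], 1L)),
                     c(d[1], d[2], 1L), vs, step, compactness,
                     as.integer(iters))
      lab[, , z] <- lz + 1L + off
      off <- off + max(lz) + 1L
    }
  }
  sp <- structure(list(labels = lab, n_regions = max(lab),
                       target_size = target_size, compactness = compactness,
                       dims = dims), class = "SupervoxelPartition")
  sp$stats <- region_stats(v, lab, sp$n_regions)
  sp$adjacency <- region_adjacency(lab)
  sp
}

#' @export
print.SupervoxelPartition <- function(x, ...) {
  cat(sprintf("<SupervoxelPartition> %d regions (%s), target %d voxels\n",
              x$n_regions, x$dims, x$target_size))
  invisible(x)
}

region_stats <- function(v, lab, n) {
  f <- factor(lab, levels = seq_len(n))
  size <- as.integer(tabulate(lab, n))
  data.frame(id = seq_len(n),
             mean = as.numeric(rowsum(as.vector(v), f) / pmax(size, 1)),
             min = as.numeric(tapply(as.vector(v), f, min, default = NA)),
             max = as.numeric(tapply(as.vector(v), f, max, default = NA)),
             size = size)
}

region_adjacency <- function(lab) {
  d <- dim(lab)
  pairs <- NULL
  if (d[1] > 1)
    pairs <- rbind(pairs, cbind(as.vector(lab[-d[1], , ]),
                                as.vector(lab[-1, , ])))
  if (d[2] > 1)
    pairs <- rbind(pairs, cbind(as.vector(lab[, -d[2], ]),
                                as.vector(lab[, -1, ])))
  if (d[3] > 1)
    pairs <- rbind(pairs, cbind(as.vector(lab[, , -d[3]]),
                                as.vector(lab[, , -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

#' Sparse object/background seed annotations
#' @param object,background binary arrays or `n x 3` voxel coordinate
#'   matrices marking the two classes
#' @param shape spatial shape (required for coordinate input)
#' @return object of class `SeedLabels` holding linear voxel indices
#' @export
seed_labels <- function(object, background, shape = NULL) {
  tolin <- function(x) {
    if (is.array(x) && length(dim(x)) == 3) return(which(x != 0))
    x <- as.matrix(x)
    if (is.null(shape)) stop("coordinate seeds need `shape`")
    x[, 1] + shape[1] * (x[, 2] - 1 + shape[2] * (x[, 3] - 1))
  }
  ob <- tolin(object); bg <- tolin(background)
  if (!length(ob) || !length(bg))
    stop("both object and background seeds are required")
  structure(list(object = as.integer(ob), background = as.integer(bg)),
            class = "SeedLabels")
}

#' Graph-cut segmentation over a supervoxel partition
#'
#' Builds the supervoxel graph whose n-link weights derive from the
#' difference between average intensities of adjacent regions,
#' `w_ij = exp(-|mean_i - mean_j| / sigma)`, adds hard terminal links for
#' seeded supervoxels, and solves max-flow/min-cut.  Similar neighboring
#' regions are expensive to separate; the cut follows intensity boundaries.
#' Seeded regions always end on their seeded side.
#'
#' @param sp a `SupervoxelPartition`
#' @param seeds a [seed_labels()]
#' @param sigma intensity scale of the edge weights (default 5% of the
#'   intensity spread of the region means)
#' @return binary 3-D array (union of object-side supervoxels)
#' @export
graphcut_segment <- function(sp, seeds, sigma = NULL) {
  lab <- sp$labels
  ob_regions <- unique(lab[seeds$object])
  bg_regions <- unique(lab[seeds$background])
  both <- intersect(ob_regions, bg_regions)
  if (length(both))
    stop("supervoxel(s) seeded with both classes: ",
         paste(both, collapse = ", "))
  mu <- sp$stats$mean
  if (is.null(sigma)) sigma <- max(0.05 * diff(range(mu)), 1e-6)
  adj <- sp$adjacency
  w <- exp(-abs(mu[adj[, 1]] - mu[adj[, 2]]) / sigma)
  n <- sp$n_regions
  src <- n + 1L; snk <- n + 2L
  hard <- sum(w) + 1
  edges <- rbind(adj,
                 cbind(rep(src, length(ob_regions)), ob_regions),
                 cbind(bg_regions, rep(snk, length(bg_regions))))
  caps <- c(w, rep(hard, length(ob_regions) + length(bg_regions)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, (n + 2) - igraph::vcount(g)))
  fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  obj_side <- setdiff(as.integer(fl$partition1), c(src, snk))
  array(as.integer(lab %in% obj_side), dim(lab))
}

#' Marker-controlled watershed segmentation
#'
#' Floods a relief from user-placed markers so each marker class claims a
#' basin; with a boundary relief (image with stained/dark boundaries
#' inverted, or a gradient-magnitude map), labelling the object and
#' background on a single slice is enough to segment a membrane-enclosed
#' organelle in 3-D.
#'
#' @param x a `LayeredDataset` (relief = image intensity, or its gradient
#'   magnitude with `use_gradient`) or a numeric 3-D boundary-relief array
#' @param seeds a [seed_labels()]
#' @param dims `"3d"` or `"2d"` (slice-by-slice flood of the seed slices)
#' @param use_gradient preprocess the relief with the gradient filter to
#'   generate boundaries (for objects without stained boundaries)
#' @return list with `labels` (1 = object, 2 = background everywhere) and
#'   `object` (binary 3-D array)
#' @export
watershed_markered <- function(x, seeds, dims = c("3d", "2d"),
                               use_gradient = FALSE) {
  dims <- match.arg(dims)
  relief <- if (inherits(x, "LayeredDataset")) {
    if (use_gradient) gradient_magnitude(x) else img3d(x)
  } else x
  d <- dim(relief)
  markers <- array(0L, d)
  markers[seeds$object] <- 1L
  markers[seeds$background] <- 2L
  if (!any(markers == 1L) || !any(markers == 2L))
    stop("markers required in both classes")
  if (dims == "2d") {
    lab <- array(0L, d)
    for (z in seq_len(d[3])) {
      mk <- markers[, , z]
      if (!any(mk == 1L) || !any(mk == 2L)) next
      lab[, , z] <- cpp_priority_flood(array(relief[, , z], c(d[1:2], 1L)),
                                       as.integer(mk), c(d[1:2], 1L), TRUE)
    }
  } else {
    lab <- array(cpp_priority_flood(relief, markers, d, TRUE), d)
  }
  list(labels = lab, object = (lab == 1L) + 0L)
}

#' Separate fused objects with the distance-transform watershed
#'
#' Computes the (anisotropy-aware, physical-unit) Euclidean distance
#' transform of the binary input, suppresses shallow maxima with an
#' h-maxima transform of depth `min_depth`, and floods the inverted
#' distance from the surviving regional maxima.  Touching near-convex
#' objects (e.g. clustered lipid droplets) split along the distance ridge;
#' previously disconnected components are never merged.
#'
#' @param bin binary 3-D array
#' @param dims `"3d"` or `"2d"` (per slice)
#' @param voxel_size physical voxel size, used when `anisotropy_aware`
#' @param anisotropy_aware measure distances in physical units
#' @param min_depth h-maxima suppression depth, in physical units
#' @return integer label volume (0 = background)
#' @export
separate_objects <- function(bin, dims = c("3d", "2d"),
                             voxel_size = c(1, 1, 1),
                             anisotropy_aware = TRUE, min_depth = 2) {
  dims <- match.arg(dims)
  d <- dim(bin)
  if (!any(bin != 0)) stop("empty binary input")
  sp <- if (anisotropy_aware) rep(voxel_size, length.out = 3) else c(1, 1, 1)
  if (dims == "2d") {
    out <- array(0L, d)
    off <- 0L
    for (z in seq_len(d[3])) {
      lz <- separate_slab(array(as.integer(bin[, , z] != 0), c(d[1:2], 1L)),
                          sp, min_depth)
      pos <- lz > 0
      lz[pos] <- lz[pos] + off
      out[, , z] <- lz
      off <- max(out)
    }
    return(out)
  }
  array(separate_slab(array(as.integer(bin != 0), d), sp, min_depth), d)
}

separate_slab <- function(fg, sp, h) {
  d <- dim(fg)
  dist <- sqrt(cpp_edt_sq(fg, d, sp))
  # h-maxima suppression, then regional maxima as markers
  hm <- cpp_reconstruct(dist - h, dist, d, TRUE)
  eps <- 1e-3
  rm_ <- cpp_reconstruct(hm - eps, hm, d, TRUE)
  maxima <- (hm - rm_) > eps / 2 & fg != 0
  markers <- cpp_label_components(as.integer(maxima), d, TRUE)
  relief <- -dist
  relief[fg == 0] <- Inf
  lab <- cpp_priority_flood(relief, markers, d, TRUE)
  lab[fg == 0] <- 0L
  array(lab, d)
}

# -- classifiers -------------------------------------------------------------

#' Per-voxel membrane-detection feature stack
#'
#' Computes, per 2-D slice: Gaussian-smoothed intensity at each scale,
#' gradient magnitude and the two Hessian eigenvalues (ridge evidence) at
#' each scale, difference-of-Gaussians between consecutive scales, and
#' ring-context intensity samples (sorted, so approximately rotation
#' invariant) at `context_radius`.  The schema id records scales and radius;
#' prediction refuses a mismatched schema.
#'
#' @param ds a `LayeredDataset`
#' @param context_radius ring radius in voxels for the context samples
#' @param scales Gaussian scales in voxels
#' @return list with `x` (matrix, one row per voxel in array order),
#'   `schema`, `shape`
#' @export
membrane_features <- function(ds, context_radius = 5, scales = c(1, 2, 4)) {
  if (!length(scales)) stop("scales must not be empty")
  v <- img3d(ds)
  d <- dim(v)
  n_ring <- 8L
  nf <- length(scales) * 4L + max(length(scales) - 1L, 0L) + n_ring
  X <- matrix(0, prod(d), nf)
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  rx <- round(context_radius * cos(ang))
  ry <- round(context_radius * sin(ang))
  for (z in seq_len(d[3])) {
    sl <- v[, , z]
    base <- (z - 1L) * d[1] * d[2]
    rows <- base + seq_len(d[1] * d[2])
    col <- 0L
    smooths <- list()
    for (si in seq_along(scales)) {
      s3 <- gauss_smooth(array(sl, c(d[1], d[2], 1)),
                         c(scales[si], scales[si], 0))
      sm <- s3[, , 1]
      smooths[[si]] <- sm
      gx <- (rbind(sm[-1, ], sm[d[1], ]) - rbind(sm[1, ], sm[-d[1], ])) / 2
      gy <- (cbind(sm[, -1], sm[, d[2]]) - cbind(sm[, 1], sm[, -d[2]])) / 2
      H <- hessian_2d(sl, scales[si])
      tr <- H$xx + H$yy
      disc <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
      X[rows, col + 1L] <- as.vector(sm)
      X[rows, col + 2L] <- as.vector(sqrt(gx^2 + gy^2))
      X[rows, col + 3L] <- as.vector((tr + disc) / 2)
      X[rows, col + 4L] <- as.vector((tr - disc) / 2)
      col <- col + 4L
    }
    for (si in seq_len(length(scales) - 1)) {
      X[rows, col + 1L] <- as.vector(smooths[[si]] - smooths[[si + 1]])
      col <- col + 1L
    }
    sm1 <- smooths[[1]]
    ring <- matrix(0, d[1] * d[2], n_ring)
    for (k in seq_len(n_ring)) {
      ix <- pmin(pmax(seq_len(d[1]) + rx[k], 1), d[1])
      iy <- pmin(pmax(seq_len(d[2]) + ry[k], 1), d[2])
      ring[, k] <- as.vector(sm1[ix, iy])
    }
    ring <- t(apply(ring, 1, sort))
    X[rows, col + seq_len(n_ring)] <- ring
  }
  schema <- paste0("membrane_v1_s", paste(scales, collapse = "-"),
                   "_r", context_radius)
  list(x = X, schema = schema, shape = d)
}

#' Per-supervoxel intensity feature table
#'
#' Basic intensity properties of each supervoxel (minimum, maximum, average
#' and decile cuts through the histogram) plus the mean of each feature over
#' the adjacent regions as neighbour context.  A region with no neighbours
#' falls back to its own features.
#' @param ds a `LayeredDataset`
#' @param sp a `SupervoxelPartition`
#' @return list with `x` (matrix, one row per region), `schema`
#' @export
supervoxel_features <- function(ds, sp) {
  v <- as.vector(img3d(ds))
  lab <- as.vector(sp$labels)
  n <- sp$n_regions
  qs <- seq(0.1, 0.9, by = 0.1)
  groups <- split(v, factor(lab, levels = seq_len(n)))
  own <- t(vapply(groups, function(g) {
    if (!length(g)) return(rep(0, 3 + length(qs)))
    c(min(g), max(g), mean(g), quantile(g, qs, names = FALSE, type = 7))
  }, numeric(3 + length(qs))))
  colnames(own) <- c("min", "max", "mean", paste0("q", qs * 100))
  adj <- sp$adjacency
  deg <- tabulate(c(adj[, 1], adj[, 2]), n)
  nbr <- matrix(0, n, ncol(own))
  for (j in seq_len(ncol(own))) {
    acc <- numeric(n)
    vals <- own[, j]
    acc_tab <- rowsum(c(vals[adj[, 2]], vals[adj[, 1]]),
                      c(adj[, 1], adj[, 2]))
    acc[as.integer(rownames(acc_tab))] <- acc_tab
    nbr[, j] <- ifelse(deg > 0, acc / pmax(deg, 1), vals)
  }
  colnames(nbr) <- paste0("nbr_", colnames(own))
  list(x = cbind(own, nbr), schema = "supervoxel_v1_deciles")
}

#' Train a random-forest classifier on labeled samples
#'
#' Fits a Random Forest on the labeled rows only (both classes required,
#' at least 10 samples each).  The same seed and data produce an identical
#' forest; the feature schema id is stored and enforced at prediction.
#'
#' @param features feature list from [membrane_features()] or
#'   [supervoxel_features()] (or a plain matrix plus `schema`)
#' @param labels integer vector over rows: 1 = object, 2 = background,
#'   0/NA = unlabeled
#' @param kind `"membrane"` or `"supervoxel"`
#' @param n_trees number of trees
#' @param seed RNG seed for the forest
#' @param schema schema id when `features` is a plain matrix
#' @return object of class `TrainedClassifier` (reports training accuracy)
#' @export
train_classifier <- function(features, labels, kind = c("membrane",
                                                        "supervoxel"),
                             n_trees = 100, seed = 42, schema = NULL) {
  kind <- match.arg(kind)
  X <- if (is.list(features)) features$x else features
  schema <- if (is.list(features)) features$schema else
    (schema %||% "unspecified")
  lab <- labels
  lab[is.na(lab)] <- 0L
  idx <- which(lab %in% c(1L, 2L))
  if (!length(idx)) stop("no labeled samples")
  y <- factor(lab[idx], levels = c(1L, 2L))
  if (any(table(y) < 10))
    stop("need >= 10 samples per class; single-class labels are an error")
  set.seed(seed)
  rf <- randomForest::randomForest(x = X[idx, , drop = FALSE], y = y,
                                   ntree = n_trees)
  pred <- stats::predict(rf, X[idx, , drop = FALSE])
  acc <- mean(pred == y)
  structure(list(forest = rf, schema = schema, kind = kind,
                 n_trees = n_trees, seed = seed, training_accuracy = acc),
            class = "TrainedClassifier")
}

#' @export
print.TrainedClassifier <- function(x, ...) {
  cat(sprintf("<TrainedClassifier> %s, %d trees, schema %s, train acc %.3f\n",
              x$kind, x$n_trees, x$schema, x$training_accuracy))
  invisible(x)
}

#' Persist / restore a trained classifier
#'
#' The container stores the forest together with its feature schema id,
#' parameters and seed, so a restored classifier refuses features computed
#' with a different schema.
#' @param model a `TrainedClassifier`
#' @param path file path
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "TrainedClassifier")) stop("not a classifier file")
  m
}

#' Predict object probability with a trained classifier
#'
#' Membrane mode paints per-voxel probabilities; supervoxel mode paints the
#' per-region probability into every voxel of the region (output constant
#' within each supervoxel).  Time-lapse (4-D) inputs are handled upstream by
#' running frame by frame.
#'
#' @param model a `TrainedClassifier`
#' @param features matching feature list/matrix
#' @param sp `SupervoxelPartition` (supervoxel mode: used to paint regions)
#' @param threshold probability cutoff for the binary output
#' @return list with `prob` (array or per-region vector painted to array
#'   when `sp` given), `selection` (binary array when paintable)
#' @export
predict_classifier <- function(model, features, sp = NULL, threshold = 0.5,
                               schema = NULL) {
  X <- if (is.list(features)) features$x else features
  schema <- if (is.list(features)) features$schema else
    (schema %||% "unspecified")
  if (!identical(schema, model$schema))
    stop("feature schema mismatch: model '", model$schema,
         "' vs features '", schema, "'")
  p <- stats::predict(model$forest, X, type = "prob")[, "1"]
  if (!is.null(sp)) {
    vol <- array(p[sp$labels], dim(sp$labels))
    return(list(prob = vol, selection = (vol >= threshold) + 0L))
  }
  if (is.list(features) && !is.null(features$shape)) {
    vol <- array(p, features$shape)
    return(list(prob = vol, selection = (vol >= threshold) + 0L))
  }
  list(prob = p, selection = as.integer(p >= threshold))
}
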