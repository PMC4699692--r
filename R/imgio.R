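# Readers/writers for the supported interchange formats (multipage TIFF,
# NRRD, PNG series, AmiraMesh) and translation-only stitching.  Images are
# held internally as [x, y, (color,) z]; the tiff/png packages use [row =
# y, col = x], so matrices are transposed at the boundary.

# -- NRRD --------------------------------------------------------------------

nrrd_type <- function(bitdepth) if (bitdepth <= 8) "uint8" else "uint16"

encode_uint <- function(x, bytes) {
  x <- as.integer(round(x))
  if (bytes == 1) return(as.raw(x))
  lo <- x %% 256L
  hi <- x %/% 256L
  as.raw(as.vector(rbind(lo, hi)))  # little endian
}

#' Write a volume in NRRD format
#'
#' Nearly-raw-raster-data with a plain-text header carrying sizes, per-axis
#' spacings and custom key-value fields, followed by `raw` or `gzip` encoded
#' unsigned 8/16-bit data (little endian, x fastest).
#'
#' @param arr 3-D array (x, y, z) or 4-D array (x, y, color, z)
#' @param path output file
#' @param spacings numeric length-3 voxel size (x, y, z)
#' @param bitdepth 8 or 16
#' @param encoding `"raw"` or `"gzip"`
#' @param keyvals named list of extra `key:=value` fields
#' @export
write_nrrd <- function(arr, path, spacings = c(1, 1, 1), bitdepth = 8,
                       encoding = c("gzip", "raw"), keyvals = list()) {
  encoding <- match.arg(encoding)
  d <- dim(arr)
  if (max(arr) > (if (bitdepth <= 8) 255 else 65535))
    stop("values exceed ", bitdepth, "-bit range")
  if (length(d) == 3) {
    sizes <- d
    sp <- spacings
  } else if (length(d) == 4) {
    sizes <- d
    sp <- c(spacings[1], spacings[2], NA, spacings[3])
  } else stop("NRRD writer expects a 3-D or 4-D array")
  hdr <- c("NRRD0004",
           "# Complete NRRD file format specification at:",
           "# http://teem.sourceforge.net/nrrd/format.html",
           paste0("type: ", nrrd_type(bitdepth)),
           paste0("dimension: ", length(sizes)),
           paste0("sizes: ", paste(sizes, collapse = " ")),
           paste0("spacings: ",
                  paste(ifelse(is.na(sp), "nan", format(sp, digits = 15)),
                        collapse = " ")),
           "endian: little",
           paste0("encoding: ", encoding))
  for (k in names(keyvals))
    hdr <- c(hdr, paste0(k, ":=", keyvals[[k]]))
  payload <- encode_uint(arr, if (bitdepth <= 8) 1 else 2)
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

#' Read an NRRD volume
#' @param path NRRD file written by [write_nrrd()] or a compatible tool
#'   (raw/gzip encodings, uint8/uint16, little endian)
#' @return list with `data` (array), `spacings`, `bitdepth`, `keyvals`
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list(); keyvals <- list()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || ln == "") break
    if (startsWith(ln, "#")) next
    if (grepl(":=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, ":=", fixed = TRUE)[[1]]
      keyvals[[kv[1]]] <- kv[2]
    } else {
      kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
      fields[[tolower(kv[1])]] <- kv[2]
    }
  }
  type <- fields$type
  if (!type %in% c("uint8", "uchar", "unsigned char", "uint16",
                   "unsigned short", "ushort"))
    stop("unsupported NRRD type: ", type)
  bytes <- if (type %in% c("uint8", "uchar", "unsigned char")) 1L else 2L
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  sp <- suppressWarnings(as.numeric(strsplit(trimws(fields$spacings %||% ""),
                                             "\\s+")[[1]]))
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(fields$encoding, "gzip"))
    payload <- memDecompress(payload, "gzip")
  else if (!identical(fields$encoding, "raw"))
    stop("unsupported NRRD encoding: ", fields$encoding)
  vals <- readBin(payload, "integer", n = n, size = bytes, signed = FALSE,
                  endian = "little")
  spac <- if (length(sizes) == 4) sp[c(1, 2, 4)] else sp
  list(data = array(vals, sizes),
       spacings = if (length(spac) == 3 && !anyNA(spac)) spac else NULL,
       bitdepth = if (bytes == 1) 8 else 16,
       keyvals = keyvals)
}

# -- TIFF / PNG --------------------------------------------------------------

# tiff/png matrices are [y, x(, c)]; convert to/from internal [x, y(, c)]
from_yx <- function(m) {
  if (length(dim(m)) == 3) aperm(m, c(2, 1, 3)) else t(m)
}
to_yx <- function(m) {
  if (length(dim(m)) == 3) aperm(m, c(2, 1, 3)) else t(m)
}

tiff_page_to_int <- function(pg) {
  # readTIFF(as.is=TRUE) yields integers; normalized reads yield [0,1]
  if (is.double(pg) && max(pg) <= 1) pg <- pg * 255
  pg
}

resolution_to_voxel <- function(info, units) {
  xr <- attr(info, "x.resolution")
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  ru <- attr(info, "resolution.unit") %||% "inch"
  per <- switch(ru, inch = 2.54e7, cm = 1e7, NULL)  # nm per resolution unit
  if (is.null(per)) return(NULL)
  tonm <- c(nm = 1, um = 1e3, micron = 1e3, mm = 1e6, cm = 1e7)[units]
  if (is.na(tonm)) tonm <- 1
  yr <- attr(info, "y.resolution") %||% xr
  c(per / xr, per / yr) / tonm
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- unique(vapply(pages, function(p) attr(p, "bits.per.sample") %||% 8L, 0L))
  if (length(bits) > 1) stop("mixed bit depths in ", path)
  list(pages = lapply(pages, function(p) from_yx(tiff_page_to_int(p))),
       bitdepth = bits, info = pages[[1]])
}

read_png_page <- function(path) {
  p <- png::readPNG(path)
  from_yx(p * 255)
}

#' Read image files into a layered dataset
#'
#' Accepts a single multipage TIFF, a single NRRD file, or a character
#' vector of TIFF/PNG files assembled along Z or Time in natural sort
#' order.  Voxel size is taken from TIFF resolution tags or NRRD spacings
#' when present; otherwise 1.0 is used and a warning is logged, never a
#' silently wrong unit.
#'
#' @param path one file or a vector of files (all sharing X, Y, color shape)
#' @param axis4 assemble along `"Z"` or `"Time"`
#' @param units dataset length unit used to interpret resolution metadata
#' @param voxel_size override voxel size (skips metadata)
#' @return a `LayeredDataset`
#' @export
read_volume <- function(path, axis4 = "Z", units = "nm", voxel_size = NULL) {
  path <- path[natural_order(path)]
  ext <- tolower(tools::file_ext(path[1]))
  vs <- voxel_size
  warn_vs <- FALSE
  if (length(path) == 1 && ext == "nrrd") {
    nr <- read_nrrd(path)
    arr <- nr$data
    if (is.null(vs)) {
      vs <- nr$spacings
      if (is.null(vs)) { vs <- c(1, 1, 1); warn_vs <- TRUE }
    }
    bitdepth <- nr$bitdepth
  } else {
    pages <- list()
    bitdepths <- integer()
    info1 <- NULL
    for (p in path) {
      e <- tolower(tools::file_ext(p))
      if (e %in% c("tif", "tiff")) {
        st <- read_tiff_stack(p)
        pages <- c(pages, st$pages)
        bitdepths <- c(bitdepths, st$bitdepth)
        if (is.null(info1)) info1 <- st$info
      } else if (e == "png") {
        pages <- c(pages, list(read_png_page(p)))
        bitdepths <- c(bitdepths, 8L)
      } else stop("unsupported format: ", p)
    }
    if (length(unique(bitdepths)) > 1) stop("mixed bit depths across files")
    bitdepth <- bitdepths[1]
    shapes <- unique(vapply(pages, function(p)
      paste(dim(p) %||% length(p), collapse = "x"), ""))
    if (length(shapes) > 1) stop("slices have inconsistent shapes")
    nc <- if (length(dim(pages[[1]])) == 3) dim(pages[[1]])[3] else 1L
    nx <- dim(pages[[1]])[1]; ny <- dim(pages[[1]])[2]
    arr <- array(0, c(nx, ny, nc, length(pages)))
    for (i in seq_along(pages))
      arr[, , , i] <- pages[[i]]
    if (is.null(vs)) {
      res <- if (!is.null(info1)) resolution_to_voxel(info1, units)
      if (!is.null(res)) vs <- c(res[1], res[2], 1)
      else { vs <- c(1, 1, 1); warn_vs <- TRUE }
    }
  }
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr)[1:2], 1, dim(arr)[3])
  ds <- layered_dataset(arr, voxel_size = vs, units = units, axis4 = axis4,
                        bitdepth = bitdepth)
  if (warn_vs) {
    warning("no voxel-size metadata found; defaulting to 1 ", units, "/voxel")
    ds <- log_action(ds, "warning", list(msg = "voxel size defaulted to 1"))
  }
  log_action(ds, "read_volume", list(files = length(path)))
}

natural_order <- function(x) {
  # order by embedded integer runs, then lexically
  key <- gsub("(\\d+)", "~\\1~", basename(x))
  parts <- strsplit(key, "~")
  maxlen <- max(lengths(parts))
  mat <- sapply(parts, function(p) {
    p <- c(p, rep("", maxlen - length(p)))
    isnum <- grepl("^\\d+$", p)
    p[isnum] <- sprintf("%020.0f", as.numeric(p[isnum]))
    p
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  do.call(order, as.data.frame(t(mat), stringsAsFactors = FALSE))
}

#' Write one dataset layer to an image file
#'
#' Binary layers (selection, mask) are written as 8-bit 0/255 in TIFF and
#' PNG; model labels are written as 8-bit label values.  NRRD output embeds
#' the voxel spacings; TIFF and PNG carry no physical metadata, so
#' [save_dataset()] writes a sidecar for them.  AmiraMesh is ASCII,
#' uniform-coordinate Lattice, write-only, with a material section for model
#' layers.
#'
#' @param ds a `LayeredDataset`
#' @param path output file (PNG series: a `sprintf` pattern with `%d`, or a
#'   directory)
#' @param layer `"image"`, `"selection"`, `"mask"` or `"model"`
#' @param format `"tiff"`, `"nrrd"`, `"png-series"` or `"amira-mesh"`;
#'   default inferred from the file extension
#' @return invisibly, the file(s) written
#' @export
write_volume <- function(ds, path, layer = c("image", "selection", "mask",
                                             "model"),
                         format = NULL) {
  layer <- match.arg(layer)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff", nrrd = "nrrd", png = "png-series",
                     am = "amira-mesh",
                     stop("cannot infer format from ", path))
  }
  if (layer == "image") {
    arr <- ds$image
    bitdepth <- ds$bitdepth
  } else {
    arr <- get_layer(ds, layer)
    if (layer != "model") arr <- arr * 255L
    bitdepth <- 8
  }
  d3 <- ds_dim(ds)
  vs <- unname(ds$geometry$voxel_size)
  if (format == "nrrd") {
    out <- if (layer == "image" && dim(arr)[3] > 1) arr else
      array(if (layer == "image") arr[, , 1, ] else arr, d3)
    write_nrrd(out, path, spacings = vs, bitdepth = bitdepth,
               keyvals = list(volseg_bbox_min =
                                paste(unname(ds$geometry$bbox_min), collapse = " "),
                              volseg_units = ds$geometry$units))
    return(invisible(path))
  }
  if (format == "tiff") {
    mx <- if (bitdepth == 8) 255 else 65535
    pages <- lapply(seq_len(d3[3]), function(z) {
      pg <- if (layer == "image") {
        if (dim(arr)[3] > 1) arr[, , , z] else arr[, , 1, z]
      } else arr[, , z]
      to_yx(pg / mx)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bitdepth,
                    compression = "deflate")
    return(invisible(path))
  }
  if (format == "png-series") {
    if (bitdepth != 8) stop("PNG series output is 8-bit only")
    if (dir.exists(path) || !grepl("%", path))
      path <- file.path(path, "slice_%04d.png")
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    files <- character(d3[3])
    for (z in seq_len(d3[3])) {
      pg <- if (layer == "image") {
        if (dim(arr)[3] > 1) arr[, , , z] else arr[, , 1, z]
      } else arr[, , z]
      files[z] <- sprintf(path, z)
      png::writePNG(to_yx(pg / 255), files[z])
    }
    return(invisible(files))
  }
  if (format == "amira-mesh") {
    out <- array(if (layer == "image") arr[, , 1, ] else arr, d3)
    write_amira_mesh(out, path, ds$geometry,
                     materials = if (layer == "model") ds$materials)
    return(invisible(path))
  }
  stop("unsupported format: ", format)
}

#' Write a label or intensity volume as ASCII AmiraMesh (write-only)
#' @param arr 3-D array
#' @param path output file
#' @param geometry a `VolumeGeometry` for the bounding box
#' @param materials optional material table for label volumes
#' @export
write_amira_mesh <- function(arr, path, geometry = volume_geometry(),
                             materials = NULL) {
  d <- dim(arr)
  bb0 <- geometry$bbox_min
  bb1 <- bb0 + d * geometry$voxel_size
  mat_block <- ""
  if (!is.null(materials) && nrow(materials)) {
    rgbs <- t(grDevices::col2rgb(materials$color)) / 255
    mats <- paste0("        ", c("Exterior { }",
      sprintf("%s { Color %.3f %.3f %.3f }", gsub("[^A-Za-z0-9]", "", materials$name),
              rgbs[, 1], rgbs[, 2], rgbs[, 3])), collapse = "\n")
    mat_block <- paste0("    Materials {\n", mats, "\n    }\n")
  }
  hdr <- paste0(
    "# AmiraMesh 3D ASCII 2.0\n\n",
    sprintf("define Lattice %d %d %d\n\n", d[1], d[2], d[3]),
    "Parameters {\n",
    mat_block,
    sprintf("    Content \"%dx%dx%d byte, uniform coordinates\",\n",
            d[1], d[2], d[3]),
    sprintf("    BoundingBox %g %g %g %g %g %g,\n",
            bb0[1], bb1[1], bb0[2], bb1[2], bb0[3], bb1[3]),
    "    CoordType \"uniform\"\n}\n\n",
    "Lattice { byte Data } @1\n\n# Data section follows\n@1\n")
  con <- file(path, "wt")
  on.exit(close(con))
  cat(hdr, file = con)
  vals <- as.integer(round(arr))
  writeLines(paste(vals, collapse = "\n"), con)
  invisible(path)
}

# -- dataset bundles ---------------------------------------------------------

#' Save a dataset bundle (layers + sidecar metadata)
#'
#' Writes each present layer as an NRRD file plus a plain-text YAML sidecar
#' (`volseg.yaml`) holding the geometry, bit depth, material table and the
#' action log.
#' @param ds a `LayeredDataset`
#' @param dir output directory (created if needed)
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ds, file.path(dir, "image.nrrd"), "image")
  for (ly in c("selection", "mask", "model"))
    if (!is.null(ds[[ly]]))
      write_volume(ds, file.path(dir, paste0(ly, ".nrrd")), ly)
  meta <- list(
    geometry = list(voxel_size = as.numeric(ds$geometry$voxel_size),
                    units = ds$geometry$units,
                    bbox_min = as.numeric(ds$geometry$bbox_min),
                    axis4 = ds$geometry$axis4),
    bitdepth = ds$bitdepth,
    depth_2d = ds$history$depth_2d, depth_3d = ds$history$depth_3d,
    materials = if (nrow(ds$materials)) lapply(seq_len(nrow(ds$materials)),
      function(i) as.list(ds$materials[i, ])) else list(),
    log = ds$log)
  yaml::write_yaml(meta, file.path(dir, "volseg.yaml"))
  invisible(dir)
}

#' Load a dataset bundle written by [save_dataset()]
#' @param dir bundle directory
#' @return a `LayeredDataset`
#' @export
load_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "volseg.yaml"))
  nr <- read_nrrd(file.path(dir, "image.nrrd"))
  g <- meta$geometry
  ds <- layered_dataset(nr$data, voxel_size = g$voxel_size, units = g$units,
                        bbox_min = g$bbox_min, axis4 = g$axis4,
                        bitdepth = meta$bitdepth,
                        depth_2d = meta$depth_2d, depth_3d = meta$depth_3d)
  for (ly in c("selection", "mask", "model")) {
    f <- file.path(dir, paste0(ly, ".nrrd"))
    if (file.exists(f)) {
      v <- read_nrrd(f)$data
      if (ly != "model") v <- (v > 0) + 0L
      ds[[ly]] <- array(as.integer(v), ds_dim(ds))
    }
  }
  if (length(meta$materials)) {
    ds$materials <- do.call(rbind, lapply(meta$materials, as.data.frame))
  }
  ds$log <- meta$log
  ds
}

# -- alignment / stitching ---------------------------------------------------

#' Estimate an in-plane translation and merge two datasets
#'
#' Translation-only stitching: the shift of `moving` relative to `fixed` is
#' estimated by FFT cross-correlation of the mean Z-projections (or given
#' manually in voxels), `moving`'s bounding box is adjusted accordingly, and
#' both datasets are painted onto the union grid.  Where they overlap, the
#' fixed dataset wins.  Voxel sizes must match exactly; there is no implicit
#' resampling.
#'
#' @param fixed,moving `LayeredDataset`s with identical voxel size
#' @param method `"cross-correlation"` or `"manual-offset"`
#' @param offset manual voxel offset `c(dx, dy)` (manual mode), applied on
#'   top of the bounding boxes
#' @param fill intensity for voxels covered by neither input
#' @return list with `shift` (estimated/applied voxel shift), `merged`
#'   (a `LayeredDataset` on the union bounding box)
#' @export
align_translation <- function(fixed, moving,
                              method = c("cross-correlation", "manual-offset"),
                              offset = c(0, 0), fill = 0) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(unname(fixed$geometry$voxel_size),
                        unname(moving$geometry$voxel_size))))
    stop("voxel sizes differ; no implicit resampling is performed")
  vs <- unname(fixed$geometry$voxel_size)
  if (method == "cross-correlation") {
    a <- apply(img3d(fixed), c(1, 2), mean)
    b <- apply(img3d(moving), c(1, 2), mean)
    n1 <- max(dim(a)[1], dim(b)[1])
    n2 <- max(dim(a)[2], dim(b)[2])
    pa <- matrix(0, n1, n2); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a - mean(a)
    pb <- matrix(0, n1, n2); pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b - mean(b)
    cc <- Re(stats::fft(stats::fft(pb) * Conj(stats::fft(pa)), inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc)) - 1L
    sh <- ifelse(pk > c(n1, n2) / 2, pk - c(n1, n2), pk)
    # moving content f(x - s): its origin must move by -s to align with fixed
    moving$geometry$bbox_min[1:2] <- fixed$geometry$bbox_min[1:2] - sh * vs[1:2]
    shift <- as.numeric(sh)
  } else {
    moving$geometry$bbox_min[1:2] <- moving$geometry$bbox_min[1:2] +
      offset * vs[1:2]
    shift <- as.numeric(offset)
  }
  # union grid
  offv <- round((moving$geometry$bbox_min - fixed$geometry$bbox_min) / vs)
  lo <- pmin(0, offv)
  hi <- pmax(ds_dim(fixed), offv + ds_dim(moving))
  shp <- as.integer(hi - lo)
  nch <- dim(fixed$image)[3]
  img <- array(fill, c(shp[1], shp[2], nch, shp[3]))
  paste_at <- function(img, block, at) {
    ix <- (at[1] + 1):(at[1] + dim(block)[1])
    iy <- (at[2] + 1):(at[2] + dim(block)[2])
    iz <- (at[3] + 1):(at[3] + dim(block)[4])
    img[ix, iy, , iz] <- block
    img
  }
  img <- paste_at(img, moving$image, as.integer(offv - lo))
  img <- paste_at(img, fixed$image, as.integer(-lo))  # fixed wins overlap
  merged <- layered_dataset(img, voxel_size = vs, units = fixed$geometry$units,
                            bbox_min = fixed$geometry$bbox_min + lo * vs,
                            axis4 = fixed$geometry$axis4,
                            bitdepth = fixed$bitdepth)
  merged <- log_action(merged, "align_translation",
                       list(method = method, shift = shift))
  list(shift = shift, merged = merged)
}
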