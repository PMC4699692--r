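# Independent oracles and small fixture builders used across tests.

# Naive priority-flood watershed oracle (R, O(n^2) frontier scan); kept
# deliberately independent of the package's compiled implementation.
flood_oracle_2d <- function(relief, markers, full = TRUE) {
  d <- dim(relief)
  n <- prod(d)
  lab <- as.integer(markers)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (!full) offs <- offs[rowSums(abs(offs)) == 1, ]
  queued <- rep(FALSE, n); pri <- rep(Inf, n); src <- rep(0L, n)
  for (i in which(lab > 0)) {
    queued[i] <- TRUE; pri[i] <- relief[i]; src[i] <- lab[i]
  }
  done <- rep(FALSE, n)
  repeat {
    cand <- which(queued & !done)
    if (!length(cand)) break
    p <- cand[which.min(pri[cand])]
    done[p] <- TRUE
    if (lab[p] == 0) lab[p] <- src[p]
    x <- (p - 1) %% d[1] + 1; y <- (p - 1) %/% d[1] + 1
    for (r in seq_len(nrow(offs))) {
      qx <- x + offs[r, 1]; qy <- y + offs[r, 2]
      if (qx < 1 || qx > d[1] || qy < 1 || qy > d[2]) next
      qi <- (qy - 1) * d[1] + qx
      if (queued[qi] || lab[qi] > 0) next
      queued[qi] <- TRUE
      pri[qi] <- max(relief[qi], pri[p])
      src[qi] <- lab[p]
    }
  }
  matrix(lab, d[1], d[2])
}

# Synthetic supervoxel partition over an abstract region graph (one voxel
# per region), for comparing the graph-cut against exhaustive enumeration.
make_toy_partition <- function(n, edges, means) {
  structure(list(labels = array(seq_len(n), c(n, 1, 1)), n_regions = n,
                 stats = data.frame(id = seq_len(n), mean = means,
                                    min = means, max = means, size = 1),
                 adjacency = edges, dims = "3d", target_size = 8,
                 compactness = 1),
            class = "SupervoxelPartition")
}

cut_cost <- function(assign, edges, w) {
  sum(w[assign[edges[, 1]] != assign[edges[, 2]]])
}

min_cut_exhaustive <- function(n, edges, w, ob, bg) {
  best <- Inf
  for (m in 0:(2^n - 1)) {
    a <- as.integer(intToBits(m))[1:n]
    if (a[ob] != 1 || a[bg] != 0) next
    best <- min(best, cut_cost(a, edges, w))
  }
  best
}

random_region_graph <- function(n) {
  all_pairs <- t(combn(n, 2))
  ne <- sample(n:nrow(all_pairs), 1)
  edges <- all_pairs[sample(nrow(all_pairs), ne), , drop = FALSE]
  unique(rbind(edges, cbind(1:(n - 1), 2:n)))  # keep it connected
}

# Minimal byte-level writer for a single-page uncompressed 8-bit grayscale
# TIFF carrying XResolution/YResolution tags (tiff::writeTIFF cannot write
# resolution tags, and binary fixtures are not checked in).
write_tiff_with_resolution <- function(mat, path, res_per_cm) {
  w <- nrow(mat); h <- ncol(mat)
  img <- as.raw(as.integer(mat))  # column-major [x, y] = TIFF row-major
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  data_off <- 8L
  xres_off <- data_off + length(img)
  yres_off <- xres_off + 8L
  ifd_off <- yres_off + 8L
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off)
  writeBin(img, con)
  u32(res_per_cm); u32(1L)  # XResolution rational
  u32(res_per_cm); u32(1L)  # YResolution rational
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3) { u16(value); u16(0L) } else u32(value)
  }
  u16(11L)  # entry count
  entry(256, 3, 1, w)          # ImageWidth
  entry(257, 3, 1, h)          # ImageLength
  entry(258, 3, 1, 8)          # BitsPerSample
  entry(259, 3, 1, 1)          # Compression: none
  entry(262, 3, 1, 1)          # Photometric: BlackIsZero
  entry(273, 4, 1, data_off)   # StripOffsets
  entry(278, 3, 1, h)          # RowsPerStrip
  entry(279, 4, 1, length(img))# StripByteCounts
  entry(282, 5, 1, xres_off)   # XResolution
  entry(283, 5, 1, yres_off)   # YResolution
  entry(296, 3, 1, 3)          # ResolutionUnit: cm
  u32(0L)
  invisible(path)
}
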