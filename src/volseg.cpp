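// Low-level volumetric primitives: exact Euclidean distance transform,
// marker-controlled priority-flood watershed, connected components,
// SLIC supervoxels, grayscale min/max filtering and morphological
// reconstruction.  All operate on flat vectors in R's column-major
// order, linear index i = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Vox {
  int x, y, z;
};

// Neighborhood offsets: face-connected (6 / 4 in a single slice) or
// fully connected (26 / 8).  dims with nz == 1 degenerate naturally.
static std::vector<Vox> neighborhood(bool full, int nz) {
  std::vector<Vox> off;
  for (int dz = -1; dz <= 1; ++dz) {
    if (nz == 1 && dz != 0) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (!full && nn > 1) continue;
        off.push_back({dx, dy, dz});
      }
    }
  }
  return off;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS, deterministic scan order).
// mask: nonzero = foreground.  Returns labels 1..k, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   bool full_conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<Vox> off = neighborhood(full_conn, nz);
  std::vector<R_xlen_t> queue_;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    queue_.clear();
    queue_.push_back(i);
    size_t head = 0;
    while (head < queue_.size()) {
      R_xlen_t p = queue_[head++];
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      for (const Vox &o : off) {
        int X = x + o.x, Y = y + o.y, Z = z + o.z;
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (mask[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          queue_.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// anisotropy-aware through per-axis sample spacing.
// Input: fg nonzero where distance is sought; distance is to nearest zero.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n, double w) {
  // Sites with infinite value can never be the nearest site; skip them.
  // Caller guarantees at least one finite site.
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0;
  zb[0] = -INF;
  zb[1] = INF;
  double w2 = w * w;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      double num = (f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k]);
      double den = 2.0 * w2 * (q - v[k]);
      s = num / den;
      if (s <= zb[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector fg, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] != 0 ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // x passes
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = d[base + x]; if (f[x] != INF) any = true; }
      if (!any) continue; // stays INF, resolved by later passes
      dt1d(f, dd, v, zb, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = dd[x];
    }
  // y passes
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      bool anyfin = false;
      for (int y = 0; y < ny; ++y) { f[y] = d[base + (R_xlen_t)nx * y]; if (f[y] != INF) anyfin = true; }
      if (!anyfin) continue;
      dt1d(f, dd, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = dd[y];
    }
  // z passes
  if (nz > 1) {
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        bool anyfin = false;
        for (int z = 0; z < nz; ++z) { f[z] = d[base + nxy * z]; if (f[z] != INF) anyfin = true; }
        if (!anyfin) continue;
        dt1d(f, dd, v, zb, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) d[base + nxy * z] = dd[z];
      }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding (Meyer).  Voxels with
// non-finite relief are never flooded (label 0).  Ties broken by insertion
// order (FIFO), which is deterministic for a deterministic input.
// [[Rcpp::export]]
IntegerVector cpp_priority_flood(NumericVector relief, IntegerVector markers,
                                 IntegerVector dims, bool full_conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<Vox> off = neighborhood(full_conn, nz);

  struct Item {
    double pri;
    long long order;
    R_xlen_t idx;
    int lab;
  };
  struct Cmp {
    bool operator()(const Item &a, const Item &b) const {
      if (a.pri != b.pri) return a.pri > b.pri;
      return a.order > b.order;
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  long long counter = 0;
  std::vector<char> queued(n, 0);

  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0 && R_FINITE(relief[i])) {
      lab[i] = markers[i];
      pq.push({relief[i], counter++, i, markers[i]});
      queued[i] = 1;
    }
  }
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    R_xlen_t p = it.idx;
    if (lab[p] == 0) lab[p] = it.lab;
    int curlab = lab[p];
    int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
    for (const Vox &o : off) {
      int X = x + o.x, Y = y + o.y, Z = z + o.z;
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
      if (lab[q] != 0 || queued[q] || !R_FINITE(relief[q])) continue;
      queued[q] = 1;
      pq.push({std::max(relief[q], it.pri), counter++, q, curlab});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Grayscale min/max filter over an arbitrary offset set (structuring
// element).  Out-of-bounds neighbors are ignored.
// [[Rcpp::export]]
NumericVector cpp_minmax_filter(NumericVector vol, IntegerVector dims,
                                IntegerMatrix offsets, bool do_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int no = offsets.nrow();
  NumericVector out(n);
  std::vector<int> ox(no), oy(no), oz(no);
  for (int k = 0; k < no; ++k) {
    ox[k] = offsets(k, 0);
    oy[k] = offsets(k, 1);
    oz[k] = offsets(k, 2);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double best = do_max ? -INF : INF;
        for (int k = 0; k < no; ++k) {
          int X = x + ox[k], Y = y + oy[k], Z = z + oz[k];
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          double v = vol[X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z)];
          if (do_max ? (v > best) : (v < best)) best = v;
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = best;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (hybrid raster +
// FIFO algorithm of Vincent).  marker must be <= mask everywhere.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dims, bool full_conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J = clone(marker);
  std::vector<Vox> all = neighborhood(full_conn, nz);
  std::vector<Vox> before, after;
  for (const Vox &o : all) {
    long long lin = o.x + (long long)nx * (o.y + (long long)ny * o.z);
    if (lin < 0) before.push_back(o); else after.push_back(o);
  }
  // forward raster scan
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[p];
        for (const Vox &o : before) {
          int X = x + o.x, Y = y + o.y, Z = z + o.z;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          double v = J[X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z)];
          if (v > m) m = v;
        }
        J[p] = std::min(m, mask[p]);
      }
  // backward raster scan + queue init
  std::queue<R_xlen_t> fifo;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[p];
        for (const Vox &o : after) {
          int X = x + o.x, Y = y + o.y, Z = z + o.z;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          double v = J[X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z)];
          if (v > m) m = v;
        }
        J[p] = std::min(m, mask[p]);
        for (const Vox &o : after) {
          int X = x + o.x, Y = y + o.y, Z = z + o.z;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
          if (J[q] < J[p] && J[q] < mask[q]) {
            fifo.push(p);
            break;
          }
        }
      }
  // FIFO propagation
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front();
    fifo.pop();
    int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
    for (const Vox &o : all) {
      int X = x + o.x, Y = y + o.y, Z = z + o.z;
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// SLIC supervoxels.  Distances measured in physical units (spacing) so the
// same code serves isotropic 2-D slices and anisotropic 3-D volumes.
// Returns 0-based contiguous labels; small disconnected fragments are merged
// into an adjacent region (standard connectivity enforcement).
// [[Rcpp::export]]
IntegerVector cpp_slic(NumericVector img, IntegerVector dims,
                       NumericVector spacing, double step,
                       double compactness, int iters) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;

  int svx = std::max(1, (int)std::lround(step / spacing[0]));
  int svy = std::max(1, (int)std::lround(step / spacing[1]));
  int svz = nz == 1 ? 1 : std::max(1, (int)std::lround(step / spacing[2]));
  int ncx = std::max(1, (nx + svx - 1) / svx);
  int ncy = std::max(1, (ny + svy - 1) / svy);
  int ncz = std::max(1, (nz + svz - 1) / svz);
  int nc = ncx * ncy * ncz;

  std::vector<double> cx(nc), cy(nc), cz(nc), ci(nc);
  int c = 0;
  for (int k = 0; k < ncz; ++k)
    for (int j = 0; j < ncy; ++j)
      for (int i = 0; i < ncx; ++i, ++c) {
        cx[c] = std::min((double)nx - 0.5, (i + 0.5) * svx);
        cy[c] = std::min((double)ny - 0.5, (j + 0.5) * svy);
        cz[c] = std::min((double)nz - 0.5, (k + 0.5) * svz);
        int xi = (int)cx[c], yi = (int)cy[c], zi = (int)cz[c];
        ci[c] = img[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
      }

  std::vector<int> lab(n, -1);
  std::vector<double> dist(n);
  double m2 = compactness * compactness;
  double S2 = step * step;

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), INF);
    for (int cc = 0; cc < nc; ++cc) {
      int x0 = std::max(0, (int)cx[cc] - 2 * svx), x1 = std::min(nx - 1, (int)cx[cc] + 2 * svx);
      int y0 = std::max(0, (int)cy[cc] - 2 * svy), y1 = std::min(ny - 1, (int)cy[cc] + 2 * svy);
      int z0 = std::max(0, (int)cz[cc] - 2 * svz), z1 = std::min(nz - 1, (int)cz[cc] + 2 * svz);
      for (int z = z0; z <= z1; ++z) {
        double pz = (z - cz[cc]) * spacing[2];
        for (int y = y0; y <= y1; ++y) {
          double py = (y - cy[cc]) * spacing[1];
          R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          for (int x = x0; x <= x1; ++x) {
            double px = (x - cx[cc]) * spacing[0];
            double ds2 = px * px + py * py + pz * pz;
            double di = img[base + x] - ci[cc];
            double D = di * di + m2 * ds2 / S2;
            if (D < dist[base + x]) {
              dist[base + x] = D;
              lab[base + x] = cc;
            }
          }
        }
      }
    }
    // update centers
    std::vector<double> sx(nc, 0), sy(nc, 0), sz(nc, 0), si(nc, 0), cnt(nc, 0);
    for (R_xlen_t p = 0; p < n; ++p) {
      int l = lab[p];
      if (l < 0) continue;
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      sx[l] += x; sy[l] += y; sz[l] += z; si[l] += img[p]; cnt[l] += 1;
    }
    for (int cc = 0; cc < nc; ++cc)
      if (cnt[cc] > 0) {
        cx[cc] = sx[cc] / cnt[cc];
        cy[cc] = sy[cc] / cnt[cc];
        cz[cc] = sz[cc] / cnt[cc];
        ci[cc] = si[cc] / cnt[cc];
      }
  }

  // connectivity enforcement: relabel contiguous fragments; fragments
  // smaller than a quarter of the target size merge into a neighbor.
  R_xlen_t minsize = std::max((R_xlen_t)1,
                              (R_xlen_t)(svx * (R_xlen_t)svy * svz / 4));
  std::vector<Vox> off = neighborhood(false, nz);
  IntegerVector out(n);
  std::fill(out.begin(), out.end(), -1);
  std::vector<R_xlen_t> comp;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (out[i] != -1) continue;
    comp.clear();
    comp.push_back(i);
    out[i] = next;
    int adj = -1;
    size_t head = 0;
    while (head < comp.size()) {
      R_xlen_t p = comp[head++];
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      for (const Vox &o : off) {
        int X = x + o.x, Y = y + o.y, Z = z + o.z;
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (lab[q] == lab[p] && out[q] == -1) {
          out[q] = next;
          comp.push_back(q);
        } else if (out[q] >= 0 && out[q] != next) {
          adj = out[q];
        }
      }
    }
    if ((R_xlen_t)comp.size() < minsize && adj >= 0) {
      for (R_xlen_t p : comp) out[p] = adj;
    } else {
      ++next;
    }
  }
  return out;
}
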