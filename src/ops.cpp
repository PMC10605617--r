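// Low-level image kernels: Gaussian spot rendering, block-matching NCC,
// separable squared Euclidean distance transform, 26-connected region
// growing, inscribed-sphere local thickness, tube voxelization and
// supercover line rasterization. All array arguments are column-major
// (R layout); continuous coordinates are in pixel/voxel units with the
// center of voxel [i,j,k] (1-based in R) at (i-0.5, j-0.5, k-0.5).
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e20;

// [[Rcpp::export]]
NumericMatrix cpp_render_spots(int nrow, int ncol, NumericVector row_px,
                               NumericVector col_px, NumericVector amp,
                               double sigma_px, NumericMatrix base) {
  NumericMatrix out(clone(base));
  const double s2 = 2.0 * sigma_px * sigma_px;
  const int w = (int)std::ceil(4.0 * sigma_px);
  for (int b = 0; b < row_px.size(); ++b) {
    // spot center in continuous units; voxel i center is at i + 0.5 (0-based)
    const double cr = row_px[b] - 0.5, cc = col_px[b] - 0.5;
    const int i0 = std::max(0, (int)std::floor(cr - w));
    const int i1 = std::min(nrow - 1, (int)std::ceil(cr + w));
    const int j0 = std::max(0, (int)std::floor(cc - w));
    const int j1 = std::min(ncol - 1, (int)std::ceil(cc + w));
    for (int j = j0; j <= j1; ++j) {
      const double dc = j - cc;
      for (int i = i0; i <= i1; ++i) {
        const double dr = i - cr;
        out(i, j) += amp[b] * std::exp(-(dr * dr + dc * dc) / s2);
      }
    }
  }
  return out;
}

// Normalized cross-correlation of the reference block centred at
// (ci, cj) (0-based) against the same-size block in `img` displaced by
// (oi + di, oj + dj), di,dj in [-s, s] around the prior offset (oi, oj).
// Returns a (2s+1) x (2s+1) matrix indexed [di + s + 1, dj + s + 1].
// Out-of-bounds shifts get -2 (below any NCC).
// [[Rcpp::export]]
NumericMatrix cpp_ncc_search(NumericMatrix ref, NumericMatrix img,
                             int ci, int cj, int hb, int s,
                             int oi = 0, int oj = 0) {
  const int n = 2 * s + 1, B = 2 * hb + 1, N = B * B;
  NumericMatrix out(n, n);
  // reference block stats
  double rm = 0.0;
  for (int j = cj - hb; j <= cj + hb; ++j)
    for (int i = ci - hb; i <= ci + hb; ++i) rm += ref(i, j);
  rm /= N;
  double rss = 0.0;
  std::vector<double> rblk(N);
  int q = 0;
  for (int j = cj - hb; j <= cj + hb; ++j)
    for (int i = ci - hb; i <= ci + hb; ++i) {
      rblk[q] = ref(i, j) - rm;
      rss += rblk[q] * rblk[q];
      ++q;
    }
  for (int dj = -s; dj <= s; ++dj) {
    for (int di = -s; di <= s; ++di) {
      const int i0 = ci + oi + di - hb, j0 = cj + oj + dj - hb;
      if (i0 < 0 || j0 < 0 || i0 + B > img.nrow() || j0 + B > img.ncol()) {
        out(di + s, dj + s) = -2.0;
        continue;
      }
      double m = 0.0;
      for (int j = 0; j < B; ++j)
        for (int i = 0; i < B; ++i) m += img(i0 + i, j0 + j);
      m /= N;
      double num = 0.0, ss = 0.0;
      q = 0;
      for (int j = 0; j < B; ++j)
        for (int i = 0; i < B; ++i) {
          const double v = img(i0 + i, j0 + j) - m;
          num += rblk[q++] * v;
          ss += v * v;
        }
      const double den = std::sqrt(rss * ss);
      out(di + s, dj + s) = den > 0 ? num / den : 0.0;
    }
  }
  return out;
}

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int qq = 1; qq < n; ++qq) {
    double s;
    while (true) {
      s = ((f[qq] + qq * (double)qq) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * qq - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = qq;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int qq = 0; qq < n; ++qq) {
    while (z[k + 1] < qq) ++k;
    d[qq] = (qq - v[k]) * (double)(qq - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the
// nearest zero (background) voxel centre. Voxels in an all-foreground
// array get INF.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims.size() > 2 ? dims[2] : 1;
  NumericVector g(fg.size());
  for (R_xlen_t i = 0; i < fg.size(); ++i) g[i] = fg[i] ? INF : 0.0;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (rows)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t off = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = g[off + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) g[off + i] = d[i];
    }
  // axis 2 (cols)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t off = i + (R_xlen_t)n1 * n2 * (R_xlen_t)k;
      for (int j = 0; j < n2; ++j) f[j] = g[off + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) g[off + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (slices)
  if (n3 > 1) {
    const R_xlen_t stride = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t off = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; ++k) f[k] = g[off + stride * k];
        dt1d(f, d, v, z, n3);
        for (int k = 0; k < n3; ++k) g[off + stride * k] = d[k];
      }
  }
  return g;
}

// 26-connected region growing over voxels with intensity >= threshold.
// [[Rcpp::export]]
LogicalVector cpp_flood26(NumericVector vol, IntegerVector dims,
                          IntegerVector seed0, double threshold) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out(vol.size(), false);
  const R_xlen_t stride = (R_xlen_t)n1 * n2;
  auto idx = [&](int i, int j, int k) { return i + (R_xlen_t)n1 * j + stride * k; };
  std::queue<std::array<int, 3>> qq;
  if (vol[idx(seed0[0], seed0[1], seed0[2])] < threshold)
    stop("seed voxel intensity is below the threshold");
  out[idx(seed0[0], seed0[1], seed0[2])] = true;
  qq.push({seed0[0], seed0[1], seed0[2]});
  while (!qq.empty()) {
    auto c = qq.front();
    qq.pop();
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          const int i = c[0] + di, j = c[1] + dj, k = c[2] + dk;
          if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) continue;
          const R_xlen_t p = idx(i, j, k);
          if (!out[p] && vol[p] >= threshold) {
            out[p] = true;
            qq.push({i, j, k});
          }
        }
  }
  return out;
}

// Local thickness by sphere painting: for each foreground voxel u with
// Euclidean distance-to-background dt[u], every voxel v with
// ||v - u|| < dt[u] receives at least dt[u]. Voxels are processed in
// decreasing dt order so each voxel is overwritten at most once.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector dt, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t stride = (R_xlen_t)n1 * n2;
  NumericVector lt(dt.size(), 0.0);
  std::vector<R_xlen_t> ord;
  for (R_xlen_t p = 0; p < dt.size(); ++p)
    if (dt[p] > 0) ord.push_back(p);
  std::sort(ord.begin(), ord.end(),
            [&](R_xlen_t a, R_xlen_t b) { return dt[a] > dt[b]; });
  for (R_xlen_t p : ord) {
    const double r = dt[p];
    const int k0 = (int)(p / stride);
    const int j0 = (int)((p - stride * k0) / n1);
    const int i0 = (int)(p - stride * k0 - (R_xlen_t)n1 * j0);
    const int w = (int)std::ceil(r);
    for (int dk = -w; dk <= w; ++dk) {
      const int k = k0 + dk;
      if (k < 0 || k >= n3) continue;
      for (int dj = -w; dj <= w; ++dj) {
        const int j = j0 + dj;
        if (j < 0 || j >= n2) continue;
        const double dd = (double)dk * dk + (double)dj * dj;
        if (dd >= r * r) continue;
        const double rem = r * r - dd;
        const int di_max = (int)std::floor(std::sqrt(rem));
        for (int di = -di_max; di <= di_max; ++di) {
          const int i = i0 + di;
          if (i < 0 || i >= n1) continue;
          if ((double)di * di + dd < r * r) {
            const R_xlen_t q = i + (R_xlen_t)n1 * j + stride * k;
            if (dt[q] > 0 && lt[q] < r) lt[q] = r;  // foreground only
          }
        }
      }
    }
  }
  return lt;
}

// Voxelize finite cylinders (no end caps) given as rows
// (x0,y0,z0,x1,y1,z1,r) plus joint spheres (x,y,z,r), all in continuous
// voxel units. Output: per-voxel tube radius (max over tubes), 0 outside.
// [[Rcpp::export]]
NumericVector cpp_render_tubes(IntegerVector dims, NumericMatrix segs,
                               NumericMatrix joints) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t stride = (R_xlen_t)n1 * n2;
  NumericVector out((R_xlen_t)stride * n3, 0.0);
  for (int srow = 0; srow < segs.nrow(); ++srow) {
    const double ax = segs(srow, 0), ay = segs(srow, 1), az = segs(srow, 2);
    const double bx = segs(srow, 3), by = segs(srow, 4), bz = segs(srow, 5);
    const double r = segs(srow, 6);
    const double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double L2 = ux * ux + uy * uy + uz * uz;
    if (L2 <= 0) continue;
    const int i0 = std::max(0, (int)std::floor(std::min(ax, bx) - r - 1));
    const int i1 = std::min(n1 - 1, (int)std::ceil(std::max(ax, bx) + r + 1));
    const int j0 = std::max(0, (int)std::floor(std::min(ay, by) - r - 1));
    const int j1 = std::min(n2 - 1, (int)std::ceil(std::max(ay, by) + r + 1));
    const int k0 = std::max(0, (int)std::floor(std::min(az, bz) - r - 1));
    const int k1 = std::min(n3 - 1, (int)std::ceil(std::max(az, bz) + r + 1));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double px = i + 0.5 - ax, py = j + 0.5 - ay, pz = k + 0.5 - az;
          const double t = (px * ux + py * uy + pz * uz) / L2;
          if (t < 0 || t > 1) continue;
          const double dx = px - t * ux, dy = py - t * uy, dz = pz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r * r) {
            const R_xlen_t p = i + (R_xlen_t)n1 * j + stride * k;
            if (out[p] < r) out[p] = r;
          }
        }
  }
  for (int srow = 0; srow < joints.nrow(); ++srow) {
    const double cx = joints(srow, 0), cy = joints(srow, 1), cz = joints(srow, 2);
    const double r = joints(srow, 3);
    const int i0 = std::max(0, (int)std::floor(cx - r - 1));
    const int i1 = std::min(n1 - 1, (int)std::ceil(cx + r + 1));
    const int j0 = std::max(0, (int)std::floor(cy - r - 1));
    const int j1 = std::min(n2 - 1, (int)std::ceil(cy + r + 1));
    const int k0 = std::max(0, (int)std::floor(cz - r - 1));
    const int k1 = std::min(n3 - 1, (int)std::ceil(cz + r + 1));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double dx = i + 0.5 - cx, dy = j + 0.5 - cy, dz = k + 0.5 - cz;
          if (dx * dx + dy * dy + dz * dz <= r * r) {
            const R_xlen_t p = i + (R_xlen_t)n1 * j + stride * k;
            if (out[p] < r) out[p] = r;
          }
        }
  }
  return out;
}

// Supercover rasterization of 2D segments on a [nrow x ncol] grid whose
// pixel (i,j) (0-based) covers rows [i, i+1) x cols [j, j+1) in
// continuous grid units. Marks every pixel a segment passes through and
// accumulates the segment direction unit vector into per-pixel sums.
// [[Rcpp::export]]
List cpp_raster_segments(NumericVector r0, NumericVector c0, NumericVector r1,
                         NumericVector c1, int nrow, int ncol) {
  IntegerMatrix cnt(nrow, ncol);
  NumericMatrix sc(nrow, ncol), ss(nrow, ncol);
  for (R_xlen_t s = 0; s < r0.size(); ++s) {
    const double ar = r0[s], ac = c0[s], br = r1[s], bc = c1[s];
    const double dr = br - ar, dc = bc - ac;
    const double ang_c = std::atan2(dr, dc); // 0 = +col direction
    const double len = std::sqrt(dr * dr + dc * dc);
    int i = (int)std::floor(ar), j = (int)std::floor(ac);
    const int ie = (int)std::floor(br), je = (int)std::floor(bc);
    const int sti = dr > 0 ? 1 : -1, stj = dc > 0 ? 1 : -1;
    double tMaxI = (dr != 0)
        ? ((sti > 0 ? (std::floor(ar) + 1 - ar) : (ar - std::floor(ar))) /
           std::fabs(dr)) : INF;
    double tMaxJ = (dc != 0)
        ? ((stj > 0 ? (std::floor(ac) + 1 - ac) : (ac - std::floor(ac))) /
           std::fabs(dc)) : INF;
    const double tDi = dr != 0 ? 1.0 / std::fabs(dr) : INF;
    const double tDj = dc != 0 ? 1.0 / std::fabs(dc) : INF;
    // exactly |ie-i| + |je-j| boundary crossings lie between the two
    // endpoint pixels; bounding the loop by that count keeps the
    // traversal finite even when an endpoint sits on a pixel boundary
    int nsteps = std::abs(ie - i) + std::abs(je - j);
    for (int st = 0; ; ++st) {
      if (i >= 0 && i < nrow && j >= 0 && j < ncol) {
        cnt(i, j) += 1;
        sc(i, j) += std::cos(ang_c);
        ss(i, j) += std::sin(ang_c);
      }
      if ((i == ie && j == je) || len == 0 || st >= nsteps) break;
      if (tMaxI < tMaxJ) {
        i += sti;
        tMaxI += tDi;
      } else {
        j += stj;
        tMaxJ += tDj;
      }
    }
  }
  return List::create(Named("count") = cnt, Named("sumcos") = sc,
                      Named("sumsin") = ss);
}
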