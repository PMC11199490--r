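// Voxel-grid cores: exact Euclidean distance transform (squared, with
// feature/nearest-site transform), 3-D connected-component labeling,
// 3-D median filtering, and sphere-fitting local thickness.
//
// Volumes are R arrays with dim = c(d1, d2, d3), first index fastest
// (column-major); all distances here are in voxel units (isotropic spacing
// is applied by the R wrappers).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb-Huttenlocher 1-D squared distance transform of a sampled
// function f, tracking which sample (its stored site id) attains the
// lower envelope at each position. Positions with f = INF carry no parabola.
static void dt1d(const std::vector<double>& f, const std::vector<int>& fs,
                 int n, std::vector<double>& d, std::vector<int>& ds,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; if (k < 0) break; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) {  // no sites on this line
    for (int q = 0; q < n; ++q) { d[q] = INF; ds[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    double dq = (double)(q - p);
    d[q] = dq * dq + f[p];
    ds[q] = fs[p];
  }
}

// Three separable lower-envelope passes over (dist, site); dist may carry
// arbitrary initial parabola heights (0 for a plain EDT, -R^2 for the
// additively weighted / power-diagram transform).
static void edt3_core(std::vector<double>& dist, std::vector<int>& site,
                      int d1, int d2, int d3) {
  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dcol(nmax), z(nmax + 1);
  std::vector<int> fs(nmax), dscol(nmax), v(nmax);

  // pass along axis 1 (stride 1)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; ++i) { f[i] = dist[base + i]; fs[i] = site[base + i]; }
      dt1d(f, fs, d1, dcol, dscol, v, z);
      for (int i = 0; i < d1; ++i) { dist[base + i] = dcol[i]; site[base + i] = dscol[i]; }
    }
  // pass along axis 2 (stride d1)
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      for (int j = 0; j < d2; ++j) { f[j] = dist[base + (R_xlen_t)d1 * j]; fs[j] = site[base + (R_xlen_t)d1 * j]; }
      dt1d(f, fs, d2, dcol, dscol, v, z);
      for (int j = 0; j < d2; ++j) { dist[base + (R_xlen_t)d1 * j] = dcol[j]; site[base + (R_xlen_t)d1 * j] = dscol[j]; }
    }
  // pass along axis 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      for (int k = 0; k < d3; ++k) { f[k] = dist[base + s3 * k]; fs[k] = site[base + s3 * k]; }
      dt1d(f, fs, d3, dcol, dscol, v, z);
      for (int k = 0; k < d3; ++k) { dist[base + s3 * k] = dcol[k]; site[base + s3 * k] = dscol[k]; }
    }
}

// Squared EDT to the target set, plus the linear (0-based) index of a
// nearest target voxel for every voxel. Exact for the distances; when two
// sites tie the attained site depends on scan order (callers that need a
// documented tie rule apply cpp_tie_sweep afterwards).
// [[Rcpp::export]]
List cpp_edt3(LogicalVector target, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> dist(n);
  std::vector<int> site(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dist[i] = target[i] ? 0.0 : INF;
    site[i] = target[i] ? (int)i : -1;
  }
  edt3_core(dist, site, d1, d2, d3);
  NumericVector out_d(n);
  IntegerVector out_s(n);
  for (R_xlen_t i = 0; i < n; ++i) { out_d[i] = dist[i]; out_s[i] = site[i] + 1; } // 1-based for R
  out_d.attr("dim") = dim;
  out_s.attr("dim") = dim;
  return List::create(_["dist2"] = out_d, _["site"] = out_s);
}

// Resolve exact distance ties in a feature transform toward the lowest
// label id. `site` is the 1-based nearest-voxel index from cpp_edt3,
// `labels` the label volume. For each voxel, if a 26-neighbour's site is
// exactly as close (squared distances are integers in voxel units) but has
// a lower label id, adopt it; sweep until stable.
// [[Rcpp::export]]
IntegerVector cpp_tie_sweep(IntegerVector site, IntegerVector labels, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector out = clone(site);
  auto coord = [&](R_xlen_t lin, int& i, int& j, int& k) {
    i = (int)(lin % d1); lin /= d1; j = (int)(lin % d2); k = (int)(lin / d2);
  };
  auto sq = [](double a) { return a * a; };
  // candidates: voxels with a neighbour whose nearest site has another label
  std::vector<R_xlen_t> cand;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t lin = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        int s0 = out[lin];
        if (s0 == NA_INTEGER || s0 <= 0) continue;
        int lab0 = labels[s0 - 1];
        bool boundary = false;
        for (int dk = -1; dk <= 1 && !boundary; ++dk)
          for (int dj = -1; dj <= 1 && !boundary; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
              int s1 = out[ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk)];
              if (s1 != NA_INTEGER && s1 > 0 && labels[s1 - 1] != lab0) { boundary = true; break; }
            }
        if (boundary) cand.push_back(lin);
      }
  bool changed = true;
  int iter = 0;
  while (changed && iter < 8) {
    changed = false; ++iter;
    for (R_xlen_t lin : cand) {
      R_xlen_t rem = lin;
      int i = (int)(rem % d1); rem /= d1; int j = (int)(rem % d2); int k = (int)(rem / d2);
      int s0 = out[lin];
      int si, sj, sk; coord(s0 - 1, si, sj, sk);
      double d0 = sq(i - si) + sq(j - sj) + sq(k - sk);
      int lab0 = labels[s0 - 1];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ni = i + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
            int s1 = out[ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk)];
            if (s1 == NA_INTEGER || s1 <= 0 || s1 == s0) continue;
            int ti, tj, tk; coord(s1 - 1, ti, tj, tk);
            double d1n = sq(i - ti) + sq(j - tj) + sq(k - tk);
            if (d1n == d0 && labels[s1 - 1] < lab0) {
              out[lin] = s1; lab0 = labels[s1 - 1]; s0 = s1; changed = true;
            }
          }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling, connectivity in {6, 18, 26}.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({di, dj, dk});
      }
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      R_xlen_t lin = cur;
      int i = (int)(lin % d1); lin /= d1; int j = (int)(lin % d2); int k = (int)(lin / d2);
      for (auto& o : nb) {
        int ni = i + o[0], nj = j + o[1], nk = k + o[2];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
        R_xlen_t nl = ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk);
        if (mask[nl] && !labels[nl]) { labels[nl] = next; stack.push_back(nl); }
      }
    }
  }
  return labels;
}

// k x k x k median filter with replicated (clamped) borders; k odd.
// Interior voxels use precomputed neighbour offsets (fast path).
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dim, int k) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int h = k / 2;
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  out.attr("dim") = dim;
  const int kk3 = k * k * k;
  std::vector<double> buf(kk3);
  std::vector<R_xlen_t> off;
  off.reserve(kk3);
  for (int dk = -h; dk <= h; ++dk)
    for (int dj = -h; dj <= h; ++dj)
      for (int di = -h; di <= h; ++di)
        off.push_back(di + (R_xlen_t)d1 * (dj + (R_xlen_t)d2 * dk));
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int kk = 0; kk < d3; ++kk)
    for (int jj = 0; jj < d2; ++jj) {
      bool edge_jk = (jj < h || jj >= d2 - h || kk < h || kk >= d3 - h);
      for (int ii = 0; ii < d1; ++ii) {
        R_xlen_t lin = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (!edge_jk && ii >= h && ii < d1 - h) {
          for (int m = 0; m < kk3; ++m) buf[m] = v[lin + off[m]];
          std::nth_element(buf.begin(), buf.begin() + kk3 / 2, buf.end());
          o[lin] = buf[kk3 / 2];
        } else {
          int m = 0;
          for (int dk = -h; dk <= h; ++dk) {
            int zk = std::min(std::max(kk + dk, 0), d3 - 1);
            for (int dj = -h; dj <= h; ++dj) {
              int zj = std::min(std::max(jj + dj, 0), d2 - 1);
              for (int di = -h; di <= h; ++di) {
                int zi = std::min(std::max(ii + di, 0), d1 - 1);
                buf[m++] = v[zi + (R_xlen_t)d1 * (zj + (R_xlen_t)d2 * zk)];
              }
            }
          }
          std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
          o[lin] = buf[m / 2];
        }
      }
    }
  return out;
}

// one-step binary dilation with 26 (Chebyshev-1) connectivity
// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n);
  out.attr("dim") = dim;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t lin = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (mask[lin]) { out[lin] = true; continue; }
        bool hit = false;
        for (int dk = -1; dk <= 1 && !hit; ++dk) {
          int nk = k + dk; if (nk < 0 || nk >= d3) continue;
          for (int dj = -1; dj <= 1 && !hit; ++dj) {
            int nj = j + dj; if (nj < 0 || nj >= d2) continue;
            for (int di = -1; di <= 1; ++di) {
              int ni = i + di; if (ni < 0 || ni >= d1) continue;
              if (mask[ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk)]) { hit = true; break; }
            }
          }
        }
        out[lin] = hit;
      }
  return out;
}

// Local thickness (Hildebrand-style largest-inscribed-sphere) in voxel
// units (diameter). Inscribed-sphere radii come from the EDT; distance-
// ridge voxels are the sphere centres. Instead of painting every sphere
// (O(sum of sphere volumes)), the additively weighted (power-diagram)
// transform min_c ||x-c||^2 - R_c^2 finds one covering sphere per voxel in
// O(n); verified neighbour-propagation sweeps then push each voxel to the
// largest covering sphere reachable through the overlap graph. Every
// reported value corresponds to an actual inscribed covering sphere, and
// each voxel keeps at least twice its own inscribed radius.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector bg(n);
  for (R_xlen_t i = 0; i < n; ++i) bg[i] = !mask[i];
  List e = cpp_edt3(bg, dim);
  NumericVector dist2 = e["dist2"];
  std::vector<double> r2(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) r2[i] = dist2[i];

  // ridge: drop voxels whose inscribed sphere sits inside a neighbour's
  std::vector<double> pw(n, INF);
  std::vector<int> site(n, -1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t lin = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!mask[lin]) continue;
        double rp = std::sqrt(r2[lin]);
        bool keep = true;
        for (int dk = -1; dk <= 1 && keep; ++dk)
          for (int dj = -1; dj <= 1 && keep; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
              R_xlen_t nl = ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk);
              if (!mask[nl]) continue;
              double dd = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (std::sqrt(r2[nl]) >= rp + dd) { keep = false; break; }
            }
        if (keep) { pw[lin] = -r2[lin]; site[lin] = (int)lin; }
      }
  edt3_core(pw, site, d1, d2, d3);

  NumericVector lt(n, 0.0);
  lt.attr("dim") = dim;
  std::vector<int> best(n, -1);
  auto coord = [&](R_xlen_t lin, int& i, int& j, int& k) {
    i = (int)(lin % d1); lin /= d1; j = (int)(lin % d2); k = (int)(lin / d2);
  };
  for (R_xlen_t x = 0; x < n; ++x) {
    if (!mask[x]) continue;
    lt[x] = 2.0 * std::sqrt(r2[x]);   // own inscribed sphere: lower bound
    best[x] = (int)x;
    int s = site[x];
    if (s >= 0 && pw[x] <= 0 && r2[s] > r2[x]) {
      lt[x] = 2.0 * std::sqrt(r2[s]);
      best[x] = s;
    }
  }
  // label-correcting propagation of covering spheres along the overlap
  // graph, run to convergence; each candidate is verified
  // (||x - c||^2 <= R_c^2), so values never exceed the true largest
  // covering sphere and the converged result is scan-order independent
  std::vector<R_xlen_t> queue;
  queue.reserve(n / 4);
  for (R_xlen_t x = 0; x < n; ++x)
    if (mask[x]) queue.push_back(x);
  std::vector<char> queued(n, 0);
  while (!queue.empty()) {
    R_xlen_t x = queue.back(); queue.pop_back();
    queued[x] = 0;
    int c = best[x];
    if (c < 0) continue;
    double rc2 = r2[c];
    int ci, cj, ck; coord((R_xlen_t)c, ci, cj, ck);
    int i, j, k; coord(x, i, j, k);
    for (int dk = -1; dk <= 1; ++dk) {
      int nk = k + dk; if (nk < 0 || nk >= d3) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int nj = j + dj; if (nj < 0 || nj >= d2) continue;
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ni = i + di; if (ni < 0 || ni >= d1) continue;
          R_xlen_t y = ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk);
          if (!mask[y] || r2[best[y]] >= rc2) continue;
          double dd = (double)(ni - ci) * (ni - ci) + (double)(nj - cj) * (nj - cj) +
            (double)(nk - ck) * (nk - ck);
          if (dd <= rc2) {
            best[y] = c;
            lt[y] = 2.0 * std::sqrt(rc2);
            if (!queued[y]) { queued[y] = 1; queue.push_back(y); }
          }
        }
      }
    }
  }
  return lt;
}

// retained for oracle use in validation: explicit sphere painting
// [[Rcpp::export]]
NumericVector cpp_local_thickness_paint(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  // EDT of the complement: distance of each foreground voxel to background
  LogicalVector bg(n);
  for (R_xlen_t i = 0; i < n; ++i) bg[i] = !mask[i];
  List e = cpp_edt3(bg, dim);
  NumericVector dist2 = e["dist2"];
  std::vector<double> r(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) r[i] = std::sqrt(dist2[i]);

  // ridge: voxel p is redundant if a neighbour's sphere contains its own
  std::vector<R_xlen_t> ridge;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t lin = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!mask[lin]) continue;
        bool keep = true;
        for (int dk = -1; dk <= 1 && keep; ++dk)
          for (int dj = -1; dj <= 1 && keep; ++dj)
            for (int di = -1; di <= 1 && keep; ++di) {
              if (!di && !dj && !dk) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3) continue;
              R_xlen_t nl = ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk);
              if (!mask[nl]) continue;
              double dd = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[nl] >= r[lin] + dd) keep = false;
            }
        if (keep) ridge.push_back(lin);
      }
  std::sort(ridge.begin(), ridge.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r[a] > r[b]; });

  NumericVector lt(n, 0.0);
  lt.attr("dim") = dim;
  for (R_xlen_t lin0 : ridge) {
    R_xlen_t lin = lin0;
    int i = (int)(lin % d1); lin /= d1; int j = (int)(lin % d2); int k = (int)(lin / d2);
    double rc = r[lin0];
    double rc2 = dist2[lin0];   // exact integer-valued squared radius
    int ir = (int)std::floor(rc + 1e-9);
    for (int dk = -ir; dk <= ir; ++dk) {
      int nk = k + dk; if (nk < 0 || nk >= d3) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        int nj = j + dj; if (nj < 0 || nj >= d2) continue;
        double dd2 = (double)dk * dk + (double)dj * dj;
        if (dd2 > rc2) continue;
        for (int di = -ir; di <= ir; ++di) {
          int ni = i + di; if (ni < 0 || ni >= d1) continue;
          if (dd2 + (double)di * di > rc2) continue;
          R_xlen_t nl = ni + (R_xlen_t)d1 * (nj + (R_xlen_t)d2 * nk);
          if (mask[nl] && lt[nl] < 2.0 * rc) lt[nl] = 2.0 * rc;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] && lt[i] < 2.0 * r[i]) lt[i] = 2.0 * r[i];
  return lt;
}
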