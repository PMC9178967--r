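// Exact Euclidean distance transform on anisotropic grids (separable
// lower-envelope algorithm, one 1-D pass per axis on squared distances)
// and 26-connectivity connected-component labelling.
#include <Rcpp.h>
#include <vector>
#include <limits>

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform over sites at coordinates x[i] (increasing);
// sites with f = INF carry no parabola and are skipped.
static void dt1d(std::vector<double> &f, const std::vector<double> &x,
                 std::vector<double> &d) {
  const int n = (int)f.size();
  std::vector<double> xs; xs.reserve(n);
  std::vector<double> fs; fs.reserve(n);
  for (int i = 0; i < n; ++i)
    if (f[i] < INF) { xs.push_back(x[i]); fs.push_back(f[i]); }
  const int m = (int)xs.size();
  if (m == 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < m; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((fs[q] + xs[q] * xs[q]) - (fs[p] + xs[p] * xs[p])) /
          (2.0 * xs[q] - 2.0 * xs[p]);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < x[q]) ++kk;
    int p = v[kk];
    d[q] = (x[q] - xs[p]) * (x[q] - xs[p]) + fs[p];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt_mm_cpp(Rcpp::LogicalVector mask, Rcpp::IntegerVector dim,
                               Rcpp::NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = mask[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx), x(nx);
    for (int i = 0; i < nx; ++i) x[i] = i * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        bool any = false;
        for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; if (f[i] < INF) any = true; }
        if (!any) continue;
        dt1d(f, x, d);
        for (int i = 0; i < nx; ++i) D[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny), x(ny);
    for (int j = 0; j < ny; ++j) x[j] = j * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        bool any = false;
        for (int j = 0; j < ny; ++j) {
          f[j] = D[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
          if (f[j] < INF) any = true;
        }
        if (!any) continue;
        dt1d(f, x, d);
        for (int j = 0; j < ny; ++j) D[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz), x(nz);
    for (int k = 0; k < nz; ++k) x[k] = k * spacing[2];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool any = false;
        for (int k = 0; k < nz; ++k) {
          f[k] = D[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
          if (f[k] < INF) any = true;
        }
        if (!any) continue;
        dt1d(f, x, d);
        for (int k = 0; k < nz; ++k) D[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
      }
  }

  Rcpp::NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = (D[i] == INF) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector label_components26_cpp(Rcpp::LogicalVector mask,
                                           Rcpp::IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  Rcpp::IntegerVector lab(N, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[u] && lab[u] == 0) { lab[u] = cur; stack.push_back(u); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// For each positive label, does any voxel touch `other` within the 26-neighborhood?
// [[Rcpp::export]]
Rcpp::LogicalVector touches26_cpp(Rcpp::IntegerVector lab, Rcpp::LogicalVector other,
                                  Rcpp::IntegerVector dim, int n_labels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  Rcpp::LogicalVector out(n_labels, false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int L = lab[v];
        if (L <= 0 || out[L - 1]) continue;
        for (int dk = -1; dk <= 1 && !out[L - 1]; ++dk)
          for (int dj = -1; dj <= 1 && !out[L - 1]; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              if (other[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) { out[L - 1] = true; break; }
            }
      }
  return out;
}
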