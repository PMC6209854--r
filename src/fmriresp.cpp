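// Compiled kernels: 3D connected components, threshold-free cluster
// enhancement, and the Freedman-Lane max-statistic permutation engine.
// These sit in the inner loops of permutation inference (hundreds of
// thousands of labellings per analysis), hence C++.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Neighbour offsets for 6/18/26 connectivity.
struct Offsets {
  std::vector<int> dx, dy, dz;
};

Offsets make_offsets(int connectivity) {
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        o.dx.push_back(dx); o.dy.push_back(dy); o.dz.push_back(dz);
      }
  return o;
}

struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  explicit UnionFind(int n) : parent(n, -1), size(n, 0) {}
  void activate(int v) { parent[v] = v; size[v] = 1; }
  bool active(int v) const { return parent[v] >= 0; }
  int find(int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

inline int lin(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// Connected-component labelling of mask > 0; labels 1..K, 0 background.
void label_components_impl(const double* val, double thr, const int* d,
                           int connectivity, std::vector<int>& labels,
                           std::vector<int>& sizes) {
  int V = d[0] * d[1] * d[2];
  labels.assign(V, 0);
  sizes.clear();
  Offsets off = make_offsets(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int v = lin(x, y, z, d);
        if (labels[v] != 0 || !(val[v] > thr)) continue;
        ++next;
        int sz = 0;
        stack.clear(); stack.push_back(v); labels[v] = next;
        while (!stack.empty()) {
          int u = stack.back(); stack.pop_back();
          ++sz;
          int uz = u / (d[0] * d[1]);
          int uy = (u / d[0]) % d[1];
          int ux = u % d[0];
          for (size_t k = 0; k < off.dx.size(); ++k) {
            int nx = ux + off.dx[k], ny = uy + off.dy[k], nz = uz + off.dz[k];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= d[0] || ny >= d[1] || nz >= d[2])
              continue;
            int w = lin(nx, ny, nz, d);
            if (labels[w] == 0 && val[w] > thr) {
              labels[w] = next;
              stack.push_back(w);
            }
          }
        }
        sizes.push_back(sz);
      }
}

// TFCE by descending-threshold incremental union-find. Heights are the
// discrete grid h = k*dh for k = 1..floor(max/dh); a voxel belongs to the
// component at height h when its value >= h - 1e-9.
void tfce_impl(const double* val, const int* d, double E, double H, double dh,
               int connectivity, std::vector<double>& out) {
  int V = d[0] * d[1] * d[2];
  out.assign(V, 0.0);
  double zmax = 0.0;
  for (int v = 0; v < V; ++v) if (val[v] > zmax) zmax = val[v];
  if (zmax <= 0.0) return;
  double dh_eff = dh > 0 ? dh : zmax / 100.0;
  int nsteps = (int)std::floor(zmax / dh_eff + 1e-9);
  if (nsteps < 1) return;
  std::vector<int> order;
  order.reserve(V);
  for (int v = 0; v < V; ++v) if (val[v] > 0) order.push_back(v);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return val[a] > val[b]; });
  UnionFind uf(V);
  Offsets off = make_offsets(connectivity);
  std::vector<int> active;
  size_t ptr = 0;
  for (int k = nsteps; k >= 1; --k) {
    double h = k * dh_eff;
    while (ptr < order.size() && val[order[ptr]] >= h - 1e-9) {
      int v = order[ptr++];
      uf.activate(v);
      active.push_back(v);
      int vz = v / (d[0] * d[1]);
      int vy = (v / d[0]) % d[1];
      int vx = v % d[0];
      for (size_t j = 0; j < off.dx.size(); ++j) {
        int nx = vx + off.dx[j], ny = vy + off.dy[j], nz = vz + off.dz[j];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d[0] || ny >= d[1] || nz >= d[2])
          continue;
        int w = lin(nx, ny, nz, d);
        if (uf.active(w)) uf.unite(v, w);
      }
    }
    double hH = std::pow(h, H) * dh_eff;
    for (size_t j = 0; j < active.size(); ++j) {
      int r = uf.find(active[j]);
      out[active[j]] += std::pow((double)uf.size[r], E) * hH;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector values, IntegerVector dims,
                                   double threshold, int connectivity) {
  int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<int> labels, sizes;
  label_components_impl(REAL(values), threshold, d, connectivity, labels, sizes);
  IntegerVector out(labels.begin(), labels.end());
  out.attr("sizes") = IntegerVector(sizes.begin(), sizes.end());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector values, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> out;
  tfce_impl(REAL(values), d, E, H, dh, connectivity, out);
  return NumericVector(out.begin(), out.end());
}

// Freedman-Lane permutation null of the max suprathreshold cluster size and
// max TFCE. Y-model: Yperm = fitted_reduced + P(resid_reduced); the full
// design X is refit to Yperm and the contrast t-statistic converted to Z.
// Columns of the data matrices correspond to mask voxel indices mask_idx
// (0-based linear indices into the dims grid).
// [[Rcpp::export]]
Rcpp::List cpp_perm_maxstat(const arma::mat& fitted_r, const arma::mat& resid_r,
                            const arma::mat& X, const arma::vec& contrast,
                            const arma::umat& perms, IntegerVector dims,
                            IntegerVector mask_idx, double z_thresh,
                            int connectivity, bool do_cluster, bool do_tfce,
                            double E, double H, double dh, bool two_sided) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int V = d[0] * d[1] * d[2];
  int n = X.n_rows, p = X.n_cols;
  int nperm = perms.n_rows;
  int nvox = mask_idx.size();
  double df = n - p;
  arma::mat XtXinv = arma::inv_sympd(X.t() * X);
  arma::mat M = XtXinv * X.t();          // p x n
  arma::rowvec cM = contrast.t() * M;    // 1 x n
  double cXXc = arma::as_scalar(contrast.t() * XtXinv * contrast);
  NumericVector max_cluster(nperm), max_tfce(nperm);
  std::vector<double> zfull(V, R_NegInf);
  std::vector<int> labels;
  std::vector<int> sizes;
  std::vector<double> tf;
  for (int ip = 0; ip < nperm; ++ip) {
    arma::uvec pr = perms.row(ip).t();
    arma::mat Yp = fitted_r + resid_r.rows(pr);
    arma::rowvec eff = cM * Yp;
    arma::mat B = M * Yp;
    arma::mat Eres = Yp - X * B;
    arma::rowvec s2 = arma::sum(Eres % Eres, 0) / df;
    std::fill(zfull.begin(), zfull.end(), R_NegInf);
    for (int j = 0; j < nvox; ++j) {
      double denom = std::sqrt(s2(j) * cXXc);
      double t = denom > 0 ? eff(j) / denom : 0.0;
      double z;
      if (t >= 0)
        z = ::Rf_qnorm5(::Rf_pt(t, df, 0, 1), 0.0, 1.0, 0, 1);
      else
        z = -::Rf_qnorm5(::Rf_pt(-t, df, 0, 1), 0.0, 1.0, 0, 1);
      if (two_sided) z = std::fabs(z);
      zfull[mask_idx[j]] = z;
    }
    if (do_cluster) {
      label_components_impl(zfull.data(), z_thresh, d, connectivity, labels, sizes);
      int mx = 0;
      for (size_t k = 0; k < sizes.size(); ++k) if (sizes[k] > mx) mx = sizes[k];
      max_cluster[ip] = mx;
    }
    if (do_tfce) {
      // background -Inf values are never positive, so they stay outside
      for (int v = 0; v < V; ++v) if (!std::isfinite(zfull[v])) zfull[v] = 0.0;
      tfce_impl(zfull.data(), d, E, H, dh, connectivity, tf);
      double mx = 0.0;
      for (int j = 0; j < nvox; ++j)
        if (tf[mask_idx[j]] > mx) mx = tf[mask_idx[j]];
      max_tfce[ip] = mx;
    }
  }
  return Rcpp::List::create(Rcpp::Named("max_cluster") = max_cluster,
                            Rcpp::Named("max_tfce") = max_tfce);
}
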