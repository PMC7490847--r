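#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Threshold-free cluster enhancement and a two-sample permutation engine.
//
// TFCE(v) = sum over thresholds h = dh, 2dh, ... <= stat(v) of
//             e(h, v)^E * h^H * dh
// where e(h, v) is the voxel count of the connected component containing v
// in the supra-threshold image {stat >= h}.  Thresholds are processed in
// descending order with an incremental union-find so each level only merges
// newly activated voxels.

namespace {

struct UF {
  std::vector<int> parent, size;
  UF(size_t n) : parent(n, -1), size(n, 0) {}
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nxt = parent[x]; parent[x] = r; x = nxt; }
    return r;
  }
  void activate(int x) { parent[x] = x; size[x] = 1; }
  bool active(int x) const { return parent[x] >= 0; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

void neighbour_offsets(int connectivity, const int dim[3],
                       std::vector<long long> &off,
                       std::vector<int> &dx, std::vector<int> &dy,
                       std::vector<int> &dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back((long long)a + (long long)dim[0] *
                      ((long long)b + (long long)dim[1] * (long long)c));
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

void tfce_into(const double *stat, const int dim[3], double H, double E,
               double dh_in, int connectivity, double *out,
               std::vector<int> &order_buf) {
  long long nvox = (long long)dim[0] * dim[1] * dim[2];
  double hmax = 0.0;
  for (long long v = 0; v < nvox; ++v) {
    out[v] = 0.0;
    if (stat[v] > hmax) hmax = stat[v];
  }
  if (hmax <= 0.0) return;
  double dh = dh_in > 0 ? dh_in : hmax / 100.0;
  int nh = (int)std::floor(hmax / dh + 1e-10);
  if (nh < 1) return;

  order_buf.clear();
  for (long long v = 0; v < nvox; ++v)
    if (stat[v] >= dh) order_buf.push_back((int)v);
  std::sort(order_buf.begin(), order_buf.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<long long> off;
  std::vector<int> ox, oy, oz;
  neighbour_offsets(connectivity, dim, off, ox, oy, oz);

  UF uf(nvox);
  size_t next = 0;
  std::vector<int> active;
  active.reserve(order_buf.size());
  for (int m = nh; m >= 1; --m) {
    double h = m * dh;
    while (next < order_buf.size() && stat[order_buf[next]] >= h) {
      int v = order_buf[next++];
      uf.activate(v);
      active.push_back(v);
      int i = v % dim[0];
      int j = (v / dim[0]) % dim[1];
      int k = v / (dim[0] * dim[1]);
      for (size_t q = 0; q < off.size(); ++q) {
        int ni = i + ox[q], nj = j + oy[q], nk = k + oz[q];
        if (ni < 0 || nj < 0 || nk < 0 ||
            ni >= dim[0] || nj >= dim[1] || nk >= dim[2]) continue;
        long long nb = v + off[q];
        if (uf.active((int)nb)) uf.unite(v, (int)nb);
      }
    }
    double hh = std::pow(h, H) * dh;
    for (size_t q = 0; q < active.size(); ++q) {
      int v = active[q];
      out[v] += std::pow((double)uf.size[uf.find(v)], E) * hh;
    }
  }
}

// pooled-variance two-sample t statistic per voxel; group1 - group0
void tmap_into(const double *data, long long nvox, int nsub,
               const int *grp, double *t) {
  int n1 = 0;
  for (int s = 0; s < nsub; ++s) n1 += grp[s];
  int n0 = nsub - n1;
  for (long long v = 0; v < nvox; ++v) {
    double s0 = 0, s1 = 0, q0 = 0, q1 = 0;
    for (int s = 0; s < nsub; ++s) {
      double x = data[v + nvox * s];
      if (grp[s]) { s1 += x; q1 += x * x; }
      else        { s0 += x; q0 += x * x; }
    }
    double m1 = s1 / n1, m0 = s0 / n0;
    double ss = (q1 - n1 * m1 * m1) + (q0 - n0 * m0 * m0);
    double sp2 = ss / (double)(n1 + n0 - 2);
    double se = std::sqrt(sp2 * (1.0 / n1 + 1.0 / n0));
    t[v] = se > 0 ? (m1 - m0) / se : 0.0;
  }
}

} // namespace

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim_, double H,
                       double E, double dh, int connectivity) {
  int dim[3] = { dim_[0], dim_[1], dim_[2] };
  NumericVector out(stat.size());
  std::vector<int> buf;
  tfce_into(REAL(stat), dim, H, E, dh, connectivity, REAL(out), buf);
  out.attr("dim") = dim_;
  return out;
}

// data: nvox x nsub matrix (one column per subject, voxels stacked
// column-major over the 3-D grid).  perms: nperm x nsub matrix of 0/1 group
// indicators; the first row is the observed labelling, the remaining rows
// form the permutation null of the maximum TFCE statistic.
// [[Rcpp::export(name = ".perm_tfce_cpp")]]
List perm_tfce_cpp(NumericMatrix data, IntegerMatrix perms, IntegerVector dim_,
                   double H, double E, double dh, int connectivity) {
  int dim[3] = { dim_[0], dim_[1], dim_[2] };
  long long nvox = (long long)dim[0] * dim[1] * dim[2];
  if ((long long)data.nrow() != nvox)
    stop("data rows must match the grid size");
  int nsub = data.ncol();
  int nperm = perms.nrow();

  NumericVector tobs(nvox), tfce_obs(nvox), null_max(nperm - 1);
  std::vector<double> t(nvox), tf(nvox);
  std::vector<int> grp(nsub), buf;

  for (int r = 0; r < nperm; ++r) {
    for (int s = 0; s < nsub; ++s) grp[s] = perms(r, s);
    tmap_into(REAL(data), nvox, nsub, grp.data(), t.data());
    tfce_into(t.data(), dim, H, E, dh, connectivity, tf.data(), buf);
    if (r == 0) {
      std::copy(t.begin(), t.end(), REAL(tobs));
      std::copy(tf.begin(), tf.end(), REAL(tfce_obs));
    } else {
      double m = 0.0;
      for (long long v = 0; v < nvox; ++v) if (tf[v] > m) m = tf[v];
      null_max[r - 1] = m;
    }
  }
  tobs.attr("dim") = dim_;
  tfce_obs.attr("dim") = dim_;
  return List::create(_["t_obs"] = tobs, _["tfce_obs"] = tfce_obs,
                      _["null_max"] = null_max);
}
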