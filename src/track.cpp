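#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Streamline propagation through a discrete per-voxel orientation field.
//
// Geometry conventions (shared with the R side):
//  * voxel indices are 0-based; voxel (i,j,k) spans
//    [i*vs_x, (i+1)*vs_x) x ... in world mm, so its centre is (i+0.5)*vs_x.
//  * hemisphere labels: -1 = left, 0 = mid-sagittal plane, +1 = right.
//  * direction array dims: (nx, ny, nz, pop, component), amplitudes
//    (nx, ny, nz, pop), both column-major as produced by R.

namespace {

struct Field {
  const double *amp;
  const double *dir;
  const int *wm;
  const int *hemi;
  int nx, ny, nz, npop;
  double vs[3];

  inline R_xlen_t vox(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
  }
  inline double amplitude(R_xlen_t v, int p) const {
    return amp[v + (R_xlen_t)nx * ny * nz * p];
  }
  inline void direction(R_xlen_t v, int p, double out[3]) const {
    R_xlen_t n3 = (R_xlen_t)nx * ny * nz;
    for (int c = 0; c < 3; ++c) out[c] = dir[v + n3 * (p + npop * c)];
  }
  inline double max_amplitude(R_xlen_t v) const {
    double m = 0.0;
    for (int p = 0; p < npop; ++p) {
      double a = amplitude(v, p);
      if (a > m) m = a;
    }
    return m;
  }
};

inline void normalize(double d[3]) {
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (n > 0) { d[0] /= n; d[1] /= n; d[2] /= n; }
}

inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Draw from a von Mises-Fisher distribution on S^2 with mean mu (unit) and
// concentration kappa.  kappa = +Inf degenerates to mu itself (deterministic
// mode).  Uses the inversion formula for the cosine of the polar angle.
void vmf_sample(const double mu[3], double kappa, double out[3]) {
  if (!R_finite(kappa)) {
    out[0] = mu[0]; out[1] = mu[1]; out[2] = mu[2];
    return;
  }
  double u = unif_rand();
  double w = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
  if (w > 1.0) w = 1.0;
  if (w < -1.0) w = -1.0;
  // orthonormal basis perpendicular to mu
  double e1[3];
  if (std::fabs(mu[0]) < 0.9) { e1[0] = 1.0; e1[1] = 0.0; e1[2] = 0.0; }
  else                        { e1[0] = 0.0; e1[1] = 1.0; e1[2] = 0.0; }
  double pr = dot3(e1, mu);
  for (int c = 0; c < 3; ++c) e1[c] -= pr * mu[c];
  normalize(e1);
  double e2[3] = { mu[1] * e1[2] - mu[2] * e1[1],
                   mu[2] * e1[0] - mu[0] * e1[2],
                   mu[0] * e1[1] - mu[1] * e1[0] };
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  for (int c = 0; c < 3; ++c)
    out[c] = w * mu[c] + s * (std::cos(phi) * e1[c] + std::sin(phi) * e2[c]);
  normalize(out);
}

// Amplitude x |cos| weighted population selection; ties -> lowest index.
// Returns the population index, or -1 when no population has amplitude > 0.
int select_population(const Field &f, R_xlen_t v, const double incoming[3]) {
  int best = -1;
  double best_w = -1.0;
  double d[3];
  for (int p = 0; p < f.npop; ++p) {
    double a = f.amplitude(v, p);
    if (a <= 0) continue;
    f.direction(v, p, d);
    double w = a * std::fabs(dot3(d, incoming));
    if (w > best_w + 1e-15) { best_w = w; best = p; }
  }
  return best;
}

// Termination codes (kept in sync with the R wrapper's factor levels)
enum Term { TERM_AMPLITUDE = 1, TERM_CURVATURE = 2, TERM_MASK_EXIT = 3,
            TERM_MAX_LENGTH = 4, TERM_MIDLINE = 5 };

struct StepperParams {
  double step, cos_max_turn, amp_threshold, kappa, max_length;
  int hemi_target;  // -1 or +1
};

// Propagate from `p0` with first direction `d0` until termination.
// Appends points (excluding the seed itself) to `pts`.  Sets `hit_midline`
// if any visited voxel is off the tracked hemisphere.  Returns the
// termination code.
int propagate(const Field &f, const StepperParams &sp,
              const double p0[3], const double d0[3],
              std::vector<double> &pts, bool &hit_midline) {
  double p[3] = { p0[0], p0[1], p0[2] };
  double d[3] = { d0[0], d0[1], d0[2] };
  double length = 0.0;
  bool first = true;
  for (;;) {
    double dnew[3];
    if (first) {
      dnew[0] = d[0]; dnew[1] = d[1]; dnew[2] = d[2];
      first = false;
    } else {
      int i = (int)std::floor(p[0] / f.vs[0]);
      int j = (int)std::floor(p[1] / f.vs[1]);
      int k = (int)std::floor(p[2] / f.vs[2]);
      R_xlen_t v = f.vox(i, j, k);
      int pop = select_population(f, v, d);
      if (pop < 0) return TERM_AMPLITUDE;
      double mu[3];
      f.direction(v, pop, mu);
      if (dot3(mu, d) < 0) { mu[0] = -mu[0]; mu[1] = -mu[1]; mu[2] = -mu[2]; }
      vmf_sample(mu, sp.kappa, dnew);
      if (dot3(dnew, d) < sp.cos_max_turn) return TERM_CURVATURE;
    }
    if (length + sp.step > sp.max_length) return TERM_MAX_LENGTH;
    double pn[3] = { p[0] + sp.step * dnew[0],
                     p[1] + sp.step * dnew[1],
                     p[2] + sp.step * dnew[2] };
    int i = (int)std::floor(pn[0] / f.vs[0]);
    int j = (int)std::floor(pn[1] / f.vs[1]);
    int k = (int)std::floor(pn[2] / f.vs[2]);
    if (i < 0 || j < 0 || k < 0 || i >= f.nx || j >= f.ny || k >= f.nz)
      return TERM_MASK_EXIT;
    R_xlen_t v = f.vox(i, j, k);
    if (f.hemi[v] != sp.hemi_target) { hit_midline = true; return TERM_MIDLINE; }
    if (!f.wm[v]) return TERM_MASK_EXIT;
    if (f.max_amplitude(v) < sp.amp_threshold) return TERM_AMPLITUDE;
    pts.push_back(pn[0]); pts.push_back(pn[1]); pts.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    d[0] = dnew[0]; d[1] = dnew[1]; d[2] = dnew[2];
    length += sp.step;
  }
}

// Mark the voxels visited by a polyline into `counts`, at most once per
// streamline, using `stamp` with the current streamline id.  Segments are
// supersampled at <= spacing/2 so no traversed voxel is skipped.
void count_visits(const Field &f, const std::vector<double> &pts,
                  std::vector<int> &counts, std::vector<int> &stamp, int id,
                  double spacing) {
  size_t n = pts.size() / 3;
  for (size_t a = 0; a < n; ++a) {
    const double *pa = &pts[3 * a];
    size_t nsub = 1;
    const double *pb = pa;
    if (a + 1 < n) {
      pb = &pts[3 * (a + 1)];
      double dx = pb[0] - pa[0], dy = pb[1] - pa[1], dz = pb[2] - pa[2];
      double seg = std::sqrt(dx * dx + dy * dy + dz * dz);
      nsub = (size_t)std::ceil(seg / (spacing / 2.0));
      if (nsub < 1) nsub = 1;
    }
    size_t smax = (a + 1 < n) ? nsub : 1;  // include endpoint only once
    for (size_t s = 0; s < smax; ++s) {
      double t = (double)s / (double)nsub;
      double x = pa[0] + t * (pb[0] - pa[0]);
      double y = pa[1] + t * (pb[1] - pa[1]);
      double z = pa[2] + t * (pb[2] - pa[2]);
      int i = (int)std::floor(x / f.vs[0]);
      int j = (int)std::floor(y / f.vs[1]);
      int k = (int)std::floor(z / f.vs[2]);
      R_xlen_t v = f.vox(i, j, k);
      if (stamp[v] != id) { stamp[v] = id; counts[v] += 1; }
    }
  }
  // final endpoint
  if (n > 0) {
    const double *pl = &pts[3 * (n - 1)];
    int i = (int)std::floor(pl[0] / f.vs[0]);
    int j = (int)std::floor(pl[1] / f.vs[1]);
    int k = (int)std::floor(pl[2] / f.vs[2]);
    R_xlen_t v = f.vox(i, j, k);
    if (stamp[v] != id) { stamp[v] = id; counts[v] += 1; }
  }
}

} // namespace

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericVector amplitudes, NumericVector directions,
               IntegerVector wm_mask, IntegerVector hemi_labels,
               IntegerVector grid_shape, NumericVector voxel_size,
               int hemi_target, int seeds_per_voxel, double step_size,
               double max_turn_deg, double amp_threshold, double kappa,
               double min_length, double max_length, bool keep_streamlines) {
  Field f;
  f.amp = REAL(amplitudes);
  f.dir = REAL(directions);
  f.wm = INTEGER(wm_mask);
  f.hemi = INTEGER(hemi_labels);
  f.nx = grid_shape[0]; f.ny = grid_shape[1]; f.nz = grid_shape[2];
  IntegerVector adim = amplitudes.attr("dim");
  f.npop = adim[3];
  f.vs[0] = voxel_size[0]; f.vs[1] = voxel_size[1]; f.vs[2] = voxel_size[2];

  StepperParams sp;
  sp.step = step_size;
  sp.cos_max_turn = std::cos(max_turn_deg * M_PI / 180.0);
  sp.amp_threshold = amp_threshold;
  sp.kappa = kappa;
  sp.max_length = max_length;
  sp.hemi_target = hemi_target;

  R_xlen_t nvox = (R_xlen_t)f.nx * f.ny * f.nz;
  std::vector<int> counts(nvox, 0), stamp(nvox, -1);

  // seed voxels in fixed column-major order for determinism
  std::vector<R_xlen_t> seeds;
  for (int k = 0; k < f.nz; ++k)
    for (int j = 0; j < f.ny; ++j)
      for (int i = 0; i < f.nx; ++i) {
        R_xlen_t v = f.vox(i, j, k);
        if (f.wm[v] && f.hemi[v] == hemi_target) seeds.push_back(v);
      }
  if (seeds.empty())
    stop("no white-matter voxels in the requested hemisphere");

  long long n_launched = 0, n_retained = 0, n_midline = 0, n_short = 0;
  int id = 0;

  std::vector<double> all_pts;
  std::vector<int> sl_len, sl_seed, sl_term_a, sl_term_b;

  std::vector<double> fwd, bwd, poly;
  for (size_t sv = 0; sv < seeds.size(); ++sv) {
    R_xlen_t v = seeds[sv];
    int i = (int)(v % f.nx);
    int j = (int)((v / f.nx) % f.ny);
    int k = (int)(v / ((R_xlen_t)f.nx * f.ny));
    for (int s = 0; s < seeds_per_voxel; ++s) {
      ++n_launched;
      double p0[3] = { (i + unif_rand()) * f.vs[0],
                       (j + unif_rand()) * f.vs[1],
                       (k + unif_rand()) * f.vs[2] };
      // launch direction: population chosen with probability ~ amplitude
      double tot = 0.0;
      for (int p = 0; p < f.npop; ++p) tot += f.amplitude(v, p);
      if (tot <= 0 || f.max_amplitude(v) < sp.amp_threshold) { ++n_short; continue; }
      double u = unif_rand() * tot, acc = 0.0;
      int pop = 0;
      for (int p = 0; p < f.npop; ++p) {
        acc += f.amplitude(v, p);
        if (u <= acc) { pop = p; break; }
      }
      double mu[3], d0[3];
      f.direction(v, pop, mu);
      vmf_sample(mu, sp.kappa, d0);

      bool hit_mid = false;
      fwd.clear(); bwd.clear();
      int term_f = propagate(f, sp, p0, d0, fwd, hit_mid);
      double d0r[3] = { -d0[0], -d0[1], -d0[2] };
      int term_b = TERM_MIDLINE;
      if (!hit_mid) term_b = propagate(f, sp, p0, d0r, bwd, hit_mid);
      if (hit_mid) { ++n_midline; continue; }

      size_t npts = fwd.size() / 3 + bwd.size() / 3 + 1;
      double len = (double)(npts - 1) * sp.step;
      if (len < min_length) { ++n_short; continue; }

      poly.clear();
      for (size_t q = bwd.size() / 3; q-- > 0;) {
        poly.push_back(bwd[3 * q]); poly.push_back(bwd[3 * q + 1]);
        poly.push_back(bwd[3 * q + 2]);
      }
      poly.push_back(p0[0]); poly.push_back(p0[1]); poly.push_back(p0[2]);
      poly.insert(poly.end(), fwd.begin(), fwd.end());

      count_visits(f, poly, counts, stamp, id, sp.step);
      ++id;
      ++n_retained;
      if (keep_streamlines) {
        all_pts.insert(all_pts.end(), poly.begin(), poly.end());
        sl_len.push_back((int)(poly.size() / 3));
        sl_seed.push_back((int)v);
        sl_term_a.push_back(term_b);  // backward end comes first in the polyline
        sl_term_b.push_back(term_f);
      }
    }
  }

  IntegerVector cnt(counts.begin(), counts.end());
  cnt.attr("dim") = grid_shape;
  List out = List::create(
    _["counts"] = cnt,
    _["n_launched"] = (double)n_launched,
    _["n_retained"] = (double)n_retained,
    _["n_midline_excluded"] = (double)n_midline,
    _["n_below_min_length"] = (double)n_short);
  if (keep_streamlines) {
    NumericMatrix pts((int)(all_pts.size() / 3), 3);
    for (size_t q = 0; q < all_pts.size() / 3; ++q) {
      pts(q, 0) = all_pts[3 * q];
      pts(q, 1) = all_pts[3 * q + 1];
      pts(q, 2) = all_pts[3 * q + 2];
    }
    out["points"] = pts;
    out["n_points"] = IntegerVector(sl_len.begin(), sl_len.end());
    out["seed_voxel"] = IntegerVector(sl_seed.begin(), sl_seed.end());
    out["term_first"] = IntegerVector(sl_term_a.begin(), sl_term_a.end());
    out["term_last"] = IntegerVector(sl_term_b.begin(), sl_term_b.end());
  }
  return out;
}

// [[Rcpp::export(name = ".count_visits_cpp")]]
IntegerVector count_visits_cpp(NumericMatrix points, IntegerVector n_points,
                               IntegerVector grid_shape,
                               NumericVector voxel_size, double spacing) {
  Field f;
  f.nx = grid_shape[0]; f.ny = grid_shape[1]; f.nz = grid_shape[2];
  f.vs[0] = voxel_size[0]; f.vs[1] = voxel_size[1]; f.vs[2] = voxel_size[2];
  R_xlen_t nvox = (R_xlen_t)f.nx * f.ny * f.nz;
  std::vector<int> counts(nvox, 0), stamp(nvox, -1);
  int row = 0;
  for (int s = 0; s < n_points.size(); ++s) {
    std::vector<double> poly;
    poly.reserve(3 * n_points[s]);
    for (int q = 0; q < n_points[s]; ++q, ++row) {
      double x = points(row, 0), y = points(row, 1), z = points(row, 2);
      if (x < 0 || y < 0 || z < 0 ||
          x >= f.nx * f.vs[0] || y >= f.ny * f.vs[1] || z >= f.nz * f.vs[2])
        stop("streamline point outside the grid");
      poly.push_back(x); poly.push_back(y); poly.push_back(z);
    }
    count_visits(f, poly, counts, stamp, s, spacing);
  }
  IntegerVector cnt(counts.begin(), counts.end());
  cnt.attr("dim") = grid_shape;
  return cnt;
}
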