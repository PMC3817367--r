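// Deterministic tensor tractography core: trilinear interpolation of the six
// unique tensor components, per-step eigen-decomposition, Euler integration
// with FA / turning-angle / volume-exit termination.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// flat index into an [nx, ny, nz, 6] R array
inline std::size_t flat(int i, int j, int k, int c,
                        int nx, int ny, int nz) {
  return (std::size_t)i +
         (std::size_t)nx * ((std::size_t)j +
         (std::size_t)ny * ((std::size_t)k + (std::size_t)nz * c));
}

arma::mat33 tensor_at_voxel(const double *t, int i, int j, int k,
                            int nx, int ny, int nz) {
  arma::mat33 m;
  double xx = t[flat(i, j, k, 0, nx, ny, nz)];
  double xy = t[flat(i, j, k, 1, nx, ny, nz)];
  double xz = t[flat(i, j, k, 2, nx, ny, nz)];
  double yy = t[flat(i, j, k, 3, nx, ny, nz)];
  double yz = t[flat(i, j, k, 4, nx, ny, nz)];
  double zz = t[flat(i, j, k, 5, nx, ny, nz)];
  m(0, 0) = xx; m(0, 1) = xy; m(0, 2) = xz;
  m(1, 0) = xy; m(1, 1) = yy; m(1, 2) = yz;
  m(2, 0) = xz; m(2, 1) = yz; m(2, 2) = zz;
  return m;
}

double fa_from_eigvals(arma::vec3 lam) {
  for (int i = 0; i < 3; ++i) if (lam(i) < 0) lam(i) = 0;
  double ss = arma::dot(lam, lam);
  if (ss == 0.0) return 0.0;
  double mean = (lam(0) + lam(1) + lam(2)) / 3.0;
  double dev = 0.0;
  for (int i = 0; i < 3; ++i) dev += (lam(i) - mean) * (lam(i) - mean);
  double fa = std::sqrt(1.5 * dev / ss);
  return fa > 1.0 ? 1.0 : fa;
}

inline bool in_grid(const arma::vec3 &v, int nx, int ny, int nz) {
  return v(0) >= 0 && v(1) >= 0 && v(2) >= 0 &&
         v(0) <= nx - 1 && v(1) <= ny - 1 && v(2) <= nz - 1;
}

// trilinear interpolation of the tensor at continuous voxel coordinates;
// returns false when outside the grid
bool interp_tensor(const double *t, int nx, int ny, int nz,
                   const arma::vec3 &v, arma::mat33 &out) {
  if (!in_grid(v, nx, ny, nz)) return false;
  int i0 = (int)std::floor(v(0)); if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)std::floor(v(1)); if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)std::floor(v(2)); if (k0 > nz - 2) k0 = nz - 2;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = v(0) - i0, fy = v(1) - j0, fz = v(2) - k0;
  double comp[6];
  for (int c = 0; c < 6; ++c) {
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk) {
      int kk = (nz == 1) ? 0 : k0 + dk;
      double wz = (nz == 1) ? (dk == 0 ? 1.0 : 0.0) : (dk ? fz : 1.0 - fz);
      if (wz == 0.0) continue;
      for (int dj = 0; dj < 2; ++dj) {
        int jj = (ny == 1) ? 0 : j0 + dj;
        double wy = (ny == 1) ? (dj == 0 ? 1.0 : 0.0) : (dj ? fy : 1.0 - fy);
        if (wy == 0.0) continue;
        for (int di = 0; di < 2; ++di) {
          int ii = (nx == 1) ? 0 : i0 + di;
          double wx = (nx == 1) ? (di == 0 ? 1.0 : 0.0)
                                : (di ? fx : 1.0 - fx);
          if (wx == 0.0) continue;
          acc += wx * wy * wz * t[flat(ii, jj, kk, c, nx, ny, nz)];
        }
      }
    }
    comp[c] = acc;
  }
  out(0, 0) = comp[0]; out(0, 1) = comp[1]; out(0, 2) = comp[2];
  out(1, 0) = comp[1]; out(1, 1) = comp[3]; out(1, 2) = comp[4];
  out(2, 0) = comp[2]; out(2, 1) = comp[4]; out(2, 2) = comp[5];
  return true;
}

arma::vec3 mm_to_vox(const arma::mat44 &inv_aff, const arma::vec3 &mm) {
  arma::vec4 h = {mm(0), mm(1), mm(2), 1.0};
  arma::vec4 v = inv_aff * h;
  return {v(0), v(1), v(2)};
}

struct HalfTrack {
  std::vector<arma::vec3> pts;  // excludes the seed itself
  std::string reason;
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_fa_volume(NumericVector tensors, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector fa((std::size_t)nx * ny * nz);
  const double *t = tensors.begin();
  arma::vec3 lam;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        arma::mat33 D = tensor_at_voxel(t, i, j, k, nx, ny, nz);
        arma::eig_sym(lam, D);
        fa[flat(i, j, k, 0, nx, ny, nz)] = fa_from_eigvals(lam);
      }
  return fa;
}

// [[Rcpp::export]]
NumericVector cpp_fa_at_points(NumericVector tensors, IntegerVector dim,
                               NumericMatrix affine, NumericMatrix points) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  arma::mat44 aff(affine.begin());
  arma::mat44 inv_aff = arma::inv(aff);
  int np = points.nrow();
  NumericVector out(np);
  const double *t = tensors.begin();
  arma::mat33 D;
  arma::vec3 lam;
  for (int p = 0; p < np; ++p) {
    arma::vec3 mm = {points(p, 0), points(p, 1), points(p, 2)};
    arma::vec3 v = mm_to_vox(inv_aff, mm);
    if (!interp_tensor(t, nx, ny, nz, v, D)) {
      out[p] = NA_REAL;
    } else {
      arma::eig_sym(lam, D);
      out[p] = fa_from_eigvals(lam);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_track(NumericVector tensors, IntegerVector dim, NumericMatrix affine,
               NumericMatrix seeds, double step_mm, double fa_thresh,
               double angle_deg, int max_steps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  arma::mat44 aff(affine.begin());
  arma::mat44 inv_aff = arma::inv(aff);
  double cos_thresh = std::cos(angle_deg * M_PI / 180.0);
  const double *t = tensors.begin();

  // one Euler half-track from `mm0` along initial direction `dir0`
  auto run = [&](const arma::vec3 &mm0, const arma::vec3 &dir0) {
    HalfTrack h;
    arma::vec3 p = mm0;
    arma::vec3 prev = dir0;
    arma::mat33 Dc, Dn, evc;
    arma::vec3 lamc, lamn;
    for (int st = 0; st < max_steps; ++st) {
      arma::vec3 vc = mm_to_vox(inv_aff, p);
      if (!interp_tensor(t, nx, ny, nz, vc, Dc)) {
        h.reason = "out_of_volume"; return h;
      }
      arma::eig_sym(lamc, evc, Dc);
      if (fa_from_eigvals(lamc) < fa_thresh) { h.reason = "fa"; return h; }
      arma::vec3 d = evc.col(2);  // principal eigenvector
      if (arma::dot(d, prev) < 0) d = -d;
      if (arma::dot(d, prev) < cos_thresh) { h.reason = "angle"; return h; }
      arma::vec3 pn = p + step_mm * d;
      arma::vec3 vn = mm_to_vox(inv_aff, pn);
      if (!interp_tensor(t, nx, ny, nz, vn, Dn)) {
        h.reason = "out_of_volume"; return h;
      }
      arma::eig_sym(lamn, Dn);
      if (fa_from_eigvals(lamn) < fa_thresh) { h.reason = "fa"; return h; }
      h.pts.push_back(pn);
      p = pn;
      prev = d;
    }
    h.reason = "max_steps";
    return h;
  };

  int ns = seeds.nrow();
  std::vector<NumericMatrix> lines;
  std::vector<int> seed_idx;
  std::vector<std::string> term_f, term_b;

  for (int s = 0; s < ns; ++s) {
    arma::vec3 mm = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    arma::vec3 v = mm_to_vox(inv_aff, mm);
    if (!in_grid(v, nx, ny, nz)) continue;
    // first step direction: principal eigenvector of the seed's voxel tensor
    int i = (int)std::lround(v(0)); if (i > nx - 1) i = nx - 1;
    int j = (int)std::lround(v(1)); if (j > ny - 1) j = ny - 1;
    int k = (int)std::lround(v(2)); if (k > nz - 1) k = nz - 1;
    arma::mat33 D = tensor_at_voxel(t, i, j, k, nx, ny, nz);
    arma::vec3 lam;
    arma::mat33 evec;
    arma::eig_sym(lam, evec, D);
    if (fa_from_eigvals(lam) < fa_thresh) continue;
    arma::vec3 e0 = evec.col(2);

    HalfTrack fwd = run(mm, e0);
    HalfTrack bwd = run(mm, -e0);

    int nv = (int)(bwd.pts.size() + 1 + fwd.pts.size());
    if (nv < 2) continue;
    NumericMatrix line(nv, 3);
    int r = 0;
    for (int q = (int)bwd.pts.size() - 1; q >= 0; --q, ++r)
      for (int c = 0; c < 3; ++c) line(r, c) = bwd.pts[q](c);
    for (int c = 0; c < 3; ++c) line(r, c) = mm(c);
    ++r;
    for (std::size_t q = 0; q < fwd.pts.size(); ++q, ++r)
      for (int c = 0; c < 3; ++c) line(r, c) = fwd.pts[q](c);
    lines.push_back(line);
    seed_idx.push_back(s + 1);
    term_f.push_back(fwd.reason);
    term_b.push_back(bwd.reason);
  }

  List out_lines(lines.size());
  for (std::size_t q = 0; q < lines.size(); ++q) out_lines[q] = lines[q];
  return List::create(_["streamlines"] = out_lines,
                      _["seed_index"] = wrap(seed_idx),
                      _["termination_fwd"] = wrap(term_f),
                      _["termination_bwd"] = wrap(term_b));
}
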