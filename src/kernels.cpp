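// Inner-loop kernels for the reference energy function and rotamer building.
//
// Energy model (see R/energy.R for the contract):
//  * 12-6 Lennard-Jones on heavy-atom pairs, sigma = r_i + r_j,
//    eps = sqrt(e_i e_j), split Weeks-Chandler-Andersen style into an
//    attractive and a repulsive component; the repulsive branch is
//    linearized below rep_frac * sigma so overlapping atoms stay finite.
//  * Directional hydrogen bond between a polar hydrogen (with its donor
//    heavy atom) and an acceptor heavy atom: donor-acceptor distance window
//    [hb_dmin, hb_dmax] with a squared-cosine ramp peaking at hb_d0, times a
//    squared-cosine falloff in the D-H...A angle (zero below 90 degrees).
//    Polar hydrogens carry no Lennard-Jones term.
//
// Angles at this interface are degrees; coordinates Angstrom.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct EnergyParams {
  double cutoff;
  double rep_frac;
  double hb_depth;
  double hb_dmin;
  double hb_d0;
  double hb_dmax;
};

struct Acc3 {
  double attr = 0.0, rep = 0.0, hb = 0.0;
};

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// split LJ for one pair; adds into acc (scaled by w)
static inline void lj_pair(double d, double sigma, double eps,
                           const EnergyParams& P, double w, Acc3& acc) {
  if (d > P.cutoff) return;
  double dlin = P.rep_frac * sigma;
  if (d < dlin) {
    // linearized repulsion below rep_frac * sigma (finite at d = 0)
    double s6 = std::pow(sigma / dlin, 6.0);
    double e_lin = eps * (s6 * s6 - 2.0 * s6) + eps;
    double slope = eps * (-12.0 * std::pow(sigma, 12.0) / std::pow(dlin, 13.0)
                          + 12.0 * std::pow(sigma, 6.0) / std::pow(dlin, 7.0));
    acc.rep += w * (e_lin + slope * (d - dlin));
    acc.attr += w * (-eps);
  } else if (d < sigma) {
    double s6 = std::pow(sigma / d, 6.0);
    acc.rep += w * (eps * (s6 * s6 - 2.0 * s6) + eps);
    acc.attr += w * (-eps);
  } else {
    double s6 = std::pow(sigma / d, 6.0);
    acc.attr += w * (eps * (s6 * s6 - 2.0 * s6));
  }
}

// hydrogen bond: h/d in one set, a (acceptor) in the other
static inline void hb_pair(const double* h, const double* d, const double* a,
                           const EnergyParams& P, double w, Acc3& acc) {
  double dda = dist3(d, a);
  if (dda < P.hb_dmin || dda > P.hb_dmax) return;
  double uhd[3], uha[3];
  double nhd = dist3(h, d), nha = dist3(h, a);
  if (nhd < 1e-9 || nha < 1e-9) return;
  for (int k = 0; k < 3; ++k) {
    uhd[k] = (d[k] - h[k]) / nhd;
    uha[k] = (a[k] - h[k]) / nha;
  }
  double ct = uhd[0] * uha[0] + uhd[1] * uha[1] + uhd[2] * uha[2];
  if (ct > 0.0) return;  // D-H...A angle below 90 degrees
  double fang = ct * ct;
  double fd;
  if (dda < P.hb_d0) {
    double x = (dda - P.hb_d0) / (P.hb_d0 - P.hb_dmin);
    fd = std::cos(M_PI_2 * x);
  } else {
    double x = (dda - P.hb_d0) / (P.hb_dmax - P.hb_d0);
    fd = std::cos(M_PI_2 * x);
  }
  fd *= fd;
  acc.hb += w * (-P.hb_depth * fd * fang);
}

static inline const double* dptr(const NumericVector& v) {
  return v.size() ? &v[0] : nullptr;
}
static inline const int* iptr(const IntegerVector& v) {
  return v.size() ? &v[0] : nullptr;
}

static EnergyParams unpack_params(NumericVector par) {
  EnergyParams P;
  P.cutoff = par["cutoff"];
  P.rep_frac = par["rep_frac"];
  P.hb_depth = par["hb_depth"];
  P.hb_dmin = par["hb_dmin"];
  P.hb_d0 = par["hb_d0"];
  P.hb_dmax = par["hb_dmax"];
  return P;
}

// score all pairs between two disjoint atom sets
static Acc3 score_sets_core(const double* x1, int n1,
                            const double* r1, const double* e1,
                            const int* hb1, const int* ac1,
                            const double* x2, int n2,
                            const double* r2, const double* e2,
                            const int* hb2, const int* ac2,
                            const double* w2,
                            const std::vector<char>& excl,
                            const EnergyParams& P) {
  Acc3 acc;
  for (int i = 0; i < n1; ++i) {
    const double* pi = x1 + 3 * i;
    bool i_is_h = hb1[i] >= 0;
    for (int j = 0; j < n2; ++j) {
      if (!excl.empty() && excl[(size_t)i * n2 + j]) continue;
      const double* pj = x2 + 3 * j;
      double w = (w2 == nullptr) ? 1.0 : w2[j];
      bool j_is_h = hb2[j] >= 0;
      if (!i_is_h && !j_is_h) {
        double d = dist3(pi, pj);
        lj_pair(d, r1[i] + r2[j], std::sqrt(e1[i] * e2[j]), P, w, acc);
      }
      if (i_is_h && ac2[j]) hb_pair(pi, x1 + 3 * hb1[i], pj, P, w, acc);
      if (j_is_h && ac1[i]) hb_pair(pj, x2 + 3 * hb2[j], pi, P, w, acc);
    }
  }
  return acc;
}

static std::vector<char> excl_mask(const IntegerMatrix& excl, int n1, int n2) {
  std::vector<char> mask;
  if (excl.nrow() == 0) return mask;
  mask.assign((size_t)n1 * n2, 0);
  for (int k = 0; k < excl.nrow(); ++k) {
    int i = excl(k, 0), j = excl(k, 1);
    if (i >= 0 && i < n1 && j >= 0 && j < n2) mask[(size_t)i * n2 + j] = 1;
  }
  return mask;
}

// [[Rcpp::export]]
NumericVector cpp_score_sets(NumericMatrix xyz1, NumericVector rad1,
                             NumericVector eps1, IntegerVector hb1,
                             IntegerVector acc1, NumericMatrix xyz2,
                             NumericVector rad2, NumericVector eps2,
                             IntegerVector hb2, IntegerVector acc2,
                             NumericVector wscale2, IntegerMatrix excl,
                             NumericVector par) {
  EnergyParams P = unpack_params(par);
  int n1 = xyz1.nrow(), n2 = xyz2.nrow();
  // row-major copies
  std::vector<double> x1(3 * n1), x2(3 * n2);
  for (int i = 0; i < n1; ++i)
    for (int k = 0; k < 3; ++k) x1[3 * i + k] = xyz1(i, k);
  for (int j = 0; j < n2; ++j)
    for (int k = 0; k < 3; ++k) x2[3 * j + k] = xyz2(j, k);
  std::vector<char> mask = excl_mask(excl, n1, n2);
  const double* wptr = (n2 > 0 && wscale2.size() == n2) ? &wscale2[0] : nullptr;
  Acc3 acc = score_sets_core(x1.data(), n1, dptr(rad1), dptr(eps1), iptr(hb1),
                             iptr(acc1), x2.data(), n2, dptr(rad2), dptr(eps2),
                             iptr(hb2), iptr(acc2), wptr, mask, P);
  return NumericVector::create(_["attr"] = acc.attr, _["rep"] = acc.rep,
                               _["hb"] = acc.hb);
}

// pairs within one set (j > i); Lennard-Jones only
// [[Rcpp::export]]
NumericVector cpp_score_self(NumericMatrix xyz, NumericVector rad,
                             NumericVector eps, IntegerVector hb,
                             IntegerMatrix excl, NumericVector par) {
  EnergyParams P = unpack_params(par);
  int n = xyz.nrow();
  std::vector<char> mask = excl_mask(excl, n, n);
  Acc3 acc;
  for (int i = 0; i < n; ++i) {
    if (hb[i] >= 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (hb[j] >= 0) continue;
      if (!mask.empty() && (mask[(size_t)i * n + j] || mask[(size_t)j * n + i]))
        continue;
      double d = std::sqrt(
          std::pow(xyz(i, 0) - xyz(j, 0), 2) + std::pow(xyz(i, 1) - xyz(j, 1), 2) +
          std::pow(xyz(i, 2) - xyz(j, 2), 2));
      lj_pair(d, rad[i] + rad[j], std::sqrt(eps[i] * eps[j]), P, 1.0, acc);
    }
  }
  return NumericVector::create(_["attr"] = acc.attr, _["rep"] = acc.rep,
                               _["hb"] = acc.hb);
}

// Score k stacked candidate side chains (m atoms each) against a fixed
// environment, plus candidate-internal Lennard-Jones. Returns k x 3
// (attr, rep, hb); environment pair terms are scaled per environment atom
// (used for ligand up-weighting).
// [[Rcpp::export]]
NumericMatrix cpp_score_rotamers(NumericMatrix cand_xyz, int k, int m,
                                 NumericVector rad1, NumericVector eps1,
                                 IntegerVector hb1, IntegerVector acc1,
                                 NumericMatrix env_xyz, NumericVector rad2,
                                 NumericVector eps2, IntegerVector hb2,
                                 IntegerVector acc2, NumericVector wscale2,
                                 IntegerMatrix excl_env, IntegerMatrix excl_self,
                                 NumericVector par) {
  EnergyParams P = unpack_params(par);
  int n2 = env_xyz.nrow();
  std::vector<double> x2(3 * n2);
  for (int j = 0; j < n2; ++j)
    for (int kk = 0; kk < 3; ++kk) x2[3 * j + kk] = env_xyz(j, kk);
  std::vector<char> env_mask = excl_mask(excl_env, m, n2);
  std::vector<char> self_mask = excl_mask(excl_self, m, m);
  const double* wptr = (n2 > 0 && wscale2.size() == n2) ? &wscale2[0] : nullptr;
  NumericMatrix out(k, 3);
  std::vector<double> x1(3 * m);
  for (int r = 0; r < k; ++r) {
    for (int i = 0; i < m; ++i)
      for (int kk = 0; kk < 3; ++kk) x1[3 * i + kk] = cand_xyz(r * m + i, kk);
    Acc3 acc = score_sets_core(x1.data(), m, dptr(rad1), dptr(eps1), iptr(hb1),
                               iptr(acc1), x2.data(), n2, dptr(rad2), dptr(eps2),
                               iptr(hb2), iptr(acc2), wptr, env_mask, P);
    // candidate-internal LJ
    for (int i = 0; i < m; ++i) {
      if (hb1[i] >= 0) continue;
      for (int j = i + 1; j < m; ++j) {
        if (hb1[j] >= 0) continue;
        if (!self_mask.empty() &&
            (self_mask[(size_t)i * m + j] || self_mask[(size_t)j * m + i]))
          continue;
        double d = dist3(&x1[3 * i], &x1[3 * j]);
        lj_pair(d, rad1[i] + rad1[j], std::sqrt(eps1[i] * eps1[j]), P, 1.0, acc);
      }
    }
    out(r, 0) = acc.attr;
    out(r, 1) = acc.rep;
    out(r, 2) = acc.hb;
  }
  return out;
}

// NeRF placement of one atom from three reference positions
static inline void nerf_place(const double* a, const double* b, const double* c,
                              double bond, double angle_deg, double dih_deg,
                              double* out) {
  const double ang = angle_deg * M_PI / 180.0;
  const double tor = dih_deg * M_PI / 180.0;
  double bc[3], ab[3], n[3], mdir[3];
  double nbc = dist3(b, c);
  for (int kk = 0; kk < 3; ++kk) bc[kk] = (c[kk] - b[kk]) / nbc;
  for (int kk = 0; kk < 3; ++kk) ab[kk] = b[kk] - a[kk];
  n[0] = ab[1] * bc[2] - ab[2] * bc[1];
  n[1] = ab[2] * bc[0] - ab[0] * bc[2];
  n[2] = ab[0] * bc[1] - ab[1] * bc[0];
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  for (int kk = 0; kk < 3; ++kk) n[kk] /= nn;
  mdir[0] = n[1] * bc[2] - n[2] * bc[1];
  mdir[1] = n[2] * bc[0] - n[0] * bc[2];
  mdir[2] = n[0] * bc[1] - n[1] * bc[0];
  double d0 = -bond * std::cos(ang);
  double d1 = bond * std::sin(ang) * std::cos(tor);
  double d2 = -bond * std::sin(ang) * std::sin(tor);
  for (int kk = 0; kk < 3; ++kk)
    out[kk] = c[kk] + d0 * bc[kk] + d1 * mdir[kk] + d2 * n[kk];
}

// Build k conformations of an m-atom chain from internal coordinates.
// Reference indices address a combined array: anchors first (na rows),
// then built atoms in order. chi_idx is 1-based into the columns of `chis`
// (0 = fixed dihedral); the realized dihedral is chis(r, chi_idx-1) + dih.
// [[Rcpp::export]]
NumericMatrix cpp_build_chains(NumericMatrix anchors, IntegerVector parent,
                               IntegerVector gp, IntegerVector ggp,
                               NumericVector bond, NumericVector angle,
                               NumericVector dih, IntegerVector chi_idx,
                               NumericMatrix chis) {
  int na = anchors.nrow(), m = parent.size(), k = chis.nrow();
  if (k == 0) k = 1;
  NumericMatrix out(k * m, 3);
  std::vector<double> pos(3 * (na + m));
  for (int i = 0; i < na; ++i)
    for (int kk = 0; kk < 3; ++kk) pos[3 * i + kk] = anchors(i, kk);
  for (int r = 0; r < k; ++r) {
    for (int t = 0; t < m; ++t) {
      double dval = dih[t];
      if (chi_idx[t] > 0 && chis.ncol() >= chi_idx[t])
        dval += chis(r, chi_idx[t] - 1);
      nerf_place(&pos[3 * ggp[t]], &pos[3 * gp[t]], &pos[3 * parent[t]],
                 bond[t], angle[t], dval, &pos[3 * (na + t)]);
      for (int kk = 0; kk < 3; ++kk) out(r * m + t, kk) = pos[3 * (na + t) + kk];
    }
  }
  return out;
}
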