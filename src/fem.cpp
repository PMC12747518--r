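// Explicit quasi-static FEM core for the differential-growth simulator:
// linear (P1) tetrahedra, one-point quadrature, compressible neo-Hookean
// energy on the elastic part A = F G^{-1}, vertex-triangle self-contact
// penalty on the boundary surface, damped explicit relaxation with a
// window-monotonicity safeguard.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline double det3(const double m[9]) {
  return m[0] * (m[4] * m[8] - m[5] * m[7]) -
         m[1] * (m[3] * m[8] - m[5] * m[6]) +
         m[2] * (m[3] * m[7] - m[4] * m[6]);
}

static inline void inv3(const double m[9], double inv[9], double det) {
  double id = 1.0 / det;
  inv[0] = (m[4] * m[8] - m[5] * m[7]) * id;
  inv[1] = (m[2] * m[7] - m[1] * m[8]) * id;
  inv[2] = (m[1] * m[5] - m[2] * m[4]) * id;
  inv[3] = (m[5] * m[6] - m[3] * m[8]) * id;
  inv[4] = (m[0] * m[8] - m[2] * m[6]) * id;
  inv[5] = (m[2] * m[3] - m[0] * m[5]) * id;
  inv[6] = (m[3] * m[7] - m[4] * m[6]) * id;
  inv[7] = (m[1] * m[6] - m[0] * m[7]) * id;
  inv[8] = (m[0] * m[4] - m[1] * m[3]) * id;
}

static inline void matmul3(const double a[9], const double b[9],
                           double c[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      c[3 * i + j] = a[3 * i] * b[j] + a[3 * i + 1] * b[3 + j] +
                     a[3 * i + 2] * b[6 + j];
}

// [[Rcpp::export]]
List tet_shape_cpp(NumericMatrix verts, IntegerMatrix tets) {
  int nt = tets.nrow();
  NumericMatrix DmInv(nt, 9);
  NumericVector vol(nt);
  for (int t = 0; t < nt; ++t) {
    int i0 = tets(t, 0) - 1, i1 = tets(t, 1) - 1, i2 = tets(t, 2) - 1,
        i3 = tets(t, 3) - 1;
    double Dm[9];
    for (int k = 0; k < 3; ++k) {
      Dm[3 * k + 0] = verts(i1, k) - verts(i0, k);
      Dm[3 * k + 1] = verts(i2, k) - verts(i0, k);
      Dm[3 * k + 2] = verts(i3, k) - verts(i0, k);
    }
    double d = det3(Dm);
    if (d <= 0)
      stop("non-positive tet volume at tet %d", t + 1);
    double inv[9];
    inv3(Dm, inv, d);
    for (int k = 0; k < 9; ++k) DmInv(t, k) = inv[k];
    vol[t] = d / 6.0;
  }
  return List::create(_["DmInv"] = DmInv, _["vol"] = vol);
}

// Elastic energy and forces. Returns total energy; accumulates forces
// (negative gradient) into `force`; writes min det F into *min_detF.
// Energy density W = mu/2 (J^{-2/3} tr(A'A) - 3) + K/2 (J-1)^2 with
// A = F Ginv, weighted per tet by `weight` (reference volume times
// det G). If an element has det F <= 0, returns +Inf and records the
// offending tet in *bad_tet (1-based).
struct TetData {
  int nt = 0;
  std::vector<int> tet;        // 4 * nt
  std::vector<double> BmT;     // 9 * nt, tet-major
  std::vector<double> GiT;     // 9 * nt, tet-major
  std::vector<double> wmu, wk, w;  // nt
};

static TetData pack_tets(const IntegerMatrix& tets,
                         const NumericMatrix& DmInv,
                         const NumericVector& weight,
                         const NumericVector& mu,
                         const NumericVector& kbulk,
                         const NumericMatrix& Ginv) {
  TetData td;
  td.nt = tets.nrow();
  td.tet.resize(4 * td.nt);
  td.BmT.resize(9 * td.nt);
  td.GiT.resize(9 * td.nt);
  td.wmu.resize(td.nt);
  td.wk.resize(td.nt);
  td.w.resize(td.nt);
  for (int t = 0; t < td.nt; ++t) {
    for (int k = 0; k < 4; ++k) td.tet[4 * t + k] = tets(t, k) - 1;
    for (int k = 0; k < 9; ++k) {
      td.BmT[9 * t + k] = DmInv(t, k);
      td.GiT[9 * t + k] = Ginv(t, k);
    }
    td.w[t] = weight[t];
    td.wmu[t] = mu[t];
    td.wk[t] = kbulk[t];
  }
  return td;
}

// Elastic energy and forces on interleaved coordinates x (3 * nv).
// Returns +Inf (recording *bad_tet) if an element inverts.
static double elastic_core(const std::vector<double>& x, const TetData& td,
                           std::vector<double>& force, double* min_detF,
                           int* bad_tet) {
  double W = 0.0;
  *min_detF = R_PosInf;
  *bad_tet = 0;
  for (int t = 0; t < td.nt; ++t) {
    const int* tv = &td.tet[4 * t];
    const double* x0 = &x[3 * tv[0]];
    const double* x1 = &x[3 * tv[1]];
    const double* x2 = &x[3 * tv[2]];
    const double* x3 = &x[3 * tv[3]];
    double Ds[9];
    for (int k = 0; k < 3; ++k) {
      Ds[3 * k + 0] = x1[k] - x0[k];
      Ds[3 * k + 1] = x2[k] - x0[k];
      Ds[3 * k + 2] = x3[k] - x0[k];
    }
    const double* Bm = &td.BmT[9 * t];
    const double* Gi = &td.GiT[9 * t];
    double F[9], A[9];
    matmul3(Ds, Bm, F);
    double dF = det3(F);
    if (dF < *min_detF) *min_detF = dF;
    if (dF <= 0.0) { *bad_tet = t + 1; return R_PosInf; }
    matmul3(F, Gi, A);
    double J = det3(A);
    if (J <= 0.0) { *bad_tet = t + 1; return R_PosInf; }
    double I1 = 0.0;
    for (int k = 0; k < 9; ++k) I1 += A[k] * A[k];
    double Jm23 = 1.0 / std::cbrt(J * J);
    double w = td.w[t], mu_t = td.wmu[t], k_t = td.wk[t];
    W += w * (0.5 * mu_t * (Jm23 * I1 - 3.0) +
              0.5 * k_t * (J - 1.0) * (J - 1.0));
    double Ainv[9];
    inv3(A, Ainv, J);
    double PA[9];
    double c1 = mu_t * Jm23;
    double c2 = -mu_t * Jm23 * I1 / 3.0 + k_t * (J - 1.0) * J;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        PA[3 * i + j] = c1 * A[3 * i + j] + c2 * Ainv[3 * j + i];
    double P[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[3 * i + j] = PA[3 * i] * Gi[3 * j] + PA[3 * i + 1] * Gi[3 * j + 1] +
                       PA[3 * i + 2] * Gi[3 * j + 2];
    double H[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        H[3 * i + j] = -w * (P[3 * i] * Bm[3 * j] + P[3 * i + 1] * Bm[3 * j + 1] +
                             P[3 * i + 2] * Bm[3 * j + 2]);
    double* f0 = &force[3 * tv[0]];
    double* f1 = &force[3 * tv[1]];
    double* f2 = &force[3 * tv[2]];
    double* f3 = &force[3 * tv[3]];
    for (int k = 0; k < 3; ++k) {
      f1[k] += H[3 * k + 0];
      f2[k] += H[3 * k + 1];
      f3[k] += H[3 * k + 2];
      f0[k] -= H[3 * k + 0] + H[3 * k + 1] + H[3 * k + 2];
    }
  }
  return W;
}

// Closest point on triangle (a, b, c) to p (Ericson); returns squared
// distance, closest point in cp, barycentrics in w.
static double point_triangle(const double p[3], const double a[3],
                             const double b[3], const double c[3],
                             double cp[3], double w[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    for (int k = 0; k < 3; ++k) cp[k] = a[k];
    w[0] = 1; w[1] = 0; w[2] = 0;
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) cp[k] = b[k];
      w[0] = 0; w[1] = 1; w[2] = 0;
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) cp[k] = a[k] + v * ab[k];
        w[0] = 1 - v; w[1] = v; w[2] = 0;
      } else {
        double cpv[3];
        for (int k = 0; k < 3; ++k) cpv[k] = p[k] - c[k];
        double d5 = ab[0] * cpv[0] + ab[1] * cpv[1] + ab[2] * cpv[2];
        double d6 = ac[0] * cpv[0] + ac[1] * cpv[1] + ac[2] * cpv[2];
        if (d6 >= 0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) cp[k] = c[k];
          w[0] = 0; w[1] = 0; w[2] = 1;
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double v = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) cp[k] = a[k] + v * ac[k];
            w[0] = 1 - v; w[1] = 0; w[2] = v;
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double v = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k)
                cp[k] = b[k] + v * (c[k] - b[k]);
              w[0] = 0; w[1] = 1 - v; w[2] = v;
            } else {
              double den = 1.0 / (va + vb + vc);
              double v = vb * den, u = vc * den;
              for (int k = 0; k < 3; ++k)
                cp[k] = a[k] + ab[k] * u + ac[k] * v;
              w[0] = 1 - u - v; w[1] = u; w[2] = v;
            }
          }
        }
      }
    }
  }
  double d2sum = 0;
  for (int k = 0; k < 3; ++k) {
    double dd = p[k] - cp[k];
    d2sum += dd * dd;
  }
  return d2sum;
}

struct ContactData {
  std::vector<int> bverts;           // 0-based volume vertex ids
  std::vector<int> btris;            // 3 * nb, 0-based volume vertex ids
  std::vector<int> excl_ptr;         // CSR over bverts
  std::vector<int> excl_idx;         // excluded volume vertex ids
  double range = 0.0, stiffness = 0.0;
  std::vector<std::pair<int, int> > pairs;  // (bvert slot, tri id)
};

static int64_t cell_key(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix) * 73856093) ^
         (static_cast<int64_t>(iy) * 19349663) ^
         (static_cast<int64_t>(iz) * 83492791);
}

// Rebuild candidate vertex-triangle pairs within `margin` using a
// uniform hash grid over triangle centroids.
static void rebuild_pairs(const std::vector<double>& x, ContactData& cd,
                          double margin) {
  cd.pairs.clear();
  int nb = static_cast<int>(cd.btris.size() / 3);
  if (nb == 0 || cd.stiffness <= 0.0) return;
  // max triangle "radius" from centroid
  double maxrad = 0.0;
  std::vector<double> cent(3 * nb);
  for (int t = 0; t < nb; ++t) {
    int a = cd.btris[3 * t], b = cd.btris[3 * t + 1], c = cd.btris[3 * t + 2];
    for (int k = 0; k < 3; ++k)
      cent[3 * t + k] = (x[3 * a + k] + x[3 * b + k] + x[3 * c + k]) / 3.0;
    for (int vi : {a, b, c}) {
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = x[3 * vi + k] - cent[3 * t + k];
        r2 += d * d;
      }
      if (r2 > maxrad) maxrad = r2;
    }
  }
  maxrad = std::sqrt(maxrad);
  double cs = margin + maxrad;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(nb * 2);
  for (int t = 0; t < nb; ++t) {
    int ix = static_cast<int>(std::floor(cent[3 * t] / cs));
    int iy = static_cast<int>(std::floor(cent[3 * t + 1] / cs));
    int iz = static_cast<int>(std::floor(cent[3 * t + 2] / cs));
    grid[cell_key(ix, iy, iz)].push_back(t);
  }
  int nbv = static_cast<int>(cd.bverts.size());
  double m2 = (margin + maxrad) * (margin + maxrad);
  for (int s = 0; s < nbv; ++s) {
    int v = cd.bverts[s];
    double p[3] = {x[3 * v], x[3 * v + 1], x[3 * v + 2]};
    int ix = static_cast<int>(std::floor(p[0] / cs));
    int iy = static_cast<int>(std::floor(p[1] / cs));
    int iz = static_cast<int>(std::floor(p[2] / cs));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int t : it->second) {
            // centroid prefilter
            double r2 = 0;
            for (int k = 0; k < 3; ++k) {
              double d = p[k] - cent[3 * t + k];
              r2 += d * d;
            }
            if (r2 > m2) continue;
            // exclusion: triangle touching the vertex's 1-ring
            bool excl = false;
            for (int e = cd.excl_ptr[s]; e < cd.excl_ptr[s + 1]; ++e) {
              int ev = cd.excl_idx[e];
              if (ev == cd.btris[3 * t] || ev == cd.btris[3 * t + 1] ||
                  ev == cd.btris[3 * t + 2]) {
                excl = true;
                break;
              }
            }
            if (!excl) cd.pairs.push_back(std::make_pair(s, t));
          }
        }
  }
}

// Contact penalty energy + forces over the current candidate pairs.
static double contact_core(const std::vector<double>& x,
                           const ContactData& cd,
                           std::vector<double>& force) {
  double E = 0.0;
  double range = cd.range, k_ = cd.stiffness;
  if (k_ <= 0.0) return 0.0;
  for (size_t q = 0; q < cd.pairs.size(); ++q) {
    int v = cd.bverts[cd.pairs[q].first];
    int t = cd.pairs[q].second;
    int a = cd.btris[3 * t], b = cd.btris[3 * t + 1], c = cd.btris[3 * t + 2];
    const double* p = &x[3 * v];
    const double* pa = &x[3 * a];
    const double* pb = &x[3 * b];
    const double* pc = &x[3 * c];
    double cp[3], w[3];
    double d2 = point_triangle(p, pa, pb, pc, cp, w);
    double r = std::sqrt(d2);
    if (r >= range || r < 1e-12) continue;
    double pen = range - r;
    E += 0.5 * k_ * pen * pen;
    double coef = k_ * pen / r;
    for (int k = 0; k < 3; ++k) {
      double dir = (p[k] - cp[k]) * coef;
      force[3 * v + k] += dir;
      force[3 * a + k] -= w[0] * dir;
      force[3 * b + k] -= w[1] * dir;
      force[3 * c + k] -= w[2] * dir;
    }
  }
  return E;
}

static ContactData contact_from_list(List contact) {
  ContactData cd;
  if (contact.size() == 0) return cd;
  IntegerVector bv = contact["bverts"];
  IntegerMatrix bt = contact["btris"];
  IntegerVector ep = contact["excl_ptr"];
  IntegerVector ei = contact["excl_idx"];
  cd.range = as<double>(contact["range"]);
  cd.stiffness = as<double>(contact["stiffness"]);
  cd.bverts.assign(bv.begin(), bv.end());
  for (auto& v : cd.bverts) --v;
  cd.btris.resize(3 * bt.nrow());
  for (int t = 0; t < bt.nrow(); ++t)
    for (int k = 0; k < 3; ++k) cd.btris[3 * t + k] = bt(t, k) - 1;
  cd.excl_ptr.assign(ep.begin(), ep.end());
  cd.excl_idx.assign(ei.begin(), ei.end());
  for (auto& v : cd.excl_idx) --v;
  return cd;
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix x, IntegerMatrix tets,
                       NumericMatrix DmInv, NumericVector weight,
                       NumericVector mu, NumericVector kbulk,
                       NumericMatrix Ginv, List contact) {
  int nv = x.nrow();
  std::vector<double> xi(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) xi[3 * i + k] = x(i, k);
  TetData td = pack_tets(tets, DmInv, weight, mu, kbulk, Ginv);
  std::vector<double> force(3 * nv, 0.0);
  double min_detF;
  int bad_tet;
  double W = elastic_core(xi, td, force, &min_detF, &bad_tet);
  double Wc = 0.0;
  if (R_finite(W) && contact.size() > 0) {
    ContactData cd = contact_from_list(contact);
    rebuild_pairs(xi, cd, cd.range);
    Wc = contact_core(xi, cd, force);
  }
  NumericMatrix f(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) f(i, k) = force[3 * i + k];
  return List::create(_["W_elastic"] = W, _["W_contact"] = Wc,
                      _["W_total"] = W + Wc, _["forces"] = f,
                      _["min_detF"] = min_detF, _["bad_tet"] = bad_tet);
}

// Damped explicit quasi-static relaxation.
// [[Rcpp::export]]
List relax_cpp(NumericMatrix x0, IntegerMatrix tets, NumericMatrix DmInv,
               NumericVector weight, NumericVector mu, NumericVector kbulk,
               NumericMatrix Ginv, NumericVector mass, LogicalVector fixed,
               List contact, double dt, double damping, double force_tol,
               int max_iters, int rebuild_every, int window,
               double window_rtol, double energy_rtol) {
  int nv = x0.nrow();
  std::vector<double> x(3 * nv), v(3 * nv, 0.0), force(3 * nv);
  std::vector<double> im(nv);
  std::vector<char> fx(nv);
  for (int i = 0; i < nv; ++i) {
    for (int k = 0; k < 3; ++k) x[3 * i + k] = x0(i, k);
    im[i] = 1.0 / mass[i];
    fx[i] = fixed[i] ? 1 : 0;
  }
  TetData td = pack_tets(tets, DmInv, weight, mu, kbulk, Ginv);
  ContactData cd = contact_from_list(contact);
  bool has_contact = cd.stiffness > 0.0 && !cd.btris.empty();
  std::vector<double> trace;
  trace.reserve(max_iters + 1);
  std::vector<double> x_best = x;
  double W_best = R_PosInf;
  bool converged = false, diverged = false;
  int iter = 0;
  double dt_min = dt * 1e-6;
  double margin = cd.range * 2.0;
  int since_rebuild = rebuild_every;  // force rebuild on first pass

  while (iter < max_iters) {
    if (has_contact && since_rebuild >= rebuild_every) {
      rebuild_pairs(x, cd, margin);
      since_rebuild = 0;
    }
    std::fill(force.begin(), force.end(), 0.0);
    double min_detF;
    int bad_tet;
    double W = elastic_core(x, td, force, &min_detF, &bad_tet);
    if (has_contact && R_finite(W)) W += contact_core(x, cd, force);

    bool reject = false;
    if (!R_finite(W) || min_detF <= 0.0) {
      reject = true;  // inverted element
    } else {
      int nback = static_cast<int>(trace.size());
      if (nback >= window) {
        double Wref = trace[nback - window];
        if (W > Wref + window_rtol * std::abs(Wref) + 1e-14)
          reject = true;  // window monotonicity safeguard
      }
    }
    if (reject) {
      // revert to the best state seen, cut the step, restart velocities
      if (R_finite(W_best)) x = x_best;
      std::fill(v.begin(), v.end(), 0.0);
      dt *= 0.5;
      since_rebuild = rebuild_every;  // geometry jumped: rebuild
      if (dt < dt_min) {
        diverged = true;
        break;
      }
      continue;  // recompute at the restored state (iter not consumed)
    }

    trace.push_back(W);
    if (W < W_best) {
      W_best = W;
      x_best = x;
    }
    double maxF = 0.0;
    for (int i = 0; i < nv; ++i) {
      if (fx[i]) continue;
      double f2 = force[3 * i] * force[3 * i] +
                  force[3 * i + 1] * force[3 * i + 1] +
                  force[3 * i + 2] * force[3 * i + 2];
      if (f2 > maxF) maxF = f2;
    }
    maxF = std::sqrt(maxF);
    bool plateau = false;
    {
      int nback = static_cast<int>(trace.size());
      if (energy_rtol > 0 && nback > window) {
        double Wref = trace[nback - 1 - window];
        plateau = std::abs(Wref - W) <
                  energy_rtol * std::abs(W) + 1e-16;
      }
    }
    if (maxF < force_tol || plateau) {
      converged = true;
      ++iter;
      break;
    }
    double damp = 1.0 - damping;
    for (int i = 0; i < nv; ++i) {
      if (fx[i]) continue;
      double s = dt * im[i];
      for (int k = 0; k < 3; ++k) {
        v[3 * i + k] = (v[3 * i + k] + s * force[3 * i + k]) * damp;
        x[3 * i + k] += dt * v[3 * i + k];
      }
    }
    ++iter;
    ++since_rebuild;
  }
  NumericMatrix xo(nv, 3), xb(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      xo(i, k) = x[3 * i + k];
      xb(i, k) = x_best[3 * i + k];
    }
  return List::create(_["x"] = xo, _["x_best"] = xb,
                      _["energy_trace"] = NumericVector(trace.begin(),
                                                        trace.end()),
                      _["iters"] = iter, _["converged"] = converged,
                      _["diverged"] = diverged, _["dt_final"] = dt,
                      _["W_final"] = W_best);
}

// Distance from query points to a triangle soup (exact point-triangle),
// with the closest point returned; brute force over a centroid hash grid
// with ring expansion.
// [[Rcpp::export]]
List surface_distance_cpp(NumericMatrix queries, NumericMatrix tv,
                          IntegerMatrix tf) {
  int nq = queries.nrow(), nt = tf.nrow();
  std::vector<double> cent(3 * nt);
  double maxrad2 = 0.0;
  for (int t = 0; t < nt; ++t) {
    int a = tf(t, 0) - 1, b = tf(t, 1) - 1, c = tf(t, 2) - 1;
    for (int k = 0; k < 3; ++k)
      cent[3 * t + k] = (tv(a, k) + tv(b, k) + tv(c, k)) / 3.0;
    for (int vi : {a, b, c}) {
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = tv(vi, k) - cent[3 * t + k];
        r2 += d * d;
      }
      if (r2 > maxrad2) maxrad2 = r2;
    }
  }
  double maxrad = std::sqrt(maxrad2);
  double cs = 2.0 * maxrad + 1e-12;
  std::unordered_map<int64_t, std::vector<int> > grid;
  for (int t = 0; t < nt; ++t) {
    int ix = static_cast<int>(std::floor(cent[3 * t] / cs));
    int iy = static_cast<int>(std::floor(cent[3 * t + 1] / cs));
    int iz = static_cast<int>(std::floor(cent[3 * t + 2] / cs));
    grid[cell_key(ix, iy, iz)].push_back(t);
  }
  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector tri_id(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    int ix = static_cast<int>(std::floor(p[0] / cs));
    int iy = static_cast<int>(std::floor(p[1] / cs));
    int iz = static_cast<int>(std::floor(p[2] / cs));
    double best = R_PosInf;
    double bcp[3] = {0, 0, 0};
    int btri = -1;
    for (int ring = 0;; ++ring) {
      bool any_cell = false;
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = -ring; dz <= ring; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy),
                                                std::abs(dz))) != ring)
              continue;  // shell only
            auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            any_cell = true;
            for (int t : it->second) {
              double cp[3], w[3];
              int a = tf(t, 0) - 1, b = tf(t, 1) - 1, c = tf(t, 2) - 1;
              double pa[3] = {tv(a, 0), tv(a, 1), tv(a, 2)};
              double pb[3] = {tv(b, 0), tv(b, 1), tv(b, 2)};
              double pc[3] = {tv(c, 0), tv(c, 1), tv(c, 2)};
              double d2 = point_triangle(p, pa, pb, pc, cp, w);
              if (d2 < best) {
                best = d2;
                bcp[0] = cp[0]; bcp[1] = cp[1]; bcp[2] = cp[2];
                btri = t;
              }
            }
          }
      // Stop once the next ring cannot contain anything closer: cells at
      // ring r cover distance >= (r-1)*cs - maxrad from p.
      if (btri >= 0) {
        double safe = (ring)*cs - maxrad;
        if (safe > 0 && safe * safe >= best) break;
      }
      if (ring > 3 && !any_cell && btri >= 0) break;
      if (ring > 1000) break;
    }
    dist[q] = std::sqrt(best);
    for (int k = 0; k < 3; ++k) closest(q, k) = bcp[k];
    tri_id[q] = btri + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["triangle"] = tri_id);
}
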