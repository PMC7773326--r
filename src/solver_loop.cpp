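// MCMC solver inner loop. Semantics mirror the R-level cost terms in
// solver.R exactly (hinge losses on surface-gap distances, scaled-radial
// boundary distance); the trace is validated against evaluate_cost() in
// the tests. Uses R's RNG stream, so runs are reproducible given the
// seed set at the R level.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Nucleus {
  double a, b, c, min_semi;
  // normalised radial coordinate
  inline double u(double x, double y, double z) const {
    double ux = x / a, uy = y / b, uz = z / c;
    return std::sqrt(ux * ux + uy * uy + uz * uz);
  }
  inline bool contains(double x, double y, double z) const {
    return u(x, y, z) <= 1.0;
  }
};

inline double unif() { return unif_rand(); }

// weighted boundary + LAD cost of one bead position
inline double bl_cost(const Nucleus &nuc, double x, double y, double z,
                      bool flagged, double shell, double w_boundary,
                      double w_lad) {
  double u = nuc.u(x, y, z);
  double r = std::sqrt(x * x + y * y + z * z);
  double v = 0.0;
  if (u > 1.0) v += w_boundary * r * (1.0 - 1.0 / u);
  if (flagged && u < shell) {
    double rb = (u > 0.0) ? r / u : nuc.min_semi;
    v += w_lad * (shell - u) * rb;
  }
  return v;
}

inline void random_axis(double &kx, double &ky, double &kz) {
  kx = norm_rand(); ky = norm_rand(); kz = norm_rand();
  double n = std::sqrt(kx * kx + ky * ky + kz * kz);
  if (n < 1e-300) { kx = 1.0; ky = 0.0; kz = 0.0; return; }
  kx /= n; ky /= n; kz /= n;
}

// Rodrigues rotation of (x,y,z) about unit axis k through origin o
inline void rotate_point(double &x, double &y, double &z,
                         double ox, double oy, double oz,
                         double kx, double ky, double kz,
                         double cosa, double sina) {
  double px = x - ox, py = y - oy, pz = z - oz;
  double crx = ky * pz - kz * py;
  double cry = kz * px - kx * pz;
  double crz = kx * py - ky * px;
  double kd = (kx * px + ky * py + kz * pz) * (1.0 - cosa);
  x = ox + px * cosa + crx * sina + kd * kx;
  y = oy + py * cosa + cry * sina + kd * ky;
  z = oz + pz * cosa + crz * sina + kd * kz;
}

} // namespace

// [[Rcpp::export(name = ".solve_loop_cpp")]]
List solve_loop_cpp(NumericMatrix coords_in, NumericVector radii,
                    LogicalVector periphery, List chains,
                    IntegerMatrix cidx, List by_bead,
                    NumericVector semi, double shell,
                    NumericVector weights,       // contact boundary lad overlap
                    NumericVector move_cumw,     // cumulative move-type probs
                    int scheme,                  // 0 greedy 1 metropolis 2 anneal
                    double temperature, double cooling,
                    double target, double max_attempts, double total0) {
  const int n = coords_in.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = coords_in(i, 0); Y[i] = coords_in(i, 1); Z[i] = coords_in(i, 2);
  }
  Nucleus nuc;
  nuc.a = semi[0]; nuc.b = semi[1]; nuc.c = semi[2];
  nuc.min_semi = std::min(nuc.a, std::min(nuc.b, nuc.c));
  const double w_contact = weights[0], w_boundary = weights[1],
               w_lad = weights[2], w_overlap = weights[3];

  const int n_chain = chains.size();
  std::vector< std::vector<int> > chain(n_chain);
  for (int c = 0; c < n_chain; ++c) {
    IntegerVector v = chains[c];
    chain[c].assign(v.begin(), v.end());
    for (size_t k = 0; k < chain[c].size(); ++k) chain[c][k] -= 1; // 0-based
  }
  const int n_con = cidx.nrow();
  std::vector<int> ca(n_con), cb(n_con);
  std::vector<double> touch(n_con), cdist(n_con);
  for (int k = 0; k < n_con; ++k) {
    ca[k] = cidx(k, 0) - 1; cb[k] = cidx(k, 1) - 1;
    touch[k] = radii[ca[k]] + radii[cb[k]];
    double dx = X[ca[k]] - X[cb[k]], dy = Y[ca[k]] - Y[cb[k]],
           dz = Z[ca[k]] - Z[cb[k]];
    cdist[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  std::vector< std::vector<int> > bead_con(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = by_bead[i];
    bead_con[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < bead_con[i].size(); ++k) bead_con[i][k] -= 1;
  }

  std::vector<double> bl(n);
  for (int i = 0; i < n; ++i) {
    bl[i] = bl_cost(nuc, X[i], Y[i], Z[i], periphery[i], shell,
                    w_boundary, w_lad);
  }

  const R_xlen_t tgt = (R_xlen_t)target;
  NumericVector trace(tgt);
  NumericVector attempted(5), accepted_by(5);
  double total = total0, temp = temperature;
  R_xlen_t n_acc = 0, attempts = 0;

  std::vector<int> rows; rows.reserve(n);
  std::vector<double> NX(n), NY(n), NZ(n);       // proposed coords (by row slot)
  std::vector<char> moved(n, 0);
  std::vector<int> con_stamp(n_con, 0);
  int stamp = 0;
  std::vector<int> con_list; con_list.reserve(64);

  while (n_acc < tgt && attempts < (R_xlen_t)max_attempts) {
    ++attempts;
    // ---- propose -------------------------------------------------------
    int move_type = -1;
    int tries = 0;
    rows.clear();
    for (; tries < 100; ++tries) {
      int ci = (int)(unif() * n_chain); if (ci >= n_chain) ci = n_chain - 1;
      const std::vector<int> &idx = chain[ci];
      const int L = (int)idx.size();
      double uu = unif();
      int type = 0;
      while (type < 4 && uu >= move_cumw[type]) ++type;
      if (type == 0 && L < 3) continue;                    // crankshaft
      if ((type == 1 || type == 2) && L < 2) continue;     // arm moves
      if (type == 0) {               // crankshaft
        int i = (int)(unif() * (L - 2)); if (i > L - 3) i = L - 3;
        int j = i + 2 + (int)(unif() * (L - i - 2));
        if (j > L - 1) j = L - 1;
        double ox = X[idx[i]], oy = Y[idx[i]], oz = Z[idx[i]];
        double kx = X[idx[j]] - ox, ky = Y[idx[j]] - oy, kz = Z[idx[j]] - oz;
        double nn = std::sqrt(kx * kx + ky * ky + kz * kz);
        if (nn < 1e-12) continue;
        kx /= nn; ky /= nn; kz /= nn;
        double ang = unif() * 2.0 * M_PI;
        double cosa = std::cos(ang), sina = std::sin(ang);
        for (int m = i + 1; m < j; ++m) {
          int b = idx[m];
          double x = X[b], y = Y[b], z = Z[b];
          rotate_point(x, y, z, ox, oy, oz, kx, ky, kz, cosa, sina);
          rows.push_back(b);
          NX[rows.size() - 1] = x; NY[rows.size() - 1] = y;
          NZ[rows.size() - 1] = z;
        }
      } else if (type == 1 || type == 2) {  // arm rotation / arm wiggle
        int k;
        if (L >= 3) k = 1 + (int)(unif() * (L - 2));
        else k = (int)(unif() * 2);
        if (k > L - 1) k = L - 1;
        bool towards_end = (k == 0) ? true :
          (k == L - 1) ? false : (unif() < 0.5);
        int from = towards_end ? k + 1 : k - 1;
        int stepdir = towards_end ? 1 : -1;
        int count = towards_end ? (L - 1 - k) : k;
        if (count <= 0) continue;
        if (type == 1) {
          double kx, ky, kz;
          random_axis(kx, ky, kz);
          double ang = unif() * 2.0 * M_PI;
          double cosa = std::cos(ang), sina = std::sin(ang);
          double ox = X[idx[k]], oy = Y[idx[k]], oz = Z[idx[k]];
          for (int m = 0, p = from; m < count; ++m, p += stepdir) {
            int b = idx[p];
            double x = X[b], y = Y[b], z = Z[b];
            rotate_point(x, y, z, ox, oy, oz, kx, ky, kz, cosa, sina);
            rows.push_back(b);
            NX[rows.size() - 1] = x; NY[rows.size() - 1] = y;
            NZ[rows.size() - 1] = z;
          }
        } else {
          // re-grow the arm as a touching-bead walk inside the nucleus
          double px = X[idx[k]], py = Y[idx[k]], pz = Z[idx[k]];
          double pr = radii[idx[k]];
          bool ok = true;
          for (int m = 0, p = from; m < count; ++m, p += stepdir) {
            int b = idx[p];
            double step = pr + radii[b];
            bool good = false;
            double cx = 0, cy = 0, cz = 0;
            for (int t2 = 0; t2 < 200; ++t2) {
              double dx, dy, dz;
              random_axis(dx, dy, dz);
              cx = px + step * dx; cy = py + step * dy; cz = pz + step * dz;
              if (nuc.contains(cx, cy, cz)) { good = true; break; }
            }
            if (!good) { ok = false; break; }
            rows.push_back(b);
            NX[rows.size() - 1] = cx; NY[rows.size() - 1] = cy;
            NZ[rows.size() - 1] = cz;
            px = cx; py = cy; pz = cz; pr = radii[b];
          }
          if (!ok) { rows.clear(); continue; }
        }
      } else if (type == 3) {        // translation
        double dx = unif() * 2.0 - 1.0, dy = unif() * 2.0 - 1.0,
               dz = unif() * 2.0 - 1.0;
        for (int m = 0; m < L; ++m) {
          int b = idx[m];
          rows.push_back(b);
          NX[rows.size() - 1] = X[b] + dx;
          NY[rows.size() - 1] = Y[b] + dy;
          NZ[rows.size() - 1] = Z[b] + dz;
        }
      } else {                       // rotation about the chain centroid
        double ox = 0, oy = 0, oz = 0;
        for (int m = 0; m < L; ++m) {
          ox += X[idx[m]]; oy += Y[idx[m]]; oz += Z[idx[m]];
        }
        ox /= L; oy /= L; oz /= L;
        double kx, ky, kz;
        random_axis(kx, ky, kz);
        double ang = unif() * 2.0 * M_PI;
        double cosa = std::cos(ang), sina = std::sin(ang);
        for (int m = 0; m < L; ++m) {
          int b = idx[m];
          double x = X[b], y = Y[b], z = Z[b];
          rotate_point(x, y, z, ox, oy, oz, kx, ky, kz, cosa, sina);
          rows.push_back(b);
          NX[rows.size() - 1] = x; NY[rows.size() - 1] = y;
          NZ[rows.size() - 1] = z;
        }
      }
      move_type = type;
      break;
    }
    if (move_type < 0) stop("could not propose a feasible move in 100 attempts");
    attempted[move_type] += 1;
    const int m = (int)rows.size();
    const bool within = (move_type == 2);

    // ---- delta cost ----------------------------------------------------
    for (int t = 0; t < m; ++t) moved[rows[t]] = 1;
    double delta = 0.0;
    // overlap: moved vs unmoved (old and new), plus within-block for
    // non-rigid moves
    for (int t = 0; t < m; ++t) {
      int i = rows[t];
      double ri = radii[i];
      for (int j = 0; j < n; ++j) {
        if (moved[j]) continue;
        double rr = ri + radii[j];
        double dxo = X[i] - X[j], dyo = Y[i] - Y[j], dzo = Z[i] - Z[j];
        double d2o = dxo * dxo + dyo * dyo + dzo * dzo;
        if (d2o < rr * rr) delta -= w_overlap * (rr - std::sqrt(d2o));
        double dxn = NX[t] - X[j], dyn = NY[t] - Y[j], dzn = NZ[t] - Z[j];
        double d2n = dxn * dxn + dyn * dyn + dzn * dzn;
        if (d2n < rr * rr) delta += w_overlap * (rr - std::sqrt(d2n));
      }
    }
    if (within && m > 1) {
      for (int t = 0; t < m; ++t) {
        int i = rows[t];
        for (int s = t + 1; s < m; ++s) {
          int j = rows[s];
          double rr = radii[i] + radii[j];
          double dxo = X[i] - X[j], dyo = Y[i] - Y[j], dzo = Z[i] - Z[j];
          double d2o = dxo * dxo + dyo * dyo + dzo * dzo;
          if (d2o < rr * rr) delta -= w_overlap * (rr - std::sqrt(d2o));
          double dxn = NX[t] - NX[s], dyn = NY[t] - NY[s],
                 dzn = NZ[t] - NZ[s];
          double d2n = dxn * dxn + dyn * dyn + dzn * dzn;
          if (d2n < rr * rr) delta += w_overlap * (rr - std::sqrt(d2n));
        }
      }
    }
    // boundary + LAD
    std::vector<double> new_bl(m);
    for (int t = 0; t < m; ++t) {
      int i = rows[t];
      new_bl[t] = bl_cost(nuc, NX[t], NY[t], NZ[t], periphery[i], shell,
                          w_boundary, w_lad);
      delta += new_bl[t] - bl[i];
    }
    // contact: constraints touching any moved bead
    ++stamp;
    con_list.clear();
    for (int t = 0; t < m; ++t) {
      int i = rows[t];
      for (size_t q = 0; q < bead_con[i].size(); ++q) {
        int k = bead_con[i][q];
        if (con_stamp[k] != stamp) { con_stamp[k] = stamp; con_list.push_back(k); }
      }
    }
    std::vector<double> new_cd(con_list.size());
    if (!con_list.empty()) {
      // row slot of a moved bead, else -1
      for (size_t q = 0; q < con_list.size(); ++q) {
        int k = con_list[q];
        int ia = ca[k], ib = cb[k];
        double ax, ay, az, bx, by, bz;
        ax = X[ia]; ay = Y[ia]; az = Z[ia];
        bx = X[ib]; by = Y[ib]; bz = Z[ib];
        if (moved[ia] || moved[ib]) {
          for (int t = 0; t < m; ++t) {
            if (rows[t] == ia) { ax = NX[t]; ay = NY[t]; az = NZ[t]; }
            if (rows[t] == ib) { bx = NX[t]; by = NY[t]; bz = NZ[t]; }
          }
        }
        double dx = ax - bx, dy = ay - by, dz = az - bz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        new_cd[q] = d;
        if (d > touch[k]) delta += w_contact * (d - touch[k]);
        if (cdist[k] > touch[k]) delta -= w_contact * (cdist[k] - touch[k]);
      }
    }

    // ---- accept --------------------------------------------------------
    bool ok;
    if (scheme == 0) ok = (delta < 0.0);
    else if (delta <= 0.0) ok = true;
    else ok = (unif() < std::exp(-delta / temp));

    if (ok) {
      for (int t = 0; t < m; ++t) {
        int i = rows[t];
        X[i] = NX[t]; Y[i] = NY[t]; Z[i] = NZ[t];
        bl[i] = new_bl[t];
      }
      for (size_t q = 0; q < con_list.size(); ++q) cdist[con_list[q]] = new_cd[q];
      total += delta;
      trace[n_acc] = total;
      ++n_acc;
      accepted_by[move_type] += 1;
      if (scheme == 2) temp *= cooling;
    }
    for (int t = 0; t < m; ++t) moved[rows[t]] = 0;
    if ((attempts & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  NumericVector trace_out = (n_acc > 0) ?
    (NumericVector)trace[Range(0, n_acc - 1)] : NumericVector(0);
  return List::create(_["coords"] = out,
                      _["trace"] = trace_out,
                      _["n_accepted"] = (double)n_acc,
                      _["n_attempts"] = (double)attempts,
                      _["attempted"] = attempted,
                      _["accepted"] = accepted_by);
}
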