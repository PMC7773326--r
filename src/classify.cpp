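// Host-bead assignment for energy deposits: for each deposit, the bead
// of deepest relative containment (smallest distance/radius among beads
// whose surface encloses the point), or 0 when outside every bead.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".host_bead_cpp")]]
IntegerVector host_bead_cpp(NumericVector dx, NumericVector dy,
                            NumericVector dz, NumericMatrix beads,
                            NumericVector radii) {
  const int nd = dx.size(), nb = beads.nrow();
  IntegerVector host(nd);
  std::vector<double> bx(nb), by(nb), bz(nb), r2(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = beads(j, 0); by[j] = beads(j, 1); bz[j] = beads(j, 2);
    r2[j] = radii[j] * radii[j];
  }
  for (int i = 0; i < nd; ++i) {
    double best = R_PosInf;
    int who = 0;
    const double x = dx[i], y = dy[i], z = dz[i];
    for (int j = 0; j < nb; ++j) {
      double ddx = x - bx[j], ddy = y - by[j], ddz = z - bz[j];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 <= r2[j]) {
        double rel = d2 / r2[j];
        if (rel < best) { best = rel; who = j + 1; }
      }
    }
    host[i] = who;
  }
  return host;
}
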