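#include <Rcpp.h>
using namespace Rcpp;

// Cellular Potts (GGH) kernels for the crypt-base model.
//
// Lattice encoding: 0 = MEDIUM, 1 = SUPPORT (frozen), >= 2 = epithelial
// cell ids. The lattice is bounded in y (rows); the x direction (columns)
// is bounded by default, optionally periodic.
// Adhesion energy runs over the order-2 (8-site) neighborhood; copy
// attempts propose order-1 (4-site) neighbors, the standard GGH choice that
// keeps interfaces compact while limiting lattice anisotropy.

static const int NBX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int NBY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
static const int NBX4[4] = {1, -1, 0, 0};
static const int NBY4[4] = {0, 0, 1, -1};

static inline int wrapx(int x, int nx, bool periodic) {
  if (!periodic) return (x < 0 || x >= nx) ? -1 : x;
  if (x < 0) return x + nx;
  if (x >= nx) return x - nx;
  return x;
}

// type of a lattice entry given the per-id type table (0-based by id)
static inline int id_type(int id, const IntegerVector &type_of_id) {
  return type_of_id[id];
}

// adhesion J between two lattice entries; same id => no boundary energy
static inline double pair_J(int a, int b, const IntegerVector &type_of_id,
                            const NumericMatrix &J) {
  if (a == b) return 0.0;
  return J(id_type(a, type_of_id), id_type(b, type_of_id));
}

// [[Rcpp::export]]
List cpm_mcs(IntegerMatrix lattice, IntegerVector type_of_id,
             NumericVector target_vol, NumericVector lambda_vol,
             NumericMatrix J, double temperature, int n_sweeps,
             bool periodic_x = false) {
  int ny = lattice.nrow(), nx = lattice.ncol();
  int nid = type_of_id.size();
  // volumes recomputed once, then maintained incrementally
  NumericVector vol(nid);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) vol[lattice(y, x)] += 1.0;

  RNGScope scope;
  long attempts = (long)nx * ny * n_sweeps;
  long accepted = 0;
  double energy_delta = 0.0;  // incremental ledger, audited against cpm_total_energy
  for (long it = 0; it < attempts; ++it) {
    int x = (int)(unif_rand() * nx); if (x == nx) x = nx - 1;
    int y = (int)(unif_rand() * ny); if (y == ny) y = ny - 1;
    int k = (int)(unif_rand() * 4); if (k == 4) k = 3;
    int qx = wrapx(x + NBX4[k], nx, periodic_x);
    int qy = y + NBY4[k];
    if (qx < 0 || qy < 0 || qy >= ny) continue;
    int s_old = lattice(y, x);
    int s_new = lattice(qy, qx);
    if (s_old == s_new) continue;
    if (s_old == 1 || s_new == 1) continue;   // SUPPORT frozen both ways
    // adhesion change at site (y,x): replace s_old by s_new
    double dE = 0.0;
    for (int m = 0; m < 8; ++m) {
      int ux = wrapx(x + NBX8[m], nx, periodic_x);
      int uy = y + NBY8[m];
      if (ux < 0 || uy < 0 || uy >= ny) continue;
      int s_u = lattice(uy, ux);
      dE += pair_J(s_new, s_u, type_of_id, J) - pair_J(s_old, s_u, type_of_id, J);
    }
    // volume-constraint change for the shrinking and growing ids
    if (lambda_vol[s_old] > 0) {
      double v = vol[s_old], t = target_vol[s_old];
      dE += lambda_vol[s_old] * ((v - 1 - t) * (v - 1 - t) - (v - t) * (v - t));
    }
    if (lambda_vol[s_new] > 0) {
      double v = vol[s_new], t = target_vol[s_new];
      dE += lambda_vol[s_new] * ((v + 1 - t) * (v + 1 - t) - (v - t) * (v - t));
    }
    bool accept;
    if (dE <= 0) accept = true;
    else if (temperature <= 0) accept = false;
    else accept = unif_rand() < std::exp(-dE / temperature);
    if (accept) {
      lattice(y, x) = s_new;
      vol[s_old] -= 1.0;
      vol[s_new] += 1.0;
      energy_delta += dE;
      ++accepted;
    }
  }
  return List::create(_["volumes"] = vol, _["accepted"] = accepted,
                      _["attempts"] = attempts, _["energy_delta"] = energy_delta);
}

// Shared boundary lengths (order-1 adjacency counts, each unordered pixel
// pair counted once) between all lattice ids.
// [[Rcpp::export]]
IntegerMatrix cpm_contacts(IntegerMatrix lattice, int nid,
                           bool periodic_x = false) {
  int ny = lattice.nrow(), nx = lattice.ncol();
  IntegerMatrix C(nid, nid);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      int a = lattice(y, x);
      int xr = wrapx(x + 1, nx, periodic_x);
      if (xr >= 0) {
        int b = lattice(y, xr);
        if (a != b) { C(a, b)++; C(b, a)++; }
      }
      if (y + 1 < ny) {
        int c = lattice(y + 1, x);
        if (a != c) { C(a, c)++; C(c, a)++; }
      }
    }
  }
  return C;
}

// Per-id pixel counts and centroids. x-centroids use the circular mean so
// cells straddling the periodic seam get sensible centers.
// [[Rcpp::export]]
List cpm_geometry(IntegerMatrix lattice, int nid, bool periodic_x = false) {
  int ny = lattice.nrow(), nx = lattice.ncol();
  NumericVector vol(nid), cy(nid);
  std::vector<double> sinx(nid, 0.0), cosx(nid, 0.0), sumx(nid, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int id = lattice(y, x);
      vol[id] += 1.0;
      cy[id] += y + 1.0;               // 1-based row coordinate
      if (periodic_x) {
        double ang = 2.0 * M_PI * x / nx;
        sinx[id] += std::sin(ang);
        cosx[id] += std::cos(ang);
      } else sumx[id] += x + 1.0;
    }
  NumericVector cx(nid);
  for (int id = 0; id < nid; ++id) {
    if (vol[id] > 0) {
      cy[id] /= vol[id];
      if (periodic_x) {
        double ang = std::atan2(sinx[id] / vol[id], cosx[id] / vol[id]);
        if (ang < 0) ang += 2.0 * M_PI;
        cx[id] = ang * nx / (2.0 * M_PI) + 1.0;  // 1-based column coordinate
      } else cx[id] = sumx[id] / vol[id];
    } else { cy[id] = NA_REAL; cx[id] = NA_REAL; }
  }
  return List::create(_["volume"] = vol, _["cx"] = cx, _["cy"] = cy);
}

// Total effective energy recomputed from scratch (test oracle for the
// incremental bookkeeping inside cpm_mcs).
// [[Rcpp::export]]
double cpm_total_energy(IntegerMatrix lattice, IntegerVector type_of_id,
                        NumericVector target_vol, NumericVector lambda_vol,
                        NumericMatrix J, bool periodic_x = false) {
  int ny = lattice.nrow(), nx = lattice.ncol();
  int nid = type_of_id.size();
  NumericVector vol(nid);
  double E = 0.0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = lattice(y, x);
      vol[a] += 1.0;
      // each unordered order-2 pair counted once: right/down/diagonals
      for (int m = 0; m < 8; ++m) {
        int dx_ = NBX8[m], dy_ = NBY8[m];
        if (!(dx_ > 0 || (dx_ == 0 && dy_ > 0))) continue;
        int uy = y + dy_;
        int ux = wrapx(x + dx_, nx, periodic_x);
        if (ux < 0 || uy < 0 || uy >= ny) continue;
        int b = lattice(uy, ux);
        if (a != b) E += J(type_of_id[a], type_of_id[b]);
      }
    }
  for (int id = 0; id < nid; ++id)
    if (lambda_vol[id] > 0)
      E += lambda_vol[id] * (vol[id] - target_vol[id]) * (vol[id] - target_vol[id]);
  return E;
}
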