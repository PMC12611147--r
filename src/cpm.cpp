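// Cellular-Potts engine on a 2-D periodic lattice with a coupled
// secretion-diffusion-decay field.
//
// Conventions used throughout:
//  - lattice ids: 0 = medium, 1..max_id = cells (single motile type);
//  - contact energy counts each unordered neighbor pair once;
//  - per-cell surface = number of 4-neighbor faces between a site of the
//    cell and a site of any other id (each face counted once per cell side);
//  - copy-attempt candidate pairs are 4-neighbors; the contact neighborhood
//    is configurable (order 1 = von Neumann, order 2 = Moore).
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

inline int wrap(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

// contact coefficient for the single-cell-type model
inline double Jpair(int a, int b, double Jcm, double Jcc) {
  if (a == b) return 0.0;
  if (a == 0 || b == 0) return Jcm;
  return Jcc;
}

// saturated chemotactic response
inline double satc(double c, double s) { return c / (s * c + 1.0); }

struct Offsets {
  std::vector<int> dr, dc;
};

Offsets contact_offsets(int order) {
  Offsets o;
  o.dr = {-1, 1, 0, 0};
  o.dc = {0, 0, -1, 1};
  if (order >= 2) {
    int dr2[] = {-1, -1, 1, 1}, dc2[] = {-1, 1, -1, 1};
    for (int i = 0; i < 4; ++i) { o.dr.push_back(dr2[i]); o.dc.push_back(dc2[i]); }
  }
  return o;
}

} // namespace

// Brute-force total energy: contact + volume + surface terms.  The
// chemotaxis term of the energy functional is path-dependent (it involves a
// copy source and destination) and contributes only to per-attempt energy
// changes, so the static total excludes it.
// [[Rcpp::export]]
double cpp_total_energy(const IntegerMatrix& lat,
                        double lambda_volume, double V_target,
                        double lambda_surface, double S_target,
                        double J_cell_medium, double J_cell_cell,
                        int contact_order, int surface_mode) {
  const int H = lat.nrow(), W = lat.ncol();
  Offsets off = contact_offsets(contact_order);
  double E = 0.0;

  // contact: iterate "forward" half of each neighborhood so every unordered
  // pair is visited exactly once (right, down, and the two down-diagonals)
  std::vector<int> fdr = {0, 1}, fdc = {1, 0};
  if (contact_order >= 2) { fdr.push_back(1); fdr.push_back(1); fdc.push_back(1); fdc.push_back(-1); }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      for (size_t k = 0; k < fdr.size(); ++k) {
        int r2 = wrap(r + fdr[k], H), c2 = wrap(c + fdc[k], W);
        E += Jpair(lat(r, c), lat(r2, c2), J_cell_medium, J_cell_cell);
      }

  // recount volumes and 4-neighbor surfaces
  int max_id = 0;
  for (int i = 0; i < H * W; ++i) max_id = std::max(max_id, lat[i]);
  std::vector<double> vol(max_id + 1, 0.0), surf(max_id + 1, 0.0);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int id = lat(r, c);
      if (id == 0) continue;
      vol[id] += 1.0;
      for (int k = 0; k < 4; ++k) {
        int r2 = wrap(r + (k == 0 ? -1 : k == 1 ? 1 : 0), H);
        int c2 = wrap(c + (k == 2 ? -1 : k == 3 ? 1 : 0), W);
        if (lat(r2, c2) != id) surf[id] += 1.0;
      }
    }
  for (int id = 1; id <= max_id; ++id) {
    if (vol[id] == 0.0) continue;
    E += lambda_volume * std::pow(vol[id] - V_target, 2.0);
    double S = surface_mode == 1 ? 2.0 * vol[id] + surf[id] : surf[id];
    E += lambda_surface * std::pow(S - S_target, 2.0);
  }
  return E;
}

// Recount per-cell volumes and surfaces from the lattice.
// [[Rcpp::export]]
List cpp_recount(const IntegerMatrix& lat, int max_id) {
  const int H = lat.nrow(), W = lat.ncol();
  IntegerVector vol(max_id), surf(max_id);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int id = lat(r, c);
      if (id == 0) continue;
      if (id > max_id) stop("lattice id exceeds max_id");
      vol[id - 1] += 1;
      for (int k = 0; k < 4; ++k) {
        int r2 = wrap(r + (k == 0 ? -1 : k == 1 ? 1 : 0), H);
        int c2 = wrap(c + (k == 2 ? -1 : k == 3 ? 1 : 0), W);
        if (lat(r2, c2) != id) surf[id - 1] += 1;
      }
    }
  return List::create(_["volumes"] = vol, _["surfaces"] = surf);
}

namespace {

// Incremental energy change of setting dest's id to source's id.
// vols/surfs are cached statistics indexed by id-1.
double delta_energy_impl(const int* lat, const double* field, int H, int W,
                         const int* vols, const int* surfs,
                         double lv, double Vt, double ls, double St,
                         double Jcm, double Jcc, double lchem, double sat,
                         int surface_mode, int chemo_mode, const Offsets& coff,
                         int sr, int sc, int dr, int dc) {
  const int a = lat[sr + (size_t)H * sc];   // id copying in
  const int b = lat[dr + (size_t)H * dc];   // id displaced

  double dH = 0.0;
  // contact over the contact neighborhood of dest
  for (size_t k = 0; k < coff.dr.size(); ++k) {
    int r2 = wrap(dr + coff.dr[k], H), c2 = wrap(dc + coff.dc[k], W);
    int nid = lat[r2 + (size_t)H * c2];
    dH += Jpair(a, nid, Jcm, Jcc) - Jpair(b, nid, Jcm, Jcc);
  }
  // volume terms
  if (a > 0) {
    double V = vols[a - 1];
    dH += lv * (std::pow(V + 1.0 - Vt, 2.0) - std::pow(V - Vt, 2.0));
  }
  if (b > 0) {
    double V = vols[b - 1];
    dH += lv * (std::pow(V - 1.0 - Vt, 2.0) - std::pow(V - Vt, 2.0));
  }
  // surface terms: closed-form change from the 4-neighbors of dest
  if (ls != 0.0 && (a > 0 || b > 0)) {
    int ma = 0, mb = 0;
    static const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int nid = lat[wrap(dr + d4r[k], H) + (size_t)H * wrap(dc + d4c[k], W)];
      if (nid == a) ++ma;
      if (nid == b) ++mb;
    }
    if (a > 0) {
      double S = surfs[a - 1], dS = 4.0 - 2.0 * ma;
      if (surface_mode == 1) { S += 2.0 * vols[a - 1]; dS += 2.0; }
      dH += ls * (std::pow(S + dS - St, 2.0) - std::pow(S - St, 2.0));
    }
    if (b > 0) {
      double S = surfs[b - 1], dS = 2.0 * mb - 4.0;
      if (surface_mode == 1) { S += 2.0 * vols[b - 1]; dS -= 2.0; }
      dH += ls * (std::pow(S + dS - St, 2.0) - std::pow(S - St, 2.0));
    }
  }
  // saturated chemotaxis, per-attempt.  chemo_mode 0 ("advance"): the term
  // applies only when a cell copies forward (medium does not chemotax), the
  // convention of the major CPM frameworks; it breaks detailed balance and
  // sustains active remodeling.  chemo_mode 1 ("both"): the antisymmetric
  // conservative variant, additionally penalizing retraction from high
  // concentration.
  if (lchem != 0.0) {
    double cd = field[dr + (size_t)H * dc], cs = field[sr + (size_t)H * sc];
    double g = satc(cd, sat) - satc(cs, sat);
    if (a > 0) dH += -lchem * g;
    else if (chemo_mode == 1 && b > 0) dH += lchem * g;
  }
  return dH;
}

void field_substep(std::vector<double>& f, std::vector<double>& buf,
                   const int* lat, int H, int W,
                   double D, double kdec, double secr, double dt) {
  for (int c = 0; c < W; ++c) {
    int cl = wrap(c - 1, W), crr = wrap(c + 1, W);
    for (int r = 0; r < H; ++r) {
      int ru = wrap(r - 1, H), rd = wrap(r + 1, H);
      size_t i = r + (size_t)H * c;
      double lap = f[ru + (size_t)H * c] + f[rd + (size_t)H * c] +
                   f[r + (size_t)H * cl] + f[r + (size_t)H * crr] - 4.0 * f[i];
      double src = (lat != nullptr && lat[i] > 0) ? secr : 0.0;
      buf[i] = f[i] + dt * (D * lap - kdec * f[i] + src);
    }
  }
  f.swap(buf);
}

} // namespace

// [[Rcpp::export]]
double cpp_delta_energy(const IntegerMatrix& lat, const NumericMatrix& field,
                        const IntegerVector& vols, const IntegerVector& surfs,
                        double lambda_volume, double V_target,
                        double lambda_surface, double S_target,
                        double J_cell_medium, double J_cell_cell,
                        double lambda_chemotaxis, double s,
                        int contact_order, int surface_mode, int chemo_mode,
                        int sr, int sc, int dr, int dc) {
  Offsets coff = contact_offsets(contact_order);
  return delta_energy_impl(&lat[0], &field[0], lat.nrow(), lat.ncol(),
                           &vols[0], &surfs[0],
                           lambda_volume, V_target, lambda_surface, S_target,
                           J_cell_medium, J_cell_cell, lambda_chemotaxis, s,
                           surface_mode, chemo_mode, coff, sr, sc, dr, dc);
}

// The Monte-Carlo driver: per MCS, H*W copy attempts (uniform site, uniform
// 4-neighbor) scored by the incremental energy change and accepted with the
// Boltzmann rule exp(-max(0, dH/T)), followed by one chemical-field update
// with secretion at cell-occupied sites.  Consumes the R RNG stream.
// [[Rcpp::export]]
List cpp_run_mcs(const IntegerMatrix& lat_in, const NumericMatrix& field_in,
                 const IntegerVector& vols_in, const IntegerVector& surfs_in,
                 double lambda_volume, double V_target,
                 double lambda_surface, double S_target,
                 double J_cell_medium, double J_cell_cell,
                 double lambda_chemotaxis, double s,
                 double temperature, int contact_order, int surface_mode,
                 int chemo_mode,
                 double D, double k_decay, double secretion_rate,
                 int pde_substeps, int n_mcs) {
  const int H = lat_in.nrow(), W = lat_in.ncol();
  const size_t N = (size_t)H * W;
  std::vector<int> lat(lat_in.begin(), lat_in.end());
  std::vector<double> field(field_in.begin(), field_in.end());
  std::vector<double> fbuf(N);
  std::vector<int> vols(vols_in.begin(), vols_in.end());
  std::vector<int> surfs(surfs_in.begin(), surfs_in.end());
  Offsets coff = contact_offsets(contact_order);
  const double dt = 1.0 / pde_substeps;
  if ((4.0 * D + k_decay) * dt > 1.0 + 1e-12)
    stop("explicit field update unstable/non-positive: (4D+k)*dt = %f > 1; increase pde_substeps",
         (4.0 * D + k_decay) * dt);

  static const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
  double n_accepted = 0.0, n_scored = 0.0;

  for (int step = 0; step < n_mcs; ++step) {
    for (size_t att = 0; att < N; ++att) {
      size_t pick = (size_t)(unif_rand() * N);
      if (pick >= N) pick = N - 1;
      int dr_ = (int)(pick % H), dc_ = (int)(pick / H);
      int nb = (int)(unif_rand() * 4.0); if (nb > 3) nb = 3;
      int sr_ = wrap(dr_ + d4r[nb], H), sc_ = wrap(dc_ + d4c[nb], W);
      int a = lat[sr_ + (size_t)H * sc_], b = lat[dr_ + (size_t)H * dc_];
      if (a == b) continue;
      double dH = delta_energy_impl(lat.data(), field.data(), H, W,
                                    vols.data(), surfs.data(),
                                    lambda_volume, V_target, lambda_surface,
                                    S_target, J_cell_medium, J_cell_cell,
                                    lambda_chemotaxis, s, surface_mode,
                                    chemo_mode, coff, sr_, sc_, dr_, dc_);
      n_scored += 1.0;
      bool accept = dH <= 0.0 || unif_rand() < std::exp(-dH / temperature);
      if (!accept) continue;
      n_accepted += 1.0;
      // bookkeeping: surfaces first (need pre-copy neighborhood), then ids
      int ma = 0, mb = 0;
      for (int k = 0; k < 4; ++k) {
        int nid = lat[wrap(dr_ + d4r[k], H) + (size_t)H * wrap(dc_ + d4c[k], W)];
        if (nid == a) ++ma;
        if (nid == b) ++mb;
      }
      if (a > 0) { surfs[a - 1] += 4 - 2 * ma; ++vols[a - 1]; }
      if (b > 0) { surfs[b - 1] += 2 * mb - 4; --vols[b - 1]; }
      lat[dr_ + (size_t)H * dc_] = a;
    }
    for (int sub = 0; sub < pde_substeps; ++sub)
      field_substep(field, fbuf, lat.data(), H, W, D, k_decay, secretion_rate, dt);
  }

  IntegerMatrix lat_out(H, W);
  NumericMatrix field_out(H, W);
  std::copy(lat.begin(), lat.end(), lat_out.begin());
  std::copy(field.begin(), field.end(), field_out.begin());
  return List::create(_["cell_lattice"] = lat_out, _["field"] = field_out,
                      _["volumes"] = IntegerVector(vols.begin(), vols.end()),
                      _["surfaces"] = IntegerVector(surfs.begin(), surfs.end()),
                      _["n_accepted"] = n_accepted, _["n_scored"] = n_scored);
}

// Explicit Euler integration of dc/dt = D lap(c) - k c + secretion on the
// periodic lattice; secretion applies where mask is TRUE.
// [[Rcpp::export]]
NumericMatrix cpp_step_field(const NumericMatrix& field_in, const LogicalMatrix& mask,
                             double D, double k_decay, double secretion_rate,
                             double dt, int n_substeps) {
  const int H = field_in.nrow(), W = field_in.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("field/mask shape mismatch");
  if ((4.0 * D + k_decay) * dt > 1.0 + 1e-12)
    stop("explicit field update unstable/non-positive: (4D+k)*dt = %f > 1", (4.0 * D + k_decay) * dt);
  const size_t N = (size_t)H * W;
  std::vector<double> f(field_in.begin(), field_in.end()), buf(N);
  std::vector<int> lmask(N);
  for (size_t i = 0; i < N; ++i) lmask[i] = mask[i] ? 1 : 0;
  for (int sub = 0; sub < n_substeps; ++sub)
    field_substep(f, buf, lmask.data(), H, W, D, k_decay, secretion_rate, dt);
  NumericMatrix out(H, W);
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// Connected-component labeling of the TRUE sites of a binary matrix.
// torus = FALSE labels in the plane (no wraparound); torus = TRUE labels on
// the periodic lattice.  connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity, bool torus) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  std::vector<int> dr = {-1, 1, 0, 0}, dc = {0, 0, -1, 1};
  if (connectivity == 8) {
    int dr2[] = {-1, -1, 1, 1}, dc2[] = {-1, 1, -1, 1};
    for (int i = 0; i < 4; ++i) { dr.push_back(dr2[i]); dc.push_back(dc2[i]); }
  } else if (connectivity != 4) stop("connectivity must be 4 or 8");
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      lab(r0, c0) = ++next;
      stack.push_back(r0 + H * c0);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % H, c = p / H;
        for (size_t k = 0; k < dr.size(); ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (torus) { r2 = wrap(r2, H); c2 = wrap(c2, W); }
          else if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + H * c2);
          }
        }
      }
    }
  return lab;
}
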