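// Compiled core of the Brownian-ratchet engine: stadium-geometry reflection,
// tau-leaped McdA surface chemistry, and the coupled chemistry-tether-motion
// loop. All randomness draws from R's RNG so set.seed() governs everything.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- geometry helpers (stadium: segment half-length c, radius r) ----------

static inline double seg_dist(double c, double x, double y, double *nx, double *ny) {
  double cx = x < -c ? -c : (x > c ? c : x);
  double dx = x - cx, dy = y;
  double d = std::sqrt(dx * dx + dy * dy);
  if (d > 1e-14) { *nx = dx / d; *ny = dy / d; }
  else { *nx = 0.0; *ny = 1.0; } // on the axis: any normal; flat wall above
  return d;
}

static inline bool inside(double c, double r, double x, double y) {
  double nx, ny;
  return seg_dist(c, x, y, &nx, &ny) <= r + 1e-12;
}

// Specular reflection of the segment a->b about the boundary, iterated.
static void reflect_point(double c, double r, double ax, double ay,
                          double bx, double by, double *ox, double *oy,
                          int max_iter) {
  for (int it = 0; it < max_iter; ++it) {
    double nx, ny;
    if (seg_dist(c, bx, by, &nx, &ny) <= r + 1e-12) { *ox = bx; *oy = by; return; }
    // bisect t in [0,1] for the boundary crossing along a->b
    double lo = 0.0, hi = 1.0;
    double d0 = seg_dist(c, ax, ay, &nx, &ny);
    if (d0 >= r - 1e-12) {
      lo = 0.0; // start effectively on the boundary
    } else {
      for (int k = 0; k < 60; ++k) {
        double mid = 0.5 * (lo + hi);
        double mx = ax + mid * (bx - ax), my = ay + mid * (by - ay);
        if (seg_dist(c, mx, my, &nx, &ny) <= r) lo = mid; else hi = mid;
      }
    }
    double xc = ax + lo * (bx - ax), yc = ay + lo * (by - ay);
    seg_dist(c, xc, yc, &nx, &ny); // outward normal at the crossing
    double vx = bx - xc, vy = by - yc;
    double vn = vx * nx + vy * ny;
    ax = xc; ay = yc;
    bx = xc + (vx - 2.0 * vn * nx);
    by = yc + (vy - 2.0 * vn * ny);
  }
  // grazing pathologies: project just inside the boundary
  double nx, ny;
  double d = seg_dist(c, bx, by, &nx, &ny);
  if (d > r) {
    bx -= nx * (d - r + 1e-9);
    by -= ny * (d - r + 1e-9);
  }
  *ox = bx; *oy = by;
}

// [[Rcpp::export]]
NumericVector cpp_reflect_into(double c, double r, NumericVector p_from,
                               NumericVector p_to, int max_iter) {
  double ox, oy;
  reflect_point(c, r, p_from[0], p_from[1], p_to[0], p_to[1], &ox, &oy, max_iter);
  return NumericVector::create(ox, oy);
}

// ---- site bookkeeping ------------------------------------------------------
// occ codes: 0 empty, 1 occupied (untethered), 2 occupied + tethered.
// Two swap-remove lists give O(1) uniform sampling of empty and of
// occupied-untethered sites.

struct SiteLists {
  std::vector<int> occ;                  // per-site state code
  std::vector<int> empty_list, pos_empty;
  std::vector<int> free_occ_list, pos_occ; // occupied & untethered
  void init(const IntegerVector &occ0) {
    int n = occ0.size();
    occ.assign(occ0.begin(), occ0.end());
    pos_empty.assign(n, -1);
    pos_occ.assign(n, -1);
    empty_list.clear(); free_occ_list.clear();
    for (int s = 0; s < n; ++s) {
      if (occ[s] == 0) { pos_empty[s] = empty_list.size(); empty_list.push_back(s); }
      else if (occ[s] == 1) { pos_occ[s] = free_occ_list.size(); free_occ_list.push_back(s); }
    }
  }
  static void list_remove(std::vector<int> &lst, std::vector<int> &pos, int s) {
    int p = pos[s], last = lst.back();
    lst[p] = last; pos[last] = p;
    lst.pop_back(); pos[s] = -1;
  }
  static void list_add(std::vector<int> &lst, std::vector<int> &pos, int s) {
    pos[s] = lst.size(); lst.push_back(s);
  }
  void occupy(int s) {           // empty -> occupied
    list_remove(empty_list, pos_empty, s);
    occ[s] = 1; list_add(free_occ_list, pos_occ, s);
  }
  void vacate_untethered(int s) { // occupied untethered -> empty
    list_remove(free_occ_list, pos_occ, s);
    occ[s] = 0; list_add(empty_list, pos_empty, s);
  }
  void tether(int s) {            // occupied untethered -> tethered
    list_remove(free_occ_list, pos_occ, s);
    occ[s] = 2;
  }
  void release_tethered(int s) {  // tethered -> empty (stimulated release)
    occ[s] = 0; list_add(empty_list, pos_empty, s);
  }
};

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One tau-leaped chemistry step on the whole lattice. Basal unbinding acts on
// untethered occupied sites only (a tethered McdA is held by its bond and can
// leave only via McdB-stimulated release).
static void chem_step(SiteLists &S, int n_total, int &n_bound, int &n_free,
                      int &n_refr, double p_off, double p_reset,
                      double k_on, double dt) {
  // stimulated-release resets
  if (n_refr > 0 && p_reset > 0) {
    int n_res = (int)R::rbinom(n_refr, p_reset);
    n_refr -= n_res; n_free += n_res;
  }
  // basal unbinding
  if (!S.free_occ_list.empty() && p_off > 0) {
    int n_unb = (int)R::rbinom((double)S.free_occ_list.size(), p_off);
    for (int k = 0; k < n_unb; ++k) {
      int s = S.free_occ_list[rand_below(S.free_occ_list.size())];
      S.vacate_untethered(s);
      --n_bound; ++n_free;
    }
  }
  // binding of free McdA to empty sites
  if (!S.empty_list.empty() && n_free > 0 && k_on > 0) {
    double p_bind = 1.0 - std::exp(-k_on * ((double)n_free / n_total) * dt);
    int n_bind = (int)R::rbinom((double)S.empty_list.size(), p_bind);
    if (n_bind > n_free) n_bind = n_free;
    for (int k = 0; k < n_bind; ++k) {
      int s = S.empty_list[rand_below(S.empty_list.size())];
      S.occupy(s);
      ++n_bound; --n_free;
    }
  }
}

// Chemistry-only run (used for lattice pre-equilibration and for validating
// the tau-leap against the exact Gillespie oracle). Records the occupied
// fraction at every `record_every` steps when > 0.
// [[Rcpp::export]]
List cpp_chem_run(IntegerVector occ0, int n_total, int n_free0, int n_refr0,
                  double k_on, double k_off, double tau_reset,
                  double dt, int n_steps, int record_every) {
  RNGScope scope;
  SiteLists S; S.init(occ0);
  int n_sites = occ0.size();
  int n_bound = 0;
  for (int s = 0; s < n_sites; ++s) if (occ0[s] != 0) ++n_bound;
  int n_free = n_free0, n_refr = n_refr0;
  double p_off = 1.0 - std::exp(-k_off * dt);
  double p_reset = 1.0 - std::exp(-dt / tau_reset);
  std::vector<double> frac;
  for (int step = 1; step <= n_steps; ++step) {
    chem_step(S, n_total, n_bound, n_free, n_refr, p_off, p_reset, k_on, dt);
    if (record_every > 0 && step % record_every == 0)
      frac.push_back((double)n_bound / n_sites);
    if (n_bound + n_free + n_refr != n_total)
      stop("McdA conservation violated in chemistry step");
  }
  IntegerVector occ_out(S.occ.begin(), S.occ.end());
  return List::create(_["occ"] = occ_out, _["n_bound"] = n_bound,
                      _["n_free"] = n_free, _["n_refractory"] = n_refr,
                      _["occupied_fraction"] = NumericVector(frac.begin(), frac.end()));
}

// ---- the full coupled loop -------------------------------------------------

// [[Rcpp::export]]
List cpp_run(double gc, double gr,                       // geometry
             NumericVector sx, NumericVector sy,          // site centers
             IntegerVector si, IntegerVector sj,          // grid indices
             double spacing, IntegerVector occ0,
             int n_total, int n_free0, int n_refr0,
             double k_on, double k_off, double tau_reset,
             double r_capture, double k_attach, double k_detach,
             double k_spring, double rest_length, int n_mcdb,
             double cargo_radius, double D_free, bool hard_disk,
             NumericVector cx0, NumericVector cy0,
             double dt, double duration, double record_interval,
             int snapshot_every,                          // in records, 0 = off
             bool pin) {
  RNGScope scope;
  const int n_sites = sx.size();
  const int n_cargo = cx0.size();

  // grid lookup (i,j) -> site index
  int imin = 0, imax = 0, jmin = 0, jmax = 0;
  for (int s = 0; s < n_sites; ++s) {
    if (si[s] < imin) imin = si[s];
    if (si[s] > imax) imax = si[s];
    if (sj[s] < jmin) jmin = sj[s];
    if (sj[s] > jmax) jmax = sj[s];
  }
  const int ni = imax - imin + 1, nj = jmax - jmin + 1;
  std::vector<int> grid((size_t)ni * nj, -1);
  for (int s = 0; s < n_sites; ++s)
    grid[(size_t)(si[s] - imin) * nj + (sj[s] - jmin)] = s;

  SiteLists S; S.init(occ0);
  int n_bound = 0;
  for (int s = 0; s < n_sites; ++s) if (occ0[s] != 0) ++n_bound;
  int n_free = n_free0, n_refr = n_refr0;

  std::vector<double> cx(cx0.begin(), cx0.end()), cy(cy0.begin(), cy0.end());
  std::vector<std::vector<int>> teth(n_cargo);
  std::vector<double> sumx(n_cargo, 0.0), sumy(n_cargo, 0.0); // anchor sums

  const double p_off = 1.0 - std::exp(-k_off * dt);
  const double p_reset = 1.0 - std::exp(-dt / tau_reset);
  const double p_det = 1.0 - std::exp(-k_detach * dt);
  const double p_att = 1.0 - std::exp(-k_attach * dt);
  const double rcap2 = r_capture * r_capture;

  // candidate cell offsets: every grid cell that can lie within r_capture of
  // a point anywhere inside the cargo's own cell (attachment proposals are
  // drawn uniformly from these and rejected if ineligible)
  std::vector<std::pair<int,int>> offsets;
  {
    int box = (int)std::ceil(r_capture / spacing) + 1;
    for (int di = -box; di <= box; ++di)
      for (int dj = -box; dj <= box; ++dj) {
        double mx = std::max(std::fabs((double)di) - 0.5, 0.0) * spacing;
        double my = std::max(std::fabs((double)dj) - 0.5, 0.0) * spacing;
        if (mx * mx + my * my <= rcap2) offsets.emplace_back(di, dj);
      }
  }
  const int n_off = (int)offsets.size();

  const long n_steps = (long)std::lround(duration / dt);
  const long rec_steps = std::max(1L, (long)std::lround(record_interval / dt));
  const int n_rec = (int)(n_steps / rec_steps) + 1;

  NumericVector times(n_rec);
  NumericMatrix X(n_rec, n_cargo), Y(n_rec, n_cargo);
  IntegerMatrix pools(n_rec, 3);
  IntegerMatrix tcount(n_rec, n_cargo);
  List snapshots;
  std::vector<double> snap_times;
  int overlap_warn = 0;

  std::vector<int> order(n_cargo);

  auto record = [&](int rec, double t) {
    times[rec] = t;
    for (int m = 0; m < n_cargo; ++m) {
      // refresh anchor sums to kill floating-point drift
      sumx[m] = 0.0; sumy[m] = 0.0;
      for (int s : teth[m]) { sumx[m] += sx[s]; sumy[m] += sy[s]; }
      X(rec, m) = cx[m]; Y(rec, m) = cy[m];
      tcount(rec, m) = (int)teth[m].size();
      if (!inside(gc, gr, cx[m], cy[m]))
        stop("cargo left the domain at t = %f", t);
    }
    pools(rec, 0) = n_bound; pools(rec, 1) = n_free; pools(rec, 2) = n_refr;
    if (n_bound + n_free + n_refr != n_total)
      stop("McdA conservation violated at t = %f", t);
    if (snapshot_every > 0 && rec % snapshot_every == 0) {
      IntegerVector snap(S.occ.begin(), S.occ.end());
      snapshots.push_back(snap);
      snap_times.push_back(t);
    }
  };
  record(0, 0.0);

  int rec = 1;
  for (long step = 1; step <= n_steps; ++step) {
    // 1) McdA chemistry on the whole lattice
    chem_step(S, n_total, n_bound, n_free, n_refr, p_off, p_reset, k_on, dt);

    // 2) tether kinetics, cargo order randomized each step
    for (int m = 0; m < n_cargo; ++m) order[m] = m;
    for (int m = n_cargo - 1; m > 0; --m)
      std::swap(order[m], order[rand_below(m + 1)]);
    for (int oi = 0; oi < n_cargo; ++oi) {
      int m = order[oi];
      // detachment: every break is a McdB-stimulated release (-> refractory)
      std::vector<int> &tm = teth[m];
      if (k_detach > 0 && !tm.empty()) {
        int n_det = (int)R::rbinom((double)tm.size(), p_det);
        for (int k = 0; k < n_det; ++k) {
          int idx = rand_below((int)tm.size());
          int s = tm[idx];
          tm[idx] = tm.back(); tm.pop_back();
          sumx[m] -= sx[s]; sumy[m] -= sy[s];
          S.release_tethered(s);
          --n_bound; ++n_refr;
        }
      }
      // attachment among eligible (occupied, untethered, within r_capture):
      // thinned uniform proposals over the candidate cells of the capture disk
      int slots = n_mcdb - (int)tm.size();
      if (slots > 0 && k_attach > 0) {
        int n_prop = (int)R::rbinom((double)n_off, p_att);
        if (n_prop > 0) {
          int ic = (int)std::lround(cx[m] / spacing);
          int jc = (int)std::lround(cy[m] / spacing);
          for (int k = 0; k < n_prop && slots > 0; ++k) {
            const std::pair<int,int> &off = offsets[rand_below(n_off)];
            int ii = ic + off.first - imin;
            int jj = jc + off.second - jmin;
            if (ii < 0 || ii >= ni || jj < 0 || jj >= nj) continue;
            int s = grid[(size_t)ii * nj + jj];
            if (s < 0 || S.occ[s] != 1) continue;
            double dx = sx[s] - cx[m], dy = sy[s] - cy[m];
            if (dx * dx + dy * dy > rcap2) continue;
            S.tether(s);
            tm.push_back(s);
            sumx[m] += sx[s]; sumy[m] += sy[s];
            --slots;
          }
        }
      }
    }

    // 3) elastic forces + overdamped Brownian step (kBT = 1, mobility = D)
    if (!pin) {
      for (int m = 0; m < n_cargo; ++m) {
        double fx = 0.0, fy = 0.0;
        if (rest_length > 0) {
          for (int s : teth[m]) {
            double dx = sx[s] - cx[m], dy = sy[s] - cy[m];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d > rest_length) {
              double f = k_spring * (d - rest_length) / d;
              fx += f * dx; fy += f * dy;
            }
          }
        } else { // zero rest length: force from the running anchor sums
          fx = k_spring * (sumx[m] - (double)teth[m].size() * cx[m]);
          fy = k_spring * (sumy[m] - (double)teth[m].size() * cy[m]);
        }
        double drift_x = D_free * fx * dt, drift_y = D_free * fy * dt;
        if (std::fabs(drift_x) + std::fabs(drift_y) >= spacing)
          stop("drift per step exceeds the lattice spacing: reduce dt "
               "(|drift| = %g um at step %ld)", std::fabs(drift_x) + std::fabs(drift_y), step);
        double sig = std::sqrt(2.0 * D_free * dt);
        double nxp = cx[m] + drift_x + sig * norm_rand();
        double nyp = cy[m] + drift_y + sig * norm_rand();
        reflect_point(gc, gr, cx[m], cy[m], nxp, nyp, &cx[m], &cy[m], 16);
      }
      // 4) hard-disk exclusion
      if (hard_disk && n_cargo > 1) {
        const double dmin = 2.0 * cargo_radius;
        bool any = true; int it = 0;
        while (any && it++ < 50) {
          any = false;
          for (int a = 0; a < n_cargo; ++a)
            for (int b = a + 1; b < n_cargo; ++b) {
              double dx = cx[b] - cx[a], dy = cy[b] - cy[a];
              double d = std::sqrt(dx * dx + dy * dy);
              if (d < dmin - 1e-12) {
                double ux, uy;
                if (d < 1e-12) { double th = unif_rand() * 2 * M_PI; ux = std::cos(th); uy = std::sin(th); }
                else { ux = dx / d; uy = dy / d; }
                double push = 0.5 * (dmin - d) + 1e-12;
                double ax2 = cx[a] - push * ux, ay2 = cy[a] - push * uy;
                double bx2 = cx[b] + push * ux, by2 = cy[b] + push * uy;
                reflect_point(gc, gr, cx[a], cy[a], ax2, ay2, &cx[a], &cy[a], 16);
                reflect_point(gc, gr, cx[b], cy[b], bx2, by2, &cx[b], &cy[b], 16);
                any = true;
              }
            }
        }
        if (any) ++overlap_warn;
      }
    }

    if (step % rec_steps == 0 && rec < n_rec)
      record(rec++, step * dt);
  }

  IntegerVector occ_out(S.occ.begin(), S.occ.end());
  return List::create(_["times"] = times, _["x"] = X, _["y"] = Y,
                      _["pools"] = pools, _["tether_count"] = tcount,
                      _["occ"] = occ_out,
                      _["snapshots"] = snapshots,
                      _["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()),
                      _["overlap_warnings"] = overlap_warn);
}
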