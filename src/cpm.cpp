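// Cellular Potts (Glazier-Graner-Hogeweg) engine core.
//
// Lattice: IntegerMatrix (ny rows = y, nx cols = x); owner 0 is Medium.
// Periodic in x, closed in y. Energy = sum lambda(v-V)^2 + sum beta(a-A)^2
// + sum_{unlike neighbor pixel pairs <= order} J(type_i, type_j)
// + sum_links strength*(l - target)^2, with l the center-to-center distance
// under the minimal-image convention in x. Migration forces enter the
// acceptance delta as force_x * d(com_x) per affected cell and are not part
// of the Hamiltonian.
//
// Surface a of a cell = number of order-1 neighbor pixel pairs with one
// pixel in the cell and the other owned differently (y-boundary pairs do
// not exist). The copy-candidate neighborhood is the order-1 shell; the
// configured neighbor order applies to contact accounting.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static const int SHELL_DX[12] = {1, -1, 0, 0, 1, 1, -1, -1, 2, -2, 0, 0};
static const int SHELL_DY[12] = {0, 0, 1, -1, 1, -1, 1, -1, 0, 0, 2, -2};

static inline int shell_size(int order) {
  return order == 1 ? 4 : (order == 2 ? 8 : 12);
}

struct CPM {
  IntegerMatrix lattice;          // ny x nx
  int ny, nx, ncell, ntypes;
  IntegerVector cell_type;        // [ncell], type ids 1..ntypes
  IntegerVector composite;        // [ncell], 0 = none
  NumericVector lambda_v, target_v, lambda_s, target_a, force_x; // [ntypes]
  LogicalVector frozen;           // [ntypes]
  NumericMatrix contacts;         // (ntypes+1)^2, row/col 0 = Medium
  NumericMatrix contacts_int;     // internal (same-composite) contact table
  int order;
  // caches
  std::vector<double> vol, surf, sum_x, sum_y; // [ncell+1], idx 0 unused
  // links (parallel vectors)
  std::vector<int> la, lb, lclass;
  std::vector<double> lstr, ltgt, lmax;
  std::vector<char> linternal;
  std::vector<std::vector<int> > cell_links; // link indices per cell

  int type_of(int c) const { return c == 0 ? 0 : cell_type[c - 1]; }

  double com_x(int c) const { return sum_x[c] / vol[c]; }
  double com_y(int c) const { return sum_y[c] / vol[c]; }

  // nearest periodic image of pixel-x relative to a reference x
  double unwrap(double x, double ref) const {
    double d = x - ref;
    d -= nx * std::floor(d / nx + 0.5);
    return ref + d;
  }

  double pair_J(int c1, int c2) const {
    if (c1 == c2) return 0.0;
    int t1 = type_of(c1), t2 = type_of(c2);
    if (c1 > 0 && c2 > 0 && composite[c1 - 1] != 0 &&
        composite[c1 - 1] == composite[c2 - 1])
      return contacts_int(t1, t2);
    return contacts(t1, t2);
  }

  double link_len(double ax, double ay, double bx, double by) const {
    double dx = ax - bx;
    dx -= nx * std::floor(dx / nx + 0.5);
    double dy = ay - by;
    return std::sqrt(dx * dx + dy * dy);
  }

  double link_energy_of(int li, double ax, double ay, double bx, double by) const {
    double l = link_len(ax, ay, bx, by);
    double e = l - ltgt[li];
    return lstr[li] * e * e;
  }

  void rebuild_cell_links() {
    cell_links.assign(ncell + 1, std::vector<int>());
    for (size_t i = 0; i < la.size(); ++i) {
      cell_links[la[i]].push_back((int)i);
      cell_links[lb[i]].push_back((int)i);
    }
  }

  void recompute_caches() {
    vol.assign(ncell + 1, 0.0);
    surf.assign(ncell + 1, 0.0);
    sum_x.assign(ncell + 1, 0.0);
    sum_y.assign(ncell + 1, 0.0);
    // circular mean of x per cell to choose an unwrap reference
    std::vector<double> cs(ncell + 1, 0.0), sn(ncell + 1, 0.0);
    for (int x = 0; x < nx; ++x) {
      double ang = 2.0 * M_PI * x / nx;
      double ca = std::cos(ang), sa = std::sin(ang);
      for (int y = 0; y < ny; ++y) {
        int c = lattice(y, x);
        if (c > 0) { cs[c] += ca; sn[c] += sa; }
      }
    }
    std::vector<double> ref(ncell + 1, 0.0);
    for (int c = 1; c <= ncell; ++c) {
      double ang = std::atan2(sn[c], cs[c]);
      if (ang < 0) ang += 2.0 * M_PI;
      ref[c] = ang * nx / (2.0 * M_PI);
    }
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        int c = lattice(y, x);
        if (c == 0) continue;
        vol[c] += 1.0;
        sum_x[c] += unwrap((double)x, ref[c]);
        sum_y[c] += (double)y;
        for (int k = 0; k < 4; ++k) {
          int qx = x + SHELL_DX[k], qy = y + SHELL_DY[k];
          if (qy < 0 || qy >= ny) continue;
          qx = (qx % nx + nx) % nx;
          if (lattice(qy, qx) != c) surf[c] += 1.0;
        }
      }
    }
  }

  double hamiltonian() const {
    double E = 0.0;
    for (int c = 1; c <= ncell; ++c) {
      int t = cell_type[c - 1];
      double dv = vol[c] - target_v[t - 1];
      double da = surf[c] - target_a[t - 1];
      E += lambda_v[t - 1] * dv * dv + lambda_s[t - 1] * da * da;
    }
    // contact: each unordered neighbor pair once (half shell)
    int ns = shell_size(order);
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        int c = lattice(y, x);
        for (int k = 0; k < ns; ++k) {
          int dx = SHELL_DX[k], dy = SHELL_DY[k];
          if (!(dy > 0 || (dy == 0 && dx > 0))) continue;
          int qy = y + dy;
          if (qy < 0 || qy >= ny) continue;
          int qx = ((x + dx) % nx + nx) % nx;
          E += pair_J(c, lattice(qy, qx));
        }
      }
    }
    for (size_t i = 0; i < la.size(); ++i)
      E += link_energy_of((int)i, com_x(la[i]), com_y(la[i]),
                          com_x(lb[i]), com_y(lb[i]));
    return E;
  }

  // Energy delta (volume+surface+contact+links) of copying owner `src` onto
  // pixel (tx,ty) currently owned by `old`, plus the migration-force bias.
  // Does not modify state.
  void attempt_delta(int tx, int ty, int old_c, int new_c,
                     double &d_core, double &d_force) const {
    d_core = 0.0;
    d_force = 0.0;
    // --- volume terms
    if (old_c > 0) {
      int t = cell_type[old_c - 1];
      double dv = vol[old_c] - target_v[t - 1];
      d_core += lambda_v[t - 1] * ((dv - 1.0) * (dv - 1.0) - dv * dv);
    }
    if (new_c > 0) {
      int t = cell_type[new_c - 1];
      double dv = vol[new_c] - target_v[t - 1];
      d_core += lambda_v[t - 1] * ((dv + 1.0) * (dv + 1.0) - dv * dv);
    }
    // --- surface deltas (order-1 pairs incident to the flipped pixel)
    int ids[6]; double ds[6]; int nids = 0;
    // accumulate per-cell surface change in a tiny map
    struct Acc {
      int *ids; double *ds; int *n;
      void add(int c, double v) {
        if (c == 0 || v == 0.0) return;
        for (int i = 0; i < *n; ++i)
          if (ids[i] == c) { ds[i] += v; return; }
        ids[*n] = c; ds[*n] = v; (*n)++;
      }
    } acc = { ids, ds, &nids };
    for (int k = 0; k < 4; ++k) {
      int qx = tx + SHELL_DX[k], qy = ty + SHELL_DY[k];
      if (qy < 0 || qy >= ny) continue;
      qx = (qx % nx + nx) % nx;
      int w = lattice(qy, qx);
      acc.add(old_c, (w != old_c) ? -1.0 : 0.0);
      acc.add(new_c, (w != new_c) ? 1.0 : 0.0);
      // neighbor's own boundary pair with the flipped pixel
      double before = (w != old_c) ? 1.0 : 0.0;
      double after = (w != new_c) ? 1.0 : 0.0;
      acc.add(w, after - before);
    }
    for (int i = 0; i < nids; ++i) {
      int c = ids[i];
      int t = cell_type[c - 1];
      if (lambda_s[t - 1] == 0.0) continue;
      double da = surf[c] - target_a[t - 1];
      double da2 = da + ds[i];
      d_core += lambda_s[t - 1] * (da2 * da2 - da * da);
    }
    // --- contact delta over the configured shell
    int nsh = shell_size(order);
    for (int k = 0; k < nsh; ++k) {
      int qy = ty + SHELL_DY[k];
      if (qy < 0 || qy >= ny) continue;
      int qx = ((tx + SHELL_DX[k]) % nx + nx) % nx;
      int w = lattice(qy, qx);
      d_core += pair_J(new_c, w) - pair_J(old_c, w);
    }
    // --- link + force terms via center-of-mass shifts
    double ox_new = 0, oy_new = 0, nx_new = 0, ny_new = 0;
    bool old_moves = (old_c > 0 && vol[old_c] > 1.0);
    bool new_moves = (new_c > 0);
    if (old_moves) {
      double xs = unwrap((double)tx, com_x(old_c));
      ox_new = (sum_x[old_c] - xs) / (vol[old_c] - 1.0);
      oy_new = (sum_y[old_c] - (double)ty) / (vol[old_c] - 1.0);
      int t = cell_type[old_c - 1];
      if (force_x[t - 1] != 0.0)
        d_force += force_x[t - 1] * (ox_new - com_x(old_c));
    }
    if (new_moves) {
      double xs = unwrap((double)tx, com_x(new_c));
      nx_new = (sum_x[new_c] + xs) / (vol[new_c] + 1.0);
      ny_new = (sum_y[new_c] + (double)ty) / (vol[new_c] + 1.0);
      int t = cell_type[new_c - 1];
      if (force_x[t - 1] != 0.0)
        d_force += force_x[t - 1] * (nx_new - com_x(new_c));
    }
    if ((old_moves && !cell_links[old_c].empty()) ||
        (new_moves && !cell_links[new_c].empty())) {
      std::unordered_set<int> seen;
      for (int pass = 0; pass < 2; ++pass) {
        int c = pass == 0 ? old_c : new_c;
        bool moves = pass == 0 ? old_moves : new_moves;
        if (!moves) continue;
        for (size_t j = 0; j < cell_links[c].size(); ++j) {
          int li = cell_links[c][j];
          if (!seen.insert(li).second) continue;
          int a = la[li], b = lb[li];
          double ax = com_x(a), ay = com_y(a), bx = com_x(b), by = com_y(b);
          double before = link_energy_of(li, ax, ay, bx, by);
          if (a == old_c && old_moves) { ax = ox_new; ay = oy_new; }
          if (a == new_c && new_moves) { ax = nx_new; ay = ny_new; }
          if (b == old_c && old_moves) { bx = ox_new; by = oy_new; }
          if (b == new_c && new_moves) { bx = nx_new; by = ny_new; }
          d_core += link_energy_of(li, ax, ay, bx, by) - before;
        }
      }
    }
  }

  // apply an accepted copy: new_c takes pixel (tx,ty) from old_c
  void apply_copy(int tx, int ty, int old_c, int new_c) {
    // surface updates (same accounting as attempt_delta)
    for (int k = 0; k < 4; ++k) {
      int qx = tx + SHELL_DX[k], qy = ty + SHELL_DY[k];
      if (qy < 0 || qy >= ny) continue;
      qx = (qx % nx + nx) % nx;
      int w = lattice(qy, qx);
      if (old_c > 0 && w != old_c) surf[old_c] -= 1.0;
      if (new_c > 0 && w != new_c) surf[new_c] += 1.0;
      if (w > 0) surf[w] += ((w != new_c) ? 1.0 : 0.0) - ((w != old_c) ? 1.0 : 0.0);
    }
    if (old_c > 0) {
      double xs = unwrap((double)tx, com_x(old_c));
      sum_x[old_c] -= xs; sum_y[old_c] -= (double)ty; vol[old_c] -= 1.0;
    }
    if (new_c > 0) {
      double xs = unwrap((double)tx, com_x(new_c));
      sum_x[new_c] += xs; sum_y[new_c] += (double)ty; vol[new_c] += 1.0;
      // keep the unwrapped center near the principal domain
      double cx = com_x(new_c);
      if (cx < -nx || cx >= 2.0 * nx) {
        double shift = nx * std::floor(cx / nx);
        sum_x[new_c] -= shift * vol[new_c];
      }
    }
    lattice(ty, tx) = new_c;
  }

  // break over-stretched external links; re-form reformable classes on contact
  void update_links(const IntegerVector &rc_ta, const IntegerVector &rc_tb,
                    const NumericVector &rc_str, const NumericVector &rc_tgt,
                    const NumericVector &rc_max, const IntegerVector &rc_id) {
    // 1. rupture
    size_t keep = 0;
    for (size_t i = 0; i < la.size(); ++i) {
      bool ok = true;
      if (!linternal[i]) {
        double l = link_len(com_x(la[i]), com_y(la[i]),
                            com_x(lb[i]), com_y(lb[i]));
        if (l > lmax[i]) ok = false;
      }
      if (ok) {
        la[keep] = la[i]; lb[keep] = lb[i]; lstr[keep] = lstr[i];
        ltgt[keep] = ltgt[i]; lmax[keep] = lmax[i];
        linternal[keep] = linternal[i]; lclass[keep] = lclass[i];
        ++keep;
      }
    }
    la.resize(keep); lb.resize(keep); lstr.resize(keep); ltgt.resize(keep);
    lmax.resize(keep); linternal.resize(keep); lclass.resize(keep);

    if (rc_ta.size() > 0) {
      // 2. existing-pair set
      std::unordered_set<long long> have;
      for (size_t i = 0; i < la.size(); ++i) {
        int a = std::min(la[i], lb[i]), b = std::max(la[i], lb[i]);
        have.insert((long long)a * (ncell + 1) + b);
      }
      // 3. adjacency scan (order-1) restricted to reformable-class types
      std::unordered_set<long long> adj;
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          int c = lattice(y, x);
          if (c == 0) continue;
          for (int k = 0; k < 4; ++k) {
            int dx = SHELL_DX[k], dy = SHELL_DY[k];
            if (!(dy > 0 || (dy == 0 && dx > 0))) continue;
            int qy = y + dy;
            if (qy < 0 || qy >= ny) continue;
            int qx = ((x + dx) % nx + nx) % nx;
            int w = lattice(qy, qx);
            if (w == 0 || w == c) continue;
            int a = std::min(c, w), b = std::max(c, w);
            adj.insert((long long)a * (ncell + 1) + b);
          }
        }
      }
      for (std::unordered_set<long long>::iterator it = adj.begin();
           it != adj.end(); ++it) {
        int a = (int)(*it / (ncell + 1)), b = (int)(*it % (ncell + 1));
        if (have.count(*it)) continue;
        int ta = cell_type[a - 1], tb = cell_type[b - 1];
        for (int r = 0; r < rc_ta.size(); ++r) {
          if ((ta == rc_ta[r] && tb == rc_tb[r]) ||
              (ta == rc_tb[r] && tb == rc_ta[r])) {
            la.push_back(a); lb.push_back(b);
            lstr.push_back(rc_str[r]); ltgt.push_back(rc_tgt[r]);
            lmax.push_back(rc_max[r]); linternal.push_back(0);
            lclass.push_back(rc_id[r]);
            have.insert(*it);
            break;
          }
        }
      }
    }
    rebuild_cell_links();
  }
};

static CPM make_cpm(IntegerMatrix lattice, IntegerVector cell_type,
                    IntegerVector composite, List types, NumericMatrix contacts,
                    NumericMatrix contacts_int, List links, int order) {
  CPM m;
  m.lattice = lattice;
  m.ny = lattice.nrow(); m.nx = lattice.ncol();
  m.cell_type = cell_type;
  m.composite = composite;
  m.ncell = cell_type.size();
  m.lambda_v = types["lambda_volume"];
  m.target_v = types["target_volume"];
  m.lambda_s = types["lambda_surface"];
  m.target_a = types["target_surface"];
  m.force_x = types["migration_force_x"];
  m.frozen = types["frozen"];
  m.ntypes = m.lambda_v.size();
  m.contacts = contacts;
  m.contacts_int = contacts_int;
  m.order = order;
  IntegerVector a = links["cell_a"], b = links["cell_b"], cls = links["class_id"];
  NumericVector s = links["strength"], t = links["target_length"],
                mx = links["max_length"];
  LogicalVector internal = links["internal"];
  m.la.assign(a.begin(), a.end());
  m.lb.assign(b.begin(), b.end());
  m.lstr.assign(s.begin(), s.end());
  m.ltgt.assign(t.begin(), t.end());
  m.lmax.assign(mx.begin(), mx.end());
  m.lclass.assign(cls.begin(), cls.end());
  m.linternal.resize(internal.size());
  for (int i = 0; i < internal.size(); ++i) m.linternal[i] = internal[i] ? 1 : 0;
  m.recompute_caches();
  m.rebuild_cell_links();
  return m;
}

static DataFrame links_df(const CPM &m) {
  int n = (int)m.la.size();
  IntegerVector a(n), b(n), cls(n);
  NumericVector s(n), t(n), mx(n);
  LogicalVector internal(n);
  for (int i = 0; i < n; ++i) {
    a[i] = m.la[i]; b[i] = m.lb[i]; s[i] = m.lstr[i]; t[i] = m.ltgt[i];
    mx[i] = m.lmax[i]; internal[i] = m.linternal[i] != 0; cls[i] = m.lclass[i];
  }
  return DataFrame::create(_["cell_a"] = a, _["cell_b"] = b,
                           _["strength"] = s, _["target_length"] = t,
                           _["max_length"] = mx, _["internal"] = internal,
                           _["class_id"] = cls);
}

// [[Rcpp::export]]
List cpp_caches(IntegerMatrix lattice, IntegerVector cell_type,
                IntegerVector composite, List types, NumericMatrix contacts,
                NumericMatrix contacts_int, List links, int order) {
  CPM m = make_cpm(lattice, cell_type, composite, types, contacts,
                   contacts_int, links, order);
  int n = m.ncell;
  NumericVector vol(n), surf(n), cx(n), cy(n);
  for (int c = 1; c <= n; ++c) {
    vol[c - 1] = m.vol[c]; surf[c - 1] = m.surf[c];
    if (m.vol[c] > 0) {
      double x = m.com_x(c);
      x -= m.nx * std::floor(x / m.nx);
      cx[c - 1] = x; cy[c - 1] = m.com_y(c);
    } else {
      cx[c - 1] = NA_REAL; cy[c - 1] = NA_REAL;
    }
  }
  return List::create(_["volume"] = vol, _["surface"] = surf,
                      _["com_x"] = cx, _["com_y"] = cy);
}

// [[Rcpp::export]]
double cpp_hamiltonian(IntegerMatrix lattice, IntegerVector cell_type,
                       IntegerVector composite, List types,
                       NumericMatrix contacts, NumericMatrix contacts_int,
                       List links, int order) {
  CPM m = make_cpm(lattice, cell_type, composite, types, contacts,
                   contacts_int, links, order);
  return m.hamiltonian();
}

// [[Rcpp::export]]
NumericVector cpp_delta_J(IntegerMatrix lattice, IntegerVector cell_type,
                          IntegerVector composite, List types,
                          NumericMatrix contacts, NumericMatrix contacts_int,
                          List links, int order,
                          int sx, int sy, int tx, int ty) {
  CPM m = make_cpm(lattice, cell_type, composite, types, contacts,
                   contacts_int, links, order);
  int old_c = m.lattice(ty, tx), new_c = m.lattice(sy, sx);
  if (old_c == new_c)
    return NumericVector::create(_["core"] = 0.0, _["force"] = 0.0);
  double dc, df;
  m.attempt_delta(tx, ty, old_c, new_c, dc, df);
  return NumericVector::create(_["core"] = dc, _["force"] = df);
}

// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix lattice, IntegerVector cell_type,
                 IntegerVector composite, List types, NumericMatrix contacts,
                 NumericMatrix contacts_int, List links, List reform_classes,
                 double temperature, double threshold, int order, int n_mcs) {
  CPM m = make_cpm(clone(lattice), cell_type, composite, types, contacts,
                   contacts_int, links, order);
  IntegerVector rc_ta = reform_classes["type_a"],
                rc_tb = reform_classes["type_b"],
                rc_id = reform_classes["class_id"];
  NumericVector rc_str = reform_classes["strength"],
                rc_tgt = reform_classes["target_length"],
                rc_max = reform_classes["max_length"];

  long long attempts = 0, accepted = 0;
  int n_sites = m.nx * m.ny;
  for (int step = 0; step < n_mcs; ++step) {
    for (int it = 0; it < n_sites; ++it) {
      ++attempts;
      int idx = (int)(unif_rand() * n_sites);
      if (idx >= n_sites) idx = n_sites - 1;
      int tx = idx / m.ny, ty = idx % m.ny;
      int dir = (int)(unif_rand() * 4.0);
      if (dir > 3) dir = 3;
      int sy = ty + SHELL_DY[dir];
      if (sy < 0 || sy >= m.ny) continue;
      int sx = ((tx + SHELL_DX[dir]) % m.nx + m.nx) % m.nx;
      int old_c = m.lattice(ty, tx), new_c = m.lattice(sy, sx);
      if (old_c == new_c) continue;
      if (old_c > 0 && m.frozen[m.cell_type[old_c - 1] - 1]) continue;
      if (new_c > 0 && m.frozen[m.cell_type[new_c - 1] - 1]) continue;
      if (old_c > 0 && m.vol[old_c] <= 1.0) continue; // no annihilation
      double dc, df;
      m.attempt_delta(tx, ty, old_c, new_c, dc, df);
      double delta = dc + df;
      bool accept = delta <= threshold;
      if (!accept)
        accept = unif_rand() < std::exp(-(delta - threshold) / temperature);
      if (accept) {
        m.apply_copy(tx, ty, old_c, new_c);
        ++accepted;
      }
    }
    m.update_links(rc_ta, rc_tb, rc_str, rc_tgt, rc_max, rc_id);
  }
  return List::create(_["lattice"] = m.lattice, _["links"] = links_df(m),
                      _["attempts"] = (double)attempts,
                      _["accepted"] = (double)accepted);
}

// [[Rcpp::export]]
List cpp_update_links(IntegerMatrix lattice, IntegerVector cell_type,
                      IntegerVector composite, List types,
                      NumericMatrix contacts, NumericMatrix contacts_int,
                      List links, List reform_classes, int order) {
  CPM m = make_cpm(lattice, cell_type, composite, types, contacts,
                   contacts_int, links, order);
  IntegerVector rc_ta = reform_classes["type_a"],
                rc_tb = reform_classes["type_b"],
                rc_id = reform_classes["class_id"];
  NumericVector rc_str = reform_classes["strength"],
                rc_tgt = reform_classes["target_length"],
                rc_max = reform_classes["max_length"];
  m.update_links(rc_ta, rc_tb, rc_str, rc_tgt, rc_max, rc_id);
  return List::create(_["links"] = links_df(m));
}

// unordered cell-id pairs sharing at least one order-1 boundary pixel pair
// [[Rcpp::export]]
IntegerMatrix cpp_adjacent_cells(IntegerMatrix lattice) {
  int ny = lattice.nrow(), nx = lattice.ncol();
  std::unordered_set<long long> adj;
  long long stride = 1;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      if (lattice(y, x) >= stride) stride = lattice(y, x);
  stride += 1;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      int c = lattice(y, x);
      if (c == 0) continue;
      for (int k = 0; k < 4; ++k) {
        int dx = SHELL_DX[k], dy = SHELL_DY[k];
        if (!(dy > 0 || (dy == 0 && dx > 0))) continue;
        int qy = y + dy;
        if (qy < 0 || qy >= ny) continue;
        int qx = ((x + dx) % nx + nx) % nx;
        int w = lattice(qy, qx);
        if (w == 0 || w == c) continue;
        long long a = std::min(c, w), b = std::max(c, w);
        adj.insert(a * stride + b);
      }
    }
  }
  IntegerMatrix out((int)adj.size(), 2);
  int i = 0;
  for (std::unordered_set<long long>::iterator it = adj.begin();
       it != adj.end(); ++it, ++i) {
    out(i, 0) = (int)(*it / stride);
    out(i, 1) = (int)(*it % stride);
  }
  return out;
}
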