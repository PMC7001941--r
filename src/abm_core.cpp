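// Off-lattice agent-based engine for cell aggregation in a 2D periodic box.
// All randomness goes through R's RNG (unif_rand) in a fixed draw order, so a
// run is bit-reproducible from set.seed() at the R level.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double CONTACT_TOL = 1e-6;   // slack on the neighbor relation (um)
static const double HARD_TOL    = 1e-9;   // slack on the hard-core constraint (um)

inline double wrap1(double x, double L) {
  double r = x - L * std::floor(x / L);
  if (r < 0.0) r += L;
  if (r >= L) r = 0.0;  // guard rounding at the upper edge
  return r;
}

inline double mimg(double dx, double L) {
  return dx - L * std::round(dx / L);
}

inline double deg2rad(double a) { return a * M_PI / 180.0; }

// ---------------------------------------------------------------------------
// Uniform-bin neighbor grid.  Bin width >= query radius, so a 3x3 bin
// neighborhood covers every query; degenerates to brute force in tiny boxes.
struct BinGrid {
  double L, w;
  int n;
  bool brute;
  std::vector< std::vector<int> > bins;
  std::vector<int> binof;

  void init(double L_, double rq, int reserve_n) {
    L = L_;
    n = (rq > 0.0) ? (int)std::floor(L / rq) : 0;
    if (n < 4) { brute = true; n = 1; }
    else brute = false;
    w = L / n;
    bins.assign((size_t)n * n, std::vector<int>());
    binof.clear();
    binof.reserve(reserve_n);
  }
  int idx(double x, double y) const {
    if (brute) return 0;
    int ix = (int)(x / w); if (ix >= n) ix = n - 1; if (ix < 0) ix = 0;
    int iy = (int)(y / w); if (iy >= n) iy = n - 1; if (iy < 0) iy = 0;
    return iy * n + ix;
  }
  void insert(int i, double x, double y) {
    int b = idx(x, y);
    bins[b].push_back(i);
    if ((int)binof.size() <= i) binof.resize(i + 1, -1);
    binof[i] = b;
  }
  void move(int i, double x, double y) {
    int b = idx(x, y);
    if (b == binof[i]) return;
    std::vector<int> &v = bins[binof[i]];
    v.erase(std::find(v.begin(), v.end(), i));
    bins[b].push_back(i);
    binof[i] = b;
  }
  // visit candidate indices near (x, y); guaranteed superset of all points
  // within distance w of (x, y)
  template <class F>
  void for_near(double x, double y, F f) const {
    if (brute) {
      for (int j : bins[0]) f(j);
      return;
    }
    int ix = (int)(x / w); if (ix >= n) ix = n - 1; if (ix < 0) ix = 0;
    int iy = (int)(y / w); if (iy >= n) iy = n - 1; if (iy < 0) iy = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = (iy + dy + n) % n;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = (ix + dx + n) % n;
        for (int j : bins[(size_t)yy * n + xx]) f(j);
      }
    }
  }
};

struct UnionFind {
  std::vector<int> p;
  UnionFind(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int i) { while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; } return i; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
};

// ---------------------------------------------------------------------------
// Geometry helpers

// Smallest travel t in [0, step] at which a center moving from (x,y) along
// unit direction (ux,uy) reaches distance dmin of any candidate; returns step
// when unobstructed.
static double min_truncation(double x, double y, double ux, double uy,
                             double step, double dmin, double L,
                             const std::vector<double> &px,
                             const std::vector<double> &py,
                             const std::vector<int> &cand, int self) {
  double tbest = step;
  double dmin2 = dmin * dmin;
  for (int j : cand) {
    if (j == self) continue;
    double wx = mimg(px[j] - x, L), wy = mimg(py[j] - y, L);
    double b = wx * ux + wy * uy;          // projection of blocker on the ray
    if (b <= 0.0) continue;                // receding or perpendicular contact
    double d2 = wx * wx + wy * wy;
    double disc = b * b - (d2 - dmin2);
    if (disc < 0.0) continue;              // ray misses the dmin-circle
    double t = b - std::sqrt(disc);
    if (t < 0.0) t = 0.0;                  // started at (or within tol of) contact
    if (t < tbest) tbest = t;
  }
  return tbest;
}

// circular (angular) per-axis mean of member coordinates under periodicity
static void circ_com(const std::vector<int> &members,
                     const std::vector<double> &px,
                     const std::vector<double> &py,
                     double L, double &cx, double &cy) {
  double k = 2.0 * M_PI / L;
  double Cx = 0, Sx = 0, Cy = 0, Sy = 0;
  for (int i : members) {
    Cx += std::cos(k * px[i]); Sx += std::sin(k * px[i]);
    Cy += std::cos(k * py[i]); Sy += std::sin(k * py[i]);
  }
  cx = wrap1(std::atan2(Sx, Cx) / k, L);
  cy = wrap1(std::atan2(Sy, Cy) / k, L);
}

inline double runif01() { return unif_rand(); }

// draw from U[center - hw, center + hw] (degrees), reduced mod 360
inline double sample_sector(double center, double hw) {
  double a = center + hw * (2.0 * runif01() - 1.0);
  a -= 360.0 * std::floor(a / 360.0);
  return a;
}

// ---------------------------------------------------------------------------
// Exported primitives (thin, used by R-level operation wrappers and tests)

// [[Rcpp::export]]
NumericMatrix cpp_wrap(NumericMatrix p, double L) {
  NumericMatrix out(p.nrow(), 2);
  for (int i = 0; i < p.nrow(); ++i) {
    if (!R_finite(p(i, 0)) || !R_finite(p(i, 1)))
      stop("non-finite coordinate");
    out(i, 0) = wrap1(p(i, 0), L);
    out(i, 1) = wrap1(p(i, 1), L);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_truncated_move(NumericVector p, double angle_deg, double step,
                                 NumericMatrix others, double dmin, double L) {
  double th = deg2rad(angle_deg);
  double ux = std::cos(th), uy = std::sin(th);
  int m = others.nrow();
  std::vector<double> px(m), py(m);
  std::vector<int> cand(m);
  for (int j = 0; j < m; ++j) { px[j] = others(j, 0); py[j] = others(j, 1); cand[j] = j; }
  double t = min_truncation(p[0], p[1], ux, uy, step, dmin, L, px, py, cand, -1);
  return NumericVector::create(wrap1(p[0] + t * ux, L), wrap1(p[1] + t * uy, L));
}

// all unordered index pairs (1-based) with minimal-image distance <= contact
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, double contact, double L) {
  int nc = pos.nrow();
  std::vector<double> px(nc), py(nc);
  BinGrid g;
  g.init(L, contact, nc);
  for (int i = 0; i < nc; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    g.insert(i, px[i], py[i]);
  }
  double c2 = contact * contact;
  std::vector<int> ia, ja;
  for (int i = 0; i < nc; ++i) {
    g.for_near(px[i], py[i], [&](int j) {
      if (j <= i) return;
      double dx = mimg(px[j] - px[i], L), dy = mimg(py[j] - py[i], L);
      if (dx * dx + dy * dy <= c2) { ia.push_back(i + 1); ja.push_back(j + 1); }
    });
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) { out(k, 0) = ia[k]; out(k, 1) = ja[k]; }
  return out;
}

// connected components from an edge list; labels 1..k in order of first
// appearance by row index
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerMatrix pairs) {
  UnionFind uf(n);
  for (int e = 0; e < pairs.nrow(); ++e) {
    int a = pairs(e, 0) - 1, b = pairs(e, 1) - 1;
    if (a < 0 || a >= n || b < 0 || b >= n) stop("pair index out of range");
    uf.unite(a, b);
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// ---------------------------------------------------------------------------
// World initialization: uniform rejection sampling under the hard-core radius

// [[Rcpp::export]]
NumericMatrix cpp_init_world(int n0, double L, double dmin, int max_attempts) {
  NumericMatrix pos(n0, 2);
  std::vector<double> px, py;
  px.reserve(n0); py.reserve(n0);
  BinGrid g;
  g.init(L, std::max(dmin, 1e-12), n0);
  double d2 = dmin * dmin;
  int attempts = 0;
  for (int i = 0; i < n0; ++i) {
    for (;;) {
      if (++attempts > max_attempts)
        stop("init_world: could not place %d cells at hard-core distance %g in a box of side %g (placed %d after %d attempts); reduce density",
             n0, dmin, L, i, max_attempts);
      double x = runif01() * L, y = runif01() * L;
      bool ok = true;
      g.for_near(x, y, [&](int j) {
        if (!ok) return;
        double dx = mimg(px[j] - x, L), dy = mimg(py[j] - y, L);
        if (dx * dx + dy * dy < d2 - HARD_TOL) ok = false;
      });
      if (ok) {
        px.push_back(x); py.push_back(y);
        g.insert(i, x, y);
        pos(i, 0) = x; pos(i, 1) = y;
        break;
      }
    }
  }
  return pos;
}

// ---------------------------------------------------------------------------
// One full iteration of the update loop.
//
// Draw order (fixed, documented): (1) one direction per aggregate of size >= 2
// in order of smallest member index; (2) a Fisher-Yates permutation of the
// cells present at iteration start; (3) per visited cell: one direction draw,
// one proliferation Bernoulli draw, and one placement angle if division is
// engaged.
//
// par: L, d, dmin, a0, kappa, compaction(bool), flux_on(bool), flux_dir(deg),
//      flux_scope(0 = individuals only, 1 = individuals and aggregates,
//      2 = individuals and small aggregates), small_threshold, cancel_mode
// [[Rcpp::export]]
List cpp_step_world(NumericMatrix pos, IntegerVector ids_in, int next_id, List par) {
  const double L      = as<double>(par["L"]);
  const double d      = as<double>(par["d"]);
  const double dmin   = as<double>(par["dmin"]);
  const double a0     = as<double>(par["a0"]);
  const double kappa  = as<double>(par["kappa"]);
  const bool compaction = as<bool>(par["compaction"]);
  const bool flux_on  = as<bool>(par["flux_on"]);
  const double flux_dir = as<double>(par["flux_dir"]);
  const int flux_scope = as<int>(par["flux_scope"]);
  const int small_thr  = as<int>(par["small_threshold"]);
  const bool cancel_mode = as<bool>(par["cancel_mode"]);

  const int n0 = pos.nrow();
  const double contact = d + CONTACT_TOL;
  std::vector<double> px(n0), py(n0);
  std::vector<int> ids(n0);
  for (int i = 0; i < n0; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); ids[i] = ids_in[i]; }

  // query radius must cover contact counting and move truncation
  const double rq = std::max(contact, a0 + dmin) + 1e-9;
  BinGrid g;
  g.init(L, rq, n0 + (int)(kappa * n0) + 8);
  for (int i = 0; i < n0; ++i) g.insert(i, px[i], py[i]);

  const double c2 = contact * contact;
  auto n_neighbors_at = [&](double x, double y, int self) {
    int cnt = 0;
    g.for_near(x, y, [&](int j) {
      if (j == self) return;
      double dx = mimg(px[j] - x, L), dy = mimg(py[j] - y, L);
      if (dx * dx + dy * dy <= c2) ++cnt;
    });
    return cnt;
  };

  // --- cluster labeling, frozen for this iteration --------------------------
  UnionFind uf(n0);
  for (int i = 0; i < n0; ++i) {
    g.for_near(px[i], py[i], [&](int j) {
      if (j <= i) return;
      double dx = mimg(px[j] - px[i], L), dy = mimg(py[j] - py[i], L);
      if (dx * dx + dy * dy <= c2) uf.unite(i, j);
    });
  }
  std::vector<int> lab(n0), csize;
  std::vector< std::vector<int> > members;
  {
    std::vector<int> remap(n0, -1);
    for (int i = 0; i < n0; ++i) {
      int r = uf.find(i);
      if (remap[r] < 0) { remap[r] = (int)members.size(); members.push_back({}); }
      lab[i] = remap[r];
      members[lab[i]].push_back(i);
    }
    csize.resize(members.size());
    for (size_t c = 0; c < members.size(); ++c) csize[c] = (int)members[c].size();
  }

  // --- phase 1: rigid collective move per aggregate -------------------------
  std::vector<char> in_cluster(n0, 0);
  for (size_t c = 0; c < members.size(); ++c) {
    int N = csize[c];
    if (N < 2) continue;
    bool fluxed = flux_on && (flux_scope == 1 || (flux_scope == 2 && N < small_thr));
    double ang = fluxed ? sample_sector(flux_dir, 90.0) : 360.0 * runif01();
    double th = deg2rad(ang);
    double ux = std::cos(th), uy = std::sin(th);
    double step = a0 / N;
    if (step <= 0.0) continue;
    // truncate against non-members only (rigid move preserves internal distances)
    for (int i : members[c]) in_cluster[i] = 1;
    double t = step;
    for (int i : members[c]) {
      std::vector<int> cand;
      g.for_near(px[i], py[i], [&](int j) { if (!in_cluster[j]) cand.push_back(j); });
      t = std::min(t, min_truncation(px[i], py[i], ux, uy, t, dmin, L, px, py, cand, i));
    }
    for (int i : members[c]) {
      px[i] = wrap1(px[i] + t * ux, L);
      py[i] = wrap1(py[i] + t * uy, L);
      g.move(i, px[i], py[i]);
    }
    for (int i : members[c]) in_cluster[i] = 0;
  }

  // --- phase 2: individual updates in a fresh random permutation ------------
  std::vector<int> perm(n0);
  for (int i = 0; i < n0; ++i) perm[i] = i;
  for (int i = n0 - 1; i > 0; --i) {
    int j = (int)(runif01() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }

  for (int k = 0; k < n0; ++k) {
    int i = perm[k];
    int c = lab[i];
    int N = csize[c];
    int n_cur = n_neighbors_at(px[i], py[i], i);

    // direction
    double ang;
    if (N >= 2) {
      if (compaction) {
        double cx, cy;
        circ_com(members[c], px, py, L, cx, cy);
        double vx = mimg(cx - px[i], L), vy = mimg(cy - py[i], L);
        double center = std::atan2(vy, vx) * 180.0 / M_PI;
        double hw = 90.0 * (1.0 + std::exp(-N / 40.0));
        ang = sample_sector(center, hw);
      } else {
        ang = 360.0 * runif01();
      }
    } else {
      ang = (flux_on) ? sample_sector(flux_dir, 90.0) : 360.0 * runif01();
    }

    double step = a0 / (1.0 + (double)n_cur * n_cur);
    double th = deg2rad(ang);
    double ux = std::cos(th), uy = std::sin(th);
    std::vector<int> cand;
    g.for_near(px[i], py[i], [&](int j) { if (j != i) cand.push_back(j); });
    double t = min_truncation(px[i], py[i], ux, uy, step, dmin, L, px, py, cand, i);
    if (cancel_mode && t < step) t = 0.0;
    if (t > 0.0) {
      double nx = wrap1(px[i] + t * ux, L), ny = wrap1(py[i] + t * uy, L);
      int n_new = n_neighbors_at(nx, ny, i);
      if (n_cur == 0 || n_new >= n_cur) {   // no-detachment rule
        px[i] = nx; py[i] = ny;
        g.move(i, nx, ny);
      }
    }

    // proliferation (daughters are obstacles immediately but are not updated
    // and do not divide this iteration)
    if (kappa > 0.0 && runif01() < kappa) {
      double pang = deg2rad(360.0 * runif01());
      double dx_ = wrap1(px[i] + d * std::cos(pang), L);
      double dy_ = wrap1(py[i] + d * std::sin(pang), L);
      bool ok = true;
      double d2 = dmin * dmin;
      g.for_near(dx_, dy_, [&](int j) {
        if (!ok) return;
        double ddx = mimg(px[j] - dx_, L), ddy = mimg(py[j] - dy_, L);
        if (ddx * ddx + ddy * ddy < d2 - HARD_TOL) ok = false;
      });
      if (ok) {
        int idx = (int)px.size();
        px.push_back(dx_); py.push_back(dy_);
        ids.push_back(next_id++);
        g.insert(idx, dx_, dy_);
      }
    }
  }

  int n = (int)px.size();
  NumericMatrix out(n, 2);
  IntegerVector oid(n);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; oid[i] = ids[i]; }
  return List::create(_["pos"] = out, _["ids"] = oid, _["next_id"] = next_id);
}

// minimum pairwise minimal-image distance (hard-core invariant checks)
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix pos, double L) {
  int n = pos.nrow();
  if (n < 2) return R_PosInf;
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(pos(j, 0) - pos(i, 0), L), dy = mimg(pos(j, 1) - pos(i, 1), L);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// Measurement: rasterize disks into a binary viewport and label components

// viewport anchored at the box origin: pixel (row r, col c), 1-based in R,
// has center ((c-0.5)*ps, (r-0.5)*ps); foreground iff within rad of any
// center under the minimal image convention
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(NumericMatrix pos, double rad, double ps,
                            double L, int width, int height) {
  IntegerMatrix mask(height, width);
  double r2 = rad * rad;
  for (int i = 0; i < pos.nrow(); ++i) {
    for (int ox = -1; ox <= 1; ++ox) {
      double cx = pos(i, 0) + ox * L;
      if (cx + rad < 0.0 || cx - rad > width * ps) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        double cy = pos(i, 1) + oy * L;
        if (cy + rad < 0.0 || cy - rad > height * ps) continue;
        int c0 = std::max(0, (int)std::floor((cx - rad) / ps - 0.5));
        int c1 = std::min(width - 1, (int)std::ceil((cx + rad) / ps - 0.5));
        int r0 = std::max(0, (int)std::floor((cy - rad) / ps - 0.5));
        int r1 = std::min(height - 1, (int)std::ceil((cy + rad) / ps - 0.5));
        for (int r = r0; r <= r1; ++r) {
          double yy = (r + 0.5) * ps - cy;
          for (int c = c0; c <= c1; ++c) {
            double xx = (c + 0.5) * ps - cx;
            if (xx * xx + yy * yy <= r2) mask(r, c) = 1;
          }
        }
      }
    }
  }
  return mask;
}

// two-pass union-find labeling of a binary mask; connectivity 4 or 8.
// wrap_x / wrap_y join the left-right / top-bottom seams: used when the
// viewport spans the full periodic box on that axis, so a disk straddling
// the seam stays one component (a cropped axis, like the 1080-px height of
// the experimental field, is left unwrapped)
// [[Rcpp::export]]
List cpp_label_mask(IntegerMatrix mask, int connectivity,
                    bool wrap_x, bool wrap_y) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  UnionFind uf(h * w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c)) continue;
      int id = r * w + c;
      if (c > 0 && mask(r, c - 1)) uf.unite(id, r * w + c - 1);
      if (r > 0 && mask(r - 1, c)) uf.unite(id, (r - 1) * w + c);
      if (connectivity == 8 && r > 0) {
        if (c > 0 && mask(r - 1, c - 1)) uf.unite(id, (r - 1) * w + c - 1);
        if (c < w - 1 && mask(r - 1, c + 1)) uf.unite(id, (r - 1) * w + c + 1);
      }
    }
  if (wrap_x && w > 1)
    for (int r = 0; r < h; ++r) {
      if (!mask(r, 0)) continue;
      if (mask(r, w - 1)) uf.unite(r * w, r * w + w - 1);
      if (connectivity == 8) {
        if (r > 0 && mask(r - 1, w - 1)) uf.unite(r * w, (r - 1) * w + w - 1);
        if (r < h - 1 && mask(r + 1, w - 1)) uf.unite(r * w, (r + 1) * w + w - 1);
      }
    }
  if (wrap_y && h > 1)
    for (int c = 0; c < w; ++c) {
      if (!mask(0, c)) continue;
      if (mask(h - 1, c)) uf.unite(c, (h - 1) * w + c);
      if (connectivity == 8) {
        if (c > 0 && mask(h - 1, c - 1)) uf.unite(c, (h - 1) * w + c - 1);
        if (c < w - 1 && mask(h - 1, c + 1)) uf.unite(c, (h - 1) * w + c + 1);
      }
    }
  if (wrap_x && wrap_y && connectivity == 8 && w > 1 && h > 1) {
    if (mask(0, 0) && mask(h - 1, w - 1)) uf.unite(0, (h - 1) * w + w - 1);
    if (mask(0, w - 1) && mask(h - 1, 0)) uf.unite(w - 1, (h - 1) * w);
  }
  std::vector<int> remap(h * w, 0);
  int next = 0;
  std::vector<int> sizes;
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c)) { lab(r, c) = 0; continue; }
      int root = uf.find(r * w + c);
      if (remap[root] == 0) { remap[root] = ++next; sizes.push_back(0); }
      lab(r, c) = remap[root];
      sizes[remap[root] - 1]++;
    }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// per-component perimeter: count of 4-neighbour pixel edges between the
// component and background (or the image border)
// [[Rcpp::export]]
NumericVector cpp_component_perimeter(IntegerMatrix lab, int ncomp) {
  NumericVector per(ncomp);
  int h = lab.nrow(), w = lab.ncol();
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      int l = lab(r, c);
      if (!l) continue;
      if (r == 0 || lab(r - 1, c) != l) per[l - 1] += 1.0;
      if (r == h - 1 || lab(r + 1, c) != l) per[l - 1] += 1.0;
      if (c == 0 || lab(r, c - 1) != l) per[l - 1] += 1.0;
      if (c == w - 1 || lab(r, c + 1) != l) per[l - 1] += 1.0;
    }
  return per;
}
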