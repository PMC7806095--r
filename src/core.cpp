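// Discrete-time engine for the tower-building lattice model.
//
// Geometry: L x L x inf cubic lattice, periodic in x and y, solid floor at
// z = 0.  Locked/covered agents at a pixel form a contiguous column
// z = 0..height-1; at most one free agent per pixel, sitting on the surface
// voxel z = height.  All randomness is drawn from R's RNG so that
// set.seed() in R makes a whole run reproducible.  Draw order per step:
// one uniform angle per free agent (agent-id order), tie-break draws inside
// direction selection, one Fisher-Yates shuffle of the free agents, collision
// fallback picks, then one Bernoulli per free agent and per uncovered locked
// agent (agent-id order).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DX8[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DY8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const double DNORM8[8] = {1.0, M_SQRT1_2, 1.0, M_SQRT1_2,
                                 1.0, M_SQRT1_2, 1.0, M_SQRT1_2};

enum AgentState { ST_FREE = 0, ST_LOCKED = 1, ST_COVERED = 2 };

static inline int imod(int v, int L) { int r = v % L; return r < 0 ? r + L : r; }

static inline int randInt(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Lattice direction (index into DX8/DY8) maximizing the cosine with v.
// Ties within a relative tolerance are broken uniformly at random; a zero
// vector returns -1 (stay).
static int selectDir(double vx, double vy) {
  if (vx == 0.0 && vy == 0.0) return -1;
  double s[8];
  double best = -1e300;
  for (int k = 0; k < 8; ++k) {
    s[k] = (vx * DX8[k] + vy * DY8[k]) * DNORM8[k];
    if (s[k] > best) best = s[k];
  }
  const double eps = 1e-9 * (std::fabs(best) + 1.0);
  int cand[8], nc = 0;
  for (int k = 0; k < 8; ++k)
    if (s[k] >= best - eps) cand[nc++] = k;
  return nc == 1 ? cand[0] : cand[randInt(nc)];
}

static int ufFind(std::vector<int>& up, int x) {
  while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; }
  return x;
}

// 8-connected components of the nonzero support of a height field,
// optionally merging across the periodic seam.  Labels are dense from 1 in
// scan order of the first pixel of each component.
static void labelHeights(const std::vector<int>& h, int L, bool wrap,
                         std::vector<int>& lab) {
  const int A = L * L;
  std::vector<int> up(A);
  for (int p = 0; p < A; ++p) up[p] = p;
  for (int y = 0; y < L; ++y) {
    for (int x = 0; x < L; ++x) {
      int p = x + L * y;
      if (h[p] == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int nx = x + DX8[k], ny = y + DY8[k];
        if (wrap) { nx = imod(nx, L); ny = imod(ny, L); }
        else if (nx < 0 || nx >= L || ny < 0 || ny >= L) continue;
        int q = nx + L * ny;
        if (h[q] > 0) {
          int a = ufFind(up, p), b = ufFind(up, q);
          if (a != b) up[std::max(a, b)] = std::min(a, b);
        }
      }
    }
  }
  lab.assign(A, 0);
  std::vector<int> dense(A, 0);
  int next = 0;
  for (int p = 0; p < A; ++p) {
    if (h[p] == 0) continue;
    int r = ufFind(up, p);
    if (dense[r] == 0) dense[r] = ++next;
    lab[p] = dense[r];
  }
}

struct Largest {
  double n_agents, hgt, area, eqd, aspect;
  int ntowers;
};

struct Engine {
  int L, N, A;
  double Pu, knl, Psl, attr;
  std::vector<int> height, freeAt;
  std::vector<std::vector<int> > column;
  std::vector<int> st, ax, ay, az;
  std::vector<int> nbr;   // per-pixel precomputed 8 wrapped neighbor pixels
  double t;

  std::vector<int> pdir, order, lockL, unlockL;

  void geom(int L_) {
    L = L_; A = L * L;
    nbr.assign((size_t)A * 8, 0);
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x) {
        int p = x + L * y;
        for (int k = 0; k < 8; ++k)
          nbr[(size_t)p * 8 + k] = imod(x + DX8[k], L) + L * imod(y + DY8[k], L);
      }
    height.assign(A, 0);
    freeAt.assign(A, -1);
    column.assign(A, std::vector<int>());
    t = 0.0;
  }

  // N free agents on uniformly random distinct pixels, z = 0
  void randomInit(int N_) {
    N = N_;
    if (N > A) stop("N exceeds L^2: no distinct starting pixels");
    st.assign(N, ST_FREE);
    ax.resize(N); ay.resize(N); az.assign(N, 0);
    std::vector<int> pix(A);
    for (int i = 0; i < A; ++i) pix[i] = i;
    for (int i = 0; i < N; ++i) {
      int j = i + randInt(A - i);
      std::swap(pix[i], pix[j]);
      ax[i] = pix[i] % L;
      ay[i] = pix[i] / L;
      freeAt[pix[i]] = i;
    }
  }

  inline int pixOf(int i) const { return ax[i] + L * ay[i]; }

  // Movement proposals from the pre-move configuration: Eq-style velocity
  // v = v_random (unit vector, uniform angle) + (c/n) * sum of horizontal
  // minimal-image offsets to all occupied voxels of the 26-neighborhood.
  void proposals() {
    pdir.assign(N, -1);
    for (int i = 0; i < N; ++i) {
      if (st[i] != ST_FREE) continue;
      const int z = az[i];
      const int* nb = &nbr[(size_t)pixOf(i) * 8];
      int nall = 0, sdx = 0, sdy = 0;
      for (int k = 0; k < 8; ++k) {
        const int q = nb[k], h = height[q];
        int lo = z - 1; if (lo < 0) lo = 0;
        int hi = z + 2; if (hi > h) hi = h;
        int cnt = hi - lo; if (cnt < 0) cnt = 0;   // locked voxels in column q within dz -1..+1
        if (freeAt[q] >= 0 && h >= z - 1 && h <= z + 1) ++cnt;  // free neighbor's voxel
        if (cnt) { nall += cnt; sdx += cnt * DX8[k]; sdy += cnt * DY8[k]; }
      }
      if (z > 0) ++nall;   // supporting locked voxel directly below: zero offset
      double ang = 2.0 * M_PI * unif_rand();
      double vx = std::cos(ang), vy = std::sin(ang);
      if (nall > 0) {
        vx += attr * (double)sdx / (double)nall;
        vy += attr * (double)sdy / (double)nall;
      }
      pdir[i] = selectDir(vx, vy);
    }
  }

  inline void moveTo(int i, int from, int to) {
    freeAt[from] = -1;
    if (height[from] > 0) st[column[from].back()] = ST_LOCKED;   // uncovered
    freeAt[to] = i;
    ax[i] = to % L; ay[i] = to / L; az[i] = height[to];
    if (height[to] > 0) st[column[to].back()] = ST_COVERED;
  }

  // Sequential resolution in fresh random order.  Climb rule: reject if the
  // target column is more than one higher than the mover's own column.  If the
  // target surface voxel holds a free agent, sidestep uniformly among the 8
  // pixels adjacent to the target that are free-agent-free and satisfy the
  // climb rule from the mover's current column; stay if none qualifies.
  void resolve() {
    order.clear();
    for (int i = 0; i < N; ++i)
      if (st[i] == ST_FREE) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = randInt(i + 1);
      std::swap(order[i], order[j]);
    }
    for (size_t oi = 0; oi < order.size(); ++oi) {
      const int i = order[oi];
      const int d = pdir[i];
      if (d < 0) continue;
      const int p = pixOf(i);
      const int tgt = nbr[(size_t)p * 8 + d];
      const int hcur = height[p];
      if (height[tgt] > hcur + 1) continue;
      if (freeAt[tgt] >= 0) {
        int cand[8], nc = 0;
        const int* tnb = &nbr[(size_t)tgt * 8];
        for (int k = 0; k < 8; ++k) {
          int q = tnb[k];
          if (freeAt[q] < 0 && height[q] <= hcur + 1) cand[nc++] = q;
        }
        if (nc > 0) moveTo(i, p, cand[randInt(nc)]);
      } else {
        moveTo(i, p, tgt);
      }
    }
  }

  // Lock/unlock decisions all drawn from the post-move snapshot, then applied;
  // a lock this step does not raise neighbors' N_n until the next step.
  // Covered flags are maintained incrementally (they only change at the top of
  // a column) and therefore always reflect the "agent directly above" rule.
  void updateStates() {
    lockL.clear(); unlockL.clear();
    for (int i = 0; i < N; ++i) {
      if (st[i] == ST_FREE) {
        const int z = az[i];
        const int* nb = &nbr[(size_t)pixOf(i) * 8];
        int nl = (z > 0) ? 1 : 0;
        for (int k = 0; k < 8; ++k) {
          const int h = height[nb[k]];
          int lo = z - 1; if (lo < 0) lo = 0;
          int hi = z + 2; if (hi > h) hi = h;
          if (hi > lo) nl += hi - lo;
        }
        double pl = Psl + knl * (double)nl;
        if (pl > 1.0) pl = 1.0;
        if (pl > 0.0 && unif_rand() < pl) lockL.push_back(i);
      } else if (st[i] == ST_LOCKED) {
        if (Pu > 0.0 && unif_rand() < Pu) unlockL.push_back(i);
      }
    }
    for (size_t k = 0; k < unlockL.size(); ++k) {
      const int j = unlockL[k];
      const int p = pixOf(j);
      column[p].pop_back();
      height[p] -= 1;
      st[j] = ST_FREE;
      freeAt[p] = j;                    // az[j] already equals the new surface
      if (height[p] > 0) st[column[p].back()] = ST_COVERED;  // j stands above it
    }
    for (size_t k = 0; k < lockL.size(); ++k) {
      const int i = lockL[k];
      const int p = pixOf(i);
      if (height[p] > 0) st[column[p].back()] = ST_COVERED;
      freeAt[p] = -1;
      column[p].push_back(i);
      st[i] = ST_LOCKED;
      height[p] += 1;
    }
  }

  void step() {
    proposals();
    resolve();
    updateStates();
    t += 1.0;
  }

  // Largest-tower statistics of the current configuration: wrap-aware
  // 8-connected components of the height field; a tower's agent count
  // includes free agents standing on its footprint.
  Largest largestStats(std::vector<int>* keepLab = 0) const {
    std::vector<int> lab;
    labelHeights(height, L, true, lab);
    int nlab = 0;
    for (int p = 0; p < A; ++p) nlab = std::max(nlab, lab[p]);
    Largest out; out.n_agents = 0; out.hgt = 0; out.area = 0;
    out.eqd = 0; out.aspect = 0; out.ntowers = nlab;
    if (nlab > 0) {
      std::vector<int> agents(nlab + 1, 0), area(nlab + 1, 0), mh(nlab + 1, 0);
      for (int p = 0; p < A; ++p) {
        const int l = lab[p];
        if (!l) continue;
        area[l] += 1;
        agents[l] += height[p] + (freeAt[p] >= 0 ? 1 : 0);
        if (height[p] > mh[l]) mh[l] = height[p];
      }
      int bestl = 1;
      for (int l = 2; l <= nlab; ++l)
        if (agents[l] > agents[bestl]) bestl = l;   // ties keep the lowest label
      out.n_agents = agents[bestl];
      out.hgt = mh[bestl];
      out.area = area[bestl];
      out.eqd = 2.0 * std::sqrt(area[bestl] / M_PI);
      out.aspect = out.eqd > 0 ? out.hgt / out.eqd : 0.0;
    }
    if (keepLab) keepLab->swap(lab);
    return out;
  }

  void fromWorld(const List& world, double Pu_, double knl_, double Psl_, double c_) {
    IntegerMatrix hm = world["height"];
    if (hm.nrow() != hm.ncol()) stop("height map must be square");
    geom(hm.nrow());
    IntegerVector s = world["state"], x = world["x"], y = world["y"], z = world["z"];
    N = s.size();
    Pu = Pu_; knl = knl_; Psl = Psl_; attr = c_;
    t = as<double>(world["t"]);
    for (int p = 0; p < A; ++p) {
      int h = hm[p];
      if (h < 0) stop("negative height");
      height[p] = h;
      column[p].assign(h, -1);
    }
    st.assign(N, 0); ax.assign(N, 0); ay.assign(N, 0); az.assign(N, 0);
    for (int i = 0; i < N; ++i) {
      st[i] = s[i]; ax[i] = x[i]; ay[i] = y[i]; az[i] = z[i];
      if (ax[i] < 0 || ax[i] >= L || ay[i] < 0 || ay[i] >= L || az[i] < 0)
        stop("agent position out of range");
      const int p = pixOf(i);
      if (st[i] == ST_FREE) {
        if (az[i] != height[p]) stop("free agent not on the surface of its pixel");
        if (freeAt[p] >= 0) stop("two free agents on one pixel");
        freeAt[p] = i;
      } else {
        if (az[i] >= height[p]) stop("locked agent above its column height");
        if (column[p][az[i]] >= 0) stop("two agents in one voxel");
        column[p][az[i]] = i;
      }
    }
    for (int p = 0; p < A; ++p)
      for (size_t k = 0; k < column[p].size(); ++k)
        if (column[p][k] < 0) stop("column has a gap: heights inconsistent with agents");
  }

  List toWorld() const {
    IntegerMatrix hm(L, L);
    for (int p = 0; p < A; ++p) hm[p] = height[p];
    IntegerVector s(N), x(N), y(N), z(N);
    for (int i = 0; i < N; ++i) { s[i] = st[i]; x[i] = ax[i]; y[i] = ay[i]; z[i] = az[i]; }
    return List::create(_["height"] = hm, _["state"] = s, _["x"] = x,
                        _["y"] = y, _["z"] = z, _["t"] = t);
  }
};

// From-scratch invariant audit, independent of the engine's incremental
// bookkeeping: recomputes per-pixel stacks and coverage from the raw agent
// table and compares against the height field.
static std::vector<std::string> auditArrays(int L,
                                            const std::vector<int>& height,
                                            const std::vector<int>& st,
                                            const std::vector<int>& ax,
                                            const std::vector<int>& ay,
                                            const std::vector<int>& az) {
  std::vector<std::string> bad;
  const int A = L * L;
  const int N = (int)st.size();
  std::vector<std::vector<int> > zs(A);        // z of non-free agents per pixel
  std::vector<std::vector<int> > zst(A);       // their states
  std::vector<int> nfree(A, 0), freeZ(A, -1);
  long stacked = 0;
  for (int i = 0; i < N; ++i) {
    if (ax[i] < 0 || ax[i] >= L || ay[i] < 0 || ay[i] >= L || az[i] < 0) {
      bad.push_back("agent position out of range");
      return bad;
    }
    const int p = ax[i] + L * ay[i];
    if (st[i] == ST_FREE) {
      nfree[p] += 1;
      freeZ[p] = az[i];
    } else if (st[i] == ST_LOCKED || st[i] == ST_COVERED) {
      zs[p].push_back(az[i]);
      zst[p].push_back(st[i]);
      ++stacked;
    } else {
      bad.push_back("invalid agent state tag");
      return bad;
    }
  }
  long hsum = 0;
  for (int p = 0; p < A; ++p) {
    const int h = height[p];
    if (h < 0) bad.push_back("negative height");
    hsum += h;
    if (nfree[p] > 1) bad.push_back("more than one free agent on a pixel");
    if (nfree[p] == 1 && freeZ[p] != h)
      bad.push_back("free agent not at its pixel surface");
    if ((int)zs[p].size() != h) {
      bad.push_back("stack size differs from height");
      continue;
    }
    if (h == 0) continue;
    // order the column by z and check contiguity + coverage
    std::vector<int> idx(h);
    for (int k = 0; k < h; ++k) idx[k] = k;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return zs[p][a] < zs[p][b]; });
    bool contiguous = true;
    for (int k = 0; k < h; ++k)
      if (zs[p][idx[k]] != k) contiguous = false;
    if (!contiguous) {
      bad.push_back("stack z-indices not contiguous 0..height-1");
      continue;
    }
    for (int k = 0; k < h - 1; ++k)
      if (zst[p][idx[k]] != ST_COVERED)
        bad.push_back("buried agent not tagged covered");
    const int topst = zst[p][idx[h - 1]];
    if (nfree[p] == 1 && topst != ST_COVERED)
      bad.push_back("column top under a free agent not tagged covered");
    if (nfree[p] == 0 && topst != ST_LOCKED)
      bad.push_back("exposed column top not tagged locked");
  }
  if (hsum != stacked)
    bad.push_back("sum(height) differs from locked+covered count");
  return bad;
}

static std::vector<std::string> auditEngine(const Engine& e) {
  return auditArrays(e.L, e.height, e.st, e.ax, e.ay, e.az);
}

static NumericMatrix seriesMatrix(const std::vector<double>& rows, int nrow) {
  NumericMatrix m(nrow, 8);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 8; ++c)
      m(r, c) = rows[(size_t)r * 8 + c];
  colnames(m) = CharacterVector::create("t", "n_agents", "height", "base_area",
                                        "eq_diameter", "aspect_ratio",
                                        "n_towers", "n_locked");
  return m;
}

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(int L, int N, double Pu, double knl, double Psl, double c,
             int steps, int sampleInterval, bool recordMaps) {
  if (L < 3) stop("L must be at least 3");
  if (sampleInterval < 1) stop("sampleInterval must be positive");
  Engine e;
  e.geom(L);
  e.Pu = Pu; e.knl = knl; e.Psl = Psl; e.attr = c;
  e.randomInit(N);

  std::vector<double> rows;
  std::vector<int> maps;
  std::vector<double> stimes;
  int nsamp = 0;
  auto record = [&]() {
    Largest lg = e.largestStats();
    int nlocked = 0;
    for (int i = 0; i < N; ++i) if (e.st[i] != ST_FREE) ++nlocked;
    double r[8] = {e.t, lg.n_agents, lg.hgt, lg.area, lg.eqd, lg.aspect,
                   (double)lg.ntowers, (double)nlocked};
    rows.insert(rows.end(), r, r + 8);
    stimes.push_back(e.t);
    if (recordMaps) maps.insert(maps.end(), e.height.begin(), e.height.end());
    ++nsamp;
  };
  record();
  for (int s = 1; s <= steps; ++s) {
    e.step();
    if (s % sampleInterval == 0 || s == steps) record();
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["world"] = e.toWorld(),
      _["series"] = seriesMatrix(rows, nsamp),
      _["sample_t"] = NumericVector(stimes.begin(), stimes.end()));
  if (recordMaps) {
    IntegerVector mv(maps.begin(), maps.end());
    mv.attr("dim") = IntegerVector::create(L, L, nsamp);
    out["maps"] = mv;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_advance")]]
List cpp_advance(List world, double Pu, double knl, double Psl, double c,
                 int steps, bool audit) {
  Engine e;
  e.fromWorld(world, Pu, knl, Psl, c);
  if (audit) {
    std::vector<std::string> bad = auditEngine(e);
    if (!bad.empty()) stop("invariant violated at t=%f: %s", e.t, bad[0]);
  }
  for (int s = 0; s < steps; ++s) {
    e.step();
    if (audit) {
      std::vector<std::string> bad = auditEngine(e);
      if (!bad.empty()) stop("invariant violated at t=%f: %s", e.t, bad[0]);
    }
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return e.toWorld();
}

// [[Rcpp::export(name = ".cpp_audit", rng = false)]]
CharacterVector cpp_audit(List world) {
  IntegerMatrix hm = world["height"];
  if (hm.nrow() != hm.ncol()) return CharacterVector::create("height map must be square");
  const int L = hm.nrow();
  IntegerVector s = world["state"], x = world["x"], y = world["y"], z = world["z"];
  std::vector<int> height(hm.begin(), hm.end());
  std::vector<int> st(s.begin(), s.end()), ax(x.begin(), x.end()),
      ay(y.begin(), y.end()), az(z.begin(), z.end());
  std::vector<std::string> bad = auditArrays(L, height, st, ax, ay, az);
  return wrap(bad);
}

// [[Rcpp::export(name = ".cpp_label", rng = false)]]
IntegerMatrix cpp_label(IntegerMatrix hm, bool wrap) {
  if (hm.nrow() != hm.ncol()) stop("height map must be square");
  const int L = hm.nrow();
  std::vector<int> h(hm.begin(), hm.end()), lab;
  for (size_t p = 0; p < h.size(); ++p)
    if (h[p] < 0) stop("height map must be non-negative");
  labelHeights(h, L, wrap, lab);
  IntegerMatrix out(L, L);
  std::copy(lab.begin(), lab.end(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_select_move")]]
IntegerVector cpp_select_move(double vx, double vy) {
  if (!R_finite(vx) || !R_finite(vy)) stop("velocity components must be finite");
  int d = selectDir(vx, vy);
  if (d < 0) return IntegerVector::create(0, 0);
  return IntegerVector::create(DX8[d], DY8[d]);
}

// Occupied voxels of an agent's 26-neighborhood: counts of all agents and of
// locked+covered agents, plus the (dx, dy, dz) offsets of occupied voxels.
// [[Rcpp::export(name = ".cpp_neighborhood", rng = false)]]
List cpp_neighborhood(List world, int agent) {
  Engine e;
  e.fromWorld(world, 0, 0, 0, 0);
  if (agent < 0 || agent >= e.N) stop("agent index out of range");
  const int x = e.ax[agent], y = e.ay[agent], z = e.az[agent];
  int nall = 0, nlocked = 0;
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int k = -1; k < 8; ++k) {           // k = -1 is the own-pixel column
      const int dx = (k < 0) ? 0 : DX8[k];
      const int dy = (k < 0) ? 0 : DY8[k];
      if (dx == 0 && dy == 0 && dz == 0) continue;
      const int q = imod(x + dx, e.L) + e.L * imod(y + dy, e.L);
      const int zn = z + dz;
      if (zn < 0) continue;
      bool occL = zn < e.height[q];
      bool occF = !occL && e.freeAt[q] >= 0 && e.freeAt[q] != agent &&
                  zn == e.height[q];
      if (occL || occF) {
        ++nall;
        if (occL) ++nlocked;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }
    }
  }
  IntegerMatrix off(odx.size(), 3);
  for (size_t i = 0; i < odx.size(); ++i) {
    off(i, 0) = odx[i]; off(i, 1) = ody[i]; off(i, 2) = odz[i];
  }
  colnames(off) = CharacterVector::create("dx", "dy", "dz");
  return List::create(_["n_all"] = nall, _["n_locked"] = nlocked,
                      _["offsets"] = off);
}
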