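// 3-D lattice cellular automaton for protein complex assembly.
//
// Each lattice site holds at most one protein instance. A simulation step
// is an interaction phase (site-by-site bond breaking with probability
// p_off, then bond formation with probability p_on toward face-adjacent
// instances whose species interact) followed by a diffusion phase
// (site-by-site rigid rotation and translation of whole complexes, with
// probabilities 1/diameter and 1/mass and recursive mass-ratio pushes).
//
// Invariants maintained throughout:
//  - at most one instance per site; instance count constant;
//  - every bond joins face-adjacent instances whose species pair is an
//    edge of the rule network; at most 6 bonds per instance;
//  - each species occurs at most once per complex;
//  - the complex partition equals the connected components of the bond
//    graph at every phase boundary.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// face directions: +x,-x,+y,-y,+z,-z
static const int DIRX[6] = {1, -1, 0, 0, 0, 0};
static const int DIRY[6] = {0, 0, 1, -1, 0, 0};
static const int DIRZ[6] = {0, 0, 0, 0, 1, -1};

// ---- the 24 proper rotations of the cube -------------------------------
// Rotation = signed axis permutation with determinant +1, stored as the
// images of the x,y,z unit vectors. ROT24[0] is the identity.
struct Rot { int m[3][3]; };
static std::vector<Rot> ROT24;
static int ROT_GEN[6];          // indices of the six 90-degree generators
static std::vector<std::array<int, 24>> ROT_COMP; // ROT_COMP[g][o] = g*o

static void rot_apply(const Rot& R, int x, int y, int z,
                      int& ox, int& oy, int& oz) {
  ox = R.m[0][0] * x + R.m[0][1] * y + R.m[0][2] * z;
  oy = R.m[1][0] * x + R.m[1][1] * y + R.m[1][2] * z;
  oz = R.m[2][0] * x + R.m[2][1] * y + R.m[2][2] * z;
}

static Rot rot_mul(const Rot& A, const Rot& B) {
  Rot C{};
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      int s = 0;
      for (int k = 0; k < 3; k++) s += A.m[i][k] * B.m[k][j];
      C.m[i][j] = s;
    }
  return C;
}

static bool rot_eq(const Rot& A, const Rot& B) {
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      if (A.m[i][j] != B.m[i][j]) return false;
  return true;
}

static void init_rotations() {
  if (!ROT24.empty()) return;
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int p = 0; p < 6; p++)
    for (int sx = -1; sx <= 1; sx += 2)
      for (int sy = -1; sy <= 1; sy += 2)
        for (int sz = -1; sz <= 1; sz += 2) {
          Rot R{};
          int sgn[3] = {sx, sy, sz};
          for (int i = 0; i < 3; i++) R.m[i][perms[p][i]] = sgn[i];
          // determinant
          int det =
            R.m[0][0]*(R.m[1][1]*R.m[2][2]-R.m[1][2]*R.m[2][1]) -
            R.m[0][1]*(R.m[1][0]*R.m[2][2]-R.m[1][2]*R.m[2][0]) +
            R.m[0][2]*(R.m[1][0]*R.m[2][1]-R.m[1][1]*R.m[2][0]);
          if (det == 1) ROT24.push_back(R);
        }
  // move identity to index 0
  for (size_t i = 0; i < ROT24.size(); i++) {
    Rot I{}; I.m[0][0] = I.m[1][1] = I.m[2][2] = 1;
    if (rot_eq(ROT24[i], I)) { std::swap(ROT24[0], ROT24[i]); break; }
  }
  // the six 90-degree generators: +/-90 about each axis
  // about x: (y,z)->(-z,y); about y: (z,x)->(-x,z); about z: (x,y)->(-y,x)
  auto find_rot = [&](const Rot& R) {
    for (size_t i = 0; i < ROT24.size(); i++)
      if (rot_eq(ROT24[i], R)) return (int)i;
    return -1;
  };
  Rot gx{}, gxm{}, gy{}, gym{}, gz{}, gzm{};
  gx.m[0][0]=1;  gx.m[1][2]=-1; gx.m[2][1]=1;   // +90 about x
  gxm.m[0][0]=1; gxm.m[1][2]=1; gxm.m[2][1]=-1; // -90 about x
  gy.m[1][1]=1;  gy.m[0][2]=1;  gy.m[2][0]=-1;  // +90 about y
  gym.m[1][1]=1; gym.m[0][2]=-1; gym.m[2][0]=1; // -90 about y
  gz.m[2][2]=1;  gz.m[0][1]=-1; gz.m[1][0]=1;   // +90 about z
  gzm.m[2][2]=1; gzm.m[0][1]=1; gzm.m[1][0]=-1; // -90 about z
  ROT_GEN[0]=find_rot(gx); ROT_GEN[1]=find_rot(gxm);
  ROT_GEN[2]=find_rot(gy); ROT_GEN[3]=find_rot(gym);
  ROT_GEN[4]=find_rot(gz); ROT_GEN[5]=find_rot(gzm);
  ROT_COMP.resize(6);
  for (int g = 0; g < 6; g++)
    for (int o = 0; o < 24; o++) {
      Rot P = rot_mul(ROT24[ROT_GEN[g]], ROT24[o]);
      for (int i = 0; i < 24; i++)
        if (rot_eq(ROT24[i], P)) { ROT_COMP[g][o] = i; break; }
    }
}

// ---- RNG: xoshiro-free, plain splitmix64 + mt19937_64 kept simple ------
// A small deterministic 64-bit generator (splitmix64) so trajectories are
// bit-reproducible across platforms and compilers.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int bounded(int n) { // uniform on 0..n-1
    uint64_t r, lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    do { r = next(); } while (r >= lim);
    return (int)(r % (uint64_t)n);
  }
};

struct Complexx {
  std::vector<int> members;
  bool alive = false;
  long stamp = -1;   // diffusion-phase "already acted" marker
};

class Sim {
public:
  int L, nsite;
  bool periodic;
  double p_on, p_off;
  bool move_by_diameter;   // translation probability 1/diameter vs 1/mass
  int n_species;
  std::vector<uint8_t> adj;           // species adjacency, n_species^2
  std::vector<int> sp, px, py, pz, orient, comp;
  std::vector<std::array<int, 6>> bnd; // bonded partner per instance slot
  std::vector<int> nb;                 // bond counts
  std::vector<int> lat;                // site -> instance or -1
  std::vector<Complexx> comps;
  std::vector<int> free_comp;
  Rng rng;
  long step_count = 0;
  long phase_stamp = 0;
  // scratch
  std::vector<uint8_t> smark;   // per-species marks
  std::vector<int> ivis;        // per-instance visit stamps
  long ivis_stamp = 0;
  std::vector<long> site_stamp; // per-site marks (rotation target check)
  long site_stamp_ctr = 0;

  Sim(int L_, bool periodic_, double pon, double poff, bool bydiam,
      int nsp, const IntegerMatrix& edges, uint64_t seed)
    : L(L_), nsite(L_ * L_ * L_), periodic(periodic_), p_on(pon),
      p_off(poff), move_by_diameter(bydiam), n_species(nsp),
      adj((size_t)nsp * nsp, 0), lat(nsite, -1), rng(seed),
      smark(nsp, 0), site_stamp(nsite, 0) {
    init_rotations();
    if (periodic && L < 3) stop("periodic boundary requires L >= 3");
    if (L < 2) stop("L must be >= 2");
    for (int i = 0; i < edges.nrow(); i++) {
      int a = edges(i, 0), b = edges(i, 1);
      if (a < 0 || b < 0 || a >= nsp || b >= nsp) stop("edge endpoint out of range");
      adj[(size_t)a * nsp + b] = 1;
      adj[(size_t)b * nsp + a] = 1;
    }
  }

  int site_of(int x, int y, int z) const { return (z * L + y) * L + x; }
  bool interacts(int s1, int s2) const { return adj[(size_t)s1 * n_species + s2] != 0; }

  // neighbour site in direction d, or -1 outside a closed boundary
  int nbr(int site, int d) const {
    int x = site % L, y = (site / L) % L, z = site / (L * L);
    x += DIRX[d]; y += DIRY[d]; z += DIRZ[d];
    if (periodic) {
      x = (x + L) % L; y = (y + L) % L; z = (z + L) % L;
    } else if (x < 0 || x >= L || y < 0 || y >= L || z < 0 || z >= L) {
      return -1;
    }
    return site_of(x, y, z);
  }

  int new_complex() {
    int c;
    if (!free_comp.empty()) { c = free_comp.back(); free_comp.pop_back(); }
    else { comps.push_back(Complexx()); c = (int)comps.size() - 1; }
    comps[c].alive = true;
    comps[c].members.clear();
    comps[c].stamp = -1;
    return c;
  }

  int add_instance(int species, int x, int y, int z, int ori) {
    int s = site_of(x, y, z);
    if (lat[s] != -1) stop("site already occupied");
    int id = (int)sp.size();
    sp.push_back(species); px.push_back(x); py.push_back(y); pz.push_back(z);
    orient.push_back(ori);
    bnd.push_back({-1, -1, -1, -1, -1, -1});
    nb.push_back(0);
    int c = new_complex();
    comps[c].members.push_back(id);
    comp.push_back(c);
    lat[s] = id;
    ivis.push_back(0);
    return id;
  }

  void random_fill(double occupancy) {
    long n_inst = (long)std::llround(occupancy * (double)nsite);
    if (n_inst < 1) stop("occupancy x L^3 must be at least 1");
    if (n_inst > nsite) stop("occupancy must be <= 1");
    if (n_inst < n_species)
      stop("number of instances is below the number of species");
    // copy numbers as equal as possible; remainder to distinct random species
    long base = n_inst / n_species, rem = n_inst % n_species;
    std::vector<int> extra(n_species, 0);
    std::vector<int> ids(n_species);
    for (int i = 0; i < n_species; i++) ids[i] = i;
    for (long r = 0; r < rem; r++) {
      int j = (int)r + rng.bounded(n_species - (int)r);
      std::swap(ids[r], ids[j]);
      extra[ids[r]] = 1;
    }
    // uniform random subset of sites (partial Fisher-Yates)
    std::vector<int> sites(nsite);
    for (int i = 0; i < nsite; i++) sites[i] = i;
    for (long k = 0; k < n_inst; k++) {
      int j = (int)k + rng.bounded(nsite - (int)k);
      std::swap(sites[k], sites[j]);
    }
    long k = 0;
    for (int s = 0; s < n_species; s++) {
      long cnt = base + extra[s];
      for (long c = 0; c < cnt; c++, k++) {
        int site = sites[k];
        add_instance(s, site % L, (site / L) % L, site / (L * L),
                     rng.bounded(24));
      }
    }
  }

  bool is_bonded(int p, int q) const {
    for (int d = 0; d < 6; d++) if (bnd[p][d] == q) return true;
    return false;
  }

  // direction slot from p toward face-adjacent q
  int dir_between(int p, int q) const {
    int sp_ = site_of(px[p], py[p], pz[p]);
    for (int d = 0; d < 6; d++) if (nbr(sp_, d) == q_site(q)) return d;
    return -1;
  }
  int q_site(int q) const { return site_of(px[q], py[q], pz[q]); }

  bool species_compatible(int p, int q) {
    int ca = comp[p], cb = comp[q];
    if (ca == cb) return true;
    const std::vector<int>& A = comps[ca].members;
    const std::vector<int>& B = comps[cb].members;
    const std::vector<int>& small = (A.size() <= B.size()) ? A : B;
    const std::vector<int>& big = (A.size() <= B.size()) ? B : A;
    bool ok = true;
    for (int m : small) smark[sp[m]] = 1;
    for (int m : big) if (smark[sp[m]]) { ok = false; break; }
    for (int m : small) smark[sp[m]] = 0;
    return ok;
  }

  void add_bond(int p, int q) {
    int dp = dir_between(p, q);
    int dq = dir_between(q, p);
    if (dp < 0 || dq < 0) stop("internal: bond between non-adjacent instances");
    bnd[p][dp] = q; bnd[q][dq] = p;
    nb[p]++; nb[q]++;
    int ca = comp[p], cb = comp[q];
    if (ca != cb) {
      if (comps[ca].members.size() < comps[cb].members.size()) std::swap(ca, cb);
      for (int m : comps[cb].members) { comp[m] = ca; comps[ca].members.push_back(m); }
      comps[cb].alive = false;
      comps[cb].members.clear();
      free_comp.push_back(cb);
    }
  }

  void remove_bond(int p, int q) {
    for (int d = 0; d < 6; d++) if (bnd[p][d] == q) { bnd[p][d] = -1; nb[p]--; }
    for (int d = 0; d < 6; d++) if (bnd[q][d] == p) { bnd[q][d] = -1; nb[q]--; }
    // connectivity recheck restricted to the affected complex
    int c = comp[p];
    ivis_stamp++;
    std::vector<int> reach;
    reach.push_back(p); ivis[p] = (int)ivis_stamp;
    bool found_q = false;
    for (size_t h = 0; h < reach.size(); h++) {
      int u = reach[h];
      if (u == q) { found_q = true; break; }
      for (int d = 0; d < 6; d++) {
        int v = bnd[u][d];
        if (v >= 0 && ivis[v] != (int)ivis_stamp) {
          ivis[v] = (int)ivis_stamp;
          reach.push_back(v);
        }
      }
    }
    if (found_q) return;
    // split: instances reached from p keep c, the rest form a new complex
    int cn = new_complex();
    std::vector<int> keep;
    for (int m : comps[c].members) {
      if (ivis[m] == (int)ivis_stamp) keep.push_back(m);
      else { comp[m] = cn; comps[cn].members.push_back(m); }
    }
    comps[c].members.swap(keep);
  }

  // ---- phases ----------------------------------------------------------

  void interaction_phase() {
    for (int site = 0; site < nsite; site++) {
      int p = lat[site];
      if (p < 0) continue;
      // break existing bonds, each with probability p_off
      if (p_off > 0) {
        std::array<int, 6> cur = bnd[p];
        for (int d = 0; d < 6; d++) {
          int q = cur[d];
          if (q >= 0 && bnd[p][d] == q && rng.u01() < p_off) remove_bond(p, q);
        }
      }
      // form new bonds toward eligible face neighbours
      for (int d = 0; d < 6; d++) {
        if (nb[p] >= 6) break;
        if (bnd[p][d] != -1) continue;           // face occupied by a bond
        int t = nbr(site, d);
        if (t < 0) continue;
        int q = lat[t];
        if (q < 0) continue;
        if (!interacts(sp[p], sp[q])) continue;
        if (is_bonded(p, q)) continue;
        if (nb[q] >= 6) continue;
        if (!species_compatible(p, q)) continue;
        if (rng.u01() < p_on) add_bond(p, q);
      }
    }
  }

  // unwrapped coordinates of a complex (consistent under periodic
  // boundaries unless the complex wraps the torus; then ok = false)
  struct Unwrapped {
    bool ok;
    std::vector<int> ux, uy, uz;  // parallel to comps[c].members
    int diameter;
  };

  Unwrapped unwrap(int c) {
    Unwrapped w; w.ok = true;
    const std::vector<int>& mem = comps[c].members;
    size_t n = mem.size();
    w.ux.resize(n); w.uy.resize(n); w.uz.resize(n);
    if (n == 1) {  // monomer fast path
      w.ux[0] = px[mem[0]]; w.uy[0] = py[mem[0]]; w.uz[0] = pz[mem[0]];
      w.diameter = 1;
      return w;
    }
    // BFS from member 0 over bonds, offsets by minimal image
    std::vector<size_t> queue_;
    std::vector<std::pair<int, size_t>> idx(n);
    for (size_t i = 0; i < n; i++) idx[i] = {mem[i], i};
    std::sort(idx.begin(), idx.end());
    auto find_slot = [&](int inst) {
      size_t lo = 0, hi = n;
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (idx[mid].first < inst) lo = mid + 1; else hi = mid;
      }
      return idx[lo].second;
    };
    std::vector<uint8_t> seen(n, 0);
    w.ux[0] = px[mem[0]]; w.uy[0] = py[mem[0]]; w.uz[0] = pz[mem[0]];
    seen[0] = 1;
    queue_.push_back(0);
    size_t head = 0;
    int half = L / 2;
    while (head < queue_.size()) {
      size_t i = queue_[head++];
      int u = mem[i];
      for (int d = 0; d < 6; d++) {
        int v = bnd[u][d];
        if (v < 0) continue;
        // minimal-image offset from u to v (face-adjacent: one axis +/-1)
        int dx = px[v] - px[u], dy = py[v] - py[u], dz = pz[v] - pz[u];
        if (periodic) {
          if (dx > half) dx -= L; else if (dx < -half) dx += L;
          if (dy > half) dy -= L; else if (dy < -half) dy += L;
          if (dz > half) dz -= L; else if (dz < -half) dz += L;
        }
        size_t j = find_slot(v);
        int nx = w.ux[i] + dx, ny = w.uy[i] + dy, nz = w.uz[i] + dz;
        if (!seen[j]) {
          seen[j] = 1;
          w.ux[j] = nx; w.uy[j] = ny; w.uz[j] = nz;
          queue_.push_back(j);
        } else if (w.ux[j] != nx || w.uy[j] != ny || w.uz[j] != nz) {
          w.ok = false;  // complex wraps around the torus
        }
      }
    }
    if (w.ok) {
      int mnx = w.ux[0], mxx = w.ux[0], mny = w.uy[0], mxy = w.uy[0],
          mnz = w.uz[0], mxz = w.uz[0];
      for (size_t i = 1; i < n; i++) {
        mnx = std::min(mnx, w.ux[i]); mxx = std::max(mxx, w.ux[i]);
        mny = std::min(mny, w.uy[i]); mxy = std::max(mxy, w.uy[i]);
        mnz = std::min(mnz, w.uz[i]); mxz = std::max(mxz, w.uz[i]);
      }
      int ext = std::max(mxx - mnx, std::max(mxy - mny, mxz - mnz));
      w.diameter = ext + 1;   // Chebyshev extent + 1; monomer = 1
    } else {
      w.diameter = L;
    }
    return w;
  }

  int wrap1(int v) const { return ((v % L) + L) % L; }

  // rigid 90-degree rotation of complex c about the rounded centre of
  // mass; rejected if blocked by any non-member or (closed) the boundary
  void attempt_rotation(int c, const Unwrapped& w, int g) {
    const std::vector<int>& mem = comps[c].members;
    size_t n = mem.size();
    if (n == 1) { // position unchanged; orientation turns
      orient[mem[0]] = ROT_COMP[g][orient[mem[0]]];
      return;
    }
    double cx = 0, cy = 0, cz = 0;
    for (size_t i = 0; i < n; i++) { cx += w.ux[i]; cy += w.uy[i]; cz += w.uz[i]; }
    cx /= n; cy /= n; cz /= n;
    int pvx = (int)std::floor(cx + 0.5), pvy = (int)std::floor(cy + 0.5),
        pvz = (int)std::floor(cz + 0.5);
    const Rot& R = ROT24[ROT_GEN[g]];
    std::vector<int> nx(n), ny(n), nz(n), nsit(n);
    ivis_stamp++;
    for (size_t i = 0; i < n; i++) ivis[mem[i]] = (int)ivis_stamp; // member mark
    site_stamp_ctr++;
    for (size_t i = 0; i < n; i++) {
      int ox, oy, oz;
      rot_apply(R, w.ux[i] - pvx, w.uy[i] - pvy, w.uz[i] - pvz, ox, oy, oz);
      int X = pvx + ox, Y = pvy + oy, Z = pvz + oz;
      if (periodic) { X = wrap1(X); Y = wrap1(Y); Z = wrap1(Z); }
      else if (X < 0 || X >= L || Y < 0 || Y >= L || Z < 0 || Z >= L) return;
      int s = site_of(X, Y, Z);
      int occ = lat[s];
      if (occ >= 0 && ivis[occ] != (int)ivis_stamp) return; // blocked
      // rotation is rigid in unwrapped space, but wrapping can alias two
      // members onto one site for complexes of extent >= L: reject
      if (site_stamp[s] == site_stamp_ctr) return;
      site_stamp[s] = site_stamp_ctr;
      nx[i] = X; ny[i] = Y; nz[i] = Z; nsit[i] = s;
    }
    for (size_t i = 0; i < n; i++) {
      int m = mem[i];
      int s = site_of(px[m], py[m], pz[m]);
      if (lat[s] == m) lat[s] = -1;
    }
    // direction remap for the bond slots (slot = face direction)
    int dmap[6];
    for (int d = 0; d < 6; d++) {
      int ox, oy, oz;
      rot_apply(R, DIRX[d], DIRY[d], DIRZ[d], ox, oy, oz);
      for (int e = 0; e < 6; e++)
        if (DIRX[e] == ox && DIRY[e] == oy && DIRZ[e] == oz) { dmap[d] = e; break; }
    }
    for (size_t i = 0; i < n; i++) {
      int m = mem[i];
      px[m] = nx[i]; py[m] = ny[i]; pz[m] = nz[i];
      lat[nsit[i]] = m;
      orient[m] = ROT_COMP[g][orient[m]];
      std::array<int, 6> nb2 = {-1, -1, -1, -1, -1, -1};
      for (int d = 0; d < 6; d++)
        if (bnd[m][d] >= 0) nb2[dmap[d]] = bnd[m][d];
      bnd[m] = nb2;
    }
  }

  // translation by one site in direction d with recursive pushes;
  // rejected wholesale if any push fails
  void attempt_translation(int c, int d) {
    std::vector<int> mvlist = {c};     // complexes committed to move
    auto in_moving = [&](int cc) {
      for (int x : mvlist) if (x == cc) return true;
      return false;
    };
    size_t head = 0;
    bool ok = true;
    while (head < mvlist.size() && ok) {
      int cc = mvlist[head++];
      double mover_mass = (double)comps[cc].members.size();
      for (int m : comps[cc].members) {
        int s = site_of(px[m], py[m], pz[m]);
        int t = nbr(s, d);
        if (t < 0) { ok = false; break; }     // closed wall
        int o = lat[t];
        if (o < 0) continue;
        int cb = comp[o];
        if (in_moving(cb)) continue;
        double ratio = mover_mass / (double)comps[cb].members.size();
        bool accept = (ratio >= 1.0) || (rng.u01() < ratio);
        if (!accept) { ok = false; break; }
        mvlist.push_back(cb);
      }
    }
    if (!ok) return;
    // apply: clear all source sites, then occupy all targets
    std::vector<int> all;
    for (int cc : mvlist)
      for (int m : comps[cc].members) all.push_back(m);
    for (int m : all) {
      int s = site_of(px[m], py[m], pz[m]);
      if (lat[s] == m) lat[s] = -1;
    }
    for (int m : all) {
      int x = px[m] + DIRX[d], y = py[m] + DIRY[d], z = pz[m] + DIRZ[d];
      if (periodic) { x = wrap1(x); y = wrap1(y); z = wrap1(z); }
      px[m] = x; py[m] = y; pz[m] = z;
      lat[site_of(x, y, z)] = m;
    }
  }

  void diffusion_phase() {
    phase_stamp++;
    for (int site = 0; site < nsite; site++) {
      int p = lat[site];
      if (p < 0) continue;
      int c = comp[p];
      if (comps[c].stamp == phase_stamp) continue;  // already acted
      comps[c].stamp = phase_stamp;
      Unwrapped w = unwrap(c);
      // rotation with probability 1/diameter
      if (rng.u01() < 1.0 / (double)w.diameter) {
        int g = rng.bounded(6);
        if (w.ok) attempt_rotation(c, w, g);
      }
      // translation with probability 1/mass (or 1/diameter)
      double denom = move_by_diameter ? (double)w.diameter
                                      : (double)comps[c].members.size();
      if (rng.u01() < 1.0 / denom) {
        int d = rng.bounded(6);
        attempt_translation(c, d);
      }
    }
  }

  void step() {
    interaction_phase();
    diffusion_phase();
    step_count++;
  }
};

static Sim* get(SEXP xp) {
  Rcpp::XPtr<Sim> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_sim_new(int n_species, IntegerMatrix edges0, int L, bool periodic,
                 double p_on, double p_off, bool move_by_diameter,
                 double occupancy, double seed, bool fill) {
  Sim* s = new Sim(L, periodic, p_on, p_off, move_by_diameter, n_species,
                   edges0, (uint64_t)seed);
  Rcpp::XPtr<Sim> xp(s, true);
  if (fill) s->random_fill(occupancy);
  return xp;
}

// [[Rcpp::export]]
void cpp_sim_step(SEXP xp, int n) {
  Sim* s = get(xp);
  for (int i = 0; i < n; i++) s->step();
}

// [[Rcpp::export]]
void cpp_sim_interaction(SEXP xp) { get(xp)->interaction_phase(); }

// [[Rcpp::export]]
void cpp_sim_diffusion(SEXP xp) { get(xp)->diffusion_phase(); }

// [[Rcpp::export]]
List cpp_sim_state(SEXP xp) {
  Sim* s = get(xp);
  int n = (int)s->sp.size();
  IntegerVector species(n), x(n), y(n), z(n), ori(n), cmp(n);
  std::vector<int> bp, bq;
  for (int i = 0; i < n; i++) {
    species[i] = s->sp[i] + 1;
    x[i] = s->px[i]; y[i] = s->py[i]; z[i] = s->pz[i];
    ori[i] = s->orient[i];
    cmp[i] = s->comp[i] + 1;
    for (int d = 0; d < 6; d++) {
      int q = s->bnd[i][d];
      if (q > i) { bp.push_back(i + 1); bq.push_back(q + 1); }
    }
  }
  IntegerMatrix bonds((int)bp.size(), 2);
  for (size_t k = 0; k < bp.size(); k++) { bonds(k, 0) = bp[k]; bonds(k, 1) = bq[k]; }
  return List::create(_["step"] = (double)s->step_count,
                      _["species"] = species, _["x"] = x, _["y"] = y,
                      _["z"] = z, _["orientation"] = ori,
                      _["complex"] = cmp, _["bonds"] = bonds,
                      _["L"] = s->L, _["periodic"] = s->periodic);
}

// [[Rcpp::export]]
List cpp_sim_complexes(SEXP xp) {
  Sim* s = get(xp);
  std::vector<int> ids;
  for (size_t c = 0; c < s->comps.size(); c++)
    if (s->comps[c].alive) ids.push_back((int)c);
  int n = (int)ids.size();
  List members(n), species(n);
  IntegerVector mass(n), diam(n);
  for (int i = 0; i < n; i++) {
    const std::vector<int>& mem = s->comps[ids[i]].members;
    IntegerVector mm(mem.size()), ss(mem.size());
    for (size_t k = 0; k < mem.size(); k++) {
      mm[k] = mem[k] + 1;
      ss[k] = s->sp[mem[k]] + 1;
    }
    std::sort(ss.begin(), ss.end());
    members[i] = mm;
    species[i] = ss;
    mass[i] = (int)mem.size();
    Sim::Unwrapped w = s->unwrap(ids[i]);
    diam[i] = w.ok ? w.diameter : NA_INTEGER;
  }
  return List::create(_["mass"] = mass, _["diameter"] = diam,
                      _["members"] = members, _["species"] = species);
}

// [[Rcpp::export]]
List cpp_sim_run(SEXP xp, int n_steps, int record_every) {
  Sim* s = get(xp);
  auto snapshot = [&](void) {
    std::vector<int> ids;
    for (size_t c = 0; c < s->comps.size(); c++)
      if (s->comps[c].alive) ids.push_back((int)c);
    int n = (int)ids.size();
    List species(n);
    IntegerVector mass(n);
    for (int i = 0; i < n; i++) {
      const std::vector<int>& mem = s->comps[ids[i]].members;
      IntegerVector ss(mem.size());
      for (size_t k = 0; k < mem.size(); k++) ss[k] = s->sp[mem[k]] + 1;
      std::sort(ss.begin(), ss.end());
      species[i] = ss;
      mass[i] = (int)mem.size();
    }
    return List::create(_["step"] = (double)s->step_count,
                        _["compositions"] = species, _["mass"] = mass);
  };
  List out;
  out.push_back(snapshot());
  for (int i = 1; i <= n_steps; i++) {
    s->step();
    if ((record_every > 0 && i % record_every == 0) || i == n_steps) {
      out.push_back(snapshot());
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
int cpp_sim_place(SEXP xp, int species1, int x, int y, int z) {
  Sim* s = get(xp);
  if (species1 < 1 || species1 > s->n_species) stop("species out of range");
  if (x < 0 || x >= s->L || y < 0 || y >= s->L || z < 0 || z >= s->L)
    stop("position out of range");
  return s->add_instance(species1 - 1, x, y, z, s->rng.bounded(24)) + 1;
}

// [[Rcpp::export]]
void cpp_sim_move(SEXP xp, int inst1, int x, int y, int z) {
  Sim* s = get(xp);
  int i = inst1 - 1;
  if (i < 0 || i >= (int)s->sp.size()) stop("instance out of range");
  if (s->nb[i] > 0) stop("cannot teleport a bonded instance");
  int t = s->site_of(x, y, z);
  if (s->lat[t] != -1 && s->lat[t] != i) stop("target site occupied");
  s->lat[s->site_of(s->px[i], s->py[i], s->pz[i])] = -1;
  s->px[i] = x; s->py[i] = y; s->pz[i] = z;
  s->lat[t] = i;
}

// [[Rcpp::export]]
void cpp_sim_bond(SEXP xp, int i1, int j1) {
  Sim* s = get(xp);
  int p = i1 - 1, q = j1 - 1;
  if (p < 0 || q < 0 || p >= (int)s->sp.size() || q >= (int)s->sp.size() || p == q)
    stop("bad instance ids");
  if (s->dir_between(p, q) < 0) stop("instances are not face-adjacent");
  if (s->is_bonded(p, q)) return;
  if (s->nb[p] >= 6 || s->nb[q] >= 6) stop("bond capacity exceeded");
  if (!s->interacts(s->sp[p], s->sp[q])) stop("species do not interact");
  if (!s->species_compatible(p, q)) stop("species-uniqueness violation");
  s->add_bond(p, q);
}

// [[Rcpp::export]]
void cpp_sim_set_rates(SEXP xp, double p_on, double p_off) {
  Sim* s = get(xp);
  s->p_on = p_on; s->p_off = p_off;
}

// [[Rcpp::export]]
List cpp_sim_params(SEXP xp) {
  Sim* s = get(xp);
  return List::create(_["L"] = s->L, _["periodic"] = s->periodic,
                      _["p_on"] = s->p_on, _["p_off"] = s->p_off,
                      _["move_by_diameter"] = s->move_by_diameter,
                      _["n_species"] = s->n_species,
                      _["n_instances"] = (int)s->sp.size(),
                      _["step"] = (double)s->step_count);
}

// [[Rcpp::export]]
bool cpp_sim_check(SEXP xp) {
  Sim* s = get(xp);
  int n = (int)s->sp.size();
  // lattice <-> positions
  int nocc = 0;
  for (int i = 0; i < s->nsite; i++) if (s->lat[i] >= 0) nocc++;
  if (nocc != n) { Rcout << "lat count mismatch\n"; return false; }
  for (int i = 0; i < n; i++) {
    if (s->lat[s->site_of(s->px[i], s->py[i], s->pz[i])] != i) {
      Rcout << "lat/pos mismatch at instance " << i << "\n"; return false;
    }
  }
  // partition vs bond graph; membership consistency
  std::vector<int> seen(n, 0);
  for (size_t c = 0; c < s->comps.size(); c++) {
    if (!s->comps[c].alive) continue;
    for (int m : s->comps[c].members) {
      if (s->comp[m] != (int)c) { Rcout << "comp id mismatch " << m << "\n"; return false; }
      seen[m]++;
    }
  }
  for (int i = 0; i < n; i++) if (seen[i] != 1) { Rcout << "member count " << i << " = " << seen[i] << "\n"; return false; }
  for (int i = 0; i < n; i++) {
    int cnt = 0;
    for (int d = 0; d < 6; d++) {
      int q = s->bnd[i][d];
      if (q < 0) continue;
      cnt++;
      if (s->comp[q] != s->comp[i]) { Rcout << "bond across complexes " << i << "-" << q << "\n"; return false; }
      if (!s->is_bonded(q, i)) { Rcout << "asymmetric bond\n"; return false; }
      if (s->dir_between(i, q) < 0) { Rcout << "non-adjacent bond " << i << "-" << q << "\n"; return false; }
      if (!s->interacts(s->sp[i], s->sp[q])) { Rcout << "illegal species bond\n"; return false; }
    }
    if (cnt != s->nb[i]) { Rcout << "nb mismatch " << i << "\n"; return false; }
  }
  // per-complex species uniqueness and connectivity
  for (size_t c = 0; c < s->comps.size(); c++) {
    if (!s->comps[c].alive) continue;
    const std::vector<int>& mem = s->comps[c].members;
    std::vector<int> spv;
    for (int m : mem) spv.push_back(s->sp[m]);
    std::sort(spv.begin(), spv.end());
    for (size_t k = 1; k < spv.size(); k++)
      if (spv[k] == spv[k-1]) { Rcout << "species dup in complex " << c << "\n"; return false; }
    // connectivity
    if (mem.size() > 1) {
      std::vector<int> stack = {mem[0]};
      std::vector<int> vis;
      s->ivis_stamp++;
      s->ivis[mem[0]] = (int)s->ivis_stamp;
      size_t cnt2 = 1;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        for (int d = 0; d < 6; d++) {
          int v = s->bnd[u][d];
          if (v >= 0 && s->ivis[v] != (int)s->ivis_stamp) {
            s->ivis[v] = (int)s->ivis_stamp; cnt2++; stack.push_back(v);
          }
        }
      }
      if (cnt2 != mem.size()) { Rcout << "disconnected complex " << c << "\n"; return false; }
    }
  }
  return true;
}

// ---- similarity matrix helper ------------------------------------------
// Compositions as sorted integer vectors; S.I. = |A n B|^2 / (|A d B| + 1).

// [[Rcpp::export]]
NumericMatrix cpp_similarity_matrix(List a, List b) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<int>> A(n), B(m);
  for (int i = 0; i < n; i++) A[i] = as<std::vector<int>>(a[i]);
  for (int j = 0; j < m; j++) B[j] = as<std::vector<int>>(b[j]);
  NumericMatrix M(n, m);
  for (int i = 0; i < n; i++) {
    const std::vector<int>& x = A[i];
    for (int j = 0; j < m; j++) {
      const std::vector<int>& y = B[j];
      size_t ii = 0, jj = 0; int inter = 0;
      while (ii < x.size() && jj < y.size()) {
        if (x[ii] < y[jj]) ii++;
        else if (x[ii] > y[jj]) jj++;
        else { inter++; ii++; jj++; }
      }
      int sdiff = (int)x.size() + (int)y.size() - 2 * inter;
      M(i, j) = (double)inter * inter / (double)(sdiff + 1);
    }
  }
  return M;
}
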