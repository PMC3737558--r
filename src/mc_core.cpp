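#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Hard-sphere bead-chain Monte Carlo core. All randomness comes from R's
// RNG (unif_rand), so set.seed() in R controls the whole run.

namespace {

struct Vec3 { double x, y, z; };

inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Rotate p about the axis through 'origin' with unit direction 'u' by theta.
inline Vec3 rotate_about(const Vec3 &p, const Vec3 &origin, const Vec3 &u,
                         double ct, double st) {
  Vec3 v = sub(p, origin);
  double du = dot(v, u);
  Vec3 cr = cross(u, v);
  return {origin.x + v.x*ct + cr.x*st + u.x*du*(1-ct),
          origin.y + v.y*ct + cr.y*st + u.y*du*(1-ct),
          origin.z + v.z*ct + cr.z*st + u.z*du*(1-ct)};
}

// Axial cell list over the bounding box of the container.
struct CellList {
  double edge, x0, y0, z0;
  int ncx, ncy, ncz;
  std::vector<int> head;   // first bead in cell, -1 if empty
  std::vector<int> nxt;    // next bead in same cell
  std::vector<int> cell;   // cell index of each bead

  void build(const std::vector<Vec3> &pos, double D, double L, double min_edge) {
    x0 = -D/2; y0 = -D/2; z0 = -L/2;
    // cells must be at least min_edge wide; cap the counts so the grid
    // stays small even for tiny beads in a huge container
    ncx = std::max(1, std::min(64, (int)std::floor(D / min_edge)));
    ncy = ncx;
    ncz = std::max(1, std::min(256, (int)std::floor(L / min_edge)));
    edge = 0; // per-axis edges implied by counts; store via spans
    exd = D / ncx; eyd = D / ncy; ezd = L / ncz;
    head.assign((size_t)ncx*ncy*ncz, -1);
    nxt.assign(pos.size(), -1);
    cell.assign(pos.size(), -1);
    for (size_t b = 0; b < pos.size(); ++b) insert((int)b, pos[b]);
  }
  double exd, eyd, ezd;
  inline int cell_of(const Vec3 &p) const {
    int ix = (int)std::floor((p.x - x0) / exd);
    int iy = (int)std::floor((p.y - y0) / eyd);
    int iz = (int)std::floor((p.z - z0) / ezd);
    if (ix < 0) ix = 0; if (ix >= ncx) ix = ncx - 1;
    if (iy < 0) iy = 0; if (iy >= ncy) iy = ncy - 1;
    if (iz < 0) iz = 0; if (iz >= ncz) iz = ncz - 1;
    return (iz * ncy + iy) * ncx + ix;
  }
  void insert(int b, const Vec3 &p) {
    int c = cell_of(p);
    cell[b] = c;
    nxt[b] = head[c];
    head[c] = b;
  }
  void remove(int b) {
    int c = cell[b];
    int cur = head[c], prev = -1;
    while (cur != b) { prev = cur; cur = nxt[cur]; }
    if (prev == -1) head[c] = nxt[b]; else nxt[prev] = nxt[b];
    nxt[b] = -1; cell[b] = -1;
  }
  void move(int b, const Vec3 &pnew) {
    int c = cell_of(pnew);
    if (c != cell[b]) { remove(b); cell[b] = c; nxt[b] = head[c]; head[c] = b; }
  }
  // visit beads in all cells intersecting the bounding box of ball(p, rad)
  template <class F> void visit_ball(const Vec3 &p, double rad, F f) const {
    int ix0 = (int)std::floor((p.x - rad - x0) / exd);
    int ix1 = (int)std::floor((p.x + rad - x0) / exd);
    int iy0 = (int)std::floor((p.y - rad - y0) / eyd);
    int iy1 = (int)std::floor((p.y + rad - y0) / eyd);
    int iz0 = (int)std::floor((p.z - rad - z0) / ezd);
    int iz1 = (int)std::floor((p.z + rad - z0) / ezd);
    if (ix0 < 0) ix0 = 0; if (ix1 >= ncx) ix1 = ncx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 >= ncy) iy1 = ncy - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 >= ncz) iz1 = ncz - 1;
    for (int jz = iz0; jz <= iz1; ++jz)
      for (int jy = iy0; jy <= iy1; ++jy)
        for (int jx = ix0; jx <= ix1; ++jx)
          for (int b = head[(jz * ncy + jy) * ncx + jx]; b != -1; b = nxt[b])
            if (!f(b)) return;
  }

  // visit beads in the 27-cell neighborhood of p
  template <class F> bool visit(const Vec3 &p, F f) const {
    int ix = (int)std::floor((p.x - x0) / exd);
    int iy = (int)std::floor((p.y - y0) / eyd);
    int iz = (int)std::floor((p.z - z0) / ezd);
    for (int dz = -1; dz <= 1; ++dz) {
      int jz = iz + dz; if (jz < 0 || jz >= ncz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy; if (jy < 0 || jy >= ncy) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx; if (jx < 0 || jx >= ncx) continue;
          for (int b = head[(jz * ncy + jy) * ncx + jx]; b != -1; b = nxt[b])
            if (!f(b)) return false;
        }
      }
    }
    return true;
  }
};

struct System {
  std::vector<Vec3> pos;
  std::vector<int> chain;      // 0 or 1
  std::vector<int> local;      // index within chain
  int n1, n2;
  bool circ1, circ2;
  double r, D, L;

  int nchain(int c) const { return c == 0 ? n1 : n2; }
  int offset(int c) const { return c == 0 ? 0 : n1; }
  bool circular(int c) const { return c == 0 ? circ1 : circ2; }

  bool bonded(int a, int b) const {
    if (chain[a] != chain[b]) return false;
    int c = chain[a], N = nchain(c);
    int d = std::abs(local[a] - local[b]);
    return d == 1 || (circular(c) && d == N - 1);
  }
  bool inside_wall(const Vec3 &p) const {
    double half = (L - D) / 2;
    double dz = std::fabs(p.z) - half; if (dz < 0) dz = 0;
    double lim = (D / 2 - r);
    return p.x*p.x + p.y*p.y + dz*dz <= lim * lim * (1 + 1e-12);
  }
};

} // namespace

// Run n_iter attempted crankshaft moves on the two-chain system.
// coords: (n1+n2) x 3; all randomness from R's RNG.
// [[Rcpp::export]]
List cpp_mc_chunk(NumericMatrix coords, int n1, int n2,
                  bool circ1, bool circ2,
                  double r, double D, double L,
                  int n_iter, int smax, double theta_max,
                  bool check_crossing) {
  RNGScope scope;
  System S;
  int n = coords.nrow();
  if (n != n1 + n2) stop("coords row count must equal n1 + n2");
  S.pos.resize(n);
  S.chain.resize(n); S.local.resize(n);
  for (int b = 0; b < n; ++b) {
    S.pos[b] = {coords(b, 0), coords(b, 1), coords(b, 2)};
    S.chain[b] = b < n1 ? 0 : 1;
    S.local[b] = b < n1 ? b : b - n1;
  }
  S.n1 = n1; S.n2 = n2; S.circ1 = circ1; S.circ2 = circ2;
  S.r = r; S.D = D; S.L = L;

  CellList cl;
  cl.build(S.pos, D, L, 3.0 * r);

  const double ev2 = (2*r) * (2*r) * (1 - 1e-9);  // hard-core threshold
  std::vector<char> moved_flag(n, 0);
  std::vector<int> moved; moved.reserve(smax + 2);
  std::vector<Vec3> prop; prop.reserve(smax + 2);
  std::vector<int> cand_of, cand_beads;
  cand_of.reserve(3 * (smax + 2)); cand_beads.reserve(256);

  long accepted = 0, sweep_rej = 0, ev_rej = 0, wall_rej = 0;

  // checks one proposed position against all static (non-moved) beads
  auto clash = [&](int b, const Vec3 &p) -> bool {
    bool ok = cl.visit(p, [&](int o) -> bool {
      if (moved_flag[o] || o == b) return true;
      if (S.bonded(b, o)) return true;
      Vec3 d = sub(p, S.pos[o]);
      if (dot(d, d) < ev2) return false;
      return true;
    });
    return !ok;
  };

  for (long it = 0; it < n_iter; ++it) {
    int c = unif_rand() < 0.5 ? 0 : 1;
    int N = S.nchain(c), off = S.offset(c);
    int smax_c = std::min(smax, N / 2);
    if (smax_c < 1) smax_c = 1;
    int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
    int s = 1 + (int)(unif_rand() * smax_c); if (s > smax_c) s = smax_c;

    moved.clear();
    Vec3 origin, axis;
    bool have_axis = false;

    if (S.circular(c)) {
      int j = (i + s) % N;
      for (int k = 1; k < s; ++k) moved.push_back(off + (i + k) % N);
      if (!moved.empty()) {
        origin = S.pos[off + i];
        Vec3 u = sub(S.pos[off + j], origin);
        double nu = norm(u);
        axis = {u.x/nu, u.y/nu, u.z/nu};
        have_axis = true;
      }
    } else {
      int dir = unif_rand() < 0.5 ? 1 : -1;
      int j = i + dir * s;
      if (j >= 0 && j <= N - 1) {
        int lo = std::min(i, j), hi = std::max(i, j);
        for (int k = lo + 1; k < hi; ++k) moved.push_back(off + k);
        if (!moved.empty()) {
          origin = S.pos[off + lo];
          Vec3 u = sub(S.pos[off + hi], origin);
          double nu = norm(u);
          axis = {u.x/nu, u.y/nu, u.z/nu};
          have_axis = true;
        }
      } else {
        // segment runs past an end: terminal rotation about a random axis
        // through the reflected pivot
        int p = (j > N - 1) ? (2 * (N - 1) - j) : (-j);
        if (p < 0) p = 0; if (p > N - 1) p = N - 1;
        if (j > N - 1) { for (int k = p + 1; k <= N - 1; ++k) moved.push_back(off + k); }
        else           { for (int k = 0; k <= p - 1; ++k) moved.push_back(off + k); }
        if (!moved.empty()) {
          origin = S.pos[off + p];
          double zu = 2 * unif_rand() - 1;
          double ph = 2 * M_PI * unif_rand();
          double rr = std::sqrt(std::max(0.0, 1 - zu * zu));
          axis = {rr * std::cos(ph), rr * std::sin(ph), zu};
          have_axis = true;
        }
      }
    }

    double theta = (2 * unif_rand() - 1) * theta_max;

    if (moved.empty() || !have_axis) { ++accepted; continue; }

    double ct = std::cos(theta), st = std::sin(theta);
    prop.clear();
    for (int b : moved) moved_flag[b] = 1;

    bool ok = true;
    double rmax2 = 0;
    for (int b : moved) {
      Vec3 p = rotate_about(S.pos[b], origin, axis, ct, st);
      prop.push_back(p);
      if (!S.inside_wall(p)) { ok = false; ++wall_rej; break; }
      Vec3 v = sub(S.pos[b], origin);
      double du = dot(v, axis);
      double d2 = dot(v, v) - du * du;  // squared distance from axis
      if (d2 > rmax2) rmax2 = d2;
    }
    if (ok) {
      for (size_t k = 0; k < moved.size(); ++k)
        if (clash(moved[k], prop[k])) { ok = false; ++ev_rej; break; }
    }

    // swept-path check: subdivide so the largest chord per substep is < r.
    // Every arc point of bead b lies within 2 R_b sin(|theta|/2) of its
    // starting position, so candidate neighbours are gathered once per bead
    // from that ball; substeps only test beads with candidates (usually none).
    if (ok && check_crossing) {
      double rmax = std::sqrt(rmax2);
      int nsub = 1;
      if (rmax > r / 2) {
        double dmax = 2 * std::asin(std::min(1.0, r / (2 * rmax)));
        nsub = (int)std::ceil(std::fabs(theta) / dmax);
        if (nsub < 1) nsub = 1;
      }
      if (nsub > 1) {
        cand_of.clear(); cand_beads.clear();
        double sh = std::sin(std::fabs(theta) / 2);
        for (size_t k = 0; k < moved.size(); ++k) {
          int b = moved[k];
          Vec3 v = sub(S.pos[b], origin);
          double du = dot(v, axis);
          double rb = std::sqrt(std::max(0.0, dot(v, v) - du * du));
          double reach = 2 * rb * sh + 2 * r;
          size_t first = cand_beads.size();
          cl.visit_ball(S.pos[b], reach, [&](int o) -> bool {
            if (moved_flag[o] || o == b || S.bonded(b, o)) return true;
            Vec3 d = sub(S.pos[b], S.pos[o]);
            if (dot(d, d) <= reach * reach) cand_beads.push_back(o);
            return true;
          });
          if (cand_beads.size() > first) {
            cand_of.push_back((int)k);
            cand_of.push_back((int)first);
            cand_of.push_back((int)cand_beads.size());
          }
        }
        for (int ksub = 1; ksub < nsub && ok; ++ksub) {
          double th = theta * (double)ksub / nsub;
          double c2 = std::cos(th), s2 = std::sin(th);
          for (size_t q = 0; q < cand_of.size() && ok; q += 3) {
            int k = cand_of[q];
            Vec3 p = rotate_about(S.pos[moved[k]], origin, axis, c2, s2);
            for (int w = cand_of[q + 1]; w < cand_of[q + 2]; ++w) {
              Vec3 d = sub(p, S.pos[cand_beads[w]]);
              if (dot(d, d) < ev2) { ok = false; ++sweep_rej; break; }
            }
          }
        }
      }
    }

    if (ok) {
      for (size_t k = 0; k < moved.size(); ++k) {
        S.pos[moved[k]] = prop[k];
        cl.move(moved[k], prop[k]);
      }
      ++accepted;
    }
    for (int b : moved) moved_flag[b] = 0;
  }

  NumericMatrix out(n, 3);
  for (int b = 0; b < n; ++b) {
    out(b, 0) = S.pos[b].x; out(b, 1) = S.pos[b].y; out(b, 2) = S.pos[b].z;
  }
  return List::create(
    _["coords"] = out,
    _["attempted"] = (double)n_iter,
    _["accepted"] = (double)accepted,
    _["rejected_wall"] = (double)wall_rej,
    _["rejected_overlap"] = (double)ev_rej,
    _["rejected_sweep"] = (double)sweep_rej);
}

// Decide one fully specified crankshaft move with the production engine's
// endpoint and swept-path logic. moved: 1-based global bead indices.
// Used to cross-validate the compiled path against the R reference path.
// [[Rcpp::export]]
bool cpp_decide_move(NumericMatrix coords, int n1, int n2,
                     bool circ1, bool circ2, double r, double D, double L,
                     IntegerVector moved_in, NumericVector origin_in,
                     NumericVector axis_in, double theta,
                     bool check_crossing) {
  System S;
  int n = coords.nrow();
  S.pos.resize(n); S.chain.resize(n); S.local.resize(n);
  for (int b = 0; b < n; ++b) {
    S.pos[b] = {coords(b,0), coords(b,1), coords(b,2)};
    S.chain[b] = b < n1 ? 0 : 1;
    S.local[b] = b < n1 ? b : b - n1;
  }
  S.n1 = n1; S.n2 = n2; S.circ1 = circ1; S.circ2 = circ2;
  S.r = r; S.D = D; S.L = L;
  CellList cl;
  cl.build(S.pos, D, L, 3.0 * r);
  const double ev2 = (2*r) * (2*r) * (1 - 1e-9);
  std::vector<char> moved_flag(n, 0);
  std::vector<int> moved(moved_in.begin(), moved_in.end());
  for (int &b : moved) { b -= 1; moved_flag[b] = 1; }
  Vec3 origin = {origin_in[0], origin_in[1], origin_in[2]};
  Vec3 axis = {axis_in[0], axis_in[1], axis_in[2]};
  double ct = std::cos(theta), st = std::sin(theta);
  double rmax2 = 0;
  bool ok = true;
  std::vector<Vec3> prop;
  for (int b : moved) {
    Vec3 p = rotate_about(S.pos[b], origin, axis, ct, st);
    prop.push_back(p);
    if (!S.inside_wall(p)) { ok = false; break; }
    Vec3 v = sub(S.pos[b], origin);
    double du = dot(v, axis);
    double d2 = dot(v, v) - du * du;
    if (d2 > rmax2) rmax2 = d2;
  }
  if (ok) {
    for (size_t k = 0; k < moved.size() && ok; ++k) {
      int b = moved[k];
      ok = cl.visit(prop[k], [&](int o) -> bool {
        if (moved_flag[o] || o == b || S.bonded(b, o)) return true;
        Vec3 d = sub(prop[k], S.pos[o]);
        return dot(d, d) >= ev2;
      });
    }
  }
  if (ok && check_crossing) {
    double rmax = std::sqrt(rmax2);
    int nsub = 1;
    if (rmax > r / 2) {
      double dmax = 2 * std::asin(std::min(1.0, r / (2 * rmax)));
      nsub = (int)std::ceil(std::fabs(theta) / dmax);
      if (nsub < 1) nsub = 1;
    }
    if (nsub > 1) {
      std::vector<int> cand_of, cand_beads;
      double sh = std::sin(std::fabs(theta) / 2);
      for (size_t k = 0; k < moved.size(); ++k) {
        int b = moved[k];
        Vec3 v = sub(S.pos[b], origin);
        double du = dot(v, axis);
        double rb = std::sqrt(std::max(0.0, dot(v, v) - du * du));
        double reach = 2 * rb * sh + 2 * r;
        size_t first = cand_beads.size();
        cl.visit_ball(S.pos[b], reach, [&](int o) -> bool {
          if (moved_flag[o] || o == b || S.bonded(b, o)) return true;
          Vec3 d = sub(S.pos[b], S.pos[o]);
          if (dot(d, d) <= reach * reach) cand_beads.push_back(o);
          return true;
        });
        if (cand_beads.size() > first) {
          cand_of.push_back((int)k);
          cand_of.push_back((int)first);
          cand_of.push_back((int)cand_beads.size());
        }
      }
      for (int ksub = 1; ksub < nsub && ok; ++ksub) {
        double th = theta * (double)ksub / nsub;
        double c2 = std::cos(th), s2 = std::sin(th);
        for (size_t q = 0; q < cand_of.size() && ok; q += 3) {
          int k = cand_of[q];
          Vec3 p = rotate_about(S.pos[moved[k]], origin, axis, c2, s2);
          for (int w = cand_of[q + 1]; w < cand_of[q + 2]; ++w) {
            Vec3 d = sub(p, S.pos[cand_beads[w]]);
            if (dot(d, d) < ev2) { ok = false; break; }
          }
        }
      }
    }
  }
  return ok;
}

// Contact counts at cutoff 3r via the cell list (the production path).
// Returns inter- and per-chain intra-chain contact pair counts plus
// end-bead counts for linear chains.
// [[Rcpp::export]]
List cpp_contact_counts(NumericMatrix coords, int n1, int n2,
                        bool circ1, bool circ2, double r,
                        double D, double L) {
  int n = coords.nrow();
  if (n != n1 + n2) stop("coords row count must equal n1 + n2");
  System S;
  S.pos.resize(n); S.chain.resize(n); S.local.resize(n);
  for (int b = 0; b < n; ++b) {
    S.pos[b] = {coords(b,0), coords(b,1), coords(b,2)};
    S.chain[b] = b < n1 ? 0 : 1;
    S.local[b] = b < n1 ? b : b - n1;
  }
  S.n1 = n1; S.n2 = n2; S.circ1 = circ1; S.circ2 = circ2;
  S.r = r; S.D = D; S.L = L;
  CellList cl;
  cl.build(S.pos, D, L, 3.0 * r);
  const double cut2 = (3*r) * (3*r);

  long inter = 0, intra1 = 0, intra2 = 0;
  // end-bead contact counts, chain x end (2 ends), inter and intra
  long e_inter[2][2] = {{0,0},{0,0}};
  long e_intra[2][2] = {{0,0},{0,0}};

  for (int b = 0; b < n; ++b) {
    cl.visit(S.pos[b], [&](int o) -> bool {
      if (o <= b) return true;
      Vec3 d = sub(S.pos[b], S.pos[o]);
      if (dot(d, d) >= cut2) return true;      // strict < 3r
      if (S.chain[b] != S.chain[o]) ++inter;
      else if (!S.bonded(b, o)) {
        if (S.chain[b] == 0) ++intra1; else ++intra2;
      }
      return true;
    });
  }

  // end-bead counts (linear chains only), exhaustive over the end's row
  for (int c = 0; c < 2; ++c) {
    if (S.circular(c)) continue;
    int N = S.nchain(c), off = S.offset(c);
    int ends[2] = {off, off + N - 1};
    for (int e = 0; e < 2; ++e) {
      int b = ends[e];
      for (int o = 0; o < n; ++o) {
        if (o == b) continue;
        Vec3 d = sub(S.pos[b], S.pos[o]);
        bool contact = dot(d, d) < cut2;
        if (!contact) continue;
        if (S.chain[o] != c) { ++e_inter[c][e]; continue; }
        // intra: internal beads only (exclude both terminals) and
        // non-consecutive to this end
        int lo = S.local[o];
        if (lo == 0 || lo == N - 1) continue;
        if (std::abs(lo - S.local[b]) == 1) continue;
        ++e_intra[c][e];
      }
    }
  }

  return List::create(
    _["inter"] = (double)inter,
    _["intra1"] = (double)intra1,
    _["intra2"] = (double)intra2,
    _["end_inter"] = NumericMatrix(2, 2,
        std::vector<double>{(double)e_inter[0][0], (double)e_inter[1][0],
                            (double)e_inter[0][1], (double)e_inter[1][1]}.begin()),
    _["end_intra"] = NumericMatrix(2, 2,
        std::vector<double>{(double)e_intra[0][0], (double)e_intra[1][0],
                            (double)e_intra[0][1], (double)e_intra[1][1]}.begin()));
}

// Exhaustive excluded-volume scan; returns the violating pairs (1-based
// global indices) and their distances.
// [[Rcpp::export]]
List cpp_ev_violations(NumericMatrix coords, int n1, int n2,
                       bool circ1, bool circ2, double r) {
  int n = coords.nrow();
  System S;
  S.pos.resize(n); S.chain.resize(n); S.local.resize(n);
  for (int b = 0; b < n; ++b) {
    S.pos[b] = {coords(b,0), coords(b,1), coords(b,2)};
    S.chain[b] = b < n1 ? 0 : 1;
    S.local[b] = b < n1 ? b : b - n1;
  }
  S.n1 = n1; S.n2 = n2; S.circ1 = circ1; S.circ2 = circ2;
  const double ev2 = (2*r) * (2*r) * (1 - 1e-9);
  std::vector<int> ia, ib;
  std::vector<double> dist;
  for (int b = 0; b < n; ++b)
    for (int o = b + 1; o < n; ++o) {
      if (S.bonded(b, o)) continue;
      Vec3 d = sub(S.pos[b], S.pos[o]);
      double d2 = dot(d, d);
      if (d2 < ev2) { ia.push_back(b + 1); ib.push_back(o + 1); dist.push_back(std::sqrt(d2)); }
    }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib), _["distance"] = wrap(dist));
}

static int64_t mod_pow(int64_t a, int64_t e, int64_t p) {
  int64_t r = 1; a %= p; if (a < 0) a += p;
  while (e) { if (e & 1) r = (__int128)r * a % p; a = (__int128)a * a % p; e >>= 1; }
  return r;
}

// Determinant of an integer matrix modulo a prime p (< 2^31), by Gaussian
// elimination in Z_p. Returns det mod p in [0, p).
// [[Rcpp::export]]
double cpp_moddet(IntegerMatrix M, double p_in) {
  int64_t p = (int64_t)p_in;
  int n = M.nrow();
  if (n != M.ncol()) stop("matrix must be square");
  if (n == 0) return 1.0;
  std::vector<int64_t> A((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int64_t v = M(i, j) % p; if (v < 0) v += p;
      A[(size_t)i * n + j] = v;
    }
  int64_t det = 1;
  for (int col = 0; col < n; ++col) {
    int piv = -1;
    for (int i = col; i < n; ++i) if (A[(size_t)i * n + col] != 0) { piv = i; break; }
    if (piv < 0) return 0.0;
    if (piv != col) {
      for (int j = col; j < n; ++j) std::swap(A[(size_t)piv * n + j], A[(size_t)col * n + j]);
      det = p - det; if (det == p) det = 0;
    }
    int64_t d = A[(size_t)col * n + col];
    det = (__int128)det * d % p;
    int64_t dinv = mod_pow(d, p - 2, p);
    for (int i = col + 1; i < n; ++i) {
      int64_t f = (__int128)A[(size_t)i * n + col] * dinv % p;
      if (f == 0) continue;
      for (int j = col; j < n; ++j) {
        int64_t v = A[(size_t)i * n + j] - (__int128)f * A[(size_t)col * n + j] % p;
        if (v < 0) v += p;
        A[(size_t)i * n + j] = v;
      }
    }
  }
  return (double)det;
}
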