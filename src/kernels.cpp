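// Performance kernels: residue-level heavy-atom contact detection,
// reference-frame enumeration and hash-table voting for geometric hashing,
// and a Jonker-Volgenant style solver for the assignment problem used by
// maximum-weight bipartite matching.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Residue pairs (1-based, i < j) having at least one atom-atom distance
// <= cutoff.  xyz: n_atoms x 3; ridx: residue index per atom (1-based).
// Brute-force over atom pairs with an early accept per residue pair; the
// atom counts seen here (interface fixtures, small complexes) keep this
// cheap.
// [[Rcpp::export(name = "atom_contact_residue_pairs")]]
IntegerMatrix atom_contact_residue_pairs(NumericMatrix xyz,
                                         IntegerVector ridx,
                                         double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::unordered_map<int64_t, char> hit;  // pairs already known to contact
  std::vector<std::pair<int, int>> out;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int ri = ridx[a], rj = ridx[b];
      if (ri == rj) continue;
      int lo = ri < rj ? ri : rj, hi = ri < rj ? rj : ri;
      int64_t key = (int64_t)lo * 1000000 + hi;
      auto it = hit.find(key);
      if (it != hit.end()) continue;
      double dx = xyz(a, 0) - xyz(b, 0);
      double dy = xyz(a, 1) - xyz(b, 1);
      double dz = xyz(a, 2) - xyz(b, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        hit[key] = 1;
        out.push_back(std::make_pair(lo, hi));
      }
    }
  }
  IntegerMatrix res(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k].first;
    res(k, 1) = out[k].second;
  }
  return res;
}

static inline void frame_basis(const NumericMatrix &pts, int p, int q, int r,
                               double B[9], double origin[3], bool &ok) {
  // columns of B: ex (p->q), ey, ez = ex x (r-p) normalized
  double ex[3], v[3], ez[3], ey[3];
  for (int k = 0; k < 3; ++k) {
    ex[k] = pts(q, k) - pts(p, k);
    v[k] = pts(r, k) - pts(p, k);
    origin[k] = pts(p, k);
  }
  double nex = std::sqrt(ex[0] * ex[0] + ex[1] * ex[1] + ex[2] * ex[2]);
  if (nex < 1e-9) { ok = false; return; }
  for (int k = 0; k < 3; ++k) ex[k] /= nex;
  ez[0] = ex[1] * v[2] - ex[2] * v[1];
  ez[1] = ex[2] * v[0] - ex[0] * v[2];
  ez[2] = ex[0] * v[1] - ex[1] * v[0];
  double nez = std::sqrt(ez[0] * ez[0] + ez[1] * ez[1] + ez[2] * ez[2]);
  if (nez < 1e-9) { ok = false; return; }
  for (int k = 0; k < 3; ++k) ez[k] /= nez;
  ey[0] = ez[1] * ex[2] - ez[2] * ex[1];
  ey[1] = ez[2] * ex[0] - ez[0] * ex[2];
  ey[2] = ez[0] * ex[1] - ez[1] * ex[0];
  B[0] = ex[0]; B[1] = ex[1]; B[2] = ex[2];
  B[3] = ey[0]; B[4] = ey[1]; B[5] = ey[2];
  B[6] = ez[0]; B[7] = ez[1]; B[8] = ez[2];
  ok = true;
}

// Ordered point triplets (p, q, r) usable as local reference frames:
// all three points in the same fragment, pairwise distances within
// [dmin, dmax], triangle area >= min_area.  Deterministic stride
// subsampling caps the output at max_frames.  Returns m x 3, 1-based.
// [[Rcpp::export(name = "enumerate_frames_cpp")]]
IntegerMatrix enumerate_frames_cpp(NumericMatrix pts, IntegerVector frag,
                                   double dmin, double dmax,
                                   double min_area, int max_frames) {
  const int n = pts.nrow();
  std::vector<std::array<double, 3>> P(n);
  for (int i = 0; i < n; ++i)
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  auto dist2 = [&](int a, int b) {
    double dx = P[a][0] - P[b][0], dy = P[a][1] - P[b][1],
           dz = P[a][2] - P[b][2];
    return dx * dx + dy * dy + dz * dz;
  };
  const double lo2 = dmin * dmin, hi2 = dmax * dmax;
  std::vector<std::array<int, 3>> frames;
  for (int p = 0; p < n; ++p) {
    for (int q = 0; q < n; ++q) {
      if (q == p || frag[q] != frag[p]) continue;
      double dpq2 = dist2(p, q);
      if (dpq2 < lo2 || dpq2 > hi2) continue;
      for (int r = q + 1; r < n; ++r) {
        // r > q halves the count; (p,q,r) and (p,r,q) give mirror-related
        // y-axes, and swapping q/r is covered by the p,q loops anyway.
        if (r == p || frag[r] != frag[p]) continue;
        double dpr2 = dist2(p, r), dqr2 = dist2(q, r);
        if (dpr2 < lo2 || dpr2 > hi2 || dqr2 < lo2 || dqr2 > hi2) continue;
        double ux = P[q][0] - P[p][0], uy = P[q][1] - P[p][1],
               uz = P[q][2] - P[p][2];
        double vx = P[r][0] - P[p][0], vy = P[r][1] - P[p][1],
               vz = P[r][2] - P[p][2];
        double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
               cz = ux * vy - uy * vx;
        double area = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
        if (area < min_area) continue;
        frames.push_back({p, q, r});
      }
    }
  }
  int m = (int)frames.size();
  int keep = (max_frames > 0 && m > max_frames) ? max_frames : m;
  IntegerMatrix res(keep, 3);
  if (keep == 0) return res;
  // deterministic stride subsample
  double step = (double)m / keep;
  for (int k = 0; k < keep; ++k) {
    int idx = (int)std::floor(k * step);
    if (idx >= m) idx = m - 1;
    res(k, 0) = frames[idx][0] + 1;
    res(k, 1) = frames[idx][1] + 1;
    res(k, 2) = frames[idx][2] + 1;
  }
  return res;
}

// Geometric-hashing vote counting.  Interface-1 points are expressed in
// every interface-1 frame, binned and stored keyed by (bin, fragment
// label); interface-2 frames probe the table, and a probe point votes for
// an interface-1 frame when some stored point of that frame shares its
// (neighborhood) bin and fragment label and the chemical-group bitmasks
// intersect.  Frame pairs reaching min_votes are returned together with
// the rigid transform (R, t) mapping interface-2 coordinates onto
// interface-1 (columns: f1, f2, votes, R column-major, t).
// [[Rcpp::export(name = "hash_vote_cpp")]]
NumericMatrix hash_vote_cpp(NumericMatrix pts1, IntegerVector frag1,
                            IntegerVector mask1, IntegerMatrix frames1,
                            NumericMatrix pts2, IntegerVector frag2,
                            IntegerVector mask2, IntegerMatrix frames2,
                            double bin_width, int min_votes) {
  const int n1 = pts1.nrow(), n2 = pts2.nrow();
  const int F1 = frames1.nrow(), F2 = frames2.nrow();
  struct Entry { int frame; uint8_t mask; };
  std::unordered_map<int64_t, std::vector<Entry>> table;
  table.reserve((size_t)F1 * n1 / 2);

  auto make_key = [](int bx, int by, int bz, int frag) {
    // 20-bit signed bins, 2 bits fragment
    return (((int64_t)(bx + 524288)) << 42) |
           (((int64_t)(by + 524288)) << 22) |
           (((int64_t)(bz + 524288)) << 2) | (int64_t)frag;
  };

  std::vector<double> B1(9 * F1), O1(3 * F1);
  std::vector<char> ok1(F1);
  for (int f = 0; f < F1; ++f) {
    bool ok;
    frame_basis(pts1, frames1(f, 0) - 1, frames1(f, 1) - 1,
                frames1(f, 2) - 1, &B1[9 * f], &O1[3 * f], ok);
    ok1[f] = ok;
    if (!ok) continue;
    const double *B = &B1[9 * f], *o = &O1[3 * f];
    for (int i = 0; i < n1; ++i) {
      double d0 = pts1(i, 0) - o[0], d1 = pts1(i, 1) - o[1],
             d2 = pts1(i, 2) - o[2];
      double u = B[0] * d0 + B[1] * d1 + B[2] * d2;
      double v = B[3] * d0 + B[4] * d1 + B[5] * d2;
      double w = B[6] * d0 + B[7] * d1 + B[8] * d2;
      int bx = (int)std::floor(u / bin_width);
      int by = (int)std::floor(v / bin_width);
      int bz = (int)std::floor(w / bin_width);
      table[make_key(bx, by, bz, frag1[i])].push_back(
          Entry{f, (uint8_t)mask1[i]});
    }
  }

  std::vector<int> votes(F1, 0);
  std::vector<int> stamp(F1, -1);
  std::vector<int> touched;
  touched.reserve(F1);
  std::vector<double> out;  // rows of 15

  for (int g = 0; g < F2; ++g) {
    bool ok;
    double B[9], o[3];
    frame_basis(pts2, frames2(g, 0) - 1, frames2(g, 1) - 1,
                frames2(g, 2) - 1, B, o, ok);
    if (!ok) continue;
    touched.clear();
    for (int j = 0; j < n2; ++j) {
      double d0 = pts2(j, 0) - o[0], d1 = pts2(j, 1) - o[1],
             d2 = pts2(j, 2) - o[2];
      double u = B[0] * d0 + B[1] * d1 + B[2] * d2;
      double v = B[3] * d0 + B[4] * d1 + B[5] * d2;
      double w = B[6] * d0 + B[7] * d1 + B[8] * d2;
      int bx = (int)std::floor(u / bin_width);
      int by = (int)std::floor(v / bin_width);
      int bz = (int)std::floor(w / bin_width);
      int fj = frag2[j];
      int mj = mask2[j];
      int point_stamp = g * n2 + j;
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay)
          for (int az = -1; az <= 1; ++az) {
            auto it = table.find(make_key(bx + ax, by + ay, bz + az, fj));
            if (it == table.end()) continue;
            for (const Entry &e : it->second) {
              if ((e.mask & mj) == 0) continue;
              if (stamp[e.frame] == point_stamp) continue;
              stamp[e.frame] = point_stamp;
              if (votes[e.frame] == 0) touched.push_back(e.frame);
              ++votes[e.frame];
            }
          }
    }
    for (int f : touched) {
      int nv = votes[f];
      votes[f] = 0;
      if (nv < min_votes || !ok1[f]) continue;
      // transform: x2 -> Bf * Bg^T * (x2 - og) + of
      const double *Bf = &B1[9 * f], *of = &O1[3 * f];
      double R[9];
      // Bf (3x3, columns ex,ey,ez stored as rows of triples) times Bg^T:
      // Bf as matrix M1 with M1[row][col] = Bf[3*col + row]
      for (int rr = 0; rr < 3; ++rr)
        for (int cc = 0; cc < 3; ++cc) {
          double s = 0;
          for (int k = 0; k < 3; ++k)
            s += Bf[3 * k + rr] * B[3 * k + cc];
          R[3 * cc + rr] = s;  // column-major
        }
      double t[3];
      for (int rr = 0; rr < 3; ++rr) {
        double s = 0;
        for (int cc = 0; cc < 3; ++cc) s += R[3 * cc + rr] * o[cc];
        t[rr] = of[rr] - s;
      }
      out.push_back(f + 1);
      out.push_back(g + 1);
      out.push_back(nv);
      for (int k = 0; k < 9; ++k) out.push_back(R[k]);
      for (int k = 0; k < 3; ++k) out.push_back(t[k]);
    }
  }
  int m = (int)(out.size() / 15);
  NumericMatrix res(m, 15);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 15; ++c) res(r, c) = out[15 * r + c];
  return res;
}

// Geometric quality of candidate transforms: for each candidate (rows of
// votes + R column-major + t), transform every interface-2 point and sum
// max(0, 1 - d/radius) over its best fragment- and chemistry-compatible
// interface-1 neighbor.  Unlike the binned vote count this varies smoothly
// with the transform, so it separates exact superpositions from near
// misses that collect the same votes; it is also invariant under joint
// rigid motion of interface 2 and the candidates.
// [[Rcpp::export(name = "hash_quality_cpp")]]
NumericVector hash_quality_cpp(NumericMatrix pts1, IntegerVector frag1,
                               IntegerVector mask1, NumericMatrix pts2,
                               IntegerVector frag2, IntegerVector mask2,
                               NumericMatrix cand, double radius) {
  const int n1 = pts1.nrow(), n2 = pts2.nrow(), K = cand.nrow();
  NumericVector out(K);
  const double r2 = radius * radius;
  for (int k = 0; k < K; ++k) {
    double R[9], t[3];
    for (int c = 0; c < 9; ++c) R[c] = cand(k, 1 + c);
    for (int c = 0; c < 3; ++c) t[c] = cand(k, 10 + c);
    double q = 0;
    for (int j = 0; j < n2; ++j) {
      double x = R[0] * pts2(j, 0) + R[3] * pts2(j, 1) + R[6] * pts2(j, 2)
                 + t[0];
      double y = R[1] * pts2(j, 0) + R[4] * pts2(j, 1) + R[7] * pts2(j, 2)
                 + t[1];
      double z = R[2] * pts2(j, 0) + R[5] * pts2(j, 1) + R[8] * pts2(j, 2)
                 + t[2];
      double best = r2;
      for (int i = 0; i < n1; ++i) {
        if (frag1[i] != frag2[j] || (mask1[i] & mask2[j]) == 0) continue;
        double dx = pts1(i, 0) - x, dy = pts1(i, 1) - y,
               dz = pts1(i, 2) - z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      if (best < r2) q += 1.0 - std::sqrt(best) / radius;
    }
    out[k] = q;
  }
  return out;
}

// Greedy leader clustering of transform candidates.  cand: rows sorted by
// votes descending, columns (votes, R column-major 9, t 3).  A candidate
// joins the first representative with relative rotation angle <= acos
// (cos_tol) and translation offset^2 <= trans_tol2; representatives
// accumulate votes.  At most rep_cap representatives are kept; candidates
// matching none once the cap is reached are dropped (low-vote tail).
// Output re-sorted by summed votes.
// [[Rcpp::export(name = "cluster_cands_cpp")]]
NumericMatrix cluster_cands_cpp(NumericMatrix cand, double cos_tol,
                                double trans_tol2, int rep_cap) {
  const int n = cand.nrow();
  std::vector<std::array<double, 13>> reps;
  reps.reserve(rep_cap > 0 ? rep_cap : 256);
  for (int k = 0; k < n; ++k) {
    double row[13];
    for (int c = 0; c < 13; ++c) row[c] = cand(k, c);
    int hit = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      double dt2 = 0;
      for (int c = 10; c < 13; ++c) {
        double d = reps[r][c] - row[c];
        dt2 += d * d;
      }
      if (dt2 > trans_tol2) continue;
      double tr = 0;
      for (int c = 1; c < 10; ++c) tr += reps[r][c] * row[c];
      if ((tr - 1.0) / 2.0 < cos_tol) continue;
      hit = (int)r;
      break;
    }
    if (hit >= 0) {
      reps[hit][0] += row[0];
    } else if (rep_cap <= 0 || (int)reps.size() < rep_cap) {
      std::array<double, 13> a;
      for (int c = 0; c < 13; ++c) a[c] = row[c];
      reps.push_back(a);
    }
  }
  std::vector<int> ord(reps.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return reps[a][0] > reps[b][0];
  });
  NumericMatrix res(reps.size(), 13);
  for (size_t i = 0; i < ord.size(); ++i)
    for (int c = 0; c < 13; ++c) res(i, c) = reps[ord[i]][c];
  return res;
}

// Assignment problem, shortest-augmenting-path formulation (O(n^2 m)).
// cost is n x m, column-major, with n <= m; fills row_to_col (0-based).
// Deterministic: ties resolved by column scan order.
static void solve_assignment(const double *cost, int n, int m,
                             std::vector<int> &row_to_col) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost[(size_t)(j - 1) * n + (i0 - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  row_to_col.assign(n, -1);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) row_to_col[p[j] - 1] = j - 1;
}

// [[Rcpp::export(name = "hungarian_cpp")]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("hungarian_cpp needs nrow <= ncol");
  std::vector<int> asg;
  solve_assignment(&cost[0], n, m, asg);
  IntegerVector ans(n);
  for (int i = 0; i < n; ++i) ans[i] = asg[i] + 1;
  return ans;
}

// One matching block (fragment pairing) for the refinement loop.
struct Block {
  std::vector<int> a, b;      // 0-based residue indices into each interface
  std::vector<double> same;   // |a| x |b| chemical-identity indicator
};

static void match_block(const arma::mat &ca1, const arma::mat &tc2,
                        const Block &bl, std::vector<int> &out1,
                        std::vector<int> &out2, std::vector<double> &outd,
                        std::vector<double> &outsame,
                        std::vector<double> &outeq) {
  const int na = (int)bl.a.size(), nb = (int)bl.b.size();
  if (na == 0 || nb == 0) return;
  // weights and distances, a-major (na x nb, column-major over b)
  std::vector<double> w((size_t)na * nb), dm((size_t)na * nb);
  double wmax = 0;
  for (int j = 0; j < nb; ++j) {
    for (int i = 0; i < na; ++i) {
      double dx = ca1(bl.a[i], 0) - tc2(bl.b[j], 0);
      double dy = ca1(bl.a[i], 1) - tc2(bl.b[j], 1);
      double dz = ca1(bl.a[i], 2) - tc2(bl.b[j], 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double s = bl.same[(size_t)j * na + i];
      double wij = 1.0 / (1.0 + 0.25 * (1.0 - s) + d2 / 16.0);
      w[(size_t)j * na + i] = wij;
      dm[(size_t)j * na + i] = std::sqrt(d2);
      if (wij > wmax) wmax = wij;
    }
  }
  std::vector<int> asg;
  if (na <= nb) {
    std::vector<double> cost((size_t)na * nb);
    for (size_t k = 0; k < cost.size(); ++k) cost[k] = wmax - w[k];
    solve_assignment(cost.data(), na, nb, asg);
    for (int i = 0; i < na; ++i) {
      int j = asg[i];
      out1.push_back(bl.a[i]);
      out2.push_back(bl.b[j]);
      outd.push_back(dm[(size_t)j * na + i]);
      outsame.push_back(bl.same[(size_t)j * na + i]);
      outeq.push_back(w[(size_t)j * na + i]);
    }
  } else {
    // transpose so rows <= cols
    std::vector<double> cost((size_t)na * nb);
    for (int j = 0; j < nb; ++j)
      for (int i = 0; i < na; ++i)
        cost[(size_t)i * nb + j] = wmax - w[(size_t)j * na + i];
    solve_assignment(cost.data(), nb, na, asg);
    for (int j = 0; j < nb; ++j) {
      int i = asg[j];
      out1.push_back(bl.a[i]);
      out2.push_back(bl.b[j]);
      outd.push_back(dm[(size_t)j * na + i]);
      outsame.push_back(bl.same[(size_t)j * na + i]);
      outeq.push_back(w[(size_t)j * na + i]);
    }
  }
}

// Iterative refinement of one candidate transform: alternate per-block
// maximum-weight matching with Kabsch superposition over the matched
// pairs; track the best summed equivalence score.  Returns the best
// iterate (R, t, pairs as a 5-column matrix of 1-based idx1, idx2, d,
// same_chem, eq_score, in idx1 order), its score, the iteration count and
// a degeneracy flag (matching below 3 pairs or collinear matched set).
// [[Rcpp::export(name = "refine_cpp")]]
List refine_cpp(NumericMatrix ca1_, NumericMatrix ca2_,
                IntegerVector a1, IntegerVector b1, IntegerVector a2,
                IntegerVector b2, NumericMatrix sameA, NumericMatrix sameB,
                NumericMatrix R0, NumericVector t0, double tol,
                int max_iter) {
  arma::mat ca1(ca1_.begin(), ca1_.nrow(), 3, false);
  arma::mat ca2(ca2_.begin(), ca2_.nrow(), 3, false);
  Block blA, blB;
  for (int i = 0; i < a1.size(); ++i) blA.a.push_back(a1[i] - 1);
  for (int i = 0; i < a2.size(); ++i) blA.b.push_back(a2[i] - 1);
  for (int i = 0; i < b1.size(); ++i) blB.a.push_back(b1[i] - 1);
  for (int i = 0; i < b2.size(); ++i) blB.b.push_back(b2[i] - 1);
  blA.same.assign(sameA.begin(), sameA.end());
  blB.same.assign(sameB.begin(), sameB.end());

  arma::mat R(R0.begin(), 3, 3);
  arma::vec t(t0.begin(), 3);
  arma::mat bestR = R;
  arma::vec bestT = t;
  std::vector<int> best1, best2;
  std::vector<double> bestd, bestsame, besteq;
  double best_score = -1.0;
  int best_iter = 0;
  bool degenerate = false;

  std::vector<int> prev1, prev2;
  double prev_score = -1e300;
  for (int it = 1; it <= max_iter; ++it) {
    arma::mat tc2 = ca2 * R.t();
    tc2.each_row() += t.t();
    std::vector<int> m1, m2;
    std::vector<double> md, msame, meq;
    match_block(ca1, tc2, blA, m1, m2, md, msame, meq);
    match_block(ca1, tc2, blB, m1, m2, md, msame, meq);
    double score = 0;
    for (double e : meq) score += e;
    if (score > best_score) {
      best_score = score;
      bestR = R;
      bestT = t;
      best1 = m1; best2 = m2; bestd = md; bestsame = msame; besteq = meq;
      best_iter = it;
    }
    if ((int)m1.size() < 3) {
      degenerate = true;
      break;
    }
    bool same_set = (m1 == prev1 && m2 == prev2);
    if (same_set || (it > 1 && std::fabs(score - prev_score) < tol)) break;
    prev1 = m1; prev2 = m2;
    prev_score = score;
    // Kabsch over the matched pairs
    const int np = (int)m1.size();
    arma::mat x1(np, 3), x2(np, 3);
    for (int k = 0; k < np; ++k) {
      for (int c = 0; c < 3; ++c) {
        x1(k, c) = ca1(m1[k], c);
        x2(k, c) = ca2(m2[k], c);
      }
    }
    arma::rowvec c1 = arma::mean(x1, 0), c2 = arma::mean(x2, 0);
    x1.each_row() -= c1;
    x2.each_row() -= c2;
    arma::mat H = x2.t() * x1;
    arma::mat U, V;
    arma::vec s;
    if (!arma::svd(U, s, V, H)) { degenerate = true; break; }
    if (s(1) <= 1e-9 * std::max(s(0), 1e-12) || s(1) <= 1e-12) {
      degenerate = true;  // collinear matched set
      break;
    }
    arma::mat Rn = V * U.t();
    if (arma::det(Rn) < 0) {
      arma::mat D = arma::eye(3, 3);
      D(2, 2) = -1;
      Rn = V * D * U.t();
    }
    R = Rn;
    t = c1.t() - R * c2.t();
  }

  // order pairs by idx1
  const int np = (int)best1.size();
  std::vector<int> ord(np);
  for (int i = 0; i < np; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (best1[x] != best1[y]) return best1[x] < best1[y];
    return best2[x] < best2[y];
  });
  NumericMatrix pairs(np, 5);
  for (int i = 0; i < np; ++i) {
    int k = ord[i];
    pairs(i, 0) = best1[k] + 1;
    pairs(i, 1) = best2[k] + 1;
    pairs(i, 2) = bestd[k];
    pairs(i, 3) = bestsame[k];
    pairs(i, 4) = besteq[k];
  }
  NumericMatrix Rout(3, 3);
  NumericVector tout(3);
  for (int c = 0; c < 3; ++c) {
    for (int r = 0; r < 3; ++r) Rout(r, c) = bestR(r, c);
    tout[c] = bestT(c);
  }
  return List::create(_["rotation"] = Rout, _["translation"] = tout,
                      _["pairs"] = pairs, _["score"] = best_score,
                      _["iterations"] = best_iter,
                      _["degenerate"] = degenerate);
}
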