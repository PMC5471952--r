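#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

// Interval of achievable values for one partially fixed coordinate:
// [pref * 2^r, pref * 2^r + 2^r - 1].  All arithmetic in double; the widest
// quantities here are squared grid distances (< 2^(2b+1), b <= ~14), exactly
// representable.

static inline void axis_diff_bounds(double loA, double hiA, double loB,
                                    double hiB, double &dmin, double &dmax) {
  if (loA > hiB)
    dmin = loA - hiB;
  else if (loB > hiA)
    dmin = loB - hiA;
  else
    dmin = 0.0; // intervals overlap
  dmax = std::max(hiA - loB, hiB - loA);
}

// Min / max achievable squared Euclidean distance between two points whose
// per-axis coordinates range over the given intervals.
static inline void pair_sq_bounds(const std::vector<double> &loI,
                                  const std::vector<double> &hiI,
                                  const std::vector<double> &loJ,
                                  const std::vector<double> &hiJ, int k,
                                  double &lo, double &hi) {
  lo = 0.0;
  hi = 0.0;
  for (int a = 0; a < k; ++a) {
    double dmin, dmax;
    axis_diff_bounds(loI[a], hiI[a], loJ[a], hiJ[a], dmin, dmax);
    lo += dmin * dmin;
    hi += dmax * dmax;
  }
}

// One refinement step: every point currently has an s-bit prefix per axis;
// choose the next l bits per point per axis so that for every pair i != j the
// interval of achievable squared distances (over the remaining r - l free
// bits) still meets the band [BLO(i,j), BHI(i,j)] (squared grid units).
//
// Complete backtracking search over the 2^(k*l) block choices per point, with
// candidate ordering by closeness of sub-square midpoints to the target
// distances (so the model returned is biased toward accurate placements).
//
// literal_rule applies both band bounds to the maximum reachable squared
// distance (the constraint exactly as printed) instead of intersecting the
// reachable interval with the band; at the final iteration the two coincide.
//
// status: 0 = SAT, 1 = UNSAT, 2 = node budget exhausted.
// [[Rcpp::export]]
List cpp_solve_step(IntegerMatrix prefixes, int b, int s, int l,
                    NumericMatrix D2, NumericMatrix BLO, NumericMatrix BHI,
                    double node_budget, bool symmetry_break,
                    bool literal_rule) {
  const int d = prefixes.nrow();
  const int k = prefixes.ncol();
  const int r = b - s;      // free bits before this step
  const int rl = r - l;     // free bits after this step
  const double span = std::pow(2.0, rl) - 1.0; // width of the residual range
  const double blockStep = std::pow(2.0, rl);
  const int nBlock = 1 << l;     // per-axis block values
  const int nCand = 1 << (k * l); // combined candidates per point

  // per point, per candidate: lo/hi interval per axis after appending
  std::vector<std::vector<double>> candLo(d), candHi(d), candMid(d);
  for (int i = 0; i < d; ++i) {
    candLo[i].assign(nCand * k, 0.0);
    candHi[i].assign(nCand * k, 0.0);
    candMid[i].assign(nCand * k, 0.0);
    for (int c = 0; c < nCand; ++c) {
      for (int a = 0; a < k; ++a) {
        int block = (c >> (a * l)) & (nBlock - 1);
        double np = (double)prefixes(i, a) * nBlock + block;
        double lo = np * blockStep;
        candLo[i][c * k + a] = lo;
        candHi[i][c * k + a] = lo + span;
        candMid[i][c * k + a] = lo + span / 2.0;
      }
    }
  }

  std::vector<int> chosen(d, -1);
  std::vector<std::vector<int>> order(d); // candidate order per point (filled per depth)
  double nodes = 0.0;
  bool budget_hit = false;

  // recursive backtracking over points 0..d-1
  std::function<bool(int)> assign = [&](int i) -> bool {
    if (i == d) return true;
    // score candidates by midpoint fit to already-assigned points
    std::vector<std::pair<double, int>> scored;
    scored.reserve(nCand);
    for (int c = 0; c < nCand; ++c) {
      if (symmetry_break && s == 0 && i == 0 && l >= 1) {
        // reflection symmetry per axis: restrict the first point's first
        // block to the lower half of each axis
        bool ok = true;
        for (int a = 0; a < k; ++a) {
          int block = (c >> (a * l)) & (nBlock - 1);
          if (block >= (nBlock >> 1) && nBlock > 1) { ok = false; break; }
        }
        if (!ok) continue;
      }
      double score = 0.0;
      for (int j = 0; j < i; ++j) {
        double md2 = 0.0;
        int cj = chosen[j];
        for (int a = 0; a < k; ++a) {
          double diff = candMid[i][c * k + a] - candMid[j][cj * k + a];
          md2 += diff * diff;
        }
        score += std::fabs(md2 - D2(i, j));
      }
      scored.push_back(std::make_pair(score, c));
    }
    std::stable_sort(scored.begin(), scored.end());

    std::vector<double> loI(k), hiI(k), loJ(k), hiJ(k);
    for (size_t t = 0; t < scored.size(); ++t) {
      int c = scored[t].second;
      nodes += 1.0;
      if (nodes > node_budget) { budget_hit = true; return false; }
      bool feasible = true;
      for (int a = 0; a < k; ++a) {
        loI[a] = candLo[i][c * k + a];
        hiI[a] = candHi[i][c * k + a];
      }
      for (int j = 0; j < i && feasible; ++j) {
        int cj = chosen[j];
        for (int a = 0; a < k; ++a) {
          loJ[a] = candLo[j][cj * k + a];
          hiJ[a] = candHi[j][cj * k + a];
        }
        double lo, hi;
        pair_sq_bounds(loI, hiI, loJ, hiJ, k, lo, hi);
        if (literal_rule) {
          if (hi > BHI(i, j) || hi < BLO(i, j)) feasible = false;
        } else if (lo > BHI(i, j) || hi < BLO(i, j)) {
          feasible = false;
        }
      }
      if (!feasible) continue;
      chosen[i] = c;
      if (assign(i + 1)) return true;
      if (budget_hit) return false;
      chosen[i] = -1;
    }
    return false;
  };

  bool sat = assign(0);
  int status = sat ? 0 : (budget_hit ? 2 : 1);
  IntegerMatrix blocks(d, k);
  if (sat) {
    for (int i = 0; i < d; ++i)
      for (int a = 0; a < k; ++a)
        blocks(i, a) = (chosen[i] >> (a * l)) & (nBlock - 1);
  }
  return List::create(Named("status") = status, Named("blocks") = blocks,
                      Named("nodes") = nodes);
}

// Full iterative-refinement synthesis with chronological backtracking across
// refinement levels: the same level-by-level, point-by-point assignment of
// l-bit blocks as cpp_solve_step, but a dead end at a later level backtracks
// into earlier levels' choices instead of failing, making the search for a
// band-satisfying embedding complete (up to the node budget). At the final
// level the reachable intervals are exact distances, so a returned embedding
// satisfies the band for every pair by construction.
//
// status: 0 = SAT, 1 = UNSAT, 2 = node budget exhausted.
// When use_hint is true, candidates are ordered by the distance of their
// sub-square midpoint to a reference configuration `hint` (d x k, grid
// units) instead of by pairwise midpoint fit; the band constraints and the
// backtracking are unchanged, so the hint only steers which satisfying
// model is found first.
// [[Rcpp::export]]
List cpp_synthesize(int d, int k, int b, int l, NumericMatrix BLO,
                    NumericMatrix BHI, double node_budget,
                    bool symmetry_break, NumericMatrix hint, bool use_hint) {
  const int levels = b / l;
  const int nBlock = 1 << l;
  const int nCand = 1 << (k * l);
  std::vector<double> pref(d * k, 0.0); // current coordinate prefixes (values)
  std::vector<int> fixed(d, 0);          // bits fixed per point
  double nodes = 0.0;
  bool budget_hit = false;
  int deepest = 0; // most bits ever fixed for any point, for diagnostics

  auto interval = [&](int i, int a, double &lo, double &hi) {
    double free_bits = b - fixed[i];
    double step = std::pow(2.0, free_bits);
    lo = pref[i * k + a] * step;
    hi = lo + step - 1.0;
  };

  std::function<bool(int, int)> assign = [&](int level, int i) -> bool {
    if (i == d) {
      if (level + 1 == levels) return true;
      return assign(level + 1, 0);
    }
    const int s = level * l;
    const int rl = b - s - l; // free bits after appending at this level
    const double span = std::pow(2.0, rl) - 1.0;
    const double blockStep = std::pow(2.0, rl);

    // candidate ordering: midpoint fit against every other point's current
    // interval midpoint (coarser for points not yet refined at this level)
    std::vector<std::pair<double, int>> scored;
    scored.reserve(nCand);
    for (int c = 0; c < nCand; ++c) {
      if (symmetry_break && level == 0 && i == 0 && nBlock > 1) {
        bool ok = true;
        for (int a = 0; a < k; ++a) {
          int block = (c >> (a * l)) & (nBlock - 1);
          if (block >= (nBlock >> 1)) { ok = false; break; }
        }
        if (!ok) continue;
      }
      double score = 0.0;
      if (use_hint) {
        for (int a = 0; a < k; ++a) {
          int block = (c >> (a * l)) & (nBlock - 1);
          double lo = (pref[i * k + a] * nBlock + block) * blockStep;
          double midI = lo + span / 2.0;
          double diff = midI - hint(i, a);
          score += diff * diff;
        }
      } else {
        for (int j = 0; j < d; ++j) {
          if (j == i) continue;
          double md2 = 0.0;
          for (int a = 0; a < k; ++a) {
            int block = (c >> (a * l)) & (nBlock - 1);
            double lo = (pref[i * k + a] * nBlock + block) * blockStep;
            double midI = lo + span / 2.0;
            double loJ, hiJ;
            interval(j, a, loJ, hiJ);
            double diff = midI - (loJ + hiJ) / 2.0;
            md2 += diff * diff;
          }
          double tgt = (BLO(i, j) + BHI(i, j)) / 2.0;
          score += std::fabs(md2 - tgt);
        }
      }
      scored.push_back(std::make_pair(score, c));
    }
    std::stable_sort(scored.begin(), scored.end());

    for (size_t t = 0; t < scored.size(); ++t) {
      int c = scored[t].second;
      nodes += 1.0;
      if (nodes > node_budget) { budget_hit = true; return false; }
      // tentatively append
      double savedPref[3];
      for (int a = 0; a < k; ++a) {
        savedPref[a] = pref[i * k + a];
        int block = (c >> (a * l)) & (nBlock - 1);
        pref[i * k + a] = pref[i * k + a] * nBlock + block;
      }
      int savedFixed = fixed[i];
      fixed[i] = s + l;
      if (s + l > deepest) deepest = s + l;
      // necessary conditions vs points already refined at this level
      bool feasible = true;
      for (int j = 0; j < i && feasible; ++j) {
        double lo = 0.0, hi = 0.0;
        for (int a = 0; a < k; ++a) {
          double loI, hiI, loJ, hiJ, dmin, dmax;
          interval(i, a, loI, hiI);
          interval(j, a, loJ, hiJ);
          axis_diff_bounds(loI, hiI, loJ, hiJ, dmin, dmax);
          lo += dmin * dmin;
          hi += dmax * dmax;
        }
        if (lo > BHI(i, j) || hi < BLO(i, j)) feasible = false;
      }
      if (feasible && assign(level, i + 1)) return true;
      // undo
      for (int a = 0; a < k; ++a) pref[i * k + a] = savedPref[a];
      fixed[i] = savedFixed;
      if (budget_hit) return false;
    }
    return false;
  };

  bool sat = assign(0, 0);
  int status = sat ? 0 : (budget_hit ? 2 : 1);
  IntegerMatrix coords(d, k);
  if (sat) {
    for (int i = 0; i < d; ++i)
      for (int a = 0; a < k; ++a)
        coords(i, a) = (int)pref[i * k + a];
  }
  return List::create(Named("status") = status, Named("coords") = coords,
                      Named("nodes") = nodes, Named("deepest") = deepest);
}

// Exhaustive search over all grid placements of d points in k = 2 dimensions
// with b-bit coordinates, minimizing the maximum additive distortion
// | ||R_i - R_j|| - D[i,j] |.  Branch-and-bound over points with per-axis
// reflection symmetry reduction on the first point.
// [[Rcpp::export]]
List cpp_brute_force_embedding(NumericMatrix D, int b, int k) {
  const int d = D.nrow();
  if (k != 2) stop("exhaustive oracle supports k = 2 only");
  if (d > 4 || b > 3) stop("instance above exhaustive-search size bounds");
  const int g = 1 << b; // grid side
  std::vector<int> X(d), Y(d), bestX(d), bestY(d);
  double best = R_PosInf;

  std::function<void(int, double)> place = [&](int i, double curMax) {
    if (i == d) {
      if (curMax < best) {
        best = curMax;
        bestX = X;
        bestY = Y;
      }
      return;
    }
    int xmax = g, ymax = g;
    if (i == 0) { // reflection symmetry: first point in the lower quadrant
      xmax = (g + 1) / 2;
      ymax = (g + 1) / 2;
    }
    for (int x = 0; x < xmax; ++x) {
      for (int y = 0; y < ymax; ++y) {
        double m = curMax;
        bool prune = false;
        for (int j = 0; j < i; ++j) {
          double dx = x - X[j], dy = y - Y[j];
          double dist = std::sqrt(dx * dx + dy * dy);
          double e = std::fabs(dist - D(i, j));
          if (e > m) m = e;
          if (m >= best) { prune = true; break; }
        }
        if (prune) continue;
        X[i] = x;
        Y[i] = y;
        place(i + 1, m);
      }
    }
  };
  place(0, 0.0);

  IntegerMatrix coords(d, 2);
  for (int i = 0; i < d; ++i) {
    coords(i, 0) = bestX[i];
    coords(i, 1) = bestY[i];
  }
  return List::create(Named("min_max_distortion") = best,
                      Named("coords") = coords);
}
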