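// Minimum-free-energy folding under a simplified nearest-neighbor model:
// Watson-Crick/GU stacking energies, length-dependent hairpin/bulge/internal
// loop penalties, affine multiloop cost, no dangles or coaxial stacking,
// plus a per-paired-nucleotide pseudo-energy vector (Deigan-style SHAPE
// restraint). Recurrences are the standard V / M / M1 / W set with the
// multiloop closed as M + M1 to force at least two branches.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;

// pair codes: 0 = not pairable, 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG
static inline int pairCode(int a, int b) {
  // bases: 0 A, 1 C, 2 G, 3 U
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct FoldCtx {
  int n, maxLoop, minHairpin;
  const int *seq;
  const double *pe;
  NumericMatrix stackE;      // 6x6, 0-based by pairCode-1
  const double *hp;          // penalty for loop size s at index s-1
  const double *bu;
  const double *in_;
  double mlA, mlB, mlC;
  std::vector<double> V, M, M1;
  std::vector<double> W;
  std::vector<int> pc;       // pairCode(i,j) cache

  inline int idx(int i, int j) const { return i * n + j; }
  inline double loopPen(const double *tab, int s) const { return tab[s - 1]; }
};

static void fill(FoldCtx &c) {
  int n = c.n;
  c.V.assign(n * n, INF);
  c.M.assign(n * n, INF);
  c.M1.assign(n * n, INF);
  c.pc.assign(n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      c.pc[c.idx(i, j)] = pairCode(c.seq[i], c.seq[j]);

  for (int span = c.minHairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i, j)
      if (c.pc[c.idx(i, j)] != 0) {
        double best = c.loopPen(c.hp, j - i - 1);
        // interior: stacks, bulges, internal loops
        for (int k = i + 1; k <= std::min(i + c.maxLoop + 1, j - c.minHairpin - 1); ++k) {
          int lmin = std::max(k + c.minHairpin + 1, j - 1 - (c.maxLoop - (k - i - 1)));
          for (int l = lmin; l <= j - 1; ++l) {
            if (k == i + 1 && l == j - 1) {
              // stack
              if (c.pc[c.idx(k, l)] && c.V[c.idx(k, l)] < INF / 2) {
                double e = c.stackE(c.pc[c.idx(i, j)] - 1, c.pc[c.idx(k, l)] - 1) +
                           c.V[c.idx(k, l)];
                if (e < best) best = e;
              }
              continue;
            }
            int u = (k - i - 1) + (j - l - 1);
            if (u == 0 || u > c.maxLoop) continue;
            if (!c.pc[c.idx(k, l)] || c.V[c.idx(k, l)] >= INF / 2) continue;
            double pen = (k == i + 1 || l == j - 1) ? c.loopPen(c.bu, u)
                                                    : c.loopPen(c.in_, u);
            double e = pen + c.V[c.idx(k, l)];
            if (e < best) best = e;
          }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          double m = c.M[c.idx(i + 1, k)];
          double m1 = c.M1[c.idx(k + 1, j - 1)];
          if (m < INF / 2 && m1 < INF / 2) {
            double e = c.mlA + c.mlB + m + m1;
            if (e < best) best = e;
          }
        }
        c.V[c.idx(i, j)] = best + c.pe[i] + c.pe[j];
      }
      // --- M1(i, j): one branch starting exactly at i
      {
        double best = INF;
        if (c.V[c.idx(i, j)] < INF / 2) best = c.V[c.idx(i, j)] + c.mlB;
        if (j - 1 > i && c.M1[c.idx(i, j - 1)] < INF / 2)
          best = std::min(best, c.M1[c.idx(i, j - 1)] + c.mlC);
        c.M1[c.idx(i, j)] = best;
      }
      // --- M(i, j): at least one branch
      {
        double best = INF;
        if (c.V[c.idx(i, j)] < INF / 2) best = c.V[c.idx(i, j)] + c.mlB;
        if (i + 1 < j && c.M[c.idx(i + 1, j)] < INF / 2)
          best = std::min(best, c.M[c.idx(i + 1, j)] + c.mlC);
        if (j - 1 > i && c.M[c.idx(i, j - 1)] < INF / 2)
          best = std::min(best, c.M[c.idx(i, j - 1)] + c.mlC);
        for (int k = i + 1; k < j; ++k) {
          double a = c.M[c.idx(i, k)], b = c.M[c.idx(k + 1, j)];
          if (a < INF / 2 && b < INF / 2) best = std::min(best, a + b);
        }
        c.M[c.idx(i, j)] = best;
      }
    }
  }
  // external
  c.W.assign(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double best = c.W[j];   // j unpaired (W indexed with offset +1)
    for (int i = 0; i + c.minHairpin + 1 <= j; ++i) {
      double v = c.V[c.idx(i, j)];
      if (v < INF / 2) {
        double e = (i > 0 ? c.W[i] : 0.0) + v;
        if (e < best) best = e;
      }
    }
    c.W[j + 1] = best;
  }
}

struct Seg { int type; int i, j; };  // 0 V, 1 M, 2 M1

static void traceback(FoldCtx &c, std::vector<int> &pt) {
  int n = c.n;
  pt.assign(n, -1);
  std::vector<Seg> st;
  // external
  int j = n - 1;
  while (j >= 0) {
    if (std::fabs(c.W[j + 1] - c.W[j]) < EPS) { --j; continue; }
    bool found = false;
    for (int i = 0; i + c.minHairpin + 1 <= j; ++i) {
      double v = c.V[c.idx(i, j)];
      if (v < INF / 2 &&
          std::fabs((i > 0 ? c.W[i] : 0.0) + v - c.W[j + 1]) < EPS) {
        st.push_back({0, i, j});
        j = i - 1;
        found = true;
        break;
      }
    }
    if (!found) stop("traceback failure in external loop");
  }
  while (!st.empty()) {
    Seg s = st.back(); st.pop_back();
    int i = s.i; j = s.j;
    if (s.type == 0) {
      pt[i] = j; pt[j] = i;
      double base = c.V[c.idx(i, j)] - c.pe[i] - c.pe[j];
      if (std::fabs(base - c.loopPen(c.hp, j - i - 1)) < EPS) continue;
      bool found = false;
      for (int k = i + 1; !found &&
           k <= std::min(i + c.maxLoop + 1, j - c.minHairpin - 1); ++k) {
        int lmin = std::max(k + c.minHairpin + 1, j - 1 - (c.maxLoop - (k - i - 1)));
        for (int l = lmin; l <= j - 1; ++l) {
          if (!c.pc[c.idx(k, l)] || c.V[c.idx(k, l)] >= INF / 2) continue;
          double pen;
          if (k == i + 1 && l == j - 1)
            pen = c.stackE(c.pc[c.idx(i, j)] - 1, c.pc[c.idx(k, l)] - 1);
          else {
            int u = (k - i - 1) + (j - l - 1);
            if (u == 0 || u > c.maxLoop) continue;
            pen = (k == i + 1 || l == j - 1) ? c.loopPen(c.bu, u)
                                            : c.loopPen(c.in_, u);
          }
          if (std::fabs(pen + c.V[c.idx(k, l)] - base) < EPS) {
            st.push_back({0, k, l});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int k = i + 2; k <= j - 2; ++k) {
        double m = c.M[c.idx(i + 1, k)], m1 = c.M1[c.idx(k + 1, j - 1)];
        if (m < INF / 2 && m1 < INF / 2 &&
            std::fabs(c.mlA + c.mlB + m + m1 - base) < EPS) {
          st.push_back({1, i + 1, k});
          st.push_back({2, k + 1, j - 1});
          found = true;
          break;
        }
      }
      if (!found) stop("traceback failure in V");
    } else if (s.type == 1) {
      double m = c.M[c.idx(i, j)];
      if (c.V[c.idx(i, j)] < INF / 2 &&
          std::fabs(c.V[c.idx(i, j)] + c.mlB - m) < EPS) {
        st.push_back({0, i, j});
      } else if (i + 1 < j && c.M[c.idx(i + 1, j)] < INF / 2 &&
                 std::fabs(c.M[c.idx(i + 1, j)] + c.mlC - m) < EPS) {
        st.push_back({1, i + 1, j});
      } else if (j - 1 > i && c.M[c.idx(i, j - 1)] < INF / 2 &&
                 std::fabs(c.M[c.idx(i, j - 1)] + c.mlC - m) < EPS) {
        st.push_back({1, i, j - 1});
      } else {
        bool found = false;
        for (int k = i + 1; k < j; ++k) {
          double a = c.M[c.idx(i, k)], b = c.M[c.idx(k + 1, j)];
          if (a < INF / 2 && b < INF / 2 && std::fabs(a + b - m) < EPS) {
            st.push_back({1, i, k});
            st.push_back({1, k + 1, j});
            found = true;
            break;
          }
        }
        if (!found) stop("traceback failure in M");
      }
    } else {
      double m1 = c.M1[c.idx(i, j)];
      if (c.V[c.idx(i, j)] < INF / 2 &&
          std::fabs(c.V[c.idx(i, j)] + c.mlB - m1) < EPS) {
        st.push_back({0, i, j});
      } else if (j - 1 > i && c.M1[c.idx(i, j - 1)] < INF / 2 &&
                 std::fabs(c.M1[c.idx(i, j - 1)] + c.mlC - m1) < EPS) {
        st.push_back({2, i, j - 1});
      } else stop("traceback failure in M1");
    }
  }
}

// [[Rcpp::export(name = ".foldDP")]]
List foldDP(IntegerVector seqCode, NumericVector pe, NumericMatrix stackE,
            NumericVector hairpinPen, NumericVector bulgePen,
            NumericVector internalPen, double mlA, double mlB, double mlC,
            int maxLoop, int minHairpin) {
  FoldCtx c;
  c.n = seqCode.size();
  c.maxLoop = maxLoop;
  c.minHairpin = minHairpin;
  std::vector<int> s(c.n);
  for (int i = 0; i < c.n; ++i) s[i] = seqCode[i];
  c.seq = s.data();
  c.pe = REAL(pe);
  c.stackE = stackE;
  c.hp = REAL(hairpinPen);
  c.bu = REAL(bulgePen);
  c.in_ = REAL(internalPen);
  c.mlA = mlA; c.mlB = mlB; c.mlC = mlC;
  fill(c);
  std::vector<int> pt;
  traceback(c, pt);
  IntegerVector pairs(c.n);
  for (int i = 0; i < c.n; ++i) pairs[i] = pt[i] + 1;  // 1-based, 0 unpaired
  return List::create(_["pairs"] = pairs, _["energy"] = c.W[c.n]);
}
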