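// Minimum-free-energy folding of a single RNA strand, pseudoknot-free.
//
// Grammar (Zuker-style):
//   V[i][j]   best energy given (i,j) paired: hairpin closure, stack /
//             bulge / interior closure (total unpaired <= max_interior),
//             or multiloop closure (>= 2 branches inside).
//   WM[i][j]  best energy of >= 1 multiloop branch in [i,j]; each branch
//             costs ml_b, unpaired multiloop bases are free.
//   WM2[i][j] best energy of >= 2 branches (split of two WM segments).
//   W[i]      best energy of the suffix [i..n-1]; external bases free.
//
// The model is fully parameterised from R (stack table, loop-penalty
// constants, per-pair bonus), so the same DP serves both the
// nearest-neighbor stacking model and the pair-count model used by the
// exhaustive test oracle. Traceback choices are recorded during the DP
// with strict-improvement updates in a fixed scan order, so ties resolve
// deterministically toward the pairing with the smallest 5' index, then
// the smallest 3' index.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double INF = 1e9;

// base codes: 0=A 1=C 2=G 3=U 4=N(unpairable)
// pair types 1..6 = AU CG GC UA GU UG (0 = not pairable)
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct Model {
  NumericMatrix stack;   // 6x6, [outer-1, inner-1]
  double pair_bonus;
  double hp_a, hp_b;
  double bulge1, bl_a, bl_b;
  double il_a, il_b, il_asym, il_asym_max;
  double ml_a, ml_b;
  int min_loop, max_interior;

  double hairpin(int n) const { return hp_a + hp_b * std::log((double)n / 3.0); }
  double bulge(int n) const {
    return n == 1 ? bulge1 : bl_a + bl_b * std::log((double)n);
  }
  double interior(int n1, int n2) const {
    double asym = il_asym * std::abs(n1 - n2);
    if (asym > il_asym_max) asym = il_asym_max;
    return il_a + il_b * std::log((n1 + n2) / 2.0) + asym;
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector codes, List model) {
  Model m;
  m.stack = as<NumericMatrix>(model["stack"]);
  m.pair_bonus = as<double>(model["pair_bonus"]);
  m.hp_a = as<double>(model["hp_a"]);
  m.hp_b = as<double>(model["hp_b"]);
  m.bulge1 = as<double>(model["bulge1"]);
  m.bl_a = as<double>(model["bl_a"]);
  m.bl_b = as<double>(model["bl_b"]);
  m.il_a = as<double>(model["il_a"]);
  m.il_b = as<double>(model["il_b"]);
  m.il_asym = as<double>(model["il_asym"]);
  m.il_asym_max = as<double>(model["il_asym_max"]);
  m.ml_a = as<double>(model["ml_a"]);
  m.ml_b = as<double>(model["ml_b"]);
  m.min_loop = as<int>(model["min_loop"]);
  m.max_interior = as<int>(model["max_interior"]);

  const int n = codes.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = codes[i];

  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF),
      WM2((size_t)n * n, INF);
  // traceback records
  // VC: -1 hairpin, -2 multiloop, else k (with VL = l) for interior/stack
  std::vector<int> VC((size_t)n * n, -3), VL((size_t)n * n, -1);
  // WMC: 0 = V branch at (i,j); k>0 split at k; -1 = drop i; -2 = drop j
  std::vector<int> WMC((size_t)n * n, -9), WM2C((size_t)n * n, -9);

  for (int j = 0; j < n; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      // ---- V ----
      int pt = pair_type(s[i], s[j]);
      if (pt > 0 && j - i - 1 >= m.min_loop) {
        double best = INF;
        int bc = -3, bl = -1;
        // stack / bulge / interior closures, scan k asc then l asc
        for (int k = i + 1; k < j && k - i - 1 <= m.max_interior; ++k) {
          int n1 = k - i - 1;
          int lmin = k + m.min_loop + 1;
          int lmax0 = j - 1;
          // need n2 = j-l-1 with n1+n2 <= max_interior -> l >= j-1-(max_interior-n1)
          int lmin2 = j - 1 - (m.max_interior - n1);
          if (lmin2 > lmin) lmin = lmin2;
          for (int l = lmin; l <= lmax0; ++l) {
            double vkl = V[idx(k, l)];
            if (vkl >= INF / 2) continue;
            int n2 = j - l - 1;
            double cost;
            if (n1 == 0 && n2 == 0) {
              int pt2 = pair_type(s[k], s[l]);
              cost = m.stack(pt - 1, pt2 - 1);
            } else if (n1 == 0 || n2 == 0) {
              cost = m.bulge(n1 + n2);
            } else {
              cost = m.interior(n1, n2);
            }
            if (cost + vkl < best) {
              best = cost + vkl;
              bc = k;
              bl = l;
            }
          }
        }
        // multiloop closure
        if (j - i - 1 >= 2) {
          double w2 = WM2[idx(i + 1, j - 1)];
          if (w2 < INF / 2 && m.ml_a + m.ml_b + w2 < best) {
            best = m.ml_a + m.ml_b + w2;
            bc = -2;
          }
        }
        // hairpin closure (checked last: ties prefer adding pairs)
        double hp = m.hairpin(j - i - 1);
        if (hp < best) {
          best = hp;
          bc = -1;
        }
        V[idx(i, j)] = m.pair_bonus + best;
        VC[idx(i, j)] = bc;
        VL[idx(i, j)] = bl;
      }

      // ---- WM ----
      {
        double best = INF;
        int bc = -9;
        double vij = V[idx(i, j)];
        if (vij < INF / 2 && vij + m.ml_b < best) {
          best = vij + m.ml_b;
          bc = 0;
        }
        for (int k = i + 1; k <= j; ++k) {
          double a = WM[idx(i, k - 1)];
          if (a >= INF / 2) continue;
          double b = WM[idx(k, j)];
          if (b >= INF / 2) continue;
          if (a + b < best) {
            best = a + b;
            bc = k;
          }
        }
        if (i + 1 <= j && WM[idx(i + 1, j)] < best) {
          best = WM[idx(i + 1, j)];
          bc = -1;
        }
        if (i <= j - 1 && WM[idx(i, j - 1)] < best) {
          best = WM[idx(i, j - 1)];
          bc = -2;
        }
        WM[idx(i, j)] = best;
        WMC[idx(i, j)] = bc;
      }
      // ---- WM2 ----
      {
        double best = INF;
        int bc = -9;
        for (int k = i + 1; k <= j; ++k) {
          double a = WM[idx(i, k - 1)];
          if (a >= INF / 2) continue;
          double b = WM[idx(k, j)];
          if (b >= INF / 2) continue;
          if (a + b < best) {
            best = a + b;
            bc = k;
          }
        }
        WM2[idx(i, j)] = best;
        WM2C[idx(i, j)] = bc;
      }
    }
  }

  // ---- external: W'[i] over suffixes, traced left to right ----
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> EC(n, -1);  // -1 = i unpaired; else partner l
  for (int i = n - 1; i >= 0; --i) {
    double best = INF;
    int bc = -2;
    for (int l = i + 1; l < n; ++l) {
      double v = V[idx(i, l)];
      if (v >= INF / 2) continue;
      if (v + W[l + 1] < best) {
        best = v + W[l + 1];
        bc = l;
      }
    }
    if (W[i + 1] < best) {
      best = W[i + 1];
      bc = -1;
    }
    W[i] = best;
    EC[i] = bc;
  }

  // ---- traceback ----
  std::vector<int> partner(n, -1);
  // stack of (i, j, state) with state 0=V 1=WM 2=WM2
  std::vector<std::array<int, 3>> st;
  {
    int i = 0;
    while (i < n) {
      if (EC[i] == -1) {
        ++i;
      } else {
        int l = EC[i];
        st.push_back({i, l, 0});
        i = l + 1;
      }
    }
  }
  while (!st.empty()) {
    auto fr = st.back();
    st.pop_back();
    int i = fr[0], j = fr[1], state = fr[2];
    if (state == 0) {
      partner[i] = j;
      partner[j] = i;
      int c = VC[idx(i, j)];
      if (c == -1) continue;  // hairpin
      if (c == -2) {
        st.push_back({i + 1, j - 1, 2});
      } else {
        st.push_back({c, VL[idx(i, j)], 0});
      }
    } else if (state == 1) {
      int c = WMC[idx(i, j)];
      if (c == 0) {
        st.push_back({i, j, 0});
      } else if (c == -1) {
        st.push_back({i + 1, j, 1});
      } else if (c == -2) {
        st.push_back({i, j - 1, 1});
      } else if (c > 0) {
        st.push_back({i, c - 1, 1});
        st.push_back({c, j, 1});
      }
    } else {
      int c = WM2C[idx(i, j)];
      st.push_back({i, c - 1, 1});
      st.push_back({c, j, 1});
    }
  }

  IntegerVector prt(n);
  for (int i = 0; i < n; ++i) prt[i] = partner[i] < 0 ? NA_INTEGER : partner[i] + 1;
  return List::create(_["energy"] = W[0], _["partner"] = prt);
}
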