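// Bundled RNA energy model: stacking energies on adjacent base pairs plus a
// flat penalty per internal-loop/bulge/multiloop event. Hairpin loops and
// exterior bases are free; minimum hairpin size 3. Dynamic programs minimize
// (energy, pair-count tie-break) lexicographically so results are fully
// deterministic.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <utility>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// base codes: A=0 C=1 G=2 U=3, N/other=-1 (unpairable)
static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': v[i] = 0; break;
    case 'C': v[i] = 1; break;
    case 'G': v[i] = 2; break;
    case 'U': v[i] = 3; break;
    default:  v[i] = -1;
    }
  }
  return v;
}

// pair codes: -1 not pairable, 0 = CG/GC, 1 = AU/UA, 2 = GU/UG
static int pair_code(int a, int b) {
  if (a < 0 || b < 0) return -1;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 2;
  return -1;
}

struct Model {
  double stack_gc, stack_mixed, stack_au, stack_gu, loop_penalty;
  int min_hairpin;
};

static Model model_from_list(List m) {
  Model mod;
  mod.stack_gc = as<double>(m["stack_gc"]);
  mod.stack_mixed = as<double>(m["stack_mixed"]);
  mod.stack_au = as<double>(m["stack_au"]);
  mod.stack_gu = as<double>(m["stack_gu"]);
  mod.loop_penalty = as<double>(m["loop_penalty"]);
  mod.min_hairpin = as<int>(m["min_hairpin"]);
  return mod;
}

// energy of stacking pair q directly on pair p
static double stack_energy(const Model& m, int p, int q) {
  if (p == 2 || q == 2) return m.stack_gu;
  int n_au = (p == 1) + (q == 1);
  if (n_au == 0) return m.stack_gc;
  if (n_au == 1) return m.stack_mixed;
  return m.stack_au;
}

// lexicographic cost: energy first, then tiebreak (lower wins)
struct Cost {
  double e;
  int t;
  bool operator<(const Cost& o) const {
    if (e != o.e) return e < o.e;
    return t < o.t;
  }
  Cost operator+(const Cost& o) const { return Cost{e + o.e, t + o.t}; }
};
static const Cost CINF = {INF, 0};

// ---------------------------------------------------------------------------
// Intermolecular duplex: antiparallel non-crossing matching between strand a
// (5'->3') and strand b (5'->3'); pairs (i, j) with i increasing, j
// decreasing. Energy = sum of stacks over adjacent consecutive pairs
// (i+1 on a, j-1 on b) + loop_penalty per non-adjacent consecutive pair.
// Intramolecular pairing is disallowed. Tie-break: more pairs.
// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(std::string trf, std::string target, List model) {
  Model mod = model_from_list(model);
  std::vector<int> a = encode(trf), b = encode(target);
  int n = a.size(), m = b.size();
  // D[i][j]: best cost of a matching whose last (largest-i) pair is (i,j);
  // tiebreak = -count (prefer more pairs)
  std::vector<std::vector<Cost>> D(n, std::vector<Cost>(m, CINF));
  std::vector<std::vector<Cost>> P(n, std::vector<Cost>(m, CINF));
  // choice[i][j]: 0 start, 1 stack on (i-1,j+1), 2 loop from argmin P
  std::vector<std::vector<int>> choice(n, std::vector<int>(m, 0));
  std::vector<std::vector<std::pair<int,int>>> ploop(
      n, std::vector<std::pair<int,int>>(m, {-1, -1}));
  // Parg[i][j]: deterministic argmin of P[i][j] (prefix minima region)
  std::vector<std::vector<std::pair<int,int>>> Parg(
      n, std::vector<std::pair<int,int>>(m, {-1, -1}));

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pc = pair_code(a[i], b[j]);
      if (pc >= 0) {
        Cost best = {0.0, -1};  // start a new matching with this pair
        int ch = 0;
        std::pair<int,int> from = {-1, -1};
        if (i > 0 && j + 1 < m) {
          int qc = pair_code(a[i - 1], b[j + 1]);
          if (qc >= 0 && D[i - 1][j + 1].e < INF) {
            Cost c = D[i - 1][j + 1] + Cost{stack_energy(mod, qc, pc), -1};
            if (c < best) { best = c; ch = 1; from = {i - 1, j + 1}; }
          }
          if (P[i - 1][j + 1].e < INF) {
            Cost c = P[i - 1][j + 1] + Cost{mod.loop_penalty, -1};
            if (c < best) { best = c; ch = 2; from = Parg[i - 1][j + 1]; }
          }
        }
        D[i][j] = best;
        choice[i][j] = ch;
        ploop[i][j] = from;
      }
      // prefix minima over i' <= i, j' >= j with deterministic argmin:
      // prefer smaller i', then larger j' on ties
      Cost pb = CINF;
      std::pair<int,int> parg = {-1, -1};
      if (i > 0 && P[i - 1][j].e < INF && P[i - 1][j] < pb) {
        pb = P[i - 1][j]; parg = Parg[i - 1][j];
      }
      if (j + 1 < m && P[i][j + 1].e < INF && P[i][j + 1] < pb) {
        pb = P[i][j + 1]; parg = Parg[i][j + 1];
      }
      if (D[i][j].e < INF && D[i][j] < pb) {
        pb = D[i][j]; parg = {i, j};
      }
      P[i][j] = pb;
      Parg[i][j] = parg;
    }
  }

  Cost best = {0.0, 0};  // empty duplex always admissible
  std::pair<int,int> last = {-1, -1};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (D[i][j].e < INF && D[i][j] < best) { best = D[i][j]; last = {i, j}; }

  std::vector<int> ti, uj;
  while (last.first >= 0) {
    ti.push_back(last.first + 1);  // 1-based positions out
    uj.push_back(last.second + 1);
    int i = last.first, j = last.second;
    if (choice[i][j] == 0) break;
    last = ploop[i][j];
  }
  std::reverse(ti.begin(), ti.end());
  std::reverse(uj.begin(), uj.end());
  return List::create(_["mfe"] = best.e,
                      _["paired_count"] = (int)ti.size(),
                      _["trf_pos"] = wrap(ti),
                      _["target_pos"] = wrap(uj));
}

// ---------------------------------------------------------------------------
// Intramolecular folding (no pseudoknots, hairpin >= min_hairpin).
// Faces: stack = stack energy; hairpin/exterior = 0; internal loop, bulge or
// multiloop = one loop_penalty each. Tie-break: fewer pairs.

// [[Rcpp::export(name = ".local_fold_cpp")]]
List local_fold_cpp(std::string window, List model, IntegerVector forced_unpaired) {
  Model mod = model_from_list(model);
  std::vector<int> s = encode(window);
  int n = s.size();
  std::vector<bool> blocked(n, false);
  for (int k = 0; k < forced_unpaired.size(); ++k) {
    int p = forced_unpaired[k] - 1;  // 1-based in
    if (p >= 0 && p < n) blocked[p] = true;
  }
  auto can_pair = [&](int i, int j) {
    if (blocked[i] || blocked[j]) return -1;
    return pair_code(s[i], s[j]);
  };

  std::vector<std::vector<Cost>> V(n, std::vector<Cost>(n, CINF));
  std::vector<std::vector<Cost>> M1(n, std::vector<Cost>(n, CINF));
  std::vector<std::vector<Cost>> M2(n, std::vector<Cost>(n, CINF));
  // inner best single component strictly inside (i,j): min V[k][l]
  std::vector<std::vector<Cost>> IN(n, std::vector<Cost>(n, CINF));
  std::vector<std::vector<std::pair<int,int>>> INarg(
      n, std::vector<std::pair<int,int>>(n, {-1, -1}));
  // V choice: 0 hairpin, 1 stack, 2 internal (INarg), 3 multiloop (M2)
  std::vector<std::vector<int>> vch(n, std::vector<int>(n, -1));
  // M splits for traceback
  std::vector<std::vector<int>> m1k(n, std::vector<int>(n, -1));
  std::vector<std::vector<int>> m2k(n, std::vector<int>(n, -1));

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // IN: best V strictly inside (i,j) — over k>=i+1, l<=j-1
      {
        Cost b = CINF; std::pair<int,int> arg = {-1, -1};
        if (j - 1 >= i + 1) {
          if (IN[i + 1][j].e < INF && IN[i + 1][j] < b) { b = IN[i + 1][j]; arg = INarg[i + 1][j]; }
          if (IN[i][j - 1].e < INF && IN[i][j - 1] < b) { b = IN[i][j - 1]; arg = INarg[i][j - 1]; }
          if (V[i + 1][j - 1].e < INF && V[i + 1][j - 1] < b) { b = V[i + 1][j - 1]; arg = {i + 1, j - 1}; }
        }
        IN[i][j] = b; INarg[i][j] = arg;
      }
      // V
      int pc = can_pair(i, j);
      if (pc >= 0) {
        Cost best = CINF; int ch = -1;
        if (j - i - 1 >= mod.min_hairpin) { best = {0.0, 1}; ch = 0; }
        if (j - i - 1 >= 2) {
          int qc = can_pair(i + 1, j - 1);
          if (qc >= 0 && V[i + 1][j - 1].e < INF) {
            Cost c = V[i + 1][j - 1] + Cost{stack_energy(mod, pc, qc), 1};
            if (c < best) { best = c; ch = 1; }
          }
          if (IN[i][j].e < INF) {
            Cost c = IN[i][j] + Cost{mod.loop_penalty, 1};
            if (c < best) { best = c; ch = 2; }
          }
          if (j - 2 >= i + 1 && M2[i + 1][j - 1].e < INF) {
            Cost c = M2[i + 1][j - 1] + Cost{mod.loop_penalty, 1};
            if (c < best) { best = c; ch = 3; }
          }
        }
        V[i][j] = best; vch[i][j] = ch;
      }
      // M1: >= 1 component in [i, j], unpaired bases free
      {
        Cost best = CINF; int karg = -1;
        if (j - 1 >= i && M1[i][j - 1].e < INF) { best = M1[i][j - 1]; karg = -2; }  // j unpaired
        for (int k = i; k < j; ++k) {
          if (V[k][j].e >= INF) continue;
          Cost pre = {0.0, 0};
          if (k > i && M1[i][k - 1].e < INF && M1[i][k - 1] < pre) pre = M1[i][k - 1];
          Cost c = pre + V[k][j];
          if (c < best) { best = c; karg = k; }
        }
        M1[i][j] = best; m1k[i][j] = karg;
      }
      // M2: >= 2 components
      {
        Cost best = CINF; int karg = -1;
        if (j - 1 >= i && M2[i][j - 1].e < INF) { best = M2[i][j - 1]; karg = -2; }
        for (int k = i + 1; k < j; ++k) {
          if (V[k][j].e >= INF || M1[i][k - 1].e >= INF) continue;
          Cost c = M1[i][k - 1] + V[k][j];
          if (c < best) { best = c; karg = k; }
        }
        M2[i][j] = best; m2k[i][j] = karg;
      }
    }
  }

  // exterior: W[j] over prefix 0..j, no penalty, unpaired free
  std::vector<Cost> W(n + 1, Cost{0.0, 0});
  std::vector<int> wk(n + 1, -1);  // -1: j unpaired; else k paired with j
  for (int j = 0; j < n; ++j) {
    Cost best = W[j]; int karg = -1;  // j unpaired
    for (int k = 0; k <= j; ++k) {
      if (V[k][j].e >= INF) continue;
      Cost c = W[k] + V[k][j];
      if (c < best) { best = c; karg = k; }
    }
    W[j + 1] = best; wk[j + 1] = karg;
  }

  // traceback with typed frames: 0 = V(i,j), 1 = M1 region, 2 = M2 region
  std::string db(n, '.');
  struct Frame { int type, i, j; };
  std::vector<Frame> st;
  int j = n;
  while (j > 0) {
    if (wk[j] < 0) { --j; continue; }
    st.push_back({0, wk[j], j - 1});
    j = wk[j];
  }
  while (!st.empty()) {
    Frame f = st.back(); st.pop_back();
    if (f.type == 0) {
      int i = f.i, jj = f.j;
      db[i] = '('; db[jj] = ')';
      switch (vch[i][jj]) {
      case 0: break;
      case 1: st.push_back({0, i + 1, jj - 1}); break;
      case 2: st.push_back({0, INarg[i][jj].first, INarg[i][jj].second}); break;
      case 3: st.push_back({2, i + 1, jj - 1}); break;
      }
    } else if (f.type == 1) {
      int a = f.i, b = f.j;
      while (m1k[a][b] == -2) --b;
      int k = m1k[a][b];
      st.push_back({0, k, b});
      // region before the last component holds more components only when
      // that improved the optimum (energy < 0; counts break ties upward)
      if (k > a && M1[a][k - 1].e < 0) st.push_back({1, a, k - 1});
    } else {
      int a = f.i, b = f.j;
      while (m2k[a][b] == -2) --b;
      int k = m2k[a][b];
      st.push_back({0, k, b});
      st.push_back({1, a, k - 1});  // mandatory remaining >= 1 component
    }
  }
  return List::create(_["structure"] = db,
                      _["energy"] = W[n].e,
                      _["n_pairs"] = W[n].t);
}
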