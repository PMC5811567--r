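// Minimum-free-energy folding of nested (pseudoknot-free) RNA structures
// under a simplified loop-based energy model, with exact traceback.
//
// Energies are handled in integer tenths of the model unit so that ties are
// exact.  Model terms (deci-units):
//   stacked pair (by outer pair type): GC/CG -30, AU/UA -20, GU/UG -10
//   isolated pair (no stacking neighbour on either side): half pair energy
//   hairpin loop: +40 initiation, +5 per unpaired nt beyond 3 (min loop 3)
//   internal/bulge loop: +20 initiation, +3 per unpaired nt (<= MAXLOOP nt)
//   multibranch loop: +20 initiation, +3 per unpaired loop nt
// Ties are broken toward the structure with more pairs, then by a fixed
// deterministic traceback order, so output is bit-stable.

#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

namespace {

const int INF = INT_MAX / 4;
const int MAXLOOP = 30;

// base coding: A=0, C=1, G=2, U=3
inline int pairClass(int a, int b) {
  // 0 = unpairable, 1 = GC/CG, 2 = AU/UA, 3 = GU/UG
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 3;
  return 0;
}

inline int stackE(int cls) {
  switch (cls) { case 1: return -30; case 2: return -20; case 3: return -10; }
  return INF;
}
inline int isoE(int cls) { return stackE(cls) / 2; }

inline int hairpinE(int u) { return 40 + 5 * (u > 3 ? u - 3 : 0); }
inline int internalE(int u) { return 20 + 3 * u; }
const int ML_INIT = 20;
const int ML_UNPAIRED = 3;

struct EP {
  int e;  // energy (deci-units)
  int p;  // number of pairs (secondary objective, maximised)
};
inline bool better(const EP& a, const EP& b) {
  return a.e < b.e || (a.e == b.e && a.p > b.p);
}
inline EP add(const EP& a, const EP& b) { return EP{a.e + b.e, a.p + b.p}; }
inline EP shift(const EP& a, int de, int dp = 0) { return EP{a.e + de, a.p + dp}; }
const EP BAD = {INF, 0};
const EP ZERO = {0, 0};

class Folder {
public:
  Folder(const std::vector<int>& s) : x(s), n((int)s.size()) {
    nostk.assign((size_t)n * n, BAD);
    vs.assign((size_t)n * n, BAD);
    vn.assign((size_t)n * n, BAD);
    wm.assign((size_t)n * n, BAD);
    w.assign(n, ZERO);
    fill();
  }

  std::string traceback() {
    pt.assign(n, -1);
    traceW(n - 1);
    std::string db(n, '.');
    for (int i = 0; i < n; ++i)
      if (pt[i] > i) { db[i] = '('; db[pt[i]] = ')'; }
    return db;
  }

  int mfe() const { return w[n - 1].e; }
  int npairs() const { return w[n - 1].p; }

private:
  const std::vector<int>& x;
  int n;
  std::vector<EP> nostk, vs, vn, wm;
  std::vector<EP> w;
  std::vector<int> pt;

  inline size_t at(int i, int j) const { return (size_t)i * n + j; }

  // branches of the "no inward stack" part of V: hairpin, internal, multi
  EP computeNoStk(int i, int j) {
    EP best = BAD;
    int u = j - i - 1;
    if (u >= 3) {  // hairpin
      EP c = {hairpinE(u), 1};
      if (better(c, best)) best = c;
    }
    // internal / bulge: inner pair (k,l), excluding the stack case
    for (int k = i + 1; k <= j - 1 && (k - i - 1) <= MAXLOOP; ++k) {
      for (int l = j - 1; l > k; --l) {
        int loop = (k - i - 1) + (j - l - 1);
        if (loop < 1) continue;         // (i+1, j-1) is the stack case
        if (loop > MAXLOOP) break;      // l too small already
        const EP& inner = vn[at(k, l)];
        if (inner.e >= INF) continue;
        EP c = shift(inner, internalE(loop), 1);
        if (better(c, best)) best = c;
      }
    }
    // multibranch: >= 2 components inside
    for (int k = i + 1; k <= j - 2; ++k) {
      const EP& a = wm[at(i + 1, k)];
      if (a.e >= INF) continue;
      const EP& b = wm[at(k + 1, j - 1)];
      if (b.e >= INF) continue;
      EP c = shift(add(a, b), ML_INIT, 1);
      if (better(c, best)) best = c;
    }
    return best;
  }

  void fill() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int cls = pairClass(x[i], x[j]);
        if (cls != 0) {
          EP ns = computeNoStk(i, j);
          nostk[at(i, j)] = ns;
          EP bs = ns, bn = shift(ns, isoE(cls));
          if (ns.e >= INF) bn = BAD;
          int icls = (j - i >= 2) ? pairClass(x[i + 1], x[j - 1]) : 0;
          if (icls != 0 && vs[at(i + 1, j - 1)].e < INF) {
            EP st = shift(vs[at(i + 1, j - 1)], stackE(cls), 1);
            if (better(st, bs)) bs = st;
            if (better(st, bn)) bn = st;
          }
          vs[at(i, j)] = bs;
          vn[at(i, j)] = bn;
        }
        // WM over [i, j]
        EP best = BAD;
        if (vn[at(i, j)].e < INF && better(vn[at(i, j)], best))
          best = vn[at(i, j)];
        if (wm[at(i + 1, j)].e < INF) {
          EP c = shift(wm[at(i + 1, j)], ML_UNPAIRED);
          if (better(c, best)) best = c;
        }
        if (wm[at(i, j - 1)].e < INF) {
          EP c = shift(wm[at(i, j - 1)], ML_UNPAIRED);
          if (better(c, best)) best = c;
        }
        for (int k = i; k < j; ++k) {
          const EP& a = wm[at(i, k)];
          if (a.e >= INF) continue;
          const EP& b = wm[at(k + 1, j)];
          if (b.e >= INF) continue;
          EP c = add(a, b);
          if (better(c, best)) best = c;
        }
        wm[at(i, j)] = best;
      }
    }
    // external
    for (int j = 0; j < n; ++j) {
      EP best = (j == 0) ? ZERO : w[j - 1];
      for (int i = 0; i + 4 <= j; ++i) {
        if (vn[at(i, j)].e >= INF) continue;
        EP c = add(i > 0 ? w[i - 1] : ZERO, vn[at(i, j)]);
        if (better(c, best)) best = c;
      }
      w[j] = best;
    }
  }

  inline bool same(const EP& a, const EP& b) { return a.e == b.e && a.p == b.p; }

  void traceW(int j) {
    while (j >= 0) {
      EP target = w[j];
      if (j == 0 || same(w[j - 1], target)) { --j; continue; }
      bool found = false;
      for (int i = 0; i + 4 <= j; ++i) {
        if (vn[at(i, j)].e >= INF) continue;
        EP c = add(i > 0 ? w[i - 1] : ZERO, vn[at(i, j)]);
        if (same(c, target)) { traceV(i, j, false); j = i - 1; found = true; break; }
      }
      if (!found) --j;  // defensive; cannot happen
    }
  }

  // stacked = true -> target stored in vs; false -> vn
  void traceV(int i, int j, bool stacked) {
    pt[i] = j; pt[j] = i;
    int cls = pairClass(x[i], x[j]);
    EP target = stacked ? vs[at(i, j)] : vn[at(i, j)];
    int icls = (j - i >= 2) ? pairClass(x[i + 1], x[j - 1]) : 0;
    if (icls != 0 && vs[at(i + 1, j - 1)].e < INF) {
      EP st = shift(vs[at(i + 1, j - 1)], stackE(cls), 1);
      if (same(st, target)) { traceV(i + 1, j - 1, true); return; }
    }
    EP ns = nostk[at(i, j)];
    EP want = stacked ? ns : shift(ns, isoE(cls));
    // must match the no-stack part; dissect its branches
    (void)want;
    EP inner = stacked ? target : shift(target, -isoE(cls));
    // hairpin branch
    int u = j - i - 1;
    if (u >= 3 && same(EP{hairpinE(u), 1}, inner)) return;
    // internal branch
    for (int k = i + 1; k <= j - 1 && (k - i - 1) <= MAXLOOP; ++k) {
      for (int l = j - 1; l > k; --l) {
        int loop = (k - i - 1) + (j - l - 1);
        if (loop < 1) continue;
        if (loop > MAXLOOP) break;
        const EP& in = vn[at(k, l)];
        if (in.e >= INF) continue;
        if (same(shift(in, internalE(loop), 1), inner)) { traceV(k, l, false); return; }
      }
    }
    // multibranch
    for (int k = i + 1; k <= j - 2; ++k) {
      const EP& a = wm[at(i + 1, k)];
      if (a.e >= INF) continue;
      const EP& b = wm[at(k + 1, j - 1)];
      if (b.e >= INF) continue;
      if (same(shift(add(a, b), ML_INIT, 1), inner)) {
        traceWM(i + 1, k); traceWM(k + 1, j - 1); return;
      }
    }
  }

  void traceWM(int i, int j) {
    EP target = wm[at(i, j)];
    if (vn[at(i, j)].e < INF && same(vn[at(i, j)], target)) { traceV(i, j, false); return; }
    if (wm[at(i + 1, j)].e < INF && same(shift(wm[at(i + 1, j)], ML_UNPAIRED), target)) {
      traceWM(i + 1, j); return;
    }
    if (wm[at(i, j - 1)].e < INF && same(shift(wm[at(i, j - 1)], ML_UNPAIRED), target)) {
      traceWM(i, j - 1); return;
    }
    for (int k = i; k < j; ++k) {
      const EP& a = wm[at(i, k)];
      if (a.e >= INF) continue;
      const EP& b = wm[at(k + 1, j)];
      if (b.e >= INF) continue;
      if (same(add(a, b), target)) { traceWM(i, k); traceWM(k + 1, j); return; }
    }
  }
};

std::vector<int> encode(const std::string& seq) {
  std::vector<int> x(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': x[i] = 0; break;
      case 'C': x[i] = 1; break;
      case 'G': x[i] = 2; break;
      case 'U': x[i] = 3; break;
      default: stop("invalid residue '%c' (expected A/C/G/U)", seq[i]);
    }
  }
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  std::vector<int> x = encode(seq);
  int n = (int)x.size();
  if (n < 5) {
    return List::create(_["structure"] = std::string(n, '.'),
                        _["mfe_deci"] = 0, _["npairs"] = 0);
  }
  Folder f(x);
  std::string db = f.traceback();
  return List::create(_["structure"] = db, _["mfe_deci"] = f.mfe(),
                      _["npairs"] = f.npairs());
}
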