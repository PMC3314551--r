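// Inner loops of the primer screening: complementarity run scans and
// nearest-neighbor free-energy minimisation over degenerate pools.
//
// Sequences arrive as 1-based integer codes into the IUPAC alphabet
// (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N); `cp` is the 15x15 can-pair matrix
// (true when some disambiguation pair is Watson-Crick) and `sets` maps
// each code to its concrete bases (1..4 = A,C,G,T). `dg` is the 4x4
// stack dG37 matrix indexed by top-strand bases.

#include <Rcpp.h>
using namespace Rcpp;

static inline bool pairs(const LogicalMatrix& cp, int a, int b) {
  return cp(a - 1, b - 1);
}

// exact minimum (most stable) sum of stack dG37 over consecutive IUPAC
// positions, jointly over disambiguations, by dynamic programming
static double dg_run_min_core(const IntegerVector& x, int from, int to,
                              const List& sets, const NumericMatrix& dg) {
  int n = to - from + 1;
  if (n < 2) return 0.0;
  IntegerVector s0 = sets[x[from] - 1];
  std::vector<double> best(s0.size(), 0.0);
  std::vector<int> prev(s0.begin(), s0.end());
  for (int k = from + 1; k <= to; ++k) {
    IntegerVector sk = sets[x[k] - 1];
    std::vector<double> nxt(sk.size());
    for (int b = 0; b < sk.size(); ++b) {
      double m = R_PosInf;
      for (size_t a = 0; a < prev.size(); ++a) {
        double v = best[a] + dg(prev[a] - 1, sk[b] - 1);
        if (v < m) m = v;
      }
      nxt[b] = m;
    }
    best = nxt;
    prev.assign(sk.begin(), sk.end());
  }
  double m = best[0];
  for (size_t a = 1; a < best.size(); ++a) if (best[a] < m) m = best[a];
  return m;
}

// [[Rcpp::export(name = ".cpp_dg_run_min")]]
double cpp_dg_run_min(IntegerVector x, List sets, NumericMatrix dg) {
  if (x.size() < 2) return 0.0;
  return dg_run_min_core(x, 0, x.size() - 1, sets, dg);
}

// longest run of consecutive can-pair positions of a against reverse(b),
// over every ungapped offset; b_rev must already be reversed
// [[Rcpp::export(name = ".cpp_dimer_run")]]
int cpp_dimer_run(IntegerVector a, IntegerVector b_rev, LogicalMatrix cp) {
  int n = a.size(), m = b_rev.size(), best = 0;
  for (int off = -(m - 1); off <= n - 1; ++off) {
    int run = 0;
    int lo = std::max(0, off), hi = std::min(n - 1, m - 1 + off);
    for (int i = lo; i <= hi; ++i) {
      if (pairs(cp, a[i], b_rev[i - off])) {
        if (++run > best) best = run;
      } else {
        run = 0;
      }
    }
  }
  return best;
}

// longest hairpin stem: pairs (i, j), i < j, extend outward along
// (i-1, j+1); the innermost pair must leave a loop >= min_loop
// [[Rcpp::export(name = ".cpp_hairpin_run")]]
int cpp_hairpin_run(IntegerVector x, LogicalMatrix cp, int min_loop) {
  int n = x.size(), best = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      int run = 0;
      while (i - run >= 0 && j + run < n &&
             pairs(cp, x[i - run], x[j + run])) ++run;
      if (run > best) best = run;
    }
  }
  return best;
}

// most negative dG37 over all maximal self-dimer and hairpin pairing runs
// of length >= 2, each run taken at its most stable disambiguation
// [[Rcpp::export(name = ".cpp_dg_min")]]
double cpp_dg_min(IntegerVector x, LogicalMatrix cp, List sets,
                  NumericMatrix dg, int min_loop) {
  int n = x.size();
  double best = 0.0;
  if (n < 2) return best;
  // self-dimer: x against its own reverse
  for (int off = -(n - 1); off <= n - 1; ++off) {
    int lo = std::max(0, off), hi = std::min(n - 1, n - 1 + off);
    int run = 0;
    for (int i = lo; i <= hi + 1; ++i) {
      bool p = (i <= hi) && pairs(cp, x[i], x[n - 1 - (i - off)]);
      if (p) {
        ++run;
      } else {
        if (run >= 2) {
          double v = dg_run_min_core(x, i - run, i - 1, sets, dg);
          if (v < best) best = v;
        }
        run = 0;
      }
    }
  }
  // hairpin stems: only maximal ones matter for the minimum
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      int run = 0;
      while (i - run >= 0 && j + run < n &&
             pairs(cp, x[i - run], x[j + run])) ++run;
      if (run >= 2) {
        double v = dg_run_min_core(x, i - run + 1, i, sets, dg);
        if (v < best) best = v;
      }
    }
  }
  return best;
}
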