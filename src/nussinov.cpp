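#include <Rcpp.h>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, U=3, N=4 (N never pairs)
static double pair_weight(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0; // GU
  return 0.0;
}

// Maximum-weight Nussinov DP with an optional per-base reactivity
// pseudo-penalty: pairing bases i and j scores w(i,j) - lambda*(r[i] + r[j]).
// Loop constraint: j - i - 1 >= min_loop. Deterministic traceback: at (i,j)
// pairing of i with the smallest admissible partner k achieving the optimum
// is preferred over leaving i unpaired.
// [[Rcpp::export(name = ".nussinov_dp")]]
List nussinov_dp(IntegerVector code, NumericVector penalty, int min_loop) {
  int L = code.size();
  NumericMatrix M(L + 1, L + 1); // 1-based [i][j], 0 for empty/invalid spans
  // fill by span length
  for (int span = min_loop + 2; span <= L; ++span) {
    for (int i = 1; i + span - 1 <= L; ++i) {
      int j = i + span - 1;
      double best = M(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = pair_weight(code[i - 1], code[k - 1]);
        if (w <= 0.0) continue;
        double sc = w - penalty[i - 1] - penalty[k - 1];
        double inner = (k - 1 >= i + 1) ? M(i + 1, k - 1) : 0.0;
        double outer = (k + 1 <= j) ? M(k + 1, j) : 0.0;
        double cand = sc + inner + outer;
        if (cand > best) best = cand;
      }
      M(i, j) = best;
    }
  }
  // traceback (iterative stack of intervals)
  std::vector<int> partner(L + 1, 0);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, L));
  while (!stack.empty()) {
    std::pair<int, int> iv = stack.back();
    stack.pop_back();
    int i = iv.first, j = iv.second;
    if (i >= j || j - i < min_loop + 1) continue;
    double target = M(i, j);
    bool found = false;
    for (int k = i + min_loop + 1; k <= j && !found; ++k) {
      double w = pair_weight(code[i - 1], code[k - 1]);
      if (w <= 0.0) continue;
      double sc = w - penalty[i - 1] - penalty[k - 1];
      double inner = (k - 1 >= i + 1) ? M(i + 1, k - 1) : 0.0;
      double outer = (k + 1 <= j) ? M(k + 1, j) : 0.0;
      if (sc + inner + outer == target) {
        partner[i] = k;
        partner[k] = i;
        if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        found = true;
      }
    }
    if (!found) stack.push_back(std::make_pair(i + 1, j));
  }
  int np = 0;
  for (int i = 1; i <= L; ++i)
    if (partner[i] > i) ++np;
  IntegerMatrix pairs(np, 2);
  int r = 0;
  for (int i = 1; i <= L; ++i) {
    if (partner[i] > i) {
      pairs(r, 0) = i;
      pairs(r, 1) = partner[i];
      ++r;
    }
  }
  return List::create(_["score"] = M(1, L),
                      _["pairs"] = pairs,
                      _["n_pairs"] = np);
}
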