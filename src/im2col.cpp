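#include <Rcpp.h>
using namespace Rcpp;

// 3x3 dilated im2col with same zero padding on an (L, L, C) array.
// Column blocks ordered by (dj, di) over {-dil, 0, dil} (dj outer loop),
// matching the R reference implementation.
// [[Rcpp::export(name = ".im2col3_cpp")]]
NumericMatrix im2col3_cpp(NumericVector P, int L, int C, int dil) {
  NumericMatrix out(L * L, 9 * C);
  int offs[3] = {-dil, 0, dil};
  for (int b = 0; b < 9; ++b) {
    int dj = offs[b / 3], di = offs[b % 3];
    for (int c = 0; c < C; ++c) {
      double *dst = &out(0, b * C + c);
      const double *src = &P[(R_xlen_t)c * L * L];
      for (int j = 0; j < L; ++j) {
        int js = j + dj;
        if (js < 0 || js >= L) continue;
        int i0 = std::max(0, -di), i1 = std::min(L, L - di);
        const double *scol = src + (R_xlen_t)js * L;
        double *dcol = dst + (R_xlen_t)j * L;
        for (int i = i0; i < i1; ++i) dcol[i] = scol[i + di];
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter-add columns back into an (L, L, C) array
// [[Rcpp::export(name = ".col2im3_cpp")]]
NumericVector col2im3_cpp(NumericMatrix dX, int L, int C, int dil) {
  NumericVector dP((R_xlen_t)L * L * C);
  int offs[3] = {-dil, 0, dil};
  for (int b = 0; b < 9; ++b) {
    int dj = offs[b / 3], di = offs[b % 3];
    for (int c = 0; c < C; ++c) {
      const double *src = &dX(0, b * C + c);
      double *dst = &dP[(R_xlen_t)c * L * L];
      for (int j = 0; j < L; ++j) {
        int js = j + dj;
        if (js < 0 || js >= L) continue;
        int i0 = std::max(0, -di), i1 = std::min(L, L - di);
        const double *scol = src + (R_xlen_t)j * L;
        double *dcol = dst + (R_xlen_t)js * L;
        for (int i = i0; i < i1; ++i) dcol[i + di] += scol[i];
      }
    }
  }
  dP.attr("dim") = IntegerVector::create(L, L, C);
  return dP;
}
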