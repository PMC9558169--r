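#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall two-subiteration topology-preserving thinning of a binary image.
// Input/output are 0/1 integer matrices; foreground shrinks to a 1-px
// 8-connected skeleton. Chosen over the Zhang-Suen scheme because the
// latter can erode tapered diagonal ribbons completely. Border pixels are
// treated as background.

static inline int px(const IntegerVector &m, int nr, int r, int c) {
  return m[r + c * nr];
}

// [[Rcpp::export]]
IntegerMatrix guo_hall_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerVector m = clone(as<IntegerVector>(mask));
  std::vector<int> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c < nc - 1; ++c) {
        for (int r = 1; r < nr - 1; ++r) {
          if (!px(m, nr, r, c)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = px(m, nr, r - 1, c);
          int p3 = px(m, nr, r - 1, c + 1);
          int p4 = px(m, nr, r, c + 1);
          int p5 = px(m, nr, r + 1, c + 1);
          int p6 = px(m, nr, r + 1, c);
          int p7 = px(m, nr, r + 1, c - 1);
          int p8 = px(m, nr, r, c - 1);
          int p9 = px(m, nr, r - 1, c - 1);
          int C = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                  ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          int md = pass == 0 ? ((p6 || p7 || !p9) && p8)
                             : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && md == 0)
            kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) m[kill[i]] = 0;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
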