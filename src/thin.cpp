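#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: 0/1 integer matrix. Returns the
// one-pixel-wide skeleton. Used to initialise the embryo midline.
// [[Rcpp::export]]
IntegerMatrix thin_binary(IntegerMatrix m) {
  int h = m.nrow(), w = m.ncol();
  IntegerMatrix a = clone(m);
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 1; c < w - 1; ++c) {
        for (int r = 1; r < h - 1; ++r) {
          if (a(r, c) == 0) continue;
          int p2 = a(r - 1, c),     p3 = a(r - 1, c + 1), p4 = a(r, c + 1);
          int p5 = a(r + 1, c + 1), p6 = a(r + 1, c),     p7 = a(r + 1, c - 1);
          int p8 = a(r, c - 1),     p9 = a(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        a(kill[i].first, kill[i].second) = 0;
    }
  }
  return a;
}
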