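#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall thinning (1989) of a binary mask to a one-pixel-wide,
// 8-connected skeleton. Border pixels are treated as background.
// [[Rcpp::export(name = ".guo_hall_thin")]]
IntegerMatrix guo_hall_thin(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 1; c < w - 1; ++c) {
        for (int r = 1; r < h - 1; ++r) {
          if (!img(r, c)) continue;
          int p2 = img(r - 1, c),     p3 = img(r - 1, c + 1);
          int p4 = img(r, c + 1),     p5 = img(r + 1, c + 1);
          int p6 = img(r + 1, c),     p7 = img(r + 1, c - 1);
          int p8 = img(r, c - 1),     p9 = img(r - 1, c - 1);
          int C = ((!p2 && (p3 || p4)) + (!p4 && (p5 || p6)) +
                   (!p6 && (p7 || p8)) + (!p8 && (p9 || p2)));
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (sub == 0) ? ((p6 || p7 || !p9) && p8)
                             : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0) {
            del.push_back(std::make_pair(r, c));
          }
        }
      }
      for (size_t k = 0; k < del.size(); ++k) {
        img(del[k].first, del[k].second) = 0;
      }
      if (!del.empty()) changed = true;
    }
  }
  // pixels on the image border cannot be part of the thinned result
  for (int r = 0; r < h; ++r) { img(r, 0) = 0; img(r, w - 1) = 0; }
  for (int c = 0; c < w; ++c) { img(0, c) = 0; img(h - 1, c) = 0; }
  return img;
}
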