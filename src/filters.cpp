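#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Connected-component labelling with 8-connectivity (iterative DFS).
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<std::pair<int, int> > stack;
  int cur = 0;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x) > 0) continue;
      ++cur;
      lab(y, x) = cur;
      stack.clear();
      stack.push_back(std::make_pair(y, x));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ny = p.first + dy, nx = p.second + dx;
            if (ny >= 0 && ny < h && nx >= 0 && nx < w &&
                mask(ny, nx) && lab(ny, nx) == 0) {
              lab(ny, nx) = cur;
              stack.push_back(std::make_pair(ny, nx));
            }
          }
      }
    }
  return lab;
}

// Square median filter with replicated borders; radius = (window - 1) / 2.
// [[Rcpp::export]]
IntegerMatrix median_filter_int(IntegerMatrix img, int radius) {
  const int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w);
  std::vector<int> buf;
  const int side = 2 * radius + 1;
  buf.reserve((size_t)side * side);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      buf.clear();
      for (int dx = -radius; dx <= radius; ++dx) {
        int xx = std::min(std::max(x + dx, 0), w - 1);
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = std::min(std::max(y + dy, 0), h - 1);
          buf.push_back(img(yy, xx));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(y, x) = buf[buf.size() / 2];
    }
  return out;
}
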