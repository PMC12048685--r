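#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Local background statistics for spot calling: for each pixel, the median
// and the (unscaled) median absolute deviation of intensities inside a
// centered square window, clipped at the image border.
// [[Rcpp::export(name = ".local_median_mad")]]
List local_median_mad(const NumericMatrix& img, const int window) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = window / 2;
  NumericMatrix med(nr, nc), mad(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int i = 0; i < nr; ++i) {
    const int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
    for (int j = 0; j < nc; ++j) {
      const int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
      buf.clear();
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r)
          buf.push_back(img(r, c));
      const size_t n = buf.size();
      std::sort(buf.begin(), buf.end());
      double m = (n % 2 == 1) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      med(i, j) = m;
      for (size_t k = 0; k < n; ++k) buf[k] = std::fabs(buf[k] - m);
      std::sort(buf.begin(), buf.end());
      mad(i, j) = (n % 2 == 1) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}

// 8-connected component labelling of a logical foreground mask.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int r = q.front().first, c = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
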