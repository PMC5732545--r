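#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// k-nearest-neighbour inverse-distance-weighted interpolation over a
// regular grid of query pixel centers, using a bucket-grid spatial index.
// A query coinciding with a sample point (d ~ 0) returns that point's
// value exactly.
// [[Rcpp::export(name = ".idwGrid")]]
NumericMatrix idwGrid(NumericVector px, NumericVector py, NumericVector pv,
                      NumericVector qx, NumericVector qy,
                      int k, double power) {
  const int np = px.size();
  const int nr = qy.size(), nc = qx.size();
  NumericMatrix out(nr, nc);
  if (np == 0) stop("no points");
  if (k < 1 || k > np) stop("k must be in [1, number of points]");

  // bucket grid over the bounding box of the points
  double xmin = *std::min_element(px.begin(), px.end());
  double xmax = *std::max_element(px.begin(), px.end());
  double ymin = *std::min_element(py.begin(), py.end());
  double ymax = *std::max_element(py.begin(), py.end());
  int nb = std::max(1, (int)std::sqrt((double)np / 4.0));
  double bx = std::max((xmax - xmin) / nb, 1e-300);
  double by = std::max((ymax - ymin) / nb, 1e-300);
  std::vector<std::vector<int> > buckets((size_t)nb * nb);
  for (int i = 0; i < np; i++) {
    int cx = std::min(nb - 1, std::max(0, (int)((px[i] - xmin) / bx)));
    int cy = std::min(nb - 1, std::max(0, (int)((py[i] - ymin) / by)));
    buckets[(size_t)cy * nb + cx].push_back(i);
  }

  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      double x = qx[c], y = qy[r];
      int cx = std::min(nb - 1, std::max(0, (int)((x - xmin) / bx)));
      int cy = std::min(nb - 1, std::max(0, (int)((y - ymin) / by)));
      int found = 0;
      double worst = R_PosInf;
      // expand rings of buckets until k found and ring distance exceeds
      // the current worst of the k best
      for (int ring = 0; ring < 2 * nb; ring++) {
        if (found >= k) {
          double ringDist = (ring - 1) * std::min(bx, by);
          if (ringDist > 0 && ringDist * ringDist > worst) break;
        }
        bool any = false;
        for (int dy = -ring; dy <= ring; dy++) {
          int yy = cy + dy;
          if (yy < 0 || yy >= nb) continue;
          for (int dx = -ring; dx <= ring; dx++) {
            if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
            int xx = cx + dx;
            if (xx < 0 || xx >= nb) continue;
            any = true;
            const std::vector<int> &b = buckets[(size_t)yy * nb + xx];
            for (size_t t = 0; t < b.size(); t++) {
              int i = b[t];
              double d2 = (px[i] - x) * (px[i] - x) +
                          (py[i] - y) * (py[i] - y);
              if (found < k) {
                bestd[found] = d2; besti[found] = i; found++;
                if (found == k)
                  worst = *std::max_element(bestd.begin(), bestd.end());
              } else if (d2 < worst) {
                int wi = (int)(std::max_element(bestd.begin(), bestd.end())
                               - bestd.begin());
                bestd[wi] = d2; besti[wi] = i;
                worst = *std::max_element(bestd.begin(), bestd.end());
              }
            }
          }
        }
        if (!any && ring > 2 * nb) break;
      }
      // exact interpolation at sample locations
      double val = NA_REAL, wsum = 0.0, vsum = 0.0;
      bool exact = false;
      for (int j = 0; j < found; j++) {
        if (bestd[j] < 1e-18) { val = pv[besti[j]]; exact = true; break; }
        double w = std::pow(std::sqrt(bestd[j]), -power);
        wsum += w;
        vsum += w * pv[besti[j]];
      }
      out(r, c) = exact ? val : vsum / wsum;
    }
  }
  return out;
}
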