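#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Time-weighted accumulation of Gaussian joint heatmaps over a clip.
//
// x, y, conf: F x J keypoint coordinates (grid pixels, 0-based) and
// confidences. ow: F x C per-frame time-encoding weights. The Gaussian is
// truncated at 5*sigma (relative amplitude < 4e-6) and evaluated
// separably, which makes the accumulation linear in the truncated window
// area instead of the full grid.
//
// Returns an array of dim (J*C, H, W): slice (j-1)*C + c is joint j's
// channel-c evolution map, each nonzero slice rescaled to max 1.
// [[Rcpp::export(name = ".pose_evolution_accumulate")]]
NumericVector pose_evolution_accumulate(NumericMatrix x, NumericMatrix y,
                                        NumericMatrix conf, NumericMatrix ow,
                                        int H, int W, double sigma,
                                        double conf_floor) {
  const int F = x.nrow(), J = x.ncol(), C = ow.ncol();
  if (ow.nrow() != F) stop("time-encoding weights must have one row per frame");
  const int nslice = J * C;
  std::vector<std::vector<double> > acc(nslice,
                                        std::vector<double>(H * W, 0.0));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double radius = 5.0 * sigma;
  std::vector<double> gx(W), gy(H);

  for (int f = 0; f < F; ++f) {
    for (int j = 0; j < J; ++j) {
      double cf = conf(f, j);
      if (!(cf > 0.0) || cf < conf_floor) continue;
      double kx = x(f, j), ky = y(f, j);
      int x0 = std::max(0, (int)std::ceil(kx - radius));
      int x1 = std::min(W - 1, (int)std::floor(kx + radius));
      int y0 = std::max(0, (int)std::ceil(ky - radius));
      int y1 = std::min(H - 1, (int)std::floor(ky + radius));
      if (x0 > x1 || y0 > y1) continue;
      for (int cx = x0; cx <= x1; ++cx) {
        double d = cx - kx;
        gx[cx] = std::exp(-d * d * inv2s2);
      }
      for (int cy = y0; cy <= y1; ++cy) {
        double d = cy - ky;
        gy[cy] = std::exp(-d * d * inv2s2);
      }
      for (int c = 0; c < C; ++c) {
        double w = ow(f, c);
        if (w <= 0.0) continue;
        std::vector<double> &a = acc[j * C + c];
        double amp = cf * w;
        for (int cx = x0; cx <= x1; ++cx) {
          double ax = amp * gx[cx];
          double *col = &a[cx * H];
          for (int cy = y0; cy <= y1; ++cy) col[cy] += ax * gy[cy];
        }
      }
    }
  }

  NumericVector out(Dimension(nslice, H, W));
  for (int s = 0; s < nslice; ++s) {
    std::vector<double> &a = acc[s];
    double mx = 0.0;
    for (int i = 0; i < H * W; ++i) mx = std::max(mx, a[i]);
    if (mx > 0.0) {
      // divide (not multiply by the reciprocal) so the peak cell is
      // exactly 1
      for (int xx = 0; xx < W; ++xx)
        for (int yy = 0; yy < H; ++yy)
          out[s + (R_xlen_t)nslice * (yy + (R_xlen_t)H * xx)] =
              a[xx * H + yy] / mx;
    }
  }
  return out;
}
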