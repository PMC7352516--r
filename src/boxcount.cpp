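#include <Rcpp.h>
using namespace Rcpp;

// Grid scan over complete boxes for one grid offset.
//
// For each box size eps the grid is anchored at (dx, dy) and only boxes
// lying fully inside the image are visited (counts are rescaled to the
// full image area on the R side). Per box the scan records, depending on
// `mode`:
//   0 binary       n_b = 1 if the box contains any pixel < 255
//   1 differential n_b = floor(max/h) - floor(min/h) + 1, grey box height h
//   2 span         n_b = 1 + (max - min) * scale
// and always the box "mass" sum(255 - v). Returns, per size: the number of
// complete boxes, the summed box count N_raw, and the mean and population
// SD of the box masses.
//
// [[Rcpp::export(name = ".boxScanCpp")]]
NumericMatrix boxScanCpp(IntegerMatrix img, IntegerVector sizes,
                         int dx, int dy, NumericVector h,
                         int mode, double spanScale) {
  const int W = img.nrow(), H = img.ncol();
  const int nS = sizes.size();
  NumericMatrix out(nS, 4);
  colnames(out) = CharacterVector::create("n_boxes", "N_raw",
                                          "mass_mean", "mass_sd");
  for (int s = 0; s < nS; ++s) {
    const int eps = sizes[s];
    const int nbx = (W - dx) / eps, nby = (H - dy) / eps;
    const double hh = h[s];
    double Nraw = 0.0, msum = 0.0, msum2 = 0.0;
    const long nb = (long)nbx * nby;
    if (nb == 0) {
      out(s, 0) = 0; out(s, 1) = NA_REAL;
      out(s, 2) = NA_REAL; out(s, 3) = NA_REAL;
      continue;
    }
    for (int bx = 0; bx < nbx; ++bx) {
      const int x0 = dx + bx * eps;
      for (int by = 0; by < nby; ++by) {
        const int y0 = dy + by * eps;
        int vmin = 255, vmax = 0;
        double mass = 0.0;
        for (int y = y0; y < y0 + eps; ++y) {
          const int *col = &img[(R_xlen_t)y * W];
          for (int x = x0; x < x0 + eps; ++x) {
            const int v = col[x];
            if (v < vmin) vmin = v;
            if (v > vmax) vmax = v;
            mass += 255 - v;
          }
        }
        double nbv;
        if (mode == 0) {
          nbv = (vmin < 255) ? 1.0 : 0.0;
        } else if (mode == 1) {
          nbv = std::floor(vmax / hh) - std::floor(vmin / hh) + 1.0;
        } else {
          nbv = 1.0 + (vmax - vmin) * spanScale;
        }
        Nraw += nbv;
        msum += mass;
        msum2 += mass * mass;
      }
    }
    const double mmean = msum / nb;
    double var = msum2 / nb - mmean * mmean;
    if (var < 0) var = 0;
    out(s, 0) = (double)nb;
    out(s, 1) = Nraw;
    out(s, 2) = mmean;
    out(s, 3) = std::sqrt(var);
  }
  return out;
}
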