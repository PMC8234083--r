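#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale opening with a non-flat spherical (ball) structuring element.
// The erosion/dilation pair is restricted to the image domain, so the
// opening is a true morphological opening on the lattice (<= identity).

// [[Rcpp::export(name = ".ball_opening_cpp")]]
NumericMatrix ball_opening_cpp(NumericMatrix img, double radius_px) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int) std::floor(radius_px);
  const double r2 = radius_px * radius_px;

  // precompute ball offsets and heights, normalized so the apex is 0:
  // b(k) = sqrt(r^2 - |k|^2) - r. The opening is invariant to this shift,
  // and with b(0) = 0 a constant image passes through without arithmetic.
  const double h0 = std::sqrt(r2);
  std::vector<int> dx, dy;
  std::vector<double> h;
  for (int j = -r; j <= r; ++j) {
    for (int i = -r; i <= r; ++i) {
      double d2 = (double) i * i + (double) j * j;
      if (d2 <= r2) {
        dy.push_back(i);
        dx.push_back(j);
        h.push_back(d2 == 0.0 ? 0.0 : std::sqrt(r2 - d2) - h0);
      }
    }
  }
  const int nk = (int) h.size();
  const double inf = std::numeric_limits<double>::infinity();

  // erosion: e(x) = min_k f(x + k) - b(k), k restricted to the domain
  NumericMatrix ero(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double m = inf;
      for (int k = 0; k < nk; ++k) {
        int y = rI + dy[k], x = c + dx[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double v = img(y, x) - h[k];
        if (v < m) m = v;
      }
      ero(rI, c) = m;
    }
  }

  // adjoint dilation: o(x) = max_k e(x - k) + b(k)
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double m = -inf;
      for (int k = 0; k < nk; ++k) {
        int y = rI - dy[k], x = c - dx[k];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double v = ero(y, x) + h[k];
        if (v > m) m = v;
      }
      out(rI, c) = m;
    }
  }
  return out;
}

// Block minimum used to shrink an image before rolling a large ball
// (the classic speed-up: background is a lower envelope, so the block
// minimum is the conservative reduction).

// [[Rcpp::export(name = ".block_min_cpp")]]
NumericMatrix block_min_cpp(NumericMatrix img, int s) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = (nr + s - 1) / s, onc = (nc + s - 1) / s;
  NumericMatrix out(onr, onc);
  for (int bc = 0; bc < onc; ++bc) {
    for (int br = 0; br < onr; ++br) {
      double m = std::numeric_limits<double>::infinity();
      for (int c = bc * s; c < std::min(nc, (bc + 1) * s); ++c)
        for (int r = br * s; r < std::min(nr, (br + 1) * s); ++r)
          if (img(r, c) < m) m = img(r, c);
      out(br, bc) = m;
    }
  }
  return out;
}
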