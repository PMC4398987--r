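#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Joint spatial+range mean-shift filtering of an LUV image with a flat
// (uniform) kernel. For every pixel, the (row, col, L, u, v) point is moved
// to the mean of the image points inside the spatial disc of radius hs and
// the range ball of radius hr around it, until the shift is below eps or
// max_iter is reached. Returns the converged (mode) color per pixel.
// [[Rcpp::export(name = ".ms_filter")]]
NumericMatrix ms_filter(NumericMatrix L, NumericMatrix U, NumericMatrix V,
                        double hs, double hr, int max_iter, double eps) {
  const int nr = L.nrow(), nc = L.ncol();
  NumericMatrix out(nr * nc, 3);
  const int rs = (int)std::ceil(hs);
  const double hs2 = hs * hs, hr2 = hr * hr, eps2 = eps * eps;
  const double *pL = L.begin(), *pU = U.begin(), *pV = V.begin();

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      double xr = r0, xc = c0;
      const int p0 = r0 + c0 * nr;
      double cl = pL[p0], cu = pU[p0], cv = pV[p0];
      for (int it = 0; it < max_iter; ++it) {
        const int rc = (int)std::lround(xr), cc = (int)std::lround(xc);
        const int rlo = std::max(0, rc - rs), rhi = std::min(nr - 1, rc + rs);
        const int clo = std::max(0, cc - rs), chi = std::min(nc - 1, cc + rs);
        double sr = 0, sc = 0, sl = 0, su = 0, sv = 0;
        int n = 0;
        for (int cj = clo; cj <= chi; ++cj) {
          const double dc = cj - xc;
          const double dc2 = dc * dc;
          const double *colL = pL + (size_t)cj * nr;
          const double *colU = pU + (size_t)cj * nr;
          const double *colV = pV + (size_t)cj * nr;
          for (int ri = rlo; ri <= rhi; ++ri) {
            const double dr = ri - xr;
            if (dr * dr + dc2 > hs2) continue;
            const double dl = colL[ri] - cl, du = colU[ri] - cu,
                         dv = colV[ri] - cv;
            if (dl * dl + du * du + dv * dv > hr2) continue;
            sr += ri; sc += cj;
            sl += colL[ri]; su += colU[ri]; sv += colV[ri];
            ++n;
          }
        }
        if (n == 0) break;
        const double nxr = sr / n, nxc = sc / n;
        const double nl = sl / n, nu = su / n, nv = sv / n;
        const double shift = (nxr - xr) * (nxr - xr) + (nxc - xc) * (nxc - xc) +
                             (nl - cl) * (nl - cl) + (nu - cu) * (nu - cu) +
                             (nv - cv) * (nv - cv);
        xr = nxr; xc = nxc; cl = nl; cu = nu; cv = nv;
        if (shift < eps2) break;
      }
      const int idx = r0 + c0 * nr;
      out(idx, 0) = cl; out(idx, 1) = cu; out(idx, 2) = cv;
    }
  }
  return out;
}

// 4-connected region labeling of the filtered image: neighboring pixels are
// fused when their mode colors differ by less than hr (Euclidean in LUV).
// Labels are 1-based in scan order of region discovery.
// [[Rcpp::export(name = ".ms_label")]]
IntegerMatrix ms_label(NumericMatrix L, NumericMatrix U, NumericMatrix V,
                       double hr) {
  const int nr = L.nrow(), nc = L.ncol();
  IntegerMatrix lab(nr, nc);
  const double hr2 = hr * hr;
  std::vector<int> stack;
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) != 0) continue;
      lab(r0, c0) = ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 4; ++k) {
          const int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (lab(qr, qc) != 0) continue;
          const double dl = L(qr, qc) - L(pr, pc), du = U(qr, qc) - U(pr, pc),
                       dv = V(qr, qc) - V(pr, pc);
          if (dl * dl + du * du + dv * dv >= hr2) continue;
          lab(qr, qc) = next;
          stack.push_back(qr + qc * nr);
        }
      }
    }
  }
  return lab;
}

// Forward-splat warp of a binary mask by a dense displacement field
// (rounded to integer pixels, clipped at the borders), followed by one
// hole-filling pass: empty pixels with >= 3 occupied 4-neighbors switch on.
// [[Rcpp::export(name = ".warp_mask_cpp")]]
LogicalMatrix warp_mask_cpp(LogicalMatrix mask, NumericMatrix dy,
                            NumericMatrix dx) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int tr = r + (int)std::lround(dy(r, c));
      const int tc = c + (int)std::lround(dx(r, c));
      if (tr < 0 || tr >= nr || tc < 0 || tc >= nc) continue;
      out(tr, tc) = 1;
    }
  }
  LogicalMatrix fill = clone(out);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (out(r, c)) continue;
      int n = 0;
      if (r > 0 && out(r - 1, c)) ++n;
      if (r + 1 < nr && out(r + 1, c)) ++n;
      if (c > 0 && out(r, c - 1)) ++n;
      if (c + 1 < nc && out(r, c + 1)) ++n;
      if (n >= 3) fill(r, c) = 1;
    }
  }
  return fill;
}
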