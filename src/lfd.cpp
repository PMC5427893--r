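#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local connected fractal dimension map.
//
// For each sampled foreground pixel p inside the ROI:
//   1. take the window of half-width R = (max box - 1)/2 centred at p,
//      clipped to the image;
//   2. flood-fill (4- or 8-connectivity) the foreground restricted to that
//      window, keeping the component that contains p;
//   3. mu_eps = number of component pixels with Chebyshev distance to p
//      <= (eps - 1)/2, for every box size eps;
//   4. LFD(p) = least-squares slope of ln(mu_eps) on ln(eps).
// Pixels whose component yields fewer than min_scales distinct masses are
// marked invalid. Slopes are clipped to [0, clip_max] and clips counted.

// [[Rcpp::export(name = ".lfd_map_cpp")]]
List lfd_map_cpp(LogicalMatrix mask, LogicalMatrix roi, IntegerVector box_sizes,
                 int stride, int connectivity, int min_scales, double clip_max) {
  int nr = mask.nrow(), nc = mask.ncol();
  int nbox = box_sizes.size();
  int maxbox = box_sizes[nbox - 1];
  int R = (maxbox - 1) / 2;
  int W = 2 * R + 1;

  NumericMatrix lfd(nr, nc);
  std::fill(lfd.begin(), lfd.end(), NA_REAL);
  LogicalMatrix valid(nr, nc);
  int n_clipped = 0, n_invalid = 0;

  std::vector<double> lx(nbox), ly(nbox);
  double lxbar = 0.0;
  for (int i = 0; i < nbox; ++i) {
    lx[i] = std::log((double)box_sizes[i]);
    lxbar += lx[i];
  }
  lxbar /= nbox;
  double sxx = 0.0;
  for (int i = 0; i < nbox; ++i) sxx += (lx[i] - lxbar) * (lx[i] - lxbar);

  std::vector<int> comp(W * W);        // visited flags for flood fill
  std::vector<int> stack(W * W);
  std::vector<double> cnt(R + 1);      // component pixels per Chebyshev radius

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {-1, 1, 0, 0};
  int ndir = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;

  for (int c0 = 0; c0 < nc; c0 += stride) {
    for (int r0 = 0; r0 < nr; r0 += stride) {
      if (!mask(r0, c0) || !roi(r0, c0)) continue;

      std::fill(comp.begin(), comp.end(), 0);
      std::fill(cnt.begin(), cnt.end(), 0.0);
      int top = 0;
      int pc = R * W + R;              // centre in window coordinates
      comp[pc] = 1;
      stack[top++] = pc;
      cnt[0] += 1.0;
      while (top > 0) {
        int q = stack[--top];
        int wr = q / W, wc = q % W;
        for (int k = 0; k < ndir; ++k) {
          int ar = wr + dr[k], ac = wc + dc[k];
          if (ar < 0 || ac < 0 || ar >= W || ac >= W) continue;
          int aq = ar * W + ac;
          if (comp[aq]) continue;
          int gr = r0 + ar - R, gc = c0 + ac - R;
          if (gr < 0 || gc < 0 || gr >= nr || gc >= nc) continue;
          if (!mask(gr, gc)) continue;
          comp[aq] = 1;
          stack[top++] = aq;
          int cd = std::max(std::abs(ar - R), std::abs(ac - R));
          cnt[cd] += 1.0;
        }
      }

      // cumulative mass per box size, then regression of ln(mu) on ln(eps)
      double mu_prev = 0.0;
      int bi = 0;
      double cum = 0.0;
      double sxy = 0.0, lybar = 0.0;
      int distinct = 0;
      std::vector<double> mu(nbox);
      for (int d = 0; d <= R && bi < nbox; ++d) {
        cum += cnt[d];
        while (bi < nbox && (box_sizes[bi] - 1) / 2 == d) {
          mu[bi] = cum;
          if (bi == 0 || mu[bi] != mu_prev) ++distinct;
          mu_prev = mu[bi];
          ++bi;
        }
      }
      if (distinct < min_scales) {
        ++n_invalid;
        continue;
      }
      for (int i = 0; i < nbox; ++i) {
        ly[i] = std::log(mu[i]);
        lybar += ly[i];
      }
      lybar /= nbox;
      for (int i = 0; i < nbox; ++i) sxy += (lx[i] - lxbar) * (ly[i] - lybar);
      double slope = sxy / sxx;
      if (slope < 0.0) { slope = 0.0; ++n_clipped; }
      else if (slope > clip_max) { slope = clip_max; ++n_clipped; }
      lfd(r0, c0) = slope;
      valid(r0, c0) = true;
    }
  }

  return List::create(_["lfd"] = lfd, _["valid"] = valid,
                      _["n_clipped"] = n_clipped, _["n_invalid"] = n_invalid);
}
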