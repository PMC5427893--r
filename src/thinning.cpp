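#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning with a corner clean-up pass.
//
// The clean-up removes degree-2 pixels whose two neighbours are themselves
// 8-adjacent (redundant staircase corners); these otherwise inflate neighbour
// counts and create spurious junction pixels in the graph extraction.
//
// Deterministic given the input raster. Orientation canonicalisation (for
// exact rotation/flip invariance of downstream metrics) happens in R.

static inline int at(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// [[Rcpp::export(name = ".thin_raster_cpp")]]
LogicalMatrix thin_raster_cpp(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix m = clone(img);
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1);
          int p4 = at(m, r,     c + 1), p5 = at(m, r + 1, c + 1);
          int p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1);
          int p8 = at(m, r,     c - 1), p9 = at(m, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        m(kill[i].first, kill[i].second) = false;
    }
  }

  // sequential reduction to a minimal skeleton: repeatedly delete 8-simple,
  // non-endpoint pixels (immediate update). An 8-simple pixel has exactly
  // one 8-connected foreground component among its neighbours and exactly
  // one 4-connected background component touching a 4-neighbour, so its
  // removal preserves topology. This clears the two-pixel staircases
  // Zhang-Suen leaves behind, which would otherwise read as junctions.
  static int simple8[256];
  static bool lut_ready = false;
  // ring order: N, NE, E, SE, S, SW, W, NW
  const int rr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int cc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  if (!lut_ready) {
    for (int msk = 0; msk < 256; ++msk) {
      // foreground components under 8-adjacency between ring cells
      int fg_comp = 0, bg_comp = 0;
      int seen[8] = {0};
      for (int i = 0; i < 8; ++i) {
        if (!((msk >> i) & 1) || seen[i]) continue;
        ++fg_comp;
        int st[8], top = 0;
        st[top++] = i; seen[i] = 1;
        while (top) {
          int q = st[--top];
          for (int j = 0; j < 8; ++j) {
            if (!((msk >> j) & 1) || seen[j]) continue;
            if (std::abs(rr[q] - rr[j]) <= 1 && std::abs(cc[q] - cc[j]) <= 1) {
              seen[j] = 1; st[top++] = j;
            }
          }
        }
      }
      // background components under 4-adjacency, counted only when they
      // contain a 4-neighbour of the centre (even ring index)
      int seenb[8] = {0};
      for (int i = 0; i < 8; ++i) {
        if (((msk >> i) & 1) || seenb[i]) continue;
        int st[8], top = 0, touches4 = 0;
        st[top++] = i; seenb[i] = 1;
        while (top) {
          int q = st[--top];
          if (q % 2 == 0) touches4 = 1;
          for (int j = 0; j < 8; ++j) {
            if (((msk >> j) & 1) || seenb[j]) continue;
            if (std::abs(rr[q] - rr[j]) + std::abs(cc[q] - cc[j]) == 1) {
              seenb[j] = 1; st[top++] = j;
            }
          }
        }
        if (touches4) ++bg_comp;
      }
      int B = 0;
      for (int i = 0; i < 8; ++i) B += (msk >> i) & 1;
      simple8[msk] = (B >= 2 && fg_comp == 1 && bg_comp == 1) ? 1 : 0;
    }
    lut_ready = true;
  }

  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m(r, c)) continue;
        int msk = 0;
        for (int i = 0; i < 8; ++i)
          if (at(m, r + rr[i], c + cc[i])) msk |= (1 << i);
        if (simple8[msk]) {
          m(r, c) = false;
          changed = true;
        }
      }
    }
  }
  return m;
}
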