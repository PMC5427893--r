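#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling: 2D (4- or 8-connectivity) and 3D
// (6-connectivity, used for HRS leaf masks). Labels are 1..K in scan order.

// [[Rcpp::export(name = ".label2d_cpp")]]
IntegerMatrix label2d_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {-1, 1, 0, 0};
  int ndir = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qr = q % nr, qc = q / nr;
        for (int k = 0; k < ndir; ++k) {
          int ar = qr + dr[k], ac = qc + dc[k];
          if (ar < 0 || ac < 0 || ar >= nr || ac >= nc) continue;
          if (!mask(ar, ac) || lab(ar, ac)) continue;
          lab(ar, ac) = next;
          stack.push_back(ar + ac * nr);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int n = n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      int a = q % n1, rem = q / n1;
      int b = rem % n2, d = rem / n2;
      const int off[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                             {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int k = 0; k < 6; ++k) {
        int aa = a + off[k][0], bb = b + off[k][1], dd = d + off[k][2];
        if (aa < 0 || bb < 0 || dd < 0 || aa >= n1 || bb >= n2 || dd >= n3)
          continue;
        int qi = aa + n1 * (bb + n2 * dd);
        if (!mask[qi] || lab[qi]) continue;
        lab[qi] = next;
        stack.push_back(qi);
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
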