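#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh) over integer-encoded
// residues. Gap of length L costs gap_open + L * gap_extend. Returns the best
// local alignment with 0-based half-open coordinates on both sequences plus
// identity bookkeeping from the traceback.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  const int na = mat.nrow();
  std::vector<int> M(mat.begin(), mat.end());   // column-major na x na
  std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  // traceback codes: 0 stop, 1 diag, 2 up(gap in s), 3 left(gap in q)
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  const int oe = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0, F = NEG, Hij = 0;
    H[0] = 0;
    const int* mrow = &M[(size_t)qv[i - 1]];  // row qi, stride na (col-major)
    size_t row = (size_t)i * (m + 1);
    unsigned char* tbHr = &tbH[row];
    unsigned char* tbEr = &tbE[row];
    unsigned char* tbFr = &tbF[row];
    for (int j = 1; j <= m; ++j) {
      // E[j] tracks vertical (gap in s, consume q), F horizontal.
      int e_open = H[j] - oe;                 // H[i-1][j] is current H[j]
      int e_ext = E[j] - gap_extend;
      int Enew = e_open >= e_ext ? e_open : e_ext;
      tbEr[j] = e_ext > e_open ? 1 : 0;
      int f_open = Hij - oe;                  // Hij = H[i][j-1]
      int f_ext = F - gap_extend;
      F = f_open >= f_ext ? f_open : f_ext;
      tbFr[j] = f_ext > f_open ? 1 : 0;
      int diag = Hdiag + mrow[(size_t)sv[j - 1] * na];
      int h = diag; unsigned char tb = 1;
      if (Enew > h) { h = Enew; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      if (h <= 0) { h = 0; tb = 0; }
      Hdiag = H[j];
      E[j] = Enew;
      H[j] = h; Hij = h;
      tbHr[j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj, matches = 0, alen = 0, ngaps = 0;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    size_t row = (size_t)i * (m + 1);
    if (state == 0) {
      unsigned char tb = tbH[row + j];
      if (tb == 0) break;
      if (tb == 1) {
        if (qv[i - 1] == sv[j - 1]) ++matches;
        ++alen; --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // vertical: gap in s, consume q
      ++alen; ++ngaps;
      if (tbE[row + j] == 0) state = 0;
      --i;
    } else { // horizontal: gap in q, consume s
      ++alen; ++ngaps;
      if (tbF[row + j] == 0) state = 0;
      --j;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["aligned_length"] = alen,
                      _["n_gaps"] = ngaps);
}

// Global affine-gap alignment (Needleman-Wunsch / Gotoh) over a precomputed
// column-pair score matrix S (n1 x n2), e.g. profile-profile column scores.
// End gaps are charged. Returns the aligned index path: two integer vectors of
// equal length, 1-based indices into each profile, 0 marking a gap column.
// [[Rcpp::export]]
List gotoh_global_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  std::vector<double> H(m + 1), E(m + 1);
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  H[0] = 0; E[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    H[j] = -gap_open - gap_extend * j;
    E[j] = NEG;
    tbH[j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    double Hdiag = H[0], F = NEG;
    H[0] = -gap_open - gap_extend * i;
    double Hij = H[0];
    tbH[(size_t)i * (m + 1)] = 2;
    size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      double e_open = H[j] - gap_open - gap_extend;
      double e_ext = E[j] - gap_extend;
      double Enew = e_open >= e_ext ? e_open : e_ext;
      tbE[row + j] = e_ext > e_open ? 1 : 0;
      double f_open = Hij - gap_open - gap_extend;
      double f_ext = F - gap_extend;
      F = f_open >= f_ext ? f_open : f_ext;
      tbF[row + j] = f_ext > f_open ? 1 : 0;
      double diag = Hdiag + S(i - 1, j - 1);
      double h = diag; unsigned char tb = 1;
      if (Enew > h) { h = Enew; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      Hdiag = H[j];
      E[j] = Enew;
      H[j] = h; Hij = h;
      tbH[row + j] = tb;
    }
  }
  std::vector<int> a1, a2;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    size_t row = (size_t)i * (m + 1);
    if (state == 0) {
      unsigned char tb = tbH[row + j];
      if (i == 0) tb = 3;
      else if (j == 0) tb = 2;
      if (tb == 1) { a1.push_back(i); a2.push_back(j); --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in profile 2
      a1.push_back(i); a2.push_back(0);
      if (tbE[row + j] == 0 || j == 0) state = 0;
      --i;
    } else {               // gap in profile 1
      a1.push_back(0); a2.push_back(j);
      if (tbF[row + j] == 0 || i == 0) state = 0;
      --j;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["idx1"] = wrap(a1), _["idx2"] = wrap(a2));
}
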