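#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise dynamic programs over an arbitrary pre-computed score
// matrix S (rows = positions of a, cols = positions of b).  A gap of length
// L costs gap_open + (L - 1) * gap_ext, i.e. the opening charge includes the
// first extension.  Traceback ties are broken diagonal > up > left, where
// "up" consumes a row (gap in b) and "left" consumes a column (gap in a).
//
// Working on a score matrix rather than on sequences lets the same kernels
// serve residue-vs-residue local alignment (Smith-Waterman), profile-vs-
// profile progressive alignment (sum-of-pairs column scores), and
// profile-HMM-vs-profile-HMM comparison (co-emission column scores).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".align_local_dp")]]
List align_local_dp(NumericMatrix S, double gap_open, double gap_ext,
                    bool traceback) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix ptrH(1, 1), ptrE(1, 1), ptrF(1, 1);
  if (traceback) {
    ptrH = IntegerMatrix(n + 1, m + 1);  // 0 stop, 1 diag, 2 up, 3 left
    ptrE = IntegerMatrix(n + 1, m + 1);  // 1 open (from H), 2 extend
    ptrF = IntegerMatrix(n + 1, m + 1);
  }
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG_INF; F(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG_INF; F(i, 0) = NEG_INF; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_ext);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_ext);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = 0.0;
      if (diag > h) h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      H(i, j) = h;
      if (traceback) {
        int p = 0;
        if (h > 0.0) {
          if (diag == h) p = 1;          // diagonal preferred on ties
          else if (F(i, j) == h) p = 2;  // then up
          else p = 3;                    // then left
        }
        ptrH(i, j) = p;
        ptrE(i, j) = (H(i, j - 1) - gap_open >= E(i, j - 1) - gap_ext) ? 1 : 2;
        ptrF(i, j) = (H(i - 1, j) - gap_open >= F(i - 1, j) - gap_ext) ? 1 : 2;
      }
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0),
                        _["end_a"] = bi, _["end_b"] = bj);
  }

  std::vector<int> av, bv;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int p = ptrH(i, j);
      if (p == 0) break;
      if (p == 1) { av.push_back(i); bv.push_back(j); --i; --j; }
      else if (p == 2) state = 2;
      else state = 1;
    } else if (state == 2) {           // gap in b, consume row
      av.push_back(i); bv.push_back(0);
      int p = ptrF(i, j); --i;
      if (p == 1) state = 0;
    } else {                           // gap in a, consume column
      av.push_back(0); bv.push_back(j);
      int p = ptrE(i, j); --j;
      if (p == 1) state = 0;
    }
  }
  std::reverse(av.begin(), av.end());
  std::reverse(bv.begin(), bv.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(av), _["b_idx"] = wrap(bv),
                      _["end_a"] = bi, _["end_b"] = bj);
}

// [[Rcpp::export(name = ".align_global_dp")]]
List align_global_dp(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix ptrH(n + 1, m + 1), ptrE(n + 1, m + 1), ptrF(n + 1, m + 1);

  H(0, 0) = 0.0; E(0, 0) = NEG_INF; F(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -(gap_open + (j - 1) * gap_ext);
    H(0, j) = E(0, j); F(0, j) = NEG_INF;
    ptrH(0, j) = 3; ptrE(0, j) = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -(gap_open + (i - 1) * gap_ext);
    H(i, 0) = F(i, 0); E(i, 0) = NEG_INF;
    ptrH(i, 0) = 2; ptrF(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_open = H(i, j - 1) - gap_open, e_ext = E(i, j - 1) - gap_ext;
      if (e_open >= e_ext) { E(i, j) = e_open; ptrE(i, j) = 1; }
      else { E(i, j) = e_ext; ptrE(i, j) = 2; }
      double f_open = H(i - 1, j) - gap_open, f_ext = F(i - 1, j) - gap_ext;
      if (f_open >= f_ext) { F(i, j) = f_open; ptrF(i, j) = 1; }
      else { F(i, j) = f_ext; ptrF(i, j) = 2; }
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = diag; int p = 1;
      if (F(i, j) > h) { h = F(i, j); p = 2; }
      if (E(i, j) > h) { h = E(i, j); p = 3; }
      H(i, j) = h; ptrH(i, j) = p;
    }
  }

  std::vector<int> av, bv;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 1; continue; }
      if (j == 0) { state = 2; continue; }
      int p = ptrH(i, j);
      if (p == 1) { av.push_back(i); bv.push_back(j); --i; --j; }
      else if (p == 2) state = 2;
      else state = 1;
    } else if (state == 2) {
      av.push_back(i); bv.push_back(0);
      int p = ptrF(i, j); --i;
      if (p == 1 || i == 0) state = 0;
    } else {
      av.push_back(0); bv.push_back(j);
      int p = ptrE(i, j); --j;
      if (p == 1 || j == 0) state = 0;
    }
  }
  std::reverse(av.begin(), av.end());
  std::reverse(bv.begin(), bv.end());
  return List::create(_["score"] = H(n, m),
                      _["a_idx"] = wrap(av), _["b_idx"] = wrap(bv));
}

// All-pairs Smith-Waterman raw scores for encoded sequences (values are
// 1-based indices into the substitution matrix).  Score-only rolling-row
// Gotoh; returns the symmetric score matrix.
// [[Rcpp::export(name = ".sw_all_pairs")]]
NumericMatrix sw_all_pairs(List seqs, NumericMatrix sub,
                           double gap_open, double gap_ext) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::vector<int> > enc(n);
  int maxlen = 1;
  for (int k = 0; k < n; ++k) {
    IntegerVector v = seqs[k];
    enc[k].assign(v.begin(), v.end());
    maxlen = std::max(maxlen, (int)enc[k].size());
  }
  std::vector<double> Hrow(maxlen + 1), Frow(maxlen + 1);

  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      const std::vector<int>& x = enc[a];
      const std::vector<int>& y = enc[b];
      const int nx = x.size(), ny = y.size();
      std::fill(Hrow.begin(), Hrow.begin() + ny + 1, 0.0);
      std::fill(Frow.begin(), Frow.begin() + ny + 1, NEG_INF);
      double best = 0.0;
      for (int i = 1; i <= nx; ++i) {
        double diag = Hrow[0];   // H(i-1, j-1)
        double e = NEG_INF;      // E(i, j-1)
        for (int j = 1; j <= ny; ++j) {
          double f = std::max(Hrow[j] - gap_open, Frow[j] - gap_ext);
          e = std::max(Hrow[j - 1] - gap_open, e - gap_ext);
          double d = diag + sub(x[i - 1] - 1, y[j - 1] - 1);
          double h = 0.0;
          if (d > h) h = d;
          if (f > h) h = f;
          if (e > h) h = e;
          diag = Hrow[j];
          Hrow[j] = h; Frow[j] = f;
          if (h > best) best = h;
        }
      }
      out(a, b) = best; out(b, a) = best;
    }
  }
  return out;
}
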