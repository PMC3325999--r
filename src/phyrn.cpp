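#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of an integer-encoded query (1..20)
// against a position-specific score matrix, affine gap penalties.
//
// States: M (query residue aligned to profile position), X (gap in the
// query: profile advances), Y (gap in the profile: query advances).
// Alignments start and end in state M; a cell counts as a hit only if its
// M score is strictly positive. Ties are broken deterministically:
// M > X > Y on traceback, and the first maximal cell in row-major order.
//
// [[Rcpp::export]]
List cpp_profile_align(IntegerVector query, NumericMatrix scores,
                       IntegerVector seed_res, double gap_open,
                       double gap_extend, bool traceback) {
  const int n = query.size();        // query length
  const int m = scores.nrow();       // profile length
  if (scores.ncol() != 20) stop("score matrix must have 20 columns");
  const double NEG = -1e30;

  std::vector<double> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // traceback codes: for M, 0 = fresh start, 1 = from M, 2 = from X, 3 = from Y
  // for X: 1 = opened from M, 2 = extended; for Y likewise
  std::vector<unsigned char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((size_t)(n + 1) * (m + 1), 0);
    tbX.assign((size_t)(n + 1) * (m + 1), 0);
    tbY.assign((size_t)(n + 1) * (m + 1), 0);
  }

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
    const int qa = query[i - 1] - 1;
    if (qa < 0 || qa > 19) stop("query residue out of range");
    for (int j = 1; j <= m; ++j) {
      // M state
      double s = scores(j - 1, qa);
      double prevM = Mp[j - 1], prevX = Xp[j - 1], prevY = Yp[j - 1];
      double cont = prevM; unsigned char code = 1;
      if (prevX > cont) { cont = prevX; code = 2; }
      if (prevY > cont) { cont = prevY; code = 3; }
      if (cont < 0.0) { cont = 0.0; code = 0; }
      Mc[j] = cont + s;
      if (traceback) tbM[(size_t)i * (m + 1) + j] = code;
      // X state: gap in query, profile advances (from column j-1, same i)
      double openX = Mc[j - 1] - gap_open;
      double extX = Xc[j - 1] - gap_extend;
      if (openX >= extX) { Xc[j] = openX; if (traceback) tbX[(size_t)i * (m + 1) + j] = 1; }
      else { Xc[j] = extX; if (traceback) tbX[(size_t)i * (m + 1) + j] = 2; }
      // Y state: gap in profile, query advances (from row i-1, same j)
      double openY = Mp[j] - gap_open;
      double extY = Yp[j] - gap_extend;
      if (openY >= extY) { Yc[j] = openY; if (traceback) tbY[(size_t)i * (m + 1) + j] = 1; }
      else { Yc[j] = extY; if (traceback) tbY[(size_t)i * (m + 1) + j] = 2; }
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    if (traceback) {
      // rows already recorded in tb matrices; nothing else to do
    }
  }

  if (best <= 0.0 || bi < 0) {
    return List::create(_["hit"] = false, _["score"] = 0.0);
  }
  if (!traceback) {
    return List::create(_["hit"] = true, _["score"] = best);
  }

  // full traceback requires the whole DP; rerun storing only directions was
  // done above (tb matrices), so walk back from (bi, bj) in state M
  std::vector<int> qpos, ppos;
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = X, 2 = Y
  while (i > 0 || j > 0) {
    if (state == 0) {
      qpos.push_back(i); ppos.push_back(j);
      unsigned char c = tbM[(size_t)i * (m + 1) + j];
      --i; --j;
      if (c == 0) break;
      state = (c == 1) ? 0 : (c == 2) ? 1 : 2;
    } else if (state == 1) {
      qpos.push_back(0); ppos.push_back(j);
      unsigned char c = tbX[(size_t)i * (m + 1) + j];
      --j;
      state = (c == 1) ? 0 : 1;
    } else {
      qpos.push_back(i); ppos.push_back(0);
      unsigned char c = tbY[(size_t)i * (m + 1) + j];
      --i;
      state = (c == 1) ? 0 : 2;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(ppos.begin(), ppos.end());

  int alen = (int)qpos.size(), aqlen = 0, ids = 0;
  for (int k = 0; k < alen; ++k) {
    if (qpos[k] > 0) ++aqlen;
    if (qpos[k] > 0 && ppos[k] > 0 &&
        query[qpos[k] - 1] == seed_res[ppos[k] - 1]) ++ids;
  }
  return List::create(_["hit"] = true, _["score"] = best,
                      _["qpos"] = wrap(qpos), _["ppos"] = wrap(ppos),
                      _["ids"] = ids, _["alen"] = alen, _["aqlen"] = aqlen,
                      _["gap_chars"] = alen - aqlen);
}

// Pairwise identity matrix from an integer alignment matrix (rows = leaves,
// 0 = gap). Identity over columns where both rows carry residues; NA when a
// pair shares no residue-residue column.
//
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_identity(IntegerMatrix aln) {
  const int n = aln.nrow(), L = aln.ncol();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    out(a, a) = 1.0;
    for (int b = a + 1; b < n; ++b) {
      long both = 0, eq = 0;
      for (int k = 0; k < L; ++k) {
        int x = aln(a, k), y = aln(b, k);
        if (x > 0 && y > 0) { ++both; if (x == y) ++eq; }
      }
      double v = both > 0 ? (double)eq / (double)both : NA_REAL;
      out(a, b) = v; out(b, a) = v;
    }
  }
  return out;
}
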