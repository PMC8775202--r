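#include <Rcpp.h>
using namespace Rcpp;

// Ungapped maximal-scoring segments of a translated sequence against a PSSM.
//
// Every alignment offset (diagonal) between the amino-acid sequence and the
// profile is scanned with a Kadane-style walk: a run is opened when the
// cumulative score rises above zero and flushed (recorded, if it reaches
// min_score) when the cumulative score falls back to zero or the diagonal
// ends.  Sentinel residues (stop codons, X) carry the matrix minimum, so
// segments naturally break at stops.
//
// aa:   residue indices 0..19 in matrix column order; < 0 for sentinel.
// pssm: profile_length x 20 score matrix.
//
// Returns one row per recorded segment: seq_start / prof_start (0-based),
// len (aligned positions) and raw score.
// [[Rcpp::export]]
DataFrame scan_pssm_cpp(IntegerVector aa, NumericMatrix pssm, double min_score) {
  int n = aa.size();
  int L = pssm.nrow();
  int nc = pssm.ncol();
  const double *P = &pssm(0, 0);
  const int *A = &aa[0];
  double mmin = R_PosInf;
  for (int i = 0; i < L * nc; ++i)
    if (P[i] < mmin) mmin = P[i];
  // row-major copy with the sentinel as an extra residue column
  std::vector<double> M((size_t)L * (nc + 1));
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < nc; ++j) M[(size_t)i * (nc + 1) + j] = P[j * L + i];
    M[(size_t)i * (nc + 1) + nc] = mmin;
  }
  std::vector<int> seq_start, prof_start, seg_len;
  std::vector<double> seg_score;
  for (int d = -(L - 1); d < n; ++d) {
    int i0 = std::max(0, -d);
    int imax = std::min(L, n - d);
    if (imax - i0 <= 0) continue;
    double run = 0.0, best = 0.0;
    int runStart = i0, bestStart = -1, bestEnd = -1;
    for (int i = i0; i <= imax; ++i) {
      bool flush = (i == imax);
      if (!flush) {
        int a = A[d + i];
        double s = M[(size_t)i * (nc + 1) + (a < 0 ? nc : a)];
        if (run <= 0) { run = 0.0; runStart = i; }
        run += s;
        if (run > best) { best = run; bestStart = runStart; bestEnd = i + 1; }
        if (run <= 0) flush = true;
      }
      if (flush && best >= min_score && bestStart >= 0) {
        seq_start.push_back(d + bestStart);
        prof_start.push_back(bestStart);
        seg_len.push_back(bestEnd - bestStart);
        seg_score.push_back(best);
        run = 0.0; best = 0.0; bestStart = -1; bestEnd = -1;
      }
    }
  }
  return DataFrame::create(_["seq_start"] = seq_start,
                           _["prof_start"] = prof_start,
                           _["len"] = seg_len,
                           _["score"] = seg_score);
}
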