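#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. Sequences arrive as 0-based
// integer encodings into the rows/columns of the scoring matrix S.
// Gap of length L costs gapOpen + gapExt * L (Biostrings convention).
//
// Tie-breaking, in this order, to guarantee a deterministic optimum:
//   * within a cell: diagonal over up (gap in target) over left (gap in query);
//   * among equal-score maxima: smallest (targetStart, queryStart), then
//     smallest (targetEnd, queryEnd).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                  double gapOpen, double gapExt) {
  const int n = q.size(), m = t.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), R_NegInf);
  std::vector<double> F((n + 1) * (m + 1), R_NegInf);
  // trace codes for H: 0 stop, 1 diag, 2 up(F), 3 left(E)
  std::vector<unsigned char> TH((n + 1) * (m + 1), 0);
  // trace for E: 1 = opened from H, 0 = extended; same for F
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);

  double best = 0.0;
  std::vector<std::pair<int, int> > maxima;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * (m + 1) + j;
      const int kup = (i - 1) * (m + 1) + j;
      const int kleft = i * (m + 1) + (j - 1);
      const int kdiag = (i - 1) * (m + 1) + (j - 1);

      double eOpen = H[kleft] - gapOpen - gapExt;
      double eExt = E[kleft] - gapExt;
      if (eOpen >= eExt) { E[k] = eOpen; TE[k] = 1; } else { E[k] = eExt; TE[k] = 0; }

      double fOpen = H[kup] - gapOpen - gapExt;
      double fExt = F[kup] - gapExt;
      if (fOpen >= fExt) { F[k] = fOpen; TF[k] = 1; } else { F[k] = fExt; TF[k] = 0; }

      double diag = H[kdiag] + S(q[i - 1], t[j - 1]);
      double h = 0.0; unsigned char th = 0;
      if (diag >= h) { h = diag; th = 1; }
      if (F[k] > h) { h = F[k]; th = 2; }
      if (E[k] > h) { h = E[k]; th = 3; }
      H[k] = h; TH[k] = th;

      if (h > best + 1e-12) {
        best = h;
        maxima.clear();
        maxima.push_back(std::make_pair(i, j));
      } else if (h > 0 && std::abs(h - best) <= 1e-12) {
        maxima.push_back(std::make_pair(i, j));
      }
    }
  }

  if (best <= 0.0 || maxima.empty()) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0,
                        _["q_path"] = IntegerVector(0),
                        _["t_path"] = IntegerVector(0));
  }

  // traceback one endpoint; returns start (i, j) and the paths
  int bi = -1, bj = -1, bsi = -1, bsj = -1;
  std::vector<int> bqp, btp;
  for (size_t c = 0; c < maxima.size(); ++c) {
    int i = maxima[c].first, j = maxima[c].second;
    std::vector<int> qp, tp;
    int ci = i, cj = j;
    int state = 0; // 0 = in H
    while (true) {
      int k = ci * (m + 1) + cj;
      if (state == 0) {
        if (TH[k] == 0 || H[k] <= 0.0) break;
        if (TH[k] == 1) {
          qp.push_back(ci - 1); tp.push_back(cj - 1);
          --ci; --cj;
        } else if (TH[k] == 2) state = 2;
        else state = 3;
      } else if (state == 2) { // F: gap in target, consume query
        qp.push_back(ci - 1); tp.push_back(-1);
        int wasOpen = TF[k];
        --ci;
        if (wasOpen) state = 0;
      } else { // E: gap in query, consume target
        qp.push_back(-1); tp.push_back(cj - 1);
        int wasOpen = TE[k];
        --cj;
        if (wasOpen) state = 0;
      }
    }
    int si = ci, sj = cj; // alignment starts at (si+1, sj+1) 1-based => 0-based si, sj
    bool take = false;
    if (bi < 0) take = true;
    else if (sj < bsj || (sj == bsj && (si < bsi ||
             (si == bsi && (j < bj || (j == bj && i < bi)))))) take = true;
    if (take) {
      bi = i; bj = j; bsi = si; bsj = sj;
      std::reverse(qp.begin(), qp.end());
      std::reverse(tp.begin(), tp.end());
      bqp = qp; btp = tp;
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = bsi, _["q_end"] = bi,
                      _["t_start"] = bsj, _["t_end"] = bj,
                      _["q_path"] = wrap(bqp), _["t_path"] = wrap(btp));
}

// Score-only variant (no traceback bookkeeping) for bulk scanning.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                    double gapOpen, double gapExt) {
  const int n = q.size(), m = t.size();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, R_NegInf), Ecur(m + 1, R_NegInf);
  std::vector<double> Fcol(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double e = std::max(Hcur[j - 1] - gapOpen - gapExt, Ecur[j - 1] - gapExt);
      double f = std::max(Hprev[j] - gapOpen - gapExt, Fcol[j] - gapExt);
      double diag = Hprev[j - 1] + S(q[i - 1], t[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(e, f)));
      Ecur[j] = e; Fcol[j] = f; Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return best;
}
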