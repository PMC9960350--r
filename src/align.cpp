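#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length k
// costs gap_open + k * gap_ext, matching the BLAST convention for its
// open/extend parameters. Sequences arrive as 0-based integer codes indexing
// the substitution matrix. Traceback prefers diagonal, then gap-in-subject,
// then gap-in-query, which makes the reported alignment deterministic; among
// equal-scoring end cells the one with the smallest subject index, then the
// smallest query index, is chosen.
//
// Returns a list with the optimal score, 0-based half-open spans on query
// and subject, the two gapped alignment strings, column count and identity
// count. Score 0 (no positive-scoring cell) is reported with empty spans.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  double gap_open, double gap_ext,
                  std::string qchars, std::string schars) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e18;
  // H, E (gap in query, moving along subject), F (gap in subject)
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j) {        // subject outer: smallest subject end wins ties
    for (int i = 1; i <= n; ++i) {
      const int ij = at(i, j);
      double e = std::max(H[at(i, j - 1)] - (gap_open + gap_ext),
                          E[at(i, j - 1)] - gap_ext);
      double f = std::max(H[at(i - 1, j)] - (gap_open + gap_ext),
                          F[at(i - 1, j)] - gap_ext);
      double diag = H[at(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
      double h = diag;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      E[ij] = e;
      F[ij] = f;
      H[ij] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string qa, sa;
  int qs = 0, qe = 0, ss = 0, se = 0, ncol = 0, nid = 0;
  if (best > 0.0) {
    // traceback from (bi, bj); state 0 = H, 1 = E, 2 = F
    int i = bi, j = bj, state = 0;
    const double eps = 1e-9;
    while (true) {
      if (state == 0) {
        double h = H[at(i, j)];
        if (h < eps) break;  // local alignment starts here
        double diag = H[at(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
        if (std::abs(h - diag) < eps) {
          qa.push_back(qchars[i - 1]);
          sa.push_back(schars[j - 1]);
          if (qchars[i - 1] == schars[j - 1]) ++nid;
          --i; --j;
        } else if (std::abs(h - E[at(i, j)]) < eps) {
          state = 1;
        } else if (std::abs(h - F[at(i, j)]) < eps) {
          state = 2;
        } else {
          stop("traceback inconsistency");
        }
      } else if (state == 1) {
        // gap in query: consume subject char
        qa.push_back('-');
        sa.push_back(schars[j - 1]);
        double e = E[at(i, j)];
        --j;
        if (std::abs(e - (H[at(i, j)] - (gap_open + gap_ext))) < eps) state = 0;
        else state = 1;
      } else {
        qa.push_back(qchars[i - 1]);
        sa.push_back('-');
        double f = F[at(i, j)];
        --i;
        if (std::abs(f - (H[at(i, j)] - (gap_open + gap_ext))) < eps) state = 0;
        else state = 2;
      }
    }
    qs = i; qe = bi; ss = j; se = bj;
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    ncol = (int)qa.size();
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["q_aln"] = qa, _["s_aln"] = sa,
                      _["aligned_cols"] = ncol, _["n_ident"] = nid);
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                    double gap_open, double gap_ext) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG);
  double best = 0.0;
  for (int j = 1; j <= m; ++j) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int i = 1; i <= n; ++i) {
      double e = std::max(Hprev[i] - (gap_open + gap_ext), Eprev[i] - gap_ext);
      double f = std::max(Hcur[i - 1] - (gap_open + gap_ext), Fcur[i - 1] - gap_ext);
      double h = Hprev[i - 1] + mat(q[i - 1], s[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      Ecur[i] = e; Fcur[i] = f; Hcur[i] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return best;
}
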