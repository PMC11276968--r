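#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

//' Exhaustive glocal alignment score
//'
//' Full quadratic affine-gap dynamic program for glocal alignment:
//' global in the query, local in the target (leading/trailing target
//' bases free). A gap of length g costs gap_open + g * gap_ext, matching
//' the convention of Biostrings::pairwiseAlignment; 'N' never matches.
//' Serves as the independent scoring oracle for [align_glocal()]
//' (single strand; run on the reverse complement as well to cover both).
//'
//' @param query,subject sequences (character scalars).
//' @param match,mismatch,gap_open,gap_ext scoring scheme.
//' @return best alignment score (numeric).
//' @export
// [[Rcpp::export]]
double glocal_best_score_cpp(std::string query, std::string subject,
                             double match, double mismatch,
                             double gap_open, double gap_ext) {
  const int m = query.size(), n = subject.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  if (m == 0 || n == 0) return NEG;
  std::vector<double> Hprev(n + 1), H(n + 1), E(n + 1), Fcol(n + 1);
  for (int j = 0; j <= n; ++j) { Hprev[j] = 0.0; Fcol[j] = NEG; }
  double best = NEG;
  for (int i = 1; i <= m; ++i) {
    H[0] = -(gap_open + i * gap_ext);
    double Erow = NEG;
    for (int j = 1; j <= n; ++j) {
      char q = query[i - 1], t = subject[j - 1];
      bool is_match = (q == t) && q != 'N' && q != 'n';
      double diag = Hprev[j - 1] + (is_match ? match : mismatch);
      Erow = std::max(H[j - 1] - (gap_open + gap_ext), Erow - gap_ext);
      Fcol[j] = std::max(Hprev[j] - (gap_open + gap_ext), Fcol[j] - gap_ext);
      H[j] = std::max(diag, std::max(Erow, Fcol[j]));
    }
    std::swap(Hprev, H);
    (void)E;
  }
  for (int j = 0; j <= n; ++j) best = std::max(best, Hprev[j]);
  return best;
}
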