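// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh recursion.
// A gap of length L costs gapOpen + L * gapExt. Traceback tie-break is
// fixed: aligned pair > gap in `a` > gap in `b`, so results are
// deterministic. Identity is matches / aligned columns with columns inside
// terminal gap runs of either sequence excluded.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e30;

// [[Rcpp::export(name = ".nwAlignC")]]
List nwAlignC(std::string a, std::string b, NumericMatrix submat,
              double gapOpen, double gapExt) {
  const int n = a.size(), m = b.size();
  // submat is 27x27 indexed by letter - 'A' (X and any letter present)
  auto sc = [&](char ca, char cb) -> double {
    return submat(ca - 'A', cb - 'A');
  };
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      Ix(n + 1, std::vector<double>(m + 1, NEG)),
      Iy(n + 1, std::vector<double>(m + 1, NEG));
  // traceback: which state preceded (0=M,1=Ix,2=Iy, -1 none)
  std::vector<std::vector<signed char>> tM(n + 1, std::vector<signed char>(m + 1, -1)),
      tX(n + 1, std::vector<signed char>(m + 1, -1)),
      tY(n + 1, std::vector<signed char>(m + 1, -1));
  M[0][0] = 0;
  for (int j = 1; j <= m; ++j) {
    Ix[0][j] = -(gapOpen + gapExt * j);
    tX[0][j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Iy[i][0] = -(gapOpen + gapExt * i);
    tY[i][0] = (i == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: a[i-1] aligned to b[j-1]; tie-break order M > Ix > Iy
      double best = M[i - 1][j - 1]; signed char st = 0;
      if (Ix[i - 1][j - 1] > best) { best = Ix[i - 1][j - 1]; st = 1; }
      if (Iy[i - 1][j - 1] > best) { best = Iy[i - 1][j - 1]; st = 2; }
      if (best > NEG / 2) {
        M[i][j] = best + sc(a[i - 1], b[j - 1]);
        tM[i][j] = st;
      }
      // Ix: gap in a, consuming b[j-1]
      double open = std::max(M[i][j - 1], Iy[i][j - 1]) - (gapOpen + gapExt);
      double ext = Ix[i][j - 1] - gapExt;
      if (ext >= open && ext > NEG / 2) { Ix[i][j] = ext; tX[i][j] = 1; }
      else if (open > NEG / 2) {
        Ix[i][j] = open;
        tX[i][j] = (M[i][j - 1] >= Iy[i][j - 1]) ? 0 : 2;
      }
      // Iy: gap in b, consuming a[i-1]
      open = std::max(M[i - 1][j], Ix[i - 1][j]) - (gapOpen + gapExt);
      ext = Iy[i - 1][j] - gapExt;
      if (ext >= open && ext > NEG / 2) { Iy[i][j] = ext; tY[i][j] = 2; }
      else if (open > NEG / 2) {
        Iy[i][j] = open;
        tY[i][j] = (M[i - 1][j] >= Ix[i - 1][j]) ? 0 : 1;
      }
    }
  }
  double score = M[n][m]; int state = 0;
  if (Ix[n][m] > score) { score = Ix[n][m]; state = 1; }
  if (Iy[n][m] > score) { score = Iy[n][m]; state = 2; }
  // traceback
  std::string alnA, alnB;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = tM[i][j];
      alnA.push_back(a[i - 1]); alnB.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tX[i][j];
      alnA.push_back('-'); alnB.push_back(b[j - 1]);
      --j;
    } else {
      prev = tY[i][j];
      alnA.push_back(a[i - 1]); alnB.push_back('-');
      --i;
    }
    state = prev;
  }
  std::reverse(alnA.begin(), alnA.end());
  std::reverse(alnB.begin(), alnB.end());
  // identity over columns spanned by both sequences
  const int L = alnA.size();
  int firstA = -1, lastA = -1, firstB = -1, lastB = -1;
  for (int k = 0; k < L; ++k) {
    if (alnA[k] != '-') { if (firstA < 0) firstA = k; lastA = k; }
    if (alnB[k] != '-') { if (firstB < 0) firstB = k; lastB = k; }
  }
  int first = std::max(firstA, firstB), last = std::min(lastA, lastB);
  int matches = 0, cols = 0;
  for (int k = first; k <= last && first >= 0; ++k) {
    ++cols;
    if (alnA[k] == alnB[k] && alnA[k] != '-') ++matches;
  }
  double identity = (cols > 0) ? (double)matches / cols : 0.0;
  return List::create(_["score"] = score, _["identity"] = identity,
                      _["columns"] = cols, _["matches"] = matches,
                      _["alignedA"] = alnA, _["alignedB"] = alnB);
}
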