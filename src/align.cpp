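#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Glocal (fitting) affine-gap alignment of a full primer against a local
// template window, under the scoring scheme match = +1, mismatch = 0,
// gap open = -1, gap extend = -0.5. The primer may carry IUPAC ambiguity
// codes, which count as a match iff the template base is a concrete A/C/G/T
// inside the code's expansion set; ambiguity in the template scores as a
// mismatch. All scores are multiples of 0.5, so double comparisons are exact.
//
// States: M = primer base vs template base; X = primer base vs '-' in the
// template; Y = '-' in the primer vs template base. Leading and trailing
// template is free (local in the template), the primer is consumed in full.

static const double NEG = -1e18;

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': return 8;  case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

static inline bool is_concrete(int mask) {
  return mask == 1 || mask == 2 || mask == 4 || mask == 8;
}

// column classification codes shared with the R layer
enum ColCode { COL_MATCH = 0, COL_MISMATCH = 1, COL_GAP_PRIMER = 2,
               COL_GAP_TEMPLATE = 3 };

// [[Rcpp::export(name = ".align_primer_cpp")]]
List align_primer_cpp(std::string primer, std::string tmpl) {
  const int m = (int) primer.size();
  const int n = (int) tmpl.size();
  if (m < 1) stop("empty primer");
  if (n < 1) stop("empty template");

  std::vector<int> pmask(m), tmask(n);
  for (int i = 0; i < m; ++i) pmask[i] = iupac_mask(primer[i]);
  for (int j = 0; j < n; ++j) tmask[j] = iupac_mask(tmpl[j]);

  // (m+1) x (n+1) matrices, row-major
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
                      Y((m + 1) * W, NEG);
  for (int j = 0; j <= n; ++j) M[j] = 0.0;  // free leading template

  for (int i = 1; i <= m; ++i) {
    // j = 0 column: primer prefix against template gaps only
    X[i * W] = std::max(M[(i - 1) * W] - 1.0, X[(i - 1) * W] - 0.5);
    for (int j = 1; j <= n; ++j) {
      const int a = (i - 1) * W + (j - 1), b = (i - 1) * W + j,
                c = i * W + (j - 1), cur = i * W + j;
      bool hit = is_concrete(tmask[j - 1]) && (pmask[i - 1] & tmask[j - 1]);
      double s = hit ? 1.0 : 0.0;
      M[cur] = std::max(M[a], std::max(X[a], Y[a])) + s;
      X[cur] = std::max(M[b] - 1.0, std::max(X[b] - 0.5, Y[b] - 1.0));
      Y[cur] = std::max(M[c] - 1.0, std::max(Y[c] - 0.5, X[c] - 1.0));
    }
  }

  // best score over all end columns, states M and X (an alignment ending in
  // Y trails free template and is always dominated)
  double best = NEG;
  for (int j = 0; j <= n; ++j) {
    best = std::max(best, std::max(M[m * W + j], X[m * W + j]));
  }

  // deterministic traceback for one candidate end; returns start column and
  // fills column codes (primer 5'->3')
  auto traceback = [&](int endj, int endstate, std::vector<int>& cols) -> int {
    cols.clear();
    int i = m, j = endj, st = endstate;  // 0 = M, 1 = X, 2 = Y
    while (i > 0) {
      if (st == 0) {
        bool hit = is_concrete(tmask[j - 1]) && (pmask[i - 1] & tmask[j - 1]);
        double s = hit ? 1.0 : 0.0;
        cols.push_back(hit ? COL_MATCH : COL_MISMATCH);
        const int a = (i - 1) * W + (j - 1);
        double need = M[i * W + j] - s;
        if (M[a] == need) st = 0;
        else if (X[a] == need) st = 1;
        else st = 2;
        --i; --j;
      } else if (st == 1) {
        cols.push_back(COL_GAP_TEMPLATE);
        const int b = (i - 1) * W + j;
        double v = X[i * W + j];
        if (M[b] - 1.0 == v) st = 0;
        else if (X[b] - 0.5 == v) st = 1;
        else st = 2;
        --i;
      } else {
        cols.push_back(COL_GAP_PRIMER);
        const int c = i * W + (j - 1);
        double v = Y[i * W + j];
        if (M[c] - 1.0 == v) st = 0;
        else if (Y[c] - 0.5 == v) st = 2;
        else st = 1;
        --j;
      }
    }
    std::reverse(cols.begin(), cols.end());
    return j;
  };

  // tie-break among maximal hits: smallest start, then shortest span,
  // then smallest end; at one end column prefer M over X
  int bestStart = -1, bestEnd = -1;
  std::vector<int> bestCols, cols;
  for (int j = 0; j <= n; ++j) {
    for (int st = 0; st <= 1; ++st) {
      double v = (st == 0) ? M[m * W + j] : X[m * W + j];
      if (v != best) continue;
      int start = traceback(j, st, cols);
      int span = j - start;
      bool better = (bestStart < 0) || (start < bestStart) ||
        (start == bestStart && (span < bestEnd - bestStart ||
         (span == bestEnd - bestStart && j < bestEnd)));
      if (better) { bestStart = start; bestEnd = j; bestCols = cols; }
    }
  }

  return List::create(
    _["score"] = best,
    _["start"] = bestStart,
    _["end"] = bestEnd,
    _["col_codes"] = IntegerVector(bestCols.begin(), bestCols.end()));
}
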