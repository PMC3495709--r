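// Viterbi dynamic programming for the alignment of two sequence graphs.
//
// Cells are node pairs in topological-position space (start = 0, end = n-1).
// Four score layers: M (match), X (gap in A, consuming B nodes), Y (gap in
// B), H (silent running maximum).  The match layer maximizes over all pairs
// of predecessors of both nodes; gap layers over one graph's predecessors.
// Edge reuse penalties are added on every traversed edge.  Tie-breaking is
// deterministic: M over X over Y, and the smallest predecessor pair in
// topological index order (predecessor slots arrive sorted).

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_graphs_cpp(int nA, int nB,
                      IntegerVector ptrA, IntegerVector predA, NumericVector penA,
                      IntegerVector ptrB, IntegerVector predB, NumericVector penB,
                      NumericMatrix S,
                      double match_init, double gap_init, double gap_ext,
                      double log_omega, double log_alpha,
                      LogicalVector pre_end_a, LogicalVector pre_end_b) {
  if ((double)nA * (double)nB > 4e6)
    stop("graphs too large for the alignment DP");

  NumericMatrix M(nA, nB), X(nA, nB), Y(nA, nB), H(nA, nB);
  IntegerMatrix Hlayer(nA, nB);
  IntegerMatrix bpM_pa(nA, nB), bpM_pb(nA, nB), bpM_sa(nA, nB), bpM_sb(nA, nB);
  IntegerMatrix bpX_pb(nA, nB), bpX_sb(nA, nB), bpX_from(nA, nB);
  IntegerMatrix bpY_pa(nA, nB), bpY_sa(nA, nB), bpY_from(nA, nB);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(X.begin(), X.end(), NEG_INF);
  std::fill(Y.begin(), Y.end(), NEG_INF);
  std::fill(H.begin(), H.end(), NEG_INF);

  H(0, 0) = 0.0;
  M(0, 0) = 0.0;
  Hlayer(0, 0) = 1;

  for (int i = 0; i < nA; ++i) {
    bool a_end = (i == nA - 1);
    for (int j = 0; j < nB; ++j) {
      if (i == 0 && j == 0) continue;
      bool b_end = (j == nB - 1);
      if (a_end != b_end) continue;   // cells with exactly one end sentinel
      if (a_end && b_end) {           // final cell: match the end sentinels
        double best = NEG_INF;
        int ba = 0, bb = 0, bsa = 0, bsb = 0;
        for (int sa = ptrA[i]; sa < ptrA[i + 1]; ++sa) {
          int pa = predA[sa];
          for (int sb = ptrB[j]; sb < ptrB[j + 1]; ++sb) {
            int pb = predB[sb];
            double v = H(pa, pb) + log_omega + penA[sa] + penB[sb];
            if (v > best) { best = v; ba = pa; bb = pb; bsa = sa + 1; bsb = sb + 1; }
          }
        }
        M(i, j) = H(i, j) = best;
        Hlayer(i, j) = 1;
        bpM_pa(i, j) = ba; bpM_pb(i, j) = bb;
        bpM_sa(i, j) = bsa; bpM_sb(i, j) = bsb;
        continue;
      }

      double m = NEG_INF;
      int m_pa = 0, m_pb = 0, m_sa = 0, m_sb = 0;
      if (i > 0 && j > 0) {
        double sij = match_init + S(i, j);
        for (int sa = ptrA[i]; sa < ptrA[i + 1]; ++sa) {
          int pa = predA[sa];
          for (int sb = ptrB[j]; sb < ptrB[j + 1]; ++sb) {
            int pb = predB[sb];
            double v = H(pa, pb) + sij + penA[sa] + penB[sb];
            if (v > m) { m = v; m_pa = pa; m_pb = pb; m_sa = sa + 1; m_sb = sb + 1; }
          }
        }
      }

      double x = NEG_INF;
      int x_pb = 0, x_sb = 0, x_from = 0;
      if (j > 0) {
        double open = (i == 0 || pre_end_a[i]) ? log_alpha : gap_init;
        for (int sb = ptrB[j]; sb < ptrB[j + 1]; ++sb) {
          int pb = predB[sb];
          double v1 = H(i, pb) + open + penB[sb];
          double v2 = X(i, pb) + gap_ext + penB[sb];
          double cand; int from;
          if (v1 >= v2) { cand = v1; from = 0; } else { cand = v2; from = 1; }
          if (cand > x) { x = cand; x_pb = pb; x_sb = sb + 1; x_from = from; }
        }
      }

      double y = NEG_INF;
      int y_pa = 0, y_sa = 0, y_from = 0;
      if (i > 0) {
        double open = (j == 0 || pre_end_b[j]) ? log_alpha : gap_init;
        for (int sa = ptrA[i]; sa < ptrA[i + 1]; ++sa) {
          int pa = predA[sa];
          double v1 = H(pa, j) + open + penA[sa];
          double v2 = Y(pa, j) + gap_ext + penA[sa];
          double cand; int from;
          if (v1 >= v2) { cand = v1; from = 0; } else { cand = v2; from = 1; }
          if (cand > y) { y = cand; y_pa = pa; y_sa = sa + 1; y_from = from; }
        }
      }

      M(i, j) = m; X(i, j) = x; Y(i, j) = y;
      bpM_pa(i, j) = m_pa; bpM_pb(i, j) = m_pb;
      bpM_sa(i, j) = m_sa; bpM_sb(i, j) = m_sb;
      bpX_pb(i, j) = x_pb; bpX_sb(i, j) = x_sb; bpX_from(i, j) = x_from;
      bpY_pa(i, j) = y_pa; bpY_sa(i, j) = y_sa; bpY_from(i, j) = y_from;

      double h = m; int hl = 1;
      if (x > h) { h = x; hl = 2; }
      if (y > h) { h = y; hl = 3; }
      H(i, j) = h; Hlayer(i, j) = hl;
    }
  }

  double score = M(nA - 1, nB - 1);
  if (!R_finite(score)) stop("end pair unreachable: graph invariant violated");

  // backtrack
  std::vector<int> type, ai, bi, ea, eb;
  int i = nA - 1, j = nB - 1;
  type.push_back(4); ai.push_back(i); bi.push_back(j);
  ea.push_back(bpM_sa(i, j)); eb.push_back(bpM_sb(i, j));
  {
    int ni = bpM_pa(i, j), nj = bpM_pb(i, j);
    i = ni; j = nj;
  }
  int layer = Hlayer(i, j);
  while (!(i == 0 && j == 0)) {
    if (layer == 1) {
      type.push_back(1); ai.push_back(i); bi.push_back(j);
      ea.push_back(bpM_sa(i, j)); eb.push_back(bpM_sb(i, j));
      int ni = bpM_pa(i, j), nj = bpM_pb(i, j);
      i = ni; j = nj;
      layer = Hlayer(i, j);
    } else if (layer == 2) {
      type.push_back(2); ai.push_back(-1); bi.push_back(j);
      ea.push_back(0); eb.push_back(bpX_sb(i, j));
      int from = bpX_from(i, j);
      int nj = bpX_pb(i, j);
      j = nj;
      layer = (from == 0) ? Hlayer(i, j) : 2;
    } else if (layer == 3) {
      type.push_back(3); ai.push_back(i); bi.push_back(-1);
      ea.push_back(bpY_sa(i, j)); eb.push_back(0);
      int from = bpY_from(i, j);
      int ni = bpY_pa(i, j);
      i = ni;
      layer = (from == 0) ? Hlayer(i, j) : 3;
    } else {
      stop("backtrack reached an invalid layer");
    }
  }
  type.push_back(0); ai.push_back(0); bi.push_back(0);
  ea.push_back(0); eb.push_back(0);

  std::reverse(type.begin(), type.end());
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  std::reverse(ea.begin(), ea.end());
  std::reverse(eb.begin(), eb.end());

  return List::create(_["score"] = score,
                      _["type"] = wrap(type), _["ai"] = wrap(ai),
                      _["bi"] = wrap(bi), _["ea"] = wrap(ea),
                      _["eb"] = wrap(eb));
}
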