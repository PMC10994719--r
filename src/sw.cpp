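#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh affine-gap Smith-Waterman over plain character scoring
// (match/mismatch), with deterministic traceback.
//
// Gap cost model: a gap of length k costs gap_open + k * gap_extend
// (gap_open is paid once on opening, gap_extend for every gapped column).
//
// Tie-breaking:
//  * end cell: highest score, then smallest (target_end, query_end);
//  * traceback at an H cell: diagonal, then vertical (consume query),
//    then horizontal (consume target);
//  * within a gap run: prefer closing the gap (re-entering H) over
//    extending it.

struct TBResult {
  int qs, qe, ts, te;
  std::vector<int> qpos, tpos; // aligned (match/mismatch) columns, 1-based
  int n_ident;
};

static TBResult traceback(const std::string &q, const std::string &t,
                          const std::vector<double> &H,
                          const std::vector<double> &E,
                          const std::vector<double> &F,
                          int n, int m, double match, double mismatch,
                          double go, double ge, int ei, int ej) {
  const int W = m + 1;
  int i = ei, j = ej;
  char state = 'H';
  TBResult r;
  r.qe = ei; r.te = ej; r.n_ident = 0;
  while (true) {
    if (state == 'H') {
      double h = H[i * W + j];
      if (h <= 0.0) break;
      double sub = (q[i - 1] == t[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && H[(i - 1) * W + (j - 1)] + sub == h) {
        r.qpos.push_back(i); r.tpos.push_back(j);
        if (q[i - 1] == t[j - 1]) r.n_ident++;
        i--; j--;
      } else if (F[i * W + j] == h) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') { // vertical: gap in target, consume query
      double f = F[i * W + j];
      if (H[(i - 1) * W + j] + go + ge == f) { i--; state = 'H'; }
      else { i--; /* stay in F */ }
    } else { // 'E', horizontal: gap in query, consume target
      double e = E[i * W + j];
      if (H[i * W + (j - 1)] + go + ge == e) { j--; state = 'H'; }
      else { j--; }
    }
  }
  r.qs = i + 1; r.ts = j + 1;
  std::reverse(r.qpos.begin(), r.qpos.end());
  std::reverse(r.tpos.begin(), r.tpos.end());
  return r;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool all_placements) {
  const int n = (int) query.size(), m = (int) target.size();
  const int W = m + 1;
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[i * W + (j - 1)] + gap_open + gap_extend,
                          E[i * W + (j - 1)] + gap_extend);
      double f = std::max(H[(i - 1) * W + j] + gap_open + gap_extend,
                          F[(i - 1) * W + j] + gap_extend);
      double sub = (query[i - 1] == target[j - 1]) ? match : mismatch;
      double h = H[(i - 1) * W + (j - 1)] + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      E[i * W + j] = e; F[i * W + j] = f; H[i * W + j] = h;
    }
  }
  // best cell: max score, then smallest (j, i)
  for (int j = 1; j <= m; ++j)
    for (int i = 1; i <= n; ++i)
      if (H[i * W + j] > best) { best = H[i * W + j]; bi = i; bj = j; }

  List out;
  out["score"] = best;
  if (best <= 0.0) {
    out["qs"] = NA_INTEGER; out["qe"] = NA_INTEGER;
    out["ts"] = NA_INTEGER; out["te"] = NA_INTEGER;
    out["n_ident"] = 0;
    out["pairs"] = IntegerMatrix(0, 2);
    if (all_placements) out["placements"] = List(0);
    return out;
  }
  TBResult r = traceback(query, target, H, E, F, n, m,
                         match, mismatch, gap_open, gap_extend, bi, bj);
  out["qs"] = r.qs; out["qe"] = r.qe; out["ts"] = r.ts; out["te"] = r.te;
  out["n_ident"] = r.n_ident;
  IntegerMatrix pr((int) r.qpos.size(), 2);
  for (int k = 0; k < (int) r.qpos.size(); ++k) {
    pr(k, 0) = r.qpos[k]; pr(k, 1) = r.tpos[k];
  }
  out["pairs"] = pr;
  if (all_placements) {
    List pls;
    for (int j = 1; j <= m; ++j) {
      for (int i = 1; i <= n; ++i) {
        if (H[i * W + j] == best) {
          TBResult a = traceback(query, target, H, E, F, n, m,
                                 match, mismatch, gap_open, gap_extend, i, j);
          IntegerMatrix ap((int) a.qpos.size(), 2);
          for (int k = 0; k < (int) a.qpos.size(); ++k) {
            ap(k, 0) = a.qpos[k]; ap(k, 1) = a.tpos[k];
          }
          pls.push_back(List::create(
            _["qs"] = a.qs, _["qe"] = a.qe, _["ts"] = a.ts, _["te"] = a.te,
            _["n_ident"] = a.n_ident, _["pairs"] = ap));
        }
      }
    }
    out["placements"] = pls;
  }
  return out;
}
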