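#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pairwise alignment cores for SL detection and hairpin calling.
//
// Conventions shared by all routines:
//  * scores are additive; match > 0 > mismatch, gaps <= mismatch
//  * a gap run of length k costs gap_open + (k - 1) * gap_extend
//    (both are negative numbers; with the default -2/-2 every gapped
//    base costs 2)
//  * coordinates returned to R are 1-based

static const double NEG = -1e18;

struct SgResult {
  double score;
  int target_end; // 1-based target coordinate of the query's 3' end
};

// Semi-global alignment: the query is aligned end-to-end, target flanks
// are free (no penalty for unaligned target prefix/suffix). Ties on the
// score are broken toward the smallest target_end.
static SgResult semiglobal_core(const std::string &q, const std::string &t,
                                double match, double mismatch,
                                double gap_open, double gap_extend) {
  const int m = (int)q.size(), n = (int)t.size();
  // three states per cell: M last column is an aligned pair,
  // X last column is query-char-vs-gap, Y last column is target-char-vs-gap
  std::vector<double> Mp(n + 1, NEG), Xp(n + 1, NEG), Yp(n + 1, NEG);
  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);

  double best = NEG;
  int best_end = 0;

  for (int i = 1; i <= m; ++i) {
    Mc.assign(n + 1, NEG);
    Xc.assign(n + 1, NEG);
    Yc.assign(n + 1, NEG);

    // j = 0: only a leading query-gap chain is possible
    {
      double open_from = (i == 1) ? 0.0 : NEG; // start state lives at i-1 == 0
      double x = std::max(open_from + gap_open,
                          (Xp[0] > NEG / 2) ? Xp[0] + gap_extend : NEG);
      Xc[0] = x;
    }

    for (int j = 1; j <= n; ++j) {
      // value of the best state at (i-1, j-1); the free-prefix start state
      // contributes 0 when no query has been consumed yet
      double diag = std::max(std::max(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
      if (i == 1) diag = std::max(diag, 0.0);
      if (diag > NEG / 2)
        Mc[j] = diag + ((q[i - 1] == t[j - 1]) ? match : mismatch);

      double up = std::max(Mp[j], Yp[j]);
      if (i == 1) up = std::max(up, 0.0);
      double x1 = (up > NEG / 2) ? up + gap_open : NEG;
      double x2 = (Xp[j] > NEG / 2) ? Xp[j] + gap_extend : NEG;
      Xc[j] = std::max(x1, x2);

      double left = std::max(Mc[j - 1], Xc[j - 1]);
      double y1 = (left > NEG / 2) ? left + gap_open : NEG;
      double y2 = (Yc[j - 1] > NEG / 2) ? Yc[j - 1] + gap_extend : NEG;
      Yc[j] = std::max(y1, y2);
    }

    if (i == m) {
      for (int j = 0; j <= n; ++j) {
        // trailing target-gap (Y) columns are dominated by the free suffix,
        // so the alignment end is taken from M/X states only
        double v = std::max(Mc[j], Xc[j]);
        if (v > best + 1e-9) { best = v; best_end = j; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  SgResult r; r.score = best; r.target_end = best_end;
  return r;
}

// fast path for linear gaps (gap_open == gap_extend): single-matrix DP.
// Returns the best score for the full query and, through row_max, the
// optimal score for every query prefix length (used to score all SL
// truncations of a reversed query in one pass).
static SgResult semiglobal_linear(const std::string &q, const std::string &t,
                                  double match, double mismatch, double gap,
                                  std::vector<double> *row_max = 0) {
  const int m = (int)q.size(), n = (int)t.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0.0;
  if (row_max) row_max->assign(m + 1, NEG);
  double best = NEG; int best_end = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    const char qc = q[i - 1];
    double rbest = cur[0]; // j = 0 allowed (query aligned to nothing)
    for (int j = 1; j <= n; ++j) {
      double v = prev[j - 1] + ((qc == t[j - 1]) ? match : mismatch);
      double up = prev[j] + gap;
      if (up > v) v = up;
      double left = cur[j - 1] + gap;
      if (left > v) v = left;
      cur[j] = v;
      if (v > rbest) rbest = v;
    }
    if (row_max) (*row_max)[i] = rbest;
    if (i == m) {
      for (int j = 0; j <= n; ++j)
        if (cur[j] > best + 1e-9) { best = cur[j]; best_end = j; }
    }
    std::swap(prev, cur);
  }
  SgResult r; r.score = best; r.target_end = best_end;
  return r;
}

static SgResult semiglobal_dispatch(const std::string &q, const std::string &t,
                                    double match, double mismatch,
                                    double gap_open, double gap_extend) {
  if (gap_open == gap_extend)
    return semiglobal_linear(q, t, match, mismatch, gap_open);
  return semiglobal_core(q, t, match, mismatch, gap_open, gap_extend);
}

//' Semi-global alignment score (query global, target ends free)
//'
//' @param query,target DNA strings (case sensitive, compared as characters).
//' @param match,mismatch,gap_open,gap_extend scoring parameters; gaps cost
//'   `gap_open` for the first base of a run and `gap_extend` thereafter.
//' @return list with `score` and `target_end` (1-based target coordinate of
//'   the query's 3' end; smallest coordinate on ties).
//' @keywords internal
// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string query, std::string target,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  if (query.empty()) stop("empty query");
  if (target.empty()) stop("empty target");
  SgResult r = semiglobal_dispatch(query, target, match, mismatch,
                                   gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["target_end"] = r.target_end);
}

// lexicographic (score, matches) pair used by the local aligner so that
// the reported identity-column count is well defined among co-optimal
// alignments (the maximum)
struct PV {
  double s;
  int m;
  int ts; // 1-based target start of the local path (0 = empty)
  int qs; // 1-based query start
};

static inline bool pv_less(const PV &a, const PV &b) {
  if (a.s != b.s) return a.s < b.s;
  return a.m < b.m;
}

static inline PV pv_max(const PV &a, const PV &b) {
  return pv_less(a, b) ? b : a;
}

//' Local (Smith-Waterman) alignment with identity-column count
//'
//' Among all score-optimal local alignments the one with the largest
//' number of identity columns is reported, making `matches` deterministic.
//'
//' @inheritParams semiglobal_align_cpp
//' @return list with `score`, `matches` (identity columns), and the
//'   1-based target/query spans of the reported alignment (0s when the
//'   best local alignment is empty).
//' @keywords internal
// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string query, std::string target,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int m = (int)query.size(), n = (int)target.size();
  PV zero; zero.s = 0.0; zero.m = 0; zero.ts = 0; zero.qs = 0;
  PV neg; neg.s = NEG; neg.m = 0; neg.ts = 0; neg.qs = 0;

  std::vector<PV> Mp(n + 1, neg), Xp(n + 1, neg), Yp(n + 1, neg);
  std::vector<PV> Mc(n + 1), Xc(n + 1), Yc(n + 1);

  PV best = zero;
  int best_te = 0, best_qe = 0;

  for (int i = 1; i <= m; ++i) {
    Mc.assign(n + 1, neg); Xc.assign(n + 1, neg); Yc.assign(n + 1, neg);
    for (int j = 1; j <= n; ++j) {
      // M: restart allowed (fresh local alignment starting at this column)
      PV diag = pv_max(pv_max(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
      PV restart = zero; restart.ts = j; restart.qs = i;
      if (pv_less(diag, zero)) diag = restart;
      else if (diag.ts == 0) { diag.ts = j; diag.qs = i; }
      bool is_match = (query[i - 1] == target[j - 1]);
      PV mcell = diag;
      mcell.s += is_match ? match : mismatch;
      mcell.m += is_match ? 1 : 0;
      Mc[j] = mcell;

      PV up = pv_max(Mp[j], Yp[j]);
      PV x1 = up; x1.s += gap_open;
      PV x2 = Xp[j]; x2.s += gap_extend;
      Xc[j] = pv_max(x1, x2);
      if (Xc[j].s < NEG / 2) Xc[j] = neg;

      PV left = pv_max(Mc[j - 1], Xc[j - 1]);
      PV y1 = left; y1.s += gap_open;
      PV y2 = Yc[j - 1]; y2.s += gap_extend;
      Yc[j] = pv_max(y1, y2);
      if (Yc[j].s < NEG / 2) Yc[j] = neg;

      // local alignments never end in a gap column (trimming it scores higher)
      if (pv_less(best, Mc[j])) { best = Mc[j]; best_te = j; best_qe = i; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  return List::create(_["score"] = best.s, _["matches"] = best.m,
                      _["target_start"] = best.ts, _["target_end"] = best_te,
                      _["query_start"] = best.qs, _["query_end"] = best_qe);
}

//' Scan one upstream window against an SL repertoire with 5' trimming
//'
//' For each SL the full-length sequence is aligned semi-globally to the
//' window; if the score reaches the per-length threshold the SL is
//' detected, otherwise 2 nt are trimmed from the SL 5' end and the scan
//' repeats down to the minimum length. `first_stop = TRUE` stops at the
//' first passing truncation; otherwise all truncations are evaluated and
//' the best passing one kept.
//'
//' @param window upstream window (reference orientation).
//' @param sls character vector of full SL sequences.
//' @param lens_list,thr_list per-SL integer truncation lengths and the
//'   matching numeric thresholds.
//' @return data.frame with one row per SL: detected, score, matched_len,
//'   target_end.
//' @keywords internal
// [[Rcpp::export(name = ".scan_repertoire_cpp")]]
DataFrame scan_repertoire_cpp(std::string window, CharacterVector sls,
                              List lens_list, List thr_list,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              bool first_stop) {
  int ns = sls.size();
  LogicalVector detected(ns);
  NumericVector score(ns);
  IntegerVector matched_len(ns), target_end(ns);

  const bool linear = (gap_open == gap_extend);
  std::string wrev(window.rbegin(), window.rend());

  for (int s = 0; s < ns; ++s) {
    std::string full = as<std::string>(sls[s]);
    IntegerVector lens = lens_list[s];
    NumericVector thr = thr_list[s];
    bool det = false;
    double bs = NEG; int bl = 0, be = 0;

    // with linear gaps, one DP over the reversed SL scores every
    // truncation at once: a 5'-truncated SL is a suffix of the SL,
    // i.e. a prefix of the reversed SL, and the semi-global score is
    // orientation invariant
    std::vector<double> rowmax;
    if (linear) {
      std::string qrev(full.rbegin(), full.rend());
      semiglobal_linear(qrev, wrev, match, mismatch, gap_open, &rowmax);
    }

    for (int k = 0; k < lens.size(); ++k) {
      int len = lens[k];
      if (linear && rowmax[len] < thr[k]) continue;
      std::string sub = full.substr(full.size() - len);
      SgResult r = semiglobal_dispatch(sub, window, match, mismatch,
                                       gap_open, gap_extend);
      if (r.score >= thr[k]) {
        bool better = !det || r.score > bs ||
          (r.score == bs && (len > bl || (len == bl && r.target_end < be)));
        if (better) { bs = r.score; bl = len; be = r.target_end; }
        det = true;
        if (first_stop) break;
      }
    }
    detected[s] = det;
    score[s] = det ? bs : NA_REAL;
    matched_len[s] = det ? bl : NA_INTEGER;
    target_end[s] = det ? be : NA_INTEGER;
  }
  return DataFrame::create(_["detected"] = detected, _["score"] = score,
                           _["matched_len"] = matched_len,
                           _["target_end"] = target_end,
                           _["stringsAsFactors"] = false);
}
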