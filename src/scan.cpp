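#include <Rcpp.h>
using namespace Rcpp;

// Penalty weights for the primer-alignment scoring scheme.
// Mismatch classes: 0 = non-3' (0.40), 1 = 3' window, not final base (1.00),
// 2 = final 3' base (3.00). Gap classes: 0 = non-3' (1.00), 1 = 3' (3.00).
static const double MM_PEN[3]  = {0.40, 1.00, 3.00};
static const double GAP_PEN[2] = {1.00, 3.00};

struct Breakdown {
  int mm_non3, mm_3p, mm_last, gap_non3, gap_3p;
  Breakdown() : mm_non3(0), mm_3p(0), mm_last(0), gap_non3(0), gap_3p(0) {}
};

static inline bool mismatch(int p, int t) { return (p & t) == 0; }

// Score all <=1-gap alignments of pattern against one window and return the
// minimum weighted penalty.  Window length must be L-1, L or L+1.
//   pat, win: IUPAC bitmasks (target N encoded as 0 so it never matches)
//   cls_mm[j]:  mismatch class of pattern position j (0-based)
//   cls_del[j]: gap class when pattern position j aligns to a gap (win = L-1)
//   cls_ins[g]: gap class for a target base inserted between pattern
//               positions g-1 and g, g = 1..L-1 (win = L+1)
static double score_window(const int* pat, int L, const int* win, int m,
                           const int* cls_mm, const int* cls_del,
                           const int* cls_ins, Breakdown* bd) {
  double best = R_PosInf;
  Breakdown best_bd;
  if (m == L) {
    double s = 0.0;
    Breakdown b;
    for (int j = 0; j < L; ++j) {
      if (mismatch(pat[j], win[j])) {
        s += MM_PEN[cls_mm[j]];
        if (cls_mm[j] == 0) b.mm_non3++;
        else if (cls_mm[j] == 1) b.mm_3p++;
        else b.mm_last++;
      }
    }
    best = s; best_bd = b;
  } else if (m == L - 1) {
    // one pattern base aligned to a gap (deletion in the target)
    for (int g = 0; g < L; ++g) {
      double s = GAP_PEN[cls_del[g]];
      Breakdown b;
      if (cls_del[g] == 0) b.gap_non3++; else b.gap_3p++;
      for (int j = 0; j < L; ++j) {
        if (j == g) continue;
        int wj = (j < g) ? j : j - 1;
        if (mismatch(pat[j], win[wj])) {
          s += MM_PEN[cls_mm[j]];
          if (cls_mm[j] == 0) b.mm_non3++;
          else if (cls_mm[j] == 1) b.mm_3p++;
          else b.mm_last++;
        }
      }
      if (s < best) { best = s; best_bd = b; }
    }
  } else if (m == L + 1) {
    // one target base aligned to a gap in the pattern (insertion), internal only
    for (int g = 1; g < L; ++g) {
      double s = GAP_PEN[cls_ins[g - 1]];
      Breakdown b;
      if (cls_ins[g - 1] == 0) b.gap_non3++; else b.gap_3p++;
      for (int j = 0; j < L; ++j) {
        int wj = (j < g) ? j : j + 1;
        if (mismatch(pat[j], win[wj])) {
          s += MM_PEN[cls_mm[j]];
          if (cls_mm[j] == 0) b.mm_non3++;
          else if (cls_mm[j] == 1) b.mm_3p++;
          else b.mm_last++;
        }
      }
      if (s < best) { best = s; best_bd = b; }
    }
  }
  if (bd) *bd = best_bd;
  return best;
}

// [[Rcpp::export]]
List cpp_score_window(IntegerVector pat, IntegerVector win,
                      IntegerVector cls_mm, IntegerVector cls_del,
                      IntegerVector cls_ins) {
  int L = pat.size(), m = win.size();
  if (m < L - 1 || m > L + 1)
    stop("window length must be within one base of the pattern length");
  Breakdown bd;
  double s = score_window(pat.begin(), L, win.begin(), m,
                          cls_mm.begin(), cls_del.begin(), cls_ins.begin(), &bd);
  return List::create(
    _["score"] = s,
    _["mm_non3"] = bd.mm_non3, _["mm_3p"] = bd.mm_3p, _["mm_last"] = bd.mm_last,
    _["gap_non3"] = bd.gap_non3, _["gap_3p"] = bd.gap_3p);
}

// Scan every start offset and window length (L-1, L, L+1) on the target,
// return the best (lowest-score) site with score <= max_score.
// Tie-break on equal score: prefer_right = false keeps the leftmost start,
// prefer_right = true keeps the rightmost.
// [[Rcpp::export]]
List cpp_scan_best(IntegerVector pat, IntegerVector tgt,
                   IntegerVector cls_mm, IntegerVector cls_del,
                   IntegerVector cls_ins, double max_score, bool prefer_right) {
  int L = pat.size(), n = tgt.size();
  double best = R_PosInf;
  int best_start = -1, best_m = -1;
  Breakdown best_bd;
  const double eps = 1e-9;
  int mlens[3] = {L, L - 1, L + 1};
  for (int s = 0; s < n; ++s) {
    for (int k = 0; k < 3; ++k) {
      int m = mlens[k];
      if (m < 1 || s + m > n) continue;
      Breakdown bd;
      double sc = score_window(pat.begin(), L, tgt.begin() + s, m,
                               cls_mm.begin(), cls_del.begin(),
                               cls_ins.begin(), &bd);
      if (sc > max_score + eps) continue;
      bool better = sc < best - eps;
      bool tie = !better && sc < best + eps && prefer_right && s > best_start;
      if (better || tie) {
        best = sc; best_start = s; best_m = m; best_bd = bd;
      }
    }
  }
  if (best_start < 0) return List::create(_["found"] = false);
  return List::create(
    _["found"] = true, _["score"] = best,
    _["start"] = best_start, _["end"] = best_start + best_m,
    _["mm_non3"] = best_bd.mm_non3, _["mm_3p"] = best_bd.mm_3p,
    _["mm_last"] = best_bd.mm_last, _["gap_non3"] = best_bd.gap_non3,
    _["gap_3p"] = best_bd.gap_3p);
}

// Draw the 1-based offset (in bonds) to the next broken bond: geometric with
// success probability lambda.  Uses R's RNG stream.
static inline double next_break_gap(double log1m_lambda) {
  double u = unif_rand();
  if (u <= 0.0) return R_PosInf;
  return 1.0 + std::floor(std::log(u) / log1m_lambda);
}

// Fragment every template copy by independent per-bond scission at rate
// lambda; return fragments of length >= min_len as (record index, start, end)
// with 0-based half-open coordinates on the template.
//   counts[i]: number of template copies of record i
// [[Rcpp::export]]
List cpp_fragment_templates(IntegerVector counts, int template_len,
                            double lambda, int min_len) {
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)");
  std::vector<int> rec, start, end;
  double l1m = (lambda > 0) ? std::log1p(-lambda) : 0.0;
  int n_bonds = template_len - 1;
  for (int i = 0; i < counts.size(); ++i) {
    for (int c = 0; c < counts[i]; ++c) {
      int cur = 0;  // fragment start (base index)
      if (lambda > 0) {
        double bond = -1;  // index of last broken bond
        for (;;) {
          bond += next_break_gap(l1m);
          if (bond >= n_bonds || !R_finite(bond)) break;
          int e = (int)bond + 1;  // fragment = [cur, e)
          if (e - cur >= min_len) {
            rec.push_back(i + 1); start.push_back(cur); end.push_back(e);
          }
          cur = e;
        }
      }
      if (template_len - cur >= min_len) {
        rec.push_back(i + 1); start.push_back(cur); end.push_back(template_len);
      }
    }
  }
  return List::create(_["record"] = wrap(rec), _["start"] = wrap(start),
                      _["end"] = wrap(end));
}

// Streaming variant for large pools: identical per-bond scission model, but
// only per-record tallies are returned — the number of fragments kept after
// the min_len filter and the number fully containing the record's amplicon
// interval [amp_start, amp_end) (0-based half-open; -1,-1 if none).
// [[Rcpp::export]]
List cpp_fragment_counts(IntegerVector counts, int template_len,
                         double lambda, int min_len,
                         IntegerVector amp_start, IntegerVector amp_end) {
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)");
  int nr = counts.size();
  IntegerVector kept(nr), amplifiable(nr);
  double l1m = (lambda > 0) ? std::log1p(-lambda) : 0.0;
  int n_bonds = template_len - 1;
  for (int i = 0; i < nr; ++i) {
    int a0 = amp_start[i], a1 = amp_end[i];
    long kept_i = 0, amp_i = 0;
    for (int c = 0; c < counts[i]; ++c) {
      int cur = 0;
      if (lambda > 0) {
        double bond = -1;
        for (;;) {
          bond += next_break_gap(l1m);
          if (bond >= n_bonds || !R_finite(bond)) break;
          int e = (int)bond + 1;
          if (e - cur >= min_len) {
            kept_i++;
            if (a0 >= 0 && cur <= a0 && e >= a1) amp_i++;
          }
          cur = e;
        }
      }
      if (template_len - cur >= min_len) {
        kept_i++;
        if (a0 >= 0 && cur <= a0 && template_len >= a1) amp_i++;
      }
    }
    kept[i] = (int)kept_i; amplifiable[i] = (int)amp_i;
  }
  return List::create(_["kept"] = kept, _["amplifiable"] = amplifiable);
}
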