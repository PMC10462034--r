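#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Suffix array by prefix doubling, O(n log^2 n). Input symbols are positive
// integers; terminators must already be encoded as distinct smallest values
// so the suffix order is total.
// [[Rcpp::export]]
IntegerVector sa_cpp(IntegerVector text) {
  int n = text.size();
  std::vector<int> sa(n), r(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; r[i] = text[i]; }
  if (n <= 1) return wrap(sa);
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + k < n ? r[a + k] : -1;
      int rb = b + k < n ? r[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    r = tmp;
    if (r[sa[n - 1]] == n - 1) break;
  }
  return wrap(sa);
}

// [[Rcpp::export]]
IntegerVector bwt_cpp(IntegerVector text, IntegerVector sa) {
  int n = text.size();
  IntegerVector bwt(n);
  for (int i = 0; i < n; ++i)
    bwt[i] = sa[i] == 0 ? text[n - 1] : text[sa[i] - 1];
  return bwt;
}

// Kasai LCP: lcp[i] = length of common prefix of suffixes SA[i-1], SA[i];
// lcp[0] = 0.
// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector text, IntegerVector sa) {
  int n = text.size();
  IntegerVector lcp(n);
  std::vector<int> isa(n);
  for (int i = 0; i < n; ++i) isa[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (isa[i] > 0) {
      int j = sa[isa[i] - 1];
      while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
      lcp[isa[i]] = h;
      if (h > 0) --h;
    } else {
      lcp[0] = 0;
      h = 0;
    }
  }
  return lcp;
}

// Maximal equal-symbol runs of a vector: 0-based starts, symbols, lengths.
// [[Rcpp::export]]
List rle_runs_cpp(IntegerVector x) {
  int n = x.size();
  std::vector<int> starts, syms, lens;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    starts.push_back(i);
    syms.push_back(x[i]);
    lens.push_back(j - i);
    i = j;
  }
  return List::create(_["starts"] = wrap(starts), _["syms"] = wrap(syms),
                      _["lens"] = wrap(lens));
}

// Thresholds: for each symbol c and each gap between consecutive BWT runs of
// c, the offset in (end_prev, start_next] where preference switches from the
// preceding to the following run, i.e. the last argmin of LCP over that
// range (last argmin => ties resolve toward the preceding run).
// Returns a list indexed by symbol value (1..maxSym) of integer vectors,
// one threshold per gap (0-based BWT offsets).
// [[Rcpp::export]]
List thresholds_cpp(IntegerVector lcp, IntegerVector runStarts,
                    IntegerVector runSyms, IntegerVector runLens,
                    int maxSym) {
  int nr = runStarts.size();
  std::vector<std::vector<int>> runsOf(maxSym + 1);
  for (int j = 0; j < nr; ++j)
    if (runSyms[j] >= 1 && runSyms[j] <= maxSym) runsOf[runSyms[j]].push_back(j);
  List out(maxSym);
  for (int c = 1; c <= maxSym; ++c) {
    const std::vector<int> &rs = runsOf[c];
    int q = rs.size();
    if (q < 2) { out[c - 1] = IntegerVector(0); continue; }
    IntegerVector th(q - 1);
    for (int g = 0; g + 1 < q; ++g) {
      int e = runStarts[rs[g]] + runLens[rs[g]] - 1;  // last offset of prev run
      int s = runStarts[rs[g + 1]];                    // first offset of next run
      int best = e + 1, bestVal = lcp[e + 1];
      for (int p = e + 1; p <= s; ++p)
        if (lcp[p] <= bestVal) { bestVal = lcp[p]; best = p; }
      th[g] = best;
    }
    out[c - 1] = th;
  }
  return out;
}

static inline double welch_t(double s1, double q1, double s2, double q2,
                             double w) {
  double m1 = s1 / w, m2 = s2 / w;
  double v1 = q1 / w - m1 * m1, v2 = q2 / w - m2 * m2;
  if (v1 < 0) v1 = 0;
  if (v2 < 0) v2 = 0;
  double d = std::fabs(m1 - m2);
  double den = std::sqrt(v1 / w + v2 / w);
  if (den == 0.0) return d == 0.0 ? 0.0 : 1e12;
  return d / den;
}

static void peaks_of(const std::vector<double> &t, double thr, double ph,
                     std::vector<int> &peaks) {
  bool in = false;
  double best = 0;
  int bestPos = -1;
  int n = t.size();
  for (int i = 0; i < n; ++i) {
    if (!in) {
      if (t[i] > thr) { in = true; best = t[i]; bestPos = i; }
    } else {
      if (t[i] > best) { best = t[i]; bestPos = i; }
      if (t[i] < thr || t[i] < best - ph) {
        peaks.push_back(bestPos);
        in = t[i] > thr;
        if (in) { best = t[i]; bestPos = i; }
      }
    }
  }
  if (in) peaks.push_back(bestPos);
}

// Two-window rolling Welch t-test boundary detector. A boundary at index i
// splits samples [., i) / [i, .). Short-window peaks above t1 catch abrupt
// level changes; long-window peaks above t2 catch subtle ones and are masked
// within w2 samples of a short-window peak. Returns sorted 0-based interior
// boundary indices.
// [[Rcpp::export]]
IntegerVector event_boundaries_cpp(NumericVector raw, int w1, int w2,
                                   double t1, double t2, double ph) {
  int n = raw.size();
  std::vector<int> bounds;
  if (n < 2 * w1 + 1) return IntegerVector(0);
  std::vector<double> cs(n + 1, 0.0), cq(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + raw[i];
    cq[i + 1] = cq[i] + raw[i] * raw[i];
  }
  auto tvec = [&](int w) {
    std::vector<double> t(n, 0.0);
    for (int i = w; i + w <= n; ++i)
      t[i] = welch_t(cs[i] - cs[i - w], cq[i] - cq[i - w],
                     cs[i + w] - cs[i], cq[i + w] - cq[i], (double)w);
    return t;
  };
  std::vector<double> ts = tvec(w1);
  std::vector<int> shortPk;
  peaks_of(ts, t1, ph, shortPk);
  std::vector<int> longPk;
  if (n >= 2 * w2 + 1) {
    std::vector<double> tl = tvec(w2);
    std::vector<int> cand;
    peaks_of(tl, t2, ph, cand);
    for (int p : cand) {
      bool masked = false;
      for (int s : shortPk)
        if (std::abs(s - p) <= w2) { masked = true; break; }
      if (!masked) longPk.push_back(p);
    }
  }
  bounds = shortPk;
  bounds.insert(bounds.end(), longPk.begin(), longPk.end());
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  std::vector<int> keep;
  for (int b : bounds)
    if (b >= 1 && b < n) keep.push_back(b);
  return wrap(keep);
}

// rank helper over per-symbol run tables: number of occurrences of symbol c
// in BWT[0..i).
static inline int rank_sym(const IntegerVector &starts, const IntegerVector &lens,
                           const IntegerVector &cum, int i) {
  int q = starts.size();
  if (q == 0 || i <= starts[0]) return 0;
  // last run with start < i
  int lo = 0, hi = q - 1, j = 0;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (starts[mid] < i) { j = mid; lo = mid + 1; } else hi = mid - 1;
  }
  int within = i - starts[j];
  if (within > lens[j]) within = lens[j];
  return cum[j] + within;
}

// Streaming PML query over the run-length BWT. Two pieces of state work
// together:
//  - the backward-search interval [lo, hi) of the pattern matched so far
//    decides extension vs reset: a reset occurs only when the extension
//    interval is empty, so exact substrings always yield the full ramp;
//  - a tracked row inside the interval carries the document label. While
//    BWT[row] equals the query symbol the label propagates through the LF
//    step; otherwise the thresholds structure repositions the row to the
//    boundary of the preceding or following run of that symbol (whichever
//    shares the longer context with the current suffix; ties toward the
//    preceding run), where the sampled document array gives the label
//    exactly.
// A match segment is attributed to the document known when the segment
// closes, i.e. when its pattern is longest and therefore most specific
// (longer matches are more likely unique to one document). Closed segments
// are emitted as decreasing ramps [L..1] with that document at every
// position; the open segment rides in the state (interval, length,
// document) until it closes or the query is flushed. A new match restarts
// at length 1 (0 with a NA document if the symbol is absent from the whole
// index, with row/interval reset to the full range).
// [[Rcpp::export]]
List pml_query_cpp(IntegerVector query, IntegerVector Ctab,
                   List symStarts, List symLens, List symCum,
                   List symDocF, List symDocL, List symThresh,
                   int n, int maxSym,
                   int lo, int hi, int len, int row, int curDoc,
                   bool flush) {
  std::vector<int> P, D;
  int m = query.size();
  P.reserve(m + len);
  D.reserve(m + len);
  auto closeSegment = [&](int L, int doc) {
    for (int j = 0; j < L; ++j) {
      P.push_back(L - j);
      D.push_back(doc);
    }
  };
  for (int qi = 0; qi < m; ++qi) {
    int c = query[qi];
    bool absent = (c < 1 || c > maxSym) || (Ctab[c + 1] - Ctab[c]) == 0;
    if (absent) {
      closeSegment(len, curDoc);
      P.push_back(0);
      D.push_back(NA_INTEGER);
      lo = 0; hi = n; len = 0; row = 0; curDoc = NA_INTEGER;
      continue;
    }
    IntegerVector st = symStarts[c - 1], le = symLens[c - 1],
                  cu = symCum[c - 1], df = symDocF[c - 1],
                  dl = symDocL[c - 1], th = symThresh[c - 1];
    int l2 = Ctab[c] + rank_sym(st, le, cu, lo);
    int h2 = Ctab[c] + rank_sym(st, le, cu, hi);
    int prevLen = len, prevDoc = curDoc;
    // reposition the tracked row onto an occurrence of c
    int q1 = st.size();
    int a = 0, b = q1 - 1, j = -1;  // last run with start <= row
    while (a <= b) {
      int mid = (a + b) / 2;
      if (st[mid] <= row) { j = mid; a = mid + 1; } else b = mid - 1;
    }
    int p;
    if (j >= 0 && st[j] + le[j] > row) {
      p = row;               // BWT[row] == c: match in place, propagate label
      if (row == st[j]) curDoc = df[j];                 // exact at run head
      else if (row == st[j] + le[j] - 1) curDoc = dl[j];  // exact at run tail
    } else {
      // j is the preceding c-run (-1 if none), j+1 the following (if any)
      bool havePrev = j >= 0, haveNext = j + 1 < q1;
      bool usePrev;
      if (havePrev && haveNext)
        usePrev = row < th[j];  // thresholds: switch offset between the runs
      else
        usePrev = havePrev;
      if (usePrev) {
        p = st[j] + le[j] - 1;
        curDoc = dl[j];
      } else {
        p = st[j + 1];
        curDoc = df[j + 1];
      }
    }
    row = Ctab[c] + rank_sym(st, le, cu, p);  // LF step from the occurrence
    if (l2 < h2) {
      lo = l2; hi = h2; ++len;
    } else {
      closeSegment(prevLen, prevDoc);
      lo = Ctab[c]; hi = Ctab[c + 1]; len = 1;
    }
  }
  if (flush) {
    closeSegment(len, curDoc);
    len = 0;
  }
  return List::create(_["P"] = wrap(P), _["D"] = wrap(D),
                      _["lo"] = lo, _["hi"] = hi, _["len"] = len,
                      _["row"] = row, _["curDoc"] = curDoc);
}

// Invert the BWT document by document. Row j-1 holds the suffix starting at
// the j-th terminator; walking LF from it spells document j back to front.
// Returns the list of document symbol vectors (terminators excluded).
// [[Rcpp::export]]
List extract_docs_cpp(IntegerVector runStarts, IntegerVector runSyms,
                      IntegerVector runLens, IntegerVector Ctab,
                      List symStarts, List symLens, List symCum,
                      int nDocs, int n) {
  int nr = runStarts.size();
  auto bwtAt = [&](int i) {
    int a = 0, b = nr - 1, j = 0;
    while (a <= b) {
      int mid = (a + b) / 2;
      if (runStarts[mid] <= i) { j = mid; a = mid + 1; } else b = mid - 1;
    }
    return runSyms[j];
  };
  List out(nDocs);
  for (int d = 1; d <= nDocs; ++d) {
    std::vector<int> seq;
    int row = d - 1;
    for (int guard = 0; guard <= n; ++guard) {
      int c = bwtAt(row);
      if (c <= nDocs) break;  // hit the preceding terminator
      seq.push_back(c);
      IntegerVector st = symStarts[c - 1], le = symLens[c - 1], cu = symCum[c - 1];
      row = Ctab[c] + rank_sym(st, le, cu, row);
    }
    std::reverse(seq.begin(), seq.end());
    out[d - 1] = wrap(seq);
  }
  return out;
}

// LF mapping for every offset (test support for bijectivity checks).
// [[Rcpp::export]]
IntegerVector lf_all_cpp(IntegerVector runStarts, IntegerVector runSyms,
                         IntegerVector runLens, IntegerVector Ctab,
                         List symStarts, List symLens, List symCum, int n) {
  int nr = runStarts.size();
  IntegerVector out(n);
  for (int j = 0; j < nr; ++j) {
    int c = runSyms[j];
    IntegerVector st = symStarts[c - 1], le = symLens[c - 1], cu = symCum[c - 1];
    for (int i = runStarts[j]; i < runStarts[j] + runLens[j]; ++i)
      out[i] = Ctab[c] + rank_sym(st, le, cu, i);
  }
  return out;
}
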