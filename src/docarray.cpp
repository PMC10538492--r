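#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>
#include <climits>

using namespace Rcpp;

// All positions crossing the R boundary are 1-based; internal loops are
// 0-based.  The integer text uses position-distinct separator codes 1..d
// (smaller = earlier in the text) and alphabet codes d+1..d+sigma, so a
// plain integer sort realises the separator ordering rule and makes every
// suffix distinct.

// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector codes) {
    int n = codes.size();
    std::vector<int> sa(n), rnk(n), tmp(n);
    for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = codes[i]; }
    for (int k = 1;; k <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            int ra = (a + k < n) ? rnk[a + k] : -1;
            int rb = (b + k < n) ? rnk[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
    }
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;
    return out;
}

// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector codes, IntegerVector sa) {
    int n = codes.size();
    std::vector<int> rank(n);
    for (int i = 0; i < n; ++i) rank[sa[i] - 1] = i;
    IntegerVector lcp(n);
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank[i] > 0) {
            int j = sa[rank[i] - 1] - 1;
            while (i + h < n && j + h < n && codes[i + h] == codes[j + h]) ++h;
            lcp[rank[i]] = h;
            if (h > 0) --h;
        } else {
            lcp[0] = 0;
            h = 0;
        }
    }
    return lcp;
}

static inline int lcp_direct(const IntegerVector &codes, int a0, int b0) {
    int n = codes.size(), l = 0;
    while (a0 + l < n && b0 + l < n && codes[a0 + l] == codes[b0 + l]) ++l;
    return l;
}

// Entry-by-entry evaluation of the defining maximum: the ground-truth
// oracle for the other constructions.  Quadratic; meant for small inputs.
// [[Rcpp::export]]
IntegerMatrix profiles_naive_cpp(IntegerVector codes, IntegerVector sa,
                                 IntegerVector da, int d) {
    int n = codes.size();
    IntegerMatrix P(n, d);
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < n; ++k) {
            int l = lcp_direct(codes, sa[i] - 1, sa[k] - 1);
            int j = da[k] - 1;
            if (l > P(i, j)) P(i, j) = l;
        }
    }
    return P;
}

// Predecessor/successor two-pass construction: for each row the best lcp
// with the nearest preceding and nearest following suffix of each document,
// chained through running minima of the LCP array.
// [[Rcpp::export]]
IntegerMatrix profiles_two_pass_cpp(IntegerVector sa, IntegerVector lcp,
                                    IntegerVector da, int d) {
    int n = sa.size();
    IntegerMatrix P(n, d);
    std::vector<int> acc(d, -1);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j)
            if (acc[j] > lcp[i]) acc[j] = lcp[i];
        acc[da[i] - 1] = n - sa[i] + 1;  // self-match: full suffix length
        for (int j = 0; j < d; ++j) P(i, j) = acc[j];
    }
    std::fill(acc.begin(), acc.end(), -1);
    for (int i = n - 1; i >= 0; --i) {
        int nextl = (i + 1 < n) ? lcp[i + 1] : 0;
        for (int j = 0; j < d; ++j)
            if (acc[j] > nextl) acc[j] = nextl;
        acc[da[i] - 1] = n - sa[i] + 1;
        for (int j = 0; j < d; ++j)
            if (acc[j] > P(i, j)) P(i, j) = acc[j];
    }
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < d; ++j)
            if (P(i, j) < 0) P(i, j) = 0;
    return P;
}

struct Tup {
    int pos;   // 1-based BWT position
    int ch;    // character class: 0 = separator, 1..sigma = alphabet
    int doc;   // DA[LF(pos)], 1-based
    int lcp;   // LCP[pos]
};

// Single left-to-right scan over (BWT, SA, LCP, DA[LF]) emitting the
// profiles P_DA[LF(s)], P_DA[LF(e)] for every run (s, e).  Pending profiles
// are kept in un-prepended units (-1 = no supporting suffix of that
// document yet); the +1 for the prepended character is applied at emission.
// [[Rcpp::export]]
List profiles_streaming_cpp(IntegerVector sa, IntegerVector lcp,
                            IntegerVector bwtcls, IntegerVector daLF,
                            IntegerVector runId, LogicalVector isStart,
                            LogicalVector isEnd, int d, int sigma, int r,
                            bool check = false) {
    int n = sa.size();
    if (lcp.size() != n || bwtcls.size() != n || daLF.size() != n ||
        runId.size() != n || isStart.size() != n || isEnd.size() != n)
        stop("inconsistent input lengths");
    IntegerMatrix profStart(d, r), profEnd(d, r);
    std::fill(profStart.begin(), profStart.end(), NA_INTEGER);
    std::fill(profEnd.begin(), profEnd.end(), NA_INTEGER);

    // Pred[j][c]: lcp between the current suffix and the nearest preceding
    // suffix of document j+1 that is preceded by character class c.
    std::vector<std::vector<int> > Pred(d, std::vector<int>(sigma + 1, -1));
    std::deque<Tup> q;
    std::deque<std::vector<int> > pend;
    std::vector<std::vector<int> > LQC(d, std::vector<int>(sigma + 1, 0));
    std::vector<int> nz(sigma + 1, 0);  // docs with LQC[.][c] > 0
    int maxQueue = 0, flushed = 0;
    bool lqcOk = true;

    auto emit = [&](const Tup &t, const std::vector<int> &p) {
        int rid = runId[t.pos - 1] - 1;
        if (isStart[t.pos - 1])
            for (int j = 0; j < d; ++j)
                profStart(j, rid) = (p[j] < 0) ? 0 : p[j] + 1;
        if (isEnd[t.pos - 1])
            for (int j = 0; j < d; ++j)
                profEnd(j, rid) = (p[j] < 0) ? 0 : p[j] + 1;
    };

    for (int i = 0; i < n; ++i) {
        int L = lcp[i];
        for (int j = 0; j < d; ++j)
            for (int c = 0; c <= sigma; ++c)
                if (Pred[j][c] > L) Pred[j][c] = L;
        int leni = n - sa[i] + 1;
        int c = bwtcls[i];
        int doc = daLF[i];
        std::vector<int> p(d, -1);
        if (c == 0) {
            // Separator position: distinct sentinels give lcp 0 with every
            // other suffix; only the own document (full suffix at LF(i))
            // contributes.  SA[i] == 1 wraps to the final separator suffix.
            Pred[doc - 1][0] = leni;
            p[doc - 1] = (sa[i] > 1) ? leni : 0;
        } else {
            Pred[doc - 1][c] = leni;
            for (int j = 0; j < d; ++j) p[j] = Pred[j][c];
        }
        Tup t; t.pos = i + 1; t.ch = c; t.doc = doc; t.lcp = L;
        q.push_back(t);
        pend.push_back(p);
        // Separator tuples are complete at insertion: distinct sentinels
        // give lcp 0 against every other suffix, so no successor update
        // can touch them.  They stay in the queue only to keep the lcp
        // chain contiguous, and are not counted in LQC.
        if (c != 0 && ++LQC[doc - 1][c] == 1) ++nz[c];

        // successor updates, newest to oldest; ell tracks the lcp between
        // the current suffix and the tuple's suffix
        int ell = leni;
        size_t m = q.size();
        for (size_t k = m; k-- > 0;) {
            Tup &u = q[k];
            if (c != 0 && u.ch == c && u.doc != doc) {
                std::vector<int> &pu = pend[k];
                if (ell > pu[doc - 1]) pu[doc - 1] = ell;
            }
            if (u.lcp < ell) ell = u.lcp;
        }
        if ((int)q.size() > maxQueue) maxQueue = (int)q.size();

        if (check) {
            std::vector<std::vector<int> > cnt(d, std::vector<int>(sigma + 1, 0));
            for (size_t k = 0; k < q.size(); ++k)
                if (q[k].ch != 0) ++cnt[q[k].doc - 1][q[k].ch];
            if (cnt != LQC) lqcOk = false;
        }

        // pop completed profiles from the front
        while (!q.empty()) {
            Tup &f = q.front();
            if (f.ch != 0 && nz[f.ch] < d) break;
            emit(f, pend.front());
            if (f.ch != 0 && --LQC[f.doc - 1][f.ch] == 0) --nz[f.ch];
            q.pop_front();
            pend.pop_front();
        }
    }
    // end-of-scan flush: missing (doc, char) successors contribute nothing
    while (!q.empty()) {
        emit(q.front(), pend.front());
        q.pop_front();
        pend.pop_front();
        ++flushed;
    }
    return List::create(_["profStart"] = profStart, _["profEnd"] = profEnd,
                        _["maxQueue"] = maxQueue, _["flushed"] = flushed,
                        _["lqcOk"] = lqcOk);
}

static inline int rank_upto(const IntegerVector &pos, int i) {
    // number of stored positions <= i
    return (int)(std::upper_bound(pos.begin(), pos.end(), i) - pos.begin());
}

// Backward search with profile maintenance.  Case 1: the interval contains
// a boundary of a run of the next character -- adopt the sampled profile
// stored there (lowest-position boundary, start sample on ties).  Case 2:
// the interval is strictly inside a run of that character -- increment all
// d entries.  Otherwise the character is absent from the interval.
// [[Rcpp::export]]
List query_profiles_cpp(IntegerVector pat, List eng) {
    int d = as<int>(eng["d"]);
    int sigma = as<int>(eng["sigma"]);
    IntegerVector Coff = eng["Coff"], cnt = eng["cnt"];
    List posC = eng["posC"];
    List cStartPos = eng["cStartPos"], cStartRid = eng["cStartRid"];
    List cEndPos = eng["cEndPos"], cEndRid = eng["cEndRid"];
    IntegerVector runCls = eng["runCls"], runIdOfPos = eng["runIdOfPos"];
    IntegerMatrix profStart = eng["profStart"], profEnd = eng["profEnd"];

    int m = pat.size();
    List absent = List::create(_["found"] = false, _["s"] = 0, _["e"] = 0,
                               _["prof"] = IntegerVector(0));
    if (m < 1) stop("empty pattern");
    int c = pat[m - 1];
    if (c == NA_INTEGER || c < 1 || c > sigma || cnt[c - 1] == 0) return absent;
    IntegerVector cs0 = cStartRid[c - 1];
    int rid = cs0[0];
    std::vector<int> prof(d);
    for (int j = 0; j < d; ++j) prof[j] = profStart(j, rid - 1);
    int s = Coff[c - 1] + 1, e = Coff[c - 1] + cnt[c - 1];

    for (int qq = m - 2; qq >= 0; --qq) {
        c = pat[qq];
        if (c == NA_INTEGER || c < 1 || c > sigma) return absent;
        IntegerVector cs = cStartPos[c - 1], ce = cEndPos[c - 1];
        IntegerVector csr = cStartRid[c - 1], cer = cEndRid[c - 1];
        int bS = INT_MAX, bE = INT_MAX;
        int iS = (int)(std::lower_bound(cs.begin(), cs.end(), s) - cs.begin());
        int iE = (int)(std::lower_bound(ce.begin(), ce.end(), s) - ce.begin());
        if (iS < cs.size()) bS = cs[iS];
        if (iE < ce.size()) bE = ce[iE];
        int b = std::min(bS, bE);
        if (b <= e) {
            if (bS <= bE) {
                rid = csr[iS];
                for (int j = 0; j < d; ++j) prof[j] = profStart(j, rid - 1);
            } else {
                rid = cer[iE];
                for (int j = 0; j < d; ++j) prof[j] = profEnd(j, rid - 1);
            }
        } else if (runCls[runIdOfPos[s - 1] - 1] == c) {
            for (int j = 0; j < d; ++j) ++prof[j];
        } else {
            return absent;
        }
        IntegerVector pc = posC[c - 1];
        int r1 = rank_upto(pc, s - 1), r2 = rank_upto(pc, e);
        s = Coff[c - 1] + r1 + 1;
        e = Coff[c - 1] + r2;
        if (s > e) return absent;
    }
    return List::create(_["found"] = true, _["s"] = s, _["e"] = e,
                        _["prof"] = IntegerVector(prof.begin(), prof.end()));
}

static inline bool suffix_less(const IntegerVector &codes, int i0,
                               const IntegerVector &read, int p0) {
    int n = codes.size(), L = read.size();
    int a = i0, b = p0;
    while (a < n && b < L) {
        if (codes[a] != read[b]) return codes[a] < read[b];
        ++a; ++b;
    }
    return a >= n;  // text suffix exhausted first => smaller
}

static inline int lcp_read(const IntegerVector &codes, int i0,
                           const IntegerVector &read, int p0) {
    int n = codes.size(), L = read.size(), l = 0;
    while (i0 + l < n && p0 + l < L && codes[i0 + l] == read[p0 + l]) ++l;
    return l;
}

// Per read position, the length of the longest prefix of read[p..] that
// occurs anywhere in the text, via binary search in the suffix array: the
// best-matching suffix is adjacent to the insertion point.
// [[Rcpp::export]]
IntegerVector matching_stats_cpp(IntegerVector readCodes, IntegerVector codes,
                                 IntegerVector sa) {
    int n = codes.size(), L = readCodes.size();
    IntegerVector ms(L);
    for (int p = 0; p < L; ++p) {
        if (readCodes[p] < 0) { ms[p] = 0; continue; }
        int lo = 0, hi = n;
        while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (suffix_less(codes, sa[mid] - 1, readCodes, p)) lo = mid + 1;
            else hi = mid;
        }
        int best = 0;
        if (lo < n) best = lcp_read(codes, sa[lo] - 1, readCodes, p);
        if (lo > 0) {
            int b2 = lcp_read(codes, sa[lo - 1] - 1, readCodes, p);
            if (b2 > best) best = b2;
        }
        ms[p] = best;
    }
    return ms;
}

// MEMs of a read against the indexed text: right-maximal by definition of
// the matching statistics, left-maximal where the previous position's match
// does not cover this one; each MEM re-queried backward to attach its SA
// interval and document array profile.
// [[Rcpp::export]]
List read_mems_cpp(IntegerVector readCls, int minLen, List eng,
                   IntegerVector codes, IntegerVector sa) {
    int d = as<int>(eng["d"]);
    int L = readCls.size();
    IntegerVector readCodes(L);
    for (int p = 0; p < L; ++p)
        readCodes[p] = (readCls[p] == NA_INTEGER || readCls[p] < 1)
                           ? -1 : d + readCls[p];
    IntegerVector ms = matching_stats_cpp(readCodes, codes, sa);
    std::vector<int> starts, lens;
    for (int p = 0; p < L; ++p) {
        if (ms[p] >= minLen && (p == 0 || ms[p - 1] <= ms[p])) {
            starts.push_back(p + 1);
            lens.push_back(ms[p]);
        }
    }
    int nm = (int)starts.size();
    IntegerMatrix prof(d, nm);
    IntegerVector ss(nm), ee(nm), st(nm), ln(nm);
    for (int k = 0; k < nm; ++k) {
        st[k] = starts[k];
        ln[k] = lens[k];
        IntegerVector pat(lens[k]);
        for (int j = 0; j < lens[k]; ++j) pat[j] = readCls[starts[k] - 1 + j];
        List res = query_profiles_cpp(pat, eng);
        if (!as<bool>(res["found"]))
            stop("internal error: MEM not found by backward search");
        ss[k] = as<int>(res["s"]);
        ee[k] = as<int>(res["e"]);
        IntegerVector pr = res["prof"];
        for (int j = 0; j < d; ++j) prof(j, k) = pr[j];
    }
    return List::create(_["start"] = st, _["len"] = ln, _["s"] = ss,
                        _["e"] = ee, _["prof"] = prof,
                        _["ms"] = ms);
}
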