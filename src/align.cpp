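#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment.
//
// Conventions used throughout:
//  - rows index the query (i = 1..m), columns the reference (j = 1..n);
//  - a gap of length k costs gap_open + k * gap_extend (Biostrings convention);
//  - modes: 0 = global (Needleman-Wunsch), 1 = glocal (query global,
//    reference terminal gaps free), 2 = local (Smith-Waterman);
//  - when n_wildcard is true an 'N' in either sequence scores 0 against
//    anything and the column is excluded from identity counting;
//  - traceback ties prefer diagonal, then up (query char vs gap), then left.

// sentinel low enough to dominate, high enough that sums cannot overflow
static const int NEG = -(1 << 28);

inline int pair_score(char a, char b, int match, int mismatch, bool n_wild) {
    if (n_wild && (a == 'N' || b == 'N')) return 0;
    return (a == b) ? match : mismatch;
}

// state codes in traceback matrices
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_START = 3 };

// [[Rcpp::export]]
List cpp_align(std::string query, std::string reference, int mode,
               int match, int mismatch, int gap_open, int gap_extend,
               bool n_wildcard) {
    const int m = (int) query.size();
    const int n = (int) reference.size();
    if (m == 0 || n == 0) stop("sequences must be non-empty");
    // penalties arrive as negative scores; convert to positive costs
    const int go = -(gap_open + gap_extend);  // cost of first gap position
    const int ge = -gap_extend;
    const int W = n + 1;

    std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
    std::vector<unsigned char> tbM((m + 1) * W, FROM_START),
        tbX((m + 1) * W, FROM_START), tbY((m + 1) * W, FROM_START);

    M[0] = 0;
    for (int i = 1; i <= m; ++i) {
        X[i * W] = -(go + ge * (i - 1));
        tbX[i * W] = (i == 1) ? FROM_M : FROM_X;
    }
    if (mode == 0) {
        for (int j = 1; j <= n; ++j) {
            Y[j] = -(go + ge * (j - 1));
            tbY[j] = (j == 1) ? FROM_M : FROM_Y;
        }
    } else if (mode == 1) {
        for (int j = 1; j <= n; ++j) M[j] = 0;  // free reference prefix
    } else {  // local
        for (int j = 1; j <= n; ++j) M[j] = 0;
        for (int i = 1; i <= m; ++i) M[i * W] = 0;
        for (int i = 1; i <= m; ++i) { X[i * W] = NEG; tbX[i * W] = FROM_START; }
    }

    int best_local = 0, best_li = 0, best_lj = 0;
    for (int i = 1; i <= m; ++i) {
        const char qc = query[i - 1];
        for (int j = 1; j <= n; ++j) {
            const int d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                      l = i * W + (j - 1), c = i * W + j;
            // M: consume both
            int s = pair_score(qc, reference[j - 1], match, mismatch, n_wildcard);
            int v = M[d]; unsigned char st = FROM_M;
            if (X[d] > v) { v = X[d]; st = FROM_X; }
            if (Y[d] > v) { v = Y[d]; st = FROM_Y; }
            if (mode == 2 && v <= 0) { v = 0; st = FROM_START; }  // fresh start
            int mv = (v <= NEG / 2) ? v : v + s;
            if (mode == 2 && mv < 0) { mv = 0; st = FROM_START; }
            M[c] = mv; tbM[c] = st;
            // X: consume query (gap in reference) -- "up"
            int xv = M[u] - go; unsigned char xst = FROM_M;
            if (X[u] - ge > xv) { xv = X[u] - ge; xst = FROM_X; }
            if (Y[u] - go > xv) { xv = Y[u] - go; xst = FROM_Y; }
            X[c] = xv; tbX[c] = xst;
            // Y: consume reference (gap in query) -- "left"
            int yv = M[l] - go; unsigned char yst = FROM_M;
            if (X[l] - go > yv) { yv = X[l] - go; yst = FROM_X; }
            if (Y[l] - ge > yv) { yv = Y[l] - ge; yst = FROM_Y; }
            Y[c] = yv; tbY[c] = yst;
            if (mode == 2 && M[c] > best_local) {
                best_local = M[c]; best_li = i; best_lj = j;
            }
        }
    }

    // locate alignment end and starting state
    int ei = m, ej = n, state;
    int score;
    if (mode == 0) {
        score = M[m * W + n]; state = FROM_M;
        if (X[m * W + n] > score) { score = X[m * W + n]; state = FROM_X; }
        if (Y[m * W + n] > score) { score = Y[m * W + n]; state = FROM_Y; }
    } else if (mode == 1) {
        score = NEG; state = FROM_M; ej = 0;
        for (int j = 1; j <= n; ++j) {  // smallest j wins ties
            if (M[m * W + j] > score) { score = M[m * W + j]; state = FROM_M; ej = j; }
            if (X[m * W + j] > score) { score = X[m * W + j]; state = FROM_X; ej = j; }
        }
    } else {
        score = best_local; state = FROM_M; ei = best_li; ej = best_lj;
        if (score == 0) {  // empty local alignment
            return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                                _["r_start"] = 0, _["r_end"] = 0, _["matches"] = 0,
                                _["mismatches"] = 0, _["gaps"] = 0,
                                _["columns"] = 0, _["n_columns"] = 0,
                                _["qpos"] = IntegerVector(0),
                                _["rpos"] = IntegerVector(0));
        }
    }

    // traceback
    std::vector<int> qp, rp;  // 0-based positions, -1 for gap
    int i = ei, j = ej, st = state;
    while (true) {
        if (st == FROM_START) break;
        if (i == 0 && j == 0) break;
        unsigned char prev;
        if (st == FROM_M) {
            prev = tbM[i * W + j];
            qp.push_back(i - 1); rp.push_back(j - 1);
            --i; --j;
        } else if (st == FROM_X) {
            prev = tbX[i * W + j];
            qp.push_back(i - 1); rp.push_back(-1);
            --i;
        } else {
            prev = tbY[i * W + j];
            qp.push_back(-1); rp.push_back(j - 1);
            --j;
        }
        if (mode == 1 && i == 0) break;       // free reference prefix reached
        if (i == 0 && j == 0) break;
        st = prev;
        if (mode == 0 && st == FROM_START && (i > 0 || j > 0)) {
            // border cells: continue along the border
            st = (i > 0) ? FROM_X : FROM_Y;
        }
    }
    std::reverse(qp.begin(), qp.end());
    std::reverse(rp.begin(), rp.end());

    // strip terminal gap columns for identity accounting (kept in spans)
    int ncol = (int) qp.size();
    int first = 0, last = ncol - 1;
    while (first <= last && (qp[first] < 0 || rp[first] < 0)) ++first;
    while (last >= first && (qp[last] < 0 || rp[last] < 0)) --last;

    int matches = 0, mismatches = 0, gaps = 0, id_cols = 0;
    for (int k = first; k <= last; ++k) {
        if (qp[k] < 0 || rp[k] < 0) { ++gaps; ++id_cols; continue; }
        char a = query[qp[k]], b = reference[rp[k]];
        if (n_wildcard && (a == 'N' || b == 'N')) continue;  // neutral column
        ++id_cols;
        if (a == b) ++matches; else ++mismatches;
    }

    int q_start = -1, q_end = -1, r_start = -1, r_end = -1;
    for (int k = 0; k < ncol; ++k) {
        if (qp[k] >= 0) { if (q_start < 0) q_start = qp[k]; q_end = qp[k] + 1; }
        if (rp[k] >= 0) { if (r_start < 0) r_start = rp[k]; r_end = rp[k] + 1; }
    }
    if (q_start < 0) { q_start = 0; q_end = 0; }
    if (r_start < 0) { r_start = 0; r_end = 0; }

    return List::create(_["score"] = score,
                        _["q_start"] = q_start, _["q_end"] = q_end,
                        _["r_start"] = r_start, _["r_end"] = r_end,
                        _["matches"] = matches, _["mismatches"] = mismatches,
                        _["gaps"] = gaps, _["columns"] = last - first + 1,
                        _["n_columns"] = id_cols,
                        _["qpos"] = wrap(qp), _["rpos"] = wrap(rp));
}

// Score-only alignment of many queries against one reference (rolling rows).
// [[Rcpp::export]]
IntegerVector cpp_score_batch(CharacterVector queries, std::string reference,
                              int mode, int match, int mismatch,
                              int gap_open, int gap_extend, bool n_wildcard) {
    const int n = (int) reference.size();
    const int go = -(gap_open + gap_extend), ge = -gap_extend;
    IntegerVector out(queries.size());
    std::vector<int> Mp(n + 1), Xp(n + 1), Yp(n + 1), Mc(n + 1), Xc(n + 1), Yc(n + 1);
    for (int q = 0; q < queries.size(); ++q) {
        std::string query = as<std::string>(queries[q]);
        const int m = (int) query.size();
        // row 0
        for (int j = 0; j <= n; ++j) { Mp[j] = NEG; Xp[j] = NEG; Yp[j] = NEG; }
        Mp[0] = 0;
        if (mode == 0) for (int j = 1; j <= n; ++j) Yp[j] = -(go + ge * (j - 1));
        else for (int j = 1; j <= n; ++j) Mp[j] = 0;
        int best_local = 0;
        for (int i = 1; i <= m; ++i) {
            Mc[0] = NEG; Yc[0] = NEG;
            Xc[0] = (mode == 2) ? NEG : -(go + ge * (i - 1));
            if (mode == 2) Mc[0] = 0;
            const char qc = query[i - 1];
            for (int j = 1; j <= n; ++j) {
                int s = pair_score(qc, reference[j - 1], match, mismatch, n_wildcard);
                int v = Mp[j - 1];
                if (Xp[j - 1] > v) v = Xp[j - 1];
                if (Yp[j - 1] > v) v = Yp[j - 1];
                int mv = (v <= NEG / 2) ? v : v + s;
                if (mode == 2 && mv < 0) mv = 0;
                Mc[j] = mv;
                int xv = Mp[j] - go;
                if (Xp[j] - ge > xv) xv = Xp[j] - ge;
                if (Yp[j] - go > xv) xv = Yp[j] - go;
                Xc[j] = xv;
                int yv = Mc[j - 1] - go;
                if (Xc[j - 1] - go > yv) yv = Xc[j - 1] - go;
                if (Yc[j - 1] - ge > yv) yv = Yc[j - 1] - ge;
                Yc[j] = yv;
                if (mode == 2 && Mc[j] > best_local) best_local = Mc[j];
            }
            std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
        }
        int score;
        if (mode == 0) {
            score = Mp[n];
            if (Xp[n] > score) score = Xp[n];
            if (Yp[n] > score) score = Yp[n];
        } else if (mode == 1) {
            score = NEG;
            for (int j = 1; j <= n; ++j) {
                if (Mp[j] > score) score = Mp[j];
                if (Xp[j] > score) score = Xp[j];
            }
        } else score = best_local;
        out[q] = score;
    }
    return out;
}

// Best ungapped placement score of each query inside the reference:
// max over offsets of sum(match=+1, mismatch=-2, N=0). For
// substitution-only data this equals the optimal glocal score, so it
// serves as a fast prefilter before exact DP. Queries longer than the
// reference get a large negative sentinel.
// Scores within keep_margin of the running global best are exact; others
// may be reported lower (they are pruned and never shortlisted).
// [[Rcpp::export]]
IntegerVector cpp_offset_scores(CharacterVector queries, std::string reference,
                                int match, int mismatch, int keep_margin) {
    const int n = (int) reference.size();
    IntegerVector out(queries.size());
    int gbest = NEG;
    for (int q = 0; q < queries.size(); ++q) {
        std::string query = as<std::string>(queries[q]);
        const int m = (int) query.size();
        if (m > n) { out[q] = NEG; continue; }
        int best = (gbest <= NEG / 2) ? NEG : gbest - keep_margin - 1;
        const char *qp = query.data(), *rp = reference.data();
        for (int off = 0; off <= n - m; ++off) {
            int s = 0;
            const char *rb = rp + off;
            for (int k = 0; k < m; ++k) {
                char a = qp[k], b = rb[k];
                if (a == 'N' || b == 'N') continue;
                s += (a == b) ? match : mismatch;
                // abandon: even perfect matches ahead cannot beat `best`
                if (s + (m - 1 - k) * match <= best) { s = NEG; break; }
            }
            if (s > best) best = s;
        }
        out[q] = best;
        if (best > gbest) gbest = best;
    }
    return out;
}

// Best ungapped overlap merge of a read pair (r2 already reverse-complemented).
// Qualifying overlaps have length >= min_overlap and mismatch fraction
// <= max_error (columns where either base is N are neutral). Among qualifying
// overlaps the one with the most matching columns wins; ties prefer the longer
// overlap. Disagreements resolve toward the higher-quality base, ties to r1.
// [[Rcpp::export]]
List cpp_merge_pair(std::string s1, std::string q1, std::string s2,
                    std::string q2, int min_overlap, double max_error) {
    const int n1 = (int) s1.size(), n2 = (int) s2.size();
    int best_o = -1, best_matches = -1, best_mm = 0;
    const int omax = std::min(n1, n2);
    for (int o = min_overlap; o <= omax; ++o) {
        int matches = 0, mm = 0;
        const int off = n1 - o;
        for (int k = 0; k < o; ++k) {
            char a = s1[off + k], b = s2[k];
            if (a == 'N' || b == 'N') continue;
            if (a == b) ++matches; else ++mm;
        }
        if ((double) mm / (double) o <= max_error &&
            (matches > best_matches || (matches == best_matches && o > best_o))) {
            best_matches = matches; best_o = o; best_mm = mm;
        }
    }
    if (best_o < 0)
        return List::create(_["success"] = false);
    const int off = n1 - best_o;
    std::string seq; seq.reserve(n1 + n2 - best_o);
    std::string qual; qual.reserve(n1 + n2 - best_o);
    bool have_q = (q1.size() == s1.size() && q2.size() == s2.size());
    seq.append(s1, 0, off);
    if (have_q) qual.append(q1, 0, off);
    for (int k = 0; k < best_o; ++k) {
        char a = s1[off + k], b = s2[k];
        char qa = have_q ? q1[off + k] : 'I', qb = have_q ? q2[k] : 'I';
        char base, q;
        if (a == b) { base = a; q = std::max(qa, qb); }
        else if (a == 'N') { base = b; q = qb; }
        else if (b == 'N') { base = a; q = qa; }
        else if (qb > qa) { base = b; q = qb; }
        else { base = a; q = qa; }  // ties -> r1
        seq.push_back(base);
        if (have_q) qual.push_back(q);
    }
    seq.append(s2, best_o, std::string::npos);
    if (have_q) qual.append(q2, best_o, std::string::npos);
    return List::create(_["success"] = true, _["sequence"] = seq,
                        _["quality"] = have_q ? qual : std::string(""),
                        _["overlap"] = best_o, _["mismatches"] = best_mm);
}

// Ungapped scan of each primer over offsets 0..(window - primer length) of the
// read; returns the best (fewest mismatches, then smallest offset, then first
// primer) hit, or index 0 when none is within max_mm.
// [[Rcpp::export]]
List cpp_scan_primer(std::string seq, CharacterVector primers, int max_mm,
                     int window) {
    int best_p = -1, best_off = -1, best_mm = max_mm + 1;
    for (int p = 0; p < primers.size(); ++p) {
        std::string pr = as<std::string>(primers[p]);
        const int pl = (int) pr.size();
        const int maxoff = std::min((int) seq.size(), window) - pl;
        for (int off = 0; off <= maxoff; ++off) {
            int mm = 0;
            for (int k = 0; k < pl && mm < best_mm; ++k)
                if (seq[off + k] != pr[k]) ++mm;
            if (mm < best_mm) { best_mm = mm; best_p = p; best_off = off; }
        }
    }
    if (best_p < 0 || best_mm > max_mm)
        return List::create(_["matched"] = false);
    return List::create(_["matched"] = true, _["primer"] = best_p + 1,
                        _["offset"] = best_off, _["mismatches"] = best_mm);
}

// Pairwise Hamming distances for equal-length strings.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector x) {
    const int n = x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            if (s[i].size() != s[j].size())
                stop("hamming distance requires equal-length strings");
            int d = 0;
            for (size_t k = 0; k < s[i].size(); ++k)
                if (s[i][k] != s[j][k]) ++d;
            out(i, j) = d; out(j, i) = d;
        }
    }
    return out;
}
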