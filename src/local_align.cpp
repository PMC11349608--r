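#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Local alignment with fixed scoring: match +1, mismatch -1, linear gap -2.
// Coordinates are 0-based half-open throughout, matching the anchor table.
// Ties among maximal alignments are broken by smallest read_start, then
// smallest segment_start, then smallest read_end / segment_end.

static const int GAP = -2;

static inline int subst(char a, char b) {
  // 'N' (or any non-ACGT) never matches, not even itself
  if (a != b) return -1;
  if (a == 'A' || a == 'C' || a == 'G' || a == 'T') return 1;
  return -1;
}

// score-only DP, rolling rows
static int sw_score(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int h = prev[j - 1] + subst(ai, b[j - 1]);
      int up = prev[j] + GAP;
      int left = cur[j - 1] + GAP;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

struct Hit {
  int score, rs, re, ss, se, track_read;
};

// full DP with traceback; `track` is a 0-based segment position whose aligned
// read position is reported (-1 if absent or not matched in the alignment)
static Hit sw_align(const std::string& a, const std::string& b, int track) {
  const int n = (int)a.size(), m = (int)b.size();
  Hit hit = {0, -1, -1, -1, -1, -1};
  if (n == 0 || m == 0) return hit;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> mv((size_t)(n + 1) * (m + 1), 0);
  const int W = m + 1;
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int diag = H[(size_t)(i - 1) * W + (j - 1)] + subst(ai, b[j - 1]);
      int up = H[(size_t)(i - 1) * W + j] + GAP;
      int left = H[(size_t)i * W + (j - 1)] + GAP;
      int h = diag;
      unsigned char move = 1;
      if (up > h) { h = up; move = 2; }
      if (left > h) { h = left; move = 3; }
      if (h <= 0) { h = 0; move = 0; }
      H[(size_t)i * W + j] = h;
      mv[(size_t)i * W + j] = move;
      if (h > best) best = h;
    }
  }
  if (best <= 0) return hit;
  // trace every maximal cell, keep the tie-break winner
  bool have = false;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[(size_t)i * W + j] != best) continue;
      int ci = i, cj = j, rs = i, ss = j, tr = -1;
      while (true) {
        unsigned char move = mv[(size_t)ci * W + cj];
        if (move == 0) break;
        if (move == 1) {
          rs = ci - 1; ss = cj - 1;
          if (cj - 1 == track) tr = ci - 1;
          --ci; --cj;
        } else if (move == 2) {
          rs = ci - 1; --ci;
        } else {
          ss = cj - 1; --cj;
        }
      }
      Hit cand = {best, rs, i, ss, j, tr};
      if (!have ||
          cand.rs < hit.rs ||
          (cand.rs == hit.rs && (cand.ss < hit.ss ||
            (cand.ss == hit.ss && (cand.re < hit.re ||
              (cand.re == hit.re && cand.se < hit.se)))))) {
        hit = cand;
        have = true;
      }
    }
  }
  return hit;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string segment, int track = -1) {
  Hit h = sw_align(read, segment, track);
  return List::create(
    _["score"] = h.score,
    _["read_start"] = h.rs, _["read_end"] = h.re,
    _["segment_start"] = h.ss, _["segment_end"] = h.se,
    _["track_read"] = h.track_read);
}

// Batch V then J assignment. Segments must be pre-sorted lexicographically by
// id so that "first strictly greater score wins" implements the lexicographic
// tie-break. J segments are aligned to the read suffix starting at the V hit's
// read_end, which enforces j.read_start >= v.read_end.
// [[Rcpp::export]]
DataFrame cpp_assign_vj(CharacterVector reads,
                        CharacterVector v_seqs, IntegerVector v_anchor,
                        CharacterVector j_seqs, IntegerVector j_anchor,
                        int min_score) {
  const int nr = reads.size(), nv = v_seqs.size(), nj = j_seqs.size();
  std::vector<std::string> vs(nv), js(nj);
  for (int k = 0; k < nv; ++k) vs[k] = as<std::string>(v_seqs[k]);
  for (int k = 0; k < nj; ++k) js[k] = as<std::string>(j_seqs[k]);

  IntegerVector v_idx(nr, NA_INTEGER), v_sc(nr, NA_INTEGER),
      v_rs(nr, NA_INTEGER), v_re(nr, NA_INTEGER), v_ss(nr, NA_INTEGER),
      v_se(nr, NA_INTEGER), v_anc(nr, NA_INTEGER), j_idx(nr, NA_INTEGER),
      j_sc(nr, NA_INTEGER), j_rs(nr, NA_INTEGER), j_re(nr, NA_INTEGER),
      j_ss(nr, NA_INTEGER), j_se(nr, NA_INTEGER), j_anc(nr, NA_INTEGER);

  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int bv = -1, bs = 0;
    for (int k = 0; k < nv; ++k) {
      int s = sw_score(rd, vs[k]);
      if (s > bs) { bs = s; bv = k; }
    }
    if (bv < 0 || bs < min_score) continue;
    Hit vh = sw_align(rd, vs[bv], v_anchor[bv]);
    v_idx[r] = bv + 1; v_sc[r] = vh.score;
    v_rs[r] = vh.rs; v_re[r] = vh.re; v_ss[r] = vh.ss; v_se[r] = vh.se;
    if (vh.track_read >= 0) v_anc[r] = vh.track_read;

    if (vh.re >= (int)rd.size()) continue;
    std::string suf = rd.substr(vh.re);
    int bj = -1; bs = 0;
    for (int k = 0; k < nj; ++k) {
      int s = sw_score(suf, js[k]);
      if (s > bs) { bs = s; bj = k; }
    }
    if (bj < 0 || bs < min_score) continue;
    Hit jh = sw_align(suf, js[bj], j_anchor[bj]);
    const int off = vh.re;
    j_idx[r] = bj + 1; j_sc[r] = jh.score;
    j_rs[r] = jh.rs + off; j_re[r] = jh.re + off;
    j_ss[r] = jh.ss; j_se[r] = jh.se;
    if (jh.track_read >= 0) j_anc[r] = jh.track_read + off;
  }

  return DataFrame::create(
    _["v_idx"] = v_idx, _["v_score"] = v_sc,
    _["v_read_start"] = v_rs, _["v_read_end"] = v_re,
    _["v_segment_start"] = v_ss, _["v_segment_end"] = v_se,
    _["v_anchor_read"] = v_anc,
    _["j_idx"] = j_idx, _["j_score"] = j_sc,
    _["j_read_start"] = j_rs, _["j_read_end"] = j_re,
    _["j_segment_start"] = j_ss, _["j_segment_end"] = j_se,
    _["j_anchor_read"] = j_anc);
}
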