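#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Pairwise and profile alignment kernels. Scores are classic BLAST-style:
// match reward, mismatch penalty, affine gaps where gap_open is the cost of
// the first gap character and gap_extend of each subsequent one.

static const double NEG_INF = -1e30;

// Gotoh alignment with traceback.
// mode 0 = fit (sequence a fully consumed, b's terminal overhangs free:
//          the semantics a centroid clusterer's "global" identity needs —
//          an overlap/dovetail mode would let unrelated pairs align over a
//          few corner columns and report a meaningless high identity),
// mode 1 = local (Smith-Waterman).
// Returns the aligned core plus 0-based half-open coordinates on each input.
// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend, int mode) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // traceback bits per cell:
  //  bits 0-1: H came from 0=diag, 1=E(gap consuming a), 2=F(gap consuming b), 3=fresh start
  //  bit 2: E opened from H (set) vs extended from E
  //  bit 3: F opened from H (set) vs extended from F
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 3);
  std::vector<double> Hprev(m + 1), Hcur(m + 1), Eprev(m + 1), Ecur(m + 1);
  std::vector<double> Fcur(m + 1);

  double best = NEG_INF; int bi = 0, bj = 0;
  if (mode == 1) { best = 0.0; }
  // row 0: in fit mode b's prefix is free; E (gap consuming a) impossible yet
  for (int j = 0; j <= m; ++j) { Hprev[j] = 0.0; Eprev[j] = NEG_INF; }

  for (int i = 1; i <= n; ++i) {
    if (mode == 1) {
      Hcur[0] = 0.0;
      Ecur[0] = NEG_INF;
    } else {
      // fit: consuming a against gaps before b starts is a real (penalised) gap
      Ecur[0] = (i == 1) ? gap_open : Eprev[0] + gap_extend;
      Hcur[0] = Ecur[0];
    }
    Fcur[0] = NEG_INF;
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    tbrow[0] = 1;  // H from E (vertical)
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      // E: gap consuming a (vertical move)
      double e_open = Hprev[j] + gap_open;
      double e_ext  = Eprev[j] + gap_extend;
      double E = e_open >= e_ext ? (t |= 4, e_open) : e_ext;
      // F: gap consuming b (horizontal move)
      double f_open = Hcur[j - 1] + gap_open;
      double f_ext  = Fcur[j - 1] + gap_extend;
      double F = f_open >= f_ext ? (t |= 8, f_open) : f_ext;
      double s = (ai == b[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double H = diag; uint8_t src = 0;
      if (E > H) { H = E; src = 1; }
      if (F > H) { H = F; src = 2; }
      if (mode == 1 && H < 0.0) { H = 0.0; src = 3; }  // local fresh start
      t |= src;
      tbrow[j] = t;
      Hcur[j] = H; Ecur[j] = E; Fcur[j] = F;
      if (mode == 1) {
        if (H > best) { best = H; bi = i; bj = j; }
      } else if (i == n) {           // fit: end anywhere on the last row
        if (H > best) { best = H; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }

  // traceback from (bi, bj)
  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
  while (i > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 3) break;                   // local fresh start
      if (src == 0) {
        if (j == 0) break;
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
      } else {
        state = src;
      }
    } else if (state == 1) {                 // E: consumed a[i-1] against gap
      aa.push_back(a[i - 1]); bb.push_back('-');
      bool opened = (t & 4) != 0;
      --i;
      if (opened) state = 0;
    } else {                                 // F: consumed b[j-1] against gap
      aa.push_back('-'); bb.push_back(b[j - 1]);
      bool opened = (t & 8) != 0;
      --j;
      if (opened) state = 0;
    }
    if (mode == 1 && j == 0) break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(
    _["a_aln"] = aa, _["b_aln"] = bb, _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,
    _["b_start"] = j, _["b_end"] = bj);
}

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Seed-and-extend ungapped search of query words in a genome (one strand).
// Exact word seeds, x-drop ungapped extension; per-diagonal coverage mask so
// seeds inside an already-extended hit are skipped. Coordinates 0-based
// half-open on both sequences.
// [[Rcpp::export]]
DataFrame seed_hits_cpp(std::string genome, std::string query, int word_size,
                        double x_drop, double match, double mismatch,
                        int min_length, double min_identity) {
  const int G = (int)genome.size(), Q = (int)query.size();
  std::vector<int> sstart, send, qstart, qend, matches_v, len_v;
  std::vector<double> score_v;
  if (Q < word_size || G < word_size) {
    return DataFrame::create(_["sstart"] = sstart, _["send"] = send,
                             _["qstart"] = qstart, _["qend"] = qend,
                             _["matches"] = matches_v, _["length"] = len_v,
                             _["score"] = score_v);
  }

  // hash query words (ACGT only)
  std::unordered_map<uint64_t, std::vector<int> > words;
  words.reserve(Q * 2);
  const uint64_t mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
  uint64_t w = 0; int run = 0;
  for (int q = 0; q < Q; ++q) {
    int c = enc(query[q]);
    if (c < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)c) & mask;
    if (++run >= word_size) words[w].push_back(q - word_size + 1);
  }

  // diagonal coverage: diag d = g - q + Q in [0, G+Q)
  std::vector<int> covered(G + Q, -1);

  w = 0; run = 0;
  for (int g = 0; g < G; ++g) {
    int c = enc(genome[g]);
    if (c < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)c) & mask;
    if (++run < word_size) continue;
    auto it = words.find(w);
    if (it == words.end()) continue;
    int gpos = g - word_size + 1;
    for (int qpos : it->second) {
      int d = gpos - qpos + Q;
      if (covered[d] >= gpos) continue;
      // extend right from end of word
      double sc = word_size * match, bestsc = sc;
      int gi = gpos + word_size, qi = qpos + word_size;
      int best_ge = gi, best_qe = qi;
      while (gi < G && qi < Q) {
        sc += (genome[gi] == query[qi]) ? match : mismatch;
        ++gi; ++qi;
        if (sc > bestsc) { bestsc = sc; best_ge = gi; best_qe = qi; }
        if (bestsc - sc > x_drop) break;
      }
      // extend left from start of word
      sc = bestsc;
      double bestsc2 = sc;
      gi = gpos - 1; qi = qpos - 1;
      int best_gs = gpos, best_qs = qpos;
      while (gi >= 0 && qi >= 0) {
        sc += (genome[gi] == query[qi]) ? match : mismatch;
        if (sc > bestsc2) { bestsc2 = sc; best_gs = gi; best_qs = qi; }
        --gi; --qi;
        if (bestsc2 - sc > x_drop) break;
      }
      covered[d] = best_ge - 1;
      int len = best_ge - best_gs;
      if (len < min_length) continue;
      int nmatch = 0;
      for (int k = 0; k < len; ++k)
        if (genome[best_gs + k] == query[best_qs + k]) ++nmatch;
      double ident = (double)nmatch / len;
      if (ident < min_identity) continue;
      sstart.push_back(best_gs); send.push_back(best_ge);
      qstart.push_back(best_qs); qend.push_back(best_qs + len);
      matches_v.push_back(nmatch); len_v.push_back(len);
      score_v.push_back(bestsc2);
    }
  }
  return DataFrame::create(_["sstart"] = sstart, _["send"] = send,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["matches"] = matches_v, _["length"] = len_v,
                           _["score"] = score_v);
}

// Global (Needleman-Wunsch, linear gap) alignment of two frequency profiles.
// Profiles are 5 x L matrices (rows A,C,G,T,gap; columns sum to 1). Column
// score is the expected substitution score over non-gap characters. Returns
// 1-based column indices into each profile, 0 where a gap column is inserted.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B,
                       double match, double mismatch, double gap_pen) {
  const int n = A.ncol(), m = B.ncol();
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 0 diag, 1 up, 2 left

  for (int j = 0; j <= m; ++j) { prev[j] = j * gap_pen; tb[j] = 2; }
  tb[0] = 0;

  // project B's columns against the substitution scores once:
  // SB[x][j] = sum_y B(y,j) * s(x,y)
  std::vector<double> SB(4 * m);
  for (int j = 0; j < m; ++j) {
    double tot = B(0, j) + B(1, j) + B(2, j) + B(3, j);
    for (int x = 0; x < 4; ++x) {
      SB[(size_t)x * m + j] = mismatch * (tot - B(x, j)) + match * B(x, j);
    }
  }

  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap_pen;
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    tbrow[0] = 1;
    const double fa0 = A(0, i - 1), fa1 = A(1, i - 1),
                 fa2 = A(2, i - 1), fa3 = A(3, i - 1);
    const double *sb0 = &SB[0], *sb1 = &SB[(size_t)m],
                 *sb2 = &SB[(size_t)2 * m], *sb3 = &SB[(size_t)3 * m];
    for (int j = 1; j <= m; ++j) {
      double s = fa0 * sb0[j - 1] + fa1 * sb1[j - 1] +
                 fa2 * sb2[j - 1] + fa3 * sb3[j - 1];
      double diag = prev[j - 1] + s;
      double up = prev[j] + gap_pen;
      double left = cur[j - 1] + gap_pen;
      double h = diag; uint8_t t = 0;
      if (up > h) { h = up; t = 1; }
      if (left > h) { h = left; t = 2; }
      cur[j] = h; tbrow[j] = t;
    }
    std::swap(prev, cur);
  }

  std::vector<int> ia, ib;
  ia.reserve(n + m); ib.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) { ia.push_back(i); ib.push_back(j); --i; --j; }
    else if (i > 0 && (t == 1 || j == 0)) { ia.push_back(i); ib.push_back(0); --i; }
    else { ia.push_back(0); ib.push_back(j); --j; }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["ia"] = wrap(ia), _["ib"] = wrap(ib));
}
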