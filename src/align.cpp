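// Alignment kernels: local Smith-Waterman with affine gaps (generic alphabet),
// banded end-to-end overlap verification with unit costs, k-mer seed candidate
// detection, and reverse complement. All coordinates returned are 0-based
// half-open; R wrappers keep that convention.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <cmath>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

static void build_lut(const std::string& alphabet, int* lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
}

static std::vector<int> encode(const std::string& s, const int* lut,
                               const char* what) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    if (c < 0)
      stop("character '%c' in %s is not in the alignment alphabet", s[i], what);
    v[i] = c;
  }
  return v;
}

static char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'N': return 'N';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    default:
      stop("cannot complement base '%c'", c);
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// Local Smith-Waterman score only, affine gaps. A gap of length g costs
// gap_open + g * gap_ext (BLAST convention: existence 11, per-residue 1).
// [[Rcpp::export]]
IntegerVector cpp_sw_score(CharacterVector queries, std::string subject,
                           IntegerMatrix submat, std::string alphabet,
                           int gap_open, int gap_ext) {
  int lut[256];
  build_lut(alphabet, lut);
  const int A = (int)alphabet.size();
  std::vector<int> S((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) S[(size_t)i * A + j] = submat(i, j);
  std::vector<int> sv = encode(subject, lut, "subject");
  const int n = (int)sv.size();
  const int gi = gap_open + gap_ext;

  IntegerVector out(queries.size());
  // H holds the previous row's scores and is updated in place; carries for
  // the current row's diagonal/left neighbours live in registers.
  std::vector<int> H(n + 1), F(n + 1);
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::vector<int> qv = encode(qs, lut, "query");
    const int m = (int)qv.size();
    if (m == 0 || n == 0) { out[q] = 0; continue; }
    std::fill(H.begin(), H.end(), 0);
    std::fill(F.begin(), F.end(), NEG_INF);
    int best = 0;
    int* __restrict Hp = H.data();
    int* __restrict Fp = F.data();
    const int* __restrict svp = sv.data();
    for (int i = 1; i <= m; ++i) {
      int Eh = NEG_INF;
      const int* __restrict Srow = &S[(size_t)qv[i - 1] * A];
      int hdiag = Hp[0];    // H[i-1][j-1]
      int hleft = 0;        // H[i][j-1]
      for (int j = 1; j <= n; ++j) {
        int hup = Hp[j];    // H[i-1][j]
        int f = hup - gi;
        int fe = Fp[j] - gap_ext;
        if (fe > f) f = fe;
        Fp[j] = f;
        int e = hleft - gi;
        int ee = Eh - gap_ext;
        if (ee > e) e = ee;
        Eh = e;
        int h = hdiag + Srow[svp[j - 1]];
        if (f > h) h = f;
        if (e > h) h = e;
        if (h < 0) h = 0;
        Hp[j] = h;
        hdiag = hup;
        hleft = h;
        if (h > best) best = h;
      }
    }
    out[q] = best;
  }
  return out;
}

// Local Smith-Waterman with traceback. Returns the single best-scoring local
// alignment: score, spans (0-based half-open) in a and b, matches, columns.
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, IntegerMatrix submat,
                  std::string alphabet, int gap_open, int gap_ext) {
  int lut[256];
  build_lut(alphabet, lut);
  const int A = (int)alphabet.size();
  std::vector<int> S((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) S[(size_t)i * A + j] = submat(i, j);
  std::vector<int> av = encode(a, lut, "a"), bv = encode(b, lut, "b");
  const int m = (int)av.size(), n = (int)bv.size();
  if ((double)(m + 1) * (n + 1) > 5e7)
    stop("sequences too long for full dynamic programming (%d x %d)", m, n);
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["a_lo"] = 0, _["a_hi"] = 0,
                        _["b_lo"] = 0, _["b_hi"] = 0, _["matches"] = 0,
                        _["columns"] = 0);
  const int gi = gap_open + gap_ext;
  const size_t W = (size_t)n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> E(W), Fv(W);
  // trace: 0 stop, 1 diag, 2 from E (left/gap in a), 3 from F (up/gap in b)
  std::vector<uint8_t> tbH((size_t)(m + 1) * W, 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * W, 0); // 1 = extend
  std::vector<uint8_t> tbF((size_t)(m + 1) * W, 0);
  std::fill(Fv.begin(), Fv.end(), NEG_INF);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Eh = NEG_INF;
    const int* Srow = &S[(size_t)av[i - 1] * A];
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int fo = H[prow + j] - gi, fe = Fv[j] - gap_ext;
      if (fe > fo) { Fv[j] = fe; tbF[row + j] = 1; } else Fv[j] = fo;
      int eo = H[row + j - 1] - gi, ee = Eh - gap_ext;
      if (ee > eo) { Eh = ee; tbE[row + j] = 1; } else Eh = eo;
      int d = H[prow + j - 1] + Srow[bv[j - 1]];
      int h = 0; uint8_t t = 0;
      if (d > h) { h = d; t = 1; }
      if (Eh > h) { h = Eh; t = 2; }
      if (Fv[j] > h) { h = Fv[j]; t = 3; }
      H[row + j] = h;
      tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 in H, 2 in E, 3 in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t t = tbH[(size_t)i * W + j];
      if (t == 0) break;
      if (t == 1) {
        ++columns;
        if (av[i - 1] == bv[j - 1]) ++matches;
        --i; --j;
      } else state = (int)t;
    } else if (state == 2) {
      ++columns;
      uint8_t ext = tbE[(size_t)i * W + j];
      --j;
      if (!ext) state = 0;
    } else {
      ++columns;
      uint8_t ext = tbF[(size_t)i * W + j];
      --i;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best, _["a_lo"] = i, _["a_hi"] = bi,
                      _["b_lo"] = j, _["b_hi"] = bj, _["matches"] = matches,
                      _["columns"] = columns);
}

// Banded global (end-to-end) alignment of the overlap region implied by a
// diagonal: oriented b starts at offset `diag` on a. Unit mismatch and indel
// costs; identity is matches / alignment columns. Band is
// max(band_min, ceil(band_frac * overlap_len)), capped at band_cap.
// Returns one row per candidate with matches, columns and the overlap region
// bounds on a and on ORIENTED b (caller converts rc coordinates).
// [[Rcpp::export]]
DataFrame cpp_verify_overlaps(CharacterVector seqs_a, CharacterVector seqs_b,
                              IntegerVector ia, IntegerVector ib,
                              LogicalVector rc_b, IntegerVector diag,
                              int band_min = 10, double band_frac = 0.10,
                              int band_cap = 2000) {
  const R_xlen_t nc = ia.size();
  // cache oriented b strings on demand
  std::vector<std::string> bfwd(seqs_b.size()), brev(seqs_b.size());
  std::vector<char> have_f(seqs_b.size(), 0), have_r(seqs_b.size(), 0);
  IntegerVector o_matches(nc), o_columns(nc), o_alo(nc), o_ahi(nc),
      o_blo(nc), o_bhi(nc);
  std::vector<int> cost_prev, cost_cur;
  std::vector<uint8_t> moves;
  for (R_xlen_t t = 0; t < nc; ++t) {
    std::string a = as<std::string>(seqs_a[ia[t] - 1]);
    int jb = ib[t] - 1;
    const std::string* bp;
    if (rc_b[t]) {
      if (!have_r[jb]) {
        brev[jb] = revcomp_str(as<std::string>(seqs_b[jb]));
        have_r[jb] = 1;
      }
      bp = &brev[jb];
    } else {
      if (!have_f[jb]) {
        bfwd[jb] = as<std::string>(seqs_b[jb]);
        have_f[jb] = 1;
      }
      bp = &bfwd[jb];
    }
    const std::string& b = *bp;
    const int La = (int)a.size(), Lb = (int)b.size(), d = diag[t];
    int a_lo = std::max(0, d), a_hi = std::min(La, d + Lb);
    int b_lo = a_lo - d, b_hi = a_hi - d;
    o_alo[t] = a_lo; o_ahi[t] = a_hi; o_blo[t] = b_lo; o_bhi[t] = b_hi;
    int m = a_hi - a_lo, n = b_hi - b_lo; // equal by construction
    if (m < 1) { o_matches[t] = 0; o_columns[t] = 0; continue; }
    int band = std::max(band_min, (int)std::ceil(band_frac * m));
    if (band > band_cap) band = band_cap;
    const int w = 2 * band + 1;
    cost_prev.assign(w, NEG_INF * -1); // large cost
    cost_cur.assign(w, NEG_INF * -1);
    moves.assign((size_t)(m + 1) * w, 0);
    const int BIG = INT_MAX / 4;
    // cell (i, j) stored at offset j - i + band when |j - i| <= band
    for (int jj = 0; jj < w; ++jj) cost_prev[jj] = BIG;
    for (int j = 0; j <= std::min(n, band); ++j) {
      cost_prev[j + band] = j;
      moves[(size_t)0 * w + j + band] = 3; // left
    }
    for (int i = 1; i <= m; ++i) {
      for (int jj = 0; jj < w; ++jj) cost_cur[jj] = BIG;
      int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
      size_t row = (size_t)i * w;
      for (int j = jlo; j <= jhi; ++j) {
        int off = j - i + band;
        int bestc = BIG; uint8_t mv = 0;
        if (j > 0) { // diag: (i-1, j-1) offset j-1-(i-1)+band = off
          int c = cost_prev[off];
          if (c < BIG) {
            c += (a[a_lo + i - 1] == b[b_lo + j - 1] &&
                  a[a_lo + i - 1] != 'N') ? 0 : 1;
            if (c < bestc) { bestc = c; mv = 1; }
          }
        } else if (i <= band) {
          // j == 0 column: all vertical gaps
          int c = cost_prev[off + 1];
          if (c < BIG && c + 1 < bestc) { bestc = c + 1; mv = 2; }
        }
        if (off + 1 < w) { // up: (i-1, j) offset j-(i-1)+band = off+1
          int c = cost_prev[off + 1];
          if (c < BIG && c + 1 < bestc) { bestc = c + 1; mv = 2; }
        }
        if (off - 1 >= 0 && j > 0) { // left: (i, j-1) offset off-1
          int c = cost_cur[off - 1];
          if (c < BIG && c + 1 < bestc) { bestc = c + 1; mv = 3; }
        }
        cost_cur[off] = bestc;
        moves[row + off] = mv;
      }
      std::swap(cost_prev, cost_cur);
    }
    // traceback from (m, n)
    int i = m, j = n, matches = 0, columns = 0;
    bool ok = std::abs(n - m) <= band;
    while (ok && (i > 0 || j > 0)) {
      int off = j - i + band;
      if (off < 0 || off >= w) { ok = false; break; }
      uint8_t mv = moves[(size_t)i * w + off];
      if (mv == 1) {
        ++columns;
        if (a[a_lo + i - 1] == b[b_lo + j - 1] && a[a_lo + i - 1] != 'N')
          ++matches;
        --i; --j;
      } else if (mv == 2) {
        ++columns; --i;
      } else if (mv == 3) {
        ++columns; --j;
      } else {
        ok = false;
      }
    }
    if (!ok) { matches = 0; columns = std::max(m, n); }
    o_matches[t] = matches;
    o_columns[t] = columns;
  }
  return DataFrame::create(_["matches"] = o_matches, _["columns"] = o_columns,
                           _["a_lo"] = o_alo, _["a_hi"] = o_ahi,
                           _["b_lo"] = o_blo, _["b_hi"] = o_bhi,
                           _["stringsAsFactors"] = false);
}

// Polishing votes: banded alignments of oriented reads against a contig,
// accumulating per-contig-position base votes, deletion votes and
// (single-base) insertion votes from the tracebacks. Candidates are given
// as (ib, rc, diag) triples as elsewhere.
// [[Rcpp::export]]
List cpp_polish_votes(std::string contig, CharacterVector reads,
                      IntegerVector ib, LogicalVector rc_b,
                      IntegerVector diag, int band_min = 10,
                      double band_frac = 0.10, int band_cap = 2000) {
  const int L = (int)contig.size();
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3; code['N'] = 4;
  IntegerVector base_votes(5 * L), del_votes(L), ins_votes(L + 1),
      ins_base(5 * (L + 1));
  std::vector<int> cost_prev, cost_cur;
  std::vector<uint8_t> moves;
  const int BIG = INT_MAX / 4;
  for (R_xlen_t t = 0; t < ib.size(); ++t) {
    std::string b = as<std::string>(reads[ib[t] - 1]);
    if (rc_b[t]) b = revcomp_str(b);
    const int Lb = (int)b.size(), d = diag[t];
    int a_lo = std::max(0, d), a_hi = std::min(L, d + Lb);
    int b_lo = a_lo - d, b_hi = a_hi - d;
    int m = a_hi - a_lo, n = b_hi - b_lo;
    if (m < 1) continue;
    int band = std::max(band_min, (int)std::ceil(band_frac * m));
    if (band > band_cap) band = band_cap;
    const int w = 2 * band + 1;
    cost_prev.assign(w, BIG);
    cost_cur.assign(w, BIG);
    moves.assign((size_t)(m + 1) * w, 0);
    for (int j = 0; j <= std::min(n, band); ++j) {
      cost_prev[j + band] = j;
      moves[(size_t)0 * w + j + band] = 3;
    }
    for (int i = 1; i <= m; ++i) {
      for (int jj = 0; jj < w; ++jj) cost_cur[jj] = BIG;
      int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
      size_t row = (size_t)i * w;
      for (int j = jlo; j <= jhi; ++j) {
        int off = j - i + band;
        int bestc = BIG; uint8_t mv = 0;
        if (j > 0) {
          int c = cost_prev[off];
          if (c < BIG) {
            c += (contig[a_lo + i - 1] == b[b_lo + j - 1] &&
                  contig[a_lo + i - 1] != 'N') ? 0 : 1;
            if (c < bestc) { bestc = c; mv = 1; }
          }
        }
        if (off + 1 < w) {
          int c = cost_prev[off + 1];
          if (c < BIG && c + 1 < bestc) { bestc = c + 1; mv = 2; }
        }
        if (off - 1 >= 0 && j > 0) {
          int c = cost_cur[off - 1];
          if (c < BIG && c + 1 < bestc) { bestc = c + 1; mv = 3; }
        }
        cost_cur[off] = bestc;
        moves[row + off] = mv;
      }
      std::swap(cost_prev, cost_cur);
    }
    if (std::abs(n - m) > band) continue;
    // traceback, recording votes (walk backwards from (m, n))
    int i = m, j = n;
    bool ok = true;
    while (ok && (i > 0 || j > 0)) {
      int off = j - i + band;
      if (off < 0 || off >= w) break;
      uint8_t mv = moves[(size_t)i * w + off];
      if (mv == 1) {
        int bc = code[(unsigned char)b[b_lo + j - 1]];
        if (bc >= 0) base_votes[5 * (a_lo + i - 1) + bc] += 1;
        --i; --j;
      } else if (mv == 2) {        // contig base skipped by the read
        del_votes[a_lo + i - 1] += 1;
        --i;
      } else if (mv == 3) {        // read base inserted before contig pos
        int bc = code[(unsigned char)b[b_lo + j - 1]];
        ins_votes[a_lo + i] += 1;
        if (bc >= 0) ins_base[5 * (a_lo + i) + bc] += 1;
        --j;
      } else ok = false;
    }
  }
  return List::create(_["base_votes"] = base_votes,
                      _["del_votes"] = del_votes,
                      _["ins_votes"] = ins_votes,
                      _["ins_base"] = ins_base);
}

// k-mer seed scan: index seqs_a (forward), scan seqs_b forward and
// reverse-complement; report, per (ia, ib, orientation), the modal diagonal
// (offset of oriented b start on a) and its vote count. With same_set = TRUE
// only pairs ia < ib are reported. k-mers containing non-ACGT are skipped, as
// are index k-mers occurring more than max_occ times.
// [[Rcpp::export]]
DataFrame cpp_seed_pairs(CharacterVector seqs_a, CharacterVector seqs_b,
                         int k = 16, bool same_set = false,
                         int max_occ = 1000, int min_votes = 1) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  index.reserve(1 << 20);
  for (R_xlen_t i = 0; i < seqs_a.size(); ++i) {
    std::string s = as<std::string>(seqs_a[i]);
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = code[(unsigned char)s[p]];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k)
        index[h].push_back(std::make_pair((int)i, p - k + 1));
    }
  }

  std::vector<int> r_ia, r_ib, r_diag, r_votes;
  std::vector<int> r_rc;
  std::unordered_map<uint64_t, int> votes;
  std::unordered_map<int, std::pair<int, int>> best; // ia -> (votes, diag)
  for (R_xlen_t j = 0; j < seqs_b.size(); ++j) {
    std::string sfwd = as<std::string>(seqs_b[j]);
    for (int orient = 0; orient < 2; ++orient) {
      std::string s = orient ? revcomp_str(sfwd) : sfwd;
      votes.clear();
      uint64_t h = 0; int run = 0;
      for (int p = 0; p < (int)s.size(); ++p) {
        int c = code[(unsigned char)s[p]];
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        auto it = index.find(h);
        if (it == index.end()) continue;
        const auto& hits = it->second;
        if ((int)hits.size() > max_occ) continue;
        int pb = p - k + 1;
        for (size_t t = 0; t < hits.size(); ++t) {
          int ia = hits[t].first;
          if (same_set) {
            if (ia == (int)j) continue;
            if (ia > (int)j) continue;
          }
          int d = hits[t].second - pb;
          uint64_t key = ((uint64_t)(uint32_t)ia << 32) |
                         (uint32_t)(d + 0x40000000);
          votes[key] += 1;
        }
      }
      if (votes.empty()) continue;
      best.clear();
      for (auto& kv : votes) {
        int ia = (int)(kv.first >> 32);
        int d = (int)(uint32_t)(kv.first & 0xFFFFFFFFULL) - 0x40000000;
        auto it = best.find(ia);
        if (it == best.end() || kv.second > it->second.first ||
            (kv.second == it->second.first && d < it->second.second))
          best[ia] = std::make_pair(kv.second, d);
      }
      for (auto& kv : best) {
        if (kv.second.first < min_votes) continue;
        r_ia.push_back(kv.first + 1);
        r_ib.push_back((int)j + 1);
        r_rc.push_back(orient);
        r_diag.push_back(kv.second.second);
        r_votes.push_back(kv.second.first);
      }
    }
  }
  return DataFrame::create(_["ia"] = r_ia, _["ib"] = r_ib,
                           _["rc"] = LogicalVector(r_rc.begin(), r_rc.end()),
                           _["diag"] = r_diag, _["votes"] = r_votes,
                           _["stringsAsFactors"] = false);
}
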