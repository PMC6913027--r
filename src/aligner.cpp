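// Core computational routines: reference de Bruijn graph (unitig) index
// construction, l-mer seed lookup, U-MEM extension, affine-gap semi-global
// alignment with traceback, banded unit-cost edit distance, and short-seed
// exon hit scanning. Interval conventions are 0-based half-open throughout;
// conversion to 1-based SAM/GTF coordinates happens in R at the I/O boundary.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <array>
#include <cstdint>
#include <climits>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------------------
// Index construction
// ---------------------------------------------------------------------------

// Build unitigs of the de Bruijn graph over all N-free k-mers of the forward
// genome, plus per-unitig genomic occurrence runs. An occurrence run records
// a maximal stretch of consecutive genome positions whose k-mers map to
// consecutive offsets of one unitig; a run with nk k-mers spells a match of
// nk + k - 1 bases.
// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int k) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> kmers;

  std::vector<std::string> chrom(seqs.size());
  for (int c = 0; c < seqs.size(); ++c) chrom[c] = as<std::string>(seqs[c]);

  // pass 1: collect distinct k-mers
  for (const std::string& s : chrom) {
    uint64_t km = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      if (++valid >= k) kmers.insert(km);
    }
  }

  auto succ = [&](uint64_t km, int b) { return ((km << 2) | (uint64_t)b) & mask; };
  auto pred = [&](uint64_t km, int b) {
    return (km >> 2) | ((uint64_t)b << (2 * (k - 1)));
  };
  auto out_deg = [&](uint64_t km, int* only) {
    int n = 0;
    for (int b = 0; b < 4; ++b)
      if (kmers.count(succ(km, b))) { n++; if (only) *only = b; }
    return n;
  };
  auto in_deg = [&](uint64_t km, int* only) {
    int n = 0;
    for (int b = 0; b < 4; ++b)
      if (kmers.count(pred(km, b))) { n++; if (only) *only = b; }
    return n;
  };

  auto decode = [&](uint64_t km) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = BASES[km & 3]; km >>= 2; }
    return s;
  };

  // kmer -> (uid, offset-within-unitig)
  std::unordered_map<uint64_t, std::pair<int, int>> place;
  place.reserve(kmers.size() * 2);
  std::vector<std::string> unitigs;

  auto walk = [&](uint64_t start) {
    std::string useq = decode(start);
    int uid = (int)unitigs.size();
    place[start] = {uid, 0};
    uint64_t cur = start;
    int off = 0;
    for (;;) {
      int b = -1;
      if (out_deg(cur, &b) != 1) break;
      uint64_t nxt = succ(cur, b);
      if (in_deg(nxt, nullptr) != 1) break;
      if (place.count(nxt)) break;  // closes a cycle
      useq.push_back(BASES[b]);
      place[nxt] = {uid, ++off};
      cur = nxt;
    }
    unitigs.push_back(useq);
  };

  // unitig start nodes: in-degree != 1, or the unique predecessor branches
  for (uint64_t km : kmers) {
    int pb = -1;
    int id = in_deg(km, &pb);
    bool start = (id != 1);
    if (!start) {
      uint64_t p = pred(km, pb);
      start = (out_deg(p, nullptr) != 1);
    }
    if (start && !place.count(km)) walk(km);
  }
  // remaining k-mers lie on pure cycles; break each at an arbitrary node
  for (uint64_t km : kmers) if (!place.count(km)) walk(km);

  // pass 2: occurrence runs
  std::vector<int> r_uid, r_chrom, r_gstart, r_uoff, r_nk;
  for (int c = 0; c < (int)chrom.size(); ++c) {
    const std::string& s = chrom[c];
    uint64_t km = 0; int valid = 0;
    int prev_uid = -1, prev_off = -1;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      bool ok = false; int uid = -1, off = -1;
      if (b < 0) { valid = 0; km = 0; }
      else {
        km = ((km << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          auto it = place.find(km);
          uid = it->second.first; off = it->second.second; ok = true;
        }
      }
      if (ok && uid == prev_uid && off == prev_off + 1) {
        r_nk.back()++;
      } else if (ok) {
        r_uid.push_back(uid); r_chrom.push_back(c);
        r_gstart.push_back((int)i - k + 1); r_uoff.push_back(off);
        r_nk.push_back(1);
      }
      prev_uid = ok ? uid : -1; prev_off = ok ? off : -1;
    }
  }

  return List::create(
    _["unitigs"] = wrap(unitigs),
    _["uid"] = r_uid, _["chrom"] = r_chrom, _["gstart"] = r_gstart,
    _["uoff"] = r_uoff, _["nk"] = r_nk);
}

// ---------------------------------------------------------------------------
// Seed index (l-mer hash over unitigs), held as an external pointer
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k, l;
  std::vector<std::string> unitigs;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> seeds;
  std::vector<char> repetitive;
};

// [[Rcpp::export]]
SEXP cpp_make_seed_index(CharacterVector unitigs, IntegerVector occ_uid,
                         int k, int l, int repeat_cap) {
  SeedIndex* idx = new SeedIndex();
  idx->k = k; idx->l = l;
  idx->unitigs.resize(unitigs.size());
  for (int u = 0; u < unitigs.size(); ++u)
    idx->unitigs[u] = as<std::string>(unitigs[u]);

  std::vector<int> nocc(unitigs.size(), 0);
  for (int i = 0; i < occ_uid.size(); ++i) nocc[occ_uid[i]]++;
  idx->repetitive.resize(unitigs.size(), 0);
  for (size_t u = 0; u < nocc.size(); ++u)
    if (nocc[u] > repeat_cap) idx->repetitive[u] = 1;

  const uint64_t lmask = (1ULL << (2 * l)) - 1;
  for (int u = 0; u < (int)idx->unitigs.size(); ++u) {
    const std::string& s = idx->unitigs[u];
    uint64_t lm = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; lm = 0; continue; }
      lm = ((lm << 2) | (uint64_t)b) & lmask;
      if (++valid >= l) idx->seeds[lm].push_back({u, (int)i - l + 1});
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

static inline bool encode_word(const std::string& s, size_t off, int len,
                               uint64_t* out) {
  uint64_t w = 0;
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[off + i]);
    if (b < 0) return false;
    w = (w << 2) | (uint64_t)b;
  }
  *out = w;
  return true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_lookup_seed(SEXP ptr, std::string seed) {
  XPtr<SeedIndex> idx(ptr);
  if ((int)seed.size() != idx->l) stop("seed length must equal l");
  uint64_t w;
  if (!encode_word(seed, 0, idx->l, &w)) stop("seed contains non-ACGT base");
  auto it = idx->seeds.find(w);
  int n = (it == idx->seeds.end()) ? 0 : (int)it->second.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = it->second[i].first;
    out(i, 1) = it->second[i].second;
  }
  colnames(out) = CharacterVector::create("uid", "uoff");
  return out;
}

// U-MEMs: seeds at read offsets 0, m, 2m, ... are looked up in the l-mer
// table and each hit is extended base-by-base in both directions within the
// read and the unitig. Duplicates found from different seeds collapse onto
// the same maximal block. Hits on highly repetitive unitigs are skipped.
// [[Rcpp::export]]
IntegerMatrix cpp_find_umems(SEXP ptr, std::string read, int m) {
  XPtr<SeedIndex> idx(ptr);
  const int l = idx->l;
  const int rlen = (int)read.size();
  std::unordered_set<uint64_t> seen;
  std::vector<std::array<int, 5>> res;

  for (int off = 0; off + l <= rlen; off += m) {
    uint64_t w;
    if (!encode_word(read, off, l, &w)) continue;  // seed contains N
    auto it = idx->seeds.find(w);
    if (it == idx->seeds.end()) continue;
    for (const auto& hit : it->second) {
      int uid = hit.first;
      if (idx->repetitive[uid]) continue;
      const std::string& u = idx->unitigs[uid];
      int rs = off, re = off + l, us = hit.second, ue = hit.second + l;
      while (rs > 0 && us > 0 && read[rs - 1] == u[us - 1] &&
             base_code(read[rs - 1]) >= 0) { rs--; us--; }
      while (re < rlen && ue < (int)u.size() && read[re] == u[ue] &&
             base_code(read[re]) >= 0) { re++; ue++; }
      uint64_t key = ((uint64_t)uid << 42) | ((uint64_t)us << 21) | (uint64_t)rs;
      if (seen.insert(key).second)
        res.push_back({rs, re, uid, us, ue});
    }
  }
  IntegerMatrix out((int)res.size(), 5);
  for (int i = 0; i < (int)res.size(); ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = res[i][j];
  colnames(out) = CharacterVector::create("rs", "re", "uid", "us", "ue");
  return out;
}

// ---------------------------------------------------------------------------
// Affine-gap semi-global alignment (query end-to-end, reference ends free)
// ---------------------------------------------------------------------------

// Gotoh DP with full traceback. Gap of length L costs go + L*ge (go, ge <= 0).
// Returns the optimal score, a CIGAR over {M,I,D} (I consumes query only),
// and the half-open reference window [ref_start, ref_end) covered.
// [[Rcpp::export]]
List cpp_semiglobal(std::string q, std::string r, int ma, int mi, int go, int ge) {
  const int m = (int)q.size(), n = (int)r.size();
  if (m == 0 || n == 0) stop("empty sequence in semiglobal alignment");
  if ((double)(m + 1) * (n + 1) > 3.2e8)
    stop("alignment problem too large (%d x %d)", m, n);
  const int NEG = INT_MIN / 4;

  std::vector<int> H(n + 1), E(n + 1);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  // tb bits: 0-1 H source (0 diag, 1 from E, 2 from F, 3 stop/boundary),
  //          2 E opened from H, 3 F opened from H
  std::vector<int> Hprev(n + 1);

  for (int j = 0; j <= n; ++j) { H[j] = 0; E[j] = NEG; }
  std::vector<int> Fcol(1, NEG);  // F as a column-wise rolling value per j
  std::vector<int> Fv(n + 1, NEG);

  for (int i = 1; i <= m; ++i) {
    Hprev = H;
    H[0] = go + ge * i;
    E[0] = NEG;
    uint8_t* trow = &tb[(size_t)i * (n + 1)];
    trow[0] = 2;  // from F (leading insertion run)
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (D, consumes reference)
      int e_open = H[j - 1] + go + ge;       // H already updated for row i
      int e_ext = E[j - 1] + ge;
      int e = e_open >= e_ext ? e_open : e_ext;
      uint8_t flags = 0;
      if (e_open >= e_ext) flags |= 4;
      E[j] = e;
      // F: gap in reference (I, consumes query)
      int f_open = Hprev[j] + go + ge;
      int f_ext = Fv[j] + ge;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_open >= f_ext) flags |= 8;
      Fv[j] = f;
      int diag = Hprev[j - 1] + ((q[i - 1] == r[j - 1] &&
                                  base_code(q[i - 1]) >= 0) ? ma : mi);
      int best = diag; uint8_t src = 0;
      if (e > best) { best = e; src = 1; }
      if (f > best) { best = f; src = 2; }
      H[j] = best;
      trow[j] = flags | src;
    }
  }

  int best = H[0], bestj = 0;
  for (int j = 1; j <= n; ++j)
    if (H[j] > best) { best = H[j]; bestj = j; }  // leftmost maximum

  // traceback
  std::string ops;
  int i = m, j = bestj, state = 0;  // 0=H, 1=E (gap in query), 2=F (gap in ref)
  while (i > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) { ops.push_back('M'); i--; j--; }
      else if (src == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      if (t & 4) state = 0;
      j--;
    } else {
      ops.push_back('I');
      if (t & 8) state = 0;
      i--;
    }
  }
  int ref_start = j;

  // run-length encode reversed ops
  std::string cigar;
  int cnt = 0; char cur = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) cnt++;
    else {
      if (cnt > 0) cigar += std::to_string(cnt) + cur;
      cur = *it; cnt = 1;
    }
  }
  if (cnt > 0) cigar += std::to_string(cnt) + cur;

  return List::create(_["score"] = best, _["cigar"] = cigar,
                      _["ref_start"] = ref_start, _["ref_end"] = bestj);
}

// ---------------------------------------------------------------------------
// Banded unit-cost edit distance with alignment-column count
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_edit_stats(std::string a, std::string b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  const int dlo = std::min(0, n - m) - band;
  const int dhi = std::max(0, n - m) + band;
  const int w = dhi - dlo + 1;
  const int INF = INT_MAX / 4;
  std::vector<int> prev(w, INF), cur(w, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * w, 0);  // 0 diag, 1 up, 2 left

  for (int d = 0; d < w; ++d) {
    int j = 0 + d + dlo;
    if (j >= 0 && j <= n) { prev[d] = j; tb[d] = 2; }
  }
  for (int i = 1; i <= m; ++i) {
    uint8_t* trow = &tb[(size_t)i * w];
    for (int d = 0; d < w; ++d) cur[d] = INF;
    for (int d = 0; d < w; ++d) {
      int j = i + d + dlo;
      if (j < 0 || j > n) continue;
      int best = INF; uint8_t t = 0;
      if (j > 0 && prev[d] < INF) {  // diag: (i-1, j-1) same offset
        int v = prev[d] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (v < best) { best = v; t = 0; }
      }
      if (d + 1 < w && prev[d + 1] < INF) {  // up: (i-1, j), delete from a
        int v = prev[d + 1] + 1;
        if (v < best) { best = v; t = 1; }
      }
      if (j > 0 && d - 1 >= 0 && cur[d - 1] < INF) {  // left: (i, j-1)
        int v = cur[d - 1] + 1;
        if (v < best) { best = v; t = 2; }
      }
      if (i > 0 && j == 0) { int v = i; if (v < best) { best = v; t = 1; } }
      cur[d] = best; trow[d] = t;
    }
    std::swap(prev, cur);
  }
  int dfin = n - m - dlo;
  int dist = prev[dfin];
  // traceback to count alignment columns
  int cols = 0, i = m, j = n;
  while (i > 0 || j > 0) {
    int d = j - i - dlo;
    uint8_t t = tb[(size_t)i * w + d];
    cols++;
    if (i == 0) { j--; continue; }
    if (j == 0) { i--; continue; }
    if (t == 0) { i--; j--; }
    else if (t == 1) { i--; }
    else { j--; }
  }
  return IntegerVector::create(dist, cols);
}

// ---------------------------------------------------------------------------
// Short-seed exon hit scan
// ---------------------------------------------------------------------------

// Number of positions of `exon` whose s-mer occurs anywhere in `part`.
// [[Rcpp::export]]
int cpp_smer_hits(std::string part, std::string exon, int s) {
  if ((int)part.size() < s || (int)exon.size() < s) return 0;
  const uint64_t mask = (1ULL << (2 * s)) - 1;
  std::unordered_set<uint64_t> set;
  uint64_t w = 0; int valid = 0;
  for (size_t i = 0; i < part.size(); ++i) {
    int b = base_code(part[i]);
    if (b < 0) { valid = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)b) & mask;
    if (++valid >= s) set.insert(w);
  }
  int hits = 0;
  w = 0; valid = 0;
  for (size_t i = 0; i < exon.size(); ++i) {
    int b = base_code(exon[i]);
    if (b < 0) { valid = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)b) & mask;
    if (++valid >= s && set.count(w)) hits++;
  }
  return hits;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], o;
    switch (c) {
      case 'A': o = 'T'; break; case 'C': o = 'G'; break;
      case 'G': o = 'C'; break; case 'T': o = 'A'; break;
      case 'a': o = 't'; break; case 'c': o = 'g'; break;
      case 'g': o = 'c'; break; case 't': o = 'a'; break;
      default: o = 'N';
    }
    out[i] = o;
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != nullptr;
}

// Diagonals (exon offset minus part offset) of all exon positions whose
// s-mer occurs in the part; used to test diagonal-consistent exon hits.
// [[Rcpp::export]]
IntegerVector cpp_smer_diagonals(std::string part, std::string exon, int s) {
  std::vector<int> out;
  if ((int)part.size() >= s && (int)exon.size() >= s) {
    const uint64_t mask = (1ULL << (2 * s)) - 1;
    std::unordered_map<uint64_t, int> first;
    uint64_t w = 0; int valid = 0;
    for (size_t i = 0; i < part.size(); ++i) {
      int b = base_code(part[i]);
      if (b < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mask;
      if (++valid >= s) first.emplace(w, (int)i - s + 1);
    }
    w = 0; valid = 0;
    for (size_t i = 0; i < exon.size(); ++i) {
      int b = base_code(exon[i]);
      if (b < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mask;
      if (valid++ >= s - 1) {
        auto it = first.find(w);
        if (it != first.end())
          out.push_back((int)i - s + 1 - it->second);
      }
    }
  }
  return wrap(out);
}
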