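// Core loops: 2-bit k-mer codec, banded edit distance, database
// construction and per-read classification, error-model read mutation.
// k is fixed at 32 bases; the stored payload is the last 16 bases
// (SUFFIX), the group key the first n bases (PREFIX).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

static const int KMER_K = 32;
static const int SUFFIX_LEN = 16;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_code(uint64_t code, int len) {
  std::string s(len, 'A');
  for (int i = len - 1; i >= 0; --i) {
    s[i] = CODE2BASE[code & 3u];
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
std::string cpp_decode_code(double code, int len) {
  return decode_code((uint64_t)code, len);
}

// Encode every valid 32-base window of `seq`.  A window is valid when all
// 32 bases are unambiguous A/C/G/T.  Returns 1-based start positions, the
// PREFIX group id (first n bases) and the SUFFIX code (last 16 bases).
// [[Rcpp::export]]
List cpp_encode_windows(std::string seq, int n) {
  const int len = (int)seq.size();
  std::vector<int> pos;
  std::vector<double> gid, suf;
  if (len >= KMER_K) {
    // roll[j] = 2-bit code of the 16 bases ending at j (0-based)
    std::vector<uint32_t> roll(len, 0u);
    uint32_t v = 0;
    int last_bad = -1;
    for (int j = 0; j < len; ++j) {
      int c = base_code(seq[j]);
      if (c < 0) { last_bad = j; c = 0; }
      v = (v << 2) | (uint32_t)c;
      roll[j] = v;
    }
    const int shift_pref = 2 * (SUFFIX_LEN - n);
    for (int p = 0; p + KMER_K <= len; ++p) {
      // bad base anywhere inside [p, p+31] invalidates the window
      if (last_bad >= p) {
        // cheap re-scan only when a bad base exists at/after p
        bool bad = false;
        for (int j = p; j < p + KMER_K; ++j)
          if (base_code(seq[j]) < 0) { bad = true; break; }
        if (bad) continue;
      }
      uint32_t front = roll[p + SUFFIX_LEN - 1];
      uint32_t back = roll[p + KMER_K - 1];
      pos.push_back(p + 1);
      gid.push_back((double)(front >> shift_pref));
      suf.push_back((double)back);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["group_id"] = wrap(gid),
                      _["suffix_code"] = wrap(suf));
}

// ---------------------------------------------------------------------------
// Quick matching: Hamming distance between two m-base 2-bit codes

static inline int qm_hamming(uint32_t a, uint32_t b, int m) {
  uint32_t x = a ^ b;
  x &= (m == 16) ? 0xFFFFFFFFu : ((1u << (2 * m)) - 1u);
  // collapse each 2-bit base to one indicator bit
  uint32_t d = (x | (x >> 1)) & 0x55555555u;
  int cnt = 0;
  while (d) { d &= d - 1; ++cnt; }
  return cnt;
}

// [[Rcpp::export]]
int cpp_qm_hamming(double a, double b, int m) {
  return qm_hamming((uint32_t)a, (uint32_t)b, m);
}

// Match under the seed-mask mechanism: equal, or equal under one of the m
// single-base wildcard masks (guaranteeing >= m-1 equal bases).
// [[Rcpp::export]]
bool cpp_qm_match(double a_, double b_, int m) {
  uint32_t a = (uint32_t)a_, b = (uint32_t)b_;
  if (a == b) return true;
  for (int i = 0; i < m; ++i) {
    uint32_t mask = ~(3u << (2 * i));
    if ((a & mask) == (b & mask)) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Banded edit distance.  `band` is the maximum diagonal offset |i - j|;
// the band therefore spans main diagonal +/- band.  Unit costs.
// Returns cost, or INF_COST when the banded optimum exceeds max_err.

static const int INF_COST = 99;

static int banded_ed_core(const char* q, int nq, const char* r, int nr,
                          int band, int max_err, bool prefix_free) {
  if (!prefix_free && std::abs(nq - nr) > band) return INF_COST;
  std::vector<int> prev(nr + 1, INF_COST), cur(nr + 1, INF_COST);
  for (int j = 0; j <= std::min(nr, band); ++j) prev[j] = j;
  int best_end = prefix_free ? ((nr <= band) ? nr : INF_COST) : INF_COST;
  for (int i = 1; i <= nq; ++i) {
    std::fill(cur.begin(), cur.end(), INF_COST);
    int jlo = std::max(0, i - band), jhi = std::min(nr, i + band);
    int rowmin = INF_COST;
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF_COST;
      if (j == 0) best = i;
      else {
        int d = prev[j - 1] + (q[i - 1] == r[j - 1] ? 0 : 1);
        if (d < best) best = d;
        if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
        if (prev[j] + 1 < best) best = prev[j] + 1;
      }
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (prefix_free && jhi == nr && cur[nr] < best_end) best_end = cur[nr];
    if (rowmin > max_err && (!prefix_free || best_end > max_err))
      return (prefix_free && best_end <= max_err) ? best_end : INF_COST;
    std::swap(prev, cur);
  }
  int ans = prefix_free ? best_end : prev[nr];
  return (ans > max_err) ? INF_COST : ans;
}

// [[Rcpp::export]]
int cpp_banded_edit_cost(std::string q, std::string r, int band, int max_err) {
  return banded_ed_core(q.c_str(), (int)q.size(), r.c_str(), (int)r.size(),
                        band, max_err, false);
}

// Minimum over prefixes of q of the banded edit distance to all of r
// (end gaps on the query side are free beyond the optimal path).
// [[Rcpp::export]]
int cpp_prefix_edit_cost(std::string q, std::string r, int band, int max_err) {
  return banded_ed_core(q.c_str(), (int)q.size(), r.c_str(), (int)r.size(),
                        band, max_err, true);
}

// Full-matrix alignment with traceback for diagnostics: best prefix of q
// against all of r (or full q when prefix_free = false).  Ties prefer the
// diagonal, then consuming more of the query.
// [[Rcpp::export]]
IntegerVector cpp_align_ops(std::string q, std::string r, bool prefix_free) {
  int nq = (int)q.size(), nr = (int)r.size();
  std::vector<std::vector<int> > D(nq + 1, std::vector<int>(nr + 1, 0));
  for (int i = 0; i <= nq; ++i) D[i][0] = i;
  for (int j = 0; j <= nr; ++j) D[0][j] = j;
  for (int i = 1; i <= nq; ++i)
    for (int j = 1; j <= nr; ++j) {
      int d = D[i - 1][j - 1] + (q[i - 1] == r[j - 1] ? 0 : 1);
      d = std::min(d, std::min(D[i - 1][j] + 1, D[i][j - 1] + 1));
      D[i][j] = d;
    }
  int iend = nq;
  if (prefix_free)
    for (int i = nq; i >= 0; --i)
      if (D[i][nr] < D[iend][nr]) iend = i;
  int i = iend, j = nr, nsub = 0, nins = 0, ndel = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i][j] == D[i - 1][j - 1] + (q[i - 1] == r[j - 1] ? 0 : 1)) {
      if (q[i - 1] != r[j - 1]) ++nsub;
      --i; --j;
    } else if (i > 0 && D[i][j] == D[i - 1][j] + 1) {
      ++nins; --i;               // extra query base
    } else {
      ++ndel; --j;               // query missing a reference base
    }
  }
  return IntegerVector::create(_["cost"] = D[iend][nr], _["nsub"] = nsub,
                               _["nins"] = nins, _["ndel"] = ndel);
}

// ---------------------------------------------------------------------------
// Approximate k-mer match of a query fragment against a stored entry.
// `query` holds the read bases from the window start: at least the PREFIX
// and QM fields, and up to 2 bases beyond the nominal 32 to absorb
// deletion-induced frame shift.  Returns c(matched, qm_subs, dp_cost).

static IntegerVector match_fragment(const std::string& query, uint64_t ref_gid,
                                    uint32_t ref_suffix, int n, int m) {
  IntegerVector out = IntegerVector::create(_["matched"] = 0,
                                            _["qm_subs"] = NA_INTEGER,
                                            _["dp_cost"] = NA_INTEGER);
  const int qlen = (int)query.size();
  const int dp_len = SUFFIX_LEN - m;
  if (qlen < SUFFIX_LEN + m) return out;
  // PREFIX must match the group exactly
  uint64_t g = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(query[i]);
    if (c < 0) return out;
    g = (g << 2) | (uint64_t)c;
  }
  if (g != ref_gid) return out;
  // QM: <= 1 substitution among the first m SUFFIX bases
  uint32_t qqm = 0;
  for (int i = SUFFIX_LEN; i < SUFFIX_LEN + m; ++i) {
    int c = base_code(query[i]);
    if (c < 0) return out;
    qqm = (qqm << 2) | (uint32_t)c;
  }
  uint32_t rqm = ref_suffix >> (2 * dp_len);
  int qsubs = qm_hamming(qqm, rqm, m);
  out["qm_subs"] = qsubs;
  if (qsubs > 1) return out;
  // DP: banded edit distance <= 2 on the remaining field, query side
  // taken from the read up to 2 bases past the nominal window end
  std::string rdp = decode_code(ref_suffix & ((dp_len == 16) ? 0xFFFFFFFFu
                                : ((1u << (2 * dp_len)) - 1u)), dp_len);
  int qstart = SUFFIX_LEN + m;
  int qstop = std::min(qlen, KMER_K + 2);
  std::string qdp = query.substr(qstart, qstop - qstart);
  int cost = banded_ed_core(qdp.c_str(), (int)qdp.size(), rdp.c_str(),
                            dp_len, 2, 2, true);
  if (cost <= 2) {
    out["matched"] = 1;
    out["dp_cost"] = cost;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_match_kmer(std::string query, double ref_gid,
                             double ref_suffix, int n, int m) {
  return match_fragment(query, (uint64_t)ref_gid, (uint32_t)ref_suffix, n, m);
}

// ---------------------------------------------------------------------------
// Database construction.  Sequences arrive grouped by species (the R side
// sorts species by taxid and appends reverse complements); k-mers are
// deduplicated within a species, k-mers shared by two species of one genus
// are promoted to the genus taxid (and always retained), k-mers shared
// across genera are dropped, and species-unique k-mers survive only if one
// of their window start positions falls on the selection stride.

struct DbEntry {
  uint64_t key;
  int tax;
  int genus;
  bool selected;
  bool conflict;
  bool genus_level;
};

// [[Rcpp::export]]
List cpp_build_db(CharacterVector seqs, IntegerVector taxid,
                  IntegerVector genus, int n, int stride) {
  const int N = seqs.size();
  std::unordered_map<uint64_t, size_t> idx;
  std::vector<DbEntry> ents;
  int i = 0;
  while (i < N) {
    const int sp = taxid[i];
    const int gn = genus[i];
    std::unordered_map<uint64_t, bool> local;   // key -> any position selected
    std::vector<uint64_t> order;                // deterministic merge order
    for (; i < N && taxid[i] == sp; ++i) {
      std::string s = as<std::string>(seqs[i]);
      List w = cpp_encode_windows(s, n);
      IntegerVector pos = w["pos"];
      NumericVector g = w["group_id"], suf = w["suffix_code"];
      for (int j = 0; j < pos.size(); ++j) {
        uint64_t key = ((uint64_t)g[j] << 32) | (uint64_t)(uint32_t)suf[j];
        bool sel = ((pos[j] - 1) % stride) == 0;
        std::unordered_map<uint64_t, bool>::iterator it = local.find(key);
        if (it == local.end()) {
          local[key] = sel;
          order.push_back(key);
        } else if (sel) {
          it->second = true;
        }
      }
    }
    for (size_t q = 0; q < order.size(); ++q) {
      uint64_t key = order[q];
      bool sel = local[key];
      std::unordered_map<uint64_t, size_t>::iterator it = idx.find(key);
      if (it == idx.end()) {
        DbEntry e; e.key = key; e.tax = sp; e.genus = gn; e.selected = sel;
        e.conflict = false; e.genus_level = false;
        idx[key] = ents.size();
        ents.push_back(e);
      } else {
        DbEntry& e = ents[it->second];
        if (e.conflict) continue;
        if (e.tax == sp && !e.genus_level) { if (sel) e.selected = true; continue; }
        if (e.genus == gn && gn > 0) {
          e.tax = gn; e.genus_level = true; e.selected = true;
        } else {
          e.conflict = true;
        }
      }
    }
  }
  // stable counting sort of surviving entries by group id
  const R_xlen_t ngroups = (R_xlen_t)1 << (2 * n);
  IntegerVector group_size(ngroups, 0);
  size_t kept = 0;
  for (size_t q = 0; q < ents.size(); ++q) {
    const DbEntry& e = ents[q];
    if (e.conflict || !(e.selected || e.genus_level)) continue;
    ++group_size[(R_xlen_t)(e.key >> 32)];
    ++kept;
  }
  std::vector<uint64_t> next(1, 0);
  next.resize((size_t)ngroups, 0);
  uint64_t acc = 0;
  for (R_xlen_t g = 0; g < ngroups; ++g) { next[(size_t)g] = acc; acc += (uint64_t)group_size[g]; }
  NumericVector suffix((R_xlen_t)kept);
  IntegerVector out_tax((R_xlen_t)kept);
  for (size_t q = 0; q < ents.size(); ++q) {
    const DbEntry& e = ents[q];
    if (e.conflict || !(e.selected || e.genus_level)) continue;
    uint64_t slot = next[(size_t)(e.key >> 32)]++;
    suffix[(R_xlen_t)slot] = (double)(uint32_t)(e.key & 0xFFFFFFFFull);
    out_tax[(R_xlen_t)slot] = e.tax;
  }
  return List::create(_["group_size"] = group_size, _["suffix_code"] = suffix,
                      _["taxid"] = out_tax);
}

// ---------------------------------------------------------------------------
// Classification: per read, probe every valid window's group linearly and
// count the first matching entry's taxid.  Returns, per read, the distinct
// hit taxids with counts and the number of windows examined.

// [[Rcpp::export]]
List cpp_classify_hits(CharacterVector reads, IntegerVector group_size,
                       NumericVector offsets, NumericVector suffix,
                       IntegerVector taxid, int n, int m) {
  const int dp_len = SUFFIX_LEN - m;
  const uint32_t dp_mask = (dp_len == 16) ? 0xFFFFFFFFu
                                          : ((1u << (2 * dp_len)) - 1u);
  List out(reads.size());
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string seq = as<std::string>(reads[ri]);
    const int len = (int)seq.size();
    std::unordered_map<int, int> counts;
    std::vector<int> order;
    int nwin = 0;
    if (len >= KMER_K) {
      std::vector<uint32_t> roll(len, 0u);
      std::vector<int> badpos;
      uint32_t v = 0;
      for (int j = 0; j < len; ++j) {
        int c = base_code(seq[j]);
        if (c < 0) { badpos.push_back(j); c = 0; }
        v = (v << 2) | (uint32_t)c;
        roll[j] = v;
      }
      size_t bptr = 0;
      const int shift_pref = 2 * (SUFFIX_LEN - n);
      const int shift_qm = 2 * dp_len;
      for (int p = 0; p + KMER_K <= len; ++p) {
        while (bptr < badpos.size() && badpos[bptr] < p) ++bptr;
        if (bptr < badpos.size() && badpos[bptr] < p + KMER_K) continue;
        ++nwin;
        uint64_t gid = (uint64_t)(roll[p + SUFFIX_LEN - 1] >> shift_pref);
        const int gsz = group_size[(R_xlen_t)gid];
        if (gsz == 0) continue;
        uint64_t off = (uint64_t)offsets[(R_xlen_t)gid];
        uint32_t qsuf = roll[p + KMER_K - 1];
        uint32_t qqm = qsuf >> shift_qm;
        // query DP region, extended up to 2 bases past the window
        int qstart = p + SUFFIX_LEN + m;
        int qstop = std::min(len, p + KMER_K + 2);
        for (int e = 0; e < gsz; ++e) {
          uint32_t rsuf = (uint32_t)suffix[(R_xlen_t)(off + e)];
          int hit_tax = taxid[(R_xlen_t)(off + e)];
          bool matched = false;
          if (rsuf == qsuf) {
            matched = true;
          } else {
            uint32_t rqm = rsuf >> shift_qm;
            if (qm_hamming(qqm, rqm, m) <= 1) {
              uint32_t rdp_code = rsuf & dp_mask;
              uint32_t qdp_code = qsuf & dp_mask;
              if (rdp_code == qdp_code) {
                matched = true;
              } else {
                std::string rdp = decode_code(rdp_code, dp_len);
                int cost = banded_ed_core(seq.c_str() + qstart, qstop - qstart,
                                          rdp.c_str(), dp_len, 2, 2, true);
                matched = (cost <= 2);
              }
            }
          }
          if (matched) {
            std::unordered_map<int, int>::iterator it = counts.find(hit_tax);
            if (it == counts.end()) { counts[hit_tax] = 1; order.push_back(hit_tax); }
            else ++(it->second);
            break;   // first match per window: entries are discriminative
          }
        }
      }
    }
    IntegerVector tx(order.size()), ct(order.size());
    for (size_t q = 0; q < order.size(); ++q) {
      tx[q] = order[q];
      ct[q] = counts[order[q]];
    }
    out[ri] = List::create(_["taxid"] = tx, _["count"] = ct,
                           _["windows"] = nwin);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read simulation: draw a source span and inject per-base errors.
// Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export]]
List cpp_simulate_reads(std::string genome, int n_reads, int read_len,
                        double error_rate, double p_sub, double p_ins,
                        double p_del) {
  const int L = (int)genome.size();
  const int span = L - read_len + 1;
  CharacterVector seqs(n_reads);
  IntegerVector start(n_reads), nsub(n_reads), nins(n_reads), ndel(n_reads);
  std::string buf;
  for (int r = 0; r < n_reads; ++r) {
    int s = (int)(unif_rand() * span);
    if (s >= span) s = span - 1;
    buf.clear();
    buf.reserve(read_len + 8);
    int cs = 0, ci = 0, cd = 0;
    for (int j = 0; j < read_len; ++j) {
      char b = genome[s + j];
      if (error_rate > 0 && unif_rand() < error_rate) {
        double u = unif_rand();
        if (u < p_sub) {
          int orig = base_code(b);
          int nb = (int)(unif_rand() * 3);
          if (nb >= 2) nb = 2;
          int code = (orig + 1 + nb) & 3;   // any of the 3 other bases
          buf.push_back(CODE2BASE[code]);
          ++cs;
        } else if (u < p_sub + p_ins) {
          buf.push_back(b);
          int nb = (int)(unif_rand() * 4);
          if (nb >= 4) nb = 3;
          buf.push_back(CODE2BASE[nb]);
          ++ci;
        } else {
          ++cd;                             // skip the source base
        }
      } else {
        buf.push_back(b);
      }
    }
    seqs[r] = buf;
    start[r] = s + 1;
    nsub[r] = cs; nins[r] = ci; ndel[r] = cd;
  }
  return List::create(_["seq"] = seqs, _["start"] = start, _["n_sub"] = nsub,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}

// [[Rcpp::export]]
std::string cpp_random_genome(int length) {
  std::string s(length, 'A');
  for (int i = 0; i < length; ++i) {
    int c = (int)(unif_rand() * 4);
    if (c >= 4) c = 3;
    s[i] = CODE2BASE[c];
  }
  return s;
}

// Number of positions at which the k-mer starting there is identical in
// both strings (used for the exact-match expectation Monte-Carlo check).
// [[Rcpp::export]]
int cpp_count_exact_matches(std::string a, std::string b, int k) {
  int n = (int)std::min(a.size(), b.size()) - k + 1;
  int cnt = 0;
  for (int p = 0; p < n; ++p) {
    bool ok = true;
    for (int j = 0; j < k; ++j)
      if (a[p + j] != b[p + j]) { ok = false; break; }
    if (ok) ++cnt;
  }
  return cnt;
}
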