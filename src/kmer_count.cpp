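#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3 (U folded to T, case-insensitive).
// -1 marks a symbol outside {A,C,G,T,U}; windows containing one are skipped.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Open-addressing hash table for k-mer counts; keys are 2-bit codes
// (k <= 31 so codes fit in 62 bits), EMPTY sentinel is all-ones.
struct KmerTable {
  std::vector<uint64_t> keys;
  std::vector<int> vals;
  size_t mask, n;
  static constexpr uint64_t EMPTY = ~0ULL;

  explicit KmerTable(size_t expect = 1 << 14) : n(0) {
    size_t cap = 1 << 10;
    while (cap < expect * 2) cap <<= 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, 0);
    mask = cap - 1;
  }
  static inline size_t hash_mix(uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33;
    return (size_t)x;
  }
  void grow() {
    std::vector<uint64_t> ok; ok.swap(keys);
    std::vector<int> ov; ov.swap(vals);
    size_t cap = (mask + 1) << 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, 0);
    mask = cap - 1;
    for (size_t i = 0; i < ok.size(); ++i) {
      if (ok[i] != EMPTY) {
        size_t j = hash_mix(ok[i]) & mask;
        while (keys[j] != EMPTY) j = (j + 1) & mask;
        keys[j] = ok[i]; vals[j] = ov[i];
      }
    }
  }
  inline void add(uint64_t key, int by = 1) {
    size_t j = hash_mix(key) & mask;
    while (true) {
      if (keys[j] == EMPTY) {
        keys[j] = key; vals[j] = by; ++n;
        if (n * 10 > (mask + 1) * 7) grow();
        return;
      }
      if (keys[j] == key) { vals[j] += by; return; }
      j = (j + 1) & mask;
    }
  }
};

// Roll the valid windows of one sequence into the table.
static void count_seq(const char* s, int len, int k, bool canonical,
                      KmerTable& tab) {
  if (len < k) return;
  uint64_t code = 0;
  const uint64_t keep = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // valid bases accumulated in current window
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & keep;
    if (++run >= k) {
      uint64_t key = code;
      if (canonical) {
        uint64_t rc = revcomp_code(code, k);
        if (rc < key) key = rc;
      }
      tab.add(key);
    }
  }
}

static List table_to_list(KmerTable& tab, int k, int min_count) {
  std::vector<std::pair<uint64_t, int> > out;
  out.reserve(tab.n);
  for (size_t i = 0; i < tab.keys.size(); ++i) {
    if (tab.keys[i] != KmerTable::EMPTY && tab.vals[i] >= min_count)
      out.push_back(std::make_pair(tab.keys[i], tab.vals[i]));
  }
  std::sort(out.begin(), out.end());
  CharacterVector kmers(out.size());
  IntegerVector counts(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    kmers[i] = decode_kmer(out[i].first, k);
    counts[i] = out[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// [[Rcpp::export]]
List cpp_count_reads(CharacterVector reads, int k, int min_count,
                     bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerTable tab;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    count_seq(s, (int)LENGTH(STRING_ELT(reads, i)), k, canonical, tab);
  }
  return table_to_list(tab, k, min_count);
}

// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::vector<std::string> out;
  int len = (int)seq.size();
  if (len >= k) {
    out.reserve(len - k + 1);
    uint64_t code = 0;
    const uint64_t keep = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & keep;
      if (++run >= k) out.push_back(decode_kmer(code, k));
    }
  }
  return wrap(out);
}

// Draw reads from weighted transcripts with substitution errors.
// Uses R's RNG so results are reproducible under set.seed().
struct ReadSim {
  const std::vector<std::string>& tx;
  std::vector<double> cum;
  int read_len;
  double err;

  ReadSim(const std::vector<std::string>& tx_, const NumericVector& w,
          int read_len_, double err_)
    : tx(tx_), read_len(read_len_), err(err_) {
    double tot = 0;
    cum.resize(w.size());
    for (R_xlen_t i = 0; i < w.size(); ++i) {
      if (w[i] < 0) stop("negative expression weight");
      tot += w[i];
      cum[i] = tot;
    }
    if (tot <= 0) stop("all expression weights are zero");
    for (size_t i = 0; i < cum.size(); ++i) cum[i] /= tot;
  }
  inline void draw(std::string& buf) {
    double u = unif_rand();
    size_t t = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (t >= tx.size()) t = tx.size() - 1;
    const std::string& s = tx[t];
    int span = (int)s.size() - read_len;
    int pos = (span <= 0) ? 0 : (int)(unif_rand() * (span + 1));
    if (pos > span) pos = span;
    buf.assign(s, pos, read_len);
    int nerr = (err > 0) ? (int)R::rbinom((double)read_len, err) : 0;
    for (int e = 0; e < nerr; ++e) {
      int p = (int)(unif_rand() * read_len);
      if (p >= read_len) p = read_len - 1;
      int cur = base_code(buf[p]);
      int sub = (cur + 1 + (int)(unif_rand() * 3)) & 3;
      buf[p] = BASES[sub];
    }
  }
};

// [[Rcpp::export]]
CharacterVector cpp_simulate_reads(CharacterVector transcripts,
                                   NumericVector weights, int n_reads,
                                   int read_len, double error_rate) {
  std::vector<std::string> tx(transcripts.size());
  for (R_xlen_t i = 0; i < transcripts.size(); ++i)
    tx[i] = as<std::string>(transcripts[i]);
  RNGScope scope;
  ReadSim sim(tx, weights, read_len, error_rate);
  CharacterVector out(n_reads);
  std::string buf;
  for (int i = 0; i < n_reads; ++i) {
    sim.draw(buf);
    out[i] = buf;
  }
  return out;
}

// Generate reads and tally their k-mers without materialising the read set;
// the RNG stream is identical to cpp_simulate_reads for the same inputs, so
// the counts equal what counting the emitted FASTQ would give. Error-free
// reads copy transcript windows verbatim, so their contribution is
// accumulated as position coverage (O(1) per read via a difference array)
// and flushed through precomputed per-position window codes; only reads
// carrying substitution errors are counted window by window.
// [[Rcpp::export]]
List cpp_simulate_count(CharacterVector transcripts, NumericVector weights,
                        int n_reads, int read_len, double error_rate,
                        int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::vector<std::string> tx(transcripts.size());
  for (R_xlen_t i = 0; i < transcripts.size(); ++i)
    tx[i] = as<std::string>(transcripts[i]);
  RNGScope scope;
  ReadSim sim(tx, weights, read_len, error_rate);
  KmerTable tab;

  // per-transcript window codes and coverage difference arrays
  const uint64_t keep = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<std::vector<uint64_t> > codes(tx.size());
  std::vector<std::vector<double> > covdiff(tx.size());
  for (size_t t = 0; t < tx.size(); ++t) {
    int len = (int)tx[t].size();
    int nwin = len - k + 1;
    if (nwin > 0) {
      codes[t].resize(nwin);
      uint64_t code = 0;
      for (int i = 0; i < len; ++i) {
        code = ((code << 2) | (uint64_t)base_code(tx[t][i])) & keep;
        if (i >= k - 1) codes[t][i - k + 1] = code;
      }
      covdiff[t].assign(nwin + 1, 0.0);
    }
  }

  std::string buf;
  for (int i = 0; i < n_reads; ++i) {
    double u = unif_rand();
    size_t t = std::lower_bound(sim.cum.begin(), sim.cum.end(), u) -
               sim.cum.begin();
    if (t >= tx.size()) t = tx.size() - 1;
    int span = (int)tx[t].size() - read_len;
    int pos = (span <= 0) ? 0 : (int)(unif_rand() * (span + 1));
    if (pos > span) pos = span;
    int nerr = (error_rate > 0) ? (int)R::rbinom((double)read_len, error_rate)
                                : 0;
    if (nerr == 0) {
      int first = pos, last = pos + read_len - k;  // window starts
      if (last >= first && !covdiff[t].empty()) {
        covdiff[t][first] += 1.0;
        covdiff[t][last + 1] -= 1.0;
      }
    } else {
      buf.assign(tx[t], pos, read_len);
      for (int e = 0; e < nerr; ++e) {
        int p = (int)(unif_rand() * read_len);
        if (p >= read_len) p = read_len - 1;
        int cur = base_code(buf[p]);
        int sub = (cur + 1 + (int)(unif_rand() * 3)) & 3;
        buf[p] = BASES[sub];
      }
      count_seq(buf.c_str(), (int)buf.size(), k, false, tab);
    }
  }
  for (size_t t = 0; t < tx.size(); ++t) {
    double cov = 0;
    for (size_t p = 0; p < codes[t].size(); ++p) {
      cov += covdiff[t][p];
      if (cov > 0) tab.add(codes[t][p], (int)(cov + 0.5));
    }
  }
  List counts = table_to_list(tab, k, min_count);
  counts["total_bp"] = (double)n_reads * (double)read_len;
  return counts;
}
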