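#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else breaks the current k-mer.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline std::string decode_kmer(uint64_t x, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static inline uint64_t encode_kmer(const char* s, int k) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("non-ACGT base in k-mer string");
    x = (x << 2) | (uint64_t)c;
  }
  return x;
}

// Walk a sequence emitting canonical k-mers; k-mers spanning a non-ACGT
// character are skipped. Template over a callback to share the rolling logic.
template <typename F>
static void for_each_canonical(const char* s, R_xlen_t n, int k, F&& emit) {
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fw = 0, rc = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fw = 0; rc = 0; continue; }
    fw = ((fw << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) emit(fw < rc ? fw : rc);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, int min_count) {
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t km) { ++counts[km]; });
  }
  std::vector<std::pair<uint64_t, int>> kept;
  kept.reserve(counts.size());
  for (const auto& kv : counts)
    if (kv.second >= min_count) kept.push_back(kv);
  std::sort(kept.begin(), kept.end());
  R_xlen_t m = (R_xlen_t)kept.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = decode_kmer(kept[i].first, k);
    count[i] = kept[i].second;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// [[Rcpp::export]]
List cpp_classify_reads(CharacterVector reads, CharacterVector mat_markers,
                        CharacterVector pat_markers, int k) {
  std::unordered_set<uint64_t> mat, pat;
  mat.reserve(mat_markers.size() * 2 + 1);
  pat.reserve(pat_markers.size() * 2 + 1);
  for (R_xlen_t i = 0; i < mat_markers.size(); ++i) {
    if (LENGTH(STRING_ELT(mat_markers, i)) != k) stop("marker length != k");
    mat.insert(encode_kmer(CHAR(STRING_ELT(mat_markers, i)), k));
  }
  for (R_xlen_t i = 0; i < pat_markers.size(); ++i) {
    if (LENGTH(STRING_ELT(pat_markers, i)) != k) stop("marker length != k");
    pat.insert(encode_kmer(CHAR(STRING_ELT(pat_markers, i)), k));
  }
  R_xlen_t n = reads.size();
  IntegerVector c_mat(n), c_pat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = LENGTH(STRING_ELT(reads, i));
    int cm = 0, cp = 0;
    for_each_canonical(s, len, k, [&](uint64_t km) {
      if (mat.count(km)) ++cm;
      if (pat.count(km)) ++cp;
    });
    c_mat[i] = cm;
    c_pat[i] = cp;
  }
  return List::create(_["c_mat"] = c_mat, _["c_pat"] = c_pat);
}
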