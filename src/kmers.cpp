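#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else is invalid.
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

static inline std::string decode_kmer(uint64_t enc, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[enc & 3ULL];
    enc >>= 2;
  }
  return s;
}

// Count canonical k-mers (lexicographic min of forward / reverse complement)
// across a set of sequences. Windows containing a non-ACGT base are skipped.
// k must be in [2, 32] so a k-mer fits one 64-bit word.
// [[Rcpp::export(name = ".kmer_count_cpp")]]
List kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 2 || k > 32) stop("k must be in [2, 32]");
  std::unordered_map<uint64_t, int> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) continue;
    const char *seq = CHAR(seqs[s]);
    size_t n = LENGTH(STRING_ELT(seqs, s));
    if ((int)n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending at i
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << rc_shift);
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rev);
        ++counts[canon];
      }
    }
  }
  R_xlen_t m = (R_xlen_t)counts.size();
  std::vector<std::pair<uint64_t, int> > items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  CharacterVector kmers(m);
  IntegerVector cnt(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmers[i] = decode_kmer(items[i].first, k);
    cnt[i] = items[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

// Canonical (lexicographic min of self / reverse complement) form of each
// string; any length, N-containing strings returned with revcomp N kept.
// [[Rcpp::export(name = ".canonical_kmers_cpp")]]
CharacterVector canonical_kmers_cpp(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(kmers[i]);
    size_t len = LENGTH(STRING_ELT(kmers, i));
    rc.assign(len, 'N');
    for (size_t j = 0; j < len; ++j) rc[len - 1 - j] = comp_base(s[j]);
    if (rc.compare(0, len, s, len) < 0) out[i] = rc;
    else out[i] = kmers[i];
  }
  return out;
}

// All k-length windows of one sequence in order (canonical if canonical=TRUE);
// windows containing non-ACGT are NA.
// [[Rcpp::export(name = ".kmer_windows_cpp")]]
CharacterVector kmer_windows_cpp(std::string seq, int k, bool canonical) {
  if (k < 2) stop("k must be >= 2");
  R_xlen_t n = (R_xlen_t)seq.size();
  if (n < k) return CharacterVector(0);
  CharacterVector out(n - k + 1);
  std::string rc(k, 'N');
  for (R_xlen_t i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j) if (base_code(seq[i + j]) < 0) { ok = false; break; }
    if (!ok) { out[i] = NA_STRING; continue; }
    if (canonical) {
      for (int j = 0; j < k; ++j) rc[k - 1 - j] = comp_base(seq[i + j]);
      if (rc.compare(0, k, seq, i, k) < 0) { out[i] = rc; continue; }
    }
    out[i] = seq.substr(i, k);
  }
  return out;
}
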