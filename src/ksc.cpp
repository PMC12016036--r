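#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// K-mer score chain (KSC) consensus.
//
// Each column p of the pileup holds the alleles observed across reads
// ("A".."T", "-" for deletion, or anchor+insertion string). A node is a
// (position, allele) pair; its score is
//   score(p, a) = max_b [ score(p-1, b) + count(chain-mer(b..a)) ] - depth(p)
// where the chain-mer is the tuple of the last chain_k alleles along b's
// best path ending in a, and its count is the number of reads whose alleles
// match the whole tuple at those columns. The first column's score is the
// allele's supporter count minus the column depth. Each node remembers the
// suffix of its own best path, so the transition chain-mer is determined by
// the predecessor's traceback (Viterbi-style approximation of the full
// chain state space).
//
// Ties in the max prefer the predecessor allele equal to the reference base
// at p-1, then the lexicographically smaller allele; the final node is
// chosen the same way. Zero-coverage columns emit the reference base with
// support 0.

struct Column {
  std::vector<std::string> alleles;          // sorted unique allele strings
  std::vector<std::vector<int> > supporters; // sorted read indices, parallel
  int depth;
};

static inline int find_allele(const Column &col, const std::string &a) {
  for (size_t i = 0; i < col.alleles.size(); ++i)
    if (col.alleles[i] == a) return (int)i;
  return -1;
}

static inline bool read_has(const Column &col, const std::string &a, int r) {
  int ai = find_allele(col, a);
  if (ai < 0) return false;
  const std::vector<int> &v = col.supporters[ai];
  return std::binary_search(v.begin(), v.end(), r);
}

// [[Rcpp::export(name = ".ksc_core_cpp")]]
List ksc_core_cpp(std::string ref, List read_alleles, IntegerVector read_starts,
                  int chain_k) {
  const int L = (int)ref.size();
  const int n_reads = read_alleles.size();
  if (L == 0) stop("empty reference sequence");
  if (chain_k < 2) stop("chain_k must be >= 2");

  // --- bucket alleles by column ------------------------------------------
  std::vector<std::unordered_map<std::string, std::vector<int> > > colmap(L);
  for (int r = 0; r < n_reads; ++r) {
    CharacterVector al = read_alleles[r];
    int s = read_starts[r];
    for (int j = 0; j < al.size(); ++j) {
      int p = s + j;
      if (p < 0 || p >= L) stop("read allele outside contig bounds");
      colmap[p][std::string(CHAR(al[j]))].push_back(r);
    }
  }
  std::vector<Column> cols(L);
  for (int p = 0; p < L; ++p) {
    Column &c = cols[p];
    c.depth = 0;
    std::vector<std::string> keys;
    for (std::unordered_map<std::string, std::vector<int> >::iterator it =
           colmap[p].begin(); it != colmap[p].end(); ++it)
      keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());
    for (size_t i = 0; i < keys.size(); ++i) {
      std::vector<int> &v = colmap[p][keys[i]];
      std::sort(v.begin(), v.end());
      c.depth += (int)v.size();
      c.alleles.push_back(keys[i]);
      c.supporters.push_back(v);
    }
    if (c.alleles.empty()) { // zero coverage: reference pseudo-allele
      c.alleles.push_back(std::string(1, ref[p]));
      c.supporters.push_back(std::vector<int>());
    }
    colmap[p].clear();
  }
  { std::vector<std::unordered_map<std::string, std::vector<int> > > tmp;
    colmap.swap(tmp); }

  // --- DP ------------------------------------------------------------------
  // global node store for traceback
  std::vector<int> node_pos, node_parent;
  std::vector<std::string> node_allele;
  std::vector<double> node_support;

  struct Live {
    int id;                           // index into node store
    double score;
    std::vector<std::string> suffix;  // last <= chain_k-1 alleles incl. own
  };
  std::vector<Live> prev, cur;

  for (int p = 0; p < L; ++p) {
    const Column &col = cols[p];
    cur.clear();
    std::string refprev = (p > 0) ? std::string(1, ref[p - 1]) : std::string();
    for (size_t ai = 0; ai < col.alleles.size(); ++ai) {
      const std::string &a = col.alleles[ai];
      const std::vector<int> &sup = col.supporters[ai];
      double best = 0.0;
      int best_prev = -1; // index into prev
      if (p == 0) {
        best = (double)sup.size();
      } else {
        bool have = false;
        for (size_t bi = 0; bi < prev.size(); ++bi) {
          // chain = prev.suffix + a, clipped to last chain_k entries
          const std::vector<std::string> &sfx = prev[bi].suffix;
          int take = std::min((int)sfx.size(), chain_k - 1);
          // count reads supporting a at p whose alleles match the suffix
          int cnt = 0;
          for (size_t si = 0; si < sup.size(); ++si) {
            int r = sup[si];
            bool ok = true;
            for (int j = 1; j <= take; ++j) {
              const Column &cq = cols[p - j];
              if (!read_has(cq, sfx[sfx.size() - j], r)) { ok = false; break; }
            }
            if (ok) ++cnt;
          }
          double cand = prev[bi].score + (double)cnt;
          bool better = false;
          if (!have || cand > best) better = true;
          else if (cand == best) {
            const std::string &ba = node_allele[prev[bi].id];
            const std::string &ca = node_allele[prev[best_prev].id];
            if (ba == refprev && ca != refprev) better = true;
            else if ((ba == refprev) == (ca == refprev) && ba < ca) better = true;
          }
          if (better) { best = cand; best_prev = (int)bi; have = true; }
        }
      }
      double score = best - (double)col.depth;
      double support = (col.depth > 0) ? (double)sup.size() / col.depth : 0.0;

      Live lv;
      lv.id = (int)node_pos.size();
      lv.score = score;
      if (best_prev >= 0) {
        lv.suffix = prev[best_prev].suffix;
        if ((int)lv.suffix.size() >= chain_k - 1)
          lv.suffix.erase(lv.suffix.begin(),
                          lv.suffix.end() - (chain_k - 2));
      }
      lv.suffix.push_back(a);

      node_pos.push_back(p);
      node_allele.push_back(a);
      node_parent.push_back(best_prev >= 0 ? prev[best_prev].id : -1);
      node_support.push_back(support);
      cur.push_back(lv);
    }
    prev.swap(cur);
  }

  // --- pick final node -----------------------------------------------------
  std::string reflast(1, ref[L - 1]);
  int best_i = 0;
  for (size_t i = 1; i < prev.size(); ++i) {
    const Live &cand = prev[i], &inc = prev[best_i];
    bool better = false;
    if (cand.score > inc.score) better = true;
    else if (cand.score == inc.score) {
      const std::string &ba = node_allele[cand.id];
      const std::string &ca = node_allele[inc.id];
      if (ba == reflast && ca != reflast) better = true;
      else if ((ba == reflast) == (ca == reflast) && ba < ca) better = true;
    }
    if (better) best_i = (int)i;
  }

  // --- traceback -----------------------------------------------------------
  CharacterVector out_allele(L);
  NumericVector out_support(L);
  IntegerVector out_depth(L);
  int id = prev[best_i].id;
  for (int p = L - 1; p >= 0; --p) {
    out_allele[p] = node_allele[id];
    out_support[p] = node_support[id];
    out_depth[p] = cols[p].depth;
    id = node_parent[id];
  }

  std::string consensus;
  consensus.reserve(L + 16);
  for (int p = 0; p < L; ++p) {
    const char *a = CHAR(out_allele[p]);
    if (a[0] == '-' && a[1] == '\0') continue;
    consensus.append(a);
  }

  return List::create(_["consensus"] = consensus,
                      _["allele"] = out_allele,
                      _["support"] = out_support,
                      _["depth"] = out_depth,
                      _["final_score"] = prev[best_i].score);
}
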