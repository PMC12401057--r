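#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Seed-and-extend all-mapping of reads against padded allele sequences.
//
// Semantics mirror an end-to-end all-mapper run with N-in-reference free:
// the read aligns globally, the placement on the allele is free, mismatches
// cost 1 except against reference N (cost 0), gaps cost 1 per base.  Only
// the best placement per (read, allele, strand) is kept; forward wins ties.
//
// Seeding: exact k-mers (default k = 15) looked up in an index of the
// allele cores; verification is a semi-global DP over a window around the
// seeded diagonals.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

struct Hit { int dist; int start; };

// Semi-global DP of read (global) against ref window [w0, w1); returns best
// distance and 0-based start of the alignment on the full allele.
// Reference 'N' matches anything at zero cost.  Alignment starts are
// restricted to [s0, s1] (anchoring to the seeded diagonals); without the
// restriction a read could slide entirely into an N flank for free.
static Hit align_window(const std::string& read, const std::string& ref,
                        int w0, int w1, int s0, int s1, int cap) {
  int m = read.size();
  int L = w1 - w0;
  const int BIG = 1 << 28;
  std::vector<int> dp(L + 1), ndp(L + 1), st(L + 1), nst(L + 1);
  for (int j = 0; j <= L; ++j) {
    int pos = w0 + j;
    dp[j] = (pos >= s0 && pos <= s1) ? 0 : BIG;
    st[j] = j;
  }
  for (int i = 1; i <= m; ++i) {
    ndp[0] = dp[0] >= BIG ? BIG : dp[0] + 1; nst[0] = 0;
    int rowmin = ndp[0];
    for (int j = 1; j <= L; ++j) {
      char rc = ref[w0 + j - 1];
      int sub = (rc == 'N' || rc == read[i - 1]) ? 0 : 1;
      int best = dp[j - 1] + sub;   // diagonal
      int bs = st[j - 1];
      if (dp[j] + 1 < best) { best = dp[j] + 1; bs = st[j]; }       // del in ref / ins in read
      if (ndp[j - 1] + 1 < best) { best = ndp[j - 1] + 1; bs = nst[j - 1]; } // gap in read
      ndp[j] = best; nst[j] = bs;
      if (best < rowmin) rowmin = best;
    }
    std::swap(dp, ndp); std::swap(st, nst);
    if (rowmin > cap) return Hit{cap + 1, -1};
  }
  Hit h{cap + 1, -1};
  for (int j = 0; j <= L; ++j) {
    if (dp[j] < h.dist) { h.dist = dp[j]; h.start = w0 + st[j]; }
  }
  return h;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector read_ids, CharacterVector read_seqs,
                        CharacterVector allele_ids, CharacterVector allele_seqs,
                        int k, int max_distance, int band, int seed_stride) {
  int n_alleles = allele_seqs.size();
  std::vector<std::string> refs(n_alleles);
  for (int a = 0; a < n_alleles; ++a) refs[a] = as<std::string>(allele_seqs[a]);

  // k-mer index over alleles (skip k-mers containing N)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int a = 0; a < n_alleles; ++a) {
    const std::string& s = refs[a];
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back({a, (int)p - k + 1});
    }
  }

  std::vector<std::string> out_read, out_allele;
  std::vector<int> out_dist, out_start;
  std::vector<std::string> out_strand;

  int n_reads = read_seqs.size();
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int m = fwd.size();
    // per-allele best over both strands
    std::unordered_map<int, std::pair<Hit, char>> best;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = strand == 0 ? fwd : revcomp(fwd);
      // collect seeded diagonal ranges per allele
      std::unordered_map<int, std::pair<int, int>> diag; // allele -> [min,max] start estimate
      uint64_t key = 0; int run = 0;
      for (int p = 0; p + 1 <= m; ++p) {
        int b = base2bits(rd[p]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= k && ((p - k + 1) % seed_stride == 0)) {
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (auto& hit : it->second) {
            int est = hit.second - (p - k + 1); // estimated alignment start
            auto d = diag.find(hit.first);
            if (d == diag.end()) diag[hit.first] = {est, est};
            else {
              d->second.first = std::min(d->second.first, est);
              d->second.second = std::max(d->second.second, est);
            }
          }
        }
      }
      for (auto& dv : diag) {
        int a = dv.first;
        int L = refs[a].size();
        int s0 = std::max(0, dv.second.first - band);
        int s1 = std::min(L - 1, dv.second.second + band);
        int w0 = s0;
        int w1 = std::min(L, s1 + m + band);
        if (w1 <= w0) continue;
        Hit h = align_window(rd, refs[a], w0, w1, s0, s1, max_distance);
        if (h.dist > max_distance) continue;
        auto cur = best.find(a);
        if (cur == best.end() || h.dist < cur->second.first.dist) {
          best[a] = {h, strand == 0 ? '+' : '-'};
        }
      }
    }
    std::vector<int> keys;
    for (auto& kv : best) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    for (int a : keys) {
      out_read.push_back(as<std::string>(read_ids[r]));
      out_allele.push_back(as<std::string>(allele_ids[a]));
      out_dist.push_back(best[a].first.dist);
      out_start.push_back(best[a].first.start);
      out_strand.push_back(std::string(1, best[a].second));
    }
  }
  return DataFrame::create(_["read_id"] = out_read, _["allele_id"] = out_allele,
                           _["edit_distance"] = out_dist, _["start"] = out_start,
                           _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}

// Plain semi-global edit distance of a read against one reference (both
// given directly); exposed for the SAM-adapter path and small utilities.
// [[Rcpp::export(name = ".semiglobal_distance_cpp")]]
List semiglobal_distance_cpp(std::string read, std::string ref, int cap) {
  Hit h = align_window(read, ref, 0, ref.size(), 0, ref.size(), cap);
  return List::create(_["edit_distance"] = h.dist, _["start"] = h.start);
}
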