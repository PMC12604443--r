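// Canonical k-mer machinery shared by read clustering, tandem detection and
// read masking. 2-bit encoding, k <= 31. Non-ACGT positions invalidate every
// k-mer overlapping them.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int BASE_CODE[256] = {
    // 'A'=0 'C'=1 'G'=2 'T'=3, everything else -1
#define X -1
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
    X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X
#undef X
};

static const char BASE_CHAR[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canon_code(uint64_t code, int k) {
  uint64_t rc = revcomp_code(code, k);
  return code < rc ? code : rc;
}

// number of mismatching base positions between two 2-bit encoded k-mers
static inline int code_mismatches(uint64_t a, uint64_t b) {
  uint64_t x = a ^ b;
  uint64_t y = (x | (x >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(y);
#else
  int n = 0;
  while (y) { y &= y - 1; ++n; }
  return n;
#endif
}

// append all valid forward-strand k-mer codes of seq to out
static void seq_kmers(const char* s, int len, int k, std::vector<uint64_t>& out) {
  if (len < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int c = BASE_CODE[(unsigned char)s[i]];
    if (c < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++valid >= k) out.push_back(cur);
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASE_CHAR[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".cpp_kmer_edges")]]
IntegerMatrix cpp_kmer_edges(CharacterVector reads, int k, int min_shared,
                             double max_pair_instances, double adaptive_frac) {
  const int n = reads.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  // distinct canonical k-mers per read, concatenated with offsets
  std::vector<uint64_t> km;
  std::vector<uint32_t> owner;
  std::vector<int> n_distinct(n, 0);
  std::vector<uint64_t> buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    buf.clear();
    seq_kmers(s, len, k, buf);
    for (auto& c : buf) c = canon_code(c, k);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    n_distinct[i] = (int)buf.size();
    for (uint64_t c : buf) { km.push_back(c); owner.push_back((uint32_t)i); }
  }
  // sort postings by k-mer
  std::vector<size_t> idx(km.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return km[a] < km[b]; });
  // guardrail on pair-instance volume
  double total_pairs = 0;
  for (size_t i = 0; i < idx.size();) {
    size_t j = i;
    while (j < idx.size() && km[idx[j]] == km[idx[i]]) ++j;
    double m = (double)(j - i);
    total_pairs += m * (m - 1) / 2.0;
    i = j;
  }
  if (total_pairs > max_pair_instances)
    stop("k-mer co-occurrence volume (%.3g read pairs) exceeds the memory guardrail "
         "(%.3g); subsample the read set explicitly before clustering",
         total_pairs, max_pair_instances);
  // emit pair codes
  std::vector<uint64_t> pairs;
  pairs.reserve((size_t)total_pairs);
  for (size_t i = 0; i < idx.size();) {
    size_t j = i;
    while (j < idx.size() && km[idx[j]] == km[idx[i]]) ++j;
    for (size_t a = i; a < j; ++a)
      for (size_t b = a + 1; b < j; ++b) {
        uint32_t ra = owner[idx[a]], rb = owner[idx[b]];
        if (ra == rb) continue;
        uint32_t lo = ra < rb ? ra : rb, hi = ra < rb ? rb : ra;
        pairs.push_back(((uint64_t)lo << 32) | hi);
      }
    i = j;
  }
  std::sort(pairs.begin(), pairs.end());
  // run-length count, keep >= min_shared
  std::vector<uint32_t> from, to;
  std::vector<int> cnt;
  for (size_t i = 0; i < pairs.size();) {
    size_t j = i;
    while (j < pairs.size() && pairs[j] == pairs[i]) ++j;
    int c = (int)(j - i);
    // low-complexity reads (tandem arrays of short monomers) may hold fewer
    // than min_shared distinct k-mers in total; require a high fraction of
    // the smaller read's repertoire instead
    uint32_t ra = (uint32_t)(pairs[i] >> 32), rb = (uint32_t)(pairs[i] & 0xffffffffULL);
    int lo_n = std::min(n_distinct[ra], n_distinct[rb]);
    int thr = std::min(min_shared,
                       (int)std::ceil(adaptive_frac * (double)lo_n));
    if (thr < 1) thr = 1;
    if (c >= thr) {
      from.push_back((uint32_t)(pairs[i] >> 32));
      to.push_back((uint32_t)(pairs[i] & 0xffffffffULL));
      cnt.push_back(c);
    }
    i = j;
  }
  IntegerMatrix out(from.size(), 3);
  for (size_t i = 0; i < from.size(); ++i) {
    out(i, 0) = (int)from[i] + 1;  // 1-based read indices
    out(i, 1) = (int)to[i] + 1;
    out(i, 2) = cnt[i];
  }
  colnames(out) = CharacterVector::create("from", "to", "shared");
  return out;
}

// [[Rcpp::export(name = ".cpp_kmer_counts")]]
List cpp_kmer_counts(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, double> counts;
  std::vector<uint64_t> buf;
  for (int i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    buf.clear();
    seq_kmers(s, len, k, buf);
    for (uint64_t c : buf) counts[canon_code(c, k)] += 1.0;
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmer(keys.size());
  NumericVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    count[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Greedy heaviest-successor walk on the (canonical-weighted) de Bruijn graph.
// Starts from the n_starts heaviest canonical k-mers, both orientations, and
// returns the best simple cycle found (max cycle mass; ties -> shorter monomer,
// then lexicographically smaller monomer).
// [[Rcpp::export(name = ".cpp_dominant_cycle")]]
List cpp_dominant_cycle(CharacterVector kmers, NumericVector counts, int k,
                        int n_starts, int max_steps) {
  const int n = kmers.size();
  std::unordered_map<uint64_t, double> w;
  w.reserve(n * 2);
  double total_mass = 0;
  std::vector<std::pair<double, uint64_t>> ranked;
  ranked.reserve(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t)BASE_CODE[(unsigned char)s[j]];
    uint64_t cc = canon_code(code, k);
    w[cc] = counts[i];
    total_mass += counts[i];
    ranked.push_back(std::make_pair(-counts[i], cc));
  }
  std::sort(ranked.begin(), ranked.end());
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  double best_mass = -1;
  std::string best_monomer;
  int starts = std::min(n_starts, (int)ranked.size());
  for (int si = 0; si < starts; ++si) {
    uint64_t canon = ranked[si].second;
    uint64_t orients[2] = {canon, revcomp_code(canon, k)};
    for (int oi = 0; oi < 2; ++oi) {
      uint64_t cur = orients[oi];
      std::unordered_map<uint64_t, int> seen;  // oriented code -> step
      std::vector<uint64_t> path;
      seen[cur] = 0;
      path.push_back(cur);
      int cyc_start = -1;
      for (int step = 0; step < max_steps; ++step) {
        double bw = 0;
        uint64_t bn = 0;
        bool found = false;
        for (uint64_t b = 0; b < 4; ++b) {
          uint64_t nxt = ((cur << 2) | b) & mask;
          auto it = w.find(canon_code(nxt, k));
          if (it != w.end() && it->second > bw) {
            bw = it->second; bn = nxt; found = true;
          }
        }
        if (!found) break;  // dead end: linear structure
        auto it = seen.find(bn);
        if (it != seen.end()) { cyc_start = it->second; break; }
        seen[bn] = (int)path.size();
        path.push_back(bn);
        cur = bn;
      }
      if (cyc_start < 0) continue;
      // cycle = path[cyc_start .. end]
      std::vector<uint64_t> cyc_canon;
      std::string monomer;
      for (size_t i = cyc_start; i < path.size(); ++i) {
        cyc_canon.push_back(canon_code(path[i], k));
        monomer.push_back(BASE_CHAR[path[i] & 3ULL]);
      }
      std::sort(cyc_canon.begin(), cyc_canon.end());
      cyc_canon.erase(std::unique(cyc_canon.begin(), cyc_canon.end()), cyc_canon.end());
      double mass = 0;
      for (uint64_t c : cyc_canon) mass += w[c];
      bool better = mass > best_mass ||
        (mass == best_mass && (monomer.size() < best_monomer.size() ||
          (monomer.size() == best_monomer.size() && monomer < best_monomer)));
      if (better) { best_mass = mass; best_monomer = monomer; }
    }
  }
  if (best_mass < 0)
    return List::create(_["monomer"] = R_NilValue, _["cycle_mass"] = 0.0,
                        _["total_mass"] = total_mass);
  return List::create(_["monomer"] = best_monomer, _["cycle_mass"] = best_mass,
                      _["total_mass"] = total_mass);
}

// Mass of k-mers attributable to the monomer ring: a k-mer counts if it lies
// within max_mismatch of some cyclic k-mer of the monomer (either strand).
// [[Rcpp::export(name = ".cpp_mass_near_cycle")]]
double cpp_mass_near_cycle(CharacterVector kmers, NumericVector counts,
                           std::string monomer, int k, int max_mismatch) {
  const int L = (int)monomer.size();
  if (L < 1) return 0.0;
  // cyclic k-mers of the monomer, both strands
  std::string doubled = monomer;
  while ((int)doubled.size() < L + k) doubled += monomer;
  std::vector<uint64_t> targets;
  for (int i = 0; i < L; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = BASE_CODE[(unsigned char)doubled[i + j]];
      if (c < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    targets.push_back(code);
    targets.push_back(revcomp_code(code, k));
  }
  std::sort(targets.begin(), targets.end());
  targets.erase(std::unique(targets.begin(), targets.end()), targets.end());
  double mass = 0;
  for (int i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t)BASE_CODE[(unsigned char)s[j]];
    int best = k + 1;
    for (uint64_t t : targets) {
      int m = code_mismatches(code, t);
      if (m < best) best = m;
      if (best == 0) break;
    }
    if (best <= max_mismatch) mass += counts[i];
  }
  return mass;
}

// Ungapped local alignment of reads against reference concatemers with a
// shared-k-mer pre-screen. For every read, candidate (reference, strand)
// pairs sharing >= screen_min_hits k-mers are aligned on all diagonals
// (match +1 / mismatch -1, best-scoring run per diagonal); the single best
// hit per read is returned (ties: forward strand, then lower reference
// index). Transitions/transversions are counted over the winning window.
// [[Rcpp::export(name = ".cpp_mask_best_hits")]]
DataFrame cpp_mask_best_hits(CharacterVector reads, CharacterVector refs,
                             int screen_k, int screen_min_hits) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::vector<uint64_t>> ref_sets(nf);
  std::vector<std::string> ref_str(nf);
  for (int f = 0; f < nf; ++f) {
    ref_str[f] = std::string(CHAR(STRING_ELT(refs, f)));
    std::vector<uint64_t> buf;
    seq_kmers(ref_str[f].c_str(), (int)ref_str[f].size(), screen_k, buf);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    ref_sets[f] = buf;
  }
  std::vector<int> out_read, out_ref, out_score, out_aligned, out_ts, out_tv;
  std::vector<std::string> out_strand;
  std::vector<uint64_t> buf;
  std::string rc;
  for (int i = 0; i < nr; ++i) {
    std::string rd(CHAR(STRING_ELT(reads, i)));
    const int lr = (int)rd.size();
    rc.assign(rd.rbegin(), rd.rend());
    for (auto& ch : rc) {
      switch (ch) {
        case 'A': ch = 'T'; break; case 'T': ch = 'A'; break;
        case 'C': ch = 'G'; break; case 'G': ch = 'C'; break;
        default: break;
      }
    }
    buf.clear();
    seq_kmers(rd.c_str(), lr, screen_k, buf);
    int best_score = 0, best_ref = -1, best_d = 0, best_s = 0, best_e = 0;
    bool best_fwd = true;
    for (int f = 0; f < nf; ++f) {
      int hits_f = 0, hits_r = 0;
      for (uint64_t c : buf) {
        if (std::binary_search(ref_sets[f].begin(), ref_sets[f].end(), c)) ++hits_f;
        if (std::binary_search(ref_sets[f].begin(), ref_sets[f].end(),
                               revcomp_code(c, screen_k))) ++hits_r;
      }
      const std::string& rs = ref_str[f];
      const int ls = (int)rs.size();
      for (int strand = 0; strand < 2; ++strand) {
        if ((strand == 0 ? hits_f : hits_r) < screen_min_hits) continue;
        const std::string& q = strand == 0 ? rd : rc;
        for (int d = -(lr - 1); d < ls; ++d) {
          int i0 = std::max(0, -d), i1 = std::min(lr, ls - d);
          int run = 0, run_start = i0, sc;
          for (int p = i0; p < i1; ++p) {
            sc = (q[p] == rs[p + d]) ? 1 : -1;
            if (run <= 0) { run = sc; run_start = p; }
            else run += sc;
            // strict improvement only: ties keep the earliest candidate
            // (forward strand, lower reference index) because of loop order
            if (run > best_score) {
              best_score = run; best_ref = f; best_d = d;
              best_s = run_start; best_e = p + 1; best_fwd = (strand == 0);
            }
          }
        }
      }
    }
    if (best_ref < 0) continue;
    const std::string& q = best_fwd ? rd : rc;
    const std::string& rs = ref_str[best_ref];
    int ts = 0, tv = 0;
    for (int p = best_s; p < best_e; ++p) {
      char a = q[p], b = rs[p + best_d];
      if (a == b) continue;
      bool pa = (a == 'A' || a == 'G'), pb = (b == 'A' || b == 'G');
      if (pa == pb) ++ts; else ++tv;
    }
    out_read.push_back(i + 1);
    out_ref.push_back(best_ref + 1);
    out_strand.push_back(best_fwd ? "+" : "-");
    out_score.push_back(best_score);
    out_aligned.push_back(best_e - best_s);
    out_ts.push_back(ts);
    out_tv.push_back(tv);
  }
  return DataFrame::create(_["read_idx"] = out_read, _["ref_idx"] = out_ref,
                           _["strand"] = out_strand, _["score"] = out_score,
                           _["aligned_bases"] = out_aligned,
                           _["n_transitions"] = out_ts,
                           _["n_transversions"] = out_tv,
                           _["stringsAsFactors"] = false);
}

// Shared-k-mer screen of reads against reference sequences. Returns two
// integer matrices (n_reads x n_refs): counts of the read's forward-strand
// k-mers found in the reference, and of its reverse-complement k-mers.
// [[Rcpp::export(name = ".cpp_screen_reads")]]
List cpp_screen_reads(CharacterVector reads, CharacterVector refs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::vector<uint64_t>> ref_sets(nf);
  for (int f = 0; f < nf; ++f) {
    std::vector<uint64_t> buf;
    seq_kmers(CHAR(STRING_ELT(refs, f)), LENGTH(STRING_ELT(refs, f)), k, buf);
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    ref_sets[f] = buf;
  }
  IntegerMatrix fwd(nr, nf), rev(nr, nf);
  std::vector<uint64_t> buf;
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    seq_kmers(CHAR(STRING_ELT(reads, i)), LENGTH(STRING_ELT(reads, i)), k, buf);
    for (uint64_t c : buf) {
      uint64_t rc = revcomp_code(c, k);
      for (int f = 0; f < nf; ++f) {
        const std::vector<uint64_t>& set = ref_sets[f];
        if (std::binary_search(set.begin(), set.end(), c)) fwd(i, f)++;
        if (std::binary_search(set.begin(), set.end(), rc)) rev(i, f)++;
      }
    }
  }
  return List::create(_["fwd"] = fwd, _["rev"] = rev);
}
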