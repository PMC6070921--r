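#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// ---- sequence utilities -----------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp(s);
  }
  return out;
}

static inline bool base2bits(char c, uint64_t& v) {
  switch (c) {
    case 'A': v = 0; return true; case 'C': v = 1; return true;
    case 'G': v = 2; return true; case 'T': v = 3; return true;
    default: return false;
  }
}

// Hamming distance of `read` against `sig` at `off` (read fully inside sig),
// early abort once `cap` is exceeded (returns cap + 1).
static inline int hamming_at(const std::string& read, const std::string& sig,
                             int off, int cap) {
  int mm = 0;
  const int L = (int) read.size();
  for (int i = 0; i < L; ++i) {
    if (read[i] != sig[off + i]) { if (++mm > cap) return cap + 1; }
  }
  return mm;
}

// ---- junction signature assignment ------------------------------------------
//
// Assignment contract (shared by the production matcher and the oracle):
// a valid alignment places the read fully inside one signature, ungapped, on
// either strand, with <= max_mm mismatches, and covers >= min_overhang bases
// on each side of the signature's exon-exon boundary. A read is assigned to
// the single signature achieving the minimum mismatch count over all valid
// alignments; ties across distinct signatures leave the read unassigned.
//
// Return codes per read: 1..K signature index, 0 = no valid alignment,
// -1 = ambiguous (tied best across >= 2 signatures).

static const int SEED_K = 16;

struct SigIndex {
  // packed 16-mer -> (signature, position) occurrences
  std::unordered_multimap<uint64_t, std::pair<int, int> > map;
};

static bool pack_kmer(const std::string& s, int pos, int k, uint64_t& key) {
  uint64_t v = 0, b;
  for (int i = 0; i < k; ++i) {
    if (!base2bits(s[pos + i], b)) return false;
    v = (v << 2) | b;
  }
  key = v;
  return true;
}

static void build_index(const std::vector<std::string>& sigs, SigIndex& idx) {
  for (size_t s = 0; s < sigs.size(); ++s) {
    const std::string& sig = sigs[s];
    if ((int) sig.size() < SEED_K) continue;
    for (int p = 0; p + SEED_K <= (int) sig.size(); ++p) {
      uint64_t key;
      if (pack_kmer(sig, p, SEED_K, key))
        idx.map.insert(std::make_pair(key, std::make_pair((int) s, p)));
    }
  }
}

struct BestHit {
  int best_mm;
  std::vector<int> sigs;  // distinct signatures achieving best_mm
  BestHit(int cap) : best_mm(cap + 1) {}
  void offer(int sig, int mm) {
    if (mm < best_mm) { best_mm = mm; sigs.clear(); sigs.push_back(sig); }
    else if (mm == best_mm) {
      for (size_t i = 0; i < sigs.size(); ++i) if (sigs[i] == sig) return;
      sigs.push_back(sig);
    }
  }
};

static inline bool overhang_ok(int jo, int off, int L, int min_over) {
  return (jo - off) >= min_over && (off + L - jo) >= min_over;
}

static void try_candidate(const std::string& rd, const std::string& sig,
                          int sig_i, int off, int jo, int min_over, int max_mm,
                          BestHit& best) {
  const int L = (int) rd.size();
  if (off < 0 || off + L > (int) sig.size()) return;
  if (!overhang_ok(jo, off, L, min_over)) return;
  int mm = hamming_at(rd, sig, off, max_mm);
  if (mm <= max_mm) best.offer(sig_i, mm);
}

// Seed-and-extend matcher: split the read into (max_mm + 1) chunks; by
// pigeonhole at least one chunk of any alignment with <= max_mm mismatches is
// error-free, so an exact 16-mer at some chunk start locates it in the index.
// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector sigs,
                               IntegerVector junction_offset, int min_overhang,
                               int max_mm) {
  const int K = (int) sigs.size();
  std::vector<std::string> S(K);
  for (int i = 0; i < K; ++i) S[i] = as<std::string>(sigs[i]);
  SigIndex idx;
  build_index(S, idx);

  IntegerVector out(reads.size());
  std::vector<int64_t> tried;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int) fwd.size();
    BestHit best(max_mm);
    int n_chunks = max_mm + 1;
    int chunk = L / n_chunks;
    bool seedable = chunk >= SEED_K;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = (strand == 0) ? fwd : revcomp(fwd);
      if (seedable) {
        tried.clear();
        for (int c = 0; c < n_chunks; ++c) {
          int s = c * chunk;
          uint64_t key;
          if (!pack_kmer(rd, s, SEED_K, key)) continue;
          auto range = idx.map.equal_range(key);
          for (auto it = range.first; it != range.second; ++it) {
            int sig_i = it->second.first;
            int off = it->second.second - s;
            int64_t tag = (int64_t) sig_i * 1000000 + (off + 1000);
            bool seen = false;
            for (size_t t = 0; t < tried.size(); ++t)
              if (tried[t] == tag) { seen = true; break; }
            if (seen) continue;
            tried.push_back(tag);
            try_candidate(rd, S[sig_i], sig_i, off, junction_offset[sig_i],
                          min_overhang, max_mm, best);
          }
        }
      } else {
        // reads too short to seed safely: exhaustive scan
        for (int sig_i = 0; sig_i < K; ++sig_i)
          for (int off = 0; off + L <= (int) S[sig_i].size(); ++off)
            try_candidate(rd, S[sig_i], sig_i, off, junction_offset[sig_i],
                          min_overhang, max_mm, best);
      }
    }
    if (best.best_mm > max_mm) out[r] = 0;
    else if (best.sigs.size() == 1) out[r] = best.sigs[0] + 1;
    else out[r] = -1;
  }
  return out;
}

// Brute-force oracle: every signature, every contained offset, both strands,
// full Hamming scan. Same contract, no index, no seeding.
// [[Rcpp::export]]
IntegerVector cpp_assign_reads_oracle(CharacterVector reads, CharacterVector sigs,
                                      IntegerVector junction_offset,
                                      int min_overhang, int max_mm) {
  const int K = (int) sigs.size();
  std::vector<std::string> S(K);
  for (int i = 0; i < K; ++i) S[i] = as<std::string>(sigs[i]);
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int) fwd.size();
    BestHit best(max_mm);
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = (strand == 0) ? fwd : revcomp(fwd);
      for (int sig_i = 0; sig_i < K; ++sig_i) {
        const std::string& sg = S[sig_i];
        for (int off = 0; off + L <= (int) sg.size(); ++off) {
          if (!overhang_ok(junction_offset[sig_i], off, L, min_overhang)) continue;
          int mm = hamming_at(rd, sg, off, max_mm);
          if (mm <= max_mm) best.offer(sig_i, mm);
        }
      }
    }
    if (best.best_mm > max_mm) out[r] = 0;
    else if (best.sigs.size() == 1) out[r] = best.sigs[0] + 1;
    else out[r] = -1;
  }
  return out;
}

// ---- alignment verification and pileup --------------------------------------

// Mismatches of each (reference-oriented) read against the locus at its
// recorded start; strand "-" reads are reverse-complemented first.
// Out-of-range placements return cap + 1.
// [[Rcpp::export]]
IntegerVector cpp_contig_mismatch(CharacterVector seqs, IntegerVector starts,
                                  CharacterVector strands, std::string ref,
                                  int cap) {
  const int refL = (int) ref.size();
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (as<std::string>(strands[i]) == "-") s = revcomp(s);
    int st = starts[i];
    int L = (int) s.size();
    if (st < 0 || st + L > refL) { out[i] = cap + 1; continue; }
    int mm = 0;
    for (int j = 0; j < L; ++j) {
      if (s[j] != ref[st + j]) { if (++mm > cap) break; }
    }
    out[i] = mm > cap ? cap + 1 : mm;
  }
  return out;
}

// Base counts per position over [lo, hi): rows A, C, G, T, depth.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector seqs, IntegerVector starts,
                         CharacterVector strands, int lo, int hi) {
  const int W = hi - lo;
  IntegerMatrix out(5, W);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (as<std::string>(strands[i]) == "-") s = revcomp(s);
    int st = starts[i];
    for (int j = 0; j < (int) s.size(); ++j) {
      int pos = st + j;
      if (pos < lo || pos >= hi) continue;
      int col = pos - lo;
      out(4, col) += 1;
      switch (s[j]) {
        case 'A': out(0, col) += 1; break;
        case 'C': out(1, col) += 1; break;
        case 'G': out(2, col) += 1; break;
        case 'T': out(3, col) += 1; break;
        default: break;
      }
    }
  }
  return out;
}

// ---- split-read alignment ----------------------------------------------------

struct SegCand {
  int pos;                    // start (fwd arrays) or end (bwd arrays)
  int len;                    // maximal extension length
  std::vector<int> mm_at;     // mismatch offsets from the anchored end
  int mm_before(int m) const {  // mismatches within the first m bases
    int k = 0;
    for (size_t i = 0; i < mm_at.size(); ++i) if (mm_at[i] < m) ++k;
    return k;
  }
};

// maximal forward extensions: seq[0:m] vs ref[p:p+m], m maximal with <= max_mm
static void fwd_ext(const std::string& seq, const std::string& ref, int max_mm,
                    int min_len, std::vector<SegCand>& out) {
  const int L = (int) seq.size(), refL = (int) ref.size();
  for (int p = 0; p + min_len <= refL; ++p) {
    int mm = 0, m = 0;
    int lim = std::min(L, refL - p);
    std::vector<int> mm_at;
    for (int i = 0; i < lim; ++i) {
      if (seq[i] != ref[p + i]) {
        if (++mm > max_mm) break;
        mm_at.push_back(i);
      }
      m = i + 1;
    }
    if (m >= min_len) {
      SegCand c; c.pos = p; c.len = m; c.mm_at = mm_at; out.push_back(c);
    }
  }
}

// maximal backward extensions: seq[L-m:L] vs ref[e-m:e], m maximal;
// mismatch offsets are counted from the read's 3' end
static void bwd_ext(const std::string& seq, const std::string& ref, int max_mm,
                    int min_len, std::vector<SegCand>& out) {
  const int L = (int) seq.size(), refL = (int) ref.size();
  for (int e = min_len; e <= refL; ++e) {
    int mm = 0, m = 0;
    int lim = std::min(L, e);
    std::vector<int> mm_at;
    for (int i = 0; i < lim; ++i) {
      if (seq[L - 1 - i] != ref[e - 1 - i]) {
        if (++mm > max_mm) break;
        mm_at.push_back(i);
      }
      m = i + 1;
    }
    if (m >= min_len) {
      SegCand c; c.pos = e; c.len = m; c.mm_at = mm_at; out.push_back(c);
    }
  }
}

static bool full_maps(const std::string& seq, const std::string& ref, int cap) {
  const int L = (int) seq.size(), refL = (int) ref.size();
  for (int p = 0; p + L <= refL; ++p) {
    if (hamming_at(seq, ref, p, cap) <= cap) return true;
  }
  return false;
}

// Exhaustive ungapped two-segment split alignment of one read against the
// panel reference (either strand per segment). Returns the best split:
// read[0:s] as segment A, read[s:] as segment B, breakpoints on the junction-
// adjacent boundaries, leftmost split under junction micro-homology.
// [[Rcpp::export]]
List cpp_split_align(std::string read, std::string ref, int min_segment,
                     int max_mm_seg, int max_normal_gap, int contig_max_mm) {
  const int L = (int) read.size();
  std::string rc = revcomp(read);
  if (full_maps(read, ref, contig_max_mm) || full_maps(rc, ref, contig_max_mm))
    return List::create(_["found"] = false, _["contiguous"] = true);

  // prefix candidates: read[0:m]
  std::vector<SegCand> pre_plus, pre_minus_raw, suf_plus_raw, suf_minus_raw;
  fwd_ext(read, ref, max_mm_seg, min_segment, pre_plus);        // pos = start p
  bwd_ext(rc, ref, max_mm_seg, min_segment, pre_minus_raw);     // pos = end e; read[0:m] maps '-' at [e-m, e)
  bwd_ext(read, ref, max_mm_seg, min_segment, suf_plus_raw);    // pos = end e; read[L-m:L] maps '+' at [e-m, e)
  fwd_ext(rc, ref, max_mm_seg, min_segment, suf_minus_raw);     // pos = start p; read[L-m:L] maps '-' at [p, p+m)

  struct Cand {
    int s; int bpA; int bpB; char strA; char strB; int support; int mm;
  };
  bool have = false;
  Cand best; best.s = 0; best.bpA = 0; best.bpB = 0; best.strA = '+';
  best.strB = '+'; best.support = -1; best.mm = 1 << 30;

  // iterate prefix x suffix candidate pairs; within a pair the split is the
  // leftmost position minimising total mismatches (micro-homology rule)
  for (int pa = 0; pa < 2; ++pa) {
    const std::vector<SegCand>& P = (pa == 0) ? pre_plus : pre_minus_raw;
    char strA = (pa == 0) ? '+' : '-';
    for (size_t i = 0; i < P.size(); ++i) {
      for (int sb = 0; sb < 2; ++sb) {
        const std::vector<SegCand>& Sv = (sb == 0) ? suf_plus_raw : suf_minus_raw;
        char strB = (sb == 0) ? '+' : '-';
        for (size_t j = 0; j < Sv.size(); ++j) {
          int a_len = P[i].len, b_len = Sv[j].len;
          if (a_len + b_len < L) continue;
          int s_lo = std::max(min_segment, L - b_len);
          int s_hi = std::min(a_len, L - min_segment);
          if (s_lo > s_hi) continue;
          int s = s_lo, mm_best = 1 << 30;
          for (int cand_s = s_lo; cand_s <= s_hi; ++cand_s) {
            int mm_tot = P[i].mm_before(cand_s) +
              Sv[j].mm_before(L - cand_s);
            if (mm_tot < mm_best) { mm_best = mm_tot; s = cand_s; }
          }
          int b = L - s;
          int bpA, bpB;
          if (strA == '+') bpA = P[i].pos + s;         // boundary after prefix
          else             bpA = P[i].pos - s;          // left end of '-' prefix
          if (strB == '+') bpB = Sv[j].pos - b;         // left end of '+' suffix
          else             bpB = Sv[j].pos + b;         // boundary after '-' suffix
          // reject splits explainable as a contiguous alignment with a tiny gap
          if (strA == strB) {
            long gap = (strA == '+') ? (long) bpB - bpA : (long) bpA - bpB;
            if (gap >= -max_normal_gap && gap <= max_normal_gap) continue;
          }
          int support = a_len + b_len;
          if (!have || mm_best < best.mm ||
              (mm_best == best.mm && support > best.support) ||
              (mm_best == best.mm && support == best.support &&
               bpA < best.bpA)) {
            have = true;
            best.s = s; best.bpA = bpA; best.bpB = bpB;
            best.strA = strA; best.strB = strB; best.support = support;
            best.mm = mm_best;
          }
        }
      }
    }
  }
  if (!have) return List::create(_["found"] = false, _["contiguous"] = false);
  return List::create(
    _["found"] = true, _["contiguous"] = false,
    _["split_pos"] = best.s,
    _["breakpoint_a"] = best.bpA, _["breakpoint_b"] = best.bpB,
    _["strand_a"] = std::string(1, best.strA),
    _["strand_b"] = std::string(1, best.strB),
    _["matched"] = best.support);
}
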