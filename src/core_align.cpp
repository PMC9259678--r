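#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Alignment scoring used throughout: match +2, mismatch -1, linear gap -3.
// Among equal-score alignments the one with the most matched bases is taken,
// so identity = matches / shorter-length is well defined.
static const int MATCH = 2;
static const int MISMATCH = -1;
static const int GAP = -3;

// base encoding: A=0 C=1 G=2 T=3 N=4 (N never matches, not even N vs N)
static inline std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = 4; break;
    }
  }
  return v;
}

static inline std::vector<uint8_t> revcomp_enc(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (3 - b) : 4;
  }
  return r;
}

// Semi-global alignment: the pattern p (caller passes the shorter sequence)
// is aligned end to end; leading and trailing bases of the subject s are
// free. Returns (best score, matched bases in the best-scoring alignment
// with maximal matches).
// Cells are packed as score*PACK + matches (0 <= matches < PACK), so the
// lexicographic (score, then matches) maximum is a single int64 comparison.
static const long long PACK = 1LL << 21;

static void semiglobal_matches(const std::vector<uint8_t>& p,
                               const std::vector<uint8_t>& s,
                               int& best_score, int& best_matches) {
  const int m = (int)p.size(), n = (int)s.size();
  const long long D_MATCH = (long long)MATCH * PACK + 1;
  const long long D_MISMATCH = (long long)MISMATCH * PACK;
  const long long D_GAP = (long long)GAP * PACK;
  std::vector<long long> prev(n + 1, 0), cur(n + 1);
  for (int i = 1; i <= m; ++i) {
    cur[0] = (long long)i * D_GAP;
    const uint8_t pc = p[i - 1];
    long long left = cur[0];
    for (int j = 1; j <= n; ++j) {
      const long long diag = prev[j - 1] +
        ((pc < 4 && pc == s[j - 1]) ? D_MATCH : D_MISMATCH);
      long long v = prev[j] + D_GAP;
      if (diag > v) v = diag;
      const long long lft = left + D_GAP;
      if (lft > v) v = lft;
      cur[j] = v; left = v;
    }
    std::swap(prev, cur);
  }
  long long best = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] > best) best = prev[j];
  long long matches = ((best % PACK) + PACK) % PACK;
  best_matches = (int)matches;
  best_score = (int)((best - matches) / PACK);
}

// [[Rcpp::export]]
List pair_identity_cpp(std::string a, std::string b, bool reverse) {
  std::vector<uint8_t> ea = encode_seq(a), eb = encode_seq(b);
  if (reverse) eb = revcomp_enc(eb);
  const bool a_shorter = ea.size() <= eb.size();
  const std::vector<uint8_t>& p = a_shorter ? ea : eb;
  const std::vector<uint8_t>& s = a_shorter ? eb : ea;
  int score, matches;
  semiglobal_matches(p, s, score, matches);
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["identity"] = (double)matches / (double)p.size());
}

// ---- k-mer machinery ------------------------------------------------------

static inline bool kmer_at(const std::vector<uint8_t>& v, int pos, int k,
                           uint32_t& out) {
  uint32_t x = 0;
  for (int i = 0; i < k; ++i) {
    uint8_t b = v[pos + i];
    if (b >= 4) return false;
    x = (x << 2) | b;
  }
  out = x;
  return true;
}

static inline uint32_t revcomp_kmer(uint32_t x, int k) {
  uint32_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (x & 3u)); x >>= 2; }
  return r;
}

static inline uint32_t canonical_kmer(uint32_t x, int k) {
  uint32_t r = revcomp_kmer(x, k);
  return x < r ? x : r;
}

// distinct canonical k-mers of a sequence
static std::unordered_set<uint32_t> canon_kmer_set(const std::vector<uint8_t>& v,
                                                   int k) {
  std::unordered_set<uint32_t> out;
  if ((int)v.size() >= k)
    for (int p = 0; p + k <= (int)v.size(); ++p) {
      uint32_t x;
      if (kmer_at(v, p, k, x)) out.insert(canonical_kmer(x, k));
    }
  return out;
}

// number of k-mer start positions (valid, N-free) in a sequence
static int valid_kmer_positions(const std::vector<uint8_t>& v, int k) {
  int n = 0;
  for (int p = 0; p + k <= (int)v.size(); ++p) {
    uint32_t x;
    if (kmer_at(v, p, k, x)) ++n;
  }
  return n;
}

// Lossless prefilter bound (substitution-budget argument): an alignment with
// identity >= c over the shorter length Ls leaves at most floor((1-c)*Ls)
// non-matching shorter positions, each destroying at most k shared k-mers,
// so at least valid_kmers - k*budget distinct shared k-mer positions remain.
static inline int prefilter_bound(int valid_kmers, int Ls, int k, double c) {
  int budget = (int)std::floor((1.0 - c) * (double)Ls + 1e-12);
  long long b = (long long)valid_kmers - (long long)k * budget;
  return b < 1 ? 1 : (int)b;
}

// ---- greedy incremental clustering ---------------------------------------
// Sequences must arrive pre-sorted (descending length, ties ascending id).

// [[Rcpp::export]]
List greedy_cluster_cpp(CharacterVector seqs, double identity_min, int kmer_size,
                        bool both_strands, bool best_hit, bool use_prefilter) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_seq(as<std::string>(seqs[i]));

  std::unordered_map<uint32_t, std::vector<int> > index; // canon kmer -> rep ids
  std::vector<int> reps;                                  // founding order
  IntegerVector assign(n);
  NumericVector ident(n);
  CharacterVector strand(n);
  std::vector<int> shared(n, 0), touched;

  for (int i = 0; i < n; ++i) {
    const std::vector<uint8_t>& q = enc[i];
    const int Ls = (int)q.size();
    // candidate representatives via shared canonical k-mers
    touched.clear();
    int n_valid = 0;
    if ((int)q.size() >= kmer_size) {
      std::unordered_set<uint32_t> seen;
      for (int p = 0; p + kmer_size <= (int)q.size(); ++p) {
        uint32_t x;
        if (!kmer_at(q, p, kmer_size, x)) continue;
        ++n_valid;
        uint32_t cx = canonical_kmer(x, kmer_size);
        if (!seen.insert(cx).second) continue; // count distinct query k-mers once
        std::unordered_map<uint32_t, std::vector<int> >::iterator it = index.find(cx);
        if (it == index.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int r = it->second[t];
          if (shared[r] == 0) touched.push_back(r);
          shared[r]++;
        }
      }
    }
    const int bound = prefilter_bound(n_valid, Ls, kmer_size, identity_min);

    int best_rep = -1; double best_ident = -1.0; bool best_rev = false;
    std::vector<int> cand;
    if (use_prefilter) {
      for (size_t t = 0; t < touched.size(); ++t)
        if (shared[touched[t]] >= bound) cand.push_back(touched[t]);
      std::sort(cand.begin(), cand.end()); // founding order == index order
    } else {
      cand = reps;
    }
    std::vector<uint8_t> qr;
    for (size_t t = 0; t < cand.size(); ++t) {
      int r = cand[t];
      int score, matches;
      semiglobal_matches(q, enc[r], score, matches);
      double idf = (double)matches / (double)Ls;
      double idr = -1.0;
      // the reverse strand only needs evaluating when the forward strand
      // does not already qualify (or when hunting the best hit)
      if (both_strands && (best_hit || idf < identity_min)) {
        if (qr.empty()) qr = revcomp_enc(q);
        semiglobal_matches(qr, enc[r], score, matches);
        idr = (double)matches / (double)Ls;
      }
      bool rev = idr > idf;
      double idbest = rev ? idr : idf;
      if (idbest >= identity_min) {
        if (!best_hit) { best_rep = r; best_ident = idbest; best_rev = rev; break; }
        if (idbest > best_ident) { best_rep = r; best_ident = idbest; best_rev = rev; }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) shared[touched[t]] = 0;

    if (best_rep < 0) {
      // found a new cluster
      reps.push_back(i);
      assign[i] = i + 1; ident[i] = 1.0; strand[i] = "+";
      std::unordered_set<uint32_t> ks = canon_kmer_set(q, kmer_size);
      for (std::unordered_set<uint32_t>::iterator it = ks.begin(); it != ks.end(); ++it)
        index[*it].push_back(i);
    } else {
      assign[i] = best_rep + 1;
      ident[i] = best_ident;
      strand[i] = best_rev ? "-" : "+";
    }
  }
  return List::create(_["rep"] = assign, _["identity"] = ident,
                      _["strand"] = strand);
}

// ---- all-pairs identity edges (used by gene consolidation) ----------------
// Returns every unordered pair whose identity (shorter-length denominator)
// reaches identity_min, among pairs passing the shared-k-mer prefilter.

// [[Rcpp::export]]
DataFrame identity_pairs_cpp(CharacterVector seqs, double identity_min,
                             int kmer_size, bool both_strands) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n);
  std::vector<int> nvalid(n);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode_seq(as<std::string>(seqs[i]));
    nvalid[i] = valid_kmer_positions(enc[i], kmer_size);
  }
  std::unordered_map<uint32_t, std::vector<int> > index;
  for (int i = 0; i < n; ++i) {
    std::unordered_set<uint32_t> ks = canon_kmer_set(enc[i], kmer_size);
    for (std::unordered_set<uint32_t>::iterator it = ks.begin(); it != ks.end(); ++it)
      index[*it].push_back(i);
  }
  std::vector<int> ii, jj; std::vector<double> id; std::vector<std::string> st;
  std::vector<int> shared(n, 0), touched;
  for (int i = 0; i < n; ++i) {
    touched.clear();
    std::unordered_set<uint32_t> seen;
    for (int p = 0; p + kmer_size <= (int)enc[i].size(); ++p) {
      uint32_t x;
      if (!kmer_at(enc[i], p, kmer_size, x)) continue;
      uint32_t cx = canonical_kmer(x, kmer_size);
      if (!seen.insert(cx).second) continue;
      std::unordered_map<uint32_t, std::vector<int> >::iterator it = index.find(cx);
      if (it == index.end()) continue;
      for (size_t t = 0; t < it->second.size(); ++t) {
        int j = it->second[t];
        if (j <= i) continue;
        if (shared[j] == 0) touched.push_back(j);
        shared[j]++;
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      int j = touched[t];
      int Ls = (int)std::min(enc[i].size(), enc[j].size());
      int nv = (int)enc[i].size() <= (int)enc[j].size() ? nvalid[i] : nvalid[j];
      if (shared[j] < prefilter_bound(nv, Ls, kmer_size, identity_min)) {
        shared[j] = 0; continue;
      }
      shared[j] = 0;
      const bool i_shorter = enc[i].size() <= enc[j].size();
      const std::vector<uint8_t>& p = i_shorter ? enc[i] : enc[j];
      const std::vector<uint8_t>& s = i_shorter ? enc[j] : enc[i];
      int score, matches;
      semiglobal_matches(p, s, score, matches);
      double idf = (double)matches / (double)p.size(), idr = -1.0;
      if (both_strands && idf < identity_min) {
        std::vector<uint8_t> pr = revcomp_enc(p);
        semiglobal_matches(pr, s, score, matches);
        idr = (double)matches / (double)p.size();
      }
      bool rev = idr > idf;
      double idbest = rev ? idr : idf;
      if (idbest >= identity_min) {
        ii.push_back(i + 1); jj.push_back(j + 1); id.push_back(idbest);
        st.push_back(rev ? "-" : "+");
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["identity"] = id,
                           _["strand"] = st, _["stringsAsFactors"] = false);
}

// ---- containment scan -----------------------------------------------------

struct Block { int start, end; };

static bool block_cmp(const Block& a, const Block& b) {
  return a.start < b.start || (a.start == b.start && a.end < b.end);
}

// verify/extend one chained diagonal run; appends blocks with ungapped
// identity >= ident_min, splitting at the largest gap on failure
static void verify_chain(const std::vector<uint8_t>& s, const std::vector<uint8_t>& l,
                         int diag, const std::vector<int>& hits, int lo, int hi,
                         int k, double ident_min, std::vector<Block>& out) {
  if (lo > hi) return;
  int s0 = hits[lo], s1 = hits[hi] + k; // [s0, s1) on the shorter sequence
  int span = s1 - s0, matches = 0;
  for (int p = s0; p < s1; ++p) {
    uint8_t a = s[p], b = l[p + diag];
    if (a < 4 && a == b) ++matches;
  }
  if ((double)matches / (double)span >= ident_min) {
    // ungapped extension while bases keep matching
    int st = s0, en = s1;
    while (st > 0 && st + diag > 0 && s[st - 1] < 4 && s[st - 1] == l[st - 1 + diag]) --st;
    while (en < (int)s.size() && en + diag < (int)l.size() && s[en] < 4 && s[en] == l[en + diag]) ++en;
    Block b; b.start = st; b.end = en; out.push_back(b);
    return;
  }
  if (lo == hi) return; // single seed failed verification
  int split = lo, gap = -1;
  for (int t = lo; t < hi; ++t)
    if (hits[t + 1] - hits[t] > gap) { gap = hits[t + 1] - hits[t]; split = t; }
  verify_chain(s, l, diag, hits, lo, split, k, ident_min, out);
  verify_chain(s, l, diag, hits, split + 1, hi, k, ident_min, out);
}

// coverage of the shorter sequence s by matched blocks against l (one strand)
static void coverage_one_strand(const std::vector<uint8_t>& s,
                                const std::vector<uint8_t>& l,
                                const std::unordered_map<uint32_t, std::vector<int> >& lmap,
                                int k, double ident_min, int chain_gap,
                                double& cov, int& nblocks) {
  // k-mer matches grouped by diagonal (pos_l - pos_s)
  std::unordered_map<int, std::vector<int> > diag_hits;
  for (int p = 0; p + k <= (int)s.size(); ++p) {
    uint32_t x;
    if (!kmer_at(s, p, k, x)) continue;
    std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = lmap.find(x);
    if (it == lmap.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t)
      diag_hits[it->second[t] - p].push_back(p);
  }
  std::vector<Block> blocks;
  for (std::unordered_map<int, std::vector<int> >::iterator it = diag_hits.begin();
       it != diag_hits.end(); ++it) {
    std::vector<int>& hits = it->second;
    std::sort(hits.begin(), hits.end());
    int lo = 0;
    for (int t = 1; t <= (int)hits.size(); ++t) {
      if (t == (int)hits.size() || hits[t] - hits[t - 1] > chain_gap) {
        verify_chain(s, l, it->first, hits, lo, t - 1, k, ident_min, blocks);
        lo = t;
      }
    }
  }
  if (blocks.empty()) { cov = 0.0; nblocks = 0; return; }
  std::sort(blocks.begin(), blocks.end(), block_cmp);
  long long covered = 0; int nb = 0;
  int cs = blocks[0].start, ce = blocks[0].end;
  for (size_t t = 1; t < blocks.size(); ++t) {
    if (blocks[t].start <= ce) { if (blocks[t].end > ce) ce = blocks[t].end; }
    else { covered += ce - cs; ++nb; cs = blocks[t].start; ce = blocks[t].end; }
  }
  covered += ce - cs; ++nb;
  cov = (double)covered / (double)s.size();
  nblocks = nb;
}

// [[Rcpp::export]]
DataFrame containment_scan_cpp(CharacterVector seqs, int kmer_size,
                               double block_identity_min, bool both_strands,
                               int chain_gap) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode_seq(as<std::string>(seqs[i]));
    len[i] = (int)enc[i].size();
  }
  // exact (strand-specific) k-mer position maps, built lazily per container
  std::vector<std::unordered_map<uint32_t, std::vector<int> > > posmap(n);
  std::vector<bool> have_posmap(n, false);
  // candidate discovery via canonical k-mers
  std::unordered_map<uint32_t, std::vector<int> > index;
  for (int i = 0; i < n; ++i) {
    std::unordered_set<uint32_t> ks = canon_kmer_set(enc[i], kmer_size);
    for (std::unordered_set<uint32_t>::iterator it = ks.begin(); it != ks.end(); ++it)
      index[*it].push_back(i);
  }
  std::vector<int> ci, cj, nb; std::vector<double> cf; std::vector<std::string> st;
  std::vector<bool> touched(n, false);
  for (int i = 0; i < n; ++i) {
    std::vector<int> cand;
    std::unordered_set<uint32_t> seen;
    for (int p = 0; p + kmer_size <= len[i]; ++p) {
      uint32_t x;
      if (!kmer_at(enc[i], p, kmer_size, x)) continue;
      uint32_t cx = canonical_kmer(x, kmer_size);
      if (!seen.insert(cx).second) continue;
      std::unordered_map<uint32_t, std::vector<int> >::iterator it = index.find(cx);
      if (it == index.end()) continue;
      for (size_t t = 0; t < it->second.size(); ++t) {
        int j = it->second[t];
        if (j == i) continue;
        // i is the contained (shorter) side: container must be longer, or
        // equal length (mutual containment handled downstream)
        if (len[j] < len[i]) continue;
        if (!touched[j]) { touched[j] = true; cand.push_back(j); }
      }
    }
    std::sort(cand.begin(), cand.end());
    std::vector<uint8_t> irc;
    for (size_t t = 0; t < cand.size(); ++t) {
      int j = cand[t];
      touched[j] = false;
      if (!have_posmap[j]) {
        for (int p = 0; p + kmer_size <= len[j]; ++p) {
          uint32_t x;
          if (kmer_at(enc[j], p, kmer_size, x)) posmap[j][x].push_back(p);
        }
        have_posmap[j] = true;
      }
      double covf, covr = -1.0; int nbf, nbr = 0;
      coverage_one_strand(enc[i], enc[j], posmap[j], kmer_size,
                          block_identity_min, chain_gap, covf, nbf);
      if (both_strands) {
        if (irc.empty()) irc = revcomp_enc(enc[i]);
        coverage_one_strand(irc, enc[j], posmap[j], kmer_size,
                            block_identity_min, chain_gap, covr, nbr);
      }
      bool rev = covr > covf;
      double cov = rev ? covr : covf;
      int nblk = rev ? nbr : nbf;
      if (cov > 0.0) {
        ci.push_back(i + 1); cj.push_back(j + 1); cf.push_back(cov);
        nb.push_back(nblk); st.push_back(rev ? "-" : "+");
      }
    }
  }
  return DataFrame::create(_["contained"] = ci, _["container"] = cj,
                           _["covered_fraction"] = cf, _["n_blocks"] = nb,
                           _["strand"] = st, _["stringsAsFactors"] = false);
}

// ---- full-length ungapped (Hamming) window matching -----------------------

// [[Rcpp::export]]
DataFrame hamming_windows_cpp(std::string text, std::string pattern,
                              int max_mismatch) {
  std::vector<uint8_t> t = encode_seq(text), p = encode_seq(pattern);
  std::vector<int> starts, mms;
  const int n = (int)t.size(), m = (int)p.size();
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int i = 0; i < m; ++i) {
      uint8_t a = t[s + i], b = p[i];
      if (a >= 4 || b >= 4 || a != b) { if (++mm > max_mismatch) break; }
    }
    if (mm <= max_mismatch) { starts.push_back(s); mms.push_back(mm); }
  }
  return DataFrame::create(_["start"] = starts, _["mismatches"] = mms);
}
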