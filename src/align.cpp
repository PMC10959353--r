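#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 marks anything outside {A,C,G,T}
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encode_seq(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) enc(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_enc(const std::vector<int8_t> &v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? b : (int8_t) (3 - b);
  }
  return r;
}

struct Hit {
  int read;      // 0-based read index
  int ref;       // 0-based reference index
  int start;     // 0-based ref start of matched block
  int end;       // half-open ref end
  int strand;    // +1 / -1
  int nm;        // mismatches inside the matched block
  int clip_left; // soft-clipped bases (alignment orientation)
  int clip_right;
};

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

// pack (ref, pos) into one word; refs < 2^24, pos < 2^40
static inline uint64_t pack_hit(int ref, int pos) {
  return ((uint64_t) ref << 40) | (uint64_t) pos;
}

static KmerIndex build_index(const std::vector<std::vector<int8_t> > &refs, int k) {
  KmerIndex idx;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::vector<int8_t> &seq = refs[r];
    if ((int) seq.size() < k) continue;
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      if (seq[i] < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) seq[i]) & mask;
      if (++valid >= k) idx[kmer].push_back(pack_hit((int) r, (int) (i - k + 1)));
    }
  }
  return idx;
}

// Ungapped X-drop extension around an exact seed (match +1, mismatch -4,
// stop when the running score falls X below its maximum). The block edge in
// each direction is the position of the best score, so blocks always end on
// a matching base and extension does not creep into unrelated sequence
// (e.g. past a circle junction or an insertion breakpoint). A global
// mismatch budget additionally caps divergence inside the block.
static const int SCORE_MATCH = 1;
static const int SCORE_MISMATCH = -4;
static const int XDROP = 10;

static void extend_seed(const std::vector<int8_t> &read,
                        const std::vector<int8_t> &ref,
                        int q, int k, int diag, int budget,
                        int &bstart, int &bend, int &nm_out) {
  const int L = (int) read.size(), RL = (int) ref.size();
  int mm = 0;
  int score = 0, best = 0;
  int bend_r = q + k;               // read pos after last base kept (right)
  for (int i = q + k; i < L; ++i) {
    int rp = diag + i;
    if (rp < 0 || rp >= RL) break;
    if (read[i] >= 0 && read[i] == ref[rp]) score += SCORE_MATCH;
    else { if (mm + 1 > budget) break; ++mm; score += SCORE_MISMATCH; }
    if (score > best) { best = score; bend_r = i + 1; }
    if (score <= best - XDROP) break;
  }
  // drop mismatches beyond the kept right edge from the budget
  int mm_used = 0;
  for (int i = q + k; i < bend_r; ++i)
    if (!(read[i] >= 0 && read[i] == ref[diag + i])) ++mm_used;
  mm = mm_used;
  score = 0; best = 0;
  int bstart_l = q;                 // first read pos kept (left)
  for (int j = q - 1; j >= 0; --j) {
    int rp = diag + j;
    if (rp < 0 || rp >= RL) break;
    if (read[j] >= 0 && read[j] == ref[rp]) score += SCORE_MATCH;
    else { if (mm + 1 > budget) break; ++mm; score += SCORE_MISMATCH; }
    if (score > best) { best = score; bstart_l = j; }
    if (score <= best - XDROP) break;
  }
  int nm = 0;
  for (int i = bstart_l; i < bend_r; ++i) {
    int rp = diag + i;
    if (!(read[i] >= 0 && read[i] == ref[rp])) ++nm;
  }
  bstart = bstart_l;
  bend = bend_r;
  nm_out = nm;
}

// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector ref_seqs, CharacterVector read_seqs,
                    int k, int stride, double mm_rate, bool all_hits,
                    int min_span) {
  const int n_ref = ref_seqs.size(), n_read = read_seqs.size();
  if (k < 1 || k > 32) stop("seed length k must be in [1, 32]");
  if (stride < 1) stop("stride must be >= 1");
  std::vector<std::vector<int8_t> > refs(n_ref);
  for (int r = 0; r < n_ref; ++r) refs[r] = encode_seq(as<std::string>(ref_seqs[r]));
  KmerIndex idx = build_index(refs, k);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<Hit> hits;
  std::vector<int> seed_pos;
  for (int rd = 0; rd < n_read; ++rd) {
    std::string s = as<std::string>(read_seqs[rd]);
    std::vector<int8_t> fwd = encode_seq(s);
    const int L = (int) fwd.size();
    if (L < k) continue;
    int budget = (int) std::floor(mm_rate * L);
    std::vector<Hit> read_hits;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int8_t> read = strand ? revcomp_enc(fwd) : fwd;
      seed_pos.clear();
      for (int q = 0; q + k <= L; q += stride) seed_pos.push_back(q);
      if (seed_pos.empty() || seed_pos.back() != L - k) seed_pos.push_back(L - k);
      // candidate diagonals, deduped
      std::unordered_map<uint64_t, int> seen; // (ref,diag) -> anchor seed pos
      for (size_t si = 0; si < seed_pos.size(); ++si) {
        int q = seed_pos[si];
        uint64_t kmer = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          if (read[q + i] < 0) { ok = false; break; }
          kmer = ((kmer << 2) | (uint64_t) read[q + i]) & mask;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(kmer);
        if (it == idx.end()) continue;
        const std::vector<uint64_t> &locs = it->second;
        for (size_t li = 0; li < locs.size(); ++li) {
          int ref = (int) (locs[li] >> 40);
          int pos = (int) (locs[li] & ((1ULL << 40) - 1));
          int diag = pos - q;
          uint64_t key = ((uint64_t) ref << 42) | (uint64_t) (diag + (1 << 20));
          if (seen.find(key) == seen.end()) seen[key] = q;
        }
      }
      for (std::unordered_map<uint64_t, int>::const_iterator it = seen.begin();
           it != seen.end(); ++it) {
        int ref = (int) (it->first >> 42);
        int diag = (int) (it->first & ((1ULL << 42) - 1)) - (1 << 20);
        int bs, be, nm;
        extend_seed(read, refs[ref], it->second, k, diag, budget, bs, be, nm);
        if (be - bs < min_span) continue;
        Hit h;
        h.read = rd; h.ref = ref;
        h.start = diag + bs; h.end = diag + be;
        h.strand = strand ? -1 : 1; h.nm = nm;
        h.clip_left = bs; h.clip_right = L - be;
        read_hits.push_back(h);
      }
    }
    // dedupe identical placements found from distinct seeds
    std::unordered_map<uint64_t, size_t> uniq;
    std::vector<Hit> kept;
    for (size_t i = 0; i < read_hits.size(); ++i) {
      const Hit &h = read_hits[i];
      uint64_t key = ((uint64_t) h.ref << 42) | ((uint64_t) (h.start + 1) << 1) |
                     (h.strand > 0 ? 1ULL : 0ULL);
      std::unordered_map<uint64_t, size_t>::iterator f = uniq.find(key);
      if (f == uniq.end()) { uniq[key] = kept.size(); kept.push_back(h); }
      else if (h.nm < kept[f->second].nm) kept[f->second] = h;
    }
    if (!all_hits && kept.size() > 1) {
      size_t best = 0;
      for (size_t i = 1; i < kept.size(); ++i) {
        const Hit &a = kept[i], &b = kept[best];
        int sa = a.end - a.start, sb = b.end - b.start;
        if (a.nm < b.nm || (a.nm == b.nm && sa > sb) ||
            (a.nm == b.nm && sa == sb &&
             (a.ref < b.ref || (a.ref == b.ref && a.start < b.start))))
          best = i;
      }
      Hit h = kept[best];
      kept.clear(); kept.push_back(h);
    }
    for (size_t i = 0; i < kept.size(); ++i) hits.push_back(kept[i]);
  }

  const int n = (int) hits.size();
  IntegerVector read_idx(n), ref_idx(n), start(n), end(n), nm(n), cl(n), cr(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    read_idx[i] = hits[i].read + 1;
    ref_idx[i] = hits[i].ref + 1;
    start[i] = hits[i].start;
    end[i] = hits[i].end;
    strand[i] = hits[i].strand > 0 ? "+" : "-";
    nm[i] = hits[i].nm;
    cl[i] = hits[i].clip_left;
    cr[i] = hits[i].clip_right;
  }
  return DataFrame::create(_["read_idx"] = read_idx, _["ref_idx"] = ref_idx,
                           _["start"] = start, _["end"] = end,
                           _["strand"] = strand, _["nm"] = nm,
                           _["clip_left"] = cl, _["clip_right"] = cr,
                           _["stringsAsFactors"] = false);
}
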