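#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Glocal alignment: the whole read must align (global in the read, so no
// soft clipping) at any position of the reference (local in the reference).
// Linear gap penalty per gap base; no separate gap-open term.

struct GHit {
  int start, end, score, mism, gapb;
};

static void glocal_dp(const std::string &read, const std::string &ref,
                      int match, int mismatch, int gap, std::vector<int> &H) {
  const int L = (int)read.size(), G = (int)ref.size();
  const size_t W = (size_t)G + 1;
  H.assign((size_t)(L + 1) * W, 0); // row 0 free: alignment may start anywhere
  for (int i = 1; i <= L; ++i) {
    int *row = &H[(size_t)i * W];
    const int *prev = &H[(size_t)(i - 1) * W];
    row[0] = prev[0] + gap;
    const char rb = read[i - 1];
    for (int j = 1; j <= G; ++j) {
      int s = prev[j - 1] + (rb == ref[j - 1] ? match : mismatch);
      const int u = prev[j] + gap;
      const int l = row[j - 1] + gap;
      if (u > s) s = u;
      if (l > s) s = l;
      row[j] = s;
    }
  }
}

// Deterministic traceback (diagonal > up > left) from one end column.
static GHit glocal_traceback(const std::string &read, const std::string &ref,
                             const std::vector<int> &H, int endj,
                             int match, int mismatch, int gap) {
  const int L = (int)read.size();
  const size_t W = (size_t)ref.size() + 1;
  int i = L, j = endj, mism = 0, gapb = 0;
  while (i > 0) {
    const int cur = H[(size_t)i * W + j];
    if (j > 0 &&
        cur == H[(size_t)(i - 1) * W + (j - 1)] +
                   (read[i - 1] == ref[j - 1] ? match : mismatch)) {
      if (read[i - 1] != ref[j - 1]) ++mism;
      --i; --j;
    } else if (cur == H[(size_t)(i - 1) * W + j] + gap) {
      ++gapb; --i;
    } else {
      ++gapb; --j;
    }
  }
  GHit h;
  h.start = j;
  h.end = endj;
  h.score = H[(size_t)L * W + endj];
  h.mism = mism;
  h.gapb = gapb;
  return h;
}

static std::vector<GHit> glocal_all_best(const std::string &read,
                                         const std::string &ref,
                                         int match, int mismatch, int gap) {
  const int L = (int)read.size(), G = (int)ref.size();
  std::vector<int> H;
  glocal_dp(read, ref, match, mismatch, gap, H);
  const size_t W = (size_t)G + 1;
  int best = H[(size_t)L * W];
  for (int j = 1; j <= G; ++j) best = std::max(best, H[(size_t)L * W + j]);
  std::vector<GHit> hits;
  for (int j = 0; j <= G; ++j) {
    if (H[(size_t)L * W + j] == best) {
      GHit h = glocal_traceback(read, ref, H, j, match, mismatch, gap);
      if (h.start < h.end) hits.push_back(h); // must consume >= 1 ref base
    }
  }
  return hits;
}

// [[Rcpp::export]]
DataFrame glocal_align_cpp(std::string read, std::string ref,
                           int match, int mismatch, int gap) {
  if (read.empty() || ref.empty())
    stop("read and reference must be non-empty");
  if ((double)(read.size() + 1) * (double)(ref.size() + 1) > 2e8)
    stop("sequences too long for exhaustive DP; use map_reads()");
  std::vector<GHit> hits = glocal_all_best(read, ref, match, mismatch, gap);
  const int n = (int)hits.size();
  IntegerVector start(n), end(n), score(n), mism(n), gapb(n);
  for (int i = 0; i < n; ++i) {
    start[i] = hits[i].start;
    end[i] = hits[i].end;
    score[i] = hits[i].score;
    mism[i] = hits[i].mism;
    gapb[i] = hits[i].gapb;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["score"] = score, _["mismatches"] = mism,
                           _["gap_bases"] = gapb);
}

// ---------------------------------------------------------------------------
// Seeded genome-scale mapper.
//
// Pigeonhole seeding: a read split into n_chunks disjoint chunks; any
// placement with at most n_chunks - 1 penalized events (substitutions or gap
// bases) leaves one chunk intact, whose leading k-mer matches the reference
// exactly. Candidate diagonals from exact k-mer hits are clustered and each
// cluster window is aligned with the exhaustive glocal DP. Complete for all
// placements within the event budget; placements beyond it score below the
// default acceptance threshold anyway.
// ---------------------------------------------------------------------------

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
  }
  return 'N';
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static bool pack_kmer(const std::string &s, size_t pos, int k, uint64_t &out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    const int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    h = (h << 2) | (uint64_t)b;
  }
  out = h;
  return true;
}

struct SeedIndex {
  std::unordered_map<uint64_t, std::vector<uint64_t>> pos; // (chrom<<32)|pos
  int k;
};

static void build_index(const std::vector<std::string> &chroms, int k,
                        SeedIndex &idx) {
  idx.k = k;
  for (size_t c = 0; c < chroms.size(); ++c) {
    const std::string &s = chroms[c];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t h;
      if (pack_kmer(s, p, k, h))
        idx.pos[h].push_back(((uint64_t)c << 32) | (uint64_t)p);
    }
  }
}

struct MapHit {
  int chrom, start, end, score, mism, gapb;
  char strand;
};

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector chrom_seqs,
                   int match, int mismatch, int gap,
                   int n_chunks, int k, int band) {
  std::vector<std::string> chroms(chrom_seqs.size());
  for (int i = 0; i < chrom_seqs.size(); ++i)
    chroms[i] = as<std::string>(chrom_seqs[i]);

  SeedIndex idx;
  build_index(chroms, k, idx);

  std::vector<int> out_read, out_chrom, out_start, out_end, out_score,
      out_mism, out_gapb, out_nbest;
  std::vector<char> out_strand;

  std::vector<int> H; // reused DP buffer (not needed; glocal_all_best owns)

  for (int r = 0; r < reads.size(); ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L == 0) continue;
    const std::string rev = revcomp_str(fwd);

    int chunk = L / n_chunks;
    int keff = std::min(k, chunk);
    std::vector<MapHit> hits;
    std::set<std::tuple<char, int, int, int>> seen;

    for (int strand_i = 0; strand_i < 2; ++strand_i) {
      const std::string &s = (strand_i == 0) ? fwd : rev;
      // candidate diagonals (ref position of read start), per chromosome
      std::vector<std::pair<int, int>> diags; // (chrom, diag)
      if (keff == k && chunk >= k) {
        for (int t = 0; t < n_chunks; ++t) {
          const int off = t * chunk;
          uint64_t h;
          if (!pack_kmer(s, off, k, h)) continue;
          auto it = idx.pos.find(h);
          if (it == idx.pos.end()) continue;
          for (uint64_t enc : it->second) {
            const int c = (int)(enc >> 32);
            const int p = (int)(enc & 0xFFFFFFFFULL);
            diags.push_back(std::make_pair(c, p - off));
          }
        }
      } else {
        // read too short for chunked seeding: every chromosome is one window
        for (size_t c = 0; c < chroms.size(); ++c)
          diags.push_back(std::make_pair((int)c, 0));
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

      // cluster diagonals per chromosome, gap <= band
      size_t i0 = 0;
      while (i0 < diags.size()) {
        size_t i1 = i0;
        while (i1 + 1 < diags.size() &&
               diags[i1 + 1].first == diags[i0].first &&
               diags[i1 + 1].second - diags[i1].second <= band)
          ++i1;
        const int c = diags[i0].first;
        const int dmin = diags[i0].second, dmax = diags[i1].second;
        const int G = (int)chroms[c].size();
        int w0, w1;
        if (keff == k && chunk >= k) {
          w0 = std::max(0, dmin - band);
          w1 = std::min(G, dmax + L + band);
        } else {
          w0 = 0;
          w1 = G;
        }
        if (w1 - w0 >= 1 && L <= (w1 - w0) + 3 * band) {
          const std::string window = chroms[c].substr(w0, w1 - w0);
          std::vector<GHit> wh =
              glocal_all_best(s, window, match, mismatch, gap);
          for (const GHit &h : wh) {
            MapHit m;
            m.chrom = c;
            m.start = h.start + w0;
            m.end = h.end + w0;
            m.score = h.score;
            m.mism = h.mism;
            m.gapb = h.gapb;
            m.strand = (strand_i == 0) ? '+' : '-';
            auto key = std::make_tuple(m.strand, m.chrom, m.start, m.end);
            if (seen.insert(key).second) hits.push_back(m);
          }
        }
        i0 = i1 + 1;
      }
    }

    if (hits.empty()) continue;
    int best = hits[0].score;
    for (const MapHit &h : hits) best = std::max(best, h.score);
    int nbest = 0;
    for (const MapHit &h : hits)
      if (h.score == best) ++nbest;
    for (const MapHit &h : hits) {
      if (h.score != best) continue;
      out_read.push_back(r + 1);
      out_chrom.push_back(h.chrom + 1);
      out_start.push_back(h.start);
      out_end.push_back(h.end);
      out_score.push_back(h.score);
      out_mism.push_back(h.mism);
      out_gapb.push_back(h.gapb);
      out_strand.push_back(h.strand);
      out_nbest.push_back(nbest);
    }
  }

  const int n = (int)out_read.size();
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) strand[i] = std::string(1, out_strand[i]);
  return List::create(
      _["read"] = wrap(out_read), _["chrom"] = wrap(out_chrom),
      _["start"] = wrap(out_start), _["end"] = wrap(out_end),
      _["strand"] = strand, _["score"] = wrap(out_score),
      _["mismatches"] = wrap(out_mism), _["gap_bases"] = wrap(out_gapb),
      _["n_best"] = wrap(out_nbest));
}

// ---------------------------------------------------------------------------
// Deterministic per-read tie randomness: hash of (seed, read_id) mapped to
// [0, 1). Reproducible read-by-read and independent of input order.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector tie_hash_cpp(CharacterVector ids, int seed) {
  const int n = ids.size();
  NumericVector out(n);
  const uint64_t sd = splitmix64((uint64_t)(uint32_t)seed);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(ids, i));
    uint64_t h = 1469598103934665603ULL; // FNV-1a 64 offset basis
    for (const char *p = s; *p; ++p)
      h = (h ^ (uint64_t)(unsigned char)*p) * 1099511628211ULL;
    h = splitmix64(h ^ sd);
    out[i] = (double)(h >> 11) / 9007199254740992.0; // 53-bit mantissa
  }
  return out;
}
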