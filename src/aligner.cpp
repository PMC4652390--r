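// Seeded local alignment engine and exhaustive Smith-Waterman oracle.
//
// Scoring follows the blastn convention: a gap of length k costs
// gap_open + k * gap_extend, so gap_open = 0 means opening is free and
// each gap base costs gap_extend.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int BASE_N = 4;

static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return BASE_N;
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)encode_base(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& q) {
  std::vector<uint8_t> r(q.size());
  for (size_t i = 0; i < q.size(); ++i) {
    uint8_t b = q[q.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)BASE_N;
  }
  return r;
}

// ---------------------------------------------------------------------------
// Local affine-gap alignment (Gotoh) with traceback over a bounded region.
// Returns best-scoring local alignment of query vs target slice.

struct AlnResult {
  int score = 0;
  int t_start = 0, t_end = 0;   // 0-based half-open on target slice
  int q_start = 0, q_end = 0;   // 0-based half-open on query
  int n_match = 0, aln_len = 0; // traceback statistics
};

static AlnResult gotoh_local(const std::vector<uint8_t>& q,
                             const uint8_t* t, int tlen,
                             int match, int mismatch,
                             int gap_open, int gap_extend) {
  const int m = (int)q.size();
  const int NEG = -1000000000;
  // DP matrices stored densely for traceback; callers bound m * tlen.
  std::vector<int> H((size_t)(m + 1) * (tlen + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (tlen + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (tlen + 1), NEG);
  auto idx = [&](int i, int j) { return (size_t)i * (tlen + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= tlen; ++j) {
      int s = (q[i - 1] < 4 && t[j - 1] < 4 && q[i - 1] == t[j - 1])
                ? match : mismatch;
      int e = std::max(H[idx(i, j - 1)] - gap_open - gap_extend,
                       E[idx(i, j - 1)] - gap_extend);
      int f = std::max(H[idx(i - 1, j)] - gap_open - gap_extend,
                       F[idx(i - 1, j)] - gap_extend);
      int h = H[idx(i - 1, j - 1)] + s;
      int v = std::max(0, std::max(h, std::max(e, f)));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  AlnResult res;
  res.score = best;
  if (best <= 0) return res;

  // Traceback from (bi, bj) until H == 0.
  int i = bi, j = bj;
  int n_match = 0, aln_len = 0;
  int state = 0; // 0 = H, 1 = E (gap in query, consumes target), 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int v = H[idx(i, j)];
      if (v == 0) break;
      int s = (q[i - 1] < 4 && t[j - 1] < 4 && q[i - 1] == t[j - 1])
                ? match : mismatch;
      if (v == H[idx(i - 1, j - 1)] + s) {
        if (s == match) ++n_match;
        ++aln_len; --i; --j;
      } else if (v == E[idx(i, j)]) {
        state = 1;
      } else if (v == F[idx(i, j)]) {
        state = 2;
      } else break;
    } else if (state == 1) {
      ++aln_len;
      if (E[idx(i, j)] == H[idx(i, j - 1)] - gap_open - gap_extend) {
        --j; state = 0;
      } else { --j; }
    } else {
      ++aln_len;
      if (F[idx(i, j)] == H[idx(i - 1, j)] - gap_open - gap_extend) {
        --i; state = 0;
      } else { --i; }
    }
  }
  res.t_start = j; res.t_end = bj;
  res.q_start = i; res.q_end = bi;
  res.n_match = n_match; res.aln_len = aln_len;
  return res;
}

// ---------------------------------------------------------------------------
// Genome k-mer index (external pointer object).

struct GenomeIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t>> seqs;
  std::vector<std::vector<uint8_t>> masked; // 1 = repeat-masked base
  // packed k-mer -> list of (contig, pos)
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t>>> kmers;
  long long total_len = 0;
};

static inline bool pack_kmer(const std::vector<uint8_t>& s, int pos, int k,
                             uint32_t* out) {
  uint32_t key = 0;
  for (int i = 0; i < k; ++i) {
    uint8_t b = s[pos + i];
    if (b >= 4) return false;
    key = (key << 2) | b;
  }
  *out = key;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector names, CharacterVector seqs, List masks,
                     int k) {
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  int n = seqs.size();
  for (int c = 0; c < n; ++c) {
    std::string s = as<std::string>(seqs[c]);
    gi->names.push_back(as<std::string>(names[c]));
    gi->seqs.push_back(encode_seq(s));
    gi->total_len += (long long)s.size();
    std::vector<uint8_t> mk(s.size(), 0);
    if (masks.size() > c && masks[c] != R_NilValue) {
      IntegerMatrix mi = masks[c]; // columns: start, end (1-based closed)
      for (int r = 0; r < mi.nrow(); ++r) {
        int a = std::max(1, mi(r, 0)), b = std::min((int)s.size(), mi(r, 1));
        for (int p = a; p <= b; ++p) mk[p - 1] = 1;
      }
    }
    gi->masked.push_back(std::move(mk));
  }
  for (int c = 0; c < n; ++c) {
    const std::vector<uint8_t>& s = gi->seqs[c];
    if ((int)s.size() < k) continue;
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint32_t key;
      if (!pack_kmer(s, p, k, &key)) continue;
      gi->kmers[key].push_back({c, p});
    }
  }
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  return List::create(_["k"] = gi->k,
                      _["contigs"] = wrap(gi->names),
                      _["total_len"] = (double)gi->total_len);
}

// ---------------------------------------------------------------------------
// Seed-and-extend search for one query against the indexed genome.

struct RawHit {
  int contig, start, end, strand; // start/end 0-based half-open on contig
  int score, n_match, aln_len;
  int q_start, q_end;
};

static void search_strand(const GenomeIndex* gi,
                          const std::vector<uint8_t>& q, int strand,
                          bool use_mask, bool two_hit,
                          int match, int mismatch, int gap_open,
                          int gap_extend, int min_score,
                          std::vector<RawHit>* hits) {
  const int k = gi->k;
  const int qlen = (int)q.size();
  if (qlen < k) return;

  // Collect seeds per contig as (diag, query_pos); diag = target_pos -
  // query_pos approximates the target start of an alignment.
  std::unordered_map<int, std::vector<std::pair<int, int>>> diags;
  for (int i = 0; i + k <= qlen; ++i) {
    uint32_t key;
    if (!pack_kmer(q, i, k, &key)) continue;
    auto it = gi->kmers.find(key);
    if (it == gi->kmers.end()) continue;
    if (it->second.size() > 5000) continue; // ultra-repetitive seed
    for (auto& pr : it->second) {
      int c = pr.first, p = pr.second;
      if (use_mask) {
        const std::vector<uint8_t>& mk = gi->masked[c];
        bool all_masked = true;
        for (int b = 0; b < k; ++b)
          if (!mk[p + b]) { all_masked = false; break; }
        if (all_masked) continue; // seeds wholly in masked repeats skipped
      }
      diags[c].push_back({p - i, i});
    }
  }

  const int pad = 60 + qlen / 10;
  for (auto& kv : diags) {
    int c = kv.first;
    std::vector<std::pair<int, int>>& ds = kv.second;
    std::sort(ds.begin(), ds.end());
    const std::vector<uint8_t>& t = gi->seqs[c];
    int tlen = (int)t.size();
    size_t i0 = 0;
    while (i0 < ds.size()) {
      size_t i1 = i0;
      // merge diagonal run: consecutive diags closer than one query
      // length, with the region capped to bound the DP size
      while (i1 + 1 < ds.size() && ds[i1 + 1].first - ds[i1].first <= qlen &&
             ds[i1 + 1].first - ds[i0].first <= 3 * qlen) ++i1;
      if (two_hit) {
        // two-hit heuristic: extend only when two non-overlapping seeds
        // support the region on near-identical diagonals (small indel
        // drift allowed); a lone k-mer match is not extended. Emulates
        // discontiguous-template specificity for window-length queries.
        bool ok = (i1 - i0 + 1) > 200; // dense evidence short-circuits
        for (size_t a = i0; !ok && a <= i1; ++a)
          for (size_t bnd = a + 1; bnd <= i1; ++bnd) {
            if (ds[bnd].first - ds[a].first > 16) break;
            if (std::abs(ds[bnd].second - ds[a].second) >= k) {
              ok = true; break;
            }
          }
        if (!ok) { i0 = i1 + 1; continue; }
      }
      int lo = std::max(0, ds[i0].first - pad);
      int hi = std::min(tlen, ds[i1].first + qlen + pad);
      if (hi > lo) {
        AlnResult a = gotoh_local(q, t.data() + lo, hi - lo,
                                  match, mismatch, gap_open, gap_extend);
        if (a.score >= min_score && a.score > 0) {
          RawHit h;
          h.contig = c;
          h.start = lo + a.t_start;
          h.end = lo + a.t_end;
          h.strand = strand;
          h.score = a.score;
          h.n_match = a.n_match;
          h.aln_len = a.aln_len;
          h.q_start = a.q_start;
          h.q_end = a.q_end;
          hits->push_back(h);
        }
      }
      i0 = i1 + 1;
    }
  }
}

static DataFrame hits_to_df(const GenomeIndex* gi, std::vector<RawHit>& hits,
                            int merge_dist) {
  // Merge near-duplicate placements (same contig/strand, starts within
  // merge_dist): keep the best-scoring representative.
  std::sort(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
    return a.score > b.score;
  });
  std::vector<RawHit> kept;
  for (auto& h : hits) {
    bool dup = false;
    for (auto& kh : kept) {
      if (kh.contig == h.contig && kh.strand == h.strand &&
          std::abs(kh.start - h.start) <= merge_dist) { dup = true; break; }
    }
    if (!dup) kept.push_back(h);
    if ((int)kept.size() >= 64) break;
  }
  int n = (int)kept.size();
  CharacterVector contig(n);
  IntegerVector start(n), end(n), score(n), n_match(n), aln_len(n),
      q_start(n), q_end(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    contig[i] = gi->names[kept[i].contig];
    start[i] = kept[i].start;       // 0-based half-open; R layer converts
    end[i] = kept[i].end;
    strand[i] = kept[i].strand == 0 ? "+" : "-";
    score[i] = kept[i].score;
    n_match[i] = kept[i].n_match;
    aln_len[i] = kept[i].aln_len;
    q_start[i] = kept[i].q_start;
    q_end[i] = kept[i].q_end;
  }
  return DataFrame::create(_["contig"] = contig, _["start"] = start,
                           _["end"] = end, _["strand"] = strand,
                           _["raw_score"] = score, _["n_match"] = n_match,
                           _["aln_len"] = aln_len, _["q_start"] = q_start,
                           _["q_end"] = q_end,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_find_hits(SEXP xp, std::string query, bool use_mask,
                        bool two_hit, int match, int mismatch, int gap_open,
                        int gap_extend, int min_score, int merge_dist) {
  XPtr<GenomeIndex> gi(xp);
  std::vector<uint8_t> q = encode_seq(query);
  std::vector<RawHit> hits;
  search_strand(gi, q, 0, use_mask, two_hit, match, mismatch, gap_open,
                gap_extend, min_score, &hits);
  std::vector<uint8_t> rc = revcomp(q);
  search_strand(gi, rc, 1, use_mask, two_hit, match, mismatch, gap_open,
                gap_extend, min_score, &hits);
  return hits_to_df(gi.get(), hits, merge_dist);
}

// Batch tag alignment: one call for many short reads; returns stacked hits
// keyed by tag index (1-based).
// [[Rcpp::export]]
List cpp_align_tags(SEXP xp, CharacterVector tags, bool use_mask,
                    bool two_hit, int match, int mismatch, int gap_open,
                    int gap_extend, int min_score, int merge_dist) {
  XPtr<GenomeIndex> gi(xp);
  std::vector<int> tag_idx;
  std::vector<std::string> contig, strand;
  std::vector<int> start, end, score, n_match, aln_len, q_start, q_end;
  for (int ti = 0; ti < tags.size(); ++ti) {
    std::vector<uint8_t> q = encode_seq(as<std::string>(tags[ti]));
    std::vector<RawHit> hits;
    search_strand(gi, q, 0, use_mask, two_hit, match, mismatch, gap_open,
                  gap_extend, min_score, &hits);
    std::vector<uint8_t> rc = revcomp(q);
    search_strand(gi, rc, 1, use_mask, two_hit, match, mismatch, gap_open,
                  gap_extend, min_score, &hits);
    std::sort(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
      return a.score > b.score;
    });
    std::vector<RawHit> kept;
    for (auto& h : hits) {
      bool dup = false;
      for (auto& kh : kept)
        if (kh.contig == h.contig && kh.strand == h.strand &&
            std::abs(kh.start - h.start) <= merge_dist) { dup = true; break; }
      if (!dup) kept.push_back(h);
      if ((int)kept.size() >= 64) break;
    }
    for (auto& h : kept) {
      tag_idx.push_back(ti + 1);
      contig.push_back(gi->names[h.contig]);
      start.push_back(h.start);
      end.push_back(h.end);
      strand.push_back(h.strand == 0 ? "+" : "-");
      score.push_back(h.score);
      n_match.push_back(h.n_match);
      aln_len.push_back(h.aln_len);
      q_start.push_back(h.q_start);
      q_end.push_back(h.q_end);
    }
    if (ti % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tag_idx"] = wrap(tag_idx), _["contig"] = wrap(contig),
                      _["start"] = wrap(start), _["end"] = wrap(end),
                      _["strand"] = wrap(strand), _["raw_score"] = wrap(score),
                      _["n_match"] = wrap(n_match),
                      _["aln_len"] = wrap(aln_len),
                      _["q_start"] = wrap(q_start),
                      _["q_end"] = wrap(q_end));
}

// Exhaustive local alignment oracle over a full target sequence,
// both strands; independent of the seeded path.
// [[Rcpp::export]]
List cpp_sw_oracle(std::string query, std::string target,
                   int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<uint8_t> q = encode_seq(query);
  std::vector<uint8_t> t = encode_seq(target);
  if ((double)q.size() * (double)t.size() > 1e8)
    stop("query x target size exceeds the 1e8-cell oracle cap");
  AlnResult fwd = gotoh_local(q, t.data(), (int)t.size(),
                              match, mismatch, gap_open, gap_extend);
  std::vector<uint8_t> rc = revcomp(q);
  AlnResult rev = gotoh_local(rc, t.data(), (int)t.size(),
                              match, mismatch, gap_open, gap_extend);
  bool plus = fwd.score >= rev.score;
  const AlnResult& a = plus ? fwd : rev;
  return List::create(_["raw_score"] = a.score,
                      _["start"] = a.t_start, _["end"] = a.t_end,
                      _["strand"] = plus ? "+" : "-",
                      _["n_match"] = a.n_match, _["aln_len"] = a.aln_len);
}

// ---------------------------------------------------------------------------
// 3' adapter trimming by best suffix overlap (leftmost qualifying start,
// overlap >= min_overlap, at most one mismatch per 10 bases of overlap).
// Returns the 0-based position where the adapter starts (== kept length),
// or the read length when no adapter is found.
// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap) {
  IntegerVector out(reads.size());
  std::vector<uint8_t> ad = encode_seq(adapter);
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    std::vector<uint8_t> rd = encode_seq(s);
    int L = (int)rd.size();
    int keep = L;
    for (int j = 0; j <= L - min_overlap; ++j) {
      int ov = std::min(L - j, (int)ad.size());
      if (ov < min_overlap) break;
      int allowed = ov / 10;
      int mm = 0;
      bool ok = true;
      for (int i = 0; i < ov; ++i) {
        if (rd[j + i] != ad[i] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { keep = j; break; }
    }
    out[r] = keep;
  }
  return out;
}
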