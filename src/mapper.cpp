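#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Base counting for gc_fraction: returns counts of A,C,G,T,N.
// [[Rcpp::export]]
IntegerVector count_bases(std::string seq) {
  IntegerVector out(5);
  for (char c : seq) {
    switch (c) {
    case 'A': out[0]++; break;
    case 'C': out[1]++; break;
    case 'G': out[2]++; break;
    case 'T': out[3]++; break;
    case 'N': out[4]++; break;
    }
  }
  return out;
}

static inline int b2i(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

struct Cand { int start; int strand; }; // start: 0-based on circle, strand 0='+',1='-'

// Maximal-scoring contiguous window over the match/mismatch profile of a read
// placed at a fixed reference diagonal (Kadane; match +1, mismatch -mm_pen).
// Earliest window of the maximal score wins (deterministic tie-break).
struct Win { int b, e, score, nm; };

static Win best_window(const std::string &read, const std::string &d, int start,
                       int mm_pen) {
  int L = (int) read.size();
  int best_s = 0, best_b = 0, best_e = 0;
  int cur_s = 0, cur_b = 0;
  for (int i = 0; i < L; ++i) {
    int sc = (read[i] == d[start + i]) ? 1 : -mm_pen;
    if (cur_s <= 0) { cur_s = sc; cur_b = i; }
    else cur_s += sc;
    if (cur_s > best_s) { best_s = cur_s; best_b = cur_b; best_e = i + 1; }
  }
  int nm = 0;
  for (int i = best_b; i < best_e; ++i)
    if (read[i] != d[start + i]) nm++;
  Win w; w.b = best_b; w.e = best_e; w.score = best_s; w.nm = nm;
  return w;
}

// Seed-and-extend mapper against a circular reference.
// ref: reference sequence (single string); internally doubled for wrap-around.
// reads: read sequences as sequenced (R2 already reverse-complement of the
// fragment end). k: seed length; stride: seed sampling stride along the read;
// min_score: minimum accepted window score; mm_pen: mismatch penalty.
// Returns one row per read: mapped, pos (0-based leftmost on the circle),
// strand (+/-), clip_left, m_len, clip_right (clips in reference orientation),
// nm (mismatches inside M), score, mapq.
// [[Rcpp::export]]
DataFrame map_reads_cpp(std::string ref, CharacterVector reads, int k = 21,
                        int stride = 7, int min_score = 30, int mm_pen = 3) {
  int n = (int) ref.size();
  std::string d = ref + ref;

  // k-mer index over circular positions 0..n-1
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve((size_t) n * 2);
  if (k > 0 && k <= 31 && n >= k) {
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < n + k - 1; ++i) {
      int code = b2i(d[i]);
      if (code < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) code) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        if (pos < n) index[key].push_back(pos);
      }
    }
  }

  int nr = reads.size();
  LogicalVector mapped(nr);
  IntegerVector pos(nr), clip_left(nr), m_len(nr), clip_right(nr), nm(nr),
      score(nr), mapq(nr);
  CharacterVector strand(nr);

  std::vector<int> offsets;
  std::vector<Cand> cands;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int L = (int) fwd.size();
    mapped[r] = false; pos[r] = NA_INTEGER; strand[r] = NA_STRING;
    clip_left[r] = 0; m_len[r] = 0; clip_right[r] = 0; nm[r] = 0;
    score[r] = 0; mapq[r] = 0;
    if (L < k) continue;
    std::string rev = revcomp(fwd);

    offsets.clear();
    for (int o = 0; o + k <= L; o += stride) offsets.push_back(o);
    if (offsets.empty() || offsets.back() != L - k) offsets.push_back(L - k);

    cands.clear();
    for (int st = 0; st < 2; ++st) {
      const std::string &s = (st == 0) ? fwd : rev;
      for (int o : offsets) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int code = b2i(s[o + j]);
          if (code < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t) code;
        }
        if (!ok) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (int p : it->second) {
          int startc = p - o;
          startc %= n; if (startc < 0) startc += n;
          bool dup = false;
          for (auto &c : cands)
            if (c.start == startc && c.strand == st) { dup = true; break; }
          if (!dup && (int) cands.size() < 64) {
            Cand c; c.start = startc; c.strand = st; cands.push_back(c);
          }
        }
      }
    }
    if (cands.empty()) continue;

    int best_i = -1, second = -1000000;
    Win best_w; best_w.score = -1000000; best_w.b = best_w.e = best_w.nm = 0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const std::string &s = (cands[ci].strand == 0) ? fwd : rev;
      Win w = best_window(s, d, cands[ci].start, mm_pen);
      bool better = false;
      if (w.score > best_w.score) better = true;
      else if (w.score == best_w.score && best_i >= 0) {
        if (cands[ci].start < cands[best_i].start) better = true;
        else if (cands[ci].start == cands[best_i].start &&
                 cands[ci].strand < cands[best_i].strand) better = true;
      }
      if (better) {
        if (best_i >= 0 && best_w.score > second) second = best_w.score;
        best_w = w; best_i = (int) ci;
      } else if (w.score > second) {
        second = w.score;
      }
    }
    if (best_w.score < min_score) continue;

    mapped[r] = true;
    pos[r] = (cands[best_i].start + best_w.b) % n;
    strand[r] = (cands[best_i].strand == 0) ? "+" : "-";
    // clips reported in reference orientation of the stored (aligned) sequence
    clip_left[r] = best_w.b;
    m_len[r] = best_w.e - best_w.b;
    clip_right[r] = L - best_w.e;
    nm[r] = best_w.nm;
    score[r] = best_w.score;
    mapq[r] = (best_w.score > second) ? 60 : 0;
  }

  return DataFrame::create(_["mapped"] = mapped, _["pos"] = pos,
                           _["strand"] = strand, _["clip_left"] = clip_left,
                           _["m_len"] = m_len, _["clip_right"] = clip_right,
                           _["nm"] = nm, _["score"] = score, _["mapq"] = mapq,
                           _["stringsAsFactors"] = false);
}

// Apply point substitutions to reads in place (simulator error model).
// read_idx: 1-based read index; at: 1-based position within the read;
// base: replacement character. Events for the same read must be applied in
// the order given.
// [[Rcpp::export]]
CharacterVector apply_substitutions(CharacterVector reads, IntegerVector read_idx,
                                    IntegerVector at, CharacterVector base) {
  std::vector<std::string> buf(reads.size());
  std::vector<bool> touched(reads.size(), false);
  for (int i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1;
    if (!touched[r]) { buf[r] = as<std::string>(reads[r]); touched[r] = true; }
    buf[r][at[i] - 1] = as<std::string>(base[i])[0];
  }
  CharacterVector out = clone(reads);
  for (int r = 0; r < (int) buf.size(); ++r)
    if (touched[r]) out[r] = buf[r];
  return out;
}

// Reverse complement of a character vector (vectorised helper for the
// simulator and mapper wrappers).
// [[Rcpp::export]]
CharacterVector revcomp_vec(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// Exact-match runs of length >= min_run on one diagonal of genome vs its
// reverse complement; used by the repeat-discovery seeding stage.
// a, b: equal-length strings; returns 0-based [start,end) runs where a==b.
// [[Rcpp::export]]
IntegerMatrix match_runs(std::string a, std::string b, int min_run) {
  int n = (int) a.size();
  std::vector<int> starts, ends;
  int i = 0;
  while (i < n) {
    if (a[i] == b[i] && a[i] != 'N') {
      int j = i;
      while (j < n && a[j] == b[j] && a[j] != 'N') ++j;
      if (j - i >= min_run) { starts.push_back(i); ends.push_back(j); }
      i = j;
    } else ++i;
  }
  IntegerMatrix out((int) starts.size(), 2);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r]; out(r, 1) = ends[r];
  }
  return out;
}
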