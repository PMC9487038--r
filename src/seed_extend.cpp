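#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Ungapped seed-and-extend local alignment between two nucleotide strings.
// Exact word_size-mer seeds are located via a subject k-mer index, each
// seed is extended in both directions without gaps under X-drop
// termination, and extensions reaching min_score are reported. N never
// seeds and never matches. Coordinates are 0-based half-open, local to
// the supplied strings; the caller handles genome offsets and the
// reverse-complement (opposite-orientation) pass.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;  // N and anything else: never seeds
  }
}

struct Hsp {
  int qs, qe, ss, se;
  double score;
  int matches;
};

// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(std::string query, std::string subject,
                          int word_size, double match_reward,
                          double mismatch_penalty, double xdrop,
                          double min_score) {
  const int nq = (int) query.size();
  const int ns = (int) subject.size();
  std::vector<Hsp> hsps;

  if (nq >= word_size && ns >= word_size) {
    // subject k-mer index: code -> positions
    const long nwords = 1L << (2 * word_size);
    std::vector<std::vector<int> > index((size_t) nwords);
    long code = 0, mask = nwords - 1;
    int valid = 0;
    for (int j = 0; j < ns; ++j) {
      int b = base_code(subject[(size_t) j]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= word_size) index[(size_t) code].push_back(j - word_size + 1);
    }

    // every seed is extended; overlapping extensions on one diagonal are
    // collapsed to the maximal-scoring one in the dedup pass below
    long qcode = 0;
    int qvalid = 0;
    for (int i = 0; i < nq; ++i) {
      int b = base_code(query[(size_t) i]);
      if (b < 0) { qvalid = 0; qcode = 0; continue; }
      qcode = ((qcode << 2) | b) & mask;
      if (++qvalid < word_size) continue;
      int qpos = i - word_size + 1;
      const std::vector<int>& hits = index[(size_t) qcode];
      for (size_t h = 0; h < hits.size(); ++h) {
        int spos = hits[h];
        // seed itself
        double score = match_reward * word_size;
        int matches = word_size;
        // extend right from the end of the seed
        int qr = qpos + word_size, sr = spos + word_size;
        double best_r = 0.0, run = 0.0;
        int best_r_len = 0, len = 0, run_matches = 0, best_r_matches = 0;
        while (qr + len < nq && sr + len < ns) {
          char a = query[(size_t)(qr + len)], c = subject[(size_t)(sr + len)];
          bool is_match = (a == c) && base_code(a) >= 0;
          run += is_match ? match_reward : -mismatch_penalty;
          if (is_match) run_matches++;
          ++len;
          if (run > best_r) { best_r = run; best_r_len = len; best_r_matches = run_matches; }
          if (best_r - run >= xdrop) break;
        }
        // extend left from the start of the seed
        int ql = qpos, sl = spos;
        double best_l = 0.0; run = 0.0;
        int best_l_len = 0; len = 0; run_matches = 0; int best_l_matches = 0;
        while (ql - len - 1 >= 0 && sl - len - 1 >= 0) {
          char a = query[(size_t)(ql - len - 1)], c = subject[(size_t)(sl - len - 1)];
          bool is_match = (a == c) && base_code(a) >= 0;
          run += is_match ? match_reward : -mismatch_penalty;
          if (is_match) run_matches++;
          ++len;
          if (run > best_l) { best_l = run; best_l_len = len; best_l_matches = run_matches; }
          if (best_l - run >= xdrop) break;
        }

        Hsp hsp;
        hsp.qs = qpos - best_l_len;
        hsp.qe = qpos + word_size + best_r_len;
        hsp.ss = spos - best_l_len;
        hsp.se = spos + word_size + best_r_len;
        hsp.score = score + best_l + best_r;
        hsp.matches = matches + best_l_matches + best_r_matches;
        if (hsp.score >= min_score) hsps.push_back(hsp);
      }
    }
  }

  // dedupe per (diagonal, overlapping run): seeds inside one alignment run
  // rediscover it (or sub-segments of it); keep the maximal-scoring HSP of
  // every group of transitively overlapping same-diagonal HSPs
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.qs - a.ss != b.qs - b.ss) return (a.qs - a.ss) < (b.qs - b.ss);
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.score > b.score;
  });
  std::vector<Hsp> kept;
  int group_diag = 0, group_end = -1;
  for (size_t k = 0; k < hsps.size(); ++k) {
    int diag = hsps[k].qs - hsps[k].ss;
    bool same_group = !kept.empty() && diag == group_diag &&
                      hsps[k].qs < group_end;
    if (same_group) {
      if (hsps[k].qe > group_end) group_end = hsps[k].qe;
      if (hsps[k].score > kept.back().score) kept.back() = hsps[k];
    } else {
      kept.push_back(hsps[k]);
      group_diag = diag;
      group_end = hsps[k].qe;
    }
  }

  std::sort(kept.begin(), kept.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });

  int n = (int) kept.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), matches(n);
  NumericVector sc(n);
  for (int k = 0; k < n; ++k) {
    qs[k] = kept[(size_t) k].qs; qe[k] = kept[(size_t) k].qe;
    ss[k] = kept[(size_t) k].ss; se[k] = kept[(size_t) k].se;
    sc[k] = kept[(size_t) k].score; matches[k] = kept[(size_t) k].matches;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["score"] = sc, _["matches"] = matches);
}
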