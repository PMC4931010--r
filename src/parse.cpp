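#include <Rcpp.h>
using namespace Rcpp;

// Ungapped linker scanning and read-pair parsing.
//
// Kind codes used throughout:
//   1 = internal  (full linker matched inside the read)
//   2 = prefix    (a linker *prefix* matched at the read 3' end)
//   3 = suffix    (a linker *suffix* matched at the read 5' end)
//   4 = full      (the matched span covers the entire read)

static inline int hamming_n(const char* a, const char* b, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i) if (a[i] != b[i]) ++d;
  return d;
}

// Collect all admissible ungapped linker matches in seq.
// Budget: mismatches <= floor(rate * matched_length).
static void linker_candidates(const std::string& seq, const std::string& linker,
                              int min_overlap, double rate,
                              bool allow_prefix, bool allow_suffix,
                              std::vector<int>& start, std::vector<int>& end,
                              std::vector<int>& mism, std::vector<int>& kind) {
  const int n = (int) seq.size();
  const int L = (int) linker.size();
  // full linker at every offset
  if (n >= L) {
    int budget = (int) std::floor(rate * L);
    for (int o = 0; o + L <= n; ++o) {
      int d = hamming_n(seq.c_str() + o, linker.c_str(), L);
      if (d <= budget) {
        start.push_back(o); end.push_back(o + L); mism.push_back(d);
        kind.push_back(n == L ? 4 : 1);
      }
    }
  } else {
    // read shorter than linker: the whole read may sit inside the linker
    int budget = (int) std::floor(rate * n);
    if (n >= min_overlap) {
      for (int o = 0; o + n <= L; ++o) {
        int d = hamming_n(seq.c_str(), linker.c_str() + o, n);
        if (d <= budget) { start.push_back(0); end.push_back(n); mism.push_back(d); kind.push_back(4); }
      }
    }
  }
  // linker prefix at the read 3' end (read runs off before linker completes)
  if (allow_prefix) {
    int omax = std::min(n, L - 1);
    for (int o = min_overlap; o <= omax; ++o) {
      int budget = (int) std::floor(rate * o);
      int d = hamming_n(seq.c_str() + (n - o), linker.c_str(), o);
      if (d <= budget) { start.push_back(n - o); end.push_back(n); mism.push_back(d); kind.push_back(2); }
    }
  }
  // linker suffix at the read 5' end (read starts inside the linker)
  if (allow_suffix) {
    int omax = std::min(n, L - 1);
    for (int o = min_overlap; o <= omax; ++o) {
      int budget = (int) std::floor(rate * o);
      int d = hamming_n(seq.c_str(), linker.c_str() + (L - o), o);
      if (d <= budget) { start.push_back(0); end.push_back(o); mism.push_back(d); kind.push_back(3); }
    }
  }
}

// Pick the best candidate: highest score = matched - mismatches,
// ties by longer match, then smaller start. Returns index or -1.
static int best_candidate(const std::vector<int>& start, const std::vector<int>& end,
                          const std::vector<int>& mism) {
  int best = -1; int bscore = -1; int blen = -1; int bstart = -1;
  for (size_t i = 0; i < start.size(); ++i) {
    int len = end[i] - start[i];
    int sc = len - mism[i];
    if (sc > bscore || (sc == bscore && (len > blen || (len == blen && start[i] < bstart)))) {
      best = (int) i; bscore = sc; blen = len; bstart = start[i];
    }
  }
  return best;
}

// Count maximal groups of mutually overlapping full-length matches; >= 2
// disjoint full occurrences flag an ambiguous (multi-linker) read.
static int disjoint_full_matches(const std::vector<int>& start, const std::vector<int>& end,
                                 const std::vector<int>& kind) {
  std::vector<std::pair<int,int> > iv;
  for (size_t i = 0; i < start.size(); ++i)
    if (kind[i] == 1 || kind[i] == 4) iv.push_back(std::make_pair(start[i], end[i]));
  if (iv.empty()) return 0;
  std::sort(iv.begin(), iv.end());
  int groups = 1; int hi = iv[0].second;
  for (size_t i = 1; i < iv.size(); ++i) {
    if (iv[i].first >= hi) { ++groups; hi = iv[i].second; }
    else hi = std::max(hi, iv[i].second);
  }
  return groups;
}

// [[Rcpp::export]]
List cpp_find_linker(std::string seq, std::string linker, int min_overlap,
                     double max_mismatch_rate, bool allow_prefix, bool allow_suffix) {
  std::vector<int> s, e, m, k;
  linker_candidates(seq, linker, min_overlap, max_mismatch_rate, allow_prefix, allow_suffix,
                    s, e, m, k);
  int bi = best_candidate(s, e, m);
  if (bi < 0) return List::create(Named("found") = false);
  return List::create(Named("found") = true,
                      Named("start") = s[bi], Named("end") = e[bi],
                      Named("mismatches") = m[bi], Named("kind") = k[bi],
                      Named("n_disjoint") = disjoint_full_matches(s, e, k));
}

// Merge mate 1 (payload, insert sense) with reverse-complemented mate 2.
// Largest suffix/prefix overlap >= min_overlap with mismatch fraction <=
// max_mismatch_rate wins. Returns "" when no admissible overlap.
// [[Rcpp::export]]
std::string cpp_merge_mates(std::string s1, std::string s2rc, int min_overlap,
                            double max_mismatch_rate) {
  const int n1 = (int) s1.size(), n2 = (int) s2rc.size();
  const int omax = std::min(n1, n2);
  for (int o = omax; o >= min_overlap; --o) {
    int budget = (int) std::floor(max_mismatch_rate * o);
    if (hamming_n(s1.c_str() + (n1 - o), s2rc.c_str(), o) <= budget)
      return s1 + s2rc.substr(o);
  }
  return std::string("");
}

// Parse a vector of read pairs (payload of read 1 + reverse-complemented
// read 2) into chimera categories and fragment sequences.
// [[Rcpp::export]]
DataFrame cpp_parse_pairs(CharacterVector payload1, CharacterVector read2rc,
                          std::string linker, int min_overlap, double max_mismatch_rate,
                          int merge_min, double merge_max_mismatch_rate, int min_frag) {
  const int n = payload1.size();
  CharacterVector category(n), rna1(n), rna2(n);
  LogicalVector merged_flag(n);
  IntegerVector linker_start(n), linker_end(n);

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(payload1[i]);
    std::string s2 = as<std::string>(read2rc[i]);
    std::string r1 = "", r2 = "";
    std::string cat;
    int lks = NA_INTEGER, lke = NA_INTEGER;

    std::string merged = cpp_merge_mates(s1, s2, merge_min, merge_max_mismatch_rate);
    bool is_merged = !merged.empty();
    merged_flag[i] = is_merged;

    if (is_merged) {
      // a merged insert is complete: only full-linker occurrences are possible
      std::vector<int> cs, ce, cm, ck;
      linker_candidates(merged, linker, min_overlap, max_mismatch_rate, false, false,
                        cs, ce, cm, ck);
      int bi = best_candidate(cs, ce, cm);
      if (bi < 0) {
        cat = "no_linker"; r1 = merged;
      } else if (disjoint_full_matches(cs, ce, ck) >= 2) {
        cat = "ambiguous";
      } else {
        lks = cs[bi]; lke = ce[bi];
        r1 = merged.substr(0, cs[bi]);
        r2 = merged.substr(ce[bi]);
        cat = "";
      }
    } else {
      // unmerged: linker may be internal to either mate, or straddle the gap
      // (prefix of linker at mate-1 3' end / suffix of linker at mate-2rc 5' end)
      std::vector<int> s1s, s1e, s1m, s1k, s2s, s2e, s2m, s2k;
      linker_candidates(s1, linker, min_overlap, max_mismatch_rate, true, false,
                        s1s, s1e, s1m, s1k);
      linker_candidates(s2, linker, min_overlap, max_mismatch_rate, false, true,
                        s2s, s2e, s2m, s2k);
      if (disjoint_full_matches(s1s, s1e, s1k) >= 2 || disjoint_full_matches(s2s, s2e, s2k) >= 2) {
        cat = "ambiguous";
      } else {
        int b1 = best_candidate(s1s, s1e, s1m);
        int b2 = best_candidate(s2s, s2e, s2m);
        bool full1 = b1 >= 0 && (s1k[b1] == 1 || s1k[b1] == 4);
        bool full2 = b2 >= 0 && (s2k[b2] == 1 || s2k[b2] == 4);
        if (full1) {
          lks = s1s[b1]; lke = s1e[b1];
          r1 = s1.substr(0, s1s[b1]);
          // RNA2 tail: mate 2 covers the insert 3' end; prefer the longer view
          std::string tail1 = s1.substr(s1e[b1]);
          r2 = (s2.size() >= tail1.size()) ? s2 : tail1;
          cat = "";
        } else if (full2) {
          lks = s2s[b2]; lke = s2e[b2];
          r2 = s2.substr(s2e[b2]);
          std::string head2 = s2.substr(0, s2s[b2]);
          r1 = (s1.size() >= head2.size()) ? s1 : head2;
          cat = "";
        } else if (b1 >= 0 && b2 >= 0) {
          // linker straddles the unsequenced gap
          r1 = s1.substr(0, s1s[b1]);
          r2 = s2.substr(s2e[b2]);
          cat = "";
        } else if (b1 >= 0) {
          r1 = s1.substr(0, s1s[b1]);
          r2 = "";
          cat = "";
        } else if (b2 >= 0) {
          r1 = "";
          r2 = s2.substr(s2e[b2]);
          cat = "";
        } else {
          cat = "no_linker"; r1 = s1;
        }
      }
    }

    if (cat.empty()) {
      if ((int) r1.size() < min_frag) r1 = "";
      if ((int) r2.size() < min_frag) r2 = "";
      if (!r1.empty() && !r2.empty()) cat = "chimeric";
      else if (r1.empty() && !r2.empty()) cat = "linker_rna2";
      else if (!r1.empty() && r2.empty()) cat = "rna1_linker";
      else cat = "linker_only";
    } else if (cat == "no_linker") {
      if ((int) r1.size() < min_frag) r1 = "";
      r2 = "";
    } else { // ambiguous
      r1 = ""; r2 = "";
    }

    category[i] = cat; rna1[i] = r1; rna2[i] = r2;
    linker_start[i] = lks; linker_end[i] = lke;
  }
  return DataFrame::create(Named("category") = category,
                           Named("rna1") = rna1, Named("rna2") = rna2,
                           Named("merged") = merged_flag,
                           Named("linker_start") = linker_start,
                           Named("linker_end") = linker_end,
                           Named("stringsAsFactors") = false);
}

// Vectorised Hamming distance between equal-length string pairs.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(b[i]);
    if (x.size() != y.size()) { out[i] = NA_INTEGER; continue; }
    out[i] = hamming_n(x.c_str(), y.c_str(), (int) x.size());
  }
  return out;
}
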