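#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum free energy by nearest-neighbour dynamic
// programming. Both sequences are 5'->3' RNA (A/C/G/U); pairing is
// antiparallel and ungapped stacks score from a 6x6 dG37 table indexed by
// pair codes AU=0, UA=1, CG=2, GC=3, GU=4, UG=5. Interior unpaired bases
// between consecutive pairs cost loop_penalty per nucleotide, with the total
// interior loop size capped at max_loop. Dangling ends are free; there is no
// helix initiation term, so the empty duplex (dG = 0) is always admissible.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'U': return 3; case 'T': return 3;
    default: return -1;
  }
}

static inline int pair_code(int x, int y) {
  if (x == 0 && y == 3) return 0; // AU
  if (x == 3 && y == 0) return 1; // UA
  if (x == 1 && y == 2) return 2; // CG
  if (x == 2 && y == 1) return 3; // GC
  if (x == 2 && y == 3) return 4; // GU
  if (x == 3 && y == 2) return 5; // UG
  return -1;
}

// [[Rcpp::export]]
double cpp_duplex_energy(std::string s, std::string t, NumericMatrix stack,
                         double loop_penalty, int max_loop) {
  const int n = (int) s.size(), m = (int) t.size();
  std::vector<int> sb(n), tb(m);
  for (int i = 0; i < n; ++i) {
    sb[i] = base_code(s[i]);
    if (sb[i] < 0) stop("non-nucleotide character in sequence 1");
  }
  for (int j = 0; j < m; ++j) {
    tb[j] = base_code(t[j]);
    if (tb[j] < 0) stop("non-nucleotide character in sequence 2");
  }
  const double INF = 1e18;
  std::vector<double> H((size_t) n * m, INF);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int p = pair_code(sb[i], tb[j]);
      if (p < 0) continue;
      double h = 0.0; // the pair may open the duplex
      int i0min = std::max(0, i - 1 - max_loop);
      for (int i0 = i - 1; i0 >= i0min; --i0) {
        int gap_i = i - i0 - 1;
        int j0max = std::min(m - 1, j + 1 + (max_loop - gap_i));
        for (int j0 = j + 1; j0 <= j0max; ++j0) {
          double prev = H[(size_t) i0 * m + j0];
          if (prev >= INF) continue;
          int p0 = pair_code(sb[i0], tb[j0]);
          double cost;
          if (gap_i == 0 && j0 == j + 1) cost = stack(p0, p);
          else cost = loop_penalty * (gap_i + (j0 - j - 1));
          if (prev + cost < h) h = prev + cost;
        }
      }
      H[(size_t) i * m + j] = h;
      if (h < best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_duplex_energy_vec(CharacterVector s, CharacterVector t,
                                    NumericMatrix stack, double loop_penalty,
                                    int max_loop) {
  const int n = s.size();
  if (t.size() != n) stop("length mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cpp_duplex_energy(as<std::string>(s[i]), as<std::string>(t[i]),
                               stack, loop_penalty, max_loop);
  return out;
}
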