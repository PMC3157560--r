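#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Mutation-only genetic search for the shortest open route through a
// set of positions with a fixed first element. Population of random
// orders; each generation is randomly partitioned into groups, the
// shortest route of each group survives and spawns one offspring per
// mutation operator (flip a segment, swap its endpoints, slide it by
// one). Restarted n_restarts times; the overall incumbent is returned.
// Uses R's RNG so results are reproducible under set.seed().

static inline int rand_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static double route_len(const std::vector<int> &ord, const NumericMatrix &d) {
  double s = 0.0;
  for (size_t k = 1; k < ord.size(); ++k) s += d(ord[k - 1], ord[k]);
  return s;
}

// [[Rcpp::export]]
List ga_evolve_cpp(NumericMatrix dmat, int anchor, int pop_size,
                   int group_size, int n_generations, int n_restarts) {
  const int n = dmat.nrow();
  if (anchor < 0 || anchor >= n) stop("anchor out of range");
  if (pop_size % group_size != 0) stop("pop_size must be divisible by group_size");

  std::vector<int> base;
  base.reserve(n - 1);
  for (int i = 0; i < n; ++i) if (i != anchor) base.push_back(i);

  std::vector<std::vector<int>> pop(pop_size, std::vector<int>(n));
  std::vector<double> len(pop_size);
  std::vector<int> perm(pop_size);

  std::vector<int> best_order;
  double best_len = R_PosInf;
  NumericVector restart_best(n_restarts);

  for (int r = 0; r < n_restarts; ++r) {
    // initialise: anchor + random shuffle of the rest
    for (int p = 0; p < pop_size; ++p) {
      std::vector<int> tail = base;
      for (int i = (int)tail.size() - 1; i > 0; --i)
        std::swap(tail[i], tail[rand_int(i + 1)]);
      pop[p][0] = anchor;
      std::copy(tail.begin(), tail.end(), pop[p].begin() + 1);
      len[p] = route_len(pop[p], dmat);
    }
    double r_best = R_PosInf;
    std::vector<int> r_best_order;

    for (int g = 0; g < n_generations; ++g) {
      // random partition into groups of group_size
      for (int p = 0; p < pop_size; ++p) perm[p] = p;
      for (int i = pop_size - 1; i > 0; --i)
        std::swap(perm[i], perm[rand_int(i + 1)]);

      for (int b = 0; b < pop_size; b += group_size) {
        int winner = perm[b];
        for (int j = 1; j < group_size; ++j)
          if (len[perm[b + j]] < len[winner]) winner = perm[b + j];
        if (len[winner] < r_best) {
          r_best = len[winner];
          r_best_order = pop[winner];
        }
        // segment endpoints within 1..n-1 (anchor excluded), I <= J
        int I = 1 + rand_int(n - 1), J = 1 + rand_int(n - 1);
        if (I > J) std::swap(I, J);
        const std::vector<int> &w = pop[winner];
        for (int j = 0, slot = 0; j < group_size; ++j) {
          int tgt = perm[b + j];
          if (tgt == winner) continue;
          std::vector<int> &m = pop[tgt];
          m = w;
          if (slot == 0) {                       // flip segment
            std::reverse(m.begin() + I, m.begin() + J + 1);
          } else if (slot == 1) {                // swap endpoints
            std::swap(m[I], m[J]);
          } else if (slot == 2) {                // slide segment by one
            std::rotate(m.begin() + I, m.begin() + I + 1, m.begin() + J + 1);
          } else {                               // extra slots: fresh swap
            int a = 1 + rand_int(n - 1), c = 1 + rand_int(n - 1);
            std::swap(m[a], m[c]);
          }
          len[tgt] = route_len(m, dmat);
          ++slot;
        }
      }
      if ((g & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    // final sweep of the last generation
    for (int p = 0; p < pop_size; ++p) {
      if (len[p] < r_best) { r_best = len[p]; r_best_order = pop[p]; }
    }
    restart_best[r] = r_best;
    if (r_best < best_len) { best_len = r_best; best_order = r_best_order; }
  }

  return List::create(_["order"] = IntegerVector(best_order.begin(), best_order.end()),
                      _["length"] = best_len,
                      _["restart_best"] = restart_best);
}
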