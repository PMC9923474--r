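#include <Rcpp.h>
using namespace Rcpp;

// Forward-time 1-D stepping-stone Wright-Fisher simulator with diploid
// stepwise-mutating microsatellites.
//
// Demes sit on a line; every generation each of the N offspring of deme d
// draws a parent deme from the (pre-normalized) dispersal kernel column d,
// then two distinct parents uniformly within that deme (or a random
// monogamous pair when `monogamy` is set), inherits one allele from each
// with free recombination across loci, and mutates each transmitted allele
// by +/-1 repeat with probability mu, reflecting at the bounds.
//
// kernel_cum: n_demes x n_demes matrix; column d holds the cumulative
// probabilities P(parent deme <= j | offspring deme d). Uses R's RNG so
// set.seed() governs reproducibility.

static inline int draw_parent_deme(const NumericMatrix &kernel_cum, int d,
                                   int n_demes) {
  double u = unif_rand();
  // linear scan; kernels are short (<= number of demes)
  for (int j = 0; j < n_demes; ++j) {
    if (u <= kernel_cum(j, d)) return j;
  }
  return n_demes - 1;
}

static inline int mutate(int allele, double mu, int amin, int amax) {
  if (mu > 0.0 && unif_rand() < mu) {
    allele += (unif_rand() < 0.5) ? -1 : 1;
    if (allele > amax) allele = amax - 1;
    if (allele < amin) allele = amin + 1;
  }
  return allele;
}

// [[Rcpp::export]]
List sim_stepping_stone_cpp(IntegerMatrix a1, IntegerMatrix a2,
                            int n_demes, int deme_size,
                            NumericMatrix kernel_cum,
                            double mu, int amin, int amax,
                            int generations, bool monogamy) {
  const int n_loci = a1.ncol();
  const int n_total = n_demes * deme_size;
  if (a1.nrow() != n_total || a2.nrow() != n_total)
    stop("genotype matrices must have n_demes * deme_size rows");

  IntegerMatrix b1(n_total, n_loci), b2(n_total, n_loci);
  std::vector<int> pairing(deme_size);

  for (int g = 0; g < generations; ++g) {
    // optional monogamous pairing: one random pairing per deme per
    // generation, offspring pick a pair instead of two random parents
    std::vector<int> pair_of;
    if (monogamy) {
      pair_of.assign((size_t)n_total, 0);
      for (int d = 0; d < n_demes; ++d) {
        for (int i = 0; i < deme_size; ++i) pairing[i] = i;
        for (int i = deme_size - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(pairing[i], pairing[j]);
        }
        for (int i = 0; i + 1 < deme_size; i += 2) {
          pair_of[d * deme_size + pairing[i]] = pairing[i + 1];
          pair_of[d * deme_size + pairing[i + 1]] = pairing[i];
        }
        if (deme_size % 2 == 1)  // odd deme: last one pairs across
          pair_of[d * deme_size + pairing[deme_size - 1]] = pairing[0];
      }
    }

    for (int d = 0; d < n_demes; ++d) {
      for (int i = 0; i < deme_size; ++i) {
        const int child = d * deme_size + i;
        const int pd = draw_parent_deme(kernel_cum, d, n_demes);
        int p1 = (int)(unif_rand() * deme_size);
        if (p1 >= deme_size) p1 = deme_size - 1;
        int p2;
        if (monogamy && deme_size > 1) {
          p2 = pair_of[pd * deme_size + p1];
        } else {
          p2 = p1;
          if (deme_size > 1) {
            while (p2 == p1) {
              p2 = (int)(unif_rand() * deme_size);
              if (p2 >= deme_size) p2 = deme_size - 1;
            }
          }
        }
        const int par1 = pd * deme_size + p1;
        const int par2 = pd * deme_size + p2;
        for (int l = 0; l < n_loci; ++l) {
          int al1 = (unif_rand() < 0.5) ? a1(par1, l) : a2(par1, l);
          int al2 = (unif_rand() < 0.5) ? a1(par2, l) : a2(par2, l);
          b1(child, l) = mutate(al1, mu, amin, amax);
          b2(child, l) = mutate(al2, mu, amin, amax);
        }
      }
    }
    std::swap(a1, b1);
    std::swap(a2, b2);
  }
  return List::create(_["a1"] = a1, _["a2"] = a2);
}
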