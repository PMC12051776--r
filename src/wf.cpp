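// Forward Wright-Fisher core for the sweep simulator.
//
// Haplotypes are rows of a 2N x S 0/1 matrix over a fixed lattice of S
// potential sites spanning seq_length bp.  Each generation: diploid
// parents are sampled proportionally to fitness (viability selection at a
// single sweep site, fitnesses 1 : 1+hs : 1+s), every offspring receives
// one recombinant gamete from each of two distinct parents (obligate
// outcrossing), and finite-sites mutation flips 0 <-> 1 at random entries.
// All randomness comes from R's RNG, so set.seed() makes runs exactly
// reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// sample an index from cumulative weights (binary search)
static int sample_cum(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

// [[Rcpp::export]]
IntegerMatrix wf_evolve(IntegerMatrix H, int gens, double mut_per_site,
                        double exp_xovers, NumericVector pos_frac,
                        int sweep_site, double s, double h) {
  const int n_hap = H.nrow(), S = H.ncol();
  const int N = n_hap / 2;
  if (n_hap % 2 != 0) stop("haplotype count must be even");
  if (sweep_site >= S) stop("sweep site index out of range");

  // column-major copies for cache-friendly row writes are not needed;
  // IntegerMatrix is column-major, gametes are rows, so work on a
  // transposed buffer: hap[i*S + j]
  std::vector<int> cur((size_t)n_hap * S), nxt((size_t)n_hap * S);
  for (int i = 0; i < n_hap; ++i)
    for (int j = 0; j < S; ++j) cur[(size_t)i * S + j] = H(i, j);

  std::vector<double> cum(N);
  std::vector<double> bp;
  const double lambda_mut = mut_per_site * (double)S * (double)n_hap;

  for (int g = 0; g < gens; ++g) {
    // fitness-weighted cumulative distribution over diploids
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      if (sweep_site >= 0 && s != 0.0) {
        int dos = cur[(size_t)(2 * i) * S + sweep_site] +
                  cur[(size_t)(2 * i + 1) * S + sweep_site];
        if (dos == 1) w = 1.0 + h * s;
        else if (dos == 2) w = 1.0 + s;
      }
      acc += w;
      cum[i] = acc;
    }
    for (int off = 0; off < N; ++off) {
      int pa = sample_cum(cum);
      int pb = sample_cum(cum);
      for (int tries = 0; pb == pa && tries < 64 && N > 1; ++tries)
        pb = sample_cum(cum);
      const int parents[2] = {pa, pb};
      for (int k = 0; k < 2; ++k) {
        int par = parents[k];
        int *dst = &nxt[(size_t)(2 * off + k) * S];
        const int *h0 = &cur[(size_t)(2 * par) * S];
        const int *h1 = &cur[(size_t)(2 * par + 1) * S];
        int chrom = (unif_rand() < 0.5) ? 0 : 1;
        int n_x = (int)R::rpois(exp_xovers);
        if (n_x == 0) {
          const int *src = chrom ? h1 : h0;
          std::copy(src, src + S, dst);
        } else {
          bp.clear();
          for (int x = 0; x < n_x; ++x) bp.push_back(unif_rand());
          std::sort(bp.begin(), bp.end());
          int j = 0;
          for (int x = 0; x < (int)bp.size(); ++x) {
            // first site strictly right of the crossover point
            int to = std::upper_bound(pos_frac.begin(), pos_frac.end(),
                                      bp[x]) - pos_frac.begin();
            const int *src = chrom ? h1 : h0;
            for (; j < to; ++j) dst[j] = src[j];
            chrom ^= 1;
          }
          const int *src = chrom ? h1 : h0;
          for (; j < S; ++j) dst[j] = src[j];
        }
      }
    }
    // finite-sites mutation: flip random (haplotype, site) entries
    int n_mut = (int)R::rpois(lambda_mut);
    for (int m = 0; m < n_mut; ++m) {
      int i = (int)(unif_rand() * n_hap); if (i == n_hap) i--;
      int j = (int)(unif_rand() * S); if (j == S) j--;
      nxt[(size_t)i * S + j] ^= 1;
    }
    std::swap(cur, nxt);
  }

  IntegerMatrix out(n_hap, S);
  for (int i = 0; i < n_hap; ++i)
    for (int j = 0; j < S; ++j) out(i, j) = cur[(size_t)i * S + j];
  return out;
}

// [[Rcpp::export]]
NumericVector wf_allele_freqs(IntegerMatrix H) {
  const int n = H.nrow(), S = H.ncol();
  NumericVector p(S);
  for (int j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < n; ++i) c += H(i, j);
    p[j] = (double)c / n;
  }
  return p;
}
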