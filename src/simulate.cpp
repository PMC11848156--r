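#include <Rcpp.h>
#include <stdint.h>
using namespace Rcpp;

// fast local RNG (xorshift128+), seeded from R's RNG so results remain
// a deterministic function of set.seed(); R's generator is too slow
// through the C API for 10^8-scale genotype draws
namespace {

struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(uint64_t a, uint64_t b) {
    // splitmix64 scrambling of the two seed words
    for (uint64_t *w : {&a, &b}) {
      uint64_t z = (*w += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      *w = z ^ (z >> 31);
    }
    s0 = a ? a : 0x853C49E6748FEA9BULL;
    s1 = b ? b : 0xDA3E39CB94B95BDBULL;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

XorShift128 seeded_from_r() {
  // two 32-bit words drawn from R's RNG stream
  uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
  return XorShift128((a << 32) ^ b, (b << 32) ^ a);
}

}  // namespace

// Hardy-Weinberg dosages with optional shared-template LD blocks.
// Independent SNPs: one uniform per genotype, inverted through the
// Binomial(2, p) CDF. Block SNPs: two haplotypes, each copying a common
// template allele with probability sqrt(r) (expected dosage correlation
// of two block members is exactly r). Uses R's RNG, so set.seed() in R
// makes the draw deterministic.
// [[Rcpp::export]]
NumericMatrix sim_dosages_cpp(int n_ind, NumericVector maf,
                              IntegerVector block, NumericVector block_r) {
  int k = maf.size();
  NumericMatrix X(n_ind, k);
  RNGScope scope;
  XorShift128 rng = seeded_from_r();

  for (int j = 0; j < k; ++j) {
    if (block[j] != NA_INTEGER) continue;
    double p = maf[j];
    double a = (1.0 - p) * (1.0 - p);
    double b = a + 2.0 * p * (1.0 - p);
    NumericMatrix::Column col = X(_, j);
    for (int i = 0; i < n_ind; ++i) {
      double u = rng.unif();
      col[i] = (u > a) + (u > b);
    }
  }

  // group block members preserving column order
  std::map<int, std::vector<int> > blocks;
  for (int j = 0; j < k; ++j) {
    if (block[j] != NA_INTEGER) blocks[block[j]].push_back(j);
  }
  std::vector<double> tmpl(n_ind);
  for (std::map<int, std::vector<int> >::iterator it = blocks.begin();
       it != blocks.end(); ++it) {
    const std::vector<int> &members = it->second;
    double p = maf[members[0]];
    double q = std::sqrt(block_r[members[0]]);
    for (int h = 0; h < 2; ++h) {
      for (int i = 0; i < n_ind; ++i) tmpl[i] = rng.unif() < p ? 1.0 : 0.0;
      for (size_t m = 0; m < members.size(); ++m) {
        NumericMatrix::Column col = X(_, members[m]);
        for (int i = 0; i < n_ind; ++i) {
          double allele = rng.unif() < q ? tmpl[i]
                                         : (rng.unif() < p ? 1.0 : 0.0);
          col[i] += allele;
        }
      }
    }
  }
  return X;
}

// per-column GWAS sufficient statistics over a row subset, in one pass
// and without materializing the submatrix: column mean, centered sum of
// squares, and centered cross-product with the (already centered)
// phenotype
// [[Rcpp::export]]
NumericMatrix col_gwas_stats_cpp(NumericMatrix X, NumericVector yc,
                                 IntegerVector rows) {
  int k = X.ncol();
  int m = rows.size();
  NumericMatrix out(3, k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0, s2 = 0.0, sxy = 0.0;
    NumericMatrix::Column col = X(_, j);
    for (int i = 0; i < m; ++i) {
      double x = col[rows[i] - 1];
      s += x;
      s2 += x * x;
      sxy += x * yc[i];
    }
    double mean = s / m;
    out(0, j) = mean;
    out(1, j) = s2 - m * mean * mean;
    out(2, j) = sxy;  // yc has mean 0, so no mean correction needed
  }
  return out;
}
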