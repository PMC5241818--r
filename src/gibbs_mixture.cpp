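#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the K-genome binomial mixture over per-cell SNV
// allele counts. Data arrive as covered (site, cell) triplets with the
// three per-genotype log-likelihoods (R/R, R/A, A/A) precomputed in R.
// One sweep alternates:
//   (i)  z_c ~ P(z_c = k) proportional to prod_sites L(r,a | g_{k,s})
//   (ii) g_{k,s} ~ P(g) proportional to prod_{cells: z_c = k} L(r,a | g)
// with uniform priors on both. Uses R's RNG, so runs are reproducible
// under set.seed().

static int sample_categorical(const double *logw, int n) {
  double m = logw[0];
  for (int i = 1; i < n; ++i) if (logw[i] > m) m = logw[i];
  double tot = 0.0;
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) { w[i] = std::exp(logw[i] - m); tot += w[i]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
List gibbs_mixture_chain(IntegerVector site, IntegerVector cell,
                         NumericMatrix ll, int nSites, int nCells, int K,
                         int nIter, int nBurnin, IntegerVector zInit,
                         IntegerMatrix gInit) {
  const int nnz = site.size();
  const int nKeep = nIter - nBurnin;
  std::vector<int> z(zInit.begin(), zInit.end());          // 0..K-1
  std::vector<int> g(nSites * K);                          // 0..2
  for (int s = 0; s < nSites; ++s)
    for (int k = 0; k < K; ++k) g[s * K + k] = gInit(s, k);

  IntegerMatrix zSamples(nKeep, nCells);
  NumericMatrix p1(nKeep, nCells);          // conditional P(z_c = 0)
  IntegerMatrix gSamples(nKeep, nSites * K);

  std::vector<double> cellLL(nCells * K);
  std::vector<double> siteLL(nSites * K * 3);

  for (int it = 0; it < nIter; ++it) {
    // (i) cell-to-genome assignments
    if (K > 1) {
      std::fill(cellLL.begin(), cellLL.end(), 0.0);
      for (int t = 0; t < nnz; ++t) {
        const int s = site[t], c = cell[t];
        for (int k = 0; k < K; ++k)
          cellLL[c * K + k] += ll(t, g[s * K + k]);
      }
      for (int c = 0; c < nCells; ++c) {
        const double *lw = &cellLL[c * K];
        z[c] = sample_categorical(lw, K);
        if (it >= nBurnin) {
          // store the conditional probability of genome 0 (K == 2)
          double m = std::max(lw[0], lw[1]);
          double w0 = std::exp(lw[0] - m), w1 = std::exp(lw[1] - m);
          p1(it - nBurnin, c) = w0 / (w0 + w1);
        }
      }
    }

    // (ii) per-genome per-site genotypes
    std::fill(siteLL.begin(), siteLL.end(), 0.0);
    for (int t = 0; t < nnz; ++t) {
      const int s = site[t], k = z[cell[t]];
      double *row = &siteLL[(s * K + k) * 3];
      row[0] += ll(t, 0);
      row[1] += ll(t, 1);
      row[2] += ll(t, 2);
    }
    for (int s = 0; s < nSites; ++s)
      for (int k = 0; k < K; ++k)
        g[s * K + k] = sample_categorical(&siteLL[(s * K + k) * 3], 3);

    if (it >= nBurnin) {
      const int row = it - nBurnin;
      for (int c = 0; c < nCells; ++c) zSamples(row, c) = z[c];
      for (int j = 0; j < nSites * K; ++j) gSamples(row, j) = g[j];
    }
  }

  return List::create(_["z"] = zSamples, _["p1"] = p1, _["g"] = gSamples);
}
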