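#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the simulation engine. Both use R's RNG (via RNGScope in
// Rcpp attributes) so results are reproducible under set.seed().

// Draw an n x m matrix of additive genotype counts (0/1/2), column j
// binomial(2, maf[j]), columns independent. A single uniform per entry is
// classified against the two Hardy-Weinberg cut points.
// [[Rcpp::export(name = ".drawGenotypesCpp")]]
NumericMatrix drawGenotypesCpp(int n, int m, NumericVector maf) {
  if (maf.size() != m) stop("maf must have length m");
  NumericMatrix G(n, m);
  for (int j = 0; j < m; ++j) {
    double p = maf[j];
    if (p < 0.0 || p > 1.0 || !R_finite(p)) stop("maf out of [0,1]");
    double q = 1.0 - p;
    double c0 = q * q;          // P(G = 0)
    double c1 = c0 + 2 * p * q; // P(G <= 1)
    double *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      col[i] = (u > c0) + (u > c1);
    }
  }
  return G;
}

// Fused null-SNP GWAS: draws M fresh null genotype columns one at a time and
// immediately regresses each phenotype on them over its own row subset,
// without materializing the genotype matrix. Y is the nTotal x K phenotype
// matrix; rowsList holds one 1-based row-index vector per phenotype. Returns
// the M x K matrix of z-scores.
// [[Rcpp::export(name = ".nullGwasCpp")]]
NumericMatrix nullGwasCpp(NumericMatrix Y, List rowsList, int M,
                          double mafLo, double mafHi) {
  int K = Y.ncol();
  int nTotal = Y.nrow();
  if (rowsList.size() != K) stop("need one row-index vector per phenotype");
  std::vector< std::vector<int> > rows(K);
  std::vector<double> Sy(K), Tyy(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector rk = rowsList[k];
    rows[k].resize(rk.size());
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < rk.size(); ++i) {
      int r = rk[i] - 1;
      if (r < 0 || r >= nTotal) stop("row index out of range");
      rows[k][i] = r;
      double yi = Y(r, k);
      s += yi;
      ss += yi * yi;
    }
    Sy[k] = s;
    Tyy[k] = ss - s * s / rk.size();
  }
  NumericMatrix Z(M, K);
  std::vector<double> g(nTotal);
  for (int s = 0; s < M; ++s) {
    double p = mafLo + unif_rand() * (mafHi - mafLo);
    double q = 1.0 - p;
    double c0 = q * q, c1 = c0 + 2 * p * q;
    for (int i = 0; i < nTotal; ++i) {
      double u = unif_rand();
      g[i] = (u > c0) + (u > c1);
    }
    for (int k = 0; k < K; ++k) {
      const std::vector<int> &rk = rows[k];
      int N = rk.size();
      double Sg = 0.0, Sgg = 0.0, Sgy = 0.0;
      for (int i = 0; i < N; ++i) {
        double gi = g[rk[i]];
        Sg += gi;
        Sgg += gi * gi;
        Sgy += gi * Y(rk[i], k);
      }
      double Tgg = Sgg - Sg * Sg / N;
      if (Tgg <= 0.0) { Z(s, k) = NA_REAL; continue; }
      double b = (Sgy - Sg * Sy[k] / N) / Tgg;
      double sse = Tyy[k] - b * b * Tgg;
      if (sse < 0.0) sse = 0.0;
      double se = sqrt(sse / ((N - 2.0) * Tgg));
      Z(s, k) = se > 0 ? b / se : NA_REAL;
    }
  }
  return Z;
}

// Simple linear regression of y on each column of G separately, using only
// the rows in `rows` (1-based). Returns per-column slope and its standard
// error. Monomorphic columns in the subsample get NA.
// [[Rcpp::export(name = ".snpRegressionCpp")]]
List snpRegressionCpp(NumericMatrix G, IntegerVector rows, NumericVector y) {
  int m = G.ncol();
  int N = rows.size();
  if (N < 3) stop("need at least 3 observations");
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) {
    int r = rows[i] - 1;
    if (r < 0 || r >= G.nrow()) stop("row index out of range");
    idx[i] = r;
  }
  if (y.size() != G.nrow()) stop("length(y) must equal nrow(G)");
  double Sy = 0.0, Syy = 0.0;
  for (int i = 0; i < N; ++i) {
    double yi = y[idx[i]];
    Sy += yi;
    Syy += yi * yi;
  }
  double Tyy = Syy - Sy * Sy / N;
  NumericVector beta(m), se(m);
  for (int j = 0; j < m; ++j) {
    double *col = &G(0, j);
    double Sg = 0.0, Sgg = 0.0, Sgy = 0.0;
    for (int i = 0; i < N; ++i) {
      double g = col[idx[i]];
      Sg += g;
      Sgg += g * g;
      Sgy += g * y[idx[i]];
    }
    double Tgg = Sgg - Sg * Sg / N;
    if (Tgg <= 0.0) {
      beta[j] = NA_REAL;
      se[j] = NA_REAL;
      continue;
    }
    double b = (Sgy - Sg * Sy / N) / Tgg;
    double sse = Tyy - b * b * Tgg;
    if (sse < 0.0) sse = 0.0;
    beta[j] = b;
    se[j] = sqrt(sse / ((N - 2.0) * Tgg));
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["n"] = N);
}
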