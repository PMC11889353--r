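#include <Rcpp.h>
using namespace Rcpp;

// One-pass generation of a structural-model cohort with per-SNP marginal
// regression accumulators.  Row-wise: for each individual draw the genotype
// row (Binomial(2, maf) as two Bernoulli allele draws), form U, X, Y from the
// three model equations, and accumulate the sufficient statistics of the
// per-SNP simple regressions of X and of Y on each genotype column.  Rows
// listed in `keep` (1-based) are copied out so the caller can subsample the
// cohort without materializing the full genotype matrix.
//
// Uses R's RNG (GetRNGstate via Rcpp), so results are governed by set.seed().
// [[Rcpp::export(name = ".sim_cohort_stats_cpp")]]
List sim_cohort_stats_cpp(int n, double maf,
                          NumericVector gamma, NumericVector alpha,
                          NumericVector phi,
                          double theta, double theta_ux, double theta_uy,
                          double noise_sd,
                          IntegerVector keep) {
  const int J = gamma.size();
  if (alpha.size() != J || phi.size() != J)
    stop("effect vectors must share one length");
  if (n < 3) stop("n must be at least 3");

  const bool any_phi = is_true(any(phi != 0.0));

  std::vector<double> sg(J, 0.0), sgg(J, 0.0), sgx(J, 0.0), sgy(J, 0.0);
  double sx = 0.0, sxx = 0.0, sy = 0.0, syy = 0.0;

  // map row index -> slot in the subsample output
  std::vector<int> slot(n, -1);
  const int nk = keep.size();
  for (int k = 0; k < nk; ++k) {
    int r = keep[k] - 1;
    if (r < 0 || r >= n) stop("keep index out of range");
    slot[r] = k;
  }
  IntegerMatrix Gk(nk > 0 ? nk : 0, nk > 0 ? J : 0);
  NumericVector Uk(nk), Xk(nk), Yk(nk);

  std::vector<int> grow(J);

  // Binomial(2, maf) via one inverse-CDF uniform per genotype
  const double p0 = (1.0 - maf) * (1.0 - maf);
  const double p01 = p0 + 2.0 * maf * (1.0 - maf);

  // RNG state is synced by the Rcpp attributes wrapper
  for (int i = 0; i < n; ++i) {
    double gdot_gamma = 0.0, gdot_alpha = 0.0, gdot_phi = 0.0;
    for (int j = 0; j < J; ++j) {
      double u = unif_rand();
      int g = (u >= p0) + (u >= p01);
      grow[j] = g;
      if (g) {
        gdot_gamma += g * gamma[j];
        gdot_alpha += g * alpha[j];
        if (any_phi) gdot_phi += g * phi[j];
      }
    }
    double U = gdot_phi + norm_rand() * noise_sd;
    double X = gdot_gamma + theta_ux * U + norm_rand() * noise_sd;
    double Y = gdot_alpha + theta * X + theta_uy * U + norm_rand() * noise_sd;

    sx += X; sxx += X * X;
    sy += Y; syy += Y * Y;
    for (int j = 0; j < J; ++j) {
      int g = grow[j];
      if (g) {
        sg[j] += g;
        sgg[j] += (double)g * g;
        sgx[j] += g * X;
        sgy[j] += g * Y;
      }
    }
    int s = slot[i];
    if (s >= 0) {
      for (int j = 0; j < J; ++j) Gk(s, j) = grow[j];
      Uk[s] = U; Xk[s] = X; Yk[s] = Y;
    }
  }

  // closed-form simple-regression summaries per SNP, for X and for Y
  NumericVector bx(J), sex(J), by(J), sey(J);
  const double dn = (double)n;
  const double sxx_c = sxx - sx * sx / dn;
  const double syy_c = syy - sy * sy / dn;
  for (int j = 0; j < J; ++j) {
    double sgg_c = sgg[j] - sg[j] * sg[j] / dn;
    if (sgg_c <= 0.0) {
      bx[j] = NA_REAL; sex[j] = NA_REAL;
      by[j] = NA_REAL; sey[j] = NA_REAL;
      continue;
    }
    double sgx_c = sgx[j] - sg[j] * sx / dn;
    double sgy_c = sgy[j] - sg[j] * sy / dn;
    double b1 = sgx_c / sgg_c;
    double rss1 = sxx_c - b1 * sgx_c; if (rss1 < 0) rss1 = 0;
    bx[j] = b1;
    sex[j] = std::sqrt(rss1 / ((dn - 2.0) * sgg_c));
    double b2 = sgy_c / sgg_c;
    double rss2 = syy_c - b2 * sgy_c; if (rss2 < 0) rss2 = 0;
    by[j] = b2;
    sey[j] = std::sqrt(rss2 / ((dn - 2.0) * sgg_c));
  }

  return List::create(
    _["beta_x"] = bx, _["se_x"] = sex,
    _["beta_y"] = by, _["se_y"] = sey,
    _["n"] = n,
    _["G_keep"] = Gk, _["U_keep"] = Uk, _["X_keep"] = Xk, _["Y_keep"] = Yk);
}
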