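#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded symmetric storage: band is a (bw+1) x m matrix with
// band(k, j) = A[j + k, j] for k = 0..bw (0-based), i.e. the diagonal and
// the bw sub-diagonals of each column.  Entries past the matrix edge are 0.

// y = A x for banded symmetric A.
// [[Rcpp::export(name = ".band_sym_mv")]]
NumericVector band_sym_mv(const NumericMatrix& band, const NumericVector& x) {
  const int m = band.ncol(), bw = band.nrow() - 1, ldb = bw + 1;
  const double* B = band.begin();
  const double* xp = x.begin();
  NumericVector y(m);
  double* yp = y.begin();
  for (int j = 0; j < m; ++j) {
    const double* col = B + (size_t)j * ldb;
    const double xj = xp[j];
    const int kmax = std::min(bw, m - 1 - j);
    double acc = col[0] * xj;
    for (int k = 1; k <= kmax; ++k) {
      const double a = col[k];
      yp[j + k] += a * xj;
      acc += a * xp[j + k];
    }
    yp[j] += acc;
  }
  return y;
}

// One coordinate-ascent pass of the variational updates for the
// spike-and-slab summary-statistic regression.  `Hr` carries H %*% (alpha*mu)
// and is maintained incrementally within the band.  `ord` is 1-based.
// `upd` marks coordinates to update (others stay frozen).
// [[Rcpp::export(name = ".vb_pass")]]
List vb_pass(const NumericVector& q, const NumericMatrix& Hband,
             const NumericVector& alpha_in, const NumericVector& mu_in,
             const NumericVector& Hr_in, const NumericVector& logodds_pi,
             const double sigma_beta2, const IntegerVector& ord,
             const LogicalVector& upd) {
  NumericVector alpha = clone(alpha_in), mu = clone(mu_in), Hr = clone(Hr_in);
  const int m = q.size(), bw = Hband.nrow() - 1, ldb = bw + 1;
  const double* B = Hband.begin();
  const double* qp = q.begin();
  const double* lo_pi = logodds_pi.begin();
  double* ap = alpha.begin();
  double* mp = mu.begin();
  double* rp = Hr.begin();
  const int* op = ord.begin();
  const int nord = ord.size();
  const double eps = 1e-12;
  for (int t = 0; t < nord; ++t) {
    const int j = op[t] - 1;
    if (!upd[j]) continue;
    const double hjj = B[(size_t)j * ldb];
    const double s2 = sigma_beta2 / (sigma_beta2 * hjj + 1.0);
    const double r_old = ap[j] * mp[j];
    // residualized linear coefficient: q_j - sum_{k != j} H_jk alpha_k mu_k
    const double resid = qp[j] - (rp[j] - hjj * r_old);
    const double mu_new = s2 * resid;
    const double lo = lo_pi[j] + 0.5 * std::log(s2 / sigma_beta2) +
                      mu_new * mu_new / (2.0 * s2);
    double a_new = 1.0 / (1.0 + std::exp(-lo));
    if (a_new < eps) a_new = eps;
    if (a_new > 1.0 - eps) a_new = 1.0 - eps;
    if (!std::isfinite(mu_new) || !std::isfinite(a_new))
      stop("non-finite variational update at SNP index %d", j + 1);
    const double delta = a_new * mu_new - r_old;
    if (delta != 0.0) {
      rp[j] += hjj * delta;
      const int klo = std::max(0, j - bw), khi = std::min(m - 1, j + bw);
      for (int k = klo; k < j; ++k)
        rp[k] += B[(size_t)k * ldb + (j - k)] * delta;
      const double* colj = B + (size_t)j * ldb;
      for (int k = j + 1; k <= khi; ++k)
        rp[k] += colj[k - j] * delta;
    }
    ap[j] = a_new;
    mp[j] = mu_new;
  }
  return List::create(_["alpha"] = alpha, _["mu"] = mu, _["Hr"] = Hr);
}

// Banded Cholesky A = L L' in the same storage; returns ok flag, the band of
// L, and log det A.  Fails (ok = FALSE) when a pivot is not positive.
// [[Rcpp::export(name = ".band_chol")]]
List band_chol(const NumericMatrix& band) {
  const int m = band.ncol(), bw = band.nrow() - 1, ldb = bw + 1;
  NumericMatrix L(clone(band));
  double* Lp = L.begin();
  double logdet = 0.0;
  for (int j = 0; j < m; ++j) {
    double* colj = Lp + (size_t)j * ldb;
    double d = colj[0];
    if (!(d > 0.0)) return List::create(_["ok"] = false, _["pivot"] = j + 1);
    d = std::sqrt(d);
    colj[0] = d;
    logdet += 2.0 * std::log(d);
    const int kmax = std::min(bw, m - 1 - j);
    for (int k = 1; k <= kmax; ++k) colj[k] /= d;
    // rank-1 downdate of the trailing band
    for (int c = 1; c <= kmax; ++c) {
      const double ljc = colj[c];
      if (ljc == 0.0) continue;
      double* colc = Lp + (size_t)(j + c) * ldb;
      for (int k = c; k <= kmax; ++k)
        colc[k - c] -= colj[k] * ljc;
    }
  }
  return List::create(_["ok"] = true, _["L"] = L, _["logdet"] = logdet);
}

// Solve A x = b given the banded Cholesky factor L (forward then back).
// [[Rcpp::export(name = ".band_chol_solve")]]
NumericVector band_chol_solve(const NumericMatrix& L, const NumericVector& b) {
  const int m = L.ncol(), bw = L.nrow() - 1, ldb = bw + 1;
  const double* Lp = L.begin();
  NumericVector x(clone(b));
  double* xp = x.begin();
  for (int j = 0; j < m; ++j) {           // L y = b
    const double* colj = Lp + (size_t)j * ldb;
    xp[j] /= colj[0];
    const int kmax = std::min(bw, m - 1 - j);
    for (int k = 1; k <= kmax; ++k) xp[j + k] -= colj[k] * xp[j];
  }
  for (int j = m - 1; j >= 0; --j) {      // L' x = y
    const double* colj = Lp + (size_t)j * ldb;
    const int kmax = std::min(bw, m - 1 - j);
    double acc = xp[j];
    for (int k = 1; k <= kmax; ++k) acc -= colj[k] * xp[j + k];
    xp[j] = acc / colj[0];
  }
  return x;
}

// Banded sample covariance of the columns of X (rows = samples), with the
// per-column forward extent `ext` giving the number of superdiagonals to
// fill for that column; denominator n - 1.
// [[Rcpp::export(name = ".band_sample_cov")]]
NumericMatrix band_sample_cov(const NumericMatrix& X, const IntegerVector& ext) {
  const int n = X.nrow(), m = X.ncol();
  if (n < 2) stop("need at least 2 panel rows to estimate LD");
  int bw = 0;
  for (int j = 0; j < m; ++j) bw = std::max(bw, ext[j]);
  NumericMatrix Xc(clone(X));
  double* Xp = Xc.begin();
  for (int j = 0; j < m; ++j) {
    double* col = Xp + (size_t)j * n;
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += col[i];
    mean /= n;
    for (int i = 0; i < n; ++i) col[i] -= mean;
  }
  NumericMatrix band(bw + 1, m);
  double* Bp = band.begin();
  const int ldb = bw + 1;
  for (int j = 0; j < m; ++j) {
    const double* colj = Xp + (size_t)j * n;
    const int kmax = std::min(ext[j], m - 1 - j);
    for (int k = 0; k <= kmax; ++k) {
      const double* colk = Xp + (size_t)(j + k) * n;
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += colj[i] * colk[i];
      Bp[(size_t)j * ldb + k] = acc / (n - 1);
    }
  }
  return band;
}

// Expected-log-likelihood part of the evidence lower bound:
// r'q - 0.5 r'Hr - 0.5 sum_j H_jj (alpha_j (mu_j^2 + s2_j) - r_j^2)
// with r = alpha * mu and s2_j = sb2 / (sb2 H_jj + 1).
// [[Rcpp::export(name = ".vb_elik")]]
double vb_elik(const NumericVector& q, const NumericMatrix& Hband,
               const NumericVector& alpha, const NumericVector& mu,
               const double sigma_beta2) {
  const int m = q.size();
  NumericVector r(m);
  for (int j = 0; j < m; ++j) r[j] = alpha[j] * mu[j];
  NumericVector Hr = band_sym_mv(Hband, r);
  const double* B = Hband.begin();
  const int ldb = Hband.nrow();
  double acc = 0.0;
  for (int j = 0; j < m; ++j) {
    const double hjj = B[(size_t)j * ldb];
    const double s2 = sigma_beta2 / (sigma_beta2 * hjj + 1.0);
    acc += r[j] * q[j] - 0.5 * r[j] * Hr[j] -
      0.5 * hjj * (alpha[j] * (mu[j] * mu[j] + s2) - r[j] * r[j]);
  }
  return acc;
}
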