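// FIML objective kernel for pair-structured family data.
//
// Families are grouped (in R, once per dataset x spec) into "patterns" that
// share a covariance class and an observed-slot mask, so the per-evaluation
// work is one Cholesky per pattern plus vectorized quadratic forms.
//
// Slot layout: for a family with m members and p traits, slot (j - 1) * p + t
// holds trait t of member j.  The design matrix D maps the mean-parameter
// vector theta to per-family slot means; D is stored with n * n_slots rows,
// row (s - 1) * n + i giving slot s of family i.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
double fiml_core(const arma::vec& theta, List sigma_list, List gmat_list,
                 List patterns) {
  double total = 0.0;
  int npat = patterns.size();
  for (int ip = 0; ip < npat; ++ip) {
    List pat = patterns[ip];
    int cls = as<int>(pat["cls"]) - 1;
    arma::uvec idx = as<arma::uvec>(pat["idx"]) - 1;  // observed slots
    arma::mat Y = as<arma::mat>(pat["Y"]);            // n x k
    arma::mat D = as<arma::mat>(pat["D"]);            // (n*nslot) x q
    int nslot = as<int>(pat["nslot"]);
    int n = Y.n_rows, k = Y.n_cols;

    arma::mat S_full = as<arma::mat>(sigma_list[cls]);
    if (!S_full.is_finite()) return R_PosInf;

    // full-slot means, then optional contrast mixing of member means
    arma::mat M = arma::reshape(D * theta, n, nslot);
    SEXP gm = gmat_list[cls];
    if (!Rf_isNull(gm)) {
      arma::mat G = as<arma::mat>(gm);
      M = M * G.t();
    }

    arma::mat S = S_full.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, S, "lower")) return R_PosInf;

    arma::mat R = Y - M.cols(idx);          // n x k residuals
    arma::mat Z = arma::solve(arma::trimatl(L), R.t());
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    total += n * (k * LOG2PI + logdet) + arma::accu(Z % Z);
  }
  return total;
}

// Same objective with the mean parameters profiled out in closed form:
// each family's contribution is quadratic in theta, so the generalized
// least-squares optimum is computed by accumulating the normal equations.
// free_cols / fixed_cols are 1-based indices into the design columns;
// fixed mean parameters keep the supplied values.
// [[Rcpp::export]]
List fiml_profiled(List sigma_list, List gmat_list, List patterns,
                   const arma::uvec& free_cols, const arma::uvec& fixed_cols,
                   const arma::vec& fixed_vals) {
  arma::uvec fr = free_cols - 1;
  arma::uvec fx = fixed_cols - 1;
  int qf = fr.n_elem;
  double constpart = 0.0, c0 = 0.0;
  arma::vec b(qf, arma::fill::zeros);
  arma::mat A(qf, qf, arma::fill::zeros);
  bool bad = false;
  int npat = patterns.size();
  for (int ip = 0; ip < npat && !bad; ++ip) {
    List pat = patterns[ip];
    int cls = as<int>(pat["cls"]) - 1;
    arma::uvec idx = as<arma::uvec>(pat["idx"]) - 1;
    arma::mat Y = as<arma::mat>(pat["Y"]);
    arma::mat D = as<arma::mat>(pat["D"]);
    int nslot = as<int>(pat["nslot"]);
    int n = Y.n_rows, k = Y.n_cols;

    arma::mat S_full = as<arma::mat>(sigma_list[cls]);
    if (!S_full.is_finite()) { bad = true; break; }
    arma::mat S = S_full.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, S, "lower")) { bad = true; break; }
    arma::mat Sinv = arma::inv_sympd(S);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    constpart += n * (k * LOG2PI + logdet);

    bool has_g = !Rf_isNull(gmat_list[cls]);
    arma::mat G;
    if (has_g) G = as<arma::mat>(gmat_list[cls]);

    for (int i = 0; i < n; ++i) {
      arma::uvec rows(nslot);
      for (int s = 0; s < nslot; ++s) rows[s] = (arma::uword)(s * n + i);
      arma::mat Df = D.rows(rows);          // nslot x q
      if (has_g) Df = G * Df;
      arma::mat Dk = Df.rows(idx);          // k x q
      arma::vec y = Y.row(i).t();
      if (fx.n_elem > 0) y -= Dk.cols(fx) * fixed_vals;
      arma::mat Dfree = Dk.cols(fr);
      arma::mat SiD = Sinv * Dfree;
      c0 += arma::as_scalar(y.t() * Sinv * y);
      b += SiD.t() * y;
      A += Dfree.t() * SiD;
    }
  }
  if (bad)
    return List::create(_["value"] = R_PosInf,
                        _["theta"] = NumericVector(qf));
  arma::vec theta(qf, arma::fill::zeros);
  double quad = c0;
  if (qf > 0) {
    if (!arma::solve(theta, A, b, arma::solve_opts::likely_sympd))
      return List::create(_["value"] = R_PosInf,
                          _["theta"] = NumericVector(qf));
    quad = c0 - arma::dot(b, theta);
  }
  return List::create(_["value"] = constpart + quad,
                      _["theta"] = NumericVector(theta.begin(), theta.end()));
}

// Profiled objective from precomputed per-pattern cross-moments (valid when
// the mean design is parameter-free, i.e. no contrast transform):
//   Syy (k x k)              = sum_i y_i y_i'
//   U   ((k*k) x q), row a*k+b = sum_i D_i[a,] * y_i[b]
//   T   ((k*k*q) x q), block a*k+b = sum_i D_i[a,]' D_i[b,]
// so A, b, c0 are contractions with Sinv and no per-family work remains.
// [[Rcpp::export]]
List fiml_profiled_mom(List sigma_list, List patterns,
                       const arma::uvec& free_cols,
                       const arma::uvec& fixed_cols,
                       const arma::vec& fixed_vals) {
  arma::uvec fr = free_cols - 1;
  arma::uvec fx = fixed_cols - 1;
  int qf = fr.n_elem;
  bool has_fx = fx.n_elem > 0;
  double constpart = 0.0, c0 = 0.0;
  arma::vec b(qf, arma::fill::zeros);
  arma::mat A(qf, qf, arma::fill::zeros);
  int npat = patterns.size();
  for (int ip = 0; ip < npat; ++ip) {
    List pat = patterns[ip];
    int cls = as<int>(pat["cls"]) - 1;
    arma::uvec idx = as<arma::uvec>(pat["idx"]) - 1;
    int n = as<int>(pat["n"]);
    arma::mat Syy = as<arma::mat>(pat["Syy"]);
    arma::mat U = as<arma::mat>(pat["U"]);
    arma::mat T = as<arma::mat>(pat["T"]);
    int k = idx.n_elem;
    int q = U.n_cols;

    arma::mat S_full = as<arma::mat>(sigma_list[cls]);
    if (!S_full.is_finite())
      return List::create(_["value"] = R_PosInf,
                          _["theta"] = NumericVector(qf));
    arma::mat S = S_full.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, S, "lower"))
      return List::create(_["value"] = R_PosInf,
                          _["theta"] = NumericVector(qf));
    arma::mat Sinv = arma::inv_sympd(S);
    constpart += n * (k * LOG2PI + 2.0 * arma::accu(arma::log(L.diag())));

    bool full_free = !has_fx && qf == q;
    for (int a = 0; a < k; ++a) {
      for (int bcol = 0; bcol < k; ++bcol) {
        double w = Sinv(a, bcol);
        if (w == 0.0) continue;
        int blk_ab = a * k + bcol;
        if (full_free) {
          c0 += w * Syy(a, bcol);
          b += w * U.row(blk_ab).t();
          A += w * T.rows(blk_ab * q, blk_ab * q + q - 1);
          continue;
        }
        int blk_ba = bcol * k + a;
        arma::mat Tab = T.rows(blk_ab * q, blk_ab * q + q - 1);
        double cterm = Syy(a, bcol);
        arma::vec Uab = U.row(blk_ab).t();  // sum_i D_i[a,] y_i[b]
        arma::vec Uba = U.row(blk_ba).t();  // sum_i D_i[b,] y_i[a]
        arma::vec bfree = Uab.elem(fr);
        if (has_fx) {
          arma::vec Tff = Tab.submat(fx, fx) * fixed_vals;
          cterm += -arma::dot(Uba.elem(fx), fixed_vals)
                   - arma::dot(Uab.elem(fx), fixed_vals)
                   + arma::dot(fixed_vals, Tff);
          bfree -= Tab.submat(fr, fx) * fixed_vals;
        }
        c0 += w * cterm;
        b += w * bfree;
        A += w * Tab.submat(fr, fr);
      }
    }
  }
  arma::vec theta(qf, arma::fill::zeros);
  double quad = c0;
  if (qf > 0) {
    if (!arma::solve(theta, A, b, arma::solve_opts::likely_sympd))
      return List::create(_["value"] = R_PosInf,
                          _["theta"] = NumericVector(qf));
    quad = c0 - arma::dot(b, theta);
  }
  return List::create(_["value"] = constpart + quad,
                      _["theta"] = NumericVector(theta.begin(), theta.end()));
}
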