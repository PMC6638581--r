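#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the three-level acquisition model
//
//   readings:  y_r ~ N(b_{img(r)}, s2e)
//   images:    b_j ~ N(a_{pat(j)} + beta[op(j)], s2v[op(j)])
//   patients:  a_i ~ N(mu, s2u)
//
// equivalently y = mu + beta_op + u_pat + v_img + e. Operator 0 is the
// instructor and carries no fixed effect (beta_0 = 0, the reference); each
// operator's image-level variance is informed by that operator's images
// only. Priors: improper flat on (mu, beta), inverse-gamma(prior_shape,
// prior_rate) on every variance.
//
// Partially collapsed update order, all conditionals conjugate:
//   1. theta = (mu, beta) ~ p(theta | variances, y): both the patient and
//      image effects are integrated out, so this is the exact GLS
//      posterior, accumulated per patient via Sherman-Morrison on the
//      image-mean covariance diag(s2v_op + s2e/n_j) + s2u * 11'.
//   2. a ~ p(a | theta, variances, y) with image effects integrated out.
//   3. b ~ p(b | a, theta, variances, y)  (full conditional).
//   4. variances ~ p(. | a, b, theta, y)  (inverse-gamma), skipped when
//      fix_variances is set.
// Steps 1-2 draw (theta, a) exactly from p(theta, a | variances, y), so
// fixed-effect mixing is limited only by the variance updates.
// Uses R's RNG: set.seed() on the R side controls reproducibility.
//
// Returned columns: mu, beta_1..beta_T, s2u, s2v_0..s2v_{n_ops-1}, s2e.
//
// [[Rcpp::export]]
arma::mat gibbs_chain(const arma::vec& y,
                      const arma::uvec& patient,   // 0-based, length N
                      const arma::uvec& image,     // 0-based, length N
                      const arma::uvec& image_op,  // 0-based, length J
                      const int n_ops,
                      const int n_iter,
                      const int burn_in,
                      const int thin,
                      const double prior_shape,
                      const double prior_rate,
                      const bool fix_variances,
                      const arma::vec& fixed_var) {
  const int N = y.n_elem;
  const int I = patient.max() + 1;
  const int J = image.max() + 1;
  const int T = n_ops - 1;  // trainees
  const int p = n_ops;      // fixed effects: mu + one beta per trainee

  // image-level constants
  arma::uvec img_pat(J);
  arma::vec n_img(J, arma::fill::zeros), sum_y_img(J, arma::fill::zeros);
  for (int r = 0; r < N; ++r) {
    img_pat(image(r)) = patient(r);
    n_img(image(r)) += 1.0;
    sum_y_img(image(r)) += y(r);
  }
  arma::vec m(J);  // per-image reading means (constant)
  for (int j = 0; j < J; ++j) m(j) = sum_y_img(j) / n_img(j);
  arma::vec J_op(n_ops, arma::fill::zeros);
  for (int j = 0; j < J; ++j) J_op(image_op(j)) += 1.0;

  // images grouped by patient
  std::vector< std::vector<int> > pat_imgs(I);
  for (int j = 0; j < J; ++j) pat_imgs[img_pat(j)].push_back(j);

  // state
  arma::vec theta(p, arma::fill::zeros);  // (mu, beta_1..beta_T)
  arma::vec a(I, arma::fill::zeros), b(J, arma::fill::zeros);
  double s2u, s2e;
  arma::vec s2v(n_ops);
  if (fix_variances) {
    s2u = fixed_var(0);
    for (int o = 0; o < n_ops; ++o) s2v(o) = fixed_var(1 + o);
    s2e = fixed_var(1 + n_ops);
  } else {
    double vy = arma::var(y);
    if (vy <= 0) vy = 1.0;
    s2u = vy / 3.0;
    s2v.fill(vy / 3.0);
    s2e = vy / 3.0;
  }

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat out(n_keep, 1 + T + 1 + n_ops + 1);
  int kept = 0;

  arma::mat A(p, p);
  arma::vec c(p), xw(p), z(p);

  for (int it = 0; it < n_iter; ++it) {
    // --- 1. theta | variances, y (a and b integrated out) ---
    A.zeros();
    c.zeros();
    for (int i = 0; i < I; ++i) {
      xw.zeros();              // sum_j w_j x_j
      double Si = 0.0, mw = 0.0;
      // diagonal part
      for (int j : pat_imgs[i]) {
        const int o = image_op(j);
        const double w = 1.0 / (s2v(o) + s2e / n_img(j));
        Si += w;
        mw += w * m(j);
        xw(0) += w;
        if (o > 0) xw(o) += w;
        A(0, 0) += w;
        if (o > 0) {
          A(0, o) += w;
          A(o, 0) += w;
          A(o, o) += w;
        }
        c(0) += w * m(j);
        if (o > 0) c(o) += w * m(j);
      }
      // rank-one patient-effect correction
      const double kappa = s2u / (1.0 + s2u * Si);
      A -= kappa * (xw * xw.t());
      c -= kappa * mw * xw;
    }
    {
      const arma::mat Ainv = arma::inv_sympd(A);
      const arma::mat L = arma::chol(Ainv, "lower");
      for (int k = 0; k < p; ++k) z(k) = norm_rand();
      theta = Ainv * c + L * z;
    }

    // --- 2. patient means a | theta, variances, y (b integrated out) ---
    for (int i = 0; i < I; ++i) {
      double prec = 1.0 / s2u, num = theta(0) / s2u;
      for (int j : pat_imgs[i]) {
        const int o = image_op(j);
        const double w = 1.0 / (s2v(o) + s2e / n_img(j));
        prec += w;
        num += w * (m(j) - (o > 0 ? theta(o) : 0.0));
      }
      a(i) = num / prec + norm_rand() / std::sqrt(prec);
    }

    // --- 3. image means b | a, theta, variances, y ---
    for (int j = 0; j < J; ++j) {
      const int o = image_op(j);
      const double s2vo = s2v(o);
      const double prior_mean = a(img_pat(j)) + (o > 0 ? theta(o) : 0.0);
      const double prec = n_img(j) / s2e + 1.0 / s2vo;
      const double mean = (sum_y_img(j) / s2e + prior_mean / s2vo) / prec;
      b(j) = mean + norm_rand() / std::sqrt(prec);
    }

    // --- 4. variances | a, b, theta, y ---
    if (!fix_variances) {
      double ss_u = 0.0;
      for (int i = 0; i < I; ++i)
        ss_u += (a(i) - theta(0)) * (a(i) - theta(0));
      s2u = 1.0 / R::rgamma(prior_shape + I / 2.0,
                            1.0 / (prior_rate + 0.5 * ss_u));

      arma::vec ss_op(n_ops, arma::fill::zeros);
      for (int j = 0; j < J; ++j) {
        const int o = image_op(j);
        const double d = b(j) - a(img_pat(j)) - (o > 0 ? theta(o) : 0.0);
        ss_op(o) += d * d;
      }
      for (int o = 0; o < n_ops; ++o)
        s2v(o) = 1.0 / R::rgamma(prior_shape + J_op(o) / 2.0,
                                 1.0 / (prior_rate + 0.5 * ss_op(o)));

      double ss_e = 0.0;
      for (int r = 0; r < N; ++r) {
        const double e = y(r) - b(image(r));
        ss_e += e * e;
      }
      s2e = 1.0 / R::rgamma(prior_shape + N / 2.0,
                            1.0 / (prior_rate + 0.5 * ss_e));
    }

    // --- store ---
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      out(kept, 0) = theta(0);
      for (int t = 1; t < n_ops; ++t) out(kept, t) = theta(t);
      out(kept, T + 1) = s2u;
      for (int o = 0; o < n_ops; ++o) out(kept, T + 2 + o) = s2v(o);
      out(kept, T + 2 + n_ops) = s2e;
      ++kept;
    }
  }
  return out;
}
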