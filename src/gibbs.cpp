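#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// One draw from N(mean, 1) truncated to (t, Inf) when y = 1 and to
// (-Inf, t] when y = 0. Inverse-CDF in the relevant tail so draws stay
// finite and on the correct side for |mean - t| up to ~8 SD.
static double rtrunc_norm(double mean, int y, double t) {
  double u = unif_rand();
  if (u <= 0.0) u = DBL_MIN;
  if (u >= 1.0) u = 1.0 - 1e-16;
  if (y == 1) {
    double s = R::pnorm(t - mean, 0.0, 1.0, 0, 0);  // P(Z > t - mean)
    double v = u * s;
    if (v <= 0.0) v = DBL_MIN;
    return mean + R::qnorm(v, 0.0, 1.0, 0, 0);
  }
  double f = R::pnorm(t - mean, 0.0, 1.0, 1, 0);    // P(Z <= t - mean)
  double v = u * f;
  if (v <= 0.0) v = DBL_MIN;
  return mean + R::qnorm(v, 0.0, 1.0, 1, 0);
}

// Gibbs sampler for the threshold liability animal model with repeated
// records: U = X b + Z_a a + Z_pe pe + e, e ~ N(0, 1), a ~ N(0, A s2a),
// pe ~ N(0, I s2pe), Y = 1(U > t). Fixed effects use a flat prior (block
// update via the Cholesky of X'X); breeding values are updated single-site
// (Gauss-Seidel) against the dense A-inverse; variances get scaled
// inverse-chi-square full conditionals. `gaussian = true` treats y as the
// observed liability (no truncation step), which is the Henderson
// mixed-model-equations check path.
// [[Rcpp::export]]
Rcpp::List gibbs_threshold_cpp(const arma::vec& y,
                               const arma::mat& X,
                               const arma::uvec& anim,
                               const arma::uvec& peid,
                               const arma::mat& Ainv,
                               int n_iter, int burnin, int thin,
                               double nu_a, double S_a,
                               double nu_pe, double S_pe,
                               double s2a_init, double s2pe_init,
                               bool gaussian, bool update_var,
                               double thresh) {
  const int N = y.n_elem;
  const int p = X.n_cols;
  const int na = Ainv.n_rows;
  const int npe = arma::max(peid) + 1;

  arma::vec cnt_a(na, arma::fill::zeros), cnt_pe(npe, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    cnt_a(anim(i)) += 1.0;
    cnt_pe(peid(i)) += 1.0;
  }

  arma::mat Rx = arma::chol(X.t() * X);  // upper: X'X = Rx' Rx

  arma::vec b(p, arma::fill::zeros), a(na, arma::fill::zeros),
      pe(npe, arma::fill::zeros), U(N);
  double s2a = s2a_init, s2pe = s2pe_init;
  if (gaussian) {
    U = y;
  } else {
    for (int i = 0; i < N; ++i)
      U(i) = thresh + (y(i) > 0.5 ? 0.5 : -0.5);
  }

  const int n_store = (n_iter - burnin) / thin;
  arma::mat keep_b(n_store, p), keep_a(n_store, na);
  arma::vec keep_s2a(n_store), keep_s2pe(n_store);
  int stored = 0;

  arma::vec xb = X * b, eta(N), sa(na), spe(npe), z(p), rhs(p);

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();

    // (1) latent liabilities
    if (!gaussian) {
      for (int i = 0; i < N; ++i) {
        double m = xb(i) + a(anim(i)) + pe(peid(i));
        U(i) = rtrunc_norm(m, y(i) > 0.5 ? 1 : 0, thresh);
        if (!std::isfinite(U(i)))
          Rcpp::stop("divergent liability at record %d (cycle %d)", i + 1,
                     iter);
      }
    }

    // (2) fixed effects: b | rest ~ N((X'X)^-1 X'r, (X'X)^-1)
    eta = U;
    for (int i = 0; i < N; ++i) eta(i) -= a(anim(i)) + pe(peid(i));
    rhs = X.t() * eta;
    arma::vec bhat = arma::solve(arma::trimatu(Rx),
                                 arma::solve(arma::trimatl(Rx.t()), rhs));
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    b = bhat + arma::solve(arma::trimatu(Rx), z);
    xb = X * b;

    // (3) breeding values, single-site given A^-1
    sa.zeros();
    for (int i = 0; i < N; ++i)
      sa(anim(i)) += U(i) - xb(i) - pe(peid(i));
    for (int j = 0; j < na; ++j) {
      double cross = arma::dot(Ainv.col(j), a) - Ainv(j, j) * a(j);
      double prec = cnt_a(j) + Ainv(j, j) / s2a;
      double mean = (sa(j) - cross / s2a) / prec;
      a(j) = mean + norm_rand() / std::sqrt(prec);
    }

    // (4) permanent environmental effects (diagonal conditionals)
    spe.zeros();
    for (int i = 0; i < N; ++i)
      spe(peid(i)) += U(i) - xb(i) - a(anim(i));
    for (int j = 0; j < npe; ++j) {
      double prec = cnt_pe(j) + 1.0 / s2pe;
      pe(j) = spe(j) / prec + norm_rand() / std::sqrt(prec);
    }

    // (5) variance components, scaled inverse chi-square
    if (update_var) {
      double qa = arma::as_scalar(a.t() * (Ainv * a));
      s2a = (qa + nu_a * S_a) / R::rchisq(na + nu_a);
      if (s2a < 1e-8) s2a = 1e-8;
      double qpe = arma::dot(pe, pe);
      s2pe = (qpe + nu_pe * S_pe) / R::rchisq(npe + nu_pe);
      if (s2pe < 1e-8) s2pe = 1e-8;
    }

    if (iter > burnin && (iter - burnin) % thin == 0) {
      keep_b.row(stored) = b.t();
      keep_a.row(stored) = a.t();
      keep_s2a(stored) = s2a;
      keep_s2pe(stored) = s2pe;
      ++stored;
    }
  }

  return Rcpp::List::create(Rcpp::Named("beta") = keep_b,
                            Rcpp::Named("a") = keep_a,
                            Rcpp::Named("sigma2_a") = keep_s2a,
                            Rcpp::Named("sigma2_pe") = keep_s2pe);
}
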