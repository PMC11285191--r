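#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Euler-Maruyama integration of the coupled Stuart-Landau network
//
//   dx_j = [(a_j - x_j^2 - y_j^2) x_j - w_j y_j + G sum_k C_jk (x_k - x_j)] dt + beta dW
//   dy_j = [(a_j - x_j^2 - y_j^2) y_j + w_j x_j + G sum_k C_jk (y_k - y_j)] dt + beta dW
//
// Noise is pregenerated on the R side (noise_x / noise_y are n x total-steps
// standard-normal draws) so that all randomness flows through R's RNG and
// per-subject seed streams stay reproducible.  The state is sampled every
// steps_per_sample steps after burn_steps; both the real (x) and imaginary
// (y) parts are returned so amplitude diagnostics are possible.
// [[Rcpp::export]]
Rcpp::List hopf_integrate_cpp(const arma::mat& C, const arma::vec& a,
                              const arma::vec& omega, double G, double beta,
                              double dt, int burn_steps, int steps_per_sample,
                              int n_samples, const arma::mat& noise_x,
                              const arma::mat& noise_y, arma::vec x,
                              arma::vec y, double bound) {
  const int n = C.n_rows;
  const vec rs = sum(C, 1);
  mat out_x(n, n_samples), out_y(n, n_samples);
  const double sq = beta * std::sqrt(dt);
  const double b2 = bound * bound;
  const int total = burn_steps + steps_per_sample * n_samples;
  int isamp = 0;
  for (int s = 0; s < total; ++s) {
    const vec r2 = x % x + y % y;
    const vec cx = C * x;
    const vec cy = C * y;
    const vec xn =
        x + dt * ((a - r2) % x - omega % y + G * (cx - rs % x)) + sq * noise_x.col(s);
    const vec yn =
        y + dt * ((a - r2) % y + omega % x + G * (cy - rs % y)) + sq * noise_y.col(s);
    x = xn;
    y = yn;
    if ((x % x + y % y).max() > b2)
      Rcpp::stop("divergence: |z| exceeded bound at step %d (unstable G/dt?)", s + 1);
    if (s >= burn_steps && ((s - burn_steps + 1) % steps_per_sample) == 0) {
      out_x.col(isamp) = x;
      out_y.col(isamp) = y;
      ++isamp;
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = out_x, Rcpp::Named("y") = out_y);
}
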