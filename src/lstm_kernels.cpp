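// Hot loops of the bidirectional-LSTM encoder: the sequential recurrence
// over timesteps. Inputs are time-major (T*B x dim) matrices; the input
// projection (x W_x + b) and all weight-gradient contractions are done in
// R as single BLAS calls, so only the per-timestep state update lives
// here. Gate layout in 4H blocks: input, forget, cell, output. Padded
// positions are handled by zeroing the carried state through the
// validity vector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& zx, const arma::mat& Wh,
                            const arma::vec& vall, const int B,
                            const int T, const bool keep_cache) {
  const int H = Wh.n_rows;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat hall(T * B, H);
  mat ci, cf, cg, co, ctc, ccp, chp;
  if (keep_cache) {
    ci.set_size(T * B, H); cf.set_size(T * B, H); cg.set_size(T * B, H);
    co.set_size(T * B, H); ctc.set_size(T * B, H);
    ccp.set_size(T * B, H); chp.set_size(T * B, H);
  }
  for (int t = 0; t < T; ++t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    mat z = zx.rows(r0, r1) + h * Wh;
    mat gi = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    mat gf = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = 1.0 / (1.0 + exp(-z.cols(3 * H, 4 * H - 1)));
    mat c_new = gf % c + gi % gg;
    mat tc = tanh(c_new);
    if (keep_cache) {
      ci.rows(r0, r1) = gi; cf.rows(r0, r1) = gf; cg.rows(r0, r1) = gg;
      co.rows(r0, r1) = go; ctc.rows(r0, r1) = tc;
      ccp.rows(r0, r1) = c; chp.rows(r0, r1) = h;
    }
    const vec v = vall.subvec(r0, r1);
    mat hn = go % tc;
    h = hn.each_col() % v;
    c = c_new;
    c.each_col() %= v;
    hall.rows(r0, r1) = h;
  }
  if (keep_cache) {
    return Rcpp::List::create(
      Rcpp::Named("hall") = hall, Rcpp::Named("i") = ci,
      Rcpp::Named("f") = cf, Rcpp::Named("g") = cg,
      Rcpp::Named("o") = co, Rcpp::Named("tc") = ctc,
      Rcpp::Named("c_prev") = ccp, Rcpp::Named("h_prev") = chp);
  }
  return Rcpp::List::create(Rcpp::Named("hall") = hall);
}

// [[Rcpp::export]]
arma::mat lstm_backward_cpp(const arma::mat& Wh, const arma::mat& dhall,
                            const arma::vec& vall, const arma::mat& ci,
                            const arma::mat& cf, const arma::mat& cg,
                            const arma::mat& co, const arma::mat& ctc,
                            const arma::mat& ccp, const int B,
                            const int T) {
  const int H = Wh.n_rows;
  mat dzall(T * B, 4 * H);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  const mat WhT = Wh.t();
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    const vec v = vall.subvec(r0, r1);
    const mat i_ = ci.rows(r0, r1), f_ = cf.rows(r0, r1);
    const mat g_ = cg.rows(r0, r1), o_ = co.rows(r0, r1);
    const mat tc = ctc.rows(r0, r1);
    mat dh = dhall.rows(r0, r1) + dh_next;
    dh.each_col() %= v;
    mat dc = dc_next;
    dc.each_col() %= v;
    mat dct = dh % o_ % (1.0 - tc % tc) + dc;
    dc_next = dct % f_;
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = dct % g_ % i_ % (1.0 - i_);
    dz.cols(H, 2 * H - 1) = dct % ccp.rows(r0, r1) % f_ % (1.0 - f_);
    dz.cols(2 * H, 3 * H - 1) = dct % i_ % (1.0 - g_ % g_);
    dz.cols(3 * H, 4 * H - 1) = (dh % tc) % o_ % (1.0 - o_);
    dzall.rows(r0, r1) = dz;
    dh_next = dz * WhT;
  }
  return dzall;
}
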