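// Convolution and LSTM time-loop kernels. The sequential recurrence over time steps is the
// only part of the network that cannot be expressed as a few large matrix
// products, so it runs compiled; the surrounding projections stay in R.
// Layout matches nn_ops.R: flat (B*T, u) state matrices, row = b + (t-1)*B,
// gate columns ordered input, forget, cell, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// 1-D convolution with 'same' zero padding on the flat layout: tap j of a
// k-tap kernel contributes shift_j(X) * W_j, a row-block shift of off*B
// rows. W is (k*Cin, Cout), tap-major.
// [[Rcpp::export]]
arma::mat conv1d_forward_cpp(const arma::mat& X, const arma::mat& W,
                             const arma::vec& b, const int k, const int B,
                             const int T) {
  const int cin = X.n_cols, cout = W.n_cols;
  const int pad = (k - 1) / 2;
  mat Y(B * T, cout);
  Y.each_row() = b.t();
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const int t0 = std::max(0, -off), t1 = std::min(T - 1, T - 1 - off);
    if (t0 > t1) continue;
    Y.rows(t0 * B, (t1 + 1) * B - 1) +=
        X.rows((t0 + off) * B, (t1 + 1 + off) * B - 1) *
        W.rows(j * cin, (j + 1) * cin - 1);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::mat& dY, const arma::mat& X,
                               const arma::mat& W, const int k, const int B,
                               const int T) {
  const int cin = X.n_cols;
  const int pad = (k - 1) / 2;
  mat dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const int t0 = std::max(0, -off), t1 = std::min(T - 1, T - 1 - off);
    if (t0 > t1) continue;
    const auto dYv = dY.rows(t0 * B, (t1 + 1) * B - 1);
    const auto Xv = X.rows((t0 + off) * B, (t1 + 1 + off) * B - 1);
    dW.rows(j * cin, (j + 1) * cin - 1) = Xv.t() * dYv;
    dX.rows((t0 + off) * B, (t1 + 1 + off) * B - 1) +=
        dYv * W.rows(j * cin, (j + 1) * cin - 1).t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = sum(dY, 0).t());
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& XW, const arma::mat& Wh,
                            const int B, const int T) {
  const int u = Wh.n_rows;
  mat H(B * T, u), Ig(B * T, u), Fg(B * T, u), Gg(B * T, u), Og(B * T, u),
      Cs(B * T, u), TC(B * T, u);
  mat h(B, u, fill::zeros), c(B, u, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    mat A = XW.rows(r0, r1) + h * Wh;
    mat i = sigmoid_m(A.cols(0, u - 1));
    mat f = sigmoid_m(A.cols(u, 2 * u - 1));
    mat g = tanh(A.cols(2 * u, 3 * u - 1));
    mat o = sigmoid_m(A.cols(3 * u, 4 * u - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    Ig.rows(r0, r1) = i; Fg.rows(r0, r1) = f;
    Gg.rows(r0, r1) = g; Og.rows(r0, r1) = o;
    Cs.rows(r0, r1) = c; TC.rows(r0, r1) = tc;
    H.rows(r0, r1) = h;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("Ig") = Ig, Rcpp::Named("Fg") = Fg,
      Rcpp::Named("Gg") = Gg, Rcpp::Named("Og") = Og, Rcpp::Named("Cs") = Cs,
      Rcpp::Named("TC") = TC);
}

// dH_seq may have zero rows (final-state mode: only dh_last feeds in).
// Returns the pre-activation gate gradients dA (B*T, 4u) and dWh; the
// caller turns dA into dX, dWx and db with three large matrix products.
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH_seq, const arma::mat& dh_last,
                             const arma::mat& Wh, const arma::mat& Ig,
                             const arma::mat& Fg, const arma::mat& Gg,
                             const arma::mat& Og, const arma::mat& Cs,
                             const arma::mat& TC, const arma::mat& H,
                             const int B, const int T) {
  const int u = Wh.n_rows;
  const bool has_seq = dH_seq.n_rows > 0;
  mat dA_all(B * T, 4 * u);
  mat dWh(u, 4 * u, fill::zeros);
  mat dh_next = dh_last;
  mat dc_next(B, u, fill::zeros);
  const mat zero_h(B, u, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    mat dh = has_seq ? mat(dH_seq.rows(r0, r1) + dh_next) : dh_next;
    const mat i = Ig.rows(r0, r1), f = Fg.rows(r0, r1);
    const mat g = Gg.rows(r0, r1), o = Og.rows(r0, r1);
    const mat tc = TC.rows(r0, r1);
    const mat c_prev = (t > 0) ? mat(Cs.rows(r0 - B, r1 - B)) : zero_h;
    mat do_ = dh % tc % o % (1.0 - o);
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat di = dc % g % i % (1.0 - i);
    mat dg = dc % i % (1.0 - g % g);
    mat df = dc % c_prev % f % (1.0 - f);
    dc_next = dc % f;
    mat dA = join_rows(join_rows(di, df), join_rows(dg, do_));
    dA_all.rows(r0, r1) = dA;
    const mat h_prev = (t > 0) ? mat(H.rows(r0 - B, r1 - B)) : zero_h;
    dWh += h_prev.t() * dA;
    dh_next = dA * Wh.t();
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA_all,
                            Rcpp::Named("dWh") = dWh);
}
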