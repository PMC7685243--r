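// Coupled striatal/prefrontal rate-network dynamics and the
// backpropagation-through-time gradient of the joint squared-error loss.
//
// Euler-discretized dynamics, per time step t (a = dt/tau):
//   x_s <- (1-a) x_s + a (W_rr_s tanh(x_s) + W_ir_s u_s(t) + eta_s(t))
//   u_v(t) = W_ro_s x_s                       (readout from currents)
//   u_p(t) = [u_v(t), u_ins(t)]
//   x_p <- (1-a) x_p + a (W_rr_p tanh(x_p) + W_ir_p u_p(t) + eta_p(t))
//   u_a(t) = W_ro_p x_p
// Loss over a block: w_str * sum (u_v - y_v)^2 + sum (u_a - y_a)^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List rnn_rollout_cpp(const arma::mat& W_rr_s, const arma::mat& W_ir_s,
                           const arma::mat& W_ro_s, const arma::mat& W_rr_p,
                           const arma::mat& W_ir_p, const arma::mat& W_ro_p,
                           const arma::mat& u_s, const arma::mat& u_ins,
                           const arma::vec& x0_s, const arma::vec& x0_p,
                           double a, const arma::mat& noise_s, const arma::mat& noise_p,
                           bool record_states) {
  const uword T = u_s.n_rows;
  const uword Ns = W_rr_s.n_rows, Np = W_rr_p.n_rows;
  const bool has_noise = noise_s.n_rows == T;
  vec xs = x0_s, xp = x0_p;
  mat UV(T, 10), UA(T, 11);
  mat XS, XP;
  if (record_states) { XS.set_size(T, Ns); XP.set_size(T, Np); }
  for (uword t = 0; t < T; ++t) {
    vec drive_s = W_rr_s * tanh(xs) + W_ir_s * u_s.row(t).t();
    if (has_noise) drive_s += noise_s.row(t).t();
    xs = (1.0 - a) * xs + a * drive_s;
    vec uv = W_ro_s * xs;
    vec up = join_cols(uv, u_ins.row(t).t());
    vec drive_p = W_rr_p * tanh(xp) + W_ir_p * up;
    if (has_noise) drive_p += noise_p.row(t).t();
    xp = (1.0 - a) * xp + a * drive_p;
    UV.row(t) = uv.t();
    UA.row(t) = (W_ro_p * xp).t();
    if (record_states) { XS.row(t) = xs.t(); XP.row(t) = xp.t(); }
    if (!xs.is_finite() || !xp.is_finite())
      Rcpp::stop("non-finite network state at step %d", (int)(t + 1));
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("u_v") = UV, Rcpp::Named("u_a") = UA,
      Rcpp::Named("x_end_s") = xs, Rcpp::Named("x_end_p") = xp);
  if (record_states) { out["x_s"] = XS; out["x_p"] = XP; }
  return out;
}

// Forward pass (storing currents), then reverse-mode accumulation of the
// loss gradient with respect to all six weight matrices.
// [[Rcpp::export]]
Rcpp::List rnn_bptt_cpp(const arma::mat& W_rr_s, const arma::mat& W_ir_s,
                        const arma::mat& W_ro_s, const arma::mat& W_rr_p,
                        const arma::mat& W_ir_p, const arma::mat& W_ro_p,
                        const arma::mat& u_s, const arma::mat& u_ins,
                        const arma::mat& y_v, const arma::mat& y_a,
                        const arma::vec& x0_s, const arma::vec& x0_p,
                        double a, double w_str,
                        const arma::mat& noise_s, const arma::mat& noise_p) {
  const uword T = u_s.n_rows;
  const uword Ns = W_rr_s.n_rows, Np = W_rr_p.n_rows;
  const bool has_noise = noise_s.n_rows == T;

  mat XS(Ns, T), XP(Np, T), UP(20, T);
  mat UV(10, T), UA(11, T);
  vec xs = x0_s, xp = x0_p;
  for (uword t = 0; t < T; ++t) {
    vec drive_s = W_rr_s * tanh(xs) + W_ir_s * u_s.row(t).t();
    if (has_noise) drive_s += noise_s.row(t).t();
    xs = (1.0 - a) * xs + a * drive_s;
    vec uv = W_ro_s * xs;
    vec up = join_cols(uv, u_ins.row(t).t());
    vec drive_p = W_rr_p * tanh(xp) + W_ir_p * up;
    if (has_noise) drive_p += noise_p.row(t).t();
    xp = (1.0 - a) * xp + a * drive_p;
    XS.col(t) = xs; XP.col(t) = xp; UP.col(t) = up;
    UV.col(t) = uv; UA.col(t) = W_ro_p * xp;
  }
  if (!XS.is_finite() || !XP.is_finite())
    Rcpp::stop("non-finite network state during BPTT forward pass");

  double loss = w_str * accu(square(UV - y_v.t())) +
                accu(square(UA - y_a.t()));

  mat gW_rr_s(size(W_rr_s), fill::zeros), gW_ir_s(size(W_ir_s), fill::zeros),
      gW_ro_s(size(W_ro_s), fill::zeros), gW_rr_p(size(W_rr_p), fill::zeros),
      gW_ir_p(size(W_ir_p), fill::zeros), gW_ro_p(size(W_ro_p), fill::zeros);
  vec gxs_next(Ns, fill::zeros), gxp_next(Np, fill::zeros);
  const mat Wirp_v = W_ir_p.cols(0, 9); // value block of prefrontal input

  for (uword tt = T; tt-- > 0;) {
    vec rp_prev = tt > 0 ? vec(tanh(XP.col(tt - 1))) : vec(tanh(x0_p));
    vec rs_prev = tt > 0 ? vec(tanh(XS.col(tt - 1))) : vec(tanh(x0_s));

    vec dua = 2.0 * (UA.col(tt) - y_a.row(tt).t());
    vec gxp = W_ro_p.t() * dua;
    {
      vec rp_t = tanh(XP.col(tt));
      gxp += (1.0 - a) * gxp_next +
             (1.0 - square(rp_t)) % (W_rr_p.t() * (a * gxp_next));
    }
    vec duv = 2.0 * w_str * (UV.col(tt) - y_v.row(tt).t()) +
              Wirp_v.t() * (a * gxp);
    vec gxs = W_ro_s.t() * duv;
    {
      vec rs_t = tanh(XS.col(tt));
      gxs += (1.0 - a) * gxs_next +
             (1.0 - square(rs_t)) % (W_rr_s.t() * (a * gxs_next));
    }
    gW_ro_p += dua * XP.col(tt).t();
    gW_ro_s += duv * XS.col(tt).t();
    vec agxp = a * gxp, agxs = a * gxs;
    gW_rr_p += agxp * rp_prev.t();
    gW_ir_p += agxp * UP.col(tt).t();
    gW_rr_s += agxs * rs_prev.t();
    gW_ir_s += agxs * u_s.row(tt);
    gxp_next = gxp;
    gxs_next = gxs;
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("gW_rr_s") = gW_rr_s, Rcpp::Named("gW_ir_s") = gW_ir_s,
      Rcpp::Named("gW_ro_s") = gW_ro_s, Rcpp::Named("gW_rr_p") = gW_rr_p,
      Rcpp::Named("gW_ir_p") = gW_ir_p, Rcpp::Named("gW_ro_p") = gW_ro_p,
      Rcpp::Named("u_v") = UV.t(), Rcpp::Named("u_a") = UA.t());
}
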