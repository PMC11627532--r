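// Rate-coded settling dynamics for the two-pathway hippocampal autoencoder.
// Layers: Input(26) -> EC_in(26) -> {DG -> CA3 -> CA1 | CA1} -> EC_out(26),
// with one-to-one big-loop recurrence EC_out -> EC_in.
// Units are bounded in [0,1]; hidden layers use a k-winners-take-all adaptive
// threshold (floored at a fixed minimum) inside a logistic transfer function.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec logistic_vec(const vec& x) {
  return 1.0 / (1.0 + exp(-x));
}

// kWTA transfer: threshold sits midway between the k-th and (k+1)-th largest
// net input, never below theta. At uniform (e.g. zero) drive the adaptive part
// equals the common drive and the floor dominates, so no unit is favoured.
static vec kwta_transfer(const vec& net, int k, double theta, double gain) {
  double thr = theta;
  int n = net.n_elem;
  if (k >= 1 && k < n) {
    vec s = sort(net, "descend");
    double adapt = 0.5 * (s(k - 1) + s(k));
    if (adapt > thr) thr = adapt;
  }
  return logistic_vec(gain * (net - thr));
}

// [[Rcpp::export]]
Rcpp::List settle_cpp(const arma::mat& W_ec_dg,
                      const arma::mat& W_ec_ca3,
                      const arma::mat& W_dg_ca3,
                      const arma::mat& W_ca3_ca1,
                      const arma::mat& W_ec_ca1,
                      const arma::mat& W_ca1_out,
                      const arma::vec& input,
                      Rcpp::Nullable<Rcpp::NumericVector> output_clamp,
                      bool tsp_on, bool msp_on, bool bigloop_on,
                      int n_cycles,
                      Rcpp::List par) {
  if (n_cycles <= 0) Rcpp::stop("n_cycles must be positive");

  const double s_ec_dg   = par["s_ec_dg"];
  const double s_ec_ca3  = par["s_ec_ca3"];
  const double s_dg_ca3  = par["s_dg_ca3"];
  const double s_ca3_ca1 = par["s_ca3_ca1"];
  const double s_ec_ca1  = par["s_ec_ca1"];
  const double s_ca1_out = par["s_ca1_out"];
  const int    k_dg      = par["k_dg"];
  const int    k_ca3     = par["k_ca3"];
  const int    k_ca1     = par["k_ca1"];
  const double gain_h    = par["gain_hidden"];
  const double gain_ca1  = par["gain_ca1"];
  const double theta_h   = par["theta_hidden"];
  const double gain_ec   = par["gain_ec"];
  const double theta_ec  = par["theta_ec"];
  const double theta_out = par["theta_out"];
  const int    k_out     = par["k_out"];
  const double loop_s    = par["loop_scale"];
  const double dt        = par["dt"];

  const uword n_ec  = input.n_elem;
  const uword n_dg  = W_ec_dg.n_rows;
  const uword n_ca3 = W_ec_ca3.n_rows;
  const uword n_ca1 = W_ec_ca1.n_rows;

  vec a_ecin(n_ec, fill::zeros);
  vec a_dg(n_dg, fill::zeros);
  vec a_ca3(n_ca3, fill::zeros);
  vec a_ca1(n_ca1, fill::zeros);
  vec a_out(n_ec, fill::zeros);

  bool clamped = output_clamp.isNotNull();
  vec clamp_vec;
  if (clamped) {
    clamp_vec = Rcpp::as<vec>(output_clamp.get());
    a_out = clamp_vec;
  }

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    vec ecin_net = input;
    if (bigloop_on) ecin_net += loop_s * a_out;
    vec ecin_tgt = logistic_vec(gain_ec * (ecin_net - theta_ec));
    a_ecin += dt * (ecin_tgt - a_ecin);

    if (tsp_on) {
      vec dg_net = s_ec_dg * (W_ec_dg * a_ecin);
      a_dg += dt * (kwta_transfer(dg_net, k_dg, theta_h, gain_h) - a_dg);
      vec ca3_net = s_ec_ca3 * (W_ec_ca3 * a_ecin) + s_dg_ca3 * (W_dg_ca3 * a_dg);
      a_ca3 += dt * (kwta_transfer(ca3_net, k_ca3, theta_h, gain_h) - a_ca3);
    } else {
      a_dg.zeros();
      a_ca3.zeros();
    }

    vec ca1_net(n_ca1, fill::zeros);
    if (tsp_on) ca1_net += s_ca3_ca1 * (W_ca3_ca1 * a_ca3);
    if (msp_on) ca1_net += s_ec_ca1 * (W_ec_ca1 * a_ecin);
    a_ca1 += dt * (kwta_transfer(ca1_net, k_ca1, theta_h, gain_ca1) - a_ca1);

    if (clamped) {
      a_out = clamp_vec;
    } else {
      vec out_net = s_ca1_out * (W_ca1_out * a_ca1);
      a_out += dt * (kwta_transfer(out_net, k_out, theta_out, gain_ec) - a_out);
    }
  }

  return Rcpp::List::create(Rcpp::Named("ec_in") = a_ecin,
                            Rcpp::Named("dg") = a_dg,
                            Rcpp::Named("ca3") = a_ca3,
                            Rcpp::Named("ca1") = a_ca1,
                            Rcpp::Named("ec_out") = a_out);
}
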