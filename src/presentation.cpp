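#include <Rcpp.h>
using namespace Rcpp;

// STDP scaling functions; rule: 0 = add, 1 = mult, 2 = log
static inline double a_plus_c(double W, int rule, double c_plus,
                              double W0, double gamma_) {
  if (rule == 2) return c_plus * std::exp(-W / (W0 * gamma_));
  return c_plus;
}

static inline double a_minus_c(double W, int rule, double c_minus,
                               double W0, double S) {
  if (rule == 0) return c_minus;
  if (rule == 1) return c_minus * W;
  double r = W / W0;
  if (r <= 1.0) return c_minus * r;
  return c_minus * (1.0 + std::log1p(S * (r - 1.0)) / S);
}

// One full presentation of a stimulus at fixed per-step spike
// probabilities. Clock-driven explicit Euler for the membranes, exact
// exponential decay for conductances, traces and homeostatic offsets.
// Weight updates use the additive-trace online STDP scheme. Uses the R
// RNG, so runs are reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List present_cpp(NumericMatrix W_in, NumericVector p_spike,
                 List exc_par, List inh_par,
                 double w_ei, double w_ie,
                 List stdp, bool plastic,
                 List state, int steps, double dt) {
  const int n_in = W_in.nrow(), n_exc = W_in.ncol();
  NumericMatrix W = clone(W_in);

  // excitatory parameters
  const double e_tau = as<double>(exc_par["tau_m"]);
  const double e_rest = as<double>(exc_par["E_rest"]);
  const double e_exc = as<double>(exc_par["E_exc"]);
  const double e_inh = as<double>(exc_par["E_inh"]);
  const double e_vth = as<double>(exc_par["v_thresh"]);
  const double e_vres = as<double>(exc_par["v_reset"]);
  const double e_refrac = as<double>(exc_par["t_refrac"]);
  const double e_tge = as<double>(exc_par["tau_ge"]);
  const double e_tgi = as<double>(exc_par["tau_gi"]);
  const double theta_inc = as<double>(exc_par["theta_inc"]);
  const double tau_theta = as<double>(exc_par["tau_theta"]);
  // inhibitory parameters
  const double i_tau = as<double>(inh_par["tau_m"]);
  const double i_rest = as<double>(inh_par["E_rest"]);
  const double i_exc = as<double>(inh_par["E_exc"]);
  const double i_inh = as<double>(inh_par["E_inh"]);
  const double i_vth = as<double>(inh_par["v_thresh"]);
  const double i_vres = as<double>(inh_par["v_reset"]);
  const double i_refrac = as<double>(inh_par["t_refrac"]);
  const double i_tge = as<double>(inh_par["tau_ge"]);
  const double i_tgi = as<double>(inh_par["tau_gi"]);
  // STDP
  const std::string rule_s = as<std::string>(stdp["rule"]);
  const int rule = rule_s == "add" ? 0 : (rule_s == "mult" ? 1 : 2);
  const double eta = as<double>(stdp["eta"]);
  const double sigma = as<double>(stdp["sigma"]);
  const double c_plus = as<double>(stdp["c_plus"]);
  const double c_minus = as<double>(stdp["c_minus"]);
  const double tau_p = as<double>(stdp["tau_plus"]);
  const double tau_mn = as<double>(stdp["tau_minus"]);
  const double S = as<double>(stdp["S"]);
  const double gamma_ = as<double>(stdp["gamma"]);
  const double W0 = as<double>(stdp["W0"]);
  const double w_min = as<double>(stdp["w_min"]);
  const double w_max = as<double>(stdp["w_max"]);
  const double A_pre0 = as<double>(stdp["A_pre0"]);
  const double A_post0 = as<double>(stdp["A_post0"]);
  const bool trunc_noise = as<bool>(stdp["truncate_noise"]);

  NumericVector Xe = clone(as<NumericVector>(state["Xe"]));
  NumericVector ge_e = clone(as<NumericVector>(state["ge_e"]));
  NumericVector gi_e = clone(as<NumericVector>(state["gi_e"]));
  NumericVector theta = clone(as<NumericVector>(state["theta"]));
  NumericVector refr_e = clone(as<NumericVector>(state["refrac_e"]));
  NumericVector Xi = clone(as<NumericVector>(state["Xi"]));
  NumericVector ge_i = clone(as<NumericVector>(state["ge_i"]));
  NumericVector refr_i = clone(as<NumericVector>(state["refrac_i"]));
  NumericVector x_pre = clone(as<NumericVector>(state["x_pre"]));
  NumericVector x_post = clone(as<NumericVector>(state["x_post"]));

  const double d_ge_e = std::exp(-dt / e_tge), d_gi_e = std::exp(-dt / e_tgi);
  const double d_ge_i = std::exp(-dt / i_tge), d_gi_i = std::exp(-dt / i_tgi);
  const double d_theta = std::exp(-dt / tau_theta);
  const double d_xpre = std::exp(-dt / tau_p), d_xpost = std::exp(-dt / tau_mn);

  IntegerVector exc_counts(n_exc), inh_counts(n_exc);
  int total_exc = 0;
  RNGScope scope;

  for (int k = 0; k < steps; ++k) {
    // homeostatic and trace decay (thresholds frozen during inference)
    if (plastic) {
      for (int j = 0; j < n_exc; ++j) theta[j] *= d_theta;
      for (int i = 0; i < n_in; ++i) x_pre[i] *= d_xpre;
      for (int j = 0; j < n_exc; ++j) x_post[j] *= d_xpost;
    }

    // input layer: Bernoulli-thinned Poisson spikes
    for (int i = 0; i < n_in; ++i) {
      if (p_spike[i] <= 0.0 || unif_rand() >= p_spike[i]) continue;
      if (plastic) {
        // depression proportional to the postsynaptic trace, then bump
        // the presynaptic trace (so an exact tie counts as potentiation)
        for (int j = 0; j < n_exc; ++j) {
          if (x_post[j] <= 0.0) continue;
          double z = sigma > 0 ? sigma * norm_rand() : 0.0;
          if (trunc_noise && z < -1.0) z = -1.0;
          double w = W(i, j);
          w -= eta * (1.0 + z) * a_minus_c(w, rule, c_minus, W0, S) * x_post[j];
          W(i, j) = w < w_min ? w_min : (w > w_max ? w_max : w);
        }
        x_pre[i] += A_pre0;
      }
      for (int j = 0; j < n_exc; ++j) ge_e[j] += W(i, j);
    }

    // excitatory membranes (explicit Euler; refractory clamp)
    for (int j = 0; j < n_exc; ++j) {
      if (refr_e[j] > 0.0) {
        Xe[j] = e_vres;
        refr_e[j] -= dt;
      } else {
        double x = Xe[j];
        x += dt / e_tau * ((e_rest - x) + ge_e[j] * (e_exc - x) +
                           gi_e[j] * (e_inh - x));
        if (!std::isfinite(x))
          stop("non-finite membrane potential at excitatory neuron %d", j + 1);
        Xe[j] = x;
      }
      ge_e[j] *= d_ge_e;
      gi_e[j] *= d_gi_e;
    }

    // inhibitory membranes
    for (int j = 0; j < n_exc; ++j) {
      if (refr_i[j] > 0.0) {
        Xi[j] = i_vres;
        refr_i[j] -= dt;
      } else {
        double x = Xi[j];
        x += dt / i_tau * ((i_rest - x) + ge_i[j] * (i_exc - x));
        (void)i_inh;  // inhibitory neurons receive no inhibitory input here
        Xi[j] = x;
      }
      ge_i[j] *= d_ge_i;
    }

    // excitatory threshold crossings
    for (int j = 0; j < n_exc; ++j) {
      if (refr_e[j] > 0.0 || Xe[j] < e_vth + theta[j]) continue;
      Xe[j] = e_vres;
      refr_e[j] = e_refrac;
      exc_counts[j] += 1;
      ++total_exc;
      if (plastic) {
        theta[j] += theta_inc;
        // potentiation proportional to the presynaptic traces
        for (int i = 0; i < n_in; ++i) {
          if (x_pre[i] <= 0.0) continue;
          double z = sigma > 0 ? sigma * norm_rand() : 0.0;
          if (trunc_noise && z < -1.0) z = -1.0;
          double w = W(i, j);
          w += eta * (1.0 + z) * a_plus_c(w, rule, c_plus, W0, gamma_) * x_pre[i];
          W(i, j) = w < w_min ? w_min : (w > w_max ? w_max : w);
        }
        x_post[j] += A_post0;
      }
      ge_i[j] += w_ei;  // one-to-one drive onto the partner inhibitory neuron
    }

    // inhibitory threshold crossings: inhibit all but the partner
    for (int j = 0; j < n_exc; ++j) {
      if (refr_i[j] > 0.0 || Xi[j] < i_vth) continue;
      Xi[j] = i_vres;
      refr_i[j] = i_refrac;
      inh_counts[j] += 1;
      for (int jj = 0; jj < n_exc; ++jj)
        if (jj != j) gi_e[jj] += w_ie;
    }
  }

  return List::create(
    _["W"] = W,
    _["exc_counts"] = exc_counts,
    _["inh_counts"] = inh_counts,
    _["total_exc"] = total_exc,
    _["state"] = List::create(
      _["Xe"] = Xe, _["ge_e"] = ge_e, _["gi_e"] = gi_e,
      _["theta"] = theta, _["refrac_e"] = refr_e,
      _["Xi"] = Xi, _["ge_i"] = ge_i, _["refrac_i"] = refr_i,
      _["x_pre"] = x_pre, _["x_post"] = x_post));
}
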