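#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// In-place Hines solve of one assembled system.
// elim: 0-based non-root node indices in elimination (child-before-parent)
// order; back-substitution runs the exact reverse.
static void hines_solve_inplace(const std::vector<int> &parent,
                                const std::vector<int> &elim,
                                std::vector<double> &d,
                                const std::vector<double> &off,
                                std::vector<double> &rhs,
                                std::vector<double> &x) {
  const int n = parent.size();
  for (int idx = 0; idx < (int)elim.size(); ++idx) {
    int i = elim[idx];
    int p = parent[i];
    double f = off[i] / d[i];
    d[p] -= f * off[i];
    rhs[p] -= f * rhs[i];
  }
  x[0] = rhs[0] / d[0];
  for (int idx = (int)elim.size() - 1; idx >= 0; --idx) {
    int i = elim[idx];
    x[i] = (rhs[i] - off[i] * x[parent[i]]) / d[i];
  }
}

// Fixed-step backward-Euler simulation of one passive tree with
// conductance-based synapses.
//
// parent: 0-based parent index per node (-1 at the root, node 0)
// elim:   elimination order (0-based non-root indices)
// synapses: kind 0 = single-exponential, 1 = double-exponential,
//           2 = double-exponential with Mg-block voltage dependence
// spike times are matched to step boundaries (dt resolution); the Mg-block
// factor is evaluated at the previous-step voltage (staggered), all other
// synaptic conductance enters the step implicitly.
// [[Rcpp::export]]
List simulate_core_cpp(IntegerVector parent, IntegerVector elim,
                       NumericVector c_nf, NumericVector g_leak,
                       NumericVector g_axial, NumericVector el,
                       NumericVector v0, NumericVector i_inj,
                       double dt, int n_steps,
                       IntegerVector syn_node, IntegerVector syn_kind,
                       NumericVector syn_gmax, NumericVector syn_tau_r,
                       NumericVector syn_tau_d, NumericVector syn_esyn,
                       NumericVector syn_norm,
                       NumericVector spike_times, IntegerVector spike_off,
                       IntegerVector record, double mg, double gamma) {
  const int n = parent.size();
  const int nsyn = syn_node.size();
  const int nrec = record.size();

  std::vector<int> par(n), order(elim.size());
  for (int i = 0; i < n; ++i) par[i] = parent[i];
  for (size_t i = 0; i < order.size(); ++i) order[i] = elim[i];

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> A(nsyn, 0.0), B(nsyn, 0.0), G(nsyn, 0.0);
  std::vector<double> ea(nsyn), eb(nsyn);
  std::vector<int> ev(nsyn); // next spike-event pointer per synapse
  for (int s = 0; s < nsyn; ++s) {
    if (syn_kind[s] == 0) {
      ea[s] = std::exp(-dt / syn_tau_d[s]);
    } else {
      ea[s] = std::exp(-dt / syn_tau_r[s]);
      eb[s] = std::exp(-dt / syn_tau_d[s]);
    }
    ev[s] = spike_off[s];
  }

  NumericMatrix traces(n_steps, nrec);
  std::vector<double> d(n), rhs(n), x(n), gsum(n), gesum(n), off(n);
  for (int i = 0; i < n; ++i) off[i] = -g_axial[i];

  for (int step = 1; step <= n_steps; ++step) {
    double t_new = step * dt;
    // advance synaptic states to t_new and collect per-node conductances
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      if (syn_kind[s] == 0) {
        G[s] *= ea[s];
        while (ev[s] < spike_off[s + 1] &&
               spike_times[ev[s]] <= t_new + 1e-9) {
          G[s] += syn_gmax[s];
          ++ev[s];
        }
      } else {
        A[s] *= ea[s];
        B[s] *= eb[s];
        while (ev[s] < spike_off[s + 1] &&
               spike_times[ev[s]] <= t_new + 1e-9) {
          A[s] += 1.0;
          B[s] += 1.0;
          ++ev[s];
        }
      }
      double g;
      if (syn_kind[s] == 0) {
        g = G[s];
      } else {
        g = syn_gmax[s] * syn_norm[s] * (B[s] - A[s]);
        if (syn_kind[s] == 2) {
          double block = 1.0 / (1.0 + mg * std::exp(-gamma * v[syn_node[s]]) / 3.57);
          g *= block;
        }
      }
      gsum[syn_node[s]] += g;
      gesum[syn_node[s]] += g * syn_esyn[s];
    }
    // assemble
    for (int i = 0; i < n; ++i) {
      double cdt = c_nf[i] / dt;
      d[i] = cdt + g_leak[i] + gsum[i];
      rhs[i] = cdt * v[i] + g_leak[i] * el[i] + gesum[i] + i_inj[i];
    }
    for (int i = 1; i < n; ++i) {
      d[i] += g_axial[i];
      d[par[i]] += g_axial[i];
    }
    hines_solve_inplace(par, order, d, off, rhs, x);
    for (int i = 0; i < n; ++i) {
      v[i] = x[i];
      if (!std::isfinite(v[i])) {
        stop("numerical instability: non-finite voltage at step %d", step);
      }
    }
    for (int r = 0; r < nrec; ++r) traces(step - 1, r) = v[record[r]];
  }

  return List::create(_["traces"] = traces,
                      _["v_final"] = NumericVector(v.begin(), v.end()),
                      _["n_steps"] = n_steps);
}

static inline double relu(double x) { return x > 0 ? x : 0.0; }

// Forward pass of the three-layer dendritic network.
//
// Input cells: passive single compartments, each driven by one
// single-exponential synapse fed by that input's spike train.
// Hidden cells: copies of one passive tree; synaptic current of contact m is
// g[m] * W[m] * relu(v_input_prev[in_idx[m]]) injected at node[m] (graded,
// staggered by one step).
// Output cells: passive single compartments with currents
// g_out[j,c] * W_out[j,c] * relu(v_hidden_soma_prev[j]).
// Argument blocks: input layer (in_*, spike trains), hidden tree topology
// and coefficients (h_*, shared by all n_hidden copies), input->hidden
// contacts (ct_*), dense hidden->output weights w_out with conductance
// scale g_out, output layer (out_*), timing and averaging windows.
// [[Rcpp::export]]
List hpcnet_forward_cpp(
    NumericVector in_cdt, NumericVector in_gl, NumericVector in_el,
    NumericVector in_gmax, double in_tau, double in_esyn,
    NumericVector spike_times, IntegerVector spike_off,
    IntegerVector h_parent, NumericVector h_cnf, NumericVector h_gl,
    NumericVector h_gax, NumericVector h_el, int n_hidden,
    IntegerVector ct_in, IntegerVector ct_hid, IntegerVector ct_node,
    NumericVector ct_g, NumericVector ct_w,
    NumericMatrix w_out, double g_out,
    NumericVector out_cdt, NumericVector out_gl, NumericVector out_el,
    double dt, int n_steps,
    double avg_lo, double avg_hi, double learn_lo, double learn_hi,
    bool record_traces) {
  const int n_in = in_cdt.size();
  const int nh = h_parent.size();
  const int n_out = out_cdt.size();
  const int nct = ct_in.size();

  std::vector<int> par(nh);
  for (int i = 0; i < nh; ++i) par[i] = h_parent[i];
  std::vector<int> order; // serial elimination: descending index
  for (int i = nh - 1; i >= 1; --i) order.push_back(i);
  std::vector<double> hoff(nh);
  for (int i = 0; i < nh; ++i) hoff[i] = -h_gax[i];

  std::vector<double> v_in(n_in), g_in(n_in, 0.0);
  for (int i = 0; i < n_in; ++i) v_in[i] = in_el[i];
  std::vector<int> ev(n_in);
  for (int i = 0; i < n_in; ++i) ev[i] = spike_off[i];
  const double edec = std::exp(-dt / in_tau);

  std::vector<std::vector<double>> v_h(n_hidden, std::vector<double>(nh));
  for (int j = 0; j < n_hidden; ++j)
    for (int i = 0; i < nh; ++i) v_h[j][i] = h_el[i];
  std::vector<double> v_out(n_out);
  for (int c = 0; c < n_out; ++c) v_out[c] = out_el[c];

  std::vector<double> vbar(n_out, 0.0), vbar_h(n_hidden, 0.0),
      s_in(n_in, 0.0), s_h(n_hidden, 0.0);
  int n_avg = 0, n_learn = 0;
  std::vector<double> d(nh), rhs(nh), x(nh);

  NumericMatrix tr_in, tr_h, tr_out;
  if (record_traces) {
    tr_in = NumericMatrix(n_steps, n_in);
    tr_h = NumericMatrix(n_steps, n_hidden);
    tr_out = NumericMatrix(n_steps, n_out);
  }

  for (int step = 1; step <= n_steps; ++step) {
    double t_new = step * dt;
    bool in_avg = (t_new > avg_lo + 1e-9) && (t_new <= avg_hi + 1e-9);
    bool in_learn = (t_new > learn_lo + 1e-9) && (t_new <= learn_hi + 1e-9);

    // presynaptic drive is the state at time t (before this step's update)
    std::vector<double> f_in(n_in), f_h(n_hidden);
    for (int i = 0; i < n_in; ++i) f_in[i] = relu(v_in[i]);
    for (int j = 0; j < n_hidden; ++j) f_h[j] = relu(v_h[j][0]);
    if (in_learn) {
      for (int i = 0; i < n_in; ++i) s_in[i] += f_in[i];
      for (int j = 0; j < n_hidden; ++j) s_h[j] += f_h[j];
      ++n_learn;
    }

    // input layer update (implicit synaptic conductance)
    for (int i = 0; i < n_in; ++i) {
      g_in[i] *= edec;
      while (ev[i] < spike_off[i + 1] && spike_times[ev[i]] <= t_new + 1e-9) {
        g_in[i] += in_gmax[i];
        ++ev[i];
      }
      double dd = in_cdt[i] / dt + in_gl[i] + g_in[i];
      double rr = (in_cdt[i] / dt) * v_in[i] + in_gl[i] * in_el[i] +
                  g_in[i] * in_esyn;
      v_in[i] = rr / dd;
    }

    // hidden layer update: graded currents from the input layer
    std::vector<std::vector<double>> inj_h(n_hidden,
                                           std::vector<double>(nh, 0.0));
    for (int m = 0; m < nct; ++m) {
      inj_h[ct_hid[m]][ct_node[m]] += ct_g[m] * ct_w[m] * f_in[ct_in[m]];
    }
    for (int j = 0; j < n_hidden; ++j) {
      for (int i = 0; i < nh; ++i) {
        double cdt = h_cnf[i] / dt;
        d[i] = cdt + h_gl[i];
        rhs[i] = cdt * v_h[j][i] + h_gl[i] * h_el[i] + inj_h[j][i];
      }
      for (int i = 1; i < nh; ++i) {
        d[i] += h_gax[i];
        d[par[i]] += h_gax[i];
      }
      hines_solve_inplace(par, order, d, hoff, rhs, x);
      for (int i = 0; i < nh; ++i) v_h[j][i] = x[i];
    }

    // output layer update: graded currents from hidden somata
    for (int c = 0; c < n_out; ++c) {
      double cur = 0.0;
      for (int j = 0; j < n_hidden; ++j) cur += g_out * w_out(j, c) * f_h[j];
      double dd = out_cdt[c] / dt + out_gl[c];
      double rr = (out_cdt[c] / dt) * v_out[c] + out_gl[c] * out_el[c] + cur;
      v_out[c] = rr / dd;
    }

    if (in_avg) {
      for (int c = 0; c < n_out; ++c) vbar[c] += v_out[c];
      for (int j = 0; j < n_hidden; ++j) vbar_h[j] += v_h[j][0];
      ++n_avg;
    }
    if (record_traces) {
      for (int i = 0; i < n_in; ++i) tr_in(step - 1, i) = v_in[i];
      for (int j = 0; j < n_hidden; ++j) tr_h(step - 1, j) = v_h[j][0];
      for (int c = 0; c < n_out; ++c) tr_out(step - 1, c) = v_out[c];
    }
  }

  for (int c = 0; c < n_out; ++c) vbar[c] /= std::max(1, n_avg);
  for (int j = 0; j < n_hidden; ++j) vbar_h[j] /= std::max(1, n_avg);

  List out = List::create(
      _["vbar_out"] = NumericVector(vbar.begin(), vbar.end()),
      _["vbar_hidden"] = NumericVector(vbar_h.begin(), vbar_h.end()),
      _["sum_f_in"] = NumericVector(s_in.begin(), s_in.end()),
      _["sum_f_hidden"] = NumericVector(s_h.begin(), s_h.end()),
      _["n_learn_steps"] = n_learn, _["n_avg_steps"] = n_avg);
  if (record_traces) {
    out["traces_in"] = tr_in;
    out["traces_hidden"] = tr_h;
    out["traces_out"] = tr_out;
  }
  return out;
}
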