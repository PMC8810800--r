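// Generic explicit monodomain / single-cell integrator shared by all ionic
// models. Geometry (0D, 1D cable, 2D grid with severed obstacle edges) is
// encoded as a neighbor index matrix built on the R side; dropping an edge
// implements both no-flux outer boundaries and zero-conductivity obstacle
// connections. Hodgkin-Huxley gates advance by exact (Rush-Larsen)
// relaxation inside each model; Vm and concentrations by forward Euler.

#include <Rcpp.h>
#include "models.h"

using namespace Rcpp;
using bacnavsim::Model;
using bacnavsim::get_model;

namespace bacnavsim {
extern const Model ord_model;
extern const Model gpv_model;
extern const Model toy_model;

const Model* get_model(const char* name) {
  std::string s(name);
  if (s == "human") return &ord_model;
  if (s == "guineapig") return &gpv_model;
  if (s == "toy") return &toy_model;
  return nullptr;
}
}  // namespace bacnavsim

static const Model* need_model(const std::string& name) {
  const Model* m = get_model(name.c_str());
  if (!m) stop("unknown ionic model '" + name + "'");
  return m;
}

// [[Rcpp::export(name = ".model_info")]]
List model_info(std::string model) {
  const Model* M = need_model(model);
  CharacterVector sn(M->ns), pn(M->np), cn(M->nc);
  for (int i = 0; i < M->ns; ++i) sn[i] = M->state_names[i];
  for (int i = 0; i < M->np; ++i) pn[i] = M->param_names[i];
  for (int i = 0; i < M->nc; ++i) cn[i] = M->current_names[i];
  NumericVector y0(M->ns), p0(M->np);
  M->init(&y0[0]);
  M->default_params(&p0[0]);
  y0.attr("names") = sn;
  p0.attr("names") = pn;
  return List::create(_["state_names"] = sn, _["param_names"] = pn,
                      _["current_names"] = cn, _["default_state"] = y0,
                      _["default_params"] = p0);
}

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(std::string model, NumericMatrix params, NumericMatrix state,
             double dt, double duration, double t0,
             IntegerVector stim_nodes, double stim_amp, double stim_dur,
             NumericVector stim_starts,
             double coupling,  // D / dx^2, 1/ms (0 = uncoupled)
             IntegerMatrix nbrs,
             double record_dt, IntegerVector record_nodes,
             bool record_currents,
             double act_threshold, double measure_from,
             bool stop_on_full_activation, double stop_margin,
             double stall_ms, double vmax_abort) {
  const Model* M = need_model(model);
  const int n = state.ncol();
  if (state.nrow() != M->ns) stop("state matrix has wrong number of rows");
  if (params.nrow() != M->np) stop("param matrix has wrong number of rows");
  const bool shared_params = (params.ncol() == 1);
  if (!shared_params && params.ncol() != n)
    stop("param matrix must have 1 or n columns");
  const int K = nbrs.ncol();
  if (nbrs.nrow() != 0 && nbrs.nrow() != n)
    stop("neighbor matrix must have n rows");

  NumericMatrix Y = clone(state);
  std::vector<double> iion(n), vnew(n);
  std::vector<double> act_time(n, NA_REAL), thresh_time(n, NA_REAL),
      max_dvdt(n, 0.0);
  std::vector<char> is_stim(n, 0);
  for (int s = 0; s < stim_nodes.size(); ++s) {
    int idx = stim_nodes[s];
    if (idx < 0 || idx >= n) stop("stimulus node out of range");
    is_stim[idx] = 1;
  }

  const long nt = (long)std::lround(duration / dt);
  const long rstride = (record_dt > 0)
                           ? std::max(1L, (long)std::lround(record_dt / dt))
                           : 0;
  const int nrec = record_nodes.size();
  const long nrt = (rstride > 0) ? (nt / rstride + 1) : 0;
  NumericVector rec_times(nrt);
  NumericMatrix rec_vm(nrt, (rstride > 0) ? nrec : 0);
  NumericVector rec_cur(
      (rstride > 0 && record_currents) ? nrt * nrec * M->nc : 0);

  int n_activated = 0;
  double last_activation = measure_from;  // for the front-stall early stop
  bool aborted = false;
  int abort_node = -1;
  double abort_time = NA_REAL;
  double t = t0;
  double t_stop = R_PosInf;
  long rec_i = 0;
  std::vector<double> curbuf(M->nc), ybuf(M->ns);

  for (long it = 0; it <= nt; ++it) {
    if (rstride > 0 && it % rstride == 0 && rec_i < nrt) {
      rec_times[rec_i] = t;
      for (int r = 0; r < nrec; ++r) {
        int node = record_nodes[r];
        rec_vm(rec_i, r) = Y(0, node);
        if (record_currents) {
          // evaluate currents at the current state without advancing it
          for (int s = 0; s < M->ns; ++s) ybuf[s] = Y(s, node);
          const double* p = shared_params ? &params(0, 0) : &params(0, node);
          M->step(&ybuf[0], p, 0.0, &curbuf[0]);
          for (int c = 0; c < M->nc; ++c)
            rec_cur[(long)c * nrt * nrec + (long)r * nrt + rec_i] = curbuf[c];
        }
      }
      ++rec_i;
    }
    if (it == nt) break;

    // stimulus active?
    double istim = 0.0;
    for (int s = 0; s < stim_starts.size(); ++s) {
      if (t >= stim_starts[s] && t < stim_starts[s] + stim_dur) {
        istim = stim_amp;
        break;
      }
    }

    for (int i = 0; i < n; ++i) {
      const double* p = shared_params ? &params(0, 0) : &params(0, i);
      iion[i] = M->step(&Y(0, i), p, dt, nullptr);
    }

    for (int i = 0; i < n; ++i) {
      double v = Y(0, i);
      double dv = -iion[i];
      if (istim != 0.0 && is_stim[i]) dv += istim;
      if (coupling > 0.0 && K > 0) {
        double lap = 0.0;
        for (int k = 0; k < K; ++k) {
          int jn = nbrs(i, k);
          if (jn >= 0) lap += Y(0, jn) - v;
        }
        dv += coupling * lap;
      }
      vnew[i] = v + dt * dv;
    }
    double tn = t + dt;
    for (int i = 0; i < n; ++i) {
      double v = Y(0, i), vn = vnew[i];
      if (!std::isfinite(vn) || std::fabs(vn) > vmax_abort) {
        aborted = true;
        abort_node = i;
        abort_time = tn;
        break;
      }
      if (tn >= measure_from) {
        // the activation instant is the maximum dVm/dt of the upstroke;
        // restricting to potentials near/above the foot keeps stimulus and
        // diffusion transients at rest from masquerading as activation
        double dvdt = (vn - v) / dt;
        if (v >= act_threshold - 30.0 && dvdt > max_dvdt[i]) {
          max_dvdt[i] = dvdt;
          act_time[i] = tn;
        }
        if (ISNA(thresh_time[i]) && v < act_threshold && vn >= act_threshold) {
          thresh_time[i] = tn;
          last_activation = tn;
          ++n_activated;
        }
      }
      Y(0, i) = vn;
    }
    if (aborted) break;
    t = tn;
    if (stop_on_full_activation && n_activated == n &&
        !std::isfinite(t_stop))
      t_stop = t + stop_margin;
    // front extinguished: no node has newly activated for stall_ms
    if (stall_ms > 0 && t > measure_from + stall_ms &&
        t - last_activation > stall_ms && !std::isfinite(t_stop))
      t_stop = t;
    if (t >= t_stop) break;
    if (it % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["state"] = Y, _["t_end"] = t,
      _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
      _["thresh_time"] = NumericVector(thresh_time.begin(), thresh_time.end()),
      _["max_dvdt"] = NumericVector(max_dvdt.begin(), max_dvdt.end()),
      _["n_activated"] = n_activated, _["aborted"] = aborted,
      _["abort_node"] = abort_node + 1, _["abort_time"] = abort_time);
  if (rstride > 0) {
    if (rec_i < nrt) {
      rec_times = rec_times[Range(0, rec_i - 1)];
      rec_vm = rec_vm(Range(0, rec_i - 1), _);
    }
    out["times"] = rec_times;
    out["vm"] = rec_vm;
    if (record_currents) {
      rec_cur.attr("dim") = IntegerVector::create(nrt, nrec, M->nc);
      out["currents"] = rec_cur;
      out["n_rec"] = rec_i;
    }
  } else {
    out["times"] = R_NilValue;
  }
  return out;
}

// Voltage-clamp protocol on a single cell: Vm follows a piecewise-constant
// command waveform; internal states relax; all currents are recorded.
// [[Rcpp::export(name = ".sim_vclamp")]]
List sim_vclamp(std::string model, NumericVector params, NumericVector state,
                NumericVector seg_starts, NumericVector seg_values,
                double seg_end, double dt, double record_dt) {
  const Model* M = need_model(model);
  if (state.size() != M->ns) stop("state vector has wrong length");
  if (params.size() != M->np) stop("param vector has wrong length");
  if (seg_starts.size() != seg_values.size() || seg_starts.size() == 0)
    stop("command waveform is empty or malformed");
  NumericVector y = clone(state);
  const long nt = (long)std::lround((seg_end - seg_starts[0]) / dt);
  const long rstride = std::max(1L, (long)std::lround(record_dt / dt));
  const long nrt = nt / rstride + 1;
  NumericVector times(nrt), vcmd(nrt);
  NumericMatrix cur(nrt, M->nc);
  std::vector<double> curbuf(M->nc);
  double t = seg_starts[0];
  int seg = 0;
  long ri = 0;
  for (long it = 0; it <= nt; ++it) {
    while (seg + 1 < seg_starts.size() && t >= seg_starts[seg + 1]) ++seg;
    y[0] = seg_values[seg];
    if (it % rstride == 0 && ri < nrt) {
      // evaluate currents at the commanded potential without advancing
      NumericVector ytmp = clone(y);
      M->step(&ytmp[0], &params[0], 0.0, &curbuf[0]);
      times[ri] = t;
      vcmd[ri] = y[0];
      for (int c = 0; c < M->nc; ++c) cur(ri, c) = curbuf[c];
      ++ri;
    }
    if (it == nt) break;
    M->step(&y[0], &params[0], dt, nullptr);
    t += dt;
  }
  CharacterVector cn(M->nc);
  for (int i = 0; i < M->nc; ++i) cn[i] = M->current_names[i];
  colnames(cur) = cn;
  return List::create(_["times"] = times, _["v"] = vcmd, _["currents"] = cur,
                      _["state"] = y);
}
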