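// Clock-driven core of the V1 layer-4 network (dt = 1 ms).
//
// Update order per global step, matching the R-level step functions:
//   (1) LGN Poisson spikes for this step (consumes R's RNG stream, one
//       uniform draw per LGN unit per step, unit-major order),
//   (2) synaptic-current update from the *previous* step's spikes
//       (one-step delay on every projection),
//   (3) AdEx integration and spike detection (E then I population),
//   (4) trace updates (always) and plasticity (only when plastic),
//   (5) weight clipping of the entries touched this step.
//
// Synaptic events are scaled so that one presynaptic spike through a
// weight w delivers total charge w*C, i.e. a w-millivolt voltage pulse
// (the current-based approximation of pulse input): the current is
// incremented by w*C/tau_syn and decays with Euler factor (1 - dt/tau).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct AdexPars {
  double C, gL, EL, DeltaT, VTrest, VTmax, tauVT, tauz, tauwad,
    Isp, a, b, tauIexc, tauIinh, uspike, syn_gain;
  int clampms;
};

struct ClopathPars {
  bool plastic;
  double A_ltp, A_ltd, u_ref, w_min, w_max, x_scale, ltd_scale;
};

struct IstdpPars {
  bool plastic;
  double eta, rho, w_min, w_max;
};

AdexPars read_adex(const List& p) {
  AdexPars a;
  a.C = p["C"]; a.gL = p["g_L"]; a.EL = p["E_L"]; a.DeltaT = p["Delta_T"];
  a.VTrest = p["VT_rest"]; a.VTmax = p["VT_max"]; a.tauVT = p["tau_VT"];
  a.tauz = p["tau_z"]; a.tauwad = p["tau_wad"]; a.Isp = p["I_sp"];
  a.a = p["a"]; a.b = p["b"]; a.tauIexc = p["tau_Iexc"];
  a.tauIinh = p["tau_Iinh"]; a.uspike = p["u_spike"];
  a.syn_gain = p["syn_gain"];
  a.clampms = as<int>(p["clamp_ms"]);
  return a;
}

ClopathPars read_clopath(const List& p) {
  ClopathPars c;
  c.plastic = as<bool>(p["plastic"]);
  c.A_ltp = p["A_ltp"]; c.A_ltd = p["A_ltd"]; c.u_ref = p["u_ref"];
  c.w_min = p["w_min"]; c.w_max = p["w_max"]; c.x_scale = p["x_scale"];
  c.ltd_scale = p["ltd_scale"];
  return c;
}

IstdpPars read_istdp(const List& p) {
  IstdpPars s;
  s.plastic = as<bool>(p["plastic"]);
  s.eta = p["eta"]; s.rho = p["rho"];
  s.w_min = p["w_min"]; s.w_max = p["w_max"];
  return s;
}

// One AdEx step for a population; fills spike indicator (0/1).
void adex_population_step(arma::vec& u, arma::vec& vt, arma::vec& wad,
                          arma::vec& z, arma::vec& clamp,
                          const arma::vec& Ie, const arma::vec& Ii,
                          arma::uvec& X, const AdexPars& P, double dt) {
  const double dVT = std::exp(-dt / P.tauVT);
  const double dz  = std::exp(-dt / P.tauz);
  const arma::uword n = u.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    vt[j] = P.VTrest + (vt[j] - P.VTrest) * dVT;
    z[j] *= dz;
    wad[j] += dt / P.tauwad * (P.a * (u[j] - P.EL) - wad[j]);
    X[j] = 0;
    if (clamp[j] > 0.0) {
      clamp[j] -= dt;
      if (clamp[j] <= 0.0) u[j] = P.EL;   // end of 2-ms spike plateau
    } else {
      double ex = (u[j] - vt[j]) / P.DeltaT;
      if (ex > 20.0) ex = 20.0;           // overflow guard near threshold
      double du = dt / P.C * (-P.gL * (u[j] - P.EL)
                              + P.gL * P.DeltaT * std::exp(ex)
                              - wad[j] + z[j] + Ie[j] - Ii[j]);
      u[j] += du;
      if (u[j] > vt[j]) {
        X[j] = 1;
        u[j] = P.uspike;
        clamp[j] = (double)P.clampms;
        vt[j] = P.VTmax;
        z[j] = P.Isp;
        wad[j] += P.b;
      }
    }
  }
}

// Voltage-STDP update for one projection, W is npre x npost.
// Uses this step's presynaptic spikes/traces and the post population's
// current voltage and voltage traces; ubb is the *pre-update* slow trace.
void clopath_step(arma::mat& W, const arma::vec& x_pre,
                  const std::vector<arma::uword>& pre_spk,
                  const arma::vec& u_post, const arma::vec& ubp,
                  const arma::vec& ubm, const arma::vec& ubb,
                  const ClopathPars& cp, double th_plus, double th_minus,
                  double dt) {
  const arma::uword npre = W.n_rows, npost = W.n_cols;
  // LTP: gated by postsynaptic depolarization
  for (arma::uword j = 0; j < npost; ++j) {
    double g1 = u_post[j] - th_plus;
    double g2 = ubp[j] - th_minus;
    if (g1 > 0.0 && g2 > 0.0) {
      // x_scale normalizes the unit-jump presynaptic trace to the
      // per-spike contribution the learning rates are calibrated for
      double ltp = cp.A_ltp * cp.x_scale * g1 * g2 * dt;
      double* col = W.colptr(j);
      for (arma::uword i = 0; i < npre; ++i) {
        col[i] += ltp * x_pre[i];
        if (col[i] > cp.w_max) col[i] = cp.w_max;
      }
    }
  }
  // LTD: on presynaptic spikes, scaled by homeostatic ubb/u_ref
  if (!pre_spk.empty()) {
    for (arma::uword j = 0; j < npost; ++j) {
      double g = ubm[j] - th_minus;
      if (g <= 0.0) continue;
      double ltd = cp.A_ltd * cp.ltd_scale * (ubb[j] / cp.u_ref) * g * dt;
      for (arma::uword k = 0; k < pre_spk.size(); ++k) {
        double& w = W(pre_spk[k], j);
        w -= ltd;
        if (w < cp.w_min) w = cp.w_min;
      }
    }
  }
}

// Symmetric homeostatic iSTDP for one projection, W is npre x npost.
void istdp_step(arma::mat& W, const arma::vec& x_pre, const arma::vec& x_post,
                const std::vector<arma::uword>& pre_spk,
                const std::vector<arma::uword>& post_spk,
                const IstdpPars& sp, bool skip_diag) {
  const arma::uword npre = W.n_rows, npost = W.n_cols;
  for (arma::uword k = 0; k < pre_spk.size(); ++k) {
    arma::uword i = pre_spk[k];
    for (arma::uword j = 0; j < npost; ++j) {
      if (skip_diag && i == j) continue;
      double& w = W(i, j);
      w += sp.eta * (x_post[j] - sp.rho);
      if (w < sp.w_min) w = sp.w_min;
      if (w > sp.w_max) w = sp.w_max;
    }
  }
  for (arma::uword k = 0; k < post_spk.size(); ++k) {
    arma::uword j = post_spk[k];
    double* col = W.colptr(j);
    for (arma::uword i = 0; i < npre; ++i) {
      if (skip_diag && i == j) continue;
      col[i] += sp.eta * x_pre[i];
      if (col[i] < sp.w_min) col[i] = sp.w_min;
      if (col[i] > sp.w_max) col[i] = sp.w_max;
    }
  }
}

// Equalize per-postsynaptic-neuron OFF-weight norm to the ON norm.
void equalize_on_off_mat(arma::mat& W) {
  const arma::uword half = W.n_rows / 2;
  for (arma::uword j = 0; j < W.n_cols; ++j) {
    double on = arma::norm(W.col(j).rows(0, half - 1));
    double off = arma::norm(W.col(j).rows(half, W.n_rows - 1));
    if (off > 0.0 && on > 0.0)
      W.col(j).rows(half, W.n_rows - 1) *= on / off;
  }
}

inline void collect(const arma::uvec& X, std::vector<arma::uword>& idx) {
  idx.clear();
  for (arma::uword i = 0; i < X.n_elem; ++i) if (X[i]) idx.push_back(i);
}

} // namespace

// [[Rcpp::export(name = ".cpp_sim_batch")]]
List cpp_sim_batch(List state, List weights, List pars, NumericMatrix rates,
                   int duration, bool plastic, bool record_detail) {
  const List adexp = pars["adex"];
  const AdexPars P = read_adex(adexp);
  const double dt = as<double>(pars["dt"]);
  const int n_lgn = as<int>(pars["n_lgn"]);
  const int n_exc = as<int>(pars["n_exc"]);
  const int n_inh = as<int>(pars["n_inh"]);
  const bool has_inh = as<bool>(pars["has_inh"]);
  const bool transmit_inh = as<bool>(pars["transmit_inh"]);
  const int equalize_every = as<int>(pars["equalize_every"]);
  const bool ubb_sub = as<bool>(pars["ubb_subthreshold"]);
  int stim_count = as<int>(pars["stim_count"]);

  const ClopathPars cp_le = read_clopath(pars["lgn_e"]);
  ClopathPars cp_li, cp_ei;
  IstdpPars sp_ie, sp_ii;
  if (has_inh) {
    cp_li = read_clopath(pars["lgn_i"]);
    cp_ei = read_clopath(pars["e_i"]);
    sp_ie = read_istdp(pars["i_e"]);
    sp_ii = read_istdp(pars["i_i"]);
  }
  const double th_plus = as<double>(pars["theta_plus"]);
  const double th_minus = as<double>(pars["theta_minus"]);
  const double tau_ubb = as<double>(pars["tau_ubb"]);
  const double tau_x = as<double>(pars["tau_x"]);
  const double tau_io = as<double>(pars["tau_istdp"]);
  const double tau_plus = as<double>(pars["tau_plus"]);
  const double tau_minus = as<double>(pars["tau_minus"]);

  // weights (copied in; returned updated)
  arma::mat W_lgn_e = as<arma::mat>(weights["lgn_e"]);
  arma::mat W_lgn_i, W_e_i, W_i_e, W_i_i;
  if (has_inh) {
    W_lgn_i = as<arma::mat>(weights["lgn_i"]);
    W_e_i = as<arma::mat>(weights["e_i"]);
    W_i_e = as<arma::mat>(weights["i_e"]);
    W_i_i = as<arma::mat>(weights["i_i"]);
  }

  // state
  arma::vec u_e = as<arma::vec>(state["u_e"]), vt_e = as<arma::vec>(state["vt_e"]),
    wad_e = as<arma::vec>(state["wad_e"]), z_e = as<arma::vec>(state["z_e"]),
    ie_e = as<arma::vec>(state["ie_e"]), ii_e = as<arma::vec>(state["ii_e"]),
    clamp_e = as<arma::vec>(state["clamp_e"]),
    ubp_e = as<arma::vec>(state["ubp_e"]), ubm_e = as<arma::vec>(state["ubm_e"]),
    ubb_lgn_e = as<arma::vec>(state["ubb_lgn_e"]),
    x_lgn = as<arma::vec>(state["x_lgn"]),
    x_e15 = as<arma::vec>(state["x_e15"]),
    x_e10 = as<arma::vec>(state["x_e10"]);
  arma::vec u_i, vt_i, wad_i, z_i, ie_i, ii_i, clamp_i, ubp_i, ubm_i,
    ubb_lgn_i, ubb_e_i, x_i10;
  if (has_inh) {
    u_i = as<arma::vec>(state["u_i"]); vt_i = as<arma::vec>(state["vt_i"]);
    wad_i = as<arma::vec>(state["wad_i"]); z_i = as<arma::vec>(state["z_i"]);
    ie_i = as<arma::vec>(state["ie_i"]); ii_i = as<arma::vec>(state["ii_i"]);
    clamp_i = as<arma::vec>(state["clamp_i"]);
    ubp_i = as<arma::vec>(state["ubp_i"]); ubm_i = as<arma::vec>(state["ubm_i"]);
    ubb_lgn_i = as<arma::vec>(state["ubb_lgn_i"]);
    ubb_e_i = as<arma::vec>(state["ubb_e_i"]);
    x_i10 = as<arma::vec>(state["x_i10"]);
  }
  arma::uvec pX_lgn = as<arma::uvec>(state["px_lgn"]);
  arma::uvec pX_e = as<arma::uvec>(state["px_e"]);
  arma::uvec pX_i = as<arma::uvec>(state["px_i"]);

  const int nstim = rates.ncol();
  arma::mat counts_e(n_exc, nstim, arma::fill::zeros);
  arma::mat counts_i(std::max(n_inh, 1), has_inh ? nstim : 0, arma::fill::zeros);
  arma::mat sum_ie(n_exc, nstim, arma::fill::zeros);
  arma::mat sum_ii(n_exc, nstim, arma::fill::zeros);
  arma::mat sum_u(n_exc, nstim, arma::fill::zeros);

  arma::imat det_spk_e, det_spk_i;
  arma::mat det_u, det_ie, det_ii;
  if (record_detail) {
    det_spk_e.zeros(n_exc, nstim * duration);
    det_u.zeros(n_exc, nstim * duration);
    det_ie.zeros(n_exc, nstim * duration);
    det_ii.zeros(n_exc, nstim * duration);
    if (has_inh) det_spk_i.zeros(n_inh, nstim * duration);
  }

  const double dec_exc = 1.0 - dt / P.tauIexc;  // Euler decay of Eq. 7
  const double dec_inh = 1.0 - dt / P.tauIinh;
  const double k_exc = P.syn_gain * P.C / P.tauIexc;  // pulse normalization
  const double k_inh = P.syn_gain * P.C / P.tauIinh;
  const double dx15 = std::exp(-dt / tau_x);
  const double dx10 = std::exp(-dt / tau_io);

  arma::uvec X_lgn(n_lgn), X_e(n_exc), X_i(std::max(n_inh, 1));
  X_i.zeros();
  std::vector<arma::uword> s_lgn, s_e, s_i, ps_lgn, ps_e, ps_i;
  collect(pX_lgn, ps_lgn); collect(pX_e, ps_e); collect(pX_i, ps_i);

  arma::vec p(n_lgn);
  arma::vec zero_i(n_exc, arma::fill::zeros);

  for (int s = 0; s < nstim; ++s) {
    for (int i = 0; i < n_lgn; ++i) {
      double pr = rates(i, s) * dt / 1000.0;
      p[i] = pr > 1.0 ? 1.0 : pr;
    }
    for (int t = 0; t < duration; ++t) {
      // (1) LGN Poisson spikes, unit-major draws from R's stream
      for (int i = 0; i < n_lgn; ++i)
        X_lgn[i] = (unif_rand() < p[i]) ? 1 : 0;

      // (2) synaptic currents from previous-step spikes
      ie_e *= dec_exc;
      for (size_t k = 0; k < ps_lgn.size(); ++k)
        ie_e += k_exc * W_lgn_e.row(ps_lgn[k]).t();
      if (has_inh) {
        if (transmit_inh) {
          ii_e *= dec_inh;
          for (size_t k = 0; k < ps_i.size(); ++k)
            ii_e += k_inh * W_i_e.row(ps_i[k]).t();
          ii_i *= dec_inh;
          for (size_t k = 0; k < ps_i.size(); ++k)
            ii_i += k_inh * W_i_i.row(ps_i[k]).t();
        }
        ie_i *= dec_exc;
        for (size_t k = 0; k < ps_lgn.size(); ++k)
          ie_i += k_exc * W_lgn_i.row(ps_lgn[k]).t();
        for (size_t k = 0; k < ps_e.size(); ++k)
          ie_i += k_exc * W_e_i.row(ps_e[k]).t();
      }

      // (3) AdEx integration and spike detection
      adex_population_step(u_e, vt_e, wad_e, z_e, clamp_e, ie_e,
                           transmit_inh ? ii_e : zero_i, X_e, P, dt);
      if (has_inh)
        adex_population_step(u_i, vt_i, wad_i, z_i, clamp_i, ie_i, ii_i,
                             X_i, P, dt);

      // (4) traces evolve always; weight changes only when plastic
      x_lgn = x_lgn * dx15 + arma::conv_to<arma::vec>::from(X_lgn);
      x_e15 = x_e15 * dx15 + arma::conv_to<arma::vec>::from(X_e);
      x_e10 = x_e10 * dx10 + arma::conv_to<arma::vec>::from(X_e);
      if (has_inh)
        x_i10 = x_i10 * dx10 + arma::conv_to<arma::vec>::from(X_i);
      ubp_e += dt / tau_plus * (u_e - ubp_e);
      ubm_e += dt / tau_minus * (u_e - ubm_e);
      if (has_inh) {
        ubp_i += dt / tau_plus * (u_i - ubp_i);
        ubm_i += dt / tau_minus * (u_i - ubm_i);
      }

      if (plastic) {
        collect(X_lgn, s_lgn); collect(X_e, s_e);
        if (has_inh) collect(X_i, s_i);
        if (cp_le.plastic)
          clopath_step(W_lgn_e, x_lgn, s_lgn, u_e, ubp_e, ubm_e, ubb_lgn_e,
                       cp_le, th_plus, th_minus, dt);
        if (has_inh) {
          if (cp_li.plastic)
            clopath_step(W_lgn_i, x_lgn, s_lgn, u_i, ubp_i, ubm_i, ubb_lgn_i,
                         cp_li, th_plus, th_minus, dt);
          if (cp_ei.plastic)
            clopath_step(W_e_i, x_e15, s_e, u_i, ubp_i, ubm_i, ubb_e_i,
                         cp_ei, th_plus, th_minus, dt);
          if (sp_ie.plastic)
            istdp_step(W_i_e, x_i10, x_e10, s_i, s_e, sp_ie, false);
          if (sp_ii.plastic)
            istdp_step(W_i_i, x_i10, x_i10, s_i, s_i, sp_ii, true);
        }
      }

      // slow homeostatic trace: updated after plasticity (LTD uses the
      // pre-update value within a step). The 29-mV spike plateau is
      // visible here, which makes the depression scale react quickly
      // to firing-rate surges as well as to sustained depolarization.
      for (int j = 0; j < n_exc; ++j) {
        double d = (ubb_sub && clamp_e[j] > 0.0) ? 0.0
          : std::max(u_e[j] - P.EL, 0.0);
        ubb_lgn_e[j] += dt / tau_ubb * (d * d - ubb_lgn_e[j]);
      }
      if (has_inh) {
        for (int j = 0; j < n_inh; ++j) {
          double d = (ubb_sub && clamp_i[j] > 0.0) ? 0.0
            : std::max(u_i[j] - P.EL, 0.0);
          double dd = d * d;
          ubb_lgn_i[j] += dt / tau_ubb * (dd - ubb_lgn_i[j]);
          ubb_e_i[j] += dt / tau_ubb * (dd - ubb_e_i[j]);
        }
      }

      // recording
      for (int j = 0; j < n_exc; ++j) {
        counts_e(j, s) += X_e[j];
        sum_ie(j, s) += ie_e[j];
        sum_ii(j, s) += transmit_inh ? ii_e[j] : 0.0;
        sum_u(j, s) += u_e[j];
      }
      if (has_inh)
        for (int j = 0; j < n_inh; ++j) counts_i(j, s) += X_i[j];
      if (record_detail) {
        int col = s * duration + t;
        for (int j = 0; j < n_exc; ++j) {
          det_spk_e(j, col) = X_e[j];
          det_u(j, col) = u_e[j];
          det_ie(j, col) = ie_e[j];
          det_ii(j, col) = transmit_inh ? ii_e[j] : 0.0;
        }
        if (has_inh)
          for (int j = 0; j < n_inh; ++j) det_spk_i(j, col) = X_i[j];
      }

      ps_lgn.clear(); ps_e.clear(); ps_i.clear();
      collect(X_lgn, ps_lgn); collect(X_e, ps_e);
      if (has_inh) collect(X_i, ps_i);
    }

    ++stim_count;
    if (plastic && equalize_every > 0 && stim_count % equalize_every == 0) {
      if (cp_le.plastic) equalize_on_off_mat(W_lgn_e);
      if (has_inh && cp_li.plastic) equalize_on_off_mat(W_lgn_i);
    }
  }

  List new_state = List::create(
    _["u_e"] = u_e, _["vt_e"] = vt_e, _["wad_e"] = wad_e, _["z_e"] = z_e,
    _["ie_e"] = ie_e, _["ii_e"] = ii_e, _["clamp_e"] = clamp_e,
    _["ubp_e"] = ubp_e, _["ubm_e"] = ubm_e, _["ubb_lgn_e"] = ubb_lgn_e,
    _["x_lgn"] = x_lgn, _["x_e15"] = x_e15, _["x_e10"] = x_e10,
    _["px_lgn"] = arma::conv_to<arma::ivec>::from(X_lgn),
    _["px_e"] = arma::conv_to<arma::ivec>::from(X_e),
    _["px_i"] = arma::conv_to<arma::ivec>::from(
        has_inh ? X_i : arma::uvec(1, arma::fill::zeros)));
  if (has_inh) {
    new_state["u_i"] = u_i; new_state["vt_i"] = vt_i;
    new_state["wad_i"] = wad_i; new_state["z_i"] = z_i;
    new_state["ie_i"] = ie_i; new_state["ii_i"] = ii_i;
    new_state["clamp_i"] = clamp_i;
    new_state["ubp_i"] = ubp_i; new_state["ubm_i"] = ubm_i;
    new_state["ubb_lgn_i"] = ubb_lgn_i; new_state["ubb_e_i"] = ubb_e_i;
    new_state["x_i10"] = x_i10;
  }

  List new_weights = List::create(_["lgn_e"] = W_lgn_e);
  if (has_inh) {
    new_weights["lgn_i"] = W_lgn_i;
    new_weights["e_i"] = W_e_i;
    new_weights["i_e"] = W_i_e;
    new_weights["i_i"] = W_i_i;
  }

  List out = List::create(
    _["state"] = new_state, _["weights"] = new_weights,
    _["counts_e"] = counts_e, _["counts_i"] = counts_i,
    _["mean_ie"] = sum_ie / duration, _["mean_ii"] = sum_ii / duration,
    _["mean_u"] = sum_u / duration, _["stim_count"] = stim_count);
  if (record_detail) {
    out["spikes_e"] = det_spk_e;
    out["spikes_i"] = det_spk_i;
    out["u_trace"] = det_u;
    out["ie_trace"] = det_ie;
    out["ii_trace"] = det_ii;
  }
  return out;
}
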