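// Fast simulation kernels for CSNTC modules.
//
// The R-level step functions (step_layer, step_bg, step_module) define the
// model; these kernels replicate the same synchronous forward-Euler update
// over long input schedules so the experiment pipelines run at C++ speed.
// A parity test in the package test suite asserts step-for-step agreement
// with the R implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct UnitParams {
  double dt, tau, alpha, th;
  double k() const { return dt / tau; }
};

inline arma::vec transfer(const arma::vec &u, const UnitParams &p) {
  return arma::clamp(arma::tanh(p.alpha * (u - p.th)), 0.0, arma::datum::inf);
}

inline void euler(arma::vec &u, const arma::vec &drive, const UnitParams &p) {
  u += p.k() * (drive - u);
}

struct BgParams {
  double bl_d1, da_d1, bl_d2, da_d2;
  double w_cs, w_xs, w_cstn, w_gpestn, w_stngpe, w_stngpi;
  double w_strgpe, w_strgpi, w_gpegpi, gpi_tonic;
  double w_gpitha, w_cttha, tha_tonic, w_thact;
};

BgParams bg_from_list(const List &bgp) {
  BgParams b;
  b.bl_d1 = bgp["bl_d1"]; b.da_d1 = bgp["da_d1"];
  b.bl_d2 = bgp["bl_d2"]; b.da_d2 = bgp["da_d2"];
  b.w_cs = bgp["w_cs"]; b.w_xs = bgp["w_xs"];
  b.w_cstn = bgp["w_cstn"]; b.w_gpestn = bgp["w_gpestn"];
  b.w_stngpe = bgp["w_stngpe"]; b.w_stngpi = bgp["w_stngpi"];
  b.w_strgpe = bgp["w_strgpe"]; b.w_strgpi = bgp["w_strgpi"];
  b.w_gpegpi = bgp["w_gpegpi"]; b.gpi_tonic = bgp["gpi_tonic"];
  b.w_gpitha = bgp["w_gpitha"]; b.w_cttha = bgp["w_cttha"];
  b.tha_tonic = bgp["tha_tonic"]; b.w_thact = bgp["w_thact"];
  return b;
}

// One CSNTC module: cortical reservoir + 5-layer basal ganglia + thalamus.
struct CsntcModule {
  arma::mat W_u, W_ux;            // reservoir weights
  arma::uvec ch_of_unit;          // 0 = not a loop unit, 1..C otherwise
  std::vector<arma::uvec> channels;
  arma::uword C;
  BgParams bg;
  UnitParams up;
  // state
  arma::vec u_ctx, z_ctx;
  arma::vec u_d1, z_d1, u_d2, z_d2, u_stn, z_stn, u_gpe, z_gpe, u_gpi, z_gpi;
  arma::vec u_tha, z_tha;

  void init_from(const List &m, const UnitParams &p) {
    up = p;
    W_u = as<arma::mat>(m["W_u"]);
    W_ux = as<arma::mat>(m["W_ux"]);
    arma::ivec ch = as<arma::ivec>(m["ch"]);
    C = as<int>(m["C"]);
    bg = bg_from_list(m["bgp"]);
    channels.resize(C);
    for (arma::uword c = 0; c < C; ++c)
      channels[c] = arma::find(ch == (int)(c + 1));
    List st = m["state"];
    u_ctx = as<arma::vec>(st["u_ctx"]);
    u_d1 = as<arma::vec>(st["u_strd1"]); u_d2 = as<arma::vec>(st["u_strd2"]);
    u_stn = as<arma::vec>(st["u_stn"]); u_gpe = as<arma::vec>(st["u_gpe"]);
    u_gpi = as<arma::vec>(st["u_gpi"]); u_tha = as<arma::vec>(st["u_tha"]);
    refresh();
  }

  void refresh() {
    z_ctx = transfer(u_ctx, up);
    z_d1 = transfer(u_d1, up); z_d2 = transfer(u_d2, up);
    z_stn = transfer(u_stn, up); z_gpe = transfer(u_gpe, up);
    z_gpi = transfer(u_gpi, up); z_tha = transfer(u_tha, up);
  }

  arma::vec pooled() const {
    arma::vec c(C);
    for (arma::uword i = 0; i < C; ++i)
      c(i) = arma::mean(z_ctx(channels[i]));
    return c;
  }

  // One synchronous step; ctx_ext is the external cortical drive already
  // projected onto the reservoir units (e.g. W_ux * x), x_str the already
  // mapped per-channel striatal input.
  void step(const arma::vec &ctx_ext, const arma::vec &x_str, double da) {
    arma::vec c = pooled();
    double stn_sum = arma::sum(z_stn);
    arma::vec in_str = bg.w_cs * c + bg.w_xs * x_str;
    arma::vec d_d1 = (bg.bl_d1 + bg.da_d1 * da) * in_str;
    arma::vec d_d2 = in_str / (bg.bl_d2 + bg.da_d2 * da);
    arma::vec d_stn = bg.w_cstn * c - bg.w_gpestn * z_gpe;
    arma::vec d_gpe = bg.w_stngpe * stn_sum - bg.w_strgpe * z_d2;
    arma::vec d_gpi = bg.gpi_tonic + bg.w_stngpi * stn_sum
                      - bg.w_strgpi * z_d1 - bg.w_gpegpi * z_gpe;
    arma::vec d_tha = bg.tha_tonic + bg.w_cttha * c - bg.w_gpitha * z_gpi;
    arma::vec d_ctx = ctx_ext + W_u * z_ctx;
    for (arma::uword i = 0; i < C; ++i)
      d_ctx(channels[i]) += bg.w_thact * z_tha(i);
    euler(u_d1, d_d1, up); euler(u_d2, d_d2, up);
    euler(u_stn, d_stn, up); euler(u_gpe, d_gpe, up);
    euler(u_gpi, d_gpi, up); euler(u_tha, d_tha, up);
    euler(u_ctx, d_ctx, up);
    refresh();
  }

  List state_out() const {
    return List::create(_["u_ctx"] = u_ctx, _["u_strd1"] = u_d1,
                        _["u_strd2"] = u_d2, _["u_stn"] = u_stn,
                        _["u_gpe"] = u_gpe, _["u_gpi"] = u_gpi,
                        _["u_tha"] = u_tha);
  }
};

UnitParams up_from_list(const List &par) {
  UnitParams p;
  p.dt = par["dt"]; p.tau = par["tau"];
  p.alpha = par["alpha"]; p.th = par["th"];
  return p;
}

} // namespace

//' @name engine
//' @title Compiled simulation kernels
//' @description Internal RcppArmadillo kernels; use the R wrappers.
//' @keywords internal
// [[Rcpp::export(name = ".cpp_run_module")]]
List cpp_run_module(List model, List par,
                    const arma::mat &X_ctx, const arma::mat &X_str,
                    const arma::vec &da,
                    const arma::mat &W_sx,
                    IntegerVector record, bool trace = false) {
  UnitParams p = up_from_list(par);
  CsntcModule m;
  m.init_from(model, p);
  const arma::uword T = da.n_elem;
  if (X_ctx.n_cols != T || X_str.n_cols != T)
    stop("input schedules must have one column per step");

  std::vector<bool> rec(T + 1, false);
  for (int r : record) {
    if (r < 1 || r > (int)T) stop("record index out of range");
    rec[r] = true;
  }
  arma::mat Z(m.W_u.n_rows, record.size());
  arma::uword zi = 0;

  arma::mat tr_d1, tr_d2, tr_stn, tr_gpe, tr_gpi, tr_tha, tr_ctx;
  if (trace) {
    tr_d1.set_size(m.C, T); tr_d2.set_size(m.C, T); tr_stn.set_size(m.C, T);
    tr_gpe.set_size(m.C, T); tr_gpi.set_size(m.C, T); tr_tha.set_size(m.C, T);
    tr_ctx.set_size(m.C, T);
  }

  for (arma::uword t = 0; t < T; ++t) {
    m.step(m.W_ux * X_ctx.col(t), W_sx * X_str.col(t), da(t));
    if (rec[t + 1]) Z.col(zi++) = m.z_ctx;
    if (trace) {
      tr_d1.col(t) = m.z_d1; tr_d2.col(t) = m.z_d2; tr_stn.col(t) = m.z_stn;
      tr_gpe.col(t) = m.z_gpe; tr_gpi.col(t) = m.z_gpi; tr_tha.col(t) = m.z_tha;
      tr_ctx.col(t) = m.pooled();
    }
  }

  List out = List::create(_["state"] = m.state_out(), _["Z"] = Z);
  if (trace) {
    out["trace"] = List::create(_["strd1"] = tr_d1, _["strd2"] = tr_d2,
                                _["stn"] = tr_stn, _["gpe"] = tr_gpe,
                                _["gpi"] = tr_gpi, _["tha"] = tr_tha,
                                _["ctx"] = tr_ctx);
  }
  return out;
}

// Online variant: dynamic read-out units (leaky, no lateral connections)
// trained with the simplified backpropagation-decorrelation rule wherever
// learn[t] is true.  Y is outputs x T (targets; ignored where not learning).
// [[Rcpp::export(name = ".cpp_run_module_online")]]
List cpp_run_module_online(List model, List par,
                           const arma::mat &X_ctx, const arma::mat &X_str,
                           const arma::vec &da, const arma::mat &W_sx,
                           arma::mat W_oz, const arma::mat &Y,
                           const LogicalVector &learn,
                           double eta, double beta, double dt_rule,
                           IntegerVector record) {
  UnitParams p = up_from_list(par);
  CsntcModule m;
  m.init_from(model, p);
  const arma::uword T = da.n_elem;
  arma::vec u_o(W_oz.n_rows, arma::fill::zeros);
  arma::vec o = transfer(u_o, p);

  std::vector<bool> rec(T + 1, false);
  for (int r : record) rec[r] = true;
  arma::mat O(W_oz.n_rows, record.size());
  arma::uword oi = 0;

  bool have_prev = false;
  arma::vec z_prev, x_prev, e_prev;

  for (arma::uword t = 0; t < T; ++t) {
    arma::vec z_t = m.z_ctx;          // pre-step rates (time t)
    arma::vec x_t = X_ctx.col(t);
    m.step(m.W_ux * x_t, W_sx * X_str.col(t), da(t));
    euler(u_o, W_oz * z_t, p);        // read-out units step like any layer
    o = transfer(u_o, p);
    if (learn[t]) {
      arma::vec e_now = o - Y.col(t);
      if (have_prev) {
        arma::vec d = z_prev / (arma::dot(z_prev, z_prev) +
                                arma::dot(x_prev, x_prev) + beta);
        arma::vec g = (1.0 - dt_rule) * e_prev - e_now;
        W_oz += (eta / dt_rule) * g * d.t();
      }
      z_prev = z_t; x_prev = x_t; e_prev = e_now;
      have_prev = true;
    } else {
      have_prev = false;
    }
    if (rec[t + 1]) O.col(oi++) = o;
  }
  return List::create(_["state"] = m.state_out(), _["W_oz"] = W_oz,
                      _["O"] = O);
}

// Two CSNTC modules (high-level motor, primary motor) plus a plain cortical
// module (somatosensory).  The task code drives the high-level module; the
// high-level cortex drives the primary module's cortex (fixed weights) and
// striatum (learnable W_sx, Oja/kWTA); the somatosensory cortex drives the
// primary cortex (fixed weights) and weakly its striatum.
// noise_sel and noise_oja are precomputed C x T Gaussian schedules (empty
// matrices disable them), drawn in R so runs are reproducible from the seed.
// [[Rcpp::export(name = ".cpp_run_system")]]
List cpp_run_system(List sys, List par,
                    const arma::mat &code, const arma::mat &sine,
                    const arma::vec &da_hl, const arma::vec &da_pm,
                    bool oja_on,
                    const arma::mat &noise_sel, const arma::mat &noise_oja,
                    const LogicalVector &window,
                    IntegerVector record) {
  UnitParams p = up_from_list(par);

  // somatosensory: plain reservoir (no BG, no thalamus)
  List som = sys["som"];
  arma::mat Ws_u = as<arma::mat>(som["W_u"]);
  arma::mat Ws_ux = as<arma::mat>(som["W_ux"]);
  arma::vec us = as<arma::vec>(as<List>(som["state"])["u_ctx"]);
  arma::vec zs = transfer(us, p);

  CsntcModule hl, pm;
  hl.init_from(sys["hl"], p);
  pm.init_from(sys["pm"], p);

  arma::mat G = as<arma::mat>(sys["G_code_hlstr"]);      // C x 9, hardwired
  arma::mat W_hl_pmctx = as<arma::mat>(sys["W_hl_pmctx"]);
  arma::mat W_som_pmctx = as<arma::mat>(sys["W_som_pmctx"]);
  arma::mat W_sx = as<arma::mat>(sys["W_sx"]);           // C x N_hl, learnable
  arma::mat W_som_pmstr = as<arma::mat>(sys["W_som_pmstr"]);
  List cfg = sys["cfg"];
  const double g_hl_str = cfg["g_hl_str"];
  const double g_som_str = cfg["g_som_str"];
  const bool center_hl = cfg["center_hl_drive"];
  const double eta_sx = cfg["eta_sx"];
  const int k_str = cfg["k_striatum"];
  const int k_ctx = cfg["k_cortex"];
  const bool sx_frozen = cfg["sx_frozen"];
  // source mask of the cortico-striatal pathway: 1 for high-level units
  // that project to the primary striatum (the loop sub-populations)
  arma::vec src_mask = as<arma::vec>(cfg["oja_src_mask"]);

  const arma::uword T = da_pm.n_elem;
  std::vector<bool> rec(T + 1, false);
  for (int r : record) rec[r] = true;
  arma::mat Z(pm.W_u.n_rows, record.size());
  arma::uword zi = 0;

  const bool use_sel_noise = noise_sel.n_cols == T;
  const bool use_oja_noise = noise_oja.n_cols == T;

  for (arma::uword t = 0; t < T; ++t) {
    // pre-step rates of every component
    arma::vec zs_t = zs, zh_t = hl.z_ctx;
    // somatosensory step
    arma::vec ds = Ws_ux * sine.col(t) + Ws_u * zs;
    euler(us, ds, p);
    zs = transfer(us, p);
    // high-level module: code to cortex (via its W_ux) and striatum (G)
    hl.step(hl.W_ux * code.col(t), G * code.col(t), da_hl(t));
    // primary module: cortical input from hl + som cortices, striatal
    // input from hl cortex (learnable) and weakly from som cortex
    arma::vec x_pmctx = W_hl_pmctx * zh_t + W_som_pmctx * zs_t;
    // learned pathway with feedforward lateral inhibition: the channel
    // mean of the drive is subtracted, so only task-specific deviations
    // compete for selection
    arma::vec hl_drive = W_sx * (zh_t % src_mask);
    if (center_hl) hl_drive -= arma::mean(hl_drive);
    arma::vec x_pmstr = g_hl_str * hl_drive + g_som_str * (W_som_pmstr * zs_t);
    if (use_sel_noise) x_pmstr += noise_sel.col(t);
    pm.step(x_pmctx, x_pmstr, da_pm(t));

    if (oja_on && !sx_frozen && window[t]) {
      // Oja/kWTA update on the post-step striatal D1 rates and the
      // pre-step high-level cortical rates
      arma::vec s_in = pm.z_d1;
      if (use_oja_noise) s_in += noise_oja.col(t);
      arma::vec s = s_in, c = zh_t % src_mask;
      // k-winner-take-all, ties to the lowest index
      {
        arma::uvec ord = arma::stable_sort_index(s, "descend");
        arma::vec filt(s.n_elem, arma::fill::zeros);
        for (int i = 0; i < k_str && i < (int)s.n_elem; ++i)
          filt(ord(i)) = s(ord(i));
        s = filt;
      }
      {
        arma::uvec ord = arma::stable_sort_index(c, "descend");
        arma::vec filt(c.n_elem, arma::fill::zeros);
        for (int i = 0; i < k_ctx && i < (int)c.n_elem; ++i)
          filt(ord(i)) = c(ord(i));
        c = filt;
      }
      W_sx += eta_sx * (s * c.t() - (s % s) * arma::ones<arma::rowvec>(c.n_elem) % W_sx);
    }
    if (rec[t + 1]) Z.col(zi++) = pm.z_ctx;
  }

  return List::create(
    _["som_state"] = List::create(_["u_ctx"] = us),
    _["hl_state"] = hl.state_out(),
    _["pm_state"] = pm.state_out(),
    _["W_sx"] = W_sx,
    _["Z"] = Z);
}
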