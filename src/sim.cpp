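// Core integrator for the four-layer neural-mass network and for a single
// isolated cortical column.  Fixed-step explicit Euler; all stochastic input
// is drawn from R's RNG so that set.seed() in R makes runs reproducible.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + arma::exp(-r * (v - v0)));
}
static inline double sigm1(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(-r * (v - v0)));
}

// Second-order ("alpha function") synaptic kernel, one Euler step.
// dy/dt = x ; dx/dt = G*om*u - 2*om*x - om^2*y
static inline void kstep(arma::vec& y, arma::vec& x, const arma::vec& u,
                         double G, double om, double dt) {
  arma::vec xn = x + dt * (G * om * u - 2.0 * om * x - om * om * y);
  y += dt * x;
  x = xn;
}

struct LayerState {
  arma::vec yp, xp, ye, xe, ys, xs, yf, xf, up, xup, uf, xuf, af;
  LayerState(int n) {
    yp.zeros(n); xp.zeros(n); ye.zeros(n); xe.zeros(n); ys.zeros(n);
    xs.zeros(n); yf.zeros(n); xf.zeros(n); up.zeros(n); xup.zeros(n);
    uf.zeros(n); xuf.zeros(n); af.zeros(n);
  }
};

// [[Rcpp::export]]
List cpp_simulate_network(List par, List syn, List sched,
                          int steps, int rec_every) {
  const double e0 = par["e0"], r = par["r"], v0 = par["v0"];
  const double G_e = par["G_e"], om_e = par["om_e"];
  const double G_s = par["G_s"], om_s = par["om_s"];
  const double G_f = par["G_f"], om_f = par["om_f"];
  const double G_W = par["G_W"], om_W = par["om_W"];
  const double G_K = par["G_K"], om_K = par["om_K"];
  const double G_A = par["G_A"], tau_A = par["tau_A"];
  const double C_ep = par["C_ep"], C_pe = par["C_pe"];
  const double C_sp = par["C_sp"], C_ps = par["C_ps"];
  const double C_fp = par["C_fp"], C_fs = par["C_fs"];
  const double C_pf = par["C_pf"], C_ff = par["C_ff"];
  const double C_pp = par["C_pp"];
  const double dt = par["dt"];

  const arma::mat W1  = syn["W1"],  K2 = syn["K2"], A2 = syn["A2"];
  const arma::mat K3  = syn["K3"],  A3 = syn["A3"], W23 = syn["W23"];
  const double g_wm_l1 = syn["g_wm_l1"], g_l1_wm = syn["g_l1_wm"];
  const double g_l1_l2 = syn["g_l1_l2"], g_l2_l3 = syn["g_l2_l3"];

  const double gate_thr = par["gate_thr"], gate_hyst = par["gate_hyst"];
  const double gate_clamp = par["gate_clamp"];

  const double noise_wm_lo = par["noise_wm_lo"], noise_wm_hi = par["noise_wm_hi"];
  const double noise_bg_lo = par["noise_bg_lo"], noise_bg_hi = par["noise_bg_hi"];
  const double noise_dt = par["noise_dt"];
  const int noise_hold = std::max(1, (int)std::lround(noise_dt / (double)par["dt"]));

  const bool dreaming = sched["dreaming"];
  const double dream_lo = sched["dream_lo"], dream_hi = sched["dream_hi"];

  // cue events: step-indexed windows driving WM pyramidal columns
  const IntegerVector ev_on = sched["ev_on"], ev_off = sched["ev_off"];
  const NumericVector ev_amp = sched["ev_amp"];
  const List ev_idx = sched["ev_idx"];   // 0-based column indices per event
  const int n_ev = ev_on.size();

  const int n = W1.n_rows;
  LayerState wm(n), l1(n), l2(n), l3(n);
  LayerState* L[4] = { &wm, &l1, &l2, &l3 };

  const int n_rec = steps / rec_every;
  arma::mat rec_wm(n_rec, n), rec_l1(n_rec, n), rec_l2(n_rec, n), rec_l3(n_rec, n);
  LogicalVector rec_gate(n_rec);

  bool gate_open = false;
  arma::vec nz0(n, arma::fill::zeros), nz1(n, arma::fill::zeros);
  arma::vec nz2(n, arma::fill::zeros), nz3(n, arma::fill::zeros);
  arma::vec nzd(n, arma::fill::zeros);
  RNGScope scope;
  int irec = 0;

  arma::vec zp[4], zf[4];
  for (int t = 0; t < steps; ++t) {
    // membrane potentials and spike densities
    for (int l = 0; l < 4; ++l) {
      LayerState& S = *L[l];
      arma::vec vp = C_pe * S.ye - C_ps * S.ys - C_pf * S.yf + S.up;
      if (l == 0) {
        // WM auto-excitation, suspended while any cue is being presented
        double cpp_now = C_pp;
        for (int e = 0; e < n_ev; ++e)
          if (t >= ev_on[e] && t < ev_off[e]) { cpp_now = 0.0; break; }
        vp += cpp_now * S.yp;
      }
      arma::vec ve = C_ep * S.yp;
      arma::vec vs = C_sp * S.yp;
      arma::vec vf = C_fp * S.yp - C_ff * S.yf - C_fs * S.ys + S.uf + S.af;
      zp[l] = sigm(vp, e0, r, v0);
      zf[l] = sigm(vf, e0, r, v0);
      arma::vec ze = sigm(ve, e0, r, v0);
      arma::vec zs = sigm(vs, e0, r, v0);
      kstep(S.ye, S.xe, ze, G_e, om_e, dt);
      kstep(S.ys, S.xs, zs, G_s, om_s, dt);
    }

    // theta gate on L2 driven by summed L1 pyramidal activity
    double l1_sum = arma::accu(zp[1]);
    if (!gate_open && l1_sum > gate_thr) gate_open = true;
    else if (gate_open && l1_sum < gate_hyst * gate_thr) gate_open = false;

    if (irec < n_rec && (t % rec_every) == 0) {
      rec_wm.row(irec) = zp[0].t(); rec_l1.row(irec) = zp[1].t();
      rec_l2.row(irec) = zp[2].t(); rec_l3.row(irec) = zp[3].t();
      rec_gate[irec] = gate_open;
      ++irec;
    }

    // external + lateral drives (spike-density units); the noise is
    // band-limited: samples are held for noise_dt so its strength does not
    // depend on the integration step
    if ((t % noise_hold) == 0) {
      for (int i = 0; i < n; ++i) {
        nz0[i] = ::unif_rand() * (noise_wm_hi - noise_wm_lo) + noise_wm_lo;
        nz1[i] = ::unif_rand() * (noise_bg_hi - noise_bg_lo) + noise_bg_lo;
        nz2[i] = ::unif_rand() * (noise_bg_hi - noise_bg_lo) + noise_bg_lo;
        nz3[i] = ::unif_rand() * (noise_bg_hi - noise_bg_lo) + noise_bg_lo;
        if (dreaming)
          nzd[i] = ::unif_rand() * (dream_hi - dream_lo) + dream_lo;
      }
    }
    arma::vec dp0 = nz0, dp1 = nz1, dp2 = nz2, dp3 = nz3;
    for (int e = 0; e < n_ev; ++e) {
      if (t >= ev_on[e] && t < ev_off[e]) {
        const IntegerVector idx = ev_idx[e];
        for (int k = 0; k < idx.size(); ++k) dp0[idx[k]] += ev_amp[e];
      }
    }
    if (dreaming) {
      dp1 += nzd;
    } else {
      dp0 += g_l1_wm * zp[1];
      dp1 += g_wm_l1 * zp[0];
    }
    dp1 += W1 * zp[1];
    dp2 += g_l1_l2 * zp[1] + W23 * zp[3];
    dp3 += g_l2_l3 * zp[2];

    arma::vec dK2 = K2 * zp[2], dK3 = K3 * zp[3];
    arma::vec dA2 = A2 * zp[2], dA3 = A3 * zp[3];
    if (!gate_open) dA2 += gate_clamp;

    // advance pyramidal-output, input and fast kernels
    for (int l = 0; l < 4; ++l) {
      LayerState& S = *L[l];
      kstep(S.yp, S.xp, zp[l], G_e, om_e, dt);
      kstep(S.yf, S.xf, zf[l], G_f, om_f, dt);
    }
    kstep(wm.up, wm.xup, dp0, G_W, om_W, dt);
    kstep(l1.up, l1.xup, dp1, G_W, om_W, dt);
    kstep(l2.up, l2.xup, dp2, G_W, om_W, dt);
    kstep(l3.up, l3.xup, dp3, G_W, om_W, dt);
    kstep(l2.uf, l2.xuf, dK2, G_K, om_K, dt);
    kstep(l3.uf, l3.xuf, dK3, G_K, om_K, dt);
    l2.af += dt / tau_A * (G_A * dA2 - l2.af);
    l3.af += dt / tau_A * (G_A * dA3 - l3.af);

    if ((t & 1023) == 0) {
      const char* nm[4] = {"WM", "L1", "L2", "L3"};
      for (int l = 0; l < 4; ++l)
        if (!L[l]->yp.is_finite())
          stop("numerical divergence (NaN/Inf) in pyramidal kernel of layer %s at t = %g s",
               nm[l], t * dt);
    }
  }

  return List::create(
    _["zp_wm"] = rec_wm, _["zp_l1"] = rec_l1,
    _["zp_l2"] = rec_l2, _["zp_l3"] = rec_l3,
    _["gate"] = rec_gate);
}

// Isolated single column (no lateral or inter-layer connections).
// ext_p / ext_f: external drives; length steps or length 1 (recycled).
// [[Rcpp::export]]
List cpp_simulate_column(List par, NumericVector ext_p, NumericVector ext_f,
                         double noise_lo, double noise_hi,
                         int steps, int rec_every, double C_pp_val) {
  const double e0 = par["e0"], r = par["r"], v0 = par["v0"];
  const double G_e = par["G_e"], om_e = par["om_e"];
  const double G_s = par["G_s"], om_s = par["om_s"];
  const double G_f = par["G_f"], om_f = par["om_f"];
  const double G_W = par["G_W"], om_W = par["om_W"];
  const double G_K = par["G_K"], om_K = par["om_K"];
  const double C_ep = par["C_ep"], C_pe = par["C_pe"];
  const double C_sp = par["C_sp"], C_ps = par["C_ps"];
  const double C_fp = par["C_fp"], C_fs = par["C_fs"];
  const double C_pf = par["C_pf"], C_ff = par["C_ff"];
  const double dt = par["dt"];

  const double noise_dt = par["noise_dt"];
  const int noise_hold = std::max(1, (int)std::lround(noise_dt / dt));
  double yp = 0, xp = 0, ye = 0, xe = 0, ys = 0, xs = 0, yf = 0, xf = 0;
  double up = 0, xup = 0, uf = 0, xuf = 0, nz = 0;
  const int n_rec = steps / rec_every;
  NumericVector zp_out(n_rec), zf_out(n_rec);
  const bool pvar = ext_p.size() > 1, fvar = ext_f.size() > 1;
  RNGScope scope;
  int irec = 0;
  for (int t = 0; t < steps; ++t) {
    double vp = C_pe * ye - C_ps * ys - C_pf * yf + C_pp_val * yp + up;
    double ve = C_ep * yp;
    double vs = C_sp * yp;
    double vf = C_fp * yp - C_ff * yf - C_fs * ys + uf;
    double zp = sigm1(vp, e0, r, v0), ze = sigm1(ve, e0, r, v0);
    double zs = sigm1(vs, e0, r, v0), zf = sigm1(vf, e0, r, v0);
    if (irec < n_rec && (t % rec_every) == 0) {
      zp_out[irec] = zp; zf_out[irec] = zf; ++irec;
    }
    if (noise_hi > noise_lo && (t % noise_hold) == 0)
      nz = ::unif_rand() * (noise_hi - noise_lo) + noise_lo;
    double dp = (pvar ? ext_p[t] : ext_p[0]) + nz;
    double df = (fvar ? ext_f[t] : ext_f[0]);
    double xn;
    xn = xp + dt * (G_e * om_e * zp - 2 * om_e * xp - om_e * om_e * yp); yp += dt * xp; xp = xn;
    xn = xe + dt * (G_e * om_e * ze - 2 * om_e * xe - om_e * om_e * ye); ye += dt * xe; xe = xn;
    xn = xs + dt * (G_s * om_s * zs - 2 * om_s * xs - om_s * om_s * ys); ys += dt * xs; xs = xn;
    xn = xf + dt * (G_f * om_f * zf - 2 * om_f * xf - om_f * om_f * yf); yf += dt * xf; xf = xn;
    xn = xup + dt * (G_W * om_W * dp - 2 * om_W * xup - om_W * om_W * up); up += dt * xup; xup = xn;
    xn = xuf + dt * (G_K * om_K * df - 2 * om_K * xuf - om_K * om_K * uf); uf += dt * xuf; xuf = xn;
    if (!std::isfinite(yp))
      stop("numerical divergence (NaN/Inf) in pyramidal kernel at t = %g s", t * dt);
  }
  return List::create(_["z_p"] = zp_out, _["z_f"] = zf_out);
}
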