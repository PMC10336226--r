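// Forward-Euler main loop for the excitatory-inhibitory seizure network.
// Mirrors the R reference operations (membrane_step, sample_spikes, ...)
// exactly, including the order of floating-point accumulation and the order
// in which uniform variates are consumed from the R random stream (one draw
// per neuron per step, excitatory population first, ascending index), so a
// short run is bit-identical to the R reference loop.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double step_prob(double V, double phi, double f0, double beta,
                               double dt, bool cap_rate, double f_cap) {
  double z = (V - phi) / beta;
  if (z > 60.0) z = 60.0;
  double f = f0 * std::exp(z);            // Hz
  if (cap_rate && f > f_cap) f = f_cap;
  return -std::expm1(-f * 1e-3 * dt);
}

// [[Rcpp::export]]
List sim_core_cpp(List np, List sp,
                  NumericMatrix W_EE, NumericMatrix W_EI,
                  NumericMatrix W_II, NumericMatrix W_IE,
                  NumericMatrix Wp_EE, NumericMatrix Wp_EI,
                  int n_steps,
                  NumericVector wave_E, NumericVector wave_I,
                  LogicalVector cross_E, LogicalVector cross_I,
                  double seiz_amp, int seiz_from, int seiz_to,
                  IntegerVector seiz_targets,
                  NumericVector gF_E, NumericVector gF_I,
                  double V_ChR2_E, double V_ChR2_I,
                  int record_every, bool record_raster,
                  List init_E, List init_I,
                  NumericVector A_E0, NumericVector A_I0) {
  const int N_E = W_EE.nrow(), N_I = W_II.nrow();
  const double C = np["C"], g_L = np["g_L"], E_L = np["E_L"], E_E = np["E_E"],
               E_K = np["E_K"], f0 = np["f0"], beta = np["beta"],
               tau_ref = np["tau_ref"], tau_syn = np["tau_syn"],
               tau_phi = np["tau_phi"], phi0 = np["phi0"],
               delta_phi = np["delta_phi"], delta_K = np["delta_K"],
               f_max = np["f_max"], V_d = np["V_d"], Fa = np["Faraday"],
               Cl_eq = np["Cl_in_eq"], Cl_out = np["Cl_out"],
               tau_Cl = np["tau_Cl"], tau_K = np["tau_K"], dt = np["dt"],
               syn_gain = np["syn_gain"], slope = np["nernst_slope"];
  const bool log10_flag =
      as<std::string>(np["nernst_log"]) == std::string("base10");
  const bool cap_rate = as<bool>(np["cap_rate"]);
  const double f_cap = 1000.0 * f_max;
  const double eta = sp["eta"], tau_STDP = sp["tau_STDP"], A0 = sp["A0"];
  const bool plastic = eta > 0.0;

  // population state (copied from the init lists)
  std::vector<double> V_E = as<std::vector<double>>(init_E["V"]);
  std::vector<double> phi_E = as<std::vector<double>>(init_E["phi"]);
  std::vector<double> gE_E = as<std::vector<double>>(init_E["g_E"]);
  std::vector<double> gI_E = as<std::vector<double>>(init_E["g_I"]);
  std::vector<double> gK_E = as<std::vector<double>>(init_E["g_K"]);
  std::vector<double> Cl_E = as<std::vector<double>>(init_E["Cl_in"]);
  std::vector<double> ECl_E = as<std::vector<double>>(init_E["E_Cl"]);
  std::vector<double> tls_E = as<std::vector<double>>(init_E["t_last_spike"]);
  std::vector<double> V_V = as<std::vector<double>>(init_I["V"]);
  std::vector<double> phi_I = as<std::vector<double>>(init_I["phi"]);
  std::vector<double> gE_I = as<std::vector<double>>(init_I["g_E"]);
  std::vector<double> gI_I = as<std::vector<double>>(init_I["g_I"]);
  std::vector<double> gK_I = as<std::vector<double>>(init_I["g_K"]);
  std::vector<double> Cl_I = as<std::vector<double>>(init_I["Cl_in"]);
  std::vector<double> ECl_I = as<std::vector<double>>(init_I["E_Cl"]);
  std::vector<double> tls_I = as<std::vector<double>>(init_I["t_last_spike"]);

  std::vector<double> Vspk_E(N_E, 0.0), Vspk_I(N_I, 0.0);
  std::vector<char> prev_E(N_E, 0), prev_I(N_I, 0);
  std::vector<char> spk_E(N_E, 0), spk_I(N_I, 0);
  std::vector<double> excin_E(N_E), inhin_E(N_E), excin_I(N_I), inhin_I(N_I);
  std::vector<double> A_E = as<std::vector<double>>(A_E0);
  std::vector<double> A_I = as<std::vector<double>>(A_I0);

  std::vector<char> seiz_mask(N_E, 0);
  for (int s = 0; s < seiz_targets.size(); s++) seiz_mask[seiz_targets[s]] = 1;

  const bool have_wE = wave_E.size() > 0, have_wI = wave_I.size() > 0;
  const bool have_gFE = gF_E.size() > 0, have_gFI = gF_I.size() > 0;
  const bool have_seiz = seiz_targets.size() > 0;

  std::vector<int> ras_id;
  std::vector<double> ras_t;
  int n_rec = n_steps / record_every + 1;
  NumericVector avg_w(n_rec), avg_t(n_rec), avg_w_ee(n_rec);
  double *wEI = REAL(W_EI), *wpEI = REAL(Wp_EI);
  double *wEE = REAL(W_EE), *wpEE = REAL(Wp_EE);
  double *wII = REAL(W_II), *wIE = REAL(W_IE);

  auto avg_ei = [&]() {
    double s = 0.0;
    const R_xlen_t n = (R_xlen_t)N_E * N_I;
    for (R_xlen_t q = 0; q < n; q++) s += wEI[q] * wpEI[q];
    return s / N_I;
  };
  auto avg_ee = [&]() {
    double s = 0.0;
    const R_xlen_t n = (R_xlen_t)N_E * N_E;
    for (R_xlen_t q = 0; q < n; q++) s += wEE[q] * wpEE[q];
    return s / N_E;
  };
  int irec = 0;
  avg_t[irec] = 0.0; avg_w[irec] = avg_ei(); avg_w_ee[irec] = avg_ee();
  irec++;

  RNGScope scope;
  for (int k = 0; k < n_steps; k++) {
    const double t = k * dt, t_new = (k + 1) * dt;
    const bool in_seiz = have_seiz && k >= seiz_from && k < seiz_to;

    // ---- applied current, membrane update, pending reset: E population
    for (int i = 0; i < N_E; i++) {
      double I = 0.0;
      if (in_seiz && seiz_mask[i]) I += seiz_amp;
      if (have_wE) I += wave_E[k];
      if (have_wI && cross_E[i]) I += wave_I[k];
      if (have_gFE) I += -gF_E[k] * (V_E[i] - V_ChR2_E);
      double dVdt = (g_L * (E_L - V_E[i]) +
                     f_max * (gE_E[i] * (E_E - V_E[i]) +
                              gI_E[i] * (ECl_E[i] - V_E[i]) +
                              gK_E[i] * (E_K - V_E[i])) + I) / C;
      V_E[i] = V_E[i] + dt * dVdt;
    }
    for (int i = 0; i < N_E; i++)
      if (prev_E[i]) V_E[i] = Vspk_E[i] - 20.0;
    // ---- I population
    for (int i = 0; i < N_I; i++) {
      double I = 0.0;
      if (have_wI) I += wave_I[k];
      if (have_wE && cross_I[i]) I += wave_E[k];
      if (have_gFI) I += -gF_I[k] * (V_V[i] - V_ChR2_I);
      double dVdt = (g_L * (E_L - V_V[i]) +
                     f_max * (gE_I[i] * (E_E - V_V[i]) +
                              gI_I[i] * (ECl_I[i] - V_V[i]) +
                              gK_I[i] * (E_K - V_V[i])) + I) / C;
      V_V[i] = V_V[i] + dt * dVdt;
    }
    for (int i = 0; i < N_I; i++)
      if (prev_I[i]) V_V[i] = Vspk_I[i] - 20.0;

    for (int i = 0; i < N_E; i++)
      if (!std::isfinite(V_E[i]))
        stop("non-finite membrane potential at step %d", k + 1);

    // ---- spike sampling: one uniform per neuron, E first, ascending
    for (int i = 0; i < N_E; i++) {
      double p = step_prob(V_E[i], phi_E[i], f0, beta, dt, cap_rate, f_cap);
      double u = unif_rand();
      spk_E[i] = (u < p) && (t_new - tls_E[i] >= tau_ref);
    }
    for (int i = 0; i < N_I; i++) {
      double p = step_prob(V_V[i], phi_I[i], f0, beta, dt, cap_rate, f_cap);
      double u = unif_rand();
      spk_I[i] = (u < p) && (t_new - tls_I[i] >= tau_ref);
    }

    // ---- spike reset + raster
    for (int i = 0; i < N_E; i++) {
      if (spk_E[i]) {
        Vspk_E[i] = V_E[i];               // pre-spike potential V(t_i)
        V_E[i] = (40.0 + V_E[i]) / 2.0;   // action-potential excursion
        phi_E[i] = phi_E[i] + delta_phi;
        tls_E[i] = t_new;
        if (record_raster) { ras_id.push_back(i + 1); ras_t.push_back(t_new); }
      }
      prev_E[i] = spk_E[i];
    }
    for (int i = 0; i < N_I; i++) {
      if (spk_I[i]) {
        Vspk_I[i] = V_V[i];
        V_V[i] = (40.0 + V_V[i]) / 2.0;
        phi_I[i] = phi_I[i] + delta_phi;
        tls_I[i] = t_new;
        if (record_raster) {
          ras_id.push_back(N_E + i + 1); ras_t.push_back(t_new);
        }
      }
      prev_I[i] = spk_I[i];
    }

    // ---- threshold relaxation
    for (int i = 0; i < N_E; i++)
      phi_E[i] = phi_E[i] + dt / tau_phi * (phi0 - phi_E[i]);
    for (int i = 0; i < N_I; i++)
      phi_I[i] = phi_I[i] + dt / tau_phi * (phi0 - phi_I[i]);

    // ---- synaptic delivery (spikes this step feed conductances used next)
    std::fill(excin_E.begin(), excin_E.end(), 0.0);
    std::fill(inhin_E.begin(), inhin_E.end(), 0.0);
    std::fill(excin_I.begin(), excin_I.end(), 0.0);
    std::fill(inhin_I.begin(), inhin_I.end(), 0.0);
    for (int i = 0; i < N_E; i++) {
      if (!spk_E[i]) continue;
      for (int j = 0; j < N_E; j++)
        excin_E[j] += wEE[i + (R_xlen_t)j * N_E] *
                      wpEE[i + (R_xlen_t)j * N_E];
      for (int j = 0; j < N_I; j++)
        excin_I[j] += wEI[i + (R_xlen_t)j * N_E] *
                      wpEI[i + (R_xlen_t)j * N_E];
    }
    for (int i = 0; i < N_I; i++) {
      if (!spk_I[i]) continue;
      for (int j = 0; j < N_I; j++)
        inhin_I[j] += wII[i + (R_xlen_t)j * N_I];
      for (int j = 0; j < N_E; j++)
        inhin_E[j] += wIE[i + (R_xlen_t)j * N_I];
    }
    // synaptic increments are impulse-normalized by tau_syn (matching the
    // sAHP increment delta_K / tau_K)
    for (int i = 0; i < N_E; i++) {
      gE_E[i] = gE_E[i] - dt / tau_syn * gE_E[i] + syn_gain * excin_E[i] / tau_syn;
      gI_E[i] = gI_E[i] - dt / tau_syn * gI_E[i] + syn_gain * inhin_E[i] / tau_syn;
      gK_E[i] = gK_E[i] - dt / tau_K * gK_E[i];
      if (spk_E[i]) gK_E[i] = gK_E[i] + delta_K / tau_K;
    }
    for (int i = 0; i < N_I; i++) {
      gE_I[i] = gE_I[i] - dt / tau_syn * gE_I[i] + syn_gain * excin_I[i] / tau_syn;
      gI_I[i] = gI_I[i] - dt / tau_syn * gI_I[i] + syn_gain * inhin_I[i] / tau_syn;
      gK_I[i] = gK_I[i] - dt / tau_K * gK_I[i];
      if (spk_I[i]) gK_I[i] = gK_I[i] + delta_K / tau_K;
    }

    // ---- chloride and GABA reversal
    for (int i = 0; i < N_E; i++) {
      double I_Cl = gI_E[i] * (V_E[i] - ECl_E[i]);
      Cl_E[i] = Cl_E[i] + dt * (I_Cl / (V_d * Fa) -
                                (Cl_E[i] - Cl_eq) / tau_Cl);
      if (Cl_E[i] <= 0.0)
        stop("non-positive [Cl_in] at step %d", k + 1);
      ECl_E[i] = log10_flag ? -slope * std::log10(Cl_out / Cl_E[i])
                            : -slope * std::log(Cl_out / Cl_E[i]);
    }
    for (int i = 0; i < N_I; i++) {
      double I_Cl = gI_I[i] * (V_V[i] - ECl_I[i]);
      Cl_I[i] = Cl_I[i] + dt * (I_Cl / (V_d * Fa) -
                                (Cl_I[i] - Cl_eq) / tau_Cl);
      if (Cl_I[i] <= 0.0)
        stop("non-positive [Cl_in] at step %d", k + 1);
      ECl_I[i] = log10_flag ? -slope * std::log10(Cl_out / Cl_I[i])
                            : -slope * std::log(Cl_out / Cl_I[i]);
    }

    // ---- STDP: weight updates from pre-step traces, then trace dynamics
    if (plastic) {
      for (int i = 0; i < N_E; i++) {
        if (!spk_E[i]) continue;
        for (int j = 0; j < N_E; j++)
          wpEE[i + (R_xlen_t)j * N_E] -= eta * A_E[j];
        for (int j = 0; j < N_I; j++)
          wpEI[i + (R_xlen_t)j * N_E] -= eta * A_I[j];
      }
      for (int j = 0; j < N_E; j++) {
        if (!spk_E[j]) continue;
        double *col = wpEE + (R_xlen_t)j * N_E;
        for (int i = 0; i < N_E; i++) col[i] += eta * A_E[i];
      }
      for (int j = 0; j < N_I; j++) {
        if (!spk_I[j]) continue;
        double *col = wpEI + (R_xlen_t)j * N_E;
        for (int i = 0; i < N_E; i++) col[i] += eta * A_E[i];
      }
      // clamp at zero: only rows/columns touched this step can go negative
      for (int i = 0; i < N_E; i++) {
        if (!spk_E[i]) continue;
        for (int j = 0; j < N_E; j++) {
          R_xlen_t q = i + (R_xlen_t)j * N_E;
          if (wpEE[q] < 0.0) wpEE[q] = 0.0;
        }
        for (int j = 0; j < N_I; j++) {
          R_xlen_t q = i + (R_xlen_t)j * N_E;
          if (wpEI[q] < 0.0) wpEI[q] = 0.0;
        }
      }
    }
    for (int i = 0; i < N_E; i++) {
      A_E[i] = A_E[i] - dt / tau_STDP * A_E[i];
      if (spk_E[i]) A_E[i] = A_E[i] + A0;
    }
    for (int i = 0; i < N_I; i++) {
      A_I[i] = A_I[i] - dt / tau_STDP * A_I[i];
      if (spk_I[i]) A_I[i] = A_I[i] + A0;
    }

    if ((k + 1) % record_every == 0) {
      avg_t[irec] = t_new; avg_w[irec] = avg_ei(); avg_w_ee[irec] = avg_ee();
      irec++;
    }
  }

  auto vec = [](std::vector<double> &x) { return NumericVector(x.begin(), x.end()); };
  List st_E = List::create(_["V"] = vec(V_E), _["phi"] = vec(phi_E),
                           _["g_E"] = vec(gE_E), _["g_I"] = vec(gI_E),
                           _["g_K"] = vec(gK_E), _["Cl_in"] = vec(Cl_E),
                           _["E_Cl"] = vec(ECl_E),
                           _["t_last_spike"] = vec(tls_E));
  List st_I = List::create(_["V"] = vec(V_V), _["phi"] = vec(phi_I),
                           _["g_E"] = vec(gE_I), _["g_I"] = vec(gI_I),
                           _["g_K"] = vec(gK_I), _["Cl_in"] = vec(Cl_I),
                           _["E_Cl"] = vec(ECl_I),
                           _["t_last_spike"] = vec(tls_I));
  return List::create(
      _["raster_id"] = IntegerVector(ras_id.begin(), ras_id.end()),
      _["raster_t"] = NumericVector(ras_t.begin(), ras_t.end()),
      _["avg_t"] = avg_t[Range(0, irec - 1)],
      _["avg_w_EI"] = avg_w[Range(0, irec - 1)],
      _["avg_w_EE"] = avg_w_ee[Range(0, irec - 1)],
      _["Wp_EE"] = Wp_EE, _["Wp_EI"] = Wp_EI,
      _["state_E"] = st_E, _["state_I"] = st_I,
      _["A_E"] = vec(A_E), _["A_I"] = vec(A_I));
}
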