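// Fixed-step exponential-Euler integrator for networks of identical
// non-spiking single-compartment neurons coupled by graded Ca-dependent
// synapses. Staggered explicit scheme per step: synapse states advance from
// presynaptic Ca at step start; then per cell the Ca gate, the Ca pool, the
// Nernst potential, and finally the membrane potential are updated.
//
// Unit contract matches the R layer: ms, mV, nA, whole-cell conductances in
// mS (1 mS * 1 mV = 1 uA = 1000 nA), Ca_i in nM.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_engine_cpp")]]
List sim_engine(List cells, List conns, List stim, List opto,
                double duration, double dt,
                IntegerVector record_cells, IntegerVector record_conns,
                int record_every, bool record_gates) {
  // --- unpack cells (whole-cell quantities precomputed in R) ---
  NumericVector gL = cells["gL"];       // mS
  NumericVector EL = cells["EL"];       // mV
  NumericVector gCa = cells["gCa"];     // mS (maximal)
  NumericVector Vmid = cells["Vmid"];
  NumericVector SCa = cells["SCa"];
  NumericVector tau_m = cells["tau_m"];
  NumericVector Beff = cells["Beff"];   // nM ms^-1 nA^-1
  NumericVector tauCa = cells["tauCa"];
  NumericVector Camin = cells["Camin"];
  NumericVector CaeNM = cells["Cae_nM"];
  NumericVector rtzf = cells["rtzf_mV"]; // RT/2F in mV
  NumericVector Ctot = cells["C_tot"];  // uF
  NumericVector V = clone(as<NumericVector>(cells["V0"]));
  NumericVector m = clone(as<NumericVector>(cells["m0"]));
  NumericVector Ca = clone(as<NumericVector>(cells["Ca0"]));
  const int n_cells = V.size();

  NumericVector ECa(n_cells);
  for (int j = 0; j < n_cells; ++j) ECa[j] = rtzf[j] * std::log(CaeNM[j] / Ca[j]);

  // --- unpack connections ---
  IntegerVector pre = conns["pre"];     // 0-based
  IntegerVector post = conns["post"];
  NumericVector Esyn = conns["Esyn"];
  NumericVector rmax = conns["rmax"];
  NumericVector Camid = conns["Camid"];
  NumericVector Sr = conns["Sr"];
  NumericVector tauT = conns["tauT"];
  NumericVector Sbind = conns["Sbind"];
  NumericVector gsyn = conns["g_tot"];  // gain * g_syn_max * area_post, mS
  NumericVector T = clone(as<NumericVector>(conns["T0"]));
  const int n_conns = pre.size();
  NumericVector msyn(n_conns);

  // --- stimulus: dense matrix over stimulated cells only ---
  IntegerVector stim_idx = stim["idx"]; // 0-based cell indices
  NumericMatrix stim_mat = stim["mat"]; // n_steps x length(stim_idx), nA
  const int n_stim = stim_idx.size();

  // --- optogenetic channels: per-cell conductance + unblock windows ---
  IntegerVector opto_idx = opto["idx"];  // 0-based
  NumericVector opto_g = opto["g_tot"];  // mS (whole cell)
  NumericVector opto_E = opto["E"];
  NumericMatrix opto_win = opto["windows"]; // columns: cell pos (0-based in
                                            // opto_idx), t0, t1 (ms)
  const int n_opto = opto_idx.size();
  const int n_win = opto_win.nrow();

  const int n_steps = (int) std::lround(duration / dt);
  const int n_rec_c = record_cells.size();
  const int n_rec_s = record_conns.size();
  const int n_out = n_steps / record_every + 1;

  NumericMatrix recV(n_out, n_rec_c);
  NumericMatrix recM(record_gates ? n_out : 0, record_gates ? n_rec_c : 0);
  NumericMatrix recCa(record_gates ? n_out : 0, record_gates ? n_rec_c : 0);
  NumericMatrix recT(record_gates ? n_out : 0, record_gates ? n_rec_s : 0);
  NumericMatrix recMsyn(record_gates ? n_out : 0, record_gates ? n_rec_s : 0);
  NumericVector rec_time(n_out);

  std::vector<double> dec_m(n_cells), dec_Ca(n_cells);
  for (int j = 0; j < n_cells; ++j) {
    dec_m[j] = std::exp(-dt / tau_m[j]);
    dec_Ca[j] = std::exp(-dt / tauCa[j]);
  }
  std::vector<double> dec_T(n_conns);
  for (int c = 0; c < n_conns; ++c) dec_T[c] = std::exp(-dt / tauT[c]);

  std::vector<double> g_acc(n_cells), gE_acc(n_cells), I_inj(n_cells);

  int out_row = 0;
  auto record_row = [&](double t) {
    rec_time[out_row] = t;
    for (int k = 0; k < n_rec_c; ++k) {
      int j = record_cells[k];
      recV(out_row, k) = V[j];
      if (record_gates) { recM(out_row, k) = m[j]; recCa(out_row, k) = Ca[j]; }
    }
    if (record_gates) {
      for (int k = 0; k < n_rec_s; ++k) {
        int c = record_conns[k];
        recT(out_row, k) = T[c];
        recMsyn(out_row, k) = msyn[c];
      }
    }
    ++out_row;
  };
  record_row(0.0);

  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    // synapses: release from Ca at step start, cleft update, receptor gate
    std::fill(g_acc.begin(), g_acc.end(), 0.0);
    std::fill(gE_acc.begin(), gE_acc.end(), 0.0);
    for (int c = 0; c < n_conns; ++c) {
      const double rate = rmax[c] / (1.0 + std::exp((Camid[c] - Ca[pre[c]]) / Sr[c]));
      const double Tinf = rate * tauT[c];
      T[c] = Tinf + (T[c] - Tinf) * dec_T[c];
      const double ms = 2.0 / (1.0 + std::exp(-T[c] / Sbind[c])) - 1.0;
      msyn[c] = ms;
      const double g = gsyn[c] * ms;
      g_acc[post[c]] += g;
      gE_acc[post[c]] += g * Esyn[c];
    }
    // optogenetic chloride channels conduct only while unblocked
    for (int w = 0; w < n_win; ++w) {
      if (t >= opto_win(w, 1) && t < opto_win(w, 2)) {
        const int p = (int) opto_win(w, 0);
        const int j = opto_idx[p];
        g_acc[j] += opto_g[p];
        gE_acc[j] += opto_g[p] * opto_E[p];
      }
    }
    // injected currents (dense per-step values, stimulated cells only)
    std::fill(I_inj.begin(), I_inj.end(), 0.0);
    for (int s = 0; s < n_stim; ++s) I_inj[stim_idx[s]] += stim_mat(i, s);
    // cells: gate -> Ca current -> Ca pool -> E_Ca -> membrane potential
    for (int j = 0; j < n_cells; ++j) {
      const double m_inf = 1.0 / (1.0 + std::exp((Vmid[j] - V[j]) / SCa[j]));
      m[j] = m_inf + (m[j] - m_inf) * dec_m[j];
      const double gCa_j = m[j] * gCa[j];                    // mS
      const double ICa = gCa_j * (V[j] - ECa[j]) * 1000.0;   // nA
      const double inflow = Beff[j] * std::max(0.0, -ICa);   // nM/ms
      const double Ca_inf = Camin[j] + inflow * tauCa[j];
      Ca[j] = Ca_inf + (Ca[j] - Ca_inf) * dec_Ca[j];
      if (Ca[j] < Camin[j]) Ca[j] = Camin[j];
      ECa[j] = rtzf[j] * std::log(CaeNM[j] / Ca[j]);
      const double g_tot = gL[j] + gCa_j + g_acc[j];
      const double gE = gL[j] * EL[j] + gCa_j * ECa[j] + gE_acc[j];
      const double V_inf = (gE + I_inj[j] / 1000.0) / g_tot;
      const double tau_V = Ctot[j] / g_tot;
      V[j] = V_inf + (V[j] - V_inf) * std::exp(-dt / tau_V);
    }
    if (((i + 1) % record_every) == 0) record_row((i + 1) * dt);
    if ((i & 1023) == 0) {
      for (int j = 0; j < n_cells; ++j) {
        if (!std::isfinite(V[j])) {
          stop("non-finite membrane potential at step %d (t = %g ms), cell index %d",
               i, t, j + 1);
        }
      }
    }
  }

  return List::create(
    _["time"] = rec_time,
    _["V"] = recV,
    _["m"] = recM,
    _["Ca"] = recCa,
    _["T"] = recT,
    _["m_syn"] = recMsyn,
    _["final_V"] = V, _["final_m"] = m, _["final_Ca"] = Ca, _["final_T"] = T);
}
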