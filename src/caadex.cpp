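// Core time-stepping engine: linearized Crank-Nicolson voltage update on a
// compartment tree (Hines solve), leap-frog exponential-propagator gating,
// spike/reset/refractory handling and event queues (BAP, synaptic spikes).
// Units throughout: pF, nS, mV, ms, pA, mM (pA/pF == mV/ms).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

// Exponential spike-initiation term is clamped at exponent +10: spikes are
// detected at V_th anyway, the clamp only guards against overflow.
static const double EXP_CLAMP = 10.0;
static inline double expclamp(double x) {
  return std::exp(x > EXP_CLAMP ? EXP_CLAMP : x);
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(x)); }

// double-exponential window normalization so the peak equals the weight
static inline double dexp_norm(double taur, double taud) {
  double tp = taur * taud / (taud - taur) * std::log(taud / taur);
  return 1.0 / (std::exp(-tp / taud) - std::exp(-tp / taur));
}

// NMDA magnesium block sigma(V) = 1 / (1 + 0.3 exp(-0.1 V))
static inline double mgblock(double v) {
  return 1.0 / (1.0 + 0.3 * std::exp(-0.1 * v));
}

// ---------------------------------------------------------------------------
// Hines solve for the symmetric tree system: A[i,i] = diag[i],
// A[i,parent[i]] = A[parent[i],i] = off[i].  Compartments must be ordered
// children-after-parents (root first, parent[0] = -1).  O(N), exact.
// [[Rcpp::export(name = "hines_solve_cpp")]]
NumericVector hines_solve_cpp(IntegerVector parent, NumericVector diag,
                              NumericVector off, NumericVector rhs) {
  int n = diag.size();
  std::vector<double> d(diag.begin(), diag.end());
  std::vector<double> b(rhs.begin(), rhs.end());
  for (int i = n - 1; i > 0; --i) {
    int p = parent[i];
    if (!(std::abs(d[i]) > 0.0))
      stop("hines_solve: singular diagonal during elimination at compartment %d", i + 1);
    double f = off[i] / d[i];
    d[p] -= f * off[i];
    b[p] -= f * b[i];
  }
  if (!(std::abs(d[0]) > 0.0))
    stop("hines_solve: singular diagonal during elimination at compartment 1");
  NumericVector x(n);
  x[0] = b[0] / d[0];
  for (int i = 1; i < n; ++i) x[i] = (b[i] - off[i] * x[parent[i]]) / d[i];
  return x;
}

// ---------------------------------------------------------------------------
// Full tree simulation.
//
// tree: list(parent, Cm, gL, EL, gC, adex_comp, adex_par, bap_target,
//            ca_comp, ca_par)
//   adex_par columns: DeltaT VthS Vth Vreset tref a b tauw gw wBAP dBAP
//   ca_par columns:   gCa ECa mslope mhalf hslope hhalf taumCa tauhCa
//                     gK EK taumK Cath kexp phi Ca0 tauCa
// stim: list(step_comp, step_amp, step_on, step_off,
//            rec_comp, rec_kind, rec_taur, rec_taud, rec_er, rec_w, rec_spikes)
//   rec_kind: 0 = conductance, 1 = NMDA conductance, 2 = current (beta)
// [[Rcpp::export(name = "simulate_cpp")]]
List simulate_cpp(List tree, List stim, double h, double T, NumericVector v0) {
  IntegerVector parent = tree["parent"];
  NumericVector Cm = tree["Cm"], gL = tree["gL"], EL = tree["EL"], gC = tree["gC"];
  IntegerVector adex_comp = tree["adex_comp"];
  NumericMatrix adex_par = tree["adex_par"];
  List bap_target = tree["bap_target"];
  IntegerVector ca_comp = tree["ca_comp"];
  NumericMatrix ca_par = tree["ca_par"];

  NumericVector step_comp = stim["step_comp"], step_amp = stim["step_amp"],
                step_on = stim["step_on"], step_off = stim["step_off"];
  IntegerVector rec_comp = stim["rec_comp"], rec_kind = stim["rec_kind"];
  NumericVector rec_taur = stim["rec_taur"], rec_taud = stim["rec_taud"],
                rec_er = stim["rec_er"], rec_w = stim["rec_w"];
  List rec_spikes = stim["rec_spikes"];

  const int nc = parent.size();
  const int na = adex_comp.size();
  const int nca = ca_comp.size();
  const int nr = rec_comp.size();
  const int nst = step_comp.size();
  const int nsteps = (int)std::llround(T / h);

  // map compartment -> adex slot (or -1)
  std::vector<int> adex_of(nc, -1);
  for (int ia = 0; ia < na; ++ia) adex_of[adex_comp[ia]] = ia;

  // state
  std::vector<double> V(nc);
  for (int i = 0; i < nc; ++i) V[i] = v0[i];
  std::vector<double> w(na, 0.0);
  std::vector<double> clamp_end(na, -1.0); // end of refractory hold
  std::vector<double> mCa(nca), hCa(nca), mK(nca), Ca(nca);
  for (int ic = 0; ic < nca; ++ic) {
    double v = V[ca_comp[ic]];
    mCa[ic] = logistic(ca_par(ic, 2) * (v - ca_par(ic, 3)));
    hCa[ic] = logistic(ca_par(ic, 4) * (v - ca_par(ic, 5)));
    Ca[ic] = ca_par(ic, 14);
    double r = std::pow(ca_par(ic, 11) / std::max(Ca[ic], 1e-300), ca_par(ic, 12));
    mK[ic] = Ca[ic] > 0.0 ? 1.0 / (1.0 + r) : 0.0;
  }

  // receptor states (value used over the step, mid-step convention)
  std::vector<double> rA(nr, 0.0), rB(nr, 0.0), rPd(nr), rPr(nr), rN(nr);
  std::vector<std::vector<int>> rSteps(nr);
  std::vector<size_t> rPtr(nr, 0);
  for (int r = 0; r < nr; ++r) {
    rPd[r] = std::exp(-h / rec_taud[r]);
    rPr[r] = std::exp(-h / rec_taur[r]);
    rN[r] = dexp_norm(rec_taur[r], rec_taud[r]);
    NumericVector sp = rec_spikes[r];
    rSteps[r].reserve(sp.size());
    for (double t : sp) rSteps[r].push_back((int)std::llround(t / h));
  }

  // BAP deliveries: per-step list of (compartment, current)
  std::vector<std::vector<std::pair<int, double>>> bap(nsteps + 1);
  std::vector<std::vector<double>> spikes(na), bap_times(na);

  // recordings
  NumericMatrix recV(nsteps + 1, nc);
  NumericMatrix recW(nsteps + 1, na);
  NumericMatrix recCa(nsteps + 1, nca), recM(nsteps + 1, nca),
      recH(nsteps + 1, nca), recMK(nsteps + 1, nca);
  for (int i = 0; i < nc; ++i) recV(0, i) = V[i];
  for (int ic = 0; ic < nca; ++ic) {
    recCa(0, ic) = Ca[ic]; recM(0, ic) = mCa[ic];
    recH(0, ic) = hCa[ic]; recMK(0, ic) = mK[ic];
  }

  std::vector<double> Adiag(nc), Aoff(nc), rhs(nc), Iext(nc);

  for (int n = 0; n < nsteps; ++n) {
    double t = n * h;
    double tmid = t + 0.5 * h;

    // advance receptor states to this step's mid-point, deliver spikes
    for (int r = 0; r < nr; ++r) {
      rA[r] *= rPd[r];
      rB[r] *= rPr[r];
      while (rPtr[r] < rSteps[r].size() && rSteps[r][rPtr[r]] <= n) {
        double inc = rec_w[r] * rN[r];
        rA[r] += inc; rB[r] += inc;
        ++rPtr[r];
      }
    }

    // external currents: DC steps + beta currents + pending BAP charge
    std::fill(Iext.begin(), Iext.end(), 0.0);
    for (int s = 0; s < nst; ++s)
      if (tmid >= step_on[s] && tmid < step_off[s]) Iext[(int)step_comp[s]] += step_amp[s];
    for (int r = 0; r < nr; ++r)
      if (rec_kind[r] == 2) Iext[rec_comp[r]] += (rA[r] - rB[r]);
    for (auto &ev : bap[n]) Iext[ev.first] += ev.second;

    // assemble linearized Crank-Nicolson system: (C/h - J/2) dV = F(V)
    for (int i = 0; i < nc; ++i) {
      double F = gL[i] * (EL[i] - V[i]) + Iext[i];
      double mJ = gL[i]; // minus Jacobian diagonal contribution
      Adiag[i] = 0.0; Aoff[i] = 0.0; rhs[i] = 0.0;
      int ia = adex_of[i];
      if (ia >= 0) {
        double DeltaT = adex_par(ia, 0), VthS = adex_par(ia, 1), gw = adex_par(ia, 8);
        double ex = expclamp((V[i] - VthS) / DeltaT);
        F += gL[i] * DeltaT * ex - gw * w[ia];
        // cap the linearization slope at C/h so the Crank-Nicolson diagonal
        // stays positive; the current itself is not capped, and spikes are
        // detected at V_th before accuracy here matters
        mJ -= std::min(gL[i] * ex, Cm[i] / h);
      }
      rhs[i] = F; Adiag[i] = mJ;
    }
    for (int ic = 0; ic < nca; ++ic) {
      int i = ca_comp[ic];
      double gca = ca_par(ic, 0) * mCa[ic] * hCa[ic];
      double gk = ca_par(ic, 8) * mK[ic];
      rhs[i] += gca * (ca_par(ic, 1) - V[i]) + gk * (ca_par(ic, 9) - V[i]);
      Adiag[i] += gca + gk;
    }
    for (int r = 0; r < nr; ++r) {
      if (rec_kind[r] == 2) continue;
      int i = rec_comp[r];
      double g = rA[r] - rB[r];
      if (rec_kind[r] == 1) { // NMDA with magnesium block
        double s = mgblock(V[i]);
        rhs[i] += g * s * (rec_er[r] - V[i]);
        Adiag[i] += g * s - g * 0.1 * s * (1.0 - s) * (rec_er[r] - V[i]);
      } else {
        rhs[i] += g * (rec_er[r] - V[i]);
        Adiag[i] += g;
      }
    }
    // coupling (Eq. 9 convention, one gC per child edge, symmetric)
    for (int i = 1; i < nc; ++i) {
      int p = parent[i];
      rhs[i] += gC[i] * (V[p] - V[i]);
      rhs[p] += gC[i] * (V[i] - V[p]);
      Adiag[i] += gC[i];
      Adiag[p] += gC[i];
      Aoff[i] = -0.5 * gC[i];
    }
    // finalize: A = C/h - J/2 ; clamped (refractory) compartments held fixed
    std::vector<char> clamped(nc, 0);
    for (int ia = 0; ia < na; ++ia)
      if (t + h <= clamp_end[ia] + 1e-9) clamped[adex_comp[ia]] = 1;
    for (int i = 0; i < nc; ++i) Adiag[i] = Cm[i] / h + 0.5 * Adiag[i];
    for (int i = 0; i < nc; ++i) {
      if (clamped[i]) { Adiag[i] = 1.0; Aoff[i] = 0.0; rhs[i] = 0.0; }
      else if (i > 0 && clamped[parent[i]]) Aoff[i] = 0.0;
    }
    for (int i = 1; i < nc; ++i) if (clamped[i]) Aoff[i] = 0.0;

    // Hines elimination (inlined)
    {
      for (int i = nc - 1; i > 0; --i) {
        int p = parent[i];
        double f = Aoff[i] / Adiag[i];
        Adiag[p] -= f * Aoff[i];
        rhs[p] -= f * rhs[i];
      }
      double dV0 = rhs[0] / Adiag[0];
      V[0] += clamped[0] ? 0.0 : dV0;
      std::vector<double> x(nc); x[0] = dV0;
      for (int i = 1; i < nc; ++i) {
        x[i] = (rhs[i] - Aoff[i] * x[parent[i]]) / Adiag[i];
        if (!clamped[i]) V[i] += x[i];
      }
    }
    for (int i = 0; i < nc; ++i)
      if (!std::isfinite(V[i]))
        stop("integration failure: non-finite voltage at step %d, compartment %d", n + 1, i + 1);

    // spike detection, reset, adaptation, BAP scheduling
    for (int ia = 0; ia < na; ++ia) {
      int i = adex_comp[ia];
      bool in_ref = clamped[i];
      bool spiked = false;
      if (!in_ref && V[i] >= adex_par(ia, 2)) {
        spiked = true;
        double ts = t + h;
        spikes[ia].push_back(ts);
        V[i] = adex_par(ia, 3);
        if (adex_par(ia, 4) > 0.0) clamp_end[ia] = ts + adex_par(ia, 4);
        int ds = (n + 1) + (int)std::llround(adex_par(ia, 10) / h);
        IntegerVector tg = bap_target[ia];
        if (adex_par(ia, 9) != 0.0 && tg.size() > 0 && ds <= nsteps - 1) {
          for (int k = 0; k < tg.size(); ++k)
            bap[ds].push_back(std::make_pair((int)tg[k], adex_par(ia, 9) / h));
          bap_times[ia].push_back(ds * h);
        }
      }
      // w: exponential integration with V held at its new value; b after reset
      double a = adex_par(ia, 5), tauw = adex_par(ia, 7);
      double P = std::exp(-h / tauw);
      w[ia] = P * w[ia] + (1.0 - P) * a * (V[i] - EL[i]);
      if (spiked) w[ia] += adex_par(ia, 6);
    }

    // gating / calcium leap-frog updates using V(t+h)
    for (int ic = 0; ic < nca; ++ic) {
      int i = ca_comp[ic];
      double v = V[i];
      double minf = logistic(ca_par(ic, 2) * (v - ca_par(ic, 3)));
      double hinf = logistic(ca_par(ic, 4) * (v - ca_par(ic, 5)));
      double Pm = std::exp(-h / ca_par(ic, 6)), Ph = std::exp(-h / ca_par(ic, 7));
      mCa[ic] = Pm * mCa[ic] + (1.0 - Pm) * minf;
      hCa[ic] = Ph * hCa[ic] + (1.0 - Ph) * hinf;
      double ICa = ca_par(ic, 0) * mCa[ic] * hCa[ic] * (ca_par(ic, 1) - v);
      double Ca0 = ca_par(ic, 14), tauCa = ca_par(ic, 15), phi = ca_par(ic, 13);
      double Cainf = Ca0 + phi * ICa * tauCa;
      double Pc = std::exp(-h / tauCa);
      Ca[ic] = Cainf + (Ca[ic] - Cainf) * Pc;
      double mkinf = 0.0;
      if (Ca[ic] > 0.0)
        mkinf = 1.0 / (1.0 + std::pow(ca_par(ic, 11) / Ca[ic], ca_par(ic, 12)));
      double Pk = std::exp(-h / ca_par(ic, 10));
      mK[ic] = Pk * mK[ic] + (1.0 - Pk) * mkinf;
    }

    for (int i = 0; i < nc; ++i) recV(n + 1, i) = V[i];
    for (int ia = 0; ia < na; ++ia) recW(n + 1, ia) = w[ia];
    for (int ic = 0; ic < nca; ++ic) {
      recCa(n + 1, ic) = Ca[ic]; recM(n + 1, ic) = mCa[ic];
      recH(n + 1, ic) = hCa[ic]; recMK(n + 1, ic) = mK[ic];
    }
  }

  NumericVector times(nsteps + 1);
  for (int n = 0; n <= nsteps; ++n) times[n] = n * h;
  List spk(na), bapt(na);
  for (int ia = 0; ia < na; ++ia) {
    spk[ia] = NumericVector(spikes[ia].begin(), spikes[ia].end());
    bapt[ia] = NumericVector(bap_times[ia].begin(), bap_times[ia].end());
  }
  return List::create(_["times"] = times, _["V"] = recV, _["w"] = recW,
                      _["Ca"] = recCa, _["m_Ca"] = recM, _["h_Ca"] = recH,
                      _["m_KCa"] = recMK, _["spikes"] = spk,
                      _["bap_events"] = bapt);
}

// ---------------------------------------------------------------------------
// Balanced network of identical two-compartment Ca-AdEx neurons.
// Conductance-based AMPA/GABA synapses on the soma, fixed delay, external
// per-neuron Poisson drive onto AMPA.  Connectivity passed in CSR form
// (out_ptr/out_idx, source -> targets); sources with index < n_exc are
// excitatory.  Deterministic for a fixed seed (std::mt19937 is
// standard-specified).
//
// pars: named numeric vector of genome fields (see R wrapper).
// [[Rcpp::export(name = "network_cpp")]]
List network_cpp(NumericVector pars, IntegerVector out_ptr, IntegerVector out_idx,
                 int n_exc, int n_inh, double J_exc, double g_ratio,
                 double delay_ms, double ext_rate_hz, double ext_w,
                 double h, double T, int seed) {
  const int N = n_exc + n_inh;
  const int nsteps = (int)std::llround(T / h);
  auto P = [&](const char *nm) { return (double)pars[nm]; };

  const double CmS = P("C_m_s"), gLs = P("g_L_s"), ELs = P("E_L_s");
  const double DeltaT = P("Delta_T"), VthS = P("V_th_s"), Vth = P("V_th");
  const double Vreset = P("V_reset"), tref = P("t_ref"), a = P("a"), b = P("b");
  const double tauw = P("tau_w"), gw = P("g_w"), wBAP = P("w_BAP"), dBAP = P("d_BAP");
  const double CmD = P("C_m_d"), gLd = P("g_L_d"), ELd = P("E_L_d"), gCc = P("g_C");
  const double gCa = P("g_Ca"), ECa = P("E_Ca"), msl = P("m_slope"), mha = P("m_half");
  const double hsl = P("h_slope"), hha = P("h_half"), taum = P("tau_m_Ca"),
               tauh = P("tau_h_Ca");
  const double gK = P("g_K"), EK = P("E_K"), taumK = P("tau_m_KCa");
  const double Cath = P("Ca_th"), kexp = P("const_KCa"), phi = P("phi_Ca"),
               Ca0 = P("Ca_0"), tauCa = P("tau_Ca");

  // somatic AMPA / GABA kinetics
  const double taurE = 0.2, taudE = 3.0, erE = 0.0;
  const double taurI = 0.2, taudI = 10.0, erI = -80.0;
  const double nE = dexp_norm(taurE, taudE), nI = dexp_norm(taurI, taudI);
  const double PdE = std::exp(-h / taudE), PrE = std::exp(-h / taurE);
  const double PdI = std::exp(-h / taudI), PrI = std::exp(-h / taurI);
  const double Pw = std::exp(-h / tauw);
  const double Pm = std::exp(-h / taum), Ph = std::exp(-h / tauh),
               Pk = std::exp(-h / taumK), Pc = std::exp(-h / tauCa);

  const int dsteps = std::max(1, (int)std::llround(delay_ms / h));
  const int bsteps = std::max(1, (int)std::llround(dBAP / h));
  const int D = dsteps + 2, DB = bsteps + 2;
  std::vector<std::vector<double>> excInc(D, std::vector<double>(N, 0.0));
  std::vector<std::vector<double>> inhInc(D, std::vector<double>(N, 0.0));
  std::vector<std::vector<double>> bapInc(DB, std::vector<double>(N, 0.0));

  std::vector<double> Vs(N, ELs), Vd(N, ELd), w(N, 0.0);
  std::vector<double> mCa(N), hCa(N), mK(N), Ca(N, Ca0);
  for (int i = 0; i < N; ++i) {
    mCa[i] = logistic(msl * (ELd - mha));
    hCa[i] = logistic(hsl * (ELd - hha));
    mK[i] = 1.0 / (1.0 + std::pow(Cath / Ca0, kexp));
  }
  std::vector<double> AE(N, 0.0), BE(N, 0.0), AI(N, 0.0), BI(N, 0.0);
  std::vector<double> clamp_end(N, -1.0);
  std::mt19937 rng((unsigned)seed);
  std::poisson_distribution<int> pois(ext_rate_hz * h / 1000.0);

  std::vector<double> spk_t; std::vector<int> spk_id;
  std::vector<int> counts(N, 0);

  for (int n = 0; n < nsteps; ++n) {
    double t = n * h;
    int slot = n % D, bslot = n % DB;
    for (int i = 0; i < N; ++i) {
      // synaptic state advance + deliveries + external noise
      AE[i] *= PdE; BE[i] *= PrE; AI[i] *= PdI; BI[i] *= PrI;
      double einc = excInc[slot][i];
      if (ext_rate_hz > 0.0) einc += ext_w * pois(rng);
      if (einc > 0.0) { AE[i] += einc * nE; BE[i] += einc * nE; }
      double iinc = inhInc[slot][i];
      if (iinc > 0.0) { AI[i] += iinc * nI; BI[i] += iinc * nI; }
      double gE = AE[i] - BE[i], gI = AI[i] - BI[i];

      bool clamped = (t + h <= clamp_end[i] + 1e-9);
      // distal row
      double gca = gCa * mCa[i] * hCa[i], gk = gK * mK[i];
      double Fd = gLd * (ELd - Vd[i]) + gca * (ECa - Vd[i]) + gk * (EK - Vd[i]) +
                  gCc * (Vs[i] - Vd[i]) + bapInc[bslot][i] / h;
      double add = CmD / h + 0.5 * (gLd + gca + gk + gCc);
      // somatic row
      double ex = expclamp((Vs[i] - VthS) / DeltaT);
      double Fs = gLs * (ELs - Vs[i]) + gLs * DeltaT * ex - gw * w[i] +
                  gE * (erE - Vs[i]) + gI * (erI - Vs[i]) + gCc * (Vd[i] - Vs[i]);
      double ads = CmS / h +
                   0.5 * (gLs + gE + gI + gCc - std::min(gLs * ex, CmS / h));
      double off = -0.5 * gCc;

      double dVs, dVd;
      if (clamped) {
        dVs = 0.0;
        dVd = Fd / add;
      } else {
        double det = ads * add - off * off;
        dVs = (Fs * add - off * Fd) / det;
        dVd = (Fd * ads - off * Fs) / det;
      }
      Vs[i] += dVs; Vd[i] += dVd;

      bool spiked = false;
      if (!clamped && Vs[i] >= Vth) {
        spiked = true;
        double ts = t + h;
        spk_t.push_back(ts); spk_id.push_back(i); ++counts[i];
        Vs[i] = Vreset;
        if (tref > 0.0) clamp_end[i] = ts + tref;
        int bs = (n + 1 + bsteps) % DB;
        bapInc[bs][i] += wBAP;
        // synaptic delivery to targets
        double wgt = (i < n_exc) ? J_exc : g_ratio * J_exc;
        bool exc = (i < n_exc);
        int ds = (n + 1 + dsteps) % D;
        for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
          int tgt = out_idx[k];
          if (exc) excInc[ds][tgt] += wgt; else inhInc[ds][tgt] += wgt;
        }
      }
      w[i] = Pw * w[i] + (1.0 - Pw) * a * (Vs[i] - ELs);
      if (spiked) w[i] += b;

      // distal gating / calcium
      double v = Vd[i];
      mCa[i] = Pm * mCa[i] + (1.0 - Pm) * logistic(msl * (v - mha));
      hCa[i] = Ph * hCa[i] + (1.0 - Ph) * logistic(hsl * (v - hha));
      double ICa = gCa * mCa[i] * hCa[i] * (ECa - v);
      double Cainf = Ca0 + phi * ICa * tauCa;
      Ca[i] = Cainf + (Ca[i] - Cainf) * Pc;
      double mkinf = Ca[i] > 0.0 ? 1.0 / (1.0 + std::pow(Cath / Ca[i], kexp)) : 0.0;
      mK[i] = Pk * mK[i] + (1.0 - Pk) * mkinf;
    }
    // zero the just-consumed delivery slots for reuse
    std::fill(excInc[slot].begin(), excInc[slot].end(), 0.0);
    std::fill(inhInc[slot].begin(), inhInc[slot].end(), 0.0);
    std::fill(bapInc[bslot].begin(), bapInc[bslot].end(), 0.0);
  }

  return List::create(_["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
                      _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()));
}
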