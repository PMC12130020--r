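#' Steady-state gating functions of the Ca hot-zone channel
#'
#' `m_inf = 1 / (1 + exp(m_slope * (V - m_half)))`; a negative slope yields
#' activation increasing with voltage.  At `V = m_half` the value is exactly
#' 0.5.
#'
#' @param V Membrane voltage (mV), vectorized.
#' @param slope Slope parameter (1/mV).
#' @param half Half-activation voltage (mV).
#' @return Gating steady state in (0, 1).
#' @export
gate_inf <- function(V, slope, half) 1 / (1 + exp(slope * (V - half)))

#' High-voltage-activated calcium current
#'
#' `I_Ca = g_Ca * m * h * (E_Ca - V)` in pA.
#'
#' @param V Voltage (mV).
#' @param m,h Activation/inactivation gating variables in \[0, 1\].
#' @param g_Ca Maximal conductance (nS).
#' @param E_Ca Reversal potential (mV).
#' @export
ca_hva_current <- function(V, m, h, g_Ca, E_Ca) g_Ca * m * h * (E_Ca - V)

#' Calcium-activated potassium current and its activation steady state
#'
#' `I_KCa = g_K * m * (E_K - V)`; the activation steady state depends on the
#' calcium concentration only: `m_inf = 1 / (1 + (Ca_th / Ca)^const_KCa)`.
#' At `Ca = 0` the continuous limit `m_inf = 0` is returned (no exception).
#'
#' @param V Voltage (mV).
#' @param m Activation variable.
#' @param g_K Maximal conductance (nS).
#' @param E_K Reversal potential (mV).
#' @export
kca_current <- function(V, m, g_K, E_K) g_K * m * (E_K - V)

#' @rdname kca_current
#' @param Ca Calcium concentration (mM), >= 0.
#' @param Ca_th Half-activation concentration (mM), > 0.
#' @param const_KCa Hill-type exponent.
#' @export
kca_m_inf <- function(Ca, Ca_th, const_KCa) {
  ifelse(Ca > 0, 1 / (1 + (Ca_th / Ca)^const_KCa), 0)
}

#' One exponential-integration step of the calcium pool
#'
#' Advances `d[Ca]/dt = phi_Ca * I_Ca - (Ca - Ca_0) / tau_Ca` by `h` ms with
#' `I_Ca` held constant over the step (exact for constant current).  The
#' steady state under constant current is `Ca_0 + phi_Ca * I_Ca * tau_Ca`.
#'
#' @param Ca Concentration (mM).
#' @param I_Ca Calcium current (pA), held constant over the step.
#' @param h Step (ms), > 0.
#' @param phi_Ca Scale (mM/(pA*ms)).
#' @param Ca_0 Baseline (mM).
#' @param tau_Ca Extrusion time constant (ms).
#' @export
update_calcium <- function(Ca, I_Ca, h, phi_Ca, Ca_0, tau_Ca) {
  stopifnot(h > 0)
  Cainf <- Ca_0 + phi_Ca * I_Ca * tau_Ca
  Cainf + (Ca - Cainf) * exp(-h / tau_Ca)
}

#' Exponential-propagator update of a first-order gating variable
#'
#' For `dy/dt = (y_inf(V) - y) / tau_y(V)` with the voltage held at its new
#' value over the step, the analytical solution is
#' `y' = P * y + (1 - P) * y_inf`, `P = exp(-h / tau_y)`.  `h = 0` returns
#' `y` unchanged; `h >> tau_y` saturates at `y_inf`.  The update is a convex
#' combination, so `y` stays in \[0, 1\] whenever `y_inf` does.
#'
#' @param y Current value.
#' @param h Step (ms), >= 0.
#' @param y_inf Steady state at the new voltage.
#' @param tau Time constant at the new voltage (ms), > 0.
#' @export
gating_step <- function(y, h, y_inf, tau) {
  stopifnot(tau > 0, h >= 0)
  P <- exp(-h / tau)
  P * y + (1 - P) * y_inf
}

#' AdEx spike-initiation and adaptation terms
#'
#' Returns `g_L_s * Delta_T * exp((V_s - V_th_s) / Delta_T) - g_w * w` in pA.
#' The exponent argument is clamped at +10 for numerical safety; spikes are
#' detected at the (lower) detection threshold `V_th` anyway, so the clamp
#' does not affect spike times.
#'
#' @param V_s Somatic voltage (mV).
#' @param w Adaptation variable (pA).
#' @param g_L_s Somatic leak conductance (nS).
#' @param Delta_T Slope factor (mV), > 0.
#' @param V_th_s Exponential threshold (mV).
#' @param g_w Adaptation coupling factor.
#' @export
adex_terms <- function(V_s, w, g_L_s, Delta_T, V_th_s, g_w = 1) {
  stopifnot(Delta_T > 0)
  arg <- pmin((V_s - V_th_s) / Delta_T, 10)
  g_L_s * Delta_T * exp(arg) - g_w * w
}

#' Synaptic receptor specifications
#'
#' Double-exponential conductance (or current) windows
#' `w * n(tau_r, tau_d) * (exp(-t/tau_d) - exp(-t/tau_r))` where the
#' normalization `n` makes the peak of a single window equal to the weight
#' `w` exactly.  Kinds: `AMPA`, `GABA`, `NMDA` (voltage-dependent magnesium
#' block), `AMPA_NMDA` (both windows share the spike train; the NMDA peak is
#' `nmda_ratio` times the AMPA peak) and `BETA_CURRENT` (the same window
#' interpreted as a current in pA, used for EPSC-shaped injections).
#' `tau_r = tau_d` is rejected: only the double-exponential form is defined.
#'
#' @param kind One of `"AMPA"`, `"GABA"`, `"NMDA"`, `"AMPA_NMDA"`,
#'   `"BETA_CURRENT"`.
#' @param tau_r,tau_d Rise and decay time constants (ms); must satisfy
#'   `tau_d > tau_r > 0`.  Defaults per kind: AMPA 0.2/3, GABA 0.2/10,
#'   NMDA 0.2/43.
#' @param e_r Reversal potential (mV); defaults AMPA/NMDA 0, GABA -80.
#' @param w Peak conductance (nS), or peak current (pA) for `BETA_CURRENT`.
#' @param nmda_ratio NMDA-to-AMPA peak ratio for `AMPA_NMDA` (default 2).
#' @return A `receptor_spec` object.
#' @export
receptor_spec <- function(kind = c("AMPA", "GABA", "NMDA", "AMPA_NMDA",
                                   "BETA_CURRENT"),
                          tau_r = NULL, tau_d = NULL, e_r = NULL, w = 1,
                          nmda_ratio = 2) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA = c(0.2, 3, 0), GABA = c(0.2, 10, -80), NMDA = c(0.2, 43, 0),
    AMPA_NMDA = c(0.2, 3, 0), BETA_CURRENT = c(1, 10, 0))
  if (is.null(tau_r)) tau_r <- def[1]
  if (is.null(tau_d)) tau_d <- def[2]
  if (is.null(e_r)) e_r <- def[3]
  if (!(tau_r > 0) || !(tau_d > tau_r))
    stop("configuration error: receptor requires tau_d > tau_r > 0")
  if (w < 0) stop("configuration error: receptor weight must be >= 0")
  structure(list(kind = kind, tau_r = tau_r, tau_d = tau_d, e_r = e_r, w = w,
                 nmda_ratio = nmda_ratio),
            class = "receptor_spec")
}

#' Double-exponential window normalization and peak time
#'
#' The unnormalized window `exp(-t/tau_d) - exp(-t/tau_r)` peaks at
#' `t* = tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)`; the normalization
#' constant is the reciprocal of its value there.
#'
#' @param tau_r,tau_d Rise/decay time constants (ms), `tau_d > tau_r > 0`.
#' @export
double_exp_norm <- function(tau_r, tau_d) {
  tp <- double_exp_peak_time(tau_r, tau_d)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' @rdname double_exp_norm
#' @export
double_exp_peak_time <- function(tau_r, tau_d) {
  stopifnot(tau_d > tau_r, tau_r > 0)
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Evaluate a receptor's conductance (or current) window
#'
#' Sums normalized double-exponential windows over all past spikes; causal
#' (zero before the first spike), continuous, with a single interior maximum
#' equal to `w` for an isolated spike.  For `AMPA_NMDA` this evaluates the
#' AMPA component; use [nmda_component()] for the NMDA window.
#'
#' @param spec A [receptor_spec()].
#' @param spike_times Numeric vector of presynaptic spike times (ms).
#' @param t Evaluation times (ms), vectorized.
#' @return Conductance in nS (current in pA for `BETA_CURRENT`).
#' @export
receptor_conductance <- function(spec, spike_times, t) {
  n <- double_exp_norm(spec$tau_r, spec$tau_d)
  out <- numeric(length(t))
  for (ts in spike_times) {
    d <- t - ts
    on <- d >= 0
    out[on] <- out[on] + spec$w * n * (exp(-d[on] / spec$tau_d) - exp(-d[on] / spec$tau_r))
  }
  out
}

#' @rdname receptor_conductance
#' @export
nmda_component <- function(spec) {
  stopifnot(spec$kind == "AMPA_NMDA")
  receptor_spec("NMDA", w = spec$w * spec$nmda_ratio)
}

#' NMDA magnesium block
#'
#' `sigma(V) = 1 / (1 + 0.3 * exp(-0.1 * V))`; strictly increasing in V with
#' range (0, 1).  The NMDA current is `g * sigma(V) * (e_r - V)`.
#'
#' @param V Voltage (mV), vectorized.
#' @export
nmda_block <- function(V) 1 / (1 + 0.3 * exp(-0.1 * V))
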