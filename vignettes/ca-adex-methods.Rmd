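---
title: "Two-compartment Ca-AdEx neurons: model, solver and fitting methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment Ca-AdEx neurons: model, solver and fitting methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caadex)
```

## The model

Large cortical pyramidal neurons separate their synaptic input into two
electrically distinct domains: a perisomatic/basal domain and a distal apical
tuft.  A regenerative Ca^2+^ spike in the apical "hot zone" lets coincident
input to the two domains produce high-frequency somatic bursts
(backpropagation-activated Ca^2+^-spike firing, *BAC firing*), while
neuromodulation can decouple the two domains or let the apical one dominate.
`caadex` implements a compact spiking model of this cell class, the
*Ca-AdEx* configuration: a two-compartment neuron whose soma is an adaptive
exponential integrate-and-fire (AdEx) unit and whose distal compartment
carries simplified Ca^2+^ dynamics.

The somatic compartment obeys

$$C_m^s \dot V_s = g_L^s (E_L^s - V_s) + g_L^s \Delta_T
e^{(V_s - V_{th}^s)/\Delta_T} - g_w w + I_s + g_C (V_d - V_s) + I_{syn}^s,$$

$$\tau_w \dot w = a (V_s - E_L^s) - w,$$

with a spike detected when $V_s \ge V_{th}$; the spike time $t_k$ is
recorded, $V_s$ is held at $V_{reset}$ for $t_{ref}$ ms (during which the
distal compartment continues to integrate), $w$ is incremented by $b$, and a
back-propagating action potential (BAP) delivers the charge $w_{BAP}$ into
the distal compartment after a delay $d_{BAP}$.

The distal compartment obeys

$$C_m^d \dot V_d = g_L^d (E_L^d - V_d) + I_{Ca} + I_{KCa} + I_d +
g_C (V_s - V_d) + w_{BAP} \textstyle\sum_k \delta(t - t_k - d_{BAP}) +
I_{syn}^d,$$

with a high-voltage-activated calcium current $I_{Ca} = g_{Ca}\, m h\,
(E_{Ca} - V_d)$ whose gates follow first-order kinetics toward logistic
steady states $x_\infty(V) = 1/(1 + e^{x_{slope}(V - x_{half})})$ (a
negative slope gives a gate opening with depolarization), a
calcium-activated potassium current $I_{KCa} = g_K\, m_{KCa} (E_K - V_d)$
that terminates the Ca^2+^ spike, with
$m_{KCa,\infty} = 1/(1 + (Ca_{th}/[Ca])^{const_{KCa}})$ (the continuous
limit 0 is used at $[Ca] = 0$), and a linear calcium pool

$$\frac{d[Ca]}{dt} = \phi_{Ca} I_{Ca} - \frac{[Ca] - [Ca]_0}{\tau_{Ca}}.$$

The relaxation term carries a minus sign so that $\tau_{Ca}$ acts as the
extrusion time constant and the pool decays toward its baseline; its
steady state under constant current is $[Ca]_0 + \phi_{Ca} I_{Ca}
\tau_{Ca}$.  Coupling uses the symmetric convention $+g_C(V_j - V_i)$ in
*every* row, which conserves the axial current exactly; one $g_C$ is stored
per edge (on the child) and used in both rows of the system matrix.

The same machinery generalizes to arbitrary compartment trees
(`build_tree()`): each compartment has capacitance, leak, an optional
coupling conductance to its parent, and arbitrary channel and receptor sets,
so soma + hot-zone + apical/basal NMDA-compartment layouts can be built and
run without code changes.  Synaptic receptors are normalized
double-exponential conductance windows (peak exactly equal to the weight);
NMDA receptors multiply the driving force by the magnesium-block factor
$\sigma(V) = 1/(1 + 0.3 e^{-0.1 V})$, and `AMPA_NMDA` receptors share a
spike train with an NMDA peak `nmda_ratio` (default 2) times the AMPA peak.
Passive dendritic membrane is assumed: no voltage-gated Na/K/HCN channels
outside the hot zone and the AdEx soma.

## Numerical scheme

Voltages are advanced with the Crank–Nicolson scheme,
$C^i (V^i(t+h) - V^i(t))/h = (F^i(t) + F^i(t+h))/2$.  The implicit
right-hand side is Taylor-expanded **once** around $V(t)$ — a single
linearization, no Newton iteration — and the resulting symmetric
tree-structured linear system is solved exactly in $O(N)$ by the Hines
elimination (leaves to root, then back-substitution).  Channel and receptor
state variables are staggered at half steps (leap-frog) and advanced with
the exact exponential propagator
$y(t + h) = P y(t) + (1 - P)\, y_\infty(V),\ P = e^{-h/\tau_y}$,
with the voltage held at its new value over the step; the calcium pool uses
the analogous exponential update with $I_{Ca}$ held constant over the step.
On passive trees the scheme is second-order accurate (the measured
log–log error slope against a closed-form eigen-decomposition reference is
2.00), and subthreshold trajectories of the full model track an explicit
reference integrator run at $h/100$ to within 0.1 mV over 150 ms.

Numerical safety choices:

* the exponential spike-initiation term is clamped at exponent $+10$
  (spikes are detected at $V_{th}$ long before the clamp matters), and its
  contribution to the Jacobian is capped at $C/h$ so the Crank–Nicolson
  diagonal stays positive — without the cap, a stiff near-threshold step can
  oscillate instead of spiking;
* spike detection uses the post-solve voltage and records the spike at the
  end of the step ($t + h$), matching event-grid semantics of reference
  simulators, with no spike-time interpolation;
* stimulus events are snapped to the nearest grid point and $d_{BAP}$ is
  rounded to a whole number of steps; the BAP is delivered as a one-step
  current $w_{BAP}/h$, so the delivered charge is independent of $h$;
* $w$ is integrated exponentially with $V_s$ at its new value; $b$ is added
  after the reset, and $w$ keeps evolving during refractoriness (the
  alternative orderings differ only at $O(h)$ and were checked to leave the
  pulse-task spike counts unchanged at $h = 0.1$ and $0.05$ ms);
* gating is initialized at its steady state for the initial voltage and
  calcium at its baseline, which makes a stimulus-free run an exact
  equilibrium.

The default step is $h = 0.1$ ms; every protocol below states its own $h$.

## The shipped reference genome

The full parameter vector (36 named parameters, fixed units: pF, nS, mV,
ms, pA, mM) is called a *genome* because it is the unit the evolutionary
search manipulates.  No reference parameter set was available to transcribe,
so the file `inst/extdata/ca_adex_genome_synthetic.json` ships a
**synthetic** reference genome produced with this package's own fitness and
search machinery (the GA of `run_ga()` over the shipped bounds followed by
local coordinate refinement), calibrated once against the canonical
BAC-firing behavior of thick-tufted layer-5 pyramidal cells:

* a subthreshold distal EPSC-like current (beta shape, peak 1,345 pA)
  deflects the soma by about 15 mV without any spike and without a Ca^2+^
  spike;
* a just supra-threshold 1,150 pA / 5 ms somatic step fires exactly one
  spike;
* the two stimuli combined (distal current 5 ms after the somatic step)
  activate BAC firing and produce a three-spike burst;
* a distal-only burst requires a peak current near 1,830 pA;
* under prolonged DC the distal-only calcium activation threshold sits at
  550 pA, with a rate jump of tens of Hz;
* the awake transfer function stays at or below 80 Hz over the scanned
  domain, while the apical-drive variant exceeds 100 Hz and the
  apical-isolation variant stays near 10 Hz.

These six behaviors were fixed as calibration targets **before** the genome
was frozen; the test suite and the acceptance script re-measure them from
scratch.  The per-parameter bounds in the same file define the biologically
plausible search box used for validation and for the GA; bounds are closed
intervals.  Beta-current kinetics default to $\tau_r = 1$ ms and
$\tau_d = 9.4$ ms, of the order of fast EPSC time constants.

## Stimulation protocols

**Pulse (BAC-firing) task** (`run_pulse_task()`): the four cases above, run
for 200 ms at $h = 0.1$ ms with onset at 20 ms, reporting spike counts,
spike times and the peak somatic deflection from rest.  A *burst* is at
least 2 spikes whose first inter-spike interval is below 25 ms
(configurable); `find_burst_threshold()` scans distal-only peaks on a 10 pA
grid.

**Prolonged-DC scan** (`run_prolonged_scan()`): each $(I_s, I_d)$
combination is a 2 s constant-current simulation started from rest; the
firing rate is the spike count over the full 2 s window with no transient
exclusion (configurable).  Combinations are run independently rather than
concatenated with zero-input gaps — starting from rest is exactly what a
long gap achieves, at half the cost.  Calcium activation is flagged by the
*gating criterion*: $\max_t m_{Ca} h_{Ca} \ge 0.5$ during the stimulus; a
concentration criterion (peak $[Ca] \ge [Ca]_0 + 0.5 (Ca_{th} - [Ca]_0$))
is available as an alternative.  The activation threshold is a regenerative
(ignition) threshold, so the choice of criterion moves the measured
activation current by at most one 10 pA grid step for this genome.

**Poisson scans** (`run_poisson_scan()`): grids of Poisson rates delivered
to AMPA+NMDA synapses at designated apical and basal compartments with GABA
synapses fixed at 20 Hz, averaged over independent 2 s episodes; reports the
output rate and mean compartment voltages.

## ThetaPlanes

The firing-rate transfer function $\nu(I_s, I_d)$ of the fitted neuron is
approximately piecewise planar: a low-rate region below the calcium
activation boundary and a high-rate region above it.  `fit_thetaplanes()`
compresses a simulated surface into 10 numbers:

* masks: $M_+$ = calcium-active points; $M_-$ = inactive points firing above
  $\nu_{low}$ (default 10 Hz — rates below that cannot drive meaningful
  spike-timing-dependent plasticity within a ~50 ms percept, so precision
  there is not useful); both masks drop the band $I_s > I_{th}$ where
  boundary nonlinearities would bias the fits;
* two ordinary-least-squares planes $\nu_\pm = a_\pm I_s + b_\pm I_d +
  d_\pm$ over the masked points;
* a boundary line fitted through the lowest active $I_d$ of each $I_s$
  column (columns without active points are skipped, never imputed);
* a rheobase line defined as the zero locus of the low plane,
  $\theta_m^\rho = -a_-/b_-$, $\theta_q^\rho = -d_-/b_-$ (a vanishing
  $b_-$ raises an explicit error).

Evaluation composes the pieces with Heaviside steps,
$\nu_F = \Theta_\rho (1 - \Theta_H) \nu_- + \Theta_H \nu_+$, with
$\Theta(0) = 1$ (the boundary belongs to the active side) decided up to a
$10^{-6}$ pA tolerance so that points lying exactly on a fitted line are
classified deterministically.  Refitting a surface generated from a known
model recovers all 10 parameters (planes to $10^{-6}$, lines to within one
grid step), and an exactly piecewise-planar surface yields a zero error
report when its boundary is commensurate with the grid.

## Fitness functions and the evolutionary loop

`ca_adex_fitness()` scores a genome with 21 components covering the pulse
task (target counts 0/1/3/burst), calcium behavior (opens in the domain,
closes after the stimulus, never with purely somatic current, not only at
extreme currents), AdEx matching of the $I_d = 0$ row against a reference
point neuron (earth mover's distance between rate curves, rheobase, last
rate, ISI coefficient of variation at the largest probed current, total
capacitance), gain and linearity of the active region (post-activation
distal-only rate, row-wise R², monotonicity violations of
$\nu(I_s, I_d = const)$, fraction of the domain with an activation jump),
and guard checks (rate cap, somatic voltage floor, distal rheobase window,
activation jump size).  Each component is a bounded score
$e^{-|error|/scale}$ with a documented scale, so the global fitness — the
*exact sum* of the components — is finite for every genome, and a failing
simulation scores 0 rather than aborting a generation.  The reference AdEx
is defined as the somatic block of the genome under study, which makes
"somatic behavior mimics the point neuron" a self-consistent target.  The
1-D earth mover's distance is the L1 distance between cumulative sums of
mass-normalized curves times the grid spacing, and equals brute-force
optimal transport (verified against a quantile-coupling oracle).

`run_ga()` is a plain generational GA: uniform initialization in the
bounds, tournament selection (size 3), uniform crossover (rate 0.5),
per-gene Gaussian mutation (sd = 10% of the bound width, rate 0.2), clipping
to bounds, elitism of one (the best trace is provably non-decreasing), all
deterministic per seed.  `convergence_stats()` summarizes repeated trials by
per-generation median, quartiles and range.  The recovery check used in the
tests frees three parameters ($g_C$, $g_{Ca}$, $b$), scores with the full
fitness at reduced resolution (3x3 current grid, 400 ms stimuli), and
requires the GA to reach 95% of the reference genome's fitness in 12
generations of 24 individuals for three seeds.

## Brain-state presets

Neuromodulation proxies are expressed as genome transforms
(`apply_brain_state()`), changing only the documented fields:

| preset | meaning | transform |
|---|---|---|
| `AA` | wakefulness, apical amplification | fitted genome (optionally another `b`) |
| `AI` | deep NREM / anesthesia, apical isolation | `b = 200`, `g_C = 0`, both `E_L` −5 mV |
| `AD` | REM / dreaming, apical drive | `b = 10`, both `E_L` −2 mV |

For $g_C = 0$ the somatic subsystem is exactly the point AdEx for any
distal input — the test suite asserts bit-identical somatic spike trains —
so `AI` with a somatic override can replace point neurons in existing
network models without changing their spikes.

## The balanced-network benchmark

`build_brunel_network()` wires a Brunel-like balanced network of identical
two-compartment neurons with **exact** fixed in-degree $K$ per neuron (4/5
excitatory, 1/5 inhibitory, sampled without self-connections), inhibitory
weights $-g \cdot J_{exc}$ with $g = 5$, conductance-based AMPA/GABA
synapses on the soma, a fixed 1.5 ms delay, and independent per-neuron
external Poisson drive (the unspecified noise process is implemented as
Poisson input onto the excitatory conductance).  Since the synaptic weights
and drive of the full-scale reference are not part of the shipped
configuration, the package instead ships a calibrated scaled-down network —
500 excitatory + 125 inhibitory neurons, $K = 125$, the same 4:1 and
$g = 5$ ratios — whose external rate was set with
`calibrate_network_rate()` (bracketing then bisection on the trial-averaged
rate) to the asynchronous-irregular operating point of about 1.23 Hz with a
mean ISI CV near 0.9.  Rates are averaged over four trials with fresh
wiring and noise seeds, which is also how the benchmark protocol defines
the measured rate.  Wall-clock throughput is hardware-dependent and is not
measured here.

## What the synthetic data generators do and do not emulate

All test inputs are generated in code: passive trees with closed-form
responses, exactly piecewise-planar transfer surfaces with Heaviside masks,
seeded Poisson trains, and scaled-down network specifications
(`generate_fixture()`, `synthetic_surface()`).  They emulate the
*structure* of the real objects (tree topologies, planar rate regions with
a sharp activation boundary, stationary input statistics) but not the
biological variability of real recordings: no channel noise, no
temperature effects, no morphological detail beyond the compartment graph,
no heterogeneous neuron populations.  Green tests therefore demonstrate
that the algorithms are implemented correctly and that the fitted model
expresses the targeted phenomenology — not that the model quantitatively
matches any particular biological cell.

## Problem sizes, tolerances and limitations

The default verification sizes, chosen to keep a full run on one CPU within
a couple of minutes, are: 2 s stimuli on 25 pA grids
($25 \times 37$ points) for brain-state scans, a 10 pA grid for the
activation-current search, 61 candidate amplitudes for the burst-threshold
scan, a 625-neuron network run for 4 s per trial, and the reduced-resolution
fitness grid for GA checks.  Solver agreement targets: $10^{-12}$ relative
against dense linear algebra for the tree solve, slope $2.0 \pm 0.2$ for
convergence, 0.1 mV against the $h/100$ explicit reference.

Known limitations: no adaptive time stepping and no spike-time
interpolation (spike times are grid-aligned); the one-step linearization
makes supra-threshold voltage *shapes* (not times or counts) step-size
dependent near spikes; the burst-threshold landscape is knife-edged at the
10 pA grid scale (an isolated burst can appear one or two grid steps below
the sustained onset; the scan reports the first occurrence); morphology
reduction itself is out of scope — reduced compartment parameters must
arrive as configuration; and the network benchmark makes no claim about
full-scale (12,500-neuron) dynamics beyond what the calibrated scaled-down
model shows.
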