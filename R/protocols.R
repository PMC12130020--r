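#' Pulse (BAC-firing) task specification
#'
#' Four short-duration current-injection cases probing backpropagation-
#' activated calcium-spike firing: (A) a subthreshold beta-shaped current at
#' the distal compartment alone, (B) a just supra-threshold rectangular step
#' at the soma alone, (C) the somatic step followed after `delay` ms by the
#' distal beta current, and (D) a stronger distal-only beta current intended
#' to evoke a burst.
#'
#' @param somatic_amp Somatic step amplitude (pA).
#' @param somatic_dur Somatic step duration (ms).
#' @param distal_peak Distal beta-current peak for cases A and C (pA).
#' @param delay Delay of the distal current relative to the somatic step (ms).
#' @param burst_peak Distal-only beta-current peak for case D (pA).
#' @param tau_r,tau_d Beta-current rise/decay constants (ms).
#' @param genome Optional genome supplying `tau_r_beta`/`tau_d_beta`.
#' @return A `pulse_task_spec`.
#' @export
pulse_task_spec <- function(somatic_amp = 1150, somatic_dur = 5,
                            distal_peak = 1345, delay = 5, burst_peak = 1830,
                            tau_r = NULL, tau_d = NULL, genome = NULL) {
  if (!is.null(genome)) {
    if (is.null(tau_r)) tau_r <- as.numeric(genome[["tau_r_beta"]])
    if (is.null(tau_d)) tau_d <- as.numeric(genome[["tau_d_beta"]])
  }
  if (is.null(tau_r)) tau_r <- 1
  if (is.null(tau_d)) tau_d <- 10
  stopifnot(somatic_dur > 0, delay >= 0)
  structure(list(somatic_amp = somatic_amp, somatic_dur = somatic_dur,
                 distal_peak = distal_peak, delay = delay,
                 burst_peak = burst_peak, tau_r = tau_r, tau_d = tau_d),
            class = "pulse_task_spec")
}

#' Run the pulse (BAC-firing) task
#'
#' Runs the four cases of [pulse_task_spec()] on a two-compartment tree and
#' reports, per case, the spike count, the spike times, the peak somatic
#' deflection from rest (mV) and, for the distal-only cases, whether a burst
#' occurred (at least `burst_min_spikes` spikes with the first inter-spike
#' interval below `burst_isi`).
#'
#' @param tree A `compartment_tree` (soma = compartment 1, distal = 2).
#' @param spec A [pulse_task_spec()].
#' @param config A [solver_config()]; its `T` must cover `onset` + ~100 ms.
#' @param onset Time of the first injection (ms).
#' @param burst_isi Maximum first ISI of a burst (ms).
#' @param burst_min_spikes Minimum spikes of a burst.
#' @return A `pulse_task_report` (list of per-case results).
#' @export
run_pulse_task <- function(tree, spec = pulse_task_spec(),
                           config = solver_config(h = 0.1, T = 200),
                           onset = 20, burst_isi = 25, burst_min_spikes = 2) {
  beta <- function(peak, t0) stim_beta(2, peak, t0, spec$tau_r, spec$tau_d)
  soma_step <- stim_step(1, spec$somatic_amp, onset, spec$somatic_dur)
  progs <- list(
    A = stim_program(beta(spec$distal_peak, onset)),
    B = stim_program(soma_step),
    C = stim_program(soma_step, beta(spec$distal_peak, onset + spec$delay)),
    D = stim_program(beta(spec$burst_peak, onset))
  )
  rest <- tree$E_L[1]
  out <- lapply(progs, function(p) {
    r <- simulate(tree, p, config)
    st <- r$spike_times
    burst <- length(st) >= burst_min_spikes &&
      (length(st) < 2 || diff(st)[1] < burst_isi)
    list(n_spikes = length(st), spike_times = st,
         peak_deflection = max(r$V[, 1]) - rest, burst = burst)
  })
  structure(out, class = "pulse_task_report")
}

#' @export
print.pulse_task_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("case %s: %d spike(s), peak somatic deflection %.2f mV%s\n",
                nm, x[[nm]]$n_spikes, x[[nm]]$peak_deflection,
                if (isTRUE(x[[nm]]$burst)) " [burst]" else ""))
  invisible(x)
}

#' Minimal distal-only beta-current peak evoking a burst
#'
#' Scans increasing peak amplitudes (default 10 pA grid) and returns the
#' smallest peak whose distal-only response is a burst.
#'
#' @inheritParams run_pulse_task
#' @param peaks Ascending peak amplitudes to probe (pA).
#' @return The threshold peak (pA), or `NA` if no probed peak bursts.
#' @export
find_burst_threshold <- function(tree, spec = pulse_task_spec(),
                                 config = solver_config(h = 0.1, T = 200),
                                 peaks = seq(1000, 2600, by = 10),
                                 onset = 20, burst_isi = 25,
                                 burst_min_spikes = 2) {
  for (p in peaks) {
    r <- simulate(tree, stim_program(
      stim_beta(2, p, onset, spec$tau_r, spec$tau_d)), config)
    st <- r$spike_times
    if (length(st) >= burst_min_spikes && diff(st)[1] < burst_isi) return(p)
  }
  NA_real_
}

#' Detect activation of the distal calcium channel
#'
#' Default (gating) criterion: the product `m_Ca * h_Ca` reaches at least
#' `threshold` (0.5) somewhere in the window.  The alternative (calcium)
#' criterion requires the peak concentration to reach
#' `Ca_0 + threshold * (Ca_th - Ca_0)` and needs the hot-zone parameters
#' from the tree.
#'
#' @param result A `simulation_result` with calcium recordings.
#' @param criterion `"gating"` or `"calcium"`.
#' @param window Time window `c(t0, t1)` in ms (default: whole recording).
#' @param tree The simulated tree (required for `"calcium"`).
#' @param threshold Activation threshold (default 0.5).
#' @return Logical.
#' @export
detect_ca_activation <- function(result, criterion = c("gating", "calcium"),
                                 window = NULL, tree = NULL, threshold = 0.5) {
  criterion <- match.arg(criterion)
  if (is.null(result$Ca) || ncol(result$Ca) == 0)
    stop("configuration error: result has no calcium/gating recordings")
  idx <- if (is.null(window)) rep(TRUE, length(result$times))
         else result$times >= window[1] & result$times <= window[2]
  if (criterion == "gating") {
    prod <- result$m_Ca[idx, , drop = FALSE] * result$h_Ca[idx, , drop = FALSE]
    return(max(prod) >= threshold)
  }
  if (is.null(tree)) stop("configuration error: 'calcium' criterion needs the tree")
  ic <- which(!vapply(tree$ca, is.null, logical(1)))[1]
  mech <- tree$ca[[ic]]
  max(result$Ca[idx, 1]) >= mech$Ca_0 + threshold * (mech$Ca_th - mech$Ca_0)
}

#' Prolonged-DC transfer-function scan
#'
#' For every combination of constant somatic (`Is_grid`) and distal
#' (`Id_grid`) currents, simulates `stim_duration` ms of DC from rest and
#' records the firing rate (spike count over the stimulus window, no
#' transient excluded) and whether the calcium channel activated.  Each
#' combination is an independent run from rest, which is equivalent to the
#' protocol of interleaving every stimulus with a long zero-input gap.
#'
#' @param tree A two-compartment tree.
#' @param Is_grid,Id_grid Strictly increasing current grids (pA).
#' @param config Solver configuration; `T` is forced to `stim_duration`.
#' @param stim_duration Stimulus duration (ms), default 2000.
#' @param gap Zero-input gap between combinations (ms, metadata only).
#' @param criterion Passed to [detect_ca_activation()].
#' @return A `transfer_surface`: grids, `rate` and `ca_active` matrices
#'   (rows = `Is_grid`, columns = `Id_grid`), `min_Vs` (mV) and metadata.
#' @export
run_prolonged_scan <- function(tree, Is_grid, Id_grid,
                               config = solver_config(h = 0.1, T = 2000),
                               stim_duration = 2000, gap = 3000,
                               criterion = "gating") {
  stopifnot(length(Is_grid) > 0, length(Id_grid) > 0)
  if (is.unsorted(Is_grid, strictly = TRUE) || is.unsorted(Id_grid, strictly = TRUE))
    stop("current grids must be strictly increasing")
  config <- solver_config(h = config$h, T = stim_duration)
  rate <- matrix(0, length(Is_grid), length(Id_grid))
  ca <- matrix(FALSE, length(Is_grid), length(Id_grid))
  minv <- Inf
  for (i in seq_along(Is_grid)) for (j in seq_along(Id_grid)) {
    prog <- stim_program(stim_step(1, Is_grid[i], 0, stim_duration),
                         stim_step(2, Id_grid[j], 0, stim_duration))
    r <- simulate(tree, prog, config)
    rate[i, j] <- length(r$spike_times) / (stim_duration / 1000)
    ca[i, j] <- detect_ca_activation(r, criterion, tree = tree)
    minv <- min(minv, min(r$V[, 1]))
  }
  structure(list(Is_grid = Is_grid, Id_grid = Id_grid, rate = rate,
                 ca_active = ca, min_Vs = minv,
                 meta = list(stim_duration = stim_duration, gap = gap,
                             h = config$h, criterion = criterion)),
            class = "transfer_surface")
}

#' @export
print.transfer_surface <- function(x, ...) {
  cat(sprintf("transfer_surface: %d x %d grid, rates %.2f..%.2f Hz, %d Ca-active point(s)\n",
              length(x$Is_grid), length(x$Id_grid), min(x$rate), max(x$rate),
              sum(x$ca_active)))
  invisible(x)
}

#' Locate the distal-only calcium-activation current
#'
#' Scans the `I_s = 0` column of the transfer function at the stated
#' resolution and returns the smallest distal current whose prolonged-DC
#' response activates the calcium channel (the sharp rate-jump current).
#'
#' @param tree A two-compartment tree.
#' @param Id_grid Distal currents to probe (pA), default 0..900 by 10.
#' @inheritParams run_prolonged_scan
#' @return The activation current (pA), or `NA`.
#' @export
find_ca_activation_current <- function(tree, Id_grid = seq(0, 900, by = 10),
                                       config = solver_config(h = 0.1, T = 2000),
                                       stim_duration = 2000,
                                       criterion = "gating") {
  config <- solver_config(h = config$h, T = stim_duration)
  for (Id in Id_grid) {
    prog <- stim_program(stim_step(2, Id, 0, stim_duration))
    r <- simulate(tree, prog, config)
    if (detect_ca_activation(r, criterion, tree = tree)) return(Id)
  }
  NA_real_
}

#' Spike-train statistics
#'
#' @param spike_times Spike times (ms).
#' @param window Observation window length (ms), > 0.
#' @return List with `rate` (Hz), `mean_isi` (ms) and `cv_isi`; the ISI
#'   statistics are `NA` for fewer than 3 spikes.
#' @export
spike_stats <- function(spike_times, window) {
  stopifnot(window > 0)
  rate <- length(spike_times) / (window / 1000)
  if (length(spike_times) < 3)
    return(list(rate = rate, mean_isi = NA_real_, cv_isi = NA_real_))
  isi <- diff(spike_times)
  list(rate = rate, mean_isi = mean(isi), cv_isi = stats::sd(isi) / mean(isi))
}

#' Poisson-input scan over dendritic sites
#'
#' Drives AMPA+NMDA synapses at the listed apical and basal compartments
#' with Poisson trains over a grid of rates (GABA synapses at every
#' stimulated compartment run at a fixed rate), averages the output rate and
#' the mean compartment voltages over `episodes` independent episodes.
#'
#' @param tree A tree whose apical/basal compartments carry no other input.
#' @param apical_rates,basal_rates Poisson rates (Hz) defining the grid.
#' @param apical_comps,basal_comps Compartment indices receiving the drive.
#' @param gaba_rate Fixed GABA Poisson rate (Hz), default 20.
#' @param episodes Episodes per rate pair (default 5).
#' @param episode_T Episode duration (ms), default 2000.
#' @param config Solver configuration (its `T` is forced to `episode_T`).
#' @param seed Seed for the Poisson realizations.
#' @param exc_w,gaba_w Synaptic weights (nS), default 1.
#' @return List with `rate` (matrix apical x basal, Hz), `mean_V_apical`,
#'   `mean_V_basal` (mV, same shape).
#' @export
run_poisson_scan <- function(tree, apical_rates, basal_rates, apical_comps,
                             basal_comps, gaba_rate = 20, episodes = 5,
                             episode_T = 2000,
                             config = solver_config(h = 0.1, T = 2000),
                             seed = 1, exc_w = 1, gaba_w = 1) {
  stopifnot(all(apical_rates >= 0), all(basal_rates >= 0))
  config <- solver_config(h = config$h, T = episode_T)
  na <- length(apical_rates); nb <- length(basal_rates)
  rate <- va <- vb <- matrix(0, na, nb)
  set.seed(seed)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    acc_r <- acc_va <- acc_vb <- 0
    for (ep in seq_len(episodes)) {
      els <- list()
      for (cc in apical_comps) {
        els <- c(els, list(
          stim_poisson(cc, receptor_spec("AMPA_NMDA", w = exc_w),
                       apical_rates[i], 0, episode_T),
          stim_poisson(cc, receptor_spec("GABA", w = gaba_w),
                       gaba_rate, 0, episode_T)))
      }
      for (cc in basal_comps) {
        els <- c(els, list(
          stim_poisson(cc, receptor_spec("AMPA_NMDA", w = exc_w),
                       basal_rates[j], 0, episode_T),
          stim_poisson(cc, receptor_spec("GABA", w = gaba_w),
                       gaba_rate, 0, episode_T)))
      }
      r <- simulate(tree, stim_program(els), config)
      acc_r <- acc_r + length(r$spike_times) / (episode_T / 1000)
      acc_va <- acc_va + mean(r$V[, apical_comps])
      acc_vb <- acc_vb + mean(r$V[, basal_comps])
    }
    rate[i, j] <- acc_r / episodes
    va[i, j] <- acc_va / episodes
    vb[i, j] <- acc_vb / episodes
  }
  list(rate = rate, mean_V_apical = va, mean_V_basal = vb,
       apical_rates = apical_rates, basal_rates = basal_rates)
}
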