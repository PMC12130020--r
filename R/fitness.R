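#' One-dimensional earth mover's (Wasserstein-1) distance
#'
#' Both curves are treated as mass distributions on a common grid,
#' normalized to unit mass; the distance is the L1 difference of their
#' cumulative sums times the grid spacing.  If either curve carries no mass
#' the distance is defined as 0.
#'
#' @param u,v Non-negative numeric vectors of equal length.
#' @param spacing Grid spacing (default 1).
#' @export
emd_1d <- function(u, v, spacing = 1) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  su <- sum(u); sv <- sum(v)
  if (su == 0 || sv == 0) return(0)
  sum(abs(cumsum(u / su) - cumsum(v / sv))) * spacing
}

# every component is a bounded score exp(-|error|/scale), so the global
# fitness (their sum) is well defined and finite for any genome
bounded_score <- function(err, scale) exp(-abs(err) / scale)

#' Pulse-task fitness components
#'
#' One score per case, maximal (1) when the spike count equals its target
#' (A: 0, B: 1, C: 3, D: a burst) and decaying symmetrically with
#' `|count - target|`.
#'
#' @param report A `pulse_task_report` from [run_pulse_task()].
#' @param targets Named integer targets for cases A, B, C.
#' @return Named numeric vector `pulse_caseA` .. `pulse_caseD`.
#' @export
pulse_fitness <- function(report, targets = c(A = 0, B = 1, C = 3)) {
  s <- c(
    pulse_caseA = bounded_score(report$A$n_spikes - targets[["A"]], 1),
    pulse_caseB = bounded_score(report$B$n_spikes - targets[["B"]], 1),
    pulse_caseC = bounded_score(report$C$n_spikes - targets[["C"]], 1),
    pulse_caseD = bounded_score(if (isTRUE(report$D$burst)) 0 else 1, 0.5)
  )
  s
}

#' Reference AdEx transfer data for the matching fitness
#'
#' Simulates the single-compartment AdEx neuron defined by a genome's
#' somatic block over a somatic-current grid and returns its rate curve, the
#' ISI coefficient of variation at the largest probed current, and its
#' capacitance.
#'
#' @param genome A genome whose somatic block defines the target AdEx.
#' @param Is_grid Somatic currents (pA).
#' @param stim_duration Stimulus duration per point (ms).
#' @param h Time step (ms).
#' @return List `Is_grid`, `rate`, `cv_isi`, `C_m`.
#' @export
make_adex_reference <- function(genome, Is_grid, stim_duration = 2000, h = 0.1) {
  tr <- build_single_adex(genome)
  cfg <- solver_config(h = h, T = stim_duration)
  rate <- numeric(length(Is_grid)); cv <- NA_real_
  for (k in seq_along(Is_grid)) {
    r <- simulate(tr, stim_program(stim_step(1, Is_grid[k], 0, stim_duration)), cfg)
    rate[k] <- length(r$spike_times) / (stim_duration / 1000)
    if (k == length(Is_grid)) cv <- spike_stats(r$spike_times, stim_duration)$cv_isi
  }
  list(Is_grid = Is_grid, rate = rate, cv_isi = cv,
       C_m = as.numeric(genome[["C_m_s"]]))
}

#' AdEx-matching fitness components
#'
#' Compares the two-compartment neuron's `I_d = 0` rate curve against the
#' reference AdEx: earth mover's distance between the curves, rheobase
#' current difference, last-rate difference, ISI-CV difference at the
#' largest probed current, and total-capacitance difference.
#'
#' @param Is_grid Common somatic-current grid (pA).
#' @param rate Two-compartment `I_d = 0` rate curve (Hz).
#' @param cv ISI CV of the two-compartment neuron at the largest current.
#' @param C_total Total capacitance of the two-compartment neuron (pF).
#' @param reference Output of [make_adex_reference()] on the same grid.
#' @param scales Named scales of the bounded scores.
#' @return Named numeric vector of five scores.
#' @export
adex_matching_fitness <- function(Is_grid, rate, cv, C_total, reference,
                                  scales = c(emd = 20, rheobase = 50,
                                             last_rate = 5, cv = 0.25,
                                             capacitance = 100)) {
  if (!identical(as.numeric(Is_grid), as.numeric(reference$Is_grid)))
    stop("grid mismatch between curve and reference")
  sp <- if (length(Is_grid) > 1) diff(Is_grid)[1] else 1
  rheo <- function(r) if (any(r > 0)) Is_grid[which(r > 0)[1]] else max(Is_grid) + sp
  dcv <- if (is.na(cv) || is.na(reference$cv_isi)) 1 else cv - reference$cv_isi
  c(adex_emd = bounded_score(emd_1d(rate, reference$rate, sp), scales[["emd"]]),
    adex_rheobase = bounded_score(rheo(rate) - rheo(reference$rate), scales[["rheobase"]]),
    adex_last_rate = bounded_score(rate[length(rate)] - reference$rate[length(rate)],
                                   scales[["last_rate"]]),
    adex_cv_isi = bounded_score(dcv, scales[["cv"]]),
    capacitance_match = bounded_score(C_total - reference$C_m, scales[["capacitance"]]))
}

#' Gain-and-linearity fitness components
#'
#' Scores the high, linear apical gain: the firing rate just after calcium
#' opening for a distal-only stimulus, the linearity (R-squared of row-wise
#' linear fits) of the rate within the active region, the count of
#' monotonicity violations of the `nu(I_s, I_d = const)` curves, and the
#' fraction of somatic-current rows in which the activation jump exists.
#'
#' @param surface A `transfer_surface`.
#' @param min_post_rate Desired distal-only post-activation rate (Hz).
#' @param mono_tol Rate decrease tolerated before counting a violation (Hz).
#' @return Named numeric vector of four scores plus attributes `violations`.
#' @export
gain_linearity_fitness <- function(surface, min_post_rate = 30, mono_tol = 0.5) {
  ca <- surface$ca_active; rt <- surface$rate
  # distal-only rate after Ca opening (Is = 0 row is row 1 when grid starts at 0)
  j <- which(ca[1, ])
  post <- if (length(j)) rt[1, j[1]] else 0
  # linearity within the active region, row-wise in Id
  r2 <- c()
  for (i in seq_len(nrow(rt))) {
    jj <- which(ca[i, ])
    if (length(jj) >= 3) {
      y <- rt[i, jj]; x <- surface$Id_grid[jj]
      ss <- sum((y - mean(y))^2)
      if (ss > 0) {
        f <- stats::lm.fit(cbind(1, x), y)
        r2 <- c(r2, 1 - sum(f$residuals^2) / ss)
      }
    }
  }
  lin_err <- if (length(r2)) 1 - mean(r2) else 1
  # monotonicity of nu(Is, Id = const): scan columns along increasing Is
  viol <- 0L
  for (j2 in seq_len(ncol(rt)))
    viol <- viol + sum(diff(rt[, j2]) < -mono_tol)
  # presence of the activation jump across the Is domain
  frac <- mean(vapply(seq_len(nrow(ca)), function(i) any(ca[i, ]), logical(1)))
  out <- c(distal_only_rate = bounded_score(max(0, min_post_rate - post),
                                            min_post_rate / 3),
           gain_linearity = bounded_score(lin_err, 0.1),
           monotonicity = bounded_score(viol, 2),
           gain_presence = bounded_score(1 - frac, 0.25))
  attr(out, "violations") <- viol
  out
}

#' Guard (exclusion and cautionary) fitness components
#'
#' Penalty scores for pathological configurations: calcium activation with
#' purely somatic current (`I_d = 0` column), calcium never activating in
#' the domain, excessively high firing rates, a somatic membrane potential
#' dipping below a floor, a distal rheobase (activation current at
#' `I_s = 0`) outside the target window, and a missing rate jump at
#' activation.
#'
#' @param surface A `transfer_surface` (its `min_Vs` is used when `traces`
#'   is `NULL`).
#' @param traces Optional list with `min_Vs` (mV).
#' @param rate_cap Maximal tolerated rate (Hz).
#' @param v_floor Somatic voltage floor (mV).
#' @param rheobase_window Accepted distal activation window at `I_s = 0` (pA).
#' @param min_jump Minimal rate jump at calcium opening (Hz).
#' @return Named numeric vector of six scores.
#' @export
guard_fitness <- function(surface, traces = NULL, rate_cap = 200,
                          v_floor = -95, rheobase_window = c(300, 800),
                          min_jump = 10) {
  ca <- surface$ca_active; rt <- surface$rate
  minv <- if (!is.null(traces$min_Vs)) traces$min_Vs
          else if (!is.null(surface$min_Vs)) surface$min_Vs else v_floor
  jj <- which(ca[1, ])
  dist_rheo <- if (length(jj)) surface$Id_grid[jj[1]] else NA_real_
  rheo_err <- if (is.na(dist_rheo)) diff(range(surface$Id_grid))
              else max(0, rheobase_window[1] - dist_rheo,
                       dist_rheo - rheobase_window[2])
  jump <- if (length(jj) && jj[1] > 1) rt[1, jj[1]] - rt[1, jj[1] - 1] else 0
  c(no_ca_somatic_only = bounded_score(if (any(ca[, 1])) 1 else 0, 0.5),
    ca_opens = bounded_score(if (any(ca)) 0 else 1, 0.5),
    pathological_rate = bounded_score(max(0, max(rt) - rate_cap), 20),
    min_Vs = bounded_score(max(0, v_floor - minv), 5),
    distal_rheobase = bounded_score(rheo_err, 100),
    rate_jump = bounded_score(max(0, min_jump - jump), 5))
}

#' Full Ca-AdEx fitness evaluation
#'
#' Runs the pulse task and a (typically coarse) prolonged-DC scan for a
#' genome and assembles the complete fitness report: pulse scores,
#' calcium-behavior scores, AdEx-matching scores, gain/linearity scores and
#' guard scores.  Every component is a bounded score `exp(-|error|/scale)`,
#' so the global fitness -- the exact sum of all components -- is finite for
#' any genome; a failing simulation scores 0 on every component.
#'
#' @param genome A complete genome (bounds are not re-checked here).
#' @param reference Output of [make_adex_reference()]; computed from the
#'   genome's somatic block if `NULL`.
#' @param Is_grid,Id_grid Scan grids (pA).
#' @param stim_duration Scan stimulus duration (ms).
#' @param h Time step (ms).
#' @param pulse_spec A [pulse_task_spec()]; defaults to the genome's.
#' @return A `fitness_report`: list with `components` (named numeric) and
#'   `global` (their exact sum).
#' @export
ca_adex_fitness <- function(genome, reference = NULL,
                            Is_grid = seq(0, 600, by = 150),
                            Id_grid = seq(0, 900, by = 150),
                            stim_duration = 1000, h = 0.1,
                            pulse_spec = NULL) {
  comp_names <- c("pulse_caseA", "pulse_caseB", "pulse_caseC", "pulse_caseD",
                  "no_ca_somatic_only", "ca_opens", "ca_closes",
                  "no_ca_at_high_I", "adex_emd", "adex_rheobase",
                  "adex_last_rate", "adex_cv_isi", "capacitance_match",
                  "distal_only_rate", "gain_linearity", "monotonicity",
                  "gain_presence", "pathological_rate", "min_Vs",
                  "distal_rheobase", "rate_jump")
  fail <- structure(list(components = stats::setNames(rep(0, length(comp_names)),
                                                      comp_names),
                         global = 0), class = "fitness_report")
  out <- tryCatch({
    if (is.null(reference))
      reference <- make_adex_reference(genome, Is_grid, stim_duration, h)
    tr <- build_two_compartment(genome, bounds = NULL)
    if (is.null(pulse_spec)) pulse_spec <- pulse_task_spec(genome = genome)
    pr <- run_pulse_task(tr, pulse_spec, solver_config(h = h, T = 150), onset = 20)
    surf <- run_prolonged_scan(tr, Is_grid, Id_grid,
                               solver_config(h = h, T = stim_duration),
                               stim_duration = stim_duration)
    # calcium closure after stimulus end: probe one active distal-only point
    jj <- which(surf$ca_active[1, ])
    closes <- TRUE
    if (length(jj)) {
      probe <- simulate(tr, stim_program(
        stim_step(2, surf$Id_grid[jj[1]], 0, stim_duration)),
        solver_config(h = h, T = stim_duration + 500))
      tail_idx <- probe$times > stim_duration + 300
      closes <- max(probe$m_Ca[tail_idx, 1] * probe$h_Ca[tail_idx, 1]) < 0.5
    }
    # calcium must not require currents beyond 80% of the distal domain
    high_ok <- length(jj) > 0 &&
      surf$Id_grid[jj[1]] <= 0.8 * max(surf$Id_grid)
    cv <- {
      rr <- simulate(tr, stim_program(
        stim_step(1, max(Is_grid), 0, stim_duration)),
        solver_config(h = h, T = stim_duration))
      spike_stats(rr$spike_times, stim_duration)$cv_isi
    }
    comps <- c(
      pulse_fitness(pr),
      c(ca_closes = bounded_score(if (closes) 0 else 1, 0.5),
        no_ca_at_high_I = bounded_score(if (high_ok) 0 else 1, 0.5)),
      adex_matching_fitness(Is_grid, surf$rate[, 1], cv,
                            as.numeric(genome[["C_m_s"]]) +
                              as.numeric(genome[["C_m_d"]]), reference),
      gain_linearity_fitness(surf),
      guard_fitness(surf)
    )
    comps <- comps[comp_names]
    structure(list(components = comps, global = sum(comps)),
              class = "fitness_report")
  }, error = function(e) fail)
  out
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("fitness_report: global =", format(x$global, digits = 5), "\n")
  print(round(x$components, 4))
  invisible(x)
}
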