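#' Stimulation program elements
#'
#' A stimulation program is a list of elements targeting compartments of a
#' tree: rectangular DC steps, beta-shaped (EPSC-like) current injections,
#' receptor inputs driven by explicit spike trains, and Poisson-driven
#' receptor inputs realized at simulation time from the simulation seed.
#'
#' @param comp Target compartment index (1-based).
#' @param amp Step amplitude (pA).
#' @param onset Start time (ms); events are snapped to the nearest grid point.
#' @param duration Step duration (ms), > 0.
#' @return A stimulus element; combine with [stim_program()].
#' @export
stim_step <- function(comp, amp, onset, duration) {
  stopifnot(duration > 0, onset >= 0)
  structure(list(type = "step", comp = as.integer(comp), amp = amp,
                 onset = onset, duration = duration), class = "caadex_stim")
}

#' @rdname stim_step
#' @param peak Peak current of the beta-shaped injection (pA).
#' @param tau_r,tau_d Rise/decay constants (ms); default `NULL` uses the
#'   genome's `tau_r_beta`/`tau_d_beta` when built via [run_pulse_task()],
#'   else 1 and 10 ms.
#' @export
stim_beta <- function(comp, peak, onset, tau_r = 1, tau_d = 10) {
  spec <- receptor_spec("BETA_CURRENT", tau_r = tau_r, tau_d = tau_d, w = peak)
  structure(list(type = "receptor", comp = as.integer(comp), spec = spec,
                 spike_times = onset), class = "caadex_stim")
}

#' @rdname stim_step
#' @param spec A [receptor_spec()].
#' @param spike_times Presynaptic spike times (ms), non-decreasing.
#' @export
stim_receptor <- function(comp, spec, spike_times) {
  if (is.unsorted(spike_times))
    stop("spike times must be non-decreasing")
  structure(list(type = "receptor", comp = as.integer(comp), spec = spec,
                 spike_times = as.numeric(spike_times)), class = "caadex_stim")
}

#' @rdname stim_step
#' @param rate Poisson rate (Hz), >= 0.
#' @param t_start,t_stop Window (ms) over which the train is generated.
#' @export
stim_poisson <- function(comp, spec, rate, t_start, t_stop) {
  stopifnot(rate >= 0, t_stop > t_start)
  structure(list(type = "poisson", comp = as.integer(comp), spec = spec,
                 rate = rate, t_start = t_start, t_stop = t_stop),
            class = "caadex_stim")
}

#' @rdname stim_step
#' @param ... Stimulus elements.
#' @export
stim_program <- function(...) {
  els <- list(...)
  if (length(els) == 1 && is.list(els[[1]]) && !inherits(els[[1]], "caadex_stim"))
    els <- els[[1]]
  stopifnot(all(vapply(els, inherits, logical(1), "caadex_stim")))
  structure(els, class = "stim_program")
}

#' Generate a homogeneous Poisson spike train
#'
#' @param rate Rate (Hz).
#' @param t_start,t_stop Window (ms).
#' @return Sorted spike times (ms).  Uses R's RNG (seed it for determinism).
#' @export
poisson_train <- function(rate, t_start, t_stop) {
  if (rate <= 0) return(numeric())
  n <- stats::rpois(1, rate * (t_stop - t_start) / 1000)
  sort(stats::runif(n, t_start, t_stop))
}
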