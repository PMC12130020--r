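#' Solver configuration
#'
#' The voltage equation is discretized in time with the Crank-Nicolson
#' scheme; the implicit right-hand side is Taylor-expanded once (a single
#' linearization, one Hines solve per step, no iteration).  Channel and
#' receptor state variables use the leap-frog staggering with exact
#' exponential propagators.  Passive trees converge at order 2 in `h`.
#'
#' @param h Time step (ms), > 0.  Default 0.1 ms.
#' @param T Total simulated time (ms), >= h.
#' @param record Recorded quantities; all state is recorded by default.
#' @return A `solver_config`.
#' @export
solver_config <- function(h = 0.1, T, record = c("V", "Ca", "gating", "w")) {
  stopifnot(h > 0, T >= h)
  structure(list(h = h, T = T, record = record), class = "solver_config")
}

#' Solve the symmetric tree-structured linear system
#'
#' Direct O(N) elimination on a tree in Hines ordering: `A[i,i] = diag[i]`,
#' `A[i, parent[i]] = A[parent[i], i] = off[i]`.  Exact (up to floating
#' point) and bitwise-deterministic for fixed input.
#'
#' @param parent Integer parent indices (1-based; `NA` for the root, which
#'   must be the first entry; children after parents).
#' @param diag Diagonal entries.
#' @param off Off-diagonal coupling entries, one per non-root compartment.
#' @param rhs Right-hand side.
#' @return Solution vector.
#' @export
hines_solve <- function(parent, diag, off, rhs) {
  n <- length(diag)
  stopifnot(length(parent) == n, length(off) == n, length(rhs) == n)
  if (!is.na(parent[1])) stop("the root (first compartment) must have parent NA")
  p0 <- as.integer(parent) - 1L
  p0[1] <- -1L
  if (n > 1 && any(p0[-1] < 0 | p0[-1] >= (seq_len(n - 1))))
    stop("compartments must be in Hines ordering (children after parents)")
  hines_solve_cpp(p0, as.numeric(diag), as.numeric(off), as.numeric(rhs))
}

tree_to_cpp <- function(tree) {
  p0 <- tree$parent - 1L
  p0[is.na(p0)] <- -1L
  ia <- which(!vapply(tree$adex, is.null, logical(1)))
  ic <- which(!vapply(tree$ca, is.null, logical(1)))
  adex_par <- matrix(0, length(ia), 11)
  for (k in seq_along(ia)) adex_par[k, ] <- unlist(tree$adex[[ia[k]]])
  ca_par <- matrix(0, length(ic), 16)
  for (k in seq_along(ic)) ca_par[k, ] <- unlist(tree$ca[[ic[k]]])
  list(parent = p0, Cm = tree$C_m, gL = tree$g_L, EL = tree$E_L, gC = tree$g_C,
       adex_comp = as.integer(ia - 1L), adex_par = adex_par,
       bap_target = lapply(ia, function(i) as.integer(tree$bap_targets[[i]] - 1L)),
       ca_comp = as.integer(ic - 1L), ca_par = ca_par)
}

kind_code <- function(kind) switch(kind, NMDA = 1L, BETA_CURRENT = 2L, 0L)

program_to_cpp <- function(tree, program, config) {
  steps <- list(comp = numeric(), amp = numeric(), on = numeric(), off = numeric())
  rc <- integer(); rk <- integer(); rtr <- numeric(); rtd <- numeric()
  rer <- numeric(); rw <- numeric(); rsp <- list()
  add_rec <- function(comp, spec, spikes) {
    if (spec$kind == "AMPA_NMDA") {
      add_rec(comp, receptor_spec("AMPA", w = spec$w), spikes)
      add_rec(comp, nmda_component(spec), spikes)
      return(invisible())
    }
    rc <<- c(rc, comp - 1L)
    rk <<- c(rk, kind_code(spec$kind))
    rtr <<- c(rtr, spec$tau_r); rtd <<- c(rtd, spec$tau_d)
    rer <<- c(rer, spec$e_r); rw <<- c(rw, spec$w)
    rsp[[length(rsp) + 1]] <<- as.numeric(spikes)
  }
  els <- c(unclass(program),
           unlist(lapply(seq_len(tree$n), function(i)
             lapply(tree$receptors[[i]], function(sp)
               stim_receptor(i, sp, numeric()))), recursive = FALSE))
  for (el in els) {
    if (el$comp < 1 || el$comp > tree$n)
      stop("stimulus targets unknown compartment ", el$comp)
    if (el$type == "step") {
      steps$comp <- c(steps$comp, el$comp - 1L)
      steps$amp <- c(steps$amp, el$amp)
      steps$on <- c(steps$on, round(el$onset / config$h) * config$h)
      steps$off <- c(steps$off, round((el$onset + el$duration) / config$h) * config$h)
    } else if (el$type == "receptor") {
      add_rec(el$comp, el$spec, el$spike_times)
    } else if (el$type == "poisson") {
      add_rec(el$comp, el$spec, poisson_train(el$rate, el$t_start, el$t_stop))
    } else stop("unknown stimulus type: ", el$type)
  }
  list(step_comp = as.numeric(steps$comp), step_amp = steps$amp,
       step_on = steps$on, step_off = steps$off,
       rec_comp = rc, rec_kind = rk, rec_taur = rtr, rec_taud = rtd,
       rec_er = rer, rec_w = rw, rec_spikes = rsp)
}

#' Simulate a compartment tree
#'
#' Runs the Crank-Nicolson/Hines stepper over `[0, T]`.  A somatic spike is
#' detected on the post-solve voltage when `V_s >= V_th`; the spike time is
#' recorded at the end of the step, `V_s` is reset and held at `V_reset` for
#' `t_ref` (during which the other compartments continue to integrate), the
#' spike-triggered increment `b` is added to the adaptation variable, and a
#' BAP charge `w_BAP` is scheduled for delivery into the target
#' compartment(s) after `d_BAP` (rounded to whole steps; the delivered
#' charge is `w_BAP` regardless of `h`).
#'
#' @param tree A `compartment_tree`.
#' @param program A [stim_program()] (may be empty).
#' @param config A [solver_config()].
#' @param seed Integer seed; used only by stochastic (Poisson) inputs.  Runs
#'   with the same seed and configuration are bit-identical.
#' @param v_init Initial voltages (mV), recycled; default is each
#'   compartment's `E_L`.
#' @return A `simulation_result`: `times`, per-compartment voltage matrix
#'   `V`, calcium/gating recordings, adaptation `w`, `spike_times` (first
#'   AdEx compartment), `spikes` per AdEx compartment and the audit list of
#'   delivered BAP events.
#' @export
simulate <- function(tree, program = stim_program(), config, seed = NULL,
                     v_init = NULL) {
  stopifnot(inherits(tree, "compartment_tree"), inherits(config, "solver_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  v0 <- if (is.null(v_init)) tree$E_L else rep_len(v_init, tree$n)
  ctree <- tree_to_cpp(tree)
  cstim <- program_to_cpp(tree, program, config)
  out <- simulate_cpp(ctree, cstim, config$h, config$T, v0)
  ia <- which(!vapply(tree$adex, is.null, logical(1)))
  ic <- which(!vapply(tree$ca, is.null, logical(1)))
  spikes <- out$spikes; names(spikes) <- as.character(ia)
  res <- structure(list(
    times = out$times, V = out$V, w = out$w, Ca = out$Ca,
    m_Ca = out$m_Ca, h_Ca = out$h_Ca, m_KCa = out$m_KCa,
    spikes = spikes,
    spike_times = if (length(ia)) out$spikes[[1]] else numeric(),
    bap_events = out$bap_events,
    adex_comps = ia, ca_comps = ic,
    h = config$h, T = config$T
  ), class = "simulation_result")
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: T=%g ms, h=%g ms, %d compartment(s), %d spike(s)\n",
              x$T, x$h, ncol(x$V), length(x$spike_times)))
  invisible(x)
}

#' Write a recording to CSV
#'
#' Columns: `t_ms`, then `V<i>_mV` per compartment, `w<i>` per AdEx
#' compartment, `Ca<i>_mM`, `m_Ca<i>`, `h_Ca<i>`, `m_KCa<i>` per calcium
#' compartment.
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(result, path) {
  df <- data.frame(t_ms = result$times)
  for (i in seq_len(ncol(result$V))) df[[paste0("V", i, "_mV")]] <- result$V[, i]
  for (k in seq_along(result$adex_comps))
    df[[paste0("w", result$adex_comps[k])]] <- result$w[, k]
  for (k in seq_along(result$ca_comps)) {
    i <- result$ca_comps[k]
    df[[paste0("Ca", i, "_mM")]] <- result$Ca[, k]
    df[[paste0("m_Ca", i)]] <- result$m_Ca[, k]
    df[[paste0("h_Ca", i)]] <- result$h_Ca[, k]
    df[[paste0("m_KCa", i)]] <- result$m_KCa[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
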