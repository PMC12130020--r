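#' Balanced-network specification
#'
#' A Brunel-like balanced network of identical two-compartment Ca-AdEx
#' neurons: `N_exc` excitatory and `N_inh` inhibitory neurons (the shipped
#' benchmark keeps the 4:1 proportion), every neuron receiving exactly `K`
#' input synapses (4/5 from excitatory, 1/5 from inhibitory sources, sampled
#' uniformly without self-connections), inhibitory weights `-g_ratio`
#' times the excitatory weight, conductance-based AMPA/GABA synapses on the
#' soma, a fixed spike-transmission delay, and independent per-neuron
#' external Poisson drive onto the AMPA conductance.
#'
#' @param N_exc,N_inh Population sizes.
#' @param g_ratio Inhibitory/excitatory weight ratio (default 5).
#' @param K Input synapses per neuron; must not exceed `N_exc + N_inh`.
#' @param J_exc Excitatory synaptic weight (nS).
#' @param delay Spike-transmission delay (ms).
#' @param ext_rate External Poisson rate per neuron (Hz).
#' @param ext_w External synaptic weight (nS); defaults to `J_exc`.
#' @param duration Simulation duration (ms).
#' @return A `network_spec`.
#' @export
network_spec <- function(N_exc = 500, N_inh = 125, g_ratio = 5, K = 125,
                         J_exc = 1, delay = 1.5, ext_rate = 3000,
                         ext_w = NULL, duration = 2000) {
  if (K > N_exc + N_inh) stop("K infeasible: exceeds network size")
  if (is.null(ext_w)) ext_w <- J_exc
  structure(list(N_exc = N_exc, N_inh = N_inh, g_ratio = g_ratio, K = K,
                 J_exc = J_exc, delay = delay, ext_rate = ext_rate,
                 ext_w = ext_w, duration = duration),
            class = "network_spec")
}

#' Build the network wiring
#'
#' Fixed in-degree: every neuron draws `round(4/5 K)` excitatory and the
#' remaining inhibitory sources uniformly without self-connections.
#' Deterministic per seed.
#'
#' @param spec A [network_spec()].
#' @param genome Neuron genome shared by all neurons.
#' @param seed Wiring seed.
#' @return A `brunel_network` (spec, genome, CSR out-adjacency, in-degrees).
#' @export
build_brunel_network <- function(spec, genome, seed = 1) {
  N <- spec$N_exc + spec$N_inh
  K_exc <- round(spec$K * 4 / 5)
  K_inh <- spec$K - K_exc
  if (K_exc > spec$N_exc || K_inh > spec$N_inh)
    stop("K infeasible for the population sizes")
  set.seed(seed)
  in_exc <- vector("list", N); in_inh <- vector("list", N)
  for (i in seq_len(N)) {
    pe <- seq_len(spec$N_exc)
    if (i <= spec$N_exc) pe <- pe[-i]
    in_exc[[i]] <- sample(pe, K_exc)
    pi <- spec$N_exc + seq_len(spec$N_inh)
    if (i > spec$N_exc) pi <- pi[pi != i]
    in_inh[[i]] <- sample(pi, K_inh)
  }
  # invert to CSR out-adjacency for the stepping loop
  src <- c(unlist(in_exc), unlist(in_inh))
  tgt <- c(rep(seq_len(N), each = K_exc), rep(seq_len(N), each = K_inh))
  o <- order(src)
  src <- src[o]; tgt <- tgt[o]
  out_ptr <- c(0L, cumsum(tabulate(src, N)))
  structure(list(spec = spec, genome = genome, seed = seed,
                 out_ptr = as.integer(out_ptr), out_idx = as.integer(tgt - 1L),
                 in_degree = rep(spec$K, N),
                 K_exc = K_exc, K_inh = K_inh),
            class = "brunel_network")
}

#' In-degree audit of a built network
#'
#' @param network A `brunel_network`.
#' @return Integer matrix with columns `exc`, `inh`: per-neuron counts of
#'   excitatory and inhibitory input synapses.
#' @export
network_in_degrees <- function(network) {
  N <- network$spec$N_exc + network$spec$N_inh
  exc <- integer(N); inh <- integer(N)
  for (s in seq_len(N)) {
    idx <- (network$out_ptr[s] + 1):(network$out_ptr[s + 1])
    if (network$out_ptr[s + 1] == network$out_ptr[s]) next
    t1 <- network$out_idx[idx] + 1L
    if (s <= network$spec$N_exc) {
      cnt <- tabulate(t1, N); exc <- exc + cnt
    } else {
      cnt <- tabulate(t1, N); inh <- inh + cnt
    }
  }
  cbind(exc = exc, inh = inh)
}

#' Simulate the balanced network
#'
#' Event-driven synaptic delivery on the time grid with fixed delay;
#' reports spikes (GDF-like), per-population and global mean rates, and an
#' irregularity summary (mean ISI CV over neurons with at least 3 spikes).
#'
#' @param network A `brunel_network`.
#' @param duration Duration (ms); defaults to the spec's.
#' @param seed Noise seed (independent of the wiring seed).
#' @param h Time step (ms).
#' @param J_exc,ext_rate,ext_w Optional overrides of the spec.
#' @return List `spikes` (data frame `t_ms`, `unit_id`), `mean_rate`,
#'   `rate_exc`, `rate_inh` (Hz), `mean_cv_isi`, `counts`.
#' @export
simulate_network <- function(network, duration = NULL, seed = 1, h = 0.1,
                             J_exc = NULL, ext_rate = NULL, ext_w = NULL) {
  sp <- network$spec
  if (is.null(duration)) duration <- sp$duration
  if (is.null(J_exc)) J_exc <- sp$J_exc
  if (is.null(ext_rate)) ext_rate <- sp$ext_rate
  if (is.null(ext_w)) ext_w <- sp$ext_w
  pars <- unclass(network$genome)
  out <- network_cpp(pars, network$out_ptr, network$out_idx,
                     sp$N_exc, sp$N_inh, J_exc, sp$g_ratio, sp$delay,
                     ext_rate, ext_w, h, duration, as.integer(seed))
  N <- sp$N_exc + sp$N_inh
  counts <- out$counts
  secs <- duration / 1000
  ids <- out$spike_id + 1L
  cvs <- c()
  if (length(ids)) {
    by_unit <- split(out$spike_t, ids)
    for (st in by_unit) if (length(st) >= 3) {
      isi <- diff(sort(st)); cvs <- c(cvs, stats::sd(isi) / mean(isi))
    }
  }
  list(spikes = data.frame(t_ms = out$spike_t, unit_id = ids),
       mean_rate = sum(counts) / N / secs,
       rate_exc = sum(counts[seq_len(sp$N_exc)]) / sp$N_exc / secs,
       rate_inh = sum(counts[sp$N_exc + seq_len(sp$N_inh)]) / sp$N_inh / secs,
       mean_cv_isi = if (length(cvs)) mean(cvs) else NA_real_,
       counts = counts)
}

#' Calibrate the external drive to a target network rate
#'
#' The excitatory weight is held fixed; the external Poisson rate is swept
#' (doubling to bracket, then bisection) until the global mean rate falls
#' within `tolerance` of `target_rate`.  Fails explicitly, with the sweep
#' log, if the budget is exhausted.
#'
#' @param spec A [network_spec()].
#' @param genome Neuron genome.
#' @param target_rate Target global mean rate (Hz), > 0.
#' @param tolerance Acceptance half-width (Hz).
#' @param seed Wiring/noise seed.
#' @param duration Calibration-run duration (ms).
#' @param max_iter Sweep budget.
#' @return List `ext_rate`, `J_exc`, `achieved_rate`, `log` (data frame).
#' @export
calibrate_network_rate <- function(spec, genome, target_rate = 1.23,
                                   tolerance = 0.1, seed = 1,
                                   duration = 2000, max_iter = 20) {
  stopifnot(target_rate > 0)
  net <- build_brunel_network(spec, genome, seed)
  log <- data.frame(ext_rate = numeric(), rate = numeric())
  probe <- function(er) {
    r <- simulate_network(net, duration = duration, seed = seed,
                          ext_rate = er)$mean_rate
    log <<- rbind(log, data.frame(ext_rate = er, rate = r))
    r
  }
  lo <- 0; hi <- spec$ext_rate
  r_hi <- probe(hi)
  it <- 1
  while (r_hi < target_rate && it < max_iter) {
    lo <- hi; hi <- hi * 2; r_hi <- probe(hi); it <- it + 1
  }
  if (r_hi < target_rate)
    stop("calibration failed to bracket the target; sweep log:\n",
         paste(utils::capture.output(print(log)), collapse = "\n"))
  best <- list(er = hi, r = r_hi)
  while (it < max_iter && abs(best$r - target_rate) > tolerance) {
    mid <- (lo + hi) / 2
    r <- probe(mid); it <- it + 1
    if (abs(r - target_rate) < abs(best$r - target_rate)) best <- list(er = mid, r = r)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  if (abs(best$r - target_rate) > tolerance)
    stop("calibration did not converge within budget; sweep log:\n",
         paste(utils::capture.output(print(log)), collapse = "\n"))
  list(ext_rate = best$er, J_exc = spec$J_exc, achieved_rate = best$r, log = log)
}

#' Read / write network specs as YAML
#'
#' @param spec A [network_spec()].
#' @param path YAML path.
#' @export
write_network_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  j <- yaml::read_yaml(path)
  do.call(network_spec, j[intersect(names(j), names(formals(network_spec)))])
}

#' The shipped calibrated scaled-down benchmark spec
#'
#' A 500 + 125 neuron network (4:1, `g_ratio = 5`, `K = 125`) whose
#' excitatory weight and external drive were calibrated with
#' [calibrate_network_rate()] to an asynchronous regime at about 1.23 Hz.
#'
#' @return A `network_spec`.
#' @export
benchmark_network_spec <- function() {
  read_network_spec(system.file("extdata", "network_benchmark.yaml",
                                package = "caadex", mustWork = TRUE))
}
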