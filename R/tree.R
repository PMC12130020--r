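#' Mechanism constructors
#'
#' `adex_mechanism()` describes the somatic adaptive-exponential spike block
#' (exponential spike initiation, detection threshold, reset, refractoriness,
#' subthreshold and spike-triggered adaptation, and the delayed
#' back-propagating action-potential charge `w_BAP` delivered to target
#' compartments).  `ca_hotzone_mechanism()` describes the distal calcium hot
#' zone: a high-voltage-activated Ca channel with first-order `m`/`h`
#' kinetics, a Ca-activated K channel, and a linear calcium pool with
#' extrusion time constant `tau_Ca`.
#'
#' @param Delta_T Slope factor (mV), must be > 0.
#' @param V_th_s Exponential threshold (mV).
#' @param V_th Spike detection threshold (mV).
#' @param V_reset Reset potential (mV).
#' @param t_ref Refractory period (ms), >= 0.
#' @param a Subthreshold adaptation (nS).
#' @param b Spike-triggered adaptation increment (pA).
#' @param tau_w Adaptation time constant (ms), > 0.
#' @param g_w Adaptation coupling factor (dimensionless, default 1).
#' @param w_BAP BAP charge (pA*ms), delivered as a one-step current `w_BAP/h`.
#' @param d_BAP BAP delay (ms), rounded to a whole number of steps.
#' @return A mechanism object (named list with a class attribute).
#' @export
adex_mechanism <- function(Delta_T, V_th_s, V_th, V_reset, t_ref = 0, a = 0,
                           b = 0, tau_w = 100, g_w = 1, w_BAP = 0, d_BAP = 1) {
  stopifnot(Delta_T > 0, t_ref >= 0, tau_w > 0)
  structure(list(Delta_T = Delta_T, V_th_s = V_th_s, V_th = V_th,
                 V_reset = V_reset, t_ref = t_ref, a = a, b = b,
                 tau_w = tau_w, g_w = g_w, w_BAP = w_BAP, d_BAP = d_BAP),
            class = "adex_mechanism")
}

#' @rdname adex_mechanism
#' @param g_Ca,E_Ca Maximal Ca conductance (nS) and reversal (mV).
#' @param m_slope,m_half,h_slope,h_half Activation/inactivation steady-state
#'   parameters (1/mV, mV); a negative slope gives a variable increasing
#'   with V.
#' @param tau_m_Ca,tau_h_Ca Gating time constants (ms), > 0.
#' @param g_K,E_K Maximal Ca-activated K conductance (nS) and reversal (mV).
#' @param tau_m_KCa K_Ca activation time constant (ms), > 0.
#' @param Ca_th Calcium half-activation concentration (mM), > 0.
#' @param const_KCa Hill-type exponent (dimensionless).
#' @param phi_Ca Current-to-concentration scale (mM/(pA*ms)).
#' @param Ca_0 Baseline concentration (mM), >= 0.
#' @param tau_Ca Calcium extrusion time constant (ms), > 0.
#' @export
ca_hotzone_mechanism <- function(g_Ca, E_Ca, m_slope, m_half, h_slope, h_half,
                                 tau_m_Ca, tau_h_Ca, g_K, E_K, tau_m_KCa,
                                 Ca_th, const_KCa, phi_Ca, Ca_0, tau_Ca) {
  stopifnot(tau_m_Ca > 0, tau_h_Ca > 0, tau_m_KCa > 0, tau_Ca > 0,
            Ca_th > 0, Ca_0 >= 0)
  structure(list(g_Ca = g_Ca, E_Ca = E_Ca, m_slope = m_slope, m_half = m_half,
                 h_slope = h_slope, h_half = h_half, tau_m_Ca = tau_m_Ca,
                 tau_h_Ca = tau_h_Ca, g_K = g_K, E_K = E_K,
                 tau_m_KCa = tau_m_KCa, Ca_th = Ca_th, const_KCa = const_KCa,
                 phi_Ca = phi_Ca, Ca_0 = Ca_0, tau_Ca = tau_Ca),
            class = "ca_hotzone_mechanism")
}

#' Describe one compartment of a tree
#'
#' @param id Integer index (1-based; compartment 1 is the root/soma).
#' @param parent Integer index of the parent compartment, or `NA` for the
#'   root.  Parents must come before children (Hines ordering).
#' @param C_m Capacitance (pF), > 0.
#' @param g_L Leak conductance (nS), >= 0.
#' @param E_L Leak reversal (mV).
#' @param g_C Coupling conductance to the parent (nS), >= 0; stored on the
#'   child, used symmetrically in both rows of the system matrix.
#' @param channels List of mechanism objects ([adex_mechanism()] and/or
#'   [ca_hotzone_mechanism()]).
#' @param receptors List of [receptor_spec()] objects permanently attached to
#'   the compartment (stimulation programs may add more).
#' @return A `caadex_compartment` description.
#' @export
compartment <- function(id, parent = NA, C_m, g_L, E_L, g_C = 0,
                        channels = list(), receptors = list()) {
  if (!(C_m > 0)) stop("validation error: C_m must be > 0 (compartment ", id, ")")
  if (g_L < 0 || g_C < 0) stop("validation error: conductances must be >= 0")
  structure(list(id = as.integer(id), parent = as.integer(parent), C_m = C_m,
                 g_L = g_L, E_L = E_L, g_C = g_C, channels = channels,
                 receptors = receptors),
            class = "caadex_compartment")
}

#' Build a validated compartment tree
#'
#' Assembles compartments into a tree in Hines ordering (children after
#' parents, exactly one root).  The multi-compartment model is always a tree
#' graph; cycles, self-parenting or multiple roots are structure errors.
#'
#' @param comps List of [compartment()] descriptions, ordered so every parent
#'   index references an earlier entry.
#' @return A `compartment_tree`.
#' @export
#' @examples
#' soma <- compartment(1, NA, C_m = 200, g_L = 10, E_L = -70)
#' dend <- compartment(2, 1, C_m = 100, g_L = 5, E_L = -70, g_C = 15)
#' tr <- build_tree(list(soma, dend))
build_tree <- function(comps) {
  n <- length(comps)
  if (n < 1) stop("structure error: empty compartment list")
  parent <- vapply(comps, function(x) x$parent, integer(1))
  ids <- vapply(comps, function(x) x$id, integer(1))
  if (!identical(ids, seq_len(n)))
    stop("structure error: compartment ids must be 1..n in order")
  roots <- which(is.na(parent))
  if (length(roots) != 1)
    stop("structure error: exactly one root required, found ", length(roots))
  if (roots != 1L) stop("structure error: the root must be compartment 1")
  for (i in seq_len(n)[-1]) {
    if (is.na(parent[i]) || parent[i] >= i || parent[i] < 1)
      stop("structure error: compartment ", i,
           " must reference an earlier parent (self-reference or cycle)")
  }
  # tree property: n-1 edges, connected by construction of the parent links
  adex <- vector("list", n); ca <- vector("list", n); recs <- vector("list", n)
  for (i in seq_len(n)) {
    for (ch in comps[[i]]$channels) {
      if (inherits(ch, "adex_mechanism")) adex[[i]] <- ch
      else if (inherits(ch, "ca_hotzone_mechanism")) ca[[i]] <- ch
      else stop("unknown channel mechanism on compartment ", i)
    }
    recs[[i]] <- comps[[i]]$receptors
  }
  structure(list(
    n = n,
    parent = parent,
    C_m = vapply(comps, function(x) x$C_m, numeric(1)),
    g_L = vapply(comps, function(x) x$g_L, numeric(1)),
    E_L = vapply(comps, function(x) x$E_L, numeric(1)),
    g_C = vapply(comps, function(x) x$g_C, numeric(1)),
    adex = adex, ca = ca, receptors = recs,
    # BAP from each AdEx compartment is delivered to its ca-hot-zone
    # neighbors by default; build_two_compartment sets this explicitly
    bap_targets = lapply(seq_len(n), function(i)
      if (!is.null(adex[[i]])) which(!vapply(ca, is.null, logical(1))) else integer())
  ), class = "compartment_tree")
}

#' Build the two-compartment Ca-AdEx neuron from a genome
#'
#' Compartment 1 is the soma (AdEx mechanism), compartment 2 the distal
#' apical compartment (calcium hot zone), coupled by `g_C`.  `g_C = 0` is
#' valid and leaves the compartments electrically independent (the
#' apical-isolation limit).
#'
#' @param genome A complete [ca_adex_genome()] within bounds.
#' @param bounds Bounds used for validation; `NULL` skips the bounds check.
#' @return A `compartment_tree`.
#' @export
build_two_compartment <- function(genome, bounds = default_genome_bounds()) {
  check_genome_complete(genome)
  if (!is.null(bounds)) {
    rep <- validate_genome(genome, bounds)
    if (nrow(rep))
      stop("validation error: genome out of bounds: ",
           paste(rep$parameter, collapse = ", "))
  }
  g <- function(p) as.numeric(genome[[p]])
  soma <- compartment(1, NA, C_m = g("C_m_s"), g_L = g("g_L_s"),
                      E_L = g("E_L_s"),
                      channels = list(adex_mechanism(
                        Delta_T = g("Delta_T"), V_th_s = g("V_th_s"),
                        V_th = g("V_th"), V_reset = g("V_reset"),
                        t_ref = g("t_ref"), a = g("a"), b = g("b"),
                        tau_w = g("tau_w"), g_w = g("g_w"),
                        w_BAP = g("w_BAP"), d_BAP = g("d_BAP"))))
  dist <- compartment(2, 1, C_m = g("C_m_d"), g_L = g("g_L_d"),
                      E_L = g("E_L_d"), g_C = g("g_C"),
                      channels = list(ca_hotzone_mechanism(
                        g_Ca = g("g_Ca"), E_Ca = g("E_Ca"),
                        m_slope = g("m_slope"), m_half = g("m_half"),
                        h_slope = g("h_slope"), h_half = g("h_half"),
                        tau_m_Ca = g("tau_m_Ca"), tau_h_Ca = g("tau_h_Ca"),
                        g_K = g("g_K"), E_K = g("E_K"),
                        tau_m_KCa = g("tau_m_KCa"), Ca_th = g("Ca_th"),
                        const_KCa = g("const_KCa"), phi_Ca = g("phi_Ca"),
                        Ca_0 = g("Ca_0"), tau_Ca = g("tau_Ca"))))
  tr <- build_tree(list(soma, dist))
  tr$bap_targets[[1]] <- 2L
  tr
}

#' Build a single-compartment AdEx neuron
#'
#' Convenience wrapper: the somatic block of a genome as a pure
#' point-neuron.  For `g_C = 0` the somatic spike train of the
#' two-compartment model reduces exactly to this neuron for any distal
#' stimulus.
#'
#' @inheritParams build_two_compartment
#' @export
build_single_adex <- function(genome) {
  check_genome_complete(genome)
  g <- function(p) as.numeric(genome[[p]])
  soma <- compartment(1, NA, C_m = g("C_m_s"), g_L = g("g_L_s"),
                      E_L = g("E_L_s"),
                      channels = list(adex_mechanism(
                        Delta_T = g("Delta_T"), V_th_s = g("V_th_s"),
                        V_th = g("V_th"), V_reset = g("V_reset"),
                        t_ref = g("t_ref"), a = g("a"), b = g("b"),
                        tau_w = g("tau_w"), g_w = g("g_w"),
                        w_BAP = 0, d_BAP = g("d_BAP"))))
  build_tree(list(soma))
}

#' @export
print.compartment_tree <- function(x, ...) {
  cat("compartment_tree with", x$n, "compartment(s)\n")
  for (i in seq_len(x$n)) {
    mech <- c(if (!is.null(x$adex[[i]])) "AdEx",
              if (!is.null(x$ca[[i]])) "Ca-HZ")
    cat(sprintf("  [%d] parent=%s C_m=%g pF g_L=%g nS E_L=%g mV g_C=%g nS %s\n",
                i, ifelse(is.na(x$parent[i]), "-", x$parent[i]),
                x$C_m[i], x$g_L[i], x$E_L[i], x$g_C[i],
                if (length(mech)) paste0("{", paste(mech, collapse = ","), "}") else ""))
  }
  invisible(x)
}

#' Serialize / parse compartment trees
#'
#' Trees round-trip losslessly through JSON or YAML (by extension): build ->
#' serialize -> parse -> build yields a field-by-field identical tree.
#'
#' @param tree A `compartment_tree`.
#' @param path Output path (`.json`, `.yaml`, `.yml`).
#' @export
write_tree <- function(tree, path) {
  comps <- lapply(seq_len(tree$n), function(i) {
    ch <- list()
    if (!is.null(tree$adex[[i]])) ch$adex <- unclass(tree$adex[[i]])
    if (!is.null(tree$ca[[i]])) ch$ca_hotzone <- unclass(tree$ca[[i]])
    c(list(id = i),
      if (!is.na(tree$parent[i])) list(parent = tree$parent[i]),
      list(C_m = tree$C_m[i], g_L = tree$g_L[i], E_L = tree$E_L[i],
           g_C = tree$g_C[i], channels = ch))
  })
  obj <- list(compartments = comps,
              bap_targets = tree$bap_targets[!vapply(tree$adex, is.null, logical(1))])
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path, precision = 15)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  j <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path)
  comps <- lapply(j$compartments, function(cj) {
    ch <- list()
    if (!is.null(cj$channels$adex)) ch <- c(ch, list(do.call(adex_mechanism, cj$channels$adex)))
    if (!is.null(cj$channels$ca_hotzone))
      ch <- c(ch, list(do.call(ca_hotzone_mechanism, cj$channels$ca_hotzone)))
    compartment(cj$id, if (is.null(cj$parent)) NA else cj$parent,
                C_m = cj$C_m, g_L = cj$g_L, E_L = cj$E_L, g_C = cj$g_C,
                channels = ch)
  })
  tr <- build_tree(comps)
  if (!is.null(j$bap_targets)) {
    ia <- which(!vapply(tr$adex, is.null, logical(1)))
    for (k in seq_along(ia)) tr$bap_targets[[ia[k]]] <- as.integer(unlist(j$bap_targets[[k]]))
  }
  tr
}
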