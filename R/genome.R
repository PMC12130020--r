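#' @title Ca-AdEx genomes
#' @description A *genome* is the full named parameter vector of the
#'   two-compartment Ca-AdEx neuron: the somatic AdEx block, the passive
#'   distal compartment, the distal calcium hot-zone (high-voltage-activated
#'   Ca channel, Ca-activated K channel, calcium pool), the somatic-to-distal
#'   back-propagating action potential (BAP) coupling and the default shape
#'   of the beta-shaped (EPSC-like) current used by the pulse task.
#'   Units are fixed: capacitances in pF, conductances in nS, potentials in
#'   mV, times in ms, currents in pA, concentrations in mM; `w_BAP` is a
#'   charge in pA*ms; `phi_Ca` is mM/(pA*ms).
#' @name genome
NULL

#' Names of all Ca-AdEx genome parameters
#'
#' @return Character vector of the canonical parameter names.
#' @export
genome_parameter_names <- function() {
  c(
    # somatic AdEx block
    "C_m_s", "g_L_s", "E_L_s", "Delta_T", "V_th_s", "V_th", "V_reset",
    "t_ref", "a", "b", "tau_w", "g_w", "w_BAP", "d_BAP",
    # distal passive block + coupling
    "C_m_d", "g_L_d", "E_L_d", "g_C",
    # high-voltage-activated Ca channel
    "g_Ca", "E_Ca", "m_slope", "m_half", "h_slope", "h_half",
    "tau_m_Ca", "tau_h_Ca",
    # Ca-activated K channel
    "g_K", "E_K", "tau_m_KCa", "Ca_th", "const_KCa",
    # calcium pool
    "phi_Ca", "Ca_0", "tau_Ca",
    # beta-shaped current defaults (pulse task)
    "tau_r_beta", "tau_d_beta"
  )
}

new_genome <- function(x) {
  x <- unlist(x)
  structure(x[genome_parameter_names()], class = "caadex_genome")
}

genome_file <- function() {
  system.file("extdata", "ca_adex_genome_synthetic.json", package = "caadex",
              mustWork = TRUE)
}

#' The shipped reference Ca-AdEx genome
#'
#' Loads the package's synthetic reference parameter set.  It was produced by
#' calibrating the model, with the package's own fitness machinery, to the
#' canonical BAC-firing behavior: a 1,345 pA distal beta current alone gives
#' a ~15 mV somatic deflection and no spike, a 1,150 pA / 5 ms somatic step
#' gives exactly one spike, their combination (5 ms delay) gives a burst of
#' three spikes, a distal-only burst requires ~1,830 pA, and under prolonged
#' DC the distal-only calcium activation threshold sits at 550 pA.  It is a
#' synthetic stand-in constructed by this package, not a transcription of
#' any published fit.
#'
#' @param ... Named parameter overrides, e.g. `ca_adex_genome(b = 10)`.
#' @return A named numeric vector of class `caadex_genome`.
#' @export
#' @examples
#' g <- ca_adex_genome()
#' g[["g_C"]]
ca_adex_genome <- function(...) {
  g <- read_genome(genome_file())
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), genome_parameter_names())
    if (length(bad)) stop("unknown genome parameter(s): ", paste(bad, collapse = ", "))
    g[names(ov)] <- unlist(ov)
  }
  g
}

#' Parameter bounds for the Ca-AdEx genome
#'
#' The shipped per-parameter `(low, high)` bounds used to constrain the
#' evolutionary search to biologically plausible values.
#'
#' @return A named list; each element is `c(low, high)`.
#' @export
default_genome_bounds <- function() {
  j <- jsonlite::read_json(genome_file(), simplifyVector = TRUE)
  b <- j$bounds
  lapply(b, as.numeric)
}

#' Validate a genome against parameter bounds
#'
#' Checks completeness (all canonical names present and finite) and that
#' every value lies within its closed `[low, high]` interval.
#'
#' @param genome A `caadex_genome` (or named numeric vector).
#' @param bounds Named list of `c(low, high)`; defaults to the shipped bounds.
#' @return A data frame report with one row per violation (columns
#'   `parameter`, `value`, `low`, `high`, `problem`); zero rows iff valid.
#' @export
validate_genome <- function(genome, bounds = default_genome_bounds()) {
  nm <- genome_parameter_names()
  rep <- data.frame(parameter = character(), value = numeric(),
                    low = numeric(), high = numeric(), problem = character(),
                    stringsAsFactors = FALSE)
  for (p in nm) {
    v <- suppressWarnings(as.numeric(genome[p]))
    if (is.na(v)) {
      rep <- rbind(rep, data.frame(parameter = p, value = NA_real_,
                                   low = NA_real_, high = NA_real_,
                                   problem = "missing"))
      next
    }
    b <- bounds[[p]]
    if (is.null(b)) next
    if (v < b[1] || v > b[2]) {
      rep <- rbind(rep, data.frame(parameter = p, value = v,
                                   low = b[1], high = b[2],
                                   problem = "out of bounds"))
    }
  }
  rep
}

check_genome_complete <- function(genome) {
  miss <- setdiff(genome_parameter_names(), names(genome))
  miss <- union(miss, names(genome)[is.na(genome)])
  if (length(miss))
    stop("genome configuration error: missing parameter(s): ",
         paste(sort(miss), collapse = ", "))
  invisible(TRUE)
}

#' Read / write genomes
#'
#' Genomes are stored as JSON or YAML (chosen by file extension) with a
#' `parameters` map keyed by the canonical parameter names and an optional
#' `bounds` map.  Round-trips are lossless.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_genome` returns a `caadex_genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  j <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$parameters)) stop("malformed genome file (no 'parameters' map): ", path)
  p <- unlist(j$parameters)
  miss <- setdiff(genome_parameter_names(), names(p))
  if (length(miss))
    stop("genome configuration error: missing parameter(s): ",
         paste(sort(miss), collapse = ", "))
  new_genome(p)
}

#' @rdname read_genome
#' @param genome A `caadex_genome`.
#' @param bounds Optional named list of `c(low, high)` to store alongside.
#' @export
write_genome <- function(genome, path, bounds = NULL) {
  obj <- list(parameters = as.list(unclass(genome)))
  if (!is.null(bounds)) obj$bounds <- bounds
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path, precision = 15)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.caadex_genome <- function(x, ...) {
  cat("Ca-AdEx genome (", length(x), " parameters)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
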