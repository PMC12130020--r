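#' Brain-state modulation presets
#'
#' Proxies for cholinergic/noradrenergic neuromodulation expressed as genome
#' transforms: apical-amplification (`AA`, wakefulness; the fitted genome,
#' optionally with a different spike-frequency-adaptation increment `b`),
#' apical-isolation (`AI`, deep NREM sleep/anesthesia; `b = 200`, coupling
#' `g_C = 0`, somatic and distal leak reversals lowered by 5 mV) and
#' apical-drive (`AD`, REM sleep/dreaming; `b = 10`, both leak reversals
#' lowered by 2 mV).
#'
#' @param name `"AA"`, `"AI"` or `"AD"`.
#' @param b Adaptation increment override (pA); `NULL` keeps the preset's
#'   value (for `AA`, the genome's own).
#' @param soma_params_override Optional named numeric vector replacing
#'   somatic-block parameters (e.g. the target-AdEx values for an exact
#'   single-compartment reduction under `AI`).
#' @return A `brain_state_preset`.
#' @export
brain_state_preset <- function(name = c("AA", "AI", "AD"), b = NULL,
                               soma_params_override = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    AA = list(name = "AA", b = b, delta_E_L = 0, g_C_override = NULL),
    AI = list(name = "AI", b = if (is.null(b)) 200 else b, delta_E_L = -5,
              g_C_override = 0),
    AD = list(name = "AD", b = if (is.null(b)) 10 else b, delta_E_L = -2,
              g_C_override = NULL))
  preset$soma_params_override <- soma_params_override
  structure(preset, class = "brain_state_preset")
}

#' Apply a brain-state preset to a genome
#'
#' Returns a transformed copy (the input genome is untouched).  The
#' transform is auditable: only the documented fields change -- `b`, the two
#' leak reversals `E_L_s`/`E_L_d`, optionally `g_C`, and any explicit
#' somatic overrides.  `AA` with the genome's own `b` is the identity.
#'
#' @param genome A `caadex_genome`.
#' @param preset A [brain_state_preset()] or a preset name.
#' @return The transformed genome.
#' @export
#' @examples
#' g <- ca_adex_genome()
#' ai <- apply_brain_state(g, "AI")
#' ai[["g_C"]] # 0
apply_brain_state <- function(genome, preset) {
  if (is.character(preset)) preset <- brain_state_preset(preset)
  if (!inherits(preset, "brain_state_preset")) stop("unknown preset")
  g <- genome
  if (!is.null(preset$b)) g[["b"]] <- preset$b
  g[["E_L_s"]] <- g[["E_L_s"]] + preset$delta_E_L
  g[["E_L_d"]] <- g[["E_L_d"]] + preset$delta_E_L
  if (!is.null(preset$g_C_override)) g[["g_C"]] <- preset$g_C_override
  ov <- preset$soma_params_override
  if (!is.null(ov)) g[names(ov)] <- ov
  g
}

#' Maximal transfer-function rate under a brain state
#'
#' Applies a preset and scans the `(I_s, I_d)` domain at the given
#' resolution, returning the maximal firing rate and the full surface.
#'
#' @param genome Base genome.
#' @param preset Preset or preset name.
#' @param Is_grid,Id_grid Scan grids (pA).
#' @param stim_duration Stimulus duration per point (ms).
#' @param h Time step (ms).
#' @return List `max_rate` (Hz), `surface`.
#' @export
brain_state_scan <- function(genome, preset, Is_grid = seq(0, 600, by = 25),
                             Id_grid = seq(0, 900, by = 25),
                             stim_duration = 2000, h = 0.1) {
  g <- apply_brain_state(genome, preset)
  tr <- build_two_compartment(g, bounds = NULL)
  surf <- run_prolonged_scan(tr, Is_grid, Id_grid,
                             solver_config(h = h, T = stim_duration),
                             stim_duration = stim_duration)
  list(max_rate = max(surf$rate), surface = surf)
}
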