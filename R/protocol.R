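#' Pacing protocol and experimental conditions
#'
#' Defines the stimulus, pacing rate, steady-state criterion and the
#' experimental conditions (temperature and external ion concentrations)
#' under which the CRN model is simulated. Defaults reproduce the study
#' conditions of the clinical recordings the calibration targets: a 2-ms,
#' -2210-pA stimulus (about twice the diastolic threshold of the baseline
#' model), pacing until no state variable changes by more than 1% between
#' beats and then 90 further beats, at 309.65 K with
#' \[Na+\]o = 149.42 mM, \[K+\]o = 4.5 mM, \[Ca2+\]o = 1.8 mM.
#'
#' The pacing cycle length is not part of the experimental record and
#' defaults to 1000 ms (1 Hz).
#'
#' @param amplitude Stimulus current in pA; must be negative (inward).
#' @param duration Stimulus duration in ms.
#' @param cycle_length Pacing cycle length in ms.
#' @param steady_state_tol Maximum relative per-state change between
#'   consecutive beats accepted as steady state.
#' @param extra_beats Number of additional beats after steady state.
#' @param max_beats Cap on beats while searching for steady state; if
#'   reached, a warning is issued and pacing proceeds with `extra_beats`.
#' @param temperature Temperature in K.
#' @param Na_o,K_o,Ca_o External ion concentrations in mM.
#' @param stim_to_K Book the stimulus charge against intracellular K+?
#'   Default `FALSE`, matching the original model's convention of an
#'   unassigned stimulus current.
#' @param rtol,max_step Solver relative tolerance and maximum step (ms).
#' @return List of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = -2210, duration = 2,
                              cycle_length = 1000, steady_state_tol = 0.01,
                              extra_beats = 90, max_beats = 1000,
                              temperature = 309.65, Na_o = 149.42,
                              K_o = 4.5, Ca_o = 1.8, stim_to_K = FALSE,
                              rtol = 1e-6, max_step = 1) {
  if (amplitude >= 0) stop("stimulus amplitude must be negative (inward)")
  if (duration <= 0 || duration >= cycle_length)
    stop("stimulus duration must be positive and below the cycle length")
  if (steady_state_tol <= 0) stop("steady_state_tol must be positive")
  if (extra_beats < 0 || max_beats < 1) stop("invalid beat counts")
  if (min(temperature, Na_o, K_o, Ca_o) <= 0)
    stop("temperature and external concentrations must be positive")
  structure(list(
    amplitude = amplitude, duration = duration, cycle_length = cycle_length,
    steady_state_tol = steady_state_tol, extra_beats = extra_beats,
    max_beats = max_beats, temperature = temperature,
    Na_o = Na_o, K_o = K_o, Ca_o = Ca_o, stim_to_K = stim_to_K,
    rtol = rtol, max_step = max_step
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Pacing protocol: %g pA for %g ms every %g ms; steady state at %g%%/beat (+%d beats)\n",
    x$amplitude, x$duration, x$cycle_length, 100 * x$steady_state_tol,
    x$extra_beats))
  cat(sprintf("Conditions: T = %g K, [Na+]o = %g, [K+]o = %g, [Ca2+]o = %g mM\n",
              x$temperature, x$Na_o, x$K_o, x$Ca_o))
  invisible(x)
}
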