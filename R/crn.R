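crn_state_names <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                     "d", "f", "fCa", "u", "v", "w", "Nai", "Ki", "Cai",
                     "Ca_up", "Ca_rel")

#' Published resting initial conditions of the CRN model
#'
#' The quiescent state of the original model under its published conditions.
#' When the protocol changes temperature or external concentrations the
#' state relaxes towards the new rest during pacing.
#'
#' @return Named numeric vector of the 21 state variables.
#' @export
crn_initial_state <- function() {
  setNames(c(
    -81.18,      # V (mV)
    2.908e-3, 9.649e-1, 9.775e-1,           # m h j
    3.043e-2, 9.992e-1,                     # oa oi
    4.966e-3, 9.986e-1,                     # ua ui
    3.296e-5, 1.869e-2,                     # xr xs
    1.367e-4, 9.996e-1, 7.755e-1,           # d f fCa
    0.0, 1.0, 9.992e-1,                     # u v w
    11.17, 139.0, 1.013e-4,                 # Nai Ki Cai (mM)
    1.488, 1.488                            # Ca_up Ca_rel (mM)
  ), crn_state_names)
}

# 18-entry parameter vector consumed by the compiled model
crn_parms_vec <- function(theta, protocol, stim_on) {
  theta <- as_crn_parameters(theta)
  c(unname(theta),
    protocol$Na_o, protocol$K_o, protocol$Ca_o, protocol$temperature,
    if (stim_on) protocol$amplitude else 0,
    as.numeric(isTRUE(protocol$stim_to_K)))
}

# Per-state absolute tolerances: loose on V (mV scale), tight on gates and
# Ca2+ concentrations (which reach 1e-4 mM).
crn_atol <- function() {
  c(1e-4, rep(1e-8, 15), 1e-6, 1e-6, 1e-10, 1e-8, 1e-8)
}

crn_ode_segment <- function(state, theta, protocol, times, stim_on) {
  parms <- crn_parms_vec(theta, protocol, stim_on)
  out <- try(deSolve::lsoda(
    y = state, times = times, func = "crn_derivs", parms = parms,
    dllname = "pomcal", initfunc = "crn_initmod",
    rtol = protocol$rtol, atol = crn_atol(), hmax = protocol$max_step,
    maxsteps = 1e5), silent = TRUE)
  if (inherits(out, "try-error") || anyNA(out) ||
      attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    simulation_failure(theta)
  out
}

simulation_failure <- function(theta) {
  cond <- structure(
    class = c("pomcal_simulation_failure", "error", "condition"),
    list(message = "stiff solver failed to integrate the CRN model",
         call = sys.call(-1), theta = theta))
  stop(cond)
}

# One paced beat; returns the end-of-beat state, and when `sample = TRUE`
# also a densely sampled trace of the whole beat.
crn_beat <- function(state, theta, protocol, sample = FALSE) {
  dur <- protocol$duration
  cl <- protocol$cycle_length
  if (sample) {
    t1 <- seq(0, dur, by = 0.01)
    up_end <- min(dur + 18, cl)
    t2 <- unique(c(seq(dur, up_end, by = 0.01), seq(up_end, cl, by = 0.5)))
  } else {
    t1 <- c(0, dur)
    t2 <- c(dur, cl)
  }
  o1 <- crn_ode_segment(state, theta, protocol, t1, stim_on = TRUE)
  s_mid <- o1[nrow(o1), -1]
  o2 <- crn_ode_segment(s_mid, theta, protocol, t2, stim_on = FALSE)
  s_end <- o2[nrow(o2), -1]
  if (!sample)
    return(list(state = setNames(as.numeric(s_end), crn_state_names)))
  states <- rbind(o1[, -1, drop = FALSE],
                  o2[-1, -1, drop = FALSE])
  tt <- c(o1[, 1], o2[-1, 1])
  # dV/dt from the model right-hand side, with the stimulus active where it
  # was during integration
  stim_mask <- tt < dur | (tt == dur & c(rep(TRUE, nrow(o1)), rep(FALSE, nrow(o2) - 1)))
  vdot <- numeric(length(tt))
  pm_on <- crn_parms_vec(theta, protocol, TRUE)
  pm_off <- crn_parms_vec(theta, protocol, FALSE)
  sm <- unname(as.matrix(states))
  if (any(stim_mask))
    vdot[stim_mask] <- .Call(C_crn_vdot, sm[stim_mask, , drop = FALSE], pm_on)
  if (any(!stim_mask))
    vdot[!stim_mask] <- .Call(C_crn_vdot, sm[!stim_mask, , drop = FALSE], pm_off)
  list(state = setNames(as.numeric(s_end), crn_state_names),
       t = tt, V = as.numeric(states[, 1]), vdot = vdot, states = sm)
}

#' Pace the CRN model to steady state and return the final beat
#'
#' Applies the pacing protocol repeatedly, starting from the published
#' resting state, until the largest relative change of any state variable
#' between consecutive beats falls below `protocol$steady_state_tol`
#' (relative changes use an absolute floor of 1e-10 so near-zero gates do
#' not stall convergence). A further `protocol$extra_beats` stimuli are then
#' applied with full state carry-over, and the final beat is returned as a
#' densely sampled trace.
#'
#' @param theta CRN parameter multipliers (see [crn_parameters()]).
#' @param protocol A [stimulus_protocol()].
#' @param init Optional initial state (defaults to [crn_initial_state()]).
#' @return An `ap_trace` object: time samples `t` (ms, spacing <= 1 ms),
#'   membrane potential `V` (mV), model-evaluated `dVdt` (mV/ms), the final
#'   21-variable state `state_final`, and the number of beats simulated.
#' @export
pace_to_steady_state <- function(theta, protocol = stimulus_protocol(),
                                 init = crn_initial_state()) {
  theta <- as_crn_parameters(theta)
  state <- init
  prev <- state
  converged <- FALSE
  beats <- 0L
  while (beats < protocol$max_beats) {
    state <- crn_beat(state, theta, protocol)$state
    beats <- beats + 1L
    rel <- abs(state - prev) / (abs(prev) + 1e-10)
    if (max(rel) <= protocol$steady_state_tol) { converged <- TRUE; break }
    prev <- state
  }
  if (!converged)
    warning(sprintf(
      "steady state not reached within %d beats; continuing with %d extra beats",
      protocol$max_beats, protocol$extra_beats), call. = FALSE)
  n_extra <- max(protocol$extra_beats, 1L)
  if (n_extra > 1) {
    for (b in seq_len(n_extra - 1)) {
      state <- crn_beat(state, theta, protocol)$state
    }
  }
  final <- crn_beat(state, theta, protocol, sample = TRUE)
  ap_trace(t = final$t, V = final$V, dVdt = final$vdot,
           state_final = final$state,
           stim_duration = protocol$duration,
           beats = beats + n_extra, converged = converged)
}

#' Simulate a parameter vector and extract its biomarkers
#'
#' The forward map of the calibration problem: paces the model to steady
#' state under the protocol and extracts the seven AP biomarkers from the
#' final beat. Deterministic: identical inputs always give identical output.
#' Both solver failures and biomarker rejections are returned as a single
#' invalid-model outcome rather than an error.
#'
#' @inheritParams pace_to_steady_state
#' @return A named biomarker vector (class `ap_biomarkers`), or an
#'   `ap_rejection` object with a `reason` field for invalid models.
#' @export
forward_map <- function(theta, protocol = stimulus_protocol()) {
  trace <- tryCatch(pace_to_steady_state(theta, protocol),
                    pomcal_simulation_failure = function(e)
                      ap_rejection("simulation-failure"))
  if (is_rejection(trace)) return(trace)
  extract_biomarkers(trace)
}

#' Diastolic stimulus-current threshold
#'
#' Finds, by bisection to a resolution of 1 pA, the minimum magnitude of an
#' inward current pulse of the protocol's duration that elicits an action
#' potential (peak above -30 mV) from the rested model, i.e. the model at
#' its published resting state.
#'
#' @inheritParams pace_to_steady_state
#' @param ceiling Largest magnitude (pA) searched before declaring the model
#'   inexcitable.
#' @param rest_time Optional unstimulated relaxation time (ms) before testing
#'   pulses; the default 0 tests pulses directly from the published resting
#'   state.
#' @return Threshold magnitude in pA (a positive number).
#' @export
diastolic_threshold <- function(theta, protocol = stimulus_protocol(),
                                ceiling = 20000, rest_time = 0) {
  theta <- as_crn_parameters(theta)
  rest <- crn_initial_state()
  if (rest_time > 0) {
    relax <- crn_ode_segment(rest, theta,
                             within_protocol(protocol, amplitude = -1),
                             c(0, rest_time), stim_on = FALSE)
    rest <- setNames(as.numeric(relax[nrow(relax), -1]), crn_state_names)
  }

  excites <- function(amp) {
    p <- within_protocol(protocol, amplitude = -abs(amp),
                         cycle_length = max(300, protocol$duration + 200))
    b <- crn_beat(rest, theta, p, sample = TRUE)
    max(b$V) > -30
  }
  if (!excites(ceiling)) {
    cond <- structure(
      class = c("pomcal_inexcitable_model", "error", "condition"),
      list(message = sprintf("no stimulus up to %g pA elicits an AP", ceiling),
           call = sys.call(), theta = theta))
    stop(cond)
  }
  lo <- 0; hi <- ceiling
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  hi
}

# protocol with some fields replaced (revalidated)
within_protocol <- function(protocol, ...) {
  repl <- list(...)
  p <- unclass(protocol)
  p[names(repl)] <- repl
  do.call(stimulus_protocol, p)
}

#' Forward-model interface around the CRN simulator
#'
#' Wraps the CRN forward map as a `forward_model` object usable by the SMC
#' calibration engine. Evaluation is row-by-row (the ODE model is not
#' vectorisable); for engine testing use the fast closed-form models from
#' [toy_models()].
#'
#' @param protocol A [stimulus_protocol()].
#' @param bounds Parameter bounds as from [crn_bounds()].
#' @return A `forward_model` object.
#' @export
crn_forward_model <- function(protocol = stimulus_protocol(),
                              bounds = crn_bounds()) {
  nm <- names(bounds$lower)
  fn <- function(theta_mat) {
    n <- nrow(theta_mat)
    y <- matrix(NA_real_, n, length(BIOMARKER_NAMES),
                dimnames = list(NULL, BIOMARKER_NAMES))
    valid <- logical(n)
    for (i in seq_len(n)) {
      th <- as_crn_parameters(setNames(theta_mat[i, ], nm))
      out <- forward_map(th, protocol)
      if (!is_rejection(out)) {
        y[i, ] <- unclass(out)[BIOMARKER_NAMES]
        valid[i] <- TRUE
      }
    }
    list(y = y, valid = valid)
  }
  forward_model(fn, param_names = nm, output_names = BIOMARKER_NAMES,
                bounds = bounds, name = "crn")
}
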