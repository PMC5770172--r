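#' Action-potential trace for one paced beat
#'
#' A sampled membrane-potential time course covering one full paced cycle,
#' with the stimulus applied at t = 0 so the first sample is the
#' pre-stimulus diastolic potential. Simulated traces additionally carry
#' dV/dt evaluated from the model right-hand side; for traces built from
#' bare (t, V) samples, dV/dt is taken as the forward finite difference.
#'
#' @param t Time samples (ms), strictly increasing, spacing <= 1 ms.
#' @param V Membrane potential (mV) at each sample.
#' @param dVdt Optional dV/dt (mV/ms) at each sample.
#' @param state_final Optional end-of-beat model state.
#' @param stim_duration Stimulus duration (ms); used to separate the
#'   stimulus artifact from the upstroke.
#' @param beats,converged Pacing provenance (optional).
#' @return An object of class `ap_trace`.
#' @export
ap_trace <- function(t, V, dVdt = NULL, state_final = NULL,
                     stim_duration = 2, beats = NA_integer_,
                     converged = NA) {
  t <- as.numeric(t); V <- as.numeric(V)
  if (length(t) != length(V)) stop("t and V must have equal length")
  if (length(t) < 3) stop("trace too short")
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (any(dt > 1 + 1e-9)) stop("sample spacing must not exceed 1 ms")
  if (is.null(dVdt)) {
    dVdt <- c(diff(V) / dt, 0)  # forward difference, assigned to left sample
  }
  structure(list(t = t, V = V, dVdt = as.numeric(dVdt),
                 state_final = state_final, stim_duration = stim_duration,
                 beats = beats, converged = converged),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("AP trace: %d samples over %.0f ms, V in [%.1f, %.1f] mV\n",
              length(x$t), max(x$t) - min(x$t), min(x$V), max(x$V)))
  invisible(x)
}

#' Rejection outcome for an invalid action potential
#'
#' @param reason One of `"no-excitation"`, `"no-repolarization"`,
#'   `"spontaneous-depolarization"`, `"simulation-failure"`.
#' @return An `ap_rejection` object.
#' @export
ap_rejection <- function(reason) {
  structure(list(reason = reason), class = "ap_rejection")
}

#' Test whether a forward-map outcome is a rejection
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_rejection <- function(x) inherits(x, "ap_rejection")

#' @export
print.ap_rejection <- function(x, ...) {
  cat("AP rejected:", x$reason, "\n")
  invisible(x)
}

# linearly interpolated time of the first downward crossing of `level`
# strictly after index `from`
first_down_crossing <- function(t, V, level, from) {
  n <- length(V)
  idx <- which(V[from:(n - 1)] >= level & V[(from + 1):n] < level)
  if (!length(idx)) return(NA_real_)
  i <- from + idx[1] - 1
  t[i] + (V[i] - level) / (V[i] - V[i + 1]) * (t[i + 1] - t[i])
}

#' Extract the seven AP biomarkers from a trace
#'
#' Measures, from one paced beat: RMP (potential immediately before the
#' stimulus), APA (peak minus RMP), maximum upstroke velocity dV/dt_max
#' (V/s), APD20/50/90 (time from the instant of maximum upstroke to the
#' first repolarisation below 20/50/90% of APA under the peak, crossings
#' located by linear interpolation), and V20 (potential at 20% of APD90
#' after activation).
#'
#' APs are rejected — returning an [ap_rejection()] rather than a partial
#' vector — when they fail to excite above -30 mV (including the degenerate
#' case of a diastolic potential that already sits above -30 mV, leaving no
#' polarised rest to excite from), fail to repolarise to RMP + 0.1 APA, or
#' show a spontaneous depolarisation (a later local maximum above that
#' level after repolarisation).
#'
#' @param trace An [ap_trace()].
#' @return Named numeric vector of class `ap_biomarkers`, or an
#'   `ap_rejection`.
#' @export
extract_biomarkers <- function(trace) {
  stopifnot(inherits(trace, "ap_trace"))
  t <- trace$t; V <- trace$V
  n <- length(t)
  RMP <- V[1]
  ipk <- which.max(V)
  peak <- V[ipk]
  if (peak <= -30) return(ap_rejection("no-excitation"))
  # a cell whose diastolic potential already sits above the excitation
  # threshold has no polarised rest to excite from (e.g. degenerate
  # parameter sets whose membrane drifts to a depolarised pseudo-rest)
  if (RMP > -30) return(ap_rejection("no-excitation"))
  APA <- peak - RMP
  if (APA <= 0) return(ap_rejection("no-excitation"))

  # upstroke: from stimulus onset to the AP peak
  up <- which(t <= t[ipk])
  iact <- up[which.max(trace$dVdt[up])]
  dVdtmax <- trace$dVdt[iact]          # mV/ms == V/s
  t_act <- t[iact]

  repol_level <- RMP + 0.1 * APA       # 90% repolarisation
  t_repol <- first_down_crossing(t, V, repol_level, ipk)
  if (is.na(t_repol)) return(ap_rejection("no-repolarization"))

  # spontaneous depolarisation: any later local maximum back above the
  # repolarisation level
  after <- which(t > t_repol)
  if (length(after) > 2) {
    va <- V[after]
    locmax <- which(diff(sign(diff(va))) < 0) + 1
    if (any(va[locmax] > repol_level))
      return(ap_rejection("spontaneous-depolarization"))
  }

  apd <- function(frac) {
    lvl <- peak - frac * APA
    tc <- first_down_crossing(t, V, lvl, ipk)
    if (is.na(tc)) NA_real_ else tc - t_act
  }
  APD20 <- apd(0.20); APD50 <- apd(0.50); APD90 <- apd(0.90)
  if (anyNA(c(APD20, APD50, APD90)))
    return(ap_rejection("no-repolarization"))
  V20 <- approx(t, V, xout = t_act + 0.2 * APD90)$y

  structure(c(APD20 = APD20, APD50 = APD50, APD90 = APD90, APA = APA,
              RMP = RMP, V20 = V20, dVdtmax = dVdtmax),
            class = "ap_biomarkers")
}

#' @export
print.ap_biomarkers <- function(x, ...) {
  v <- unclass(x)
  cat("AP biomarkers:\n")
  print(round(v, 3))
  invisible(x)
}
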