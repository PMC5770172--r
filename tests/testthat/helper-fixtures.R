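# Shared fixtures, built in code at test time.

# The baseline CRN pacing run is used by several tests; cache it once.
.fixture_env <- new.env(parent = emptyenv())

baseline_trace <- function() {
  if (is.null(.fixture_env$baseline))
    .fixture_env$baseline <- pace_to_steady_state(crn_parameters())
  .fixture_env$baseline
}

baseline_biomarkers <- function() {
  if (is.null(.fixture_env$baseline_bm))
    .fixture_env$baseline_bm <- extract_biomarkers(baseline_trace())
  .fixture_env$baseline_bm
}

# Piecewise-linear toy AP: rest at -80 mV for 10 ms, linear rise to +25 mV
# over 1 ms, linear fall back to -80 mV over 300 ms, sampled every 1 ms.
# Closed-form biomarkers (worked by hand from the segment slopes):
#   RMP -80, peak +25, APA 105, dVdtmax 105 V/s (the rise slope),
#   activation at t = 10 (forward differences put the max slope there),
#   fall slope 105/300 = 0.35 mV/ms, so
#   APD90 = 1 + (0.9*105 - (25 - (-69.5)))... crossing of -69.5 at 270 ms
#   after the peak: APD90 = 271; APD20 crossing of +4 at 60 ms: APD20 = 61;
#   APD50 crossing of -27.5 at 150 ms: APD50 = 151;
#   V20 = V(10 + 0.2*271) = 25 - 0.35*(64.2 - 11) = 6.38.
pwl_trace <- function(peak = 25, rest = -80, fall_ms = 300) {
  t_rest <- 0:9
  t_rise <- 10:11
  t_fall <- seq(12, 11 + fall_ms, by = 1)
  t <- c(t_rest, t_rise, t_fall)
  V <- c(rep(rest, 10),
         rest, peak,
         peak + (peak - rest) / fall_ms * (11 - t_fall))
  ap_trace(t, V, stim_duration = 0)
}

# hand-built KDE object for analytic eval_density checks
manual_kde <- function(points, H, transform = NULL) {
  points <- as.matrix(points)
  if (is.null(colnames(points)))
    colnames(points) <- paste0("y", seq_len(ncol(points)))
  if (is.null(transform))
    transform <- setNames(rep("identity", ncol(points)), colnames(points))
  structure(list(points = points, H = H, h_opt = NA_real_,
                 transform = transform, sigma2 = apply(points, 2, var),
                 convention = "linear", group_label = NULL),
            class = "biomarker_kde")
}

# exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (no ties), the independent oracle for small samples
enumerate_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# 2-D identity forward model on [0, 1]^2, for range-calibration geometry
identity2d_model <- function() {
  forward_model(
    function(theta) list(y = theta, valid = rep(TRUE, nrow(theta))),
    param_names = c("a", "b"), output_names = c("u", "v"),
    bounds = list(lower = c(a = 0, b = 0), upper = c(a = 1, b = 1)),
    name = "identity2d")
}
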