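#' Specification of a synthetic biomarker dataset
#'
#' Parameter sets for the synthetic generator, targeting the qualitative
#' structure of clinical atrial AP biomarker data rather than any
#' particular study's moments: sinus-rhythm-like (SR) tables have a
#' strongly right-skewed APD20, a bimodal APD50 (a minor mode of cells
#' that repolarise more than half-way during the initial rapid phase), and
#' near-zero correlation between APA and the maximum upstroke velocity;
#' chronic-AF-like (cAF) tables are unimodal with shorter, more triangular
#' APs.
#'
#' @param style `"SR"` or `"cAF"`.
#' @return List of generator parameters (means, SDs, mixture weights).
#' @export
synthetic_spec <- function(style = c("SR", "cAF")) {
  style <- match.arg(style)
  if (style == "SR") {
    list(style = style,
         apd90_mean = 300, apd90_sd = 45,
         frac50_modes = c(0.18, 0.72), frac50_sds = c(0.04, 0.07),
         frac50_weight1 = 0.25,           # early-repolarising mode weight
         apd20_logmean = log(4), apd20_logsd = 0.85,
         apa_mean = 105, apa_sd = 9,
         rmp_mean = -74, rmp_sd = 4.5,
         dvdt_mean = 210, dvdt_sd = 55,
         shared_exc = 0.1,                # APA/dVdtmax shared factor
         v20_drop_logmean = log(18), v20_drop_logsd = 0.35)
  } else {
    list(style = style,
         apd90_mean = 210, apd90_sd = 40,
         frac50_modes = c(0.55, 0.55), frac50_sds = c(0.08, 0.08),
         frac50_weight1 = 0.5,
         apd20_logmean = log(14), apd20_logsd = 0.55,
         apa_mean = 100, apa_sd = 9,
         rmp_mean = -78, rmp_sd = 4.5,
         dvdt_mean = 200, dvdt_sd = 55,
         shared_exc = 0.1,
         v20_drop_logmean = log(30), v20_drop_logsd = 0.35)
  }
}

#' Generate a synthetic biomarker table
#'
#' Draws `n` rows of the seven AP biomarkers with the structure described
#' in [synthetic_spec()]. Rows are valid by construction:
#' `0 < APD20 <= APD50 <= APD90`, positive APA and upstroke velocity, and
#' `V20 <= RMP + APA`. Fully reproducible from the seed.
#'
#' @param n Number of rows (>= 2).
#' @param style `"SR"` or `"cAF"`.
#' @param seed Integer seed.
#' @param spec Generator parameters; defaults to [synthetic_spec()] for
#'   `style`.
#' @return Data frame with columns
#'   `APD20, APD50, APD90, APA, RMP, V20, dVdtmax`.
#' @export
generate_dataset <- function(n = 469, style = c("SR", "cAF"), seed = 1,
                             spec = synthetic_spec(style)) {
  style <- match.arg(style)
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  s <- spec
  z_apd <- rnorm(n)
  APD90 <- pmax(s$apd90_mean + s$apd90_sd * z_apd + rnorm(n, 0, 10), 40)
  mode1 <- runif(n) < s$frac50_weight1
  frac50 <- ifelse(mode1,
                   rnorm(n, s$frac50_modes[1], s$frac50_sds[1]),
                   rnorm(n, s$frac50_modes[2], s$frac50_sds[2]))
  frac50 <- pmin(pmax(frac50, 0.05), 0.92)
  APD50 <- frac50 * APD90
  APD20 <- exp(rnorm(n, s$apd20_logmean + 0.2 * z_apd, s$apd20_logsd))
  APD20 <- pmin(pmax(APD20, 0.5), 0.9 * APD50)
  z_shared <- rnorm(n)
  APA <- s$apa_mean + s$apa_sd * (s$shared_exc * z_shared +
                                    sqrt(1 - s$shared_exc^2) * rnorm(n))
  dVdtmax <- pmax(s$dvdt_mean + s$dvdt_sd * (s$shared_exc * z_shared +
                    sqrt(1 - s$shared_exc^2) * rnorm(n)), 20)
  RMP <- s$rmp_mean + s$rmp_sd * rnorm(n)
  V20 <- RMP + APA - exp(rnorm(n, s$v20_drop_logmean, s$v20_drop_logsd))
  data.frame(APD20 = APD20, APD50 = APD50, APD90 = APD90, APA = APA,
             RMP = RMP, V20 = V20, dVdtmax = dVdtmax)
}

# saturating response of the surrogate: bounded in (-1, 1), zero at the
# baseline multiplier 1
surrogate_response <- function(theta) tanh(theta - 1)

surrogate_weights <- function() {
  nm <- crn_param_names()
  W <- matrix(0, length(BIOMARKER_NAMES), length(nm),
              dimnames = list(BIOMARKER_NAMES, nm))
  # directions mirror the currents' roles: repolarising conductances
  # shorten APDs, the L-type Ca2+ current sustains the plateau, gK1 sets
  # RMP, gNa drives both APA and the upstroke (their built-in correlation)
  W["APD20", c("gto", "gKur", "gCaL")] <- c(-0.30, -0.20, 0.15)
  W["APD50", c("gto", "gKur", "gKr", "gCaL")] <- c(-0.20, -0.15, -0.15, 0.25)
  W["APD90", c("gKr", "gKs", "gK1", "gCaL", "Iup_max")] <-
    c(-0.20, -0.08, -0.15, 0.15, -0.05)
  W["APA", c("gNa", "gCaL")] <- c(0.12, 0.04)
  W["RMP", c("gK1", "INaK_max")] <- c(-0.04, -0.02)
  W["V20", c("gCaL", "gto", "krel")] <- c(0.30, -0.20, 0.05)
  W["dVdtmax", "gNa"] <- 0.45
  W["dVdtmax", "INaCa_max"] <- 0.05
  W
}

surrogate_base <- function() {
  c(APD20 = 15, APD50 = 150, APD90 = 280, APA = 105, RMP = -80,
    V20 = -10, dVdtmax = 200)
}

#' Closed-form forward models for testing the calibration engine
#'
#' Fast deterministic maps with known pushforward behaviour:
#' \describe{
#'   \item{identity}{1-D, `y = theta` on `[0, 1]`; the pushforward of
#'     uniform parameters is uniform.}
#'   \item{square}{1-D, `y = theta^2` on `[0, 1]`; uniform parameters give
#'     output density `1 / (2 sqrt(y))`.}
#'   \item{corr2d}{2-D map with built-in output correlation
#'     (`y1 = a`, `y2 = 0.8 a + 0.2 b`), for exercising the de-emphasised
#'     divergence.}
#'   \item{surrogate}{11 parameters named after the CRN multipliers mapped
#'     to 7 biomarker-named outputs through a linear-plus-saturating
#'     response with current-like directionality (e.g. raising the gK1
#'     analogue shortens the APD90 analogue and both APA and dVdtmax load
#'     on the gNa analogue). Evaluates vectorised in microseconds, making
#'     thousands-of-particle SMC runs take seconds.}
#' }
#'
#' @return Named list of [forward_model()] objects.
#' @export
toy_models <- function() {
  all_valid <- function(y) rep(TRUE, nrow(y))
  identity_m <- forward_model(
    function(theta) list(y = theta, valid = all_valid(theta)),
    param_names = "theta", output_names = "y",
    bounds = list(lower = c(theta = 0), upper = c(theta = 1)),
    name = "identity",
    pushforward = function(y) as.numeric(y >= 0 & y <= 1))
  square_m <- forward_model(
    function(theta) list(y = theta^2, valid = all_valid(theta)),
    param_names = "theta", output_names = "y",
    bounds = list(lower = c(theta = 0), upper = c(theta = 1)),
    name = "square",
    pushforward = function(y)
      ifelse(y > 0 & y <= 1, 1 / (2 * sqrt(y)), 0))
  corr2d_m <- forward_model(
    function(theta) {
      y <- cbind(y1 = theta[, 1], y2 = 0.8 * theta[, 1] + 0.2 * theta[, 2])
      list(y = y, valid = all_valid(theta))
    },
    param_names = c("a", "b"), output_names = c("y1", "y2"),
    bounds = list(lower = c(a = 0, b = 0), upper = c(a = 1, b = 1)),
    name = "corr2d")
  W <- surrogate_weights()
  base <- surrogate_base()
  nm <- crn_param_names()
  surrogate_m <- forward_model(
    function(theta) {
      resp <- surrogate_response(theta) %*% t(W)
      y <- sweep(1 + resp, 2, base, "*")
      list(y = y, valid = all_valid(theta))
    },
    param_names = nm, output_names = BIOMARKER_NAMES,
    bounds = crn_bounds(),
    name = "surrogate")
  list(identity = identity_m, square = square_m, corr2d = corr2d_m,
       surrogate = surrogate_m)
}

#' End-to-end recovery study on the surrogate forward model
#'
#' The pipeline's self-test: draws "true" parameter vectors from a known
#' Gaussian population, pushes them through the surrogate model to build a
#' synthetic data table, then runs the full calibration (density fit,
#' tempered SMC, annealed refinement) plus a range-calibrated population of
#' equal size for comparison. Optionally repeats the whole exercise for a
#' second group whose true population shifts one parameter by a known
#' factor, and compares the two calibrated populations.
#'
#' @param seed Integer seed for the whole study.
#' @param n_data Synthetic data rows.
#' @param N SMC particle count.
#' @param truth_center Named center of the true parameter population
#'   (defaults to all ones with mild shifts in gto and gK1).
#' @param truth_sd Per-dimension SD of the true population.
#' @param shift_param,shift Optional second-group parameter shift (e.g.
#'   `shift_param = "gto", shift = -0.4` scales the gto center by 0.6).
#' @param refine_budget,n_bins Annealing trials and JSD grid resolution.
#' @return List: `rho_refined`, `rho_range`, `median_shift_vs_truth`
#'   (percent per parameter), sizes, and — when a shift is requested —
#'   `comparison` (from [compare_parameter_distributions()]) and
#'   `most_significant`.
#' @export
end_to_end_recovery <- function(seed = 1, n_data = 120, N = 300,
                                truth_center = NULL, truth_sd = 0.15,
                                shift_param = NULL, shift = NULL,
                                refine_budget = 2000, n_bins = 48) {
  model <- toy_models()$surrogate
  nm <- model$param_names
  if (is.null(truth_center)) {
    truth_center <- setNames(rep(1, length(nm)), nm)
    truth_center[c("gto", "gK1")] <- c(0.8, 1.2)
  }
  set.seed(seed)

  run_group <- function(center, grp_seed) {
    th_true <- matrix(rnorm(n_data * length(nm), rep(center, each = n_data),
                            truth_sd), n_data, length(nm))
    th_true <- pmin(pmax(th_true, rep(model$bounds$lower, each = n_data)),
                    rep(model$bounds$upper, each = n_data))
    colnames(th_true) <- nm
    data <- evaluate_forward(model, th_true)$y
    est <- fit_density(data)
    pool <- smc_calibrate(est, model, N = N, seed = grp_seed)
    refined <- anneal_refine(
      pool, est,
      refinement_config(min_size = n_data, step_budget = refine_budget),
      mode = "rho", n_bins = n_bins, seed = grp_seed)
    list(data = data, est = est, pool = pool, refined = refined)
  }

  g1 <- run_group(truth_center, seed)
  # range calibration sized to match the refined population
  n_ref <- nrow(g1$refined$theta)
  range_pom <- lhs_range_calibrate(g1$data, model, replicates = 2,
                                   divisions = max(N, 500), seed = seed)
  if (nrow(range_pom$theta) > n_ref) {
    keep <- sample.int(nrow(range_pom$theta), n_ref)
    range_pom <- subset_pom(range_pom, keep)
  }
  rho_range <- divergence(range_pom, g1$est, mode = "rho",
                          n_bins = n_bins)$value
  med <- median_model(g1$refined)
  out <- list(
    rho_refined = attr(g1$refined, "rho"),
    rho_range = rho_range,
    refined_size = n_ref,
    range_size = nrow(range_pom$theta),
    pool_size = nrow(g1$pool$theta),
    median_shift_vs_truth = 100 * (med - truth_center) / truth_center)

  if (!is.null(shift_param)) {
    center2 <- truth_center
    center2[shift_param] <- center2[shift_param] * (1 + shift)
    g2 <- run_group(center2, seed + 1000)
    cmp <- compare_parameter_distributions(g1$refined, g2$refined)
    out$comparison <- cmp
    out$most_significant <- cmp$parameter[which.min(cmp$p_value)]
  }
  out
}
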