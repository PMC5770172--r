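#' Per-biomarker range box of a data table
#'
#' @param x Data frame or matrix of biomarker observations.
#' @return Matrix with rows `min` and `max`, one column per biomarker.
#' @export
range_box <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, range)
}

#' Range-calibrate a population by Latin hypercube sampling
#'
#' Generates `replicates` independent Latin hypercube samples of
#' `divisions` points each (every replicate places exactly one point in
#' each of `divisions` equal strata per dimension), evaluates the forward
#' model, and accepts the models whose every output lies within the
#' per-biomarker range of the data — the classical range-based calibration
#' that distributional calibration is compared against.
#'
#' @param data Biomarker data table (defines the acceptance ranges).
#' @param model A [forward_model()].
#' @param replicates,divisions LHS replicates and strata per dimension.
#' @param seed Integer seed.
#' @return A [pom()] of accepted models; provenance records counts.
#' @export
lhs_range_calibrate <- function(data, model, replicates = 10,
                                divisions = 1000, seed = 1) {
  if (replicates < 1 || divisions < 1) stop("invalid LHS settings")
  lo <- model$bounds$lower; hi <- model$bounds$upper
  d <- length(lo)
  set.seed(seed)
  theta <- do.call(rbind, lapply(seq_len(replicates), function(r)
    lhs::randomLHS(divisions, d)))
  theta <- sweep(sweep(theta, 2, hi - lo, "*"), 2, lo, "+")
  colnames(theta) <- model$param_names
  out <- evaluate_forward(model, theta)
  box <- range_box(as.matrix(data)[, model$output_names, drop = FALSE])
  inside <- out$valid
  for (k in seq_along(model$output_names)) {
    yk <- out$y[, k]
    inside <- inside & !is.na(yk) & yk >= box[1, k] & yk <= box[2, k]
  }
  pom(theta[inside, , drop = FALSE], out$y[inside, , drop = FALSE],
      provenance = list(method = "lhs-range", model = model$name,
                        replicates = replicates, divisions = divisions,
                        seed = seed, n_trialed = nrow(theta),
                        n_accepted = sum(inside)))
}

#' Compare parameter distributions of two populations
#'
#' For each parameter, reports the percentage change of the second
#' population's median relative to the first's, a two-sided Mann-Whitney U
#' p-value, and a flag: `"*"` (significant) below `sig_level`, `"<->"`
#' (no change) at or above `nochange_level`, empty in between.
#'
#' @param pom_a,pom_b Two [pom()]s with the same parameter layout.
#' @param sig_level,nochange_level Significance and no-change p-value
#'   thresholds.
#' @return Data frame with one row per parameter.
#' @export
compare_parameter_distributions <- function(pom_a, pom_b, sig_level = 0.001,
                                            nochange_level = 0.01) {
  A <- pom_a$theta; B <- pom_b$theta
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty population")
  if (!identical(colnames(A), colnames(B)))
    stop("populations have different parameter layouts")
  rows <- lapply(seq_len(ncol(A)), function(k) {
    ma <- median(A[, k]); mb <- median(B[, k])
    p <- suppressWarnings(wilcox.test(A[, k], B[, k])$p.value)
    # identical samples: U test is degenerate, no evidence of change
    if (is.nan(p)) p <- 1
    data.frame(parameter = colnames(A)[k],
               median_a = ma, median_b = mb,
               median_shift_pct = 100 * (mb - ma) / ma,
               p_value = p,
               flag = if (p < sig_level) "*"
                      else if (p >= nochange_level) "<->" else "")
  })
  do.call(rbind, rows)
}

#' Component-wise median model of a population
#'
#' Takes the median of each parameter independently across the population,
#' the standard way of collapsing a calibrated population into a single
#' representative parameter set.
#'
#' @param x A [pom()].
#' @return Named numeric vector of parameter medians.
#' @export
median_model <- function(x) {
  stopifnot(inherits(x, "pom"))
  if (nrow(x$theta) == 0) stop("empty population")
  apply(x$theta, 2, median)
}

#' Ion-channel block experiment on a population
#'
#' For every member: simulates the full pacing protocol, applies a
#' fractional block to the named current, re-runs the full protocol from
#' scratch with the blocked parameter set, and returns paired pre/post
#' biomarkers. Members whose post-block AP repolarises to a resting
#' potential above `rmp_limit` are flagged `elevated_rmp`; members whose
#' APD90 shortens under block are flagged `apd_decreased`. Post-block
#' simulation failures are recorded per member, not fatal.
#'
#' @param x A [pom()] whose parameters are CRN multipliers, or a matrix of
#'   such parameter rows.
#' @param current_name One of [crn_param_names()].
#' @param block_fraction Fraction blocked in `[0, 1]`.
#' @param protocol A [stimulus_protocol()].
#' @param rmp_limit Elevated-resting-potential flag threshold (mV).
#' @return Data frame with `pre_*` and `post_*` biomarker columns plus
#'   `post_valid`, `elevated_rmp` and `apd_decreased` flags.
#' @export
drug_block_experiment <- function(x, current_name, block_fraction,
                                  protocol = stimulus_protocol(),
                                  rmp_limit = -60) {
  theta <- if (inherits(x, "pom")) x$theta else as.matrix(x)
  n <- nrow(theta)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    th <- as_crn_parameters(setNames(theta[i, ], colnames(theta)))
    pre <- forward_map(th, protocol)
    post <- forward_map(apply_drug_block(th, current_name, block_fraction),
                        protocol)
    row <- setNames(rep(NA_real_, 14),
                    c(paste0("pre_", BIOMARKER_NAMES),
                      paste0("post_", BIOMARKER_NAMES)))
    if (!is_rejection(pre)) row[1:7] <- unclass(pre)[BIOMARKER_NAMES]
    if (!is_rejection(post)) row[8:14] <- unclass(post)[BIOMARKER_NAMES]
    res[[i]] <- data.frame(t(row),
                           pre_valid = !is_rejection(pre),
                           post_valid = !is_rejection(post))
  }
  out <- do.call(rbind, res)
  out$elevated_rmp <- !is.na(out$post_RMP) & out$post_RMP > rmp_limit
  out$apd_decreased <- !is.na(out$post_APD90) & !is.na(out$pre_APD90) &
    out$post_APD90 < out$pre_APD90
  out
}
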