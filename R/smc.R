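#' Metropolis-Hastings acceptance probability for the tempered target
#'
#' The acceptance probability of an independence-proposal move under the
#' tempered target proportional to `p(M(theta))^gamma`:
#' `min(1, (p_new / p_old)^gamma * J_old / J_new)`. A proposed model with
#' zero data density (including invalid forward-map outcomes) is never
#' accepted.
#'
#' @param p_new,p_old Data-density values of the proposed and current
#'   model outputs (`p_old` must be positive).
#' @param gamma Temper exponent in `[0, 1]`.
#' @param J_new,J_old Proposal densities at the proposed and current
#'   parameter vectors (`J_new` must be positive).
#' @return Acceptance probability in `[0, 1]`.
#' @export
mh_accept_probability <- function(p_new, p_old, gamma, J_new, J_old) {
  stopifnot(p_old > 0, J_new > 0, gamma >= 0, gamma <= 1)
  if (p_new <= 0) return(0)
  min(1, (p_new / p_old)^gamma * J_old / J_new)
}

new_ensemble <- function(theta, y, logp, weights, gamma, seed) {
  structure(list(theta = theta, y = y, logp = logp, weights = weights,
                 gamma = gamma, seed = seed),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("Particle ensemble: N = %d, gamma = %.4f, ESS = %.1f\n",
              nrow(x$theta), x$gamma, 1 / sum(x$weights^2)))
  invisible(x)
}

target_logp <- function(est, y, valid) {
  lp <- rep(-Inf, nrow(y))
  if (any(valid))
    lp[valid] <- eval_density(est, y[valid, , drop = FALSE],
                              log = TRUE, jacobian = FALSE)
  lp
}

#' Initialise the particle ensemble at gamma = 0
#'
#' Draws `N` parameter vectors uniformly within the bounds (the gamma = 0
#' target), evaluates the forward model, and redraws any particle whose
#' outcome is invalid — invalid models carry zero density for every
#' gamma > 0 and would otherwise be dead weight.
#'
#' @param model A [forward_model()].
#' @param est The data's [fit_density()] estimate.
#' @param N Particle count (>= 2).
#' @param seed Integer seed.
#' @param max_tries Redraw rounds before giving up on an all-invalid model.
#' @return A `particle_ensemble` with equal weights and gamma = 0.
#' @export
initialize_particles <- function(model, est, N, seed = 1, max_tries = 50) {
  if (N < 2) stop("N must be >= 2")
  lo <- model$bounds$lower; hi <- model$bounds$upper
  d <- length(lo)
  set.seed(seed)
  theta <- matrix(runif(N * d, rep(lo, each = N), rep(hi, each = N)), N, d)
  colnames(theta) <- model$param_names
  out <- evaluate_forward(model, theta)
  y <- out$y; valid <- out$valid
  tries <- 0
  while (any(!valid) && tries < max_tries) {
    idx <- which(!valid)
    redraw <- matrix(runif(length(idx) * d, rep(lo, each = length(idx)),
                           rep(hi, each = length(idx))), length(idx), d)
    r <- evaluate_forward(model, redraw)
    theta[idx, ] <- redraw
    y[idx, ] <- r$y
    valid[idx] <- r$valid
    tries <- tries + 1
  }
  if (any(!valid))
    stop("could not find ", sum(!valid), " valid initial particles in ",
         max_tries, " redraw rounds")
  new_ensemble(theta, y, target_logp(est, y, valid),
               rep(1 / N, N), gamma = 0, seed = seed)
}

ess <- function(w) 1 / sum(w^2)

#' Advance the temper exponent to hold the effective sample size
#'
#' Chooses the increment `delta` by bisection so that reweighting by
#' `p(M(theta))^delta` leaves the effective sample size at
#' `ess_frac * N` (capped so gamma never exceeds 1), and returns the
#' reweighted ensemble.
#'
#' @param ens A `particle_ensemble` with gamma < 1.
#' @param ess_frac Target ESS as a fraction of N.
#' @param tol Bisection tolerance on delta.
#' @return The ensemble with updated weights and gamma.
#' @export
temper_step <- function(ens, ess_frac = 0.5, tol = 1e-8) {
  if (ens$gamma >= 1) stop("gamma is already 1")
  if (all(!is.finite(ens$logp)))
    stop("degenerate ensemble: all particles have zero density")
  N <- nrow(ens$theta)
  target <- ess_frac * N
  w_at <- function(delta) {
    lw <- log(ens$weights) + delta * ens$logp
    lw <- lw - max(lw)
    w <- exp(lw)
    w / sum(w)
  }
  d_max <- 1 - ens$gamma
  if (ess(w_at(d_max)) >= target) {
    delta <- d_max
  } else {
    lo <- 0; hi <- d_max
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (ess(w_at(mid)) >= target) lo <- mid else hi <- mid
    }
    delta <- (lo + hi) / 2
  }
  ens$weights <- w_at(delta)
  ens$gamma <- min(ens$gamma + delta, 1)
  ens
}

#' Systematic resampling of the ensemble
#'
#' Draws N particles with a single uniform offset so that the copy count of
#' particle i is either `floor(N w_i)` or `ceiling(N w_i)`; weights reset
#' to 1/N.
#'
#' @param ens A `particle_ensemble`.
#' @return The resampled ensemble.
#' @export
resample <- function(ens) {
  N <- nrow(ens$theta)
  u <- runif(1) / N
  pos <- u + (seq_len(N) - 1) / N
  idx <- findInterval(pos, cumsum(ens$weights)) + 1L
  idx[idx > N] <- N
  new_ensemble(ens$theta[idx, , drop = FALSE], ens$y[idx, , drop = FALSE],
               ens$logp[idx], rep(1 / N, N), ens$gamma, ens$seed)
}

#' Fit the Gaussian-mixture jumping distribution
#'
#' Fits a Gaussian mixture model to a regularised version of the current
#' particle locations: each location is jittered by `jitter_frac` of the
#' per-dimension ensemble standard deviation, the component count is chosen
#' by BIC over `G`, and a covariance floor is added to every component.
#' Falls back to a single Gaussian when the fit fails or too few unique
#' locations remain.
#'
#' @param ens A (resampled) `particle_ensemble`.
#' @param G Candidate component counts.
#' @param jitter_frac Jitter scale as a fraction of the per-dimension SD.
#' @param cov_floor Diagonal floor added to component covariances.
#' @param fit_max Largest number of (jittered) locations used for fitting;
#'   larger ensembles are subsampled for speed.
#' @return Object of class `gmm_proposal`.
#' @export
fit_proposal <- function(ens, G = 1:3, jitter_frac = 0.1, cov_floor = 1e-6,
                         fit_max = 500) {
  X <- ens$theta
  d <- ncol(X)
  sds <- apply(X, 2, sd)
  Xj <- X + matrix(rnorm(length(X)), nrow(X), d) *
    rep(jitter_frac * pmax(sds, sqrt(cov_floor)), each = nrow(X))
  fitX <- if (nrow(Xj) > fit_max) Xj[sample.int(nrow(Xj), fit_max), , drop = FALSE] else Xj
  # Mclust evaluates its model-selection call in the caller's environment,
  # so the selector must be visible there when mclust is not attached
  run_mclust <- function(data, G, modelNames) {
    mclustBIC <- mclust::mclustBIC
    mclust::Mclust(data, G = G, modelNames = modelNames, verbose = FALSE)
  }
  fit <- tryCatch(
    suppressWarnings(run_mclust(
      fitX, G = G, modelNames = if (d == 1) "V" else "VVV")),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) {
    mu <- matrix(colMeans(Xj), d, 1)
    S <- array(stats::cov(Xj), c(d, d, 1))
    pro <- 1
  } else {
    p <- fit$parameters
    pro <- p$pro
    mu <- matrix(p$mean, d, fit$G)
    S <- if (d == 1) array(p$variance$sigmasq, c(1, 1, fit$G))
         else p$variance$sigma
    if (length(dim(S)) == 2) S <- array(S, c(d, d, length(pro)))
  }
  chols <- vector("list", length(pro))
  for (g in seq_along(pro)) {
    S[, , g] <- S[, , g] + diag(cov_floor, d)
    chols[[g]] <- chol(S[, , g])
  }
  structure(list(pro = pro / sum(pro), mean = mu, sigma = S, chol = chols,
                 d = d), class = "gmm_proposal")
}

#' Sample parameter vectors from a fitted proposal
#' @param prop A `gmm_proposal`.
#' @param n Number of draws.
#' @return `n x d` matrix.
#' @export
sample_proposal <- function(prop, n) {
  comp <- sample.int(length(prop$pro), n, replace = TRUE, prob = prop$pro)
  Z <- matrix(rnorm(n * prop$d), n, prop$d)
  X <- matrix(0, n, prop$d)
  for (g in unique(comp)) {
    i <- comp == g
    X[i, ] <- Z[i, , drop = FALSE] %*% prop$chol[[g]] +
      rep(prop$mean[, g], each = sum(i))
  }
  X
}

#' Log density of the proposal at given parameter vectors
#' @param prop A `gmm_proposal`.
#' @param X Matrix of parameter vectors (rows).
#' @return Numeric vector of log densities.
#' @export
dens_proposal <- function(prop, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n <- nrow(X); d <- prop$d
  L <- matrix(-Inf, n, length(prop$pro))
  for (g in seq_along(prop$pro)) {
    R <- prop$chol[[g]]
    Z <- forwardsolve(t(R), t(X) - prop$mean[, g])
    L[, g] <- log(prop$pro[g]) - 0.5 * d * log(2 * pi) -
      sum(log(diag(R))) - 0.5 * colSums(Z^2)
  }
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' Move the ensemble by independence Metropolis-Hastings
#'
#' Applies `n_steps` independence-MH updates to every particle under the
#' tempered target. Proposals outside the bounds or with an invalid
#' forward-map outcome are rejected. When `n_steps` is `NULL`, a one-step
#' pilot estimates the acceptance rate and the total step count is set to
#' `ceiling(log(0.01) / log(1 - p_acc))`, giving each particle a >= 99%
#' chance of moving at least once.
#'
#' @param ens A resampled `particle_ensemble`.
#' @param prop A fitted `gmm_proposal`.
#' @param model The [forward_model()].
#' @param est The data's [fit_density()] estimate.
#' @param n_steps Number of MH updates, or `NULL` for the adaptive rule.
#' @param max_steps Cap on the adaptive step count.
#' @return The moved ensemble; attribute `acc_rate` holds the mean
#'   acceptance rate.
#' @export
mh_move <- function(ens, prop, model, est, n_steps = NULL, max_steps = 100) {
  lo <- model$bounds$lower; hi <- model$bounds$upper
  N <- nrow(ens$theta)
  lJ_old <- dens_proposal(prop, ens$theta)
  one_step <- function(ens, lJ_old) {
    cand <- sample_proposal(prop, N)
    inb <- rowSums(sweep(cand, 2, lo, "<") | sweep(cand, 2, hi, ">")) == 0
    lp_new <- rep(-Inf, N)
    y_new <- matrix(NA_real_, N, ncol(ens$y))
    if (any(inb)) {
      out <- evaluate_forward(model, cand[inb, , drop = FALSE])
      y_new[inb, ] <- out$y
      ok <- rep(FALSE, N); ok[inb] <- out$valid
      lp_new <- target_logp(est, y_new, ok)
    }
    lJ_new <- dens_proposal(prop, cand)
    lr <- ens$gamma * (lp_new - ens$logp) + lJ_old - lJ_new
    acc <- is.finite(lp_new) & (log(runif(N)) < lr)
    ens$theta[acc, ] <- cand[acc, , drop = FALSE]
    ens$y[acc, ] <- y_new[acc, , drop = FALSE]
    ens$logp[acc] <- lp_new[acc]
    lJ_old[acc] <- lJ_new[acc]
    list(ens = ens, lJ_old = lJ_old, acc = mean(acc))
  }
  rates <- numeric(0)
  if (is.null(n_steps)) {
    s <- one_step(ens, lJ_old)
    ens <- s$ens; lJ_old <- s$lJ_old
    rates <- s$acc
    if (s$acc == 0)
      stop("pilot acceptance rate is zero: proposal does not match the target")
    n_steps <- min(ceiling(log(0.01) / log(1 - min(s$acc, 0.999))),
                   max_steps)
    n_rem <- n_steps - 1
  } else n_rem <- n_steps
  for (i in seq_len(n_rem)) {
    s <- one_step(ens, lJ_old)
    ens <- s$ens; lJ_old <- s$lJ_old
    rates <- c(rates, s$acc)
  }
  attr(ens, "acc_rate") <- mean(rates)
  attr(ens, "n_steps") <- length(rates)
  ens
}

#' Calibrate a population of models to a data density by tempered SMC
#'
#' Samples parameter vectors from the sequence of distributions
#' proportional to `p(M(theta))^gamma`, ramping gamma from 0 to 1 by
#' ESS-controlled increments with systematic resampling and adaptive
#' independence-MH move steps after each increment. The final unique
#' particles, with their cached biomarker outputs, form the returned
#' population.
#'
#' Note the pushforward caveat: the result is distributed over parameter
#' space proportionally to `p(M(theta))`; the implied distribution of
#' outputs `M(theta)` is not guaranteed to equal `p(y)`, which is why
#' [anneal_refine()] exists.
#'
#' @param est The data's [fit_density()] estimate.
#' @param model A [forward_model()].
#' @param N Particle count.
#' @param seed Integer seed (all randomness flows from it).
#' @param ess_frac ESS fraction maintained by [temper_step()].
#' @param G Candidate GMM component counts for the proposal.
#' @param max_iter Safety cap on temper iterations.
#' @param rejuvenate Extra adaptive move rounds after gamma reaches 1;
#'   they reduce the residual dependence left by resampling.
#' @param verbose Print per-iteration progress?
#' @return A [pom()] of the unique final particles; provenance records the
#'   gamma schedule, acceptance rates and seed.
#' @export
smc_calibrate <- function(est, model, N = 2000, seed = 1, ess_frac = 0.5,
                          G = 1:3, max_iter = 100, rejuvenate = 1,
                          verbose = FALSE) {
  ens <- initialize_particles(model, est, N, seed)
  gammas <- numeric(0)
  accs <- numeric(0)
  iter <- 0
  while (ens$gamma < 1 && iter < max_iter) {
    iter <- iter + 1
    ens <- temper_step(ens, ess_frac)
    gammas <- c(gammas, ens$gamma)
    ens <- resample(ens)
    prop <- fit_proposal(ens, G = G)
    ens <- mh_move(ens, prop, model, est)
    accs <- c(accs, attr(ens, "acc_rate"))
    if (verbose)
      message(sprintf("  gamma = %.4f, acc = %.3f, unique = %d",
                      ens$gamma, attr(ens, "acc_rate"),
                      nrow(unique(ens$theta))))
  }
  if (ens$gamma < 1)
    stop("temper schedule did not reach gamma = 1 in ", max_iter,
         " iterations")
  for (r in seq_len(rejuvenate)) {
    prop <- fit_proposal(ens, G = G)
    ens <- mh_move(ens, prop, model, est)
    accs <- c(accs, attr(ens, "acc_rate"))
  }
  keep <- !duplicated(ens$theta)
  pom(ens$theta[keep, , drop = FALSE], ens$y[keep, , drop = FALSE],
      provenance = list(method = "smc", model = model$name, N = N,
                        seed = seed, ess_frac = ess_frac,
                        gamma_schedule = gammas, acc_rates = accs,
                        n_unique = sum(keep)))
}
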