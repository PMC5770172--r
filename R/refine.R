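#' Jensen-Shannon distance between two gridded densities
#'
#' The square-rooted, symmetrised Kullback-Leibler divergence of each
#' density against their equal mixture, with all integrals taken as Riemann
#' sums on the shared grid. Bounded by `sqrt(log(2))` (natural logarithms),
#' attained for densities with disjoint support; 0 iff the gridded densities
#' coincide.
#'
#' @param p,q Nonnegative arrays of identical shape (values on a shared
#'   regular grid). They are Riemann-normalised internally.
#' @param cell Grid cell volume.
#' @return Scalar distance in `[0, sqrt(log(2))]`.
#' @export
jsd <- function(p, q, cell = 1) {
  if (!identical(dim(p), dim(q)) || length(p) != length(q))
    stop("p and q must be on the same grid")
  if (any(p < 0) || any(q < 0)) stop("densities must be nonnegative")
  p <- p / (sum(p) * cell)
  q <- q / (sum(q) * cell)
  m <- 0.5 * (p + q)
  ip <- p > 0
  iq <- q > 0
  kl_p <- sum(p[ip] * log(p[ip] / m[ip])) * cell
  kl_q <- sum(q[iq] * log(q[iq] / m[iq])) * cell
  sqrt(max(0.5 * kl_p + 0.5 * kl_q, 0))
}

# Shared-grid KDE machinery used by divergence() and anneal_refine():
# per-dimension grids covering data and POM points, and per-point 1-D
# kernel matrices from which marginal (colMeans) and pairwise
# (crossprod / n) density grids follow exactly for product kernels.
jsd_grids <- function(data_pts, data_H, pom_pts, pom_H, n_bins, expand) {
  d <- ncol(data_pts)
  lapply(seq_len(d), function(k) {
    bw <- max(sqrt(data_H[k]), sqrt(pom_H[k]))
    r <- range(data_pts[, k], pom_pts[, k])
    seq(r[1] - expand * bw, r[2] + expand * bw, length.out = n_bins)
  })
}

kernel_rows <- function(pts, H, grids) {
  lapply(seq_along(grids), function(k)
    outer(pts[, k], grids[[k]],
          function(p, g) dnorm(g, mean = p, sd = sqrt(H[k]))))
}

pom_bandwidth <- function(pts, convention) {
  s2 <- apply(pts, 2, var)
  if (any(s2 <= 0))
    stop("degenerate population: zero variance in dimension ",
         colnames(pts)[s2 <= 0][1])
  h <- optimal_bandwidth(nrow(pts), ncol(pts))
  switch(convention, linear = h * s2, squared = h^2 * s2)
}

# P matrix and its norm from marginal/pairwise density grids.
# marg/pair lists hold POM-side grids; dmarg/dpair the data side.
pmatrix_norm <- function(marg, dmarg, pair, dpair, cells, cell2,
                         deemph, norm_type) {
  d <- length(marg)
  P <- matrix(0, d, d)
  for (i in seq_len(d))
    P[i, i] <- jsd(marg[[i]], dmarg[[i]], cells[i])
  for (nm in names(pair)) {
    ij <- as.integer(strsplit(nm, "_")[[1]])
    v <- jsd(pair[[nm]], dpair[[nm]], cell2[nm])
    P[ij[1], ij[2]] <- P[ij[2], ij[1]] <- v
  }
  value <- if (norm_type == "spectral") norm(P, "2") else norm(P, "F")
  list(P = P, value = value)
}

pair_names <- function(d, deemph) {
  out <- character(0)
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    if (!is.null(deemph) && (i == deemph || j == deemph)) next
    out <- c(out, paste(i, j, sep = "_"))
  }
  out
}

#' Divergence between a population's outputs and the data density
#'
#' Builds, on shared per-dimension grids, kernel density estimates of every
#' marginal and pairwise biomarker distribution for both the population and
#' the data (each side with its own normal-reference bandwidth), fills the
#' symmetric matrix `P` with the marginal Jensen-Shannon distances on its
#' diagonal and the pairwise distances off it, and returns `rho`, the matrix
#' 2-norm of `P`. In `rho_hat` mode the row and column of the de-emphasised
#' dimension (by default `dVdtmax`) are zeroed except for the diagonal,
#' which cannot increase the spectral norm.
#'
#' All densities are computed in the data estimate's transformed space.
#'
#' @param x A [pom()], or a matrix/data frame of biomarker rows.
#' @param data_est The data's [fit_density()] estimate.
#' @param mode `"rho"` or `"rho_hat"`.
#' @param deemph Dimension name or index de-emphasised in `rho_hat` mode.
#' @param n_bins,expand Grid resolution and range extension.
#' @param norm_type `"spectral"` (the matrix 2-norm) or `"frobenius"`.
#' @param pom_H Optional fixed population-side bandwidth (used by the
#'   annealer to keep increments consistent); default recomputes it from
#'   the population's own size and variances.
#' @param range_points Optional matrix of biomarker rows (original space)
#'   whose transformed range defines the grids instead of `x`'s own rows —
#'   lets a subpopulation's divergence be computed on the grids of its
#'   parent pool, matching [anneal_refine()]'s bookkeeping exactly.
#' @return List with the matrix `P`, scalar `value`, and settings.
#' @export
divergence <- function(x, data_est, mode = c("rho", "rho_hat"),
                       deemph = "dVdtmax", n_bins = 128, expand = 3,
                       norm_type = c("spectral", "frobenius"),
                       pom_H = NULL, range_points = NULL) {
  mode <- match.arg(mode)
  norm_type <- match.arg(norm_type)
  Y <- if (inherits(x, "pom")) x$biomarkers else as.matrix(x)
  if (nrow(Y) < 2) stop("population must have at least 2 members")
  pts <- apply_transform(
    Y[, colnames(data_est$points), drop = FALSE], data_est$transform)
  d <- ncol(pts)
  de <- if (mode == "rho_hat") {
    if (is.character(deemph)) match(deemph, colnames(data_est$points))
    else as.integer(deemph)
  } else NULL
  if (mode == "rho_hat" && (is.na(de) || is.null(de)))
    stop("de-emphasised dimension not found")
  if (is.null(pom_H)) pom_H <- pom_bandwidth(pts, data_est$convention)

  rng <- if (is.null(range_points)) pts else
    apply_transform(as.matrix(range_points)[, colnames(data_est$points),
                                            drop = FALSE],
                    data_est$transform)
  grids <- jsd_grids(data_est$points, data_est$H, rng, pom_H, n_bins, expand)
  Kd <- kernel_rows(data_est$points, data_est$H, grids)
  Kp <- kernel_rows(pts, pom_H, grids)
  cells <- vapply(grids, function(g) g[2] - g[1], numeric(1))

  marg <- lapply(Kp, colMeans)
  dmarg <- lapply(Kd, colMeans)
  pn <- pair_names(d, de)
  pair <- dpair <- setNames(vector("list", length(pn)), pn)
  cell2 <- setNames(numeric(length(pn)), pn)
  for (nm in pn) {
    ij <- as.integer(strsplit(nm, "_")[[1]])
    pair[[nm]] <- crossprod(Kp[[ij[1]]], Kp[[ij[2]]]) / nrow(pts)
    dpair[[nm]] <- crossprod(Kd[[ij[1]]], Kd[[ij[2]]]) / nrow(data_est$points)
    cell2[nm] <- cells[ij[1]] * cells[ij[2]]
  }
  res <- pmatrix_norm(marg, dmarg, pair, dpair, cells, cell2, de, norm_type)
  list(P = res$P, value = res$value, mode = mode, deemph = de,
       n_bins = n_bins, norm_type = norm_type, pom_H = pom_H)
}

#' Refinement configuration
#'
#' Settings of the fixed-temperature Metropolis subset selection.
#'
#' @param T Temperature of the acceptance rule `exp(-delta_rho / T)`.
#' @param check_interval Trial steps between wander checks.
#' @param restart_threshold Relative excess over the best divergence that
#'   triggers a restart from the best configuration.
#' @param min_size Minimum population size; `NULL` means "set to the number
#'   of data points" at refinement time.
#' @param step_budget Total trial steps.
#' @return List of class `refinement_config`.
#' @export
refinement_config <- function(T = 0.2, check_interval = 1000,
                              restart_threshold = 0.01, min_size = NULL,
                              step_budget = 200000) {
  if (T <= 0) stop("temperature must be positive")
  if (check_interval < 1 || step_budget < 1) stop("invalid step counts")
  if (!is.null(min_size) && min_size < 1) stop("min_size must be >= 1")
  structure(list(T = T, check_interval = check_interval,
                 restart_threshold = restart_threshold,
                 min_size = min_size, step_budget = step_budget),
            class = "refinement_config")
}

#' Select the best-matching subpopulation by simulated annealing
#'
#' Starting from the full candidate pool, repeatedly proposes toggling the
#' membership of a uniformly chosen candidate (removal, or reintroduction if
#' currently removed) and accepts with probability
#' `min(1, exp(-delta_rho / T))` at fixed temperature. Removals that would
#' shrink the population below `min_size` are rejected outright. Every
#' `check_interval` trials, if the current divergence exceeds the best found
#' by more than `restart_threshold`, the state resets to the best
#' configuration. Returns the best subpopulation visited.
#'
#' The population-side bandwidth is frozen at the full pool's
#' normal-reference value for the whole anneal so that incremental
#' divergence updates are exact; see the package vignette.
#'
#' @param pool Candidate [pom()] (e.g. the SMC output).
#' @param data_est The data's [fit_density()] estimate.
#' @param config A [refinement_config()].
#' @param mode,deemph,n_bins,expand,norm_type As in [divergence()].
#' @param seed Integer seed; the run is fully reproducible.
#' @return The refined `pom`; attributes `rho` (best divergence), `P`, and
#'   `trace` (a data frame `step, rho_current, rho_best`).
#' @export
anneal_refine <- function(pool, data_est, config = refinement_config(),
                          mode = c("rho", "rho_hat"), deemph = "dVdtmax",
                          n_bins = 128, expand = 3,
                          norm_type = c("spectral", "frobenius"),
                          seed = 1) {
  mode <- match.arg(mode)
  norm_type <- match.arg(norm_type)
  stopifnot(inherits(pool, "pom"))
  n_pool <- nrow(pool$theta)
  min_size <- config$min_size
  if (is.null(min_size)) min_size <- nrow(data_est$points)
  if (n_pool <= min_size) {
    out <- pool
    attr(out, "rho") <- divergence(pool, data_est, mode, deemph, n_bins,
                                   expand, norm_type)$value
    attr(out, "trace") <- data.frame(step = 0L,
                                     rho_current = attr(out, "rho"),
                                     rho_best = attr(out, "rho"))
    return(out)
  }
  set.seed(seed)

  pts <- apply_transform(
    pool$biomarkers[, colnames(data_est$points), drop = FALSE],
    data_est$transform)
  d <- ncol(pts)
  de <- if (mode == "rho_hat") {
    if (is.character(deemph)) match(deemph, colnames(data_est$points))
    else as.integer(deemph)
  } else NULL
  pom_H <- pom_bandwidth(pts, data_est$convention)
  grids <- jsd_grids(data_est$points, data_est$H, pts, pom_H, n_bins, expand)
  cells <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  Kp <- kernel_rows(pts, pom_H, grids)
  Kd <- kernel_rows(data_est$points, data_est$H, grids)
  dmarg <- lapply(Kd, colMeans)
  pn <- pair_names(d, de)
  pij <- lapply(pn, function(nm) as.integer(strsplit(nm, "_")[[1]]))
  names(pij) <- pn
  dpair <- setNames(vector("list", length(pn)), pn)
  cell2 <- setNames(numeric(length(pn)), pn)
  for (nm in pn) {
    ij <- pij[[nm]]
    dpair[[nm]] <- crossprod(Kd[[ij[1]]], Kd[[ij[2]]]) / nrow(data_est$points)
    cell2[nm] <- cells[ij[1]] * cells[ij[2]]
  }

  active <- rep(TRUE, n_pool)
  Smarg <- lapply(Kp, colSums)             # un-normalised marginal sums
  Spair <- setNames(vector("list", length(pn)), pn)
  for (nm in pn) {
    ij <- pij[[nm]]
    Spair[[nm]] <- crossprod(Kp[[ij[1]]], Kp[[ij[2]]])
  }

  rho_of <- function(Smarg, Spair, n_act) {
    # incremental subtraction can leave tiny negative residues where the
    # summed kernel mass underflows; clamp before normalising
    marg <- lapply(Smarg, function(s) pmax(s, 0) / n_act)
    pair <- lapply(Spair, function(s) pmax(s, 0) / n_act)
    pmatrix_norm(marg, dmarg, pair, dpair, cells, cell2, de,
                 norm_type)$value
  }

  n_act <- n_pool
  rho_cur <- rho_of(Smarg, Spair, n_act)
  rho_best <- rho_cur
  best_active <- active
  trace_step <- integer(0); trace_cur <- numeric(0); trace_best <- numeric(0)
  any_accept <- FALSE
  Tq <- config$T

  for (step in seq_len(config$step_budget)) {
    m <- sample.int(n_pool, 1)
    removing <- active[m]
    if (removing && n_act <= min_size) {
      # removal would violate the size constraint: rejected outright
    } else {
      sgn <- if (removing) -1 else 1
      S2m <- Smarg
      for (k in seq_len(d)) S2m[[k]] <- S2m[[k]] + sgn * Kp[[k]][m, ]
      S2p <- Spair
      for (nm in pn) {
        ij <- pij[[nm]]
        S2p[[nm]] <- S2p[[nm]] +
          sgn * outer(Kp[[ij[1]]][m, ], Kp[[ij[2]]][m, ])
      }
      n2 <- n_act + sgn
      rho_new <- rho_of(S2m, S2p, n2)
      if (runif(1) < exp(-(rho_new - rho_cur) / Tq)) {
        active[m] <- !removing
        Smarg <- S2m; Spair <- S2p; n_act <- n2; rho_cur <- rho_new
        any_accept <- TRUE
        if (rho_cur < rho_best) {
          rho_best <- rho_cur
          best_active <- active
        }
      }
    }
    if (step %% config$check_interval == 0) {
      trace_step <- c(trace_step, step)
      trace_cur <- c(trace_cur, rho_cur)
      trace_best <- c(trace_best, rho_best)
      if (rho_cur > (1 + config$restart_threshold) * rho_best) {
        active <- best_active
        n_act <- sum(active)
        for (k in seq_len(d)) Smarg[[k]] <- colSums(Kp[[k]][active, , drop = FALSE])
        for (nm in pn) {
          ij <- pij[[nm]]
          Spair[[nm]] <- crossprod(Kp[[ij[1]]][active, , drop = FALSE],
                                   Kp[[ij[2]]][active, , drop = FALSE])
        }
        rho_cur <- rho_best
      }
    }
  }
  if (!any_accept)
    warning("step budget exhausted without any accepted move; returning the pool",
            call. = FALSE)

  out <- subset_pom(pool, best_active)
  out$provenance <- c(pool$provenance,
                      list(refine = mode, T = config$T, seed = seed,
                           rho = rho_best))
  attr(out, "rho") <- rho_best
  attr(out, "pom_H") <- pom_H
  attr(out, "trace") <- data.frame(step = trace_step,
                                   rho_current = trace_cur,
                                   rho_best = trace_best)
  out
}
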