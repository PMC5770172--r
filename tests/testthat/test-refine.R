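test_that("Jensen-Shannon distance meets its bounds and symmetry", {
  g <- seq(-6, 6, length.out = 400)
  cell <- g[2] - g[1]
  p <- dnorm(g, 0, 1)
  q <- dnorm(g, 1, 1)
  expect_equal(jsd(p, p, cell), 0)
  expect_equal(jsd(p, q, cell), jsd(q, p, cell))

  # disjoint supports attain the maximum sqrt(log(2))
  a <- c(rep(1, 200), rep(0, 200))
  b <- rev(a)
  expect_equal(jsd(a, b, cell), sqrt(log(2)), tolerance = 1e-6)
  expect_true(jsd(p, q, cell) >= 0 && jsd(p, q, cell) <= sqrt(log(2)))
  expect_error(jsd(p, q[-1]), "same grid")
})

test_that("gridded JSD of two Gaussians matches adaptive quadrature", {
  # independent oracle: adaptive quadrature of the defining integral
  f_p <- function(x) dnorm(x, 0, 1)
  f_q <- function(x) dnorm(x, 1, 1)
  integrand <- function(x, fa, fb) {
    fx <- fa(x); m <- 0.5 * (fa(x) + fb(x))
    ifelse(fx > 0, fx * log(fx / m), 0)
  }
  kl_p <- stats::integrate(integrand, -10, 10, fa = f_p, fb = f_q,
                           rel.tol = 1e-10)$value
  kl_q <- stats::integrate(integrand, -10, 10, fa = f_q, fb = f_p,
                           rel.tol = 1e-10)$value
  oracle <- sqrt(0.5 * kl_p + 0.5 * kl_q)
  g <- seq(-8, 9, length.out = 2000)
  expect_equal(jsd(f_p(g), f_q(g), g[2] - g[1]), oracle, tolerance = 1e-3)
})

test_that("divergence is zero for identical empirical sets and rho_hat <= rho", {
  d <- generate_dataset(80, "SR", seed = 14)
  est <- fit_density(d)
  same <- pom(matrix(seq_len(80), ncol = 1, dimnames = list(NULL, "id")),
              as.matrix(d))
  dv <- divergence(same, est, n_bins = 64)
  expect_lt(dv$value, 1e-8)
  expect_true(all(abs(dv$P) < 1e-8))

  other <- pom(matrix(1:80, ncol = 1, dimnames = list(NULL, "id")),
               as.matrix(generate_dataset(80, "cAF", seed = 15)))
  rho <- divergence(other, est, mode = "rho", n_bins = 48)
  rho_hat <- divergence(other, est, mode = "rho_hat", n_bins = 48)
  expect_lte(rho_hat$value, rho$value + 1e-12)
  # the de-emphasised row/column is zero except its diagonal
  de <- rho_hat$deemph
  offdiag <- rho_hat$P[de, -de]
  expect_true(all(offdiag == 0))
  expect_gte(rho_hat$P[de, de], 0)
  expect_true(isSymmetric(rho$P))
  expect_true(all(rho$P >= 0 & rho$P <= sqrt(log(2)) + 1e-12))
})

test_that("a KDE-matched population diverges less than a uniform one", {
  d <- generate_dataset(150, "SR", seed = 16)
  est <- fit_density(d)
  box <- range_box(d)
  wins <- logical(100)
  for (s in seq_len(100)) {
    set.seed(s)
    from_kde <- sample_density(est, 500)
    unif <- sapply(seq_len(7), function(k)
      runif(500, box[1, k], box[2, k]))
    colnames(unif) <- colnames(d)
    r_kde <- divergence(from_kde, est, n_bins = 32)$value
    r_unif <- divergence(unif, est, n_bins = 32)$value
    wins[s] <- r_kde < r_unif
  }
  expect_gte(mean(wins), 0.95)
})

test_that("annealing respects the size constraint and only improves", {
  d2 <- cbind(u = rnorm(40, 0, 1), v = rnorm(40, 5, 2))
  set.seed(100); d2 <- cbind(u = rnorm(40), v = rnorm(40, 5, 2))
  est <- fit_density(d2, transform = "identity")
  pool_y <- rbind(sample_density(est, 20),
                  sweep(sample_density(est, 20), 2, c(4, 8), "+"))
  pool <- pom(matrix(seq_len(40), ncol = 1, dimnames = list(NULL, "id")),
              pool_y)

  # pool already at min_size: returned unchanged
  small <- subset_pom(pool, 1:12)
  out_small <- anneal_refine(small, est,
                             refinement_config(min_size = 12,
                                               step_budget = 10),
                             n_bins = 24, seed = 1)
  expect_equal(nrow(out_small$theta), 12)
  expect_identical(out_small$theta, small$theta)

  cfg <- refinement_config(min_size = 15, step_budget = 3000,
                           check_interval = 250)
  ref <- anneal_refine(pool, est, cfg, n_bins = 24, seed = 3)
  tr <- attr(ref, "trace")
  expect_true(all(diff(tr$rho_best) <= 0))
  expect_gte(nrow(ref$theta), 15)
  rho_pool <- divergence(pool, est, n_bins = 24,
                         pom_H = attr(ref, "pom_H"),
                         range_points = pool$biomarkers)$value
  expect_lte(attr(ref, "rho"), rho_pool)

  # reproducibility
  ref2 <- anneal_refine(pool, est, cfg, n_bins = 24, seed = 3)
  expect_identical(ref$theta, ref2$theta)
  expect_equal(attr(ref, "rho"), attr(ref2, "rho"))

  # near-zero temperature is greedy: every accepted move improves, so the
  # current rho trace equals the best trace
  cold <- anneal_refine(pool, est,
                        refinement_config(T = 1e-9, min_size = 15,
                                          step_budget = 2000,
                                          check_interval = 100),
                        n_bins = 24, seed = 4)
  trc <- attr(cold, "trace")
  expect_true(all(abs(trc$rho_current - trc$rho_best) < 1e-12))
})

test_that("incremental divergence bookkeeping matches full recomputation", {
  d2 <- local({set.seed(7); cbind(u = rnorm(30), v = rnorm(30, 2))})
  est <- fit_density(d2, transform = "identity")
  pool <- pom(matrix(seq_len(25), ncol = 1, dimnames = list(NULL, "id")),
              local({set.seed(8); sample_density(est, 25)}))
  ref <- anneal_refine(pool, est,
                       refinement_config(min_size = 10, step_budget = 500,
                                         check_interval = 100),
                       n_bins = 32, seed = 5)
  full <- divergence(ref, est, n_bins = 32, pom_H = attr(ref, "pom_H"),
                     range_points = pool$biomarkers)$value
  expect_equal(attr(ref, "rho"), full, tolerance = 1e-10)
})

test_that("annealing agrees with the exhaustive-subset oracle", {
  # 12 candidates: 6 drawn from the data KDE, 6 shifted far outside;
  # brute force over all subsets of size >= 6 under the frozen objective
  set.seed(60)
  d2 <- cbind(u = rnorm(30, 0, 1), v = rnorm(30, 3, 1.5))
  est <- fit_density(d2, transform = "identity")
  good <- sample_density(est, 6)
  bad <- sweep(sample_density(est, 6), 2,
               5 * apply(d2, 2, sd), "+")
  pool <- pom(matrix(seq_len(12), ncol = 1, dimnames = list(NULL, "id")),
              rbind(good, bad))
  pom_H <- pomcal:::pom_bandwidth(pool$biomarkers, est$convention)

  subset_rho <- function(active) {
    divergence(subset_pom(pool, active), est, n_bins = 24,
               pom_H = pom_H, range_points = pool$biomarkers)$value
  }
  best_rho <- Inf; best_set <- NULL
  for (k in 6:12) {
    for (cols in utils::combn(12, k, simplify = FALSE)) {
      r <- subset_rho(cols)
      if (r < best_rho) { best_rho <- r; best_set <- cols }
    }
  }
  hits <- logical(50)
  for (s in seq_len(50)) {
    ref <- anneal_refine(pool, est,
                         refinement_config(min_size = 6, step_budget = 6000,
                                           check_interval = 200),
                         n_bins = 24, seed = s)
    hits[s] <- setequal(ref$theta[, 1], best_set)
  }
  expect_gte(mean(hits), 0.9)
})
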