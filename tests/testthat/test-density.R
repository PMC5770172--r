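test_that("bandwidth factor matches the normal-reference rule", {
  expect_equal(optimal_bandwidth(1, 2), 1)           # (4/4)^(2/6)
  # direct evaluation of the rule at the study's sample size/dimension
  expect_equal(optimal_bandwidth(469, 7), 0.2820324, tolerance = 1e-6)
  expect_lt(optimal_bandwidth(1000, 7), optimal_bandwidth(100, 7))
  expect_error(optimal_bandwidth(0, 7), "positive")
})

test_that("fitting is deterministic and applies the APD20 log transform", {
  d <- generate_dataset(200, "SR", seed = 4)
  e1 <- fit_density(d)
  e2 <- fit_density(d)
  expect_identical(e1$points, e2$points)
  expect_identical(e1$H, e2$H)
  expect_equal(unname(e1$transform["APD20"]), "log")
  expect_equal(e1$points[, "APD20"], log(d$APD20), ignore_attr = TRUE)
  # a point outside the log domain has zero density
  y <- as.numeric(d[1, ]); names(y) <- names(d)
  y["APD20"] <- -1
  expect_equal(eval_density(e1, y), 0)
  # paper vs squared convention differ by a factor h_opt
  es <- fit_density(d, bandwidth_convention = "squared")
  expect_equal(es$H / e1$H, rep(es$h_opt, 7), ignore_attr = TRUE)
})

test_that("degenerate data are refused with the dimension named", {
  d <- generate_dataset(50, "SR", seed = 1)
  d$APA <- 100
  expect_error(fit_density(d), "APA")
})

test_that("kernel evaluation matches closed forms", {
  # single kernel at its centre: (2*pi)^(-7/2) for identity bandwidth
  est <- manual_kde(matrix(0, 1, 7), H = rep(1, 7))
  expect_equal(eval_density(est, rep(0, 7)), (2 * pi)^(-7 / 2))
  # kernel symmetry about a lone datum
  expect_equal(eval_density(est, c(1, rep(0, 6))),
               eval_density(est, c(-1, rep(0, 6))))
})

test_that("the density integrates to one", {
  d <- generate_dataset(150, "SR", seed = 8)
  est <- fit_density(d)
  # defensive importance sampling: half KDE draws, half a wide Gaussian,
  # so the weight p/q is bounded and the estimate of the integral is stable
  set.seed(42)
  n <- 40000
  mu <- colMeans(as.matrix(d)); sd2 <- 2 * apply(as.matrix(d), 2, sd)
  from_kde <- sample_density(est, n / 2)
  from_wide <- matrix(rnorm(n / 2 * 7, rep(mu, each = n / 2),
                            rep(sd2, each = n / 2)), n / 2, 7,
                      dimnames = list(NULL, names(d)))
  x <- rbind(from_kde, from_wide)
  dens_wide <- function(x)
    exp(rowSums(dnorm(x, rep(mu, each = nrow(x)),
                      rep(sd2, each = nrow(x)), log = TRUE)))
  p <- q <- numeric(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 5000))) {
    p[chunk] <- eval_density(est, x[chunk, ])
    q[chunk] <- 0.5 * p[chunk] + 0.5 * dens_wide(x[chunk, , drop = FALSE])
  }
  expect_equal(mean(p / q), 1, tolerance = 0.01)
})

test_that("scale equivariance holds for identity-transform dimensions", {
  d <- generate_dataset(80, "cAF", seed = 9)   # no log transform needed
  est <- fit_density(d, transform = "identity")
  c0 <- 3.7
  d2 <- d; d2$APA <- d2$APA * c0
  est2 <- fit_density(d2, transform = "identity")
  expect_equal(est2$sigma2[["APA"]], c0^2 * est$sigma2[["APA"]])
  y <- as.numeric(d[5, ]); y2 <- y; y2[4] <- y2[4] * c0
  expect_equal(eval_density(est2, y2), eval_density(est, y) / c0)
})

test_that("gridded marginals are normalised, symmetric and consistent", {
  d <- generate_dataset(100, "SR", seed = 10)
  est <- fit_density(d)
  g1 <- grid_density(est, "APD90", n_bins = 128)
  expect_equal(sum(g1$values) * g1$cell, 1, tolerance = 0.01)
  g2 <- grid_density(est, c("APD50", "APD90"), n_bins = 96)
  expect_equal(sum(g2$values) * g2$cell, 1, tolerance = 0.01)
  expect_error(grid_density(est, integer(0)), "dims")
  expect_error(grid_density(est, c(1, 2, 3)), "dims")

  # symmetric two-point dataset: marginal symmetric about the midpoint
  est_sym <- manual_kde(cbind(y1 = c(-1, 1)), H = c(y1 = 0.5))
  gs <- grid_density(est_sym, 1, n_bins = 101)
  expect_equal(gs$values, rev(gs$values))

  # marginalising the 2-D grid recovers the 1-D marginal
  gm <- grid_density(est, c("APD50", "APD90"), n_bins = 128, expand = 5)
  g50 <- grid_density(est, "APD50", n_bins = 128, expand = 5)
  marg <- rowSums(gm$values) * (gm$axes[[2]][2] - gm$axes[[2]][1])
  expect_lt(max(abs(marg - g50$values)), 1e-3)
})

test_that("pairwise KDE factorises for crossed independent-dimension data", {
  x1 <- seq(-1, 1, length.out = 8)
  x2 <- seq(2, 4, length.out = 8)
  crossed <- as.matrix(expand.grid(u = x1, v = x2))
  est <- fit_density(crossed, transform = "identity")
  g2 <- grid_density(est, c("u", "v"), n_bins = 40)
  m1 <- grid_density(est, "u", n_bins = 40)
  m2 <- grid_density(est, "v", n_bins = 40)
  expect_equal(g2$values, outer(m1$values, m2$values), tolerance = 1e-10)
})

test_that("KDE converges towards a known Gaussian with sample size", {
  true_d <- function(x) dnorm(x[, 1]) * dnorm(x[, 2])
  grid <- as.matrix(expand.grid(a = seq(-2, 2, 0.5), b = seq(-2, 2, 0.5)))
  sup_err <- sapply(c(100, 10000), function(n) {
    set.seed(n)
    x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
    est <- fit_density(x, transform = "identity",
                       bandwidth_convention = "squared")
    max(abs(eval_density(est, grid) - true_d(grid)))
  })
  expect_lt(sup_err[2], sup_err[1])
})

test_that("densities from an analytic wrapper evaluate directly", {
  a <- analytic_density(function(y) ifelse(y >= 0 & y <= 1, 1, 0), d = 1)
  expect_equal(eval_density(a, 0.3), 1)
  expect_equal(eval_density(a, 1.7), 0)
  expect_equal(eval_density(a, c(0.1, 0.5), log = TRUE), c(0, 0))
})
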