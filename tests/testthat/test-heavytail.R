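test_that("alpha-stable sampler hits its Gaussian and Cauchy special cases", {
  set.seed(1)
  # alpha = 2 is Gaussian with variance 2 scale^2
  g <- sample_alpha_stable(2e5, 2, scale = 1.5)
  expect_equal(var(g), 2 * 1.5^2, tolerance = 0.05)
  expect_equal(mean(g), 0, tolerance = 0.05)
  # alpha = 1 is Cauchy: quartiles at +/- scale, median 0
  ca <- sample_alpha_stable(2e5, 1, scale = 2)
  expect_equal(median(ca), 0, tolerance = 0.1)
  expect_equal(unname(quantile(ca, 0.75)), 2, tolerance = 0.1)
  expect_equal(unname(quantile(ca, 0.25)), -2, tolerance = 0.1)
  # determinism and parameter validation
  set.seed(9); a <- sample_alpha_stable(100, 1.5)
  set.seed(9); b <- sample_alpha_stable(100, 1.5)
  expect_identical(a, b)
  expect_error(sample_alpha_stable(10, 0), "alpha")
  expect_error(sample_alpha_stable(10, 2.5), "alpha")
  expect_error(sample_alpha_stable(10, 1.5, scale = -1), "scale")
})

test_that("Levy-driven mean-reverting trajectories match Gaussian closed forms", {
  set.seed(2)
  # Gaussian case: stationary variance = scale^2 / drift_rate
  tr <- simulate_ou_levy(2, drift_rate = 0.5, scale = 1,
                         n_steps = 2e5, dt = 0.05)
  expect_equal(var(tr[-(1:2000), 1]), 1 / 0.5, tolerance = 0.1)
  # no drift, alpha = 2: variance grows linearly (Brownian scaling)
  set.seed(3)
  nrep <- 400
  ends <- replicate(nrep, {
    x <- simulate_ou_levy(2, 0, 1, n_steps = 100, dt = 0.1)
    c(x[51, 1], x[101, 1])
  })
  v_half <- var(ends[1, ]); v_full <- var(ends[2, ])
  expect_equal(v_full / v_half, 2, tolerance = 0.35)
  # heavier tails (smaller alpha) give larger increment kurtosis
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  set.seed(4)
  ks <- vapply(c(2.0, 1.7, 1.4, 1.1), function(a) {
    mean(replicate(5, {
      tr <- simulate_ou_levy(a, 0.5, 1, n_steps = 2e4, dt = 0.05)
      kurt(diff(tr[, 1]))
    }))
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  # 3-D support
  tr3 <- simulate_ou_levy(1.5, 0.1, 1, n_steps = 50, dims = 3)
  expect_equal(dim(tr3), c(51, 3))
})

test_that("the jump-driven membrane SDE matches its deterministic and shot-noise laws", {
  # deterministic limit: pure exponential decay
  out <- simulate_membrane_sde(W = 1, lambda_pre = 0, tau = 2,
                               T_total = 4, dt = 1e-3, x0 = 3)
  expect_equal(out$X[length(out$X)], 3 * exp(-4 / 2), tolerance = 1e-2)
  expect_length(out$post_spike_times, 0)
  # fixed point at zero
  out0 <- simulate_membrane_sde(W = 0, lambda_pre = 5, tau = 1,
                                T_total = 1, dt = 1e-3, x0 = 0)
  expect_true(all(out0$X == 0))
  # shot-noise stationary mean E[X] = W lambda tau
  set.seed(5)
  out2 <- simulate_membrane_sde(W = 0.5, lambda_pre = 20, tau = 0.05,
                                T_total = 400, dt = 5e-4, x0 = 0)
  burn <- out2$time > 1
  expect_equal(mean(out2$X[burn]), 0.5 * 20 * 0.05, tolerance = 0.05)
  # post-spike process fires and drops the potential
  set.seed(6)
  out3 <- simulate_membrane_sde(W = 1, lambda_pre = 50, tau = 0.1,
                                beta_fn = function(x) 10 * max(x, 0),
                                T_total = 20, dt = 1e-3)
  expect_gt(length(out3$post_spike_times), 0)
})

test_that("the block log-moment estimator recovers stability indices", {
  set.seed(7)
  n <- 223^2  # an exact K x m block factorization
  # Gaussian input sits at the upper boundary
  expect_gt(estimate_tail_index(rnorm(n)), 1.85)
  # Cauchy input near 1
  expect_equal(as.numeric(estimate_tail_index(sample_alpha_stable(n, 1))),
               1, tolerance = 0.12)
  # intermediate stable law
  expect_equal(as.numeric(estimate_tail_index(sample_alpha_stable(n, 1.5))),
               1.5, tolerance = 0.12)
  # monotone in the true index
  est <- vapply(c(1.1, 1.4, 1.7, 2.0), function(a)
    as.numeric(estimate_tail_index(sample_alpha_stable(n, a))),
    numeric(1))
  expect_true(all(diff(est) > 0))
  # degenerate and malformed inputs
  expect_error(estimate_tail_index(rep(1, 100)), "constant")
  expect_error(estimate_tail_index(rnorm(10), m = 9), "blocks")
  expect_warning(estimate_tail_index(rnorm(1003), m = 10), "trailing")
})

test_that("the BG index is the per-group maximum and is scale invariant", {
  set.seed(8)
  x1 <- sample_alpha_stable(1e4, 1.2)
  x2 <- sample_alpha_stable(1e4, 1.8)
  rep1 <- bg_index(x1)
  expect_equal(rep1$bg_index, unname(rep1$alpha_hat[1]))
  rep2 <- bg_index(c(x1, x2), grouping = rep(1:2, each = 1e4))
  expect_equal(rep2$bg_index, max(rep2$alpha_hat))
  expect_lt(rep2$alpha_hat[1], rep2$alpha_hat[2])
  # scaling all increments by a positive constant leaves the index alone
  rep3 <- bg_index(5.7 * x1)
  expect_equal(rep3$bg_index, rep1$bg_index, tolerance = 1e-10)
  # always in (0, 2]
  g <- bg_index(rnorm(1e4))
  expect_lte(g$bg_index, 2)
  expect_gt(g$bg_index, 0)
  # trajectory input uses the final-iteration increments
  snaps <- rbind(rep(0, 1000), rep(0.5, 1000), rep(0.5, 1000) + x1[1:1000])
  wt <- weight_trajectory(snaps)
  suppressWarnings(
    expect_equal(bg_index(wt)$bg_index,
                 as.numeric(estimate_tail_index(x1[1:1000]))))
  expect_error(bg_index(weight_trajectory(snaps[1, , drop = FALSE])),
               "snapshots")
})

test_that("the Gaussian KDE matches its closed form and normalizes", {
  # single point at zero, unit bandwidth: density 1/sqrt(2 pi) at zero
  d <- kde_pdf(0, grid = 0, t = 1)
  expect_equal(d$density, 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(d$density, 0.39894, tolerance = 1e-4)
  # integrates to one
  set.seed(10)
  vals <- rnorm(200)
  grid <- seq(-8, 8, length.out = 2001)
  dd <- kde_pdf(vals, grid = grid, t = 0.3)
  integral <- sum(dd$density) * diff(grid)[1]
  expect_equal(integral, 1, tolerance = 1e-3)
  # symmetric samples give a symmetric estimate
  ds <- kde_pdf(c(-2, 2), grid = seq(-4, 4, length.out = 81), t = 0.5)
  expect_equal(ds$density, rev(ds$density), tolerance = 1e-12)
  # histogram limit: sup grows like t^{-1/2} as t -> 0
  sup1 <- max(kde_pdf(c(-1, 1), grid = c(-1, 1), t = 1e-2)$density)
  sup2 <- max(kde_pdf(c(-1, 1), grid = c(-1, 1), t = 1e-4)$density)
  expect_equal(sup2 / sup1, 10, tolerance = 0.01)
})
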