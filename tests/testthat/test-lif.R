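test_that("passive membrane decay matches the closed form with first-order convergence", {
  p <- neuron_params("excitatory")
  horizon <- 100  # ms
  run_decay <- function(dt) {
    s <- neuron_state(1, p)
    s$X <- p$v_thresh  # start at threshold, no conductance
    for (k in seq_len(round(horizon / dt)))
      s <- step_membrane(s, p, dt, t_now = k * dt)
    s$X
  }
  closed <- p$E_rest + (p$v_thresh - p$E_rest) * exp(-horizon / p$tau_m)
  err1 <- abs(run_decay(0.2) - closed)
  err2 <- abs(run_decay(0.1) - closed)
  err3 <- abs(run_decay(0.05) - closed)
  expect_lt(err1, 0.05)  # integrator tolerance at dt = 0.2 ms
  # halving dt halves the error (explicit Euler is first order)
  expect_equal(err1 / err2, 2, tolerance = 0.15)
  expect_equal(err2 / err3, 2, tolerance = 0.15)
})

test_that("membrane stays within the reversal-potential bounds", {
  p <- neuron_params("excitatory")
  s <- neuron_state(1, p)
  xs <- numeric(200)
  for (k in seq_len(200)) {
    s$g_e <- 100  # strong sustained excitatory drive
    s <- step_membrane(s, p, 0.2, t_now = k * 0.2)
    xs[k] <- s$X
  }
  expect_true(all(xs <= p$E_exc))
  expect_true(all(diff(xs) >= 0))  # monotone approach toward E_exc
  # inhibitory side
  s2 <- neuron_state(1, p)
  for (k in seq_len(200)) {
    s2$g_i <- 100
    s2 <- step_membrane(s2, p, 0.2, t_now = k * 0.2)
  }
  expect_gte(s2$X, p$E_inh)
  # resting fixed point
  s3 <- neuron_state(1, p)
  for (k in seq_len(50)) s3 <- step_membrane(s3, p, 0.5, t_now = k * 0.5)
  expect_equal(s3$X, p$E_rest)
  # dt precondition and non-finite detection
  expect_error(step_membrane(s3, p, 30), "dt")
  s3$X <- NaN
  expect_error(step_membrane(s3, p, 0.5), "neuron index 1")
})

test_that("spike delivery increments conductances by the connecting weights", {
  p <- neuron_params("excitatory")
  s <- neuron_state(3, p)
  W <- matrix(c(0.2, 0.3, 0.1,
                0.5, 0.0, 0.4), nrow = 2, byrow = TRUE)
  s1 <- deliver_spikes(s, W, 1L, "excitatory")
  expect_equal(s1$g_e, W[1, ])
  expect_equal(s1$X, s$X)  # membrane untouched
  # simultaneous spikes add
  s2 <- deliver_spikes(s, W, c(1L, 2L), "excitatory")
  expect_equal(s2$g_e, colSums(W))
  # empty spike list is the identity
  expect_identical(deliver_spikes(s, W, integer(0), "excitatory"), s)
  # inhibitory routing and invariant checks
  s3 <- deliver_spikes(s, W, 2L, "inhibitory")
  expect_equal(s3$g_i, W[2, ])
  expect_error(deliver_spikes(s, W, 5L), "out of range")
  Wneg <- W; Wneg[1, 1] <- -0.1
  expect_error(deliver_spikes(s, Wneg, 1L), "negative")
})

test_that("firing uses the adaptive threshold, resets, and respects refractoriness", {
  p <- neuron_params("excitatory", theta_inc = 1, tau_theta = 1e4,
                     t_refrac = 5)
  s <- neuron_state(2, p)
  # just below threshold: no spike, theta only decays
  s$X <- c(p$v_thresh - 1e-6, p$E_rest)
  r <- fire_and_reset(s, p, t_now = 0, dt = 0.5)
  expect_length(r$spikes, 0)
  # at threshold: spike, reset, homeostatic increment, refractory armed
  s$X[1] <- p$v_thresh
  r <- fire_and_reset(s, p, t_now = 0, dt = 0.5)
  expect_equal(r$spikes, 1L)
  expect_equal(r$state$X[1], p$v_reset)
  expect_equal(r$state$refrac_until[1], 5)
  expect_gt(r$state$theta[1], 0.99)
  # second firing needs strictly larger X than the first did
  s2 <- r$state
  s2$X[1] <- p$v_thresh
  s2$refrac_until[1] <- -Inf
  r2 <- fire_and_reset(s2, p, t_now = 10, dt = 0.5)
  expect_length(r2$spikes, 0)
  s2$X[1] <- p$v_thresh + s2$theta[1]
  r3 <- fire_and_reset(s2, p, t_now = 10, dt = 0.5)
  expect_equal(r3$spikes, 1L)
  # above threshold but refractory: no spike
  s3 <- neuron_state(1, p)
  s3$X <- p$v_thresh + 10
  s3$refrac_until <- 3
  r4 <- fire_and_reset(s3, p, t_now = 1, dt = 0.5)
  expect_length(r4$spikes, 0)
})

test_that("network topology obeys the lateral-inhibition combinatorics", {
  expect_error(build_network(4, 1), "n_exc")
  n2 <- build_network(4, 2, seed = 3)
  expect_equal(n_inh_to_exc(n2), 2L)
  n100 <- build_network(16, 100, seed = 3)
  expect_equal(n_inh_to_exc(n100), 9900L)  # n (n - 1)
  # reproducible initialization; weights within bounds
  n100b <- build_network(16, 100, seed = 3)
  expect_identical(n100$input_to_exc, n100b$input_to_exc)
  expect_true(all(n100$input_to_exc >= 0 & n100$input_to_exc <= 1))
  n_diff <- build_network(16, 100, seed = 4)
  expect_false(identical(n100$input_to_exc, n_diff$input_to_exc))
})

test_that("the compiled kernel reproduces the R membrane primitives without input", {
  # with no input spikes, subthreshold drive, and plasticity off, the
  # kernel must evolve the excitatory layer exactly as the R-level
  # step/fire primitives do
  p_exc <- neuron_params("excitatory", theta_inc = 0)
  p_inh <- inh_pars()
  net <- build_network(4, 3, seed = 5)
  cfg <- mini_stdp("log")
  st <- network_state(net, p_exc, p_inh)
  st$ge_e <- c(0.2, 0.1, 0)   # subthreshold conductance, decays freely
  res <- run_presentation(net, p_exc, p_inh, cfg,
                          rates = rep(0, 4), state = st, duration = 20,
                          dt = 0.5, plastic = FALSE, min_spikes = 0)
  # R reference: same operations in the same order
  s <- neuron_state(3, p_exc)
  s$g_e <- c(0.2, 0.1, 0)
  for (k in seq_len(40)) {
    s <- step_membrane(s, p_exc, 0.5, t_now = (k - 1) * 0.5)
    fr <- fire_and_reset(s, p_exc, t_now = (k - 1) * 0.5, dt = 0)
    s <- fr$state
  }
  expect_equal(sum(res$spike_counts), 0)
  expect_equal(sum(s$spike_count), 0)
  expect_equal(res$state$Xe, s$X, tolerance = 1e-12)
  expect_equal(res$state$ge_e, s$g_e, tolerance = 1e-12)
})

test_that("presentation protocol boosts silent inputs and freezes frozen weights", {
  p_exc <- exc_pars(); p_inh <- inh_pars()
  net <- build_network(16, 4, seed = 2)
  cfg <- mini_stdp("log")
  # zero rates with a boost cap: divergence error naming the cap
  expect_error(
    run_presentation(net, p_exc, p_inh, cfg, rates = rep(0, 16),
                     max_boosts = 1),
    "boost")
  # frozen rule: weights identical before and after presentation
  set.seed(8)
  res <- run_presentation(net, p_exc, p_inh, cfg,
                          rates = rep(40, 16), plastic = FALSE)
  expect_identical(res$W, net$input_to_exc)
  # plastic run changes the weights
  set.seed(8)
  res2 <- run_presentation(net, p_exc, p_inh, cfg,
                           rates = rep(40, 16), plastic = TRUE)
  expect_false(identical(res2$W, net$input_to_exc))
})

test_that("lateral inhibition propagates through the partner inhibitory neuron", {
  p_exc <- exc_pars(theta_inc = 0)
  p_inh <- inh_pars()
  cfg <- mini_stdp("log")
  n_exc <- 4
  net <- build_network(4, n_exc, seed = 1)
  # single strong input wired to excitatory neuron 1 only
  net$input_to_exc <- matrix(0, 4, n_exc)
  net$input_to_exc[, 1] <- 1
  set.seed(3)
  res <- run_presentation(net, p_exc, p_inh, cfg,
                          rates = rep(200, 4), plastic = FALSE,
                          min_spikes = 1)
  expect_gt(res$spike_counts[1], 0)
  expect_equal(sum(res$spike_counts[-1]), 0)
  # its partner inhibitory neuron fired, and the others received g_i
  expect_gt(res$inh_counts[1], 0)
  expect_gt(max(res$state$gi_e[-1]), 0)
})

test_that("homeostasis equalizes firing rates across repeated presentations", {
  cfg <- mini_stdp("log")
  p_inh <- inh_pars()
  net <- build_network(16, 8, seed = 21)
  img_rates <- rep(c(60, 10), each = 8)
  run_total <- function(theta_inc) {
    p_exc <- exc_pars(theta_inc = theta_inc)
    st <- network_state(net, p_exc, p_inh)
    counts <- integer(8)
    set.seed(99)
    for (rep in 1:12) {
      st <- relax_state(st, p_exc, p_inh, cfg, 150)
      res <- run_presentation(net, p_exc, p_inh, cfg, img_rates,
                              state = st, plastic = TRUE, min_spikes = 0)
      st <- res$state
      counts <- counts + res$spike_counts
    }
    counts
  }
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(run_total(2)), cv(run_total(0)))
})
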