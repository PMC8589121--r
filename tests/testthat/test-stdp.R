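test_that("scaling functions match their closed forms for all three rules", {
  add <- stdp_config("add", c_plus = 1, c_minus = 0.6)
  mult <- stdp_config("mult", c_plus = 1, c_minus = 2, W0 = 0.25)
  logr <- stdp_config("log", c_plus = 1, c_minus = 0.5, S = 5,
                      gamma = 50, W0 = 0.006)
  w <- c(0.001, 0.006, 0.012, 0.5)
  # additive: weight-independent
  expect_equal(a_plus(w, add), rep(1, 4))
  expect_equal(a_minus(w, add), rep(0.6, 4))
  # multiplicative: linear LTD
  expect_equal(a_plus(w, mult), rep(1, 4))
  expect_equal(a_minus(w, mult), 2 * w)
  # log rule at W = 0 and at the fixed point
  expect_equal(a_plus(0, logr), 1)
  expect_equal(a_plus(logr$W0, logr), exp(-1 / 50), tolerance = 1e-12)
  expect_equal(a_plus(logr$W0, logr), 0.98020, tolerance = 1e-4)
  # both LTD branches agree at W0 (continuity at the fixed point)
  expect_equal(a_minus(logr$W0, logr), 0.5)
  expect_equal(a_minus(logr$W0 * (1 - 1e-12), logr),
               a_minus(logr$W0 * (1 + 1e-12), logr), tolerance = 1e-9)
  # log LTD above the fixed point: c-[1 + ln(1 + S(W/W0 - 1))/S]
  l1 <- stdp_config("log", c_plus = 1, c_minus = 1, S = 5, gamma = 50,
                    W0 = 0.006)
  expect_equal(a_minus(2 * l1$W0, l1), 1 + log(6) / 5, tolerance = 1e-12)
  expect_equal(a_minus(2 * l1$W0, l1), 1.35835, tolerance = 1e-4)
})

test_that("the pair window potentiates pre-before-post and decays exponentially", {
  cfg <- stdp_config("add", c_plus = 1, c_minus = 0.6)
  # u -> 0- gives +a_plus
  expect_equal(stdp_window(0.5, -1e-12, cfg), 1, tolerance = 1e-9)
  # exact tie treated as potentiation
  expect_gt(stdp_window(0.5, 0, cfg), 0)
  # one LTP time constant: a_plus * exp(-1)
  expect_equal(stdp_window(0.5, -cfg$tau_plus, cfg), exp(-1),
               tolerance = 1e-12)
  expect_equal(stdp_window(0.5, -cfg$tau_plus, cfg), 0.36788,
               tolerance = 1e-4)
  # depression side
  expect_equal(stdp_window(0.5, cfg$tau_minus, cfg), -0.6 * exp(-1),
               tolerance = 1e-12)
  # decay to zero at long lags
  expect_lt(abs(stdp_window(0.5, -2000, cfg)), 1e-10)
  expect_lt(abs(stdp_window(0.5, 2000, cfg)), 1e-10)
})

test_that("delta_w is exact at sigma = 0, unbiased under noise, and clips at bounds", {
  cfg <- stdp_config("log", eta = 0.01, sigma = 0, W0 = 0.05,
                     c_minus = 0.5)
  W <- 0.1; u <- -5
  expect_equal(delta_w(W, u, cfg), cfg$eta * stdp_window(W, u, cfg))
  # Monte-Carlo mean of the noisy update equals the noiseless one
  cfgn <- stdp_config("log", eta = 0.01, sigma = 0.5, W0 = 0.05,
                      c_minus = 0.5)
  set.seed(42)
  draws <- replicate(4000, delta_w(W, u, cfgn))
  target <- cfg$eta * stdp_window(W, u, cfg)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - target), 3 * se)
  # at the upper bound an LTP update is fully clipped
  expect_equal(delta_w(cfg$w_max, -1, cfg), 0)
})

test_that("trace-based events reproduce the pair rule for isolated pairs", {
  cfg <- stdp_config("log", eta = 0.01, sigma = 0, W0 = 0.05,
                     c_minus = 0.5, A_pre0 = 1, A_post0 = 0.5)
  W <- matrix(0.2, 1, 1)
  tr <- list(x_pre = 0, x_post = 0)
  # pre spike, then a lag dt, then post spike
  lag <- 7
  st <- on_pre_spike(tr, W, 1, cfg)
  expect_equal(st$W[1, 1], 0.2)          # no LTD: post trace was zero
  st$traces <- decay_traces(st$traces, lag, cfg)
  st2 <- on_post_spike(st$traces, st$W, 1, cfg)
  ltp <- st2$W[1, 1] - 0.2
  expect_equal(ltp, cfg$eta * a_plus(0.2, cfg) * exp(-lag / cfg$tau_plus),
               tolerance = 1e-12)
  # no pre spike ever: post spike produces zero LTP
  st3 <- on_post_spike(list(x_pre = 0, x_post = 0), W, 1, cfg)
  expect_equal(st3$W[1, 1], W[1, 1])
  # two pre spikes tau_plus apart superpose: trace = A_pre0 (1 + e^-1)
  tr <- list(x_pre = 0, x_post = 0)
  s <- on_pre_spike(tr, W, 1, cfg)
  s$traces <- decay_traces(s$traces, cfg$tau_plus, cfg)
  s <- on_pre_spike(s$traces, s$W, 1, cfg)
  expect_equal(s$traces$x_pre, 1 + exp(-1), tolerance = 1e-12)
})

test_that("log rule reduces to mult as S -> 0, gamma -> Inf, and flattens as S grows", {
  W0 <- 0.05
  grid <- seq(0.001, 3 * W0, length.out = 200)
  mult <- stdp_config("mult", c_plus = 1, c_minus = 1 / W0)
  loglim <- stdp_config("log", c_plus = 1, c_minus = 1, S = 1e-8,
                        gamma = 1e8, W0 = W0)
  # a_minus(log, c-=1, W0) ~ W/W0 * 1 = mult with c- = 1/W0
  rel <- abs(a_minus(grid, loglim) - a_minus(grid, mult)) /
    pmax(abs(a_minus(grid, mult)), 1e-300)
  expect_lt(max(rel), 1e-6)
  rel_p <- abs(a_plus(grid, loglim) - a_plus(grid, mult)) /
    abs(a_plus(grid, mult))
  expect_lt(max(rel_p), 1e-6)
  # LTD slope at 2 W0 decreases monotonically in S (toward add-STDP)
  slopes <- vapply(c(0.5, 1, 2, 5, 10, 50), function(S) {
    cfg <- stdp_config("log", c_plus = 1, c_minus = 1, S = S,
                       gamma = 50, W0 = W0)
    h <- 1e-6
    (a_minus(2 * W0 + h, cfg) - a_minus(2 * W0 - h, cfg)) / (2 * h)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("LTP and LTD balance at the fixed point with the default log constants", {
  cfg <- stdp_config("log")  # c+ = 1, c- = 0.5, tau+ = 17, tau- = 34
  ltp <- cfg$tau_plus * a_plus(cfg$W0, cfg)
  ltd <- cfg$tau_minus * a_minus(cfg$W0, cfg)
  expect_lt(abs(ltp - ltd) / ltd, 0.05)
})

test_that("additive drift with c+tau+ < c-tau- depresses weights under Poisson trains", {
  cfg <- stdp_config("add", eta = 0.005, sigma = 0, c_plus = 1,
                     c_minus = 0.6,  # 1 * 17 < 0.6 * 34
                     A_pre0 = 1, A_post0 = 1)  # unit pair increments
  set.seed(11)
  n_syn <- 200
  W <- matrix(0.5, 1, n_syn)
  tr <- list(x_pre = 0, x_post = rep(0, n_syn))
  # independent pre (20 Hz) and post (20 Hz) trains over 2 s, 1 ms grid
  for (t in seq_len(2000)) {
    tr <- decay_traces(tr, 1, cfg)
    if (runif(1) < 0.02) {
      st <- on_pre_spike(tr, W, 1, cfg); tr <- st$traces; W <- st$W
    }
    post <- which(runif(n_syn) < 0.02)
    if (length(post) > 0) {
      st <- on_post_spike(tr, W, post, cfg); tr <- st$traces; W <- st$W
    }
  }
  expect_lt(mean(W), 0.5)
})

test_that("STDP config serialization round-trips and rejects bad keys", {
  cfg <- stdp_config("log", eta = 0.01, sigma = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_stdp_config(cfg, path)
  back <- read_stdp_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(stdp_config_from_list(list(rule = "log", bogus = 1)),
               "unknown")
  expect_error(stdp_config_from_list(list(rule = "add", S = 3)),
               "log rule")
  expect_error(stdp_config(
    "log", S = -1), "S")
})
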