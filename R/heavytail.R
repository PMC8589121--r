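#' Symmetric alpha-stable deviates
#'
#' Samples from the symmetric \eqn{\alpha}-stable law S\eqn{\alpha}S via the
#' Chambers-Mallows-Stuck construction. For \code{alpha = 2} this is a
#' Gaussian with variance \eqn{2 \cdot scale^2}; for \code{alpha = 1} a
#' Cauchy with the given scale.
#'
#' @param n sample count.
#' @param alpha stability index in (0, 2].
#' @param scale positive scale parameter.
#' @return numeric vector of length \code{n}.
#' @examples
#' set.seed(1)
#' x <- sample_alpha_stable(1000, 1.5)
#' @export
sample_alpha_stable <- function(n, alpha, scale = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2)
    stop("alpha must lie in (0, 2]")
  if (scale <= 0) stop("scale must be positive")
  V <- stats::runif(n, -pi / 2, pi / 2)
  Wexp <- stats::rexp(n)
  x <- if (abs(alpha - 1) < 1e-12) {
    tan(V)
  } else {
    sin(alpha * V) / cos(V)^(1 / alpha) *
      (cos((1 - alpha) * V) / Wexp)^((1 - alpha) / alpha)
  }
  scale * x
}

#' Levy-driven Ornstein-Uhlenbeck trajectories
#'
#' Euler-Maruyama iterates
#' \eqn{x_{k+1} = x_k - \theta x_k \Delta t + s\,\Delta t^{1/\alpha} L_k}
#' with iid symmetric \eqn{\alpha}-stable innovations \eqn{L_k}. With
#' \code{drift_rate = 0} and \code{alpha = 2} this is Brownian motion
#' (variance growing linearly in time); with drift it is the classical
#' mean-reverting process, whose Gaussian stationary variance is
#' \eqn{s^2/\theta}. Smaller \code{alpha} gives visibly jumpier, heavier-
#' tailed paths.
#'
#' @param alpha stability index in (0, 2].
#' @param drift_rate mean-reversion rate \eqn{\theta \ge 0} (per unit time).
#' @param scale innovation scale \eqn{s > 0}.
#' @param n_steps number of steps.
#' @param dt time step.
#' @param dims number of independent coordinates (3 for the classic
#'   3-D random-walk illustration).
#' @param x0 initial value (recycled over \code{dims}).
#' @return matrix \code{(n_steps + 1) x dims} of trajectory values.
#' @export
simulate_ou_levy <- function(alpha, drift_rate, scale, n_steps, dt = 1,
                             dims = 1, x0 = 0) {
  if (drift_rate < 0) stop("drift_rate must be >= 0")
  out <- matrix(0, n_steps + 1, dims)
  out[1, ] <- rep_len(x0, dims)
  amp <- scale * dt^(1 / alpha)
  for (d in seq_len(dims)) {
    L <- sample_alpha_stable(n_steps, alpha)
    x <- out[1, d]
    for (k in seq_len(n_steps)) {
      x <- x - drift_rate * x * dt + amp * L[k]
      out[k + 1, d] <- x
    }
  }
  out
}

#' Jump-driven membrane potential SDE
#'
#' Simulates the single-synapse membrane model
#' \deqn{dX = -X/\tau\, dt + W\, dN_\lambda - g(X^-)\, dN_{\beta,X}}
#' where presynaptic spikes arrive as a homogeneous Poisson process with
#' rate \eqn{\lambda} (each adds \eqn{W} to the potential), and
#' postsynaptic spikes are an inhomogeneous Poisson process with intensity
#' \eqn{\beta(X^-)}; a postsynaptic spike in state \eqn{x} drops the
#' potential by \eqn{g(x)}. Between jumps the potential leaks exponentially
#' with time constant \eqn{\tau}. With \eqn{\beta \equiv 0} the stationary
#' mean is the shot-noise value \eqn{W \lambda \tau}.
#'
#' @param W synaptic weight (jump height per presynaptic spike).
#' @param lambda_pre presynaptic Poisson rate (events per unit time), >= 0.
#' @param tau leak time constant, > 0.
#' @param beta_fn postsynaptic intensity function of the pre-jump state.
#' @param g_drop_fn drop function \eqn{g(x)} applied at postsynaptic
#'   spikes; default resets to zero (\eqn{g(x) = x}).
#' @param T_total total simulated time.
#' @param dt time step (thinning resolution for both point processes).
#' @param x0 initial potential.
#' @return list with \code{time}, \code{X} (path sampled at the grid), and
#'   \code{post_spike_times}.
#' @export
simulate_membrane_sde <- function(W, lambda_pre, tau,
                                  beta_fn = function(x) 0,
                                  g_drop_fn = function(x) x,
                                  T_total, dt = 0.01, x0 = 0) {
  if (lambda_pre < 0) stop("lambda_pre must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  n <- ceiling(T_total / dt)
  decay <- exp(-dt / tau)
  X <- numeric(n + 1)
  X[1] <- x0
  post_times <- numeric(0)
  x <- x0
  for (k in seq_len(n)) {
    x <- x * decay
    npre <- stats::rpois(1, lambda_pre * dt)
    if (npre > 0) x <- x + W * npre
    rate_post <- beta_fn(x)
    if (rate_post > 0 && stats::runif(1) < rate_post * dt) {
      x <- x - g_drop_fn(x)
      post_times <- c(post_times, k * dt)
    }
    X[k + 1] <- x
  }
  list(time = seq(0, by = dt, length.out = n + 1), X = X,
       post_spike_times = post_times)
}

#' Block log-moment tail-index estimator
#'
#' Estimates the stability (tail) index \eqn{\alpha} of a sample of
#' increments using the ratio of log-moments of block sums: with the data
#' centered, split into \eqn{K} blocks of size \eqn{m} with sums
#' \eqn{Y_j},
#' \deqn{\frac{1}{\hat\alpha} = \frac{1}{\log m}\left[\frac{1}{K}\sum_j
#'   \log|Y_j| - \frac{1}{N}\sum_i \log|X_i|\right].}
#' The estimate is clipped to the admissible interval (0, 2]; a clip is
#' flagged in the \code{clipped} attribute.
#'
#' @param x numeric vector of increments (length \eqn{N = K m}; a trailing
#'   remainder is dropped with a warning).
#' @param m block size (default \eqn{\lfloor\sqrt N\rfloor}).
#' @param center subtract the sample mean first (default \code{TRUE}).
#' @return estimated \eqn{\hat\alpha} in (0, 2], with attributes \code{m},
#'   \code{K} and \code{clipped}.
#' @examples
#' set.seed(1)
#' estimate_tail_index(rnorm(1e4))   # close to 2
#' @export
estimate_tail_index <- function(x, m = NULL, center = TRUE) {
  x <- as.numeric(x)
  N0 <- length(x)
  if (is.null(m)) m <- floor(sqrt(N0))
  if (m < 2) stop("block size m must be >= 2")
  K <- N0 %/% m
  if (K < 2) stop("need at least 2 blocks; reduce m or supply more data")
  if (K * m < N0) {
    warning(sprintf("dropping %d trailing values not filling a block",
                    N0 - K * m))
    x <- x[seq_len(K * m)]
  }
  if (center) x <- x - mean(x)
  eps <- .Machine$double.eps
  absx <- pmax(abs(x), eps)
  if (all(absx <= eps)) stop("all increments are (numerically) constant")
  Y <- pmax(abs(colSums(matrix(x, nrow = m))), eps)
  inv_alpha <- (mean(log(Y)) - mean(log(absx))) / log(m)
  alpha <- 1 / inv_alpha
  clipped <- FALSE
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2) {
    alpha <- if (is.finite(alpha) && alpha > 0) 2 else 2
    clipped <- TRUE
  }
  structure(alpha, m = m, K = K, clipped = clipped)
}

#' Blumenthal-Getoor index of a weight trajectory
#'
#' The learning trajectory of the plastic weights is treated as a sample
#' path of a heavy-tailed process; the tail index \eqn{\alpha_l} of the
#' final-iteration weight increments is estimated per group (layer), and
#' the Blumenthal-Getoor index \eqn{\beta = \max_l \alpha_l \in (0, 2]} —
#' an upper bound on the Hausdorff dimension of the path, hence a
#' test-set-independent generalizability measure (lower = heavier tails =
#' better expected generalization) — is returned.
#'
#' @param trajectory a \code{weight_trajectory} (see
#'   \code{\link{weight_trajectory}}) or a plain numeric vector of
#'   increments.
#' @param grouping optional factor/integer vector assigning each increment
#'   coordinate to a layer; default: one group.
#' @param m block size passed to \code{\link{estimate_tail_index}}.
#' @return list of class \code{tail_report}: \code{alpha_hat} (named per
#'   group), \code{bg_index}, \code{m}, \code{K}, \code{n_increments}.
#' @export
bg_index <- function(trajectory, grouping = NULL, m = NULL) {
  inc <- if (inherits(trajectory, "weight_trajectory")) {
    ns <- nrow(trajectory$snapshots)
    if (ns < 2) stop("trajectory needs at least 2 snapshots")
    trajectory$snapshots[ns, ] - trajectory$snapshots[ns - 1, ]
  } else {
    as.numeric(trajectory)
  }
  if (is.null(grouping)) grouping <- rep(1L, length(inc))
  groups <- split(inc, grouping)
  alpha_hat <- vapply(groups, function(g) {
    if (stats::sd(g) == 0)
      stop("constant increments in a group; tail index undefined")
    as.numeric(estimate_tail_index(g, m = m))
  }, numeric(1))
  rep <- list(alpha_hat = alpha_hat,
              bg_index = max(alpha_hat),
              m = m,
              n_increments = length(inc))
  class(rep) <- "tail_report"
  rep
}

#' @export
print.tail_report <- function(x, ...) {
  cat(sprintf("<tail_report> BG index = %.4f over %d group(s), %d increments\n",
              x$bg_index, length(x$alpha_hat), x$n_increments))
  invisible(x)
}

#' Gaussian kernel density estimate
#'
#' Evaluates \eqn{\hat f(x; t) = \frac{1}{N}\sum_i
#' \frac{1}{\sqrt{2\pi t}} e^{-(x - X_i)^2 / (2t)}} on a grid. The
#' bandwidth \code{t} is the kernel variance (scale); the default is the
#' square of Silverman's rule-of-thumb bandwidth.
#'
#' @param values sample \eqn{X_1, \dots, X_N}.
#' @param grid evaluation points (default: 512 points spanning the data
#'   plus 3 standard deviations).
#' @param t kernel variance (> 0).
#' @return data.frame with columns \code{x} and \code{density}.
#' @export
kde_pdf <- function(values, grid = NULL, t = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("need at least one value")
  if (is.null(t)) {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) s <- max(abs(values), 1e-3)
    t <- (0.9 * s * length(values)^(-1 / 5))^2
  }
  if (t <= 0) stop("bandwidth t must be > 0")
  if (is.null(grid)) {
    pad <- 3 * sqrt(t + stats::var(c(values, values)))
    grid <- seq(min(values) - pad, max(values) + pad, length.out = 512)
  }
  dens <- vapply(grid, function(g) {
    mean(exp(-(g - values)^2 / (2 * t))) / sqrt(2 * pi * t)
  }, numeric(1))
  data.frame(x = grid, density = dens)
}
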