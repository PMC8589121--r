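#' Hyperparameter search space for STDP rules
#'
#' A search space is a list of dimension definitions, each with a
#' \code{name}, \code{type} (\code{"continuous"}, \code{"log"} for a
#' log-scaled interval, or \code{"integer"}), and bounds. The default
#' space covers the log-rule hyperparameters: learning-rate multiplier
#' \eqn{\eta \in [0.05, 0.2]} (log-scaled), noise \eqn{\sigma \in
#' [0.1, 1]}, saturation \eqn{S \in \{1..10\}}, LTP decay \eqn{\gamma \in
#' \{10..100\}}, fixed point \eqn{W_0 \in (0, 1]}, scaling amplitudes
#' \eqn{c_\pm \in (0, 1]}, and window constants \eqn{\tau_+ \in [10, 20]},
#' \eqn{\tau_- \in [20, 40]} ms.
#'
#' @param rule which rule the space parameterizes.
#' @return list of class \code{search_space}.
#' @export
default_search_space <- function(rule = c("log", "add", "mult")) {
  rule <- match.arg(rule)
  dims <- list(
    list(name = "eta", type = "log", lower = 0.05, upper = 0.2),
    list(name = "sigma", type = "continuous", lower = 0.1, upper = 1),
    list(name = "c_plus", type = "continuous", lower = 0.05, upper = 1),
    list(name = "c_minus", type = "continuous", lower = 0.05, upper = 1),
    list(name = "tau_plus", type = "continuous", lower = 10, upper = 20),
    list(name = "tau_minus", type = "continuous", lower = 20, upper = 40))
  if (rule == "log") {
    dims <- c(dims, list(
      list(name = "S", type = "integer", lower = 1, upper = 10),
      list(name = "gamma", type = "integer", lower = 10, upper = 100),
      list(name = "W0", type = "continuous", lower = 0.01, upper = 1)))
  }
  structure(list(rule = rule, dims = dims), class = "search_space")
}

space_dim <- function(space) length(space$dims)

#' Decode unit-cube coordinates into named hyperparameters
#'
#' Maps a point in \eqn{[0,1]^d} onto the search space: linear for
#' continuous dimensions, geometric for log-scaled ones, rounded for
#' integer ones.
#'
#' @param space a \code{search_space}.
#' @param u numeric vector in the unit cube.
#' @return named list of hyperparameter values.
#' @export
space_decode <- function(space, u) {
  out <- list()
  for (k in seq_along(space$dims)) {
    d <- space$dims[[k]]
    v <- switch(d$type,
                continuous = d$lower + u[k] * (d$upper - d$lower),
                log = exp(log(d$lower) + u[k] * (log(d$upper) - log(d$lower))),
                integer = round(d$lower + u[k] * (d$upper - d$lower)))
    out[[d$name]] <- v
  }
  out
}

#' Expected improvement acquisition
#'
#' For minimization with a Gaussian posterior \eqn{N(\mu, sd^2)} at a
#' candidate and best observed value \eqn{f_{min}}:
#' \deqn{EI = (f_{min} - \mu)\Phi(z) + sd\,\phi(z), \quad
#'   z = (f_{min} - \mu)/sd} when \eqn{sd > 0}, and
#' \eqn{\max(f_{min} - \mu, 0)} in the degenerate \eqn{sd = 0} case.
#' This is the closed form of the improvement integral
#' \eqn{\int_{-\infty}^{f_{min}} (f_{min} - f)\, p(f)\, df}.
#'
#' @param mu posterior mean(s).
#' @param sd posterior standard deviation(s), >= 0.
#' @param f_min best (smallest) observed objective value.
#' @return nonnegative acquisition value(s).
#' @export
expected_improvement <- function(mu, sd, f_min) {
  stopifnot(all(sd >= 0))
  out <- pmax(f_min - mu, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- (f_min - mu[pos]) / sd[pos]
    out[pos] <- (f_min - mu[pos]) * stats::pnorm(z) +
      sd[pos] * stats::dnorm(z)
  }
  out
}

# --- Gaussian-process surrogate (Matern-5/2, constant mean) -------------
#
# Inputs live on the unit cube; outputs are standardized. The single
# isotropic lengthscale is selected by maximizing the log marginal
# likelihood over a small grid. A fixed noise jitter keeps the Cholesky
# well conditioned.

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit the GP surrogate
#'
#' @param U matrix of evaluated points in the unit cube (rows = points).
#' @param y objective values.
#' @param jitter observation-noise variance added to the diagonal.
#' @param ell_grid candidate isotropic lengthscales.
#' @return list of class \code{gp_fit}.
#' @export
gp_fit <- function(U, y, jitter = 1e-6,
                   ell_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 1, 2)) {
  U <- as.matrix(U)
  n <- nrow(U)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  D <- cross_dist(U, U)
  best <- NULL
  for (ell in ell_grid) {
    K <- matern52(D, ell) + diag(jitter + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, ell = ell, chol = ch, alpha = alpha)
  }
  if (is.null(best)) stop("GP fit failed for all lengthscales")
  structure(list(U = U, ys = ys, mu_y = mu_y, sd_y = sd_y,
                 ell = best$ell, chol = best$chol, alpha = best$alpha,
                 jitter = jitter),
            class = "gp_fit")
}

#' @rdname gp_fit
#' @param fit a \code{gp_fit}.
#' @param Unew matrix of query points in the unit cube.
#' @return \code{gp_predict}: list with \code{mean} and \code{sd} on the
#'   original objective scale.
#' @export
gp_predict <- function(fit, Unew) {
  Unew <- as.matrix(Unew)
  Ks <- matern52(cross_dist(Unew, fit$U), fit$ell)
  mean_s <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(1 + fit$jitter - colSums(v^2), 0)
  list(mean = fit$mu_y + fit$sd_y * mean_s,
       sd = fit$sd_y * sqrt(var_s))
}

#' Propose the next configuration by maximizing expected improvement
#'
#' Multi-start search: EI is evaluated on a cloud of uniform candidates
#' plus perturbations of the incumbent, and the best few starts are
#' refined with box-constrained local optimization. Integer dimensions
#' are rounded at decode time. If the surrogate is flat (all observed
#' values equal), a uniform random point is returned instead, flagged via
#' the \code{fallback} attribute.
#'
#' @param fit a \code{gp_fit}.
#' @param space a \code{search_space}.
#' @param f_min incumbent objective value.
#' @param u_best incumbent location in the unit cube.
#' @param n_candidates size of the random candidate cloud.
#' @return unit-cube coordinates of the proposal.
#' @export
propose_next <- function(fit, space, f_min, u_best,
                         n_candidates = 500) {
  d <- space_dim(space)
  if (stats::sd(fit$ys) == 0) {
    return(structure(stats::runif(d), fallback = TRUE))
  }
  cand <- matrix(stats::runif(n_candidates * d), ncol = d)
  pert <- matrix(pmin(pmax(rep(u_best, each = 20) +
                             stats::rnorm(20 * d, 0, 0.1), 0), 1), ncol = d)
  cand <- rbind(cand, pert)
  pr <- gp_predict(fit, cand)
  ei <- expected_improvement(pr$mean, pr$sd, f_min)
  starts <- cand[order(-ei)[seq_len(3)], , drop = FALSE]
  neg_ei <- function(u) {
    p <- gp_predict(fit, matrix(u, nrow = 1))
    -expected_improvement(p$mean, p$sd, f_min)
  }
  best_u <- starts[1, ]; best_v <- neg_ei(best_u)
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[s, ], neg_ei, method = "L-BFGS-B",
                   lower = rep(0, d), upper = rep(1, d)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < best_v) {
      best_v <- opt$value; best_u <- opt$par
    }
  }
  structure(best_u, fallback = FALSE)
}

#' Sequential model-based optimization loop
#'
#' Latin-hypercube initial design followed by fit/propose/evaluate
#' iterations with the expected-improvement acquisition on a GP
#' surrogate. The objective is called with a named list of
#' hyperparameters (decoded from the unit cube).
#'
#' @param space a \code{search_space}.
#' @param objective function(named list of hyperparameters) -> numeric.
#' @param n_init initial design size (>= 2).
#' @param budget total number of objective evaluations (> n_init).
#' @param seed RNG seed.
#' @param penalty_cap objective values at or above this are treated as
#'   failed runs and excluded from surrogate fitting once more than
#'   \code{max_penalty_frac} of evaluations would be dropped.
#' @param max_penalty_frac see \code{penalty_cap}.
#' @return list of class \code{bo_run}: \code{points} (unit cube),
#'   \code{configs}, \code{values}, incumbent \code{best_value} /
#'   \code{best_config}, and the \code{incumbent_trace}.
#' @export
smbo_loop <- function(space, objective, n_init = 5, budget = 15,
                      seed = 1, penalty_cap = 2, max_penalty_frac = 0.5) {
  stopifnot(n_init >= 2, budget >= n_init)
  set.seed(seed)
  d <- space_dim(space)
  U <- lhs::randomLHS(n_init, d)
  configs <- list(); values <- numeric(0)
  for (i in seq_len(nrow(U))) {
    cfg <- space_decode(space, U[i, ])
    configs[[i]] <- cfg
    values[i] <- objective(cfg)
  }
  while (length(values) < budget) {
    fit_mask <- values < penalty_cap
    if (mean(fit_mask) < max_penalty_frac) fit_mask[] <- TRUE
    fit <- gp_fit(U[fit_mask, , drop = FALSE], values[fit_mask])
    i_best <- which.min(values)
    u <- propose_next(fit, space, min(values), U[i_best, ])
    cfg <- space_decode(space, as.numeric(u))
    U <- rbind(U, as.numeric(u))
    configs[[length(configs) + 1L]] <- cfg
    values <- c(values, objective(cfg))
  }
  trace <- cummin(values)
  i_best <- which.min(values)
  structure(list(points = U, configs = configs, values = values,
                 best_value = values[i_best],
                 best_config = configs[[i_best]],
                 incumbent_trace = trace, seed = seed),
            class = "bo_run")
}

#' @export
print.bo_run <- function(x, ...) {
  cat(sprintf("<bo_run> %d evaluations, incumbent objective = %.4f\n",
              length(x$values), x$best_value))
  invisible(x)
}

#' Cross-validated BG-index objective for hyperparameter search
#'
#' The quantity the Bayesian optimizer minimizes: the training stream is
#' split into \code{K_folds} contiguous folds, a network is trained on
#' each fold with the candidate STDP hyperparameters, the
#' Blumenthal-Getoor index of each trained run's final-iteration weight
#' increments is computed, and the fold mean is returned. No test data is
#' touched. A fold whose training diverges (or whose increments are
#' degenerate) contributes the penalty value 2 — the upper bound of the
#' BG index — so failures are maximally unattractive without distorting
#' the scale.
#'
#' @param lambda_cfg named list of hyperparameters overriding the base
#'   STDP configuration. \code{eta} is interpreted as a multiplier on
#'   \code{eta_base}.
#' @param base an experiment base: list with \code{dataset}, \code{net}
#'   template arguments, neuron parameters and protocol settings; see
#'   \code{\link{desk_experiment}}.
#' @param K_folds number of folds (>= 2).
#' @param seed seed controlling fold training.
#' @return mean BG index across folds.
#' @export
bg_objective <- function(lambda_cfg, base, K_folds = 2, seed = 1) {
  stopifnot(K_folds >= 2)
  n <- length(base$dataset$images)
  fold_id <- cut(seq_len(n), K_folds, labels = FALSE)
  stdp_args <- base$stdp_args
  for (nm in names(lambda_cfg)) stdp_args[[nm]] <- lambda_cfg[[nm]]
  stdp_args$eta <- (lambda_cfg$eta %||% 1) * base$eta_base
  cfg <- do.call(stdp_config, stdp_args)
  vals <- vapply(seq_len(K_folds), function(k) {
    fold <- base$dataset
    keep <- fold_id == k
    fold$images <- fold$images[keep]
    fold$labels <- fold$labels[keep]
    out <- tryCatch({
      net <- build_network(base$n_input, base$n_exc,
                           w_min = base$w_min, w_max = base$w_max,
                           seed = seed + 1000L * k)
      run <- train_snn(fold, net, base$exc_params, base$inh_params, cfg,
                       images_per_iteration = base$images_per_iteration,
                       gain_divisor = base$gain_divisor,
                       duration = base$duration, dt = base$dt,
                       relax_ms = base$relax_ms, seed = seed + k)
      bg_index(run$trajectory)$bg_index
    }, error = function(e) 2)
    out
  }, numeric(1))
  mean(vals)
}
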