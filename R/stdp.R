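#' STDP rule configuration
#'
#' Builds a validated hyperparameter set for one spike-timing-dependent
#' plasticity rule. Three rules are supported, differing only in their
#' scaling functions \eqn{a_\pm(W)}:
#' \describe{
#'   \item{\code{"add"}}{additive: \eqn{a_+ = c_+}, \eqn{a_- = c_-}
#'     (weight-independent; needs hard bounds for stability).}
#'   \item{\code{"mult"}}{multiplicative: \eqn{a_+ = c_+},
#'     \eqn{a_- = c_- W} (linear LTD weight dependence).}
#'   \item{\code{"log"}}{logarithmic: \eqn{a_+ = c_+ e^{-W/(W_0\gamma)}};
#'     LTD linear below the fixed point \eqn{W_0} and log-saturating above
#'     it, with saturation degree \code{S}. As \eqn{S \to 0, \gamma \to
#'     \infty} it reduces to the multiplicative rule; as \eqn{S \to \infty}
#'     LTD flattens toward the additive rule.}
#' }
#' A pair update is \eqn{\Delta W = \eta (1 + \zeta) H(W; u)} with lag
#' \eqn{u = t_{pre} - t_{post}}, window \eqn{H} built from \eqn{a_\pm} and
#' the time constants \eqn{\tau_\pm}, and multiplicative Gaussian noise
#' \eqn{\zeta \sim N(0, \sigma^2)}.
#'
#' @param rule one of \code{"log"}, \code{"add"}, \code{"mult"}.
#' @param eta learning rate (dimensionless).
#' @param sigma standard deviation of the multiplicative update noise.
#' @param c_plus,c_minus LTP/LTD scaling amplitudes. The ratio
#'   \code{c_plus/c_minus} is the scaling-function ratio (SFR). Defaults:
#'   \code{c_minus} is 0.6 for \code{"add"}, \code{0.5/W0} for
#'   \code{"mult"} (matching output rates to the log rule for uncorrelated
#'   inputs), and 0.5 for \code{"log"} (so that
#'   \eqn{\tau_+ a_+(W_0) \approx \tau_- a_-(W_0)}).
#' @param tau_plus,tau_minus LTP/LTD window time constants (ms).
#' @param S log-LTD saturation degree (log rule only, > 0).
#' @param gamma exponential LTP decay factor (log rule only, > 0).
#' @param W0 fixed-point weight (log/mult calibration).
#' @param w_min,w_max hard weight bounds.
#' @param A_pre0,A_post0 trace increments on pre-/post-synaptic spikes.
#' @param truncate_noise if \code{TRUE}, noise draws are truncated at
#'   \eqn{-1} so an update can never flip sign.
#' @return an object of class \code{stdp_config} (a named list).
#' @examples
#' cfg <- stdp_config("log")
#' a_plus(cfg$W0, cfg)
#' @export
stdp_config <- function(rule = c("log", "add", "mult"),
                        eta = 2e-4,
                        sigma = 0,
                        c_plus = 1,
                        c_minus = NULL,
                        tau_plus = 17,
                        tau_minus = 34,
                        S = 5,
                        gamma = 50,
                        W0 = 0.006,
                        w_min = 0,
                        w_max = 1,
                        A_pre0 = 1,
                        A_post0 = NULL,
                        truncate_noise = FALSE) {
  rule <- match.arg(rule)
  if (is.null(c_minus)) {
    c_minus <- switch(rule, add = 0.6, mult = 0.5 / W0, log = 0.5)
  }
  if (is.null(A_post0)) {
    A_post0 <- switch(rule, add = 0.55, mult = 0.5, log = 0.5)
  }
  cfg <- list(rule = rule, eta = eta, sigma = sigma,
              c_plus = c_plus, c_minus = c_minus,
              tau_plus = tau_plus, tau_minus = tau_minus,
              S = S, gamma = gamma, W0 = W0,
              w_min = w_min, w_max = w_max,
              A_pre0 = A_pre0, A_post0 = A_post0,
              truncate_noise = isTRUE(truncate_noise))
  validate_stdp_config(cfg)
  class(cfg) <- "stdp_config"
  cfg
}

validate_stdp_config <- function(cfg) {
  stopifnot(cfg$eta >= 0, cfg$sigma >= 0,
            cfg$c_plus > 0, cfg$c_minus > 0,
            cfg$tau_plus > 0, cfg$tau_minus > 0,
            cfg$w_min < cfg$w_max,
            cfg$A_pre0 >= 0, cfg$A_post0 >= 0)
  if (cfg$rule == "log") {
    stopifnot(cfg$S > 0, cfg$gamma > 0, cfg$W0 > 0)
  }
  invisible(cfg)
}

#' @export
print.stdp_config <- function(x, ...) {
  cat(sprintf("<stdp_config> rule=%s eta=%g sigma=%g c+=%g c-=%g (SFR=%.3g) tau+=%g tau-=%g\n",
              x$rule, x$eta, x$sigma, x$c_plus, x$c_minus,
              x$c_plus / x$c_minus, x$tau_plus, x$tau_minus))
  if (x$rule == "log")
    cat(sprintf("  S=%g gamma=%g W0=%g\n", x$S, x$gamma, x$W0))
  invisible(x)
}

#' STDP scaling functions
#'
#' \code{a_plus} is the long-term-potentiation (LTP) scaling function,
#' \code{a_minus} the long-term-depression (LTD) one. Both are vectorized
#' over \code{W}.
#'
#' @param W synaptic weight(s).
#' @param cfg an \code{\link{stdp_config}}.
#' @return scaling value(s), same length as \code{W}.
#' @export
a_plus <- function(W, cfg) {
  switch(cfg$rule,
         add = rep_len(cfg$c_plus, length(W)),
         mult = rep_len(cfg$c_plus, length(W)),
         log = cfg$c_plus * exp(-W / (cfg$W0 * cfg$gamma)))
}

#' @rdname a_plus
#' @export
a_minus <- function(W, cfg) {
  switch(cfg$rule,
         add = rep_len(cfg$c_minus, length(W)),
         mult = cfg$c_minus * W,
         log = {
           r <- W / cfg$W0
           ifelse(r <= 1,
                  cfg$c_minus * r,
                  cfg$c_minus * (1 + log1p(cfg$S * (r - 1)) / cfg$S))
         })
}

#' Pair-based STDP window
#'
#' The temporal kernel \eqn{H(W; u)} for a pre/post spike pair with lag
#' \eqn{u = t_{pre} - t_{post}} (ms): potentiation for \eqn{u \le 0}
#' (pre precedes post; an exact tie is treated as potentiation, since
#' simultaneous events are artifacts of the discrete clock), depression
#' for \eqn{u > 0}.
#'
#' @param W synaptic weight(s).
#' @param u pre-minus-post lag(s), ms.
#' @param cfg an \code{\link{stdp_config}}.
#' @return window value(s); positive for LTP, negative for LTD.
#' @export
stdp_window <- function(W, u, cfg) {
  n <- max(length(W), length(u))
  W <- rep_len(W, n); u <- rep_len(u, n)
  ifelse(u <= 0,
         a_plus(W, cfg) * exp(-abs(u) / cfg$tau_plus),
         -a_minus(W, cfg) * exp(-abs(u) / cfg$tau_minus))
}

#' Single pair-update weight increment
#'
#' Draws the multiplicative noise \eqn{\zeta \sim N(0,\sigma^2)} and returns
#' \eqn{\eta (1+\zeta) H(W; u)}, clipped so \eqn{W + \Delta W} stays inside
#' \code{[w_min, w_max]}.
#'
#' @inheritParams stdp_window
#' @return weight increment(s).
#' @export
delta_w <- function(W, u, cfg) {
  n <- max(length(W), length(u))
  W <- rep_len(W, n); u <- rep_len(u, n)
  zeta <- if (cfg$sigma > 0) stats::rnorm(n, 0, cfg$sigma) else numeric(n)
  if (cfg$truncate_noise) zeta <- pmax(zeta, -1)
  dw <- cfg$eta * (1 + zeta) * stdp_window(W, u, cfg)
  pmin(pmax(W + dw, cfg$w_min), cfg$w_max) - W
}

#' Trace-based online STDP events
#'
#' The online implementation keeps an additive presynaptic trace
#' \code{x_pre} (decay \eqn{\tau_+}) and postsynaptic trace \code{x_post}
#' (decay \eqn{\tau_-}). On a presynaptic spike, depression proportional to
#' \code{x_post} is applied and \code{x_pre} is incremented by
#' \code{A_pre0}; on a postsynaptic spike, potentiation proportional to
#' \code{x_pre} is applied and \code{x_post} is incremented by
#' \code{A_post0}. For an isolated pre-then-post pair this reproduces the
#' pair-based window exactly; overlapping pairs accumulate (all-to-all
#' pairing).
#'
#' \code{traces} is a list with numeric fields \code{x_pre}, \code{x_post};
#' \code{decay_traces} advances both by \code{dt} ms.
#'
#' @param traces list with \code{x_pre} (length = number of presynaptic
#'   units) and \code{x_post} (length = number of postsynaptic units).
#' @param W weight matrix, presynaptic units in rows.
#' @param pre_idx,post_idx indices of the units that spiked.
#' @param cfg an \code{\link{stdp_config}}.
#' @return list with updated \code{traces} and \code{W}.
#' @export
on_pre_spike <- function(traces, W, pre_idx, cfg) {
  for (i in pre_idx) {
    z <- if (cfg$sigma > 0) stats::rnorm(ncol(W), 0, cfg$sigma) else 0
    if (cfg$truncate_noise) z <- pmax(z, -1)
    dw <- -cfg$eta * (1 + z) * a_minus(W[i, ], cfg) * traces$x_post
    W[i, ] <- pmin(pmax(W[i, ] + dw, cfg$w_min), cfg$w_max)
  }
  traces$x_pre[pre_idx] <- traces$x_pre[pre_idx] + cfg$A_pre0
  list(traces = traces, W = W)
}

#' @rdname on_pre_spike
#' @export
on_post_spike <- function(traces, W, post_idx, cfg) {
  for (j in post_idx) {
    z <- if (cfg$sigma > 0) stats::rnorm(nrow(W), 0, cfg$sigma) else 0
    if (cfg$truncate_noise) z <- pmax(z, -1)
    dw <- cfg$eta * (1 + z) * a_plus(W[, j], cfg) * traces$x_pre
    W[, j] <- pmin(pmax(W[, j] + dw, cfg$w_min), cfg$w_max)
  }
  traces$x_post[post_idx] <- traces$x_post[post_idx] + cfg$A_post0
  list(traces = traces, W = W)
}

#' @rdname on_pre_spike
#' @param dt elapsed time (ms).
#' @export
decay_traces <- function(traces, dt, cfg) {
  traces$x_pre <- traces$x_pre * exp(-dt / cfg$tau_plus)
  traces$x_post <- traces$x_post * exp(-dt / cfg$tau_minus)
  traces
}

#' Serialize / deserialize an STDP configuration
#'
#' Flat JSON with rule-specific key validation: unknown keys are rejected,
#' and log-rule-only keys (\code{S}, \code{gamma}) are rejected for the
#' additive and multiplicative rules.
#'
#' @param cfg an \code{\link{stdp_config}}.
#' @param path file path.
#' @return \code{read_stdp_config} returns an \code{stdp_config}.
#' @export
write_stdp_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stdp_config
#' @export
read_stdp_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stdp_config_from_list(doc)
}

#' @rdname write_stdp_config
#' @param doc a named list of fields, as from JSON.
#' @export
stdp_config_from_list <- function(doc) {
  known <- names(formals(stdp_config))
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0)
    stop("unknown stdp_config keys: ", paste(bad, collapse = ", "))
  if (!is.null(doc$rule) && doc$rule != "log") {
    misplaced <- intersect(names(doc), c("S", "gamma"))
    if (length(misplaced) > 0)
      stop("keys only valid for the log rule: ",
           paste(misplaced, collapse = ", "))
  }
  do.call(stdp_config, doc)
}
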