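#' Conductance-based LIF neuron parameters
#'
#' Membrane dynamics: \eqn{\tau \dot X = (E_{rest} - X) + g_e (E_{exc} - X)
#' + g_i (E_{inh} - X)}, with synaptic conductances decaying exponentially
#' (\eqn{\tau_g \dot g = -g}) and incremented instantaneously by the
#' synaptic weight on presynaptic spikes. Excitatory neurons additionally
#' carry an adaptive threshold offset \eqn{\theta} (homeostasis): the
#' effective threshold is \eqn{v_{thresh} + \theta}, \eqn{\theta} is
#' incremented by \code{theta_inc} on every spike and decays with
#' \code{tau_theta}, equalizing firing rates across the population.
#'
#' Defaults are the standard reference values for this two-layer
#' architecture. All potentials in mV, times in ms.
#'
#' @param type \code{"excitatory"} or \code{"inhibitory"} preset.
#' @param tau_m membrane time constant (ms).
#' @param E_rest,E_exc,E_inh resting / excitatory-reversal /
#'   inhibitory-reversal potentials (mV).
#' @param v_thresh,v_reset base threshold and reset potentials (mV).
#' @param t_refrac refractory period (ms).
#' @param tau_ge,tau_gi conductance decay time constants (ms).
#' @param theta_inc homeostatic threshold increment per spike (mV).
#' @param tau_theta homeostatic decay time constant (ms).
#' @return object of class \code{neuron_params}.
#' @export
neuron_params <- function(type = c("excitatory", "inhibitory"),
                          tau_m = NULL, E_rest = NULL, E_exc = NULL,
                          E_inh = NULL, v_thresh = NULL, v_reset = NULL,
                          t_refrac = NULL, tau_ge = 1, tau_gi = 2,
                          theta_inc = NULL, tau_theta = 1e5) {
  type <- match.arg(type)
  def <- if (type == "excitatory") {
    list(tau_m = 100, E_rest = -65, E_exc = 0, E_inh = -100,
         v_thresh = -52, v_reset = -65, t_refrac = 5, theta_inc = 0.05)
  } else {
    list(tau_m = 10, E_rest = -60, E_exc = 0, E_inh = -85,
         v_thresh = -40, v_reset = -45, t_refrac = 2, theta_inc = 0)
  }
  p <- list(type = type,
            tau_m = tau_m %||% def$tau_m,
            E_rest = E_rest %||% def$E_rest,
            E_exc = E_exc %||% def$E_exc,
            E_inh = E_inh %||% def$E_inh,
            v_thresh = v_thresh %||% def$v_thresh,
            v_reset = v_reset %||% def$v_reset,
            t_refrac = t_refrac %||% def$t_refrac,
            tau_ge = tau_ge, tau_gi = tau_gi,
            theta_inc = theta_inc %||% def$theta_inc,
            tau_theta = tau_theta)
  stopifnot(p$tau_m > 0, p$tau_ge > 0, p$tau_gi > 0,
            p$E_inh < p$E_rest, p$E_rest < p$v_thresh,
            p$v_thresh < p$E_exc,
            p$t_refrac >= 0, p$theta_inc >= 0, p$tau_theta > 0)
  class(p) <- "neuron_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fresh dynamic state for a neuron population
#'
#' @param n number of neurons.
#' @param params a \code{\link{neuron_params}}.
#' @return list of class \code{neuron_state} with fields \code{X},
#'   \code{g_e}, \code{g_i}, \code{theta}, \code{refrac_until},
#'   \code{spike_count}.
#' @export
neuron_state <- function(n, params) {
  s <- list(X = rep(params$E_rest, n), g_e = numeric(n), g_i = numeric(n),
            theta = numeric(n), refrac_until = rep(-Inf, n),
            spike_count = integer(n))
  class(s) <- "neuron_state"
  s
}

#' One explicit integration step of the membrane equation
#'
#' Advances the membrane potential by one explicit (Euler) step of
#' \eqn{\tau \dot X = (E_{rest} - X) + g_e (E_{exc} - X) + g_i (E_{inh} -
#' X)} and decays both conductances exponentially. Neurons inside their
#' refractory window are clamped at \code{v_reset}.
#'
#' @param state a \code{\link{neuron_state}}.
#' @param params a \code{\link{neuron_params}}.
#' @param dt time step (ms); must satisfy \code{dt <= tau_m / 5} (the
#'   conductances decay in closed form, so only the membrane equation
#'   constrains the step).
#' @param t_now current simulation time (ms), used for the refractory
#'   window.
#' @return the advanced state.
#' @export
step_membrane <- function(state, params, dt, t_now = 0) {
  if (dt <= 0 || dt > params$tau_m / 5)
    stop("dt must be positive and at most tau_m/5")
  bad <- which(!is.finite(state$X) | !is.finite(state$g_e) |
                 !is.finite(state$g_i))
  if (length(bad) > 0)
    stop("non-finite state at neuron index ", bad[1])
  dX <- ((params$E_rest - state$X) +
           state$g_e * (params$E_exc - state$X) +
           state$g_i * (params$E_inh - state$X)) / params$tau_m
  state$X <- state$X + dt * dX
  refr <- t_now < state$refrac_until
  state$X[refr] <- params$v_reset
  state$g_e <- state$g_e * exp(-dt / params$tau_ge)
  state$g_i <- state$g_i * exp(-dt / params$tau_gi)
  state
}

#' Deliver presynaptic spikes into postsynaptic conductances
#'
#' Each presynaptic spike increments the conductance of every postsynaptic
#' target by the connecting weight, instantaneously; the membrane potential
#' is untouched.
#'
#' @param state postsynaptic \code{\link{neuron_state}}.
#' @param weights weight matrix, presynaptic units in rows, postsynaptic in
#'   columns.
#' @param pre_spikes integer indices of presynaptic units that spiked.
#' @param kind \code{"excitatory"} (targets \code{g_e}) or
#'   \code{"inhibitory"} (targets \code{g_i}).
#' @return the updated state.
#' @export
deliver_spikes <- function(state, weights, pre_spikes,
                           kind = c("excitatory", "inhibitory")) {
  kind <- match.arg(kind)
  if (length(pre_spikes) == 0) return(state)
  if (any(pre_spikes < 1 | pre_spikes > nrow(weights)))
    stop("spike index out of range for the presynaptic population")
  w <- weights[pre_spikes, , drop = FALSE]
  if (any(w < 0)) stop("negative plastic weight: invariant violation")
  inc <- colSums(w)
  if (kind == "excitatory") state$g_e <- state$g_e + inc
  else state$g_i <- state$g_i + inc
  state
}

#' Threshold crossing, reset, and homeostatic update
#'
#' Neurons with \eqn{X \ge v_{thresh} + \theta} that are not refractory
#' spike: their potential is reset, \eqn{\theta} is incremented by
#' \code{theta_inc}, and the refractory window is armed. \eqn{\theta} of
#' every neuron then decays exponentially over one step \code{dt}.
#'
#' @inheritParams step_membrane
#' @param dt step length (ms) used for the homeostatic decay.
#' @return list with fields \code{state} and \code{spikes} (indices).
#' @export
fire_and_reset <- function(state, params, t_now, dt = 0) {
  if (any(!is.finite(state$X))) stop("non-finite membrane potential")
  can_fire <- t_now >= state$refrac_until
  spikes <- which(can_fire & state$X >= params$v_thresh + state$theta)
  if (length(spikes) > 0) {
    state$X[spikes] <- params$v_reset
    state$theta[spikes] <- state$theta[spikes] + params$theta_inc
    state$refrac_until[spikes] <- t_now + params$t_refrac
    state$spike_count[spikes] <- state$spike_count[spikes] + 1L
  }
  if (dt > 0)
    state$theta <- state$theta * exp(-dt / params$tau_theta)
  list(state = state, spikes = spikes)
}

#' Two-layer network topology with lateral inhibition
#'
#' Input neurons project all-to-all through plastic weights onto the
#' excitatory layer. Each excitatory neuron drives its partner inhibitory
#' neuron one-to-one with fixed weight \code{w_ei}; each inhibitory neuron
#' inhibits every excitatory neuron except its partner with fixed weight
#' \code{w_ie}. The plastic weights are initialized uniformly at random in
#' \code{[w_min, w_max]}.
#'
#' @param n_input number of input neurons (pixels).
#' @param n_exc number of excitatory neurons (>= 2); the inhibitory layer
#'   has the same size.
#' @param w_ei fixed excitatory-to-inhibitory weight.
#' @param w_ie fixed inhibitory-to-excitatory weight.
#' @param w_min,w_max plastic weight bounds (and initialization range).
#' @param seed RNG seed for the weight initialization.
#' @return object of class \code{snn_topology} with the plastic matrix
#'   \code{input_to_exc} (\code{n_input x n_exc}).
#' @export
build_network <- function(n_input, n_exc, w_ei = 10.4, w_ie = 17.0,
                          w_min = 0, w_max = 1, seed = 1) {
  if (n_exc < 2) stop("n_exc must be >= 2")
  if (w_min >= w_max) stop("w_min must be < w_max")
  set.seed(seed)
  W <- matrix(stats::runif(n_input * n_exc, w_min, w_max), n_input, n_exc)
  net <- list(n_input = n_input, n_exc = n_exc, n_inh = n_exc,
              input_to_exc = W, w_ei = w_ei, w_ie = w_ie,
              w_min = w_min, w_max = w_max, seed = seed)
  class(net) <- "snn_topology"
  net
}

#' @export
print.snn_topology <- function(x, ...) {
  cat(sprintf("<snn_topology> %d input -> %d exc <-> %d inh (w_ei=%g, w_ie=%g)\n",
              x$n_input, x$n_exc, x$n_inh, x$w_ei, x$w_ie))
  invisible(x)
}

#' Number of inhibitory-to-excitatory connections
#'
#' Each of the \code{n_exc} inhibitory neurons connects to all excitatory
#' neurons except its partner, so the count is \code{n_exc * (n_exc - 1)}.
#'
#' @param net an \code{snn_topology}.
#' @return integer connection count.
#' @export
n_inh_to_exc <- function(net) net$n_inh * (net$n_exc - 1L)

#' Fresh simulation state for a network
#'
#' The flat state consumed by the clock-driven kernel: excitatory
#' potentials \code{Xe}, conductances \code{ge_e}/\code{gi_e}, homeostatic
#' offsets \code{theta}, remaining refractory times, the inhibitory-layer
#' analogues, and the synaptic traces \code{x_pre}/\code{x_post}.
#'
#' @param net an \code{snn_topology}.
#' @param exc_params,inh_params \code{\link{neuron_params}} for the two
#'   layers.
#' @return named list of state vectors.
#' @export
network_state <- function(net, exc_params, inh_params) {
  list(Xe = rep(exc_params$E_rest, net$n_exc),
       ge_e = numeric(net$n_exc), gi_e = numeric(net$n_exc),
       theta = numeric(net$n_exc), refrac_e = numeric(net$n_exc),
       Xi = rep(inh_params$E_rest, net$n_inh),
       ge_i = numeric(net$n_inh), refrac_i = numeric(net$n_inh),
       x_pre = numeric(net$n_input), x_post = numeric(net$n_exc))
}

#' Relax all dynamic variables over a silent interval
#'
#' Between presentations no input is given for \code{interval} ms so that
#' all variables decay toward rest; the decay is applied in closed form
#' (potentials relax toward \code{E_rest}; conductances, traces and —
#' during training — the homeostatic offsets decay exponentially).
#'
#' @param st a state from \code{\link{network_state}}.
#' @param exc_params,inh_params layer parameters.
#' @param stdp an \code{\link{stdp_config}} (trace time constants).
#' @param interval silent time (ms).
#' @param frozen if \code{TRUE}, homeostatic thresholds are held fixed.
#' @return the relaxed state.
#' @export
relax_state <- function(st, exc_params, inh_params, stdp,
                        interval = 150, frozen = FALSE) {
  st$Xe <- exc_params$E_rest +
    (st$Xe - exc_params$E_rest) * exp(-interval / exc_params$tau_m)
  st$ge_e <- st$ge_e * exp(-interval / exc_params$tau_ge)
  st$gi_e <- st$gi_e * exp(-interval / exc_params$tau_gi)
  if (!frozen)
    st$theta <- st$theta * exp(-interval / exc_params$tau_theta)
  st$refrac_e <- pmax(st$refrac_e - interval, 0)
  st$Xi <- inh_params$E_rest +
    (st$Xi - inh_params$E_rest) * exp(-interval / inh_params$tau_m)
  st$ge_i <- st$ge_i * exp(-interval / inh_params$tau_ge)
  st$refrac_i <- pmax(st$refrac_i - interval, 0)
  st$x_pre <- st$x_pre * exp(-interval / stdp$tau_plus)
  st$x_post <- st$x_post * exp(-interval / stdp$tau_minus)
  st
}

#' Present one stimulus to the network
#'
#' Runs the clock-driven simulation of a single stimulus presentation:
#' Poisson input spikes at the given per-pixel rates drive the excitatory
#' layer through the plastic weights, lateral inhibition competes the
#' excitatory neurons, and (unless \code{plastic = FALSE}) the trace-based
#' STDP rule updates the plastic weights online. If the excitatory layer
#' fires fewer than \code{min_spikes} spikes in total, all pixel rates are
#' boosted proportionally (the rate ceiling is raised by \code{boost_hz}
#' Hz) and the stimulus is re-presented, cumulating spikes, until the
#' floor is met or \code{max_boosts} is exceeded.
#'
#' @param net an \code{snn_topology}.
#' @param exc_params,inh_params \code{\link{neuron_params}}.
#' @param stdp an \code{\link{stdp_config}}; pass \code{plastic = FALSE}
#'   to freeze learning and homeostasis (inference mode).
#' @param rates per-input firing rates (Hz).
#' @param state a \code{\link{network_state}} (carried across
#'   presentations); created fresh when \code{NULL}.
#' @param duration presentation time (ms).
#' @param dt time step (ms).
#' @param plastic apply STDP and homeostasis?
#' @param min_spikes minimum total excitatory spikes before moving on.
#' @param boost_hz rate-ceiling increment per boost (Hz).
#' @param rate_ceiling nominal maximum rate (Hz) the boost is relative to.
#' @param max_boosts divergence cap on the boost loop.
#' @return list with \code{W} (updated plastic weights), \code{state},
#'   \code{spike_counts} (per excitatory neuron, cumulative over boosts),
#'   \code{inh_counts}, \code{n_boosts}.
#' @export
run_presentation <- function(net, exc_params, inh_params, stdp, rates,
                             state = NULL, duration = 350, dt = 0.5,
                             plastic = TRUE, min_spikes = 5,
                             boost_hz = 32, rate_ceiling = 63.75,
                             max_boosts = 20) {
  stopifnot(all(rates >= 0), duration > 0, dt > 0)
  if (length(rates) != net$n_input)
    stop("rates must have one entry per input neuron")
  if (is.null(state)) state <- network_state(net, exc_params, inh_params)
  steps <- round(duration / dt)
  W <- net$input_to_exc
  counts <- integer(net$n_exc)
  inh_counts <- integer(net$n_inh)
  total <- 0L
  boosts <- -1L
  repeat {
    boosts <- boosts + 1L
    if (boosts > max_boosts)
      stop(sprintf(paste0("presentation failed to elicit %d spikes after ",
                          "%d rate boosts"), min_spikes, max_boosts))
    factor <- (rate_ceiling + boost_hz * boosts) / rate_ceiling
    p <- pmin(rates * factor * dt / 1000, 1)
    res <- present_cpp(W, p, exc_params, inh_params, net$w_ei, net$w_ie,
                       stdp, plastic, state, steps, dt)
    W <- res$W
    state <- res$state
    counts <- counts + res$exc_counts
    inh_counts <- inh_counts + res$inh_counts
    total <- total + res$total_exc
    if (total >= min_spikes) break
  }
  list(W = W, state = state, spike_counts = counts,
       inh_counts = inh_counts, n_boosts = boosts)
}
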