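# Trace-based spike-timing-dependent plasticity. Each neuron carries a
# low-pass filtered record of its own spikes (the trace); sampling the
# opposite side's trace at a spike collapses the sum over all preceding
# opposite-side spikes into a single constant-time update. The brute-force
# all-pairs evaluation is kept alongside as the correctness oracle.

#' STDP rule parameters
#'
#' Power-law weight-dependent STDP: a postsynaptic spike at time lag
#' `dt > 0` after a presynaptic spike potentiates by
#' `lam * w0^(1-mu) * w^mu * exp(-dt/tau)`; a presynaptic spike following
#' (or level with) a postsynaptic one depresses by
#' `lam * alpha * w * exp(-|dt|/tau)`. `mu = 0` gives an additive rule,
#' `mu = 1` a fully multiplicative one.
#'
#' @param lam Learning rate (dimensionless, >= 0).
#' @param w0 Reference weight (nA, > 0).
#' @param mu Weight-dependence exponent in `[0, 1]`.
#' @param alpha Relative depression strength (>= 0).
#' @param tau Trace/kernel time constant (ms, > 0).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(lam = 0.1, w0 = 0.001, mu = 0.4, alpha = 0.1,
                        tau = 20) {
  check_number(lam, "lam", lower = 0)
  check_number(w0, "w0", lower = 1e-300)
  check_number(mu, "mu", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 0)
  check_number(tau, "tau", lower = 1e-12)
  structure(list(lam = lam, w0 = w0, mu = mu, alpha = alpha, tau = tau),
            class = "stdp_params")
}

#' Advance per-neuron spike traces by one timestep
#'
#' All traces decay by `exp(-dt/tau)`; neurons that spiked this step then
#' increment their trace by one. Plasticity updates sample the trace
#' before this same-step increment, so a spike never pairs with itself or
#' with a same-step opposite-side spike.
#'
#' @param trace Numeric vector of traces.
#' @param spiked Integer indices of neurons that spiked this step.
#' @param dt Timestep (ms).
#' @param tau Trace time constant (ms).
#' @return The updated trace vector.
#' @export
trace_step <- function(trace, spiked, dt, tau) {
  check_number(dt, "dt", lower = 1e-12)
  check_number(tau, "tau", lower = 1e-12)
  trace <- trace * exp(-dt / tau)
  trace[spiked] <- trace[spiked] + 1
  trace
}

#' Depression triggered by a presynaptic spike
#'
#' Applies the accumulated depression of all preceding postsynaptic
#' spikes in one update: `w' = max(0, w - lam * alpha * w * s_post)`.
#'
#' @param w Current weight (nA, >= 0).
#' @param s_post Postsynaptic trace sampled at the presynaptic spike.
#' @param p An [stdp_params()].
#' @return The updated weight.
#' @export
depress_on_pre <- function(w, s_post, p) {
  pmax(0, w - p$lam * p$alpha * w * s_post)
}

#' Potentiation triggered by a postsynaptic spike
#'
#' Applies the accumulated potentiation of all preceding presynaptic
#' spikes in one update: `w' = w + lam * w0^(1-mu) * w^mu * s_pre`.
#'
#' @param w Current weight (nA, >= 0).
#' @param s_pre Presynaptic trace sampled at the postsynaptic spike.
#' @param p An [stdp_params()].
#' @return The updated weight.
#' @export
potentiate_on_post <- function(w, s_pre, p) {
  if (any(w < 0)) {
    abort("weights must be non-negative.", class = "snnkit_invalid_state")
  }
  w + p$lam * p$w0^(1 - p$mu) * w^p$mu * s_pre
}

#' All-pairs STDP oracle
#'
#' Brute-force evaluation of the pair rule: events are processed in time
#' order and every new spike is paired with all strictly preceding
#' opposite-side spikes, using the current weight at each event. When a
#' presynaptic and postsynaptic spike share an event time, depression
#' (pre-triggered) is applied before potentiation, mirroring the
#' simulation kernel order; same-time pairs are never formed.
#'
#' @param pre_times,post_times Sorted spike times (ms) of the pre- and
#'   postsynaptic neuron.
#' @param w_init Initial weight (nA).
#' @param p An [stdp_params()].
#' @return The final weight after all events.
#' @export
stdp_all_pairs_oracle <- function(pre_times, post_times, w_init, p) {
  stopifnot(inherits(p, "stdp_params"), !is.unsorted(pre_times),
            !is.unsorted(post_times))
  w <- w_init
  for (t in sort(unique(c(pre_times, post_times)))) {
    if (t %in% pre_times) {
      dep <- sum(exp(-(t - post_times[post_times < t]) / p$tau))
      w <- max(0, w - p$lam * p$alpha * w * dep)
    }
    if (t %in% post_times) {
      pot <- sum(exp(-(t - pre_times[pre_times < t]) / p$tau))
      w <- w + p$lam * p$w0^(1 - p$mu) * w^p$mu * pot
    }
  }
  w
}

#' Trace-based STDP simulation of a single synapse
#'
#' Steps the pre- and postsynaptic traces over the simulation grid and
#' applies the constant-time trace updates ([depress_on_pre()] then
#' [potentiate_on_post()] within a step, traces sampled before the
#' same-step increment). For spike trains on the grid this is exactly
#' equivalent to [stdp_all_pairs_oracle()].
#'
#' @param pre_times,post_times Sorted spike times (ms) aligned to the grid.
#' @param w_init Initial weight (nA).
#' @param p An [stdp_params()].
#' @param dt Timestep (ms).
#' @return The final weight.
#' @export
stdp_trace_sim <- function(pre_times, post_times, w_init, p, dt = 0.1) {
  stopifnot(inherits(p, "stdp_params"))
  check_number(dt, "dt", lower = 1e-12)
  pre_steps <- as.integer(round(pre_times / dt))
  post_steps <- as.integer(round(post_times / dt))
  n_steps <- max(pre_steps, post_steps, 0L) + 1L
  decay <- exp(-dt / p$tau)
  s_pre <- 0; s_post <- 0; w <- w_init
  pre_set <- post_set <- logical(n_steps)
  pre_set[pre_steps + 1L] <- TRUE
  post_set[post_steps + 1L] <- TRUE
  last <- 0L
  events <- which(pre_set | post_set)
  for (step in events) {
    d <- decay^(step - last)
    s_pre <- s_pre * d
    s_post <- s_post * d
    last <- step
    if (pre_set[step]) w <- depress_on_pre(w, s_post, p)
    if (post_set[step]) w <- potentiate_on_post(w, s_pre, p)
    if (pre_set[step]) s_pre <- s_pre + 1
    if (post_set[step]) s_post <- s_post + 1
  }
  w
}
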