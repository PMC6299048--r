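# Exact single-timestep propagators for current-based LIF neurons and
# their synaptic input filters. Because the synaptic current is held
# constant over a step while the membrane equation is solved, and vice
# versa, every update below is the closed-form solution of its linear ODE
# (Rotter-Diesmann exact integration); the only approximation is the
# one-timestep delay this staggering introduces.

#' Exponential decay multiplier for one integration step
#'
#' Converts a decay time constant into the multiplier `exp(-dt/tau)`
#' applied to a state variable over one timestep of length `dt`.
#'
#' @param tau Time constant in ms. Must be positive.
#' @param dt Timestep in ms. Must be non-negative.
#' @return The dimensionless multiplier in (0, 1].
#' @examples
#' decay_factor(20, 0.1)
#' @export
decay_factor <- function(tau, dt) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    abort("`tau` must be positive and finite.", class = "snnkit_invalid_parameter")
  }
  if (!is.numeric(dt) || any(!is.finite(dt)) || any(dt < 0)) {
    abort("`dt` must be non-negative and finite.", class = "snnkit_invalid_parameter")
  }
  exp(-dt / tau)
}

#' Leaky integrate-and-fire parameter set
#'
#' @param tau_m Membrane time constant (ms).
#' @param r_m Membrane resistance (MOhm).
#' @param v_rest Resting potential (mV).
#' @param v_thresh Spike threshold (mV).
#' @param v_reset Post-spike reset potential (mV). Defaults to `v_rest`.
#' @param tau_ref Absolute refractory period (ms); rounded to whole
#'   timesteps when a spike occurs.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, r_m = 40, v_rest = -65, v_thresh = -50,
                       v_reset = v_rest, tau_ref = 2) {
  check_number(tau_m, "tau_m", lower = 1e-12)
  check_number(r_m, "r_m")
  check_number(tau_ref, "tau_ref", lower = 0)
  check_number(v_rest, "v_rest")
  check_number(v_thresh, "v_thresh")
  check_number(v_reset, "v_reset")
  if (v_thresh <= v_reset) {
    abort("`v_thresh` must exceed `v_reset`.", class = "snnkit_invalid_parameter")
  }
  structure(list(tau_m = tau_m, r_m = r_m, v_rest = v_rest,
                 v_thresh = v_thresh, v_reset = v_reset, tau_ref = tau_ref),
            class = "lif_params")
}

#' Per-neuron state container
#'
#' Holds the membrane potential, the refractory countdown (in whole
#' timesteps) and the plasticity trace of a population of neurons.
#'
#' @param n Number of neurons.
#' @param v Initial membrane potential(s), recycled to length `n`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(n, v = 0) {
  check_number(n, "n", lower = 1, integerish = TRUE)
  structure(list(v = rep_len(as.double(v), n),
                 refractory_steps = integer(n),
                 trace = double(n)),
            class = "neuron_state")
}

#' Advance a LIF population by one timestep
#'
#' Non-refractory neurons follow the exact solution of the membrane
#' equation with the input current held constant over the step:
#' `V' = V_rest + R_m I + (V - V_rest - R_m I) exp(-dt/tau_m)`.
#' Refractory neurons hold their potential and decrement their countdown.
#' Neurons whose updated potential reaches `v_thresh` are reported as
#' spikes, reset to `v_reset`, and made refractory for
#' `round(tau_ref/dt)` steps.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()].
#' @param input_current Input current per neuron (nA); a scalar is recycled.
#' @param dt Timestep (ms).
#' @return A list with elements `state` (updated [neuron_state()]) and
#'   `spikes` (integer indices of neurons that fired this step).
#' @export
lif_step <- function(state, params, input_current, dt) {
  check_number(dt, "dt", lower = 1e-12)
  n <- length(state$v)
  if (length(input_current) == 1L) input_current <- rep.int(input_current, n)
  if (length(input_current) != n) {
    abort("`input_current` length must match the number of neurons.",
          class = "snnkit_invalid_input")
  }
  refr <- state$refractory_steps > 0L
  v_inf <- params$v_rest + params$r_m * input_current
  a <- exp(-dt / params$tau_m)
  v_new <- v_inf + (state$v - v_inf) * a
  v_new[refr] <- state$v[refr]
  state$refractory_steps[refr] <- state$refractory_steps[refr] - 1L
  spikes <- which(!refr & v_new >= params$v_thresh)
  if (length(spikes)) {
    v_new[spikes] <- params$v_reset
    state$refractory_steps[spikes] <- as.integer(round(params$tau_ref / dt))
  }
  state$v <- v_new
  list(state = state, spikes = spikes)
}

#' Exponential synapse filter state
#'
#' Single-exponential postsynaptic current filter: every impulse (summed
#' weight of events landing in a step) is added to the filtered current
#' `I`, which decays with time constant `tau_syn`.
#'
#' @param n Number of neurons.
#' @param tau_syn Synaptic time constant (ms).
#' @return An object of class `exp_synapse_state`.
#' @export
exp_synapse_state <- function(n, tau_syn = 0.5) {
  check_number(n, "n", lower = 1, integerish = TRUE)
  check_number(tau_syn, "tau_syn", lower = 1e-12)
  structure(list(i = double(n), tau_syn = tau_syn), class = "exp_synapse_state")
}

#' Advance an exponential synapse filter by one timestep
#'
#' `I' = I exp(-dt/tau_syn) + impulse`.
#'
#' @param state An [exp_synapse_state()].
#' @param impulse Summed event weight per neuron this step (nA).
#' @param dt Timestep (ms).
#' @return The updated state.
#' @export
exp_synapse_step <- function(state, impulse, dt) {
  check_number(dt, "dt", lower = 1e-12)
  n <- length(state$i)
  if (length(impulse) == 1L) impulse <- rep.int(impulse, n)
  if (length(impulse) != n) {
    abort("`impulse` length must match the filter state.",
          class = "snnkit_invalid_input")
  }
  state$i <- state$i * exp(-dt / state$tau_syn) + impulse
  state
}

#' Alpha synapse filter state
#'
#' Two-variable filter producing an alpha-function postsynaptic current:
#' impulses enter the auxiliary variable `x`, which feeds `I`; both share
#' the time constant `tau_syn`, so a unit impulse yields a current peaking
#' at `1/e` after `tau_syn` ms.
#'
#' @inheritParams exp_synapse_state
#' @return An object of class `alpha_synapse_state`.
#' @export
alpha_synapse_state <- function(n, tau_syn = 0.33) {
  check_number(n, "n", lower = 1, integerish = TRUE)
  check_number(tau_syn, "tau_syn", lower = 1e-12)
  structure(list(i = double(n), x = double(n), tau_syn = tau_syn),
            class = "alpha_synapse_state")
}

#' Advance an alpha synapse filter by one timestep
#'
#' With `h = dt/tau_syn` the exact propagator of the coupled pair is
#' `I' = (I + x h) exp(-h)`, `x' = x exp(-h) + impulse`.
#'
#' @param state An [alpha_synapse_state()].
#' @inheritParams exp_synapse_step
#' @return The updated state.
#' @export
alpha_synapse_step <- function(state, impulse, dt) {
  check_number(dt, "dt", lower = 1e-12)
  n <- length(state$i)
  if (length(impulse) == 1L) impulse <- rep.int(impulse, n)
  if (length(impulse) != n) {
    abort("`impulse` length must match the filter state.",
          class = "snnkit_invalid_input")
  }
  h <- dt / state$tau_syn
  e <- exp(-h)
  state$i <- (state$i + state$x * h) * e
  state$x <- state$x * e + impulse
  state
}
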