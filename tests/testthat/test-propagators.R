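# Exact propagators for membrane and synapse dynamics.

test_that("decay_factor matches the closed form and rejects bad input", {
  expect_equal(decay_factor(20, 0.1), exp(-0.005))
  expect_equal(decay_factor(0.5, 0.1), exp(-0.2))
  expect_equal(decay_factor(7.3, 0), 1)
  expect_error(decay_factor(0, 0.1), class = "snnkit_invalid_parameter")
  expect_error(decay_factor(-2, 0.1), class = "snnkit_invalid_parameter")
})

test_that("resting neurons with no input are a fixed point of lif_step", {
  p <- lif_params()
  st <- neuron_state(5, v = p$v_rest)
  out <- lif_step(st, p, 0, 0.1)
  expect_equal(out$state$v, rep(p$v_rest, 5))
  expect_length(out$spikes, 0)
})

test_that("constant-current membrane trajectory matches a fine-step ODE oracle", {
  p <- lif_params(tau_m = 20, r_m = 40, v_rest = -65, v_thresh = 100)
  i_in <- 0.3                     # nA; threshold far away, pure integration
  dt <- 0.1
  n <- 400
  st <- neuron_state(1, v = p$v_rest)
  for (k in seq_len(n)) st <- lif_step(st, p, i_in, dt)$state
  # independent fine-step ODE oracle
  v <- rk4(p$v_rest,
           function(v) (-(v - p$v_rest) + p$r_m * i_in) / p$tau_m,
           t_total = n * dt, h = dt / 100)
  expect_equal(st$v, v, tolerance = 1e-9)
  # and converges to the analytic steady state
  st2 <- neuron_state(1, v = p$v_rest)
  for (k in seq_len(5000)) st2 <- lif_step(st2, p, i_in, dt)$state
  expect_equal(st2$v, p$v_rest + p$r_m * i_in, tolerance = 1e-6)
})

test_that("halving the timestep twice reproduces the same trajectory", {
  p <- lif_params(tau_m = 13, v_thresh = 1e6)
  st1 <- neuron_state(1, v = -57)
  st2 <- neuron_state(1, v = -57)
  for (k in 1:50) {
    st1 <- lif_step(st1, p, 0.17, 0.2)$state
    st2 <- lif_step(st2, p, 0.17, 0.1)$state
    st2 <- lif_step(st2, p, 0.17, 0.1)$state
  }
  expect_equal(st1$v, st2$v, tolerance = 1e-12)
})

test_that("threshold crossing spikes, resets and starts the refractory countdown", {
  p <- lif_params(tau_m = 10, r_m = 40, v_rest = -65, v_thresh = -50,
                  tau_ref = 2)
  st <- neuron_state(1, v = -50.5)
  out <- lif_step(st, p, 2, 0.1)   # strong input pushes it over threshold
  expect_equal(out$spikes, 1L)
  expect_equal(out$state$v, p$v_reset)
  expect_equal(out$state$refractory_steps, 20L)  # round(2 / 0.1)
  # no further spikes while refractory, even under huge input
  for (k in 1:20) {
    out <- lif_step(out$state, p, 100, 0.1)
    expect_length(out$spikes, 0)
  }
  # first step after the countdown can spike again
  out <- lif_step(out$state, p, 100, 0.1)
  expect_equal(out$spikes, 1L)
})

test_that("lif_step validates input shape", {
  st <- neuron_state(4)
  expect_error(lif_step(st, lif_params(), c(1, 2), 0.1),
               class = "snnkit_invalid_input")
})

test_that("exponential synapse follows its closed form and conserves charge", {
  s <- exp_synapse_state(1, tau_syn = 0.5)
  s$i <- 1
  s <- exp_synapse_step(s, 0, 0.1)
  expect_equal(s$i, exp(-0.2))
  s <- exp_synapse_state(1, tau_syn = 0.5)
  s <- exp_synapse_step(s, 0.7, 0.1)
  expect_equal(s$i, 0.7)
  # time integral of the current after one impulse is w * tau_syn
  dt <- 1e-3
  s <- exp_synapse_state(1, tau_syn = 0.5)
  s <- exp_synapse_step(s, 0.3, dt)
  total <- 0
  for (k in 1:20000) {
    total <- total + s$i * dt
    s <- exp_synapse_step(s, 0, dt)
  }
  expect_equal(total, 0.3 * 0.5, tolerance = 5e-3)
})

test_that("alpha synapse propagator is exact against a fine-step oracle", {
  s <- alpha_synapse_state(1, tau_syn = 0.5)
  s$x <- 1
  s <- alpha_synapse_step(s, 0, 0.1)
  expect_equal(s$i, 0.2 * exp(-0.2))
  expect_equal(s$x, exp(-0.2))

  # peak of the alpha kernel: at t = tau_syn the current is w / e
  tau <- 0.5; w <- 0.8; dt <- 1e-4
  s <- alpha_synapse_state(1, tau_syn = tau)
  s <- alpha_synapse_step(s, w, dt)
  peak <- 0
  for (k in seq_len(round(3 * tau / dt))) {
    peak <- max(peak, s$i)
    s <- alpha_synapse_step(s, 0, dt)
  }
  expect_equal(peak, w / exp(1), tolerance = 1e-3)

  # exact stepping at dt matches a fine-step ODE oracle over 10 time constants
  dt <- 0.1; tau <- 0.5
  se <- alpha_synapse_state(1, tau_syn = tau)
  se <- alpha_synapse_step(se, 1, dt)
  y <- c(i = se$i, x = se$x)
  rel_err <- 0
  for (k in seq_len(round(10 * tau / dt))) {
    se <- alpha_synapse_step(se, 0, dt)
    y <- rk4(y, function(y) c(y[2] - y[1], -y[2]) / tau, dt, dt / 100)
    rel_err <- max(rel_err, abs(se$i - y[1]) / max(abs(y[1]), 1e-12))
  }
  expect_lt(rel_err, 1e-6)
})

test_that("exponential stepping matches a fine-step ODE oracle over 10 tau", {
  dt <- 0.05; tau <- 0.5
  s <- exp_synapse_state(1, tau_syn = tau)
  s <- exp_synapse_step(s, 1, dt)
  io <- s$i
  rel_err <- 0
  for (k in seq_len(round(10 * tau / dt))) {
    s <- exp_synapse_step(s, 0, dt)
    io <- rk4(io, function(y) -y / tau, dt, dt / 100)
    rel_err <- max(rel_err, abs(s$i - io) / io)
  }
  expect_lt(rel_err, 1e-6)
})
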