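# Small hand-built network specifications for exercising the simulation
# paths without the benchmark builders.

test_population <- function(name, size, syn_kind = "exp", tau_syn = 0.5,
                            dc = 0, stdp_tau = NA_real_, tau_ref = 2,
                            v_init_mean = -60, v_init_sd = 3) {
  tibble::tibble(name = name, size = as.integer(size),
                 tau_m = 10, r_m = 40, v_rest = -65, v_thresh = -50,
                 v_reset = -65, tau_ref = tau_ref,
                 syn_kind = syn_kind, tau_syn = tau_syn,
                 poisson_rate = 0, poisson_weight = 0, dc = dc,
                 v_init_mean = v_init_mean, v_init_sd = v_init_sd,
                 stdp_tau = stdp_tau)
}

test_projection <- function(src, tgt, connector = "fixed_total",
                            n_syn = NA_real_, p = NA_real_,
                            weight_mean = 0.1, weight_sd = 0.01,
                            delay_mean = 1, delay_sd = 0.3, sign = 1,
                            structure = "ragged", plastic = FALSE,
                            lam = 0.05, w0 = 0.1, mu = 0.4, alpha = 1.1,
                            tau = 20) {
  tibble::tibble(name = paste0(src, "->", tgt), src = src, tgt = tgt,
                 connector = connector, n_syn = n_syn, p = p,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 delay_mean = delay_mean, delay_sd = delay_sd, sign = sign,
                 structure = structure, plastic = plastic,
                 lam = if (plastic) lam else NA_real_,
                 w0 = if (plastic) w0 else NA_real_,
                 mu = if (plastic) mu else NA_real_,
                 alpha = if (plastic) alpha else NA_real_,
                 tau = if (plastic) tau else NA_real_)
}

test_network_spec <- function(populations, projections, dt = 0.1,
                              duration = 100) {
  snnkit:::new_network_spec(populations, projections, dt = dt,
                            duration = duration, meta = list(model = "test"))
}

# Two DC-driven populations with mixed excitatory/inhibitory recurrence;
# deterministic (no Poisson), suitable for engine-vs-reference checks.
two_pop_spec <- function(syn_kind = "exp", plastic = FALSE,
                         duration = 60, structure = "ragged") {
  pops <- dplyr::bind_rows(
    test_population("a", 40, syn_kind = syn_kind, dc = 0.42,
                    stdp_tau = if (plastic) 20 else NA_real_),
    test_population("b", 25, syn_kind = syn_kind, dc = 0.40))
  projs <- dplyr::bind_rows(
    test_projection("a", "a", n_syn = 220, weight_mean = 0.05,
                    plastic = plastic),
    test_projection("a", "b", n_syn = 150, weight_mean = 0.06),
    test_projection("b", "a", n_syn = 130, weight_mean = -0.25,
                    weight_sd = 0.02, sign = -1))
  if (structure == "bitmask") {
    # bitmask projections cannot hold multapses: use Bernoulli connectivity
    projs$structure[2] <- "bitmask"
    projs$connector[2] <- "fixed_prob"
    projs$n_syn[2] <- NA_real_
    projs$p[2] <- 0.2
    projs$weight_sd[2] <- NA_real_
    projs$delay_sd[2] <- 0
  }
  test_network_spec(pops, projs, duration = duration)
}

# Classical RK4 integration of dy/dt = f(y), an independent high-accuracy
# ODE oracle for the exact propagators.
rk4 <- function(y, f, t_total, h) {
  for (k in seq_len(round(t_total / h))) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Poisson spike train helper (ms), sorted, on the dt grid.
poisson_train <- function(rate_hz, duration_ms, dt = 0.1) {
  n_steps <- round(duration_ms / dt)
  steps <- which(runif(n_steps) < rate_hz * dt / 1000)
  steps * dt
}
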