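# Connectivity-initialisation samplers. These are designed so that every
# sample is produced in constant time and rows can be generated
# independently: sorted postsynaptic targets come from successive
# first-order statistics of the uniform distribution (computed through the
# exponential transform), and Bernoulli connectivity comes from geometric
# inter-connection skips.

#' Fixed-total-synapse connectivity specification
#'
#' Connectivity defined by the total number of synapses `n_syn` placed
#' uniformly at random (with replacement) over the `n_pre x n_post` grid.
#'
#' @param n_pre,n_post Population sizes.
#' @param n_syn Total synapse count.
#' @return An object of class `fixed_total_spec`.
#' @export
fixed_number_total <- function(n_pre, n_post, n_syn) {
  check_number(n_pre, "n_pre", lower = 1, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  check_number(n_syn, "n_syn", lower = 1, integerish = TRUE)
  structure(list(n_pre = as.double(n_pre), n_post = as.double(n_post),
                 n_syn = as.double(n_syn)),
            class = "fixed_total_spec")
}

#' Fixed-probability connectivity specification
#'
#' Each of the `n_pre x n_post` pairs is connected independently with
#' probability `p_conn`.
#'
#' @param n_pre,n_post Population sizes.
#' @param p_conn Connection probability in (0, 1].
#' @return An object of class `fixed_prob_spec`.
#' @export
fixed_probability <- function(n_pre, n_post, p_conn) {
  check_number(n_pre, "n_pre", lower = 1, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  if (!is.numeric(p_conn) || length(p_conn) != 1L || p_conn <= 0 || p_conn > 1) {
    abort("`p_conn` must lie in (0, 1].", class = "snnkit_invalid_parameter")
  }
  structure(list(n_pre = as.double(n_pre), n_post = as.double(n_post),
                 p_conn = p_conn),
            class = "fixed_prob_spec")
}

#' Normally distributed synaptic weight and delay specification
#'
#' @param weight_mean,weight_sd Weight distribution (nA); `weight_sd >= 0`.
#' @param delay_mean,delay_sd Delay distribution (ms); `delay_sd >= 0`.
#' @return An object of class `weight_delay_dist`.
#' @export
weight_delay_dist <- function(weight_mean, weight_sd, delay_mean, delay_sd) {
  check_number(weight_mean, "weight_mean")
  check_number(weight_sd, "weight_sd", lower = 0)
  check_number(delay_mean, "delay_mean", lower = 0)
  check_number(delay_sd, "delay_sd", lower = 0)
  structure(list(weight_mean = weight_mean, weight_sd = weight_sd,
                 delay_mean = delay_mean, delay_sd = delay_sd),
            class = "weight_delay_dist")
}

#' Row-capacity bound for fixed-total connectivity
#'
#' The padded column count needed so that, with probability
#' `0.9999^(1/n_pre)` per row (hence ~0.9999 for the whole matrix), no row
#' of a fixed-total connection matrix overflows: the smallest `k` with
#' `P(Binomial(n_syn, 1/n_pre) <= k) >=` that level.
#'
#' @param spec A [fixed_number_total()] specification.
#' @return An integer row capacity, at most `n_syn`.
#' @export
max_row_length_fixed_total <- function(spec) {
  stopifnot(inherits(spec, "fixed_total_spec"))
  level <- 0.9999^(1 / spec$n_pre)
  k <- qbinom(level, size = spec$n_syn, prob = 1 / spec$n_pre)
  min(k, spec$n_syn)
}

#' Row-capacity bound for fixed-probability connectivity
#'
#' Bernoulli analogue of [max_row_length_fixed_total()]: the smallest `k`
#' with `P(Binomial(n_post, p) <= k) >= 0.9999^(1/n_pre)`.
#'
#' @param n_pre,n_post Population sizes.
#' @param p Connection probability in (0, 1].
#' @return An integer row capacity, at most `n_post`.
#' @export
max_row_length_fixed_prob <- function(n_pre, n_post, p) {
  spec <- fixed_probability(n_pre, n_post, p)
  level <- 0.9999^(1 / spec$n_pre)
  qbinom(level, size = spec$n_post, prob = spec$p_conn)
}

#' Partition a fixed synapse total over presynaptic rows
#'
#' Samples per-row synapse counts from Multinomial(`n_syn`; equal
#' probabilities `1/n_pre`), so the counts always sum to `n_syn` exactly.
#' This step is inherently serial and is performed once per projection.
#'
#' @param spec A [fixed_number_total()] specification.
#' @return An integer vector of length `n_pre` summing to `n_syn`.
#' @export
partition_rows_fixed_total <- function(spec) {
  stopifnot(inherits(spec, "fixed_total_spec"))
  n_pre <- as.integer(spec$n_pre)
  if (n_pre == 1L) return(as.integer(spec$n_syn))
  as.integer(rmultinom(1, size = spec$n_syn, prob = rep.int(1 / n_pre, n_pre)))
}

# Vectorised streaming order statistics: k ascending sorted Uniform(0,1)
# samples. With E_i ~ Exp(1), u_(i) = 1 - exp(-sum_{j<=i} E_j/(k-j+1)):
# each successive value is the first-order statistic (Beta[1, remaining])
# of the samples still to place, obtained through the exponential
# transform in constant time.
sorted_uniforms <- function(k) {
  if (k == 0L) return(double(0))
  1 - exp(-cumsum(rexp(k) / seq.int(k, 1)))
}

#' Sorted postsynaptic targets for one connectivity row
#'
#' Draws `k` targets with replacement from the discrete uniform on
#' `1..n_post`, already in non-decreasing order, by walking successive
#' first-order statistics of the uniform distribution (each obtained in
#' constant time via the exponential transform) instead of sorting.
#'
#' @param k Number of synapses in the row (>= 0).
#' @param n_post Postsynaptic population size.
#' @return A non-decreasing integer vector of length `k` with values in
#'   `1..n_post` (duplicates, i.e. multapses, allowed).
#' @export
sorted_row_sample <- function(k, n_post) {
  check_number(k, "k", lower = 0, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  u <- sorted_uniforms(as.integer(k))
  as.integer(pmin(floor(u * n_post), n_post - 1)) + 1L
}

#' Bernoulli connectivity row via geometric skips
#'
#' Generates the strictly increasing target indices of one
#' fixed-probability row without touching non-connected pairs: starting
#' before the row, repeatedly skip ahead by `1 + floor(log(U)/log(1-p))`
#' (a geometric inter-success gap) and emit each landing position while it
#' remains inside the row.
#'
#' @param n_post Postsynaptic population size.
#' @param p Connection probability; `p = 0` yields an empty row,
#'   `p` outside `[0, 1]` is an error.
#' @return A strictly increasing integer vector with values in `1..n_post`.
#' @export
geometric_row_sample <- function(n_post, p) {
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    abort("`p` must lie in [0, 1].", class = "snnkit_invalid_parameter")
  }
  if (p == 0) return(integer(0))
  if (p == 1) return(seq_len(n_post))
  out <- integer(0)
  j <- -1           # position before the row, 0-based
  log1mp <- log1p(-p)
  chunk <- max(16L, as.integer(ceiling(n_post * p * 1.5 + 10)))
  while (j < n_post) {
    skips <- floor(log(runif(chunk)) / log1mp)
    pos <- j + cumsum(skips + 1)
    keep <- pos < n_post
    out <- c(out, pos[keep])
    if (!all(keep)) break
    j <- pos[chunk]
  }
  as.integer(out[out < n_post]) + 1L
}

#' Sample synaptic weights and delays
#'
#' Weights are normal with the given mean and sd, truncated (clamped at
#' zero) so that an excitatory weight never becomes negative nor an
#' inhibitory weight positive. Delays are normal in ms, rounded to the
#' nearest timestep and clamped to at least one step (the minimum
#' delivery latency). Weights are drawn before delays, so the two streams
#' are reproducible given the session RNG seed.
#'
#' @param n Number of synapses.
#' @param dist A [weight_delay_dist()].
#' @param dt Timestep (ms) used to discretise delays.
#' @param sign `+1` for excitatory (weights clamped below at 0), `-1` for
#'   inhibitory (weights clamped above at 0; supply a negative mean).
#' @return A list with numeric `weight` (nA) and integer `delay_steps`.
#' @export
sample_weights_delays <- function(n, dist, dt, sign = 1) {
  check_number(n, "n", lower = 0, integerish = TRUE)
  check_number(dt, "dt", lower = 1e-12)
  stopifnot(inherits(dist, "weight_delay_dist"), sign %in% c(-1, 1))
  n <- as.integer(n)
  w <- rnorm(n, dist$weight_mean, dist$weight_sd)
  w <- if (sign > 0) pmax(w, 0) else pmin(w, 0)
  d <- as.integer(pmax(round(rnorm(n, dist$delay_mean, dist$delay_sd) / dt), 1))
  list(weight = w, delay_steps = d)
}
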