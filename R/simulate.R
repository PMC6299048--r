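# Turning a network_spec into realized state (connectivity, weights,
# initial potentials) and running it through the compiled engine. All
# randomness flows from one root seed through labelled substreams, so
# e.g. changing the Poisson substream leaves the connectivity untouched.

# Deterministic 31-bit substream seed from a root seed and a label.
sub_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 2147483563
  as.integer((as.double(seed) * 48271 + h) %% 2147483563) + 1L
}

next_pow2 <- function(x) {
  p <- 1L
  while (p < x) p <- p * 2L
  p
}

# Vectorised fixed-total realization of one projection: multinomial row
# partition, then streaming sorted targets for all rows at once via
# grouped cumulative sums of scaled exponentials.
realize_fixed_total <- function(n_pre, n_post, n_syn) {
  spec <- fixed_number_total(n_pre, n_post, n_syn)
  row_length <- partition_rows_fixed_total(spec)
  k <- row_length[row_length > 0]
  if (!length(k)) {
    return(list(row_length = row_length, post = integer(0)))
  }
  den <- sequence(k, from = k, by = -1L)       # k_i, k_i - 1, ..., 1 per row
  e <- rexp(sum(k)) / den
  cs <- cumsum(e)
  start <- cumsum(c(0, head(k, -1)))
  offset <- rep.int(c(0, cs[cumsum(k)][-length(k)]), k)
  u <- 1 - exp(-(cs - offset))
  post <- as.integer(pmin(floor(u * n_post), n_post - 1)) + 1L
  list(row_length = row_length, post = post)
}

realize_projection <- function(pr, sizes, dt, seed) {
  n_pre <- sizes[[pr$src]]
  n_post <- sizes[[pr$tgt]]
  set.seed(sub_seed(seed, paste0("conn:", pr$name)))
  if (pr$connector == "fixed_total") {
    rt <- realize_fixed_total(n_pre, n_post, pr$n_syn)
    row_length <- rt$row_length
    post <- rt$post
  } else {
    rows <- lapply(seq_len(n_pre), function(i) geometric_row_sample(n_post, pr$p))
    row_length <- lengths(rows)
    post <- unlist(rows, use.names = FALSE) %||% integer(0)
  }
  n_syn <- sum(row_length)

  set.seed(sub_seed(seed, paste0("wd:", pr$name)))
  if (is.na(pr$weight_sd)) {
    weight <- rep.int(pr$weight_mean, n_syn)
    delay <- rep.int(max(1L, as.integer(round(pr$delay_mean / dt))), n_syn)
  } else {
    wd <- sample_weights_delays(
      n_syn,
      weight_delay_dist(pr$weight_mean, pr$weight_sd, pr$delay_mean, pr$delay_sd),
      dt = dt, sign = pr$sign)
    weight <- wd$weight
    delay <- wd$delay_steps
  }

  if (pr$structure == "bitmask") {
    pre_idx <- rep.int(seq_len(n_pre), row_length)
    m <- bitmask_matrix(n_pre, n_post, pre_idx, post)
    return(list(name = pr$name, src = pr$src, tgt = pr$tgt, type = 1L,
                n_pre = n_pre, n_post = n_post, n_syn = n_syn,
                bitmask = m, const_w = pr$weight_mean,
                const_d = max(1L, as.integer(round(pr$delay_mean / dt))),
                plastic = FALSE, max_delay = max(1L, as.integer(round(pr$delay_mean / dt)))))
  }
  m <- ragged_from_rows(n_pre, n_post, row_length, post, weight, delay)
  out <- list(name = pr$name, src = pr$src, tgt = pr$tgt, type = 0L,
              n_pre = n_pre, n_post = n_post, n_syn = n_syn,
              ragged = m, plastic = isTRUE(pr$plastic),
              max_delay = if (n_syn > 0) max(delay) else 1L)
  if (out$plastic) {
    out$stdp <- stdp_params(lam = pr$lam, w0 = pr$w0, mu = pr$mu,
                            alpha = pr$alpha, tau = pr$tau)
    out$column_view <- build_column_view(m)
  }
  out
}

#' Realize a network specification
#'
#' Draws the connectivity, synaptic weights/delays and initial membrane
#' potentials of every population and projection, using labelled
#' substreams of the root seed (`conn:*`, `wd:*`, `vinit:*`), and sizes
#' the dendritic-delay ring buffers.
#'
#' @param spec A `network_spec`.
#' @param seed Root integer seed.
#' @return An object of class `realized_network`.
#' @export
realize_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  check_number(seed, "seed", integerish = TRUE)
  sizes <- setNames(spec$populations$size, spec$populations$name)
  projections <- lapply(seq_len(nrow(spec$projections)), function(k) {
    realize_projection(spec$projections[k, ], sizes, spec$dt, seed)
  })
  v_init <- lapply(seq_len(nrow(spec$populations)), function(k) {
    p <- spec$populations[k, ]
    set.seed(sub_seed(seed, paste0("vinit:", p$name)))
    pmin(rnorm(p$size, p$v_init_mean, p$v_init_sd), p$v_thresh - 1e-6)
  })
  d_max <- vapply(spec$populations$name, function(nm) {
    incoming <- projections[vapply(projections, function(j) j$tgt == nm, logical(1))]
    md <- max(vapply(incoming, `[[`, integer(1) + 0L, "max_delay"), 1L)
    next_pow2(md + 1L)
  }, integer(1))
  structure(list(spec = spec, seed = seed, projections = projections,
                 v_init = v_init, d_max = d_max),
            class = "realized_network")
}

#' @export
print.realized_network <- function(x, ...) {
  n_syn <- sum(vapply(x$projections, `[[`, numeric(1), "n_syn"))
  cat(sprintf("<realized_network> seed %d, %d neurons, %.3g synapses\n",
              x$seed, sum(x$spec$populations$size), n_syn))
  invisible(x)
}

pack_for_engine <- function(net) {
  spec <- net$spec
  pop_names <- spec$populations$name
  pops <- lapply(seq_len(nrow(spec$populations)), function(k) {
    p <- spec$populations[k, ]
    list(n = p$size, tau_m = p$tau_m, r_m = p$r_m, v_rest = p$v_rest,
         v_thresh = p$v_thresh, v_reset = p$v_reset, tau_ref = p$tau_ref,
         syn_kind = if (p$syn_kind == "alpha") 1L else 0L,
         tau_syn = p$tau_syn,
         poisson_rate_per_step = p$poisson_rate * spec$dt / 1000,
         poisson_weight = p$poisson_weight, dc = p$dc,
         stdp_tau = if (is.na(p$stdp_tau)) 0 else p$stdp_tau,
         d_max = net$d_max[[p$name]], v_init = net$v_init[[k]])
  })
  projs <- lapply(net$projections, function(j) {
    base <- list(type = j$type, src = match(j$src, pop_names) - 1L,
                 tgt = match(j$tgt, pop_names) - 1L,
                 n_pre = j$n_pre, n_post = j$n_post,
                 plastic = isTRUE(j$plastic))
    if (j$type == 1L) {
      return(c(base, list(bits = j$bitmask$bits, const_w = j$const_w,
                          const_d = j$const_d)))
    }
    m <- j$ragged
    out <- c(base, list(
      max_row = m$max_row_length,
      row_length = m$row_length,
      post = as.integer(t(m$post_index)) - 1L,
      weight = as.double(t(m$weight)),
      delay = as.integer(t(m$delay_steps))))
    if (base$plastic) {
      cv <- j$column_view
      pos0 <- cv$position - 1L                       # column-major, 0-based
      row <- pos0 %% m$n_pre
      col <- pos0 %/% m$n_pre
      out <- c(out, list(lam = j$stdp$lam, w0 = j$stdp$w0, mu = j$stdp$mu,
                         alpha = j$stdp$alpha,
                         col_ptr = cv$col_ptr,
                         col_pos = as.integer(row * m$max_row_length + col),
                         col_pre = cv$pre - 1L))
    }
    out
  })
  list(pops = pops, projs = projs)
}

#' Run a realized network through the simulation engine
#'
#' Executes the per-timestep loop (ring-buffer read, background Poisson
#' drive, synapse filter, exact LIF update, plasticity, delayed spike
#' delivery) for `duration/dt` steps.
#'
#' @param net A `realized_network` (or a `network_spec`, which is realized
#'   first with the same root seed).
#' @param seed Root seed (used when `net` is a spec, and to derive the
#'   Poisson substream).
#' @param poisson_seed Override for the Poisson substream; with the
#'   default, it is derived from the root seed. Varying only this seed
#'   reruns identical connectivity under fresh background noise.
#' @param duration Override of the spec duration (ms).
#' @param record_spikes Record the spike raster.
#' @param spike_record_start Discard spikes before this time (ms).
#' @param record_weights_every Record plastic-weight mean/sd every this
#'   many ms (`NULL` to disable).
#' @return An object of class `sim_result` with the spike raster
#'   (tibble `time`, `neuron`, `population`), plastic weight trajectories
#'   and final weights, and a manifest of seeds and sizes.
#' @export
simulate_network <- function(net, seed = 1, poisson_seed = NULL,
                             duration = NULL, record_spikes = TRUE,
                             spike_record_start = 0,
                             record_weights_every = NULL) {
  if (inherits(net, "network_spec")) net <- realize_network(net, seed)
  stopifnot(inherits(net, "realized_network"))
  spec <- net$spec
  duration <- duration %||% spec$duration
  n_steps <- as.integer(round(duration / spec$dt))
  poisson_seed <- poisson_seed %||% sub_seed(net$seed, "poisson")
  packed <- pack_for_engine(net)
  weight_every <- if (is.null(record_weights_every)) 0L else
    max(1L, as.integer(round(record_weights_every / spec$dt)))
  res <- .run_engine(packed$pops, packed$projs, n_steps, spec$dt,
                     as.double(poisson_seed),
                     as.integer(round(spike_record_start / spec$dt)),
                     weight_every, isTRUE(record_spikes))
  pop_names <- spec$populations$name
  spikes <- tibble(time = res$spike_time,
                   neuron = res$spike_id,
                   population = pop_names[res$spike_pop])
  plastic_names <- vapply(net$projections[res$plastic_projections + 1L],
                          `[[`, character(1), "name")
  weight_stats <- NULL
  if (weight_every > 0 && length(plastic_names)) {
    weight_stats <- dplyr::bind_rows(
      setNames(lapply(res$weight_stats, as_tibble), plastic_names),
      .id = "projection")
  }
  structure(list(
    spikes = spikes,
    populations = setNames(spec$populations$size, pop_names),
    dt = spec$dt, duration = duration,
    weight_stats = weight_stats,
    final_weights = setNames(res$final_weights, plastic_names),
    manifest = list(model = spec$meta$model %||% "custom",
                    seed = net$seed, poisson_seed = poisson_seed,
                    dt = spec$dt, duration = duration,
                    n_steps = n_steps,
                    spike_time_convention = "detection step, time = (step + 1) * dt",
                    populations = as.list(setNames(spec$populations$size, pop_names)),
                    package_version = as.character(utils::packageVersion("snnkit")))),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g ms at dt = %g ms, %d spikes from %d neurons\n",
              x$duration, x$dt, nrow(x$spikes), sum(x$populations)))
  invisible(x)
}

#' Spike raster of a simulation as a tibble
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The raster tibble (`time`, `neuron`, `population`).
#' @export
tidy.sim_result <- function(x, ...) x$spikes

#' One-row summary of a simulation
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A tibble with totals and the grand-mean firing rate.
#' @export
glance.sim_result <- function(x, ...) {
  tibble(duration_ms = x$duration, dt_ms = x$dt,
         n_neurons = sum(x$populations), n_spikes = nrow(x$spikes),
         mean_rate_hz = nrow(x$spikes) /
           sum(x$populations) / (x$duration / 1000))
}

#' Spike-train set over a simulation window
#'
#' @param x A `sim_result`.
#' @param t_start,t_stop Analysis window (ms); defaults to the full run.
#' @return A [spike_train_set()].
#' @export
as_spike_train_set <- function(x, t_start = 0, t_stop = NULL) {
  stopifnot(inherits(x, "sim_result"))
  spike_train_set(x$spikes, t_start, t_stop %||% x$duration, x$populations)
}
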