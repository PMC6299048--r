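# Pure-R reference simulation loop, composed from the exported
# primitives. It is the executable definition of the per-step semantics
# the compiled engine implements; tests run both paths on small
# deterministic networks and require agreement. Poisson drive is not
# supported here (the two paths use different RNGs); use DC drive to
# evoke activity.

simulate_reference <- function(net, duration = NULL) {
  stopifnot(inherits(net, "realized_network"))
  spec <- net$spec
  if (any(spec$populations$poisson_rate > 0)) {
    abort("the reference loop only supports deterministic (DC) drive.",
          class = "snnkit_invalid_input")
  }
  duration <- duration %||% spec$duration
  n_steps <- as.integer(round(duration / spec$dt))
  dt <- spec$dt
  pop_names <- spec$populations$name

  states <- filters <- bufs <- list()
  params <- list()
  for (k in seq_len(nrow(spec$populations))) {
    p <- spec$populations[k, ]
    st <- neuron_state(p$size)
    st$v <- net$v_init[[k]]
    states[[p$name]] <- st
    filters[[p$name]] <- if (p$syn_kind == "alpha") {
      alpha_synapse_state(p$size, p$tau_syn)
    } else {
      exp_synapse_state(p$size, p$tau_syn)
    }
    bufs[[p$name]] <- delay_ring_buffer(net$d_max[[p$name]], p$size)
    params[[p$name]] <- lif_params(p$tau_m, p$r_m, p$v_rest, p$v_thresh,
                                   p$v_reset, p$tau_ref)
  }
  weights <- lapply(net$projections, function(j) {
    if (j$type == 0L) j$ragged$weight else NULL
  })

  spike_time <- double(0); spike_id <- integer(0); spike_pop <- character(0)
  for (t in seq_len(n_steps) - 1L) {
    cur_spikes <- list()
    for (k in seq_len(nrow(spec$populations))) {
      p <- spec$populations[k, ]
      nm <- p$name
      rs <- read_slot(bufs[[nm]], t)
      bufs[[nm]] <- rs$buf
      filters[[nm]] <- if (p$syn_kind == "alpha") {
        alpha_synapse_step(filters[[nm]], rs$impulse, dt)
      } else {
        exp_synapse_step(filters[[nm]], rs$impulse, dt)
      }
      ls <- lif_step(states[[nm]], params[[nm]], filters[[nm]]$i + p$dc, dt)
      states[[nm]] <- ls$state
      cur_spikes[[nm]] <- ls$spikes
      if (length(ls$spikes)) {
        spike_time <- c(spike_time, rep.int((t + 1) * dt, length(ls$spikes)))
        spike_id <- c(spike_id, ls$spikes)
        spike_pop <- c(spike_pop, rep.int(nm, length(ls$spikes)))
      }
    }
    for (k in seq_len(nrow(spec$populations))) {
      p <- spec$populations[k, ]
      if (!is.na(p$stdp_tau)) {
        states[[p$name]]$trace <- states[[p$name]]$trace * exp(-dt / p$stdp_tau)
      }
    }
    for (q in seq_along(net$projections)) {
      j <- net$projections[[q]]
      sp <- cur_spikes[[j$src]]
      if (j$type == 1L) {
        bufs[[j$tgt]] <- deliver_bitmask(bufs[[j$tgt]], sp, j$bitmask,
                                         j$const_w, t, j$const_d)
      } else {
        m <- j$ragged
        m$weight <- weights[[q]]
        if (j$plastic && length(sp)) {
          tr_tgt <- states[[j$tgt]]$trace
          for (i in sp) {
            l <- m$row_length[i]
            if (l == 0L) next
            kk <- seq_len(l)
            m$weight[i, kk] <- depress_on_pre(m$weight[i, kk],
                                              tr_tgt[m$post_index[i, kk]],
                                              j$stdp)
          }
        }
        bufs[[j$tgt]] <- deliver_ragged(bufs[[j$tgt]], sp, m, t)
        if (j$plastic && length(cur_spikes[[j$tgt]])) {
          cv <- j$column_view
          tr_src <- states[[j$src]]$trace
          for (jj in cur_spikes[[j$tgt]]) {
            rng <- seq.int(cv$col_ptr[jj] + 1L, length.out = cv$col_ptr[jj + 1L] - cv$col_ptr[jj])
            if (!length(rng)) next
            pos <- cv$position[rng]
            m$weight[pos] <- potentiate_on_post(m$weight[pos],
                                                tr_src[cv$pre[rng]], j$stdp)
          }
        }
        weights[[q]] <- m$weight
      }
    }
    for (k in seq_len(nrow(spec$populations))) {
      p <- spec$populations[k, ]
      if (!is.na(p$stdp_tau)) {
        tr <- states[[p$name]]$trace
        sp <- cur_spikes[[p$name]]
        tr[sp] <- tr[sp] + 1
        states[[p$name]]$trace <- tr
      }
    }
  }
  final_weights <- list()
  for (q in seq_along(net$projections)) {
    j <- net$projections[[q]]
    if (j$type == 0L && j$plastic) {
      m <- j$ragged
      live <- cbind(rep.int(seq_len(m$n_pre), m$row_length), sequence(m$row_length))
      final_weights[[j$name]] <- weights[[q]][live]
    }
  }
  list(spikes = tibble(time = spike_time, neuron = spike_id,
                       population = spike_pop),
       final_v = lapply(states, `[[`, "v"),
       final_weights = final_weights)
}
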