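# Spike delivery into dendritic-delay ring buffers. A delay of d steps
# written at step t lands in slot (t + d) mod d_max and is read (and the
# slot cleared) when the target population reaches step t + d. Clearing on
# read is what prevents a slot from ever being counted twice.

#' Dendritic-delay ring buffer
#'
#' A `d_max x n_post` accumulator: row `t mod d_max` holds the summed
#' synaptic impulses due to arrive at the postsynaptic population at step
#' `t`.
#'
#' @param d_max Number of delay slots; must exceed every delay in use.
#' @param n_post Postsynaptic population size.
#' @return An object of class `delay_ring_buffer`.
#' @export
delay_ring_buffer <- function(d_max, n_post) {
  check_number(d_max, "d_max", lower = 1, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  structure(list(d_max = as.integer(d_max), n_post = as.integer(n_post),
                 slots = matrix(0, as.integer(d_max), as.integer(n_post))),
            class = "delay_ring_buffer")
}

#' Deliver spikes through a ragged matrix
#'
#' For every spiking presynaptic neuron `i` and every synapse `k` of its
#' row, adds `weight[i, k]` to slot `(t + delay[i, k]) mod d_max` at the
#' postsynaptic column.
#'
#' @param buf A [delay_ring_buffer()].
#' @param spikes Integer indices of spiking presynaptic neurons.
#' @param m A [ragged_matrix()] with weight and delay tables; all delays
#'   must satisfy `1 <= d < d_max` (checked when the network is built).
#' @param t Current timestep counter (0-based).
#' @return The updated buffer.
#' @export
deliver_ragged <- function(buf, spikes, m, t) {
  stopifnot(inherits(buf, "delay_ring_buffer"), inherits(m, "ragged_matrix"))
  if (max(m$delay_steps[cbind(rep.int(seq_len(m$n_pre), m$row_length),
                              sequence(m$row_length))], 0L) >= buf$d_max) {
    abort("synaptic delays must be smaller than the ring buffer depth.",
          class = "snnkit_configuration_error")
  }
  for (i in spikes) {
    l <- m$row_length[i]
    if (l == 0L) next
    k <- seq_len(l)
    slot <- ((t + m$delay_steps[i, k]) %% buf$d_max) + 1L
    j <- m$post_index[i, k]
    w <- m$weight[i, k]
    # accumulate; duplicated (slot, j) cells must sum, so loop via rowsum
    cell <- slot + (as.double(j) - 1) * buf$d_max
    agg <- rowsum(w, group = cell)
    buf$slots[as.double(rownames(agg))] <- buf$slots[as.double(rownames(agg))] +
      agg[, 1L]
  }
  buf
}

#' Deliver spikes through a bitmask matrix
#'
#' Each postsynaptic neuron accumulates `weight` for every spiking
#' presynaptic neuron whose bit is set; the sum lands `delay` steps ahead
#' in the ring buffer.
#'
#' @param buf A [delay_ring_buffer()].
#' @param spikes Integer indices of spiking presynaptic neurons.
#' @param m A [bitmask_matrix()].
#' @param weight Constant synaptic weight (nA) of the projection.
#' @param t Current timestep counter (0-based).
#' @param delay Constant delay in steps (default 1).
#' @return The updated buffer.
#' @export
deliver_bitmask <- function(buf, spikes, m, weight, t, delay = 1L) {
  stopifnot(inherits(buf, "delay_ring_buffer"), inherits(m, "bitmask_matrix"))
  if (delay >= buf$d_max) {
    abort("synaptic delays must be smaller than the ring buffer depth.",
          class = "snnkit_configuration_error")
  }
  counts <- double(m$n_post)
  for (i in spikes) counts <- counts + bitmask_row(m, i)
  slot <- ((t + delay) %% buf$d_max) + 1L
  buf$slots[slot, ] <- buf$slots[slot, ] + weight * counts
  buf
}

#' Read (and clear) the current ring-buffer slot
#'
#' Returns the impulse vector accumulated for step `t` and zeroes that
#' slot so it can be reused `d_max` steps later.
#'
#' @param buf A [delay_ring_buffer()].
#' @param t Current timestep counter (0-based).
#' @return A list with `impulse` (numeric, length `n_post`) and `buf`
#'   (the updated buffer).
#' @export
read_slot <- function(buf, t) {
  stopifnot(inherits(buf, "delay_ring_buffer"))
  slot <- (t %% buf$d_max) + 1L
  impulse <- buf$slots[slot, ]
  buf$slots[slot, ] <- 0
  list(impulse = impulse, buf = buf)
}
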