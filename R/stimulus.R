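# Background drive: per-neuron Poisson event streams injected into the
# synaptic filter, and direct DC current injection.

#' Poisson background drive
#'
#' Describes an independent Poisson event stream per neuron: on every
#' timestep each neuron receives a Poisson-distributed number of events
#' (mean `rate_per_step`, typically `n_ext * nu_ext * dt`), each carrying
#' `weight` nA into the synaptic filter.
#'
#' @param rate_per_step Expected events per neuron per timestep (>= 0).
#' @param weight Current per event (nA).
#' @return An object of class `poisson_drive`.
#' @export
poisson_drive <- function(rate_per_step, weight) {
  check_number(rate_per_step, "rate_per_step", lower = 0)
  check_number(weight, "weight")
  structure(list(rate_per_step = rate_per_step, weight = weight),
            class = "poisson_drive")
}

#' Direct current drive
#'
#' A constant current added directly to the neuron input (bypassing the
#' synaptic filter): it models a mean current, not discrete events.
#'
#' @param current Current per neuron (nA).
#' @return An object of class `dc_drive`.
#' @export
dc_drive <- function(current) {
  check_number(current, "current")
  structure(list(current = current), class = "dc_drive")
}

# Product-of-uniforms Poisson sampler for small means: multiply uniforms
# until the product drops below exp(-mean); the number of factors needed,
# minus one, is the deviate. Vectorised over draws.
poisson_product <- function(n, mean) {
  thresh <- exp(-mean)
  k <- integer(n)
  prod <- runif(n)
  active <- which(prod >= thresh)
  while (length(active)) {
    k[active] <- k[active] + 1L
    prod[active] <- prod[active] * runif(length(active))
    active <- active[prod[active] >= thresh]
  }
  k
}

#' Sample Poisson deviates by the product-of-uniforms method
#'
#' Means below 10 are drawn directly with the product-of-uniforms method;
#' larger means are drawn exactly as the sum of independent small-mean
#' draws (Poisson additivity), so no approximation is involved.
#' Randomness comes from the R session RNG (`set.seed()` for
#' reproducibility).
#'
#' @param n Number of deviates.
#' @param mean Expected count (>= 0).
#' @return An integer vector of length `n`.
#' @examples
#' set.seed(1)
#' mean(sample_poisson(1000, 5))
#' @export
sample_poisson <- function(n, mean) {
  check_number(n, "n", lower = 0, integerish = TRUE)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean < 0) {
    abort("`mean` must be a single non-negative number.",
          class = "snnkit_invalid_parameter")
  }
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  if (mean == 0) return(integer(n))
  if (mean < 10) return(poisson_product(n, mean))
  chunks <- ceiling(mean / 5)
  out <- integer(n)
  for (i in seq_len(chunks)) out <- out + poisson_product(n, mean / chunks)
  out
}

#' Per-neuron background impulse for one timestep
#'
#' Draws each neuron's Poisson event count and multiplies it by the drive
#' weight; the result is the impulse to add to the synaptic filter this
#' step.
#'
#' @param drive A [poisson_drive()].
#' @param n_neurons Number of neurons.
#' @return A numeric vector of impulses (nA).
#' @export
background_impulse <- function(drive, n_neurons) {
  check_number(n_neurons, "n_neurons", lower = 1, integerish = TRUE)
  if (drive$rate_per_step == 0 || drive$weight == 0) return(double(n_neurons))
  sample_poisson(n_neurons, drive$rate_per_step) * drive$weight
}
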