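# Declarative network construction: a network_spec bundles population and
# projection tables; builders fill them for the two benchmark models from
# bundled literature configs, and downscale() applies statistics-
# preserving scaling rules.

#' Downscaling configuration
#'
#' @param K Scale factor in (0, 1]: the ratio of reduced to full network
#'   size.
#' @param weight_exponent Exponent `g` of the compensating weight scaling
#'   `w -> w * K^(-g)` applied when in-degrees shrink; the default 0.5
#'   (i.e. `1/sqrt(K)`) preserves the variance of the summed synaptic
#'   input.
#' @param dc_compensation Replace the mean input lost to scaling by a DC
#'   current computed from full-scale in-degrees, weights and reference
#'   rates.
#' @param indegree `"scale"` (default): per-neuron in-degrees shrink by
#'   `K` and the weight/DC compensation applies. `"preserve"`: total
#'   synapse counts shrink only by `K`, keeping in-degrees (and therefore
#'   input statistics) unchanged, with no compensation needed.
#' @return An object of class `scale_config`.
#' @export
scale_config <- function(K = 1, weight_exponent = 0.5, dc_compensation = TRUE,
                         indegree = c("scale", "preserve")) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K > 1) {
    abort("`K` must lie in (0, 1].", class = "snnkit_invalid_parameter")
  }
  check_number(weight_exponent, "weight_exponent", lower = 0)
  structure(list(K = K, weight_exponent = weight_exponent,
                 dc_compensation = isTRUE(dc_compensation),
                 indegree = match.arg(indegree)),
            class = "scale_config")
}

new_network_spec <- function(populations, projections, dt, duration, meta) {
  structure(list(populations = populations, projections = projections,
                 dt = dt, duration = duration, meta = meta),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d populations, %d projections, dt = %g ms, duration = %g ms\n",
              nrow(x$populations), nrow(x$projections), x$dt, x$duration))
  cat(sprintf("  neurons: %s (total %d)\n",
              paste(sprintf("%s=%d", x$populations$name, x$populations$size),
                    collapse = ", "),
              sum(x$populations$size)))
  invisible(x)
}

#' Total synapse count implied by a pairwise connection probability
#'
#' The source model's convention: the expected number of draws with
#' replacement from the `n_pre x n_post` grid after which a given pair has
#' been hit at least once with probability `p`:
#' `round(log(1-p) / log(1 - 1/(n_pre n_post)))`. A simple-product
#' alternative `round(p n_pre n_post)` is selectable.
#'
#' @param p Connection probability.
#' @param n_pre,n_post Population sizes.
#' @param convention `"pairwise_bernoulli"` (default) or `"product"`.
#' @return A synapse count.
#' @export
n_syn_from_probability <- function(p, n_pre, n_post,
                                   convention = c("pairwise_bernoulli", "product")) {
  convention <- match.arg(convention)
  if (p <= 0) return(0)
  grid <- as.double(n_pre) * as.double(n_post)
  if (convention == "product") return(round(p * grid))
  round(log1p(-p) / log1p(-1 / grid))
}

read_model_config <- function(name, config = NULL) {
  path <- config %||% system.file("extdata", paste0(name, ".yaml"),
                                  package = "snnkit", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !length(cfg)) {
    abort(sprintf("configuration file %s is empty.", path),
          class = "snnkit_configuration_error")
  }
  cfg
}

require_keys <- function(cfg, keys, where) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing)) {
    abort(sprintf("configuration block `%s` is missing keys: %s",
                  where, paste(missing, collapse = ", ")),
          class = "snnkit_configuration_error")
  }
}

#' Build the eight-population layered cortical microcircuit
#'
#' Constructs the full-scale model (77,169 neurons in four excitatory/
#' inhibitory layer pairs, 64 fixed-total projections with
#' literature-derived synapse counts, normally distributed weights and
#' delays, exponential synapse filters and per-population Poisson drive)
#' and then applies [downscale()] with the given scaling configuration.
#'
#' @param scale A [scale_config()]; the default builds at full scale.
#' @param duration Biological time to simulate (ms).
#' @param config Optional path to an alternative model configuration.
#' @param nsyn_convention Probability-to-count convention, see
#'   [n_syn_from_probability()].
#' @return A `network_spec`.
#' @examples
#' spec <- build_microcircuit(scale_config(0.1), duration = 1000)
#' sum(spec$populations$size)
#' @export
build_microcircuit <- function(scale = scale_config(1), duration = 10000,
                               config = NULL,
                               nsyn_convention = "pairwise_bernoulli") {
  stopifnot(inherits(scale, "scale_config"))
  cfg <- read_model_config("microcircuit", config)
  require_keys(cfg, c("dt_ms", "populations", "neuron", "conn_prob", "weights",
                      "delays", "external", "reference_rates_hz"), "microcircuit")
  require_keys(cfg$neuron, c("tau_m_ms", "c_m_pf", "v_rest_mv", "v_thresh_mv",
                             "v_reset_mv", "tau_ref_ms", "tau_syn_ms",
                             "v_init_mean_mv", "v_init_sd_mv"), "neuron")
  nm <- cfg$populations$names
  sizes <- as.integer(cfg$populations$sizes)
  nu <- cfg$neuron
  r_m <- nu$tau_m_ms / (cfg$neuron$c_m_pf / 1000)  # MOhm from pF: tau/C
  exc <- grepl("e$", nm)

  pops <- tibble(
    name = nm, size = sizes,
    tau_m = nu$tau_m_ms, r_m = r_m,
    v_rest = nu$v_rest_mv, v_thresh = nu$v_thresh_mv,
    v_reset = nu$v_reset_mv, tau_ref = nu$tau_ref_ms,
    syn_kind = "exp", tau_syn = nu$tau_syn_ms,
    poisson_rate = as.double(cfg$external$k_ext) * cfg$external$nu_ext_hz,
    poisson_weight = cfg$external$weight_na,
    dc = 0,
    v_init_mean = nu$v_init_mean_mv, v_init_sd = nu$v_init_sd_mv,
    stdp_tau = NA_real_)

  w <- cfg$weights; d <- cfg$delays
  proj <- tidyr::expand_grid(tgt = nm, src = nm)
  proj <- dplyr::mutate(proj,
    p = purrr::map2_dbl(.data$tgt, .data$src, ~cfg$conn_prob[[.x]][[.y]]),
    name = paste0(.data$src, "->", .data$tgt))
  proj <- proj[proj$p > 0, ]
  src_exc <- grepl("e$", proj$src)
  n_pre <- sizes[match(proj$src, nm)]
  n_post <- sizes[match(proj$tgt, nm)]
  proj <- dplyr::mutate(proj,
    connector = "fixed_total",
    n_syn = purrr::pmap_dbl(list(.data$p, n_pre, n_post),
                            n_syn_from_probability,
                            convention = nsyn_convention),
    weight_mean = ifelse(src_exc, w$exc_mean_na, w$inh_mean_na),
    weight_sd = ifelse(src_exc, w$exc_sd_na, w$inh_sd_na),
    delay_mean = ifelse(src_exc, d$exc_mean_ms, d$inh_mean_ms),
    delay_sd = ifelse(src_exc, d$exc_sd_ms, d$inh_sd_ms),
    sign = ifelse(src_exc, 1, -1),
    structure = "ragged", plastic = FALSE,
    lam = NA_real_, w0 = NA_real_, mu = NA_real_, alpha = NA_real_,
    tau = NA_real_)
  dev <- proj$src == "L4e" & proj$tgt == "L23e"
  proj$weight_mean[dev] <- w$l4e_to_l23e_mean_na
  proj$weight_sd[dev] <- w$l4e_to_l23e_sd_na

  spec <- new_network_spec(
    pops, proj, dt = cfg$dt_ms, duration = duration,
    meta = list(model = "microcircuit",
                full_sizes = setNames(sizes, nm),
                full_n_syn = setNames(proj$n_syn, proj$name),
                reference_rates_hz = setNames(as.double(cfg$reference_rates_hz), nm)))
  downscale(spec, scale)
}

# Mean synaptic current (nA) per neuron of each population at full scale:
# tau_syn * (sum over sources of indegree * mean weight * rate + external
# drive), with rates in events/ms. Used for DC compensation.
full_scale_mean_input <- function(spec) {
  pops <- spec$populations
  mu <- setNames(numeric(nrow(pops)), pops$name)
  ref <- spec$meta$reference_rates_hz
  full_sizes <- spec$meta$full_sizes
  for (k in seq_len(nrow(spec$projections))) {
    pr <- spec$projections[k, ]
    n_syn_full <- spec$meta$full_n_syn[[pr$name]]
    indeg <- n_syn_full / full_sizes[[pr$tgt]]
    mu[pr$tgt] <- mu[pr$tgt] +
      indeg * pr$weight_mean * (ref[[pr$src]] / 1000)
  }
  mu <- mu * pops$tau_syn[match(names(mu), pops$name)]
  mu_ext <- pops$tau_syn * (pops$poisson_rate / 1000) * pops$poisson_weight
  list(recurrent = mu, external = setNames(mu_ext, pops$name))
}

#' Downscale a network specification
#'
#' Applies size scaling with compensating adjustments designed to
#' preserve spiking statistics. Population sizes always shrink by `K`.
#' In `indegree = "scale"` mode, fixed-total synapse counts shrink by
#' `K^2` (in-degrees by `K`), all synaptic weights are multiplied by
#' `K^(-g)` (default `1/sqrt(K)`, preserving input variance), the Poisson
#' background rate shrinks by `K`, and the mean input lost to these
#' changes is replaced by a DC current `(1 - K^g) * mu_full` computed from
#' full-scale in-degrees, weights and reference rates. In
#' `indegree = "preserve"` mode, synapse totals shrink only by `K`,
#' leaving per-neuron input statistics untouched, so no compensation is
#' applied. `K = 1` is the identity in both modes (no DC drive).
#'
#' @param spec A full-scale `network_spec` with fixed-total projections.
#' @param scale A [scale_config()].
#' @return The scaled `network_spec`.
#' @export
downscale <- function(spec, scale) {
  stopifnot(inherits(spec, "network_spec"), inherits(scale, "scale_config"))
  K <- scale$K
  g <- scale$weight_exponent
  out <- spec
  out$populations$size <- as.integer(round(spec$populations$size * K))
  if (any(out$populations$size < 1L)) {
    abort("scaling factor K leaves an empty population.",
          class = "snnkit_invalid_parameter")
  }
  ft <- spec$projections$connector == "fixed_total"
  if (scale$indegree == "preserve") {
    out$projections$n_syn[ft] <- pmax(round(spec$projections$n_syn[ft] * K), 1)
    return(out)
  }
  out$projections$n_syn[ft] <- pmax(round(spec$projections$n_syn[ft] * K^2), 1)
  wf <- K^(-g)
  out$projections$weight_mean <- spec$projections$weight_mean * wf
  out$projections$weight_sd <- spec$projections$weight_sd * wf
  out$populations$poisson_rate <- spec$populations$poisson_rate * K
  out$populations$poisson_weight <- spec$populations$poisson_weight * wf
  if (scale$dc_compensation && K < 1) {
    mu <- full_scale_mean_input(spec)
    out$populations$dc <- spec$populations$dc +
      (1 - K^g) * (mu$recurrent[out$populations$name] +
                     mu$external[out$populations$name])
  }
  out
}

#' Build the plastic balanced random network
#'
#' Two populations (excitatory and inhibitory, 4:1) with ~0.1 fixed
#' connection probability, alpha synapse filters, constant-weight static
#' projections (bitmask-representable) and power-law STDP on the
#' excitatory-to-excitatory projection.
#'
#' When `preserve_indegree = TRUE` the connection probability is raised to
#' `min(1, p/scale)` so per-neuron in-degrees stay as close to full scale
#' as the reduced population allows; the residual in-degree fraction `k`
#' is compensated by scaling every synaptic weight, the external drive
#' weight and the STDP reference weight `w0` by `1/sqrt(k)` (preserving
#' input variance and the rule's relative equilibrium) plus a
#' mean-restoring DC term, with the background rate scaled by `k`.
#'
#' @param scale Size scale factor in (0, 1].
#' @param duration Biological time to simulate (ms).
#' @param structure Structure for the static projections: `"bitmask"`
#'   (default) or `"ragged"`.
#' @param preserve_indegree Compensated in-degree preservation, see above.
#' @param config Optional path to an alternative model configuration.
#' @return A `network_spec`.
#' @examples
#' spec <- build_balanced_network(scale = 0.02, duration = 1000)
#' spec$populations$size
#' @export
build_balanced_network <- function(scale = 1, duration = 10000,
                                   structure = c("bitmask", "ragged"),
                                   preserve_indegree = FALSE, config = NULL) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1) {
    abort("`scale` must lie in (0, 1].", class = "snnkit_invalid_parameter")
  }
  structure_kind <- match.arg(structure)
  cfg <- read_model_config("balanced", config)
  require_keys(cfg, c("dt_ms", "populations", "neuron", "connectivity",
                      "weights", "stdp", "external"), "balanced")
  nu <- cfg$neuron
  r_m <- nu$tau_m_ms / (nu$c_m_pf / 1000)
  n_exc <- as.integer(round(cfg$populations$n_exc * scale))
  n_inh <- as.integer(round(cfg$populations$n_inh * scale))
  p0 <- cfg$connectivity$p_conn
  p_eff <- if (preserve_indegree) min(1, p0 / scale) else p0
  # achieved fraction of the full-scale in-degree
  k <- (p_eff * scale) / p0
  wf <- k^(-0.5)
  w_exc <- cfg$weights$exc_init_na
  w_inh <- cfg$weights$inh_init_na
  ext_rate <- cfg$external$rate_hz * k
  ext_w <- cfg$external$weight_na * wf
  # mean-input compensation for the reduced in-degree (full in-degrees,
  # equilibrium weights, nominal stationary rate)
  dc <- 0
  if (k < 1) {
    ref_hz <- cfg$stdp$reference_rate_hz %||% 8.8
    k_e <- p0 * cfg$populations$n_exc
    k_i <- p0 * cfg$populations$n_inh
    mu_rec <- nu$tau_syn_ms * (ref_hz / 1000) * (k_e * w_exc + k_i * w_inh)
    mu_ext <- nu$tau_syn_ms * (cfg$external$rate_hz / 1000) * cfg$external$weight_na
    dc <- (1 - sqrt(k)) * (mu_rec + mu_ext)
  }

  pop_tbl <- tibble(
    name = c("exc", "inh"), size = c(n_exc, n_inh),
    tau_m = nu$tau_m_ms, r_m = r_m,
    v_rest = nu$v_rest_mv, v_thresh = nu$v_thresh_mv,
    v_reset = nu$v_reset_mv, tau_ref = nu$tau_ref_ms,
    syn_kind = "alpha", tau_syn = nu$tau_syn_ms,
    poisson_rate = ext_rate, poisson_weight = ext_w,
    dc = dc,
    v_init_mean = nu$v_init_mean_mv, v_init_sd = nu$v_init_sd_mv,
    stdp_tau = c(cfg$stdp$tau_ms, NA_real_))

  st <- cfg$stdp
  delay <- cfg$connectivity$delay_ms
  proj_row <- function(src, tgt, weight, plastic) {
    tibble(tgt = tgt, src = src, name = paste0(src, "->", tgt),
           connector = "fixed_prob", n_syn = NA_real_, p = p_eff,
           weight_mean = weight, weight_sd = NA_real_,
           delay_mean = delay, delay_sd = 0,
           sign = sign(weight),
           structure = if (plastic) "ragged" else structure_kind,
           plastic = plastic,
           lam = if (plastic) st$lambda else NA_real_,
           w0 = if (plastic) st$w0_na * wf else NA_real_,
           mu = if (plastic) st$mu else NA_real_,
           alpha = if (plastic) st$alpha else NA_real_,
           tau = if (plastic) st$tau_ms else NA_real_)
  }
  proj <- dplyr::bind_rows(
    proj_row("exc", "exc", w_exc * wf, TRUE),
    proj_row("exc", "inh", w_exc * wf, FALSE),
    proj_row("inh", "exc", w_inh * wf, FALSE),
    proj_row("inh", "inh", w_inh * wf, FALSE))

  new_network_spec(
    pop_tbl, proj, dt = cfg$dt_ms, duration = duration,
    meta = list(model = "balanced", scale = scale, indegree_fraction = k,
                stdp = st))
}
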