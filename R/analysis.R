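# Spike-train statistics used to validate simulations: per-neuron rates
# and CV ISI, binned pairwise correlations, Freedman-Diaconis histogram
# grids, fixed-bandwidth Gaussian smoothing, KL divergence against a
# reference run, and the Fano factor of pooled population counts.

#' Bundle a spike raster into a spike-train set
#'
#' @param spikes A data frame with columns `time` (ms), `neuron`
#'   (1-based id within its population) and `population`.
#' @param t_start,t_stop Analysis window (ms); spikes outside are dropped.
#' @param sizes Named integer vector of population sizes (so silent
#'   neurons are representable).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, t_start, t_stop, sizes) {
  check_number(t_start, "t_start", lower = 0)
  check_number(t_stop, "t_stop")
  if (t_stop <= t_start) {
    abort("`t_stop` must exceed `t_start`.", class = "snnkit_invalid_parameter")
  }
  stopifnot(is.data.frame(spikes), !is.null(names(sizes)))
  keep <- spikes$time >= t_start & spikes$time < t_stop
  spikes <- as_tibble(spikes[keep, c("time", "neuron", "population")])
  spikes <- dplyr::arrange(spikes, .data$population, .data$neuron, .data$time)
  structure(list(spikes = spikes, t_start = t_start, t_stop = t_stop,
                 sizes = sizes),
            class = "spike_train_set")
}

#' Per-neuron firing rates
#'
#' Spike count inside the analysis window divided by the window length;
#' silent neurons are reported with rate 0.
#'
#' @param s A [spike_train_set()].
#' @return A tibble with `population`, `neuron`, `rate` (Hz).
#' @export
firing_rates <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  window_s <- (s$t_stop - s$t_start) / 1000
  counts <- dplyr::count(s$spikes, .data$population, .data$neuron)
  full <- tidyr::expand_grid(
    population = names(s$sizes)
  )
  full <- dplyr::mutate(full,
                        neuron = purrr::map(.data$population,
                                            ~seq_len(s$sizes[[.x]])))
  full <- tidyr::unnest(full, "neuron")
  out <- dplyr::left_join(full, counts, by = c("population", "neuron"))
  dplyr::mutate(out,
                rate = dplyr::coalesce(.data$n, 0L) / window_s,
                n = NULL)
}

#' Coefficient of variation of inter-spike intervals
#'
#' SD of a neuron's inter-spike intervals divided by their mean. The
#' population SD convention (divide by the number of intervals) is the
#' default; neurons with fewer than three spikes are undefined (`NA`).
#'
#' @param train Sorted spike times of one neuron (ms).
#' @param convention `"population"` (divide by n) or `"sample"`
#'   (divide by n - 1).
#' @return A single CV value, or `NA` for fewer than two intervals.
#' @export
cv_isi <- function(train, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(train) < 3L) return(NA_real_)
  isi <- diff(train)
  m <- mean(isi)
  if (m == 0) return(NA_real_)
  s2 <- if (convention == "population") mean((isi - m)^2) else var(isi)
  sqrt(s2) / m
}

#' Per-neuron CV ISI table
#'
#' @param s A [spike_train_set()].
#' @inheritParams cv_isi
#' @return A tibble with `population`, `neuron`, `cv` (NA when undefined).
#' @export
cv_isi_set <- function(s, convention = "population") {
  stopifnot(inherits(s, "spike_train_set"))
  dplyr::summarise(dplyr::group_by(s$spikes, .data$population, .data$neuron),
                   cv = cv_isi(.data$time, convention = convention),
                   .groups = "drop")
}

#' Pairwise correlations of binned spike trains
#'
#' Samples `n_sample` active (at least one spike) neurons from one
#' population, bins their trains, and returns the
#' `n_sample (n_sample - 1)/2` distinct-pair Pearson correlation
#' coefficients. Sampling uses the session RNG; seed it for
#' reproducibility.
#'
#' @param s A [spike_train_set()].
#' @param population Population name.
#' @param n_sample Number of neurons to correlate (default 200).
#' @param bin Bin width (ms, default 2).
#' @return A numeric vector of off-diagonal correlation coefficients.
#' @export
binned_correlations <- function(s, population, n_sample = 200, bin = 2) {
  stopifnot(inherits(s, "spike_train_set"))
  check_number(n_sample, "n_sample", lower = 2, integerish = TRUE)
  check_number(bin, "bin", lower = 1e-12)
  sp <- s$spikes[s$spikes$population == population, ]
  active <- unique(sp$neuron)
  if (length(active) < n_sample) {
    abort(sprintf("population %s has only %d active neurons (< %d).",
                  population, length(active), n_sample),
          class = "snnkit_invalid_input")
  }
  chosen <- sort(sample(active, n_sample))
  n_bins <- ceiling((s$t_stop - s$t_start) / bin)
  counts <- matrix(0L, n_bins, n_sample)
  for (k in seq_along(chosen)) {
    tt <- sp$time[sp$neuron == chosen[k]]
    b <- pmin(floor((tt - s$t_start) / bin) + 1L, n_bins)
    counts[, k] <- tabulate(b, nbins = n_bins)
  }
  cc <- cor(counts)
  cc[upper.tri(cc)]
}

#' Freedman-Diaconis histogram edges
#'
#' Bin width `2 IQR n^(-1/3)` computed from a reference sample; the edges
#' span the sample range.
#'
#' @param reference_sample Numeric values (length >= 2, positive IQR).
#' @return A numeric vector of bin edges.
#' @export
fd_bin_edges <- function(reference_sample) {
  x <- reference_sample[is.finite(reference_sample)]
  if (length(x) < 2L) {
    abort("need at least two finite values.", class = "snnkit_invalid_parameter")
  }
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (iqr <= 0) {
    abort("degenerate sample: inter-quartile range is zero.",
          class = "snnkit_degenerate_sample")
  }
  width <- 2 * iqr * length(x)^(-1 / 3)
  lo <- min(x)
  n_bins <- max(1, ceiling((max(x) - lo) / width))
  seq(lo, by = width, length.out = n_bins + 1)
}

#' Smoothed, discretised distribution on a fixed grid
#'
#' Evaluates a Gaussian-kernel density with the given fixed bandwidth at
#' the centres of the supplied bin edges and normalises the masses to sum
#' to one.
#'
#' @param sample Numeric values.
#' @param bandwidth Kernel standard deviation, in the sample's units.
#' @param edges Bin edges (e.g. from [fd_bin_edges()]).
#' @return An object of class `dist_summary` with fields `edges`, `mass`
#'   and `bandwidth`.
#' @export
kde_distribution <- function(sample, bandwidth, edges) {
  check_number(bandwidth, "bandwidth", lower = 1e-300)
  x <- sample[is.finite(sample)]
  if (!length(x)) {
    abort("empty sample.", class = "snnkit_invalid_parameter")
  }
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  dens <- vapply(centers, function(c0) sum(dnorm(c0, mean = x, sd = bandwidth)),
                 numeric(1))
  total <- sum(dens)
  if (total == 0) dens <- rep.int(1, length(dens))  # uniform fallback
  structure(list(edges = edges, mass = dens / sum(dens), bandwidth = bandwidth),
            class = "dist_summary")
}

#' Kullback-Leibler divergence between two discretised distributions
#'
#' `sum p_k log(p_k / q_k)` in nats over bins with `p_k > 0`; the
#' reference-side masses `q` are floored at `1e-12` and renormalised so
#' empty reference bins stay finite.
#'
#' @param p,q [kde_distribution()] summaries on identical edges; `q` is
#'   the reference.
#' @return KL divergence in nats (>= 0 up to the epsilon flooring).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "dist_summary"), inherits(q, "dist_summary"))
  if (length(p$edges) != length(q$edges) ||
      max(abs(p$edges - q$edges)) > 1e-9) {
    abort("`p` and `q` must share identical bin edges.",
          class = "snnkit_invalid_input")
  }
  qm <- pmax(q$mass, 1e-12)
  qm <- qm / sum(qm)
  keep <- p$mass > 0
  sum(p$mass[keep] * log(p$mass[keep] / qm[keep]))
}

#' Fano factor of pooled population spike counts
#'
#' Pools the spike trains of `n_sample` neurons from one population into a
#' single histogram with `bin`-ms bins and returns the variance of the
#' per-bin counts divided by their mean.
#'
#' @param s A [spike_train_set()].
#' @param population Population name.
#' @param n_sample Number of neurons to pool (default 1000); sampled from
#'   the whole population with the session RNG.
#' @param bin Bin width in ms (default 3).
#' @return The Fano factor, or `NA` if the mean count is zero.
#' @export
fano_factor <- function(s, population, n_sample = 1000, bin = 3) {
  stopifnot(inherits(s, "spike_train_set"))
  check_number(n_sample, "n_sample", lower = 1, integerish = TRUE)
  size <- s$sizes[[population]]
  if (is.null(size) || size < n_sample) {
    abort("population smaller than `n_sample`.", class = "snnkit_invalid_input")
  }
  chosen <- sample(seq_len(size), n_sample)
  sp <- s$spikes[s$spikes$population == population &
                   s$spikes$neuron %in% chosen, ]
  n_bins <- floor((s$t_stop - s$t_start) / bin)
  if (n_bins < 2L) {
    abort("analysis window shorter than two bins.",
          class = "snnkit_invalid_parameter")
  }
  b <- floor((sp$time - s$t_start) / bin) + 1L
  counts <- tabulate(b[b <= n_bins], nbins = n_bins)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  # population variance over bins, matching the CV ISI convention
  mean((counts - m)^2) / m
}

#' Compare two recorded runs population by population
#'
#' Computes, for every population, the KL divergence of the smoothed
#' rate, CV ISI and binned-correlation distributions of a candidate run
#' against a reference run. Histogram grids come from the reference
#' sample (Freedman-Diaconis rule); smoothing uses the fixed bandwidths
#' 0.3 /s, 0.04 and 0.002 respectively; the reference is the `q` side of
#' the divergence. Correlations are computed for populations with at
#' least `n_sample` active neurons, using `corr_seed` for the neuron
#' sampling in both runs.
#'
#' @param candidate,reference [spike_train_set()] objects over matching
#'   populations.
#' @param n_sample Neurons per population for the correlation measure.
#' @param corr_seed Seed for correlation neuron sampling.
#' @return A tibble with `population`, `measure` (`"rate"`, `"cv_isi"`,
#'   `"correlation"`) and `kl` (nats; `NA` where a measure is undefined).
#' @export
compare_spike_trains <- function(candidate, reference, n_sample = 100,
                                 corr_seed = 1) {
  stopifnot(inherits(candidate, "spike_train_set"),
            inherits(reference, "spike_train_set"))
  bandwidths <- c(rate = 0.3, cv_isi = 0.04, correlation = 0.002)
  pops <- names(reference$sizes)
  ref_rates <- firing_rates(reference)
  can_rates <- firing_rates(candidate)
  ref_cv <- cv_isi_set(reference)
  can_cv <- cv_isi_set(candidate)
  grab <- function(s, pop) {
    n_active <- length(unique(s$spikes$neuron[s$spikes$population == pop]))
    if (n_active < n_sample) return(NULL)
    set.seed(corr_seed)
    binned_correlations(s, pop, n_sample = n_sample)
  }
  rows <- list()
  for (pop in pops) {
    vals <- list(
      rate = list(ref = ref_rates$rate[ref_rates$population == pop],
                  can = can_rates$rate[can_rates$population == pop]),
      cv_isi = list(ref = ref_cv$cv[ref_cv$population == pop],
                    can = can_cv$cv[can_cv$population == pop]),
      correlation = list(ref = grab(reference, pop),
                         can = grab(candidate, pop)))
    for (measure in names(vals)) {
      v <- vals[[measure]]
      kl <- NA_real_
      ref_ok <- sum(is.finite(v$ref)) > 2 && !is.null(v$can)
      if (ref_ok && length(unique(v$ref[is.finite(v$ref)])) > 2) {
        edges <- tryCatch(fd_bin_edges(v$ref), error = function(e) NULL)
        if (!is.null(edges)) {
          bw <- bandwidths[[measure]]
          kl <- kl_divergence(kde_distribution(v$can, bw, edges),
                              kde_distribution(v$ref, bw, edges))
        }
      }
      rows[[length(rows) + 1L]] <- tibble(population = pop,
                                          measure = measure, kl = kl)
    }
  }
  dplyr::bind_rows(rows)
}

#' Summary statistics table for a spike-train set
#'
#' Mean rate, mean defined CV ISI and active-neuron count per population.
#'
#' @param s A [spike_train_set()].
#' @return A tibble with one row per population.
#' @export
summarise_spike_trains <- function(s) {
  rates <- dplyr::summarise(dplyr::group_by(firing_rates(s), .data$population),
                            mean_rate = mean(.data$rate),
                            active = sum(.data$rate > 0), .groups = "drop")
  cvs <- dplyr::summarise(dplyr::group_by(cv_isi_set(s), .data$population),
                          mean_cv_isi = mean(.data$cv, na.rm = TRUE),
                          .groups = "drop")
  dplyr::left_join(rates, cvs, by = "population")
}
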