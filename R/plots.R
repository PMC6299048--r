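# ggplot2 views of simulation results and analysis summaries.

#' Raster plot of a simulation
#'
#' @param object A `sim_result`.
#' @param fraction Fraction of neurons per population to draw
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, fraction = 0.05, ...) {
  sp <- object$spikes
  keep <- unlist(lapply(names(object$populations), function(pop) {
    n <- object$populations[[pop]]
    shown <- max(1L, floor(n * fraction))
    which(sp$population == pop & sp$neuron <= shown)
  }))
  sp <- sp[keep, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Histogram of final plastic weights
#'
#' @param x A `sim_result` with recorded plastic weights.
#' @param projection Projection name (default: first plastic projection).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(x, projection = NULL, bins = 60) {
  stopifnot(inherits(x, "sim_result"), length(x$final_weights) > 0)
  projection <- projection %||% names(x$final_weights)[1]
  w <- tibble(weight_pa = x$final_weights[[projection]] * 1000)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight_pa)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "synaptic weight (pA)", y = "synapses",
                  title = projection) +
    ggplot2::theme_minimal()
}

#' Smoothed distribution summary as a line plot
#'
#' @param object A `dist_summary` from [kde_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dist_summary <- function(object, ...) {
  centers <- (head(object$edges, -1) + tail(object$edges, -1)) / 2
  df <- tibble(x = centers, mass = object$mass)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mass)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "probability mass") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
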