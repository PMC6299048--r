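# Spike-train statistics pipeline.

make_set <- function(spikes, t_start, t_stop, sizes) {
  spike_train_set(spikes, t_start, t_stop, sizes)
}

test_that("firing rates are counts over the window, with silent neurons at zero", {
  sp <- tibble::tibble(time = seq(500, 8500, length.out = 9),
                       neuron = 1L, population = "p")
  s <- make_set(sp, 0, 9000, c(p = 3L))
  r <- firing_rates(s)
  expect_equal(r$rate, c(1, 0, 0))
  set.seed(51)
  sp2 <- tibble::tibble(time = sort(runif(700, 0, 1e5)), neuron = 1L,
                        population = "p")
  s2 <- make_set(sp2, 0, 1e5, c(p = 1L))
  expect_lt(abs(firing_rates(s2)$rate[1] - 7), 4 * sqrt(700) / 100)
  expect_error(spike_train_set(sp, 10, 10, c(p = 1L)),
               class = "snnkit_invalid_parameter")
})

test_that("CV ISI follows the population-SD convention and flags short trains", {
  expect_equal(cv_isi(seq(0, 100, by = 10)), 0)
  expect_equal(cv_isi(c(0, 1, 4)), 0.5)        # intervals (1, 3), sd_pop = 1
  expect_true(is.na(cv_isi(c(1, 2))))
  set.seed(52)
  train <- cumsum(rexp(20000, rate = 1))
  expect_equal(cv_isi(train), 1, tolerance = 0.05)
})

test_that("binned correlations: identical trains give 1, independent give ~0", {
  set.seed(53)
  dup <- sort(runif(400, 0, 1e4))
  sp <- dplyr::bind_rows(
    tibble::tibble(time = dup, neuron = 1L, population = "p"),
    tibble::tibble(time = dup, neuron = 2L, population = "p"))
  s <- make_set(sp, 0, 1e4, c(p = 2L))
  expect_equal(binned_correlations(s, "p", n_sample = 2), 1)
  # independent Poisson trains at 8 Hz for 100 s
  n <- 60
  sp2 <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
    tibble::tibble(time = sort(runif(800, 0, 1e5)), neuron = j,
                   population = "q")
  }))
  s2 <- make_set(sp2, 0, 1e5, c(q = n))
  cc <- binned_correlations(s2, "q", n_sample = n)
  expect_length(cc, n * (n - 1) / 2)
  expect_lt(abs(mean(cc)), 0.01)
  expect_error(binned_correlations(s2, "q", n_sample = n + 1),
               class = "snnkit_invalid_input")
})

test_that("Freedman-Diaconis edges use 2 IQR n^(-1/3) and span the sample", {
  set.seed(54)
  x <- runif(8000)
  e <- fd_bin_edges(x)
  width <- 2 * diff(quantile(x, c(0.25, 0.75), names = FALSE)) * 8000^(-1 / 3)
  expect_equal(diff(e)[1], width)
  expect_lte(min(e), min(x))
  expect_gte(max(e), max(x))
  expect_error(fd_bin_edges(rep(1, 50)), class = "snnkit_degenerate_sample")
})

test_that("fixed-bandwidth KDE discretisation is normalised and converges to the histogram", {
  e <- seq(-1, 1, by = 0.1)
  d <- kde_distribution(0.05, bandwidth = 0.1, edges = e)
  expect_equal(sum(d$mass), 1)
  expect_equal(which.max(d$mass), which.min(abs((head(e, -1) + tail(e, -1)) / 2 - 0.05)))
  set.seed(55)
  x <- rnorm(20000)
  e2 <- fd_bin_edges(x)
  w <- diff(e2)[1]
  h <- hist(x, breaks = e2, plot = FALSE)$counts
  tv <- function(bw) {
    d <- kde_distribution(x, bandwidth = bw, edges = e2)
    sum(abs(d$mass - h / sum(h))) / 2
  }
  # shrinking the bandwidth converges on the raw histogram mass
  expect_lt(tv(w / 5), tv(2 * w))
  expect_lt(tv(w / 5), 0.05)
  expect_error(kde_distribution(x, 0, e2), class = "snnkit_invalid_parameter")
})

test_that("KL divergence matches hand-computed masses and is non-negative", {
  e <- c(0, 1, 2)
  p <- structure(list(edges = e, mass = c(0.5, 0.5), bandwidth = 1),
                 class = "dist_summary")
  q <- structure(list(edges = e, mass = c(0.25, 0.75), bandwidth = 1),
                 class = "dist_summary")
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-10)
  expect_equal(kl_divergence(p, p), 0)
  set.seed(56)
  for (r in 1:20) {
    a <- runif(6); b <- runif(6)
    pa <- structure(list(edges = 0:6, mass = a / sum(a), bandwidth = 1),
                    class = "dist_summary")
    pb <- structure(list(edges = 0:6, mass = b / sum(b), bandwidth = 1),
                    class = "dist_summary")
    expect_gte(kl_divergence(pa, pb), 0)
  }
  bad <- structure(list(edges = c(0, 1, 3), mass = c(0.5, 0.5), bandwidth = 1),
                   class = "dist_summary")
  expect_error(kl_divergence(p, bad), class = "snnkit_invalid_input")
})

test_that("Fano factor of pooled independent Poisson trains is ~1", {
  set.seed(57)
  n <- 1000
  sp <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
    k <- rpois(1, 5 * 30)       # 5 Hz for 30 s
    tibble::tibble(time = sort(runif(k, 0, 3e4)), neuron = j,
                   population = "e")
  }))
  s <- make_set(sp, 0, 3e4, c(e = n))
  set.seed(58)
  f <- fano_factor(s, "e", n_sample = 1000, bin = 3)
  expect_equal(f, 1, tolerance = 0.06)
  # constant counts per bin give a Fano factor of 0
  reg <- tibble::tibble(time = seq(0.5, 2999.5, by = 1), neuron = 1L,
                        population = "r")
  sr <- make_set(reg, 0, 3000, c(r = 1L))
  expect_equal(fano_factor(sr, "r", n_sample = 1, bin = 3), 0)
})
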