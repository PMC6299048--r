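# Benchmark model builders and downscaling rules.

test_that("the full-scale microcircuit has the documented structure", {
  spec <- build_microcircuit(scale_config(1), duration = 100)
  expect_equal(nrow(spec$populations), 8)
  expect_equal(sum(spec$populations$size), 77169)
  expect_setequal(spec$populations$name,
                  c("L23e", "L23i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i"))
  exc_rows <- grepl("^L\\d+e", spec$projections$src) &
    !(spec$projections$src == "L4e" & spec$projections$tgt == "L23e")
  expect_true(all(spec$projections$weight_mean[exc_rows] == 0.0878))
  inh_rows <- grepl("i$", spec$projections$src)
  expect_true(all(spec$projections$weight_mean[inh_rows] == -0.3512))
  dev <- spec$projections$src == "L4e" & spec$projections$tgt == "L23e"
  expect_equal(spec$projections$weight_mean[dev], 2 * 0.0878)
  expect_true(all(spec$populations$dc == 0))  # no DC at full scale
})

test_that("downscaled sizes follow per-population rounding", {
  expect_equal(sum(build_microcircuit(scale_config(0.25))$populations$size),
               19292)
  full <- build_microcircuit(scale_config(1))
  half <- build_microcircuit(scale_config(0.5))
  expect_true(all(abs(half$populations$size - full$populations$size / 2) <= 1))
})

test_that("downscaling compensates weights, drive and mean input", {
  full <- build_microcircuit(scale_config(1), duration = 10)
  down <- build_microcircuit(scale_config(0.1), duration = 10)
  expect_equal(down$projections$weight_mean,
               full$projections$weight_mean / sqrt(0.1))
  expect_equal(down$projections$n_syn, round(full$projections$n_syn * 0.01))
  expect_equal(down$populations$poisson_rate,
               full$populations$poisson_rate * 0.1)
  expect_true(all(down$populations$dc > 0))
  # preserve mode: only totals shrink
  pres <- build_microcircuit(scale_config(0.1, indegree = "preserve"),
                             duration = 10)
  expect_equal(pres$projections$weight_mean, full$projections$weight_mean)
  expect_equal(pres$projections$n_syn, round(full$projections$n_syn * 0.1))
  expect_true(all(pres$populations$dc == 0))
  expect_error(scale_config(1.5), class = "snnkit_invalid_parameter")
})

test_that("the balanced network matches its printed structure", {
  spec <- build_balanced_network(scale = 1, duration = 100)
  expect_equal(spec$populations$size, c(90000L, 22500L))
  expect_equal(spec$projections$p, rep(0.1, 4))
  ee <- spec$projections$name == "exc->exc"
  expect_equal(spec$projections$weight_mean[ee], 0.04561)
  expect_true(spec$projections$plastic[ee])
  expect_equal(spec$projections$mu[ee], 0.4)
  expect_equal(spec$projections$weight_mean[spec$projections$src == "inh"],
               rep(-0.22805, 2))
  expect_equal(spec$populations$syn_kind, c("alpha", "alpha"))
  # the rule's uncorrelated fixed point sits at the initial weight
  st <- spec$projections[ee, ]
  expect_equal(st$w0 * st$alpha^(-1 / (1 - st$mu)), 0.04561,
               tolerance = 0.02)
})

test_that("probability-to-count conversion supports both conventions", {
  expect_equal(n_syn_from_probability(0.1, 100, 200, "product"), 2000)
  pb <- n_syn_from_probability(0.1, 100, 200)
  expect_equal(pb, round(log(0.9) / log(1 - 1 / 20000)))
  expect_gt(pb, 2000)  # with-replacement needs more draws than pairs
})

test_that("realised fixed-total projections hit their synapse totals exactly", {
  pops <- dplyr::bind_rows(test_population("x", 30), test_population("y", 20))
  projs <- dplyr::bind_rows(
    test_projection("x", "y", n_syn = 517),
    test_projection("y", "x", n_syn = 201, weight_mean = -0.2, sign = -1))
  net <- realize_network(test_network_spec(pops, projs), seed = 9)
  expect_equal(vapply(net$projections, `[[`, numeric(1), "n_syn"), c(517, 201))
  # determinism: same seed, identical realisation
  net2 <- realize_network(test_network_spec(pops, projs), seed = 9)
  expect_identical(net$projections[[1]]$ragged$post_index,
                   net2$projections[[1]]$ragged$post_index)
  expect_identical(net$projections[[1]]$ragged$weight,
                   net2$projections[[1]]$ragged$weight)
})

test_that("missing configuration keys raise a configuration error naming them", {
  cfg <- yaml::read_yaml(system.file("extdata", "microcircuit.yaml",
                                     package = "snnkit"))
  cfg$neuron$tau_m_ms <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  expect_error(build_microcircuit(config = tmp, duration = 10),
               "tau_m_ms", class = "snnkit_configuration_error")
})
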