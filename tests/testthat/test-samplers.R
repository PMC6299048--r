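# Constant-time connectivity-initialisation samplers, checked against
# brute-force oracles.

# independent row-bound oracle: enumerate the binomial CDF directly
bound_oracle <- function(size, prob, n_pre) {
  level <- 0.9999^(1 / n_pre)
  cdf <- cumsum(dbinom(0:size, size, prob))
  which(cdf >= level - 1e-15)[1] - 1
}

test_that("fixed-total row bound matches exact CDF enumeration", {
  expect_equal(max_row_length_fixed_total(fixed_number_total(1, 10, 57)), 57)
  # n_pre = 2, n_syn = 10: Binom(10, 0.5) CDF at 9 is 1 - 2^-10 < 0.9999^(1/2)
  expect_equal(max_row_length_fixed_total(fixed_number_total(2, 5, 10)), 10)
  expect_equal(max_row_length_fixed_total(fixed_number_total(100, 50, 1000)),
               bound_oracle(1000, 1 / 100, 100))
  expect_equal(max_row_length_fixed_total(fixed_number_total(17, 9, 400)),
               bound_oracle(400, 1 / 17, 17))
})

test_that("fixed-probability row bound matches enumeration and the printed example", {
  expect_equal(max_row_length_fixed_prob(5, 12, 1), 12)
  expect_equal(max_row_length_fixed_prob(2, 10, 0.5), bound_oracle(10, 0.5, 2))
  expect_equal(max_row_length_fixed_prob(30, 200, 0.13),
               bound_oracle(200, 0.13, 30))
  # a 10,000 -> 10,000 projection at 10% needs over 1,000 padded columns
  expect_gt(max_row_length_fixed_prob(10000, 10000, 0.1), 1000)
})

test_that("row bounds are rarely exceeded by realised rows", {
  set.seed(5)
  k_total <- max_row_length_fixed_total(fixed_number_total(20, 30, 300))
  overflow <- 0L
  for (r in 1:2000) {
    l <- partition_rows_fixed_total(fixed_number_total(20, 30, 300))
    if (max(l) > k_total) overflow <- overflow + 1L
  }
  # designed per-network overflow probability ~1e-4
  expect_lte(overflow, 3L)
})

test_that("multinomial row partition conserves the total and matches binomial marginals", {
  expect_equal(partition_rows_fixed_total(fixed_number_total(1, 10, 57)), 57L)
  set.seed(11)
  for (r in 1:20) {
    l <- partition_rows_fixed_total(fixed_number_total(7, 3, 123))
    expect_equal(sum(l), 123)
  }
  # marginal of row 1 over many draws ~ Binomial(100, 1/4)
  set.seed(12)
  draws <- replicate(1e4, partition_rows_fixed_total(
    fixed_number_total(4, 10, 100))[1])
  expect_lt(abs(mean(draws) - 25), 4 * sqrt(100 * 0.25 * 0.75 / 1e4))
  obs <- tabulate(draws + 1L, nbins = 101)
  expected <- dbinom(0:100, 100, 0.25) * 1e4
  keep <- expected > 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("streaming sorted sampling equals sort-based sampling in distribution", {
  expect_equal(sorted_row_sample(0, 10), integer(0))
  set.seed(21)
  for (r in 1:50) {
    s <- sorted_row_sample(sample(0:40, 1), 17)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= 1 & s <= 17))
  }
  set.seed(22)
  pooled <- unlist(lapply(1:1e4, function(i) sorted_row_sample(50, 1000)))
  oracle <- unlist(lapply(1:1e4, function(i)
    sort(floor(runif(50) * 1000) + 1)))
  expect_gt(suppressWarnings(ks.test(pooled, oracle))$p.value, 0.01)
  # per-position marginal: the smallest of 50 draws
  set.seed(23)
  first <- vapply(1:4000, function(i) sorted_row_sample(50, 1000)[1], 1L)
  first_oracle <- vapply(1:4000, function(i)
    min(floor(runif(50) * 1000) + 1), 1)
  expect_gt(suppressWarnings(ks.test(first, first_oracle))$p.value, 0.01)
})

test_that("geometric-skip rows equal per-index Bernoulli sampling", {
  expect_equal(geometric_row_sample(6, 1), 1:6)
  expect_equal(geometric_row_sample(6, 0), integer(0))
  expect_error(geometric_row_sample(6, 1.2), class = "snnkit_invalid_parameter")
  set.seed(31)
  lens <- integer(1e4)
  gaps <- integer(0)
  for (r in 1:1e4) {
    s <- geometric_row_sample(500, 0.1)
    expect_true(all(diff(s) > 0) && all(s >= 1 & s <= 500))
    lens[r] <- length(s)
    if (r <= 2000 && length(s) > 1) gaps <- c(gaps, diff(s) - 1L)
  }
  expect_lt(abs(mean(lens) - 50), 4 * sqrt(500 * 0.1 * 0.9 / 1e4))
  # gap-minus-one counts ~ Geometric(p): chi-square against the pmf
  obs <- tabulate(gaps + 1L, nbins = max(gaps) + 1L)
  expected <- dgeom(0:max(gaps), 0.1) * length(gaps)
  keep <- expected > 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("weight and delay sampling respects sign, clamps and discretisation", {
  d0 <- weight_delay_dist(0.2, 0, 1.5, 0)
  wd <- sample_weights_delays(5, d0, dt = 0.1, sign = 1)
  expect_equal(wd$weight, rep(0.2, 5))
  expect_equal(wd$delay_steps, rep(15L, 5))
  set.seed(41)
  dist <- weight_delay_dist(0.0878, 0.00878, 1.5, 0.75)
  wd <- sample_weights_delays(1e4, dist, dt = 0.1, sign = 1)
  expect_lt(abs(mean(wd$weight) - 0.0878), 4 * 0.00878 / 100)
  expect_true(all(wd$weight >= 0))
  expect_true(all(wd$delay_steps >= 1L))
  wdn <- sample_weights_delays(1e3, weight_delay_dist(-0.35, 0.2, 1, 0.5),
                               dt = 0.1, sign = -1)
  expect_true(all(wdn$weight <= 0))
})
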