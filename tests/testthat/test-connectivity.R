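# Connectivity containers and their memory accounting.

random_ragged <- function(n_pre, n_post, multapses = FALSE) {
  rows <- lapply(seq_len(n_pre), function(i) {
    k <- sample(0:min(6, n_post), 1)
    s <- sample(n_post, k, replace = multapses)
    sort(s)
  })
  rl <- lengths(rows)
  ragged_from_rows <- snnkit:::ragged_from_rows
  ragged_from_rows(n_pre, n_post, rl, unlist(rows),
                   flat_weight = runif(sum(rl)),
                   flat_delay = sample(1:5, sum(rl), replace = TRUE))
}

test_that("bitmask storage is rounded up once to whole 32-bit words", {
  expect_equal(bitmask_bytes(90000, 22500), 253125000)
  expect_identical(floor(bitmask_bytes(90000, 22500) / 2^20), 241)
  expect_equal(bitmask_bytes(1, 32), 4)
  expect_equal(bitmask_bytes(3, 3), 4)
  expect_error(bitmask_bytes(0, 5), class = "snnkit_invalid_parameter")
})

test_that("ragged storage accounting is n_pre * max_row * bytes plus row lengths", {
  expect_equal(ragged_bytes(2, 3, 8), 48 + 8)
  expect_equal(ragged_bytes(1, 1, 4), 4 + 4)
  k <- max_row_length_fixed_prob(90000, 22500, 0.1)
  expect_equal(ragged_bytes(90000, k, 4), 4 * 90000 * k + 360000)
})

test_that("bitmask bits land at the documented positions", {
  # single synapse at 0-based pair (0, 5) of a 1 x 8 matrix: only bit 5 set
  m <- bitmask_matrix(1, 8, pre = 1, post = 6)
  bits <- as.logical(rawToBits(m$bits))
  expect_true(bits[6])
  expect_equal(sum(bits), 1)
  expect_length(m$bits, bitmask_bytes(1, 8))
  # empty matrix: all-zero bitfield
  expect_true(all(bitmask_matrix(4, 4)$bits == as.raw(0)))
})

test_that("ragged-to-bitmask conversion preserves the synapse count", {
  set.seed(1)
  m <- random_ragged(20, 33)
  b <- bitmask_from_ragged(m)
  expect_equal(snnkit:::bitmask_popcount(b), sum(m$row_length))
  for (i in c(1, 7, 20)) {
    row <- snnkit:::bitmask_row(b, i)
    expect_setequal(which(row), unique(m$post_index[i, seq_len(m$row_length[i])]))
  }
})

test_that("multapses are representable in ragged form but rejected by the bitmask", {
  m <- snnkit:::ragged_from_rows(2, 5, c(2L, 0L), c(3L, 3L),
                                 flat_weight = c(0.1, 0.2),
                                 flat_delay = c(1L, 1L))
  expect_equal(sum(m$row_length), 2)
  expect_error(bitmask_from_ragged(m), class = "snnkit_multapse_unsupported")
})

test_that("column view is a bijection onto the synapses", {
  # degenerate and full cases
  empty <- snnkit:::ragged_from_rows(3, 4, c(0L, 0L, 0L), integer(0))
  cv <- build_column_view(empty)
  expect_equal(cv$col_ptr, rep(0L, 5))
  full <- snnkit:::ragged_from_rows(2, 2, c(2L, 2L), c(1L, 2L, 1L, 2L))
  cv <- build_column_view(full)
  expect_equal(diff(cv$col_ptr), c(2L, 2L))
  expect_equal(cv$pre, c(1L, 2L, 1L, 2L))
  # round trip on many random matrices: every synapse recovered exactly once
  set.seed(3)
  for (r in 1:1000) {
    m <- random_ragged(sample(1:8, 1), sample(1:9, 1), multapses = TRUE)
    cv <- build_column_view(m)
    expect_equal(length(cv$position), sum(m$row_length))
    expect_equal(sort(unique(cv$position)), sort(cv$position))  # bijection
    # following a column position recovers the same weight cell
    if (length(cv$position)) {
      j_of_pos <- m$post_index[cv$position]
      expect_equal(j_of_pos,
                   rep.int(seq_len(m$n_post), diff(cv$col_ptr)))
    }
  }
})

test_that("a 50 x 70 matrix survives the row -> column -> row round trip", {
  set.seed(9)
  m <- random_ragged(50, 70)
  cv <- build_column_view(m)
  got <- tibble::tibble(pre = cv$pre, post = m$post_index[cv$position],
                        weight = m$weight[cv$position])
  want <- tidy(m)[, c("pre", "post", "weight")]
  expect_equal(dplyr::arrange(got, pre, post, weight),
               dplyr::arrange(want, pre, post, weight))
})

test_that("connectivity snapshots round-trip through plain text", {
  set.seed(4)
  m <- random_ragged(12, 9)
  path <- withr::local_tempfile()
  write_connectivity(m, path)
  m2 <- read_connectivity(path)
  expect_equal(tidy(m2), dplyr::arrange(tidy(m), pre, post))
})
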