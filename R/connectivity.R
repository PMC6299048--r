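# Sparse synaptic connectivity containers: the padded row-major ragged
# matrix (per-synapse weights/delays), the one-bit-per-pair bitmask for
# constant-weight projections, and the column view that lets
# post-spike-triggered plasticity reach row-major storage column-wise.

#' Padded ragged connectivity matrix
#'
#' Row-major sparse connectivity: row `i` holds the `row_length[i]`
#' synapses of presynaptic neuron `i`, padded out to `max_row_length`
#' columns (padding entries are never read). Optional parallel tables
#' carry per-synapse weights (nA) and delays (timesteps). Duplicate
#' `(pre, post)` pairs (multapses) are permitted.
#'
#' @param n_pre,n_post Population sizes.
#' @param row_length Integer vector of per-row synapse counts.
#' @param post_index Integer matrix `n_pre x max_row_length` of
#'   postsynaptic indices in `1..n_post`; each row non-decreasing over its
#'   first `row_length[i]` entries.
#' @param weight,delay_steps Optional matrices parallel to `post_index`.
#' @return An object of class `ragged_matrix`.
#' @export
ragged_matrix <- function(n_pre, n_post, row_length, post_index,
                          weight = NULL, delay_steps = NULL) {
  check_number(n_pre, "n_pre", lower = 1, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  n_pre <- as.integer(n_pre); n_post <- as.integer(n_post)
  row_length <- as.integer(row_length)
  if (length(row_length) != n_pre || any(row_length < 0)) {
    abort("`row_length` must hold one non-negative count per presynaptic neuron.",
          class = "snnkit_invalid_input")
  }
  if (!is.matrix(post_index) || nrow(post_index) != n_pre) {
    abort("`post_index` must be a matrix with `n_pre` rows.",
          class = "snnkit_invalid_input")
  }
  if (any(row_length > ncol(post_index))) {
    abort("`row_length` exceeds the padded column count.",
          class = "snnkit_invalid_input")
  }
  live <- cbind(rep.int(seq_len(n_pre), row_length), sequence(row_length))
  idx <- post_index[live]
  if (length(idx) && (anyNA(idx) || any(idx < 1L | idx > n_post))) {
    abort("`post_index` entries must lie in 1..n_post.",
          class = "snnkit_corrupt_matrix")
  }
  structure(list(n_pre = n_pre, n_post = n_post,
                 max_row_length = ncol(post_index),
                 row_length = row_length,
                 post_index = post_index,
                 weight = weight, delay_steps = delay_steps),
            class = "ragged_matrix")
}

# Pack per-row lists produced by the samplers into a padded ragged matrix.
ragged_from_rows <- function(n_pre, n_post, row_length, flat_post,
                             flat_weight = NULL, flat_delay = NULL) {
  max_row <- max(row_length, 1L)
  live <- cbind(rep.int(seq_len(n_pre), row_length), sequence(row_length))
  post <- matrix(0L, n_pre, max_row)
  post[live] <- as.integer(flat_post)
  w <- d <- NULL
  if (!is.null(flat_weight)) { w <- matrix(0, n_pre, max_row); w[live] <- flat_weight }
  if (!is.null(flat_delay)) { d <- matrix(0L, n_pre, max_row); d[live] <- as.integer(flat_delay) }
  ragged_matrix(n_pre, n_post, row_length, post, w, d)
}

#' Synapse table of a ragged matrix
#'
#' @param x A [ragged_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per synapse: `pre`, `post`, and any
#'   `weight` / `delay_steps` tables present.
#' @export
tidy.ragged_matrix <- function(x, ...) {
  live <- cbind(rep.int(seq_len(x$n_pre), x$row_length), sequence(x$row_length))
  out <- tibble(pre = live[, 1L], post = x$post_index[live])
  if (!is.null(x$weight)) out$weight <- x$weight[live]
  if (!is.null(x$delay_steps)) out$delay_steps <- x$delay_steps[live]
  out
}

#' Storage size of a bitmask connectivity bitfield
#'
#' One bit per `(pre, post)` pair, with the whole flat bitfield rounded up
#' once to a whole number of 32-bit words: `4 * ceil(n_pre n_post / 32)`
#' bytes.
#'
#' @param n_pre,n_post Population sizes (>= 1).
#' @return Size in bytes.
#' @examples
#' bitmask_bytes(90000, 22500) / 2^20  # ~241 MiB
#' @export
bitmask_bytes <- function(n_pre, n_post) {
  check_number(n_pre, "n_pre", lower = 1, integerish = TRUE)
  check_number(n_post, "n_post", lower = 1, integerish = TRUE)
  4 * ceiling(as.double(n_pre) * as.double(n_post) / 32)
}

#' Storage size of a padded ragged matrix
#'
#' `n_pre * max_row_length * bytes_per_synapse` for the padded synapse
#' tables plus 4 bytes per row for the row-length array.
#'
#' @param n_pre Presynaptic population size.
#' @param max_row_length Padded column count.
#' @param bytes_per_synapse Bytes per synapse entry across all tables.
#' @return Size in bytes.
#' @export
ragged_bytes <- function(n_pre, max_row_length, bytes_per_synapse) {
  check_number(n_pre, "n_pre", lower = 1, integerish = TRUE)
  check_number(max_row_length, "max_row_length", lower = 1, integerish = TRUE)
  check_number(bytes_per_synapse, "bytes_per_synapse", lower = 1, integerish = TRUE)
  as.double(n_pre) * max_row_length * bytes_per_synapse + 4 * as.double(n_pre)
}

#' Bitmask connectivity matrix
#'
#' One bit per `(pre, post)` pair stored in a flat little-endian bitfield
#' rounded up to a whole number of 32-bit words; pair `(i, j)` occupies
#' bit `(i-1) * n_post + (j-1)`, and bit `k` of word `w` covers pair index
#' `32 w + k`. Only single synapses with a shared constant weight can be
#' represented.
#'
#' @param n_pre,n_post Population sizes.
#' @param pre,post Optional parallel integer vectors of synapses to set.
#' @return An object of class `bitmask_matrix` whose `bits` field is a raw
#'   vector of exactly [bitmask_bytes()] bytes.
#' @export
bitmask_matrix <- function(n_pre, n_post, pre = integer(0), post = integer(0)) {
  nbytes <- bitmask_bytes(n_pre, n_post)
  bits <- raw(nbytes)
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length.", class = "snnkit_invalid_input")
  }
  if (length(pre)) {
    if (any(pre < 1 | pre > n_pre) || any(post < 1 | post > n_post)) {
      abort("synapse indices out of range.", class = "snnkit_corrupt_matrix")
    }
    b <- (as.double(pre) - 1) * n_post + (post - 1)   # 0-based pair index
    if (anyDuplicated(b)) {
      abort("bitmask cannot represent multapses (duplicate pre/post pairs).",
            class = "snnkit_multapse_unsupported")
    }
    byte <- b %/% 8
    mask <- bitwShiftL(1L, as.integer(b %% 8))
    agg <- rowsum(mask, group = byte)
    bits[as.double(rownames(agg)) + 1] <- as.raw(agg[, 1L])
  }
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 bits = bits),
            class = "bitmask_matrix")
}

#' Convert a ragged matrix to a bitmask
#'
#' Fails if the ragged matrix contains multapses, which a one-bit-per-pair
#' structure cannot represent.
#'
#' @param m A [ragged_matrix()].
#' @return A [bitmask_matrix()] with the same connectivity.
#' @export
bitmask_from_ragged <- function(m) {
  stopifnot(inherits(m, "ragged_matrix"))
  syn <- tidy(m)
  bitmask_matrix(m$n_pre, m$n_post, syn$pre, syn$post)
}

# Logical connectivity row i of a bitmask (length n_post).
bitmask_row <- function(m, i) {
  b0 <- (as.double(i) - 1) * m$n_post
  b1 <- b0 + m$n_post - 1
  first_byte <- b0 %/% 8
  last_byte <- b1 %/% 8
  bits <- as.logical(rawToBits(m$bits[(first_byte + 1):(last_byte + 1)]))
  bits[(b0 - first_byte * 8 + 1):(b0 - first_byte * 8 + m$n_post)]
}

# Number of set bits.
bitmask_popcount <- function(m) {
  sum(as.integer(rawToBits(m$bits)))
}

#' Column view of a ragged matrix
#'
#' Builds the post-major companion structure needed for
#' postsynaptic-spike-triggered plasticity: for every postsynaptic neuron,
#' the flat positions (into the row-major padded tables) of its incoming
#' synapses, ordered by presynaptic index. The mapping is a bijection onto
#' the synapses of the ragged matrix.
#'
#' @param m A [ragged_matrix()].
#' @return An object of class `column_view` with fields `n_post`,
#'   `col_ptr` (0-based CSR offsets, length `n_post + 1`), `position`
#'   (1-based flat positions into the padded tables) and `pre`
#'   (presynaptic index of each entry).
#' @export
build_column_view <- function(m) {
  stopifnot(inherits(m, "ragged_matrix"))
  live_row <- rep.int(seq_len(m$n_pre), m$row_length)
  live_col <- sequence(m$row_length)
  post <- m$post_index[cbind(live_row, live_col)]
  if (length(post) && any(post < 1L | post > m$n_post)) {
    abort("`post_index` entries must lie in 1..n_post.",
          class = "snnkit_corrupt_matrix")
  }
  flat <- live_row + (live_col - 1L) * m$n_pre  # column-major flat position
  ord <- order(post, live_row)
  counts <- tabulate(post, nbins = m$n_post)
  structure(list(n_post = m$n_post,
                 col_ptr = c(0L, cumsum(counts)),
                 position = flat[ord],
                 pre = live_row[ord]),
            class = "column_view")
}

#' Write / read a plain-text connectivity snapshot
#'
#' One line per synapse, `pre post weight_nA delay_steps`, after a header
#' carrying the matrix dimensions. The round trip is lossless.
#'
#' @param m A [ragged_matrix()] with weight and delay tables.
#' @param path File path.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a [ragged_matrix()].
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "ragged_matrix"))
  syn <- tidy(m)
  if (is.null(syn$weight)) syn$weight <- 0
  if (is.null(syn$delay_steps)) syn$delay_steps <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_pre %d n_post %d n_syn %d",
                     m$n_pre, m$n_post, nrow(syn)), con)
  writeLines(sprintf("%d %d %.17g %d", syn$pre, syn$post, syn$weight,
                     syn$delay_steps), con)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  header <- readLines(path, n = 1L)
  dims <- as.integer(regmatches(header, gregexpr("[0-9]+", header))[[1]])
  if (length(dims) != 3L) {
    abort("malformed connectivity header.", class = "snnkit_parse_error")
  }
  tab <- utils::read.table(path, skip = 1L,
                           col.names = c("pre", "post", "weight", "delay_steps"))
  ord <- order(tab$pre, tab$post)
  tab <- tab[ord, , drop = FALSE]
  row_length <- tabulate(tab$pre, nbins = dims[1])
  ragged_from_rows(dims[1], dims[2], row_length, tab$post,
                   tab$weight, tab$delay_steps)
}
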