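# Plain-text spike raster files and the end-to-end run driver.

#' Write a spike raster to a plain-text file
#'
#' One file per population: a commented header (population, size, dt,
#' duration) followed by `time id` records sorted by time, with times
#' printed at the timestep resolution.
#'
#' @param x A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_raster <- function(x, dir) {
  stopifnot(inherits(x, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digits <- max(0, ceiling(-log10(x$dt)))
  paths <- character(0)
  for (pop in names(x$populations)) {
    sp <- x$spikes[x$spikes$population == pop, ]
    sp <- sp[order(sp$time, sp$neuron), ]
    path <- file.path(dir, paste0(pop, ".spikes"))
    con <- file(path, "w")
    writeLines(c(sprintf("# population %s", pop),
                 sprintf("# size %d", x$populations[[pop]]),
                 sprintf("# dt %g", x$dt),
                 sprintf("# duration %g", x$duration)), con)
    writeLines(sprintf(paste0("%.", digits, "f %d"), sp$time, sp$neuron), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a spike raster file
#'
#' @param path A file written by [write_raster()].
#' @return A list with `population`, `size`, `dt`, `duration` and a
#'   `spikes` tibble (`time`, `neuron`, `population`).
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  header <- lines[hdr]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), header, value = TRUE)
    if (!length(ln)) {
      abort(sprintf("raster header is missing `%s`.", key),
            class = "snnkit_parse_error")
    }
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  pop <- get("population")
  size <- as.integer(get("size"))
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      abort(sprintf("malformed raster record at line %d.",
                    which(!hdr)[bad[1]]),
            class = "snnkit_parse_error")
    }
    time <- as.double(vapply(parts, `[[`, character(1), 1L))
    neuron <- as.integer(vapply(parts, `[[`, character(1), 2L))
    if (anyNA(time) || anyNA(neuron)) {
      abort("malformed raster record (non-numeric field).",
            class = "snnkit_parse_error")
    }
    if (is.unsorted(time)) {
      abort("raster records must be sorted by time.",
            class = "snnkit_parse_error")
    }
    if (any(neuron < 1L | neuron > size)) {
      abort("raster neuron id outside the population.",
            class = "snnkit_parse_error")
    }
  } else {
    time <- double(0); neuron <- integer(0)
  }
  list(population = pop, size = size,
       dt = as.double(get("dt")), duration = as.double(get("duration")),
       spikes = tibble(time = time, neuron = neuron, population = pop))
}

#' Build, simulate and record a benchmark model end to end
#'
#' Thin driver over [build_microcircuit()] / [build_balanced_network()],
#' [realize_network()] and [simulate_network()]: runs the model and writes
#' per-population rasters, an optional plastic-weight snapshot, an
#' optional connectivity dump and a manifest sufficient to re-run the
#' simulation bit-identically.
#'
#' @param model `"microcircuit"` or `"balanced"`.
#' @param out_dir Output directory.
#' @param scale Scale factor in (0, 1].
#' @param duration Biological time (ms).
#' @param dt Timestep override (ms; `NULL` keeps the model default).
#' @param seed Root seed.
#' @param structure Static-projection structure for the balanced model.
#' @param record_weights Write final plastic weights to
#'   `weights.txt`.
#' @param dump_connectivity Write every ragged projection to a
#'   connectivity snapshot file.
#' @return The `sim_result`, invisibly.
#' @export
run_simulation <- function(model = c("microcircuit", "balanced"),
                           out_dir, scale = 1, duration = 1000, dt = NULL,
                           seed = 1, structure = "bitmask",
                           record_weights = FALSE,
                           dump_connectivity = FALSE) {
  model <- match.arg(model)
  spec <- if (model == "microcircuit") {
    build_microcircuit(scale_config(scale), duration = duration)
  } else {
    build_balanced_network(scale = scale, duration = duration,
                           structure = structure)
  }
  if (!is.null(dt)) spec$dt <- dt
  net <- realize_network(spec, seed)
  res <- simulate_network(net,
                          record_weights_every = if (record_weights) 1000 else NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(res, out_dir)
  if (record_weights && length(res$final_weights)) {
    dims <- setNames(lapply(net$projections, function(j) j[c("n_pre", "n_post")]),
                     vapply(net$projections, `[[`, character(1), "name"))
    for (nm in names(res$final_weights)) {
      w <- res$final_weights[[nm]]
      path <- file.path(out_dir, paste0("weights-", gsub("[^A-Za-z0-9]+", "_", nm), ".txt"))
      writeLines(c(sprintf("# projection %s n_pre %d n_post %d count %d", nm,
                           dims[[nm]]$n_pre, dims[[nm]]$n_post, length(w)),
                   sprintf("%.9g", w)), path)
    }
  }
  if (dump_connectivity) {
    for (j in net$projections) {
      if (j$type == 0L) {
        write_connectivity(j$ragged,
                           file.path(out_dir, paste0("conn-", gsub("[^A-Za-z0-9]+", "_", j$name), ".txt")))
      }
    }
  }
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
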