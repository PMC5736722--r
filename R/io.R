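# Plain-text round-trips: time series, edge lists, results, manifests.
# Unit indices are 1-based in all files, matching the in-memory layout.

#' Write / read a sampled time series as TSV
#'
#' One row per sample with `segment` and `time` columns and one column per
#' component named `u{i}_c{d}`; the full-precision doubles round-trip
#' exactly.  A sidecar `<path>.meta` key-value file carries `model`, `dt`,
#' `eta` and `seed` (reading fails without a `dt`, since derivatives would
#' be undefined).
#'
#' @param ts a `ts_set`.
#' @param path output TSV path.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_ts <- function(ts, path, force = FALSE) {
  if (file.exists(path) && !force) stop("file exists; use force = TRUE: ", path)
  tbl <- purrr::imap_dfr(ts$segments, function(seg, s) {
    out <- tibble::as_tibble(as.data.frame(seg), .name_repair = "minimal")
    names(out) <- paste0("u", ts$layout$unit, "_c", ts$layout$comp)
    dplyr::bind_cols(tibble::tibble(segment = as.integer(s),
                                    time = (seq_len(nrow(seg)) - 1) * ts$dt),
                     out)
  })
  readr::write_tsv(tbl, path)
  write_manifest(list(model = ts$model, dt = ts$dt, eta = ts$eta,
                      seed = ts$seed, n_units = length(unique(ts$layout$unit)),
                      n_components = nrow(ts$layout)),
                 paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_ts
#' @return `read_ts()` returns a `ts_set`.
#' @export
read_ts <- function(path) {
  meta <- read_manifest(paste0(path, ".meta"))
  if (is.null(meta$dt)) stop("metadata is missing dt; derivatives undefined")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  comp_cols <- setdiff(names(tbl), c("segment", "time"))
  un <- regmatches(comp_cols, regexec("^u(\\d+)_c(\\d+)$", comp_cols))
  lay <- tibble::tibble(
    column = seq_along(comp_cols),
    unit = vapply(un, function(m) as.integer(m[2L]), 0L),
    comp = vapply(un, function(m) as.integer(m[3L]), 0L),
    name = comp_cols)
  segs <- lapply(split(tbl[comp_cols], tbl$segment), as.matrix)
  segs <- segs[order(as.integer(names(segs)))]
  segs <- unname(lapply(segs, unname))
  new_ts_set(segs, as.numeric(meta$dt), lay, meta$model %||% "unknown",
             as.numeric(meta$eta %||% NA), as.integer(meta$seed %||% NA))
}

#' Write / read a network specification as a plain-text edge list
#'
#' Versioned header, then one line per interaction: `i<TAB>j<TAB>weight` for
#' a pairwise link j -> i, `i<TAB>j<TAB>k<TAB>weight` for a second-order
#' entry `E^i[j, k]` (term in the argument order `x_j - x_k`).
#'
#' @param spec a `network_spec`.
#' @param path file path.
#' @param force overwrite an existing file.
#' @return `path` invisibly; `read_network()` returns a `network_spec`.
#' @export
write_network <- function(spec, path, force = FALSE) {
  if (file.exists(path) && !force) stop("file exists; use force = TRUE: ", path)
  lines <- c("# arni-edgelist v1", paste0("# N ", spec$N))
  idx <- which(spec$J != 0, arr.ind = TRUE)
  if (nrow(idx) && is.null(spec$E)) {
    lines <- c(lines, sprintf("%d\t%d\t%.17g", idx[, 1L], idx[, 2L],
                              spec$J[idx]))
  }
  if (!is.null(spec$E)) {
    for (i in seq_len(spec$N)) {
      e <- which(spec$E[[i]] != 0, arr.ind = TRUE)
      if (nrow(e)) {
        lines <- c(lines, sprintf("%d\t%d\t%d\t%.17g", i, e[, 1L], e[, 2L],
                                  spec$E[[i]][e]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# arni-edgelist")) {
    stop("not an edge-list file (missing version header): ", path)
  }
  N <- as.integer(sub("^# N ", "", lines[2L]))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  J <- matrix(0, N, N)
  E <- NULL
  n_in <- integer(N)
  for (p in parts[nf == 3L]) {
    J[as.integer(p[1L]), as.integer(p[2L])] <- as.numeric(p[3L])
  }
  if (any(nf == 4L)) {
    E <- replicate(N, matrix(0, N, N), simplify = FALSE)
    for (p in parts[nf == 4L]) {
      i <- as.integer(p[1L]); j <- as.integer(p[2L]); k <- as.integer(p[3L])
      E[[i]][j, k] <- as.numeric(p[4L])
      if (k == i) J[i, j] <- as.numeric(p[4L])   # degenerate pairwise entry
    }
    n_in <- vapply(E, function(e) sum(e != 0), 0L)
  } else {
    n_in <- rowSums(J != 0)
  }
  new_network_spec(N, J, E, as.integer(n_in),
                   kind = if (is.null(E)) "network" else "hypernetwork")
}

#' Write inference results as TSV
#'
#' One row per (target component, selected interaction): target, key, rank,
#' train cost, validation cost; plus the dense unit-level score matrix in a
#' second file `<path>.scores.tsv` when present.
#'
#' @param net an `arni_net`.
#' @param path output TSV path.
#' @param force overwrite existing files.
#' @return `path`, invisibly.
#' @export
write_results <- function(net, path, force = FALSE) {
  if (file.exists(path) && !force) stop("file exists; use force = TRUE: ", path)
  readr::write_tsv(tidy(net), path)
  sc <- tibble::as_tibble(as.data.frame(net$scores), .name_repair = "minimal")
  names(sc) <- paste0("u", colnames(net$scores))
  readr::write_tsv(sc, paste0(path, ".scores.tsv"))
  invisible(path)
}

#' Write / read a flat key-value manifest
#'
#' `key<TAB>value` lines echoing the resolved configuration of a run.
#'
#' @param x named list of scalar values.
#' @param path file path.
#' @return `path` invisibly; `read_manifest()` returns a named list of
#'   character values.
#' @export
write_manifest <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  vals <- vapply(x, function(v) {
    if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  }, "")
  writeLines(paste(names(x), vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) paste(p[-1L], collapse = "\t")),
                  vapply(parts, `[`, "", 1L))
}
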