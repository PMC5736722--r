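# Model-free baselines: thresholded correlations, partial correlations and
# transfer entropy, all returned as unit-level score matrices.

ts_stack <- function(ts) {
  X <- do.call(rbind, ts$segments)
  seg <- rep(seq_along(ts$segments), vapply(ts$segments, nrow, 0L))
  list(X = X, segment = seg)
}

# pool a component-level score matrix to unit level by max absolute value
pool_units <- function(S, layout) {
  units <- sort(unique(layout$unit))
  if (nrow(layout) == length(units)) {
    dimnames(S) <- list(units, units)
    return(S)
  }
  out <- matrix(0, length(units), length(units), dimnames = list(units, units))
  gi <- match(layout$unit, units)
  for (a in seq_along(units)) {
    ra <- which(gi == a)
    for (b in seq_along(units)) {
      out[a, b] <- max(abs(S[ra, which(gi == b), drop = FALSE]))
    }
  }
  out
}

#' Correlation baseline
#'
#' Absolute Pearson correlation between series, pooled across all segments;
#' multi-component units are pooled by the maximum absolute value over their
#' component pairs.  Symmetric; the diagonal is set to 0 and is excluded from
#' scoring anyway.
#'
#' @param ts a `ts_set` with at least 3 usable samples.
#' @return a unit-level score matrix.
#' @export
corr_baseline <- function(ts) {
  st <- ts_stack(ts)
  if (nrow(st$X) < 3L) stop("need at least 3 samples")
  sds <- apply(st$X, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance series scored 0")
  C <- suppressWarnings(abs(stats::cor(st$X)))
  C[!is.finite(C)] <- 0
  S <- pool_units(C, ts$layout)
  diag(S) <- 0
  S
}

#' Partial-correlation baseline
#'
#' Absolute partial correlations from the inverse covariance
#' (`rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`); with `ridge > 0` the
#' covariance is regularised by `ridge * mean(diag) * I` before inversion,
#' which is required when the covariance is singular (e.g. fewer samples
#' than components).
#'
#' @param ts a `ts_set`.
#' @param ridge nonnegative ridge fraction.
#' @return a unit-level score matrix.
#' @export
pcorr_baseline <- function(ts, ridge = 0) {
  st <- ts_stack(ts)
  S <- stats::cov(st$X)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), ncol(S))
  Om <- tryCatch(solve(S), error = function(e)
    stop("covariance is singular; supply a positive `ridge`", call. = FALSE))
  d <- sqrt(diag(Om))
  R <- abs(-Om / outer(d, d))
  diag(R) <- 0
  out <- pool_units(R, ts$layout)
  diag(out) <- 0
  out
}

# equal-frequency discretisation into `bins` levels
discretize_ef <- function(x, bins) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7)
  qs[1L] <- -Inf; qs[bins + 1L] <- Inf
  findInterval(x, unique(qs), rightmost.closed = TRUE)
}

#' Transfer-entropy baseline
#'
#' Plug-in estimate of `TE_{j -> i}` from equal-frequency-binned series,
#' `sum p(x_i', x_i, x_j) log2[ p(x_i' | x_i, x_j) / p(x_i' | x_i) ]`, where
#' the future value is `lag` samples ahead; lagged pairs never straddle
#' segment boundaries, empty bins follow the `0 log 0 = 0` convention and
#' numerically negative estimates are clipped at 0.  Multi-component units
#' are pooled by the maximum over component pairs.
#'
#' @param ts a `ts_set`.
#' @param bins number of equal-frequency bins.
#' @param lag prediction lag in samples.
#' @return a directed unit-level score matrix (entry `(i, j)` scores
#'   j -> i), in bits.
#' @export
te_baseline <- function(ts, bins = 4L, lag = 1L) {
  st <- ts_stack(ts)
  D <- ncol(st$X)
  disc <- matrix(0L, nrow(st$X), D)
  for (d in seq_len(D)) disc[, d] <- discretize_ef(st$X[, d], bins)
  nb <- max(disc)
  # rows where t and t+lag are in the same segment
  ok <- which(st$segment == c(st$segment[-seq_len(lag)], rep(NA, lag)))
  fut <- disc[ok + lag, , drop = FALSE]
  now <- disc[ok, , drop = FALSE]
  TE <- matrix(0, D, D)
  log2p <- function(x) ifelse(x > 0, log2(x), 0)
  for (i in seq_len(D)) {
    yi <- fut[, i]; xi <- now[, i]
    n_yx <- tabulate((yi - 1L) * nb + xi, nb * nb)        # p(y, xi)
    n_x <- tabulate(xi, nb)
    for (j in seq_len(D)) {
      if (i == j) next
      xj <- now[, j]
      code3 <- ((yi - 1L) * nb + (xi - 1L)) * nb + xj
      n_yxx <- tabulate(code3, nb^3)
      code2 <- (xi - 1L) * nb + xj
      n_xx <- tabulate(code2, nb * nb)
      idx <- which(n_yxx > 0)
      y_id <- (idx - 1L) %/% (nb * nb) + 1L
      xi_id <- ((idx - 1L) %/% nb) %% nb + 1L
      xj_id <- (idx - 1L) %% nb + 1L
      p <- n_yxx[idx] / length(yi)
      te <- sum(p * (log2p(n_yxx[idx]) + log2p(n_x[xi_id]) -
                       log2p(n_xx[(xi_id - 1L) * nb + xj_id]) -
                       log2p(n_yx[(y_id - 1L) * nb + xi_id])))
      TE[i, j] <- max(te, 0)
    }
  }
  pool_units(TE, ts$layout)
}
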