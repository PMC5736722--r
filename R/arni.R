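# Greedy block orthogonal least squares: ranked interaction discovery per
# target unit, cost curves and knee detection.

# Orthonormalise the columns of B (column-pivoted QR), dropping directions
# below a relative rank tolerance.
orth_cols <- function(B, rtol = 1e-10) {
  if (!ncol(B)) return(B)
  qz <- qr(B, LAPACK = TRUE)
  d <- abs(diag(qr.R(qz)))
  if (!length(d) || max(d) <= 0) return(B[, 0, drop = FALSE])
  rank <- sum(d > rtol * max(d))
  if (!rank) return(B[, 0, drop = FALSE])
  qr.Q(qz)[, seq_len(rank), drop = FALSE]
}

# deflate B against an orthonormal basis Q (modified Gram-Schmidt, applied
# twice -- "twice is enough" -- to control drift)
deflate <- function(B, Q) {
  if (!ncol(Q) || !ncol(B)) return(B)
  B <- B - Q %*% crossprod(Q, B)
  B - Q %*% crossprod(Q, B)
}

# squared-norm reduction of the residual achievable by a block with
# off-span Gram matrix S and right-hand side b (rank-guarded small solve)
gain_from_normal <- function(S, b, rtol = 1e-10) {
  g <- tryCatch({
    R <- chol(S)
    sum(backsolve(R, b, transpose = TRUE)^2)
  }, error = function(e) NA_real_)
  if (is.na(g)) {
    ev <- eigen(S, symmetric = TRUE)
    pos <- ev$values > (rtol^2) * max(ev$values, 0)
    if (!any(pos)) return(-Inf)
    z <- crossprod(ev$vectors[, pos, drop = FALSE], b)
    g <- sum(z^2 / ev$values[pos])
  }
  g
}

# solve S beta = b for symmetric positive (semi-)definite S
solve_psd <- function(S, b, rtol = 1e-10) {
  out <- tryCatch({
    R <- chol(S)
    backsolve(R, backsolve(R, b, transpose = TRUE))
  }, error = function(e) NULL)
  if (is.null(out)) {
    ev <- eigen(S, symmetric = TRUE)
    pos <- ev$values > (rtol^2) * max(ev$values, 0)
    out <- ev$vectors[, pos, drop = FALSE] %*%
      (crossprod(ev$vectors[, pos, drop = FALSE], b) / ev$values[pos])
  }
  out
}

ols_fit <- function(X, y, rtol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > rtol * max(sv$d, 0)
  if (sum(pos) < ncol(X)) {
    warning("rank-deficient selected set; coefficients via pseudo-inverse")
  }
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  as.vector(coef)
}

split_rows <- function(segment, train_frac, seed) {
  segs <- unique(segment)
  if (length(segs) >= 2L) {
    set.seed(child_seed(seed, 23L))
    n_tr <- min(length(segs) - 1L, max(1L, round(train_frac * length(segs))))
    tr_segs <- sample(segs, n_tr)
    list(train = which(segment %in% tr_segs),
         val = which(!segment %in% tr_segs))
  } else {
    # single continuous segment: contiguous block split (no leakage shuffle)
    n <- length(segment)
    n_tr <- min(n - 1L, max(2L, floor(train_frac * n)))
    list(train = seq_len(n_tr), val = seq(n_tr + 1L, n))
  }
}

#' Greedy block-orthogonal least-squares inference for one target
#'
#' Iteratively selects the candidate block whose column space, orthogonalised
#' against the already selected blocks, most reduces the squared training
#' residual of the estimated derivative; records the mean-squared fitting
#' cost on training and validation rows after every selection.  Selection
#' uses training rows only; the validation curve is the learning-curve
#' diagnostic.  Final coefficients are an ordinary least-squares refit of the
#' response on the union of selected (unorthogonalised) blocks.
#'
#' @param blocks a `design_blocks` object.
#' @param y response vector (estimated derivative of the target component),
#'   row-aligned with the blocks.
#' @param L_max maximum number of selections; default
#'   `min(#candidates, floor(M_eff / max block width))`.
#' @param tol relative training-cost decrease below which selection stops.
#' @param train_frac fraction of segments assigned to the training split
#'   (split by whole segments; a single continuous segment is split into
#'   contiguous blocks).
#' @param seed seed for the split.
#' @return an `arni_fit`: ranked tibble (`key`, `j`, `k`, `step`,
#'   `cost_train`, `cost_val`), baseline costs at `l = 0`, coefficients,
#'   stop reason, and the detected knee of the validation curve.
#' @export
infer_unit <- function(blocks, y, L_max = NULL, tol = 1e-4,
                       train_frac = 0.6, seed = 1L) {
  stopifnot(inherits(blocks, "design_blocks"))
  if (length(y) != blocks$M_eff) stop("response not row-aligned with blocks")
  sp <- split_rows(blocks$segment, train_frac, seed)
  y_tr <- y[sp$train]; y_va <- y[sp$val]
  M_tr <- length(y_tr)
  keys <- blocks$keys
  widths <- vapply(blocks$blocks, ncol, 0L)
  usable <- widths > 0L
  if (is.null(L_max)) {
    L_max <- min(sum(usable), max(1L, floor(blocks$M_eff / max(widths, 1L))))
  }
  C0_tr <- mean(y_tr^2)
  C0_va <- if (length(y_va)) mean(y_va^2) else NA_real_

  ranked <- tibble::tibble(key = character(0), step = integer(0),
                           cost_train = numeric(0), cost_val = numeric(0))
  stop_reason <- "max_steps"
  sel <- character(0)
  if (C0_tr <= 1e-28 || !any(usable)) {
    stop_reason <- if (!any(usable)) "degenerate" else "residual_tol"
  } else {
    cand_keys <- names(blocks$blocks)[usable]
    # stacked design: one matrix, per-block column index ranges
    Xall <- do.call(cbind, lapply(blocks$blocks[usable], function(B)
      B[sp$train, , drop = FALSE]))
    w <- widths[usable]
    col_end <- cumsum(w)
    col_idx <- lapply(seq_along(w), function(ci)
      seq(col_end[ci] - w[ci] + 1L, col_end[ci]))
    G0 <- lapply(col_idx, function(ix) crossprod(Xall[, ix, drop = FALSE]))
    active <- rep(TRUE, length(w))
    Ctot <- ncol(Xall)
    maxw <- max(w)
    Q <- matrix(0, M_tr, L_max * maxw)    # preallocated selected basis
    U <- matrix(0, L_max * maxw, Ctot)    # U = t(Q) %*% Xall, grown rowwise
    qn <- 0L
    r <- y_tr
    cost_prev <- C0_tr
    # incremental Gram factors for the per-step validation refit
    sel_ix <- integer(0)
    Gsel <- matrix(0, 0, 0)
    for (l in seq_len(L_max)) {
      # r is orthogonal to span(Q), so the off-span right-hand side of every
      # candidate block is simply t(B_j) %*% r; the off-span Gram matrix is
      # G0_j - t(U_j) %*% U_j
      b_all <- crossprod(Xall, r)
      gains <- rep(-Inf, length(w))
      Urows <- U[seq_len(qn), , drop = FALSE]
      for (ci in which(active)) {
        ix <- col_idx[[ci]]
        S <- G0[[ci]] - crossprod(Urows[, ix, drop = FALSE])
        gains[ci] <- gain_from_normal(S, b_all[ix])
      }
      if (!any(is.finite(gains)) || max(gains) <= 0) {
        stop_reason <- "cost_plateau"; break
      }
      pick <- which.max(gains)            # first max: lowest key wins ties
      Qp <- orth_cols(deflate(Xall[, col_idx[[pick]], drop = FALSE],
                              Q[, seq_len(qn), drop = FALSE]))
      key <- cand_keys[pick]
      r <- r - Qp %*% crossprod(Qp, r)
      np <- ncol(Qp)
      if (np > 0L) {
        Q[, qn + seq_len(np)] <- Qp
        U[qn + seq_len(np), ] <- crossprod(Qp, Xall)
        qn <- qn + np
      }
      sel <- c(sel, key)
      active[pick] <- FALSE
      cost_tr <- mean(r^2)
      new_ix <- col_idx[[pick]]
      if (length(sel_ix)) {
        cross <- crossprod(Xall[, sel_ix, drop = FALSE],
                           Xall[, new_ix, drop = FALSE])
        Gsel <- rbind(cbind(Gsel, cross),
                      cbind(t(cross), G0[[pick]]))
      } else {
        Gsel <- G0[[pick]]
      }
      sel_ix <- c(sel_ix, new_ix)
      cost_va <- if (length(y_va)) {
        bsel <- crossprod(Xall[, sel_ix, drop = FALSE], y_tr)
        beta <- solve_psd(Gsel, bsel)
        Xva <- do.call(cbind, lapply(sel, function(k)
          blocks$blocks[[k]][sp$val, , drop = FALSE]))
        mean((y_va - Xva %*% beta)^2)
      } else NA_real_
      ranked <- dplyr::bind_rows(ranked, tibble::tibble(
        key = key, step = l, cost_train = cost_tr, cost_val = cost_va))
      if (cost_tr <= 1e-24 * C0_tr) { stop_reason <- "residual_tol"; break }
      if ((cost_prev - cost_tr) / cost_prev < tol) {
        stop_reason <- "cost_plateau"; break
      }
      cost_prev <- cost_tr
    }
  }

  coefs <- NULL
  if (length(sel)) {
    Xfull <- do.call(cbind, lapply(blocks$blocks[sel], function(B)
      B[sp$train, , drop = FALSE]))
    beta <- suppressWarnings(ols_fit(Xfull, y_tr))
    # report on the original (pre-normalisation) column scale
    coefs <- tibble::tibble(
      key = rep(sel, times = vapply(blocks$blocks[sel], ncol, 0L)),
      column = unlist(lapply(sel, function(k) seq_len(ncol(blocks$blocks[[k]])))),
      estimate = beta / unlist(blocks$scales[sel]))
  } else {
    coefs <- tibble::tibble(key = character(0), column = integer(0),
                            estimate = numeric(0))
  }

  ranked <- split_key(ranked)
  knee <- if (nrow(ranked) >= 3L && length(y_va)) {
    detect_knee(ranked$cost_val, l = ranked$step)
  } else list(l_star = NA_integer_, confident = FALSE, flat = FALSE)
  # in-degree estimate at the knee: discovered interactions minus the
  # intrinsic self block
  knee_indegree <- if (!is.na(knee$l_star) && knee$l_star > 0) {
    sum(ranked$step <= knee$l_star &
          !(is.na(ranked$k) & ranked$j == blocks$target))
  } else NA_integer_

  structure(list(target = blocks$target, target_comp = blocks$target_comp,
                 ranked = ranked, cost0_train = C0_tr, cost0_val = C0_va,
                 coefficients = coefs, stop_reason = stop_reason,
                 knee = knee$l_star, knee_indegree = knee_indegree,
                 knee_confident = isTRUE(knee$confident),
                 L_max = L_max, M_train = M_tr, M_val = length(y_va),
                 order = blocks$order, family = blocks$family,
                 units = blocks$units, seed = seed),
            class = "arni_fit")
}

split_key <- function(ranked) {
  if (!nrow(ranked)) {
    ranked$j <- integer(0); ranked$k <- integer(0)
    return(ranked[c("key", "j", "k", "step", "cost_train", "cost_val")])
  }
  parts <- strsplit(ranked$key, "+", fixed = TRUE)
  ranked$j <- as.integer(vapply(parts, `[`, "", 1L))
  ranked$k <- as.integer(vapply(parts, function(p)
    if (length(p) > 1L) p[2L] else NA_character_, ""))
  ranked[c("key", "j", "k", "step", "cost_train", "cost_val")]
}

#' @export
print.arni_fit <- function(x, ...) {
  cat(sprintf("<arni_fit> target u%d_c%d: %d selection(s), stop = %s, knee l* = %s%s\n",
              x$target, x$target_comp, nrow(x$ranked), x$stop_reason,
              ifelse(is.na(x$knee), "NA", x$knee),
              if (isTRUE(x$knee_confident)) " (confident)" else ""))
  invisible(x)
}

#' Fitting-cost learning curve of a fit
#'
#' Mean-squared fitting cost on the training and validation splits for
#' `l = 0` (zero predictor) through the last selection.
#'
#' @param fit an `arni_fit`.
#' @return a tibble with columns `l`, `cost_train`, `cost_val`.
#' @export
cost_curve <- function(fit) {
  stopifnot(inherits(fit, "arni_fit"))
  tibble::tibble(
    l = c(0L, fit$ranked$step),
    cost_train = c(fit$cost0_train, fit$ranked$cost_train),
    cost_val = c(fit$cost0_val, fit$ranked$cost_val))
}

#' Locate the knee of an L-shaped learning curve
#'
#' Distance-to-chord on the log-cost curve: each point of the sequence is
#' scored by its (normalised) deviation below the chord joining the curve's
#' endpoints; the maximising position is the knee, ties broken toward
#' smaller `l`.  A knee is flagged `confident` only when (i) the interior
#' deviation exceeds 10% of the normalised curve box and (ii) the cost at
#' the knee sits at least one decade below the start of the curve --
#' near-linear decays, mild decays without an L-shape, and flat curves all
#' fail the flag.
#'
#' @param cost positive cost sequence (length >= 3).
#' @param l positions of the costs; defaults to `seq_along(cost)`.
#' @return a list with `l_star` (0 for flat curves), `confident`, `flat`,
#'   and the normalised chord `distance` profile.
#' @export
detect_knee <- function(cost, l = seq_along(cost)) {
  stopifnot(length(cost) >= 3L, length(l) == length(cost))
  cost <- pmax(cost, 1e-300)
  y <- log10(cost)
  ry <- diff(range(y))
  if (ry < 1e-12) {
    return(list(l_star = 0L, confident = FALSE, flat = TRUE,
                distance = rep(0, length(cost))))
  }
  xs <- (l - l[1L]) / (l[length(l)] - l[1L])
  ys <- (y - min(y)) / ry
  chord <- ys[1L] + (ys[length(ys)] - ys[1L]) * xs
  dist <- chord - ys                      # positive below the chord
  interior <- seq(2L, length(cost) - 1L)
  i_star <- interior[which.max(dist[interior])]
  d_star <- dist[i_star]
  drop_decades <- y[1L] - y[i_star]
  list(l_star = if (d_star > 0) l[i_star] else 0L,
       confident = d_star >= 0.1 && drop_decades >= 1,
       flat = FALSE, distance = dist)
}

#' Infer the interaction network from a time series
#'
#' Runs derivative estimation, block construction and greedy selection
#' independently for every target component, then aggregates a unit-level
#' interaction score matrix (earlier discovery = higher score; unselected
#' candidates share the minimal score 0; multi-component units pool their
#' components' scores by maximum).
#'
#' @param ts a `ts_set`.
#' @param family,P,order,include_self,max_candidates passed to
#'   [build_blocks()].
#' @param scheme derivative scheme, see [estimate_derivatives()].
#' @param L_max,tol,train_frac passed to [infer_unit()].
#' @param seed integer seed (splits and center placement).
#' @return an `arni_net`: list of per-component fits, a unit-level `scores`
#'   matrix (`scores[i, j]` scores the candidate link j -> i), and -- when
#'   `order = "pairwise_plus_hyper2"` -- a `pair_scores` tibble with one row
#'   per (target, unordered pair) candidate.
#' @export
infer_network <- function(ts, family = "c", P = NULL,
                          order = c("pairwise", "pairwise_plus_hyper2"),
                          scheme = c("forward2", "central3"),
                          L_max = NULL, tol = 1e-4, train_frac = 0.6,
                          include_self = TRUE, max_candidates = Inf,
                          seed = 1L) {
  order <- match.arg(order); scheme <- match.arg(scheme)
  ds <- estimate_derivatives(ts, scheme)
  lay <- ds$layout
  units <- sort(unique(lay$unit))
  fits <- list()
  for (ci in seq_len(nrow(lay))) {
    u <- lay$unit[ci]; d <- lay$comp[ci]
    bl <- build_blocks(ds, target = u, target_comp = d, family = family,
                       P = P, order = order, include_self = include_self,
                       max_candidates = max_candidates, seed = seed)
    fits[[lay$name[ci]]] <- infer_unit(bl, ds$derivs[, lay$column[ci]],
                                       L_max = L_max, tol = tol,
                                       train_frac = train_frac, seed = seed)
  }
  L_ref <- max(vapply(fits, function(f) as.integer(f$L_max), 0L))
  scores <- matrix(0, length(units), length(units),
                   dimnames = list(units, units))
  pair_scores <- NULL
  for (f in fits) {
    i <- match(f$target, units)
    rk <- f$ranked
    pw <- rk[is.na(rk$k), , drop = FALSE]
    if (nrow(pw)) {
      jj <- match(pw$j, units)
      sc <- L_ref - pw$step + 1L
      scores[i, jj] <- pmax(scores[i, jj], sc)
    }
  }
  if (order == "pairwise_plus_hyper2") {
    pair_scores <- purrr::map_dfr(fits, function(f) {
      rk <- f$ranked
      # a selected single-unit block of target i is the degenerate pair {j, i}
      pw <- is.na(rk$k) & rk$j != f$target
      rk$k[pw] <- pmax(rk$j[pw], f$target)
      rk$j[pw] <- pmin(rk$j[pw], f$target)
      rk <- rk[!is.na(rk$k), , drop = FALSE]
      if (!nrow(rk)) return(tibble::tibble())
      tibble::tibble(target = f$target, key = paste0(rk$j, "+", rk$k),
                     j = rk$j, k = rk$k, score = L_ref - rk$step + 1L)
    })
    if (nrow(pair_scores)) {
      pair_scores <- dplyr::summarise(
        dplyr::group_by(pair_scores, .data$target, .data$key, .data$j, .data$k),
        score = max(.data$score), .groups = "drop")
    }
  }
  structure(list(fits = fits, scores = scores, pair_scores = pair_scores,
                 units = units, order = order, family = family,
                 L_ref = L_ref, model = ts$model, seed = seed),
            class = "arni_net")
}

#' @export
print.arni_net <- function(x, ...) {
  cat(sprintf("<arni_net> %d unit(s), %d fit(s), order %s, family %s\n",
              length(x$units), length(x$fits), x$order,
              paste(x$family, collapse = "+")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arni_fit <- function(x, ...) {
  dplyr::mutate(x$ranked, target = x$target, target_comp = x$target_comp,
                .before = 1L)
}

#' @exportS3Method generics::glance
glance.arni_fit <- function(x, ...) {
  tibble::tibble(target = x$target, target_comp = x$target_comp,
                 n_selected = nrow(x$ranked), stop_reason = x$stop_reason,
                 knee = x$knee, knee_indegree = x$knee_indegree,
                 knee_confident = x$knee_confident,
                 cost_train_final = if (nrow(x$ranked))
                   x$ranked$cost_train[nrow(x$ranked)] else x$cost0_train,
                 cost_val_final = if (nrow(x$ranked))
                   x$ranked$cost_val[nrow(x$ranked)] else x$cost0_val,
                 M_train = x$M_train, M_val = x$M_val)
}

#' @exportS3Method generics::tidy
tidy.arni_net <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @exportS3Method generics::glance
glance.arni_net <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}

#' Plot the learning curve of a fit
#'
#' @param object an `arni_fit`.
#' @param ... unused.
#' @return a ggplot: training and validation mean-squared cost versus the
#'   number of selected interactions (log scale), with the detected knee.
#' @exportS3Method ggplot2::autoplot
autoplot.arni_fit <- function(object, ...) {
  cc <- tidyr::pivot_longer(cost_curve(object), -"l",
                            names_to = "split", values_to = "cost")
  p <- ggplot2::ggplot(cc, ggplot2::aes(.data$l, .data$cost,
                                        colour = .data$split)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selected interactions l", y = "fitting cost C(l)",
                  colour = NULL)
  if (!is.na(object$knee) && object$knee > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$knee, linetype = 2)
  }
  p
}

#' Heatmap of unit-level interaction scores
#'
#' @param x an `arni_net` (or any matrix of scores with targets in rows).
#' @return a ggplot tile map of the score matrix.
#' @export
plot_scores <- function(x) {
  m <- if (inherits(x, "arni_net")) x$scores else as.matrix(x)
  df <- tibble::tibble(
    target = rep(seq_len(nrow(m)), times = ncol(m)),
    source = rep(seq_len(ncol(m)), each = nrow(m)),
    score = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$source, .data$target,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "source unit j", y = "target unit i")
}
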