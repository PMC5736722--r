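# Derivative estimation and grouped basis-function design blocks.

#' Construct a derivative set directly from states and derivatives
#'
#' Low-level constructor for the container pairing state rows with estimated
#' (or exactly known) time derivatives.  [estimate_derivatives()] is the
#' usual way to obtain one from a sampled time series.
#'
#' @param states numeric matrix (`M_eff x D`) of states.
#' @param derivs numeric matrix (`M_eff x D`) of matching derivatives.
#' @param segment integer vector of segment ids per row (defaults to one
#'   segment).
#' @param layout optional component layout tibble (`column`, `unit`, `comp`,
#'   `name`); defaults to one single-component unit per column.
#' @param dt sampling interval the derivatives were estimated at (metadata).
#' @return a `deriv_set`.
#' @export
derivative_set <- function(states, derivs, segment = rep(1L, nrow(states)),
                           layout = NULL, dt = NA_real_) {
  states <- as.matrix(states); derivs <- as.matrix(derivs)
  stopifnot(nrow(states) == nrow(derivs), ncol(states) == ncol(derivs),
            length(segment) == nrow(states))
  if (is.null(layout)) layout <- unit_layout(seq_len(ncol(states)))
  structure(list(states = states, derivs = derivs,
                 segment = as.integer(segment), layout = layout, dt = dt,
                 M_eff = nrow(states)),
            class = "deriv_set")
}

#' @export
print.deriv_set <- function(x, ...) {
  cat(sprintf("<deriv_set> M_eff = %d rows, %d component column(s), %d segment(s)\n",
              x$M_eff, ncol(x$states), length(unique(x$segment))))
  invisible(x)
}

#' Estimate time derivatives from sampled segments
#'
#' Finite differences that never straddle segment boundaries:
#' `forward2` pairs `(x_{m+1} - x_m) / dt` with the state `x_m` (dropping the
#' last row of each segment, error O(dt)); `central3` pairs
#' `(x_{m+1} - x_{m-1}) / (2 dt)` with `x_m` (dropping both ends, error
#' O(dt^2)).  Segments shorter than the stencil are skipped with a warning.
#'
#' @param ts a `ts_set`.
#' @param scheme `"forward2"` or `"central3"`.
#' @return a `deriv_set` with `M_eff = sum_s (m_s - k)` rows, `k` the stencil
#'   width minus one.
#' @export
estimate_derivatives <- function(ts, scheme = c("forward2", "central3")) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "forward2") 2L else 3L
  skipped <- 0L
  st <- list(); dv <- list(); seg <- list()
  for (s in seq_along(ts$segments)) {
    X <- ts$segments[[s]]
    m <- nrow(X)
    if (m < need) { skipped <- skipped + 1L; next }
    if (scheme == "forward2") {
      keep <- seq_len(m - 1L)
      d <- (X[keep + 1L, , drop = FALSE] - X[keep, , drop = FALSE]) / ts$dt
    } else {
      keep <- seq(2L, m - 1L)
      d <- (X[keep + 1L, , drop = FALSE] - X[keep - 1L, , drop = FALSE]) /
        (2 * ts$dt)
    }
    st[[length(st) + 1L]] <- X[keep, , drop = FALSE]
    dv[[length(dv) + 1L]] <- d
    seg[[length(seg) + 1L]] <- rep(s, length(keep))
  }
  if (skipped > 0L) {
    warning(skipped, " segment(s) shorter than the ", scheme,
            " stencil were skipped")
  }
  if (!length(st)) stop("no segment long enough for scheme '", scheme, "'")
  derivative_set(do.call(rbind, st), do.call(rbind, dv),
                 segment = unlist(seg), layout = ts$layout, dt = ts$dt)
}

default_P <- function(family) {
  switch(family, a = 3L, b = 3L, e = 3L, c = 4L, f = 4L, d = 10L,
         stop("unknown basis family '", family, "'"))
}

# single-argument families (used for candidate columns of e/f and for the
# self block, which maps pair families onto their single-variable analogues)
basis_single <- function(x, family, P, centers = NULL) {
  switch(family,
         e = vapply(seq_len(P), function(p) x^p, numeric(length(x))),
         f = do.call(cbind, lapply(seq_len(P), function(p)
           cbind(sin(p * x), cos(p * x)))),
         d = vapply(seq_len(nrow(centers)), function(p)
           1 / (1 + (x - centers[p, 1L])^2), numeric(length(x))),
         stop("family '", family, "' has no single-variable form"))
}

# two-argument families on (x_i, x_j) or on a hyper pair (x_j, x_k)
basis_pair <- function(xi, xj, family, P, centers = NULL) {
  switch(family,
         a = vapply(seq_len(P), function(p) (xj - xi)^p, numeric(length(xi))),
         c = do.call(cbind, lapply(seq_len(P), function(p)
           cbind(sin(p * (xj - xi)), cos(p * (xj - xi))))),
         b = {
           ex <- expand.grid(p1 = 0:P, p2 = 0:P)
           ex <- ex[ex$p1 + ex$p2 >= 1 & ex$p1 + ex$p2 <= P, , drop = FALSE]
           mapply(function(p1, p2) xi^p1 * xj^p2, ex$p1, ex$p2)
         },
         d = vapply(seq_len(nrow(centers)), function(p)
           1 / (1 + (xi - centers[p, 1L])^2 + (xj - centers[p, 2L])^2),
           numeric(length(xi))),
         e = basis_single(xj, "e", P),
         f = basis_single(xj, "f", P),
         stop("unknown basis family '", family, "'"))
}

# map pair families to the single-variable family used for the self block
self_family <- function(family) {
  switch(family, a = "e", b = "e", e = "e", c = "f", f = "f", d = "d", family)
}

#' Draw radial-basis-function centers from observed samples
#'
#' Centers are drawn uniformly without replacement from the observed
#' `(x_i, x_j)` sample pairs, so they always lie within the componentwise
#' range of the data.
#'
#' @param ds a `deriv_set`.
#' @param pair integer vector `c(i, j)` of component column indices.
#' @param P number of centers (`P <= M_eff`).
#' @param seed integer seed.
#' @return a `P x 2` matrix of centers.
#' @export
place_rbf_centers <- function(ds, pair, P, seed = 1L) {
  if (P > ds$M_eff) stop("P exceeds the number of observed samples")
  set.seed(child_seed(seed, 13L))
  rows <- sample(ds$M_eff, P)
  cbind(ds$states[rows, pair[1L]], ds$states[rows, pair[2L]])
}

normalize_block <- function(B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 1)
  nrm <- sqrt(colSums(B^2))
  keep <- which(nrm > 1e-12 * sqrt(nrow(B)))
  B <- B[, keep, drop = FALSE]
  nrm <- nrm[keep]
  list(B = sweep(B, 2, nrm, "/"), scale = nrm, kept = keep)
}

#' Build grouped regressor blocks for one target component
#'
#' One block of basis-function columns per candidate interaction: a block per
#' candidate unit `j` (pairwise), optionally plus a block per unordered pair
#' `{j, k}` of units (second interaction order).  For multi-component
#' candidate units the block stacks the basis evaluated on every component,
#' so whole units are selected or rejected together.  Each column is scaled
#' to unit Euclidean norm (the scale is recorded so fitted coefficients can
#' be reported on the original scale); exactly zero columns are dropped, and
#' the self block always carries a leading intercept column so constant
#' intrinsic terms are absorbable.
#'
#' @param ds a `deriv_set`.
#' @param target target unit id.
#' @param target_comp component of the target unit whose derivative is the
#'   regression response (1 for scalar units).
#' @param family basis family id(s) from the set `a`--`f`; a vector
#'   concatenates several families' columns within each block.  Families:
#'   `a` powers of `x_j - x_i`; `b` monomials `x_i^{p1} x_j^{p2}` up to total
#'   degree `P`; `c` `sin/cos(p (x_j - x_i))`; `d` inverse-quadratic radial
#'   basis functions at sampled centers; `e` powers `x_j^p`; `f`
#'   `sin/cos(p x_j)`.
#' @param P basis functions per family (per family defaults: 3 for `a`/`b`/
#'   `e`, 4 for `c`/`f`, 10 centers for `d`).
#' @param order `"pairwise"` or `"pairwise_plus_hyper2"` (adds all unordered
#'   unit pairs, family `c` acting on `x_j - x_k`).
#' @param include_self include the self block (single-variable family
#'   analogue plus intercept).
#' @param rbf_centers optional precomputed centers for family `d`.
#' @param max_candidates cap on the number of hyper-order pair blocks.
#' @param seed seed for center placement.
#' @return a `design_blocks` object: named list of normalised blocks (names
#'   are candidate keys `"j"` or `"j+k"`, `j < k`), plus alignment metadata.
#' @export
build_blocks <- function(ds, target, target_comp = 1L, family = "c", P = NULL,
                         order = c("pairwise", "pairwise_plus_hyper2"),
                         include_self = TRUE, rbf_centers = NULL,
                         max_candidates = Inf, seed = 1L) {
  order <- match.arg(order)
  families <- as.character(family)
  stopifnot(all(families %in% c("a", "b", "c", "d", "e", "f")))
  Pv <- if (is.null(P)) vapply(families, default_P, 0L) else
    rep_len(as.integer(P), length(families))
  lay <- ds$layout
  units <- sort(unique(lay$unit))
  icol <- lay$column[lay$unit == target & lay$comp == target_comp]
  if (length(icol) != 1L) stop("target unit/component not found in layout")
  xi <- ds$states[, icol]

  eval_block <- function(cols, is_self) {
    mats <- list()
    for (fi in seq_along(families)) {
      fam <- families[fi]; Pp <- Pv[fi]
      for (col in cols) {
        xj <- ds$states[, col]
        if (is_self) {
          sfam <- self_family(fam)
          ctr <- if (sfam == "d") {
            if (!is.null(rbf_centers)) rbf_centers else
              place_rbf_centers(ds, c(col, col), Pp, seed)
          } else NULL
          mats[[length(mats) + 1L]] <- basis_single(xj, sfam, Pp, ctr)
        } else {
          ctr <- if (fam == "d") {
            if (!is.null(rbf_centers)) rbf_centers else
              place_rbf_centers(ds, c(icol, col), Pp, seed)
          } else NULL
          mats[[length(mats) + 1L]] <- basis_pair(xi, xj, fam, Pp, ctr)
        }
      }
    }
    B <- do.call(cbind, mats)
    if (is_self) B <- cbind(1, B)
    B
  }

  blocks <- list(); scales <- list()
  for (j in units) {
    if (j == target && !include_self) next
    cols <- lay$column[lay$unit == j]
    nb <- normalize_block(eval_block(cols, is_self = (j == target)))
    key <- as.character(j)
    blocks[[key]] <- nb$B
    scales[[key]] <- nb$scale
  }

  if (order == "pairwise_plus_hyper2") {
    hyper_fams <- intersect(families, c("b", "c", "d"))
    if (!length(hyper_fams)) {
      stop("hyper-order blocks need a two-argument family (b, c or d)")
    }
    prs <- utils::combn(units, 2L)
    if (ncol(prs) > max_candidates) {
      prs <- prs[, seq_len(max_candidates), drop = FALSE]
    }
    for (e in seq_len(ncol(prs))) {
      j <- prs[1L, e]; k <- prs[2L, e]
      cj <- lay$column[lay$unit == j][1L]
      ck <- lay$column[lay$unit == k][1L]
      mats <- list()
      for (fi in seq_along(families)) {
        fam <- families[fi]
        if (!fam %in% hyper_fams) next
        ctr <- if (fam == "d") {
          if (!is.null(rbf_centers)) rbf_centers else
            place_rbf_centers(ds, c(cj, ck), Pv[fi], seed)
        } else NULL
        # family c acts on the difference x_j - x_k; b/d on the 2-D pair
        mats[[length(mats) + 1L]] <-
          basis_pair(ds$states[, ck], ds$states[, cj], fam, Pv[fi], ctr)
      }
      nb <- normalize_block(do.call(cbind, mats))
      key <- paste0(j, "+", k)
      blocks[[key]] <- nb$B
      scales[[key]] <- nb$scale
    }
  }

  keys <- names(blocks)
  structure(list(target = target, target_comp = target_comp,
                 target_column = icol, keys = keys, blocks = blocks,
                 scales = scales, family = families, P = Pv, order = order,
                 M_eff = ds$M_eff, segment = ds$segment,
                 units = units),
            class = "design_blocks")
}

#' @export
print.design_blocks <- function(x, ...) {
  cat(sprintf("<design_blocks> target u%d_c%d: %d block(s), family %s (P = %s), M_eff = %d\n",
              x$target, x$target_comp, length(x$blocks),
              paste(x$family, collapse = "+"),
              paste(x$P, collapse = "+"), x$M_eff))
  invisible(x)
}
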