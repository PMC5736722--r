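# Random network / hypernetwork generation and ground-truth dependency
# matrices for the benchmark dynamical systems.

#' Derive a deterministic child seed
#'
#' Counter-based scheme: one user-facing integer seed spawns independent child
#' seeds per unit (or per role), so unit-level generation is order-independent.
#'
#' @param seed integer master seed.
#' @param k integer counter (unit index or role id).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 1299721
  as.integer(s %% 2147483646) + 1L
}

new_network_spec <- function(N, J, E = NULL, n_in, self_allowed = FALSE,
                             kind = c("network", "hypernetwork")) {
  kind <- match.arg(kind)
  structure(
    list(N = as.integer(N), J = J, E = E, n_in = as.integer(n_in),
         self_allowed = isTRUE(self_allowed), kind = kind),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: N = %d, in-degree = %s, %d pairwise links%s\n",
              x$kind, x$N, paste(unique(x$n_in), collapse = "/"),
              sum(x$J != 0),
              if (!is.null(x$E)) sprintf(", %d second-order entries",
                                         sum(vapply(x$E, function(e) sum(e != 0), 0)))
              else ""))
  invisible(x)
}

#' Generate a random directed network with fixed in-degree
#'
#' Each unit `i` receives exactly `n_in` incoming links from distinct units
#' drawn uniformly without replacement from the other units (no self-loops).
#' `J[i, j]` is the weight of the directed link from `j` to `i`.
#'
#' @param N number of units.
#' @param n_in in-degree, scalar or length-`N` vector; must satisfy
#'   `1 <= n_in <= N - 1`.
#' @param seed integer seed; generation is deterministic given the seed and
#'   independent across units (counter-based child seeds).
#' @param weight_scheme `"unit"` sets every present weight to 1 (the
#'   normalised `1/n_i` coupling of the benchmark models reads naturally with
#'   homogeneous weights); `"uniform_range"` draws weights from U(0.5, 1).
#' @return a `network_spec` object with fields `N`, `J`, `E` (NULL), `n_in`.
#' @examples
#' net <- random_indegree_network(10, 3, seed = 1)
#' rowSums(net$J != 0)
#' @export
random_indegree_network <- function(N, n_in, seed = 1L,
                                    weight_scheme = c("unit", "uniform_range")) {
  weight_scheme <- match.arg(weight_scheme)
  N <- as.integer(N)
  if (length(n_in) == 1L) n_in <- rep(as.integer(n_in), N)
  if (length(n_in) != N) stop("`n_in` must be a scalar or length-N vector")
  if (any(n_in < 1L) || any(n_in > N - 1L)) {
    stop("invalid in-degree: need 1 <= n_in <= N - 1")
  }
  J <- matrix(0, N, N)
  for (i in seq_len(N)) {
    set.seed(child_seed(seed, i))
    nb <- sample(setdiff(seq_len(N), i), n_in[i])
    w <- switch(weight_scheme,
                unit = rep(1, n_in[i]),
                uniform_range = stats::runif(n_in[i], 0.5, 1))
    J[i, nb] <- w
  }
  new_network_spec(N, J, NULL, n_in, kind = "network")
}

#' Generate a random hypernetwork of pairwise and three-point interactions
#'
#' For each unit `i`, `n_in` distinct interactions are drawn.  Independently
#' with probability `p_h` an interaction is a genuine two-source coupling
#' `{j, k}` with `j != k`, both different from `i`; otherwise it is a plain
#' pairwise link from a unit `j`, encoded as the degenerate pair `{j, i}` in
#' the second-order matrix `E^i` so that the hypernetwork coupling form
#' reduces exactly to the pairwise phase coupling when `p_h = 0`.
#'
#' `E[[i]][j, k] != 0` denotes a coupling term in the argument order
#' `x_j - x_k`; for degenerate pairs the second index is always `i`.
#'
#' @param N number of units (`N >= 3` whenever `p_h > 0`).
#' @param n_in interactions per unit.
#' @param p_h probability in `[0, 1]` that an interaction is a genuine
#'   two-source pair.
#' @param seed integer seed.
#' @return a `network_spec` with `kind = "hypernetwork"` and `E` a list of
#'   `N` matrices.
#' @export
random_hypernetwork <- function(N, n_in, p_h, seed = 1L) {
  N <- as.integer(N)
  if (p_h < 0 || p_h > 1) stop("`p_h` must lie in [0, 1]")
  if (N < 3L && p_h > 0) stop("N < 3 admits no genuine two-source pair")
  if (n_in < 1L || n_in > choose(N - 1, 2) + N - 1) stop("invalid `n_in`")
  E <- vector("list", N)
  J <- matrix(0, N, N)
  for (i in seq_len(N)) {
    set.seed(child_seed(seed, i))
    Ei <- matrix(0, N, N)
    keys <- character(0)
    while (length(keys) < n_in) {
      others <- setdiff(seq_len(N), i)
      if (stats::runif(1) < p_h) {
        jk <- sample(others, 2L)       # ordered: term is x_j - x_k
        key <- paste(sort(jk), collapse = "+")
        if (key %in% keys) next
        Ei[jk[1L], jk[2L]] <- 1
      } else {
        j <- sample(others, 1L)
        key <- paste(sort(c(j, i)), collapse = "+")
        if (key %in% keys) next
        Ei[j, i] <- 1                  # degenerate pair: x_j - x_i
        J[i, j] <- 1
      }
      keys <- c(keys, key)
    }
    E[[i]] <- Ei
  }
  new_network_spec(N, J, E, rep(as.integer(n_in), N), kind = "hypernetwork")
}

# fixed dependency structure of the 7-species glycolysis model
lambda_glycolysis <- function() {
  sp <- paste0("S", 1:7)
  L <- matrix(0L, 7, 7, dimnames = list(sp, sp))
  dep <- list(c(1, 6), c(1, 6, 2, 5), c(2, 5, 3, 6), c(3, 6, 4, 5, 7),
              c(2, 5, 4), c(1, 6, 3), c(4, 7))
  for (i in 1:7) L[i, dep[[i]]] <- 1L
  L
}

# fixed dependency structure of the 10-variable circadian clock model
lambda_circadian <- function() {
  sp <- c("MP", "P0", "P1", "P2", "MT", "T0", "T1", "T2", "C", "CN")
  L <- matrix(0L, 10, 10, dimnames = list(sp, sp))
  dep <- list(
    MP = c(1, 10), P0 = c(1, 2, 3), P1 = c(2, 3, 4), P2 = c(3, 4, 8, 9),
    MT = c(5, 10), T0 = c(5, 6, 7), T1 = c(6, 7, 8), T2 = c(7, 8, 4, 9),
    C = c(4, 8, 9, 10), CN = c(9, 10))
  for (i in 1:10) L[i, dep[[i]]] <- 1L
  L
}

#' Ground-truth explicit dependency matrices
#'
#' Reads off, symbolically from the right-hand sides of the benchmark models,
#' which units appear in each unit's equation of motion.  Row `i` of the
#' returned binary matrix is the diagonal of the explicit dependency matrix
#' of unit `i`: entry `(i, j)` is 1 iff unit `j`'s state enters unit `i`'s
#' rate of change (including intrinsic self-dependencies).
#'
#' @param model one of `"mm"`, `"phase_net"`, `"phase_hyper"`, `"roessler"`,
#'   `"glycolysis"`, `"circadian"`.
#' @param spec a [network_spec] for the network-parameterised models; ignored
#'   (and unnecessary) for the fixed 7-unit glycolysis and 10-unit circadian
#'   systems.
#' @return an `N x N` binary matrix at unit level.
#' @export
dependency_matrices <- function(model, spec = NULL) {
  model <- match.arg(model, c("mm", "phase_net", "phase_hyper", "roessler",
                              "glycolysis", "circadian"))
  if (model == "glycolysis") return(lambda_glycolysis())
  if (model == "circadian") return(lambda_circadian())
  if (is.null(spec)) stop("model '", model, "' requires a network_spec")
  N <- spec$N
  L <- (spec$J != 0) * 1L
  if (!is.null(spec$E)) {
    for (i in seq_len(N)) {
      idx <- which(spec$E[[i]] != 0, arr.ind = TRUE)
      if (nrow(idx)) L[i, unique(as.vector(idx))] <- 1L
    }
  }
  if (model %in% c("mm", "roessler")) {
    diag(L) <- 1L
  } else if (model == "phase_net") {
    # pairwise phase coupling g(x_j - x_i) involves x_i whenever n_in >= 1
    diag(L) <- pmax(diag(L), as.integer(rowSums(spec$J != 0) > 0))
  }
  # phase_hyper: self-dependency only through degenerate pairs containing i,
  # already captured from E above
  L
}

#' Tidy the true interactions of a network specification
#'
#' @param x a `network_spec`.
#' @param ... unused.
#' @return a tibble with one row per true interaction: columns `target`,
#'   `key` (candidate key, `"j"` or `"j+k"` with `j < k`), `j`, `k` (NA for
#'   pairwise links).
#' @exportS3Method generics::tidy
tidy.network_spec <- function(x, ...) {
  rows <- list()
  if (is.null(x$E)) {
    idx <- which(x$J != 0, arr.ind = TRUE)
    rows <- tibble::tibble(target = idx[, 1L], j = idx[, 2L], k = NA_integer_,
                           key = as.character(idx[, 2L]))
  } else {
    rows <- purrr::map_dfr(seq_len(x$N), function(i) {
      idx <- which(x$E[[i]] != 0, arr.ind = TRUE)
      if (!nrow(idx)) return(tibble::tibble())
      lo <- pmin(idx[, 1L], idx[, 2L]); hi <- pmax(idx[, 1L], idx[, 2L])
      tibble::tibble(target = i, j = lo, k = hi,
                     key = paste0(lo, "+", hi))
    })
  }
  dplyr::arrange(tibble::as_tibble(rows), .data$target, .data$key)
}
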