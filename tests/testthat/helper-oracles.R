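# Independent oracles: literal re-transcriptions of the model equations,
# brute-force greedy selection, chord-distance knee, finite-difference
# sensitivities.  These deliberately share no code with the package
# internals they check.

# ---- literal model right-hand sides (one state vector at a time) ----------

oracle_rhs_mm <- function(x, J, n_in) {
  N <- length(x)
  vapply(seq_len(N), function(i) {
    -x[i] + sum(J[i, ] * x / (1 + x)) / n_in[i]
  }, 0)
}

oracle_rhs_phase <- function(x, J, n_in, omega) {
  N <- length(x)
  vapply(seq_len(N), function(i) {
    cp <- sum(J[i, ] * (sin(x - x[i] - 1.05) + 0.33 * sin(2 * (x - x[i]))))
    omega[i] + cp / n_in[i]
  }, 0)
}

oracle_rhs_phase_hyper <- function(x, E, n_in, omega) {
  N <- length(x)
  vapply(seq_len(N), function(i) {
    cp <- 0
    for (j in seq_len(N)) for (k in seq_len(N)) {
      if (E[[i]][j, k] != 0) {
        cp <- cp + E[[i]][j, k] *
          (sin(x[j] - x[k] - 1.05) + 0.33 * sin(2 * (x[j] - x[k])))
      }
    }
    omega[i] + cp / n_in[i]
  }, 0)
}

oracle_rhs_roessler <- function(x, J, n_in) {
  N <- length(x) / 3
  out <- numeric(length(x))
  for (i in seq_len(N)) {
    x1 <- x[3 * i - 2]; x2 <- x[3 * i - 1]; x3 <- x[3 * i]
    cp <- sum(J[i, ] * sin(x[3 * seq_len(N) - 2])) / n_in[i]
    out[3 * i - 2] <- -x2 - x3 + cp
    out[3 * i - 1] <- x1 + 0.1 * x2
    out[3 * i] <- 0.1 + x3 * (x1 - 18.0)
  }
  out
}

oracle_rhs_glycolysis <- function(x, p) {
  S1 <- x[1]; S2 <- x[2]; S3 <- x[3]; S4 <- x[4]; S5 <- x[5]; S6 <- x[6]
  S7 <- x[7]
  v1 <- p$k1 * S1 * S6 / (1 + (S6 / p$K1)^p$q)
  c(p$J0 - v1,
    2 * v1 - p$k2 * S2 * (p$N_tot - S5) - p$k6 * S2 * S5,
    p$k2 * S2 * (p$N_tot - S5) - p$k3 * S3 * (p$A_tot - S6),
    p$k3 * S3 * (p$A_tot - S6) - p$k4 * S4 * S5 - p$kappa * (S4 - S7),
    p$k2 * S2 * (p$N_tot - S5) - p$k4 * S4 * S5 - p$k6 * S2 * S5,
    -2 * v1 + 2 * p$k3 * S3 * (p$A_tot - S6) - p$k5 * S6,
    p$psi * p$kappa * (S4 - S7) - p$k * S7)
}

oracle_rhs_circadian <- function(x, p) {
  MP <- x[1]; P0 <- x[2]; P1 <- x[3]; P2 <- x[4]; MT <- x[5]
  T0 <- x[6]; T1 <- x[7]; T2 <- x[8]; C <- x[9]; CN <- x[10]
  c(p$vsP * p$KIP^p$n / (p$KIP^p$n + CN^p$n) -
      p$vmP * MP / (p$KmP + MP) - p$kd * MP,
    p$ksP * MP - p$V1P * P0 / (p$K1P + P0) +
      p$V2P * P1 / (p$K2P + P1) - p$kd * P0,
    p$V1P * P0 / (p$K1P + P0) - p$V2P * P1 / (p$K2P + P1) -
      p$V3P * P1 / (p$K3P + P1) + p$V4P * P2 / (p$K4P + P2) - p$kd * P1,
    p$V3P * P1 / (p$K3P + P1) - p$V4P * P2 / (p$K4P + P2) -
      p$k3 * P2 * T2 + p$k4 * C - p$vdP * P2 / (p$KdP + P2) - p$kd * P2,
    p$vsT * p$KIT^p$n / (p$KIT^p$n + CN^p$n) -
      p$vmT * MT / (p$KmT + MT) - p$kd * MT,
    p$ksT * MT - p$V1T * T0 / (p$K1T + T0) +
      p$V2T * T1 / (p$K2T + T1) - p$kd * T0,
    p$V1T * T0 / (p$K1T + T0) - p$V2T * T1 / (p$K2T + T1) -
      p$V3T * T1 / (p$K3T + T1) + p$V4T * T2 / (p$K4T + T2) - p$kd * T1,
    p$V3T * T1 / (p$K3T + T1) - p$V4T * T2 / (p$K4T + T2) -
      p$k3 * P2 * T2 + p$k4 * C - p$vdT * T2 / (p$KdT + T2) - p$kd * T2,
    p$k3 * P2 * T2 - p$k4 * C - p$k1 * C + p$k2 * CN - p$kdC * C,
    p$k1 * C - p$k2 * CN - p$kdN * CN)
}

# ---- finite-difference dependency pattern --------------------------------

# OR of |df_i/dx_j| > tol over several random states, pooled to unit level
oracle_sensitivity_pattern <- function(rhs, D, unit_of, n_states = 30,
                                       sampler = function(n) runif(n, 0.2, 1.5),
                                       h = 1e-6, tol = 1e-4) {
  units <- sort(unique(unit_of))
  pat <- matrix(FALSE, length(units), length(units))
  for (s in seq_len(n_states)) {
    x <- sampler(D)
    f0 <- rhs(x)
    for (cj in seq_len(D)) {
      xp <- x; xp[cj] <- xp[cj] + h
      dif <- abs(rhs(xp) - f0) / h
      hit <- which(dif > tol)
      if (length(hit)) {
        pat[cbind(match(unit_of[hit], units),
                  match(unit_of[cj], units))] <- TRUE
      }
    }
  }
  pat * 1L
}

# ---- brute-force greedy step ---------------------------------------------

# residual sum of squares of OLS of y on X (pseudo-inverse via svd)
oracle_rss <- function(X, y) {
  if (!ncol(X)) return(sum(y^2))
  sv <- svd(X)
  pos <- sv$d > 1e-10 * max(sv$d)
  fit <- sv$u[, pos, drop = FALSE] %*% crossprod(sv$u[, pos, drop = FALSE], y)
  sum((y - fit)^2)
}

# at each step pick the candidate whose addition minimises the refit RSS
oracle_greedy <- function(block_list, y, L) {
  sel <- character(0)
  rss_path <- numeric(0)
  for (l in seq_len(L)) {
    remaining <- setdiff(names(block_list), sel)
    rss <- vapply(remaining, function(k) {
      X <- do.call(cbind, block_list[c(sel, k)])
      oracle_rss(X, y)
    }, 0)
    best <- remaining[which.min(rss)]
    sel <- c(sel, best)
    rss_path <- c(rss_path, min(rss))
  }
  list(keys = sel, rss = rss_path)
}

# ---- independent chord-distance knee -------------------------------------

oracle_knee <- function(cost, l = seq_along(cost)) {
  y <- log10(pmax(cost, 1e-300))
  xs <- (l - min(l)) / diff(range(l))
  ys <- (y - min(y)) / diff(range(y))
  a <- c(xs[1], ys[1]); b <- c(xs[length(xs)], ys[length(ys)])
  ab <- b - a
  d <- vapply(seq_along(xs), function(i) {
    v <- c(xs[i], ys[i]) - a
    cr <- ab[1] * v[2] - ab[2] * v[1]          # signed area: below chord < 0
    -cr / sqrt(sum(ab^2))
  }, 0)
  inter <- 2:(length(xs) - 1)
  l[inter[which.max(d[inter])]]
}

# ---- small fixtures -------------------------------------------------------

# random orthogonal-ish design blocks plus a response; used by greedy tests
make_random_instance <- function(N = 6, P = 3, M = 60, k_true = 2, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(N), function(j) {
    B <- matrix(rnorm(M * P), M, P)
    sweep(B, 2, sqrt(colSums(B^2)), "/")
  })
  names(blocks) <- as.character(seq_len(N))
  true_keys <- as.character(sample(N, k_true))
  beta <- lapply(true_keys, function(k) rnorm(P))
  y <- Reduce(`+`, Map(function(k, b) blocks[[k]] %*% b, true_keys, beta))
  y <- as.vector(y) + 0.05 * rnorm(M)
  list(blocks = blocks, y = y, true_keys = true_keys)
}

# wrap raw blocks in a design_blocks object (single segment)
as_design_blocks <- function(blocks, target = 1L) {
  M <- nrow(blocks[[1]])
  structure(list(target = target, target_comp = 1L, target_column = target,
                 keys = names(blocks), blocks = blocks,
                 scales = lapply(blocks, function(B) rep(1, ncol(B))),
                 family = "e", P = vapply(blocks, ncol, 0L)[1],
                 order = "pairwise", M_eff = M,
                 segment = rep(seq_len(4), length.out = M),
                 units = seq_along(blocks)),
            class = "design_blocks")
}

phase_ts_quick <- function(N = 10, n_in = 3, S = 50, m = 10, seed = 1,
                           eta = 0, dt = 0.05) {
  net <- random_indegree_network(N, n_in, seed = seed)
  ts <- simulate_phase(net, sim_config(m = m, S = S, dt = dt, eta = eta,
                                       seed = seed))
  list(net = net, ts = ts)
}
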