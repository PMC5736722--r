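# Stochastic simulators for the five benchmark model systems and the
# sampled time-series container.

#' Simulation configuration
#'
#' @param m samples per segment (for `mode = "continuous"`, the total length).
#' @param S number of segments (independent initial conditions);
#'   forced to 1 for continuous sampling.
#' @param dt sampling interval between recorded points.
#' @param dt_int internal integrator step; `dt / dt_int` must be a positive
#'   integer.  Default `dt / 10`.
#' @param eta standard deviation of the additive dynamical noise (the noise
#'   enters as `eta * dW`, Euler--Maruyama discretisation).
#' @param seed integer seed controlling initial conditions and noise.
#' @param mode `"distributed"` integrates `S` independent short segments from
#'   i.i.d. initial conditions; `"continuous"` records one long trajectory.
#' @param init optional function `function(n) -> numeric(n)` drawing initial
#'   values per state component; each model has a documented default.
#' @param params named list of model parameters overriding the per-model
#'   defaults (used by the glycolysis and circadian models).
#' @return a `sim_config` list.
#' @export
sim_config <- function(m = 10L, S = 100L, dt = 0.05, dt_int = dt / 10,
                       eta = 0, seed = 1L,
                       mode = c("distributed", "continuous"),
                       init = NULL, params = list()) {
  mode <- match.arg(mode)
  nsub <- dt / dt_int
  if (abs(nsub - round(nsub)) > 1e-8 || nsub < 1) {
    stop("dt / dt_int must be a positive integer")
  }
  if (mode == "continuous") S <- 1L
  structure(list(m = as.integer(m), S = as.integer(S), dt = dt,
                 dt_int = dt_int, eta = eta, seed = as.integer(seed),
                 mode = mode, init = init, params = params),
            class = "sim_config")
}

new_ts_set <- function(segments, dt, layout, model, eta, seed, params = list()) {
  structure(list(segments = segments, dt = dt, layout = layout,
                 model = model, eta = eta, seed = seed, params = params),
            class = "ts_set")
}

#' Construct a time-series set from raw segments
#'
#' @param segments list of numeric matrices (rows = samples at spacing `dt`,
#'   columns = state components, identical layout across segments).
#' @param dt sampling interval.
#' @param layout optional component layout (`column`, `unit`, `comp`,
#'   `name`); defaults to one scalar unit per column.
#' @param model,eta,seed optional metadata.
#' @return a `ts_set`.
#' @export
ts_set <- function(segments, dt, layout = NULL, model = "custom", eta = NA_real_,
                   seed = NA_integer_) {
  segments <- lapply(segments, function(s) {
    if (is.null(dim(s))) matrix(s, ncol = 1) else as.matrix(s)
  })
  D <- unique(vapply(segments, ncol, 0L))
  if (length(D) != 1L) stop("all segments must share one column layout")
  if (is.null(layout)) layout <- unit_layout(seq_len(D))
  new_ts_set(segments, dt, layout, model, eta, seed)
}

#' @export
print.ts_set <- function(x, ...) {
  m <- vapply(x$segments, nrow, 0L)
  cat(sprintf("<ts_set> %s: %d unit(s) / %d component column(s), %d segment(s), M = %d samples, dt = %g, eta = %g\n",
              x$model, length(unique(x$layout$unit)), nrow(x$layout),
              length(x$segments), sum(m), x$dt, x$eta))
  invisible(x)
}

#' Tidy a sampled time-series set into long format
#'
#' @param x a `ts_set`.
#' @param ... unused.
#' @return a tibble with columns `segment`, `time`, `unit`, `comp`, `name`,
#'   `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.ts_set <- function(x, ...) {
  purrr::imap_dfr(x$segments, function(seg, s) {
    tibble::tibble(
      segment = as.integer(s),
      time = rep((seq_len(nrow(seg)) - 1) * x$dt, times = ncol(seg)),
      unit = rep(x$layout$unit, each = nrow(seg)),
      comp = rep(x$layout$comp, each = nrow(seg)),
      name = rep(x$layout$name, each = nrow(seg)),
      value = as.vector(seg))
  })
}

unit_layout <- function(units, D = 1L, names = NULL) {
  lay <- tibble::tibble(
    column = seq_len(length(units) * D),
    unit = rep(units, each = D),
    comp = rep(seq_len(D), times = length(units)))
  lay$name <- if (is.null(names)) paste0("u", lay$unit, "_c", lay$comp) else names
  lay
}

#' Restrict a time-series set to a subset of units
#'
#' Drops all components of the unobserved units while keeping the original
#' unit labels in the layout (hidden-unit experiments score only links among
#' the retained units).
#'
#' @param ts a `ts_set`.
#' @param units unit ids to keep.
#' @return a `ts_set`.
#' @export
subset_units <- function(ts, units) {
  keep <- which(ts$layout$unit %in% units)
  ts$segments <- lapply(ts$segments, function(seg) seg[, keep, drop = FALSE])
  ts$layout <- dplyr::mutate(ts$layout[keep, ], column = dplyr::row_number())
  ts
}

# Fixed-step integrator batched over segments.  X0 is an S x D matrix of
# initial states; returns a list of S segments (m x D each).  Heun's method
# in the deterministic case, Euler--Maruyama with additive noise otherwise.
integrate_batch <- function(rhs, X0, m, dt, dt_int, eta, guard = NULL) {
  S <- nrow(X0); D <- ncol(X0)
  nsub <- round(dt / dt_int)
  out <- array(NA_real_, c(m, S, D))
  X <- X0
  out[1, , ] <- X
  for (step in seq_len(m - 1L)) {
    for (sub in seq_len(nsub)) {
      if (eta == 0) {
        k1 <- rhs(X)
        k2 <- rhs(X + dt_int * k1)
        X <- X + (dt_int / 2) * (k1 + k2)
      } else {
        X <- X + dt_int * rhs(X) +
          (eta * sqrt(dt_int)) * matrix(stats::rnorm(S * D), S, D)
      }
    }
    if (!is.null(guard)) guard(X)
    out[step + 1L, , ] <- X
  }
  lapply(seq_len(S), function(s) matrix(out[, s, ], nrow = m, ncol = D))
}

guard_divergence <- function(limit = 1e6) {
  function(X) {
    if (any(!is.finite(X)) || max(abs(X)) > limit) {
      stop("trajectory diverged beyond |x| = ", limit,
           "; reduce dt_int or noise level")
    }
  }
}

guard_negative <- function(tol = 0.5, label = "state") {
  function(X) {
    if (min(X) < -tol) {
      stop("negative ", label, " excursion beyond tolerance (min = ",
           signif(min(X), 3), "); reduce dt_int")
    }
  }
}

rhs_mm <- function(spec) {
  Jn <- spec$J / pmax(spec$n_in, 1L)
  function(X) -X + (X / (1 + X)) %*% t(Jn)
}

rhs_phase <- function(spec, omega) {
  Jn <- spec$J / pmax(spec$n_in, 1L)
  tJ <- t(Jn)
  c105 <- cos(1.05); s105 <- sin(1.05)
  function(X) {
    s <- sin(X); c <- cos(X); s2 <- sin(2 * X); c2 <- cos(2 * X)
    A1 <- s %*% tJ; B1 <- c %*% tJ
    A2 <- s2 %*% tJ; B2 <- c2 %*% tJ
    sinD <- A1 * c - B1 * s            # sum_j J_ij sin(x_j - x_i)
    cosD <- B1 * c + A1 * s
    sin2D <- A2 * c2 - B2 * s2
    sweep(c105 * sinD - s105 * cosD + 0.33 * sin2D, 2, omega, "+")
  }
}

rhs_phase_hyper <- function(spec, omega) {
  edges <- do.call(rbind, lapply(seq_len(spec$N), function(i) {
    idx <- which(spec$E[[i]] != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    cbind(i = i, j = idx[, 1L], k = idx[, 2L],
          w = spec$E[[i]][idx] / max(spec$n_in[i], 1L))
  }))
  # incidence: column e contributes edges[e, "w"] to target edges[e, "i"]
  inc <- matrix(0, spec$N, nrow(edges))
  inc[cbind(edges[, "i"], seq_len(nrow(edges)))] <- edges[, "w"]
  tinc <- t(inc)
  function(X) {
    d <- X[, edges[, "j"], drop = FALSE] - X[, edges[, "k"], drop = FALSE]
    g <- sin(d - 1.05) + 0.33 * sin(2 * d)
    sweep(g %*% tinc, 2, omega, "+")
  }
}

rhs_roessler <- function(spec) {
  N <- spec$N
  i1 <- 3 * seq_len(N) - 2L; i2 <- i1 + 1L; i3 <- i1 + 2L
  Jn <- spec$J / pmax(spec$n_in, 1L)
  tJ <- t(Jn)
  function(X) {
    x1 <- X[, i1, drop = FALSE]; x2 <- X[, i2, drop = FALSE]
    x3 <- X[, i3, drop = FALSE]
    out <- X
    out[, i1] <- -x2 - x3 + sin(x1) %*% tJ
    out[, i2] <- x1 + 0.1 * x2
    out[, i3] <- 0.1 + x3 * (x1 - 18.0)
    out
  }
}

#' Default glycolytic oscillator parameters
#'
#' The standard anaerobic yeast glycolysis parameter set (Wolf--Heinrich
#' model family); all values may be overridden through `sim_config(params=)`.
#' @return named list.
#' @export
glycolysis_params <- function() {
  list(J0 = 2.5, k1 = 100, k2 = 6, k3 = 16, k4 = 100, k5 = 1.28, k6 = 12,
       K1 = 0.52, q = 4, N_tot = 1, A_tot = 4, kappa = 13, psi = 0.1, k = 1.8)
}

rhs_glycolysis <- function(p) {
  function(X) {
    S1 <- X[, 1]; S2 <- X[, 2]; S3 <- X[, 3]; S4 <- X[, 4]
    S5 <- X[, 5]; S6 <- X[, 6]; S7 <- X[, 7]
    v1 <- p$k1 * S1 * S6 / (1 + (S6 / p$K1)^p$q)
    v2 <- p$k2 * S2 * (p$N_tot - S5)
    v3 <- p$k3 * S3 * (p$A_tot - S6)
    v4 <- p$k4 * S4 * S5
    v6 <- p$k6 * S2 * S5
    ex <- p$kappa * (S4 - S7)
    cbind(p$J0 - v1,
          2 * v1 - v2 - v6,
          v2 - v3,
          v3 - v4 - ex,
          v2 - v4 - v6,
          -2 * v1 + 2 * v3 - p$k5 * S6,
          p$psi * ex - p$k * S7)
  }
}

#' Default circadian clock parameters
#'
#' The PER--TIM negative-feedback oscillator defaults (Leloup--Goldbeter
#' model family, constant darkness); override through `sim_config(params=)`.
#' @return named list.
#' @export
circadian_params <- function() {
  list(vsP = 1.1, vsT = 1.0, vmP = 1.0, vmT = 0.7, KmP = 0.2, KmT = 0.2,
       ksP = 0.9, ksT = 0.9, vdP = 2.2, vdT = 3.0, KdP = 0.2, KdT = 0.2,
       k1 = 0.6, k2 = 0.2, k3 = 1.2, k4 = 0.6, kd = 0.01, kdC = 0.01,
       kdN = 0.01, n = 4, KIP = 1, KIT = 1,
       V1P = 8, V2P = 1, V3P = 8, V4P = 1, K1P = 2, K2P = 2, K3P = 2, K4P = 2,
       V1T = 8, V2T = 1, V3T = 8, V4T = 1, K1T = 2, K2T = 2, K3T = 2, K4T = 2)
}

rhs_circadian <- function(p) {
  function(X) {
    MP <- X[, 1]; P0 <- X[, 2]; P1 <- X[, 3]; P2 <- X[, 4]; MT <- X[, 5]
    T0 <- X[, 6]; T1 <- X[, 7]; T2 <- X[, 8]; C <- X[, 9]; CN <- X[, 10]
    rep_P <- p$vsP * p$KIP^p$n / (p$KIP^p$n + CN^p$n)
    rep_T <- p$vsT * p$KIT^p$n / (p$KIT^p$n + CN^p$n)
    cbind(
      rep_P - p$vmP * MP / (p$KmP + MP) - p$kd * MP,
      p$ksP * MP - p$V1P * P0 / (p$K1P + P0) + p$V2P * P1 / (p$K2P + P1) - p$kd * P0,
      p$V1P * P0 / (p$K1P + P0) - p$V2P * P1 / (p$K2P + P1) -
        p$V3P * P1 / (p$K3P + P1) + p$V4P * P2 / (p$K4P + P2) - p$kd * P1,
      p$V3P * P1 / (p$K3P + P1) - p$V4P * P2 / (p$K4P + P2) -
        p$k3 * P2 * T2 + p$k4 * C - p$vdP * P2 / (p$KdP + P2) - p$kd * P2,
      rep_T - p$vmT * MT / (p$KmT + MT) - p$kd * MT,
      p$ksT * MT - p$V1T * T0 / (p$K1T + T0) + p$V2T * T1 / (p$K2T + T1) - p$kd * T0,
      p$V1T * T0 / (p$K1T + T0) - p$V2T * T1 / (p$K2T + T1) -
        p$V3T * T1 / (p$K3T + T1) + p$V4T * T2 / (p$K4T + T2) - p$kd * T1,
      p$V3T * T1 / (p$K3T + T1) - p$V4T * T2 / (p$K4T + T2) -
        p$k3 * P2 * T2 + p$k4 * C - p$vdT * T2 / (p$KdT + T2) - p$kd * T2,
      p$k3 * P2 * T2 - p$k4 * C - p$k1 * C + p$k2 * CN - p$kdC * C,
      p$k1 * C - p$k2 * CN - p$kdN * CN)
  }
}

run_simulation <- function(rhs, cfg, D, model, guard = NULL, default_init,
                           omega = NULL, x0 = NULL, params = list()) {
  set.seed(child_seed(cfg$seed, 101L))
  X0 <- if (!is.null(x0)) {
    matrix(x0, cfg$S, D, byrow = TRUE)
  } else {
    init <- if (is.null(cfg$init)) default_init else cfg$init
    matrix(init(cfg$S * D), cfg$S, D)
  }
  segs <- integrate_batch(rhs, X0, cfg$m, cfg$dt, cfg$dt_int, cfg$eta, guard)
  segs
}

#' Simulate gene-regulatory dynamics with Michaelis--Menten kinetics
#'
#' `dx_i/dt = -x_i + (1/n_i) sum_j J_ij x_j / (1 + x_j) + xi_i`.  Transients
#' relax toward a steady state; distributed sampling records `S` short
#' segments from independent random initial conditions (default U(0, 2)).
#'
#' @param spec a [network_spec] with nonnegative weights.
#' @param cfg a [sim_config]; a default of `dt = 0.25` is applied when the
#'   config was built with the generic `dt = 0.05`.
#' @param x0 optional fixed initial state (length `N`), recycled across
#'   segments.
#' @return a `ts_set`.
#' @export
simulate_mm <- function(spec, cfg = sim_config(), x0 = NULL) {
  if (any(spec$J < 0)) stop("Michaelis-Menten coupling assumes nonnegative weights")
  segs <- run_simulation(rhs_mm(spec), cfg, spec$N, "mm",
                         guard = guard_negative(0.5, "concentration"),
                         default_init = function(n) stats::runif(n, 0, 2),
                         x0 = x0)
  new_ts_set(segs, cfg$dt, unit_layout(seq_len(spec$N)), "mm",
             cfg$eta, cfg$seed)
}

#' Simulate phase-coupled oscillator networks or hypernetworks
#'
#' Pairwise coupling with two Fourier modes,
#' `sin(x_j - x_i - 1.05) + 0.33 sin(2 (x_j - x_i))`, scaled by `1/n_i`;
#' with `hyper = TRUE` the same coupling acts on differences `x_j - x_k` of
#' the second-order interaction pairs in `spec$E`.  Initial phases default to
#' U(-pi, pi); phases are integrated unwrapped on the real line (set
#' `wrap = TRUE` to record them modulo 2 pi).  Natural frequencies `omega`
#' default to i.i.d. standard normal draws (seeded).
#'
#' @param spec a [network_spec] (hypernetwork spec when `hyper = TRUE`).
#' @param cfg a [sim_config].
#' @param hyper use the second-order coupling on `spec$E`.
#' @param omega optional length-`N` natural frequencies.
#' @param wrap record phases modulo 2 pi.
#' @param x0 optional fixed initial phases.
#' @return a `ts_set` with attribute-carried `omega` in `$params$omega`.
#' @export
simulate_phase <- function(spec, cfg = sim_config(), hyper = FALSE,
                           omega = NULL, wrap = FALSE, x0 = NULL) {
  if (is.null(omega)) {
    set.seed(child_seed(cfg$seed, 7L))
    omega <- stats::rnorm(spec$N)
  }
  rhs <- if (hyper) rhs_phase_hyper(spec, omega) else rhs_phase(spec, omega)
  segs <- run_simulation(rhs, cfg, spec$N,
                         if (hyper) "phase_hyper" else "phase_net",
                         guard = guard_divergence(),
                         default_init = function(n) stats::runif(n, -pi, pi),
                         x0 = x0)
  if (wrap) segs <- lapply(segs, function(s) (s + pi) %% (2 * pi) - pi)
  ts <- new_ts_set(segs, cfg$dt, unit_layout(seq_len(spec$N)),
                   if (hyper) "phase_hyper" else "phase_net",
                   cfg$eta, cfg$seed, params = list(omega = omega))
  ts
}

#' Simulate networks of chaotic Roessler oscillators
#'
#' Three components per unit; unit `j` couples into the first component of
#' unit `i` through `(1/n_i) sum_j J_ij sin(x_j^1)`.  Initial conditions
#' default to U(-10, 10) for the first two components and U(0, 10) for the
#' third.  A divergence guard aborts if `|x| > 1e6`.
#'
#' @param spec a [network_spec].
#' @param cfg a [sim_config]; `dt_int = dt / 25` is a sensible choice for the
#'   stiff third component.
#' @param x0 optional fixed initial state of length `3 N`.
#' @return a `ts_set` whose layout maps each unit to 3 component columns.
#' @export
simulate_roessler <- function(spec, cfg = sim_config(dt_int = 0.05 / 25),
                              x0 = NULL) {
  N <- spec$N
  init <- function(n) stats::runif(n, -10, 10)
  set.seed(child_seed(cfg$seed, 101L))
  X0 <- if (!is.null(x0)) matrix(x0, cfg$S, 3 * N, byrow = TRUE) else {
    ini <- if (is.null(cfg$init)) init else cfg$init
    X <- matrix(ini(cfg$S * 3 * N), cfg$S, 3 * N)
    X[, 3 * seq_len(N)] <- abs(X[, 3 * seq_len(N)])  # x^3 starts nonnegative
    X
  }
  segs <- integrate_batch(rhs_roessler(spec), X0, cfg$m, cfg$dt, cfg$dt_int,
                          cfg$eta, guard_divergence())
  new_ts_set(segs, cfg$dt, unit_layout(seq_len(N), D = 3L), "roessler",
             cfg$eta, cfg$seed)
}

#' Simulate the 7-species glycolytic oscillator
#'
#' Transients toward a periodic orbit of the anaerobic yeast glycolysis
#' model; parameters default to [glycolysis_params()] and can be overridden
#' via `cfg$params`.  Initial concentrations default to U(0.1, 2) per species
#' (ATP, `S6`, within U(0.1, 3.5)).  A negativity guard aborts on invalid
#' integration steps.
#'
#' @param cfg a [sim_config]; use a small `dt` (0.01) as the fast kinase
#'   rates make the system stiff.
#' @param x0 optional fixed initial state (length 7).
#' @return a `ts_set` of 7 single-component units.
#' @export
simulate_glycolysis <- function(cfg = sim_config(dt = 0.01, dt_int = 4e-4),
                                x0 = NULL) {
  p <- utils::modifyList(glycolysis_params(), cfg$params)
  default_init <- function(n) stats::runif(n, 0.1, 2)
  segs <- run_simulation(rhs_glycolysis(p), cfg, 7L, "glycolysis",
                         guard = guard_negative(0.05, "concentration"),
                         default_init = default_init, x0 = x0)
  new_ts_set(segs, cfg$dt,
             unit_layout(1:7, names = paste0("S", 1:7)),
             "glycolysis", cfg$eta, cfg$seed, params = p)
}

#' Simulate the 10-variable circadian clock
#'
#' Transients toward the limit cycle of the PER--TIM negative-feedback
#' oscillator; parameters default to [circadian_params()].  Initial
#' concentrations default to U(0.1, 2) nM.
#'
#' @param cfg a [sim_config]; time is in hours, `dt = 0.25` resolves the
#'   roughly daily cycle comfortably.
#' @param x0 optional fixed initial state (length 10).
#' @return a `ts_set` of 10 single-component units.
#' @export
simulate_circadian <- function(cfg = sim_config(dt = 0.25, dt_int = 0.025),
                               x0 = NULL) {
  p <- utils::modifyList(circadian_params(), cfg$params)
  segs <- run_simulation(rhs_circadian(p), cfg, 10L, "circadian",
                         guard = guard_negative(0.05, "concentration"),
                         default_init = function(n) stats::runif(n, 0.1, 2),
                         x0 = x0)
  nm <- c("MP", "P0", "P1", "P2", "MT", "T0", "T1", "T2", "C", "CN")
  new_ts_set(segs, cfg$dt, unit_layout(1:10, names = nm),
             "circadian", cfg$eta, cfg$seed, params = p)
}

#' Simulate any benchmark model by name
#'
#' Dispatch helper used by experiments and the command line: builds the
#' network (when needed) and runs the matching simulator.
#'
#' @param model model name (see [dependency_matrices()]).
#' @param spec optional [network_spec]; required for the network models.
#' @param cfg a [sim_config].
#' @param ... passed to the individual simulator.
#' @return a `ts_set`.
#' @export
simulate_model <- function(model, spec = NULL, cfg = sim_config(), ...) {
  model <- match.arg(model, c("mm", "phase_net", "phase_hyper", "roessler",
                              "glycolysis", "circadian"))
  switch(model,
         mm = simulate_mm(spec, cfg, ...),
         phase_net = simulate_phase(spec, cfg, hyper = FALSE, ...),
         phase_hyper = simulate_phase(spec, cfg, hyper = TRUE, ...),
         roessler = simulate_roessler(spec, cfg, ...),
         glycolysis = simulate_glycolysis(cfg, ...),
         circadian = simulate_circadian(cfg, ...))
}

#' Deterministic right-hand side of a benchmark model
#'
#' Returns a function evaluating the drift of the chosen model at a single
#' state vector (useful for steady-state and sensitivity checks).
#'
#' @param model model name.
#' @param spec a [network_spec] for network-parameterised models.
#' @param params parameter overrides for the biological models.
#' @param omega natural frequencies for the phase models (default 0).
#' @return `function(x) -> numeric` of the full component state.
#' @export
model_rhs <- function(model, spec = NULL, params = list(), omega = NULL) {
  f <- switch(model,
              mm = rhs_mm(spec),
              phase_net = rhs_phase(spec, omega %||% rep(0, spec$N)),
              phase_hyper = rhs_phase_hyper(spec, omega %||% rep(0, spec$N)),
              roessler = rhs_roessler(spec),
              glycolysis = rhs_glycolysis(utils::modifyList(glycolysis_params(), params)),
              circadian = rhs_circadian(utils::modifyList(circadian_params(), params)),
              stop("unknown model ", model))
  function(x) as.vector(f(matrix(x, nrow = 1)))
}
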