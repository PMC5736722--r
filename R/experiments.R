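# Figure-level experiment orchestration: simulate -> infer -> score over
# grids of sample size, noise, hypernetwork fraction and hidden units.

model_defaults <- function(model) {
  switch(model,
         mm = list(dt = 0.25, dt_int = 0.025, m = 5L, family = "e", P = 3L,
                   order = "pairwise"),
         phase_net = list(dt = 0.05, dt_int = 0.005, m = 10L, family = "c",
                          P = 4L, order = "pairwise"),
         phase_hyper = list(dt = 0.05, dt_int = 0.005, m = 10L, family = "c",
                            P = 2L, order = "pairwise_plus_hyper2"),
         roessler = list(dt = 0.05, dt_int = 0.002, m = 10L,
                         family = c("e", "f"), P = c(2L, 1L),
                         order = "pairwise"),
         glycolysis = list(dt = 0.01, dt_int = 4e-4, m = 10L, family = "b",
                           P = 3L, order = "pairwise"),
         circadian = list(dt = 0.25, dt_int = 0.025, m = 10L, family = "b",
                          P = 3L, order = "pairwise"),
         stop("unknown model ", model))
}

#' Run one simulate--infer--score pass
#'
#' Simulates the requested benchmark model, optionally hides a random subset
#' of units, infers the network with the greedy block selection and (on
#' request) the model-free baselines, and scores every method by AUC against
#' the ground truth restricted to observed units.
#'
#' @param model benchmark model name.
#' @param N,n_in network size and in-degree (ignored for the fixed
#'   biological models).
#' @param M total number of recorded samples (`M = S x m`).
#' @param methods subset of `c("arni", "corr", "pcorr", "te")`.
#' @param eta dynamical noise standard deviation.
#' @param p_h hypernetwork interaction probability (phase_hyper only).
#' @param R fraction of observed (non-hidden) units.
#' @param m samples per segment; model-specific default.
#' @param family,P,order basis settings; model-specific defaults.
#' @param L_max,tol,scheme passed to [infer_network()].
#' @param seed integer seed for network, simulation, split and hiding.
#' @return a tibble with one row per method: `method`, `auc`, `n_obs`, `M`.
#' @export
run_once <- function(model, N = 20L, n_in = 5L, M = 1000L,
                     methods = c("arni", "corr", "pcorr", "te"),
                     eta = 0, p_h = 0, R = 1, m = NULL, family = NULL,
                     P = NULL, order = NULL, L_max = NULL, tol = 1e-4,
                     scheme = "forward2", seed = 1L) {
  def <- model_defaults(model)
  m <- m %||% def$m
  family <- family %||% def$family
  P <- P %||% def$P
  order <- order %||% def$order
  S <- as.integer(round(M / m))
  if (S < 2L) stop("M must allow at least two segments of length m")
  cfg <- sim_config(m = m, S = S, dt = def$dt, dt_int = def$dt_int,
                    eta = eta, seed = seed)
  spec <- switch(model,
                 phase_hyper = random_hypernetwork(N, n_in, p_h, seed = seed),
                 glycolysis = , circadian = NULL,
                 random_indegree_network(N, n_in, seed = seed))
  ts <- simulate_model(model, spec, cfg)
  truth <- if (is.null(spec)) dependency_matrices(model) else spec
  units <- sort(unique(ts$layout$unit))
  observed <- units
  if (R < 1) {
    set.seed(child_seed(seed, 31L))
    observed <- sort(sample(units, max(2L, round(R * length(units)))))
    ts <- subset_units(ts, observed)
  }
  out <- list()
  # ranking depth: a few multiples of the in-degree suffices for a stable
  # AUC ranking (everything unselected shares the tied minimum)
  if (is.null(L_max)) L_max <- min(length(observed), max(15L, 3L * n_in))
  for (method in methods) {
    if (method == "arni") {
      net <- infer_network(ts, family = family, P = P, order = order,
                           L_max = L_max, tol = tol, scheme = scheme,
                           seed = seed)
      auc <- if (order == "pairwise_plus_hyper2") {
        auc_hypernetwork(net$pair_scores, spec)
      } else {
        auc_network(net$scores, truth, observed)
      }
    } else {
      Sm <- switch(method,
                   corr = corr_baseline(ts),
                   pcorr = tryCatch(pcorr_baseline(ts),
                                    error = function(e) pcorr_baseline(ts, ridge = 1e-2)),
                   te = te_baseline(ts))
      auc <- auc_network(Sm, truth, observed)
    }
    out[[method]] <- tibble::tibble(method = method, auc = auc,
                                    n_obs = length(observed), M = M)
  }
  dplyr::bind_rows(out)
}

new_eval_report <- function(tbl, design) {
  structure(dplyr::as_tibble(tbl), design = design,
            class = c("eval_report", class(tbl)))
}

#' Run a figure-level experiment design
#'
#' Sweeps one design variable over `grid` with seeded replicates and scores
#' every requested method; the `m095_*` designs instead bisect over the
#' sample size `M` for the smallest value whose mean AUC exceeds 0.95.
#'
#' @param design one of `"auc_vs_M"`, `"auc_vs_eta"`, `"auc_vs_ph"`,
#'   `"auc_vs_hidden"`, `"m095_vs_N"`, `"m095_vs_nin"`.
#' @param grid values of the design variable (`M`, `eta`, `p_h`, `R`, `N` or
#'   `n_in` respectively).
#' @param replicates seeded replicates per grid point.
#' @param seed master seed.
#' @param model benchmark model; `auc_vs_ph` forces `phase_hyper`.
#' @param methods methods to run (the `m095` designs use `"arni"` only).
#' @param max_runs budget guard on the total number of simulations; when the
#'   sweep would exceed it, the report is truncated and flagged.
#' @param M_range search interval for the `m095` bisections.
#' @param ... fixed arguments forwarded to [run_once()] (e.g. `N`, `n_in`,
#'   `M`, `family`).
#' @return an `eval_report` tibble: one row per (grid value, replicate,
#'   method) with the AUC, or one row per grid value with `M095` for the
#'   bisection designs.  Attribute `budget_exceeded` flags truncation.
#' @export
run_experiment <- function(design = c("auc_vs_M", "auc_vs_eta", "auc_vs_ph",
                                      "auc_vs_hidden", "m095_vs_N",
                                      "m095_vs_nin"),
                           grid, replicates = 5L, seed = 1L,
                           model = "phase_net", methods = "arni", ...,
                           max_runs = Inf, M_range = c(100L, 4000L)) {
  design <- match.arg(design)
  args <- list(...)
  if (design == "auc_vs_ph") model <- "phase_hyper"
  if (startsWith(design, "m095")) {
    rows <- purrr::map_dfr(seq_along(grid), function(g) {
      fixed <- args
      if (design == "m095_vs_N") fixed$N <- grid[g] else fixed$n_in <- grid[g]
      res <- m095_search(model = model, fixed = fixed, replicates = replicates,
                         seed = child_seed(seed, g), M_range = M_range)
      tibble::tibble(design = design, value = grid[g], method = "arni",
                     M095 = res$M095, auc_at_M095 = res$auc,
                     n_evals = res$n_evals)
    })
    return(new_eval_report(rows, design))
  }
  runs <- 0L
  truncated <- FALSE
  rows <- list()
  for (g in seq_along(grid)) {
    for (rep in seq_len(replicates)) {
      if (runs >= max_runs) { truncated <- TRUE; break }
      runs <- runs + 1L
      fixed <- args
      fixed$model <- model
      fixed$methods <- methods
      fixed$seed <- child_seed(seed, g * 1000L + rep)
      switch(design,
             auc_vs_M = { fixed$M <- grid[g] },
             auc_vs_eta = { fixed$eta <- grid[g] },
             auc_vs_ph = { fixed$p_h <- grid[g] },
             auc_vs_hidden = { fixed$R <- grid[g] })
      res <- do.call(run_once, fixed)
      res$design <- design; res$value <- grid[g]; res$replicate <- rep
      rows[[length(rows) + 1L]] <- res
    }
    if (truncated) break
  }
  rep_tbl <- new_eval_report(dplyr::bind_rows(rows), design)
  attr(rep_tbl, "budget_exceeded") <- truncated
  if (truncated) warning("simulation budget exhausted; partial report")
  rep_tbl
}

# bisect over S (M = S * m) for the smallest tested M with mean AUC > 0.95
m095_search <- function(model, fixed, replicates, seed, M_range,
                        target = 0.95) {
  def <- model_defaults(model)
  m <- fixed$m %||% def$m
  mean_auc <- function(M) {
    mean(vapply(seq_len(replicates), function(rep) {
      a <- do.call(run_once, c(fixed, list(model = model, M = M,
                                           methods = "arni",
                                           seed = child_seed(seed, rep))))
      a$auc
    }, 0))
  }
  lo <- max(2L, floor(M_range[1L] / m)); hi <- ceiling(M_range[2L] / m)
  n_evals <- 1L
  a_hi <- mean_auc(hi * m)
  if (a_hi <= target) {
    return(list(M095 = NA_integer_, auc = a_hi, n_evals = n_evals))
  }
  best <- hi; best_auc <- a_hi
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    a <- mean_auc(mid * m)
    n_evals <- n_evals + 1L
    if (a > target) { hi <- mid; best <- mid; best_auc <- a } else lo <- mid
  }
  list(M095 = best * m, auc = best_auc, n_evals = n_evals)
}

#' Summarise an evaluation report
#'
#' @param x an `eval_report` from [run_experiment()].
#' @param ... unused.
#' @return mean, sd and standard error of the AUC per (grid value, method).
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  if (!"auc" %in% names(x)) return(dplyr::as_tibble(x))
  dplyr::summarise(dplyr::group_by(x, .data$design, .data$value, .data$method),
                   mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
                   se_auc = stats::sd(.data$auc) / sqrt(dplyr::n()),
                   n = dplyr::n(), .groups = "drop")
}

#' Plot an evaluation report
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot of mean AUC (with +/- 1 SE ribbon) or `M095` versus the
#'   design variable, one line per method.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  if ("M095" %in% names(object)) {
    return(ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$M095)) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(x = attr(object, "design"), y = "M(0.95)"))
  }
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(.data$value, .data$mean_auc,
                                  colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$se_auc,
                                      ymax = .data$mean_auc + .data$se_auc,
                                      fill = .data$method),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "design"), y = "mean AUC", colour = NULL,
                  fill = NULL)
}
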