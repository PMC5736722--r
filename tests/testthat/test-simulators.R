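test_that("all model drifts agree with independent literal transcriptions", {
  set.seed(7)
  net <- random_indegree_network(12, 4, seed = 1)
  hyp <- random_hypernetwork(12, 4, p_h = 0.6, seed = 1)
  omega <- rnorm(12)
  gp <- glycolysis_params(); cp <- circadian_params()
  f_mm <- model_rhs("mm", net)
  f_ph <- model_rhs("phase_net", net, omega = omega)
  f_hy <- model_rhs("phase_hyper", hyp, omega = omega)
  f_ro <- model_rhs("roessler", net)
  f_gl <- model_rhs("glycolysis")
  f_ci <- model_rhs("circadian")
  for (s in seq_len(1000)) {
    x <- runif(12, 0.05, 3)
    expect_equal(f_mm(x), oracle_rhs_mm(x, net$J, net$n_in), tolerance = 1e-12)
    xp <- runif(12, -pi, pi)
    expect_equal(f_ph(xp), oracle_rhs_phase(xp, net$J, net$n_in, omega),
                 tolerance = 1e-12)
    if (s <= 100) {   # the quadruple-loop oracle is slow; 100 states suffice
      expect_equal(f_hy(xp), oracle_rhs_phase_hyper(xp, hyp$E, hyp$n_in, omega),
                   tolerance = 1e-12)
    }
    xr <- runif(36, -5, 5)
    expect_equal(f_ro(xr), oracle_rhs_roessler(xr, net$J, net$n_in),
                 tolerance = 1e-12)
    xg <- runif(7, 0.05, 2)
    expect_equal(f_gl(xg), oracle_rhs_glycolysis(xg, gp), tolerance = 1e-12)
    xc <- runif(10, 0.05, 2)
    expect_equal(f_ci(xc), oracle_rhs_circadian(xc, cp), tolerance = 1e-12)
  }
})

test_that("decoupled Michaelis-Menten units decay exponentially to zero", {
  # a 2-unit network with weight 0 on all links behaves as dx/dt = -x
  spec <- random_indegree_network(2, 1, seed = 1)
  spec$J[] <- 0
  x0 <- c(1.7, 0.4)
  ts <- simulate_mm(spec, sim_config(m = 9, S = 1, dt = 0.25, dt_int = 0.005,
                                     eta = 0, seed = 1,
                                     mode = "continuous"), x0 = x0)
  times <- (0:8) * 0.25
  expect_equal(ts$segments[[1]][, 1], x0[1] * exp(-times), tolerance = 1e-4)
  expect_equal(ts$segments[[1]][, 2], x0[2] * exp(-times), tolerance = 1e-4)
})

test_that("noise-free transients reach a steady state of the drift", {
  # subcritical weights give exponential relaxation; unit weights sit at the
  # critical point where decay toward zero is only algebraic
  net <- random_indegree_network(10, 3, seed = 4,
                                 weight_scheme = "uniform_range")
  ts <- simulate_mm(net, sim_config(m = 400, S = 1, dt = 0.25,
                                    dt_int = 0.025, seed = 4,
                                    mode = "continuous"))
  xT <- ts$segments[[1]][400, ]
  expect_lt(max(abs(model_rhs("mm", net)(xT))), 1e-6)
})

test_that("distributed sampling yields S segments totalling M samples", {
  net <- random_indegree_network(20, 10, seed = 2)
  ts <- simulate_mm(net, sim_config(m = 5, S = 40, dt = 0.25, seed = 2))
  expect_length(ts$segments, 40)
  expect_equal(sum(vapply(ts$segments, nrow, 0L)), 200)

  tc <- simulate_mm(net, sim_config(m = 100, S = 7, dt = 0.25, seed = 2,
                                    mode = "continuous"))
  expect_length(tc$segments, 1)
  expect_equal(nrow(tc$segments[[1]]), 100)

  # byte-identical reruns under the same seed
  again <- simulate_mm(net, sim_config(m = 5, S = 40, dt = 0.25, seed = 2))
  expect_identical(ts$segments, again$segments)
})

test_that("phase coupling evaluates to its closed form", {
  spec <- random_indegree_network(2, 1, seed = 1)
  spec$J <- matrix(c(0, 1, 1, 0), 2, 2)      # unit weights both ways
  f <- model_rhs("phase_net", spec, omega = c(0, 0))
  # x = (0, 0): sin(-1.05) + 0.33 sin(0)
  expect_equal(f(c(0, 0)), rep(sin(-1.05), 2), tolerance = 1e-12)

  # hyper pair {2, 3} acting on unit 1 with equal phases: sin(-1.05)
  E <- replicate(3, matrix(0, 3, 3), simplify = FALSE)
  E[[1]][2, 3] <- 1
  hyp <- structure(list(N = 3L, J = matrix(0, 3, 3), E = E,
                        n_in = rep(1L, 3), self_allowed = FALSE,
                        kind = "hypernetwork"), class = "network_spec")
  fh <- model_rhs("phase_hyper", hyp, omega = c(0, 0, 0))
  expect_equal(fh(c(0.2, 0.7, 0.7))[1], sin(-1.05), tolerance = 1e-12)
})

test_that("Roessler components follow the printed coefficients", {
  net <- random_indegree_network(4, 2, seed = 3)
  f <- model_rhs("roessler", net)
  x <- rep(c(1, 1, 1), 4)
  expect_equal(unname(f(x)[seq(2, 12, by = 3)]), rep(1.1, 4),
               tolerance = 1e-12)
  x2 <- rep(c(18, 0.5, 2), 4)
  expect_equal(unname(f(x2)[seq(3, 12, by = 3)]), rep(0.1, 4),
               tolerance = 1e-12)

  ts <- simulate_roessler(net, sim_config(m = 4, S = 3, dt = 0.05,
                                          dt_int = 0.002, seed = 3))
  expect_equal(ncol(ts$segments[[1]]), 12)
  expect_equal(nrow(ts$layout), 12)
  expect_equal(unique(table(ts$layout$unit)), 3L)
})

test_that("glycolysis and circadian drifts honour their cancellation identities", {
  f <- model_rhs("glycolysis")
  # S4 = S7 removes the exchange flux from both pools
  x <- c(1, 1, 1, 0.8, 0.3, 1.2, 0.8)
  p <- glycolysis_params()
  expect_equal(f(x)[7], -p$k * 0.8, tolerance = 1e-12)
  # S2 = 0 reduces the NADH balance to -k4 S4 S5
  x2 <- c(1, 0, 1, 0.8, 0.3, 1.2, 0.5)
  expect_equal(f(x2)[5], -p$k4 * 0.8 * 0.3, tolerance = 1e-12)

  g <- model_rhs("circadian")
  cp <- circadian_params()
  xc <- rep(0.5, 10); xc[9] <- 0; xc[10] <- 0
  expect_equal(g(xc)[10], 0, tolerance = 1e-12)
  # with no nuclear complex the per transcription term saturates at vsP
  expect_equal(g(xc)[1],
               cp$vsP - cp$vmP * 0.5 / (cp$KmP + 0.5) - cp$kd * 0.5,
               tolerance = 1e-12)

  tg <- simulate_glycolysis(sim_config(m = 5, S = 4, dt = 0.01,
                                       dt_int = 4e-4, seed = 5))
  expect_equal(ncol(tg$segments[[1]]), 7)
  expect_true(min(unlist(tg$segments)) >= 0 - 1e-9)
  tc <- simulate_circadian(sim_config(m = 5, S = 4, dt = 0.25,
                                      dt_int = 0.025, seed = 5))
  expect_equal(ncol(tc$segments[[1]]), 10)
})

test_that("the deterministic integrator converges at second order", {
  net <- random_indegree_network(6, 2, seed = 8)
  x0 <- runif(6, -pi, pi)
  run <- function(dt_int) {
    simulate_phase(net, sim_config(m = 11, S = 1, dt = 0.5, dt_int = dt_int,
                                   seed = 8, mode = "continuous"),
                   omega = rep(0.3, 6), x0 = x0)$segments[[1]][11, ]
  }
  ref <- run(0.5 / 320)
  e1 <- max(abs(run(0.5 / 10) - ref))
  e2 <- max(abs(run(0.5 / 20) - ref))
  expect_gt(e1 / e2, 3)      # halving the step cuts the error ~4x (order 2)
  expect_lt(e1 / e2, 6)
})

test_that("Euler-Maruyama noise variance scales as eta^2 dt", {
  spec <- random_indegree_network(2, 1, seed = 1)
  spec$J[] <- 0
  eta <- 0.4; dt <- 0.02
  x0 <- c(1, 1)
  noisy <- simulate_mm(spec, sim_config(m = 2, S = 4000, dt = dt,
                                        dt_int = dt, eta = eta, seed = 9),
                       x0 = x0)
  ends <- t(vapply(noisy$segments, function(s) s[2, ], numeric(2)))
  v <- apply(ends, 2, var)
  expect_equal(mean(v), eta^2 * dt, tolerance = 0.1)
})

test_that("divergence and negativity guards trigger on invalid settings", {
  net <- random_indegree_network(3, 1, seed = 1)
  # a coarse internal step on the stiff third component blows up
  expect_error(
    simulate_roessler(net, sim_config(m = 50, S = 1, dt = 2, dt_int = 2,
                                      seed = 1, mode = "continuous"),
                      x0 = rep(c(1, 1, 30), 3)),
    "diverged")
  expect_error(sim_config(dt = 0.05, dt_int = 0.03), "integer")
})

test_that("time series tidy to long format with unit/component labels", {
  net <- random_indegree_network(3, 1, seed = 1)
  ts <- simulate_roessler(net, sim_config(m = 4, S = 2, dt = 0.05,
                                          dt_int = 0.002, seed = 1))
  tb <- as_tibble(ts)
  expect_equal(nrow(tb), 2 * 4 * 9)
  expect_setequal(unique(tb$comp), 1:3)
  sub <- subset_units(ts, c(1, 3))
  expect_equal(sort(unique(sub$layout$unit)), c(1, 3))
  expect_equal(ncol(sub$segments[[1]]), 6)
})
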