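test_that("an exactly representable response is found first with zero cost", {
  set.seed(1)
  M <- 80
  blocks <- lapply(1:5, function(j) {
    B <- matrix(rnorm(M * 3), M, 3)
    sweep(B, 2, sqrt(colSums(B^2)), "/")
  })
  names(blocks) <- as.character(1:5)
  y <- blocks[["4"]][, 1] * 2.5
  fit <- infer_unit(as_design_blocks(blocks), y, L_max = 5, seed = 1)
  expect_equal(fit$ranked$key[1], "4")
  expect_lt(fit$ranked$cost_train[1], 1e-20)
  expect_equal(fit$stop_reason, "residual_tol")
})

test_that("a zero response selects nothing", {
  set.seed(2)
  blocks <- lapply(1:3, function(j) matrix(rnorm(40), 40, 2))
  names(blocks) <- as.character(1:3)
  fit <- infer_unit(as_design_blocks(blocks), rep(0, 40), seed = 1)
  expect_equal(nrow(fit$ranked), 0)
  expect_equal(fit$cost0_train, 0)
  expect_equal(fit$stop_reason, "residual_tol")
})

test_that("fully degenerate candidates yield an empty ranking with a reason", {
  blocks <- list("1" = matrix(0, 30, 0), "2" = matrix(0, 30, 0))
  fit <- infer_unit(as_design_blocks(blocks), rnorm(30), seed = 1)
  expect_equal(nrow(fit$ranked), 0)
  expect_equal(fit$stop_reason, "degenerate")
})

test_that("every greedy step matches the brute-force OLS refit oracle", {
  for (s in 1:8) {
    inst <- make_random_instance(N = 6, P = 3, M = 60, k_true = 2, seed = s)
    db <- as_design_blocks(inst$blocks)
    fit <- infer_unit(db, inst$y, L_max = 4, tol = 0, train_frac = 0.6,
                      seed = s)
    sp <- arni:::split_rows(db$segment, 0.6, s)
    tr_blocks <- lapply(inst$blocks, function(B) B[sp$train, , drop = FALSE])
    orc <- oracle_greedy(tr_blocks, inst$y[sp$train], nrow(fit$ranked))
    expect_identical(fit$ranked$key, orc$keys)
    expect_equal(fit$ranked$cost_train, orc$rss / length(sp$train),
                 tolerance = 1e-9)
  }
})

test_that("training cost is non-increasing and matches nested OLS refits", {
  inst <- make_random_instance(N = 8, P = 2, M = 80, k_true = 3, seed = 11)
  db <- as_design_blocks(inst$blocks)
  fit <- infer_unit(db, inst$y, L_max = 6, tol = 0, seed = 11)
  expect_true(all(diff(c(fit$cost0_train, fit$ranked$cost_train)) <= 1e-12))
  sp <- arni:::split_rows(db$segment, 0.6, 11)
  for (l in seq_len(nrow(fit$ranked))) {
    X <- do.call(cbind, lapply(inst$blocks[fit$ranked$key[seq_len(l)]],
                               function(B) B[sp$train, , drop = FALSE]))
    expect_equal(fit$ranked$cost_train[l],
                 oracle_rss(X, inst$y[sp$train]) / length(sp$train),
                 tolerance = 1e-9)
  }
})

test_that("the cost curve starts at the zero-predictor mean square", {
  inst <- make_random_instance(seed = 3)
  db <- as_design_blocks(inst$blocks)
  fit <- infer_unit(db, inst$y, L_max = 3, seed = 3)
  cc <- cost_curve(fit)
  sp <- arni:::split_rows(db$segment, 0.6, 3)
  expect_equal(cc$cost_train[1], mean(inst$y[sp$train]^2))
  expect_equal(cc$cost_val[1], mean(inst$y[sp$val]^2))
  expect_equal(cc$l, 0:3)
})

test_that("sparse linear dynamics are recovered exactly with power basis", {
  set.seed(42)
  net <- random_indegree_network(10, 3, seed = 42)
  A <- net$J * matrix(runif(100, 0.5, 1.5) * sign(rnorm(100)), 10, 10)
  X <- matrix(rnorm(400 * 10), 400, 10)
  Y <- X %*% t(A)
  ds <- derivative_set(X, Y, segment = rep(1:40, each = 10))
  scores <- matrix(0, 10, 10)
  for (i in 1:10) {
    bl <- build_blocks(ds, target = i, family = "e", P = 1)
    fit <- infer_unit(bl, Y[, i], L_max = 5, seed = 1)
    sel3 <- fit$ranked$j[1:3]
    expect_setequal(sel3, which(A[i, ] != 0))
    scores[i, fit$ranked$j] <- 10 - fit$ranked$step
  }
  expect_equal(auc_network(scores, net), 1)
})

test_that("knee detection reproduces the chord-distance oracle", {
  toy <- c(100, 10, 1, 0.95, 0.94, 0.93)
  k <- detect_knee(toy)
  expect_equal(k$l_star, 3)
  expect_equal(k$l_star, oracle_knee(toy))
  expect_true(k$confident)

  flat <- detect_knee(rep(2.5, 6))
  expect_equal(flat$l_star, 0)
  expect_true(flat$flat)
  expect_false(flat$confident)

  # strictly geometric decay: log-linear, no interior curvature maximum
  geo <- detect_knee(2^-(1:10))
  expect_false(geo$confident)

  set.seed(6)
  for (rep in 1:5) {
    shape <- c(10^seq(2, -2, length.out = 4), 10^runif(6, -2.1, -1.9))
    expect_equal(detect_knee(shape)$l_star, oracle_knee(shape))
  }
})

test_that("network inference is deterministic and label-equivariant", {
  qp <- phase_ts_quick(N = 8, n_in = 3, S = 40, seed = 31)
  f1 <- infer_network(qp$ts, family = "c", P = 2, L_max = 6, seed = 31)
  f2 <- infer_network(qp$ts, family = "c", P = 2, L_max = 6, seed = 31)
  expect_identical(f1$scores, f2$scores)
  expect_identical(tidy(f1), tidy(f2))

  # permuting unit labels permutes the score matrix identically
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  ts_p <- qp$ts
  ts_p$segments <- lapply(ts_p$segments, function(s) s[, perm])
  f3 <- infer_network(ts_p, family = "c", P = 2, L_max = 6, seed = 31)
  expect_equal(unname(f3$scores), unname(f1$scores[perm, perm]))
})

test_that("phase coupling coefficients are recovered at the true blocks", {
  net <- random_indegree_network(6, 2, seed = 51)
  ts <- simulate_phase(net, sim_config(m = 10, S = 30, dt = 0.01,
                                       dt_int = 0.001, seed = 51))
  fit <- infer_network(ts, family = "c", P = 2, scheme = "central3",
                       L_max = 4, seed = 51)
  for (i in 1:6) {
    co <- fit$fits[[i]]$coefficients
    for (j in which(net$J[i, ] != 0)) {
      cj <- co[co$key == as.character(j), ]
      expect_equal(sqrt(sum(cj$estimate[cj$column %in% 1:2]^2)), 1 / 2,
                   tolerance = 5e-3)
      expect_equal(sqrt(sum(cj$estimate[cj$column %in% 3:4]^2)), 0.33 / 2,
                   tolerance = 5e-3)
    }
  }
})

test_that("fit accessors tidy, glance and autoplot work", {
  qp <- phase_ts_quick(N = 6, n_in = 2, S = 30, seed = 61)
  net <- infer_network(qp$ts, family = "c", P = 2, L_max = 5, seed = 61)
  td <- tidy(net)
  expect_true(all(c("target", "key", "step", "cost_train", "cost_val")
                  %in% names(td)))
  gl <- glance(net)
  expect_equal(nrow(gl), 6)
  expect_s3_class(autoplot(net$fits[[1]]), "ggplot")
  expect_s3_class(plot_scores(net), "ggplot")
})
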