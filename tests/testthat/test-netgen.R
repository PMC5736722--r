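test_that("fixed in-degree networks satisfy their structural constraints", {
  net <- random_indegree_network(5, 2, seed = 7)
  expect_equal(unname(rowSums(net$J != 0)), rep(2, 5))
  expect_equal(diag(net$J), rep(0, 5))

  # n_in = N - 1 forces the complete graph
  full <- random_indegree_network(3, 2, seed = 42)
  expect_equal(sum(full$J != 0), 6)

  expect_identical(random_indegree_network(20, 10, seed = 1)$J,
                   random_indegree_network(20, 10, seed = 1)$J)
  expect_false(identical(random_indegree_network(20, 10, seed = 1)$J,
                         random_indegree_network(20, 10, seed = 2)$J))

  expect_error(random_indegree_network(5, 5, seed = 1), "in-degree")
  expect_error(random_indegree_network(5, 0, seed = 1), "in-degree")

  w <- random_indegree_network(10, 3, seed = 1, weight_scheme = "uniform_range")
  nz <- w$J[w$J != 0]
  expect_true(all(nz >= 0.5 & nz <= 1))
})

test_that("hypernetworks interpolate between pairwise and pure three-point", {
  # p_h = 0: every interaction is a degenerate pair {j, i}
  h0 <- random_hypernetwork(20, 5, p_h = 0, seed = 3)
  for (i in 1:20) {
    idx <- which(h0$E[[i]] != 0, arr.ind = TRUE)
    expect_equal(nrow(idx), 5)
    expect_true(all(idx[, 1] != i & idx[, 2] == i))
  }
  # its dependency matrix matches the plain-network reading of J
  lam_h <- dependency_matrices("phase_hyper", h0)
  net_equiv <- structure(list(N = 20L, J = h0$J, E = NULL,
                              n_in = rep(5L, 20), self_allowed = FALSE,
                              kind = "network"), class = "network_spec")
  lam_n <- dependency_matrices("phase_net", net_equiv)
  expect_identical(lam_h, lam_n)

  # p_h = 1: every interaction involves two units different from the target
  h1 <- random_hypernetwork(20, 5, p_h = 1, seed = 3)
  for (i in 1:20) {
    idx <- which(h1$E[[i]] != 0, arr.ind = TRUE)
    expect_equal(nrow(idx), 5)
    expect_true(all(idx[, 1] != i & idx[, 2] != i))
  }

  expect_error(random_hypernetwork(2, 1, p_h = 0.5, seed = 1), "pair")
})

test_that("pair fraction at p_h = 0.5 matches the binomial oracle", {
  n_pair <- 0L; n_tot <- 0L
  for (rep in 1:50) {
    h <- random_hypernetwork(20, 5, p_h = 0.5, seed = 1000 + rep)
    for (i in 1:20) {
      idx <- which(h$E[[i]] != 0, arr.ind = TRUE)
      n_pair <- n_pair + sum(idx[, 2] != i)
      n_tot <- n_tot + nrow(idx)
    }
  }
  se <- sqrt(0.25 / n_tot)
  expect_lt(abs(n_pair / n_tot - 0.5), 4 * se)
})

test_that("biological dependency matrices match the symbolic equations", {
  gly <- dependency_matrices("glycolysis")
  expect_equal(which(gly["S1", ] == 1), c(S1 = 1L, S6 = 6L))
  expect_equal(which(gly["S7", ] == 1), c(S4 = 4L, S7 = 7L))
  expect_equal(unname(rowSums(gly)), c(2, 4, 4, 5, 3, 3, 2))

  cir <- dependency_matrices("circadian")
  expect_equal(which(cir["MP", ] == 1), c(MP = 1L, CN = 10L))
  expect_equal(which(cir["CN", ] == 1), c(C = 9L, CN = 10L))

  expect_error(dependency_matrices("unknown"), "arg")
  expect_error(dependency_matrices("mm"), "network_spec")
})

test_that("dependency matrices agree with finite-difference RHS sensitivity", {
  set.seed(99)
  net <- random_indegree_network(8, 3, seed = 5)
  for (model in c("mm", "phase_net")) {
    lam <- dependency_matrices(model, net)
    rhs <- model_rhs(model, net, omega = rnorm(8))
    pat <- oracle_sensitivity_pattern(rhs, 8, unit_of = 1:8)
    expect_identical(unname(lam), unname(pat), label = model)
  }

  hyp <- random_hypernetwork(8, 3, p_h = 0.5, seed = 5)
  lam <- dependency_matrices("phase_hyper", hyp)
  pat <- oracle_sensitivity_pattern(model_rhs("phase_hyper", hyp), 8,
                                    unit_of = 1:8)
  expect_identical(unname(lam), unname(pat))

  rnet <- random_indegree_network(5, 2, seed = 6)
  lam <- dependency_matrices("roessler", rnet)
  pat <- oracle_sensitivity_pattern(
    model_rhs("roessler", rnet), 15, unit_of = rep(1:5, each = 3),
    sampler = function(n) runif(n, 0.5, 3))
  expect_identical(unname(lam), unname(pat))

  for (model in c("glycolysis", "circadian")) {
    lam <- dependency_matrices(model)
    pat <- oracle_sensitivity_pattern(model_rhs(model), ncol(lam),
                                      unit_of = seq_len(ncol(lam)))
    expect_identical(unname(lam), unname(pat), label = model)
  }
})

test_that("edge lists round-trip through the text format", {
  net <- random_indegree_network(7, 2, seed = 9, weight_scheme = "uniform_range")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, force = TRUE)
  back <- read_network(path)
  expect_equal(back$J, net$J)
  expect_equal(back$N, net$N)

  hyp <- random_hypernetwork(6, 2, p_h = 0.7, seed = 9)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(hyp, path2, force = TRUE)
  back2 <- read_network(path2)
  expect_equal(back2$E, hyp$E)
  expect_equal(back2$J, hyp$J)
  expect_error(write_network(hyp, path2), "force")
})

test_that("tidying a network spec lists each true interaction once", {
  net <- random_indegree_network(6, 2, seed = 2)
  td <- tidy(net)
  expect_equal(nrow(td), 12)
  expect_true(all(is.na(td$k)))

  hyp <- random_hypernetwork(6, 3, p_h = 1, seed = 2)
  tdh <- tidy(hyp)
  expect_equal(nrow(tdh), 18)
  expect_true(all(tdh$j < tdh$k))
})
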