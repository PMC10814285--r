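toy_data <- function(seed = 51, sep = 6) {
  # 3 + 3 points, t = 1: three fairlets, two well-separated groups
  set.seed(seed)
  X1 <- rbind(c(0, 0), c(0.4, 0.2), c(sep, sep)) + matrix(rnorm(6, 0, 0.05), 3)
  X2 <- rbind(c(0.2, 0.1), c(0.5, 0), c(sep + 0.3, sep)) +
    matrix(rnorm(6, 0, 0.05), 3)
  tibble::tibble(
    x = c(X1[, 1], X2[, 1]), y = c(X1[, 2], X2[, 2]),
    a = rep(c("g1", "g2"), each = 3)
  )
}

test_that("log joint is linear in the temperatures and zero at zero", {
  set.seed(52)
  L <- matrix(runif(9), 3, 3)
  B <- fairlet_assignment(c(2L, 1L, 3L), 3)
  u <- matrix(rnorm(6), 3, 2)
  lab <- c(1L, 2L, 1L)
  expect_equal(log_joint(B, lab, L, u, 0, 0, 2), 0)
  v1 <- log_joint(B, lab, L, u, 1, 1.5, 2)
  expect_equal(log_joint(B, lab, L, u, 2, 3, 2), 2 * v1)
  expect_equal(v1, -fairlet_loss(B, L) - 1.5 * cluster_loss(u, lab, 2))
})

test_that("the two-step optimum maximizes the joint on a separated toy", {
  d <- toy_data()
  fd <- fair_dataset(d, a)
  L <- fairlet_cost_matrix(fd)
  X1 <- fd$points[1:3, ]
  X2 <- fd$points[4:6, ]
  parts <- enumerate_2partitions(3)
  best <- -Inf
  for (o in enumerate_owners(3, 1)) {
    B <- fairlet_assignment(o, 3)
    u <- X1
    for (j in 1:3) u[o[j], ] <- (X1[o[j], ] + X2[j, ]) / 2
    for (p in parts) {
      best <- max(best, log_joint(B, p, L, u, 1, 1, 2))
    }
  }
  B_opt <- optimal_fairlets(L, 1)
  dec <- fairlet_decomposition(B_opt, fd)
  set.seed(53)
  fit <- map_clustering(dec$centers, 2, n_restarts = 5)
  expect_equal(log_joint(B_opt, fit$labels, L, dec$centers, 1, 1, 2), best)
})

test_that("MC-EM draws are balanced, reproducible, and degenerate at low temperature", {
  d <- simulate_well_specified(seed = 61)
  fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                    mode = "mcem", n_iterations = 150, burn_in = 50,
                    seed = 2)
  expect_true(all(fit$summary$balance_per_draw == 1))
  expect_equal(fit$summary$balance_map, 1)
  # identical seed, identical draw sequence
  fit2 <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                     mode = "mcem", n_iterations = 150, burn_in = 50,
                     seed = 2)
  expect_identical(fit$draws$observation_partitions,
                   fit2$draws$observation_partitions)
  # at a very low temperature every draw is the MAP clustering of the centers
  fit3 <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                     mode = "mcem", lambda_c = 1000, n_iterations = 80,
                     burn_in = 20, seed = 3)
  expect_equal(nrow(unique(fit3$draws$fairlet_partitions)), 1)
  expect_identical(canonical(fit3$draws$observation_partitions[1, ]),
                   fit3$cfcf_partition)
})

test_that("full MCMC keeps margins and exactly K blocks in every draw", {
  d <- simulate_misspecified(seed = 62)
  fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                    mode = "mcmc", n_iterations = 200, burn_in = 50,
                    seed = 4)
  for (s in seq_len(nrow(fit$draws$fairlet_assignments))) {
    expect_equal(tabulate(fit$draws$fairlet_assignments[s, ], 50),
                 rep(1L, 50))
    expect_equal(length(unique(fit$draws$fairlet_partitions[s, ])), 2)
  }
  expect_true(all(fit$summary$balance_per_draw == 1))
})

test_that("expanded partitions inherit fairlet structure", {
  d <- toy_data(seed = 63)
  fd <- fair_dataset(d, a)
  B <- optimal_fairlets(fairlet_cost_matrix(fd), 1)
  obs <- expand_labels(c(1L, 1L, 2L), B, fd)
  expect_equal(cluster_balance(obs, attribute_codes_for_test(fd)), 1)
  expect_equal(as.vector(table(obs)), c(4, 2))  # (t + 1) x fairlet sizes

  # t = 2: balance exactly 1/2
  df <- tibble::tibble(
    x = c(0, 10, 0.1, 0.2, 10.1, 10.2),
    y = rep(0, 6),
    a = rep(c("g1", "g2"), c(2, 4))
  )
  fd2 <- fair_dataset(df, a)
  B2 <- optimal_fairlets(fairlet_cost_matrix(fd2), 2)
  obs2 <- expand_labels(c(1L, 2L), B2, fd2)
  expect_equal(cluster_balance(obs2, attribute_codes_for_test(fd2)), 0.5)
  expect_equal(as.vector(table(obs2)), c(3, 3))
  expect_error(expand_labels(1L, B2, fd2), class = "fairgibbs_input_error")
})

test_that("the joint MAP draw solves the enumerated joint on the toy", {
  d <- toy_data(seed = 64)
  fit <- fair_gibbs(d, a, K = 2, lambda_f = 1, lambda_c = 1,
                    n_iterations = 4000, burn_in = 500, seed = 5)
  fd <- fit$dataset
  L <- fit$cost_matrix
  X1 <- fd$points[1:3, ]
  X2 <- fd$points[4:6, ]
  best <- -Inf
  for (o in enumerate_owners(3, 1)) {
    u <- X1
    for (j in 1:3) u[o[j], ] <- (X1[o[j], ] + X2[j, ]) / 2
    for (p in enumerate_2partitions(3)) {
      best <- max(best, log_joint(fairlet_assignment(o, 3), p, L, u, 1, 1, 2))
    }
  }
  expect_equal(max(fit$draws$log_joint), best, tolerance = 1e-10)
})

test_that("at high temperatures the MAP draw equals the two-step estimator", {
  d <- simulate_well_specified(seed = 65)
  fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                    lambda_f = 100, lambda_c = 100,
                    n_iterations = 150, burn_in = 50, seed = 6)
  map_part <- fit$summary$map_partition
  expect_identical(canonical(map_part), canonical(fit$cfcf_partition))
})

test_that("configuration errors are classed and informative", {
  d <- toy_data()
  expect_error(fair_gibbs(d, a, K = 1), class = "fairgibbs_config_error")
  expect_error(fair_gibbs(d, a, K = 2, lambda_f = -1),
               class = "fairgibbs_config_error")
  expect_error(fair_gibbs(d, a, K = 2, n_iterations = 10, burn_in = 20),
               class = "fairgibbs_config_error")
  expect_error(fair_gibbs(d, a, K = 2, thin = 0),
               class = "fairgibbs_config_error")
})
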