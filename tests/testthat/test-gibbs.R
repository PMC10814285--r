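test_that("cluster loss matches hand computation and an inertia oracle", {
  # two points in one cluster: center (1,0), squared deviations 1 + 1
  u <- matrix(c(0, 2, 0, 0), 2, 2)
  expect_equal(cluster_loss(u, c(1, 1), 1), 2)
  # every unit its own cluster: zero loss
  expect_equal(cluster_loss(u, 1:2, 2), 0)

  set.seed(31)
  u20 <- matrix(rnorm(40), 20, 2)
  lab <- sample(1:3, 20, replace = TRUE)
  lab <- canonical(lab)
  inertia <- sum(vapply(unique(lab), function(k) {
    rows <- u20[lab == k, , drop = FALSE]
    sum(sweep(rows, 2, colMeans(rows))^2)
  }, numeric(1)))
  expect_equal(cluster_loss(u20, lab, max(lab)), inertia)

  # Manhattan loss with lower-median centers
  u4 <- matrix(c(0, 1, 5, 10), 4, 1)
  # lower median = 1; loss = 1 + 0 + 4 + 9
  expect_equal(cluster_loss(u4, rep(1, 4), 1, "manhattan"), 14)
  expect_error(cluster_loss(u20, rep(1, 20), 2),
               class = "fairgibbs_input_error")
})

test_that("label conditional is symmetric, sharp at low temperature, valid", {
  u <- matrix(c(-1, 1, 0, 0, 0, 0), 3, 2)  # unit 3 equidistant
  p <- gibbs_label_conditional(3, c(1, 2, 1), u, 2, lambda_c = 0.7)
  expect_equal(p, c(0.5, 0.5))
  expect_error(gibbs_label_conditional(3, c(1, 1, 1), u, 1, 1),
               class = "fairgibbs_config_error")

  set.seed(32)
  u5 <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2), matrix(rnorm(4, 5, 0.1), 2, 2))
  p5 <- gibbs_label_conditional(1, c(1, 1, 1, 2, 2), u5, 2, lambda_c = 1000)
  expect_gte(p5[1], 0.999)

  # singleton units must stay: degenerate conditional
  p_single <- gibbs_label_conditional(5, c(1, 1, 1, 1, 2), u5, 2, 1)
  expect_equal(p_single, c(0, 1))
})

test_that("conditional equals the joint-enumeration conditional to 1e-10", {
  set.seed(33)
  for (loss in c("squared_euclidean", "manhattan")) {
    for (m in c(5, 8)) {
      u <- matrix(rnorm(2 * m), m, 2)
      lab <- canonical(c(1, 2, sample(1:2, m - 2, replace = TRUE)))
      for (i in seq_len(m)) {
        cond <- gibbs_label_conditional(i, lab, u, 2, 0.8, loss)
        joint <- vapply(1:2, function(k) {
          l <- lab
          l[i] <- k
          if (any(tabulate(l, 2) == 0)) return(0)
          exp(-0.8 * cluster_loss(u, l, 2, loss))
        }, numeric(1))
        expect_lt(max(abs(cond - joint / sum(joint))), 1e-10)
      }
    }
  }
})

test_that("a sweep preserves the clustering-state invariants", {
  set.seed(34)
  u <- matrix(rnorm(24), 12, 2)
  lab <- rep(1:3, 4)
  out <- gibbs_sweep(lab, u, 3, lambda_c = 1)
  expect_length(out, 12)
  expect_true(all(tabulate(out, 3) >= 1))
  lossval <- cluster_loss(u, out, 3)
  expect_gte(lossval, 0)
  expect_true(is.finite(lossval))
})

test_that("at near-zero temperature a Lloyd fixed point is held", {
  set.seed(35)
  u <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2), matrix(rnorm(10, 8, 0.3), 5, 2))
  fix <- map_clustering(u, 2, n_restarts = 5)
  out <- gibbs_sweep(fix$labels, u, 2, lambda_c = 1000)
  expect_equal(out, fix$labels)
})

test_that("sweep chain matches the Boltzmann partition law by enumeration", {
  set.seed(36)
  m <- 7
  u <- rbind(matrix(rnorm(8, 0, 1), 4, 2), matrix(rnorm(6, 3, 1), 3, 2))
  lambda <- 0.5
  parts <- enumerate_2partitions(m)
  pr <- vapply(parts, function(p) exp(-lambda * cluster_loss(u, p, 2)),
               numeric(1))
  pr <- pr / sum(pr)
  res <- fairgibbs:::cpp_sweep_chain(rep(1:2, c(4, 3)), u, 2L, lambda, 0L,
                                     100000L, 1000L, 1L, FALSE)
  keys <- apply(res$draws, 1, partition_index, parts = parts)
  emp <- tabulate(keys, length(parts)) / length(keys)
  expect_lt(total_variation(emp, pr), 0.03)
})

test_that("MAP clustering matches exhaustive and baseline optima", {
  # K = m: singletons, zero loss
  set.seed(37)
  u <- matrix(rnorm(8), 4, 2)
  fit <- map_clustering(u, 4, n_restarts = 3)
  expect_equal(fit$loss, 0)

  # four square corners, K = 2: brute force over all 7 two-partitions
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  best <- min(vapply(enumerate_2partitions(4),
                     function(p) cluster_loss(sq, p, 2), numeric(1)))
  fit_sq <- map_clustering(sq, 2, n_restarts = 10)
  expect_equal(fit_sq$loss, best)

  # well-separated data: agrees with the k-means baseline
  d <- simulate_well_specified(seed = 8)
  X <- as.matrix(d[, c("x1", "x2")])
  fit_x <- map_clustering(X, 2, n_restarts = 10)
  km <- stats::kmeans(X, 2, nstart = 20)
  expect_equal(mclust::adjustedRandIndex(fit_x$labels, km$cluster), 1)
  expect_equal(fit_x$loss, km$tot.withinss, tolerance = 1e-8)
  expect_error(map_clustering(u, 5), class = "fairgibbs_input_error")
})

test_that("rule centers never increase their own cluster's loss term", {
  set.seed(38)
  for (loss in c("squared_euclidean", "manhattan")) {
    for (rep in 1:20) {
      u <- matrix(rnorm(20), 10, 2)
      lab <- canonical(c(1, 2, sample(1:2, 8, replace = TRUE)))
      cen <- fairgibbs:::rule_centers(u, lab, 2, loss)
      for (k in 1:2) {
        rows <- u[lab == k, , drop = FALSE]
        at_rule <- sum(fairgibbs:::cross_discrepancy(
          rows, cen[k, , drop = FALSE], loss))
        probe <- cen[k, ] + runif(2, -1, 1)
        at_probe <- sum(fairgibbs:::cross_discrepancy(
          rows, matrix(probe, 1), loss))
        expect_lte(at_rule, at_probe + 1e-12)
      }
    }
  }
})
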