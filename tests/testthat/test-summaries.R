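test_that("co-clustering probabilities match a direct recomputation", {
  # identical draws: the association matrix itself
  draw <- c(1L, 1L, 2L, 2L)
  eta <- coclustering(rbind(draw, draw))
  expect_true(all(eta %in% c(0, 1)))
  expect_equal(eta, naive_coclustering(rbind(draw, draw)))

  # two draws disagreeing on every off-diagonal pair: entries in {0, 0.5}
  eta2 <- coclustering(rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)))
  expect_true(all(eta2[upper.tri(eta2)] %in% c(0, 0.5)))

  set.seed(71)
  draws <- matrix(sample(1:3, 60, replace = TRUE), 10, 6)
  eta3 <- coclustering(draws)
  expect_equal(eta3, naive_coclustering(draws))
  expect_equal(eta3, t(eta3))
  expect_equal(diag(eta3), rep(1, 6))
  expect_error(coclustering(matrix(integer(0), 0, 3)),
               class = "fairgibbs_input_error")
})

test_that("the least-squares draw minimizes the Dahl objective", {
  A <- c(1L, 1L, 2L, 2L)
  B <- c(1L, 2L, 1L, 2L)
  draws <- rbind(A, A, B)
  eta <- coclustering(draws)
  obj <- function(lab) {
    assoc <- outer(lab, lab, "==") * 1
    sum((assoc - eta)^2)
  }
  ls <- dahl_partition(draws, eta)
  expect_equal(as.integer(ls), A)          # the majority draw wins
  expect_lt(obj(A), obj(B))
  expect_equal(attr(ls, "index"), 1L)      # ties broken by earliest draw
  # argmin contract against every stored draw
  for (s in 1:3) expect_lte(obj(as.integer(ls)), obj(draws[s, ]))
  # single draw: returned as-is
  expect_equal(as.integer(dahl_partition(matrix(A, 1))), A)
})

test_that("misclassification probabilities follow the medioid definition", {
  pts <- matrix(c(0, 0, 0.1, 0, 5, 0, 5.1, 0), 4, 2, byrow = TRUE)
  draws <- rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L))
  eta <- coclustering(draws)
  mis <- misclassification_prob(eta, c(1L, 1L, 2L, 2L), pts)
  # medioids (obs 1 and obs 3, first on distance ties) get exactly 0
  expect_equal(mis, c(0, 1 - eta[2, 1], 0, 1 - eta[4, 3]))
  expect_equal(mis[2], 0.5)
  expect_true(all(mis >= 0 & mis <= 1))

  # all draws identical to the reference partition: all zeros
  same <- rbind(c(1L, 1L, 2L, 2L))
  mis0 <- misclassification_prob(coclustering(same), c(1L, 1L, 2L, 2L), pts)
  expect_equal(mis0, rep(0, 4))
})

test_that("the MAP draw maximizes the stored log joint", {
  draws <- rbind(c(1L, 2L, 2L), c(1L, 1L, 2L), c(1L, 2L, 1L))
  lj <- c(-5, -1, -3)
  mp <- map_draw(draws, lj)
  expect_equal(as.integer(mp), c(1L, 1L, 2L))
  expect_equal(attr(mp, "index"), 2L)
  expect_true(all(lj[attr(mp, "index")] >= lj))
  expect_equal(as.integer(map_draw(matrix(1:2, 1), -1)), 1:2)
  expect_error(map_draw(draws, -1), class = "fairgibbs_input_error")
})

test_that("fit summaries satisfy the structural contracts", {
  d <- simulate_well_specified(seed = 72)
  fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                    n_iterations = 200, burn_in = 50, seed = 7)
  s <- fit$summary
  eta <- s$coclustering
  expect_equal(eta, t(eta))
  expect_equal(diag(eta), rep(1, 100))
  expect_true(all(eta >= 0 & eta <= 1))
  # the least-squares configuration is a stored draw
  expect_true(any(apply(fit$draws$observation_partitions, 1,
                        identical, y = s$ls_partition)))
  # medioids of the MAP clusters have misclassification exactly 0
  for (k in unique(s$map_partition)) {
    idx <- which(s$map_partition == k)
    expect_true(any(s$misclassification[idx] == 0))
  }
  expect_true(all(s$misclassification >= 0 & s$misclassification <= 1))
})

test_that("tidy, glance and plots expose the fit in tabular form", {
  d <- simulate_well_specified(seed = 73)
  fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                    n_iterations = 120, burn_in = 40, seed = 8)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 100)
  expect_true(all(c("observation", "map_cluster", "ls_cluster",
                    "misclassification") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$balance_map, 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_coclustering(fit), "ggplot")

  v <- gibbs_kmeans(d, K = 2, attribute = attribute,
                    features = c("x1", "x2"), n_iterations = 120,
                    burn_in = 40, seed = 8)
  expect_s3_class(tidy(v), "tbl_df")
  expect_equal(nrow(glance(v)), 1)
  expect_true(glance(v)$balance_map < 1)
})
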