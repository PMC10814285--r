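# Factorized-loss clustering of unit vectors (typically fairlet centers).
# The loss pairs a discrepancy with the center rule that minimizes it:
# squared Euclidean <-> mean, Manhattan <-> componentwise lower median.

loss_code <- function(loss) {
  loss <- match_metric(loss)
  c(squared_euclidean = 0L, manhattan = 1L)[[loss]]
}

# Rule centers of each cluster (K x d).
rule_centers <- function(u, labels, K, loss) {
  loss <- match_metric(loss)
  d <- ncol(u)
  cen <- matrix(0, K, d)
  for (k in seq_len(K)) {
    rows <- u[labels == k, , drop = FALSE]
    if (nrow(rows) == 0) abort_input(sprintf("Cluster %d is empty.", k))
    cen[k, ] <- if (loss == "squared_euclidean") {
      colMeans(rows)
    } else {
      apply(rows, 2, lower_median)
    }
  }
  cen
}

# Deterministic lower median: the ((n+1) %/% 2)-th order statistic.
lower_median <- function(x) sort(x)[(length(x) + 1) %/% 2]

#' Factorized clustering loss
#'
#' \eqn{L_c(C \mid u) = \sum_k \sum_{i \in C_k} D(u_i, u_{(k)})} with cluster
#' centers given by the center rule of the chosen discrepancy (means for
#' squared Euclidean, componentwise lower medians for Manhattan). Every
#' cluster index in `1..K` must be nonempty.
#'
#' @param u Numeric `m x d` matrix of unit vectors (e.g. fairlet centers).
#' @param labels Integer cluster labels in `1..K`.
#' @param K Number of clusters.
#' @param loss `"squared_euclidean"` or `"manhattan"`.
#' @return A nonnegative number.
#' @export
cluster_loss <- function(u, labels, K = max(labels),
                         loss = c("squared_euclidean", "manhattan")) {
  loss <- match_metric(loss)
  u <- as.matrix(u)
  if (length(labels) != nrow(u)) abort_input("`labels` must match rows of `u`.")
  if (any(tabulate(labels, K) == 0)) abort_input("Every cluster must be nonempty.")
  cpp_cluster_loss(as.integer(labels), u, as.integer(K), loss_code(loss))
}

#' Full conditional of one unit's cluster label
#'
#' The Gibbs full conditional for unit `i` in the product-partition Gibbs
#' posterior: the probability of allocation to cluster `k` is proportional to
#' \eqn{\exp(-\lambda_c [\mathrm{term}_k^{+i} - \mathrm{term}_k^{-i}])},
#' where the terms are cluster k's within-cluster loss with and without unit
#' `i`, each with its center recomputed under the center rule. When unit `i`
#' is a singleton it must stay (the uniform prior has support only on
#' partitions with exactly `K` blocks), so the conditional is degenerate at
#' the current label.
#'
#' @param i Unit index.
#' @param labels Current cluster labels in `1..K`.
#' @param u Numeric `m x d` matrix of unit vectors.
#' @param K Number of clusters (at least 2).
#' @param lambda_c Positive clustering temperature.
#' @inheritParams cluster_loss
#' @return A probability vector of length `K` summing to 1.
#' @export
gibbs_label_conditional <- function(i, labels, u, K, lambda_c,
                                    loss = c("squared_euclidean", "manhattan")) {
  loss <- match_metric(loss)
  if (K < 2) abort_config("`K` must be at least 2.")
  u <- as.matrix(u)
  lc <- loss_code(loss)
  if (sum(labels == labels[i]) == 1) {
    p <- numeric(K)
    p[labels[i]] <- 1
    return(p)
  }
  others <- labels[-i]
  idx <- setdiff(seq_len(nrow(u)), i)
  delta <- vapply(seq_len(K), function(k) {
    mem <- idx[others == k]
    t_minus <- if (length(mem)) {
      cpp_cluster_loss(rep(1L, length(mem)), u[mem, , drop = FALSE], 1L, lc)
    } else 0
    memp <- c(mem, i)
    t_plus <- cpp_cluster_loss(rep(1L, length(memp)),
                               u[memp, , drop = FALSE], 1L, lc)
    t_plus - t_minus
  }, numeric(1))
  w <- exp(-lambda_c * (delta - min(delta)))
  w / sum(w)
}

#' One Gibbs sweep over cluster labels
#'
#' Visits every unit once (sequentially, or in a uniformly permuted order
#' when `random_scan = TRUE`), resampling its label from
#' [gibbs_label_conditional()] with the affected cluster centers recomputed
#' exactly after each move.
#'
#' @inheritParams gibbs_label_conditional
#' @param labels Current labels; all `K` clusters nonempty.
#' @param random_scan Visit units in random order instead of sequentially.
#' @return The updated label vector (all `K` clusters nonempty).
#' @export
gibbs_sweep <- function(labels, u, K, lambda_c,
                        loss = c("squared_euclidean", "manhattan"),
                        random_scan = FALSE) {
  loss <- match_metric(loss)
  u <- as.matrix(u)
  if (any(tabulate(labels, K) == 0)) abort_input("Every cluster must be nonempty.")
  cpp_gibbs_sweep(as.integer(labels), u, as.integer(K), lambda_c,
                  loss_code(loss), random_scan)
}

#' MAP clustering by Lloyd-style alternating minimization
#'
#' Alternates nearest-center assignment under the configured discrepancy
#' (ties broken toward the lowest cluster index) with re-centering under the
#' center rule, from `n_restarts` random initializations, returning the
#' lowest-loss fixed point. An emptied cluster is re-seeded at the unit
#' currently farthest from its center. Each iteration is checked to be
#' non-increasing in loss. With squared-Euclidean loss this is the k-means
#' objective; with Manhattan loss, k-medians.
#'
#' @inheritParams cluster_loss
#' @param n_restarts Number of random initializations.
#' @return A list (`labels`, `centers`, `loss`, `K`) describing the best
#'   fixed point found.
#' @export
map_clustering <- function(u, K, loss = c("squared_euclidean", "manhattan"),
                           n_restarts = 10) {
  loss <- match_metric(loss)
  u <- as.matrix(u)
  m <- nrow(u)
  if (m < K) abort_input(sprintf("Need at least K = %d units; got %d.", K, m))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(u, K, loss)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  best
}

lloyd_once <- function(u, K, loss, max_iter = 100) {
  m <- nrow(u)
  centers <- u[sample.int(m, K), , drop = FALSE]
  labels <- rep(1L, m)
  prev_loss <- Inf
  for (it in seq_len(max_iter)) {
    D <- cross_discrepancy(u, centers, loss)
    new_labels <- max.col(-D, ties.method = "first")
    counts <- tabulate(new_labels, K)
    while (any(counts == 0)) {  # re-seed an emptied cluster at the farthest unit
      k <- which(counts == 0)[1]
      cur <- D[cbind(seq_len(m), new_labels)]
      cand <- which(counts[new_labels] > 1)
      far <- cand[which.max(cur[cand])]
      new_labels[far] <- k
      counts <- tabulate(new_labels, K)
    }
    centers <- rule_centers(u, new_labels, K, loss)
    lossval <- cpp_cluster_loss(new_labels, u, K, loss_code(loss))
    if (lossval > prev_loss + 1e-8) {
      abort_internal("Lloyd iteration increased the clustering loss.")
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    prev_loss <- lossval
  }
  list(labels = labels, centers = centers,
       loss = cpp_cluster_loss(labels, u, K, loss_code(loss)), K = K)
}
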