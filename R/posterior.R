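#' Unnormalized log joint posterior over (B, C)
#'
#' \eqn{-\lambda_f \langle B, L\rangle - \lambda_c L_c(C \mid u)}: the log of
#' the joint Gibbs posterior over fairlet decompositions and cluster
#' configurations, up to the additive constant from the (fixed) normalizer of
#' the fairlet factor and the uniform priors.
#'
#' @param B A [fairlet_assignment()] or binary matrix.
#' @param labels Cluster labels of the fairlet centers, in `1..K`.
#' @param L Cost matrix.
#' @param u Fairlet-center matrix (`N1 x d`) induced by `B`.
#' @param lambda_f,lambda_c Nonnegative temperatures.
#' @param K Number of clusters.
#' @inheritParams cluster_loss
#' @return A single number.
#' @export
log_joint <- function(B, labels, L, u, lambda_f, lambda_c, K = max(labels),
                      loss = c("squared_euclidean", "manhattan")) {
  loss <- match_metric(loss)
  -lambda_f * fairlet_loss(B, L) -
    lambda_c * cluster_loss(u, labels, K, loss)
}

#' Expand a fairlet-level partition to observations
#'
#' Each observation inherits the cluster of its fairlet, so every cluster
#' receives label-1 and label-2 observations in the exact ratio `1:t` and the
#' expanded partition has balance `1/t` by construction.
#'
#' @param fairlet_labels Length-`N1` cluster labels of the fairlets.
#' @param B The [fairlet_assignment()] defining fairlet membership.
#' @param dataset The [fair_dataset()] (provides the original row order).
#' @return A length-N integer partition in original row order.
#' @export
expand_labels <- function(fairlet_labels, B, dataset) {
  B <- as_assignment(B)
  if (length(fairlet_labels) != B$N1) {
    abort_input("`fairlet_labels` must have one label per fairlet.")
  }
  internal <- c(fairlet_labels, fairlet_labels[B$owner])
  out <- integer(dataset$N)
  out[c(dataset$idx1, dataset$idx2)] <- internal
  if (anyNA(out) || any(out == 0)) abort_internal("Uncovered observation.")
  out
}

# First-occurrence canonical form, so label switching cannot make equal
# partitions look different.
canonical_labels <- function(x) match(x, unique(x))

# Feature matrix in the original row order of the data.
points_original <- function(fd) {
  X <- matrix(0, fd$N, ncol(fd$points))
  X[c(fd$idx1, fd$idx2), ] <- fd$points
  X
}

#' Fair clustering through the Gibbs posterior
#'
#' Fits the generalized Bayesian fair clustering model: a joint Gibbs
#' posterior over (1, t)-fairlet decompositions `B` and cluster
#' configurations `C` of the fairlet centers,
#' \eqn{\pi(B, C) \propto \exp(-\lambda_f \langle B, L\rangle)
#' \exp(-\lambda_c L_c(C \mid u(B)))}. Inference is by
#' Metropolis-within-Gibbs: checkerboard-swap updates of `B` (accepted with
#' the product-weight ratio times the induced change in clustering loss,
#' i.e. the exact full conditional of `B` given `C`) alternate with Gibbs
#' sweeps over the cluster labels. With `mode = "mcem"` the decomposition is
#' fixed at the optimal-transport optimum and only labels are sampled. Every
#' stored draw is perfectly balanced by construction, so all reported point
#' estimates attain balance `1/t` exactly.
#'
#' @param data A data frame (or a [fair_dataset()]).
#' @param attribute Protected-attribute column (bare name or string); must
#'   have two levels with counts in an exact `1:t` integer ratio.
#' @param K Number of clusters (at least 2), fixed in advance.
#' @param loss Clustering discrepancy: `"squared_euclidean"` (k-means, mean
#'   centers) or `"manhattan"` (k-medians, componentwise-median centers).
#'   Also used for the fairlet cost matrix.
#' @param lambda_f,lambda_c Positive temperatures of the fairlet and
#'   clustering factors. Larger values concentrate the posterior at the
#'   loss minimizers.
#' @param mode `"mcmc"` (joint sampling of `B` and `C`) or `"mcem"` (fixed
#'   optimal `B`).
#' @param n_iterations,burn_in,thin Outer iterations, burn-in, and thinning;
#'   `T = (n_iterations - burn_in) / thin` draws are stored.
#' @param wrla_inner_steps Checkerboard proposals on `B` per outer iteration
#'   (default `N1`, one expected touch per fairlet).
#' @param n_restarts Random restarts for the MAP initialization.
#' @param seed Optional integer seed.
#' @param features Optional character vector of feature columns.
#' @param random_scan Visit units in random order within each sweep.
#' @return An object of class `fair_gibbs` with stored draws, traces, and
#'   posterior summaries; see [tidy.fair_gibbs()], [glance.fair_gibbs()],
#'   [autoplot.fair_gibbs()].
#' @examples
#' d <- simulate_well_specified(seed = 11)
#' fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
#'                   n_iterations = 200, burn_in = 50, seed = 1)
#' glance(fit)
#' @export
fair_gibbs <- function(data, attribute, K,
                       loss = c("squared_euclidean", "manhattan"),
                       lambda_f = 1, lambda_c = 1,
                       mode = c("mcmc", "mcem"),
                       n_iterations = 2000, burn_in = 500, thin = 1,
                       wrla_inner_steps = NULL, n_restarts = 10,
                       seed = NULL, features = NULL, random_scan = FALSE) {
  loss <- match_metric(loss)
  mode <- match.arg(mode)
  if (K < 2 || K != round(K)) abort_config("`K` must be an integer >= 2.")
  if (lambda_f <= 0 || lambda_c <= 0) {
    abort_config("Temperatures `lambda_f` and `lambda_c` must be positive.")
  }
  if (burn_in >= n_iterations) {
    abort_config("`burn_in` must be smaller than `n_iterations`.")
  }
  if (thin < 1) abort_config("`thin` must be at least 1.")
  fd <- if (inherits(data, "fair_dataset")) data else {
    fair_dataset(data, !!ensym(attribute), features = features)
  }
  check_ratio(fd)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wrla_inner_steps)) wrla_inner_steps <- fd$N1
  if (wrla_inner_steps < 1) abort_config("`wrla_inner_steps` must be >= 1.")

  L <- fairlet_cost_matrix(fd, loss)
  B_opt <- optimal_fairlets(L, fd$t)
  dec <- fairlet_decomposition(B_opt, fd)
  init <- map_clustering(dec$centers, K, loss, n_restarts = n_restarts)
  if (fd$N1 < K) abort_input("Fewer fairlets than clusters.")

  X1 <- fd$points[seq_len(fd$N1), , drop = FALSE]
  X2 <- fd$points[fd$N1 + seq_len(fd$N2), , drop = FALSE]
  res <- cpp_joint_mcmc(
    X1, X2, B_opt$owner, init$labels, L, lambda_f, lambda_c,
    as.integer(K), loss_code(loss), as.integer(fd$t),
    as.integer(wrla_inner_steps), as.integer(n_iterations),
    as.integer(burn_in), as.integer(thin),
    update_B = (mode == "mcmc"), random_scan = random_scan
  )

  T_draws <- nrow(res$labels)
  obs_draws <- matrix(0L, T_draws, fd$N)
  for (s in seq_len(T_draws)) {
    B_s <- fairlet_assignment(res$owners[s, ], fd$N1)
    obs_draws[s, ] <- canonical_labels(expand_labels(res$labels[s, ], B_s, fd))
  }

  draws <- list(
    observation_partitions = obs_draws,
    fairlet_partitions = res$labels,
    fairlet_assignments = res$owners,
    log_joint = res$log_joint, Lf = res$Lf, Lc = res$Lc
  )

  # Two-step comparison estimator: optimal decomposition, then MAP clustering.
  cfcf <- canonical_labels(expand_labels(init$labels, B_opt, fd))

  fit <- structure(list(
    dataset = fd,
    config = list(K = as.integer(K), loss = loss, lambda_f = lambda_f,
                  lambda_c = lambda_c, mode = mode,
                  n_iterations = n_iterations, burn_in = burn_in,
                  thin = thin, wrla_inner_steps = wrla_inner_steps,
                  n_restarts = n_restarts, seed = seed,
                  random_scan = random_scan),
    cost_matrix = L,
    optimal_assignment = B_opt,
    draws = draws,
    cfcf_partition = cfcf,
    n_accept = res$n_accept,
    n_checkerboard = res$n_checkerboard
  ), class = "fair_gibbs")
  fit$summary <- summarize_draws(fit)
  fit
}

# Shared posterior summaries for fitted objects holding observation-level
# draws: co-clustering matrix, MAP and least-squares draws, misclassification
# probabilities, and the balance of every draw.
summarize_draws <- function(fit) {
  obs <- fit$draws$observation_partitions
  eta <- coclustering(obs)
  map_idx <- which.max(fit$draws$log_joint)
  map_part <- obs[map_idx, ]
  ls <- dahl_partition(obs, eta)
  X <- points_original(fit$dataset)
  mis <- misclassification_prob(eta, map_part, X, fit$config$loss)
  a_codes <- attribute_codes(fit$dataset)
  list(
    coclustering = eta,
    map_index = map_idx,
    map_partition = map_part,
    ls_index = attr(ls, "index"),
    ls_partition = as.integer(ls),
    misclassification = mis,
    balance_per_draw = balance_draws(obs, a_codes),
    balance_map = cluster_balance(map_part, a_codes),
    balance_ls = cluster_balance(as.integer(ls), a_codes)
  )
}

#' @export
print.fair_gibbs <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<fair_gibbs> %s, K = %d, loss = %s, %d stored draws\n",
           "  MAP balance %.3f | least-squares balance %.3f | ",
           "mean misclassification %.3f\n"),
    x$config$mode, x$config$K, x$config$loss,
    nrow(x$draws$observation_partitions),
    s$balance_map, s$balance_ls, mean(s$misclassification)
  ))
  invisible(x)
}

#' Pairwise co-clustering probability matrix
#'
#' Entry (i, j) is the fraction of stored draws in which observations i and j
#' share a cluster. Symmetric with unit diagonal.
#'
#' @param draws A `T x N` matrix of stored partitions (one per row).
#' @return An `N x N` matrix with entries in `[0, 1]`.
#' @export
coclustering <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  if (nrow(draws) == 0) abort_input("No draws supplied.")
  N <- ncol(draws)
  eta <- matrix(0, N, N)
  for (k in sort(unique(as.vector(draws)))) {
    Z <- draws == k
    storage.mode(Z) <- "double"
    eta <- eta + crossprod(Z)
  }
  eta / nrow(draws)
}

#' Dahl's least-squares clustering configuration
#'
#' The stored draw whose association matrix minimizes the squared deviation
#' from the co-clustering matrix, \eqn{\sum_{ij} (\eta_{ij}(s) -
#' \bar\eta_{ij})^2}. Because the estimate is itself a stored draw, any
#' structural property of the draws (such as exact balance) is retained.
#' Ties go to the earliest draw.
#'
#' @param draws A `T x N` matrix of stored partitions.
#' @param eta_bar The co-clustering matrix (computed from `draws` if absent).
#' @return The selected partition (integer vector) with attribute `index`
#'   giving the draw number.
#' @export
dahl_partition <- function(draws, eta_bar = coclustering(draws)) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  M <- 1 - 2 * eta_bar  # minimizing sum((eta_s - eta_bar)^2) over draws
  obj <- vapply(seq_len(nrow(draws)), function(s) {
    lab <- draws[s, ]
    tot <- 0
    for (k in unique(lab)) {
      idx <- which(lab == k)
      tot <- tot + sum(M[idx, idx])
    }
    tot
  }, numeric(1))
  idx <- which.min(obj)
  out <- draws[idx, ]
  attr(out, "index") <- idx
  out
}

#' Misclassification probabilities from the co-clustering matrix
#'
#' For each observation i, the medioid \eqn{i^\star} of i's cluster in the
#' reference (MAP) partition is the member minimizing the summed discrepancy
#' to the other members; the misclassification probability is
#' \eqn{1 - \bar\eta_{i i^\star}}, the posterior probability that i is not
#' clustered with its medioid. Medioids themselves get exactly 0.
#'
#' @param eta_bar Co-clustering matrix.
#' @param partition Reference partition (e.g. the MAP draw).
#' @param points `N x d` feature matrix in the same observation order.
#' @inheritParams cluster_loss
#' @return A numeric vector in `[0, 1]` of length N.
#' @export
misclassification_prob <- function(eta_bar, partition, points,
                                   loss = c("squared_euclidean", "manhattan")) {
  loss <- match_metric(loss)
  points <- as.matrix(points)
  out <- numeric(length(partition))
  for (k in unique(partition)) {
    idx <- which(partition == k)
    D <- cross_discrepancy(points[idx, , drop = FALSE],
                           points[idx, , drop = FALSE], loss)
    med <- idx[which.min(rowSums(D))]
    out[idx] <- 1 - eta_bar[idx, med]
  }
  out
}

#' Joint MAP draw
#'
#' The stored draw with the highest unnormalized log joint posterior: the
#' MCMC approximation to the joint posterior mode over decompositions and
#' configurations.
#'
#' @param draws A `T x N` matrix of stored partitions.
#' @param log_joint Length-T log joint trace aligned with `draws`.
#' @return The selected partition with attribute `index`.
#' @export
map_draw <- function(draws, log_joint) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  if (length(log_joint) != nrow(draws)) {
    abort_input("`log_joint` must have one value per draw.")
  }
  idx <- which.max(log_joint)
  out <- draws[idx, ]
  attr(out, "index") <- idx
  out
}
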