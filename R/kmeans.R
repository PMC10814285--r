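#' Unconstrained Gibbs-posterior k-means (vanilla comparator)
#'
#' The product-partition Gibbs posterior applied directly to the raw
#' observations, with no balance constraint: a Gibbs sweep chain over
#' cluster labels under \eqn{\exp(-\lambda_c L_c)}, initialized at the MAP
#' (Lloyd / k-means) clustering. Used as the unfair baseline against which
#' the balance of the fair fit is compared.
#'
#' @param data A data frame of numeric features (an attribute column, if
#'   named, is excluded from the features and used only for balance
#'   reporting).
#' @param K Number of clusters.
#' @param attribute Optional protected-attribute column (bare name or
#'   string) for balance summaries.
#' @inheritParams fair_gibbs
#' @return An object of class `gibbs_kmeans` with the MAP clustering, stored
#'   draws, and summaries.
#' @examples
#' d <- simulate_well_specified(seed = 3)
#' fit <- gibbs_kmeans(d, K = 2, attribute = attribute,
#'                     features = c("x1", "x2"), n_iterations = 200,
#'                     burn_in = 50, seed = 1)
#' glance(fit)$balance_map
#' @export
gibbs_kmeans <- function(data, K, attribute = NULL,
                         loss = c("squared_euclidean", "manhattan"),
                         lambda_c = 1, n_iterations = 1500, burn_in = 500,
                         thin = 1, n_restarts = 10, seed = NULL,
                         features = NULL, random_scan = FALSE) {
  loss <- match_metric(loss)
  if (K < 2 || K != round(K)) abort_config("`K` must be an integer >= 2.")
  if (burn_in >= n_iterations) {
    abort_config("`burn_in` must be smaller than `n_iterations`.")
  }
  attr_quo <- rlang::enquo(attribute)
  attr_name <- if (rlang::quo_is_null(attr_quo)) NULL else {
    as_name(rlang::quo_get_expr(attr_quo))
  }
  if (is.null(features)) {
    cand <- setdiff(names(data), attr_name)
    features <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  X <- as.matrix(as.data.frame(data)[features])
  if (!is.null(seed)) set.seed(seed)
  map <- map_clustering(X, K, loss, n_restarts = n_restarts)
  res <- cpp_sweep_chain(map$labels, X, as.integer(K), lambda_c,
                         loss_code(loss), as.integer(n_iterations),
                         as.integer(burn_in), as.integer(thin), random_scan)
  obs_draws <- t(apply(res$draws, 1, canonical_labels))
  eta <- coclustering(obs_draws)
  ls <- dahl_partition(obs_draws, eta)
  mis <- misclassification_prob(eta, map$labels, X, loss)
  a <- if (!is.null(attr_name)) as.character(data[[attr_name]]) else NULL
  structure(list(
    points = X,
    attribute = a,
    config = list(K = as.integer(K), loss = loss, lambda_c = lambda_c,
                  n_iterations = n_iterations, burn_in = burn_in,
                  thin = thin, n_restarts = n_restarts, seed = seed),
    map = map,
    draws = list(observation_partitions = obs_draws, Lc = res$loss),
    summary = list(
      coclustering = eta,
      map_partition = canonical_labels(map$labels),
      ls_partition = as.integer(ls),
      ls_index = attr(ls, "index"),
      misclassification = mis,
      balance_map = if (!is.null(a)) cluster_balance(map$labels, a) else NA_real_,
      balance_ls = if (!is.null(a)) cluster_balance(as.integer(ls), a) else NA_real_
    )
  ), class = "gibbs_kmeans")
}

#' @export
print.gibbs_kmeans <- function(x, ...) {
  cat(sprintf(
    "<gibbs_kmeans> K = %d, loss = %s, MAP loss %.4g, MAP balance %s\n",
    x$config$K, x$config$loss, x$map$loss,
    ifelse(is.na(x$summary$balance_map), "n/a",
           sprintf("%.3f", x$summary$balance_map))
  ))
  invisible(x)
}
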