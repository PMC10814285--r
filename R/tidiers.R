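#' Tidy a fair Gibbs clustering fit
#'
#' One row per observation, in the original row order: the input columns,
#' the MAP and least-squares cluster labels, and the misclassification
#' probability \eqn{1 - \bar\eta_{i i^\star}}.
#'
#' @param x A [fair_gibbs()] fit.
#' @param ... Unused.
#' @return A tibble with N rows.
#' @export
tidy.fair_gibbs <- function(x, ...) {
  s <- x$summary
  dplyr::bind_cols(
    tibble(observation = seq_len(x$dataset$N)),
    x$dataset$data,
    tibble(
      map_cluster = s$map_partition,
      ls_cluster = s$ls_partition,
      misclassification = s$misclassification
    )
  )
}

#' One-row summary of a fair Gibbs clustering fit
#'
#' @param x A [fair_gibbs()] fit.
#' @param ... Unused.
#' @return A tibble with one row: problem size, configuration, number of
#'   stored draws, the balance of the MAP and least-squares partitions, the
#'   optimal fairlet loss, and mean losses over the draws.
#' @export
glance.fair_gibbs <- function(x, ...) {
  s <- x$summary
  tibble(
    N = x$dataset$N, K = x$config$K, t = x$dataset$t,
    loss = x$config$loss, mode = x$config$mode,
    n_draws = nrow(x$draws$observation_partitions),
    balance_map = s$balance_map,
    balance_ls = s$balance_ls,
    min_balance_draws = min(s$balance_per_draw),
    Lf_optimal = attr(x$optimal_assignment, "cost"),
    Lf_mean = mean(x$draws$Lf),
    Lc_mean = mean(x$draws$Lc),
    log_joint_map = max(x$draws$log_joint),
    mean_misclassification = mean(s$misclassification)
  )
}

#' @rdname tidy.fair_gibbs
#' @export
tidy.gibbs_kmeans <- function(x, ...) {
  s <- x$summary
  out <- tibble(
    observation = seq_len(nrow(x$points)),
    map_cluster = s$map_partition,
    ls_cluster = s$ls_partition,
    misclassification = s$misclassification
  )
  if (!is.null(x$attribute)) out$attribute <- x$attribute
  out
}

#' @rdname glance.fair_gibbs
#' @export
glance.gibbs_kmeans <- function(x, ...) {
  s <- x$summary
  tibble(
    N = nrow(x$points), K = x$config$K, loss = x$config$loss,
    n_draws = nrow(x$draws$observation_partitions),
    balance_map = s$balance_map,
    balance_ls = s$balance_ls,
    Lc_map = x$map$loss,
    mean_misclassification = mean(s$misclassification)
  )
}
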