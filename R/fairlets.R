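#' Cost matrix between label-1 and label-2 observations
#'
#' Entry \eqn{l_{ik}} is the discrepancy \eqn{D(x_i, x_{N_1+k})} between the
#' i-th label-1 observation and the k-th label-2 observation, under the same
#' discrepancy used by the clustering loss.
#'
#' @param dataset A [fair_dataset()].
#' @param metric `"squared_euclidean"` or `"manhattan"`.
#' @return An `N1 x N2` nonnegative matrix with attribute `metric`.
#' @export
fairlet_cost_matrix <- function(dataset,
                                metric = c("squared_euclidean", "manhattan")) {
  metric <- match_metric(metric)
  X <- dataset$points
  X1 <- X[seq_len(dataset$N1), , drop = FALSE]
  X2 <- X[dataset$N1 + seq_len(dataset$N2), , drop = FALSE]
  L <- cross_discrepancy(X1, X2, metric)
  attr(L, "metric") <- metric
  L
}

match_metric <- function(metric) {
  metric <- metric[1]
  if (!metric %in% c("squared_euclidean", "manhattan")) {
    abort_config(sprintf("Unknown metric '%s'.", metric))
  }
  metric
}

# Pairwise discrepancies between the rows of A (n x d) and B (m x d).
cross_discrepancy <- function(A, B, metric) {
  if (metric == "squared_euclidean") {
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    M <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    pmax(M, 0)
  } else {
    n <- nrow(A)
    out <- matrix(0, n, nrow(B))
    for (j in seq_len(ncol(A))) {
      out <- out + abs(outer(A[, j], B[, j], "-"))
    }
    out
  }
}

#' Fairlet assignment: a binary matrix with fixed margins
#'
#' Encodes a (1, t)-fairlet decomposition as an `N1 x N2` binary matrix `B`
#' whose rows sum to `t` and columns to 1: column j carries a 1 in the row of
#' the label-1 observation whose fairlet the j-th label-2 observation joins.
#' Stored compactly as the length-`N2` owner vector of the columns.
#'
#' @param owner Integer vector of length N2 with values in `1..N1`; each value
#'   `i` must occur exactly `t` times.
#' @param N1 Number of rows (label-1 observations).
#' @return An object of class `fairlet_assignment`.
#' @export
fairlet_assignment <- function(owner, N1) {
  owner <- as.integer(owner)
  t_ratio <- length(owner) / N1
  if (t_ratio != round(t_ratio)) {
    abort_input("Margin infeasibility: N2 must be a multiple of N1.")
  }
  tab <- tabulate(owner, nbins = N1)
  if (any(tab != t_ratio)) {
    abort_input("Every row must own exactly t columns.")
  }
  structure(list(owner = owner, N1 = as.integer(N1),
                 N2 = length(owner), t = as.integer(t_ratio)),
            class = "fairlet_assignment")
}

#' @export
print.fairlet_assignment <- function(x, ...) {
  cat(sprintf("<fairlet_assignment> %d x %d binary matrix, row sums %d, column sums 1\n",
              x$N1, x$N2, x$t))
  invisible(x)
}

#' @export
as.matrix.fairlet_assignment <- function(x, ...) {
  B <- matrix(0L, x$N1, x$N2)
  B[cbind(x$owner, seq_len(x$N2))] <- 1L
  B
}

# Accept either a fairlet_assignment or a raw binary matrix.
as_assignment <- function(B, N1 = NULL) {
  if (inherits(B, "fairlet_assignment")) return(B)
  if (!is.matrix(B)) abort_input("Expected a fairlet_assignment or a binary matrix.")
  if (any(colSums(B) != 1)) abort_input("Every column of B must sum to 1.")
  owner <- apply(B, 2, which.max)
  fairlet_assignment(owner, nrow(B))
}

#' Optimal fairlet decomposition by constrained binary optimal transport
#'
#' Minimizes \eqn{\langle B, L \rangle} over binary `N1 x N2` matrices with
#' row sums `t` and column sums 1. For `t = 1` this is a minimum-cost perfect
#' matching; for `t >= 2` the rows are replicated `t` times, reducing the
#' transportation problem to an assignment problem (valid because the
#' transportation polytope has integral vertices). Solved through weighted
#' maximum bipartite matching.
#'
#' @param L Cost matrix (`N1 x N2`), e.g. from [fairlet_cost_matrix()].
#' @param t Integer ratio with `t * N1 = N2`.
#' @return A [fairlet_assignment()] attaining the minimum, with attribute
#'   `cost` holding \eqn{\langle B', L \rangle}.
#' @export
optimal_fairlets <- function(L, t = ncol(L) / nrow(L)) {
  N1 <- nrow(L)
  N2 <- ncol(L)
  if (t != round(t) || t < 1 || t * N1 != N2) {
    abort_input(sprintf(
      "Margin infeasibility: need t * N1 = N2 with integer t; got N1 = %d, N2 = %d.",
      N1, N2
    ))
  }
  t <- as.integer(t)
  rows <- rep(seq_len(N1), each = t)
  C <- L[rows, , drop = FALSE]  # N2 x N2 assignment costs
  col_of <- solve_assignment(C)
  owner <- integer(N2)
  owner[col_of] <- rows
  B <- fairlet_assignment(owner, N1)
  attr(B, "cost") <- sum(L[cbind(owner, seq_len(N2))])
  B
}

# Minimum-cost perfect matching on a square cost matrix via igraph's weighted
# maximum bipartite matching (costs negated and shifted to positive weights).
# Returns the matched column of each row.
solve_assignment <- function(C) {
  n <- nrow(C)
  if (n == 1) return(1L)
  w <- max(C) - C + 1
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight,
                                   eps = 1e-10)
  col_of <- as.integer(m$matching[seq_len(n)]) - n
  if (anyNA(col_of) || any(col_of < 1)) {
    abort_internal("Assignment solver failed to produce a perfect matching.")
  }
  col_of
}

#' Fairlet loss of an assignment
#'
#' The trace inner product \eqn{\langle B, L \rangle = \sum_{ik} b_{ik} l_{ik}},
#' i.e. the total within-fairlet discrepancy of the decomposition encoded by
#' `B`.
#'
#' @param B A [fairlet_assignment()] or binary matrix.
#' @param L Cost matrix of matching shape.
#' @return A nonnegative number.
#' @export
fairlet_loss <- function(B, L) {
  B <- as_assignment(B)
  if (B$N1 != nrow(L) || B$N2 != ncol(L)) {
    abort_input("Shapes of B and L do not match.")
  }
  sum(L[cbind(B$owner, seq_len(B$N2))])
}

#' Fairlets, fairlet centers, and membership induced by an assignment
#'
#' Fairlet i contains the i-th label-1 observation and the `t` label-2
#' observations whose columns are owned by row i; its center is the
#' arithmetic mean of the `t + 1` points. Together the fairlets partition all
#' N observations.
#'
#' @param B A [fairlet_assignment()] or binary matrix.
#' @param dataset The [fair_dataset()] the assignment refers to.
#' @return A list with `centers` (`N1 x d`), `membership` (a tibble with
#'   `observation` in original row order and `fairlet`), and `fairlets`
#'   (a list of original-order index vectors).
#' @export
fairlet_decomposition <- function(B, dataset) {
  B <- as_assignment(B)
  if (B$N1 != dataset$N1 || B$N2 != dataset$N2) {
    abort_input("Assignment does not match the dataset dimensions.")
  }
  X <- dataset$points
  d <- ncol(X)
  centers <- matrix(0, B$N1, d)
  for (i in seq_len(B$N1)) {
    members <- c(i, dataset$N1 + which(B$owner == i))
    centers[i, ] <- colMeans(X[members, , drop = FALSE])
  }
  orig <- c(dataset$idx1, dataset$idx2)           # internal row -> original row
  fairlet_of_internal <- c(seq_len(B$N1), B$owner)
  membership <- tibble(
    observation = orig,
    fairlet = fairlet_of_internal
  )
  membership <- membership[order(membership$observation), ]
  fairlets <- split(membership$observation, membership$fairlet)
  list(centers = centers, membership = membership,
       fairlets = unname(fairlets), t = B$t)
}

#' Entrywise weights from a cost matrix
#'
#' \eqn{\omega_{ij} = \exp(-\lambda_f l_{ij})}: the relative probability of a
#' 1 at cell (i, j) under the Gibbs posterior over fairlet decompositions.
#'
#' @param L Nonnegative cost matrix.
#' @param lambda_f Positive fairlet temperature.
#' @return A matrix of weights in `(0, 1]`.
#' @export
fairlet_weights <- function(L, lambda_f) {
  if (!is.numeric(lambda_f) || length(lambda_f) != 1 || lambda_f <= 0) {
    abort_config("`lambda_f` must be a positive scalar.")
  }
  exp(-lambda_f * L)
}

#' One weighted rectangular-loop (checkerboard swap) Metropolis step
#'
#' Draws a row pair and a column pair uniformly at random. If the selected
#' 2x2 submatrix of `B` is a checkerboard, the swap to the opposite
#' checkerboard is proposed and accepted with probability
#' \eqn{\min\{1, \prod \omega_{\mathrm{new}} / \prod \omega_{\mathrm{old}}\}}
#' (product of weights at entries turning 1 over entries turning 0);
#' otherwise `B` is returned unchanged. Margins are always conserved. The
#' induced chain is reversible with respect to
#' \eqn{P(H) \propto \prod_{ij} \omega_{ij}^{h_{ij}}}.
#'
#' @param B A [fairlet_assignment()].
#' @param Omega Strictly positive `N1 x N2` weight matrix.
#' @return A `fairlet_assignment` (possibly identical to the input) with
#'   attribute `moved` indicating whether a swap was accepted.
#' @export
wrla_step <- function(B, Omega) {
  B <- as_assignment(B)
  if (any(Omega <= 0)) {
    abort_input("All weights must be strictly positive for full support.")
  }
  if (B$N1 < 2 || B$N2 < 2) {
    attr(B, "moved") <- FALSE
    return(B)  # singleton polytope: nothing to propose
  }
  ij <- sort(sample.int(B$N1, 2))
  jj <- sort(sample.int(B$N2, 2))
  o1 <- B$owner[jj[1]]
  o2 <- B$owner[jj[2]]
  moved <- FALSE
  if ((o1 == ij[1] && o2 == ij[2]) || (o1 == ij[2] && o2 == ij[1])) {
    ratio <- (Omega[o2, jj[1]] * Omega[o1, jj[2]]) /
             (Omega[o1, jj[1]] * Omega[o2, jj[2]])
    if (runif(1) < ratio) {
      B$owner[jj[1]] <- o2
      B$owner[jj[2]] <- o1
      moved <- TRUE
    }
  }
  attr(B, "moved") <- moved
  B
}

#' Run a weighted rectangular-loop chain
#'
#' Iterates [wrla_step()] (in compiled code) for `n_steps` proposals,
#' optionally storing thinned states. Every state is margin-feasible; the
#' stationary law is \eqn{P(H) \propto \prod \omega_{ij}^{h_{ij}}}.
#'
#' @param B0 Starting [fairlet_assignment()].
#' @param Omega Strictly positive weight matrix.
#' @param n_steps Number of proposals (at least 1).
#' @param burn_in,thin Storage control for `draws`.
#' @param store Whether to store thinned owner vectors.
#' @return A list with the final `assignment`, a `draws` matrix of stored
#'   owner vectors (`T x N2`, if `store`), and acceptance counters.
#' @export
wrla_chain <- function(B0, Omega, n_steps, burn_in = 0, thin = 1,
                       store = FALSE) {
  B0 <- as_assignment(B0)
  if (n_steps < 1) abort_config("`n_steps` must be at least 1.")
  if (any(Omega <= 0)) {
    abort_input("All weights must be strictly positive for full support.")
  }
  res <- cpp_wrla_chain(B0$owner, log(Omega), as.integer(n_steps),
                        as.integer(burn_in), as.integer(thin), store)
  out <- fairlet_assignment(res$owner, B0$N1)
  list(assignment = out, draws = if (store) res$draws else NULL,
       n_accept = res$n_accept, n_checkerboard = res$n_checkerboard)
}
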