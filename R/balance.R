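#' Balance of a clustering with respect to a protected attribute
#'
#' Balance of cluster \eqn{C_k} is the minimum over ordered pairs of attribute
#' levels of the count ratio \eqn{|C_k^{j_1}|/|C_k^{j_2}|}; the overall
#' balance is the minimum over clusters. It lies in \eqn{[0, 1]}: 1 means
#' every cluster reproduces the attribute proportions of a perfectly balanced
#' split, 0 means some cluster misses a level entirely. The formula is
#' defined for any number of levels, although the fair-clustering pipeline in
#' this package supports two.
#'
#' @param partition Cluster labels (integer-like), one per observation. Every
#'   cluster index present must have at least one member.
#' @param attribute Protected-attribute codes, same length as `partition`.
#' @return A single number in `[0, 1]`.
#' @examples
#' cluster_balance(rep(1:2, each = 50),
#'                 rep(c(1, 2, 1, 2), c(20, 30, 30, 20)))
#' @export
cluster_balance <- function(partition, attribute) {
  if (length(partition) != length(attribute)) {
    abort_input("`partition` and `attribute` must have the same length.")
  }
  if (length(partition) == 0) abort_input("Empty partition.")
  if (anyNA(partition) || anyNA(attribute)) {
    abort_input("Missing values in partition or attribute.")
  }
  levs <- sort(unique(attribute))
  if (length(levs) < 2) {
    abort_input("At least 2 distinct attribute levels are required.")
  }
  tab <- table(factor(partition), factor(attribute, levels = levs))
  if (any(rowSums(tab) == 0)) abort_input("Every cluster must be nonempty.")
  r <- ncol(tab)
  worst <- 1
  for (k in seq_len(nrow(tab))) {
    for (j1 in seq_len(r - 1)) {
      for (j2 in seq((j1 + 1), r)) {
        n1 <- tab[k, j1]; n2 <- tab[k, j2]
        ratio <- if (n1 == 0 || n2 == 0) 0 else min(n1 / n2, n2 / n1)
        if (ratio < worst) worst <- ratio
      }
    }
  }
  as.numeric(worst)
}

#' Balance of each draw in a set of posterior partitions
#'
#' Applies [cluster_balance()] to every row of a matrix of stored partitions,
#' e.g. to verify that all posterior draws of a fair clustering attain balance
#' \eqn{1/t} by construction.
#'
#' @param draws A T-by-N integer matrix; each row is a partition.
#' @param attribute Length-N attribute codes.
#' @return A numeric vector of length T.
#' @export
balance_draws <- function(draws, attribute) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  if (nrow(draws) == 0) abort_input("No draws supplied.")
  unname(apply(draws, 1, cluster_balance, attribute = attribute))
}
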