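# Synthetic two-cluster designs with a two-level protected attribute. Both
# designs use the same 2x2 cluster-by-attribute layout: cluster 1 holds 20
# attribute-1 and 30 attribute-2 individuals, cluster 2 holds 30 and 20, so
# the attribute is perfectly balanced overall (50:50, t = 1) while each true
# cluster has within-cluster balance 2/3.

# Bivariate Student-t via the standard construction: a Gaussian draw scaled by
# an independent chi-square. At nu = 2 the variance does not exist, so far
# outliers are expected.
rmv_student <- function(n, mu, S, nu) {
  z <- MASS::mvrnorm(n, mu = rep(0, length(mu)), Sigma = S)
  z <- matrix(z, nrow = n)
  w <- sqrt(rchisq(n, df = nu) / nu)
  sweep(z / w, 2, mu, "+")
}

simulate_design <- function(family, counts, means, S, nu = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, mu) {
    if (family == "gaussian") {
      matrix(MASS::mvrnorm(n, mu = mu, Sigma = S), nrow = n)
    } else {
      rmv_student(n, mu, S, nu)
    }
  }
  blocks <- list(
    list(n = as.integer(counts[["n11"]]), mu = means$mu11, a = "1", cl = 1L),
    list(n = as.integer(counts[["n21"]]), mu = means$mu21, a = "2", cl = 1L),
    list(n = as.integer(counts[["n12"]]), mu = means$mu12, a = "1", cl = 2L),
    list(n = as.integer(counts[["n22"]]), mu = means$mu22, a = "2", cl = 2L)
  )
  pts <- do.call(rbind, lapply(blocks, function(b) draw(b$n, b$mu)))
  tibble(
    x1 = pts[, 1],
    x2 = pts[, 2],
    attribute = rep(vapply(blocks, `[[`, "", "a"),
                    vapply(blocks, `[[`, 0L, "n")),
    cluster = rep(vapply(blocks, `[[`, 0L, "cl"),
                  vapply(blocks, `[[`, 0L, "n"))
  )
}

#' Simulate the well-specified two-cluster Gaussian design
#'
#' Two isotropic bivariate Gaussian clusters with a two-level protected
#' attribute. Cluster 1: 20 attribute-1 draws from \eqn{N((4,4), 4I)} and 30
#' attribute-2 draws from \eqn{N((2,2), 4I)}. Cluster 2: 30 attribute-1 draws
#' from \eqn{N((10,10), 4I)} and 20 attribute-2 draws from
#' \eqn{N((8,8), 4I)}. The attribute is balanced overall (50:50) but each
#' true cluster has balance 2/3, so an unconstrained clustering that recovers
#' the clusters is unfair.
#'
#' @param seed Optional integer seed; identical seeds give identical data.
#' @param n11,n21,n12,n22 Cell counts (attribute within cluster).
#' @param mu11,mu21,mu12,mu22 Component means (length-2).
#' @param scale Common isotropic variance (the covariance is `scale * I`).
#' @return A tibble with columns `x1`, `x2`, `attribute` (character levels
#'   "1"/"2") and the generating `cluster` (the truth side channel, excluded
#'   automatically from features by [fair_dataset()] when listed in
#'   `features`; pass `features = c("x1", "x2")` when fitting).
#' @examples
#' d <- simulate_well_specified(seed = 7)
#' table(d$attribute, d$cluster)
#' @export
simulate_well_specified <- function(seed = NULL, n11 = 20, n21 = 30,
                                    n12 = 30, n22 = 20,
                                    mu11 = c(4, 4), mu21 = c(2, 2),
                                    mu12 = c(10, 10), mu22 = c(8, 8),
                                    scale = 4) {
  simulate_design(
    "gaussian",
    counts = c(n11 = n11, n21 = n21, n12 = n12, n22 = n22),
    means = list(mu11 = mu11, mu21 = mu21, mu12 = mu12, mu22 = mu22),
    S = diag(scale, 2), seed = seed
  )
}

#' Simulate the misspecified heavy-tailed two-cluster design
#'
#' Same cluster-by-attribute layout and means as
#' [simulate_well_specified()], but each component is a bivariate Student-t
#' with scale matrix \eqn{3I} and \eqn{\nu = 2} degrees of freedom, so the
#' component variance does not exist and gross outliers occur. Used to probe
#' robustness of the clustering losses under model misspecification.
#'
#' @inheritParams simulate_well_specified
#' @param scale Common isotropic scale (scale matrix `scale * I`).
#' @param nu Degrees of freedom of the Student-t components (`nu >= 1`).
#' @return A tibble as in [simulate_well_specified()].
#' @export
simulate_misspecified <- function(seed = NULL, n11 = 20, n21 = 30,
                                  n12 = 30, n22 = 20,
                                  mu11 = c(4, 4), mu21 = c(2, 2),
                                  mu12 = c(10, 10), mu22 = c(8, 8),
                                  scale = 3, nu = 2) {
  if (nu < 1) abort_config("`nu` must be at least 1.")
  simulate_design(
    "student_t",
    counts = c(n11 = n11, n21 = n21, n12 = n12, n22 = n22),
    means = list(mu11 = mu11, mu21 = mu21, mu12 = mu12, mu22 = mu22),
    S = diag(scale, 2), nu = nu, seed = seed
  )
}
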