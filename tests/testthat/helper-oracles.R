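# Independent oracles used across the suite: exhaustive enumeration of
# permutations, fixed-margin binary matrices and K-block partitions, plus a
# naive co-clustering recomputation. These never call the code paths they
# check.

# All permutations of a vector (recursive; n small).
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Exhaustive minimum of <B, L> over t = 1 assignments (square L).
brute_assignment_min <- function(L) {
  n <- nrow(L)
  best <- Inf
  for (p in perms_of(seq_len(n))) {
    best <- min(best, sum(L[cbind(p, seq_len(n))]))
  }
  best
}

# All owner vectors for N1 rows, N2 columns, row sums t (each row owns
# exactly t columns). Returned as a list of length-N2 integer vectors.
enumerate_owners <- function(N1, t) {
  N2 <- N1 * t
  res <- list()
  recurse <- function(owner, counts, j) {
    if (j > N2) {
      res[[length(res) + 1]] <<- owner
      return(invisible())
    }
    for (i in seq_len(N1)) {
      if (counts[i] < t) {
        owner[j] <- i
        counts[i] <- counts[i] + 1
        recurse(owner, counts, j + 1)
        counts[i] <- counts[i] - 1
      }
    }
  }
  recurse(integer(N2), integer(N1), 1L)
  res
}

# All canonical label vectors of m units into exactly K = 2 nonempty blocks.
enumerate_2partitions <- function(m) {
  out <- list()
  for (mask in seq_len(2^(m - 1) - 1)) {
    out[[length(out) + 1]] <-
      c(1L, 1L + as.integer(intToBits(mask))[seq_len(m - 1)])
  }
  out
}

canonical <- function(x) match(x, unique(x))

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# O(T N^2) direct recomputation of the co-clustering matrix.
naive_coclustering <- function(draws) {
  N <- ncol(draws)
  eta <- matrix(0, N, N)
  for (s in seq_len(nrow(draws))) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        eta[i, j] <- eta[i, j] + (draws[s, i] == draws[s, j])
      }
    }
  }
  eta / nrow(draws)
}

# Index of a canonical partition within enumerate_2partitions(m).
partition_index <- function(lab, parts) {
  cl <- canonical(lab)
  which(vapply(parts, function(p) all(p == cl), logical(1)))
}

# Attribute codes (1/2) in original row order for a fair_dataset.
attribute_codes_for_test <- function(fd) {
  a <- integer(fd$N)
  a[fd$idx1] <- 1L
  a[fd$idx2] <- 2L
  a
}
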