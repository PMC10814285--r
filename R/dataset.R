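#' Construct a protected-attribute dataset for fair clustering
#'
#' Bundles a numeric feature table with a two-level protected attribute into
#' the object the fairlet machinery operates on. The attribute level with the
#' smaller count is coded 1 (ties broken by sorted level order), so that the
#' level counts satisfy `N2 = t * N1` for a positive integer ratio `t`.
#' Fairlet-based operations require this exact integer ratio and exactly two
#' observed levels; other inputs are rejected.
#'
#' @param data A data frame. All columns except `attribute` (and any columns
#'   excluded via `features`) must be numeric features.
#' @param attribute Column holding the protected attribute (bare name or
#'   string). Must have exactly two observed levels.
#' @param features Optional character vector naming the feature columns. By
#'   default every numeric column other than the attribute is used.
#' @return An object of class `fair_dataset`: a list with the feature matrix
#'   `points` (label-1 rows first, then label-2 rows), integer codes `a`
#'   (1/2 in internal order), the original row order (`idx1`, `idx2`), counts
#'   `N1`, `N2`, the ratio `t`, the attribute `levels`, and the original
#'   `data` as a tibble.
#' @examples
#' d <- simulate_well_specified(seed = 1)
#' fd <- fair_dataset(d, attribute)
#' fd$t
#' @export
fair_dataset <- function(data, attribute, features = NULL) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  attr_name <- as_name(ensym(attribute))
  if (!attr_name %in% names(data)) {
    abort_input(sprintf(
      "Attribute column '%s' not found. Available columns: %s.",
      attr_name, paste(names(data), collapse = ", ")
    ))
  }
  a_raw <- as.character(data[[attr_name]])
  levs <- sort(unique(a_raw))
  if (length(levs) != 2) {
    abort_input(sprintf(
      "The protected attribute must have exactly 2 levels; found %d (%s).",
      length(levs), paste(levs, collapse = ", ")
    ))
  }
  if (is.null(features)) {
    cand <- setdiff(names(data), attr_name)
    features <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(features) < 1) abort_input("No numeric feature columns found.")
  for (f in features) {
    if (!f %in% names(data)) abort_input(sprintf("Feature column '%s' not found.", f))
    v <- data[[f]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      abort_input(sprintf(
        "Feature column '%s' is not numeric (first offending row: %d).",
        f, if (length(bad)) bad[1] else 1L
      ))
    }
    if (anyNA(v)) {
      abort_input(sprintf("Feature column '%s' has missing values (row %d).",
                          f, which(is.na(v))[1]))
    }
  }
  X <- as.matrix(data[features])
  counts <- c(sum(a_raw == levs[1]), sum(a_raw == levs[2]))
  minority <- which.min(counts)  # ties -> first sorted level
  lev1 <- levs[minority]
  lev2 <- levs[-minority]
  idx1 <- which(a_raw == lev1)
  idx2 <- which(a_raw == lev2)
  N1 <- length(idx1)
  N2 <- length(idx2)
  t_ratio <- N2 / N1
  structure(list(
    points = rbind(X[idx1, , drop = FALSE], X[idx2, , drop = FALSE]),
    a = rep(1:2, c(N1, N2)),
    idx1 = idx1, idx2 = idx2,
    N1 = N1, N2 = N2, N = N1 + N2,
    t = if (t_ratio == round(t_ratio)) as.integer(t_ratio) else t_ratio,
    levels = c(lev1, lev2),
    features = features,
    attribute = attr_name,
    data = as_tibble(data)
  ), class = "fair_dataset")
}

#' @export
print.fair_dataset <- function(x, ...) {
  cat(sprintf(
    "<fair_dataset> N = %d (%s: %d, %s: %d), %d feature(s), ratio 1:%s\n",
    x$N, x$levels[1], x$N1, x$levels[2], x$N2, length(x$features),
    format(x$t)
  ))
  invisible(x)
}

# Fairlet machinery needs an exact 1:t integer ratio.
check_ratio <- function(fd) {
  if (!is.integer(fd$t) && fd$t != round(fd$t)) {
    abort_input(sprintf(
      paste0("Fairlet decomposition needs attribute counts in an exact 1:t ",
             "integer ratio; got %d:%d (ratio %.4g). Sub-sample the data to ",
             "an integer ratio first."),
      fd$N1, fd$N2, fd$t
    ))
  }
  invisible(fd)
}

# Attribute codes in the original row order of fd$data.
attribute_codes <- function(fd) {
  a <- integer(fd$N)
  a[fd$idx1] <- 1L
  a[fd$idx2] <- 2L
  a
}

#' Read a delimited dataset with a protected attribute
#'
#' Reads a comma-separated file (header required, UTF-8) and builds a
#' [fair_dataset()]. All columns except the attribute must be numeric.
#'
#' @param path Path to a CSV file.
#' @param attribute Name of the protected-attribute column (string).
#' @param features Optional character vector of feature columns.
#' @return A `fair_dataset`.
#' @export
read_fair_dataset <- function(path, attribute, features = NULL) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  fair_dataset(df, !!attribute, features = features)
}

#' Write per-observation cluster labels and misclassification probabilities
#'
#' @param path Output CSV path.
#' @param partition Integer cluster labels, one per observation.
#' @param misclassification Optional numeric vector (same length) of
#'   misclassification probabilities.
#' @return The written tibble, invisibly.
#' @export
write_cluster_labels <- function(path, partition, misclassification = NULL) {
  n <- length(partition)
  out <- tibble(
    observation = seq_len(n),
    cluster = as.integer(partition)
  )
  if (!is.null(misclassification)) {
    if (length(misclassification) != n) {
      abort_input("`misclassification` must match `partition` in length.")
    }
    out$misclassification <- misclassification
  }
  readr::write_csv(out, path)
  invisible(out)
}
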