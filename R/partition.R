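#' Interior quantile cutpoints for equal-frequency binning
#'
#' Returns the `k - 1` interior quantiles of `values` at fractions
#' `1/k, ..., (k-1)/k`, computed with rank-based linear interpolation
#' (the conventional type-7 estimator). These are the value-scale boundaries
#' of an equal-frequency binning and are what gets drawn as cluster-boundary
#' lines when visualizing a partition; cluster *assignment* itself is done on
#' rank percentiles (see [partition_numeric()]), which coincides with value
#' thresholds on tie-free data.
#'
#' @param values numeric vector, non-empty.
#' @param k integer number of bins, at least 2.
#' @return Numeric vector of `k - 1` non-decreasing cutpoints.
#' @examples
#' quantile_cutpoints(1:10, 2) # 5.5
#' @seealso [partition_numeric()]
#' @export
quantile_cutpoints <- function(values, k) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values)) stop("'values' contains missing values")
  k <- as.integer(k)
  if (is.na(k) || k < 2) stop("'k' must be an integer >= 2")
  stats::quantile(values, probs = seq_len(k - 1) / k, type = 7, names = FALSE)
}

## Construct a partition object; labels must already be compacted 1..k.
new_partition <- function(labels, source_k) {
  structure(
    list(labels = as.integer(labels), k = max(as.integer(labels)),
         source_k = as.integer(source_k)),
    class = "ccc_partition"
  )
}

#' @export
print.ccc_partition <- function(x, ...) {
  cat(sprintf("<ccc_partition> n = %d, k = %d (requested %d)\n",
              length(x$labels), x$k, x$source_k))
  cat("cluster sizes:", tabulate(x$labels, x$k), "\n")
  invisible(x)
}

#' Quantile-based partition of a numerical variable
#'
#' Assigns the `n` objects to `k` equal-frequency clusters on the rank scale:
#' object `i` goes to cluster `l` when `(l-1)/k < rank_i/n <= l/k`, with
#' average ranks for ties (a tied group is always kept together). Empty
#' clusters (possible under heavy ties) are dropped and labels compacted; a
#' result with fewer than 2 non-empty clusters is not a usable partition and
#' `NULL` is returned.
#'
#' Because assignment depends only on ranks, the induced set partition is
#' invariant under any strictly increasing transformation of `values`.
#'
#' @param values numeric vector, length at least 2.
#' @param k requested number of clusters, integer at least 2.
#' @return A `ccc_partition` (fields `labels` in `1..k`, `k` non-empty
#'   clusters, `source_k` the requested count), or `NULL` if fewer than two
#'   clusters are non-empty.
#' @examples
#' partition_numeric(1:10, 2)$labels # 1 1 1 1 1 2 2 2 2 2
#' partition_numeric(rep(1, 5), 3)   # NULL: constant vector
#' @export
partition_numeric <- function(values, k) {
  if (!is.numeric(values)) stop("'values' must be numeric")
  n <- length(values)
  if (n < 2) stop("need at least 2 values to partition")
  if (anyNA(values)) stop("'values' contains missing values")
  k <- as.integer(k)
  if (is.na(k) || k < 2) stop("'k' must be an integer >= 2")
  ## twice the average rank is integral, so bin arithmetic below is exact
  r2 <- as.integer(round(2 * rank(values, ties.method = "average")))
  raw <- as.integer(ceiling((r2 * as.double(k)) / (2 * n)))
  f <- factor(raw)
  if (nlevels(f) < 2) return(NULL)
  new_partition(as.integer(f), k)
}

#' Category partition of a categorical variable
#'
#' One cluster per distinct label, in order of first appearance (the order is
#' irrelevant downstream: the adjusted Rand index is invariant to cluster
#' relabeling). Categories are nominal; no ordering is ever used.
#'
#' @param values character vector or factor, length at least 2.
#' @return A `ccc_partition` with `k` = number of distinct labels, or `NULL`
#'   if fewer than 2 distinct labels are present.
#' @examples
#' partition_categorical(c("red", "green", "blue", "red"))$labels # 1 2 3 1
#' @export
partition_categorical <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to partition")
  if (anyNA(values)) stop("'values' contains missing values")
  values <- as.character(values)
  f <- factor(values, levels = unique(values))
  if (nlevels(f) < 2) return(NULL)
  new_partition(as.integer(f), nlevels(f))
}

#' Candidate partitions of one variable
#'
#' For a numerical variable, generates the valid quantile partitions for every
#' requested cluster count `k = 2, ..., kmax`; for a categorical variable, the
#' single category partition (independent of `kmax`). Duplicate partitions —
#' identical label vectors arising from ties at different `k` — are dropped,
#' keeping the smallest `k`; this cannot change any downstream maximum.
#'
#' @param v numeric vector (numerical variable) or character/factor
#'   (categorical variable), length at least 2.
#' @param kmax maximum number of clusters, integer at least 2. Ignored for
#'   categorical input.
#' @return List of `ccc_partition` objects (possibly empty), with attribute
#'   `variable_kind` set to `"numerical"` or `"categorical"`.
#' @examples
#' length(generate_partitions(1:10, 4)) # 3 (k = 2, 3, 4)
#' @export
generate_partitions <- function(v, kmax = 10) {
  kmax <- as.integer(kmax)
  if (is.na(kmax) || kmax < 2) stop("'kmax' must be an integer >= 2")
  if (length(v) < 2) stop("need at least 2 observations")
  if (is.numeric(v)) {
    parts <- lapply(2:kmax, function(k) partition_numeric(v, k))
    parts <- Filter(Negate(is.null), parts)
    dup <- duplicated(lapply(parts, `[[`, "labels"))
    parts <- parts[!dup]
    kind <- "numerical"
  } else {
    p <- partition_categorical(v)
    parts <- if (is.null(p)) list() else list(p)
    kind <- "categorical"
  }
  attr(parts, "variable_kind") <- kind
  parts
}

## labels of every partition in a set, for the C++ kernels
partition_labels <- function(parts) lapply(parts, `[[`, "labels")
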