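#' Pair-agreement counts between two partitions
#'
#' Classifies all `n(n-1)/2` object pairs by co-clustering agreement:
#' `n0` co-clustered in both partitions, `n1` separated in both, `n2`
#' co-clustered in `p` only, `n3` co-clustered in `q` only. `n0 + n1` is the
#' number of pairs on which the partitions agree. Computed from the cluster
#' overlap contingency table in `O(n + kp*kq)`, never by enumerating pairs.
#'
#' @param p,q partitions of the same objects: `ccc_partition` objects or
#'   integer cluster label vectors.
#' @return Named numeric vector `c(n0, n1, n2, n3)`; the four counts sum to
#'   `n(n-1)/2`.
#' @examples
#' pair_counts(c(1, 1, 2, 2), c(1, 2, 1, 2)) # n0=0 n1=2 n2=2 n3=2
#' @export
pair_counts <- function(p, q) {
  p <- as_labels(p)
  q <- as_labels(q)
  if (length(p) != length(q)) stop("partitions cover different numbers of objects")
  .cpp_pair_counts(p, q)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement:
#' `ARI = 2(n0*n1 - n2*n3) / ((n0+n2)(n2+n1) + (n0+n3)(n3+n1))`.
#' Equals 1 for identical partitions and is close to 0 in expectation for
#' independently drawn partitions regardless of their cluster counts (the
#' constant-baseline property that makes partitions with different `k`
#' comparable). When the denominator vanishes — both partitions one-cluster or
#' both all-singletons, hence identical — the value is 1 by convention.
#'
#' @inheritParams pair_counts
#' @return Numeric scalar in `[-1, 1]`; symmetric in its arguments and
#'   invariant to cluster relabeling.
#' @examples
#' ari(c(1, 1, 2, 2), c(1, 1, 2, 2)) # 1
#' ari(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
#' @export
ari <- function(p, q) {
  p <- as_labels(p)
  q <- as_labels(q)
  if (length(p) != length(q)) stop("partitions cover different numbers of objects")
  .cpp_ari(p, q)
}

## Accept a ccc_partition or a bare label vector; compact to 1..k integers.
as_labels <- function(p) {
  if (inherits(p, "ccc_partition")) return(p$labels)
  if (is.null(p)) stop("invalid (degenerate) partition")
  if (anyNA(p)) stop("labels contain missing values")
  as.integer(factor(p))
}
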