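## Candidate cluster counts for a numerical variable of length n. Cluster
## counts are capped at round(sqrt(n)): beyond that, quantile partitions are
## dominated by singletons, which carry no pattern information, and the cap is
## what reproduces the method's published worked examples at small n (at
## n = 100 and kmax = 10 the cap is inactive).
candidate_ks <- function(n, kmax) {
  2:max(2L, min(as.integer(kmax), as.integer(round(sqrt(n)))))
}

## Partition set actually used by the coefficient for one variable.
coef_partitions <- function(v, kmax) {
  if (is.numeric(v)) {
    ks <- candidate_ks(length(v), kmax)
    generate_partitions(v, max(ks))
  } else {
    generate_partitions(v, kmax)
  }
}

is_constant <- function(v) {
  if (is.numeric(v)) length(unique(v)) < 2 else length(unique(as.character(v))) < 2
}

check_pair_input <- function(x, y, na_action) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 2) stop("need at least 2 observations")
  keep <- !(vec_na(x) | vec_na(y))
  if (!all(keep)) {
    if (na_action == "pairwise-complete") {
      x <- x[keep]
      y <- y[keep]
      if (length(x) < 2) stop("fewer than 2 complete observations")
    } else {
      stop("missing values present; use na_action = \"pairwise-complete\" to drop them")
    }
  }
  list(x = x, y = y)
}

vec_na <- function(v) if (is.numeric(v)) !is.finite(v) else is.na(v)

#' Clustermatch Correlation Coefficient between two variables
#'
#' `ccc()` returns the coefficient value only; [ccc_pair()] additionally
#' reports the maximizing partitions and an optional permutation p-value.
#'
#' Each variable is converted into a set of candidate partitions — quantile
#' (rank-percentile) clusterings with `k = 2, ..., min(kmax, round(sqrt(n)))`
#' clusters for a numerical variable, the single category partition for a
#' categorical one — and the coefficient is the maximum adjusted Rand index
#' over all partition pairs, clamped below at 0:
#' `CCC(x, y) = max(0, max_{pi in Px, pj in Py} ARI(pi, pj))`.
#'
#' The coefficient lies in `[0, 1]`, is symmetric, depends only on ranks of
#' numerical inputs (hence is invariant under strictly increasing transforms),
#' and inherits the ARI's constant baseline: for independent variables it is
#' close to 0 regardless of `kmax`. If either variable is constant the
#' coefficient is undefined: `NA` is returned with a warning.
#'
#' @param x,y variables over the same `n >= 2` objects: numeric vectors
#'   (numerical) or character/factor vectors (categorical), in any
#'   combination.
#' @param kmax maximum number of clusters per partition (default 10, the
#'   practical default of the method). Candidate cluster counts are
#'   additionally capped at `round(sqrt(n))`; see Details.
#' @param permutations number of permutations for the null; 0 (default in
#'   `ccc_pair`) skips the p-value. See [ccc_perm_test()].
#' @param seed optional integer seed governing the permutations.
#' @param na_action `"error"` (default) or `"pairwise-complete"` (drop objects
#'   missing in either variable before partitioning).
#' @return `ccc()`: a numeric scalar in `[0, 1]`, or `NA` if undefined.
#'   `ccc_pair()`: a `ccc_result` list with elements `value`, `kx`, `ky`
#'   (cluster counts of the maximizing partitions), `labels_x`, `labels_y`
#'   (the maximizing partitions), `p_value` (or `NA` if not requested), `n`,
#'   and `kmax`. Ties on the maximum are resolved toward the smallest
#'   `kx * ky`, then smallest `kx`.
#' @examples
#' x <- seq_len(20)
#' ccc(x, 2 * x)                      # 1: identical rank order
#' ccc(x, (x - 10.5)^2)               # high: quadratic pattern
#' r <- ccc_pair(x, 2 * x)
#' r$value; r$kx; r$ky
#' @export
ccc <- function(x, y, kmax = 10, na_action = c("error", "pairwise-complete")) {
  ccc_pair(x, y, kmax = kmax, na_action = na_action)$value
}

#' @rdname ccc
#' @export
ccc_pair <- function(x, y, kmax = 10, permutations = 0, seed = NULL,
                     na_action = c("error", "pairwise-complete")) {
  na_action <- match.arg(na_action)
  inp <- check_pair_input(x, y, na_action)
  x <- inp$x
  y <- inp$y
  n <- length(x)

  if (is_constant(x) || is_constant(y)) {
    warning("constant variable: CCC is undefined")
    return(new_ccc_result(NA_real_, NA_integer_, NA_integer_, NULL, NULL,
                          NA_real_, n, kmax))
  }

  px <- coef_partitions(x, kmax)
  py <- coef_partitions(y, kmax)
  if (length(px) == 0 || length(py) == 0) {
    ## no detectable structure in one variable (possible only under extreme
    ## ties); distinct from the undefined constant case
    return(new_ccc_result(0, NA_integer_, NA_integer_, NULL, NULL,
                          NA_real_, n, kmax))
  }

  gm <- .cpp_grid_max(partition_labels(px), partition_labels(py))
  best_x <- px[[gm[2]]]
  best_y <- py[[gm[3]]]
  value <- max(0, gm[1])

  p_value <- NA_real_
  if (permutations > 0) {
    p_value <- perm_pvalue_from_partitions(px, py, value, permutations, seed)
  }
  new_ccc_result(value, best_x$k, best_y$k, best_x$labels, best_y$labels,
                 p_value, n, kmax)
}

new_ccc_result <- function(value, kx, ky, labels_x, labels_y, p_value, n, kmax) {
  structure(
    list(value = value, kx = kx, ky = ky, labels_x = labels_x,
         labels_y = labels_y, p_value = p_value, n = n,
         kmax = as.integer(kmax)),
    class = "ccc_result"
  )
}

#' @export
print.ccc_result <- function(x, ...) {
  cat("Clustermatch correlation\n")
  cat(sprintf("  c = %s  (n = %d, kmax = %d)\n",
              format(x$value, digits = 4), x$n, x$kmax))
  if (!is.na(x$kx)) {
    cat(sprintf("  maximizing partitions: kx = %d, ky = %d\n", x$kx, x$ky))
  }
  if (!is.na(x$p_value)) {
    cat(sprintf("  permutation p-value: %s\n", format.pval(x$p_value)))
  }
  invisible(x)
}
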