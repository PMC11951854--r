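## Shared permutation kernel: partitions of the permuted y are the permuted
## partition labels, so partitioning is done once and the permutation loop
## runs over relabelings in compiled code. R's RNG drives the shuffles, so a
## single set.seed() reproduces serial and chunked runs alike.
perm_pvalue_from_partitions <- function(px, py, observed, permutations,
                                        seed = NULL, smoothing = FALSE) {
  permutations <- as.integer(permutations)
  if (permutations < 1) stop("'permutations' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- .cpp_perm_count(partition_labels(px), partition_labels(py),
                       permutations, observed)
  if (smoothing) (r + 1) / (permutations + 1) else r / permutations
}

#' Permutation test for the Clustermatch Correlation Coefficient
#'
#' Tests the null hypothesis that the two variables are independent: the
#' values of `y` are permuted, the coefficient is recomputed for each
#' permutation, and the p-value is the proportion of permuted coefficients
#' greater than or equal to the observed one. With the default plain
#' proportion the p-value can be 0; the opt-in `smoothing` returns
#' `(r + 1) / (P + 1)`, which is never 0 and slightly conservative.
#'
#' Permuting `x` instead of `y` is equivalent by symmetry of the coefficient.
#' An observed coefficient of 0 always gives p = 1, since permuted values are
#' clamped at 0 as well.
#'
#' @inheritParams ccc
#' @param permutations number of permutations (default 10000, suitable for
#'   single-pair use; large-scale screens may need more for small p-values).
#' @param smoothing if `TRUE`, use the add-one estimator `(r + 1) / (P + 1)`.
#' @return A `ccc_test` list: `value` (the observed coefficient), `p_value`,
#'   `n_permutations`, `kx`, `ky`, `n`.
#' @examples
#' a <- anscombe_quartet()
#' t1 <- ccc_perm_test(a$I$x, a$I$y, permutations = 1000, seed = 1)
#' t1$value  # 1: strong linear pattern
#' @export
ccc_perm_test <- function(x, y, kmax = 10, permutations = 10000, seed = NULL,
                          smoothing = FALSE,
                          na_action = c("error", "pairwise-complete")) {
  na_action <- match.arg(na_action)
  inp <- check_pair_input(x, y, na_action)
  x <- inp$x
  y <- inp$y
  if (is_constant(x) || is_constant(y)) {
    stop("constant variable: CCC is undefined, there is no null to test")
  }
  obs <- ccc_pair(x, y, kmax = kmax)
  px <- coef_partitions(x, kmax)
  py <- coef_partitions(y, kmax)
  p <- if (length(px) == 0 || length(py) == 0) {
    1  # observed value is 0 and every permuted value is 0 as well
  } else {
    perm_pvalue_from_partitions(px, py, obs$value, permutations, seed, smoothing)
  }
  structure(
    list(value = obs$value, p_value = p,
         n_permutations = as.integer(permutations),
         kx = obs$kx, ky = obs$ky, n = obs$n),
    class = "ccc_test"
  )
}

#' @export
print.ccc_test <- function(x, ...) {
  cat("Clustermatch permutation test\n")
  p_str <- if (x$p_value == 0) {
    sprintf("< %g", 1 / x$n_permutations)
  } else {
    format(x$p_value, digits = 3)
  }
  cat(sprintf("  c = %s, p = %s (%d permutations, n = %d)\n",
              format(x$value, digits = 4), p_str, x$n_permutations, x$n))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment controlling the FDR across a family of tests;
#' output is order-preserving with the input and elementwise no smaller than
#' the raw p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
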