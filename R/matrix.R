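#' Condensed upper-triangle indexing
#'
#' Bijection between variable pairs `(i, j)` with `1 <= i < j <= n_vars` and
#' positions `1 .. n_vars*(n_vars-1)/2` of the condensed (flat, row-major
#' upper triangle) representation of a symmetric pairwise matrix.
#'
#' @param i,j 1-based variable indices, `i < j`.
#' @param idx 1-based condensed position.
#' @param n_vars number of variables.
#' @return `condensed_index()`: the condensed position. `condensed_pair()`:
#'   integer vector `c(i, j)`.
#' @examples
#' condensed_index(1, 2, 4) # 1
#' condensed_index(3, 4, 4) # 6
#' condensed_pair(6, 4)     # 3 4
#' @export
condensed_index <- function(i, j, n_vars) {
  i <- as.integer(i); j <- as.integer(j); n_vars <- as.integer(n_vars)
  if (any(i >= j)) stop("'i' must be smaller than 'j'")
  if (any(i < 1) || any(j > n_vars)) stop("indices out of range")
  (i - 1L) * n_vars - (i * (i - 1L)) %/% 2L + (j - i)
}

#' @rdname condensed_index
#' @export
condensed_pair <- function(idx, n_vars) {
  idx <- as.integer(idx); n_vars <- as.integer(n_vars)
  n_pairs <- (n_vars * (n_vars - 1L)) %/% 2L
  if (any(idx < 1) || any(idx > n_pairs)) stop("condensed index out of range")
  i <- integer(length(idx)); j <- integer(length(idx))
  for (t in seq_along(idx)) {
    r <- 1L
    off <- idx[t]
    while (off > n_vars - r) {
      off <- off - (n_vars - r)
      r <- r + 1L
    }
    i[t] <- r
    j[t] <- r + off
  }
  if (length(idx) == 1L) c(i, j) else cbind(i = i, j = j)
}

#' Pairwise Clustermatch correlation matrix
#'
#' Computes the coefficient for every unordered pair of rows (variables) of an
#' expression-style matrix. Per-variable partition sets are computed once and
#' reused across all pairs. Work is split over pair chunks when `jobs > 1`
#' (forked processes via the parallel package); the output is identical for
#' any `jobs` value, including every permutation p-value, because each pair's
#' permutation stream is seeded independently from `seed` and the pair index.
#'
#' Constant rows yield undefined (NA) coefficients with a single warning, so
#' large matrix runs complete.
#'
#' @param m numeric matrix or data.frame with variables (e.g. genes) as rows
#'   and samples as columns, or a list of equal-length vectors (numeric or
#'   character, mixed kinds allowed).
#' @param kmax maximum number of clusters per partition (default 10).
#' @param jobs number of worker processes (default 1).
#' @param permutations permutations per pair for p-values; 0 (default) skips
#'   significance. When > 0, Benjamini-Hochberg adjusted values are included.
#' @param seed integer seed governing all permutation streams.
#' @param categorical_rows optional row names or indices to treat as
#'   categorical (their values are used as category labels).
#' @param pairs optional two-column matrix (or data.frame) of variable name
#'   pairs restricting which pairs receive a permutation p-value; default all.
#' @return A `ccc_matrix` object: list with `names`, `n_vars`, `condensed`
#'   (coefficients in row-major upper-triangle order), `kx`, `ky`, and, when
#'   requested, `p_value` and `fdr`. Use `as.matrix()` for the square form
#'   (unit diagonal) or `as.data.frame()` for the long pair list.
#' @examples
#' m <- rbind(a = 1:10, b = (1:10)^2, c = rnorm(10))
#' cm <- ccc_matrix(m)
#' as.data.frame(cm)
#' @export
ccc_matrix <- function(m, kmax = 10, jobs = 1, permutations = 0, seed = 1,
                       categorical_rows = NULL, pairs = NULL) {
  rows <- as_variable_list(m, categorical_rows)
  nv <- length(rows)
  if (nv < 2) stop("need at least 2 variables (rows)")
  n <- unique(lengths(rows))
  if (length(n) != 1) stop("ragged rows: all variables must have the same length")
  nms <- names(rows)

  constant <- vapply(rows, is_constant, logical(1))
  if (any(constant)) {
    warning(sprintf("%d constant variable(s) have undefined CCC: %s",
                    sum(constant), paste(head(nms[constant], 5), collapse = ", ")))
  }
  psets <- vector("list", nv)
  for (v in seq_len(nv)) {
    if (!constant[v]) psets[[v]] <- coef_partitions(rows[[v]], kmax)
  }

  n_pairs <- (nv * (nv - 1L)) %/% 2L
  do_pvals <- permutations > 0
  pair_allowed <- rep(TRUE, n_pairs)
  if (do_pvals && !is.null(pairs)) {
    pair_allowed <- allowlist_mask(pairs, nms)
  }

  compute_pair <- function(idx) {
    ij <- condensed_pair(idx, nv)
    i <- ij[1]; j <- ij[2]
    if (constant[i] || constant[j]) {
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    }
    px <- psets[[i]]; py <- psets[[j]]
    if (length(px) == 0 || length(py) == 0) {
      return(c(0, NA_real_, NA_real_, if (do_pvals && pair_allowed[idx]) 1 else NA_real_))
    }
    gm <- .cpp_grid_max(partition_labels(px), partition_labels(py))
    value <- max(0, gm[1])
    p <- NA_real_
    if (do_pvals && pair_allowed[idx]) {
      p <- perm_pvalue_from_partitions(
        px, py, value, permutations,
        seed = (as.integer(seed) + idx) %% .Machine$integer.max
      )
    }
    c(value, px[[gm[2]]]$k, py[[gm[3]]]$k, p)
  }

  jobs <- max(1L, as.integer(jobs))
  res <- if (jobs > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(n_pairs), cut(seq_len(n_pairs), jobs, labels = FALSE))
    out <- parallel::mclapply(chunks, function(ix) lapply(ix, compute_pair),
                              mc.cores = jobs)
    unlist(out, recursive = FALSE, use.names = FALSE)
  } else {
    lapply(seq_len(n_pairs), compute_pair)
  }
  res <- do.call(rbind, res)

  out <- structure(
    list(names = nms, n_vars = nv, condensed = res[, 1],
         kx = as.integer(res[, 2]), ky = as.integer(res[, 3]),
         n_samples = n, kmax = as.integer(kmax),
         permutations = as.integer(permutations), seed = as.integer(seed)),
    class = "ccc_matrix"
  )
  if (do_pvals) {
    out$p_value <- res[, 4]
    out$fdr <- rep(NA_real_, n_pairs)
    ok <- !is.na(out$p_value)
    out$fdr[ok] <- bh_adjust(out$p_value[ok])
  }
  out
}

## rows of a matrix / data.frame / list -> named list of variables
as_variable_list <- function(m, categorical_rows = NULL) {
  if (is.list(m) && !is.data.frame(m)) {
    rows <- m
    if (is.null(names(rows))) names(rows) <- paste0("V", seq_along(rows))
  } else {
    m <- as.matrix(m)
    nms <- rownames(m)
    if (is.null(nms)) nms <- paste0("V", seq_len(nrow(m)))
    rows <- lapply(seq_len(nrow(m)), function(i) m[i, ])
    names(rows) <- nms
  }
  if (anyDuplicated(names(rows))) stop("duplicate variable names")
  if (!is.null(categorical_rows)) {
    sel <- if (is.character(categorical_rows)) {
      match(categorical_rows, names(rows))
    } else {
      as.integer(categorical_rows)
    }
    if (anyNA(sel) || any(sel < 1) || any(sel > length(rows))) {
      stop("unknown categorical row selection")
    }
    for (s in sel) rows[[s]] <- as.character(rows[[s]])
  }
  rows
}

allowlist_mask <- function(pairs, nms) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("'pairs' must have two columns")
  nv <- length(nms)
  mask <- rep(FALSE, (nv * (nv - 1L)) %/% 2L)
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1], nms)
    j <- match(pairs[r, 2], nms)
    if (is.na(i) || is.na(j)) stop("unknown variable name in 'pairs'")
    mask[condensed_index(min(i, j), max(i, j), nv)] <- TRUE
  }
  mask
}

#' @export
print.ccc_matrix <- function(x, ...) {
  cat(sprintf("<ccc_matrix> %d variables, %d samples, %d pairs (kmax = %d)\n",
              x$n_vars, x$n_samples, length(x$condensed), x$kmax))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p-values: %d permutations, seed %d\n",
                x$permutations, x$seed))
  }
  invisible(x)
}

#' @export
as.matrix.ccc_matrix <- function(x, ...) {
  nv <- x$n_vars
  m <- diag(1, nv)  # self-similarity: ARI of a partition with itself is 1
  for (idx in seq_along(x$condensed)) {
    ij <- condensed_pair(idx, nv)
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- x$condensed[idx]
  }
  dimnames(m) <- list(x$names, x$names)
  m
}

#' @export
as.data.frame.ccc_matrix <- function(x, ...) {
  nv <- x$n_vars
  ij <- do.call(rbind, lapply(seq_along(x$condensed), condensed_pair, n_vars = nv))
  df <- data.frame(
    var_i = x$names[ij[, 1]], var_j = x$names[ij[, 2]],
    ccc = x$condensed, kx = x$kx, ky = x$ky,
    stringsAsFactors = FALSE
  )
  if (!is.null(x$p_value)) {
    df$p_value <- x$p_value
    df$fdr <- x$fdr
  }
  df
}
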