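#' Read an expression-style matrix from TSV/CSV
#'
#' Expects a delimited file with a header row and a first column of
#' identifiers. Orientation is normalized to genes (variables) as rows.
#'
#' @param path readable file path.
#' @param format `"auto"` (by extension; default), `"tsv"` or `"csv"`.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`
#'   (the matrix is transposed after reading).
#' @param categorical_rows optional identifiers of rows holding categorical
#'   values; all other cells must be numeric.
#' @return Numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames; when `categorical_rows` are present, a list of
#'   row vectors (mixed numeric/character) with a `names` attribute instead.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "tsv", "csv"),
                                   orientation = c("genes_as_rows",
                                                   "samples_as_rows"),
                                   categorical_rows = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- switch(format,
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    tsv = "\t",
    csv = ","
  )
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stop("expected an identifier column plus data columns")
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers: ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  vals <- dt[, -1, drop = FALSE]
  if (anyDuplicated(names(vals))) stop("duplicate column identifiers")

  if (orientation == "samples_as_rows") {
    gene_ids <- names(vals)
    sample_ids <- ids
    rows <- lapply(seq_along(vals), function(j) as_cell_vector(vals[[j]], gene_ids[j]))
    names(rows) <- gene_ids
    rows <- lapply(rows, stats::setNames, sample_ids)
  } else {
    gene_ids <- ids
    sample_ids <- names(vals)
    rows <- lapply(seq_len(nrow(vals)), function(i) {
      stats::setNames(as_cell_vector(unlist(vals[i, ], use.names = FALSE),
                                     gene_ids[i]), sample_ids)
    })
    names(rows) <- gene_ids
  }

  cat_rows <- intersect(categorical_rows, gene_ids)
  if (length(setdiff(categorical_rows, gene_ids)) > 0) {
    stop("categorical rows not found: ",
         paste(setdiff(categorical_rows, gene_ids), collapse = ", "))
  }
  for (g in seq_along(rows)) {
    if (names(rows)[g] %in% cat_rows) {
      rows[[g]] <- as.character(rows[[g]])
    } else if (!is.numeric(rows[[g]])) {
      bad <- suppressWarnings(is.na(as.numeric(rows[[g]])) & !is.na(rows[[g]]))
      stop(sprintf("non-numeric value in row '%s' (e.g. column '%s')",
                   names(rows)[g], sample_ids[which(bad)[1]]))
    }
  }
  if (length(cat_rows) > 0) return(rows)
  out <- do.call(rbind, rows)
  rownames(out) <- gene_ids
  colnames(out) <- sample_ids
  out
}

as_cell_vector <- function(v, label) {
  if (is.numeric(v)) return(as.numeric(v))
  suppressWarnings(num <- as.numeric(v))
  if (any(is.na(num) & !is.na(v))) return(v)  # leave as character; checked later
  num
}

#' Write an expression matrix as TSV/CSV
#'
#' @param m numeric matrix with rownames (genes) and colnames (samples).
#' @param path output path; extension `.csv` selects comma separation.
#' @param id_column name of the identifier column (default `"gene_id"`).
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.table::data.table(ids = rownames(m))
  data.table::setnames(df, "ids", id_column)
  out <- cbind(df, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Select top-variance genes after log transform
#'
#' Applies `log(x + 1)` to every expression value (guarding against bias
#' toward highly expressed genes), ranks genes by the variance of the
#' transformed values, and returns the `top_n` transformed rows, ordered by
#' decreasing variance.
#'
#' @param m numeric matrix, genes as rows, non-negative expression values
#'   (e.g. TPM).
#' @param top_n number of genes to keep (default 5000).
#' @return Numeric matrix of the `top_n` log-transformed rows.
#' @examples
#' m <- rbind(flat = rep(1, 4), varied = c(0, 10, 100, 1000))
#' rownames(select_top_variance_genes(m, 1)) # "varied"
#' @export
select_top_variance_genes <- function(m, top_n = 5000) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("expression matrix must be numeric")
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  if (top_n > nrow(m)) stop("'top_n' exceeds the number of genes")
  lm <- log1p(m)
  v <- apply(lm, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(top_n)]
  lm[keep, , drop = FALSE]
}

#' Run the pairwise-correlation pipeline on an expression file
#'
#' Read, optionally preprocess (log transform + top-variance gene selection),
#' compute the pairwise Clustermatch correlation matrix, optionally attach
#' permutation p-values with Benjamini-Hochberg adjustment, and write the
#' result. Output columns of the default long format are fixed:
#' `var_i, var_j, ccc, kx, ky` plus `p_value, fdr` when permutations are
#' requested. A run manifest (parameters, seed, package version) is emitted
#' through [message()].
#'
#' @inheritParams read_expression_matrix
#' @inheritParams ccc_matrix
#' @param input input matrix file path.
#' @param output output file path; on failure partial output is removed.
#' @param top_n_genes if non-NULL, apply [select_top_variance_genes()] with
#'   this cutoff before correlating.
#' @param out_format `"pairs"` (long pair list, default) or `"square"`
#'   (symmetric matrix with unit diagonal).
#' @param pairs optional two-column data.frame/matrix of variable-name pairs
#'   restricting which pairs receive p-values.
#' @return The result `data.frame` (long format) invisibly.
#' @export
run_corr <- function(input, output, kmax = 10, jobs = 1, permutations = 0,
                     seed = 1, top_n_genes = NULL,
                     out_format = c("pairs", "square"),
                     orientation = c("genes_as_rows", "samples_as_rows"),
                     categorical_rows = NULL, pairs = NULL) {
  out_format <- match.arg(out_format)
  orientation <- match.arg(orientation)
  ok <- FALSE
  on.exit(if (!ok && file.exists(output)) unlink(output))

  m <- read_expression_matrix(input, orientation = orientation,
                              categorical_rows = categorical_rows)
  if (!is.null(top_n_genes)) {
    if (!is.matrix(m)) stop("top-variance selection requires an all-numeric matrix")
    m <- select_top_variance_genes(m, top_n_genes)
  }
  message(sprintf(
    "clustermatch %s | input=%s variables=%d samples=%d kmax=%d jobs=%d permutations=%d seed=%d",
    as.character(utils::packageVersion("clustermatch")), input,
    if (is.matrix(m)) nrow(m) else length(m),
    if (is.matrix(m)) ncol(m) else length(m[[1]]), kmax, jobs, permutations,
    as.integer(seed)))

  cm <- ccc_matrix(m, kmax = kmax, jobs = jobs, permutations = permutations,
                   seed = seed, pairs = pairs)
  df <- as.data.frame(cm)
  sep <- if (grepl("\\.csv$", output, ignore.case = TRUE)) "," else "\t"
  if (out_format == "square") {
    sq <- as.matrix(cm)
    out <- cbind(data.table::data.table(variable = rownames(sq)),
                 data.table::as.data.table(sq))
    data.table::fwrite(out, output, sep = sep)
  } else {
    data.table::fwrite(df, output, sep = sep)
  }
  ok <- TRUE
  invisible(df)
}
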