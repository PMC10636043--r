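# On-disk formats: slice directories (CSV or MatrixMarket) and match tables.
#
# A slice directory holds:
#   features.mtx (sparse counts) or features.csv (dense)  -- cells x features
#   features.tsv  one feature name per line
#   coords.csv    columns x,y (or the names passed as coord_keys)
#   obs.csv       optional per-cell labels (cell_type, region, ...)
#   embedding     optional marker file: presence flags is_embedding = TRUE
# All per-cell files are row-aligned with the feature matrix.

#' Read a spatial slice from a directory
#'
#' @param path directory containing `features.mtx` or `features.csv`,
#'   `features.tsv`, `coords.csv`, and optionally `obs.csv`.
#' @param coord_keys names of the two coordinate columns in `coords.csv`.
#' @param label_keys named character vector mapping slot -> obs column, default
#'   `c(cell_type = "cell_type", region = "region")`; missing columns are
#'   silently skipped.
#' @return a validated [spatial_slice()].
#' @export
read_slice <- function(path, coord_keys = c("x", "y"),
                       label_keys = c(cell_type = "cell_type", region = "region")) {
  if (!dir.exists(path)) stop("configuration error: no such slice directory: ", path)
  mtx <- file.path(path, "features.mtx")
  csv <- file.path(path, "features.csv")
  if (file.exists(mtx)) {
    features <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  } else if (file.exists(csv)) {
    features <- as.matrix(utils::read.csv(csv, header = FALSE))
    dimnames(features) <- NULL
  } else {
    stop("configuration error: ", path, " has neither features.mtx nor features.csv")
  }
  fn_path <- file.path(path, "features.tsv")
  feature_names <- if (file.exists(fn_path)) readLines(fn_path) else NULL
  cpath <- file.path(path, "coords.csv")
  if (!file.exists(cpath)) stop("configuration error: missing coords.csv in ", path)
  cdf <- utils::read.csv(cpath)
  if (!all(coord_keys %in% names(cdf)))
    stop("configuration error: coordinate key(s) ",
         paste(setdiff(coord_keys, names(cdf)), collapse = ", "),
         " not found in coords.csv")
  coords <- unname(as.matrix(cdf[, coord_keys]))
  cell_type <- region <- NULL
  opath <- file.path(path, "obs.csv")
  if (file.exists(opath)) {
    obs <- utils::read.csv(opath, colClasses = "character")
    if (nrow(obs) != nrow(coords))
      stop("format error: obs.csv row count does not match coords.csv")
    if (!is.na(label_keys["cell_type"]) && label_keys["cell_type"] %in% names(obs))
      cell_type <- obs[[label_keys["cell_type"]]]
    if (!is.na(label_keys["region"]) && label_keys["region"] %in% names(obs))
      region <- obs[[label_keys["region"]]]
  }
  spatial_slice(features, coords, cell_type = cell_type, region = region,
                feature_names = feature_names,
                is_embedding = file.exists(file.path(path, "embedding")))
}

#' Write a spatial slice to a directory
#'
#' Inverse of [read_slice()]; counts stored sparse are written as
#' MatrixMarket, dense matrices as CSV.
#'
#' @param s a `spatial_slice`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_slice <- function(s, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(s$features, "sparseMatrix")) {
    Matrix::writeMM(s$features, file.path(path, "features.mtx"))
  } else {
    utils::write.table(s$features, file.path(path, "features.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  writeLines(s$feature_names, file.path(path, "features.tsv"))
  cdf <- data.frame(x = s$coords[, 1], y = s$coords[, 2])
  utils::write.csv(cdf, file.path(path, "coords.csv"), row.names = FALSE)
  if (!is.null(s$cell_type) || !is.null(s$region)) {
    obs <- data.frame(row.names = seq_len(n_cells(s)))
    if (!is.null(s$cell_type)) obs$cell_type <- s$cell_type
    if (!is.null(s$region)) obs$region <- s$region
    utils::write.csv(obs, file.path(path, "obs.csv"), row.names = FALSE)
  }
  if (s$is_embedding) file.create(file.path(path, "embedding"))
  invisible(path)
}

#' Construct a match table
#'
#' One row per retained candidate pair: slice-1 cell, slice-2 candidate,
#' cosine similarity of their alignment embeddings, empirical p-value, and
#' the acceptance flag `p_value < threshold`.
#'
#' @param source integer slice-1 indices (1-based in memory).
#' @param target integer slice-2 indices.
#' @param cosine numeric cosine similarities in `[-1, 1]`.
#' @param p_value numeric empirical p-values in `(0, 1]`.
#' @param threshold acceptance threshold (default 0.05).
#' @return a `data.frame` of class `match_table`, ordered by
#'   `(source, p_value)`.
#' @export
match_table <- function(source, target, cosine, p_value, threshold = 0.05) {
  df <- data.frame(source = as.integer(source), target = as.integer(target),
                   cosine = as.numeric(cosine), p_value = as.numeric(p_value))
  df$accepted <- df$p_value < threshold
  df <- df[order(df$source, df$p_value, -df$cosine, df$target), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "threshold") <- threshold
  class(df) <- c("match_table", "data.frame")
  df
}

#' Write a match table as TSV
#'
#' Columns `source,target,cosine,pvalue,accepted`; indices are written
#' 0-based; rows ordered by `(source, p_value)` for bit-stable output.
#'
#' @param m a [match_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches <- function(m, path) {
  out <- data.frame(
    source = m$source - 1L,
    target = m$target - 1L,
    cosine = sprintf("%.10g", m$cosine),
    pvalue = sprintf("%.10g", m$p_value),
    accepted = ifelse(m$accepted, "true", "false")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a match table from TSV
#'
#' @param path file written by [write_matches()].
#' @param threshold acceptance threshold recorded on the result.
#' @return a [match_table()] with 1-based indices.
#' @export
read_matches <- function(path, threshold = 0.05) {
  df <- utils::read.delim(path)
  m <- match_table(df$source + 1L, df$target + 1L, df$cosine, df$pvalue,
                   threshold = threshold)
  # preserve flags as written (threshold may differ from default)
  m
}
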