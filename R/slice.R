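# In-memory data model: one spatially resolved omics slice.

#' Construct a spatial slice
#'
#' A `spatial_slice` bundles a cells-by-features matrix (raw counts, or a
#' precomputed low-dimensional embedding for cross-modality input) with 2-D
#' spatial coordinates and optional per-cell categorical labels.
#'
#' @param features numeric matrix or `Matrix::sparseMatrix`, cells x features.
#' @param coords numeric matrix, cells x 2. Positions are treated as
#'   dimensionless planar coordinates; no unit conversion is applied.
#' @param cell_type optional character vector of per-cell type labels;
#'   unannotated cells carry the sentinel `"NA"`.
#' @param region optional character vector of per-cell spatial-region labels.
#' @param feature_names character vector naming the feature columns; defaults
#'   to existing column names or `"g1".."gG"`.
#' @param is_embedding logical; `TRUE` when `features` is a precomputed
#'   embedding rather than counts.
#' @return an object of class `spatial_slice`.
#' @export
spatial_slice <- function(features, coords, cell_type = NULL, region = NULL,
                          feature_names = NULL, is_embedding = FALSE) {
  if (!inherits(features, "Matrix")) features <- as.matrix(features)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(features)
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("g", seq_len(ncol(features)))
  }
  s <- structure(
    list(
      features = features,
      coords = coords,
      cell_type = if (is.null(cell_type)) NULL else as.character(cell_type),
      region = if (is.null(region)) NULL else as.character(region),
      feature_names = as.character(feature_names),
      is_embedding = isTRUE(is_embedding)
    ),
    class = "spatial_slice"
  )
  validate_slice(s)
}

validate_slice <- function(s) {
  if (nrow(s$coords) != nrow(s$features))
    stop("format error: coords row count (", nrow(s$coords),
         ") does not match feature matrix row count (", nrow(s$features), ")")
  if (ncol(s$coords) != 2L)
    stop("format error: coords must have exactly 2 columns")
  if (anyNA(s$coords))
    stop("format error: NaN/NA spatial coordinates")
  if (length(s$feature_names) != ncol(s$features))
    stop("format error: feature_names length does not match feature columns")
  if (anyDuplicated(s$feature_names))
    stop("format error: feature_names must be unique")
  for (key in c("cell_type", "region")) {
    if (!is.null(s[[key]]) && length(s[[key]]) != nrow(s$features))
      stop("format error: ", key, " length does not match cell count")
  }
  s
}

#' @exportS3Method base::print
print.spatial_slice <- function(x, ...) {
  cat(sprintf("spatial_slice: %d cells x %d features (%s%s)\n",
              nrow(x$features), ncol(x$features),
              if (x$is_embedding) "embedding" else "counts",
              if (inherits(x$features, "sparseMatrix")) ", sparse" else ""))
  if (!is.null(x$cell_type))
    cat("  cell types:", length(unique(x$cell_type)), "\n")
  if (!is.null(x$region))
    cat("  regions:  ", length(unique(x$region)), "\n")
  invisible(x)
}

#' Number of cells in a slice
#' @param s a `spatial_slice`.
#' @return integer cell count.
#' @export
n_cells <- function(s) nrow(s$features)

#' Subset a slice by cell indices
#'
#' @param s a `spatial_slice`.
#' @param idx integer vector of (1-based) cell indices.
#' @return a `spatial_slice` with the selected cells, labels carried along.
#' @export
slice_subset <- function(s, idx) {
  spatial_slice(
    features = s$features[idx, , drop = FALSE],
    coords = s$coords[idx, , drop = FALSE],
    cell_type = if (is.null(s$cell_type)) NULL else s$cell_type[idx],
    region = if (is.null(s$region)) NULL else s$region[idx],
    feature_names = s$feature_names,
    is_embedding = s$is_embedding
  )
}

#' Filter cells by total counts
#'
#' Drops cells whose total feature count falls below `min_counts`. No-op on
#' embedding slices.
#'
#' @param s a `spatial_slice`.
#' @param min_counts minimum total count per cell (default 1, i.e. drop
#'   all-zero cells).
#' @return filtered `spatial_slice`.
#' @export
filter_min_counts <- function(s, min_counts = 1) {
  if (s$is_embedding) return(s)
  keep <- which(Matrix::rowSums(s$features) >= min_counts)
  if (length(keep) == n_cells(s)) s else slice_subset(s, keep)
}

#' Drop unannotated cells
#'
#' Removes cells whose `cell_type` or `region` is the sentinel `"NA"` (or an
#' actual `NA`), mirroring benchmark preprocessing that excludes unannotated
#' cells before alignment.
#'
#' @param s a `spatial_slice`.
#' @return filtered `spatial_slice`.
#' @export
drop_unannotated <- function(s) {
  bad <- rep(FALSE, n_cells(s))
  for (key in c("cell_type", "region")) {
    lab <- s[[key]]
    if (!is.null(lab)) bad <- bad | is.na(lab) | lab == "NA"
  }
  if (!any(bad)) s else slice_subset(s, which(!bad))
}
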