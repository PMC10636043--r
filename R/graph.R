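# Per-slice spatial neighborhood graphs and the normalized propagation
# operator A_hat = D~^(-1/2) (A + I) D~^(-1/2).

new_spatial_graph <- function(A, mode, param) {
  A <- methods::as(A, "CsparseMatrix")
  structure(
    list(A = A, A_hat = normalize_adjacency(A), mode = mode, param = param,
         N = nrow(A)),
    class = "spatial_graph"
  )
}

#' @exportS3Method base::print
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d nodes, %d undirected edges (%s, %s = %s)\n",
              x$N, Matrix::nnzero(x$A) / 2, x$mode,
              if (x$mode == "knn") "K" else "r", format(x$param)))
  invisible(x)
}

#' Build a spatial k-nearest-neighbor graph
#'
#' Directed K-NN edges by Euclidean distance (self excluded, distance ties
#' broken by lower index), then symmetrized: by union (default, edge if
#' either direction is present) or mutually (both directions required).
#'
#' @param coords numeric matrix, cells x 2.
#' @param K neighbors per cell; must satisfy `K < N`.
#' @param mutual logical; `TRUE` keeps only mutual neighbor pairs.
#' @return a `spatial_graph` with binary symmetric adjacency `A` (zero
#'   diagonal) and normalized operator `A_hat`.
#' @export
build_knn_graph <- function(coords, K = 50, mutual = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (K >= n) stop("K = ", K, " must be smaller than the number of cells (", n, ")")
  nn <- knn_indices(coords, coords, K, omit_self = TRUE)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = K), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  A <- if (mutual) A * Matrix::t(A) else A + Matrix::t(A)
  A@x[] <- 1
  A <- Matrix::drop0(A)
  Matrix::diag(A) <- 0
  new_spatial_graph(Matrix::drop0(A), "knn", K)
}

#' Build a spatial radius graph
#'
#' Edge between two cells iff `0 < distance <= r`; symmetric by construction.
#' Isolated nodes are kept with a warning (the self-loop added during
#' normalization keeps propagation defined).
#'
#' @param coords numeric matrix, cells x 2.
#' @param r neighborhood radius, `> 0`.
#' @return a `spatial_graph`.
#' @export
build_radius_graph <- function(coords, r) {
  stopifnot(r > 0)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  ij <- NULL
  chunk <- max(1L, floor(8e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- pdist2(coords[s:e, , drop = FALSE], coords)
    hits <- which(d2 <= r^2, arr.ind = TRUE)
    hits[, 1] <- hits[, 1] + s - 1L
    hits <- hits[hits[, 1] != hits[, 2], , drop = FALSE]
    ij <- rbind(ij, hits)
  }
  A <- if (is.null(ij) || nrow(ij) == 0L) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1, dims = c(n, n))
  }
  deg <- Matrix::rowSums(A)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s) at radius r = ", r)
  new_spatial_graph(A, "radius", r)
}

#' Symmetric normalization of a binary adjacency matrix
#'
#' Adds self-loops and applies the symmetric degree normalization
#' `A_hat = D~^(-1/2) (A + I) D~^(-1/2)`; the spectrum of `A_hat` lies in
#' `[-1, 1]` with largest eigenvalue exactly 1.
#'
#' @param A sparse binary symmetric matrix with zero diagonal.
#' @return sparse normalized operator.
#' @export
normalize_adjacency <- function(A) {
  At <- A + Matrix::Diagonal(nrow(A))
  dh <- 1 / sqrt(Matrix::rowSums(At))
  methods::as(Matrix::Diagonal(x = dh) %*% At %*% Matrix::Diagonal(x = dh),
              "CsparseMatrix")
}

#' Export a graph's undirected edge list as TSV
#'
#' One `i<TAB>j` pair per line (`i < j`, 0-based), sorted.
#'
#' @param g a `spatial_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  tri <- Matrix::summary(methods::as(Matrix::triu(g$A, k = 1), "TsparseMatrix"))
  tri <- tri[order(tri$i, tri$j), , drop = FALSE]
  utils::write.table(data.frame(i = tri$i - 1L, j = tri$j - 1L), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
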