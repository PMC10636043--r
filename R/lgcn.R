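# Lightweight graph convolution: parameter-free stepwise propagation of node
# features by the normalized adjacency, with all depths concatenated. The
# result encodes the cell itself (block 0), its microenvironment (block 1)
# and progressively coarser positional context (higher blocks).

#' Holistic multi-scale representation by lightweight graph convolution
#'
#' Computes `Concat(X, A_hat X, A_hat^2 X, ..., A_hat^L X)` iteratively with
#' sparse products; no learned weights, no nonlinearity, and no
#' re-standardization of the propagated blocks.
#'
#' @param A_hat sparse normalized operator from [normalize_adjacency()].
#' @param X dense numeric matrix, N x M node features.
#' @param L propagation depth, `>= 0` (default 3). `L = 0` returns `X`.
#' @return numeric matrix N x (L+1)M with attributes `L` and `M`.
#' @export
lgcn_forward <- function(A_hat, X, L = 3) {
  stopifnot(L >= 0)
  X <- as_dense(X)
  if (nrow(X) != nrow(A_hat))
    stop("dimension mismatch: ", nrow(X), " feature rows vs ",
         nrow(A_hat), " graph nodes")
  blocks <- vector("list", L + 1)
  H <- X
  blocks[[1]] <- H
  if (L > 0) {
    for (l in seq_len(L)) {
      H <- as.matrix(A_hat %*% H)
      blocks[[l + 1]] <- H
    }
  }
  out <- do.call(cbind, blocks)
  attr(out, "L") <- L
  attr(out, "M") <- ncol(X)
  out
}

#' Holistic representations for an embedding pair
#'
#' Applies [lgcn_forward()] independently per slice with a shared depth.
#'
#' @param ep embedding pair from [embed_pair()].
#' @param g1,g2 `spatial_graph` objects for the two slices.
#' @param L shared propagation depth (default 3).
#' @return list of the two holistic representations `Xt1`, `Xt2`.
#' @export
holistic_pair <- function(ep, g1, g2, L = 3) {
  stopifnot(nrow(ep$X1) == g1$N, nrow(ep$X2) == g2$N)
  list(Xt1 = lgcn_forward(g1$A_hat, ep$X1, L),
       Xt2 = lgcn_forward(g2$A_hat, ep$X2, L))
}
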