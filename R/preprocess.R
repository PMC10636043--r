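# Batch-corrected shared embeddings for two slices.
#
# Counts are library-size normalized, log1p-transformed and z-scored per
# feature, then the two scaled matrices are coupled through an SVD of their
# cross-product G1 %*% t(G2) = U S V'; the slice embeddings are the leading
# M columns of U S^(1/2) and V S^(1/2). The cross-product is never
# materialized: both matrices are QR-factored and the SVD is taken of the
# small R1 %*% t(R2) core, which gives the identical truncation.

#' Log-normalize and scale a count matrix
#'
#' Each cell is scaled to `target_sum` total counts, `log1p` is applied, and
#' each feature is centered and scaled to unit variance (population `n`
#' denominator). Zero-variance features become all-zero columns. Scaled
#' values are clipped at `± scale_clip`.
#'
#' @param s a `spatial_slice` with raw counts (`is_embedding = FALSE`).
#' @param target_sum per-cell total after normalization (default `1e4`).
#' @param scale_clip clip bound for scaled values (default 10).
#' @param min_counts cells with total counts below this are an error here;
#'   filter first with [filter_min_counts()] (default 1).
#' @return dense numeric matrix, cells x features.
#' @export
lognorm_scale <- function(s, target_sum = 1e4, scale_clip = 10, min_counts = 1) {
  stopifnot(!s$is_embedding)
  X <- as_dense(s$features)
  tot <- rowSums(X)
  if (any(tot < min_counts))
    stop("all-zero (or below min_counts) cell encountered; ",
         "apply filter_min_counts() before normalization")
  X <- log1p(X * (target_sum / tot))
  mu <- colMeans(X)
  sd_n <- sqrt(colMeans(X^2) - mu^2)  # population (n) denominator
  X <- sweep(X, 2, mu)
  nz <- sd_n > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, sd_n[nz], "/")
  X[, !nz] <- 0
  X[X > scale_clip] <- scale_clip
  X[X < -scale_clip] <- -scale_clip
  X
}

#' Restrict two slices to their shared features
#'
#' @param s1,s2 `spatial_slice` objects with feature names.
#' @return list of the two slices restricted to the intersection, in the
#'   same column order.
#' @export
shared_features <- function(s1, s2) {
  common <- intersect(s1$feature_names, s2$feature_names)
  if (length(common) == 0L)
    stop("no overlapping features between the slices; for disjoint feature ",
         "spaces supply precomputed embeddings (is_embedding = TRUE) instead")
  take <- function(s) {
    idx <- match(common, s$feature_names)
    spatial_slice(s$features[, idx, drop = FALSE], s$coords,
                  cell_type = s$cell_type, region = s$region,
                  feature_names = common, is_embedding = s$is_embedding)
  }
  list(take(s1), take(s2))
}

#' SVD embedding of two scaled matrices
#'
#' Computes the truncated SVD of `G1t %*% t(G2t)` and returns
#' `X1 = U[,1:M] S^(1/2)`, `X2 = V[,1:M] S^(1/2)`. The sign of each singular
#' vector pair is fixed by forcing the largest-magnitude entry of each left
#' vector positive, so repeated calls are bit-identical.
#'
#' @param G1t,G2t scaled matrices, `N1 x G` and `N2 x G` (same `G`).
#' @param M embedding dimensionality (default 30); shrunk with a warning if
#'   it exceeds the available rank.
#' @return list with `X1`, `X2`, `M`, `d` (singular values) and
#'   `provenance = "svd"`.
#' @export
svd_embed <- function(G1t, G2t, M = 30) {
  stopifnot(ncol(G1t) == ncol(G2t))
  G1t <- as_dense(G1t); G2t <- as_dense(G2t)
  rmax <- min(nrow(G1t), nrow(G2t), ncol(G1t))
  if (M > rmax) {
    warning("svd_embed: M = ", M, " exceeds attainable rank ", rmax,
            "; shrinking")
    M <- rmax
  }
  # QR route: G1 = Q1 R1, G2 = Q2 R2  =>  G1 G2' = Q1 (R1 R2') Q2'
  if (ncol(G1t) < min(nrow(G1t), nrow(G2t))) {
    q1 <- qr(G1t); q2 <- qr(G2t)
    R1 <- qr.R(q1); R2 <- qr.R(q2)
    core <- svd(tcrossprod(R1, R2), nu = M, nv = M)
    U <- qr.Q(q1) %*% core$u
    V <- qr.Q(q2) %*% core$v
    d <- core$d
  } else {
    sv <- svd(tcrossprod(G1t, G2t), nu = M, nv = M)
    U <- sv$u; V <- sv$v; d <- sv$d
  }
  d <- d[seq_len(M)]
  # deterministic sign convention
  for (k in seq_len(M)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  sq <- sqrt(pmax(d, 0))
  list(X1 = sweep(U, 2, sq, "*"), X2 = sweep(V, 2, sq, "*"),
       M = M, d = d, provenance = "svd")
}

#' Batch-corrected embedding pair for two slices
#'
#' For count slices: shared features, per-slice log-normalize/scale, then
#' [svd_embed()]. For precomputed-embedding slices (both must be): pass
#' through with `provenance = "external"`.
#'
#' @param s1,s2 `spatial_slice` objects.
#' @param M SVD dimensionality (default 30); ignored for external embeddings.
#' @param target_sum,scale_clip see [lognorm_scale()].
#' @param hvg `0` (default) uses all shared features; a positive integer
#'   restricts to the top-n features by pooled log-normalized variance
#'   before scaling. Off by default because the core coupling uses the full
#'   scaled matrices.
#' @return list with `X1`, `X2`, `M`, `provenance`.
#' @export
embed_pair <- function(s1, s2, M = 30, target_sum = 1e4, scale_clip = 10,
                       hvg = 0) {
  if (s1$is_embedding || s2$is_embedding) {
    if (!(s1$is_embedding && s2$is_embedding))
      stop("mixed input: one slice has precomputed embeddings and the other ",
           "raw counts; supply embeddings for both or counts for both")
    X1 <- as_dense(s1$features); X2 <- as_dense(s2$features)
    if (ncol(X1) != ncol(X2))
      stop("external embeddings must share dimensionality")
    return(list(X1 = X1, X2 = X2, M = ncol(X1), provenance = "external"))
  }
  sh <- shared_features(s1, s2)
  if (hvg > 0 && hvg < length(sh[[1]]$feature_names)) {
    lognorm <- function(s) {
      X <- as_dense(s$features)
      log1p(X * (target_sum / rowSums(X)))
    }
    v <- apply(lognorm(sh[[1]]), 2, stats::var) +
      apply(lognorm(sh[[2]]), 2, stats::var)
    top <- sort(order(v, decreasing = TRUE)[seq_len(hvg)])
    sh <- lapply(sh, function(s)
      spatial_slice(s$features[, top, drop = FALSE], s$coords,
                    cell_type = s$cell_type, region = s$region,
                    feature_names = s$feature_names[top]))
  }
  G1t <- lognorm_scale(sh[[1]], target_sum = target_sum, scale_clip = scale_clip)
  G2t <- lognorm_scale(sh[[2]], target_sum = target_sum, scale_clip = scale_clip)
  svd_embed(G1t, G2t, M = M)
}
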