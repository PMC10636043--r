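# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs in minutes on one CPU.

# tiny labeled count slice on a unit square
tiny_slice <- function(n = 20, g = 10, seed = 42) {
  set.seed(seed)
  spatial_slice(
    features = matrix(rpois(n * g, lambda = 5), n, g),
    coords = matrix(runif(2 * n), n, 2),
    cell_type = sample(c("A", "B"), n, replace = TRUE),
    region = sample(c("r1", "r2"), n, replace = TRUE),
    feature_names = paste0("g", seq_len(g))
  )
}

# quick pipeline config: small nets and few steps, for smoke/determinism
# tests where convergence quality is irrelevant
quick_config <- function(...) {
  align_config(steps = 40, embed_hidden = 128, embed_dim = 16, svd_dim = 10,
               graph_K = 5, match_K = 5, plateau_tol = 0, ...)
}

# brute-force k-NN oracle: full double loop over pairwise distances,
# ties by lower index, union symmetrization
oracle_knn_adjacency <- function(coords, K) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    nb <- order(d)[seq_len(K)]
    A[i, nb] <- 1
  }
  pmin(A + t(A), 1)
}

# dense normalized-adjacency oracle
oracle_normalize <- function(A) {
  At <- A + diag(nrow(A))
  dh <- diag(1 / sqrt(rowSums(At)), nrow(A))
  dh %*% At %*% dh
}

# dense matrix-power LGCN oracle
oracle_lgcn <- function(A, X, L) {
  Ah <- oracle_normalize(A)
  out <- X
  H <- X
  for (l in seq_len(L)) {
    H <- Ah %*% H
    out <- cbind(out, H)
  }
  out
}
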