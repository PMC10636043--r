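# Internal helpers shared across modules.

#' Derive a module-level seed from a global seed
#'
#' Deterministic fan-out of one user-facing seed into independent per-module
#' seeds, so that e.g. the model seed and the null-distribution seed never
#' collide. The derived value is always a valid 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param label character tag naming the consumer (e.g. `"model"`, `"null"`).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # all arithmetic stays below 2^53, exact in doubles
  as.integer((abs(seed) * 69069 + h * 40503) %% 2147483646)
}

# Pairwise squared Euclidean distances between rows of a (n x d) and b (m x d).
pdist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Exact k-nearest-neighbour indices of each row of `query` among rows of
# `ref`, ties broken by lower reference index. `omit_self = TRUE` skips
# ref row i for query row i (requires conformable sets). Chunked so the
# full query-x-ref matrix is never larger than ~64M doubles.
knn_indices <- function(query, ref, k, omit_self = FALSE) {
  n <- nrow(query)
  m <- nrow(ref)
  stopifnot(k >= 1, k <= m - as.integer(omit_self))
  out <- matrix(0L, n, k)
  chunk <- max(1L, floor(8e6 / m))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- pdist2(query[s:e, , drop = FALSE], ref)
    if (omit_self) d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    if (k == 1L) {
      # vectorized arg-min; "first" resolves ties to the lower index
      out[s:e, 1L] <- max.col(-d2, ties.method = "first")
    } else {
      for (r in seq_len(e - s + 1L)) {
        # order() is stable: equal distances resolve to the lower index
        out[s + r - 1L, ] <- order(d2[r, ])[seq_len(k)]
      }
    }
  }
  out
}

# Row-wise cosine similarity between matched rows of two matrices.
row_cosine <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  ifelse(den > 0, num / den, 0)
}

# Cosine similarity between one vector and each row of a matrix.
cosine_to_rows <- function(z, M) {
  num <- as.numeric(M %*% z)
  den <- sqrt(sum(z^2)) * sqrt(rowSums(M^2))
  ifelse(den > 0, num / den, 0)
}

# 2-D counter-clockwise rotation matrix (degrees), column-vector convention.
rot2 <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Rotate row-vector coordinates about their centroid.
rotate_coords <- function(S, theta_deg, center = colMeans(S)) {
  sweep(sweep(S, 2, center) %*% t(rot2(theta_deg)), 2, center, "+")
}

# Signed angular difference a - b wrapped to (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
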