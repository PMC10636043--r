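# Probabilistic match calling: spatial candidate sets, cosine similarity in
# the alignment space, and empirical p-values against a null of randomly
# sampled cross-slice cell pairs.

#' Spatial candidate sets
#'
#' For each slice-1 cell, the K nearest slice-2 cells in the matched
#' coordinate frame (ties broken by lower index).
#'
#' @param S1 slice-1 coordinates, N1 x 2.
#' @param S2p slice-2 coordinates already transformed into slice-1's frame.
#' @param K candidate count; values above `N2` are truncated with a warning.
#' @return integer matrix N1 x K of slice-2 indices.
#' @export
candidate_set <- function(S1, S2p, K) {
  S1 <- as.matrix(S1); S2p <- as.matrix(S2p)
  if (K > nrow(S2p)) {
    warning("K = ", K, " exceeds slice-2 size; using K = ", nrow(S2p))
    K <- nrow(S2p)
  }
  knn_indices(S1, S2p, K)
}

#' Empirical null distribution of cross-slice cosine similarities
#'
#' Cosines of `n_null` uniformly sampled (with replacement) cross-slice cell
#' pairs in the alignment embedding space; shared by all cells.
#'
#' @param Z1,Z2 alignment embeddings.
#' @param n_null number of sampled pairs (default 1000).
#' @param seed RNG seed for pair sampling.
#' @return object of class `null_distribution` holding the sorted samples.
#' @export
null_distribution <- function(Z1, Z2, n_null = 1000, seed = 0) {
  set.seed(seed)
  i <- sample.int(nrow(Z1), n_null, replace = TRUE)
  j <- sample.int(nrow(Z2), n_null, replace = TRUE)
  samples <- row_cosine(Z1[i, , drop = FALSE], Z2[j, , drop = FALSE])
  structure(list(samples = sort(samples), n_null = n_null, seed = seed),
            class = "null_distribution")
}

#' Empirical exceedance p-value
#'
#' Add-one estimator `p = (#{null >= sim} + 1) / (n_null + 1)` of the
#' probability that a random cross-slice pair is at least as similar as the
#' observed one; never exactly zero, at most 1.
#'
#' @param sim cosine similarity (scalar or vector).
#' @param null a [null_distribution()].
#' @return p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(sim, null) {
  n <- null$n_null
  # exploit the sorted null: #{null >= sim} = n - #{null < sim}
  below <- findInterval(sim, null$samples, left.open = TRUE)
  (n - below + 1) / (n + 1)
}

#' Call probabilistic matches between two slices
#'
#' For each slice-1 cell: select the K spatially nearest slice-2 candidates,
#' score each by cosine similarity of the alignment embeddings, convert to
#' empirical p-values against the shared null, and accept candidates with
#' `p < threshold`. All candidate rows are returned with their acceptance
#' flag; the per-cell best match minimizes p (ties to maximal cosine).
#'
#' @param Z1,Z2 alignment embeddings.
#' @param S1 slice-1 coordinates; `S2p` slice-2 coordinates in the matched
#'   frame.
#' @param K spatial candidate count (default 50, conventionally equal to the
#'   graph neighbor count).
#' @param threshold acceptance p-value threshold (default 0.05).
#' @param n_null null sample count (default 1000).
#' @param seed seed for null-pair sampling.
#' @param best_only return only each cell's best match row.
#' @return a [match_table()] with attribute `null` (the null distribution).
#' @export
call_matches <- function(Z1, Z2, S1, S2p, K = 50, threshold = 0.05,
                         n_null = 1000, seed = 0, best_only = FALSE) {
  cand <- candidate_set(S1, S2p, K)
  K <- ncol(cand)
  n1 <- nrow(Z1)
  null <- null_distribution(Z1, Z2, n_null = n_null, seed = seed)
  src <- rep(seq_len(n1), each = K)
  tgt <- as.vector(t(cand))
  cos <- row_cosine(Z1[src, , drop = FALSE], Z2[tgt, , drop = FALSE])
  pv <- empirical_pvalue(cos, null)
  m <- match_table(src, tgt, cos, pv, threshold = threshold)
  if (best_only) m <- best_matches(m)
  attr(m, "null") <- null
  m
}

#' Best match per slice-1 cell
#'
#' The candidate with minimal p-value, ties broken by maximal cosine then
#' lower target index (the row order of [match_table()] guarantees this is
#' each source's first row).
#'
#' @param m a [match_table()].
#' @return a [match_table()] with one row per source cell.
#' @export
best_matches <- function(m) {
  keep <- !duplicated(m$source)
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(m)
  attr(out, "threshold") <- attr(m, "threshold")
  out
}

#' Per-cell alignment similarity score
#'
#' For each slice-1 cell, the maximum cosine similarity over its candidate
#' set; higher scores indicate higher alignment confidence. Cells absent
#' from the table (empty candidate sets) get `NaN`.
#'
#' @param m a [match_table()].
#' @param n1 number of slice-1 cells (default: largest source index in `m`).
#' @return numeric vector of length `n1` in `[-1, 1]` (or `NaN`).
#' @export
similarity_score <- function(m, n1 = max(m$source, 0L)) {
  score <- rep(NaN, n1)
  if (nrow(m) > 0) {
    agg <- tapply(m$cosine, m$source, max)
    score[as.integer(names(agg))] <- as.numeric(agg)
  }
  score
}
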