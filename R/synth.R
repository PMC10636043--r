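# Synthetic benchmark inputs: structured slices (cell types arranged in
# spatial region blocks with negative-binomial counts), duplicate-with-noise
# slices, random splits, subsampling and graph corruption. All randomness is
# seed-controlled; the NB is parameterized by mean mu and inverse dispersion
# theta (variance mu + mu^2 / theta), sampled as a gamma-Poisson mixture via
# rnbinom(mu =, size = theta).

#' Synthetic slice configuration
#'
#' Defaults describe the smallest geometry with nontrivial type/region
#' structure: 500 cells on a 2x2 grid of unit region blocks, 4 regions,
#' 3 cell types with log-normal mean expression profiles over 200 genes,
#' and near-noiseless NB counts.
#'
#' @param n_cells total cells (default 500).
#' @param n_genes genes (default 200).
#' @param region_grid integer c(rows, cols) of unit region blocks
#'   (default c(2, 2), i.e. 4 regions).
#' @param n_types number of cell types (default 3).
#' @param composition regions x types matrix of type proportions per region
#'   (rows sum to 1). Default gives each region a distinct dominant type.
#' @param mean_log,sd_log log-normal parameters of per-type gene mean
#'   profiles (default meanlog log(2), sdlog 1, i.e. a median of 2 counts
#'   per gene and a realistic right tail).
#' @param nb_theta inverse dispersion of the generated counts (default 1e6,
#'   effectively Poisson).
#' @param rotate_deg rotation applied by [duplicate_with_noise()]
#'   (default 60).
#' @param seed RNG seed.
#' @return named list of settings.
#' @export
synth_config <- function(n_cells = 500, n_genes = 200, region_grid = c(2, 2),
                         n_types = 3, composition = NULL,
                         mean_log = log(2), sd_log = 1,
                         nb_theta = 1e6, rotate_deg = 60, seed = 0) {
  n_regions <- prod(region_grid)
  if (is.null(composition)) {
    composition <- matrix(0.15 / max(1, n_types - 1), n_regions, n_types)
    for (r in seq_len(n_regions))
      composition[r, (r - 1L) %% n_types + 1L] <- 0.85
    composition <- composition / rowSums(composition)
  }
  stopifnot(nrow(composition) == n_regions, ncol(composition) == n_types,
            all(abs(rowSums(composition) - 1) < 1e-8), nb_theta > 0)
  list(n_cells = n_cells, n_genes = n_genes, region_grid = region_grid,
       n_regions = n_regions, n_types = n_types, composition = composition,
       mean_log = mean_log, sd_log = sd_log, nb_theta = nb_theta,
       rotate_deg = rotate_deg, seed = seed)
}

#' Generate a structured synthetic slice
#'
#' Cells are placed uniformly within their region's unit block on the grid,
#' types are drawn from the region's composition row, and counts are NB
#' draws around the type's gene-mean profile.
#'
#' @param cfg configuration from [synth_config()].
#' @return a labeled `spatial_slice` with attribute `type_profiles` (the
#'   types x genes mean matrix).
#' @export
make_structured_slice <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  profiles <- matrix(stats::rlnorm(cfg$n_types * cfg$n_genes,
                                   cfg$mean_log, cfg$sd_log),
                     cfg$n_types, cfg$n_genes)
  region <- sample.int(cfg$n_regions, cfg$n_cells, replace = TRUE)
  gr <- cfg$region_grid
  block_row <- (region - 1L) %/% gr[2] # 0-based grid position
  block_col <- (region - 1L) %% gr[2]
  coords <- cbind(block_col + stats::runif(cfg$n_cells),
                  block_row + stats::runif(cfg$n_cells))
  type <- vapply(region, function(r)
    sample.int(cfg$n_types, 1, prob = cfg$composition[r, ]), 0L)
  mu <- profiles[type, , drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), size = cfg$nb_theta, mu = mu),
                   cfg$n_cells, cfg$n_genes)
  s <- spatial_slice(counts, coords,
                     cell_type = paste0("T", type),
                     region = paste0("R", region),
                     feature_names = paste0("g", seq_len(cfg$n_genes)))
  attr(s, "type_profiles") <- profiles
  s
}

#' Duplicate a slice with negative-binomial noise and rotation
#'
#' Each count is replaced by an NB draw centered at the measured value
#' (`mu` = observed count, inverse dispersion `theta`; zeros stay zero), and
#' the coordinates are rotated about their centroid. The ground-truth
#' pairing of the result to the input is the identity.
#'
#' @param s a count `spatial_slice`.
#' @param theta inverse dispersion; large values approach a Poisson, small
#'   values are very noisy.
#' @param rotate_deg rotation in degrees (default 60).
#' @param seed RNG seed.
#' @return the noisy rotated `spatial_slice`.
#' @export
duplicate_with_noise <- function(s, theta, rotate_deg = 60, seed = 0) {
  set.seed(seed)
  X <- as_dense(s$features)
  noisy <- matrix(stats::rnbinom(length(X), size = theta, mu = X),
                  nrow(X), ncol(X))
  spatial_slice(noisy, rotate_coords(s$coords, rotate_deg),
                cell_type = s$cell_type, region = s$region,
                feature_names = s$feature_names)
}

#' Randomly split a slice into two pseudo-slices
#'
#' Disjoint halves sampled without replacement (sizes differ by at most 1);
#' both halves inherit coordinates and labels.
#'
#' @param s a `spatial_slice` with at least 2 cells.
#' @param seed RNG seed.
#' @return list of two `spatial_slice` halves plus the index vectors
#'   `idx1`, `idx2` into the original slice.
#' @export
split_slice <- function(s, seed = 0) {
  n <- n_cells(s)
  stopifnot(n >= 2)
  set.seed(seed)
  perm <- sample.int(n)
  half <- ceiling(n / 2)
  idx1 <- sort(perm[seq_len(half)])
  idx2 <- sort(perm[(half + 1L):n])
  list(s1 = slice_subset(s, idx1), s2 = slice_subset(s, idx2),
       idx1 = idx1, idx2 = idx2)
}

#' Uniform subsample of a slice
#'
#' @param s a `spatial_slice`.
#' @param n cells to keep, `0 < n <= N`.
#' @param seed RNG seed.
#' @return subsampled `spatial_slice`.
#' @export
subsample_slice <- function(s, n, seed = 0) {
  N <- n_cells(s)
  if (n > N) stop("cannot subsample ", n, " cells from ", N)
  if (n < 1) stop("subsample size must be positive")
  set.seed(seed)
  slice_subset(s, sort(sample.int(N, n)))
}

#' Randomly mask graph edges
#'
#' Removes a fraction of the undirected edges uniformly at random; the
#' self-loops added during normalization are unaffected, so propagation
#' stays defined even for nodes that lose all neighbors.
#'
#' @param g a `spatial_graph`.
#' @param mask_ratio fraction of undirected edges to remove, in `[0, 1)`.
#' @param seed RNG seed.
#' @return a corrupted `spatial_graph` (mode/parameter inherited).
#' @export
corrupt_graph <- function(g, mask_ratio, seed = 0) {
  stopifnot(mask_ratio >= 0, mask_ratio < 1)
  if (mask_ratio == 0) return(g)
  tri <- Matrix::summary(methods::as(Matrix::triu(g$A, k = 1), "TsparseMatrix"))
  ne <- nrow(tri)
  set.seed(seed)
  drop <- sample.int(ne, round(mask_ratio * ne))
  keep <- tri[-drop, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(keep$i, keep$j), j = c(keep$j, keep$i),
                            x = 1, dims = dim(g$A))
  new_spatial_graph(A, g$mode, g$param)
}
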