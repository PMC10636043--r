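test_that("lognorm_scale matches hand-computed z-scores", {
  # single cell: centering one sample gives all zeros
  s1 <- spatial_slice(matrix(c(2, 2), 1, 2), matrix(0, 1, 2))
  expect_equal(lognorm_scale(s1, target_sum = 4), matrix(0, 1, 2))

  # two cells [[4,0],[0,4]], target 4: normalization is a no-op, log1p then
  # per-feature z-score (population denominator) gives +/- 1 exactly
  s2 <- spatial_slice(rbind(c(4, 0), c(0, 4)), matrix(0:3, 2, 2))
  G <- lognorm_scale(s2, target_sum = 4)
  expect_equal(G, rbind(c(1, -1), c(-1, 1)), tolerance = 1e-12)

  # all-zero cell is an error unless filtered first
  s3 <- spatial_slice(rbind(c(0, 0), c(1, 1)), matrix(0:3, 2, 2))
  expect_error(lognorm_scale(s3), "filter_min_counts")

  # scaled values are clipped
  set.seed(1)
  X <- matrix(rpois(300, 3), 30, 10); X[1, 1] <- 10000
  s4 <- spatial_slice(X, matrix(runif(60), 30, 2))
  expect_lte(max(abs(lognorm_scale(s4, scale_clip = 3))), 3)
})

test_that("shared_features intersects in stable order", {
  mk <- function(names) spatial_slice(matrix(seq_len(2 * length(names)), 2),
                                      matrix(0:3, 2, 2), feature_names = names)
  sh <- shared_features(mk(c("a", "b", "c")), mk(c("b", "c", "d")))
  expect_equal(sh[[1]]$feature_names, c("b", "c"))
  expect_equal(sh[[2]]$feature_names, c("b", "c"))
  expect_equal(as.matrix(sh[[1]]$features), matrix(c(3, 4, 5, 6), 2))

  same <- shared_features(mk(c("a", "b")), mk(c("a", "b")))
  expect_equal(as.matrix(same[[1]]$features), matrix(1:4, 2))

  expect_error(shared_features(mk(c("a", "b")), mk(c("x", "y"))),
               "cross-modality|embedding")
})

test_that("svd_embed equals the full-SVD truncation oracle", {
  set.seed(7)
  G1 <- matrix(rnorm(8 * 6), 8, 6)
  G2 <- matrix(rnorm(5 * 6), 5, 6)
  M <- 3
  ep <- svd_embed(G1, G2, M = M)

  # oracle: dense SVD of the explicit cross-product
  sv <- svd(G1 %*% t(G2))
  oracle <- sv$u[, 1:M] %*% diag(sv$d[1:M]) %*% t(sv$v[, 1:M])
  expect_equal(ep$X1 %*% t(ep$X2), oracle, tolerance = 1e-9)

  # per-component column norms of X1 and X2 agree (both carry Sigma^1/2)
  expect_equal(colSums(ep$X1^2), colSums(ep$X2^2), tolerance = 1e-9)

  # identical inputs: symmetric PSD product has U = V up to the shared sign fix
  eps <- svd_embed(G1, G1, M = M)
  expect_equal(eps$X1, eps$X2, tolerance = 1e-9)

  # joint orthogonal rotation of the feature axes leaves the product unchanged
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  epq <- svd_embed(G1 %*% Q, G2 %*% Q, M = M)
  expect_equal(epq$X1, ep$X1, tolerance = 1e-9)
  expect_equal(epq$X2, ep$X2, tolerance = 1e-9)

  # M above the attainable rank shrinks with a warning
  expect_warning(svd_embed(G1[1:2, ], G2, M = 4), "rank")

  # determinism: repeated calls bit-identical
  expect_identical(svd_embed(G1, G2, M = M)$X1, ep$X1)
})

test_that("embed_pair dispatches on input provenance", {
  s1 <- tiny_slice(n = 15, g = 8, seed = 3)
  s2 <- tiny_slice(n = 12, g = 8, seed = 4)
  ep <- embed_pair(s1, s2, M = 5)
  expect_equal(ep$provenance, "svd")
  expect_equal(ncol(ep$X1), 5)

  e1 <- spatial_slice(matrix(rnorm(15 * 7), 15, 7), s1$coords, is_embedding = TRUE)
  e2 <- spatial_slice(matrix(rnorm(12 * 7), 12, 7), s2$coords, is_embedding = TRUE)
  epe <- embed_pair(e1, e2)
  expect_equal(epe$provenance, "external")
  expect_equal(epe$M, 7)

  expect_error(embed_pair(s1, e2), "mixed")
})

test_that("optional hvg flag restricts the coupling to top-variance genes", {
  s1 <- tiny_slice(n = 20, g = 12, seed = 8)
  s2 <- tiny_slice(n = 18, g = 12, seed = 9)
  ep_all <- embed_pair(s1, s2, M = 4)
  ep_hvg <- embed_pair(s1, s2, M = 4, hvg = 6)
  expect_equal(ncol(ep_hvg$X1), 4)
  # a different gene set changes the coupling
  expect_false(isTRUE(all.equal(ep_all$X1, ep_hvg$X1)))
  # hvg >= G is a no-op
  expect_equal(embed_pair(s1, s2, M = 4, hvg = 12)$X1, ep_all$X1)
})

test_that("duplicated slices embed almost identically as noise vanishes", {
  s <- make_structured_slice(synth_config(n_cells = 200, seed = 5))
  # exact duplicate (only rotated): matched rows coincide up to 1
  s_copy <- spatial_slice(s$features, slicealign:::rotate_coords(s$coords, 30),
                          feature_names = s$feature_names)
  ep0 <- embed_pair(s, s_copy, M = 10)
  expect_gt(mean(slicealign:::row_cosine(ep0$X1, ep0$X2)), 1 - 1e-9)
  # theta = 1e6 is the Poisson limit of the noise model (variance = mu, not
  # zero), so matched-row cosine approaches but does not reach 1
  s2 <- duplicate_with_noise(s, theta = 1e6, rotate_deg = 0, seed = 6)
  ep <- embed_pair(s, s2, M = 10)
  expect_gt(mean(slicealign:::row_cosine(ep$X1, ep$X2)), 0.95)
})
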