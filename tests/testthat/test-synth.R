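test_that("structured slices honor their configuration", {
  cfg <- synth_config(n_cells = 120, n_genes = 30, region_grid = c(1, 1),
                      n_types = 1, composition = matrix(1, 1, 1), seed = 50)
  s <- make_structured_slice(cfg)
  expect_equal(unique(s$cell_type), "T1")
  expect_equal(unique(s$region), "R1")
  expect_equal(dim(s$features), c(120, 30))
  expect_true(all(s$coords >= 0 & s$coords <= 1))

  # fixed seed: bit-identical regeneration
  s2 <- make_structured_slice(cfg)
  expect_identical(as.matrix(s$features), as.matrix(s2$features))
  expect_identical(s$coords, s2$coords)

  # cells land inside their region's unit block on the grid
  cfg4 <- synth_config(n_cells = 200, seed = 51)   # 2x2 grid
  s4 <- make_structured_slice(cfg4)
  r <- as.integer(sub("R", "", s4$region))
  col <- (r - 1L) %% 2L; row <- (r - 1L) %/% 2L
  expect_true(all(s4$coords[, 1] >= col & s4$coords[, 1] <= col + 1))
  expect_true(all(s4$coords[, 2] >= row & s4$coords[, 2] <= row + 1))
  # composition rows sum to 1 by construction
  expect_equal(rowSums(cfg4$composition), rep(1, 4))
})

test_that("NB sampler matches analytic moments across a (mu, theta) grid", {
  set.seed(52)
  n <- 20000
  for (mu in c(0.5, 2, 10)) {
    for (theta in c(0.5, 1, 10, 1e6)) {
      base <- spatial_slice(matrix(mu, 200, 100), matrix(runif(400), 200, 2))
      dup <- duplicate_with_noise(base, theta, rotate_deg = 0,
                                  seed = round(mu * 100 + theta %% 97))
      x <- as.numeric(dup$features)
      v_true <- mu + mu^2 / theta
      # Monte-Carlo error bounds from the sample's own moments
      se_mean <- stats::sd(x) / sqrt(n)
      m4 <- mean((x - mean(x))^4)
      se_var <- sqrt(max(m4 - stats::var(x)^2, 0) / n)
      expect_lt(abs(mean(x) - mu), 5 * se_mean)
      expect_lt(abs(stats::var(x) - v_true), 5 * se_var + 1e-9)
    }
  }
})

test_that("theta -> infinity limit is Poisson-like (variance ~ mean)", {
  cfg <- synth_config(n_cells = 300, n_genes = 60, nb_theta = 1e6, seed = 53)
  s <- make_structured_slice(cfg)
  one_type <- which(s$cell_type == "T1")
  X <- as.matrix(s$features[one_type, ])
  mu_hat <- colMeans(X)
  v_hat <- apply(X, 2, stats::var)
  keep <- mu_hat > 2
  # per-gene variance tracks the mean within 25% on average (MC noise at
  # ~100 cells per gene); the Poisson limit makes the ratio's center 1
  expect_lt(abs(mean(v_hat[keep] / mu_hat[keep]) - 1), 0.25)
})

test_that("duplicate_with_noise preserves zeros, labels and geometry", {
  s <- tiny_slice(n = 10, g = 6, seed = 54)
  s$features[1, ] <- 0
  s <- spatial_slice(s$features, s$coords, s$cell_type, s$region,
                     s$feature_names)
  dup <- duplicate_with_noise(s, theta = 1, rotate_deg = 90, seed = 55)
  expect_true(all(dup$features[1, ] == 0))       # NB(0, theta) is identically 0
  expect_equal(dup$cell_type, s$cell_type)
  # rotation preserves pairwise distances
  expect_equal(as.matrix(dist(dup$coords)), as.matrix(dist(s$coords)),
               tolerance = 1e-9)
  # rotation recovery sees the applied angle
  expect_equal(procrustes_rotation(s$coords, dup$coords)$angle_deg, 90,
               tolerance = 1e-9)
})

test_that("split_slice produces disjoint equal halves covering the slice", {
  s <- tiny_slice(n = 21, g = 5, seed = 56)
  sp <- split_slice(s, seed = 57)
  expect_equal(sort(c(sp$idx1, sp$idx2)), 1:21)
  expect_equal(length(intersect(sp$idx1, sp$idx2)), 0L)
  expect_lte(abs(length(sp$idx1) - length(sp$idx2)), 1L)
  expect_identical(split_slice(s, seed = 57)$idx1, sp$idx1)

  # label proportions of halves stay near the original (hypergeometric)
  big <- make_structured_slice(synth_config(n_cells = 400, seed = 58))
  spb <- split_slice(big, seed = 59)
  p0 <- mean(big$cell_type == "T1")
  p1 <- mean(spb$s1$cell_type == "T1")
  se <- sqrt(p0 * (1 - p0) / 200)
  expect_lt(abs(p1 - p0), 4 * se)
})

test_that("subsample_slice is uniform without replacement and seeded", {
  s <- tiny_slice(n = 15, g = 4, seed = 60)
  expect_equal(n_cells(subsample_slice(s, 15, seed = 1)), 15L)
  sub <- subsample_slice(s, 6, seed = 2)
  expect_equal(n_cells(sub), 6L)
  expect_identical(subsample_slice(s, 6, seed = 2)$coords, sub$coords)
  expect_error(subsample_slice(s, 16, seed = 1), "cannot")
  expect_error(subsample_slice(s, 0, seed = 1), "positive")
})

test_that("corrupt_graph removes the requested fraction of edges", {
  set.seed(61)
  g <- build_knn_graph(matrix(runif(60), 30, 2), K = 4)
  ne <- sum(g$A) / 2
  expect_identical(corrupt_graph(g, 0, seed = 1)$A, g$A)
  g5 <- corrupt_graph(g, 0.5, seed = 1)
  expect_equal(sum(g5$A) / 2, round(0.5 * ne), tolerance = 0.51)
  # surviving edges are a subset of the original
  expect_true(all((g$A - g5$A)@x >= 0))
  # normalization still defined even if nodes become isolated
  expect_true(all(is.finite(g5$A_hat@x)))
})
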