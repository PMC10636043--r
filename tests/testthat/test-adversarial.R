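test_that("wasserstein loss is the difference of selected means", {
  expect_equal(wasserstein_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_loss(c(1, 1), 0), 1)
  d1 <- rnorm(5); d2 <- rnorm(3)
  expect_equal(wasserstein_loss(3 * d1, 3 * d2), 3 * wasserstein_loss(d1, d2))
  expect_error(wasserstein_loss(numeric(0), 1), "empty")
})

test_that("dynamic clipping selects arg-k-min / arg-k-max with index ties", {
  sel <- dynamic_clip(c(3, 1, 2), c(0, 0, 0), c = 2 / 3)
  expect_setequal(sel$V1, c(2L, 3L))          # values 1 and 2
  sel2 <- dynamic_clip(c(0, 0), c(3, 1, 2), c = 1 / 3)
  expect_equal(sel2$V2, 1L)                   # value 3
  # c = 1 keeps everything
  sel3 <- dynamic_clip(rnorm(7), rnorm(4), c = 1)
  expect_setequal(sel3$V1, 1:7)
  expect_setequal(sel3$V2, 1:4)
  # floor with minimum 1
  sel4 <- dynamic_clip(c(5, 4), c(1, 2), c = 0.1)
  expect_equal(lengths(sel4), c(V1 = 1L, V2 = 1L))
  # ties resolve to the lower index
  sel5 <- dynamic_clip(c(7, 7, 7), c(7, 7, 7), c = 1 / 3)
  expect_equal(sel5$V1, 1L)
  expect_equal(sel5$V2, 1L)
})

test_that("dynamic clipping agrees with a brute-force sort oracle", {
  set.seed(400)
  for (trial in 1:100) {
    n1 <- sample(2:100, 1); n2 <- sample(2:100, 1)
    d1 <- rnorm(n1); d2 <- rnorm(n2)
    c <- runif(1, 0.05, 1)
    sel <- dynamic_clip(d1, d2, c)
    k1 <- max(1, floor(c * n1)); k2 <- max(1, floor(c * n2))
    expect_equal(sort(d1[sel$V1]), sort(d1)[seq_len(k1)], tolerance = 1e-12)
    expect_equal(sort(d2[sel$V2], decreasing = TRUE),
                 sort(d2, decreasing = TRUE)[seq_len(k2)], tolerance = 1e-12)
  }
})

test_that("reconstruction loss is the summed per-slice mean residual norm", {
  X <- matrix(c(1, 2), 1, 2)
  expect_equal(reconstruction_loss(X, X, X, X), 0)
  # one cell per slice, residual (3,4) each: 5 + 5 = 10
  R <- matrix(c(3, 4), 1, 2)
  Z0 <- matrix(0, 1, 2)
  expect_equal(reconstruction_loss(R, R, Z0, Z0), 10)
  expect_equal(reconstruction_loss(2 * R, 2 * R, Z0, Z0), 20)
})

test_that("one critic step increases the clipped Wasserstein loss", {
  set.seed(401)
  n <- 40; P <- 8
  Z1 <- matrix(rnorm(n * P), n, P)
  Z2 <- matrix(rnorm(n * P, mean = 0.5), n, P)
  Z <- rbind(Z1, Z2)
  fD <- slicealign:::mlp_init(P, 16, 1)
  opt <- slicealign:::adam_init(fD, lr = 1e-3)
  lw_of <- function(p) {
    d <- as.numeric(slicealign:::mlp_forward(p, Z)$Y)
    wasserstein_loss(d[1:n], d[n + 1:n])  # c = 1
  }
  before <- lw_of(fD)
  fwd <- slicealign:::mlp_forward(fD, Z)
  dY <- matrix(c(rep(1 / n, n), rep(-1 / n, n)), ncol = 1)
  grads <- slicealign:::mlp_backward(fD, fwd, dY)$grads
  up <- slicealign:::adam_step(fD, lapply(grads, function(g) -g), opt)
  expect_gt(lw_of(up$params), before)
})

test_that("self-alignment training is reproducible and aligns matched cells", {
  s <- make_structured_slice(synth_config(n_cells = 80, n_genes = 40, seed = 20))
  ep <- embed_pair(s, s, M = 8)
  g <- build_knn_graph(s$coords, K = 6)
  h <- holistic_pair(ep, g, g, L = 2)
  cfg <- train_config(embed_dim = 12, embed_hidden = 64, steps = 50,
                      plateau_tol = 0, seed = 33)
  m1 <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2, cfg)
  m2 <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2, cfg)
  expect_identical(m1$Z1, m2$Z1)   # bit-identical under a fixed seed
  expect_identical(m1$Z2, m2$Z2)
  expect_gt(mean(slicealign:::row_cosine(m1$Z1, m1$Z2)), 0.99)
  expect_equal(m1$steps_run, 50)
})

test_that("reconstruction loss trends downward over a self-alignment run", {
  s <- make_structured_slice(synth_config(n_cells = 60, n_genes = 30, seed = 21))
  ep <- embed_pair(s, s, M = 6)
  g <- build_knn_graph(s$coords, K = 5)
  h <- holistic_pair(ep, g, g, L = 2)
  m <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2,
                   train_config(embed_dim = 10, embed_hidden = 64, steps = 120,
                                plateau_tol = 0, seed = 2))
  win <- function(i) mean(m$L_R[i:(i + 19)])
  # trailing 20-step averages are non-increasing (small tolerance for noise)
  starts <- seq(1, 101, by = 20)
  avgs <- vapply(starts, win, 0)
  expect_true(all(diff(avgs) <= 1e-3))
})

test_that("no_discriminator ablation trains on reconstruction only", {
  s <- make_structured_slice(synth_config(n_cells = 50, n_genes = 30, seed = 22))
  ep <- embed_pair(s, s, M = 6)
  g <- build_knn_graph(s$coords, K = 5)
  h <- holistic_pair(ep, g, g, L = 1)
  m <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2,
                   train_config(embed_dim = 8, embed_hidden = 32, steps = 30,
                                plateau_tol = 0, seed = 3,
                                ablate = "no_discriminator"))
  expect_true(all(m$L_W == 0))
  expect_equal(ncol(m$Z1), 8)
})
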