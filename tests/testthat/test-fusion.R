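test_that("raw alignment replicates the slice across frequency planes", {
  set.seed(20)
  s <- matrix(rnorm(3 * 125), 3)
  a <- align_raw(s, F = 125)
  expect_equal(dim(a), c(3L, 125L, 125L))
  expect_equal(a[, , 1], s)
  expect_equal(a[, , 77], s)
  expect_true(all(apply(a, c(1, 2), function(v) max(v) - min(v)) == 0))
  expect_equal(align_raw(matrix(0, 3, 125)), array(0, c(3, 125, 125)))
  expect_error(align_raw(rnorm(125)), "matrix")
})

test_that("identity/zero fusion weights pass the scalogram through exactly", {
  set.seed(21)
  tfr <- array(abs(rnorm(3 * 125 * 125)), c(3, 125, 125))
  raw <- align_raw(matrix(rnorm(3 * 125), 3))
  w <- list(tfr = list(W = diag(3), b = numeric(3)),
            raw = list(W = matrix(0, 3, 3), b = numeric(3)))
  expect_identical(fuse(tfr, raw, w), tfr)
})

test_that("bias-free fusion is linear in both views", {
  set.seed(22)
  w <- list(tfr = list(W = matrix(rnorm(9), 3), b = numeric(3)),
            raw = list(W = matrix(rnorm(9), 3), b = numeric(3)))
  tfr <- array(rnorm(3 * 20 * 20), c(3, 20, 20))
  raw <- array(rnorm(3 * 20 * 20), c(3, 20, 20))
  expect_equal(fuse(3 * tfr, 3 * raw, w), 3 * fuse(tfr, raw, w),
               tolerance = 1e-12)
})

test_that("fusion matches the per-pixel matrix oracle", {
  set.seed(23)
  w <- list(tfr = list(W = matrix(rnorm(9), 3), b = rnorm(3)),
            raw = list(W = matrix(rnorm(9), 3), b = rnorm(3)))
  tfr <- array(rnorm(3 * 125 * 125), c(3, 125, 125))
  raw <- align_raw(matrix(rnorm(3 * 125), 3))
  fast <- fuse(tfr, raw, w)
  slow <- oracle_fuse(tfr, raw, w)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-6)
  expect_error(fuse(tfr, raw[, 1:100, ], w), "share one shape")
})

test_that("pooling commutes with the 1x1 fusion map", {
  # the training path pools each view before fusing; this is exact
  set.seed(24)
  w <- fusion_weights("random")
  tfr <- array(rnorm(3 * 125 * 125), c(3, 125, 125))
  raw <- align_raw(matrix(rnorm(3 * 125), 3))
  pool <- function(a) mieeg:::pool_view_tensor(a, 5L)
  fused_then_pool <- pool(fuse(tfr, raw, w))
  pt <- pool(tfr)
  pr <- pool(raw)
  pool_then_fuse <- pt %*% t(w$tfr$W) + pr %*% t(w$raw$W)
  pool_then_fuse <- sweep(pool_then_fuse, 2, w$tfr$b + w$raw$b, `+`)
  expect_equal(fused_then_pool, pool_then_fuse, tolerance = 1e-10)
})

test_that("both fusion convolutions receive gradient when both views are live", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.8, seed = 41)
  cfg <- train_config(epochs = 1, seed = 2, dropout = 0,
                      raw_norm = "scale")
  feats <- prepare_features(ds, cfg)
  model <- mieeg_model(mieeg:::as_model_config(cfg), seed = 2,
                       n_tokens = feats$n)
  batch <- mieeg:::assemble_batch(feats, 1:4)
  fw <- mieeg:::model_forward(model, batch, feats$n, train = FALSE)
  g <- mieeg:::model_backward(model, fw, feats$labels[1:4])
  expect_gt(sum(abs(g$fus_Wt)), 0)
  expect_gt(sum(abs(g$fus_Wr)), 0)
})

test_that("freezing the raw branch reduces the model to the scalogram-only variant", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.8, seed = 42)
  cfg_f <- train_config(epochs = 1, seed = 9, dropout = 0)
  feats <- prepare_features(ds, cfg_f)
  fused <- mieeg_model(mieeg:::as_model_config(cfg_f), seed = 9,
                       n_tokens = feats$n)
  fused$params$fus_Wr[] <- 0
  fused$params$fus_br[] <- 0
  tfr_only <- fused
  tfr_only$cfg$view <- "tfr_only"
  batch <- mieeg:::assemble_batch(feats, 1:4)
  p1 <- mieeg:::model_forward(fused, batch, feats$n, train = FALSE)$probs
  p2 <- mieeg:::model_forward(tfr_only, batch, feats$n, train = FALSE)$probs
  expect_identical(p1, p2)
})
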