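test_that("configuration rejects unsupported backbones and bare pretrained", {
  expect_error(model_config(backbone = "resnet18"), "unsupported backbone")
  expect_error(model_config(pretrained = TRUE), "weights_file")
  expect_error(model_config(n_heads = 5L), "divisible")
})

test_that("slice encoding has the contracted shape and is deterministic", {
  m <- mieeg_model(model_config(), seed = 4)
  set.seed(30)
  fused <- array(rnorm(3 * 125 * 125), c(3, 125, 125))
  v1 <- encode_slice(m, fused)
  v2 <- encode_slice(m, fused)
  expect_length(v1, m$cfg$d)
  expect_identical(v1, v2)
  expect_error(encode_slice(m, array(0, c(2, 125, 125))), "3 x T x F")

  # both backbones accept the same input and emit d-vectors
  mp <- mieeg_model(model_config(backbone = "plain_micro"), seed = 4)
  expect_length(encode_slice(mp, fused), mp$cfg$d)
})

test_that("saved parameter files can re-initialize a model", {
  m <- mieeg_model(model_config(), seed = 15)
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m$params, f)
  m2 <- mieeg_model(model_config(pretrained = TRUE, weights_file = f),
                    seed = 99)
  expect_identical(m2$params, m$params)
  bad <- m$params
  bad$conv1_W <- matrix(0, 2, 2)
  saveRDS(bad, f)
  expect_error(mieeg_model(model_config(pretrained = TRUE,
                                        weights_file = f), seed = 1),
               "shape mismatch")
})

test_that("attention weights are row-stochastic and a single token attends to itself", {
  set.seed(31)
  Q <- matrix(rnorm(8 * 4), 8)
  K <- matrix(rnorm(8 * 4), 8)
  V <- matrix(rnorm(8 * 4), 8)
  at <- scaled_dot_attention(Q, K, V)
  expect_equal(rowSums(at$weights), rep(1, 8), tolerance = 1e-12)
  expect_true(all(at$weights >= 0))

  one <- scaled_dot_attention(Q[1, , drop = FALSE], K[1, , drop = FALSE],
                              V[1, , drop = FALSE])
  expect_equal(as.numeric(one$weights), 1)
  expect_equal(one$output, V[1, , drop = FALSE])
})

test_that("attention matches a hand-coded oracle on a tiny fixed instance", {
  set.seed(32)
  Q <- matrix(rnorm(2 * 3), 2)
  K <- matrix(rnorm(2 * 3), 2)
  V <- matrix(rnorm(2 * 5), 2)
  fast <- scaled_dot_attention(Q, K, V)
  slow <- oracle_attention(Q, K, V)
  expect_lt(max(abs(fast$output - slow$output)), 1e-6)
  expect_lt(max(abs(fast$weights - slow$weights)), 1e-6)
})

test_that("encode_sequence exposes row-stochastic per-head attention", {
  m <- mieeg_model(model_config(), seed = 33)
  set.seed(33)
  M <- matrix(rnorm(32 * 8), 32)
  res <- encode_sequence(m, M, collect_weights = TRUE)
  expect_equal(dim(res$context), c(32L, 8L))
  for (l in seq_along(res$weights)) {
    for (A in res$weights[[l]]) {
      expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-9)
    }
  }
  expect_error(encode_sequence(m, M[1:10, ]), "rows")
})

test_that("without positional encodings the pooled sequence code is permutation invariant", {
  m <- mieeg_model(model_config(positional_encoding = "none"), seed = 34)
  set.seed(34)
  M <- matrix(rnorm(32 * 8), 32)
  perm <- sample(8)
  c1 <- encode_sequence(m, M)
  c2 <- encode_sequence(m, M[, perm])
  expect_equal(rowMeans(c2), rowMeans(c1), tolerance = 1e-9)
  expect_equal(c2, c1[, perm], tolerance = 1e-9)  # equivariance
  # with sinusoidal positions invariance must break
  ms <- mieeg_model(model_config(), seed = 34)
  expect_gt(max(abs(rowMeans(encode_sequence(ms, M[, perm])) -
                      rowMeans(encode_sequence(ms, M)))), 1e-6)
})

test_that("classification probabilities live on the simplex", {
  m <- mieeg_model(model_config(), seed = 35)
  set.seed(35)
  ctx <- matrix(rnorm(32 * 8), 32)
  pr <- classify(m, ctx)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_named(pr, c("left", "right"))
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  expect_equal(unname(classify(m, ctx)), c(0.5, 0.5))
})

test_that("cross-entropy has its closed-form values and per-sample oracle", {
  expect_equal(cross_entropy_loss(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                  c("left", "right")), 0)
  uni <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(uni, c("left", "right", "left", "right")),
               log(2), tolerance = 1e-12)
  set.seed(36)
  p1 <- runif(6, 0.01, 0.99)
  pred <- cbind(p1, 1 - p1)
  labs <- sample(c("left", "right"), 6, replace = TRUE)
  manual <- -mean(vapply(1:6, function(i) {
    log(pred[i, if (labs[i] == "left") 1 else 2])
  }, numeric(1)))
  expect_equal(cross_entropy_loss(pred, labs), manual, tolerance = 1e-12)
  expect_error(cross_entropy_loss(uni, c("left", "up", "left", "right")),
               "labels")
})

test_that("analytic gradients agree with central finite differences", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.9, seed = 37)
  cfg <- train_config(epochs = 1, seed = 11, dropout = 0)
  feats <- prepare_features(ds, cfg)
  model <- mieeg_model(mieeg:::as_model_config(cfg), seed = 11,
                       n_tokens = feats$n)
  batch <- mieeg:::assemble_batch(feats, 1:4)
  labels <- feats$labels[1:4]
  fw <- mieeg:::model_forward(model, batch, feats$n, train = FALSE)
  grads <- mieeg:::model_backward(model, fw, labels)
  loss_at <- function(m) {
    f <- mieeg:::model_forward(m, batch, feats$n, train = FALSE)
    cross_entropy_loss(f$probs, labels)
  }
  set.seed(37)
  h <- 1e-5
  for (nm in names(model$params)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    i <- sample(length(model$params[[nm]]), 1)
    up <- model
    up$params[[nm]][i] <- up$params[[nm]][i] + h
    dn <- model
    dn$params[[nm]][i] <- dn$params[[nm]][i] - h
    fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
    an <- as.numeric(grads[[nm]])[i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 5e-3,
              label = paste("rel grad err at", nm))
  }
})

test_that("dropping the Transformer reduces to mean-pooled slice features", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.8, seed = 38)
  cfg <- train_config(epochs = 1, seed = 21, dropout = 0,
                      use_transformer = FALSE)
  feats <- prepare_features(ds, cfg)
  m <- mieeg_model(mieeg:::as_model_config(cfg), seed = 21,
                   n_tokens = feats$n)
  batch <- mieeg:::assemble_batch(feats, 1:2)
  fw <- mieeg:::model_forward(m, batch, feats$n, train = FALSE)
  # manual route: per-slice embeddings -> temporal mean -> head softmax
  M <- fw$M
  pooled <- colMeans(M[1:feats$n, , drop = FALSE])
  logits <- drop(pooled %*% m$params$head_W) + m$params$head_b
  manual <- exp(logits - max(logits))
  manual <- manual / sum(manual)
  expect_equal(unname(fw$probs[1, ]), unname(manual), tolerance = 1e-12)
})
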