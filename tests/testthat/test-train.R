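test_that("a toy training run produces finite per-epoch losses", {
  ds <- toy_dataset(n_per_class = 1, erd = 0.9, seed = 50)
  fit <- train_subject(ds, train_config(epochs = 2, seed = 1))
  expect_s3_class(fit, "mieeg_fit")
  expect_length(fit$history, 2)
  expect_true(all(is.finite(fit$history)))
  expect_false(is.null(fit$model$prep))
})

test_that("single-class training sets are rejected", {
  ds <- toy_dataset(n_per_class = 2, seed = 51)
  keep <- ds$labels == "left"
  ds$trials <- ds$trials[keep]
  ds$labels <- ds$labels[keep]
  expect_error(train_subject(ds, train_config(epochs = 1)),
               "per class")
})

test_that("training is deterministic under a fixed seed", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.9, seed = 52)
  cfg <- train_config(epochs = 2, seed = 7)
  feats <- prepare_features(ds, cfg)
  f1 <- train_subject(feats, cfg)
  f2 <- train_subject(feats, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("evaluate matches a hand count of argmax predictions", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.9, seed = 53)
  cfg <- train_config(epochs = 2, seed = 3)
  fit <- train_subject(ds, cfg)
  te <- toy_dataset(n_per_class = 2, erd = 0.9, seed = 54)
  probs <- predict(fit, te)
  expect_equal(dim(probs), c(4L, 2L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-9)
  pred <- ifelse(probs[, "left"] >= probs[, "right"], "left", "right")
  expect_equal(evaluate(fit, te), mean(pred == te$labels) * 100)
  empty <- te
  empty$trials <- list()
  empty$labels <- character(0)
  expect_error(evaluate(fit, empty), "empty")
})

test_that("test-time features reuse the training-set statistics", {
  ds <- toy_dataset(n_per_class = 2, erd = 0.5, seed = 55)
  cfg <- train_config(epochs = 1, seed = 5, tfr_norm = "per_dataset",
                      raw_norm = "scale")
  fit <- train_subject(ds, cfg)
  te <- toy_dataset(n_per_class = 1, erd = 0.5, seed = 56)
  fe <- prepare_features(te, cfg, prep = fit$model$prep)
  expect_identical(fe$prep, fit$model$prep)
  # scaling the test set must not silently re-standardize it
  te_scaled <- te
  te_scaled$trials <- lapply(te$trials, function(t) {
    t$data <- 2 * t$data
    t
  })
  fe2 <- prepare_features(te_scaled, cfg, prep = fit$model$prep)
  expect_gt(max(abs(fe2$trials[[1]]$Xr)),
            max(abs(fe$trials[[1]]$Xr)) * 1.5)
})

test_that("the ablation harness tabulates every config and records failures", {
  subj <- list(
    S1 = list(train = toy_dataset(2, erd = 0.9, seed = 60),
              test = toy_dataset(2, erd = 0.9, seed = 61)))
  ok_a <- train_config(epochs = 1, seed = 1, view = "fused")
  ok_b <- train_config(epochs = 1, seed = 1, view = "tfr_only",
                       use_transformer = FALSE)
  bad <- train_config(epochs = 1, seed = 1)
  bad$backbone <- "imaginary_net"
  res <- run_ablation(subj, list(fused = ok_a, tfr_only = ok_b,
                                 broken = bad))
  expect_s3_class(res, "mieeg_ablation")
  expect_equal(res$config, c("fused", "tfr_only", "broken"))
  expect_true(all(is.finite(res$S1[1:2])))
  expect_true(all(res$S1[1:2] >= 0 & res$S1[1:2] <= 100))
  expect_true(is.na(res$S1[3]))
  fails <- attr(res, "failures")
  expect_length(fails, 1)
  expect_match(fails[["broken/S1"]], "backbone")
  expect_output(print(res), "\\+/-")
})

test_that("accuracy summary equals recomputation from per-subject entries", {
  # mean +/- sd formatting is backed by the actual column statistics
  acc <- c(71.17, 64.05, 82.30, 95.89, 90.78, 80.76, 83.57, 92.93, 78.66)
  expect_equal(round(mean(acc), 2), 82.23)
  expect_equal(round(sd(acc), 2), 10.27)
  subj <- list(
    A = list(train = toy_dataset(1, seed = 62),
             test = toy_dataset(1, seed = 63)),
    B = list(train = toy_dataset(1, seed = 64),
             test = toy_dataset(1, seed = 65)))
  res <- run_ablation(subj, list(m = train_config(epochs = 1, seed = 2)))
  expect_equal(res$mean, mean(c(res$A, res$B)))
  expect_equal(res$sd, sd(c(res$A, res$B)))
})
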