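# Cross-validation bookkeeping, optimizers, freezing, determinism.

test_that("folds are disjoint, covering, and balanced to within one", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  f2 <- make_folds(103, 5, seed = 2)
  expect_equal(as.vector(sort(table(f2))), c(20, 20, 21, 21, 21))
  expect_identical(make_folds(50, 5, 3), make_folds(50, 5, 3))
  expect_error(make_folds(3, 5), class = "ecgdelin_bad_arg")
})

test_that("uniform logits give cross-entropy ln(4) and L1 matches hand sums", {
  ls <- ecgdelin:::softmax_xent(matrix(0, 4, 6), rep(0:3, length.out = 6))
  expect_equal(ls$loss, log(4))
  # constant predictor against a 2-beat fixture: mean absolute deviation
  pred <- matrix(5, 8, 2)
  target <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 4, 6, 8, 10, 3, 5, 7))
  expect_equal(ecgdelin:::l1_loss(pred, target)$loss,
               mean(abs(pred - target)))
  expect_equal(ecgdelin:::l1_loss(target, target)$loss, 0)
})

test_that("Adam and SGD step in the right direction on a quadratic", {
  params <- list(w = c(2, -3))
  grad_at <- function(p) list(w = 2 * p$w)  # d/dw of sum(w^2)
  st <- ecgdelin:::adam_init(params)
  for (i in 1:200) {
    upd <- ecgdelin:::adam_step(params, grad_at(params), st, lr = 0.05)
    params <- upd$params; st <- upd$state
  }
  expect_lt(sum(abs(params$w)), 0.05)
  params <- list(w = c(2, -3))
  st <- ecgdelin:::sgd_init(params)
  for (i in 1:200) {
    upd <- ecgdelin:::sgd_step(params, grad_at(params), st,
                               lr = 0.05, momentum = 0.9)
    params <- upd$params; st <- upd$state
  }
  expect_lt(sum(abs(params$w)), 0.05)
})

test_that("pretext training is deterministic and reports per-fold accuracy", {
  beats <- tiny_beats(n = 16, len = 64)
  d <- build_pretext_dataset(beats, seed = 1)
  cfg <- tiny_config(l_net = 64, head_dim = 4, dropout = 0.2)
  f1 <- train_pretext(d, cfg, epochs = 2, batch_size = 16, folds = 2, seed = 5)
  f2 <- train_pretext(d, cfg, epochs = 2, batch_size = 16, folds = 2, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_length(f1$fold_accuracy, 2)
  expect_equal(f1$mean_accuracy, mean(f1$fold_accuracy))
  expect_s3_class(glance(f1), "tbl_df")
})

test_that("transfer freezes the backbone bit-for-bit during fine-tuning", {
  beats <- tiny_beats(n = 16, len = 64)
  d <- build_pretext_dataset(beats, seed = 1)
  cfg <- tiny_config(l_net = 64, head_dim = 4)
  pre <- train_pretext(d, cfg, epochs = 1, batch_size = 16, folds = 2, seed = 5)
  model <- transfer_and_freeze(pre, l_net = 64, head_dim = 8, seed = 6)
  x <- tiny_beats(n = 20, len = 64, seed = 7)
  y <- t(replicate(20, sort(sample(2:63, 8))))
  fit <- train_downstream(model, x, y, epochs = 5, batch_size = 8,
                          folds = 1, patience = 5, seed = 8)
  before <- ecgdelin:::backbone_params(model)
  after <- ecgdelin:::backbone_params(fit$net)
  expect_identical(before, after)
  expect_identical(model$buffers, fit$net$buffers)
  # the head did move
  expect_false(identical(model$params$head, fit$net$params$head))
  # trainable parameters = head only
  counts <- parameter_counts(model)
  expect_equal(unname(counts["total"] - counts["backbone"]),
               unname(counts["head"]))
  expect_equal(unname(counts["head"]),
               ecgdelin:::tree_n_params(model$params$head))
})

test_that("the transferred backbone really carries the pretext weights", {
  beats <- tiny_beats(n = 16, len = 64)
  d <- build_pretext_dataset(beats, seed = 1)
  cfg <- tiny_config(l_net = 64, head_dim = 4)
  pre <- train_pretext(d, cfg, epochs = 1, batch_size = 16, folds = 2, seed = 5)
  model <- transfer_and_freeze(pre, l_net = 64, head_dim = 8, seed = 6)
  expect_identical(ecgdelin:::backbone_params(model),
                   pre$checkpoint$params[setdiff(names(pre$checkpoint$params),
                                                 "head")])
  expect_equal(model$config$head_dim, 8)
  # head re-initialization is seeded
  m2 <- transfer_and_freeze(pre, l_net = 64, head_dim = 8, seed = 6)
  expect_identical(model$params$head, m2$params$head)
})

test_that("downstream training is seeded end to end", {
  beats <- tiny_beats(n = 16, len = 64)
  d <- build_pretext_dataset(beats, seed = 1)
  cfg <- tiny_config(l_net = 64, head_dim = 4)
  pre <- train_pretext(d, cfg, epochs = 1, batch_size = 16, folds = 2, seed = 5)
  model <- transfer_and_freeze(pre, l_net = 64, head_dim = 8, seed = 6)
  x <- tiny_beats(n = 20, len = 64, seed = 7)
  y <- t(replicate(20, sort(sample(2:63, 8))))
  f1 <- train_downstream(model, x, y, epochs = 3, batch_size = 8,
                         folds = 1, seed = 9)
  f2 <- train_downstream(model, x, y, epochs = 3, batch_size = 8,
                         folds = 1, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$test_pred, f2$test_pred)
  # 8:2 split bookkeeping
  expect_equal(length(f1$test_idx), round(0.2 * 20))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), length(f1$test_idx) * 8)
})
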