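# Pretext training, transfer with a frozen convolutional backbone, and
# downstream fine-tuning of the fully connected head.

#' Assign samples to cross-validation folds
#'
#' Deterministic given `seed`; folds are disjoint, cover all indices, and
#' their sizes differ by at most one.
#'
#' @param n Number of samples (>= `k`).
#' @param k Number of folds.
#' @param seed Integer seed.
#'
#' @return Integer vector of length `n` with fold ids in `1..k`.
#' @export
#' @examples
#' table(make_folds(103, 5, seed = 1))
make_folds <- function(n, k = 5, seed = 1L) {
  if (n < k) stop_ecg("need at least as many samples as folds.", "bad_arg")
  with_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    fold
  })
}

# ---- optimizers over parameter trees ---------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, st$v, grads)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, st$m, st$v)
  list(params = params, state = st)
}

sgd_init <- function(params) list(vel = tree_zeros_like(params))

sgd_step <- function(params, grads, st, lr = 1e-3, momentum = 0.9) {
  st$vel <- tree_map(function(v, g) momentum * v - lr * g, st$vel, grads)
  params <- tree_map(function(p, v) p + v, params, st$vel)
  list(params = params, state = st)
}

# ---- pretext task ----------------------------------------------------------

#' Train the transformation-recognition pretext task
#'
#' K-fold cross-validation with cross-entropy loss and the Adam optimizer.
#' Each fold trains a freshly initialized network on the remaining folds and
#' validates on the held-out one, with early stopping on validation loss.
#' The reported accuracy is the mean of the per-fold best accuracies, and
#' the checkpoint comes from the fold with the lowest validation loss.
#'
#' @param dataset A [build_pretext_dataset()] result.
#' @param config A [net_config()] with `head_dim = 4`; its `l_net` must match
#'   the pretext signal length.
#' @param epochs Maximum epochs per fold.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param folds Number of cross-validation folds.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling folds, initialization, shuffling and
#'   dropout.
#' @param verbose Print per-epoch progress.
#'
#' @return Object of class `pretext_fit`: list with `checkpoint` (params,
#'   buffers, config of the best fold), `fold_accuracy`, `mean_accuracy` and
#'   `history` (tibble of per-fold, per-epoch losses).
#' @export
train_pretext <- function(dataset, config, epochs = 8, batch_size = 32,
                          lr = 1e-3, folds = 5, patience = 10, seed = 1L,
                          verbose = FALSE) {
  x <- dataset$x
  y <- dataset$label
  n <- nrow(x)
  stopifnot(ncol(x) == config$l_net, config$head_dim == 4)
  fold_id <- make_folds(n, folds, seed)
  best_overall <- NULL
  fold_acc <- numeric(folds)
  hist <- list()
  for (f in seq_len(folds)) {
    tr_idx <- which(fold_id != f)
    va_idx <- which(fold_id == f)
    net <- init_network(config, seed = derive_seed(seed, 100 + f))
    st <- adam_init(net$params)
    best <- list(loss = Inf, acc = 0, params = net$params, buffers = net$buffers)
    wait <- 0L
    set.seed(derive_seed(seed, 200 + f))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- beats_to_tensor(x[idx, , drop = FALSE])
        fw <- network_fw(net, xb, train = TRUE)
        net$buffers <- fw$buffers
        ls <- softmax_xent(fw$out, y[idx])
        if (!is.finite(ls$loss)) {
          stop_ecg("non-finite pretext loss; aborting.", "diverged")
        }
        bw <- network_bw(net, fw$cache, ls$dlogits)
        upd <- adam_step(net$params, bw$grads, st, lr = lr)
        net$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      va <- evaluate_pretext(net, x[va_idx, , drop = FALSE], y[va_idx])
      hist[[length(hist) + 1]] <- tibble(fold = f, epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = va$loss, val_acc = va$acc)
      if (verbose) {
        message(sprintf("fold %d epoch %d train %.4f val %.4f acc %.3f",
                        f, ep, ep_loss / nb, va$loss, va$acc))
      }
      if (va$loss < best$loss - 1e-6) {
        best <- list(loss = va$loss, acc = va$acc, params = net$params,
                     buffers = net$buffers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    fold_acc[f] <- best$acc
    if (is.null(best_overall) || best$loss < best_overall$loss) {
      best_overall <- best
    }
  }
  structure(
    list(checkpoint = list(params = best_overall$params,
                           buffers = best_overall$buffers, config = config),
         fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
         history = dplyr::bind_rows(hist)),
    class = "pretext_fit"
  )
}

evaluate_pretext <- function(net, xmat, y, batch_size = 128) {
  n <- nrow(xmat)
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- network_fw(net, beats_to_tensor(xmat[idx, , drop = FALSE]),
                     train = FALSE)
    ls <- softmax_xent(fw$out, y[idx])
    loss <- loss + ls$loss * length(idx)
    correct <- correct + sum(ls$pred == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' @export
print.pretext_fit <- function(x, ...) {
  cat("<pretext_fit> mean CV accuracy ", sprintf("%.3f", x$mean_accuracy),
      " over ", length(x$fold_accuracy), " folds\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pretext_fit <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy,
         n_folds = length(x$fold_accuracy),
         best_fold_accuracy = max(x$fold_accuracy))
}

#' @exportS3Method generics::tidy
tidy.pretext_fit <- function(x, ...) x$history

# ---- transfer --------------------------------------------------------------

#' Transfer pretext weights and freeze the convolutional backbone
#'
#' Copies every convolutional and batch-norm parameter (stem, dense blocks,
#' attention modules, transitions, neck) plus the batch-norm running
#' statistics from the checkpoint, re-initializes all fully connected layers
#' with He initialization, and marks the backbone frozen: subsequent
#' fine-tuning updates only the head and leaves backbone weights and
#' statistics bit-identical.
#'
#' @param fit A `pretext_fit` or its `checkpoint`.
#' @param l_net Input length of the downstream task (default 324). The
#'   backbone is length-agnostic; only the head's flatten widths depend on
#'   it.
#' @param head_dim Output dimension of the new head (8 landmarks).
#' @param seed Seed for the He draws of the head.
#'
#' @return Object of class `ecg_network` with attribute `frozen = "backbone"`.
#' @export
transfer_and_freeze <- function(fit, l_net = 324, head_dim = 8, seed = 1L) {
  ckpt <- if (inherits(fit, "pretext_fit")) fit$checkpoint else fit
  cfg <- ckpt$config
  cfg$l_net <- l_net
  cfg$head_dim <- head_dim
  params <- ckpt$params
  params$head <- with_seed(seed, init_head(cfg))
  net <- structure(list(params = params, buffers = ckpt$buffers, config = cfg),
                   class = "ecg_network")
  attr(net, "frozen") <- "backbone"
  net
}

backbone_params <- function(net) {
  net$params[setdiff(names(net$params), "head")]
}

#' Number of trainable (head) parameters of a frozen-backbone model
#' @param net An `ecg_network`.
#' @return Named vector with `head`, `backbone` and `total` counts.
#' @export
parameter_counts <- function(net) {
  head_n <- tree_n_params(net$params$head)
  total <- tree_n_params(net$params)
  c(head = head_n, backbone = total - head_n, total = total)
}

# ---- downstream task -------------------------------------------------------

# Head-only forward/backward on cached backbone features.
head_train_fw <- function(net, feat, train) {
  dp <- dropout_fw(feat, net$config$dropout, train)
  hd <- head_fw(net$params$head, dp$out)
  list(out = hd$out, cache = list(drop = dp$cache, head = hd$cache))
}

head_train_bw <- function(net, cache, dout) {
  hb <- head_bw(net$params$head, cache$head, dout)
  hb$grads
}

#' Fine-tune (or train from scratch) the landmark regressor
#'
#' Splits beats 8:2 into a training portion and a held-out test set, runs
#' k-fold cross-validation inside the training portion with SGD (fixed
#' learning rate, momentum) on the L1 loss, early-stops each fold on
#' validation L1, and returns the best fold's model together with held-out
#' predictions. When the model's backbone is frozen (see
#' [transfer_and_freeze()]) only the fully connected head is updated --
#' backbone activations are computed once and reused -- and batch-norm
#' statistics stay fixed. Otherwise the whole network trains.
#'
#' Positions are regressed on a normalized scale (position / input length)
#' internally; all reported losses are converted back to resampled samples.
#'
#' @param net An `ecg_network` (frozen-backbone from [transfer_and_freeze()],
#'   or fresh from [init_network()] for a fully supervised baseline).
#' @param x Beats matrix (n x `l_net`).
#' @param y Integer matrix (n x 8) of label positions (1-based, resampled
#'   coordinates).
#' @param epochs Maximum epochs per fold.
#' @param batch_size Minibatch size.
#' @param lr,momentum SGD hyperparameters.
#' @param test_frac Held-out fraction (default 0.2).
#' @param folds Folds within the training portion.
#' @param patience Early-stopping patience.
#' @param seed Integer seed.
#' @param verbose Print progress.
#'
#' @return Object of class `delineation_fit`: list with `net` (best model),
#'   `history`, `val_l1` (best validation L1, resampled samples),
#'   `test_idx`, `test_pred` (matrix of held-out predictions, 1-based
#'   positions), `test_truth`, and `test_mae` (per-point MAE, samples).
#' @export
train_downstream <- function(net, x, y, epochs = 60, batch_size = 32,
                             lr = 0.001, momentum = 0.9, test_frac = 0.2,
                             folds = 5, patience = 10, seed = 1L,
                             verbose = FALSE) {
  n <- nrow(x)
  l_net <- net$config$l_net
  stopifnot(ncol(x) == l_net, ncol(y) == 8, net$config$head_dim == 8)
  frozen <- identical(attr(net, "frozen"), "backbone")
  yt <- t((y - 1) / l_net)                     # (8, n) normalized targets
  test_idx <- with_seed(derive_seed(seed, 7),
                        sort(sample.int(n, size = round(test_frac * n))))
  train_pool <- setdiff(seq_len(n), test_idx)
  # fixed 5-way partition of the training portion; `folds` says how many of
  # the five CV iterations to run (1 = a single 80/20 validation split)
  fold_id <- make_folds(length(train_pool), 5, derive_seed(seed, 11))
  folds <- min(folds, 5)

  feat <- if (frozen) backbone_features(net, x) else NULL

  run_epoch_eval <- function(cur, idx) {
    if (frozen) {
      fw <- head_train_fw(cur, feat[, , idx, drop = FALSE], train = FALSE)
      out <- fw$out
    } else {
      out <- t(predict(cur, x[idx, , drop = FALSE]))
    }
    mean(abs(out - yt[, idx, drop = FALSE])) * l_net
  }

  best_overall <- NULL
  hist <- list()
  for (f in seq_len(folds)) {
    va_idx <- train_pool[fold_id == f]
    tr_idx <- train_pool[fold_id != f]
    cur <- net
    st <- sgd_init(if (frozen) cur$params$head else cur$params)
    best <- list(l1 = Inf, params = cur$params, buffers = cur$buffers)
    wait <- 0L
    set.seed(derive_seed(seed, 300 + f))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        target <- yt[, idx, drop = FALSE]
        if (frozen) {
          fw <- head_train_fw(cur, feat[, , idx, drop = FALSE], train = TRUE)
          ls <- l1_loss(fw$out, target)
          grads <- head_train_bw(cur, fw$cache, ls$dpred)
          upd <- sgd_step(cur$params$head, grads, st, lr = lr,
                          momentum = momentum)
          cur$params$head <- upd$params
        } else {
          xb <- beats_to_tensor(x[idx, , drop = FALSE])
          fw <- network_fw(cur, xb, train = TRUE)
          cur$buffers <- fw$buffers
          ls <- l1_loss(fw$out, target)
          bw <- network_bw(cur, fw$cache, ls$dpred)
          upd <- sgd_step(cur$params, bw$grads, st, lr = lr,
                          momentum = momentum)
          cur$params <- upd$params
        }
        if (!is.finite(ls$loss)) {
          stop_ecg("non-finite downstream loss; aborting.", "diverged")
        }
        st <- upd$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      val_l1 <- run_epoch_eval(cur, va_idx)
      hist[[length(hist) + 1]] <- tibble(fold = f, epoch = ep,
                                         train_l1 = ep_loss / nb * l_net,
                                         val_l1 = val_l1)
      if (verbose) {
        message(sprintf("fold %d epoch %d train %.2f val %.2f (samples)",
                        f, ep, ep_loss / nb * l_net, val_l1))
      }
      if (val_l1 < best$l1 - 1e-9) {
        best <- list(l1 = val_l1, params = cur$params, buffers = cur$buffers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    if (is.null(best_overall) || best$l1 < best_overall$l1) {
      best_overall <- best
    }
  }

  final <- net
  final$params <- best_overall$params
  final$buffers <- best_overall$buffers
  test_pred <- predict_positions(final, x[test_idx, , drop = FALSE])
  test_truth <- y[test_idx, , drop = FALSE]
  mae <- colMeans(abs(test_pred - test_truth))
  names(mae) <- fiducial_names()
  structure(
    list(net = final, history = dplyr::bind_rows(hist),
         val_l1 = best_overall$l1, test_idx = test_idx,
         test_pred = test_pred, test_truth = test_truth, test_mae = mae),
    class = "delineation_fit"
  )
}

#' Predicted landmark positions for a matrix of beats
#'
#' @param net A trained `ecg_network` with the landmark head.
#' @param x Beats matrix (n x `l_net`).
#' @return Matrix (n x 8) of continuous positions in 1-based resampled
#'   sample coordinates.
#' @export
predict_positions <- function(net, x) {
  out <- predict(net, x)
  pos <- out * net$config$l_net + 1
  colnames(pos) <- fiducial_names()
  pos
}

#' @export
print.delineation_fit <- function(x, ...) {
  cat("<delineation_fit> best val L1 ", sprintf("%.2f", x$val_l1),
      " samples; held-out MAE ", sprintf("%.2f", mean(x$test_mae)),
      " samples\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.delineation_fit <- function(x, ...) {
  tibble(val_l1 = x$val_l1, test_mae = mean(x$test_mae),
         n_test = length(x$test_idx), epochs_run = max(x$history$epoch))
}

#' @exportS3Method generics::tidy
tidy.delineation_fit <- function(x, ...) {
  tibble(
    beat = rep(x$test_idx, times = 8),
    point = rep(fiducial_names(), each = length(x$test_idx)),
    truth = as.vector(x$test_truth),
    pred = as.vector(x$test_pred)
  )
}

#' Compare self-supervised initialization against training from scratch
#'
#' Runs the downstream task twice per seed under the same epoch budget and
#' optimizer: once from the pretext checkpoint with a frozen backbone, once
#' from He initialization training the whole network. Reports the best
#' validation L1 (resampled samples) of each arm.
#'
#' @param checkpoint A `pretext_fit` or checkpoint to transfer from.
#' @param x,y Beats and labels as in [train_downstream()].
#' @param seeds Integer vector of run seeds; the median over seeds is the
#'   headline comparison.
#' @param epochs,batch_size,lr,momentum Shared training budget.
#' @param folds Validation folds per arm (1 fold = single split).
#'
#' @return Tibble with columns `seed`, `arm`, `val_l1`, `test_mae`.
#' @export
compare_ssl_vs_scratch <- function(checkpoint, x, y, seeds = c(1, 2, 3),
                                   epochs = 25, batch_size = 32, lr = 0.001,
                                   momentum = 0.9, folds = 1) {
  l_net <- ncol(x)
  ckpt <- if (inherits(checkpoint, "pretext_fit")) checkpoint$checkpoint else checkpoint
  rows <- list()
  for (s in seeds) {
    ssl_net <- transfer_and_freeze(ckpt, l_net = l_net, head_dim = 8,
                                   seed = derive_seed(s, 1))
    ssl <- train_downstream(ssl_net, x, y, epochs = epochs,
                            batch_size = batch_size, lr = lr,
                            momentum = momentum, folds = folds,
                            patience = epochs, seed = s)
    cfg <- ckpt$config
    cfg$l_net <- l_net
    cfg$head_dim <- 8
    scratch_net <- init_network(cfg, seed = derive_seed(s, 2))
    scratch <- train_downstream(scratch_net, x, y, epochs = epochs,
                                batch_size = batch_size, lr = lr,
                                momentum = momentum, folds = folds,
                                patience = epochs, seed = s)
    rows[[length(rows) + 1]] <- tibble(
      seed = s,
      arm = c("self_supervised", "from_scratch"),
      val_l1 = c(ssl$val_l1, scratch$val_l1),
      test_mae = c(mean(ssl$test_mae), mean(scratch$test_mae))
    )
  }
  dplyr::bind_rows(rows)
}
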