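# Architecture: shape contracts, attention math, dense connectivity,
# and a finite-difference check of the full backward pass.

test_that("the default configuration reproduces the reference shape table", {
  tr <- shape_trace(net_config())
  got <- function(stage) {
    row <- tr[tr$stage == stage, ]
    c(row$len[1], row$ch[1])
  }
  expect_equal(got("input"), c(324, 1))
  expect_equal(got("conv"), c(324, 64))
  expect_equal(got("pool"), c(162, 64))
  expect_equal(got("dense_block_1"), c(162, 320))
  expect_equal(got("transition_1"), c(81, 160))
  expect_equal(got("dense_block_2"), c(81, 288))
  expect_equal(got("transition_2"), c(40, 144))
  expect_equal(got("dense_block_3"), c(40, 208))
  expect_equal(got("transition_3"), c(20, 104))
  expect_equal(got("pool_pad"), c(21, 104))
  expect_equal(got("conv_final"), c(20, 128))
  expect_equal(got("dropout"), c(20, 128))
  expect_equal(tr$len[tr$stage == "flatten"], 2560)
  expect_equal(tr$len[tr$stage == "flatten_2x"], 1280)
  expect_equal(tr$len[tr$stage == "flatten_4x"], 640)
  expect_equal(tr$len[tr$stage == "concat"], 768)
  expect_equal(tr$len[tr$stage == "fc_merge"], 256)
  expect_equal(tr$len[tr$stage == "fc_out"], 8)
})

test_that("dense-block channel arithmetic follows C_in + n * k", {
  # the three blocks of the default config: 64+8*32, 160+4*32, 144+2*32
  expect_equal(64 + 8 * 32, 320)
  ch <- ecgdelin:::config_channels(net_config())
  expect_equal(vapply(ch$blocks, function(b) b$c_out, numeric(1)),
               c(320, 288, 208))
  expect_equal(vapply(ch$blocks, function(b) b$c_trans, numeric(1)),
               c(160, 144, 104))
})

test_that("channel attention matches hand-computed sigmoid arithmetic", {
  # C = 1, r = 1, unit MLP weights, x = (1, 3): avg 2, max 3 -> sigmoid(5)
  W <- matrix(1, 1, 1)
  mc <- channel_attention(matrix(c(1, 3), ncol = 1), W, W)
  expect_equal(as.numeric(mc), 1 / (1 + exp(-5)))
  # zero MLP -> exactly 0.5 everywhere, any input
  x <- matrix(rnorm(40), 10, 4)
  W0 <- matrix(0, 2, 4); W1 <- matrix(0, 4, 2)
  expect_equal(unname(channel_attention(x, W0, W1)), matrix(0.5, 4, 1))
  # sigmoid outputs live strictly inside (0, 1)
  W0r <- matrix(rnorm(8), 2, 4); W1r <- matrix(rnorm(8), 4, 2)
  mcr <- channel_attention(x, W0r, W1r)
  expect_true(all(mcr > 0 & mcr < 1))
})

test_that("spatial attention pools channels and keeps the length", {
  spW <- matrix(rnorm(6), 1, 6); spb <- 0.3
  for (L in c(5, 20, 324)) {
    x <- matrix(rnorm(L * 4), L, 4)
    ms <- spatial_attention(x, spW, spb)
    expect_equal(nrow(ms), L)
    expect_true(all(ms > 0 & ms < 1))
  }
  # constant feature map: channel mean equals channel max everywhere
  xc <- matrix(2, 15, 3)
  ms0 <- spatial_attention(xc, matrix(0, 1, 6), 0)
  expect_equal(unname(ms0), matrix(0.5, 15, 1))
})

test_that("the CBAM block preserves shape and contracts magnitudes", {
  p <- ecgdelin:::init_cbam(8, 2, 3)
  x <- array(rnorm(8 * 30 * 2), c(8, 30, 2))
  out <- ecgdelin:::cbam_fw(p, x)$out
  expect_equal(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("transition layers floor odd lengths (81 -> 40)", {
  tr <- shape_trace(net_config())
  expect_equal(tr$len[tr$stage == "transition_2"], 40)
  p <- ecgdelin:::avgpool2_fw(array(1, c(2, 81, 1)))
  expect_equal(dim(p$out)[2], 40)
})

test_that("a batch of identical beats yields identical outputs in eval mode", {
  cfg <- tiny_config(head_dim = 4, dropout = 0.2)
  net <- init_network(cfg, seed = 1)
  beat <- tiny_beats(1, 64)[1, ]
  out <- predict(net, rbind(beat, beat))
  expect_equal(out[1, ], out[2, ])
  expect_equal(ncol(out), 4)
})

test_that("the analytic gradient matches finite differences everywhere", {
  cfg <- tiny_config(head_dim = 4, dropout = 0)
  net <- init_network(cfg, seed = 2)
  x <- withr::with_seed(9, array(rnorm(64 * 3), c(1, 64, 3)))
  y <- c(0L, 2L, 3L)
  loss_fn <- function(n) {
    fw <- ecgdelin:::network_fw(n, x, train = TRUE)
    ecgdelin:::softmax_xent(fw$out, y)$loss
  }
  fw <- ecgdelin:::network_fw(net, x, train = TRUE)
  ls <- ecgdelin:::softmax_xent(fw$out, y)
  bw <- ecgdelin:::network_bw(net, fw$cache, ls$dlogits)
  ana <- ecgdelin:::tree_flatten(bw$grads)
  idx <- withr::with_seed(42,
                          sample(length(ana), 80))
  num <- numeric_grad_sample(net, loss_fn, idx)
  rel <- abs(num - ana[idx]) / pmax(1e-6, abs(num) + abs(ana[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("the L1 regression path also backpropagates correctly", {
  cfg <- tiny_config(head_dim = 8, dropout = 0)
  net <- init_network(cfg, seed = 3)
  x <- withr::with_seed(10, array(rnorm(64 * 2), c(1, 64, 2)))
  target <- withr::with_seed(11, matrix(runif(16), 8, 2))
  loss_fn <- function(n) {
    fw <- ecgdelin:::network_fw(n, x, train = TRUE)
    ecgdelin:::l1_loss(fw$out, target)$loss
  }
  fw <- ecgdelin:::network_fw(net, x, train = TRUE)
  ls <- ecgdelin:::l1_loss(fw$out, target)
  bw <- ecgdelin:::network_bw(net, fw$cache, ls$dpred)
  ana <- ecgdelin:::tree_flatten(bw$grads)
  idx <- withr::with_seed(43, sample(length(ana), 60))
  num <- numeric_grad_sample(net, loss_fn, idx)
  rel <- abs(num - ana[idx]) / pmax(1e-6, abs(num) + abs(ana[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("pretext and downstream heads share backbone parameter counts", {
  cfg4 <- tiny_config(head_dim = 4)
  cfg8 <- tiny_config(head_dim = 8)
  n4 <- init_network(cfg4, seed = 1)
  n8 <- init_network(cfg8, seed = 1)
  bk4 <- ecgdelin:::tree_n_params(ecgdelin:::backbone_params(n4))
  bk8 <- ecgdelin:::tree_n_params(ecgdelin:::backbone_params(n8))
  expect_equal(bk4, bk8)
  # heads differ only in the final layer (fc_dim + 1 params per extra output)
  h4 <- ecgdelin:::tree_n_params(n4$params$head)
  h8 <- ecgdelin:::tree_n_params(n8$params$head)
  expect_equal(h8 - h4, 4 * (cfg4$fc_dim + 1))
})

test_that("invalid channel/reduction combinations fail at construction", {
  expect_error(net_config(stem_channels = 8, growth = 4,
                          block_layers = c(1, 1, 1), cbam_reduction = 2),
               class = "ecgdelin_bad_config")
})
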