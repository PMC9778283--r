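# Shared fixtures and a cached desk-scale pipeline run. Everything is
# generated in code; nothing is read from disk.

# tiny network configuration used by gradient checks and training-mechanics
# tests (channel arithmetic must satisfy the divisibility constraints)
tiny_config <- function(l_net = 64, head_dim = 4, dropout = 0) {
  net_config(l_net = l_net, stem_channels = 8, stem_kernel = 7, growth = 4,
             block_layers = c(2, 2, 2), bottleneck = 2, cbam_reduction = 2,
             final_channels = 8, fc_dim = 8, dropout = dropout,
             head_dim = head_dim)
}

# small matrix of smooth pseudo-beats for fast training tests
tiny_beats <- function(n = 24, len = 64, seed = 5) {
  withr::with_seed(seed, {
    t(sapply(seq_len(n), function(i) {
      mu <- 0.3 + 0.4 * runif(1)
      exp(-((seq_len(len) / len) - mu)^2 / 0.01) + rnorm(len, 0, 0.05)
    }))
  })
}

# The desk-scale end-to-end run used by the synthetic-recovery checks: run
# once per session, cached. Scale: 300 synthetic beats, 5-fold pretext CV
# with 8 epochs, long head-only fine-tuning, 3-seed SSL-vs-scratch
# comparison at an equal 30-epoch budget.
.pipeline_cache <- new.env(parent = emptyenv())

acceptance_pipeline <- function() {
  if (is.null(.pipeline_cache$run)) {
    .pipeline_cache$run <- run_delineation_pipeline(
      n_beats = 300, seed = 1, verbose = FALSE
    )
  }
  .pipeline_cache$run
}

# finite-difference gradient of a scalar loss with respect to a parameter
# tree, evaluated at a sample of coordinates
numeric_grad_sample <- function(net, loss_fn, indices, eps = 1e-5) {
  flat <- ecgdelin:::tree_flatten(net$params)
  vapply(indices, function(i) {
    p1 <- flat; p1[i] <- p1[i] + eps
    p2 <- flat; p2[i] <- p2[i] - eps
    n1 <- net; n1$params <- ecgdelin:::tree_unflatten(net$params, p1)
    n2 <- net; n2$params <- ecgdelin:::tree_unflatten(net$params, p2)
    (loss_fn(n1) - loss_fn(n2)) / (2 * eps)
  }, numeric(1))
}
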