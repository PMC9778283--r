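# The delineation network: a 1-D DenseNet backbone (stem conv + three dense
# blocks, each followed by a convolutional block attention module and a
# transition layer), a padded-pool + conv neck, and a feature-pyramid
# regression head. The same backbone serves the 4-class pretext head and the
# 8-landmark downstream head; only the fully connected layers differ.

#' Network configuration
#'
#' Defaults reproduce the reference architecture exactly: with
#' `l_net = 324`, channels run 64 -> 320 -> 160 -> 288 -> 144 -> 208 -> 104
#' through the dense blocks and transitions, the neck emits a (20, 128)
#' feature map, and the pyramid head flattens 2560 / 1280 / 640 features into
#' three 256-wide projections (768 concatenated) before the output layer.
#'
#' @param l_net Input length (324 downstream, 300 for the pretext task).
#' @param stem_channels,stem_kernel Stem convolution width and kernel size.
#' @param growth Growth rate k of the dense blocks.
#' @param block_layers Dense layers per block; `c(8, 4, 2)` solves the
#'   reference channel arithmetic (64 + 8k = 320, 160 + 4k = 288,
#'   144 + 2k = 208 with k = 32).
#' @param bottleneck Bottleneck width of the 1x1 convolution inside each
#'   dense layer, as a multiple of `growth` (DenseNet convention: 4).
#' @param cbam_reduction Channel-attention reduction ratio r; must divide
#'   the channel count entering each attention module.
#' @param spatial_kernel Spatial-attention convolution kernel size.
#' @param final_channels Channels of the neck convolution.
#' @param fc_dim Width of each fully connected projection.
#' @param dropout Dropout rate after the neck.
#' @param head_dim Output dimension: 8 landmarks or 4 pretext classes.
#'
#' @return An object of class `net_config`.
#' @export
#' @examples
#' cfg <- net_config()
#' shape_trace(cfg)
net_config <- function(l_net = 324, stem_channels = 64, stem_kernel = 7,
                       growth = 32, block_layers = c(8, 4, 2), bottleneck = 4,
                       cbam_reduction = 8, spatial_kernel = 3,
                       final_channels = 128, fc_dim = 256, dropout = 0.2,
                       head_dim = 8) {
  cfg <- list(l_net = l_net, stem_channels = stem_channels,
              stem_kernel = stem_kernel, growth = growth,
              block_layers = block_layers, bottleneck = bottleneck,
              cbam_reduction = cbam_reduction, spatial_kernel = spatial_kernel,
              final_channels = final_channels, fc_dim = fc_dim,
              dropout = dropout, head_dim = head_dim)
  class(cfg) <- "net_config"
  # validate channel arithmetic up front
  ch <- stem_channels
  for (i in seq_along(block_layers)) {
    ch <- ch + block_layers[i] * growth
    if (ch %% cbam_reduction != 0) {
      stop_ecg(sprintf(
        "channel count %d after block %d is not divisible by cbam_reduction %d.",
        ch, i, cbam_reduction), "bad_config")
    }
    ch <- ch %/% 2
  }
  cfg
}

#' A reduced configuration for desk-scale experiments
#'
#' Same topology as [net_config()] with narrower channels and shallower
#' blocks, sized so that full training runs finish in seconds to minutes on
#' one CPU core.
#'
#' @inheritParams net_config
#' @return A `net_config`.
#' @export
net_config_small <- function(l_net = 324, head_dim = 8) {
  net_config(l_net = l_net, stem_channels = 16, stem_kernel = 7, growth = 8,
             block_layers = c(2, 2, 2), bottleneck = 4, cbam_reduction = 4,
             final_channels = 32, fc_dim = 64, dropout = 0.2,
             head_dim = head_dim)
}

# channel count entering each stage; used by init and the shape trace
config_channels <- function(cfg) {
  ch <- cfg$stem_channels
  blocks <- list()
  for (i in seq_along(cfg$block_layers)) {
    c_in <- ch
    c_out <- c_in + cfg$block_layers[i] * cfg$growth
    c_trans <- c_out %/% 2
    blocks[[i]] <- list(c_in = c_in, c_out = c_out, c_trans = c_trans)
    ch <- c_trans
  }
  list(blocks = blocks, neck_in = ch)
}

# lengths through the network for a given input length
config_lengths <- function(cfg) {
  L <- cfg$l_net %/% 2                 # stem pool
  lens <- integer(length(cfg$block_layers))
  for (i in seq_along(cfg$block_layers)) {
    lens[i] <- L                       # dense block preserves length
    L <- L %/% 2                       # transition pool
  }
  list(block = lens, neck = L + 1 - 1, # padded pool adds 1, neck conv (k=2) removes 1
       pool1 = L, head_full = L,
       head_half = L %/% 2, head_quarter = (L %/% 2) %/% 2)
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

init_conv <- function(c_out, c_in, k) {
  list(W = he_mat(c_out, k * c_in, k * c_in), b = numeric(c_out))
}

init_bn_params <- function(c) list(gamma = rep(1, c), beta = numeric(c))
init_bn_buffers <- function(c) list(mean = numeric(c), var = rep(1, c))

init_cbam <- function(c, r, sk) {
  list(W0 = he_mat(c %/% r, c, c), W1 = he_mat(c, c %/% r, c %/% r),
       spW = he_mat(1, sk * 2, sk * 2), spb = numeric(1))
}

init_head <- function(cfg) {
  lens <- config_lengths(cfg)
  cf <- cfg$final_channels
  dims <- c(lens$head_full, lens$head_half, lens$head_quarter) * cf
  proj <- lapply(dims, function(d) list(W = he_mat(cfg$fc_dim, d, d),
                                        b = numeric(cfg$fc_dim)))
  list(proj = proj,
       merge = list(W = he_mat(cfg$fc_dim, 3 * cfg$fc_dim, 3 * cfg$fc_dim),
                    b = numeric(cfg$fc_dim)),
       out = list(W = he_mat(cfg$head_dim, cfg$fc_dim, cfg$fc_dim),
                  b = numeric(cfg$head_dim)))
}

#' Initialize a network (He initialization)
#'
#' @param config A [net_config()].
#' @param seed Integer seed for the weight draws.
#'
#' @return Object of class `ecg_network`: list with `params` (trainable
#'   weights), `buffers` (batch-norm running statistics) and `config`.
#' @export
init_network <- function(config, seed = 1L) {
  ch <- config_channels(config)
  with_seed(seed, {
    params <- list()
    buffers <- list()
    params$stem <- list(conv = init_conv(config$stem_channels, 1, config$stem_kernel),
                        bn = init_bn_params(config$stem_channels))
    buffers$stem <- list(bn = init_bn_buffers(config$stem_channels))
    params$blocks <- list()
    buffers$blocks <- list()
    for (i in seq_along(config$block_layers)) {
      bi <- ch$blocks[[i]]
      bw <- config$bottleneck * config$growth
      layers <- list(); lbuf <- list()
      c_cur <- bi$c_in
      for (t in seq_len(config$block_layers[i])) {
        layers[[t]] <- list(
          bn1 = init_bn_params(c_cur),
          conv1 = init_conv(bw, c_cur, 1),
          bn2 = init_bn_params(bw),
          conv2 = init_conv(config$growth, bw, 3)
        )
        lbuf[[t]] <- list(bn1 = init_bn_buffers(c_cur),
                          bn2 = init_bn_buffers(bw))
        c_cur <- c_cur + config$growth
      }
      params$blocks[[i]] <- list(
        layers = layers,
        cbam = init_cbam(bi$c_out, config$cbam_reduction, config$spatial_kernel),
        trans = list(bn = init_bn_params(bi$c_out),
                     conv = init_conv(bi$c_trans, bi$c_out, 1))
      )
      buffers$blocks[[i]] <- list(layers = lbuf,
                                  trans = list(bn = init_bn_buffers(bi$c_out)))
    }
    params$final <- list(conv = init_conv(config$final_channels, ch$neck_in, 2),
                         bn = init_bn_params(config$final_channels))
    buffers$final <- list(bn = init_bn_buffers(config$final_channels))
    params$head <- init_head(config)
    structure(list(params = params, buffers = buffers, config = config),
              class = "ecg_network")
  })
}

#' @export
print.ecg_network <- function(x, ...) {
  cat("<ecg_network> input length ", x$config$l_net, ", head dim ",
      x$config$head_dim, ", ", format(tree_n_params(x$params), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# ---- CBAM ------------------------------------------------------------------

cbam_fw <- function(p, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  pl <- pool_len(x)                             # channel descriptors over positions
  savg <- pl$avg; smax <- pl$max
  h_avg <- p$W0 %*% savg; r_avg <- pmax(h_avg, 0)
  h_max <- p$W0 %*% smax; r_max <- pmax(h_max, 0)
  Mc <- sigmoid(p$W1 %*% r_avg + p$W1 %*% r_max)
  x2 <- x * expand_cn(Mc, L)
  # spatial: per-position channel mean and max
  cmx <- cm(x2)                                 # (C, L*N)
  pavg <- matrix(colMeans(cmx), L, N)
  pmax_ch <- max.col(t(cmx), ties.method = "first")
  pmaxv <- matrix(cmx[(seq_len(L * N) - 1L) * C + pmax_ch], L, N)
  z2 <- array(0, c(2, L, N))
  z2[1, , ] <- pavg
  z2[2, , ] <- pmaxv
  sk <- ncol(p$spW) / 2
  cv <- conv1d_fw(p$spW, p$spb, z2, pad = (sk - 1) / 2)
  Ms <- matrix(sigmoid(cv$out), L, N)
  out <- x2 * expand_ln(Ms, C)
  list(out = out,
       cache = list(x = x, x2 = x2, Mc = Mc, Ms = Ms, savg = savg, smax = smax,
                    h_avg = h_avg, r_avg = r_avg, h_max = h_max, r_max = r_max,
                    amax_pos = pl$argmax, pmax_ch = pmax_ch, conv = cv$cache,
                    L = L, C = C, N = N))
}

cbam_bw <- function(p, cache, dout) {
  L <- cache$L; C <- cache$C; N <- cache$N
  x <- cache$x; x2 <- cache$x2
  Ms <- cache$Ms; Mc <- cache$Mc
  # out = x2 * Ms
  dMs <- matrix(colSums(cm(dout * x2)), L, N)
  dx2 <- dout * expand_ln(Ms, C)
  # spatial attention backward
  dz <- dMs * Ms * (1 - Ms)
  cb <- conv1d_bw(p$spW, cache$conv, array(dz, c(1, L, N)))
  dz2 <- cb$dx                                  # (2, L, N)
  davg <- matrix(dz2[1, , ], L, N)
  dmaxv <- matrix(dz2[2, , ], L, N)
  dx2 <- dx2 + expand_ln(davg, C) / C
  # scatter max-channel gradient: element (pmax_ch, l, n) of x2
  dx2_m <- cm(dx2)                              # (C, L*N)
  idx <- (seq_len(L * N) - 1L) * C + cache$pmax_ch
  dx2_m[idx] <- dx2_m[idx] + as.vector(dmaxv)
  dx2 <- icm(dx2_m, L, N)
  # x2 = x * Mc
  tm <- cm(dx2 * x)                             # (C, L*N)
  dMc <- matrix(0, C, N)
  for (n in seq_len(N)) {
    dMc[, n] <- rowSums(tm[, ((n - 1) * L + 1):(n * L), drop = FALSE])
  }
  dx <- dx2 * expand_cn(Mc, L)
  da <- dMc * Mc * (1 - Mc)
  # shared MLP, two branches
  dW1 <- tcrossprod(da, cache$r_avg) + tcrossprod(da, cache$r_max)
  dr <- crossprod(p$W1, da)                     # same for both branches
  dh_avg <- dr * (cache$h_avg > 0)
  dh_max <- dr * (cache$h_max > 0)
  dW0 <- tcrossprod(dh_avg, cache$savg) + tcrossprod(dh_max, cache$smax)
  dsavg <- crossprod(p$W0, dh_avg)
  dsmax <- crossprod(p$W0, dh_max)
  dx <- dx + expand_cn(dsavg, L) / L
  # scatter per-(channel, sample) max-position gradient into x:
  # element (c, argmax[c, n], n)
  dxv <- as.vector(dx)
  sidx <- as.vector(rep(seq_len(C), N) +
                      (as.vector(cache$amax_pos) - 1L) * C +
                      rep(seq_len(N) - 1L, each = C) * C * L)
  dxv[sidx] <- dxv[sidx] + as.vector(dsmax)
  dx <- array(dxv, c(C, L, N))
  list(dx = dx,
       grads = list(W0 = dW0, W1 = dW1, spW = cb$dW, spb = cb$db))
}

#' Channel attention weights of a feature map
#'
#' Exposed for testing and inspection: computes
#' `sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` with the shared two-layer
#' MLP, pooling over positions.
#'
#' @param x Feature map array `(L, C, N)` or matrix `(L, C)`.
#' @param W0,W1 MLP weights of shapes `(C/r, C)` and `(C, C/r)`.
#' @return Matrix `(C, N)` of weights in (0, 1).
#' @export
channel_attention <- function(x, W0, W1) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  d <- dim(x); L <- d[1]; C <- d[2]; N <- d[3]
  m2 <- matrix(x, L, C * N)                    # user-facing positions x channels
  savg <- matrix(colMeans(m2), C, N)
  smax <- matrix(apply(m2, 2, max), C, N)
  sigmoid(W1 %*% pmax(W0 %*% savg, 0) + W1 %*% pmax(W0 %*% smax, 0))
}

#' Spatial attention weights of a feature map
#'
#' Per-position channel mean and max are stacked into a two-channel map and
#' passed through a small convolution and a sigmoid.
#'
#' @param x Feature map array `(L, C, N)` or matrix `(L, C)`.
#' @param spW,spb Convolution weight `(1, 2k)` and bias.
#' @return Matrix `(L, N)` of weights in (0, 1).
#' @export
spatial_attention <- function(x, spW, spb) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  d <- dim(x); L <- d[1]; C <- d[2]; N <- d[3]
  # user-facing layout is positions x channels; mean/max across channels
  z2 <- array(0, c(2, L, N))
  for (n in seq_len(N)) {
    z2[1, , n] <- rowMeans(matrix(x[, , n], L, C))
    z2[2, , n] <- apply(matrix(x[, , n], L, C), 1, max)
  }
  k <- ncol(spW) / 2
  cv <- conv1d_fw(spW, spb, z2, pad = (k - 1) / 2)
  matrix(sigmoid(cv$out), L, N)
}

# ---- dense block -----------------------------------------------------------

dense_layer_fw <- function(p, bufs, x, train) {
  b1 <- bn_fw(p$bn1$gamma, p$bn1$beta, x, bufs$bn1$mean, bufs$bn1$var, train)
  r1 <- relu_fw(b1$out)
  c1 <- conv1d_fw(p$conv1$W, p$conv1$b, r1$out, pad = 0)
  b2 <- bn_fw(p$bn2$gamma, p$bn2$beta, c1$out, bufs$bn2$mean, bufs$bn2$var, train)
  r2 <- relu_fw(b2$out)
  c2 <- conv1d_fw(p$conv2$W, p$conv2$b, r2$out, pad = 1)
  list(out = c2$out,
       cache = list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache,
                    b2 = b2$cache, r2 = r2$cache, c2 = c2$cache),
       buffers = list(bn1 = list(mean = b1$run_mean, var = b1$run_var),
                      bn2 = list(mean = b2$run_mean, var = b2$run_var)))
}

dense_layer_bw <- function(p, cache, dout) {
  cb2 <- conv1d_bw(p$conv2$W, cache$c2, dout)
  dr2 <- relu_bw(cache$r2, cb2$dx)
  bb2 <- bn_bw(p$bn2$gamma, cache$b2, dr2)
  cb1 <- conv1d_bw(p$conv1$W, cache$c1, bb2$dx)
  dr1 <- relu_bw(cache$r1, cb1$dx)
  bb1 <- bn_bw(p$bn1$gamma, cache$b1, dr1)
  list(dx = bb1$dx,
       grads = list(bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                    conv1 = list(W = cb1$dW, b = cb1$db),
                    bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                    conv2 = list(W = cb2$dW, b = cb2$db)))
}

dense_block_fw <- function(p_layers, buf_layers, x, growth, train) {
  caches <- list(); new_bufs <- list()
  xs <- x
  for (t in seq_along(p_layers)) {
    lf <- dense_layer_fw(p_layers[[t]], buf_layers[[t]], xs, train)
    caches[[t]] <- lf$cache
    new_bufs[[t]] <- lf$buffers
    xs <- cat_channels(xs, lf$out)
  }
  list(out = xs, cache = caches, buffers = new_bufs)
}

dense_block_bw <- function(p_layers, caches, dout, growth) {
  grads <- vector("list", length(p_layers))
  d <- dout
  for (t in rev(seq_along(p_layers))) {
    C_tot <- dim(d)[1]
    d_new <- d[(C_tot - growth + 1):C_tot, , , drop = FALSE]
    d <- d[1:(C_tot - growth), , , drop = FALSE]
    lb <- dense_layer_bw(p_layers[[t]], caches[[t]], d_new)
    d <- d + lb$dx
    grads[[t]] <- lb$grads
  }
  list(dx = d, grads = grads)
}

# ---- backbone --------------------------------------------------------------

# Everything up to (and including) the neck conv/BN/ReLU: the "convolutional
# layers" that the transfer step freezes. x: (L, 1, N) batch tensor.
backbone_fw <- function(net, x, train = FALSE) {
  p <- net$params; bufs <- net$buffers; cfg <- net$config
  trace <- list(list(stage = "input", len = dim(x)[2], ch = dim(x)[1]))
  cache <- list()
  new_bufs <- bufs

  sc <- conv1d_fw(p$stem$conv$W, p$stem$conv$b, x, pad = (cfg$stem_kernel - 1) / 2)
  sb <- bn_fw(p$stem$bn$gamma, p$stem$bn$beta, sc$out,
              bufs$stem$bn$mean, bufs$stem$bn$var, train)
  new_bufs$stem$bn <- list(mean = sb$run_mean, var = sb$run_var)
  sr <- relu_fw(sb$out)
  trace <- c(trace, list(list(stage = "conv", len = dim(sr$out)[2], ch = dim(sr$out)[1])))
  sp <- maxpool2_fw(sr$out)
  h <- sp$out
  trace <- c(trace, list(list(stage = "pool", len = dim(h)[2], ch = dim(h)[1])))
  cache$stem <- list(conv = sc$cache, bn = sb$cache, relu = sr$cache, pool = sp$cache)

  cache$blocks <- list()
  for (i in seq_along(p$blocks)) {
    blk <- p$blocks[[i]]
    db <- dense_block_fw(blk$layers, bufs$blocks[[i]]$layers, h, cfg$growth, train)
    new_bufs$blocks[[i]]$layers <- db$buffers
    trace <- c(trace, list(list(stage = paste0("dense_block_", i),
                                len = dim(db$out)[2], ch = dim(db$out)[1])))
    cb <- cbam_fw(blk$cbam, db$out)
    tb <- bn_fw(blk$trans$bn$gamma, blk$trans$bn$beta, cb$out,
                bufs$blocks[[i]]$trans$bn$mean, bufs$blocks[[i]]$trans$bn$var, train)
    new_bufs$blocks[[i]]$trans$bn <- list(mean = tb$run_mean, var = tb$run_var)
    tr <- relu_fw(tb$out)
    tc <- conv1d_fw(blk$trans$conv$W, blk$trans$conv$b, tr$out, pad = 0)
    tp <- avgpool2_fw(tc$out)
    h <- tp$out
    trace <- c(trace, list(list(stage = paste0("transition_", i),
                                len = dim(h)[2], ch = dim(h)[1])))
    cache$blocks[[i]] <- list(dense = db$cache, cbam = cb$cache, bn = tb$cache,
                              relu = tr$cache, conv = tc$cache, pool = tp$cache)
  }

  pp <- avgpool_pad_fw(h)
  trace <- c(trace, list(list(stage = "pool_pad", len = dim(pp$out)[2],
                              ch = dim(pp$out)[1])))
  fc <- conv1d_fw(p$final$conv$W, p$final$conv$b, pp$out, pad = 0)
  fb <- bn_fw(p$final$bn$gamma, p$final$bn$beta, fc$out,
              bufs$final$bn$mean, bufs$final$bn$var, train)
  new_bufs$final$bn <- list(mean = fb$run_mean, var = fb$run_var)
  fr <- relu_fw(fb$out)
  trace <- c(trace, list(list(stage = "conv_final", len = dim(fr$out)[2],
                              ch = dim(fr$out)[1])))
  cache$final <- list(pool = pp$cache, conv = fc$cache, bn = fb$cache,
                      relu = fr$cache)

  list(out = fr$out, cache = cache, buffers = new_bufs, trace = trace)
}

# Full forward: backbone -> dropout -> feature-pyramid head.
network_fw <- function(net, x, train = FALSE) {
  bk <- backbone_fw(net, x, train = train)
  dp <- dropout_fw(bk$out, net$config$dropout, train)
  trace <- c(bk$trace, list(list(stage = "dropout", len = dim(dp$out)[2],
                                 ch = dim(dp$out)[1])))
  hd <- head_fw(net$params$head, dp$out)
  trace <- c(trace, hd$trace)
  cache <- bk$cache
  cache$drop <- dp$cache
  cache$head <- hd$cache
  list(out = hd$out, cache = cache, buffers = bk$buffers,
       trace = dplyr::bind_rows(lapply(trace, as_tibble)))
}

head_fw <- function(ph, feat) {
  d <- dim(feat); C <- d[1]; L <- d[2]; N <- d[3]
  flat1 <- matrix(feat, L * C, N)
  p1 <- avgpool2_fw(feat)
  d1 <- dim(p1$out)
  flat2 <- matrix(p1$out, d1[2] * C, N)
  p2 <- avgpool2_fw(p1$out)
  d2 <- dim(p2$out)
  flat3 <- matrix(p2$out, d2[2] * C, N)
  f1 <- fc_fw(ph$proj[[1]]$W, ph$proj[[1]]$b, flat1); r1 <- relu_fw(f1$out)
  f2 <- fc_fw(ph$proj[[2]]$W, ph$proj[[2]]$b, flat2); r2 <- relu_fw(f2$out)
  f3 <- fc_fw(ph$proj[[3]]$W, ph$proj[[3]]$b, flat3); r3 <- relu_fw(f3$out)
  concat <- rbind(r1$out, r2$out, r3$out)
  fm <- fc_fw(ph$merge$W, ph$merge$b, concat); rm <- relu_fw(fm$out)
  fo <- fc_fw(ph$out$W, ph$out$b, rm$out)
  trace <- list(
    list(stage = "flatten", len = L * C, ch = NA_integer_),
    list(stage = "fc_full", len = nrow(f1$out), ch = NA_integer_),
    list(stage = "pool_2x", len = d1[2], ch = d1[1]),
    list(stage = "flatten_2x", len = d1[2] * C, ch = NA_integer_),
    list(stage = "fc_2x", len = nrow(f2$out), ch = NA_integer_),
    list(stage = "pool_4x", len = d2[2], ch = d2[1]),
    list(stage = "flatten_4x", len = d2[2] * C, ch = NA_integer_),
    list(stage = "fc_4x", len = nrow(f3$out), ch = NA_integer_),
    list(stage = "concat", len = nrow(concat), ch = NA_integer_),
    list(stage = "fc_merge", len = nrow(fm$out), ch = NA_integer_),
    list(stage = "fc_out", len = nrow(fo$out), ch = NA_integer_)
  )
  list(out = fo$out,
       cache = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache, r2 = r2$cache,
                    f3 = f3$cache, r3 = r3$cache, fm = fm$cache, rm = rm$cache,
                    fo = fo$cache, p1 = p1$cache, p2 = p2$cache,
                    dims = list(L = L, C = C, N = N, L1 = d1[2], L2 = d2[2])),
       trace = trace)
}

head_bw <- function(ph, cache, dout) {
  dm <- cache$dims
  fob <- fc_bw(ph$out$W, cache$fo, dout)
  drm <- relu_bw(cache$rm, fob$dx)
  fmb <- fc_bw(ph$merge$W, cache$fm, drm)
  fcd <- nrow(ph$proj[[1]]$W)
  dc1 <- fmb$dx[1:fcd, , drop = FALSE]
  dc2 <- fmb$dx[(fcd + 1):(2 * fcd), , drop = FALSE]
  dc3 <- fmb$dx[(2 * fcd + 1):(3 * fcd), , drop = FALSE]
  f1b <- fc_bw(ph$proj[[1]]$W, cache$f1, relu_bw(cache$r1, dc1))
  f2b <- fc_bw(ph$proj[[2]]$W, cache$f2, relu_bw(cache$r2, dc2))
  f3b <- fc_bw(ph$proj[[3]]$W, cache$f3, relu_bw(cache$r3, dc3))
  dflat3 <- array(f3b$dx, c(dm$C, dm$L2, dm$N))
  dp2 <- avgpool2_bw(cache$p2, dflat3)
  dflat2 <- array(f2b$dx, c(dm$C, dm$L1, dm$N)) + dp2
  dp1 <- avgpool2_bw(cache$p1, dflat2)
  dfeat <- array(f1b$dx, c(dm$C, dm$L, dm$N)) + dp1
  list(dx = dfeat,
       grads = list(
         proj = list(list(W = f1b$dW, b = f1b$db),
                     list(W = f2b$dW, b = f2b$db),
                     list(W = f3b$dW, b = f3b$db)),
         merge = list(W = fmb$dW, b = fmb$db),
         out = list(W = fob$dW, b = fob$db)))
}

# Backward through the whole network. dout: (head_dim, N).
network_bw <- function(net, cache, dout) {
  p <- net$params; cfg <- net$config
  hb <- head_bw(p$head, cache$head, dout)
  grads <- list(head = hb$grads)
  d <- dropout_bw(cache$drop, hb$dx)
  d <- relu_bw(cache$final$relu, d)
  bb <- bn_bw(p$final$bn$gamma, cache$final$bn, d)
  cb <- conv1d_bw(p$final$conv$W, cache$final$conv, bb$dx)
  d <- avgpool_pad_bw(cache$final$pool, cb$dx)
  grads$final <- list(conv = list(W = cb$dW, b = cb$db),
                      bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  grads$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    blk <- p$blocks[[i]]
    ca <- cache$blocks[[i]]
    d <- avgpool2_bw(ca$pool, d)
    tcb <- conv1d_bw(blk$trans$conv$W, ca$conv, d)
    d <- relu_bw(ca$relu, tcb$dx)
    tbb <- bn_bw(blk$trans$bn$gamma, ca$bn, d)
    cbb <- cbam_bw(blk$cbam, ca$cbam, tbb$dx)
    dbb <- dense_block_bw(blk$layers, ca$dense, cbb$dx, cfg$growth)
    d <- dbb$dx
    grads$blocks[[i]] <- list(
      layers = dbb$grads,
      cbam = cbb$grads,
      trans = list(bn = list(gamma = tbb$dgamma, beta = tbb$dbeta),
                   conv = list(W = tcb$dW, b = tcb$db)))
  }
  d <- maxpool2_bw(cache$stem$pool, d)
  d <- relu_bw(cache$stem$relu, d)
  sbb <- bn_bw(p$stem$bn$gamma, cache$stem$bn, d)
  scb <- conv1d_bw(p$stem$conv$W, cache$stem$conv, sbb$dx)
  grads$stem <- list(conv = list(W = scb$dW, b = scb$db),
                     bn = list(gamma = sbb$dgamma, beta = sbb$dbeta))
  # order grads to match the params tree
  list(grads = grads[names(net$params)], dx = scb$dx)
}

# Eval-mode backbone features for a beat matrix (n x L) -> (Lf, Cf, n).
# Used to cache activations once when the backbone is frozen.
backbone_features <- function(net, xmat, batch_size = 128) {
  n <- nrow(xmat)
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    bk <- backbone_fw(net, beats_to_tensor(xmat[idx, , drop = FALSE]),
                      train = FALSE)
    if (is.null(out)) {
      d <- dim(bk$out)
      out <- array(0, c(d[1], d[2], n))
    }
    out[, , idx] <- bk$out
  }
  out
}

#' Trace the feature-map shapes of a configuration
#'
#' Runs one forward pass on a zero input and records every stage's output
#' shape (length, channels; fully connected stages report the vector width).
#'
#' @param config A [net_config()].
#' @return A tibble with columns `stage`, `len`, `ch`.
#' @export
shape_trace <- function(config) {
  net <- init_network(config, seed = 1L)
  x <- array(0, c(1, config$l_net, 1))
  network_fw(net, x, train = FALSE)$trace
}

# matrix of beats (n x L) -> batch tensor (L, 1, n)
beats_to_tensor <- function(xmat) {
  array(t(xmat), c(1, ncol(xmat), nrow(xmat)))
}

#' Forward pass on a matrix of beats
#'
#' @param object An `ecg_network`.
#' @param x Matrix (beats x length) matching `config$l_net`.
#' @param batch_size Beats per forward batch.
#' @param ... Unused.
#' @return Matrix (beats x head_dim) of raw network outputs.
#' @export
predict.ecg_network <- function(object, x, batch_size = 64, ...) {
  n <- nrow(x)
  out <- matrix(0, n, object$config$head_dim)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- network_fw(object, beats_to_tensor(x[idx, , drop = FALSE]),
                     train = FALSE)
    out[idx, ] <- t(fw$out)
  }
  out
}
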