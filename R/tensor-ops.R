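# Low-level differentiable operations on batched 1-D feature maps.
# Layout: a batch is an array of dim (C, L, N) = channels x positions x
# samples. Channel-major order makes the channel-matrix view (C, L*N) a
# plain reshape (no transposes anywhere on the hot path); the heavy lifting
# is BLAS matrix multiplication via im2col. Each op returns its output plus
# the cache its backward pass needs; backward passes return the input
# gradient and parameter gradients. All double precision.

# (C, L, N) -> channel-major matrix (C, L*N); a reshape, not a copy of order
cm <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

# inverse of cm()
icm <- function(m, L, N) {
  dim(m) <- c(nrow(m), L, N)
  m
}

# broadcast a (C, N) per-channel map over positions -> (C, L, N)
expand_cn <- function(m, L) {
  C <- nrow(m); N <- ncol(m)
  idx <- rep.int(seq_len(C), L * N) + rep(seq_len(N) - 1L, each = C * L) * C
  array(as.vector(m)[idx], c(C, L, N))
}

# broadcast a (L, N) per-position map over channels -> (C, L, N)
expand_ln <- function(m, C) {
  L <- nrow(m); N <- ncol(m)
  idx <- rep(rep(seq_len(L), each = C), N) + rep(seq_len(N) - 1L, each = C * L) * L
  array(as.vector(m)[idx], c(C, L, N))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

# per-(channel, sample) mean, max and argmax over positions
pool_len <- function(x) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  m <- cm(x)
  avg <- matrix(0, C, N); mx <- matrix(0, C, N); arg <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    blk <- m[, ((n - 1) * L + 1):(n * L), drop = FALSE]
    avg[, n] <- rowMeans(blk)
    a <- max.col(blk, ties.method = "first")
    arg[, n] <- a
    mx[, n] <- blk[(a - 1L) * C + seq_len(C)]
  }
  list(avg = avg, max = mx, argmax = arg)
}

# ---- convolution (stride 1) ------------------------------------------------

conv1d_fw <- function(W, b, x, pad = 0) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  k <- ncol(W) / C
  if (pad > 0) {
    xp <- array(0, c(C, L + 2 * pad, N))
    xp[, (pad + 1):(pad + L), ] <- x
  } else xp <- x
  Lo <- L + 2 * pad - k + 1
  if (k == 1) {
    col <- cm(xp)
  } else {
    col <- matrix(0, k * C, Lo * N)
    for (j in seq_len(k)) {
      blk <- xp[, j:(j + Lo - 1), , drop = FALSE]
      dim(blk) <- c(C, Lo * N)
      col[((j - 1) * C + 1):(j * C), ] <- blk
    }
  }
  out <- icm(W %*% col + b, Lo, N)
  list(out = out, cache = list(col = col, L = L, C = C, N = N, k = k,
                               pad = pad, Lo = Lo))
}

conv1d_bw <- function(W, cache, dout) {
  L <- cache$L; C <- cache$C; N <- cache$N
  k <- cache$k; pad <- cache$pad; Lo <- cache$Lo
  dm <- cm(dout)                      # (Cout, Lo*N)
  dW <- tcrossprod(dm, cache$col)
  db <- rowSums(dm)
  dcol <- crossprod(W, dm)            # (k*C, Lo*N)
  if (k == 1 && pad == 0) {
    return(list(dx = icm(dcol, Lo, N), dW = dW, db = db))
  }
  dxp <- array(0, c(C, L + 2 * pad, N))
  for (j in seq_len(k)) {
    blk <- icm(dcol[((j - 1) * C + 1):(j * C), , drop = FALSE], Lo, N)
    idx <- j:(j + Lo - 1)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + blk
  }
  dx <- if (pad > 0) dxp[, (pad + 1):(pad + L), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization (per channel) -------------------------------------

bn_fw <- function(gamma, beta, x, run_mean, run_var, train,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x); L <- d[2]; N <- d[3]
  m <- cm(x)
  if (train) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * inv
  out <- icm(gamma * xhat + beta, L, N)
  list(out = out,
       cache = list(xhat = xhat, inv = inv, L = L, N = N, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(gamma, cache, dout) {
  dm <- cm(dout)
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * gamma
  if (cache$train) {
    dx_m <- cache$inv *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx_m <- cache$inv * dxhat
  }
  list(dx = icm(dx_m, cache$L, cache$N), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, dout) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -40), 40)))

# ---- pooling (along positions) ---------------------------------------------

# kernel 2, stride 2, floor semantics
maxpool2_fw <- function(x) {
  d <- dim(x); L2 <- d[2] %/% 2
  a <- x[, seq(1, 2 * L2, by = 2), , drop = FALSE]
  b <- x[, seq(2, 2 * L2, by = 2), , drop = FALSE]
  take_a <- a >= b
  out <- b
  out[take_a] <- a[take_a]
  list(out = out, cache = list(take_a = take_a, L = d[2], L2 = L2))
}

maxpool2_bw <- function(cache, dout) {
  d <- dim(dout)
  dx <- array(0, c(d[1], cache$L, d[3]))
  dx[, seq(1, 2 * cache$L2, by = 2), ] <- dout * cache$take_a
  dx[, seq(2, 2 * cache$L2, by = 2), ] <- dout * !cache$take_a
  dx
}

avgpool2_fw <- function(x) {
  d <- dim(x); L2 <- d[2] %/% 2
  a <- x[, seq(1, 2 * L2, by = 2), , drop = FALSE]
  b <- x[, seq(2, 2 * L2, by = 2), , drop = FALSE]
  list(out = (a + b) / 2, cache = list(L = d[2], L2 = L2))
}

avgpool2_bw <- function(cache, dout) {
  d <- dim(dout)
  dx <- array(0, c(d[1], cache$L, d[3]))
  dx[, seq(1, 2 * cache$L2, by = 2), ] <- dout / 2
  dx[, seq(2, 2 * cache$L2, by = 2), ] <- dout / 2
  dx
}

# kernel 2, stride 1, zero pad 1 each side: length L -> L + 1. Zeros at the
# pad positions are included in the average (count_include_pad semantics).
avgpool_pad_fw <- function(x) {
  d <- dim(x); L <- d[2]
  out <- array(0, c(d[1], L + 1, d[3]))
  out[, 1, ] <- x[, 1, ] / 2
  out[, L + 1, ] <- x[, L, ] / 2
  if (L > 1) {
    out[, 2:L, ] <- (x[, 1:(L - 1), , drop = FALSE] + x[, 2:L, , drop = FALSE]) / 2
  }
  list(out = out, cache = list(L = L))
}

avgpool_pad_bw <- function(cache, dout) {
  L <- cache$L
  (dout[, 1:L, , drop = FALSE] + dout[, 2:(L + 1), , drop = FALSE]) / 2
}

# ---- dropout ---------------------------------------------------------------

dropout_fw <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- 1 - p
  mask <- array(stats::rbinom(length(x), 1, keep), dim(x)) / keep
  list(out = x * mask, cache = mask)
}

dropout_bw <- function(cache, dout) {
  if (is.null(cache)) return(dout)
  dout * cache
}

# ---- fully connected -------------------------------------------------------

fc_fw <- function(W, b, x) {
  list(out = W %*% x + b, cache = x)
}

fc_bw <- function(W, cache, dout) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, cache), db = rowSums(dout))
}

# ---- losses ----------------------------------------------------------------

softmax_xent <- function(logits, y) {
  # logits (K, N), y integer in 0..K-1
  K <- nrow(logits); N <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- (seq_len(N) - 1L) * K + (y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N,
       pred = max.col(t(p), ties.method = "first") - 1L)
}

l1_loss <- function(pred, target) {
  diff <- pred - target
  list(loss = mean(abs(diff)), dpred = sign(diff) / length(diff))
}
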